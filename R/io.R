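#' Write a data frame as CSV with a reproducibility metadata header
#'
#' Output tables carry `#`-prefixed header lines recording the producing
#' subcommand/function, the seed, the package version and any extra
#' parameters, so every artifact is self-describing.
#'
#' @param df data frame to write.
#' @param path output file path.
#' @param meta named list of metadata values (scalars).
#' @return `path`, invisibly.
#' @export
write_csv_meta <- function(df, path, meta = list()) {
  meta <- c(list(package = paste0("fdcretention ",
                                  as.character(utils::packageVersion("fdcretention"))),
                 written = "deterministic"), meta)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k,
                       paste(format(meta[[k]], trim = TRUE), collapse = " ")),
               con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written with [write_csv_meta()]
#'
#' @param path file path.
#' @return Data frame; metadata lines are returned in attribute `meta`.
#' @export
read_csv_meta <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  attr(df, "meta") <- sub("^# ", "", meta)
  df
}

#' Read / write bond-kinetics parameters as YAML
#'
#' Parameter blocks use the keys `k_off_per_s`, `k_on_per_s`, `n_L`,
#' `patch_area_um2`.
#'
#' @param path YAML file path.
#' @return `read_params_yaml` returns a [bond_params];
#'   `write_params_yaml` returns `path` invisibly.
#' @export
read_params_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  required <- c("k_off_per_s", "k_on_per_s", "n_L")
  missing <- setdiff(required, names(y))
  if (length(missing))
    stop("parameter YAML is missing keys: ", paste(missing, collapse = ", "))
  bond_params(k_off = y$k_off_per_s, k_on = y$k_on_per_s, n_L = y$n_L,
              patch_area = if (is.null(y$patch_area_um2)) 1
              else y$patch_area_um2)
}

#' @param params a [bond_params] object.
#' @rdname read_params_yaml
#' @export
write_params_yaml <- function(params, path) {
  stopifnot(inherits(params, "bond_params"))
  yaml::write_yaml(list(k_off_per_s = params$k_off,
                        k_on_per_s = params$k_on,
                        n_L = params$n_L,
                        patch_area_um2 = params$patch_area), path)
  invisible(path)
}
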