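#' Multi-channel follicle image container
#'
#' A named list of 2D rasters sharing dimensions: one structural channel
#' (the CR2/CD21 stain delineating the FDC network) and one or more antigen
#' channels, plus the physical pixel size.
#'
#' @param channels named list of numeric matrices with identical dimensions;
#'   the structural channel should be named `"structural"` (otherwise the
#'   first channel is taken as structural).
#' @param pixel_size pixel edge length in um (> 0).
#' @return A `follicle_image` object.
#' @export
follicle_image <- function(channels, pixel_size) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))),
            is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1L), dims[[1L]])))
    stop("all channels must share dimensions")
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1L))))
    stop("channel intensities must be non-negative")
  structure(list(channels = channels, pixel_size = pixel_size),
            class = "follicle_image")
}

#' @export
print.follicle_image <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("follicle image: %d x %d px at %g um/px, channels: %s\n",
              d[1L], d[2L], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

structural_channel <- function(img) {
  if ("structural" %in% names(img$channels)) img$channels[["structural"]]
  else img$channels[[1L]]
}

#' Read / write multi-channel follicle TIFFs
#'
#' Channels are stored as successive directories of a single (32-bit float)
#' TIFF file; channel names and pixel size travel in the arguments, not in
#' the file.
#'
#' @param path TIFF file path.
#' @param channel_names names assigned to the frames on reading.
#' @param pixel_size pixel edge length in um.
#' @return `read_follicle_tiff` returns a [follicle_image];
#'   `write_follicle_tiff` returns `path` invisibly.
#' @export
read_follicle_tiff <- function(path, channel_names = NULL, pixel_size = 1) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1L] # collapse accidental RGB
    f
  })
  if (is.null(channel_names)) {
    channel_names <- if (length(frames) == 1L) "structural"
    else c("structural", paste0("antigen", seq_len(length(frames) - 1L)))
  }
  names(frames) <- channel_names
  follicle_image(frames, pixel_size = pixel_size)
}

#' @param img a [follicle_image].
#' @rdname read_follicle_tiff
#' @export
write_follicle_tiff <- function(img, path) {
  stopifnot(inherits(img, "follicle_image"))
  # scale jointly to [0,1] so relative channel intensities survive the
  # round trip (writeTIFF float storage expects [0,1])
  mx <- max(1, vapply(img$channels, max, numeric(1L)))
  tiff::writeTIFF(lapply(img$channels, function(ch) ch / mx), path,
                  bits.per.sample = 32L)
  invisible(path)
}

# block-mean subsampling by an integer factor (edges cropped to a multiple)
.block_mean <- function(m, f) {
  f <- as.integer(f)
  if (f == 1L) return(m)
  nr <- (nrow(m) %/% f) * f
  nc <- (ncol(m) %/% f) * f
  a <- array(m[seq_len(nr), seq_len(nc)], c(f, nr %/% f, f, nc %/% f))
  apply(a, c(2L, 4L), mean)
}

#' Build an FDC-network mask from the structural channel
#'
#' Mirrors the quantification pipeline applied to cleared-LN confocal data:
#' the structural (CD21) channel is subsampled in x and y, Gaussian-smoothed,
#' thresholded globally, and hole-filled to yield a binary mask of the FDC
#' networks. A blank image yields an empty mask (downstream operations must
#' tolerate zero follicles); a saturated constant image yields a full-frame
#' mask.
#'
#' @param structural structural-channel matrix, or a [follicle_image].
#' @param subsample_factor integer x/y subsampling factor (default 4).
#' @param smoothing_sigma Gaussian smoothing scale in (subsampled) pixels.
#' @param threshold_method `"otsu"` (default) or `"mean"`.
#' @return Logical matrix at subsampled resolution with attributes
#'   `subsample_factor` and (when available) `pixel_size` of the subsampled
#'   grid.
#' @export
preprocess_and_mask <- function(structural, subsample_factor = 4,
                                smoothing_sigma = 2,
                                threshold_method = c("otsu", "mean")) {
  pixel_size <- NULL
  if (inherits(structural, "follicle_image")) {
    pixel_size <- structural$pixel_size
    structural <- structural_channel(structural)
  }
  stopifnot(is.matrix(structural), length(structural) > 0,
            subsample_factor >= 1, subsample_factor == round(subsample_factor),
            smoothing_sigma >= 0)
  threshold_method <- match.arg(threshold_method)

  sub <- .block_mean(structural, subsample_factor)
  if (smoothing_sigma > 0)
    sub <- EBImage::imageData(EBImage::gblur(EBImage::Image(sub),
                                             sigma = smoothing_sigma))
  rng <- range(sub)
  if (rng[2L] <= rng[1L]) {
    mask <- matrix(rng[1L] > 0, nrow(sub), ncol(sub))
  } else {
    norm <- (sub - rng[1L]) / (rng[2L] - rng[1L])
    thr <- switch(threshold_method,
                  otsu = EBImage::otsu(EBImage::Image(norm), range = c(0, 1)),
                  mean = mean(norm))
    mask <- norm > thr
    mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  }
  structure(mask,
            subsample_factor = as.integer(subsample_factor),
            pixel_size = if (!is.null(pixel_size))
              pixel_size * subsample_factor else NULL)
}

# union-find merge of label pairs that touch diagonally, giving
# 8-connectivity on top of EBImage's component labelling
.merge_diagonal <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr < 2L || nc < 2L) return(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])), # down-right
    cbind(as.vector(lab[-nr, -1L]), as.vector(lab[-1L, -nc]))) # down-left
  pairs <- pairs[pairs[, 1L] > 0 & pairs[, 2L] > 0 &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  K <- max(lab)
  parent <- seq_len(K)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1L]); b <- find(pairs[r, 2L])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(K), find, integer(1L))
  lab[lab > 0] <- root[lab[lab > 0]]
  lab
}

#' Detect and label individual follicles in a network mask
#'
#' Connected components (8-connectivity) of the binary mask, with components
#' below `min_area` discarded and the survivors relabelled 1..K.
#'
#' @param mask logical/binary matrix from [preprocess_and_mask()].
#' @param min_area minimum component area in (subsampled) pixels.
#' @return A `labeled_follicles` object: integer `labels` matrix
#'   (0 = background), `ids`, `areas` (pixel counts per id).
#' @export
label_follicles <- function(mask, min_area = 500) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "double"
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  lab <- .merge_diagonal(lab)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(areas >= min_area)
    newid <- integer(max(lab))
    newid[keep] <- seq_along(keep)
    lab[lab > 0] <- newid[lab[lab > 0]]
    areas <- areas[keep]
  } else {
    areas <- integer(0)
  }
  structure(list(labels = lab, ids = seq_along(areas), areas = areas),
            class = "labeled_follicles",
            subsample_factor = attr(mask, "subsample_factor"),
            pixel_size = attr(mask, "pixel_size"))
}

#' @export
print.labeled_follicles <- function(x, ...) {
  cat(sprintf("%d follicle(s); areas (px): %s\n", length(x$ids),
              paste(x$areas, collapse = ", ")))
  invisible(x)
}

#' Segment each follicle into concentric depth shells
#'
#' Pixels are assigned to `n_shells` equal-width bins of their normalised
#' Euclidean distance to the follicle boundary (distance transform divided
#' by the follicle's maximum). Shell 1 is the innermost core; shell
#' `n_shells` hugs the boundary and serves as the local background ring in
#' [shell_profile()]. On a disk the shells are annuli of equal radial
#' thickness.
#'
#' @param labeled a `labeled_follicles` object.
#' @param n_shells number of shells (default 6: five reporting rings plus
#'   the peripheral background ring).
#' @return A `shell_map`: integer `shells` matrix (0 outside any follicle),
#'   `follicle` label matrix, `n_shells`, `ids`.
#' @export
concentric_shells <- function(labeled, n_shells = 6) {
  stopifnot(inherits(labeled, "labeled_follicles"),
            n_shells >= 2, n_shells == round(n_shells))
  n_shells <- as.integer(n_shells)
  lab <- labeled$labels
  shells <- matrix(0L, nrow(lab), ncol(lab))
  for (id in labeled$ids) {
    bin <- lab == id
    d <- EBImage::imageData(EBImage::distmap(EBImage::Image(bin * 1)))
    dmax <- max(d[bin])
    if (dmax < n_shells / 2)
      warning(sprintf(paste0("follicle %d is thinner than %d pixels at its ",
                             "widest; shells collapse"), id, n_shells))
    depth <- d[bin] / dmax
    sh <- n_shells - floor(depth * n_shells)
    sh[sh < 1L] <- 1L
    shells[bin] <- as.integer(sh)
  }
  structure(list(shells = shells, follicle = lab, n_shells = n_shells,
                 ids = labeled$ids),
            class = "shell_map",
            subsample_factor = attr(labeled, "subsample_factor"),
            pixel_size = attr(labeled, "pixel_size"))
}

#' Normalised radial antigen profile per follicle
#'
#' For each follicle and channel: mean intensity in the inner
#' `n_shells - 1` rings, minus the outermost-ring (background) mean, floored
#' at zero and divided by the mean of the resulting vector
#' (mean-normalisation). The reported profile is the antigen vector divided
#' elementwise by the structural (CD21) vector processed identically, so a
#' uniformly loaded network reads 1 in every shell regardless of staining
#' intensity. Shells where the normalised structural value is 0 are flagged
#' (`NaN` profile).
#'
#' @param antigen antigen-channel matrix at acquisition resolution.
#' @param structural structural-channel matrix at acquisition resolution.
#' @param shells a `shell_map`; its recorded subsample factor is applied to
#'   the channels before measurement.
#' @return A `shell_profile` data frame with columns `follicle`, `shell`
#'   (1 = innermost), `antigen_norm`, `structural_norm`, `profile`, `flag`.
#' @export
shell_profile <- function(antigen, structural, shells) {
  stopifnot(inherits(shells, "shell_map"),
            is.matrix(antigen), is.matrix(structural))
  f <- attr(shells, "subsample_factor")
  if (is.null(f)) f <- 1L
  ant <- .block_mean(antigen, f)
  str <- .block_mean(structural, f)
  dm <- dim(shells$shells)
  if (!all(dim(ant) >= dm) || !all(dim(str) >= dm))
    stop("channel dimensions do not cover the shell map")
  ant <- ant[seq_len(dm[1L]), seq_len(dm[2L])]
  str <- str[seq_len(dm[1L]), seq_len(dm[2L])]

  n <- shells$n_shells
  out <- list()
  for (id in shells$ids) {
    sel <- shells$follicle == id
    sh <- shells$shells[sel]
    m_ant <- vapply(seq_len(n), function(s) mean(ant[sel][sh == s]),
                    numeric(1L))
    m_str <- vapply(seq_len(n), function(s) mean(str[sel][sh == s]),
                    numeric(1L))
    v_ant <- .bg_subtract_normalise(m_ant)
    v_str <- .bg_subtract_normalise(m_str)
    prof <- v_ant / v_str
    flag <- !is.finite(prof)
    out[[length(out) + 1L]] <-
      data.frame(follicle = id, shell = seq_len(n - 1L),
                 antigen_norm = v_ant, structural_norm = v_str,
                 profile = prof, flag = flag)
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(follicle = integer(0), shell = integer(0),
                  antigen_norm = numeric(0), structural_norm = numeric(0),
                  profile = numeric(0), flag = logical(0))
  class(res) <- c("shell_profile", "data.frame")
  res
}

# inner-ring means minus outermost-ring background, floored, mean-normalised.
# A vector with no contrast above the background ring normalises to the flat
# all-ones profile (the scale-free limit of mean-normalisation), so channels
# that are constant across the follicle read as uniformly distributed.
.bg_subtract_normalise <- function(shell_means) {
  n <- length(shell_means)
  v <- pmax(shell_means[-n] - shell_means[n], 0)
  mv <- mean(v)
  if (mv == 0) rep(1, n - 1L) else v / mv
}

#' Thresholded FDC network volume
#'
#' In-mask voxel count times the voxel volume. A binary stack yields the
#' total volume; an integer-labelled stack yields one volume per network.
#'
#' @param mask_stack 2D or 3D binary/labelled array.
#' @param voxel_size volume of one voxel, um^3 (> 0).
#' @return Named numeric vector of volumes (one entry per label), or a
#'   single total for a binary stack; 0 for an empty stack.
#' @export
network_volume <- function(mask_stack, voxel_size = 1) {
  stopifnot(is.numeric(voxel_size), length(voxel_size) == 1L, voxel_size > 0)
  v <- as.integer(round(mask_stack[mask_stack > 0]))
  if (length(v) == 0L) return(0)
  labs <- sort(unique(v))
  if (identical(labs, 1L)) return(length(v) * voxel_size)
  counts <- tabulate(v, nbins = max(labs))[labs]
  stats::setNames(counts * voxel_size, labs)
}
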