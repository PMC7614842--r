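#' Specification of one synthetic follicle
#'
#' Describes a disk-like FDC network for the image generator: geometry,
#' structural staining intensity, and the radial antigen deposition pattern
#' — `"uniform"` emulates the early (day-1-like) state where antigen covers
#' the whole network, `"gaussian"` the later centralized state where antigen
#' concentrates at the follicle centre.
#'
#' @param center follicle centre in pixels, length-2 (row, col).
#' @param radius_um follicle radius in um (> 0).
#' @param structural_intensity in-disk intensity of the structural channel.
#' @param antigen_profile `"uniform"` or `"gaussian"`.
#' @param antigen_peak antigen intensity (uniform level, or Gaussian peak at
#'   the centre).
#' @param sigma_um Gaussian radial width in um (required for
#'   `"gaussian"`).
#' @param edge_width_um width of the soft rim over which network staining
#'   (and the antigen it carries) ramps down to background at the follicle
#'   boundary. Real FDC networks end in a cell-scale fringe rather than a
#'   hard step; the default is one dendrite-cell diameter. Set 0 for an
#'   ideal hard-edged disk.
#' @return A `follicle_spec` object.
#' @export
follicle_spec <- function(center, radius_um, structural_intensity = 100,
                          antigen_profile = c("uniform", "gaussian"),
                          antigen_peak = 100, sigma_um = NULL,
                          edge_width_um = 12) {
  antigen_profile <- match.arg(antigen_profile)
  stopifnot(length(center) == 2L, is.numeric(center),
            is.numeric(radius_um), radius_um > 0,
            structural_intensity >= 0, antigen_peak >= 0,
            edge_width_um >= 0, edge_width_um < radius_um)
  if (antigen_profile == "gaussian") {
    if (is.null(sigma_um) || sigma_um <= 0)
      stop("gaussian antigen profile requires sigma_um > 0")
  }
  structure(list(center = center, radius_um = radius_um,
                 structural_intensity = structural_intensity,
                 antigen_profile = antigen_profile,
                 antigen_peak = antigen_peak, sigma_um = sigma_um,
                 edge_width_um = edge_width_um),
            class = "follicle_spec")
}

# network envelope: 1 in the follicle core, linear ramp to 0 across the rim
.follicle_envelope <- function(r_um, radius_um, edge_width_um) {
  if (edge_width_um <= 0) return(as.numeric(r_um <= radius_um))
  pmin(pmax((radius_um - r_um) / edge_width_um, 0), 1)
}

# radial intensity functions of one follicle, in um
.follicle_radial <- function(spec) {
  f <- function(r) .follicle_envelope(r, spec$radius_um, spec$edge_width_um)
  str_fun <- function(r) spec$structural_intensity * f(r)
  ant_fun <- if (spec$antigen_profile == "uniform") {
    function(r) spec$antigen_peak * f(r)
  } else {
    function(r) spec$antigen_peak * exp(-r^2 / (2 * spec$sigma_um^2)) * f(r)
  }
  list(structural = str_fun, antigen = ant_fun)
}

#' Generate a synthetic multi-channel follicle image
#'
#' Renders disk-like FDC networks with uniform structural staining and
#' either uniform or centre-weighted (Gaussian) antigen deposition, plus a
#' constant background and additive Gaussian read noise. Ground truth
#' (per-follicle masks, radii in pixels, and analytic shell means) is
#' attached so downstream quantification can be tested closed-loop.
#'
#' @param specs a `follicle_spec` or list of them; overlapping follicles are
#'   allowed and flagged in the ground truth.
#' @param frame frame size in pixels, length-2 (rows, cols).
#' @param pixel_size um per pixel.
#' @param background constant background level added to both channels.
#' @param noise_sd additive Gaussian noise sd (0 = noiseless).
#' @param seed integer seed; the generator is a pure function of
#'   (specs, seed).
#' @return A [follicle_image] with channels `structural` and `antigen`, and
#'   attribute `ground_truth` (list with `masks`, `specs`, `overlap`).
#' @export
gen_follicle_image <- function(specs, frame = c(512, 512), pixel_size = 4,
                               background = 10, noise_sd = 0, seed = 1L) {
  if (inherits(specs, "follicle_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1L), "follicle_spec")),
            length(frame) == 2L, all(frame >= 8), pixel_size > 0,
            background >= 0, noise_sd >= 0)
  nr <- frame[1L]; nc <- frame[2L]
  row_idx <- matrix(seq_len(nr), nr, nc)
  col_idx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

  structural <- matrix(0, nr, nc)
  antigen <- matrix(0, nr, nc)
  masks <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    R_px <- sp$radius_um / pixel_size
    if (sp$center[1L] - R_px < 1 || sp$center[1L] + R_px > nr ||
        sp$center[2L] - R_px < 1 || sp$center[2L] + R_px > nc)
      stop(sprintf("follicle %d does not fit in the frame", i))
    r_px <- sqrt((row_idx - sp$center[1L])^2 + (col_idx - sp$center[2L])^2)
    disk <- r_px <= R_px
    masks[[i]] <- disk
    rad <- .follicle_radial(sp)
    r_um <- r_px[disk] * pixel_size
    structural[disk] <- structural[disk] + rad$structural(r_um)
    antigen[disk] <- antigen[disk] + rad$antigen(r_um)
  }
  overlap <- Reduce(`+`, lapply(masks, `+`, 0),
                    accumulate = FALSE)
  overlap_flag <- any(overlap > 1)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  structural <- structural + background +
    matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc)
  antigen <- antigen + background +
    matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc)

  img <- follicle_image(list(structural = pmax(structural, 0),
                             antigen = pmax(antigen, 0)),
                        pixel_size = pixel_size)
  attr(img, "ground_truth") <- list(masks = masks, specs = specs,
                                    overlap = overlap_flag, seed = seed,
                                    background = background,
                                    noise_sd = noise_sd)
  img
}

#' Analytic mean of a centred radial Gaussian over an annulus
#'
#' Mean of `A exp(-r^2 / (2 sigma^2))` over the annulus `r in [r1, r2]`:
#' `A * 2 sigma^2 (exp(-r1^2/(2 sigma^2)) - exp(-r2^2/(2 sigma^2))) /
#' (r2^2 - r1^2)`. Used as the ground-truth shell mean for centralized
#' antigen patterns.
#'
#' @param r1,r2 annulus radii (same units as `sigma`), `r2 > r1 >= 0`.
#' @param sigma Gaussian radial width.
#' @param peak central amplitude `A`.
#' @return Mean intensity over the annulus.
#' @export
annulus_gaussian_mean <- function(r1, r2, sigma, peak = 1) {
  stopifnot(all(r2 > r1), all(r1 >= 0), sigma > 0)
  peak * 2 * sigma^2 *
    (exp(-r1^2 / (2 * sigma^2)) - exp(-r2^2 / (2 * sigma^2))) /
    (r2^2 - r1^2)
}

#' Expected shell profile for a synthetic follicle
#'
#' Pushes the generator's exact radial intensity model through the same
#' annulus-mean / background-subtract / mean-normalise / structural-ratio
#' arithmetic as [shell_profile()], using 1-D radial quadrature of the
#' closed-form intensity functions — an oracle independent of the pixel
#' pipeline. Uniform antigen (which rides the same network envelope as the
#' structural stain) gives the all-ones profile.
#'
#' @param spec a [follicle_spec].
#' @param n_shells number of shells (outermost = background).
#' @param mask_radius_um radius of the detected follicle mask that defines
#'   the shell edges; defaults to the spec's nominal radius. Pass the
#'   measured mask radius when comparing against a thresholded pipeline,
#'   whose boundary sits inside the soft rim.
#' @return Numeric vector of `n_shells - 1` expected profile values,
#'   innermost first.
#' @export
expected_shell_profile <- function(spec, n_shells = 6,
                                   mask_radius_um = NULL) {
  stopifnot(inherits(spec, "follicle_spec"))
  if (spec$antigen_profile == "uniform") return(rep(1, n_shells - 1L))
  R_m <- if (is.null(mask_radius_um)) spec$radius_um else mask_radius_um
  edges <- seq(0, R_m, length.out = n_shells + 1L)
  rad <- .follicle_radial(spec)
  annulus_mean <- function(fun, r1, r2) {
    2 * stats::integrate(function(r) fun(r) * r, r1, r2,
                         rel.tol = 1e-10)$value / (r2^2 - r1^2)
  }
  m_ant <- vapply(seq_len(n_shells), function(k)
    annulus_mean(rad$antigen, edges[k], edges[k + 1L]), numeric(1L))
  m_str <- vapply(seq_len(n_shells), function(k)
    annulus_mean(rad$structural, edges[k], edges[k + 1L]), numeric(1L))
  .bg_subtract_normalise(m_ant) / .bg_subtract_normalise(m_str)
}

#' Generate per-animal IC decay observations
#'
#' Emulates flow-cytometry time courses of IC levels on FDCs: for each mean
#' CR2 density and sampling day, the forward model's mean IC surface level
#' `<S(t)> <n_R>` is multiplied by per-animal multiplicative lognormal noise
#' (MFI is positive and its spread grows with signal).
#'
#' @param params a [bond_params] object (typically calibrated).
#' @param densities mean CR2 densities, molecules/um^2.
#' @param days sampling days (> 0).
#' @param n_animals animals per density group (>= 1).
#' @param noise_sdlog lognormal sigma of the multiplicative noise
#'   (0 = noiseless).
#' @param seed integer seed.
#' @return Data frame with columns `animal_id`, `density`, `day`, `mfi`,
#'   and `mfi_true` (the noiseless forward-model level).
#' @export
gen_decay_dataset <- function(params, densities, days = c(1, 4, 7),
                              n_animals = 5, noise_sdlog = 0.1, seed = 1L) {
  stopifnot(inherits(params, "bond_params"), all(densities >= 0),
            all(days > 0), n_animals >= 1, noise_sdlog >= 0)
  times <- sort(unique(days)) * 86400
  rows <- list()
  for (dens in densities) {
    mean_nR <- density_to_mean_nR(dens, params$patch_area)
    curve <- poisson_mixture_survival(params, mean_nR,
                                      c(0, times))
    lev <- ic_surface_level(curve)
    truth <- stats::setNames(lev$level[-1L], sort(unique(days)))
    for (a in seq_len(n_animals)) {
      for (d in days) {
        rows[[length(rows) + 1L]] <-
          data.frame(animal_id = sprintf("d%g_a%d", dens, a),
                     density = dens, day = d,
                     mfi_true = unname(truth[as.character(d)]))
      }
    }
  }
  out <- do.call(rbind, rows)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  noise <- if (noise_sdlog > 0)
    exp(stats::rnorm(nrow(out), sd = noise_sdlog)) else 1
  out$mfi <- out$mfi_true * noise
  out[c("animal_id", "density", "day", "mfi", "mfi_true")]
}

#' Generate a panel of synthetic sensorgrams
#'
#' Wraps [simulate_sensorgram()] over an analyte concentration series with
#' deterministic per-trace sub-seeds.
#'
#' @param k_on,k_off,R_max generating 1:1 Langmuir truth.
#' @param concentrations analyte concentrations, M.
#' @param t_assoc,t_dissoc,dt phase durations and sampling interval, s.
#' @param noise_sd additive Gaussian noise sd, RU.
#' @param seed integer root seed.
#' @return List of `sensorgram` objects.
#' @export
gen_sensorgram_panel <- function(k_on, k_off, R_max = 1,
                                 concentrations = bli_concentration_series(),
                                 t_assoc = 300, t_dissoc = 300, dt = 0.5,
                                 noise_sd = 0, seed = 1L) {
  lapply(seq_along(concentrations), function(i)
    simulate_sensorgram(k_on, k_off, R_max, concentrations[i],
                        t_assoc = t_assoc, t_dissoc = t_dissoc, dt = dt,
                        noise_sd = noise_sd,
                        seed = as.integer(seed) + i))
}

#' Generate a synthetic fluorescent-bead calibration panel
#'
#' Four (by default) bead levels on a known fluorescence-to-molecule line
#' with optional Gaussian MFI noise, emulating a PE quantitation kit.
#'
#' @param slope,intercept generating calibration line
#'   (molecules = slope * MFI + intercept).
#' @param mfi_levels bead MFI levels.
#' @param noise_sd Gaussian noise sd on the molecule counts.
#' @param seed integer seed.
#' @return Data frame with columns `mfi`, `molecules`.
#' @export
gen_bead_panel <- function(slope = 10, intercept = 0,
                           mfi_levels = c(50, 200, 800, 3200),
                           noise_sd = 0, seed = 1L) {
  stopifnot(length(mfi_levels) >= 2L, noise_sd >= 0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  mol <- slope * mfi_levels + intercept +
    stats::rnorm(length(mfi_levels), sd = noise_sd)
  data.frame(mfi = mfi_levels, molecules = mol)
}
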