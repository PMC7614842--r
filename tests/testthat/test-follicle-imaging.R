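# shared synthetic follicles for the imaging tests
uniform_spec <- follicle_spec(c(256, 256), radius_um = 150,
                              structural_intensity = 100,
                              antigen_profile = "uniform",
                              antigen_peak = 80)
central_spec <- follicle_spec(c(256, 256), radius_um = 150,
                              antigen_profile = "gaussian",
                              antigen_peak = 200, sigma_um = 50)

test_that("masking recovers a noisy disk and handles degenerate frames", {
  img <- gen_follicle_image(uniform_spec, pixel_size = 4, background = 10,
                            noise_sd = 10, seed = 42) # SNR 10
  mask <- preprocess_and_mask(img, subsample_factor = 1)
  truth <- attr(img, "ground_truth")$masks[[1L]]
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.9)
  # blank frame: empty mask, no error
  expect_true(all(!preprocess_and_mask(matrix(0, 64, 64))))
  # saturated constant frame: full-frame mask
  expect_true(all(preprocess_and_mask(matrix(100, 64, 64))))
})

test_that("follicles are labelled with 8-connectivity and an area floor", {
  m <- matrix(FALSE, 120, 120)
  rr <- row(m); cc <- col(m)
  m[(rr - 30)^2 + (cc - 30)^2 <= 15^2] <- TRUE
  m[(rr - 85)^2 + (cc - 85)^2 <= 15^2] <- TRUE
  two <- label_follicles(structure(m, subsample_factor = 1L), min_area = 50)
  expect_length(two$ids, 2L)
  # overlapping disks merge into one component
  m2 <- matrix(FALSE, 120, 120)
  m2[(rr - 50)^2 + (cc - 50)^2 <= 20^2] <- TRUE
  m2[(rr - 70)^2 + (cc - 65)^2 <= 20^2] <- TRUE
  expect_length(label_follicles(structure(m2, subsample_factor = 1L),
                                min_area = 50)$ids, 1L)
  # a component below the area floor is dropped
  m3 <- m
  m3[5, 5] <- TRUE
  expect_length(label_follicles(structure(m3, subsample_factor = 1L),
                                min_area = 50)$ids, 2L)
  # blobs touching only diagonally are one follicle
  d <- matrix(FALSE, 40, 40)
  d[5:15, 5:15] <- TRUE
  d[16:26, 16:26] <- TRUE
  expect_length(label_follicles(structure(d, subsample_factor = 1L),
                                min_area = 10)$ids, 1L)
})

test_that("disk shells are annuli with near-analytic pixel counts", {
  m <- matrix(FALSE, 300, 300)
  m[(row(m) - 150)^2 + (col(m) - 150)^2 <= 120^2] <- TRUE
  lab <- label_follicles(structure(m, subsample_factor = 1L), min_area = 100)
  sh <- concentric_shells(lab)
  counts <- tabulate(sh$shells[sh$shells > 0], 6)
  edges <- seq(0, 120, length.out = 7)
  analytic <- pi * (edges[-1L]^2 - edges[-7L]^2) # innermost first
  expect_true(all(abs(counts - analytic) / analytic < 0.03))
  # shells partition the mask exactly
  expect_equal(sum(counts), sum(m))
  expect_true(all(sh$shells[m] >= 1 & sh$shells[m] <= 6))
  expect_true(all(sh$shells[!m] == 0))
})

test_that("thin regions collapse with a warning", {
  m <- matrix(FALSE, 40, 40)
  m[20, 5:35] <- TRUE
  lab <- label_follicles(structure(m, subsample_factor = 1L), min_area = 10)
  expect_warning(concentric_shells(lab), "thinner")
})

test_that("shell profiles are exact for identical or constant channels", {
  img <- gen_follicle_image(uniform_spec, noise_sd = 0, seed = 1)
  mask <- preprocess_and_mask(img, subsample_factor = 1)
  sh <- concentric_shells(label_follicles(mask, min_area = 100))
  str <- img$channels$structural
  self <- shell_profile(str, str, sh)
  expect_equal(self$profile, rep(1, 5))
  const <- shell_profile(matrix(5, nrow(str), ncol(str)),
                         matrix(9, nrow(str), ncol(str)), sh)
  expect_equal(const$profile, rep(1, 5))
})

test_that("shell profiles are invariant to intensity scale and translation", {
  img <- gen_follicle_image(central_spec, noise_sd = 2, seed = 9)
  mask <- preprocess_and_mask(img, subsample_factor = 1)
  sh <- concentric_shells(label_follicles(mask, min_area = 100))
  ant <- img$channels$antigen
  str <- img$channels$structural
  base <- shell_profile(ant, str, sh)$profile
  expect_equal(shell_profile(ant * 7.3, str, sh)$profile, base,
               tolerance = 1e-10)
  expect_equal(shell_profile(ant, str * 0.2, sh)$profile, base,
               tolerance = 1e-10)
  # same follicle placed elsewhere in the frame
  moved <- follicle_spec(c(180, 300), radius_um = 150,
                         antigen_profile = "gaussian", antigen_peak = 200,
                         sigma_um = 50)
  img2 <- gen_follicle_image(moved, noise_sd = 0, seed = 9)
  img0 <- gen_follicle_image(
    follicle_spec(c(256, 256), radius_um = 150,
                  antigen_profile = "gaussian", antigen_peak = 200,
                  sigma_um = 50), noise_sd = 0, seed = 9)
  prof_for <- function(im) {
    msk <- preprocess_and_mask(im, subsample_factor = 1)
    shm <- concentric_shells(label_follicles(msk, min_area = 100))
    shell_profile(im$channels$antigen, im$channels$structural, shm)$profile
  }
  expect_equal(prof_for(img2), prof_for(img0), tolerance = 1e-6)
})

test_that("uniform antigen reads flat and centralized antigen decreasing", {
  # day-1-like pattern at SNR 10: flat within 0.1
  img <- gen_follicle_image(uniform_spec, noise_sd = 10, seed = 42)
  mask <- preprocess_and_mask(img, subsample_factor = 1)
  sh <- concentric_shells(label_follicles(mask, min_area = 100))
  prof <- shell_profile(img$channels$antigen, img$channels$structural, sh)
  expect_lt(max(abs(prof$profile - 1)), 0.1)
  # day-14-like pattern: strictly decreasing centre -> periphery
  img2 <- gen_follicle_image(central_spec, noise_sd = 10, seed = 43)
  mask2 <- preprocess_and_mask(img2, subsample_factor = 1)
  sh2 <- concentric_shells(label_follicles(mask2, min_area = 100))
  prof2 <- shell_profile(img2$channels$antigen, img2$channels$structural,
                         sh2)
  expect_true(all(diff(prof2$profile) < 0))
  expect_gt(prof2$profile[1L], 1)
  expect_lt(prof2$profile[5L], 1)
})

test_that("measured centralized profiles match the radial quadrature oracle", {
  img <- gen_follicle_image(central_spec, noise_sd = 2, seed = 43)
  mask <- preprocess_and_mask(img, subsample_factor = 1)
  lab <- label_follicles(mask, min_area = 100)
  sh <- concentric_shells(lab)
  prof <- shell_profile(img$channels$antigen, img$channels$structural, sh)
  R_det <- sqrt(lab$areas[1L] / pi) * img$pixel_size
  expected <- expected_shell_profile(central_spec, mask_radius_um = R_det)
  expect_equal(prof$profile, expected, tolerance = 0.05)
})

test_that("network volume counts voxels", {
  cube <- array(0L, c(20, 20, 20))
  cube[6:15, 6:15, 6:15] <- 1L
  expect_equal(network_volume(cube, 1), 1000)
  expect_equal(network_volume(array(0L, c(5, 5, 5)), 1), 0)
  ball <- array(0L, c(45, 45, 45))
  ctr <- 23
  for (z in 1:45) {
    d2 <- (row(ball[, , z]) - ctr)^2 + (col(ball[, , z]) - ctr)^2 +
      (z - ctr)^2
    ball[, , z][d2 <= 400] <- 1L
  }
  expect_equal(network_volume(ball, 1), 4 / 3 * pi * 8000, tolerance = 0.02)
  # labelled stacks report one volume per network
  two <- array(0L, c(10, 10, 2))
  two[1:2, 1:2, 1] <- 1L
  two[7:9, 7:9, ] <- 2L
  vols <- network_volume(two, 2)
  expect_equal(unname(vols), c(8, 36))
  expect_equal(names(vols), c("1", "2"))
})

test_that("follicle TIFFs round-trip through disk", {
  img <- gen_follicle_image(uniform_spec, noise_sd = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".tif")
  write_follicle_tiff(img, path)
  back <- read_follicle_tiff(path, channel_names = names(img$channels),
                             pixel_size = img$pixel_size)
  # joint scaling preserves relative intensities
  sc <- max(img$channels$structural) / max(back$channels$structural)
  expect_equal(back$channels$structural * sc, img$channels$structural,
               tolerance = 1e-5)
  expect_equal(back$channels$antigen * sc, img$channels$antigen,
               tolerance = 1e-5)
})
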