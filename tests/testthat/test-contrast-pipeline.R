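make_stack <- function(counts) {
  frame_stack(counts, exposure_time = 2e-3, frame_rate = 100)
}

test_that("dark statistics: per-pixel mean and unbiased variance", {
  const <- array(7L, dim = c(5, 4, 4))
  ds <- estimate_dark_statistics(make_stack(const))
  expect_true(all(ds$mean_map == 7))
  expect_true(all(ds$var_map == 0))
  expect_equal(ds$n_frames_used, 5)
  expect_error(estimate_dark_statistics(make_stack(array(1L, c(1, 4, 4)))))
  # Poisson stack: mean approximately equals variance
  dk <- generate_dark_frames(dark_model(4, 0, 2), 800, c(16, 16), seed = 21)
  ds <- estimate_dark_statistics(dk)
  expect_equal(mean(ds$mean_map), 4, tolerance = 0.02)
  expect_equal(mean(ds$var_map) / mean(ds$mean_map), 1, tolerance = 0.05)
  # matches R's var() frame-wise on one pixel
  expect_equal(ds$var_map[1, 1], stats::var(dk$counts[, 1, 1]))
})

test_that("3-sigma rule: uniform image, planted outlier, Gaussian tail fraction", {
  expect_equal(flag_bad_pixels(matrix(5, 10, 10))$n_flagged, 0)
  ref <- matrix(stats::rnorm(400, 100, 1), 20, 20)
  ref[7, 7] <- 100 + 100  # 100 sigma outlier
  mk <- flag_bad_pixels(ref)
  expect_false(mk$valid[7, 7])
  expect_equal(mk$n_flagged, 1)
  # Gaussian reference: flagged fraction near 2*pnorm(-3) = 0.27%
  big <- withr::with_seed(99, matrix(stats::rnorm(512 * 512), 512, 512))
  frac <- flag_bad_pixels(big)$n_flagged / (512 * 512)
  expect_equal(frac, 2 * stats::pnorm(-3), tolerance = 0.15)
})

test_that("planted hot pixels are recovered from the dark mean map", {
  dk <- generate_dark_frames(dark_model(2, 0.01, 50), n_frames = 200,
                             shape = c(128, 128), seed = 31)
  ds <- estimate_dark_statistics(dk)
  mask <- flag_bad_pixels(ds$mean_map)
  truth <- dk$metadata$hot_index
  flagged <- which(!mask$valid)
  sensitivity <- length(intersect(truth, flagged)) / length(truth)
  expect_gte(sensitivity, 0.99)
  # false positives stay rare
  expect_lt(length(setdiff(flagged, truth)) / (128 * 128 - length(truth)),
            0.01)
})

test_that("noise-corrected contrast separates speckle from shot noise", {
  # pure Poisson flat field: corrected contrast centers on zero while the
  # measured contrast carries the shot-noise floor 1/<Ic>
  nfr <- 150
  kc <- km <- mi <- numeric(nfr)
  withr::with_seed(41, {
    for (f in seq_len(nfr)) {
      fr <- matrix(stats::rpois(64 * 64, 40), 64, 64)
      cc <- corrected_contrast_sq(fr)
      kc[f] <- cc$kappa_c_sq; km[f] <- cc$kappa_m_sq
      mi[f] <- cc$mean_intensity
    }
  })
  se <- stats::sd(kc) / sqrt(nfr)
  expect_lt(abs(mean(kc)), 3 * se)
  expect_equal(mean(km), 1 / mean(mi), tolerance = 0.02)
  # gamma-Poisson with M = 4: corrected contrast centers on 0.25
  st <- generate_speckle_frames(0.25, 40, 100, c(64, 64), seed = 42)
  res <- purrr::map_dbl(seq_len(100),
                        function(f) corrected_contrast_sq(st$counts[f, , ])$kappa_c_sq)
  se <- stats::sd(res) / sqrt(length(res))
  expect_lt(abs(mean(res) - 0.25), 3 * se + 0.003)
})

test_that("contrast decomposition identity holds frame by frame", {
  dk <- generate_dark_frames(dark_model(2, 0.005, 30), 100, c(32, 32),
                             seed = 51)
  ds <- estimate_dark_statistics(dk)
  mask <- flag_bad_pixels(ds$mean_map)
  st <- generate_speckle_frames(0.2, 30, 10, c(32, 32), seed = 52)
  for (f in 1:10) {
    fr <- st$counts[f, , ] + dk$counts[f, , ]
    cc <- corrected_contrast_sq(fr, ds, mask)
    nb <- cc$noise_budget
    expect_equal(cc$kappa_m_sq - cc$kappa_c_sq,
                 nb$kappa_s_sq + nb$kappa_d_sq, tolerance = 1e-12)
    expect_equal(nb$kappa_s_sq, 1 / cc$mean_intensity, tolerance = 1e-12)
    expect_identical(nb$kappa_r_sq, 0)  # photon counting: no read noise
    expect_identical(nb$kappa_q_sq, 0)  # and no quantization
  }
})

test_that("masked pixels never influence the statistics", {
  st <- generate_speckle_frames(0.2, 30, 1, c(32, 32), seed = 61)
  fr <- st$counts[1, , ]
  valid <- matrix(TRUE, 32, 32)
  valid[1:3, 1:3] <- FALSE
  mask <- structure(list(valid = valid, n_flagged = 9L, rule = "manual"),
                    class = "pixel_mask")
  base <- corrected_contrast_sq(fr, NULL, mask)
  poisoned <- fr
  poisoned[1:3, 1:3] <- 1e6L  # extreme values in the masked region
  after <- corrected_contrast_sq(poisoned, NULL, mask)
  expect_identical(base, after)
  # degenerate input: fewer than two valid pixels
  allbad <- structure(list(valid = matrix(FALSE, 32, 32), n_flagged = 1024L,
                           rule = "manual"), class = "pixel_mask")
  expect_error(corrected_contrast_sq(fr, NULL, allbad), "valid pixels")
})

test_that("blood flow index is the reciprocal of corrected contrast", {
  expect_equal(bfi_from_contrast(0.25), 4)
  expect_equal(bfi_from_contrast(1), 1)
  expect_equal(bfi_from_contrast(0.1) / bfi_from_contrast(0.2), 2)
  expect_true(is.na(bfi_from_contrast(0)))
  expect_true(is.na(bfi_from_contrast(-0.05)))  # over-subtracted: no flow info
  expect_true(is.na(bfi_from_contrast(NA_real_)))
})

test_that("process_frames produces a per-frame series with metadata", {
  st <- generate_speckle_frames(0.25, 30, 20, c(32, 32), seed = 71,
                                frame_rate = 100)
  ser <- process_frames(st)
  expect_s3_class(ser, "contrast_series")
  expect_equal(nrow(ser), 20)
  expect_equal(ser$time_s, (0:19) / 100)
  expect_equal(ser$bfi, bfi_from_contrast(ser$kappa_c_sq))
  expect_equal(attr(ser, "frame_rate"), 100)
})

test_that("baseline normalization makes the baseline-window mean exactly one", {
  ser <- tibble::tibble(time_s = (0:99) / 10,
                        bfi = c(rep(7, 35), rep(14, 65)))
  out <- normalize_bfi(ser, c(0, 3.5))
  expect_equal(mean(out$rbfi[out$time_s < 3.5]), 1)
  expect_equal(out$rbfi[50], 2)
  # constant series: rbfi identically one
  cst <- tibble::tibble(time_s = (0:49) / 10, bfi = rep(7, 50))
  expect_true(all(normalize_bfi(cst, c(0, 2))$rbfi == 1))
  expect_error(normalize_bfi(ser, c(90, 95)), "no samples")
  neg <- tibble::tibble(time_s = (0:9) / 10, bfi = rep(-1, 10))
  expect_error(normalize_bfi(neg, c(0, 1)), "not positive")
})

test_that("centered moving average: identity, impulse plateau, NA handling", {
  ser <- tibble::tibble(time_s = 1:100, bfi = rnorm(100))
  expect_equal(smooth_series(ser, "bfi", window = 1)$bfi, ser$bfi)
  cst <- tibble::tibble(time_s = 1:50, bfi = rep(3, 50))
  expect_equal(smooth_series(cst, "bfi", window = 20)$bfi, rep(3, 50))
  imp <- tibble::tibble(time_s = 1:101, bfi = c(rep(0, 50), 1, rep(0, 50)))
  sm <- smooth_series(imp, "bfi", window = 20)$bfi
  expect_equal(sum(sm > 0), 20)                    # plateau spans the window
  expect_equal(unique(round(sm[sm > 0], 12)), 1 / 20)
  # missing values are excluded, not propagated
  nas <- tibble::tibble(time_s = 1:30, bfi = c(rep(2, 14), NA, rep(2, 15)))
  expect_true(all(smooth_series(nas, "bfi", window = 5)$bfi == 2))
  expect_error(smooth_series(cst, "bfi", window = 100), "exceeds")
})

test_that("local-window contrast agrees with the ensemble statistic on average", {
  expect_true(all(local_contrast_sq(matrix(5, 16, 16), window = 3) == 0))
  st <- generate_speckle_frames(0.25, 200, 1, c(64, 64), seed = 101)
  fr <- st$counts[1, , ]
  loc <- local_contrast_sq(fr, window = 7)
  glob <- corrected_contrast_sq(fr)$kappa_m_sq
  # local windows are unbiased for the variance, so the map mean tracks the
  # full-array statistic (within local-sampling noise)
  expect_equal(mean(loc, na.rm = TRUE), glob, tolerance = 0.1)
  # masked pixels drop out of their neighbourhoods
  valid <- matrix(TRUE, 64, 64); valid[10, 10] <- FALSE
  mask <- structure(list(valid = valid, n_flagged = 1L, rule = "manual"),
                    class = "pixel_mask")
  poisoned <- fr; poisoned[10, 10] <- 1e6L
  expect_equal(local_contrast_sq(poisoned, mask = mask, window = 5),
               local_contrast_sq(fr, mask = mask, window = 5))
  expect_error(local_contrast_sq(fr, window = 4))
})
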