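test_that("gamma-Poisson frames satisfy the variance-decomposition identity", {
  # E[(var - mean)/mean^2] over the pixel ensemble equals 1/M
  for (m in c(2, 4, 10)) {
    for (mu in c(5, 50, 500)) {
      st <- generate_speckle_frames(1 / m, mean_photons = mu, n_frames = 40,
                                    shape = c(64, 64),
                                    seed = 1000 + m * 10 + round(mu))
      per_frame <- apply(st$counts, 1, function(fr) {
        (stats::var(as.vector(fr)) - mean(fr)) / mean(fr)^2
      })
      se <- stats::sd(per_frame) / sqrt(length(per_frame))
      expect_lt(abs(mean(per_frame) - 1 / m), 4 * se + 0.002)
    }
  }
})

test_that("speckle generator edge cases and input validation", {
  st0 <- generate_speckle_frames(0.25, mean_photons = 0, n_frames = 3,
                                 shape = c(8, 8), seed = 1)
  expect_true(all(st0$counts == 0))
  expect_error(generate_speckle_frames(0, 10, 2, c(8, 8), 1))
  expect_error(generate_speckle_frames(1.2, 10, 2, c(8, 8), 1))
  # kappa^2 = 1 means exponentially distributed latents: CV of counts in a
  # high-intensity frame approaches 1
  st1 <- generate_speckle_frames(1, mean_photons = 500, n_frames = 10,
                                 shape = c(64, 64), seed = 2)
  cv <- apply(st1$counts, 1, function(fr) stats::sd(fr) / mean(fr))
  expect_equal(mean(cv), 1, tolerance = 0.05)
})

test_that("stacks are reproducible under a fixed seed and differ across seeds", {
  a <- generate_speckle_frames(0.25, 20, 5, c(16, 16), seed = 11)
  b <- generate_speckle_frames(0.25, 20, 5, c(16, 16), seed = 11)
  c <- generate_speckle_frames(0.25, 20, 5, c(16, 16), seed = 12)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts, c$counts))
  d1 <- generate_dark_frames(dark_model(2, 0.01, 50), 10, c(16, 16), seed = 5)
  d2 <- generate_dark_frames(dark_model(2, 0.01, 50), 10, c(16, 16), seed = 5)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$metadata$hot_index, d2$metadata$hot_index)
})

test_that("dark frames have Poisson statistics and planted hot pixels", {
  expect_true(all(generate_dark_frames(dark_model(0, 0, 2), 5,
                                       c(8, 8), 1)$counts == 0))
  dk <- generate_dark_frames(dark_model(3, 0, 2), n_frames = 1000,
                             shape = c(16, 16), seed = 3)
  m <- colMeans(dk$counts, dims = 1)
  v <- apply(dk$counts, c(2, 3), stats::var)
  expect_equal(mean(m), 3, tolerance = 0.02)
  expect_equal(mean(v) / mean(m), 1, tolerance = 0.05)  # Poisson: var = mean
  hot <- generate_dark_frames(dark_model(2, 0.01, 50), 100, c(32, 32),
                              seed = 4)
  expect_equal(length(hot$metadata$hot_index), round(0.01 * 32 * 32))
  mm <- colMeans(hot$counts, dims = 1)
  expect_gt(min(mm[hot$metadata$hot_index]), 10 * median(mm))
})

test_that("dark counts add to the speckle mean", {
  sp <- generate_speckle_frames(0.25, 30, 60, c(32, 32), seed = 6)
  dk <- generate_dark_frames(dark_model(5, 0, 2), 60, c(32, 32), seed = 6)
  both <- sp$counts + dk$counts  # independence: sum is the combined stack
  expect_equal(mean(both), mean(sp$counts) + mean(dk$counts),
               tolerance = 1e-12)
  expect_equal(mean(both), 35, tolerance = 0.03)
})

test_that("scenario stacks carry ground truth matched to the forward model", {
  op <- tissue_optics()
  ge <- tissue_geometry(20)
  prof <- cuff_occlusion_profile(baseline_s = 1, occlusion_s = 1,
                                 recovery_s = 1, sampling_rate_hz = 10)
  sim <- generate_scenario_stack(prof, op, ge, T_exp = 2e-3,
                                 mean_photons = 30, shape = c(32, 32),
                                 seed = 9)
  expect_equal(nrow(sim$truth), dim(sim$stack)[1])
  expect_equal(sim$truth$bfi_true, 1 / sim$truth$kappa_sq_true)
  # truth follows the forward model at each flow level
  i <- which(sim$truth$segment == "occlusion")[1]
  expect_equal(sim$truth$kappa_sq_true[i],
               speckle_contrast_sq(op, flow_params(sim$truth$alpha_db[i]),
                                   ge, 2e-3))
  # occlusion raises contrast (slower scatterers), baseline lowers it
  expect_gt(sim$truth$kappa_sq_true[i], sim$truth$kappa_sq_true[1])
  # same profile, different seed: same truth, different counts
  sim2 <- generate_scenario_stack(prof, op, ge, T_exp = 2e-3,
                                  mean_photons = 30, shape = c(32, 32),
                                  seed = 10)
  expect_identical(sim$truth, sim2$truth)
  expect_false(identical(sim$stack$counts, sim2$stack$counts))
})

test_that("scenario profiles encode the intended timelines", {
  occ <- cuff_occlusion_profile(sampling_rate_hz = 20)
  expect_equal(range(occ$time_s), c(0, 14.5 - 0.05))
  expect_setequal(unique(occ$segment), c("baseline", "occlusion", "recovery"))
  base_a <- occ$alpha_db[occ$segment == "baseline"][1]
  expect_equal(occ$alpha_db[occ$segment == "occlusion"][1], 0.1 * base_a)
  # hyperemic overshoot decays toward baseline
  rec <- occ$alpha_db[occ$segment == "recovery"]
  expect_gt(rec[1], base_a)
  expect_true(all(diff(rec) < 0))
  task <- task_activation_profile(task_increase = 0.08, sampling_rate_hz = 20)
  expect_equal(unique(task$alpha_db[task$segment == "task"]) /
                 unique(task$alpha_db[task$segment == "baseline"]), 1.08)
})
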