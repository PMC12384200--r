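#' Photon-count frame stack
#'
#' Container for a time-ordered stack of photon-counting images plus the
#' acquisition metadata the processing pipeline needs. Counts are stored as a
#' 3-D integer array (frames x rows x cols).
#'
#' @param counts 3-D array of non-negative integer counts,
#'   `n_frames x n_rows x n_cols`.
#' @param exposure_time Exposure per frame, s.
#' @param frame_rate Frames per second.
#' @param rho Source-detector separation, mm (NA for dark stacks).
#' @param metadata Named list of provenance (seed, scenario, ...).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(counts, exposure_time, frame_rate, rho = NA_real_,
                        metadata = list()) {
  stopifnot(is.array(counts), length(dim(counts)) == 3)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!is.integer(counts)) {
    if (any(counts != round(counts))) {
      stop("counts must be integers", call. = FALSE)
    }
    storage.mode(counts) <- "integer"
  }
  stopifnot(is.numeric(exposure_time), exposure_time > 0)
  stopifnot(is.numeric(frame_rate), frame_rate > 0)
  structure(
    list(counts = counts, exposure_time = exposure_time,
         frame_rate = frame_rate, rho = rho, metadata = metadata),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<frame_stack> %d frames of %d x %d, exposure %g s, %.1f fps, rho = %s mm\n",
    d[1], d[2], d[3], x$exposure_time, x$frame_rate,
    ifelse(is.na(x$rho), "NA", format(x$rho))
  ))
  cat(sprintf("  counts: mean %.2f, range [%d, %d]\n",
              mean(x$counts), min(x$counts), max(x$counts)))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$counts)

n_frames <- function(stack) dim(stack$counts)[1]

#' Per-pixel dark-count model
#'
#' Expected dark counts per pixel per frame, with a minority population of
#' "hot" pixels whose dark rate is elevated by a fixed multiplier. The hot
#' set is drawn uniformly at random from the array, pinned by `hot_seed`:
#' hotness is a property of the detector, so every stack generated from the
#' same model (dark calibration and measurement alike) shares the same hot
#' pixels.
#'
#' @param base_rate Expected dark counts per ordinary pixel per frame (>= 0).
#' @param hot_fraction Fraction of pixels designated hot, in `[0, 1)`.
#' @param hot_multiplier Dark-rate multiplier for hot pixels (> 1).
#' @param hot_seed Integer seed fixing the hot-pixel placement.
#' @return An object of class `dark_model`.
#' @examples
#' dark_model(base_rate = 2, hot_fraction = 0.01, hot_multiplier = 50)
#' @export
dark_model <- function(base_rate = 2, hot_fraction = 0.01,
                       hot_multiplier = 50, hot_seed = 1L) {
  stopifnot(is.numeric(base_rate), base_rate >= 0)
  stopifnot(is.numeric(hot_fraction), hot_fraction >= 0, hot_fraction < 1)
  stopifnot(is.numeric(hot_multiplier), hot_multiplier > 1)
  stopifnot(is.numeric(hot_seed))
  structure(
    list(base_rate = base_rate, hot_fraction = hot_fraction,
         hot_multiplier = hot_multiplier, hot_seed = as.integer(hot_seed)),
    class = "dark_model"
  )
}

#' Materialise the per-pixel dark-rate map
#'
#' @param dark A [dark_model()] object.
#' @param shape Length-2 integer vector (rows, cols).
#' @return A list with `rate_map` (matrix of expected dark counts) and
#'   `hot_index` (integer indices of the planted hot pixels). Deterministic
#'   given the model (placement is pinned by the model's `hot_seed`).
#' @export
dark_rate_map <- function(dark, shape = c(128, 128)) {
  stopifnot(inherits(dark, "dark_model"), length(shape) == 2)
  npix <- prod(shape)
  rate <- matrix(dark$base_rate, shape[1], shape[2])
  hot_index <- integer(0)
  n_hot <- round(dark$hot_fraction * npix)
  if (n_hot > 0) {
    hot_index <- withr::with_seed(dark$hot_seed, sample.int(npix, n_hot))
    rate[hot_index] <- dark$base_rate * dark$hot_multiplier
  }
  list(rate_map = rate, hot_index = sort(hot_index))
}

#' Simulate fully developed speckle frames on a photon-counting array
#'
#' Each pixel in each frame receives a latent speckle intensity drawn from a
#' gamma distribution with shape `M = 1 / kappa_sq_target` and mean
#' `mean_photons` (the exposure-integrated intensity of fully developed
#' speckle with `M` effective speckle modes), then a Poisson photon count
#' with that latent mean. By the law of total variance the count variance is
#' `mean + mean^2 / M`, so the ensemble statistic `(var - mean) / mean^2`
#' recovers `kappa_sq_target`: shot noise and speckle contrast are separable
#' exactly as the noise-corrected pipeline assumes. Pixels are statistically
#' independent and the speckle realisation is redrawn every frame.
#'
#' @param kappa_sq_target Target squared speckle contrast in (0, 1].
#' @param mean_photons Mean photon count per pixel per frame (>= 0).
#' @param n_frames Number of frames.
#' @param shape Sensor shape, rows x cols (default 128 x 128 macropixels).
#' @param seed Integer seed; identical inputs and seed give identical stacks.
#' @param exposure_time,frame_rate,rho Acquisition metadata passed through to
#'   the [frame_stack()].
#' @return A [frame_stack()].
#' @examples
#' st <- generate_speckle_frames(0.25, mean_photons = 20, n_frames = 5,
#'                               shape = c(16, 16), seed = 1)
#' dim(st)
#' @export
generate_speckle_frames <- function(kappa_sq_target, mean_photons,
                                    n_frames, shape = c(128, 128), seed = 1,
                                    exposure_time = 2e-3, frame_rate = 361.7,
                                    rho = 20) {
  stopifnot(is.numeric(kappa_sq_target), length(kappa_sq_target) == 1)
  if (kappa_sq_target <= 0 || kappa_sq_target > 1) {
    stop("kappa_sq_target must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(is.numeric(mean_photons), mean_photons >= 0)
  m_shape <- 1 / kappa_sq_target
  npix <- prod(shape)
  counts <- withr::with_seed(seed, {
    if (mean_photons == 0) {
      array(0L, dim = c(n_frames, shape))
    } else {
      out <- array(0L, dim = c(n_frames, shape))
      for (f in seq_len(n_frames)) {
        latent <- stats::rgamma(npix, shape = m_shape,
                                scale = mean_photons / m_shape)
        out[f, , ] <- stats::rpois(npix, latent)
      }
      out
    }
  })
  frame_stack(counts, exposure_time, frame_rate, rho,
              metadata = list(seed = seed, scenario = "constant",
                              kappa_sq_target = kappa_sq_target,
                              mean_photons = mean_photons))
}

#' Simulate dark frames
#'
#' Pure Poisson dark counts, pixel-independent, with rates given by the
#' materialised per-pixel map of a [dark_model()] (hot pixels included).
#'
#' @param dark A [dark_model()] object.
#' @param n_frames Number of dark frames (typical calibration uses 1000).
#' @param shape Sensor shape.
#' @param seed Integer seed for the Poisson draws (hot-pixel placement is
#'   pinned by the model's `hot_seed`).
#' @param exposure_time,frame_rate Acquisition metadata.
#' @return A [frame_stack()] whose `metadata$hot_index` records the planted
#'   hot pixels (ground truth for detection tests).
#' @export
generate_dark_frames <- function(dark, n_frames = 1000, shape = c(128, 128),
                                 seed = 1, exposure_time = 2e-3,
                                 frame_rate = 361.7) {
  stopifnot(inherits(dark, "dark_model"))
  dm <- dark_rate_map(dark, shape)
  npix <- prod(shape)
  counts <- withr::with_seed(seed, {
    out <- array(0L, dim = c(n_frames, shape))
    for (f in seq_len(n_frames)) {
      out[f, , ] <- stats::rpois(npix, dm$rate_map)
    }
    out
  })
  frame_stack(counts, exposure_time, frame_rate, rho = NA_real_,
              metadata = list(seed = seed, scenario = "dark",
                              hot_index = dm$hot_index,
                              base_rate = dark$base_rate))
}

#' Time-varying flow scenario profiles
#'
#' A scenario profile is a tibble of time points with the underlying flow
#' index `alpha_db` and a segment label; it drives the frame generator so
#' that recovered blood-flow traces can be compared against known ground
#' truth.
#'
#' `cuff_occlusion_profile()` emulates an arterial cuff occlusion: baseline,
#' an occlusion plateau at a small fraction of baseline flow, then a
#' reactive-hyperemia overshoot decaying back towards baseline after
#' release. The default timeline (3.5 s baseline, 7 s occlusion, 4 s
#' recovery) follows the standard protocol for wrist measurements.
#'
#' `task_activation_profile()` emulates a functional activation block: an
#' 8 s rest baseline, a sustained plateau at `1 + task_increase` times
#' baseline flow during the task, and return to baseline afterwards.
#'
#' @param baseline_s,occlusion_s,recovery_s Segment durations, s.
#' @param alpha_db_baseline Baseline flow index, mm^2/s.
#' @param occlusion_fraction Flow during occlusion as a fraction of baseline.
#' @param hyperemia_factor Peak post-release flow as a multiple of baseline.
#' @param hyperemia_tau_s Exponential decay time of the overshoot, s.
#' @param sampling_rate_hz Profile sampling rate (should match the frame
#'   rate of the stack to be generated).
#' @return A tibble of class `scenario_profile` with columns `time_s`,
#'   `alpha_db`, `segment`.
#' @examples
#' cuff_occlusion_profile(sampling_rate_hz = 10)
#' @export
cuff_occlusion_profile <- function(baseline_s = 3.5, occlusion_s = 7,
                                   recovery_s = 4, alpha_db_baseline = 1e-6,
                                   occlusion_fraction = 0.1,
                                   hyperemia_factor = 3,
                                   hyperemia_tau_s = 2,
                                   sampling_rate_hz = 50) {
  total <- baseline_s + occlusion_s + recovery_s
  t <- seq(0, total - 1 / sampling_rate_hz, by = 1 / sampling_rate_hz)
  seg <- dplyr::case_when(
    t < baseline_s ~ "baseline",
    t < baseline_s + occlusion_s ~ "occlusion",
    TRUE ~ "recovery"
  )
  t_rel <- t - (baseline_s + occlusion_s)
  a <- dplyr::case_when(
    seg == "baseline" ~ alpha_db_baseline,
    seg == "occlusion" ~ alpha_db_baseline * occlusion_fraction,
    TRUE ~ alpha_db_baseline *
      (1 + (hyperemia_factor - 1) * exp(-t_rel / hyperemia_tau_s))
  )
  new_scenario_profile(t, a, seg, name = "cuff_occlusion")
}

#' @rdname cuff_occlusion_profile
#' @param task_s Task duration, s.
#' @param task_increase Fractional flow increase during the task (0.08 =
#'   +8 percent).
#' @export
task_activation_profile <- function(baseline_s = 8, task_s = 30,
                                    recovery_s = 10,
                                    alpha_db_baseline = 1e-6,
                                    task_increase = 0.08,
                                    sampling_rate_hz = 50) {
  total <- baseline_s + task_s + recovery_s
  t <- seq(0, total - 1 / sampling_rate_hz, by = 1 / sampling_rate_hz)
  seg <- dplyr::case_when(
    t < baseline_s ~ "baseline",
    t < baseline_s + task_s ~ "task",
    TRUE ~ "recovery"
  )
  a <- ifelse(seg == "task", alpha_db_baseline * (1 + task_increase),
              alpha_db_baseline)
  new_scenario_profile(t, a, seg, name = "task_activation")
}

new_scenario_profile <- function(time_s, alpha_db, segment, name) {
  stopifnot(all(diff(time_s) > 0), all(alpha_db > 0))
  out <- tibble::tibble(time_s = time_s, alpha_db = alpha_db,
                        segment = segment)
  class(out) <- c("scenario_profile", class(out))
  attr(out, "scenario_name") <- name
  out
}

#' Generate a frame stack following a flow scenario
#'
#' For each time point of the profile the forward model converts the
#' instantaneous flow index into a target squared contrast
#' `kappa^2(t) = speckle_contrast_sq(alpha_db(t))`; a gamma-Poisson speckle
#' frame at that contrast is generated and dark counts are added. The
#' returned ground-truth table makes the stack usable for end-to-end
#' recovery tests.
#'
#' @param profile A scenario profile tibble (`time_s`, `alpha_db`,
#'   `segment`).
#' @param optics An [optical_properties()] object.
#' @param geom A [semi_infinite_geometry()] object.
#' @param T_exp Exposure time, s.
#' @param beta Coherence factor.
#' @param mean_photons Mean speckle photons per pixel per frame.
#' @param dark A [dark_model()] or NULL for no dark counts.
#' @param shape Sensor shape.
#' @param seed Integer seed.
#' @return A list with `stack` (a [frame_stack()]) and `truth` (a tibble
#'   `time_s`, `segment`, `alpha_db`, `kappa_sq_true`, `bfi_true`).
#' @export
generate_scenario_stack <- function(profile, optics, geom, T_exp = 2e-3,
                                    beta = 1, mean_photons = 50,
                                    dark = NULL, shape = c(128, 128),
                                    seed = 1) {
  stopifnot(inherits(profile, "scenario_profile"))
  fs <- 1 / mean(diff(profile$time_s))
  # kappa^2 depends on alpha_db only; evaluate once per distinct level
  lv <- unique(profile$alpha_db)
  k_lv <- vapply(lv, function(a) {
    speckle_contrast_sq(optics, flow_params(a, beta), geom, T_exp)
  }, numeric(1))
  kappa_true <- k_lv[match(profile$alpha_db, lv)]
  npix <- prod(shape)
  nfr <- nrow(profile)
  dm <- if (!is.null(dark)) dark_rate_map(dark, shape) else NULL
  counts <- withr::with_seed(seed + 1L, {
    out <- array(0L, dim = c(nfr, shape))
    for (f in seq_len(nfr)) {
      m_shape <- 1 / kappa_true[f]
      latent <- stats::rgamma(npix, shape = m_shape,
                              scale = mean_photons / m_shape)
      if (!is.null(dm)) latent <- latent + dm$rate_map
      out[f, , ] <- stats::rpois(npix, latent)
    }
    out
  })
  stack <- frame_stack(
    counts, exposure_time = T_exp, frame_rate = fs, rho = geom$rho,
    metadata = list(seed = seed,
                    scenario = attr(profile, "scenario_name"),
                    mean_photons = mean_photons,
                    hot_index = if (!is.null(dm)) dm$hot_index else integer(0))
  )
  truth <- tibble::tibble(
    time_s = profile$time_s,
    segment = profile$segment,
    alpha_db = profile$alpha_db,
    kappa_sq_true = kappa_true,
    bfi_true = 1 / kappa_true
  )
  list(stack = stack, truth = truth)
}
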