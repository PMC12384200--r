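#' Write and read photon-count frame stacks
#'
#' The on-disk frame container is a multi-page 16-bit TIFF (one page per
#' frame) with a JSON sidecar (`<path>.json`) carrying the acquisition
#' metadata: `exposure_s`, `frame_rate_fps`, `rho_mm` and the free-form
#' provenance map (seed, scenario, ...). Writing then reading reproduces
#' counts and metadata exactly.
#'
#' @param stack A [frame_stack()] with all counts < 65536.
#' @param path Output TIFF path.
#' @return `write_frames()` returns `path` invisibly; `read_frames()`
#'   returns a [frame_stack()].
#' @export
write_frames <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  if (max(stack$counts) > 65535) {
    stop("counts exceed 16-bit TIFF range (65535)", call. = FALSE)
  }
  nfr <- dim(stack$counts)[1]
  pages <- lapply(seq_len(nfr), function(f) stack$counts[f, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  meta <- c(
    list(exposure_s = stack$exposure_time,
         frame_rate_fps = stack$frame_rate,
         rho_mm = stack$rho),
    stack$metadata
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing metadata sidecar: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (key in c("exposure_s", "frame_rate_fps", "rho_mm")) {
    if (is.null(meta[[key]])) {
      stop("frame metadata is missing required key \"", key, "\"",
           call. = FALSE)
    }
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nfr <- length(pages)
  d <- dim(pages[[1]])
  counts <- array(0L, dim = c(nfr, d[1], d[2]))
  for (f in seq_len(nfr)) {
    counts[f, , ] <- as.integer(round(pages[[f]] * 65535))
  }
  extra <- meta[setdiff(names(meta),
                        c("exposure_s", "frame_rate_fps", "rho_mm"))]
  rho <- if (is.null(meta$rho_mm) || is.na(meta$rho_mm)) NA_real_ else meta$rho_mm
  frame_stack(counts, exposure_time = meta$exposure_s,
              frame_rate = meta$frame_rate_fps, rho = rho,
              metadata = extra)
}

#' Write a contrast series with a JSON summary sidecar
#'
#' CSV columns are `time_s`, `kappa_m_sq`, `kappa_c_sq`, `bfi`, `rbfi`
#' (when present), `mean_intensity`; the sidecar (`<path>.json`) records
#' the noise-budget summary, number of flagged pixels, acquisition metadata
#' and package version, so every output carries its provenance.
#'
#' @param series A `contrast_series` tibble.
#' @param path Output CSV path.
#' @param extra Named list merged into the JSON summary (e.g. config echo).
#' @return `path`, invisibly.
#' @export
write_contrast_series <- function(series, path, extra = list()) {
  stopifnot(is.data.frame(series))
  readr::write_csv(series, path)
  summary <- c(
    list(
      n_frames = nrow(series),
      n_flagged = attr(series, "n_flagged") %||% NA_integer_,
      frame_rate_fps = attr(series, "frame_rate") %||% NA_real_,
      exposure_s = attr(series, "exposure_s") %||% NA_real_,
      rho_mm = attr(series, "rho_mm") %||% NA_real_,
      baseline_window = attr(series, "baseline_window"),
      n_negative_kappa_c = sum(series$kappa_c_sq < 0, na.rm = TRUE),
      mean_kappa_c_sq = mean(series$kappa_c_sq, na.rm = TRUE),
      package_version = as.character(utils::packageVersion("speckleflow"))
    ),
    extra
  )
  jsonlite::write_json(summary, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_contrast_series
#' @export
read_contrast_series <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  class(out) <- c("contrast_series", class(out))
  out
}

#' Run the simulate / process / analyze chain from one configuration
#'
#' Orchestrates the whole desk-scale study: generate a scenario frame stack
#' and dark stack, estimate dark statistics, flag hot pixels, compute the
#' noise-corrected contrast series, baseline-normalize and smooth it, and
#' write the series CSV plus a JSON run summary. Every random draw flows
#' from the single configured seed, so re-runs are bit-identical.
#'
#' @param config Named list with (all optional, defaults shown by
#'   [default_run_config()]): `seed`, `scenario` ("cuff_occlusion" or
#'   "task_activation"), `mean_photons`, `sampling_rate_hz`, `shape`,
#'   `rho_mm`, `exposure_ms`, `beta`, optics fields (`mua_mm`, `musp_mm`,
#'   `n`, `wavelength_nm`), dark fields (`dark_rate`, `hot_fraction`,
#'   `hot_multiplier`, `n_dark_frames`), `baseline_window`,
#'   `smooth_window`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `series`, `truth`, `summary`, and the
#'   output paths.
#' @export
run_pipeline <- function(config = list(), out_dir = tempdir()) {
  cfg <- utils::modifyList(default_run_config(), config)
  if (is.null(cfg$seed)) stop("config$seed is mandatory", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  optics <- optical_properties(cfg$mua_mm, cfg$musp_mm, cfg$n,
                               cfg$wavelength_nm)
  geom <- semi_infinite_geometry(cfg$rho_mm, optics)
  profile <- switch(
    cfg$scenario,
    cuff_occlusion = cuff_occlusion_profile(
      alpha_db_baseline = cfg$alpha_db_baseline,
      sampling_rate_hz = cfg$sampling_rate_hz),
    task_activation = task_activation_profile(
      alpha_db_baseline = cfg$alpha_db_baseline,
      task_increase = cfg$task_increase,
      sampling_rate_hz = cfg$sampling_rate_hz),
    stop("unknown scenario: ", cfg$scenario, call. = FALSE)
  )
  if (cfg$baseline_window[2] > max(profile$time_s)) {
    stop("baseline window extends beyond the simulated series", call. = FALSE)
  }

  dark <- dark_model(cfg$dark_rate, cfg$hot_fraction, cfg$hot_multiplier,
                     hot_seed = cfg$seed)
  dark_stack <- generate_dark_frames(dark, cfg$n_dark_frames,
                                     shape = cfg$shape, seed = cfg$seed,
                                     exposure_time = cfg$exposure_ms * 1e-3,
                                     frame_rate = cfg$sampling_rate_hz)
  sim <- generate_scenario_stack(
    profile, optics, geom, T_exp = cfg$exposure_ms * 1e-3, beta = cfg$beta,
    mean_photons = cfg$mean_photons, dark = dark, shape = cfg$shape,
    seed = cfg$seed + 1L
  )
  dk <- estimate_dark_statistics(dark_stack)
  mask <- flag_bad_pixels(dk$mean_map)
  series <- process_frames(sim$stack, dk, mask)
  series <- normalize_bfi(series, cfg$baseline_window)
  series <- smooth_series(series, cols = c("bfi", "rbfi"),
                          window = cfg$smooth_window)

  series_path <- file.path(out_dir, "series.csv")
  write_contrast_series(series, series_path,
                        extra = list(config = cfg[order(names(cfg))]))
  truth_path <- file.path(out_dir, "truth.csv")
  readr::write_csv(sim$truth, truth_path)
  summary <- jsonlite::read_json(paste0(series_path, ".json"),
                                 simplifyVector = TRUE)
  invisible(list(series = series, truth = sim$truth, summary = summary,
                 series_path = series_path, truth_path = truth_path))
}

#' @rdname run_pipeline
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    scenario = "cuff_occlusion",
    alpha_db_baseline = 1e-6,
    task_increase = 0.08,
    mean_photons = 50,
    sampling_rate_hz = 50,
    shape = c(128, 128),
    rho_mm = 20,
    exposure_ms = 2,
    beta = 1,
    mua_mm = 0.01,
    musp_mm = 1,
    n = 1.33,
    wavelength_nm = 785,
    dark_rate = 2,
    hot_fraction = 0.01,
    hot_multiplier = 50,
    n_dark_frames = 200,
    baseline_window = c(0, 3.5),
    smooth_window = 20
  )
}

#' Read a run configuration from a YAML file
#'
#' Flat YAML keys mirroring [default_run_config()]; unknown keys are
#' rejected so typos fail loudly before any processing starts.
#'
#' @param path YAML file path.
#' @return A named list suitable for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(default_run_config()))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
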