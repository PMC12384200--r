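#' Per-pixel dark statistics from a dark stack
#'
#' Temporal mean and unbiased variance of each pixel over a stack of
#' laser-off frames. The mean map is the dark offset subtracted from raw
#' intensity frames; the variance map supplies the dark-noise term of the
#' contrast correction.
#'
#' @param dark_stack A [frame_stack()] of dark frames (>= 2 frames).
#' @return An object of class `dark_statistics`: list with `mean_map`,
#'   `var_map` (matrices) and `n_frames_used`.
#' @export
estimate_dark_statistics <- function(dark_stack) {
  stopifnot(inherits(dark_stack, "frame_stack"))
  nfr <- n_frames(dark_stack)
  if (nfr < 2) {
    stop("at least 2 dark frames are needed to estimate a variance",
         call. = FALSE)
  }
  x <- dark_stack$counts
  mean_map <- colMeans(x, dims = 1)
  # unbiased per-pixel variance: E[x^2] - mean^2, scaled n/(n-1)
  sq_mean <- colMeans(x^2, dims = 1)
  var_map <- (sq_mean - mean_map^2) * nfr / (nfr - 1)
  var_map[var_map < 0] <- 0  # numerical guard
  structure(
    list(mean_map = mean_map, var_map = var_map, n_frames_used = nfr),
    class = "dark_statistics"
  )
}

#' @export
print.dark_statistics <- function(x, ...) {
  cat(sprintf(
    "<dark_statistics> %d frames, mean dark %.3f counts/pixel, mean var %.3f\n",
    x$n_frames_used, mean(x$mean_map), mean(x$var_map)
  ))
  invisible(x)
}

#' Flag outlier ("hot") pixels by the 3-sigma rule
#'
#' Pixels whose value in the reference image deviates from the image mean by
#' more than `n_sigma` standard deviations (mean and SD taken over all
#' pixels of the reference) are flagged and excluded from every downstream
#' statistic. The canonical reference is the per-pixel mean dark image, in
#' which hot pixels stand out by their elevated dark counts; an intensity
#' frame can be supplied instead to apply the rule to frame data directly.
#'
#' @param reference_image Numeric matrix of per-pixel reference values.
#' @param n_sigma Threshold in standard deviations (default 3).
#' @return An object of class `pixel_mask`: list with `valid` (logical
#'   matrix, FALSE = flagged), `n_flagged` and `rule`.
#' @examples
#' ref <- matrix(10, 8, 8); ref[5, 5] <- 1000
#' flag_bad_pixels(ref)$n_flagged
#' @export
flag_bad_pixels <- function(reference_image, n_sigma = 3) {
  stopifnot(is.matrix(reference_image), all(is.finite(reference_image)))
  mu <- mean(reference_image)
  sg <- stats::sd(reference_image)
  valid <- if (sg == 0) {
    matrix(TRUE, nrow(reference_image), ncol(reference_image))
  } else {
    abs(reference_image - mu) <= n_sigma * sg
  }
  structure(
    list(valid = valid, n_flagged = sum(!valid),
         rule = sprintf("|I - mean| > %g sd over reference image", n_sigma)),
    class = "pixel_mask"
  )
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("<pixel_mask> %d / %d pixels flagged (%s)\n",
              x$n_flagged, length(x$valid), x$rule))
  invisible(x)
}

#' Noise-corrected ensemble speckle contrast of one frame
#'
#' Computes, over the valid pixels of a single frame, the measured squared
#' contrast and its noise-corrected counterpart:
#' \deqn{\kappa_m^2 = \frac{Var(I_c)}{\langle I_c\rangle^2}, \qquad
#'   \kappa_c^2 = \frac{Var(I_c) - \bar\sigma_D^2 - \langle I_c\rangle}
#'                     {\langle I_c\rangle^2}}
#' where `Ic = I - dark mean` per pixel, `Var` is the sample variance over
#' the pixel ensemble (the full valid array, not a local window),
#' `sigma_D^2` is the dark variance averaged over valid pixels, and the
#' subtracted mean is the Poisson shot-noise variance (counts are photon
#' units on a photon-counting array, so shot variance equals the mean).
#' Read-noise and quantization terms are identically zero for a
#' single-photon detector.
#'
#' A negative corrected contrast (noise over-subtraction at low signal) is
#' returned as-is and flagged; a non-positive mean corrected intensity makes
#' the contrast undefined and yields `NA`.
#'
#' @param frame 2-D numeric matrix of photon counts.
#' @param dark A `dark_statistics` object, or NULL for zero dark.
#' @param mask A `pixel_mask`, or NULL for all-valid.
#' @return A list with `kappa_m_sq`, `kappa_c_sq`, `mean_intensity`, and
#'   `noise_budget` (components `kappa_s_sq`, `kappa_d_sq`, `kappa_r_sq`,
#'   `kappa_q_sq`).
#' @export
corrected_contrast_sq <- function(frame, dark = NULL, mask = NULL) {
  stopifnot(is.matrix(frame))
  if (!is.null(dark)) {
    stopifnot(inherits(dark, "dark_statistics"),
              all(dim(dark$mean_map) == dim(frame)))
  }
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "pixel_mask"),
              all(dim(mask$valid) == dim(frame)))
  }
  valid <- if (is.null(mask)) rep(TRUE, length(frame)) else as.vector(mask$valid)
  if (sum(valid) < 2) {
    stop("fewer than 2 valid pixels: contrast undefined", call. = FALSE)
  }
  ic <- if (is.null(dark)) frame[valid] else (frame - dark$mean_map)[valid]
  dark_var <- if (is.null(dark)) 0 else mean(dark$var_map[valid])
  mi <- mean(ic)
  if (mi <= 0) {
    return(list(kappa_m_sq = NA_real_, kappa_c_sq = NA_real_,
                mean_intensity = mi,
                noise_budget = list(kappa_s_sq = NA_real_,
                                    kappa_d_sq = NA_real_,
                                    kappa_r_sq = 0, kappa_q_sq = 0)))
  }
  v <- stats::var(ic)
  kappa_m_sq <- v / mi^2
  kappa_s_sq <- 1 / mi               # shot noise: variance = mean intensity
  kappa_d_sq <- dark_var / mi^2
  kappa_c_sq <- kappa_m_sq - kappa_s_sq - kappa_d_sq
  list(kappa_m_sq = kappa_m_sq, kappa_c_sq = kappa_c_sq,
       mean_intensity = mi,
       noise_budget = list(kappa_s_sq = kappa_s_sq, kappa_d_sq = kappa_d_sq,
                           kappa_r_sq = 0, kappa_q_sq = 0))
}

#' Local-window speckle contrast map
#'
#' Compatibility mode for workflows that compute contrast over small sliding
#' windows (3x3, 5x5, 7x7) instead of the full pixel array: returns the
#' per-pixel map of measured squared contrast, each entry the sample
#' variance over its centered `window x window` neighbourhood divided by
#' the squared neighbourhood mean. Masked pixels are excluded from every
#' neighbourhood; windows shrink at the array edges. The ensemble
#' statistic over the full array ([corrected_contrast_sq()]) is the
#' recommended estimator — local windows trade statistical power for
#' spatial resolution.
#'
#' @param frame 2-D numeric matrix of photon counts.
#' @param dark A `dark_statistics` object, or NULL.
#' @param mask A `pixel_mask`, or NULL.
#' @param window Odd window edge length (default 7).
#' @return Matrix of local `kappa_m^2` values (NA where the neighbourhood
#'   has fewer than 2 valid pixels or non-positive mean).
#' @export
local_contrast_sq <- function(frame, dark = NULL, mask = NULL, window = 7) {
  stopifnot(is.matrix(frame), window >= 3, window %% 2 == 1)
  ic <- if (is.null(dark)) frame else frame - dark$mean_map
  if (!is.null(mask)) ic[!mask$valid] <- NA
  h <- (window - 1) / 2
  nr <- nrow(ic); nc <- ncol(ic)
  # neighbourhood sums of values, squares and counts via shifted additions
  s <- s2 <- cnt <- matrix(0, nr, nc)
  ok <- !is.na(ic)
  v <- ifelse(ok, ic, 0)
  for (di in -h:h) {
    ri_dst <- max(1, 1 - di):min(nr, nr - di)
    ri_src <- ri_dst + di
    for (dj in -h:h) {
      cj_dst <- max(1, 1 - dj):min(nc, nc - dj)
      cj_src <- cj_dst + dj
      s[ri_dst, cj_dst] <- s[ri_dst, cj_dst] + v[ri_src, cj_src]
      s2[ri_dst, cj_dst] <- s2[ri_dst, cj_dst] + v[ri_src, cj_src]^2
      cnt[ri_dst, cj_dst] <- cnt[ri_dst, cj_dst] + ok[ri_src, cj_src]
    }
  }
  mu <- s / cnt
  varl <- (s2 - cnt * mu^2) / (cnt - 1)
  out <- varl / mu^2
  out[cnt < 2 | mu <= 0] <- NA
  out
}

#' Blood flow index from corrected contrast
#'
#' `BFi = 1 / kappa_c^2`. Vectorised; non-positive or missing contrast
#' yields `NA` (never infinity), since an over-subtracted contrast carries
#' no flow information.
#'
#' @param kappa_c_sq Numeric vector of corrected squared contrasts.
#' @return Numeric vector of blood flow indices.
#' @examples
#' bfi_from_contrast(c(0.25, 1, -0.01))
#' @export
bfi_from_contrast <- function(kappa_c_sq) {
  out <- ifelse(is.na(kappa_c_sq) | kappa_c_sq <= 0, NA_real_,
                1 / kappa_c_sq)
  as.numeric(out)
}

#' Process a frame stack into a contrast time series
#'
#' Runs the full per-frame chain: dark subtraction, bad-pixel exclusion,
#' noise-corrected ensemble contrast, and blood flow index, returning one
#' row per frame.
#'
#' @param stack A [frame_stack()] of intensity frames.
#' @param dark_stats A `dark_statistics` object (or NULL: no dark
#'   correction).
#' @param mask A `pixel_mask`; when NULL and `dark_stats` is given, the mask
#'   is derived from the dark mean map via [flag_bad_pixels()]; when both
#'   are NULL, all pixels are valid.
#' @return A tibble of class `contrast_series` with columns `time_s`,
#'   `kappa_m_sq`, `kappa_c_sq`, `bfi`, `mean_intensity`; attributes carry
#'   the mask summary and acquisition metadata.
#' @export
process_frames <- function(stack, dark_stats = NULL, mask = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(mask) && !is.null(dark_stats)) {
    mask <- flag_bad_pixels(dark_stats$mean_map)
  }
  nfr <- n_frames(stack)
  res <- purrr::map(seq_len(nfr), function(f) {
    cc <- corrected_contrast_sq(stack$counts[f, , ], dark_stats, mask)
    tibble::tibble(kappa_m_sq = cc$kappa_m_sq, kappa_c_sq = cc$kappa_c_sq,
                   mean_intensity = cc$mean_intensity)
  })
  out <- dplyr::bind_rows(res)
  out <- dplyr::mutate(
    out,
    time_s = (seq_len(nfr) - 1) / stack$frame_rate,
    bfi = bfi_from_contrast(.data$kappa_c_sq),
    .before = 1
  )
  out <- out[, c("time_s", "kappa_m_sq", "kappa_c_sq", "bfi",
                 "mean_intensity")]
  class(out) <- c("contrast_series", class(out))
  attr(out, "n_flagged") <- if (is.null(mask)) 0L else mask$n_flagged
  attr(out, "frame_rate") <- stack$frame_rate
  attr(out, "exposure_s") <- stack$exposure_time
  attr(out, "rho_mm") <- stack$rho
  out
}

#' Baseline-normalize a blood flow series
#'
#' Adds `rbfi = bfi / mean(bfi over the baseline window)` so that traces
#' from different subjects or separations are comparable; by construction
#' the baseline-window mean of `rbfi` is 1.
#'
#' @param series A `contrast_series` tibble (or any data frame with
#'   `time_s` and `bfi`).
#' @param baseline_window Length-2 numeric, `[start, end)` in seconds
#'   (default the first 3.5 s).
#' @return The input with an `rbfi` column added.
#' @export
normalize_bfi <- function(series, baseline_window = c(0, 3.5)) {
  stopifnot(is.data.frame(series),
            all(c("time_s", "bfi") %in% names(series)),
            length(baseline_window) == 2,
            baseline_window[2] > baseline_window[1])
  in_base <- series$time_s >= baseline_window[1] &
    series$time_s < baseline_window[2]
  if (!any(in_base)) {
    stop("baseline window [", baseline_window[1], ", ", baseline_window[2],
         ") contains no samples", call. = FALSE)
  }
  base <- mean(series$bfi[in_base], na.rm = TRUE)
  if (!is.finite(base) || base <= 0) {
    stop("baseline mean BFi is not positive; cannot normalize",
         call. = FALSE)
  }
  out <- dplyr::mutate(series, rbfi = .data$bfi / base)
  attr(out, "baseline_window") <- baseline_window
  attr(out, "bfi_baseline") <- base
  out
}

#' Centered moving-average smoothing
#'
#' Smooths one or more series columns with a centered moving average of
#' `window` samples, the standard noise-reduction step before visualising
#' blood-flow dynamics. Windows shrink at the edges so the output length
#' equals the input length, and missing values are excluded from each
#' window's average.
#'
#' @param series A data frame.
#' @param cols Character vector of column names to smooth (default every
#'   series column present among `kappa_m_sq`, `kappa_c_sq`, `bfi`,
#'   `rbfi`).
#' @param window Window length in samples (default 20).
#' @return The input with the named columns replaced by their smoothed
#'   versions.
#' @export
smooth_series <- function(series, cols = NULL, window = 20) {
  stopifnot(is.data.frame(series), window >= 1)
  if (window > nrow(series)) {
    stop("smoothing window (", window, ") exceeds series length (",
         nrow(series), ")", call. = FALSE)
  }
  if (is.null(cols)) {
    cols <- intersect(c("kappa_m_sq", "kappa_c_sq", "bfi", "rbfi"),
                      names(series))
  }
  stopifnot(all(cols %in% names(series)))
  for (cl in cols) {
    series[[cl]] <- moving_average(series[[cl]], window)
  }
  series
}

# centered moving average, shrink-at-edges, NA-excluding
moving_average <- function(x, window) {
  n <- length(x)
  half_lo <- floor((window - 1) / 2)
  half_hi <- ceiling((window - 1) / 2)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half_lo)
    hi <- min(n, i + half_hi)
    w <- x[lo:hi]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}
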