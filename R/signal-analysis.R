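#' Welch power spectral density estimate
#'
#' Averaged-periodogram spectral estimate: the series is cut into
#' overlapping segments, each segment is mean-detrended, tapered with a
#' window function, and its periodogram computed; the periodograms are
#' averaged and scaled as a one-sided density (power per Hz), so that the
#' integral of the PSD over frequency approximates the series variance.
#'
#' @param series Numeric vector, or a data frame with a `bfi` column (a
#'   `contrast_series`), in which case `sampling_rate` defaults to its
#'   `frame_rate` attribute.
#' @param sampling_rate Sampling rate, Hz.
#' @param segment_length Samples per segment (default 256).
#' @param overlap_fraction Fractional overlap between segments (default
#'   0.5).
#' @param window_name Taper: `"hann"` or `"rectangular"`.
#' @param detrend Subtract each segment's mean before tapering (default
#'   TRUE; with the mean retained the DC bin carries the squared mean).
#' @return A tibble of class `psd_estimate` with columns `frequency_hz`,
#'   `power`; attributes `n_segments`, `segment_length`,
#'   `overlap_fraction`, `window_name`, `sampling_rate`.
#' @examples
#' x <- sin(2 * pi * 5 * (0:999) / 100)
#' p <- welch_psd(x, sampling_rate = 100, segment_length = 128)
#' p$frequency_hz[which.max(p$power)]  # 5 Hz
#' @export
welch_psd <- function(series, sampling_rate = NULL, segment_length = 256,
                      overlap_fraction = 0.5,
                      window_name = c("hann", "rectangular"),
                      detrend = TRUE) {
  if (is.data.frame(series)) {
    if (is.null(sampling_rate)) sampling_rate <- attr(series, "frame_rate")
    series <- series$bfi
  }
  stopifnot(is.numeric(series), is.numeric(sampling_rate),
            sampling_rate > 0)
  window_name <- match.arg(window_name)
  n <- length(series)
  nseg <- as.integer(segment_length)
  if (nseg > n) {
    stop("segment_length (", nseg, ") exceeds series length (", n, ")",
         call. = FALSE)
  }
  stopifnot(overlap_fraction >= 0, overlap_fraction < 1)
  step <- max(1L, as.integer(round(nseg * (1 - overlap_fraction))))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- switch(window_name,
              hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1) / nseg),
              rectangular = rep(1, nseg))
  u <- sum(w^2)  # window power normalisation
  nfreq <- nseg %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- series[s:(s + nseg - 1L)]
    if (detrend) seg <- seg - mean(seg)
    ft <- stats::fft(seg * w)
    pxx <- Mod(ft[seq_len(nfreq)])^2 / (sampling_rate * u)
    # one-sided: double everything except DC and (for even nseg) Nyquist
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[nfreq] <- 1
    acc <- acc + pxx * dbl
  }
  out <- tibble::tibble(
    frequency_hz = (seq_len(nfreq) - 1L) * sampling_rate / nseg,
    power = acc / length(starts)
  )
  class(out) <- c("psd_estimate", class(out))
  attr(out, "n_segments") <- length(starts)
  attr(out, "segment_length") <- nseg
  attr(out, "overlap_fraction") <- overlap_fraction
  attr(out, "window_name") <- window_name
  attr(out, "sampling_rate") <- sampling_rate
  out
}

#' Signal-to-noise ratio in decibels
#'
#' `SNR = 20 log10(S / N)` on the amplitude convention used for
#' photon-counting signals. For a blood-flow trace the operational choice
#' `S = mean, N = standard deviation` over a stationary segment is provided
#' by [series_snr_db()]; this function takes the two estimates directly.
#'
#' @param signal_estimate Positive signal amplitude S.
#' @param noise_estimate Positive noise amplitude N.
#' @return SNR in dB.
#' @examples
#' snr_db(10, 1)  # 20 dB
#' @export
snr_db <- function(signal_estimate, noise_estimate) {
  if (any(signal_estimate <= 0) || any(noise_estimate <= 0)) {
    stop("signal and noise estimates must be positive", call. = FALSE)
  }
  20 * log10(signal_estimate / noise_estimate)
}

#' @rdname snr_db
#' @param x Numeric vector: a stationary segment of a series (NAs dropped).
#' @export
series_snr_db <- function(x) {
  x <- x[!is.na(x)]
  snr_db(mean(x), stats::sd(x))
}

#' Peak-envelope trend of a series
#'
#' Upper and lower envelopes interpolated through local maxima/minima
#' separated by at least `window` samples (spline interpolation, endpoints
#' pinned to the series values to avoid extrapolation blow-up), and their
#' midline `trend = (upper + lower) / 2` — a smooth trend estimate robust
#' to oscillatory (e.g. cardiac) content riding on the signal.
#'
#' @param series Numeric vector, or data frame with a value column.
#' @param window Minimum peak separation in samples (default 250).
#' @param value_col Column holding the series when `series` is a data frame
#'   (default `"bfi"`).
#' @return A tibble of class `envelope_trend` with columns `index`,
#'   `value`, `upper`, `lower`, `trend` (plus `time_s` when present in the
#'   input).
#' @export
envelope_trend <- function(series, window = 250, value_col = "bfi") {
  time_s <- NULL
  if (is.data.frame(series)) {
    if ("time_s" %in% names(series)) time_s <- series$time_s
    series <- series[[value_col]]
  }
  stopifnot(is.numeric(series), window >= 1)
  n <- length(series)
  if (n <= window) {
    stop("series length (", n, ") must exceed the envelope window (",
         window, ")", call. = FALSE)
  }
  upper <- envelope_one_side(series, window, upper = TRUE)
  lower <- envelope_one_side(series, window, upper = FALSE)
  # guard against spline crossings from sparse extrema
  swap <- upper < lower
  if (any(swap)) {
    tmp <- upper[swap]
    upper[swap] <- lower[swap]
    lower[swap] <- tmp
  }
  out <- tibble::tibble(
    index = seq_len(n), value = series,
    upper = upper, lower = lower, trend = (upper + lower) / 2
  )
  if (!is.null(time_s)) out <- dplyr::mutate(out, time_s = time_s, .before = 1)
  class(out) <- c("envelope_trend", class(out))
  attr(out, "window") <- window
  out
}

# spline through local extrema with minimum separation `window`;
# endpoints pinned to the series values
envelope_one_side <- function(x, window, upper = TRUE) {
  n <- length(x)
  y <- if (upper) x else -x
  d <- diff(y)
  # strict local maxima of y (plateaus: take first point)
  cand <- which(c(FALSE, d > 0) & c(d <= 0, FALSE))
  # enforce minimum separation, keeping the larger peak greedily
  if (length(cand) > 1) {
    keep <- cand[order(-y[cand])]
    sel <- integer(0)
    for (i in keep) {
      if (all(abs(i - sel) >= window)) sel <- c(sel, i)
    }
    cand <- sort(sel)
  }
  knots_x <- unique(c(1L, cand, n))
  knots_y <- y[knots_x]
  if (length(knots_x) < 2) return(rep(x[1], n))
  env <- stats::spline(knots_x, knots_y, xout = seq_len(n),
                       method = "fmm")$y
  if (upper) env else -env
}

#' Percent change of a trend relative to an initial baseline
#'
#' `100 * (trend - baseline) / baseline`, with the baseline taken as the
#' mean of the trend over an initial time window (default the first 8 s) —
#' the standard way of expressing task-evoked blood-flow changes.
#'
#' @param trend_series Data frame with `time_s` and a `trend` column (an
#'   [envelope_trend()] result carrying `time_s`), or a numeric trend
#'   vector with `time_s` supplied separately.
#' @param baseline_window Length-2 numeric `[start, end)` in seconds.
#' @param time_s Time stamps when `trend_series` is a plain vector.
#' @return A tibble with `time_s`, `trend`, `percent_change`.
#' @export
percent_change <- function(trend_series, baseline_window = c(0, 8),
                           time_s = NULL) {
  if (is.data.frame(trend_series)) {
    stopifnot(all(c("time_s", "trend") %in% names(trend_series)))
    tt <- trend_series$time_s
    tr <- trend_series$trend
  } else {
    stopifnot(is.numeric(trend_series), !is.null(time_s))
    tt <- time_s
    tr <- trend_series
  }
  in_base <- tt >= baseline_window[1] & tt < baseline_window[2]
  if (!any(in_base)) {
    stop("baseline window contains no samples", call. = FALSE)
  }
  base <- mean(tr[in_base], na.rm = TRUE)
  if (!is.finite(base) || base == 0) {
    stop("baseline mean is zero or undefined; percent change not defined",
         call. = FALSE)
  }
  tibble::tibble(
    time_s = tt, trend = tr,
    percent_change = 100 * (tr - base) / base
  )
}
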