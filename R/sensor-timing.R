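#' Photon-counting acquisition timing configuration
#'
#' The SPAD camera's photon-counting mode exposes three timing controls: the
#' pixel clock frequency, the number of clock periods per accumulation bin
#' (which fixes the minimum exposure), and the number of on-chip accumulation
#' iterations. Exposure time is `iterations * tbin_clk_periods /
#' clock_frequency`; a fixed frame readout time is added to give the frame
#' time, whose reciprocal is the frame rate.
#'
#' @param clock_frequency Pixel clock in Hz (default 20 MHz).
#' @param tbin_clk_periods Clock periods per accumulation bin (>= 1,
#'   default 32).
#' @param tint_tbin_iterations Number of on-chip accumulations, in
#'   `[1, 65535]`.
#' @param readout_time Frame readout time in seconds (default 1.1264 ms).
#' @return An object of class `timing_config`.
#' @examples
#' timing_config(tint_tbin_iterations = 1024)
#' @export
timing_config <- function(clock_frequency = 20e6, tbin_clk_periods = 32,
                          tint_tbin_iterations = 1024,
                          readout_time = 1.1264e-3) {
  stopifnot(is.numeric(clock_frequency), clock_frequency > 0)
  stopifnot(is.numeric(tbin_clk_periods), tbin_clk_periods >= 1)
  stopifnot(is.numeric(tint_tbin_iterations),
            tint_tbin_iterations >= 1, tint_tbin_iterations <= 65535)
  stopifnot(is.numeric(readout_time), readout_time >= 0)
  structure(
    list(clock_frequency = clock_frequency,
         tbin_clk_periods = tbin_clk_periods,
         tint_tbin_iterations = tint_tbin_iterations,
         readout_time = readout_time),
    class = "timing_config"
  )
}

#' @export
print.timing_config <- function(x, ...) {
  cat(sprintf(
    "<timing_config> clock %g MHz, %g periods/bin, %g iterations, readout %g s\n",
    x$clock_frequency / 1e6, x$tbin_clk_periods, x$tint_tbin_iterations,
    x$readout_time
  ))
  cat(sprintf("  exposure %.6g s, frame time %.6g s, %.1f fps\n",
              exposure_time(x), frame_time(x), frame_rate(x)))
  invisible(x)
}

#' Exposure, frame time and frame rate of a timing configuration
#'
#' `exposure_time()` is `iterations * tbin_clk_periods / clock_frequency`;
#' `frame_time()` adds the readout time; `frame_rate()` is `1 / frame_time()`.
#'
#' @param cfg A [timing_config()] object.
#' @return A scalar in seconds (`exposure_time`, `frame_time`) or frames per
#'   second (`frame_rate`).
#' @examples
#' cfg <- timing_config(tint_tbin_iterations = 32)
#' exposure_time(cfg)  # 51.2 microseconds
#' frame_rate(cfg)     # 849.2 fps
#' @export
exposure_time <- function(cfg) {
  stopifnot(inherits(cfg, "timing_config"))
  cfg$tint_tbin_iterations * cfg$tbin_clk_periods / cfg$clock_frequency
}

#' @rdname exposure_time
#' @export
frame_time <- function(cfg) {
  exposure_time(cfg) + cfg$readout_time
}

#' @rdname exposure_time
#' @export
frame_rate <- function(cfg) {
  1 / frame_time(cfg)
}

#' Acquisition-timing table across accumulation settings
#'
#' Tabulate exposure time, frame readout time, frame time and frame rate for
#' a set of accumulation counts at fixed clock settings. The default
#' iteration sweep covers the powers of two from 32 to 4096 that span the
#' practical photon-counting operating range at a 20 MHz clock. Frame rates
#' are rounded half-up to one decimal, the precision at which they are
#' usually quoted.
#'
#' @param iterations Integer vector of accumulation counts.
#' @param clock_frequency Pixel clock, Hz.
#' @param tbin_clk_periods Clock periods per bin.
#' @param readout_time Frame readout time, s.
#' @return A tibble with columns `tint_tbin_iterations`, `exposure_s`,
#'   `readout_s`, `frame_time_s`, `frame_rate_fps`.
#' @examples
#' timing_table()
#' @export
timing_table <- function(iterations = c(32, 64, 128, 256, 512, 1024, 2048, 4096),
                         clock_frequency = 20e6, tbin_clk_periods = 32,
                         readout_time = 1.1264e-3) {
  rows <- purrr::map(iterations, function(it) {
    cfg <- timing_config(clock_frequency, tbin_clk_periods, it, readout_time)
    tibble::tibble(
      tint_tbin_iterations = it,
      exposure_s = exposure_time(cfg),
      readout_s = cfg$readout_time,
      frame_time_s = frame_time(cfg),
      frame_rate_fps = round_half_up(frame_rate(cfg), 1)
    )
  })
  dplyr::bind_rows(rows)
}

# round half away from zero at `digits` decimals (presentation rounding for
# frame rates; base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
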