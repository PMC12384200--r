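#' Field autocorrelation on a semi-infinite dynamic turbid medium
#'
#' Normalized electric-field temporal autocorrelation `g1(rho, tau)` for a
#' point source on a half space of Brownian scatterers, from the
#' extrapolated-boundary Green's function
#' \deqn{G_1(\rho,\tau) \propto \frac{e^{-K(\tau) r_1}}{r_1} -
#'       \frac{e^{-K(\tau) r_b}}{r_b}, \quad
#'       K(\tau) = \sqrt{3\mu_a\mu_s' + 6\mu_s'^2 k_0^2 \alpha D_b \tau}}
#' normalized so that `g1(rho, 0) = 1`. The Brownian mean-square displacement
#' model `<dr^2> = 6 alpha_db tau` is assumed.
#'
#' @param optics An [optical_properties()] object.
#' @param flow A [flow_params()] object (only `alpha_db` is used).
#' @param geom A [semi_infinite_geometry()] object.
#' @param tau Lag times in seconds (vectorised, all >= 0).
#' @return Numeric vector of `g1` values in (0, 1], non-increasing in `tau`.
#' @examples
#' op <- optical_properties()
#' g1_semi_infinite(op, flow_params(1e-6), semi_infinite_geometry(20, op),
#'                  tau = c(0, 1e-5, 1e-4, 1e-3))
#' @export
g1_semi_infinite <- function(optics, flow, geom, tau) {
  stopifnot(inherits(optics, "optical_properties"),
            inherits(flow, "flow_params"),
            inherits(geom, "semi_infinite_geometry"))
  stopifnot(is.numeric(tau), all(tau >= 0))
  k0 <- wavenumber(optics)
  kk <- sqrt(3 * optics$mua * optics$musp +
               6 * optics$musp^2 * k0^2 * flow$alpha_db * tau)
  g1_unnorm <- function(k) {
    exp(-k * geom$r1) / geom$r1 - exp(-k * geom$rb) / geom$rb
  }
  k_static <- sqrt(3 * optics$mua * optics$musp)
  g1_unnorm(kk) / g1_unnorm(k_static)
}

#' Exposure-integrated contrast of an arbitrary decorrelation kernel
#'
#' Squared speckle contrast accumulated over a finite exposure `T`:
#' \deqn{\kappa^2(T) = \frac{2\beta}{T}\int_0^T
#'   \left(1 - \frac{\tau}{T}\right) g_1(\tau)^2\, d\tau.}
#' Exposed separately from [speckle_contrast_sq()] so that analytic test
#' kernels (e.g. a single-exponential `g1`) can be integrated with the same
#' quadrature.
#'
#' The integrand can span many scales when `g1` collapses at lags far below
#' `T`; the interval is split at the lag where `g1^2` falls below 1e-12
#' (located by bisection) and each piece is handled by adaptive quadrature at
#' relative tolerance `rel_tol`.
#'
#' @param g1_fun Function of lag time (s) returning the normalized field
#'   autocorrelation; must satisfy `g1_fun(0) == 1`.
#' @param T_exp Exposure time in seconds (> 0).
#' @param beta Coherence factor in (0, 1].
#' @param rel_tol Relative quadrature tolerance.
#' @return Squared contrast in (0, beta].
#' @examples
#' # exponential kernel has the closed form beta*(exp(-2x) - 1 + 2x)/(2x^2)
#' contrast_integral(function(tau) exp(-tau / 1e-3), T_exp = 1e-3)
#' @export
contrast_integral <- function(g1_fun, T_exp, beta = 1, rel_tol = 1e-8) {
  stopifnot(is.function(g1_fun), is.numeric(T_exp), T_exp > 0,
            beta > 0, beta <= 1)
  integrand <- function(tau) (1 - tau / T_exp) * g1_fun(tau)^2
  # split point: earliest tau where g1^2 < 1e-12, if the kernel collapses
  # inside the exposure
  split <- NA_real_
  if (g1_fun(T_exp)^2 < 1e-12) {
    lo <- 0
    hi <- T_exp
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (g1_fun(mid)^2 < 1e-12) hi <- mid else lo <- mid
      if ((hi - lo) < 1e-6 * T_exp) break
    }
    split <- hi
  }
  quad <- function(a, b) {
    res <- tryCatch(
      stats::integrate(integrand, a, b, rel.tol = rel_tol, abs.tol = 0,
                       subdivisions = 500L),
      error = function(e) stop("quadrature failed on [", a, ", ", b, "]: ",
                               conditionMessage(e), call. = FALSE)
    )
    res$value
  }
  total <- if (is.na(split) || split >= T_exp) {
    quad(0, T_exp)
  } else {
    quad(0, split) + quad(split, T_exp)
  }
  (2 * beta / T_exp) * total
}

#' Exposure-integrated squared speckle contrast
#'
#' Evaluates the contrast integral for the semi-infinite correlation-diffusion
#' kernel [g1_semi_infinite()] at exposure `T_exp`. The result lies in
#' `(0, beta]`, approaches `beta` as the exposure shrinks below the
#' decorrelation time, and decreases as exposure, separation or flow grow.
#'
#' @inheritParams g1_semi_infinite
#' @param T_exp Exposure time, seconds (> 0).
#' @param rel_tol Relative quadrature tolerance.
#' @return Squared speckle contrast, dimensionless.
#' @examples
#' op <- optical_properties()
#' ge <- semi_infinite_geometry(20, op)
#' speckle_contrast_sq(op, flow_params(1e-6), ge, T_exp = 2e-3)
#' @export
speckle_contrast_sq <- function(optics, flow, geom, T_exp, rel_tol = 1e-8) {
  stopifnot(is.numeric(T_exp), all(T_exp > 0))
  if (length(T_exp) > 1) {
    return(vapply(T_exp, function(tt) {
      speckle_contrast_sq(optics, flow, geom, tt, rel_tol)
    }, numeric(1)))
  }
  if (flow$alpha_db == 0) return(flow$beta)  # static medium: g1 == 1
  g1 <- function(tau) g1_semi_infinite(optics, flow, geom, tau)
  contrast_integral(g1, T_exp, beta = flow$beta, rel_tol = rel_tol)
}

#' Contrast and inverse contrast across a flow grid
#'
#' Sweep the flow index and tabulate `kappa^2` and `1/kappa^2` at a fixed
#' exposure and geometry. In the diffuse regime the blood flow index
#' `1/kappa^2` grows linearly with `alpha_db`, the basis for using inverse
#' squared contrast as a flow surrogate.
#'
#' @param optics An [optical_properties()] object.
#' @param geom A [semi_infinite_geometry()] object.
#' @param T_exp Exposure time, s.
#' @param beta Coherence factor.
#' @param alpha_db_grid Numeric vector of flow indices, mm^2/s (> 0).
#' @return A tibble with columns `rho_mm`, `exposure_s`, `alpha_db`,
#'   `kappa_sq`, `inv_kappa_sq`.
#' @examples
#' op <- optical_properties()
#' contrast_vs_flow_curve(op, semi_infinite_geometry(20, op), T_exp = 2e-3,
#'                        alpha_db_grid = c(1e-7, 1e-6, 1e-5))
#' @export
contrast_vs_flow_curve <- function(optics, geom, T_exp, beta = 1,
                                   alpha_db_grid) {
  stopifnot(is.numeric(alpha_db_grid), all(alpha_db_grid > 0))
  kap <- purrr::map_dbl(alpha_db_grid, function(a) {
    speckle_contrast_sq(optics, flow_params(a, beta), geom, T_exp)
  })
  tibble::tibble(
    rho_mm = geom$rho,
    exposure_s = T_exp,
    alpha_db = alpha_db_grid,
    kappa_sq = kap,
    inv_kappa_sq = 1 / kap
  )
}

#' Linear fit of inverse contrast against flow index
#'
#' Fits `1/kappa^2 ~ alpha_db` by ordinary least squares on the output of
#' [contrast_vs_flow_curve()], quantifying how closely the inverse squared
#' contrast tracks the flow index over the sweep.
#'
#' @param curve A tibble from [contrast_vs_flow_curve()].
#' @return An object of class `flow_linearity` wrapping the `lm` fit;
#'   [generics::tidy()] returns the coefficient table,
#'   [generics::glance()] the fit summary including `r.squared`.
#' @export
fit_flow_linearity <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("alpha_db", "inv_kappa_sq") %in% names(curve)))
  fit <- stats::lm(inv_kappa_sq ~ alpha_db, data = curve)
  structure(list(fit = fit, n = nrow(curve)), class = "flow_linearity")
}

#' @export
print.flow_linearity <- function(x, ...) {
  s <- summary(x$fit)
  cat(sprintf("<flow_linearity> n = %d, R^2 = %.6f, slope = %.4g\n",
              x$n, s$r.squared, stats::coef(x$fit)[["alpha_db"]]))
  invisible(x)
}

#' @rdname fit_flow_linearity
#' @param x A `flow_linearity` object.
#' @param ... Unused.
#' @method tidy flow_linearity
#' @export
tidy.flow_linearity <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  tibble::tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std.error = co[, "Std. Error"],
    statistic = co[, "t value"],
    p.value = co[, "Pr(>|t|)"]
  )
}

#' @rdname fit_flow_linearity
#' @method glance flow_linearity
#' @export
glance.flow_linearity <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    nobs = x$n
  )
}
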