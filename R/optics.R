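#' Tissue optical properties
#'
#' Bundle the static optical parameters of the probed medium. All lengths are
#' stored in millimetres internally; the wavelength is accepted in nanometres
#' (the unit lasers are specified in) and converted.
#'
#' @param mua Absorption coefficient, mm^-1.
#' @param musp Reduced scattering coefficient, mm^-1.
#' @param n Refractive index of the medium (>= 1).
#' @param wavelength_nm Vacuum wavelength in nm.
#'
#' @return An object of class `optical_properties`: a list with fields
#'   `mua`, `musp`, `n` and `wavelength` (mm).
#' @examples
#' optical_properties(mua = 0.01, musp = 1, n = 1.33, wavelength_nm = 785)
#' @export
optical_properties <- function(mua = 0.01, musp = 1, n = 1.33,
                               wavelength_nm = 785) {
  stopifnot(is.numeric(mua), length(mua) == 1, mua > 0)
  stopifnot(is.numeric(musp), length(musp) == 1, musp > 0)
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  stopifnot(is.numeric(wavelength_nm), length(wavelength_nm) == 1,
            wavelength_nm > 0)
  structure(
    list(mua = mua, musp = musp, n = n, wavelength = wavelength_nm * 1e-6),
    class = "optical_properties"
  )
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "<optical_properties> mua = %g mm^-1, musp = %g mm^-1, n = %g, lambda = %g nm\n",
    x$mua, x$musp, x$n, x$wavelength * 1e6
  ))
  invisible(x)
}

#' Dynamic (flow) parameters
#'
#' The Brownian flow index `alpha_db` (effective diffusion coefficient of the
#' moving scatterers, mm^2/s) and the coherence factor `beta` set by the
#' collection optics, which bounds the squared speckle contrast from above.
#'
#' @param alpha_db Brownian flow index, mm^2/s (>= 0).
#' @param beta Coherence factor in (0, 1].
#' @return An object of class `flow_params`.
#' @examples
#' flow_params(alpha_db = 1e-6, beta = 1)
#' @export
flow_params <- function(alpha_db = 1e-6, beta = 1) {
  stopifnot(is.numeric(alpha_db), length(alpha_db) == 1, alpha_db >= 0)
  stopifnot(is.numeric(beta), length(beta) == 1, beta > 0, beta <= 1)
  structure(list(alpha_db = alpha_db, beta = beta), class = "flow_params")
}

#' @export
print.flow_params <- function(x, ...) {
  cat(sprintf("<flow_params> alpha_db = %g mm^2/s, beta = %g\n",
              x$alpha_db, x$beta))
  invisible(x)
}

#' Optical wavenumber in the medium
#'
#' `k0 = 2 * pi * n / lambda`, the magnitude of the optical wavevector inside
#' the medium, which sets the sensitivity of the field decorrelation to
#' scatterer displacement.
#'
#' @param optics An [optical_properties()] object.
#' @return Wavenumber in mm^-1.
#' @examples
#' wavenumber(optical_properties(n = 1.33, wavelength_nm = 785))
#' @export
wavenumber <- function(optics) {
  stopifnot(inherits(optics, "optical_properties"))
  2 * pi * optics$n / optics$wavelength
}

#' Effective reflection coefficient of a refractive-index-mismatched boundary
#'
#' The extrapolated-boundary condition for the diffusion (and correlation
#' diffusion) equation places an image source at a distance governed by the
#' effective reflection coefficient `Reff`, which summarises internal Fresnel
#' reflection at the tissue-air interface.
#'
#' The default method evaluates the flux-weighted hemispherical average of
#' the unpolarized internal Fresnel reflectance numerically:
#' \deqn{R_{eff} = \int_0^{\pi/2} 2\sin\theta\cos\theta\, R_F(\theta)\,d\theta}
#' (total internal reflection included beyond the critical angle), which is
#' exactly 0 for a matched boundary (n = 1). The cubic polynomial fit in `n`
#' widely used in the diffuse-optics literature approximates this integral to
#' about 5e-4 over physiological indices and is available as
#' `method = "polynomial"`.
#'
#' @param n Refractive index ratio (inside / outside), >= 1.
#' @param method `"fresnel"` (numerical integral, default) or `"polynomial"`.
#' @return Effective reflection coefficient in `[0, 1)`.
#' @examples
#' effective_reflection(1)     # matched boundary: 0
#' effective_reflection(1.33)  # tissue-air: about 0.47
#' @export
effective_reflection <- function(n, method = c("fresnel", "polynomial")) {
  stopifnot(is.numeric(n), length(n) == 1)
  if (n < 1) stop("refractive index ratio `n` must be >= 1", call. = FALSE)
  method <- match.arg(method)
  if (method == "polynomial") {
    return(-1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n)
  }
  if (n == 1) return(0)
  # unpolarized Fresnel reflectance for internal incidence at angle theta;
  # total internal reflection beyond the critical angle asin(1/n)
  rf <- function(theta) {
    st <- sin(theta)
    out <- rep(1, length(theta))
    ok <- n * st < 1
    tt <- asin(pmin(n * st[ok], 1))       # transmitted angle
    ci <- cos(theta[ok]); ct <- cos(tt)
    rs <- ((n * ci - ct) / (n * ci + ct))^2
    rp <- ((n * ct - ci) / (n * ct + ci))^2
    out[ok] <- (rs + rp) / 2
    out
  }
  theta_c <- asin(1 / n)  # integrand kinks at the critical angle
  below <- stats::integrate(function(th) 2 * sin(th) * cos(th) * rf(th),
                            0, theta_c, rel.tol = 1e-10)$value
  above <- cos(theta_c)^2  # R_F = 1 beyond critical: integral of 2 s c
  below + above
}

#' Semi-infinite measurement geometry
#'
#' Derived geometry for the extrapolated-boundary, image-source solution of
#' the correlation diffusion equation on a half space: the effective isotropic
#' source sits at depth `z0 = 1/musp`, the extrapolated boundary at
#' `zb = (2/3) (1 + Reff) / ((1 - Reff) musp)` above the surface, and the
#' detector at separation `rho` sees the real source at distance `r1` and its
#' negative image at `rb`.
#'
#' @param rho Source-detector separation on the surface, mm (> 0).
#' @param optics An [optical_properties()] object (supplies `musp` and `n`).
#' @param reff Optional effective reflection coefficient; computed from
#'   `optics$n` via [effective_reflection()] when `NULL`.
#' @return An object of class `semi_infinite_geometry` with fields `rho`,
#'   `z0`, `zb`, `r1`, `rb`, `reff`.
#' @examples
#' semi_infinite_geometry(rho = 20, optical_properties())
#' @export
semi_infinite_geometry <- function(rho, optics, reff = NULL) {
  stopifnot(is.numeric(rho), length(rho) == 1, rho > 0)
  stopifnot(inherits(optics, "optical_properties"))
  if (is.null(reff)) reff <- effective_reflection(optics$n)
  stopifnot(reff >= 0, reff < 1)
  z0 <- 1 / optics$musp
  zb <- (2 / 3) * (1 + reff) / ((1 - reff) * optics$musp)
  r1 <- sqrt(rho^2 + z0^2)
  rb <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  if (r1 == 0) stop("degenerate geometry: detector coincides with source",
                    call. = FALSE)
  structure(
    list(rho = rho, z0 = z0, zb = zb, r1 = r1, rb = rb, reff = reff),
    class = "semi_infinite_geometry"
  )
}

#' @export
print.semi_infinite_geometry <- function(x, ...) {
  cat(sprintf(
    "<semi_infinite_geometry> rho = %g mm, z0 = %g, zb = %g, r1 = %g, rb = %g, Reff = %.4f\n",
    x$rho, x$z0, x$zb, x$r1, x$rb, x$reff
  ))
  invisible(x)
}
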