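# shared fixtures: typical tissue optics and a mid-range separation
tissue_optics <- function() {
  optical_properties(mua = 0.01, musp = 1, n = 1.33, wavelength_nm = 785)
}

tissue_geometry <- function(rho = 20) {
  semi_infinite_geometry(rho, tissue_optics())
}

# independently coded evaluation of the semi-infinite correlation-diffusion
# autocorrelation, used as the oracle for g1_semi_infinite(); written from
# the closed form, not by calling package internals
g1_oracle <- function(mua, musp, n, wavelength_mm, alpha_db, rho, tau) {
  k0 <- 2 * pi * n / wavelength_mm
  reff <- speckleflow::effective_reflection(n)
  z0 <- 1 / musp
  zb <- 2 * (1 + reff) / (3 * musp * (1 - reff))
  r1 <- sqrt(rho^2 + z0^2)
  rb <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  gg <- function(tau1) {
    msd <- 6 * alpha_db * tau1
    kd <- sqrt(3 * mua * musp + musp^2 * k0^2 * msd)
    exp(-kd * r1) / r1 - exp(-kd * rb) / rb
  }
  gg(tau) / gg(0)
}

# closed-form contrast for an exponential field correlation g1 = exp(-tau/tc)
kappa_sq_exponential <- function(T_exp, tau_c, beta = 1) {
  x <- T_exp / tau_c
  beta * (exp(-2 * x) - 1 + 2 * x) / (2 * x^2)
}
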