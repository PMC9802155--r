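# shared fixtures used across test files
fx_factors <- fyn22_factors()
fx_runs <- fyn22_runs()
fx_fit <- fit_quadratic(fx_runs, fx_factors)

# a small separable two-factor toy surface for optimizer tests:
# builds a quad_fit directly from chosen true coefficients by fitting
# noiseless simulated responses (exact interpolation).
toy_fit <- function(true_coef, factors = NULL) {
  if (is.null(factors)) {
    factors <- rsm_factors(c("x1", "x2", "x3"), c("A", "B", "C"),
                           center = 0, step = 1)
  }
  sim <- simulate_surface(factors, true_coef, n_center = 3, noise_sd = 0,
                          seed = 1)
  sim$response <- sim$response + 10  # keep responses positive-ish; shifts intercept
  fit <- fit_quadratic(sim, factors)
  fit
}
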