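#' Simulate responses from a known quadratic surface on a BBD
#'
#' Generates a response table whose ground truth is a chosen
#' second-order polynomial: `y = quadratic(coded run) + Normal(0,
#' noise_sd)`, independent across runs. This is exactly the statistical
#' model the response-surface ANOVA assumes (additive i.i.d. Gaussian
#' error on the response scale); set `lognormal = TRUE` for a
#' positive-valued multiplicative-error variant. All simulators are
#' pure functions of their arguments and `seed`, and leave the caller's
#' RNG state untouched.
#'
#' @param factors A factor tibble; the design is generated with
#'   [bbd_design()].
#' @param true_coef Named numeric vector of true coefficients using the
#'   canonical term labels (`"(Intercept)"`, `"A"`, `"A:B"`, `"A^2"`,
#'   ...). Unnamed terms default to 0.
#' @param n_center Number of center replicates (default 5).
#' @param noise_sd Response SD of the added noise (>= 0), in response
#'   units.
#' @param seed Integer seed (mandatory).
#' @param lognormal If `TRUE`, responses are
#'   `true * exp(Normal(0, noise_sd))` instead of additive-Gaussian.
#' @return A run tibble in the same schema as [fyn22_runs()] (coded and
#'   actual columns, `response`, `center`), ready for
#'   [fit_quadratic()].
#' @examples
#' fct <- fyn22_factors()
#' truth <- c("(Intercept)" = 1.8, A = -0.05, "A^2" = -0.1)
#' sim <- simulate_surface(fct, truth, noise_sd = 0.046, seed = 1)
#' @export
simulate_surface <- function(factors, true_coef, n_center = 5, noise_sd = 0,
                             seed, lognormal = FALSE) {
  stopifnot(noise_sd >= 0, !missing(seed))
  design <- bbd_design(factors, n_center = n_center)
  X <- build_model_matrix(design, factors$symbol)
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  unknown <- setdiff(names(true_coef), names(beta))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown term(s) in true_coef: ",
                        paste(unknown, collapse = ", ")),
                 class = "fermrsm_invalid_value")
  }
  beta[names(true_coef)] <- true_coef
  mu <- drop(X %*% beta)
  eps <- withr_seed(seed, stats::rnorm(length(mu), 0, noise_sd))
  design$response <- if (lognormal) mu * exp(eps) else mu + eps
  design
}

#' Simulate DPP-IV assay plates with known true inhibition
#'
#' Constructs four-arm plates whose noiseless inhibition equals
#' `true_inhibition`: the blank `dT` and sample background `dP` sit at
#' a baseline absorbance, `dS = dT + control_window`, and
#' `dX = dP + (1 - true/100) * control_window`. Independent Gaussian
#' noise of SD `noise_sd` is then added to every well.
#'
#' @param true_inhibition True percent inhibition.
#' @param control_window Noiseless `dS - dT` (> 0), absorbance units.
#' @param noise_sd Per-well absorbance noise SD (>= 0).
#' @param n Number of plates.
#' @param seed Integer seed (mandatory).
#' @param baseline Baseline absorbance for the blank wells.
#' @return A tibble of `n` plates with columns `dX`, `dP`, `dS`, `dT`,
#'   ready for [dppiv_inhibition()].
#' @examples
#' pl <- simulate_dppiv_plate(58.73, control_window = 0.8, noise_sd = 0.005,
#'                            n = 3, seed = 7)
#' dppiv_inhibition(pl)
#' @export
simulate_dppiv_plate <- function(true_inhibition, control_window = 0.8,
                                 noise_sd = 0, n = 1, seed, baseline = 0.1) {
  stopifnot(!missing(seed), noise_sd >= 0)
  if (control_window <= 0) {
    rlang::abort("control_window must be positive",
                 class = "fermrsm_invalid_control")
  }
  noise <- withr_seed(seed, matrix(stats::rnorm(4 * n, 0, noise_sd), ncol = 4))
  tibble::tibble(
    dX = baseline + (1 - true_inhibition / 100) * control_window + noise[, 1],
    dP = baseline + noise[, 2],
    dS = baseline + control_window + noise[, 3],
    dT = baseline + noise[, 4]
  )
}

#' Simulate per-seedling measurements for two groups
#'
#' Draws individual Gaussian seedling measurements matching specified
#' per-trait, per-group means and SDs - the raw data behind a
#' `mean +/- SD, n` summary table - so that summary-statistic tests can
#' be validated against tests on raw samples.
#'
#' @param spec A data frame with columns `trait`, `group`, `mean`, `sd`
#'   (e.g. [fyn22_seedlings()]; an `n` column is ignored in favor of
#'   the `n` argument).
#' @param n Seedlings per trait-group cell (>= 2).
#' @param seed Integer seed (mandatory).
#' @return A long tibble with `trait`, `group`, `seedling`, `value`.
#' @examples
#' raw <- simulate_seedlings(fyn22_seedlings(), n = 20, seed = 3)
#' @export
simulate_seedlings <- function(spec, n = 20, seed) {
  stopifnot(!missing(seed), n >= 2)
  spec <- tibble::as_tibble(spec)
  need <- c("trait", "group", "mean", "sd")
  if (!all(need %in% names(spec))) {
    rlang::abort("spec must have columns trait, group, mean, sd",
                 class = "fermrsm_invalid_value")
  }
  draws <- withr_seed(seed, matrix(stats::rnorm(nrow(spec) * n), nrow = nrow(spec)))
  out <- purrr::map_dfr(seq_len(nrow(spec)), function(i) {
    tibble::tibble(
      trait = spec$trait[i], group = spec$group[i], seedling = seq_len(n),
      value = spec$mean[i] + spec$sd[i] * draws[i, ]
    )
  })
  out
}
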