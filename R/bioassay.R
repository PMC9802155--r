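#' DPP-IV inhibition rate from a four-arm microplate scheme
#'
#' Computes the percent inhibition of dipeptidyl peptidase IV from the
#' standard four-well blank-correction scheme read at 405 nm:
#' \deqn{100 \left(1 - \frac{\Delta X - \Delta P}{\Delta S - \Delta T}\right)}
#' where `dX` is the sample + substrate + enzyme well, `dP` the sample
#' background without enzyme, `dS` the enzyme-only positive control and
#' `dT` the substrate-only blank. Values below 0 (apparent activation)
#' or above 100 (over-blanking) are returned as computed and flagged.
#'
#' @param plates A data frame with numeric columns `dX`, `dP`, `dS`,
#'   `dT`, one row per plate/sample.
#' @return `plates` as a tibble with `inhibition_pct` and logical
#'   `flagged` (outside `[0, 100]`) appended.
#' @examples
#' dppiv_inhibition(tibble::tibble(dX = 0.5, dP = 0.1, dS = 0.9, dT = 0.1))
#' @export
dppiv_inhibition <- function(plates) {
  plates <- tibble::as_tibble(plates)
  need <- c("dX", "dP", "dS", "dT")
  if (!all(need %in% names(plates))) {
    rlang::abort("plates must have columns dX, dP, dS, dT",
                 class = "fermrsm_invalid_value")
  }
  vals <- as.matrix(plates[need])
  if (!all(is.finite(vals))) {
    rlang::abort("absorbances must be finite", class = "fermrsm_invalid_value")
  }
  window <- plates$dS - plates$dT
  if (any(window <= 0)) {
    rlang::abort("control window dS - dT must be positive",
                 class = "fermrsm_invalid_control")
  }
  dplyr::mutate(
    plates,
    inhibition_pct = 100 * (1 - (.data$dX - .data$dP) / (.data$dS - .data$dT)),
    flagged = .data$inhibition_pct < 0 | .data$inhibition_pct > 100
  )
}

#' Fit a colorimetric standard curve
#'
#' Ordinary least-squares line `concentration = slope * od + intercept`,
#' the orientation used for Salkowski-reaction IAA quantification
#' (concentration regressed on OD530), so that reading a sample off the
#' curve needs no inversion.
#'
#' @param points A data frame with columns `od` and `conc` (>= 3 rows,
#'   not all `od` equal).
#' @return An object of class `std_curve`: list with `slope`,
#'   `intercept`, `r2`, `range` (calibrated OD interval) and the
#'   calibration `points`. Has `tidy()` and `glance()` methods.
#' @examples
#' pts <- tibble::tibble(od = c(0, 0.2, 0.5, 1.0), conc = 30 * od)
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(points) {
  points <- tibble::as_tibble(points)
  if (!all(c("od", "conc") %in% names(points))) {
    rlang::abort("points must have columns od and conc",
                 class = "fermrsm_invalid_value")
  }
  if (nrow(points) < 3) {
    rlang::abort("a standard curve needs at least 3 points",
                 class = "fermrsm_invalid_value")
  }
  if (stats::sd(points$od) == 0) {
    rlang::abort("all OD values identical: degenerate curve",
                 class = "fermrsm_degenerate_curve")
  }
  ls <- stats::lm(conc ~ od, data = points)
  ss_tot <- sum((points$conc - mean(points$conc))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(ls)^2) / ss_tot else NA_real_
  structure(list(
    slope = unname(stats::coef(ls)[2]),
    intercept = unname(stats::coef(ls)[1]),
    r2 = r2,
    range = range(points$od),
    points = points
  ), class = "std_curve")
}

#' @export
print.std_curve <- function(x, ...) {
  cat(sprintf("Standard curve: conc = %.4f * OD %+.4f (r2 = %.4f, OD range [%g, %g])\n",
              x$slope, x$intercept, x$r2, x$range[1], x$range[2]))
  invisible(x)
}

#' @param x A `std_curve`.
#' @param ... Unused.
#' @rdname fit_standard_curve
#' @method tidy std_curve
#' @export
tidy.std_curve <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "od"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname fit_standard_curve
#' @method glance std_curve
#' @export
glance.std_curve <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, n = nrow(x$points),
                 od_min = x$range[1], od_max = x$range[2])
}

#' Quantify IAA in samples against a standard curve
#'
#' Reads each sample's OD530 off the fitted line and multiplies by its
#' dilution factor: `conc = dilution * (slope * od + intercept)`.
#' Negative back-calculated concentrations are floored at 0; samples
#' outside the calibrated OD range are flagged, not refused.
#'
#' @param samples A data frame with column `od` and optionally
#'   `dilution` (default 1, must be >= 1).
#' @param curve A `std_curve` from [fit_standard_curve()].
#' @return `samples` as a tibble with `conc` (ug/ml) and logical
#'   `out_of_range` appended.
#' @examples
#' curve <- fit_standard_curve(tibble::tibble(od = c(0, 0.5, 1), conc = c(0, 15, 30)))
#' quantify_iaa(tibble::tibble(od = 0.5, dilution = 4), curve)
#' @export
quantify_iaa <- function(samples, curve) {
  stopifnot(inherits(curve, "std_curve"))
  samples <- tibble::as_tibble(samples)
  if (!"od" %in% names(samples)) {
    rlang::abort("samples must have an od column", class = "fermrsm_invalid_value")
  }
  if (!"dilution" %in% names(samples)) samples$dilution <- 1
  if (any(samples$dilution < 1)) {
    rlang::abort("dilution factors must be >= 1",
                 class = "fermrsm_invalid_dilution")
  }
  dplyr::mutate(
    samples,
    conc = pmax(0, .data$dilution * (curve$slope * .data$od + curve$intercept)),
    out_of_range = .data$od < curve$range[1] | .data$od > curve$range[2]
  )
}

#' Stress-tolerance survival rates
#'
#' Percent of viable spores surviving an acid or bile-salt challenge:
#' `100 * final / initial`, computed per condition. Scale-invariant in
#' the counts, so any consistent CFU unit works.
#'
#' @param counts A data frame with numeric columns `initial_count` and
#'   `final_count` (initial > 0).
#' @return `counts` as a tibble with `survival_pct` appended (full
#'   precision; round to 2 dp for report parity with published tables).
#' @examples
#' survival_rate(fyn22_tolerance())
#' @export
survival_rate <- function(counts) {
  counts <- tibble::as_tibble(counts)
  need <- c("initial_count", "final_count")
  if (!all(need %in% names(counts))) {
    rlang::abort("counts must have columns initial_count and final_count",
                 class = "fermrsm_invalid_value")
  }
  if (any(counts$initial_count <= 0)) {
    rlang::abort("initial counts must be positive",
                 class = "fermrsm_invalid_count")
  }
  dplyr::mutate(counts,
                survival_pct = 100 * .data$final_count / .data$initial_count)
}

# Welch's two-sample t test from summary statistics
welch_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  se <- sqrt(v1 + v2)
  if (se == 0) {
    return(list(statistic = 0, df = n1 + n2 - 2, p.value = 1))
  }
  t <- (m2 - m1) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = t, df = df, p.value = 2 * stats::pt(-abs(t), df))
}

#' Growth-promotion statistics for two-group seedling trials
#'
#' For each morphometric trait, computes the treatment-vs-control
#' percent change `100 * (treatment mean - control mean) / control
#' mean` and a two-sample t test from the group summary statistics.
#' Welch's unequal-variance test is the default; set `var_equal = TRUE`
#' for the pooled Student's t.
#'
#' @param groups A data frame in the layout of [fyn22_seedlings()]:
#'   columns `trait`, `group` (`"control"`/`"treatment"`), `mean`,
#'   `sd`, `n` (n >= 2, sd >= 0).
#' @param var_equal Use the pooled-variance Student's t instead of
#'   Welch's (default `FALSE`).
#' @return A tibble with one row per trait: `control_mean`,
#'   `treatment_mean`, `pct_change`, `statistic`, `df`, `p.value`.
#' @examples
#' growth_promotion(fyn22_seedlings())
#' @export
growth_promotion <- function(groups, var_equal = FALSE) {
  groups <- tibble::as_tibble(groups)
  need <- c("trait", "group", "mean", "sd", "n")
  if (!all(need %in% names(groups))) {
    rlang::abort("groups must have columns trait, group, mean, sd, n",
                 class = "fermrsm_invalid_value")
  }
  if (any(groups$n < 2) || any(groups$sd < 0)) {
    rlang::abort("each group needs n >= 2 and sd >= 0",
                 class = "fermrsm_invalid_value")
  }
  wide <- tidyr::pivot_wider(groups, names_from = "group",
                             values_from = c("mean", "sd", "n"))
  if (!all(c("mean_control", "mean_treatment") %in% names(wide))) {
    rlang::abort("both a control and a treatment group are required per trait",
                 class = "fermrsm_invalid_value")
  }
  if (any(wide$mean_control == 0)) {
    rlang::abort("control mean of zero: percent change undefined",
                 class = "fermrsm_invalid_value")
  }
  purrr::pmap_dfr(wide, function(trait, mean_control, mean_treatment,
                                 sd_control, sd_treatment, n_control,
                                 n_treatment, ...) {
    tst <- if (var_equal) {
      sp2 <- ((n_control - 1) * sd_control^2 + (n_treatment - 1) * sd_treatment^2) /
        (n_control + n_treatment - 2)
      se <- sqrt(sp2 * (1 / n_control + 1 / n_treatment))
      t <- if (se == 0) 0 else (mean_treatment - mean_control) / se
      df <- n_control + n_treatment - 2
      list(statistic = t, df = df,
           p.value = if (se == 0) 1 else 2 * stats::pt(-abs(t), df))
    } else {
      welch_from_summary(mean_control, sd_control, n_control,
                         mean_treatment, sd_treatment, n_treatment)
    }
    tibble::tibble(
      trait = trait,
      control_mean = mean_control,
      treatment_mean = mean_treatment,
      pct_change = 100 * (mean_treatment - mean_control) / mean_control,
      statistic = tst$statistic, df = tst$df, p.value = tst$p.value
    )
  })
}
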