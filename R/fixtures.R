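#' Bundled FYN-22 medium-optimization dataset
#'
#' The 29-run, four-factor Box-Behnken experiment measuring Bacillus
#' licheniformis FYN-22 spore concentration (x 1e9 CFU/ml) as a function
#' of soluble starch, yeast, NH4Cl and FeCl3 in the fermentation medium,
#' together with the factor definitions centering the design on the
#' one-factor-at-a-time winners. Five center replicates (runs 1-5) allow
#' the lack-of-fit/pure-error split.
#'
#' @return `fyn22_runs()`: a 29-row tibble with `run`, coded columns
#'   `A`-`D`, actual-scale columns, `response` and `center`.
#'   `fyn22_factors()`: the matching four-row factor tibble.
#' @examples
#' runs <- fyn22_runs()
#' sum(runs$center)  # 5 center replicates
#' @export
fyn22_runs <- function() {
  path <- system.file("extdata", "fyn22_bbd_runs.csv", package = "fermrsm",
                      mustWork = TRUE)
  read_response_csv(path, fyn22_factors())
}

#' @rdname fyn22_runs
#' @export
fyn22_factors <- function() {
  path <- system.file("extdata", "fyn22_factors.json", package = "fermrsm",
                      mustWork = TRUE)
  read_factors_json(path)
}

#' Bundled FYN-22 stress-tolerance and seedling tables
#'
#' `fyn22_tolerance()` holds the acid (pH 2-4) and bile-salt (0.5-1.5%)
#' challenge counts (x 1e8 CFU/ml viable spores before and after 24-48 h
#' exposure). `fyn22_seedlings()` holds per-trait summary statistics
#' (mean, SD, n = 20) for control and FYN-22-treated rice seedlings
#' after 14 days of hydroponic culture.
#'
#' @return A tibble (`stress`, `condition`, `initial_count`,
#'   `final_count` resp. `trait`, `group`, `mean`, `sd`, `n`).
#' @export
fyn22_tolerance <- function() {
  path <- system.file("extdata", "fyn22_tolerance.csv", package = "fermrsm",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname fyn22_tolerance
#' @export
fyn22_seedlings <- function() {
  path <- system.file("extdata", "fyn22_seedlings.csv", package = "fermrsm",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
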