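#' Define design factors with coded/actual transforms
#'
#' A factor table describes each medium component on two scales: the
#' *actual* scale the experiment is pipetted on (e.g. g per 100 ml) and
#' the *coded* scale used by the design and the fitted model, related by
#' `coded = (actual - center) / step`. The half-range `step` must be
#' strictly positive; the coded levels -1, 0, +1 then correspond to
#' `center - step`, `center`, `center + step`.
#'
#' @param name Character vector of factor names (column names on the
#'   actual scale).
#' @param symbol One-letter codes (`"A"`, `"B"`, ...) naming the coded
#'   columns and model terms.
#' @param center Actual value at coded 0, one per factor.
#' @param step Actual half-range (> 0), one per factor.
#' @param unit Unit label for the actual scale (e.g. `"1e-2 g/ml"`).
#' @param g_per_l Multiplier converting the actual scale to g/l, used
#'   when reporting optima in conventional medium-recipe units.
#'
#' @return A tibble with one row per factor and columns `name`,
#'   `symbol`, `unit`, `center`, `step`, `g_per_l`.
#' @examples
#' rsm_factors(
#'   name   = c("soluble_starch", "yeast"),
#'   symbol = c("A", "B"),
#'   center = c(1.2, 2.5),
#'   step   = c(0.2, 0.5),
#'   unit   = c("1e-2 g/ml", "1e-3 g/ml"),
#'   g_per_l = c(10, 1)
#' )
#' @export
rsm_factors <- function(name, symbol, center, step, unit = NA_character_,
                        g_per_l = 1) {
  fct <- tibble::tibble(
    name = as.character(name),
    symbol = as.character(symbol),
    unit = as.character(unit),
    center = as.numeric(center),
    step = as.numeric(step),
    g_per_l = as.numeric(g_per_l)
  )
  validate_factors(fct)
  fct
}

validate_factors <- function(factors) {
  stopifnot(is.data.frame(factors))
  required <- c("name", "symbol", "center", "step")
  missing <- setdiff(required, names(factors))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("factor table lacks column(s): ", paste(missing, collapse = ", ")),
      class = "fermrsm_invalid_factors"
    )
  }
  if (anyDuplicated(factors$symbol) || anyDuplicated(factors$name)) {
    rlang::abort("factor names and symbols must be unique",
                 class = "fermrsm_invalid_factors")
  }
  if (!all(is.finite(factors$center)) || !all(is.finite(factors$step))) {
    rlang::abort("factor centers and steps must be finite",
                 class = "fermrsm_invalid_factors")
  }
  if (any(factors$step <= 0)) {
    rlang::abort("factor step must be > 0", class = "fermrsm_invalid_factors")
  }
  invisible(factors)
}

#' Convert between actual and coded factor values
#'
#' `code_value()` maps actual concentrations to the coded scale
#' `(actual - center) / step`; `decode_value()` is its exact inverse.
#' Both are vectorized over `value`.
#'
#' @param factor A single-row factor tibble (one row of [rsm_factors()]).
#' @param value Numeric vector of actual (`code_value`) or coded
#'   (`decode_value`) values.
#' @return Numeric vector on the other scale.
#' @examples
#' starch <- rsm_factors("soluble_starch", "A", 1.2, 0.2)
#' code_value(starch, 1.0)    # -1
#' decode_value(starch, 0.5)  # 1.3
#' @export
code_value <- function(factor, value) {
  stopifnot(is.data.frame(factor), nrow(factor) == 1)
  validate_factors(factor)
  if (!all(is.finite(value))) {
    rlang::abort("values to code must be finite", class = "fermrsm_invalid_value")
  }
  (value - factor$center) / factor$step
}

#' @rdname code_value
#' @export
decode_value <- function(factor, value) {
  stopifnot(is.data.frame(factor), nrow(factor) == 1)
  validate_factors(factor)
  if (!all(is.finite(value))) {
    rlang::abort("values to decode must be finite", class = "fermrsm_invalid_value")
  }
  factor$center + factor$step * value
}

#' Add coded or actual columns to a run table
#'
#' `code_runs()` takes a data frame holding actual-scale columns (named
#' after `factors$name`) and adds the coded columns (named after
#' `factors$symbol`); `decode_runs()` does the reverse. Existing columns
#' of the target names are overwritten.
#'
#' @param data A data frame of runs.
#' @param factors A factor tibble from [rsm_factors()].
#' @return `data` as a tibble with the converted columns added.
#' @export
code_runs <- function(data, factors) {
  validate_factors(factors)
  data <- tibble::as_tibble(data)
  missing <- setdiff(factors$name, names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0("actual-scale column(s) missing: ",
                        paste(missing, collapse = ", ")),
                 class = "fermrsm_invalid_value")
  }
  for (i in seq_len(nrow(factors))) {
    data[[factors$symbol[i]]] <- code_value(factors[i, ], data[[factors$name[i]]])
  }
  data
}

#' @rdname code_runs
#' @export
decode_runs <- function(data, factors) {
  validate_factors(factors)
  data <- tibble::as_tibble(data)
  missing <- setdiff(factors$symbol, names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0("coded column(s) missing: ",
                        paste(missing, collapse = ", ")),
                 class = "fermrsm_invalid_value")
  }
  for (i in seq_len(nrow(factors))) {
    data[[factors$name[i]]] <- decode_value(factors[i, ], data[[factors$symbol[i]]])
  }
  data
}

#' Read and write factor definitions as JSON
#'
#' The on-disk schema is an array of objects with fields `name`,
#' `symbol`, `unit`, `center`, `step` and optionally `g_per_l`.
#'
#' @param path File path.
#' @param factors A factor tibble.
#' @return `read_factors_json()` returns a validated factor tibble;
#'   `write_factors_json()` returns `path` invisibly.
#' @export
read_factors_json <- function(path) {
  raw <- jsonlite::fromJSON(path)
  if (is.null(raw$g_per_l)) raw$g_per_l <- 1
  if (is.null(raw$unit)) raw$unit <- NA_character_
  rsm_factors(raw$name, raw$symbol, raw$center, raw$step,
              unit = raw$unit, g_per_l = raw$g_per_l)
}

#' @rdname read_factors_json
#' @export
write_factors_json <- function(factors, path) {
  validate_factors(factors)
  jsonlite::write_json(factors, path, auto_unbox = FALSE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
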