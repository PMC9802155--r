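#' Read and write run tables as CSV
#'
#' The CSV schema has a header row with `run`, the coded columns named
#' by factor symbol and/or the actual columns named by factor name, and
#' `response`. Whichever scale is absent is reconstructed from the
#' factor definitions; if both are present they must agree. Reading a
#' table written by `write_response_csv()` round-trips exactly.
#'
#' @param path File path.
#' @param factors The factor tibble defining symbols, names and
#'   transforms.
#' @param data A run tibble (as from [fyn22_runs()] or
#'   [simulate_surface()]).
#' @return `read_response_csv()`: a run tibble with `run`, coded and
#'   actual columns, `response` and logical `center`.
#'   `write_response_csv()`: `path`, invisibly.
#' @export
read_response_csv <- function(path, factors) {
  validate_factors(factors)
  data <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(data) == 0) {
    rlang::abort(paste0("no runs in ", path), class = "fermrsm_parse_error")
  }
  if (!"response" %in% names(data)) {
    rlang::abort("response column missing", class = "fermrsm_parse_error")
  }
  if (!"run" %in% names(data)) data$run <- seq_len(nrow(data))
  if (anyDuplicated(data$run)) {
    rlang::abort(paste0("duplicated run id(s): ",
                        paste(unique(data$run[duplicated(data$run)]),
                              collapse = ", ")),
                 class = "fermrsm_duplicate_run")
  }
  has_coded <- all(factors$symbol %in% names(data))
  has_actual <- all(factors$name %in% names(data))
  if (!has_coded && !has_actual) {
    rlang::abort("neither coded nor actual factor columns found; header must match the factor definitions",
                 class = "fermrsm_parse_error")
  }
  if (has_coded && has_actual) {
    recoded <- code_runs(data[c("run", factors$name)], factors)
    for (s in factors$symbol) {
      if (max(abs(recoded[[s]] - data[[s]])) > 1e-8) {
        rlang::abort(paste0("coded and actual values disagree for factor ", s,
                            "; check units against the factor definitions"),
                     class = "fermrsm_unit_mismatch")
      }
    }
  } else if (has_actual) {
    data <- code_runs(data, factors)
  } else {
    data <- decode_runs(data, factors)
  }
  if (any(!is.finite(data$response)) || any(data$response <= 0)) {
    rlang::abort("responses must be finite and positive",
                 class = "fermrsm_parse_error")
  }
  data$center <- rowSums(abs(data[factors$symbol])) == 0
  data[c("run", factors$symbol, factors$name, "response", "center")]
}

#' @rdname read_response_csv
#' @export
write_response_csv <- function(data, path, factors) {
  validate_factors(factors)
  cols <- intersect(c("run", factors$symbol, factors$name, "response"),
                    names(data))
  readr::write_csv(data[cols], path)
  invisible(path)
}

#' Run the full medium-optimization analysis
#'
#' One call from a run table to the complete report: quadratic fit,
#' coefficient table, partial-SS ANOVA with lack-of-fit split, fit
#' statistics, effect rankings, the constrained optimum on both scales,
#' and contour slices for every factor pair. Equivalent to chaining
#' [fit_quadratic()], [anova_quad()], [fit_statistics()],
#' [rank_effects()], [maximize_in_cube()] and [surface_slice()].
#'
#' @param data A run tibble (e.g. [fyn22_runs()], [read_response_csv()]
#'   or [simulate_surface()] output).
#' @param factors The matching factor tibble.
#' @param alpha Significance level for ANOVA flags.
#' @param lower,upper Coded optimization bounds (default the tested
#'   range, -1 to 1).
#' @param slices If `TRUE` (default), evaluate a [surface_slice()] for
#'   every factor pair at center levels.
#' @param response Response column name.
#' @return A list of class `rsm_report` with elements `fit`,
#'   `coefficients`, `anova`, `fit_stats`, `effects`, `optimum`,
#'   `optimum_tbl`, `slices` (named list of `quad_slice`), and
#'   `exact_fit` flag.
#' @examples
#' rep <- run_pipeline(fyn22_runs(), fyn22_factors())
#' rep$fit_stats
#' @export
run_pipeline <- function(data, factors, alpha = 0.05, lower = -1, upper = 1,
                         slices = TRUE, response = "response") {
  fit <- fit_quadratic(data, factors, response = response)
  an <- anova_quad(fit, alpha = alpha)
  opt <- maximize_in_cube(fit, lower = lower, upper = upper)
  sl <- list()
  if (slices) {
    pairs <- utils::combn(factors$symbol, 2)
    sl <- lapply(seq_len(ncol(pairs)), function(p)
      surface_slice(fit, pairs[, p]))
    names(sl) <- apply(pairs, 2, paste, collapse = "")
  }
  structure(list(
    fit = fit,
    coefficients = tidy(fit),
    anova = an,
    fit_stats = fit_statistics(fit),
    effects = rank_effects(an),
    optimum = opt,
    optimum_tbl = tidy(opt),
    slices = sl,
    exact_fit = isTRUE(attr(an, "exact_fit"))
  ), class = "rsm_report")
}

#' @export
print.rsm_report <- function(x, ...) {
  cat("== Response-surface medium optimization ==\n\nCoefficients (coded scale):\n")
  print(as.data.frame(dplyr::mutate(x$coefficients,
                                    dplyr::across(dplyr::where(is.numeric),
                                                  ~ round(.x, 4)))),
        row.names = FALSE)
  cat("\n")
  print(x$anova)
  cat("\nFit statistics:\n")
  print(as.data.frame(round(x$fit_stats, 4)), row.names = FALSE)
  cat("\n")
  print(x$optimum)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits the coefficient table, ANOVA, fit statistics, effect rankings
#' and optimum as CSV and/or a single JSON document, plus one CSV grid
#' per surface slice. JSON keeps full precision; the CSV/text outputs
#' are full precision too (round for display with [format_anova()]).
#' Output is deterministic: identical inputs give byte-identical files.
#'
#' @param report An `rsm_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "json")`.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir, formats = c("csv", "json")) {
  stopifnot(inherits(report, "rsm_report"))
  formats <- match.arg(formats, c("csv", "json"), several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(tbl, name) {
    f <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(tibble::as_tibble(tbl), f)
    written <<- c(written, f)
  }
  if ("csv" %in% formats) {
    emit(report$coefficients, "coefficients")
    emit(report$anova, "anova")
    emit(report$fit_stats, "fit_statistics")
    emit(report$effects, "effect_ranking")
    emit(report$optimum_tbl, "optimum")
    for (nm in names(report$slices)) {
      emit(tibble::as_tibble(report$slices[[nm]]), paste0("slice_", nm))
    }
  }
  if ("json" %in% formats) {
    f <- file.path(dir, "report.json")
    jsonlite::write_json(list(
      coefficients = report$coefficients,
      anova = report$anova,
      fit_statistics = report$fit_stats,
      effect_ranking = report$effects,
      optimum = list(
        coordinates = report$optimum$coded,
        predicted = report$optimum$predicted,
        interior = report$optimum$interior,
        hessian_class = report$optimum$hessian_class
      ),
      exact_fit = report$exact_fit
    ), f, auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE,
    na = "null")
    written <- c(written, f)
  }
  invisible(written)
}
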