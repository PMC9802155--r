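#' ANOVA of a quadratic response-surface fit
#'
#' Decomposes the corrected total sum of squares into the model and
#' residual, splits the residual into lack of fit and pure error using
#' replicated runs, and reports a partial (Type III) sum of squares for
#' every model term: `SS(term) = RSS(model without that term) -
#' RSS(full model)`, each obtained by an explicit refit. `F(term) =
#' MS(term) / MS(residual)`; `F(lack of fit) = MS(LOF) / MS(pure
#' error)`; p-values from the F distribution.
#'
#' Pure error is computed from groups of runs with identical coded
#' vectors (on a Box-Behnken design these are the center replicates):
#' `SS_PE = sum over groups of sum((y - group mean)^2)` on
#' `sum(n_g - 1)` degrees of freedom. With no replicated runs the
#' lack-of-fit and pure-error rows are `NA` and a warning of class
#' `fermrsm_lof_undefined` is raised; the residual row is still
#' produced.
#'
#' On an exactly interpolating fit (residual SS numerically zero) term
#' F statistics are reported as `Inf` and the table carries attribute
#' `exact_fit = TRUE`.
#'
#' @param fit A `quad_fit` from [fit_quadratic()].
#' @param alpha Significance level for the `significant` flag
#'   (default 0.05).
#' @return A tibble of class `quad_anova` with columns `source`, `ss`,
#'   `df`, `ms`, `statistic`, `p.value`, `significant`, containing the
#'   Model row, one row per term, Residual, Lack of fit, Pure error and
#'   Corrected total. Attribute `alpha` records the level used.
#' @examples
#' fit <- fit_quadratic(fyn22_runs(), fyn22_factors())
#' anova_quad(fit)
#' @export
anova_quad <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "quad_fit"), alpha > 0, alpha < 1)
  X <- build_model_matrix(fit$data, fit$factors$symbol)
  y <- fit$y
  n <- length(y)
  rss <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  df_model <- ncol(X) - 1
  df_res <- fit$df_residual
  exact <- rss <= 1e-12 * max(ss_tot, 1)
  ms_res <- rss / df_res

  terms <- fit$term_order[-1]
  partial <- vapply(terms, function(tm) {
    j <- match(tm, colnames(X))
    sub <- qr(X[, -j, drop = FALSE])
    sum(qr.resid(sub, y)^2) - rss
  }, numeric(1))
  # guard tiny negative values from floating cancellation
  partial <- pmax(partial, 0)

  f_of <- function(ss, df) if (exact) Inf else (ss / df) / ms_res
  p_of <- function(f, df1, df2) stats::pf(f, df1, df2, lower.tail = FALSE)

  ss_model <- ss_tot - rss
  f_model <- f_of(ss_model, df_model)
  term_f <- vapply(partial, f_of, numeric(1), df = 1)

  # replicate groups for the pure-error split
  key <- apply(as.matrix(fit$data[fit$factors$symbol]), 1, paste, collapse = "\r")
  groups <- split(y, key)
  reps <- groups[vapply(groups, length, integer(1)) >= 2]
  if (length(reps) == 0) {
    rlang::warn("no replicated runs: lack of fit is undefined",
                class = "fermrsm_lof_undefined")
    ss_pe <- NA_real_; df_pe <- NA_integer_
    ss_lof <- NA_real_; df_lof <- NA_integer_
    f_lof <- NA_real_; p_lof <- NA_real_
  } else {
    ss_pe <- sum(vapply(reps, function(g) sum((g - mean(g))^2), numeric(1)))
    df_pe <- sum(vapply(reps, length, integer(1))) - length(reps)
    ss_lof <- rss - ss_pe
    df_lof <- df_res - df_pe
    f_lof <- (ss_lof / df_lof) / (ss_pe / df_pe)
    p_lof <- p_of(f_lof, df_lof, df_pe)
  }

  out <- tibble::tibble(
    source = c("Model", terms, "Residual", "Lack of fit", "Pure error",
               "Corrected total"),
    ss = c(ss_model, unname(partial), rss, ss_lof, ss_pe, ss_tot),
    df = c(df_model, rep(1L, length(terms)), df_res, df_lof, df_pe, n - 1L),
    ms = c(ss_model / df_model, unname(partial), ms_res,
           if (is.na(df_lof)) NA_real_ else ss_lof / df_lof,
           if (is.na(df_pe)) NA_real_ else ss_pe / df_pe,
           NA_real_),
    statistic = c(f_model, unname(term_f), NA_real_, f_lof, NA_real_, NA_real_),
    p.value = c(p_of(f_model, df_model, df_res),
                p_of(unname(term_f), 1, df_res),
                NA_real_, p_lof, NA_real_, NA_real_)
  )
  out$significant <- !is.na(out$p.value) & out$p.value < alpha
  structure(out, class = c("quad_anova", class(out)),
            alpha = alpha, exact_fit = exact)
}

#' Model fit statistics
#'
#' `R^2 = SS_model / SS_total`;
#' `Adj-R^2 = 1 - (1 - R^2)(n - 1)/df_residual`;
#' `CV% = 100 sqrt(MS_residual) / mean(y)`, the coefficient of
#' variation of the fit.
#'
#' @param fit A `quad_fit`.
#' @return A one-row tibble with `r2`, `adj_r2`, `cv_percent`.
#' @examples
#' fit_statistics(fit_quadratic(fyn22_runs(), fyn22_factors()))
#' @export
fit_statistics <- function(fit) {
  stopifnot(inherits(fit, "quad_fit"))
  if (fit$df_residual <= 0) {
    rlang::abort("no residual degrees of freedom", class = "fermrsm_invalid_value")
  }
  ybar <- mean(fit$y)
  if (ybar == 0) {
    rlang::abort("mean response is zero: CV undefined",
                 class = "fermrsm_invalid_value")
  }
  rss <- sum(fit$residuals^2)
  ss_tot <- sum((fit$y - ybar)^2)
  r2 <- 1 - rss / ss_tot
  n <- length(fit$y)
  tibble::tibble(
    r2 = r2,
    adj_r2 = 1 - (1 - r2) * (n - 1) / fit$df_residual,
    cv_percent = 100 * sqrt(rss / fit$df_residual) / ybar
  )
}

#' Rank factor and interaction effects
#'
#' Orders main effects by descending partial F statistic and two-factor
#' interactions by descending partial sum of squares, the conventions
#' used to read influence order off a response-surface ANOVA. Ties (to
#' `tol`) share a rank.
#'
#' @param anova A `quad_anova` tibble from [anova_quad()].
#' @param tol Absolute tolerance within which two statistics are
#'   considered tied.
#' @return A tibble with `type` (`"main"`/`"interaction"`), `term`,
#'   `metric` (F resp. SS), and integer `rank` (1 = most influential;
#'   tied terms share the smallest rank).
#' @export
rank_effects <- function(anova, tol = 1e-8) {
  stopifnot(inherits(anova, "quad_anova"))
  terms <- anova[!anova$source %in%
                   c("Model", "Residual", "Lack of fit", "Pure error",
                     "Corrected total"), ]
  is_inter <- grepl(":", terms$source, fixed = TRUE)
  is_quad <- grepl("^", terms$source, fixed = TRUE)
  rank_block <- function(term, metric) {
    o <- order(-metric)
    term <- term[o]; metric <- metric[o]
    rk <- integer(length(metric))
    if (length(metric) > 0) {
      rk[1] <- 1L
      for (i in seq_along(metric)[-1]) {
        tied <- metric[i] == metric[i - 1] ||
          isTRUE(abs(metric[i] - metric[i - 1]) <= tol)
        rk[i] <- if (tied) rk[i - 1] else i
      }
    }
    tibble::tibble(term = term, metric = metric, rank = rk)
  }
  main <- terms[!is_inter & !is_quad, ]
  inter <- terms[is_inter, ]
  dplyr::bind_rows(
    dplyr::mutate(rank_block(main$source, main$statistic), type = "main",
                  .before = 1),
    dplyr::mutate(rank_block(inter$source, inter$ss), type = "interaction",
                  .before = 1)
  )
}

#' Format an ANOVA table for display
#'
#' Renders a `quad_anova` the way response-surface software prints it:
#' SS and MS to 4 decimals, F to 2, p to 4 with values below 1e-4 shown
#' as `"<0.0001"`, and a significance annotation column.
#'
#' @param anova A `quad_anova`.
#' @return A character-matrix-backed data frame suitable for printing;
#'   also printed by `print.quad_anova`.
#' @export
format_anova <- function(anova) {
  stopifnot(inherits(anova, "quad_anova"))
  fmt_p <- function(p) {
    ifelse(is.na(p), "", ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p)))
  }
  fmt_num <- function(x, d) ifelse(is.na(x), "", sprintf(paste0("%.", d, "f"), x))
  data.frame(
    Source = anova$source,
    `Sum of squares` = fmt_num(anova$ss, 4),
    DF = ifelse(is.na(anova$df), "", anova$df),
    `Mean square` = fmt_num(anova$ms, 4),
    `F value` = fmt_num(anova$statistic, 2),
    `Prob > F` = fmt_p(anova$p.value),
    ` ` = ifelse(anova$significant & !is.na(anova$p.value), "Significant", ""),
    check.names = FALSE
  )
}

#' @export
print.quad_anova <- function(x, ...) {
  cat("Response-surface ANOVA (partial SS, alpha = ", attr(x, "alpha"), ")\n",
      sep = "")
  print(format_anova(x), row.names = FALSE, right = FALSE)
  invisible(x)
}
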