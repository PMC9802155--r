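#' Build the second-order model matrix for a design
#'
#' Expands coded factor columns into the full quadratic model basis in
#' canonical order: intercept, linear terms, two-factor interactions in
#' lexicographic pair order, then pure quadratic terms. For four factors
#' A-D the columns are
#' `(Intercept), A, B, C, D, A:B, A:C, A:D, B:C, B:D, C:D, A^2, ..., D^2`
#' (15 terms).
#'
#' @param data A data frame containing the coded columns.
#' @param symbols Character vector of coded column names, in factor
#'   order.
#' @return A numeric matrix with one row per run and named columns.
#' @export
build_model_matrix <- function(data, symbols) {
  missing <- setdiff(symbols, names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0("coded column(s) missing: ",
                        paste(missing, collapse = ", ")),
                 class = "fermrsm_invalid_value")
  }
  x <- as.matrix(data[symbols])
  storage.mode(x) <- "double"
  k <- length(symbols)
  pairs <- if (k >= 2) utils::combn(k, 2) else matrix(integer(0), nrow = 2)
  inter <- apply(pairs, 2, function(p) x[, p[1]] * x[, p[2]])
  inter <- matrix(inter, nrow = nrow(x))
  colnames(inter) <- apply(pairs, 2, function(p)
    paste0(symbols[p[1]], ":", symbols[p[2]]))
  quad <- x^2
  colnames(quad) <- paste0(symbols, "^2")
  out <- cbind(`(Intercept)` = 1, x, inter, quad)
  rownames(out) <- NULL
  out
}

#' Fit the full second-order response-surface model
#'
#' Fits the quadratic polynomial
#' \deqn{Y = \beta_0 + \sum_i \beta_i x_i + \sum_{i<j} \beta_{ij} x_i x_j
#'   + \sum_i \beta_{ii} x_i^2}
#' to a run table by ordinary least squares on the coded factors, via a
#' QR decomposition of the model matrix. This is the model a
#' Box-Behnken design is built to estimate; with `k` factors it has
#' `1 + 2k + k(k-1)/2` terms.
#'
#' @param data A run table holding the coded columns and the response;
#'   typically [fyn22_runs()], [bbd_design()] output joined with
#'   measurements, or [simulate_surface()] output.
#' @param factors The factor tibble defining symbols and the
#'   coded/actual transforms.
#' @param response Name of the response column (default `"response"`).
#' @return An object of class `quad_fit`: a list with named
#'   `coefficients` (canonical term order), `residuals`, `fitted`,
#'   `df_residual`, `sigma2` (residual mean square), `vcov_unscaled`
#'   (`(X'X)^{-1}`), the `factors` table and the coded `data`. Methods:
#'   [predict.quad_fit()], [tidy.quad_fit()], [glance.quad_fit()],
#'   [anova_quad()].
#' @examples
#' fit <- fit_quadratic(fyn22_runs(), fyn22_factors())
#' tidy(fit)
#' @export
fit_quadratic <- function(data, factors, response = "response") {
  validate_factors(factors)
  data <- tibble::as_tibble(data)
  if (!response %in% names(data)) {
    rlang::abort(paste0("response column '", response, "' not found"),
                 class = "fermrsm_invalid_value")
  }
  X <- build_model_matrix(data, factors$symbol)
  y <- as.numeric(data[[response]])
  if (nrow(X) <= ncol(X)) {
    rlang::abort("more model terms than runs; design cannot support a full quadratic",
                 class = "fermrsm_singular_design")
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    rlang::abort(paste0("model matrix is rank deficient; collinear term(s): ",
                        paste(dropped, collapse = ", ")),
                 class = "fermrsm_singular_design")
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  df_res <- nrow(X) - ncol(X)
  R <- qr.R(qrx)
  xtx_inv <- chol2inv(R)[order(qrx$pivot), order(qrx$pivot), drop = FALSE]
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  structure(list(
    coefficients = beta,
    term_order = colnames(X),
    residuals = res,
    fitted = fitted,
    y = y,
    df_residual = df_res,
    sigma2 = sum(res^2) / df_res,
    vcov_unscaled = xtx_inv,
    factors = factors,
    data = data,
    response = response
  ), class = "quad_fit")
}

#' Predict from a fitted quadratic surface
#'
#' Evaluates the fitted polynomial at coded points.
#'
#' @param object A `quad_fit`.
#' @param newdata A data frame with one coded column per factor symbol,
#'   or a numeric matrix/vector of coded coordinates in factor order.
#'   Defaults to the training runs.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.quad_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  symbols <- object$factors$symbol
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1)
  }
  if (is.matrix(newdata)) {
    if (ncol(newdata) != length(symbols)) {
      rlang::abort(paste0("points must have ", length(symbols), " coordinates"),
                   class = "fermrsm_invalid_point")
    }
    colnames(newdata) <- symbols
    newdata <- tibble::as_tibble(newdata)
  }
  if (!all(symbols %in% names(newdata))) {
    rlang::abort("newdata lacks coded factor columns",
                 class = "fermrsm_invalid_point")
  }
  X <- build_model_matrix(newdata, symbols)
  drop(X %*% object$coefficients[colnames(X)])
}

#' @export
print.quad_fit <- function(x, ...) {
  k <- nrow(x$factors)
  cat("Second-order response-surface fit (", k, " coded factors, ",
      length(x$y), " runs)\n", sep = "")
  print(round(x$coefficients, 4))
  cat("Residual df:", x$df_residual,
      " residual SD:", signif(sqrt(x$sigma2), 4), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Coefficient table of a quadratic surface fit
#'
#' @param x A `quad_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`
#'   (t) and `p.value`, in canonical term order. Estimates are on the
#'   coded scale.
#' @method tidy quad_fit
#' @export
tidy.quad_fit <- function(x, ...) {
  se <- sqrt(x$sigma2 * diag(x$vcov_unscaled))
  stat <- x$coefficients / se
  tibble::tibble(
    term = x$term_order,
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * stats::pt(-abs(unname(stat)), x$df_residual)
  )
}

#' One-row fit summary of a quadratic surface fit
#'
#' @param x A `quad_fit`.
#' @param ... Unused.
#' @return A tibble with `r.squared`, `adj.r.squared`, `cv_percent`,
#'   `sigma`, `statistic` (overall model F), `p.value`, `df` (model)
#'   and `df.residual`. See [fit_statistics()] for definitions.
#' @method glance quad_fit
#' @export
glance.quad_fit <- function(x, ...) {
  fs <- fit_statistics(x)
  p <- length(x$term_order) - 1
  ss_tot <- sum((x$y - mean(x$y))^2)
  rss <- sum(x$residuals^2)
  fstat <- ((ss_tot - rss) / p) / x$sigma2
  tibble::tibble(
    r.squared = fs$r2,
    adj.r.squared = fs$adj_r2,
    cv_percent = fs$cv_percent,
    sigma = sqrt(x$sigma2),
    statistic = fstat,
    p.value = stats::pf(fstat, p, x$df_residual, lower.tail = FALSE),
    df = p,
    df.residual = x$df_residual
  )
}

#' Re-express coded coefficients on the actual scale
#'
#' The model is fitted on coded factors; this helper algebraically
#' expands the polynomial in the actual concentrations. Derived, for
#' reporting only - all inference stays on the coded scale.
#'
#' @param fit A `quad_fit`.
#' @return A tibble with `term` (in actual-variable names) and
#'   `estimate`.
#' @export
actual_scale_coefficients <- function(fit) {
  fct <- fit$factors
  k <- nrow(fct)
  b <- fit$coefficients
  cen <- fct$center; stp <- fct$step
  lin_c <- b[fct$symbol] / stp
  quad_c <- b[paste0(fct$symbol, "^2")] / stp^2
  pairs <- utils::combn(k, 2)
  int_lab <- apply(pairs, 2, function(p) paste0(fct$symbol[p[1]], ":", fct$symbol[p[2]]))
  int_c <- b[int_lab] / (stp[pairs[1, ]] * stp[pairs[2, ]])
  # constant and linear corrections from substituting x = (v - c)/s
  b0 <- unname(b["(Intercept)"]) - sum(lin_c * cen) + sum(quad_c * cen^2) +
    sum(int_c * cen[pairs[1, ]] * cen[pairs[2, ]])
  lin_act <- lin_c - 2 * quad_c * cen
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    lin_act[i] <- lin_act[i] - int_c[p] * cen[j]
    lin_act[j] <- lin_act[j] - int_c[p] * cen[i]
  }
  tibble::tibble(
    term = c("(Intercept)", fct$name,
             apply(pairs, 2, function(p) paste0(fct$name[p[1]], ":", fct$name[p[2]])),
             paste0(fct$name, "^2")),
    estimate = unname(c(b0, lin_act, int_c, quad_c))
  )
}
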