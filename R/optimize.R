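# quadratic-form pieces of a fitted surface: b0 + g'x + x'Hx/2
quad_form <- function(fit) {
  fct <- fit$factors
  k <- nrow(fct)
  b <- fit$coefficients
  g <- unname(b[fct$symbol])
  H <- diag(2 * unname(b[paste0(fct$symbol, "^2")]), k)
  if (k >= 2) {
    pairs <- utils::combn(k, 2)
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      H[i, j] <- H[j, i] <- unname(b[paste0(fct$symbol[i], ":", fct$symbol[j])])
    }
  }
  list(b0 = unname(b["(Intercept)"]), g = g, H = H)
}

#' Stationary point of a fitted quadratic surface
#'
#' Solves the gradient system of the fitted polynomial,
#' `H x = -g` where `H` has `2 * beta_ii` on the diagonal and `beta_ij`
#' off it, and classifies the stationary point by the sign pattern of
#' the Hessian eigenvalues: all negative is a maximum, all positive a
#' minimum, mixed a saddle.
#'
#' @param fit A `quad_fit`.
#' @return A list with `coded` (named coordinates), `hessian_class`
#'   (`"maximum"`, `"minimum"` or `"saddle"`), `eigenvalues`, and
#'   `predicted` (the surface value there).
#' @examples
#' fit <- fit_quadratic(fyn22_runs(), fyn22_factors())
#' stationary_point(fit)
#' @export
stationary_point <- function(fit) {
  qf <- quad_form(fit)
  if (abs(det(qf$H)) < 1e-12 * max(abs(qf$H), 1)^nrow(qf$H)) {
    rlang::abort("Hessian is singular: degenerate surface",
                 class = "fermrsm_degenerate_surface")
  }
  x <- drop(solve(qf$H, -qf$g))
  ev <- eigen(qf$H, symmetric = TRUE, only.values = TRUE)$values
  cls <- if (all(ev < 0)) "maximum" else if (all(ev > 0)) "minimum" else "saddle"
  names(x) <- fit$factors$symbol
  list(coded = x, hessian_class = cls, eigenvalues = ev,
       predicted = unname(predict(fit, x)))
}

#' Maximize the fitted surface over the coded design cube
#'
#' Finds the global maximum of the fitted quadratic over the box of
#' tested factor levels (coded `[-1, 1]^k` by default; no
#' extrapolation). If the unconstrained stationary point is interior
#' and the Hessian negative definite, it is the maximizer and is
#' returned directly; otherwise an L-BFGS-B search with analytic
#' gradient is multistarted from every cube vertex, every face center,
#' the cube center and the clipped stationary point, and the best
#' result is kept.
#'
#' @param fit A `quad_fit`.
#' @param lower,upper Coded bounds, scalar or per-factor (default -1, 1).
#' @return An object of class `quad_optimum`: list with `coded` (tibble
#'   `symbol`, `name`, `coded`, `actual`, `g_per_l`), `predicted`
#'   response at the maximizer, `interior` (no bound active),
#'   `hessian_class` of the unconstrained stationary point, and the
#'   bounds. `tidy()` returns the coordinate tibble with the prediction
#'   attached.
#' @examples
#' fit <- fit_quadratic(fyn22_runs(), fyn22_factors())
#' maximize_in_cube(fit)
#' @export
maximize_in_cube <- function(fit, lower = -1, upper = 1) {
  fct <- fit$factors
  k <- nrow(fct)
  lower <- rep_len(lower, k); upper <- rep_len(upper, k)
  stopifnot(all(lower < upper))
  qf <- quad_form(fit)
  obj <- function(x) qf$b0 + sum(qf$g * x) + 0.5 * drop(crossprod(x, qf$H %*% x))
  grad <- function(x) qf$g + drop(qf$H %*% x)

  sp <- tryCatch(stationary_point(fit), fermrsm_degenerate_surface = function(e) NULL)
  best_x <- NULL
  if (!is.null(sp) && sp$hessian_class == "maximum" &&
      all(sp$coded >= lower & sp$coded <= upper)) {
    best_x <- unname(sp$coded)
  } else {
    verts <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
    verts <- t(t(verts * (upper - lower) / 2) + (upper + lower) / 2)
    faces <- matrix(rep((upper + lower) / 2, 2 * k), ncol = k, byrow = TRUE)
    for (i in seq_len(k)) {
      faces[2 * i - 1, i] <- lower[i]
      faces[2 * i, i] <- upper[i]
    }
    starts <- rbind(verts, faces, (upper + lower) / 2)
    if (!is.null(sp)) starts <- rbind(starts, pmin(pmax(unname(sp$coded), lower), upper))
    cand <- apply(starts, 1, function(s) {
      o <- stats::optim(s, fn = function(x) -obj(x), gr = function(x) -grad(x),
                        method = "L-BFGS-B", lower = lower, upper = upper,
                        control = list(factr = 10))
      c(o$par, -o$value)
    })
    best_x <- cand[seq_len(k), which.max(cand[k + 1, ])]
  }
  actual <- fct$center + fct$step * best_x
  coded_tbl <- tibble::tibble(
    symbol = fct$symbol, name = fct$name,
    coded = unname(best_x), actual = unname(actual),
    g_per_l = unname(actual * fct$g_per_l)
  )
  structure(list(
    coded = coded_tbl,
    predicted = unname(obj(best_x)),
    interior = all(best_x > lower + 1e-9 & best_x < upper - 1e-9),
    hessian_class = if (is.null(sp)) "degenerate" else sp$hessian_class,
    lower = lower, upper = upper
  ), class = "quad_optimum")
}

#' @export
print.quad_optimum <- function(x, ...) {
  cat("Constrained optimum of the fitted surface\n")
  print(as.data.frame(x$coded), row.names = FALSE)
  cat("Predicted response:", signif(x$predicted, 6),
      if (x$interior) "(interior)" else "(on boundary)", "\n")
  invisible(x)
}

#' @param x A `quad_optimum`.
#' @param ... Unused.
#' @rdname maximize_in_cube
#' @method tidy quad_optimum
#' @export
tidy.quad_optimum <- function(x, ...) {
  dplyr::mutate(x$coded, predicted = x$predicted,
                interior = x$interior, hessian_class = x$hessian_class)
}

#' Measured-to-predicted validation ratio
#'
#' The percent of the model's theoretical optimum actually attained in
#' a confirmation run: `100 * measured / predicted`.
#'
#' @param measured Measured response at the recommended settings.
#' @param predicted Model-predicted response there (> 0).
#' @return Percent, as a bare number (e.g. `101.083`).
#' @examples
#' validation_ratio(1.913, 1.8925)
#' @export
validation_ratio <- function(measured, predicted) {
  if (any(predicted <= 0)) {
    rlang::abort("predicted response must be > 0",
                 class = "fermrsm_invalid_prediction")
  }
  100 * measured / predicted
}

#' Evaluate a two-factor slice of the fitted surface
#'
#' Grids the fitted polynomial over two free factors with the remaining
#' factors clamped at given coded levels (the construction behind
#' response-surface/contour plots, which conventionally hold the other
#' factors at their centers).
#'
#' @param fit A `quad_fit`.
#' @param free Character vector of two factor symbols to vary.
#' @param fixed Coded levels for the clamped factors: a scalar applied
#'   to all, or a named vector by symbol. Default 0 (centers).
#' @param n Grid resolution per axis (default 101).
#' @param lower,upper Coded range of the grid.
#' @return A tibble of class `quad_slice` with the two coded columns
#'   and `predicted`; attributes `free`, `fixed` and `slice_max` (a
#'   one-row tibble with the grid maximum). Plot with [autoplot()].
#' @examples
#' fit <- fit_quadratic(fyn22_runs(), fyn22_factors())
#' sl <- surface_slice(fit, c("A", "B"))
#' attr(sl, "slice_max")
#' @export
surface_slice <- function(fit, free, fixed = 0, n = 101,
                          lower = -1, upper = 1) {
  symbols <- fit$factors$symbol
  if (length(free) != 2 || !all(free %in% symbols)) {
    rlang::abort("free must name two factor symbols of the fit",
                 class = "fermrsm_invalid_factor")
  }
  held <- setdiff(symbols, free)
  if (length(fixed) == 1 && is.null(names(fixed))) {
    fixed <- stats::setNames(rep(fixed, length(held)), held)
  }
  if (!all(held %in% names(fixed))) {
    rlang::abort("fixed levels must cover all held factors",
                 class = "fermrsm_invalid_factor")
  }
  grid <- tidyr::expand_grid(
    ..x1 = seq(lower, upper, length.out = n),
    ..x2 = seq(lower, upper, length.out = n)
  )
  names(grid) <- free
  for (h in held) grid[[h]] <- unname(fixed[h])
  grid$predicted <- predict(fit, grid[symbols])
  out <- grid[c(free, "predicted")]
  mx <- out[which.max(out$predicted), ]
  structure(out, class = c("quad_slice", class(out)),
            free = free, fixed = fixed[held], slice_max = mx)
}
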