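test_that("model matrix has canonical columns and full rank on the fixture", {
  X <- build_model_matrix(fx_runs, fx_factors$symbol)
  expect_equal(colnames(X),
               c("(Intercept)", "A", "B", "C", "D",
                 "A:B", "A:C", "A:D", "B:C", "B:D", "C:D",
                 "A^2", "B^2", "C^2", "D^2"))
  expect_equal(unname(X[1, ]), c(1, rep(0, 14)))  # a center run
  row <- build_model_matrix(tibble::tibble(A = 1, B = 1, C = 0, D = 0),
                            fx_factors$symbol)
  expect_equal(unname(row[1, c("A:B", "A^2", "B^2", "C^2", "D^2")]),
               c(1, 1, 1, 0, 0))
  expect_equal(qr(X)$rank, 15)
})

test_that("refit of the 29-run spore dataset reproduces the published model", {
  b <- fx_fit$coefficients
  expect_equal(unname(b["(Intercept)"]), 1.842, tolerance = 1e-10)
  expect_equal(unname(b["A"]), -31 / 600, tolerance = 1e-10)   # -0.0517
  expect_equal(unname(b["B"]), -59 / 1200, tolerance = 1e-10)  # -0.0492
  expect_equal(unname(b["C"]), 61 / 1200, tolerance = 1e-10)   # 0.0508
  expect_equal(unname(b["D"]), 0.045, tolerance = 1e-10)
  expect_equal(unname(b["A:B"]), 0.065, tolerance = 1e-10)
  expect_equal(unname(b["B^2"]), -0.161, tolerance = 1e-10)
  # linear coefficients equal their contrast closed form sum(x_i * y)/12
  m <- as.matrix(fx_runs[c("A", "B", "C", "D")])
  for (s in c("A", "B", "C", "D")) {
    expect_equal(unname(b[s]), sum(m[, s] * fx_runs$response) / 12,
                 tolerance = 1e-12)
  }
  # hand summation for A: (sum y at A=+1 minus sum y at A=-1) / 12
  expect_equal(unname(b["A"]),
               (sum(fx_runs$response[fx_runs$A == 1]) -
                  sum(fx_runs$response[fx_runs$A == -1])) / 12,
               tolerance = 1e-12)
})

test_that("least squares agrees with lm() and the normal equations", {
  lmfit <- lm(response ~ A + B + C + D + A:B + A:C + A:D + B:C + B:D + C:D +
                I(A^2) + I(B^2) + I(C^2) + I(D^2), data = fx_runs)
  expect_equal(unname(sort(fx_fit$coefficients)),
               unname(sort(coef(lmfit))), tolerance = 1e-10)
  X <- build_model_matrix(fx_runs, fx_factors$symbol)
  beta_ne <- solve(crossprod(X), crossprod(X, fx_runs$response))
  expect_equal(unname(fx_fit$coefficients), unname(drop(beta_ne)),
               tolerance = 1e-10)
  # residuals orthogonal to every model column
  expect_lt(max(abs(crossprod(X, fx_fit$residuals))), 1e-8)
  # fitted + residual reproduces y
  expect_equal(fx_fit$fitted + fx_fit$residuals, fx_runs$response)
})

test_that("noiseless simulated surfaces are recovered exactly and refits are stable", {
  truth <- c("(Intercept)" = 1.8, A = -0.05, B = 0.03, C = 0.02, D = -0.04,
             "A:B" = 0.06, "C:D" = 0.01,
             "A^2" = -0.1, "B^2" = -0.15, "C^2" = -0.05, "D^2" = -0.07)
  sim <- simulate_surface(fx_factors, truth, noise_sd = 0, seed = 5)
  fit <- fit_quadratic(sim, fx_factors)
  full <- setNames(numeric(15), fit$term_order)
  full[names(truth)] <- truth
  expect_equal(fit$coefficients, full, tolerance = 1e-10)
  # refit on fitted values returns identical coefficients
  sim2 <- fx_runs
  sim2$response <- fx_fit$fitted
  expect_equal(fit_quadratic(sim2, fx_factors)$coefficients,
               fx_fit$coefficients, tolerance = 1e-10)
})

test_that("rank-deficient designs fail with the collinear terms named", {
  dup <- fx_runs
  dup$D <- dup$C  # makes C and D columns identical
  dup$fecl3 <- dup$nh4cl
  expect_error(fit_quadratic(dup, fx_factors), "collinear",
               class = "fermrsm_singular_design")
  few <- fx_runs[1:10, ]
  expect_error(fit_quadratic(few, fx_factors),
               class = "fermrsm_singular_design")
})

test_that("prediction matches term-by-term accumulation at arbitrary points", {
  expect_equal(predict(fx_fit, c(0, 0, 0, 0)),
               unname(fx_fit$coefficients["(Intercept)"]))
  set.seed(11)
  pts <- matrix(runif(40, -1, 1), ncol = 4)
  manual <- apply(pts, 1, function(p) {
    b <- fx_fit$coefficients
    acc <- b["(Intercept)"]
    syms <- c("A", "B", "C", "D")
    for (i in 1:4) acc <- acc + b[syms[i]] * p[i] + b[paste0(syms[i], "^2")] * p[i]^2
    for (i in 1:3) for (j in (i + 1):4) {
      acc <- acc + b[paste0(syms[i], ":", syms[j])] * p[i] * p[j]
    }
    unname(acc)
  })
  expect_equal(predict(fx_fit, pts), manual, tolerance = 1e-12)
  expect_error(predict(fx_fit, c(0, 0)), class = "fermrsm_invalid_point")
})

test_that("tidy and glance expose the broom-style summaries", {
  td <- tidy(fx_fit)
  expect_equal(td$term, fx_fit$term_order)
  expect_true(all(td$std.error > 0))
  lmfit <- lm(response ~ A + B + C + D + A:B + A:C + A:D + B:C + B:D + C:D +
                I(A^2) + I(B^2) + I(C^2) + I(D^2), data = fx_runs)
  lms <- summary(lmfit)$coefficients
  expect_equal(sort(td$std.error), sort(unname(lms[, 2])), tolerance = 1e-8)
  gl <- glance(fx_fit)
  expect_printed(gl$r.squared, 0.9216, 4)
  expect_equal(gl$df, 14)
})

test_that("actual-scale re-expression evaluates identically to the coded fit", {
  ac <- actual_scale_coefficients(fx_fit)
  eval_actual <- function(v) {
    # v named by factor name
    b <- setNames(ac$estimate, ac$term)
    acc <- b[["(Intercept)"]]
    nms <- fx_factors$name
    for (nm in nms) acc <- acc + b[[nm]] * v[[nm]] + b[[paste0(nm, "^2")]] * v[[nm]]^2
    for (i in 1:3) for (j in (i + 1):4) {
      acc <- acc + b[[paste0(nms[i], ":", nms[j])]] * v[[nms[i]]] * v[[nms[j]]]
    }
    acc
  }
  set.seed(3)
  for (r in 1:10) {
    coded <- runif(4, -1, 1)
    actual <- setNames(fx_factors$center + fx_factors$step * coded,
                       fx_factors$name)
    expect_equal(eval_actual(as.list(actual)), predict(fx_fit, coded),
                 tolerance = 1e-9)
  }
})
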