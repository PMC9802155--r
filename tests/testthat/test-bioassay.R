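test_that("four-arm inhibition arithmetic handles the canonical cases", {
  p <- dppiv_inhibition(tibble::tibble(dX = 0.5, dP = 0.1, dS = 0.9, dT = 0.1))
  expect_equal(p$inhibition_pct, 50)
  expect_false(p$flagged)
  # numerator zero: complete inhibition
  expect_equal(dppiv_inhibition(tibble::tibble(dX = 0.2, dP = 0.2, dS = 1,
                                               dT = 0.1))$inhibition_pct, 100)
  # full enzyme activity retained
  expect_equal(dppiv_inhibition(tibble::tibble(dX = 0.9, dP = 0.1, dS = 0.9,
                                               dT = 0.1))$inhibition_pct, 0)
  out <- dppiv_inhibition(tibble::tibble(dX = c(1.2, 0.0), dP = c(0.1, 0.2),
                                         dS = 1, dT = 0.2))
  expect_true(all(out$flagged))  # activation and over-blanking both flagged
  expect_error(dppiv_inhibition(tibble::tibble(dX = 1, dP = 1, dS = 0.1,
                                               dT = 0.2)),
               class = "fermrsm_invalid_control")
})

test_that("inhibition depends only on the two well differences", {
  set.seed(21)
  base <- tibble::tibble(dX = runif(20, 0.2, 0.8), dP = runif(20, 0, 0.2),
                         dS = runif(20, 0.9, 1.2), dT = runif(20, 0, 0.2))
  shift <- runif(1)
  shifted <- dplyr::mutate(base, dX = dX + shift, dP = dP + shift,
                           dS = dS + shift, dT = dT + shift)
  expect_equal(dppiv_inhibition(shifted)$inhibition_pct,
               dppiv_inhibition(base)$inhibition_pct, tolerance = 1e-12)
})

test_that("standard curves fit the published 8-level design and invert exactly", {
  conc <- c(0, 0.5, 1, 5, 10, 15, 20, 25)
  # exact line conc = 30*od: perfect recovery
  exact <- tibble::tibble(od = conc / 30, conc = conc)
  cv <- fit_standard_curve(exact)
  expect_equal(cv$slope, 30, tolerance = 1e-10)
  expect_equal(cv$intercept, 0, tolerance = 1e-10)
  expect_equal(cv$r2, 1, tolerance = 1e-12)
  # closed-form simple-regression oracle on noisy synthetic ODs
  set.seed(8)
  pts <- tibble::tibble(od = conc / 30 + rnorm(8, 0, 0.01), conc = conc)
  cv2 <- fit_standard_curve(pts)
  sxy <- sum((pts$od - mean(pts$od)) * (pts$conc - mean(pts$conc)))
  sxx <- sum((pts$od - mean(pts$od))^2)
  expect_equal(cv2$slope, sxy / sxx, tolerance = 1e-10)
  expect_equal(cv2$intercept, mean(pts$conc) - cv2$slope * mean(pts$od),
               tolerance = 1e-10)
  # permutation invariance
  cv3 <- fit_standard_curve(pts[sample(8), ])
  expect_equal(cv3$slope, cv2$slope, tolerance = 1e-12)
  expect_error(fit_standard_curve(pts[1:2, ]), class = "fermrsm_invalid_value")
  expect_error(fit_standard_curve(tibble::tibble(od = rep(0.5, 4),
                                                 conc = 1:4)),
               class = "fermrsm_degenerate_curve")
})

test_that("IAA quantification reads samples off the curve with dilution", {
  cv <- fit_standard_curve(tibble::tibble(od = c(0, 0.25, 0.5, 1),
                                          conc = 30 * c(0, 0.25, 0.5, 1)))
  q <- quantify_iaa(tibble::tibble(od = 0.5, dilution = 4), cv)
  expect_equal(q$conc, 60)
  expect_false(q$out_of_range)
  expect_equal(quantify_iaa(tibble::tibble(od = 0), cv)$conc, 0)
  # in-range ODs invert the perfect line exactly
  ods <- seq(0.05, 0.95, by = 0.1)
  expect_equal(quantify_iaa(tibble::tibble(od = ods), cv)$conc, 30 * ods,
               tolerance = 1e-10)
  expect_true(quantify_iaa(tibble::tibble(od = 1.5), cv)$out_of_range)
  expect_error(quantify_iaa(tibble::tibble(od = 0.5, dilution = 0.5), cv),
               class = "fermrsm_invalid_dilution")
})

test_that("survival rates reproduce the published tolerance table", {
  out <- survival_rate(fyn22_tolerance())
  expect_equal(round(out$survival_pct, 2),
               c(85.98, 93.12, 96.30, 93.65, 90.33, 87.29))
  expect_equal(survival_rate(tibble::tibble(initial_count = 2,
                                            final_count = 2))$survival_pct, 100)
  # scale invariance
  sc <- survival_rate(dplyr::mutate(fyn22_tolerance(),
                                    initial_count = initial_count * 7.3,
                                    final_count = final_count * 7.3))
  expect_equal(sc$survival_pct, out$survival_pct, tolerance = 1e-12)
  expect_error(survival_rate(tibble::tibble(initial_count = 0, final_count = 1)),
               class = "fermrsm_invalid_count")
})

test_that("seedling growth promotion reproduces the published percent gains", {
  gp <- growth_promotion(fyn22_seedlings())
  g <- setNames(gp$pct_change, gp$trait)
  expect_printed(unname(g["shoot_length_mm"]), 48.31, 2)
  expect_printed(unname(g["root_length_mm"]), 16.73, 2)
  expect_printed(unname(g["dry_weight_mg"]), 21.97, 2)
  # fresh weight recomputes to ~18.46% from the table means
  expect_printed(unname(g["fresh_weight_mg"]), 18.46, 2)
  # shoot length highly significant, fresh weight significant at 0.05 only
  p <- setNames(gp$p.value, gp$trait)
  expect_lt(p[["shoot_length_mm"]], 0.01)
  expect_lt(p[["fresh_weight_mg"]], 0.05)
  expect_gt(p[["fresh_weight_mg"]], 0.01)
})

test_that("summary-statistic Welch test agrees with t.test on raw data", {
  raw <- simulate_seedlings(fyn22_seedlings(), n = 20, seed = 14)
  summ <- raw |>
    dplyr::group_by(trait, group) |>
    dplyr::summarise(mean = mean(value), sd = sd(value), n = dplyr::n(),
                     .groups = "drop")
  gp <- growth_promotion(summ)
  for (tr in unique(raw$trait)) {
    tt <- t.test(value ~ group, data = raw[raw$trait == tr, ])
    row <- gp[gp$trait == tr, ]
    expect_equal(abs(row$statistic), abs(unname(tt$statistic)), tolerance = 1e-8)
    expect_equal(row$p.value, tt$p.value, tolerance = 1e-8)
    expect_equal(row$df, unname(tt$parameter), tolerance = 1e-6)
  }
  # pooled variant matches var.equal t.test
  gp2 <- growth_promotion(summ, var_equal = TRUE)
  tt2 <- t.test(value ~ group, data = raw[raw$trait == "dry_weight_mg", ],
                var.equal = TRUE)
  expect_equal(abs(gp2$statistic[gp2$trait == "dry_weight_mg"]),
               abs(unname(tt2$statistic)), tolerance = 1e-8)
  # identical groups: zero change, p = 1
  same <- tibble::tibble(trait = "x", group = c("control", "treatment"),
                         mean = 5, sd = 1, n = 10)
  out <- growth_promotion(same)
  expect_equal(out$pct_change, 0)
  expect_equal(out$p.value, 1)
})

test_that("Welch p-value matches a permutation test within Monte Carlo error", {
  raw <- simulate_seedlings(
    tibble::tibble(trait = "t", group = c("control", "treatment"),
                   mean = c(10, 11), sd = c(1.5, 1.5)),
    n = 20, seed = 99
  )
  x <- raw$value[raw$group == "control"]
  y <- raw$value[raw$group == "treatment"]
  obs <- abs(mean(y) - mean(x))
  pool <- c(x, y)
  set.seed(5)
  perm <- replicate(1e4, {
    idx <- sample(40, 20)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  summ <- tibble::tibble(trait = "t", group = c("control", "treatment"),
                         mean = c(mean(x), mean(y)), sd = c(sd(x), sd(y)),
                         n = 20)
  p_welch <- growth_promotion(summ)$p.value
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / 1e4) + 0.01
  expect_lt(abs(p_welch - p_perm), max(mc_err, 0.02))
})
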