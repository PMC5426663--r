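test_that("mid-parent difference arithmetic matches published trial means", {
  expect_equal(mid_parent_difference(2204, 1934, 2096), 189)
  expect_equal(mid_parent_difference(941, 791, 889), 101)
  expect_equal(mid_parent_difference(5, 5, 5), 0)
  x <- rnorm(5, 100)
  expect_equal(mid_parent_difference(x[1], x[2], x[3]),
               x[1] - mean(x[2:3]))
})

test_that("externally studentized residuals match a leave-one-out oracle", {
  plots <- make_plot_fixture(n = 30, seed = 42)
  r <- studentized_residuals(plots, "yield")
  # brute-force oracle: refit without each observation, standardize its
  # deletion residual by the deleted fit's error
  fml <- yield ~ genotype + block + poly(row, 4, raw = TRUE) +
    poly(column, 4, raw = TRUE)
  oracle <- vapply(seq_len(nrow(plots)), function(i) {
    fit_i <- lm(fml, data = plots[-i, ])
    pr <- predict(fit_i, newdata = plots[i, ], se.fit = TRUE)
    (plots$yield[i] - pr$fit) / sqrt(pr$residual.scale^2 + pr$se.fit^2)
  }, 0)
  expect_equal(r, oracle, tolerance = 1e-8)
})

test_that("outlier screening drops exactly the planted aberrant plot", {
  tt <- trial_truth(seed = 11, residual_sd = 150, locations = "Kinston")
  plots <- simulate_trial(tt)
  victim <- 17
  plots$yield[victim] <- plots$yield[victim] + 10 * 150
  out <- flag_outliers(plots, "yield")
  expect_equal(nrow(out$dropped), 1)
  expect_equal(out$dropped$row, plots$row[victim])
  expect_equal(out$dropped$column, plots$column[victim])
  # noise-free data has no outliers
  tt0 <- trial_truth(seed = 11, residual_sd = 0, block_sd = 0,
                     locations = "Kinston")
  expect_equal(nrow(flag_outliers(simulate_trial(tt0), "yield")$dropped), 0)
})

test_that("trend covariate elimination recovers a planted quadratic", {
  tt <- trial_truth(seed = 5, residual_sd = 50, heterosis_shift = 0,
                    row_poly = c(0, 0, 30), locations = "Kinston",
                    n_blocks = 5)
  plots <- simulate_trial(tt)
  kept <- select_trend_covariates(plots, "yield")
  expect_setequal(kept, c("row1", "row2"))
})

test_that("no planted trend leaves the covariate set empty in most runs", {
  empties <- vapply(1:7, function(s) {
    tt <- trial_truth(seed = 5 + s, residual_sd = 150, locations = "Kinston")
    length(select_trend_covariates(simulate_trial(tt), "yield")) == 0
  }, logical(1))
  expect_gt(mean(empties), 0.5)
})

test_that("hierarchy rule keeps lower orders under a significant cubic", {
  # trend = component of row^3 orthogonal to {1, row, row^2}: sequential
  # tests then see nothing at orders 1-2 and a large effect at order 3
  set.seed(8)
  n <- 60
  d <- data.frame(location = "L", block = rep(c("B1", "B2"), each = n / 2),
                  row = rep(1:30, 2), column = rep(1:2, each = n / 2),
                  genotype = rep(c("A", "B"), n / 2),
                  stringsAsFactors = FALSE)
  x <- d$row - mean(d$row)
  cubic <- resid(lm(I(x^3) ~ x + I(x^2)))
  d$yield <- 100 + 40 * cubic / sd(cubic) + rnorm(n, 0, 5)
  kept <- select_trend_covariates(d, "yield")
  expect_true(all(c("row1", "row2", "row3") %in% kept))
})

test_that("adjusted means and covariance match the normal-equations oracle", {
  plots <- make_plot_fixture(n = 20, seed = 3)
  fit <- fit_location_model(plots, "yield", covariates = character(0))
  # direct matrix solve
  X <- model.matrix(~ genotype + block, data = plots)
  beta <- solve(crossprod(X), crossprod(X, plots$yield))
  s2 <- sum((plots$yield - X %*% beta)^2) / (nrow(X) - ncol(X))
  L <- rbind(A = c(1, 0, 0, 0.5), B = c(1, 1, 0, 0.5), C = c(1, 0, 1, 0.5))
  expect_equal(unname(coef(fit)), unname(drop(L %*% beta)), tolerance = 1e-10)
  Vo <- L %*% (s2 * solve(crossprod(X))) %*% t(L)
  expect_equal(unname(vcov(fit)), unname(Vo), tolerance = 1e-10)
})

test_that("adjusted means are translation equivariant", {
  plots <- make_plot_fixture(n = 30, seed = 12)
  f1 <- fit_location_model(plots, "yield")
  plots$yield <- plots$yield + 37
  f2 <- fit_location_model(plots, "yield")
  expect_equal(coef(f2), coef(f1) + 37, tolerance = 1e-9)
  # contrasts invariant to translation, equivariant to scaling
  cc <- c(A = 1, B = -0.5, C = -0.5)
  expect_equal(trial_contrast(f1, cc)$estimate, trial_contrast(f2, cc)$estimate,
               tolerance = 1e-9)
  plots$yield <- plots$yield * 2
  f3 <- fit_location_model(plots, "yield")
  expect_equal(trial_contrast(f3, cc)$estimate,
               2 * trial_contrast(f2, cc)$estimate, tolerance = 1e-9)
})

test_that("contrast statistics match the direct formula oracle", {
  plots <- make_plot_fixture(n = 30, seed = 7)
  fit <- fit_location_model(plots, "yield")
  cc <- c(A = 1, B = -0.5, C = -0.5)
  res <- trial_contrast(fit, cc)
  est <- sum(cc * coef(fit)[names(cc)])
  se <- sqrt(drop(t(cc) %*% vcov(fit)[names(cc), names(cc)] %*% cc))
  expect_equal(res$estimate, est)
  expect_equal(res$std_error, se)
  expect_equal(res$p_value, 2 * pt(-abs(est / se), fit$df))
  # one-sided halves the two-sided p on the hypothesized side
  res1 <- trial_contrast(fit, cc, one_sided = TRUE)
  expect_equal(res1$p_value,
               if (est > 0) res$p_value / 2 else 1 - res$p_value / 2)
})

test_that("contrast contracts are enforced", {
  plots <- make_plot_fixture(n = 30, seed = 7)
  fit <- fit_location_model(plots, "yield")
  expect_error(trial_contrast(fit, c(A = 1, B = -0.5)), "sum to zero")
  expect_error(trial_contrast(fit, c(A = 1, A = -1)), "duplicated")
  # equal fitted means give estimate 0 and two-sided p = 1
  plots$yield <- 100
  fit0 <- suppressWarnings(fit_location_model(plots, "yield"))
  r0 <- trial_contrast(fit0, c(A = 1, B = -1))
  expect_equal(r0$estimate, 0)
})

test_that("pooled contrasts follow inverse-variance weighting", {
  mk <- function(est, se, df = 20)
    structure(data.frame(label = "c", estimate = est, std_error = se,
                         df = df, p_value = NA, one_sided = FALSE),
              class = c("contrast_result", "data.frame"))
  # equal inputs: same estimate, SE shrinks by sqrt(2)
  p <- pooled_contrast(list(mk(5, 2), mk(5, 2)))
  expect_equal(p$estimate, 5)
  expect_equal(p$std_error, 2 / sqrt(2))
  # GLS oracle on unequal variances
  e <- c(3, 7); s <- c(1, 3)
  p2 <- pooled_contrast(list(mk(e[1], s[1]), mk(e[2], s[2])))
  w <- 1 / s^2
  expect_equal(p2$estimate, sum(w * e) / sum(w))
  expect_equal(p2$std_error, sqrt(1 / sum(w)))
  # an (effectively) infinite-variance location carries no weight
  p3 <- pooled_contrast(list(mk(3, 1), mk(100, 1e8)))
  expect_equal(p3$estimate, 3, tolerance = 1e-6)
  # single estimable location returns that location's result with warning
  expect_warning(p4 <- pooled_contrast(list(mk(3, 1))), "one location")
  expect_equal(p4$estimate, 3)
})

test_that("heterosis report reproduces published contrasts from its means", {
  plots <- table2_plots()
  r <- heterosis_report(plots, traits = c("yield", "protein",
                                          "harvestable_protein"))
  g <- function(tr, loc, con)
    r$estimate[r$trait == tr & r$location == loc & r$contrast == con]
  expect_equal(g("yield", "Kinston", "F1_vs_midparent"), 189)
  expect_equal(g("yield", "Clayton", "F1_vs_midparent"), 223)
  expect_equal(g("protein", "Kinston", "F1_vs_midparent"), 1.1)
  expect_equal(g("harvestable_protein", "Kinston", "F1_vs_midparent"), 101)
  expect_equal(g("harvestable_protein", "Clayton", "F1_vs_midparent"), 100)
  expect_equal(g("yield", "Clayton", "F2_vs_midparent"), 134)
  # inbreeding depression: F2 yield below F1 at both locations
  ib <- attr(r, "inbreeding_depression")
  expect_true(all(ib$f2_below_f1))
  # identical means everywhere give zero contrasts
  plots0 <- plots; plots0$yield <- 1; plots0$protein <- 1
  plots0$harvestable_protein <- 1
  r0 <- heterosis_report(plots0)
  expect_true(all(r0$estimate == 0))
})

test_that("harvestable protein is derived from yield and protein if absent", {
  plots <- table2_plots()
  plots$harvestable_protein <- NULL
  r <- heterosis_report(plots, traits = "harvestable_protein")
  est <- r$estimate[r$location == "Kinston" & r$contrast == "F1_vs_midparent"]
  # derived per-plot values: 2204*46/100 etc.
  expect_equal(est, 2204 * 0.460 - (1934 * 0.441 + 2096 * 0.457) / 2,
               tolerance = 1e-9)
})
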