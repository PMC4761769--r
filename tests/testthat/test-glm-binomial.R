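test_that("intercept-only fit recovers the pooled logit in closed form", {
  d <- data.frame(y = c(1, 2, 1, 1), n = c(4, 4, 4, 8))
  fit <- binom_glm(cbind(y, n - y) ~ 1, d)
  expect_equal(unname(coef(fit)), qlogis(5 / 20), tolerance = 1e-8)
  expect_equal(fit$deviance, fit$null_deviance, tolerance = 1e-8)
  expect_equal(percent_deviance_explained(fit), 0, tolerance = 1e-6)
})

test_that("IRLS matches an independent Newton maximizer on random data", {
  for (s in 1:20) {
    rd <- random_binom_data(12, n_cov = 2, seed = 400 + s)
    fit <- suppressWarnings(binom_glm(cbind(y, n - y) ~ x1 + x2, rd$data))
    oracle <- newton_binom(rd$X, rd$y, rd$n)
    expect_equal(unname(coef(fit)), oracle, tolerance = 1e-6)
  }
})

test_that("IRLS fixed point satisfies the score equations", {
  for (s in 1:5) {
    rd <- random_binom_data(30, n_cov = 2, seed = 50 + s)
    fit <- suppressWarnings(binom_glm(cbind(y, n - y) ~ x1 + x2, rd$data))
    score <- crossprod(fit$x, fit$successes -
                         fit$prior_trials * fit$fitted_p)
    expect_lt(max(abs(score)), 1e-6)
  }
})

test_that("fit agrees with stats::glm as an independent cross-check", {
  d <- simulate_survey(survey_params(seed = 9))
  d <- d[!is.na(d$girth_m), ]
  f <- cbind(n_sp_positive, n_samples - n_sp_positive) ~
    girth_m * region + tmax_c * region
  # the south intercept offset is legitimately large with Tmax in degC,
  # so the separation guard warns; the comparison is unaffected
  fit <- suppressWarnings(binom_glm(f, d))
  ref <- glm(f, binomial, d)
  expect_equal(coef(fit), coef(ref), tolerance = 1e-6)
  expect_equal(fit$deviance, deviance(ref), tolerance = 1e-8)
  expect_equal(fit$null_deviance, ref$null.deviance, tolerance = 1e-8)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
})

test_that("saturated model has zero residual deviance", {
  d <- data.frame(id = factor(1:6), y = c(0, 1, 2, 3, 4, 2), n = 4)
  fit <- suppressWarnings(binom_glm(cbind(y, n - y) ~ id, d))
  expect_equal(fit$deviance, 0, tolerance = 1e-6)
  expect_equal(percent_deviance_explained(fit), 100, tolerance = 1e-4)
})

test_that("deviance is invariant to affine covariate rescaling", {
  rd <- random_binom_data(25, n_cov = 1, seed = 77)
  d <- rd$data
  d$x_scaled <- 10 * d$x1 + 3
  f1 <- suppressWarnings(binom_glm(cbind(y, n - y) ~ x1, d))
  f2 <- suppressWarnings(binom_glm(cbind(y, n - y) ~ x_scaled, d))
  expect_equal(f1$deviance, f2$deviance, tolerance = 1e-8)
  expect_equal(unname(coef(f1)["x1"]), 10 * unname(coef(f2)["x_scaled"]),
               tolerance = 1e-6)
})

test_that("adding a term never increases residual deviance", {
  set.seed(123)
  for (s in 1:10) {
    rd <- random_binom_data(30, n_cov = 3, seed = 800 + s)
    d <- rd$data
    f0 <- suppressWarnings(binom_glm(cbind(y, n - y) ~ x1, d))
    f1 <- suppressWarnings(binom_glm(cbind(y, n - y) ~ x1 + x2, d))
    f2 <- suppressWarnings(binom_glm(cbind(y, n - y) ~ x1 + x2 + x3, d))
    expect_lte(f1$deviance, f0$deviance + 1e-8)
    expect_lte(f2$deviance, f1$deviance + 1e-8)
  }
})

test_that("rank-deficient designs fail naming the aliased term", {
  d <- data.frame(y = c(1, 2, 1), n = 4, x1 = c(1, 2, 3))
  d$x2 <- 2 * d$x1
  expect_error(binom_glm(cbind(y, n - y) ~ x1 + x2, d),
               "rank deficient.*x2")
})

test_that("LRT p-values match chi-square integration and oracle refits", {
  # identical specs: zero deviance change, p = 1
  rd <- random_binom_data(15, seed = 31)
  f <- suppressWarnings(binom_glm(cbind(y, n - y) ~ x1, rd$data))
  same <- binom_lrt(f, f)
  expect_equal(same$delta_deviance, 0)
  expect_equal(same$p_value, 1)
  # the 1%-critical chi-square value on 1 df
  expect_equal(pchisq(6.63, 1, lower.tail = FALSE),
               chisq_upper_by_integration(6.63, 1), tolerance = 1e-8)
  expect_equal(round(chisq_upper_by_integration(6.63, 1), 3), 0.010)
  # delta deviance agrees with oracle refits of both models
  rd <- random_binom_data(20, n_cov = 2, seed = 32)
  full <- suppressWarnings(binom_glm(cbind(y, n - y) ~ x1 + x2, rd$data))
  red <- suppressWarnings(binom_glm(cbind(y, n - y) ~ x1, rd$data))
  lr <- binom_lrt(red, full)
  b_full <- newton_binom(rd$X, rd$y, rd$n)
  b_red <- newton_binom(rd$X[, 1:2], rd$y, rd$n)
  dev_o <- function(Xb) binom_dev_oracle(rd$y, rd$n, plogis(Xb))
  expect_equal(lr$delta_deviance,
               dev_o(rd$X[, 1:2] %*% b_red) - dev_o(rd$X %*% b_full),
               tolerance = 1e-6)
  expect_equal(lr$p_value,
               chisq_upper_by_integration(lr$delta_deviance, 1),
               tolerance = 1e-8)
  expect_error(binom_lrt(full, red), "nested")
})

test_that("Wald intervals cover generating coefficients at about 95%", {
  set.seed(2024)
  hits <- 0L
  total <- 0L
  for (r in 1:120) {
    X <- cbind(1, rnorm(250), rnorm(250))
    beta <- c(-0.5, 0.7, -0.4)
    n <- rep(4L, 250)
    y <- rbinom(250, n, plogis(drop(X %*% beta)))
    d <- data.frame(y = y, n = n, x1 = X[, 2], x2 = X[, 3])
    fit <- binom_glm(cbind(y, n - y) ~ x1 + x2, d)
    lo <- coef(fit) - 1.96 * fit$se
    hi <- coef(fit) + 1.96 * fit$se
    hits <- hits + sum(lo <= beta & beta <= hi)
    total <- total + 3L
  }
  expect_gt(hits / total, 0.91)
  expect_lt(hits / total, 0.99)
})

test_that("stepwise drops a null covariate and alpha = 0 strips the model", {
  d <- simulate_survey(survey_params(seed = 42))
  f0 <- cbind(n_sp_positive, n_samples - n_sp_positive) ~
    girth_m * region + tmax_c * region + other_yeast_freq
  sel <- suppressWarnings(stepwise_simplify(f0, d, alpha = 0.05))
  kept <- attr(terms(sel$formula), "term.labels")
  expect_false("other_yeast_freq" %in% kept)
  # every tested deletion is logged with its test
  expect_true(all(c("term", "delta_deviance", "delta_df", "p_value",
                    "deleted") %in% names(sel$log)))
  expect_true("other_yeast_freq" %in% sel$log$term[sel$log$deleted])
  # alpha = 0 accepts every deletion down to the intercept
  sel0 <- suppressWarnings(stepwise_simplify(f0, d, alpha = 0))
  expect_length(attr(terms(sel0$formula), "term.labels"), 0)
})

test_that("stepwise comparisons share one fixed row set despite missing girth", {
  d <- simulate_survey(survey_params(seed = 8))
  expect_true(anyNA(d$girth_m))
  sel <- suppressWarnings(stepwise_simplify(
    cbind(n_sp_positive, n_samples - n_sp_positive) ~
      girth_m * region + tmax_c * region, d))
  expect_equal(nrow(sel$fit$model_frame), sum(!is.na(d$girth_m)))
})

test_that("collapsing identical-effect factor levels is accepted", {
  # merge-nothing grouping reparameterises: delta deviance 0, p = 1
  d <- simulate_survey(survey_params(seed = 4))
  f <- cbind(n_sp_positive, n_samples - n_sp_positive) ~ oak_type
  res0 <- collapse_factor(f, d, "oak_type",
                          c("robur-like" = "a", "frainetto-like" = "b",
                            "ilex" = "c"))
  expect_equal(res0$lrt$delta_deviance, 0, tolerance = 1e-6)
  expect_equal(res0$lrt$p_value, 1, tolerance = 1e-6)
  # frainetto-like and ilex share a generating effect (region south), so
  # collapsing them onto region is usually accepted
  accepted <- 0L
  for (s in 1:40) {
    ds <- simulate_survey(survey_params(seed = 600 + s))
    res <- suppressWarnings(collapse_factor(
      cbind(n_sp_positive, n_samples - n_sp_positive) ~
        girth_m * oak_type + tmax_c * oak_type,
      ds, "oak_type",
      c("robur-like" = "north", "frainetto-like" = "south",
        "ilex" = "south")))
    expect_gte(res$lrt$delta_df, 1L)
    if (res$lrt$p_value > 0.05) accepted <- accepted + 1L
  }
  # true acceptance rate is ~95%; 34/40 bounds the >=90% claim with
  # Monte Carlo slack
  expect_gte(accepted, 34L)
  expect_error(collapse_factor(f, d, "oak_type", c("robur-like" = "x")),
               "grouping")
})

test_that("collapse is rejected when levels have distinct effects", {
  rejected <- 0L
  for (s in 1:25) {
    set.seed(700 + s)
    lv <- sample(rep(c("a", "b", "c"), each = 60))
    eta <- c(a = -2, b = 0.5, c = -2)[lv]
    d <- data.frame(lv = lv, n = 6,
                    y = rbinom(180, 6, plogis(unname(eta))))
    res <- collapse_factor(cbind(y, n - y) ~ lv, d, "lv",
                           c(a = "g1", b = "g1", c = "g2"))
    if (res$lrt$p_value < 0.05) rejected <- rejected + 1L
  }
  expect_gte(rejected, 23L)
})

test_that("Cook's distance is symmetric for duplicated rows and tracks LOO refits", {
  d <- data.frame(x = rep(c(0, 1, 2), each = 2),
                  y = rep(c(1, 2, 3), each = 2), n = 5)
  fit <- binom_glm(cbind(y, n - y) ~ x, d)
  cd <- unname(cooks_distance(fit))
  expect_equal(cd[1], cd[2])
  expect_equal(cd[3], cd[4])
  expect_equal(cd[5], cd[6])
  # matches the standard one-step formula as computed by stats on glm
  ref <- glm(cbind(y, n - y) ~ x, binomial, d)
  expect_equal(unname(cd), unname(cooks.distance(ref)), tolerance = 1e-5)
  # rank correlation with exact leave-one-out deviance change
  rd <- random_binom_data(15, seed = 55)
  f2 <- suppressWarnings(binom_glm(cbind(y, n - y) ~ x1, rd$data))
  cd2 <- cooks_distance(f2)
  loo <- vapply(seq_len(15), function(i) {
    f_i <- suppressWarnings(refit_without(f2, i))
    sum((coef(f2) - coef(f_i))^2)
  }, numeric(1))
  expect_gt(cor(cd2, loo, method = "spearman"), 0.7)
})

test_that("removing the top-influence tree does not flip coefficient signs", {
  flips <- 0L
  for (s in 1:10) {
    d <- simulate_survey(survey_params(seed = 300 + s))
    fit <- suppressWarnings(binom_glm(
      cbind(n_sp_positive, n_samples - n_sp_positive) ~
        girth_m * region + tmax_c * region, d))
    top <- which.max(cooks_distance(fit))
    fit2 <- suppressWarnings(refit_without(fit, top))
    main <- c("girth_m", "girth_m:regionsouth", "regionsouth:tmax_c")
    if (any(sign(coef(fit)[main]) != sign(coef(fit2)[main])))
      flips <- flips + 1L
  }
  expect_lte(flips, 1L)
})
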