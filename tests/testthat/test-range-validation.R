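test_that("fisher_exact matches exhaustive enumeration on random tables", {
  set.seed(23)
  for (i in 1:30) {
    t <- matrix(rpois(4, sample(c(3, 10, 40), 1)) + 1, 2)
    expect_equal(fisher_exact(t),
                 fisher_enum(t[1, 1], t[1, 2], t[2, 1], t[2, 2]),
                 tolerance = 1e-10)
  }
})

test_that("fisher_exact is invariant to row/column transposition", {
  set.seed(29)
  for (i in 1:10) {
    t <- matrix(rpois(4, 15) + 1, 2)
    p <- fisher_exact(t)
    expect_equal(fisher_exact(t[2:1, ]), p, tolerance = 1e-12)
    expect_equal(fisher_exact(t[, 2:1]), p, tolerance = 1e-12)
    expect_equal(fisher_exact(t(t)), p, tolerance = 1e-12)
  }
})

test_that("hypergeometric pmf sums to one over the support", {
  for (pars in list(c(12, 7, 9), c(40, 60, 33), c(5, 5, 5))) {
    m <- pars[1]; nn <- pars[2]; k <- pars[3]
    support <- max(0, k - nn):min(k, m)
    expect_equal(sum(dhyper(support, m, nn, k)), 1, tolerance = 1e-12)
  }
})

test_that("fisher_exact rejects degenerate tables and is conservative under the null", {
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "degenerate")
  expect_error(fisher_exact(c(1.5, 2, 3, 4)), "integers")
  # type-I error at nominal 0.05 under simulated null tables
  set.seed(31)
  rejections <- 0L
  n_sim <- 400L
  for (i in seq_len(n_sim)) {
    x1 <- rbinom(1, 30, 0.3)
    x2 <- rbinom(1, 45, 0.3)
    t <- matrix(c(x1, 30 - x1, x2, 45 - x2), 2, byrow = TRUE)
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    if (fisher_exact(t) < 0.05) rejections <- rejections + 1L
  }
  # conservative exact test: rejection rate at or below nominal (3 SE slack)
  expect_lte(rejections / n_sim, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("wilcoxon p matches exact enumeration for small untied samples", {
  set.seed(37)
  for (i in 1:10) {
    x <- round(runif(sample(3:6, 1), 0, 100), 3)
    y <- round(runif(sample(3:6, 1), 20, 120), 3)
    if (anyDuplicated(c(x, y))) next
    expect_equal(wilcoxon_rank_sum(x, y), wilcox_enum(x, y),
                 tolerance = 1e-10)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("wilcoxon approximation is calibrated under the null and near 1 at zero shift", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  expect_gte(wilcoxon_rank_sum(x, x), 0.99)
  # null calibration: p-values roughly uniform (KS check)
  set.seed(41)
  ps <- replicate(300, wilcoxon_rank_sum(rnorm(30), rnorm(30)))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("classification equals manual per-strain extraction and interval check", {
  g <- simulate_raster(c(0, 30, 20, 60), 1, base_c = 40, noise_c = 2,
                       seed = 6)
  env <- temp_envelope("t", c(24, 27), c(22, 30))
  st <- simulate_strains(g, env, strain_sim_params(n_wild = 20, n_human = 20,
                                                   wild_displacement_km = 30,
                                                   human_displacement_km = 900,
                                                   seed = 7))
  cl <- classify_strains(st, g, env$occurrence)
  mask <- in_range_mask(g, env$occurrence)
  for (i in seq_len(nrow(cl))) {
    v <- tryCatch(value_at(g, st$lat[i], st$lon[i]),
                  error = function(e) NA_real_)
    if (is.na(v)) {
      expect_false(cl$classifiable[i])
      next
    }
    expect_equal(cl$tmax_c[i], v)
    expect_identical(cl$in_range[i], v >= 22 && v <= 30)
    if (cl$in_range[i]) expect_equal(cl$distance_km[i], 0)
    else expect_equal(cl$distance_km[i],
                      distance_to_range(g, env$occurrence,
                                        st$lat[i], st$lon[i], mask = mask))
  }
  expect_true(all(cl$distance_km[cl$in_range & cl$classifiable] == 0))
})

test_that("validation summaries satisfy count identities", {
  g <- simulate_raster(c(0, 30, 20, 60), 1, base_c = 40, noise_c = 2,
                       nodata_fraction = 0.05, seed = 8)
  env <- temp_envelope("t", c(24, 27), c(22, 30))
  st <- simulate_strains(g, env, strain_sim_params(n_wild = 30, n_human = 30,
                                                   human_displacement_km = 700,
                                                   seed = 9))
  cl <- suppressMessages(classify_strains(st, g, env$occurrence))
  sm <- summarize_validation(cl)
  expect_equal(sm$n_in_range + sm$n_out_of_range + sm$n_nodata, sm$n_total)
  expect_equal(sum(sm$n_total), nrow(st))
  # widening the interval never decreases the in-range count
  cl_wide <- suppressMessages(classify_strains(st, g, c(20, 32)))
  sm_wide <- summarize_validation(cl_wide)
  expect_gte(sum(sm_wide$n_in_range), sum(sm$n_in_range))
  # empty class reports missing fraction
  empty_sm <- summarize_validation(rbind(cl, transform(cl[1, ],
    genotype_class = "mosaic", classifiable = FALSE, in_range = NA,
    distance_km = NA_real_, tmax_c = NA_real_)))
  mosaic <- empty_sm[empty_sm$genotype_class == "mosaic", ]
  expect_equal(mosaic$n_classifiable, 0L)
  expect_true(is.na(mosaic$fraction_in_range))
})

test_that("vineyard substrate filtering is configurable", {
  st <- data.frame(strain_id = c("a", "b", "c", "d"),
                   species = "Saccharomyces cerevisiae",
                   genotype_class = "wild",
                   lat = 40, lon = 10,
                   substrate = c("oak bark", "wine must",
                                 "vineyard grapes", "vineyard soil"),
                   source_study = "x", stringsAsFactors = FALSE)
  kept <- filter_vineyard_strains(st)
  expect_setequal(kept$strain_id, c("a", "d"))  # soil retained by default
  kept2 <- filter_vineyard_strains(st, patterns = c("wine", "grape",
                                                    "vineyard"))
  expect_setequal(kept2$strain_id, "a")
})
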