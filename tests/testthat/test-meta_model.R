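test_that("homogeneous observations collapse to the fixed-effect limit", {
  k <- 12
  obs <- data.frame(compound_id = "X", r = rep(0.2, k), var_r = rep(0.01, k),
                    region = rep(c("a", "b", "c"), each = 4),
                    category = rep(c("d", "p", "l"), 4))
  fit <- reml_fit(obs)
  expect_equal(fit$M_r, 0.2, tolerance = 1e-8)
  expect_equal(fit$tau2_1, 0)
  expect_equal(fit$tau2_2, 0)
  expect_equal(fit$se, sqrt(0.01 / k), tolerance = 1e-6)
})

test_that("with variance components fixed at zero the pooled estimate is the
          inverse-variance average", {
  obs <- data.frame(compound_id = "X", r = c(0.1, 0.3),
                    var_r = c(0.01, 0.04),
                    region = c("a", "b"), category = c("x", "y"))
  fit <- reml_fit(obs, fixed_tau2 = c(0, 0))
  expect_equal(fit$M_r, (0.1 * 100 + 0.3 * 25) / 125, tolerance = 1e-9)
  expect_equal(fit$se, sqrt(1 / 125), tolerance = 1e-7)
  # equal known variances and zero heterogeneity: arithmetic mean
  obs2 <- data.frame(compound_id = "X", r = c(0.05, 0.1, 0.3, -0.1),
                     var_r = rep(0.02, 4), region = letters[1:4],
                     category = letters[1:4])
  fit2 <- reml_fit(obs2, fixed_tau2 = c(0, 0))
  expect_equal(fit2$M_r, mean(obs2$r), tolerance = 1e-9)
})

test_that("REML estimates agree with an independent multi-level fit", {
  skip_if_not_installed("metafor")
  for (seed in 1:12) {
    obs <- random_obs(k = sample(8:40, 1), seed = 100 + seed, theta = -0.1)
    fit <- reml_fit(obs)
    m <- metafor::rma.mv(
      yi = obs$r, V = obs$var_r,
      random = list(~1 | region, ~1 | cell),
      data = data.frame(region = factor(obs$region),
                        cell = factor(paste(obs$region, obs$category))))
    expect_equal(fit$M_r, as.numeric(coef(m)), tolerance = 1e-5)
    expect_equal(fit$se, as.numeric(m$se), tolerance = 1e-5)
    expect_equal(c(fit$tau2_1, fit$tau2_2), as.numeric(m$sigma2),
                 tolerance = 1e-4)
    expect_true(fit$converged)
  }
})

test_that("a single outer group reduces to the one-level model", {
  set.seed(55)
  k <- 15
  obs <- data.frame(compound_id = "X", r = rnorm(k, 0.1, 0.1),
                    var_r = runif(k, 0.005, 0.02),
                    region = "only", category = sample(letters[1:3], k, TRUE))
  two <- reml_fit(obs)
  one <- reml_fit(transform(obs, region = obs$category),
                  random_structure("region"))
  # with one outer group the nested level carries all structure
  expect_equal(two$M_r, one$M_r, tolerance = 1e-5)
  expect_equal(two$se, one$se, tolerance = 1e-5)
  expect_equal(two$tau2_2, one$tau2_1, tolerance = 1e-4)
})

test_that("observation order does not affect the fit", {
  obs <- random_obs(k = 24, seed = 77, theta = -0.3)
  fit <- reml_fit(obs)
  perm <- sample(nrow(obs))
  fit2 <- reml_fit(obs[perm, ])
  expect_identical(fit$M_r, fit2$M_r)
  expect_identical(fit$se, fit2$se)
  expect_identical(fit$tau2_1, fit2$tau2_1)
})

test_that("pooled standard errors shrink as observations accumulate", {
  set.seed(88)
  ses <- vapply(c(6, 12, 24, 48), function(k) {
    mean(vapply(1:20, function(i)
      reml_fit(random_obs(k, seed = 1000 * k + i))$se, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
})

test_that("simulation recovers a planted pooled effect within 3 SE", {
  hits <- 0
  n_rep <- 60
  for (i in 1:n_rep) {
    obs <- random_obs(k = 30, seed = 5000 + i, theta = -0.4,
                      tau = c(0.01, 0.005))
    fit <- reml_fit(obs)
    if (abs(fit$M_r - (-0.4)) <= 3 * fit$se) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("insufficient data and bad variances raise classed errors", {
  expect_error(reml_fit(data.frame(r = 0.1, var_r = 0.01, region = "a",
                                   category = "b")),
               class = "revscreen_insufficient_data_error")
  obs <- random_obs(6, seed = 1)
  obs$var_r[2] <- 0
  expect_error(reml_fit(obs), class = "revscreen_validation_error")
})

test_that("FDR classification splits by sign and excludes non-converged", {
  res <- data.frame(
    compound_id = paste0("C", 1:6), k = 10,
    M_r = c(-0.5, -0.3, 0.4, -0.02, 0.01, -0.6),
    se = 0.05, tau2_1 = 0, tau2_2 = 0,
    z = c(-10, -6, 8, -0.4, 0.2, -12),
    p = c(1e-20, 1e-9, 1e-15, 0.7, 0.8, 1e-30),
    direction = c("negative", "negative", "positive", "negative",
                  "positive", "negative"),
    converged = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  cl <- suppressMessages(fdr_classify(res))
  expect_setequal(cl$negative$compound_id, c("C1", "C2"))
  expect_equal(cl$positive$compound_id, "C3")
  expect_equal(cl$excluded$compound_id, "C6")
  expect_true(all(is.na(cl$results$p_adj[cl$results$compound_id == "C6"])))
  # vacuous threshold
  cl0 <- suppressMessages(fdr_classify(res, alpha = 0))
  expect_equal(nrow(cl0$negative) + nrow(cl0$positive), 0L)
})

test_that("benchmark comparison reports present, absent and flagged", {
  res <- data.frame(
    compound_id = c("hit", "bench1", "bench2"), k = 10,
    M_r = c(-0.5, -0.05, 0.02), se = 0.05, tau2_1 = 0, tau2_2 = 0,
    z = c(-10, -1, 0.4), p = c(1e-20, 0.3, 0.7),
    direction = c("negative", "negative", "positive"),
    converged = TRUE)
  cl <- fdr_classify(res)
  bc <- benchmark_compare(cl, c("bench1", "bench2", "missing_drug"))
  expect_setequal(bc$present$compound_id, c("bench1", "bench2"))
  expect_equal(bc$absent, "missing_drug")
  expect_false(any(bc$present$in_negative_set))
  # a benchmark planted as a strong reverser is flagged
  bc2 <- benchmark_compare(cl, c("hit"))
  expect_true(bc2$present$in_negative_set)
  # fully disjoint benchmark set
  bc3 <- benchmark_compare(cl, c("a", "b"))
  expect_equal(nrow(bc3$present), 0L)
  expect_setequal(bc3$absent, c("a", "b"))
})
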