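test_that("the standard curve inverts absorbance to concentration", {
  std <- data.frame(concentration = c(0, 6), absorbance = c(0, 0.6))
  curve <- fit_standard_curve(std)
  expect_equal(curve$slope, 0.1)
  expect_equal(predict_concentration(curve, 0.3)$concentration, 3.0)
  expect_equal(predict_concentration(curve, 0)$concentration, 0)
  expect_true(predict_concentration(curve, 0.9)$extrapolated)
  expect_error(fit_standard_curve(
    data.frame(concentration = c(2, 2), absorbance = c(0.1, 0.2))),
    class = "revscreen_degenerate_error")
})

test_that("a noisy standard curve recovers its slope within the OLS CI", {
  set.seed(61)
  conc <- rep(seq(0, 6, by = 1), each = 2)
  absb <- 0.005 + 0.12 * conc + rnorm(length(conc), 0, 0.01)
  curve <- fit_standard_curve(data.frame(concentration = conc,
                                         absorbance = absb))
  ci <- confint(curve$fit)["concentration", ]
  expect_gt(0.12, ci[1])
  expect_lt(0.12, ci[2])
})

test_that("type-III sums of squares equal sequential on balanced designs", {
  set.seed(62)
  rec <- data.frame(sex = rep(c("male", "female"), each = 20),
                    treatment = rep(rep(c("control", "cocaine"), each = 10), 2),
                    movement_s = rnorm(40, 20, 5))
  t3 <- anova_type3(rec)
  seq_tab <- anova(lm(movement_s ~ sex * treatment, rec))
  expect_equal(t3$SS[1:3], seq_tab$`Sum Sq`[1:3], tolerance = 1e-10)
  expect_equal(t3$p[1:3], seq_tab$`Pr(>F)`[1:3], tolerance = 1e-10)
})

test_that("type-III SS match the hand-built full-vs-reduced oracle on an
          unbalanced fixture", {
  rec <- data.frame(
    sex = c("m", "m", "f", "f", "m", "m", "f", "f", "f"),
    treatment = c("a", "a", "a", "a", "b", "b", "b", "b", "b"),
    movement_s = c(12.1, 14.3, 18.2, 17.9, 9.4, 10.2, 15.8, 16.4, 14.9))
  t3 <- anova_type3(rec)
  oracle <- type3_oracle(rec)
  expect_equal(t3$SS[1:3], unname(oracle$SS), tolerance = 1e-10)
  expect_equal(t3$SS[t3$term == "residual"], oracle$rss_full,
               tolerance = 1e-10)
  expect_equal(t3$df[t3$term == "residual"], oracle$df_res)
})

test_that("type-III SS agree with the car implementation on unbalanced
          factorials", {
  skip_if_not_installed("car")
  set.seed(63)
  for (i in 1:5) {
    n <- c(sample(3:12, 4))
    rec <- data.frame(
      sex = c(rep("m", n[1] + n[2]), rep("f", n[3] + n[4])),
      treatment = c(rep("a", n[1]), rep("b", n[2]), rep("a", n[3]),
                    rep("b", n[4])),
      movement_s = rnorm(sum(n), 20, 4))
    t3 <- anova_type3(rec)
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    fit <- lm(movement_s ~ sex * treatment, rec)
    ca <- car::Anova(fit, type = 3)
    options(old)
    expect_equal(t3$SS[1:3], ca$`Sum Sq`[2:4], tolerance = 1e-8)
    expect_equal(t3$p[1:3], ca$`Pr(>F)`[2:4], tolerance = 1e-8)
  }
})

test_that("degenerate ANOVA inputs raise informative errors", {
  rec <- data.frame(sex = c("m", "m", "f", "f"),
                    treatment = c("a", "a", "a", "b"),
                    movement_s = c(1, 2, 3, 4))
  # cell (f, ... ) fine; remove male-b cell entirely
  expect_error(anova_type3(rec), "sex=m, treatment=b")
  rec2 <- data.frame(sex = rep(c("m", "f"), each = 4),
                     treatment = rep(c("a", "b"), 4),
                     movement_s = rep(5, 8))
  expect_error(anova_type3(rec2), class = "revscreen_degenerate_error")
})

test_that("pooled-variance t tests match the hand formula and symmetry", {
  rec <- data.frame(sex = "m",
                    treatment = rep(c("x", "y"), each = 3),
                    movement_s = c(5.1, 4.9, 5.0, 7.0, 7.2, 6.8))
  out <- posthoc_t(rec, list(treatment = "x"), list(treatment = "y"))
  sp <- sqrt((var(c(5.1, 4.9, 5.0)) * 2 + var(c(7.0, 7.2, 6.8)) * 2) / 4)
  t_hand <- (5.0 - 7.0) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(out$t, t_hand, tolerance = 1e-10)
  expect_equal(out$df, 4)
  swapped <- posthoc_t(rec, list(treatment = "y"), list(treatment = "x"))
  expect_equal(swapped$t, -out$t)
  expect_equal(swapped$p, out$p)
  same <- data.frame(sex = "m", treatment = rep(c("x", "y"), each = 3),
                     movement_s = rep(c(1, 2, 3), 2))
  out2 <- posthoc_t(same, list(treatment = "x"), list(treatment = "y"))
  expect_equal(out2$t, 0)
  expect_equal(out2$p, 1)
})

test_that("Fisher's exact test matches enumeration on worked examples", {
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(3, 3, 3, 3), 2)), 1)
  tab <- matrix(c(12, 5, 3, 9), 2)
  expect_equal(fisher_exact(tab), fisher_exact(t(tab)))
  expect_equal(fisher_exact(tab), fisher_oracle(tab), tolerance = 1e-12)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)),
               class = "revscreen_validation_error")
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)),
               class = "revscreen_validation_error")
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2)),
               class = "revscreen_validation_error")
})

test_that("consumption readouts average duplicate wells before inversion", {
  std <- data.frame(concentration = c(0, 2, 4, 6),
                    absorbance = c(0, 0.2, 0.4, 0.6))
  curve <- fit_standard_curve(std)
  rec <- data.frame(sex = rep("male", 4),
                    treatment = rep(c("control", "drug"), each = 2),
                    absorbance_1 = c(0.30, 0.10, 0.20, 0.22),
                    absorbance_2 = c(0.32, 0.12, 0.22, 0.20))
  out <- consumption_compare(rec, curve)
  # mean(0.30, 0.32) = 0.31 -> 3.1 ug/mL -> 0.93 ug at 300 uL
  expect_equal(out$per_fly$consumption_ug[1], 3.1 * 0.3, tolerance = 1e-10)
  expect_equal(nrow(out$summary), 2L)
  expect_named(out$tests, "male.control.vs.drug")
  # all-zero absorbance maps to zero consumption without error
  rec0 <- data.frame(sex = "male", treatment = c("a", "a", "b", "b"),
                     absorbance_1 = 0, absorbance_2 = 0)
  out0 <- consumption_compare(rec0, curve)
  expect_true(all(abs(out0$per_fly$consumption_ug) < 1e-12))
  # above-range absorbance is flagged as extrapolation
  rec2 <- data.frame(sex = "male", treatment = c("a", "b"),
                     absorbance_1 = c(0.9, 0.1), absorbance_2 = c(0.95, 0.1))
  out2 <- suppressMessages(consumption_compare(rec2, curve))
  expect_true(out2$per_fly$extrapolated[1])
})

test_that("a planted consumption difference is detected by the post-hoc t", {
  std <- data.frame(concentration = c(0, 6), absorbance = c(0, 0.6))
  curve <- fit_standard_curve(std)
  hits <- vapply(1:40, function(i) {
    bc <- behavior_sim_config(seed = 4000 + i)
    rec <- simulate_behavior(bc)
    males <- rec[rec$sex == "male" & rec$treatment %in% c("control", "drug"), ]
    out <- consumption_compare(males, curve)
    tt <- out$tests[["male.control.vs.drug"]]
    tt$p < 0.05 && tt$mean_a < tt$mean_b
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
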