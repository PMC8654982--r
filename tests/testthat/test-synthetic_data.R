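test_that("configuration invariants are enforced with named fields", {
  expect_error(sim_config(planted_effects = c(CMPD0001 = 1.2)),
               class = "revscreen_config_error")
  expect_error(sim_config(tau2_region = -1), class = "revscreen_config_error")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(signatures_per_compound = c(5, 2)),
               class = "revscreen_config_error")
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
  # planted effect for an unknown compound id
  cfg2 <- sim_config(n_compounds = 3, planted_effects = c(CMPD0099 = -0.5))
  sim <- simulate_disease_profiles(cfg2)
  expect_error(simulate_compound_library(cfg2, sim),
               class = "revscreen_config_error")
})

test_that("identical configurations give bit-identical outputs", {
  cfg <- sim_config(n_genes = 300, n_compounds = 6,
                    signatures_per_compound = c(1, 4), seed = 99)
  a <- simulate_disease_profiles(cfg)
  b <- simulate_disease_profiles(cfg)
  expect_identical(a, b)
  expect_identical(simulate_compound_library(cfg, a),
                   simulate_compound_library(cfg, b))
  expect_identical(simulate_followup_dataset(cfg, a, TRUE, "invitro"),
                   simulate_followup_dataset(cfg, b, TRUE, "invitro"))
  bc <- behavior_sim_config(seed = 4)
  expect_identical(simulate_behavior(bc), simulate_behavior(bc))
})

test_that("zero region noise with only shared effects gives identical
          regional profiles", {
  cfg <- sim_config(n_genes = 500, noise_sd = 0, de_frac = 0,
                    shared_frac = 0.3, seed = 3)
  sim <- simulate_disease_profiles(cfg)
  e <- sapply(sim$profiles, function(p) p$effect)
  expect_equal(e[, 1], e[, 2])
  expect_equal(e[, 1], e[, 3])
  nz <- apply(e, 1, function(x) any(x != 0))
  expect_equal(cor(e[nz, 1], e[nz, 2]), 1)
})

test_that("without shared effects inter-region pathway correlations center
          on zero", {
  rs <- replicate(60, {
    cfg <- sim_config(n_genes = 2000, shared_frac = 0, n_pathway = 100,
                      seed = sample.int(1e6, 1))
    sim <- simulate_disease_profiles(cfg)
    idx <- match(sim$pathway_genes, sim$genes)
    cor(sim$effects[idx, 1], sim$effects[idx, 2])
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("a strongly planted reverser yields the target correlation in
          every slice in the zero-noise limit", {
  cfg <- sim_config(n_genes = 10000, n_compounds = 1,
                    signatures_per_compound = c(3, 3),
                    planted_effects = c(CMPD0001 = -0.9),
                    tau2_region = 0, tau2_category = 0, noise_sd = 0,
                    de_frac = 0, shared_frac = 0.2,
                    n_pathway = 1500, n_landmark = 4000, seed = 8)
  sim <- simulate_disease_profiles(cfg)
  lib <- simulate_compound_library(cfg, sim)
  inp <- build_input(sim$profiles, sim$pathway_genes, sim$landmark_genes)
  obs <- suppressMessages(match_all(lib, inp))
  expect_true(all(abs(obs$r - (-0.9)) < 0.02))
})

test_that("null compound correlations match the sampling-variance scale", {
  cfg <- sim_config(n_genes = 2000, n_compounds = 10,
                    signatures_per_compound = c(2, 2), seed = 13)
  sim <- simulate_disease_profiles(cfg)
  lib <- simulate_compound_library(cfg, sim)
  inp <- build_input(sim$profiles, sim$pathway_genes, sim$landmark_genes)
  obs <- suppressMessages(match_all(lib, inp))
  # standardized correlations should be roughly unit-scale
  zz <- obs$r / sqrt(obs$var_r)
  expect_lt(abs(mean(zz)), 0.5)
  expect_gt(sd(zz), 0.6)
  expect_lt(sd(zz), 1.6)
})

test_that("requesting zero signatures yields an empty library", {
  cfg <- sim_config(n_genes = 200, n_compounds = 4,
                    signatures_per_compound = c(0, 0), seed = 2)
  sim <- simulate_disease_profiles(cfg)
  lib <- simulate_compound_library(cfg, sim)
  expect_equal(ncol(lib$scores), 0L)
  expect_equal(nrow(lib$meta), 0L)
})

test_that("compound sub-streams are insertion-order independent", {
  cfg_small <- sim_config(n_genes = 300, n_compounds = 3,
                          signatures_per_compound = c(2, 2), seed = 5)
  cfg_big <- sim_config(n_genes = 300, n_compounds = 6,
                        signatures_per_compound = c(2, 2), seed = 5)
  sim <- simulate_disease_profiles(cfg_small)
  lib_small <- simulate_compound_library(cfg_small, sim)
  lib_big <- simulate_compound_library(cfg_big, sim)
  shared <- lib_small$meta$signature_id
  expect_identical(lib_small$scores[, shared], lib_big$scores[, shared])
})

test_that("concordant follow-ups align with the discovery input and null
          follow-ups do not", {
  cfg <- sim_config(n_genes = 1000, followup_noise = 0, seed = 17)
  sim <- simulate_disease_profiles(cfg)
  fu <- simulate_followup_dataset(cfg, sim, concordant = TRUE, "invitro")
  expect_equal(length(fu$profiles), 4L)  # two times x two non-zero doses
  dbar <- rowMeans(sim$effects)
  expect_equal(cor(fu$profiles[[1]]$effect, dbar), 1, tolerance = 1e-12)
  mouse <- simulate_followup_dataset(cfg, sim, concordant = TRUE, "mouse")
  expect_equal(length(mouse$profiles), 3L)
  cfg2 <- sim_config(n_genes = 1000, seed = 18)
  rs <- replicate(40, {
    c2 <- sim_config(n_genes = 1000, seed = sample.int(1e6, 1))
    s2 <- simulate_disease_profiles(c2)
    f2 <- simulate_followup_dataset(c2, s2, concordant = FALSE, "invitro")
    cor(f2$profiles[[1]]$effect, rowMeans(s2$effects))
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("the synthetic ortholog map exercises ambiguity exclusion", {
  cfg <- sim_config(n_genes = 400, seed = 23)
  map <- simulate_ortholog_map(cfg, n_ambiguous = 5)
  genes <- data.frame(gene = sprintf("G%05d", 1:400), effect = rnorm(400))
  out <- suppressMessages(map_orthologs(genes, map))
  expect_equal(nrow(out), 400 - 10)  # 5 families of 2 sources dropped
  expect_true(all(grepl("^MG", out$gene)))
})

test_that("behavior simulation honors group sizes, the assay window and
          degenerate probabilities", {
  bc <- behavior_sim_config(seed = 31)
  rec <- simulate_behavior(bc)
  # reported group sizes of the validation assay
  expect_equal(sum(rec$sex == "male" & rec$treatment == "control"), 61)
  expect_equal(sum(rec$sex == "male" & rec$treatment == "cocaine"), 140)
  expect_equal(sum(rec$sex == "male" & rec$treatment == "cocaine+drug"), 132)
  expect_equal(sum(rec$sex == "female" & rec$treatment == "control"), 66)
  expect_equal(sum(rec$sex == "female" & rec$treatment == "cocaine"), 141)
  expect_equal(sum(rec$sex == "female" & rec$treatment == "cocaine+drug"), 142)
  expect_true(all(rec$movement_s >= 0 & rec$movement_s <= 45))
  # all-zero seizure probabilities
  bc0 <- behavior_sim_config(seizure_probs = setNames(
    rep(0, length(bc$group_sizes)), names(bc$group_sizes)), seed = 1)
  expect_equal(sum(simulate_behavior(bc0)$seizure), 0L)
  expect_error(behavior_sim_config(seizure_probs = setNames(
    rep(1.4, length(bc$group_sizes)), names(bc$group_sizes))),
    class = "revscreen_config_error")
})

test_that("with equal movement means the treatment p-value is uniform", {
  bc0 <- behavior_sim_config()
  eq <- setNames(rep(18, length(bc0$group_sizes)), names(bc0$group_sizes))
  ps <- vapply(1:120, function(i) {
    bc <- behavior_sim_config(movement_means = eq, seed = 7000 + i)
    rec <- simulate_behavior(bc)
    tab <- anova_type3(rec)
    tab$p[tab$term == "treatment"]
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
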