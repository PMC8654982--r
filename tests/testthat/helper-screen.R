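# Full-pipeline replicate helpers shared by the calibration, recovery and
# benchmark acceptance checks. Scales (gene count, signature counts) are the
# package's chosen desk-scale study conditions; the compound counts and
# planted effects follow the screen design being validated.

# one all-null screen replicate: returns the per-compound meta table
null_screen_replicate <- function(seed, n_compounds = 200) {
  cfg <- sim_config(n_genes = 600, n_compounds = n_compounds,
                    signatures_per_compound = c(2, 2), seed = seed)
  sim <- simulate_disease_profiles(cfg)
  lib <- simulate_compound_library(cfg, sim)
  inp <- build_input(sim$profiles, sim$pathway_genes, sim$landmark_genes)
  obs <- suppressMessages(match_all(lib, inp))
  meta_screen(obs)
}

# one planted-reverser replicate: a single theta = -0.5 compound with 30
# signatures among null compounds, plus two concordant follow-up datasets
# and a designated null benchmark set
planted_screen_replicate <- function(seed, n_compounds = 100,
                                     theta = -0.5, n_benchmark = 10) {
  planted_id <- "CMPD0001"
  benchmark_ids <- sprintf("CMPD%04d", seq(n_compounds - n_benchmark + 1,
                                           n_compounds))
  cfg <- sim_config(n_genes = 600, n_compounds = n_compounds,
                    signatures_per_compound = c(3, 3),
                    planted_effects = setNames(theta, planted_id),
                    seed = seed)
  sim <- simulate_disease_profiles(cfg)
  lib <- simulate_compound_library(cfg, sim)
  # give the planted compound its 30 signatures by regenerating it alone
  cfg30 <- sim_config(n_genes = 600, n_compounds = 1,
                      signatures_per_compound = c(30, 30),
                      planted_effects = setNames(theta, planted_id),
                      seed = seed)
  lib30 <- simulate_compound_library(cfg30, sim)
  keep <- lib$meta$compound_id != planted_id
  lib <- signature_library(cbind(lib30$scores, lib$scores[, keep]),
                           rbind(lib30$meta, lib$meta[keep, ]))
  inp <- build_input(sim$profiles, sim$pathway_genes, sim$landmark_genes)
  obs <- suppressMessages(match_all(lib, inp))
  cl <- suppressMessages(fdr_classify(meta_screen(obs)))
  bench <- benchmark_compare(cl, benchmark_ids)
  prioritized <- NULL
  if (nrow(cl$negative) > 0) {
    fu1 <- simulate_followup_dataset(cfg, sim, TRUE, "invitro")
    fu2 <- simulate_followup_dataset(cfg, sim, TRUE, "mouse")
    fus <- suppressMessages(list(
      invitro = followup_score(cl$negative$compound_id, lib, fu1$profiles,
                               dataset_id = "invitro"),
      mouse = followup_score(cl$negative$compound_id, lib, fu2$profiles,
                             dataset_id = "mouse")))
    prioritized <- suppressWarnings(suppressMessages(
      prioritize(cl$negative, fus)))
  }
  list(planted_id = planted_id, negative = cl$negative$compound_id,
       benchmark_flagged = bench$present$compound_id[
         bench$present$in_negative_set],
       prioritized = if (is.null(prioritized)) character(0) else
         prioritized$compound_id)
}

# lazily-computed shared state for the acceptance blocks
.acceptance_cache <- new.env(parent = emptyenv())

planted_screen_results <- function(n_rep = 200) {
  key <- paste0("planted_", n_rep)
  if (is.null(.acceptance_cache[[key]])) {
    .acceptance_cache[[key]] <- lapply(seq_len(n_rep), function(i)
      planted_screen_replicate(seed = 20000 + i))
  }
  .acceptance_cache[[key]]
}
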