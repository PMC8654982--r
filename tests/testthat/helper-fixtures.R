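# Small builders shared across test files.

# tiny disease input table with full-coverage categories, built by hand
tiny_input <- function(genes, effects, regions = c("dlPFC", "hippocampus"),
                       categories = c("DEG", "PATHWAY", "LANDMARK")) {
  out <- do.call(rbind, lapply(regions, function(rg) {
    do.call(rbind, lapply(categories, function(ct) {
      data.frame(region = rg, category = ct, gene = genes,
                 effect = effects[[rg]], stringsAsFactors = FALSE)
    }))
  }))
  out$group <- paste(out$category, out$region, sep = "_")
  structure(out, class = c("disease_input", "data.frame"))
}

# signature library with given per-signature score vectors (named list)
tiny_library <- function(scores_list, compounds, genes) {
  scores <- do.call(cbind, scores_list)
  rownames(scores) <- genes
  colnames(scores) <- names(scores_list)
  meta <- data.frame(signature_id = names(scores_list),
                     compound_id = compounds,
                     cell_line = "NEU", dose = "1uM", time = "6h",
                     stringsAsFactors = FALSE)
  signature_library(scores, meta)
}

# random observation table for one compound with a nested 2-level layout
random_obs <- function(k, seed, theta = 0, tau = c(0.02, 0.02)) {
  set.seed(seed)
  g1 <- sample(3, k, replace = TRUE)
  g2 <- sample(3, k, replace = TRUE)
  u <- rnorm(3, 0, sqrt(tau[1]))
  w <- matrix(rnorm(9, 0, sqrt(tau[2])), 3, 3)
  v <- runif(k, 0.002, 0.05)
  r <- theta + u[g1] + w[cbind(g1, g2)] + rnorm(k, 0, sqrt(v))
  data.frame(compound_id = "X", r = r, var_r = v,
             region = paste0("rg", g1), category = paste0("ct", g2),
             stringsAsFactors = FALSE)
}
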