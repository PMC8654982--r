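#' Simulation configuration for the drug-discovery screen
#'
#' Defines the generative conditions for the synthetic screen: disease
#' profiles across brain regions, an L1000-like compound signature library,
#' and follow-up datasets. Gene effect statistics are generated on a
#' log2-fold-change-like continuous scale with p-values from a
#' known-variance z model, so differential-expression truth sets are exact.
#' Compound signatures are built at the gene level (planted correlation
#' plus region / category random-effect tilts plus gene-level noise), so
#' the Pearson sampling-variance machinery is genuinely exercised.
#'
#' @param n_genes number of genes in the shared namespace.
#' @param n_regions number of brain regions / studies (default 3:
#'   dlPFC, hippocampus, midbrain).
#' @param n_categories number of input categories; the screen defines
#'   exactly 3 (DEG, PATHWAY, LANDMARK).
#' @param n_compounds number of compounds in the library.
#' @param signatures_per_compound length-2 integer range; each compound
#'   receives a count drawn uniformly from it.
#' @param planted_effects named numeric vector mapping compound ids to true
#'   pooled correlations, each strictly inside (-1, 1). Unnamed compounds
#'   are null (theta = 0).
#' @param tau2_region level-1 (region) random-effect variance, >= 0.
#' @param tau2_category level-2 (category-within-region) variance, >= 0.
#' @param noise_sd residual scale of the region-specific effect noise (also
#'   the known standard error of the z model), > 0 (0 allowed as the exact
#'   zero-noise limit).
#' @param de_frac fraction of genes carrying a region-private true
#'   differential-expression effect.
#' @param shared_frac fraction of genes carrying a shared (cross-region)
#'   latent disease effect.
#' @param effect_sd standard deviation of true disease-gene effects.
#' @param n_pathway size of the synthetic pathway gene set.
#' @param n_landmark size of the synthetic directly-measured gene set.
#' @param concord_strength latent-effect loading of concordant follow-up
#'   datasets, in (0, 1].
#' @param followup_noise residual scale of follow-up effects.
#' @param seed integer seed; identical configurations give bit-identical
#'   output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000, n_regions = 3, n_categories = 3,
                       n_compounds = 100, signatures_per_compound = c(2, 6),
                       planted_effects = numeric(0),
                       tau2_region = 0.001, tau2_category = 0.001,
                       noise_sd = 1, de_frac = 0.1, shared_frac = 0.02,
                       effect_sd = 3, n_pathway = 50, n_landmark = 80,
                       concord_strength = 0.7, followup_noise = 0.7,
                       seed = 1L) {
  for (f in c("n_genes", "n_regions", "n_compounds", "n_pathway",
              "n_landmark")) {
    if (!is_count(get(f)) || get(f) < 1)
      rs_config_error(paste0("field '", f, "' must be a positive count"))
  }
  if (!is_count(n_categories) || n_categories != 3)
    rs_config_error("field 'n_categories': the screen defines exactly 3 input categories")
  if (length(signatures_per_compound) != 2 ||
      !all(vapply(signatures_per_compound, is_count, logical(1))) ||
      signatures_per_compound[1] > signatures_per_compound[2])
    rs_config_error("field 'signatures_per_compound' must be a non-decreasing count range")
  if (length(planted_effects) > 0 &&
      (is.null(names(planted_effects)) || any(names(planted_effects) == "")))
    rs_config_error("field 'planted_effects' must be named by compound id")
  if (any(abs(planted_effects) >= 1))
    rs_config_error("field 'planted_effects': all planted effects must lie strictly inside (-1, 1)")
  if (tau2_region < 0 || tau2_category < 0)
    rs_config_error("fields 'tau2_region'/'tau2_category' must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    rs_config_error("field 'noise_sd' must be >= 0")
  if (!is_prob(de_frac) || !is_prob(shared_frac))
    rs_config_error("fields 'de_frac'/'shared_frac' must be probabilities")
  if (!is_count(abs(seed)))
    rs_config_error("field 'seed' must be an integer")
  structure(list(
    n_genes = as.integer(n_genes), n_regions = as.integer(n_regions),
    n_categories = 3L, n_compounds = as.integer(n_compounds),
    signatures_per_compound = as.integer(signatures_per_compound),
    planted_effects = planted_effects, tau2_region = tau2_region,
    tau2_category = tau2_category, noise_sd = noise_sd, de_frac = de_frac,
    shared_frac = shared_frac,
    effect_sd = effect_sd, n_pathway = as.integer(n_pathway),
    n_landmark = as.integer(n_landmark),
    concord_strength = concord_strength, followup_noise = followup_noise,
    seed = as.integer(seed)), class = "sim_config")
}

sim_region_names <- function(n) {
  base <- c("dlPFC", "hippocampus", "midbrain")
  if (n <= 3) base[seq_len(n)] else c(base, paste0("region", seq_len(n - 3)))
}

#' Simulate per-region disease differential-expression profiles
#'
#' The effect of gene g in region r is
#' `d_rg = L_g + B_rg + noise_sd * eta_rg`: a shared latent disease
#' component (`shared_frac` of genes, N(0, `effect_sd`^2)), a
#' region-private differential-expression component (`de_frac` of genes
#' per region, N(0, `effect_sd`^2)), and region noise. The shared-to-noise
#' variance ratio controls the cross-region correlation of effects —
#' `noise_sd = 0` with `de_frac = 0` reproduces identical effect vectors
#' (inter-region r = 1), while `shared_frac = 0` gives independent
#' regions — so the weak inter-region concordance seen in real multi-study
#' brain data is reproducible structurally. Region-private components make
#' the differentially expressed gene sets largely region-specific, again
#' matching the minimal cross-region DEG overlap of real data. P-values
#' come from the known-variance z statistic `effect / noise_sd`, so the
#' differential-expression truth set is exact. Pathway and landmark gene
#' sets are drawn once from the namespace.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `disease_sim` with elements `profiles` (list of
#'   [disease_profile()], one per region), `pathway_genes`,
#'   `landmark_genes`, `truth` (data frame of latent gene effects) and
#'   internal latent components used by [simulate_compound_library()].
#' @export
simulate_disease_profiles <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  regions <- sim_region_names(cfg$n_regions)
  latent <- with_seed(stable_seed(cfg$seed, "disease", "latent"), {
    is_shared <- runif(cfg$n_genes) < cfg$shared_frac
    L <- ifelse(is_shared, rnorm(cfg$n_genes, 0, cfg$effect_sd), 0)
    pathway <- sort(sample(genes, cfg$n_pathway))
    landmark <- sort(sample(genes, cfg$n_landmark))
    list(L = L, is_shared = is_shared, pathway = pathway, landmark = landmark)
  })
  effects <- matrix(0, cfg$n_genes, cfg$n_regions,
                    dimnames = list(genes, regions))
  is_de <- matrix(FALSE, cfg$n_genes, cfg$n_regions,
                  dimnames = list(genes, regions))
  profiles <- vector("list", cfg$n_regions)
  names(profiles) <- regions
  for (ri in seq_along(regions)) {
    reg_draw <- with_seed(stable_seed(cfg$seed, "disease", regions[ri]), {
      private <- runif(cfg$n_genes) < cfg$de_frac
      B <- ifelse(private, rnorm(cfg$n_genes, 0, cfg$effect_sd), 0)
      list(private = private,
           d = latent$L + B + cfg$noise_sd * rnorm(cfg$n_genes))
    })
    d <- reg_draw$d
    is_de[, ri] <- latent$is_shared | reg_draw$private
    effects[, ri] <- d
    if (cfg$noise_sd > 0) {
      p <- 2 * pnorm(-abs(d / cfg$noise_sd))
    } else {
      p <- ifelse(d != 0, 0, 1)  # exact zero-noise limit
    }
    profiles[[ri]] <- disease_profile(genes, d, p, region = regions[ri],
                                      study_id = paste0("study_", regions[ri]))
  }
  structure(list(profiles = profiles, pathway_genes = latent$pathway,
                 landmark_genes = latent$landmark,
                 truth = data.frame(gene = genes, latent = latent$L,
                                    is_shared = latent$is_shared,
                                    stringsAsFactors = FALSE),
                 is_de = is_de,
                 genes = genes, regions = regions,
                 latent = latent$L, effects = effects),
            class = "disease_sim")
}

# Per-(region x category) basis system for planting signature correlations.
# For each non-degenerate input cell, the basis vector is the cell's
# centered disease effect restricted to the cell's gene subset. A_full
# gives cross-covariances of basis vectors with each cell's disease
# effects over that cell's subset; H[[c]] gives basis covariances over
# cell c's subset; G gives uncentered cross-products over the whole
# namespace (for the global variance of a planted mean pattern).
cell_basis <- function(sim, alpha = 0.05, min_genes = 5L) {
  cells <- list()
  for (rg in sim$regions) {
    pr <- sim$profiles[[rg]]
    deg <- pr$gene[pr$p_adj < alpha]
    pth <- intersect(sim$pathway_genes, pr$gene)
    lmk <- intersect(sim$landmark_genes, union(deg, pth))
    for (catg in c("DEG", "PATHWAY", "LANDMARK")) {
      gset <- switch(catg, DEG = deg, PATHWAY = pth, LANDMARK = lmk)
      idx <- match(sort(gset), sim$genes)
      if (length(idx) < min_genes) next
      dvec <- sim$effects[idx, rg]
      if (sd(dvec) == 0) next
      cells[[paste(catg, rg, sep = "_")]] <-
        list(region = rg, category = catg, idx = idx,
             d = dvec, sd_d = sd(dvec))
    }
  }
  m <- length(cells)
  if (m == 0L) rs_validation_error("no usable input cell for the generator")
  n_genes <- length(sim$genes)
  # dense basis matrix (n_genes x m); cells are small so this is cheap
  E <- matrix(0, n_genes, m)
  for (ci in seq_len(m)) {
    cl <- cells[[ci]]
    E[cl$idx, ci] <- cl$d - mean(cl$d)
  }
  A <- matrix(0, m, m)     # A[c, c2] = cov over cell c of (basis c2, d_c)
  H <- vector("list", m)   # H[[c]][c2, c3] = cov over cell c of bases
  for (ci in seq_len(m)) {
    cl <- cells[[ci]]
    sub <- E[cl$idx, , drop = FALSE]
    n <- length(cl$idx)
    dc <- cl$d - mean(cl$d)
    mu <- colMeans(sub)
    A[ci, ] <- (as.numeric(crossprod(sub, dc))) / (n - 1)
    H[[ci]] <- (crossprod(sub) - n * tcrossprod(mu)) / (n - 1)
  }
  G <- crossprod(E) / (n_genes - 1)
  list(cells = cells, E = E, A = A, H = H, G = G, m = m)
}

# Solve for basis loadings so the expected correlation on each input cell
# matches its target; ridge-regularized because overlapping cells
# (LANDMARK inside DEG/PATHWAY) make the system ill-conditioned.
solve_loadings <- function(basis, targets, n_iter = 8L, ridge = 1e-5) {
  m <- basis$m
  sd_d <- vapply(basis$cells, `[[`, numeric(1), "sd_d")
  AtA <- crossprod(basis$A)
  lam <- ridge * mean(diag(AtA))
  reg <- AtA + diag(lam, m)
  gamma <- rep(0, m)
  resid_var <- 1
  for (it in seq_len(n_iter)) {
    sd_s <- vapply(seq_len(m), function(ci)
      sqrt(max(as.numeric(gamma %*% basis$H[[ci]] %*% gamma), 0) + resid_var),
      numeric(1))
    rhs <- targets * sd_d * sd_s
    gamma <- as.numeric(solve(reg, crossprod(basis$A, rhs)))
    base_var <- as.numeric(gamma %*% basis$G %*% gamma)
    resid_var <- max(1 - base_var, 1e-4)
  }
  list(gamma = gamma, resid_var = resid_var)
}

#' Simulate an L1000-like compound signature library
#'
#' Builds gene-level signatures whose expected Pearson correlation with the
#' disease input of each region-by-category slice equals
#' `theta_c + u_region + w_cell`, with `u ~ N(0, tau2_region)` per region
#' and `w ~ N(0, tau2_category)` per slice drawn once per compound. The
#' planted pattern is assembled from per-slice basis vectors (the centered
#' disease effects restricted to each slice's gene subset) with loadings
#' solved from the realized covariance structure of those slices, so the
#' targets hold on the gene subsets the screen actually correlates —
#' including subsets selected for large effects. Gene-level residual noise
#' is scaled so signatures have unit variance; correlations computed
#' downstream therefore genuinely exercise the sampling-variance formula.
#' Sub-streams are seeded by compound id, making the library
#' insertion-order independent. Signatures carry neuronal cell-line, dose
#' and time labels.
#'
#' @param cfg a [sim_config()].
#' @param sim a `disease_sim` from [simulate_disease_profiles()].
#' @param alpha FDR threshold defining the DEG category subsets.
#' @return a [signature_library()].
#' @export
simulate_compound_library <- function(cfg, sim, alpha = 0.05) {
  stopifnot(inherits(cfg, "sim_config"), inherits(sim, "disease_sim"))
  compounds <- sprintf("CMPD%04d", seq_len(cfg$n_compounds))
  planted <- cfg$planted_effects
  if (length(planted) > 0 && !all(names(planted) %in% compounds))
    rs_config_error("planted effect refers to an unknown compound")
  basis <- cell_basis(sim, alpha = alpha)
  cell_region <- vapply(basis$cells, `[[`, character(1), "region")
  cell_cat <- vapply(basis$cells, `[[`, character(1), "category")
  regions <- sim$regions
  cells <- c("NEU", "NPC")
  doses <- c("0.1uM", "1uM", "10uM")
  times <- c("6h", "24h")
  score_cols <- list()
  meta_rows <- list()
  for (cid in compounds) {
    theta <- if (cid %in% names(planted)) unname(planted[cid]) else 0
    block <- with_seed(stable_seed(cfg$seed, "library", cid), {
      n_sig <- if (cfg$signatures_per_compound[1] ==
                   cfg$signatures_per_compound[2])
        cfg$signatures_per_compound[1]
      else sample(seq(cfg$signatures_per_compound[1],
                      cfg$signatures_per_compound[2]), 1L)
      if (n_sig == 0L) {
        NULL
      } else {
        u <- setNames(rnorm(length(regions), 0, sqrt(cfg$tau2_region)),
                      regions)
        w <- rnorm(basis$m, 0, sqrt(cfg$tau2_category))
        targets <- theta + u[cell_region] + w
        targets <- pmax(pmin(targets, 0.98), -0.98)
        sol <- solve_loadings(basis, targets)
        base <- as.numeric(basis$E %*% sol$gamma)
        sigs <- matrix(0, cfg$n_genes, n_sig)
        labels <- vector("list", n_sig)
        for (j in seq_len(n_sig)) {
          sigs[, j] <- base + sqrt(sol$resid_var) * rnorm(cfg$n_genes)
          labels[[j]] <- data.frame(
            signature_id = sprintf("%s_sig%02d", cid, j), compound_id = cid,
            cell_line = cells[(j - 1L) %% 2L + 1L],
            dose = doses[(j - 1L) %/% 2L %% 3L + 1L],
            time = times[(j - 1L) %/% 6L %% 2L + 1L],
            stringsAsFactors = FALSE)
        }
        list(sigs = sigs, meta = do.call(rbind, labels))
      }
    })
    if (is.null(block)) next
    score_cols[[cid]] <- block$sigs
    meta_rows[[cid]] <- block$meta
  }
  if (length(score_cols) == 0L) {
    scores <- matrix(numeric(0), nrow = cfg$n_genes, ncol = 0,
                     dimnames = list(sim$genes, character(0)))
    meta <- data.frame(signature_id = character(0), compound_id = character(0),
                       cell_line = character(0), dose = character(0),
                       time = character(0), stringsAsFactors = FALSE)
    return(signature_library(scores, meta))
  }
  scores <- do.call(cbind, score_cols)
  meta <- do.call(rbind, meta_rows)
  dimnames(scores) <- list(sim$genes, meta$signature_id)
  rownames(meta) <- NULL
  signature_library(scores, meta)
}

#' Simulate an independent follow-up differential-expression dataset
#'
#' Emulates the two computational follow-up designs: an in vitro neuronal
#' exposure experiment grouped by dose x time (two post-exposure times,
#' two non-zero doses) or an in vivo self-administration experiment grouped
#' by brain region (three regions). When `concordant`, each group's gene
#' effects load on the discovery latent disease vector with coefficient
#' `concord_strength`; otherwise effects are independent noise. For the
#' mouse-like design, identifiers can be passed through a synthetic
#' ortholog map (see [simulate_ortholog_map()]).
#'
#' @param cfg a [sim_config()].
#' @param sim the discovery `disease_sim` the follow-up should relate to.
#' @param concordant logical; plant a positive correlation with the
#'   discovery input?
#' @param design `"invitro"` (dose x time groups) or `"mouse"`
#'   (three brain regions).
#' @param ortholog_map optional mapping applied to the gene namespace
#'   (mouse design).
#' @return list of class `followup_sim`: `profiles` (list of
#'   [disease_profile()] per group), `dataset_id`, `design`.
#' @export
simulate_followup_dataset <- function(cfg, sim, concordant = TRUE,
                                      design = c("invitro", "mouse"),
                                      ortholog_map = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(sim, "disease_sim"))
  design <- match.arg(design)
  groups <- if (design == "invitro") {
    as.vector(outer(c("1uM", "5uM"), c("6h", "24h"), paste, sep = "_"))
  } else {
    c("VTA", "hippocampus", "PFC")
  }
  dataset_id <- if (design == "invitro") "neuronal_exposure" else
    "mouse_self_administration"
  profiles <- list()
  for (gp in groups) {
    d <- with_seed(stable_seed(cfg$seed, "followup", design, gp,
                               as.integer(concordant)), {
      if (concordant) {
        cfg$concord_strength * rowMeans(sim$effects) +
          cfg$followup_noise * rnorm(cfg$n_genes)
      } else {
        rnorm(cfg$n_genes)
      }
    })
    scale_sd <- if (concordant) cfg$followup_noise else 1
    p <- if (scale_sd > 0) 2 * pnorm(-abs(d / scale_sd)) else
      ifelse(d != 0, 0, 1)
    genes <- sim$genes
    df <- data.frame(gene = genes, effect = d, p = p,
                     stringsAsFactors = FALSE)
    if (!is.null(ortholog_map))
      df <- map_orthologs(df, ortholog_map)
    profiles[[gp]] <- disease_profile(df$gene, df$effect, df$p, region = gp,
                                      study_id = dataset_id)
  }
  structure(list(profiles = profiles, dataset_id = dataset_id,
                 design = design, groups = groups),
            class = "followup_sim")
}

#' Simulate a human-to-model-organism ortholog map
#'
#' Produces a two-column mapping over the simulated gene namespace that is
#' one-to-one for most genes (target symbols carry an `m` prefix), with a
#' configurable number of many-to-many families to exercise the
#' ambiguous-ortholog exclusion rule.
#'
#' @param cfg a [sim_config()].
#' @param n_ambiguous number of 2-source x 2-target ambiguous families.
#' @return data frame with columns `source`, `target`.
#' @export
simulate_ortholog_map <- function(cfg, n_ambiguous = 5L) {
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  map <- data.frame(source = genes, target = paste0("M", genes),
                    stringsAsFactors = FALSE)
  if (n_ambiguous > 0 && cfg$n_genes >= 2 * n_ambiguous) {
    idx <- with_seed(stable_seed(cfg$seed, "orthologs"),
                     sample(cfg$n_genes, 2L * n_ambiguous))
    for (a in seq_len(n_ambiguous)) {
      i <- idx[2 * a - 1L]; j <- idx[2 * a]
      # cross-link two sources to each other's targets -> 2x2 family
      map <- rbind(map, data.frame(source = genes[i], target = map$target[j]),
                   data.frame(source = genes[j], target = map$target[i]))
    }
  }
  map[order(map$source, map$target), , drop = FALSE]
}
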