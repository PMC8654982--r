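#' Build a single-category disease input from follow-up profiles
#'
#' Follow-up datasets are grouped by dose x time or brain region with no
#' category nesting: every gene of each group's profile enters one `ALL`
#' category, so the grouping label becomes the single random-effect level.
#'
#' @param profiles list of [disease_profile()] objects (one per group).
#' @return a `disease_input` data frame with `category = "ALL"`.
#' @export
followup_input <- function(profiles) {
  pieces <- lapply(profiles, function(pr) {
    data.frame(region = attr(pr, "region"), category = "ALL",
               gene = pr$gene, effect = pr$effect, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out) || nrow(out) == 0L)
    rs_validation_error("follow-up profiles are empty")
  out$group <- paste(out$category, out$region, sep = "_")
  structure(out, class = c("disease_input", "data.frame"))
}

#' Re-score candidate compounds against a follow-up dataset
#'
#' Runs the same connectivity-plus-meta machinery on an independent
#' differential-expression dataset: candidate signatures are correlated
#' with each follow-up group's effects, pooled per compound with the
#' grouping label (dose x time, or brain region) as a single random
#' effect, and BH-adjusted within the candidate family only (the family a
#' small follow-up of a discovery screen actually tests).
#'
#' @param candidates character vector of candidate compound ids (must be
#'   present in `library`).
#' @param library the full [signature_library()].
#' @param followup_profiles list of [disease_profile()] objects for the
#'   follow-up dataset's groups.
#' @param dataset_id label recorded in the result.
#' @param alpha FDR threshold for the `consistent_negative` flag.
#' @param min_overlap,variance_method passed to [match_all()].
#' @return data frame with one row per candidate: `compound_id`,
#'   `dataset_id`, `k`, `M_r`, `se`, `tau2_1`, `z`, `p`, `p_adj`,
#'   `consistent_negative`, `evaluable`.
#' @export
followup_score <- function(candidates, library, followup_profiles,
                           dataset_id = "followup", alpha = 0.05,
                           min_overlap = 10, variance_method = "raw") {
  if (length(candidates) == 0L)
    rs_validation_error("no candidate compounds supplied")
  if (!all(candidates %in% library$meta$compound_id))
    rs_validation_error("candidates must be drawn from the signature library")
  input <- followup_input(followup_profiles)
  sub <- filter_compounds(library, candidates)
  obs <- tryCatch(
    match_all(sub, input, min_overlap = min_overlap,
              variance_method = variance_method),
    revscreen_empty_input_error = function(e) NULL)
  rows <- lapply(sort(candidates), function(cid) {
    o <- if (is.null(obs)) NULL else obs[obs$compound_id == cid, , drop = FALSE]
    base <- data.frame(compound_id = cid, dataset_id = dataset_id,
                       k = 0L, M_r = NA_real_, se = NA_real_,
                       tau2_1 = NA_real_, z = NA_real_, p = NA_real_,
                       evaluable = FALSE, stringsAsFactors = FALSE)
    if (is.null(o) || nrow(o) < 2L) {
      rs_log("followup", "candidate ", cid, " unevaluable in ", dataset_id)
      return(base)
    }
    fit <- tryCatch(reml_fit(o, random_structure("region")),
                    revscreen_error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(base)
    base$k <- fit$k; base$M_r <- fit$M_r; base$se <- fit$se
    base$tau2_1 <- fit$tau2_1; base$z <- fit$z; base$p <- fit$p
    base$evaluable <- TRUE
    base
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- out$evaluable
  if (any(ok)) out$p_adj[ok] <- bh_adjust(out$p[ok])
  out$consistent_negative <- ok & !is.na(out$M_r) & out$M_r < 0 &
    !is.na(out$p_adj) & out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Prioritize discovery candidates using follow-up evidence
#'
#' Default rule: keep compounds whose pooled estimate is negative in every
#' follow-up dataset and significant (`p_adj < alpha`) in at least one;
#' rank by the number of datasets in which the compound is significant,
#' breaking ties by the mean absolute pooled estimate across follow-ups.
#' The rule is pluggable via `rule`.
#'
#' @param discovery_negatives data frame of discovery-negative compounds
#'   (needs a `compound_id` column), e.g. `fdr_classify()$negative`.
#' @param followup_results list of [followup_score()] outputs, one per
#'   follow-up dataset (at least one required).
#' @param alpha significance threshold used by the default rule.
#' @param rule optional function `(compound rows across datasets) ->
#'   logical` replacing the default retention rule.
#' @return data frame of retained compounds, ranked: `compound_id`,
#'   `n_datasets`, `n_negative`, `n_significant`, `mean_abs_M_r`, `rank`.
#' @export
prioritize <- function(discovery_negatives, followup_results, alpha = 0.05,
                       rule = NULL) {
  if (length(followup_results) == 0L)
    rs_validation_error("at least one follow-up dataset is required")
  empty <- data.frame(compound_id = character(0), n_datasets = integer(0),
                      n_negative = integer(0), n_significant = integer(0),
                      mean_abs_M_r = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(discovery_negatives) || nrow(discovery_negatives) == 0L) {
    warning("empty discovery set: nothing to prioritize")
    return(empty)
  }
  all_fu <- do.call(rbind, followup_results)
  rows <- lapply(sort(unique(discovery_negatives$compound_id)), function(cid) {
    fu <- all_fu[all_fu$compound_id == cid & all_fu$evaluable, , drop = FALSE]
    n_data <- length(followup_results)
    neg <- sum(fu$M_r < 0, na.rm = TRUE)
    sig <- sum(fu$M_r < 0 & fu$p_adj < alpha, na.rm = TRUE)
    keep <- if (is.null(rule)) {
      nrow(fu) == n_data && neg == n_data && sig >= 1L
    } else {
      isTRUE(rule(fu))
    }
    if (!keep) return(NULL)
    data.frame(compound_id = cid, n_datasets = n_data, n_negative = neg,
               n_significant = sig,
               mean_abs_M_r = mean(abs(fu$M_r), na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- out[order(-out$n_significant, -out$mean_abs_M_r, out$compound_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
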