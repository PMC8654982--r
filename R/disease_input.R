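#' Disease differential-expression profile
#'
#' A `disease_profile` is a data frame with one row per gene and columns
#' `gene`, `effect` (signed differential-expression statistic, log2FC-like),
#' `p` and `p_adj` (Benjamini-Hochberg adjusted), tagged with the brain
#' region (or grouping label) and study it came from. Gene symbols are
#' case-normalized to upper case; duplicate symbols collapse to the row with
#' the smallest p-value so each gene appears once.
#'
#' @param genes character vector of gene identifiers.
#' @param effect numeric vector of signed effect statistics.
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param region region / grouping label.
#' @param study_id study label.
#' @param p_adj optional pre-computed adjusted p-values; recomputed with
#'   [bh_adjust()] when missing.
#' @return a data frame of class `disease_profile` with attributes `region`
#'   and `study_id`.
#' @export
disease_profile <- function(genes, effect, p, region, study_id = region,
                            p_adj = NULL) {
  if (length(genes) != length(effect) || length(genes) != length(p))
    rs_validation_error("genes, effect and p must have equal length")
  if (!is_prob(p))
    rs_validation_error("p-values must lie in [0, 1]")
  genes <- toupper(as.character(genes))
  df <- data.frame(gene = genes, effect = as.numeric(effect),
                   p = as.numeric(p), stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene)) {
    # deterministic de-duplication: keep the smallest-p row per symbol
    df <- df[order(df$gene, df$p), ]
    df <- df[!duplicated(df$gene), ]
  }
  df <- df[order(df$gene), ]
  rownames(df) <- NULL
  if (is.null(p_adj)) {
    df$p_adj <- bh_adjust(df$p)
  } else {
    if (length(p_adj) != length(genes))
      rs_validation_error("p_adj must match genes in length")
    pa <- data.frame(gene = genes, p_adj = as.numeric(p_adj))
    pa <- pa[!duplicated(pa$gene), ]
    df$p_adj <- pa$p_adj[match(df$gene, pa$gene)]
    if (!is_prob(df$p_adj))
      rs_validation_error("p_adj values must lie in [0, 1]")
  }
  structure(df, region = as.character(region),
            study_id = as.character(study_id),
            class = c("disease_profile", "data.frame"))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p-values with the Benjamini-Hochberg step-up
#' procedure, the multiplicity correction used throughout the screen
#' (differential-expression gene selection and the per-compound FDR family).
#'
#' @param pvalues numeric vector of p-values, each in `[0, 1]`.
#' @return adjusted p-values in the input order, each in `[0, 1]` and no
#'   smaller than the corresponding raw p-value.
#' @examples
#' bh_adjust(c(0.002, 0.01, 0.03, 0.04))
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (!is.numeric(pvalues) || anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    rs_validation_error("p-values must be numeric in [0, 1] with no NA")
  p.adjust(pvalues, method = "BH")
}

#' Select differentially expressed genes from a profile
#'
#' @param profile a [disease_profile()].
#' @param alpha FDR threshold; rows with `p_adj < alpha` are kept.
#' @return the selected rows, effects carried through unchanged.
#' @export
select_deg <- function(profile, alpha = 0.05) {
  stopifnot(inherits(profile, "disease_profile"))
  out <- profile[profile$p_adj < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the three-category disease gene input
#'
#' Assembles the query input for signature matching from per-region
#' differential-expression profiles. Per region, three categories are
#' formed: `DEG` (all genes at BH FDR below `alpha`), `PATHWAY` (every
#' pathway gene present in the profile, regardless of significance — the
#' category targets the behavioral disease process, not statistical
#' selection), and `LANDMARK` (directly measured genes that already belong
#' to at least one of the first two categories). Grouping keys combine
#' category and region (e.g. `PATHWAY_dlPFC`), mirroring how observations
#' are later nested in the meta-regression.
#'
#' @param profiles list of [disease_profile()] objects (one per region/study).
#' @param pathway_genes character vector of pathway gene symbols.
#' @param landmark_genes character vector of directly-measured gene symbols.
#' @param alpha FDR threshold for the DEG category.
#' @return data frame of class `disease_input` with columns `region`,
#'   `category`, `gene`, `effect`, `group`.
#' @export
build_input <- function(profiles, pathway_genes, landmark_genes,
                        alpha = 0.05) {
  if (length(profiles) == 0L)
    rs_validation_error("at least one disease profile is required")
  pathway_genes <- toupper(pathway_genes)
  landmark_genes <- toupper(landmark_genes)
  pieces <- lapply(profiles, function(pr) {
    stopifnot(inherits(pr, "disease_profile"))
    region <- attr(pr, "region")
    deg <- select_deg(pr, alpha)
    path <- pr[pr$gene %in% pathway_genes, , drop = FALSE]
    union_genes <- union(deg$gene, path$gene)
    lmk_genes <- intersect(landmark_genes, union_genes)
    lmk <- pr[pr$gene %in% lmk_genes, , drop = FALSE]
    cat_block <- function(d, category) {
      if (nrow(d) == 0L) return(NULL)
      data.frame(region = region, category = category,
                 gene = d$gene, effect = d$effect,
                 stringsAsFactors = FALSE)
    }
    do.call(rbind, Filter(Negate(is.null), list(
      cat_block(deg, "DEG"),
      cat_block(path, "PATHWAY"),
      cat_block(lmk, "LANDMARK")
    )))
  })
  out <- do.call(rbind, Filter(Negate(is.null), pieces))
  if (is.null(out) || nrow(out) == 0L)
    rs_error("disease input is empty: no gene passed any category",
             "revscreen_empty_input_error")
  out$group <- paste(out$category, out$region, sep = "_")
  out <- out[order(out$region, out$category, out$gene), ]
  rownames(out) <- NULL
  structure(out, class = c("disease_input", "data.frame"))
}

#' Translate gene effects through an ortholog map
#'
#' Maps gene identifiers to another species' namespace keeping only
#' one-to-one orthologs: a pair is retained when its source gene maps to
#' exactly one target and that target is reached by exactly one source.
#' Many-to-many families are dropped entirely to avoid double-counting genes
#' in downstream correlations.
#'
#' @param genes data frame with columns `gene` and `effect` (extra columns
#'   are carried through).
#' @param mapping data frame with columns `source` and `target` (or the
#'   first two columns are taken as such).
#' @return the input rows whose genes map one-to-one, with `gene` replaced
#'   by the target identifier (upper-cased).
#' @export
map_orthologs <- function(genes, mapping) {
  if (is.null(mapping) || nrow(mapping) == 0L)
    rs_validation_error("ortholog mapping is empty")
  map <- data.frame(source = toupper(as.character(mapping[[1]])),
                    target = toupper(as.character(mapping[[2]])),
                    stringsAsFactors = FALSE)
  map <- unique(map)
  one2one <- !(map$source %in% map$source[duplicated(map$source)]) &
    !(map$target %in% map$target[duplicated(map$target)])
  map <- map[one2one, , drop = FALSE]
  out <- genes
  out$gene <- toupper(as.character(out$gene))
  idx <- match(out$gene, map$source)
  dropped <- sum(is.na(idx))
  if (dropped > 0L)
    rs_log("orthologs", dropped, " gene(s) without a one-to-one ortholog dropped")
  out <- out[!is.na(idx), , drop = FALSE]
  out$gene <- map$target[idx[!is.na(idx)]]
  rownames(out) <- NULL
  out
}
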