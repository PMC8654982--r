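#' Pearson product-moment correlation
#'
#' The effect size used to score a compound signature against the disease
#' input: plain product-moment correlation over the shared genes.
#'
#' @param x,y numeric vectors of equal length (at least 3), neither constant.
#' @return the correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    rs_validation_error("x and y must have equal length")
  if (length(x) < 3L)
    rs_validation_error("at least 3 paired values are required")
  if (anyNA(x) || anyNA(y) || !all(is.finite(x)) || !all(is.finite(y)))
    rs_validation_error("inputs must be finite with no NA")
  if (sd(x) == 0 || sd(y) == 0)
    rs_error("constant vector: correlation undefined",
             "revscreen_degenerate_error")
  as.numeric(cor(x, y))
}

#' Sampling variance of a correlation
#'
#' Large-sample variance of a Pearson correlation on the raw-correlation
#' scale, `(1 - r^2)^2 / (n - 1)`; this is the known within-observation
#' error the meta-regression receives. A Fisher-z pipeline (variance
#' `1/(n - 3)` on the z scale) is available via `method = "fisher_z"`; it
#' must agree with the raw-scale route on sign and FDR classification.
#'
#' @param r correlation, `|r| < 1`.
#' @param n number of paired observations (gene overlap), at least 4.
#' @param method `"raw"` (default) or `"fisher_z"`.
#' @return strictly positive variance, decreasing in `n`.
#' @examples
#' sampling_variance(0, 11)   # 0.1
#' @export
sampling_variance <- function(r, n, method = c("raw", "fisher_z")) {
  method <- match.arg(method)
  if (!is_count(n) || n < 4)
    rs_error("at least 4 overlapping observations are required",
             "revscreen_overlap_error")
  if (!is.numeric(r) || !is.finite(r) || abs(r) >= 1)
    rs_validation_error("r must satisfy |r| < 1")
  if (method == "raw") (1 - r^2)^2 / (n - 1) else 1 / (n - 3)
}

#' Signature library container
#'
#' Bundles a genes-by-signatures score matrix with its signature metadata
#' (compound, cell line, dose, time), the in-memory form of a GCT-like
#' matrix plus a metadata table. Duplicate gene identifiers are rejected.
#'
#' @param scores numeric matrix, rownames = gene symbols, colnames =
#'   signature ids.
#' @param meta data frame with columns `signature_id`, `compound_id`,
#'   `cell_line`, `dose`, `time`; one row per column of `scores`.
#' @return an object of class `signature_library`.
#' @export
signature_library <- function(scores, meta) {
  if (!is.matrix(scores) || !is.numeric(scores))
    rs_validation_error("scores must be a numeric matrix")
  rownames(scores) <- toupper(rownames(scores))
  if (anyDuplicated(rownames(scores)))
    rs_validation_error("signature matrix has duplicate gene identifiers")
  need <- c("signature_id", "compound_id", "cell_line", "dose", "time")
  if (!all(need %in% names(meta)))
    rs_validation_error(paste("signature metadata must have columns:",
                              paste(need, collapse = ", ")))
  if (nrow(meta) != ncol(scores) ||
      (ncol(scores) > 0L &&
       !identical(as.character(meta$signature_id), colnames(scores))))
    rs_validation_error("metadata rows must match score matrix columns")
  structure(list(scores = scores, meta = as.data.frame(meta)),
            class = "signature_library")
}

#' @export
print.signature_library <- function(x, ...) {
  cat(sprintf("signature_library: %d genes x %d signatures, %d compounds\n",
              nrow(x$scores), ncol(x$scores),
              length(unique(x$meta$compound_id))))
  invisible(x)
}

#' Restrict a signature library to a set of compounds
#'
#' Used both to keep only repurposable (e.g. FDA-approved / clinical-stage)
#' compounds before matching, and to pull candidate compounds for follow-up.
#'
#' @param library a [signature_library()].
#' @param compounds character vector of compound ids to keep.
#' @return a filtered `signature_library`.
#' @export
filter_compounds <- function(library, compounds) {
  keep <- library$meta$compound_id %in% compounds
  if (!any(keep))
    rs_validation_error("no signature left after compound filtering")
  signature_library(library$scores[, keep, drop = FALSE],
                    library$meta[keep, , drop = FALSE])
}

#' Score one signature against one disease-input slice
#'
#' Correlates a signature's gene scores with the disease effects of a
#' single region-by-category slice over their shared genes (ordered by gene
#' id), and attaches the analytic sampling variance.
#'
#' @param sig list with fields `compound_id`, `cell_line`, `dose`, `time`
#'   and `scores` (named numeric vector of gene-level scores).
#' @param input_slice rows of a `disease_input` for one region x category.
#' @param min_overlap minimum shared-gene count; below it the observation
#'   is skipped (returns `NULL`) with a logged reason.
#' @param variance_method passed to [sampling_variance()].
#' @return a one-row data frame (an effect observation) or `NULL`.
#' @export
match_signature <- function(sig, input_slice, min_overlap = 10,
                            variance_method = "raw") {
  genes <- sort(intersect(toupper(names(sig$scores)), input_slice$gene))
  if (length(genes) < min_overlap) {
    rs_log("connectivity", "signature ", sig$compound_id, "/", sig$cell_line,
           " vs ", input_slice$group[1], ": overlap ", length(genes),
           " < ", min_overlap, ", skipped")
    return(NULL)
  }
  x <- sig$scores[match(genes, toupper(names(sig$scores)))]
  y <- input_slice$effect[match(genes, input_slice$gene)]
  r <- pearson_r(x, y)
  # clamp only for the variance formula so |r| = 1 stays reportable
  r_v <- max(min(r, 0.999999), -0.999999)
  v <- sampling_variance(r_v, length(genes), method = variance_method)
  if (variance_method == "fisher_z") r <- atanh(r_v)
  data.frame(compound_id = sig$compound_id, signature_id = sig$signature_id %||%
               paste(sig$compound_id, sig$cell_line, sig$dose, sig$time, sep = "|"),
             cell_line = sig$cell_line, dose = sig$dose, time = sig$time,
             region = input_slice$region[1], category = input_slice$category[1],
             group = input_slice$group[1],
             r = r, var_r = v,
             n = length(genes), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score every signature against every disease-input slice
#'
#' Produces the effect-observation table the meta-regression consumes: one
#' row per signature x region x category passing the gene-overlap minimum,
#' in deterministic (compound, signature, region, category) order.
#'
#' @param library a [signature_library()].
#' @param input a `disease_input` from [build_input()].
#' @param min_overlap minimum shared-gene count per observation.
#' @param variance_method `"raw"` or `"fisher_z"` (see [sampling_variance()]).
#' @return data frame of effect observations with columns `compound_id`,
#'   `signature_id`, `cell_line`, `dose`, `time`, `region`, `category`,
#'   `group`, `r`, `var_r`, `n`.
#' @export
match_all <- function(library, input, min_overlap = 10,
                      variance_method = "raw") {
  stopifnot(inherits(library, "signature_library"))
  if (nrow(input) == 0L || ncol(library$scores) == 0L)
    rs_validation_error("library and disease input must be non-empty")
  slices <- split(seq_len(nrow(input)), input$group)
  mat <- library$scores
  meta <- library$meta
  out <- vector("list", length(slices))
  for (si in seq_along(slices)) {
    slice <- input[slices[[si]], , drop = FALSE]
    genes <- sort(intersect(rownames(mat), slice$gene))
    if (length(genes) < min_overlap) next
    sub <- mat[genes, , drop = FALSE]
    y <- slice$effect[match(genes, slice$gene)]
    if (sd(y) == 0) next
    sds <- apply(sub, 2, sd)
    ok <- which(sds > 0)
    if (length(ok) == 0L) next
    r <- as.numeric(cor(sub[, ok, drop = FALSE], y))
    r_v <- pmax(pmin(r, 0.999999), -0.999999)
    nn <- length(genes)
    if (variance_method == "raw") {
      var_r <- (1 - r_v^2)^2 / (nn - 1)
    } else {
      # Fisher-z route: the pooled effect lives on the z scale
      r <- atanh(r_v)
      var_r <- rep(1 / (nn - 3), length(r))
    }
    out[[si]] <- data.frame(
      compound_id = meta$compound_id[ok], signature_id = meta$signature_id[ok],
      cell_line = meta$cell_line[ok], dose = meta$dose[ok], time = meta$time[ok],
      region = slice$region[1], category = slice$category[1],
      group = slice$group[1], r = r, var_r = var_r, n = nn,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(res) || nrow(res) == 0L)
    rs_error("no observation passed the overlap threshold",
             "revscreen_empty_input_error")
  res <- res[order(res$compound_id, res$signature_id, res$region,
                   res$category), ]
  rownames(res) <- NULL
  res
}
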