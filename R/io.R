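#' Read / write a differential-expression table
#'
#' TSV with header columns `gene`, `effect`, `p` and optionally `p_adj`
#' (recomputed with [bh_adjust()] when absent).
#'
#' @param path file path.
#' @param region,study_id labels attached to the profile.
#' @return a [disease_profile()].
#' @export
read_de_table <- function(path, region, study_id = region) {
  if (!file.exists(path))
    rs_validation_error(paste0("file not found: ", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "effect", "p")
  if (!all(need %in% names(df)))
    rs_validation_error(paste0("DE table ", path, " must have columns gene, effect, p"))
  disease_profile(df$gene, df$effect, df$p, region = region,
                  study_id = study_id,
                  p_adj = if ("p_adj" %in% names(df)) df$p_adj else NULL)
}

#' @rdname read_de_table
#' @param profile a [disease_profile()] to write.
#' @export
write_de_table <- function(profile, path) {
  write.table(as.data.frame(profile)[, c("gene", "effect", "p", "p_adj")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a GCT-like signature matrix with metadata
#'
#' The signature matrix is a GCT-like TSV (first column `gene`, one column
#' per signature id); metadata is a TSV with columns `signature_id`,
#' `compound_id`, `cell_line`, `dose`, `time`.
#'
#' @param matrix_path path of the genes-by-signatures TSV.
#' @param meta_path path of the signature metadata TSV.
#' @return a [signature_library()].
#' @export
read_signature_library <- function(matrix_path, meta_path) {
  for (p in c(matrix_path, meta_path))
    if (!file.exists(p)) rs_validation_error(paste0("file not found: ", p))
  mat_df <- read.delim(matrix_path, check.names = FALSE,
                       stringsAsFactors = FALSE)
  if (names(mat_df)[1] != "gene")
    rs_validation_error("signature matrix must start with a 'gene' column")
  if (anyDuplicated(toupper(mat_df$gene)))
    rs_validation_error("signature matrix has duplicate gene identifiers")
  scores <- as.matrix(mat_df[, -1, drop = FALSE])
  rownames(scores) <- mat_df$gene
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  signature_library(scores, meta)
}

#' @rdname read_signature_library
#' @param library a [signature_library()] to write.
#' @export
write_signature_library <- function(library, matrix_path, meta_path) {
  df <- data.frame(gene = rownames(library$scores), library$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(library$meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(matrix_path)
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene symbols.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path))
    rs_validation_error(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      rs_validation_error("malformed GMT line (need name, description, genes)")
    toupper(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors to write.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column ortholog map TSV
#'
#' @param path TSV with header `source`, `target` (or any two columns taken
#'   in order).
#' @return data frame with columns `source`, `target`.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path))
    rs_validation_error(paste0("file not found: ", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    rs_validation_error("ortholog map needs two columns")
  data.frame(source = as.character(df[[1]]), target = as.character(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Read / write behavioral records CSV
#'
#' Columns: `fly_id`, `sex`, `treatment`, `movement_s`, `seizure`,
#' `absorbance_1`, `absorbance_2`.
#'
#' @param path file path.
#' @return a `behavior_records` data frame.
#' @export
read_behavior_csv <- function(path) {
  if (!file.exists(path))
    rs_validation_error(paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fly_id", "sex", "treatment", "movement_s", "seizure")
  if (!all(need %in% names(df)))
    rs_validation_error("behavior CSV missing required columns")
  if (any(df$movement_s < 0 | df$movement_s > 45))
    rs_validation_error("movement_s outside the [0, 45] s assay window")
  df$seizure <- as.logical(df$seizure)
  structure(df, class = c("behavior_records", "data.frame"))
}

#' @rdname read_behavior_csv
#' @param records behavior records to write.
#' @export
write_behavior_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a 384-well plate-reader export
#'
#' Long-format CSV with columns `well` and `absorbance_630nm`.
#'
#' @param path file path.
#' @return data frame with columns `well`, `absorbance`.
#' @export
read_plate_export <- function(path) {
  if (!file.exists(path))
    rs_validation_error(paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("well", "absorbance_630nm") %in% names(df)))
    rs_validation_error("plate export needs columns well, absorbance_630nm")
  data.frame(well = df$well, absorbance = as.numeric(df$absorbance_630nm),
             stringsAsFactors = FALSE)
}
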