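#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Either
#' supply file paths for every input (they are checked and parsed up front,
#' before any computation starts) or set `simulate = TRUE` to generate all
#' inputs from a [sim_config()].
#'
#' @param outdir output directory (created if missing).
#' @param simulate generate inputs with the synthetic module instead of
#'   reading files.
#' @param sim a [sim_config()] used when `simulate = TRUE`.
#' @param de_tables named character vector `region -> path` of DE tables.
#' @param signature_matrix,signature_meta paths of the signature library.
#' @param gene_sets path of a GMT file containing sets named `PATHWAY` and
#'   `LANDMARK`.
#' @param ortholog_map optional path of a two-column ortholog TSV.
#' @param behavior_csv optional path of behavioral records.
#' @param benchmark_ids character vector of benchmark compound ids.
#' @param alpha FDR threshold.
#' @param min_overlap minimum gene overlap per observation.
#' @param variance_method `"raw"` or `"fisher_z"`.
#' @param seed integer seed governing every stochastic step.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, simulate = TRUE, sim = sim_config(),
                            de_tables = NULL, signature_matrix = NULL,
                            signature_meta = NULL, gene_sets = NULL,
                            ortholog_map = NULL, behavior_csv = NULL,
                            benchmark_ids = character(0), alpha = 0.05,
                            min_overlap = 10,
                            variance_method = c("raw", "fisher_z"),
                            seed = 1L) {
  variance_method <- match.arg(variance_method)
  if (!is_prob(alpha)) rs_config_error("field 'alpha' must be in [0, 1]")
  if (!simulate) {
    paths <- c(de_tables, signature_matrix, signature_meta, gene_sets,
               ortholog_map, behavior_csv)
    missing <- paths[!vapply(paths, file.exists, logical(1))]
    if (length(missing) > 0)
      rs_config_error(paste0("input file(s) not found: ",
                             paste(missing, collapse = ", ")))
    if (is.null(de_tables) || is.null(signature_matrix) ||
        is.null(signature_meta) || is.null(gene_sets))
      rs_config_error("non-simulated runs need DE tables, signatures and gene sets")
  }
  structure(list(outdir = outdir, simulate = simulate, sim = sim,
                 de_tables = de_tables, signature_matrix = signature_matrix,
                 signature_meta = signature_meta, gene_sets = gene_sets,
                 ortholog_map = ortholog_map, behavior_csv = behavior_csv,
                 benchmark_ids = benchmark_ids, alpha = alpha,
                 min_overlap = min_overlap,
                 variance_method = variance_method, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML key-value file mirroring [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    rs_validation_error(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  raw$sim <- NULL
  args <- raw
  args$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, args)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the end-to-end screen
#'
#' Executes the staged flow — build input, match signatures, per-compound
#' meta-regression, FDR classification, benchmark comparison, follow-up
#' re-scoring, prioritization, and (optionally) behavioral statistics —
#' writing every stage's table under `outdir` together with a JSON manifest
#' recording the package version, seed and parameters. A rerun with the
#' same configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    rs_log(name, "running")
    tryCatch(expr, error = function(e) {
      rs_error(paste0("stage '", name, "' failed: ", conditionMessage(e)),
               "revscreen_stage_error")
    })
  }

  inputs <- stage("inputs", {
    if (config$simulate) {
      sim <- simulate_disease_profiles(config$sim)
      library <- simulate_compound_library(config$sim, sim,
                                           alpha = config$alpha)
      fu <- list(
        invitro = simulate_followup_dataset(config$sim, sim, TRUE, "invitro"),
        mouse = simulate_followup_dataset(config$sim, sim, TRUE, "mouse"))
      list(profiles = sim$profiles, pathway = sim$pathway_genes,
           landmark = sim$landmark_genes, library = library,
           followups = lapply(fu, `[[`, "profiles"))
    } else {
      profiles <- mapply(read_de_table, config$de_tables,
                         names(config$de_tables), SIMPLIFY = FALSE)
      sets <- read_gmt(config$gene_sets)
      if (!all(c("PATHWAY", "LANDMARK") %in% names(sets)))
        rs_config_error("gene-set GMT must define PATHWAY and LANDMARK sets")
      list(profiles = profiles, pathway = sets$PATHWAY,
           landmark = sets$LANDMARK,
           library = read_signature_library(config$signature_matrix,
                                            config$signature_meta),
           followups = list())
    }
  })

  input <- stage("build_input", build_input(inputs$profiles, inputs$pathway,
                                            inputs$landmark,
                                            alpha = config$alpha))
  write_tsv(input, file.path(config$outdir, "disease_input.tsv"))

  obs <- stage("match", match_all(inputs$library, input,
                                  min_overlap = config$min_overlap,
                                  variance_method = config$variance_method))
  write_tsv(obs, file.path(config$outdir, "observations.tsv"))

  results <- stage("meta", meta_screen(obs))
  classified <- stage("classify", fdr_classify(results, config$alpha))
  write_tsv(classified$results, file.path(config$outdir, "meta_results.tsv"))
  write_tsv(classified$negative, file.path(config$outdir, "negative.tsv"))
  write_tsv(classified$positive, file.path(config$outdir, "positive.tsv"))

  benchmark <- NULL
  if (length(config$benchmark_ids) > 0) {
    benchmark <- stage("benchmark",
                       benchmark_compare(classified, config$benchmark_ids,
                                         config$alpha))
    write_tsv(benchmark$present, file.path(config$outdir, "benchmark.tsv"))
  }

  followups <- list()
  prioritized <- NULL
  if (nrow(classified$negative) > 0 && length(inputs$followups) > 0) {
    followups <- stage("followup", {
      lapply(names(inputs$followups), function(nm) {
        followup_score(classified$negative$compound_id, inputs$library,
                       inputs$followups[[nm]], dataset_id = nm,
                       alpha = config$alpha,
                       min_overlap = config$min_overlap,
                       variance_method = config$variance_method)
      })
    })
    names(followups) <- names(inputs$followups)
    for (nm in names(followups))
      write_tsv(followups[[nm]],
                file.path(config$outdir, paste0("followup_", nm, ".tsv")))
    prioritized <- stage("prioritize",
                         prioritize(classified$negative, followups,
                                    alpha = config$alpha))
    write_tsv(prioritized, file.path(config$outdir, "prioritized.tsv"))
  }

  behavior <- NULL
  if (!is.null(config$behavior_csv)) {
    behavior <- stage("behavior", {
      rec <- read_behavior_csv(config$behavior_csv)
      list(anova = anova_type3(rec))
    })
    write_tsv(behavior$anova, file.path(config$outdir, "behavior_anova.tsv"))
  }

  manifest <- list(
    package = "revscreen",
    version = as.character(utils::packageVersion("revscreen")),
    seed = config$seed, alpha = config$alpha,
    min_overlap = config$min_overlap,
    variance_method = config$variance_method,
    simulate = config$simulate,
    n_compounds = length(unique(inputs$library$meta$compound_id)),
    n_signatures = ncol(inputs$library$scores),
    n_observations = nrow(obs),
    n_negative = nrow(classified$negative),
    n_positive = nrow(classified$positive),
    n_prioritized = if (is.null(prioritized)) 0L else nrow(prioritized))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  rs_log("pipeline", "done: ", manifest$n_negative, " negative / ",
         manifest$n_positive, " positive compounds")
  invisible(list(input = input, observations = obs, results = results,
                 classified = classified, benchmark = benchmark,
                 followups = followups, prioritized = prioritized,
                 behavior = behavior, manifest = manifest))
}
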