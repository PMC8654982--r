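#' Configuration for the behavioral-assay simulator
#'
#' Defaults emulate the validation assay's design and narrative: four food
#' treatments crossed with sex, group sizes matching the reported assay
#' (61/140/132 control / cocaine / cocaine+drug males, 66/141/142 females,
#' plus drug-only groups of 66 and 68), a 45 s startle window, cocaine
#' lowering male movement with co-treatment restoring it in both sexes,
#' seizures concentrated in the male cocaine group and reduced by
#' co-treatment (female incidence lower throughout), and consumption read
#' out as duplicate-well absorbances generated from the dye calibration
#' line.
#'
#' @param group_sizes named integer vector `"<sex>.<treatment>" -> n`.
#' @param movement_means named numeric vector of mean movement times
#'   (seconds, within `[0, 45]`) per group.
#' @param movement_sd common movement standard deviation (seconds).
#' @param seizure_probs named numeric vector of per-group seizure
#'   probabilities in `[0, 1]`.
#' @param consumption_means named numeric vector of mean consumed dye mass
#'   (ug) per group.
#' @param consumption_sd standard deviation of consumed dye mass (ug).
#' @param calibration list with `slope` (absorbance per ug/mL) and
#'   `intercept` (absorbance) of the standard line.
#' @param absorbance_noise_sd well-level absorbance noise.
#' @param extraction_volume_ml dye extraction volume (mL).
#' @param seed integer seed.
#' @return a validated list of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(
    group_sizes = c(male.control = 61, male.cocaine = 140,
                    `male.cocaine+drug` = 132, male.drug = 66,
                    female.control = 66, female.cocaine = 141,
                    `female.cocaine+drug` = 142, female.drug = 68),
    movement_means = c(male.control = 22, male.cocaine = 12,
                       `male.cocaine+drug` = 17, male.drug = 22,
                       female.control = 20, female.cocaine = 15,
                       `female.cocaine+drug` = 19, female.drug = 20),
    movement_sd = 8,
    seizure_probs = c(male.control = 0.02, male.cocaine = 0.55,
                      `male.cocaine+drug` = 0.25, male.drug = 0.02,
                      female.control = 0.02, female.cocaine = 0.14,
                      `female.cocaine+drug` = 0.115, female.drug = 0.02),
    consumption_means = c(male.control = 0.55, male.cocaine = 0.55,
                          `male.cocaine+drug` = 0.60, male.drug = 0.75,
                          female.control = 0.65, female.cocaine = 0.65,
                          `female.cocaine+drug` = 0.70, female.drug = 0.75),
    consumption_sd = 0.15,
    calibration = list(slope = 0.10, intercept = 0.005),
    absorbance_noise_sd = 0.004,
    extraction_volume_ml = 0.3,
    seed = 1L) {
  groups <- names(group_sizes)
  if (is.null(groups) || any(groups == ""))
    rs_config_error("field 'group_sizes' must be named '<sex>.<treatment>'")
  for (nm in c("movement_means", "seizure_probs", "consumption_means")) {
    val <- get(nm)
    if (!all(groups %in% names(val)))
      rs_config_error(paste0("field '", nm, "' must cover every group"))
  }
  if (!is_prob(seizure_probs))
    rs_config_error("field 'seizure_probs' must lie in [0, 1]")
  if (any(movement_means < 0 | movement_means > 45))
    rs_config_error("field 'movement_means' must lie in [0, 45] seconds")
  if (!all(vapply(group_sizes, is_count, logical(1))))
    rs_config_error("field 'group_sizes' must be counts")
  if (!is.numeric(calibration$slope) || calibration$slope <= 0)
    rs_config_error("field 'calibration' slope must be positive")
  structure(list(group_sizes = group_sizes,
                 movement_means = movement_means, movement_sd = movement_sd,
                 seizure_probs = seizure_probs,
                 consumption_means = consumption_means,
                 consumption_sd = consumption_sd, calibration = calibration,
                 absorbance_noise_sd = absorbance_noise_sd,
                 extraction_volume_ml = extraction_volume_ml,
                 seed = as.integer(seed)),
            class = "behavior_sim_config")
}

#' Simulate fly behavioral records
#'
#' One record per fly: movement time drawn normal and truncated to the
#' `[0, 45]` s assay window (seizing flies are scored as stationary, so
#' group means already reflect that convention), a Bernoulli seizure flag,
#' and duplicate-well absorbances generated from the consumed dye mass
#' through the calibration line plus well noise.
#'
#' @param cfg a [behavior_sim_config()].
#' @return data frame of class `behavior_records`: `fly_id`, `sex`,
#'   `treatment`, `movement_s`, `seizure`, `absorbance_1`, `absorbance_2`.
#' @export
simulate_behavior <- function(cfg) {
  stopifnot(inherits(cfg, "behavior_sim_config"))
  rows <- lapply(names(cfg$group_sizes), function(gp) {
    n <- cfg$group_sizes[[gp]]
    if (n == 0L) return(NULL)
    parts <- strsplit(gp, ".", fixed = TRUE)[[1]]
    sex <- parts[1]; treatment <- paste(parts[-1], collapse = ".")
    with_seed(stable_seed(cfg$seed, "behavior", gp), {
      movement <- pmin(pmax(rnorm(n, cfg$movement_means[[gp]],
                                  cfg$movement_sd), 0), 45)
      seizure <- runif(n) < cfg$seizure_probs[[gp]]
      consumption <- pmax(rnorm(n, cfg$consumption_means[[gp]],
                                cfg$consumption_sd), 0)
      conc <- consumption / cfg$extraction_volume_ml  # ug/mL in extract
      mu_abs <- cfg$calibration$intercept + cfg$calibration$slope * conc
      data.frame(
        fly_id = paste0(gp, "_", seq_len(n)), sex = sex,
        treatment = treatment, movement_s = movement, seizure = seizure,
        absorbance_1 = pmax(mu_abs + rnorm(n, 0, cfg$absorbance_noise_sd), 0),
        absorbance_2 = pmax(mu_abs + rnorm(n, 0, cfg$absorbance_noise_sd), 0),
        stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  structure(out, class = c("behavior_records", "data.frame"))
}
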