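#' Fit the dye standard curve
#'
#' Ordinary least-squares line of absorbance (630 nm) against dye
#' concentration, used to invert measured absorbances into consumed-dye
#' concentrations. The standard range (0-6 ug/mL for FD&C Blue #1 in
#' water) is recorded so inverse predictions outside it can be flagged as
#' extrapolation.
#'
#' @param standards data frame with columns `concentration` (ug/mL) and
#'   `absorbance`; at least two distinct concentrations.
#' @param range numeric length-2 standard range in ug/mL.
#' @return object of class `calibration_curve` with `slope`, `intercept`,
#'   `range` and the `lm` fit.
#' @export
fit_standard_curve <- function(standards, range = c(0, 6)) {
  if (!all(c("concentration", "absorbance") %in% names(standards)))
    rs_validation_error("standards need 'concentration' and 'absorbance' columns")
  if (length(unique(standards$concentration)) < 2L)
    rs_error("standard curve needs at least two distinct concentrations",
             "revscreen_degenerate_error")
  fit <- lm(absorbance ~ concentration, data = standards)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    rs_error("standard curve slope must be positive",
             "revscreen_degenerate_error")
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 range = range, fit = fit),
            class = "calibration_curve")
}

#' Invert absorbance to concentration via a calibration curve
#'
#' @param curve a [calibration_curve][fit_standard_curve()].
#' @param absorbance numeric vector of optical densities.
#' @return data frame with `concentration` (ug/mL) and `extrapolated`
#'   (outside the standard range).
#' @export
predict_concentration <- function(curve, absorbance) {
  conc <- (absorbance - curve$intercept) / curve$slope
  data.frame(concentration = conc,
             extrapolated = conc < curve$range[1] | conc > curve$range[2])
}

# residual sum of squares of the OLS projection of y on X
rss <- function(X, y) {
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Two-way factorial ANOVA with type-III sums of squares
#'
#' Fixed-effects model `response ~ sex + treatment + sex:treatment` with
#' marginal (type-III) sums of squares, appropriate when cell sizes
#' differ: each term's SS is the increase in residual SS when that term's
#' columns are dropped from the full sum-to-zero-coded design, all other
#' terms retained. F statistics use the full-model residual mean square.
#'
#' @param records data frame of behavioral records with factors `sex` and
#'   `treatment`.
#' @param response name of the numeric response column (default
#'   `movement_s`).
#' @return data frame with rows sex, treatment, sex:treatment, residual
#'   and columns `SS`, `df`, `F`, `p`.
#' @export
anova_type3 <- function(records, response = "movement_s") {
  sex <- factor(records$sex)
  treatment <- factor(records$treatment)
  y <- as.numeric(records[[response]])
  if (nlevels(sex) < 2L || nlevels(treatment) < 2L)
    rs_validation_error("both factors need at least 2 levels")
  cells <- table(sex, treatment)
  if (any(cells == 0L)) {
    idx <- which(cells == 0L, arr.ind = TRUE)[1, ]
    rs_validation_error(sprintf(
      "empty design cell: sex=%s, treatment=%s",
      rownames(cells)[idx[1]], colnames(cells)[idx[2]]))
  }
  if (var(y) == 0)
    rs_error("response is constant: zero-variance design",
             "revscreen_degenerate_error")
  # sum-to-zero contrasts make the dropped-term comparison marginal
  d <- data.frame(y = y, S = sex, TR = treatment)
  X <- model.matrix(~ S + TR + S:TR, d,
                    contrasts.arg = list(S = "contr.sum", TR = "contr.sum"))
  asgn <- attr(X, "assign")  # 0 = intercept, 1 = S, 2 = TR, 3 = S:TR
  rss_full <- rss(X, y)
  df_res <- nrow(X) - ncol(X)
  ms_res <- rss_full / df_res
  term_row <- function(term_id, label) {
    keep <- asgn != term_id
    ss <- rss(X[, keep, drop = FALSE], y) - rss_full
    df <- sum(asgn == term_id)
    Fv <- (ss / df) / ms_res
    data.frame(term = label, SS = ss, df = df, F = Fv,
               p = pf(Fv, df, df_res, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  out <- rbind(term_row(1L, "sex"), term_row(2L, "treatment"),
               term_row(3L, "sex:treatment"),
               data.frame(term = "residual", SS = rss_full, df = df_res,
                          F = NA_real_, p = NA_real_))
  rownames(out) <- NULL
  out
}

#' Pooled-variance two-sample t test between two groups
#'
#' Student's t (equal-variance pooling) as the post-hoc comparison after
#' the factorial ANOVA; Welch correction available behind `welch = TRUE`.
#'
#' @param records data frame of behavioral records.
#' @param group_a,group_b named lists / one-row data frames of factor
#'   values selecting each group (e.g. `list(sex = "male",
#'   treatment = "cocaine")`), or logical vectors over rows.
#' @param response numeric response column name.
#' @param welch use the Welch unequal-variance test instead.
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
posthoc_t <- function(records, group_a, group_b, response = "movement_s",
                      welch = FALSE) {
  pick <- function(sel) {
    if (is.logical(sel)) return(sel)
    keep <- rep(TRUE, nrow(records))
    for (nm in names(sel)) keep <- keep & records[[nm]] == sel[[nm]]
    keep
  }
  a <- as.numeric(records[[response]][pick(group_a)])
  b <- as.numeric(records[[response]][pick(group_b)])
  if (length(a) < 2L || length(b) < 2L)
    rs_validation_error("both groups need at least 2 observations")
  if (var(a) == 0 && var(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                mean_a = mean(a), mean_b = mean(b)))
  if (!welch && var(a) == 0 && var(b) == 0)
    rs_error("zero pooled variance: t undefined",
             "revscreen_degenerate_error")
  ht <- t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by summation of hypergeometric probabilities no
#' larger than the observed table's, the test applied to seizure-incidence
#' contrasts.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return the two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2))
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    rs_validation_error("a 2x2 count table is required")
  if (any(table < 0) || any(table != round(table)) || anyNA(table))
    rs_validation_error("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    rs_validation_error("both margins must be positive")
  fisher.test(table)$p.value
}

#' Per-group consumption summaries with pairwise tests
#'
#' Averages each fly's duplicate absorbance wells, inverts through the
#' calibration curve, converts concentration (ug/mL) to consumed dye mass
#' (ug) via the extraction volume, and reports group means with standard
#' errors plus pairwise pooled-variance t tests between treatments within
#' sex.
#'
#' @param records data frame with `sex`, `treatment` and absorbance columns
#'   `absorbance_1`, `absorbance_2` (or a single `absorbance`).
#' @param curve a [calibration_curve][fit_standard_curve()].
#' @param extraction_volume_ml extraction volume in mL (default 0.3, i.e.
#'   300 uL).
#' @return list with `per_fly` (consumption per fly, ug, with an
#'   extrapolation flag), `summary` (group mean, se, n) and `tests`
#'   (pairwise treatment contrasts within sex).
#' @export
consumption_compare <- function(records, curve, extraction_volume_ml = 0.3) {
  stopifnot(inherits(curve, "calibration_curve"))
  abs_mean <- if (all(c("absorbance_1", "absorbance_2") %in% names(records))) {
    (records$absorbance_1 + records$absorbance_2) / 2
  } else if ("absorbance" %in% names(records)) {
    records$absorbance
  } else {
    rs_validation_error("records need absorbance_1/absorbance_2 (or absorbance)")
  }
  inv <- predict_concentration(curve, abs_mean)
  if (any(inv$extrapolated))
    rs_log("behavior", sum(inv$extrapolated),
           " absorbance value(s) outside the standard range (extrapolated)")
  # ug consumed = (ug/mL) * extraction volume in mL
  per_fly <- data.frame(sex = records$sex, treatment = records$treatment,
                        consumption_ug = inv$concentration *
                          extraction_volume_ml,
                        extrapolated = inv$extrapolated,
                        stringsAsFactors = FALSE)
  grp <- aggregate(consumption_ug ~ sex + treatment, per_fly, function(x)
    c(mean = mean(x), se = sd(x) / sqrt(length(x)), n = length(x)))
  summary <- data.frame(sex = grp$sex, treatment = grp$treatment,
                        mean = grp$consumption_ug[, "mean"],
                        se = grp$consumption_ug[, "se"],
                        n = as.integer(grp$consumption_ug[, "n"]))
  tests <- list()
  for (sx in unique(per_fly$sex)) {
    trts <- sort(unique(per_fly$treatment[per_fly$sex == sx]))
    if (length(trts) < 2L) next
    for (i in seq_len(length(trts) - 1L)) {
      for (j in seq(i + 1L, length(trts))) {
        na <- sum(per_fly$sex == sx & per_fly$treatment == trts[i])
        nb <- sum(per_fly$sex == sx & per_fly$treatment == trts[j])
        if (na < 2L || nb < 2L) next
        key <- paste(sx, trts[i], "vs", trts[j], sep = ".")
        tests[[key]] <- posthoc_t(per_fly, list(sex = sx, treatment = trts[i]),
                                  list(sex = sx, treatment = trts[j]),
                                  response = "consumption_ug")
      }
    }
  }
  list(per_fly = per_fly, summary = summary, tests = tests)
}
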