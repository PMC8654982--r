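#' Random-effects grouping structure
#'
#' Names the observation columns that define the nested random effects of
#' the per-compound meta-regression: `level1` (e.g. brain region or study)
#' and, optionally, `level2` (e.g. input category within study). Level-2
#' groups are encoded as composite `level1:level2` keys so they nest
#' uniquely.
#'
#' @param level1 column name of the outer grouping.
#' @param level2 column name of the inner grouping, or `NULL` for a
#'   single-level model.
#' @return an object of class `random_structure`.
#' @export
random_structure <- function(level1, level2 = NULL) {
  stopifnot(is.character(level1), length(level1) == 1L)
  structure(list(level1 = level1, level2 = level2),
            class = "random_structure")
}

# deterministic restart values for the variance components (on tau2 scale);
# the fifth start is a DerSimonian-Laird-flavored moment estimate
reml_starts <- function(r, v) {
  q <- max(var(r) - mean(v), 0)
  unique(pmax(c(1e-8, 1e-4, 1e-2, 0.1, q / 2 + 1e-8), 1e-10))
}

#' Multi-level random-effects meta-regression for one compound
#'
#' Pools a compound's effect observations (correlation `r` with known
#' sampling variance `var_r`) under the model
#' \deqn{r_{ij} = \theta + u_i + w_{ij} + \varepsilon_{ij}}
#' with `u_i ~ N(0, tau2_1)` per level-1 group, `w_ij ~ N(0, tau2_2)` per
#' nested level-2 group, and known residual variances. Variance components
#' are estimated by restricted maximum likelihood (bounded quasi-Newton on
#' log-parameterized tau-squared values with deterministic restarts); the
#' pooled mean is the generalized least-squares estimate at the REML
#' solution, with a two-sided normal Wald test.
#'
#' @param obs data frame of effect observations with columns `r`, `var_r`
#'   and the grouping columns named by `structure`.
#' @param structure a [random_structure()].
#' @param n_starts number of deterministic optimizer restarts (default 5).
#' @param fixed_tau2 optional numeric vector fixing the variance components
#'   (length 1 or 2 matching the structure) instead of estimating them,
#'   e.g. `c(0, 0)` for the inverse-variance fixed-effect limit.
#' @return an object of class `meta_result`: a list with `compound_id`,
#'   `M_r`, `se`, `tau2_1`, `tau2_2`, `k`, `z`, `p`, `direction`,
#'   `converged` and optimizer diagnostics.
#' @export
reml_fit <- function(obs, structure = random_structure("region", "category"),
                     n_starts = 5L, fixed_tau2 = NULL) {
  stopifnot(inherits(structure, "random_structure"))
  k <- nrow(obs)
  if (is.null(k) || k < 2L)
    rs_error("at least 2 observations are required for pooling",
             "revscreen_insufficient_data_error")
  if (any(!is.finite(obs$r)) || any(!is.finite(obs$var_r)) ||
      any(obs$var_r <= 0))
    rs_validation_error("r must be finite and var_r strictly positive")
  # canonical internal order makes the fit exactly permutation-invariant
  has2 <- !is.null(structure$level2)
  ord <- if (has2) {
    order(obs[[structure$level1]], obs[[structure$level2]], obs$r, obs$var_r)
  } else {
    order(obs[[structure$level1]], obs$r, obs$var_r)
  }
  obs <- obs[ord, , drop = FALSE]
  r <- as.numeric(obs$r)
  v <- as.numeric(obs$var_r)
  g1 <- as.integer(factor(obs[[structure$level1]])) - 1L
  g2 <- if (has2) {
    key <- paste(obs[[structure$level1]], obs[[structure$level2]], sep = ":")
    as.integer(factor(key)) - 1L
  } else integer(k)
  # a random level with a single group is not identifiable under REML
  # (the restricted likelihood is flat in its variance); drop it
  drop1 <- max(g1) == 0L
  if (drop1 && has2 && max(g2) > 0L) {
    g1 <- g2
    g2 <- integer(k)
    has2 <- FALSE
  } else if (drop1) {
    # no grouping structure at all: pure fixed-effect pooling
    fit0 <- reml_nll_cpp(r, v, g1, integer(k), 0, 0, FALSE, FALSE)
    z0 <- fit0$theta / fit0$se
    return(structure(list(
      compound_id = if (!is.null(obs$compound_id)) obs$compound_id[1] else NA_character_,
      M_r = fit0$theta, se = fit0$se, tau2_1 = 0,
      tau2_2 = if (!is.null(structure$level2)) 0 else NA_real_,
      k = k, z = z0, p = 2 * pnorm(-abs(z0)),
      direction = if (fit0$theta < 0) "negative" else "positive",
      converged = TRUE,
      diagnostics = list(nll = fit0$nll, degenerate_grouping = TRUE)
    ), class = "meta_result"))
  }
  level1_dropped <- drop1 && !has2 && !is.null(structure$level2)

  npar <- if (has2) 2L else 1L
  cache <- list(par = NULL, res = NULL)
  nll_at <- function(logt) {
    if (!is.null(cache$par) && identical(cache$par, logt)) return(cache$res)
    t1 <- exp(logt[1]); t2 <- if (has2) exp(logt[2]) else 0
    res <- reml_nll_cpp(r, v, g1, g2, t1, t2, has2, TRUE)
    cache$par <<- logt; cache$res <<- res
    res
  }
  fn <- function(logt) nll_at(logt)$nll
  gr <- function(logt) {
    res <- nll_at(logt)
    if (!isTRUE(res$ok)) return(rep(0, npar))
    # chain rule for the log parameterization
    as.numeric(res$grad) * exp(logt)
  }
  lower <- rep(log(1e-10), npar)
  upper <- rep(log(10), npar)
  if (!is.null(fixed_tau2)) {
    tau2 <- rep(pmax(fixed_tau2, 0), length.out = npar)
    at <- reml_nll_cpp(r, v, g1, g2, tau2[1],
                       if (has2) tau2[2] else 0, has2, FALSE)
    M_r <- at$theta
    se <- at$se
    z <- M_r / se
    return(structure(list(
      compound_id = if (!is.null(obs$compound_id)) obs$compound_id[1] else NA_character_,
      M_r = M_r, se = se, tau2_1 = tau2[1],
      tau2_2 = if (has2) tau2[2] else NA_real_,
      k = k, z = z, p = 2 * pnorm(-abs(z)),
      direction = if (M_r < 0) "negative" else "positive",
      converged = isTRUE(at$ok),
      diagnostics = list(nll = at$nll, fixed = TRUE)
    ), class = "meta_result"))
  }
  starts <- reml_starts(r, v)[seq_len(min(n_starts, 5L))]
  best <- NULL
  for (s in starts) {
    par0 <- rep(log(s), npar)
    fit <- tryCatch(
      optim(par0, fn, gr, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 1e4, pgtol = 1e-9, maxit = 200L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    rs_error("REML optimization failed from every start",
             "revscreen_convergence_error")
  # tight polish from the best restart
  polish <- tryCatch(
    optim(best$par, fn, gr, method = "L-BFGS-B", lower = lower,
          upper = upper,
          control = list(factr = 1e1, pgtol = 1e-11, maxit = 200L)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) best <- polish

  at <- nll_at(best$par)
  grad <- as.numeric(at$grad) * exp(best$par)
  # KKT: boundary coordinates with an outward-pushing (positive) gradient
  # are at their constrained optimum
  proj <- grad
  proj[best$par <= lower + 1e-9 & grad > 0] <- 0
  converged <- isTRUE(at$ok) && sqrt(sum(proj^2)) < 1e-6
  tau2 <- exp(best$par)
  tau2[tau2 <= 1.5e-10] <- 0

  M_r <- at$theta
  se <- at$se
  z <- M_r / se
  if (level1_dropped) {
    # the estimated component belongs to the nested level
    tau2 <- c(0, tau2[1])
    has2 <- TRUE
  }
  structure(list(
    compound_id = if (!is.null(obs$compound_id)) obs$compound_id[1] else NA_character_,
    M_r = M_r, se = se,
    tau2_1 = tau2[1], tau2_2 = if (has2) tau2[2] else NA_real_,
    k = k, z = z, p = 2 * pnorm(-abs(z)),
    direction = if (M_r < 0) "negative" else "positive",
    converged = converged,
    diagnostics = list(nll = best$value, grad_norm = sqrt(sum(proj^2)),
                       optim_convergence = best$convergence)
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta_result %s: M_r = %.4f (se %.4f), z = %.3f, p = %.4g\n",
              x$compound_id, x$M_r, x$se, x$z, x$p))
  cat(sprintf("  tau2_1 = %.5f, tau2_2 = %s, k = %d, converged = %s\n",
              x$tau2_1,
              if (is.na(x$tau2_2)) "-" else sprintf("%.5f", x$tau2_2),
              x$k, x$converged))
  invisible(x)
}

#' Fit the meta-regression for every compound in an observation table
#'
#' @param observations output of [match_all()].
#' @param structure a [random_structure()].
#' @return data frame with one row per compound: `compound_id`, `k`, `M_r`,
#'   `se`, `tau2_1`, `tau2_2`, `z`, `p`, `direction`, `converged`.
#' @export
meta_screen <- function(observations,
                        structure = random_structure("region", "category")) {
  split_obs <- split(observations, observations$compound_id)
  rows <- lapply(split_obs, function(o) {
    fit <- tryCatch(reml_fit(o, structure), revscreen_error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(compound_id = o$compound_id[1], k = nrow(o),
                        M_r = NA_real_, se = NA_real_, tau2_1 = NA_real_,
                        tau2_2 = NA_real_, z = NA_real_, p = NA_real_,
                        direction = NA_character_, converged = FALSE,
                        stringsAsFactors = FALSE))
    data.frame(compound_id = fit$compound_id, k = fit$k, M_r = fit$M_r,
               se = fit$se, tau2_1 = fit$tau2_1, tau2_2 = fit$tau2_2,
               z = fit$z, p = fit$p, direction = fit$direction,
               converged = fit$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$compound_id), ]
  rownames(out) <- NULL
  out
}

#' Classify reversal and mimic candidates under FDR control
#'
#' Adjusts the per-compound Wald p-values jointly with Benjamini-Hochberg
#' across all converged fits and splits significant compounds by the sign
#' of the pooled estimate: negative pooled correlations are candidate
#' disease reversers (potential therapeutics), positive ones mimic the
#' disease profile. Non-converged compounds are excluded from the FDR
#' family and reported separately.
#'
#' @param results data frame from [meta_screen()].
#' @param alpha FDR threshold (default 0.05).
#' @return list with elements `negative`, `positive` (data frames),
#'   `results` (the full table with `p_adj` added) and `excluded`
#'   (non-converged compounds).
#' @export
fdr_classify <- function(results, alpha = 0.05) {
  ok <- results$converged & !is.na(results$p)
  excluded <- results[!ok, , drop = FALSE]
  if (nrow(excluded) > 0L)
    rs_log("meta", nrow(excluded), " non-converged compound(s) excluded from ",
           "the FDR family (family size ", sum(ok), ")")
  fam <- results[ok, , drop = FALSE]
  fam$p_adj <- bh_adjust(fam$p)
  results$p_adj <- NA_real_
  results$p_adj[ok] <- fam$p_adj
  list(
    negative = fam[fam$M_r < 0 & fam$p_adj < alpha, , drop = FALSE],
    positive = fam[fam$M_r > 0 & fam$p_adj < alpha, , drop = FALSE],
    results = results,
    excluded = excluded
  )
}

#' Compare screen results against benchmark compounds
#'
#' Benchmarks the screen against a reference set (e.g. compounds currently
#' in clinical trials for the disorder): reports each benchmark compound's
#' pooled estimate, adjusted p and whether it reached the negative
#' (reversal) set, and lists benchmark compounds absent from the screened
#' library.
#'
#' @param classified output of [fdr_classify()].
#' @param benchmark_ids character vector of benchmark compound ids.
#' @param alpha FDR threshold used for the flag.
#' @return list with data frame `present` (columns `compound_id`, `M_r`,
#'   `p_adj`, `in_negative_set`) and character vector `absent`.
#' @export
benchmark_compare <- function(classified, benchmark_ids, alpha = 0.05) {
  res <- classified$results
  present_ids <- intersect(benchmark_ids, res$compound_id)
  absent <- setdiff(benchmark_ids, res$compound_id)
  present <- res[res$compound_id %in% present_ids,
                 c("compound_id", "M_r", "p_adj"), drop = FALSE]
  present$in_negative_set <- present$compound_id %in%
    classified$negative$compound_id
  rownames(present) <- NULL
  list(present = present, absent = absent)
}
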