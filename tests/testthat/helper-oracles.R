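# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive direct-definition
# computations, not the code paths they check.

# O(m^2) Benjamini-Hochberg step-up by direct definition:
# adj(i) = min over j >= rank(i) of p_(j) * m / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj_sorted <- vapply(seq_len(m), function(i)
    min(1, min(ps[i:m] * m / (i:m))), numeric(1))
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# naive two-pass Pearson correlation from the covariance/SD definition
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m1 <- a + b
  m2 <- c + d
  kk <- a + c
  lo <- max(0, kk - m2)
  hi <- min(kk, m1)
  support <- lo:hi
  probs <- dhyper(support, m1, m2, kk)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# restricted log-likelihood of the nested two-level meta-regression,
# computed from the direct matrix definition with base R solve/determinant
reml_loglik_oracle <- function(tau, r, v, g1, g2) {
  k <- length(r)
  V <- diag(v) + tau[1] * outer(g1, g1, "==") + tau[2] * outer(g2, g2, "==")
  Vi <- solve(V)
  one <- rep(1, k)
  s11 <- sum(Vi %*% one * one)
  theta <- sum(Vi %*% r * one) / s11
  res <- r - theta
  ld <- determinant(V, logarithm = TRUE)
  -0.5 * (as.numeric(ld$modulus) + log(s11) +
            as.numeric(res %*% Vi %*% res))
}

# exhaustive grid-plus-refinement search of the restricted likelihood over
# tau2 in [0, 1]^2; returns the maximizing variance components and the GLS
# pooled estimate there
reml_grid_oracle <- function(r, v, g1, g2, levels = 5L, width = 1,
                             n_grid = 21L) {
  center <- c(0.5, 0.5)
  best <- NULL
  for (lev in seq_len(levels)) {
    grid1 <- seq(max(center[1] - width / 2, 0),
                 min(center[1] + width / 2, 1), length.out = n_grid)
    grid2 <- seq(max(center[2] - width / 2, 0),
                 min(center[2] + width / 2, 1), length.out = n_grid)
    for (t1 in grid1) {
      for (t2 in grid2) {
        ll <- reml_loglik_oracle(c(t1, t2), r, v, g1, g2)
        if (is.null(best) || ll > best$ll)
          best <- list(ll = ll, tau = c(t1, t2))
      }
    }
    center <- best$tau
    width <- width * 2.5 / (n_grid - 1)  # zoom around the incumbent
  }
  # GLS at the best grid point
  k <- length(r)
  V <- diag(v) + best$tau[1] * outer(g1, g1, "==") +
    best$tau[2] * outer(g2, g2, "==")
  Vi <- solve(V)
  one <- rep(1, k)
  s11 <- sum(Vi %*% one * one)
  theta <- sum(Vi %*% r * one) / s11
  list(tau = best$tau, theta = theta, ll = best$ll)
}

# type-III sums of squares by explicit full-vs-reduced design matrices
# under sum-to-zero coding, built by hand (no model.matrix / lm)
type3_oracle <- function(records, response = "movement_s") {
  y <- as.numeric(records[[response]])
  code_factor <- function(f) {
    f <- factor(f)
    L <- nlevels(f)
    X <- matrix(0, length(f), L - 1)
    for (i in seq_len(L - 1)) {
      X[f == levels(f)[i], i] <- 1
      X[f == levels(f)[L], i] <- -1
    }
    X
  }
  XS <- code_factor(records$sex)
  XT <- code_factor(records$treatment)
  XI <- matrix(0, length(y), ncol(XS) * ncol(XT))
  col <- 1L
  for (i in seq_len(ncol(XS))) {
    for (j in seq_len(ncol(XT))) {
      XI[, col] <- XS[, i] * XT[, j]
      col <- col + 1L
    }
  }
  icept <- matrix(1, length(y), 1)
  rss_of <- function(X) {
    beta <- qr.solve(X, y)
    sum((y - X %*% beta)^2)
  }
  full <- cbind(icept, XS, XT, XI)
  rss_full <- rss_of(full)
  ss <- c(
    sex = rss_of(cbind(icept, XT, XI)) - rss_full,
    treatment = rss_of(cbind(icept, XS, XI)) - rss_full,
    `sex:treatment` = rss_of(cbind(icept, XS, XT)) - rss_full
  )
  list(SS = ss, rss_full = rss_full,
       df_res = length(y) - ncol(full))
}
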