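# Independent oracles used across the suite. Each is a direct, brute-force
# or closed-form computation sharing no code with the implementation paths
# it checks.

# exact HWE p-value by enumerating every heterozygote configuration with the
# observed allele counts, probabilities from the combinatorial formula
oracle_hwe <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  rare <- 2 * min(n_hom1, n_hom2) + n_het
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  hom_r <- (rare - hets) / 2
  hom_c <- n - hets - hom_r
  logp <- lfactorial(n) - lfactorial(hom_r) - lfactorial(hets) -
    lfactorial(hom_c) + hets * log(2) - lchoose(2 * n, rare)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  sum(p[p <= obs * (1 + 1e-10)])
}

# dense double-loop GRM with pairwise-complete missing handling
oracle_grm <- function(calls, freqs = NULL) {
  p <- if (is.null(freqs)) rowMeans(calls, na.rm = TRUE) / 2 else freqs
  keep <- p > 0 & p < 1
  calls <- calls[keep, , drop = FALSE]; p <- p[keep]
  w <- (calls - 2 * p) / sqrt(2 * p * (1 - p))
  n <- ncol(calls)
  G <- matrix(0, n, n)
  for (j in 1:n) for (k in 1:n) {
    ok <- !is.na(w[, j]) & !is.na(w[, k])
    G[j, k] <- sum(w[ok, j] * w[ok, k]) / sum(ok)
  }
  G
}

# restricted log-likelihood grid search for a single-trait GRM model,
# eigen-rotated so each grid point is O(n); coarse pass then 1e-3 refinement
oracle_grid_reml <- function(G, y, X = matrix(1, length(y), 1),
                             fine = 1e-3) {
  eg <- eigen(G, symmetric = TRUE)
  yt <- drop(crossprod(eg$vectors, y))
  Xt <- crossprod(eg$vectors, X)
  d <- eg$values
  rll <- function(vg, ve) {
    lam <- vg * d + ve
    if (any(lam <= 1e-12)) return(-Inf)
    XtWX <- crossprod(Xt, Xt / lam)
    b <- solve(XtWX, crossprod(Xt, yt / lam))
    r <- yt - drop(Xt %*% b)
    -0.5 * (sum(log(lam)) + determinant(XtWX)$modulus[1] + sum(r^2 / lam))
  }
  vp <- stats::var(y)
  best <- c(vp / 2, vp / 2); bl <- rll(best[1], best[2])
  for (vg in seq(1e-6, 2 * vp, by = 0.02 * vp))
    for (ve in seq(0.05 * vp, 2 * vp, by = 0.02 * vp)) {
      l <- rll(vg, ve)
      if (l > bl) { bl <- l; best <- c(vg, ve) }
    }
  step <- fine * vp
  for (vg in seq(max(1e-8, best[1] - 0.04 * vp), best[1] + 0.04 * vp,
                 by = step))
    for (ve in seq(max(1e-8, best[2] - 0.04 * vp), best[2] + 0.04 * vp,
                   by = step)) {
      l <- rll(vg, ve)
      if (l > bl) { bl <- l; best <- c(vg, ve) }
    }
  list(vg = best[1], ve = best[2], logLik = bl)
}

# Henderson mixed-model equations for a single-trait GBLUP, solved densely:
# u over ALL GRM samples, records y on a subset via incidence Z
oracle_mme_blup <- function(G, obs_idx, y, X, sg2, se2) {
  n_all <- nrow(G)
  Z <- matrix(0, length(y), n_all)
  Z[cbind(seq_along(y), obs_idx)] <- 1
  Gi <- solve(G + diag(1e-10, n_all))
  lhs <- rbind(
    cbind(crossprod(X) / se2, crossprod(X, Z) / se2),
    cbind(crossprod(Z, X) / se2, crossprod(Z) / se2 + Gi / sg2))
  rhs <- c(crossprod(X, y), crossprod(Z, y)) / se2
  sol <- solve(lhs, rhs)
  list(b = sol[seq_len(ncol(X))], u = sol[-seq_len(ncol(X))])
}

# closed-form simple-regression line for one predictor with intercept
oracle_ols <- function(y, x) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - beta * mean(x)
  rss <- sum((y - a - beta * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  t <- beta / se
  list(beta = beta, se = se, p = 2 * stats::pt(-abs(t), n - 2))
}

# Welch two-sample t-test from its printed formulas
oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(t), df)
}

# delete-one-block jackknife SE of a statistic over ordered data
oracle_jackknife_se <- function(est_fun, n_items, n_blocks) {
  blk <- sort(rep_len(seq_len(n_blocks), n_items))
  est <- vapply(seq_len(n_blocks), function(b) est_fun(blk != b), numeric(1))
  sqrt((n_blocks - 1) / n_blocks * sum((est - mean(est))^2))
}

# brute-force windowed LD scores (adjusted r^2, self term included)
oracle_ld_scores <- function(calls, pos, window_bp, n) {
  m <- nrow(calls)
  l <- numeric(m)
  for (j in 1:m) {
    tot <- 0
    for (k in 1:m) {
      if (abs(pos[k] - pos[j]) > window_bp) next
      r2 <- if (j == k) 1 else suppressWarnings(
        stats::cor(calls[j, ], calls[k, ])^2)
      if (is.na(r2)) r2 <- 0
      tot <- tot + (r2 - (1 - r2) / (n - 2))
    }
    l[j] <- tot
  }
  l
}

# standardised true genetic values of a simulated dataset for one
# architecture column
true_genetic_values <- function(d, effects, column) {
  p <- attr(d, "freqs")
  ci <- effects$causal_idx
  w <- (d$calls[ci, , drop = FALSE] - 2 * p[ci]) / sqrt(2 * p[ci] * (1 - p[ci]))
  g <- drop(crossprod(w, effects$beta[, column]))
  if (stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else g
}

# small genotype fixture with explicit values
tiny_dataset <- function(calls, a1 = NULL, a2 = NULL, chrom = "1") {
  m <- nrow(calls); n <- ncol(calls)
  if (is.null(a1)) a1 <- rep("A", m)
  if (is.null(a2)) a2 <- rep("G", m)
  genotype_dataset(
    data.frame(id = paste0("v", 1:m), chrom = chrom, pos = (1:m) * 1000L,
               allele1 = a1, allele2 = a2, stringsAsFactors = FALSE),
    data.frame(fid = "F", iid = paste0("i", 1:n), sex = 2L,
               stringsAsFactors = FALSE),
    calls)
}
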