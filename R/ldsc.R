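# LD scores and LD score regression.
#
# The univariate regression exploits E[chi^2_j] = 1 + n h^2 l_j / m (plus a
# confounding intercept term); the cross-trait version regresses z1*z2 on
# sqrt(n1 n2) l_j / m to estimate genetic covariance. Standard errors come
# from a block jackknife over contiguous variant blocks. Weights are
# 1 / max(l_j, 1), a simple heteroskedasticity weighting.

#' Compute LD scores from genotype data
#'
#' For each variant j, \eqn{l_j = \sum_k \tilde r^2_{jk}} over variants k on
#' the same chromosome within \code{window_kb}, with the bias-adjusted
#' squared correlation \eqn{\tilde r^2 = r^2 - (1 - r^2)/(n - 2)} and the
#' self term included (its adjusted value is 1).
#'
#' @param d A \code{genotype_dataset}; variants must be sorted by
#'   chromosome then position.
#' @param window_kb Window half-width in kilobases (default 1000).
#' @return data.frame of class \code{ld_score_table}: \code{chrom},
#'   \code{id}, \code{pos}, \code{l2}, plus attribute \code{n_reference}.
#' @export
compute_ld_scores <- function(d, window_kb = 1000) {
  stopifnot(inherits(d, "genotype_dataset"))
  if (window_kb <= 0) stop("window must be positive")
  v <- d$variants
  ord <- order(v$chrom, v$pos)
  if (!identical(ord, seq_len(nrow(v))))
    stop("variants must be sorted by chromosome and position")
  n <- ncol(d$calls)
  if (n < 4) stop("too few samples to estimate LD")
  w_bp <- window_kb * 1000
  l2 <- numeric(nrow(v))
  for (ch in unique(v$chrom)) {
    vi <- which(v$chrom == ch)
    X <- t(d$calls[vi, , drop = FALSE])
    X <- scale(X)
    X[is.na(X)] <- 0                       # missing contributes nothing
    sds <- attr(X, "scaled:scale")
    mono <- !is.finite(sds) | sds == 0
    pos <- v$pos[vi]
    m_c <- length(vi)
    lo <- findInterval(pos - w_bp, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + w_bp, pos)
    chunk <- 512L
    for (start in seq(1, m_c, by = chunk)) {
      jj <- start:min(start + chunk - 1L, m_c)
      rng <- min(lo[jj]):max(hi[jj])
      R <- crossprod(X[, jj, drop = FALSE], X[, rng, drop = FALSE]) / (n - 1)
      r2 <- R^2
      r2adj <- r2 - (1 - r2) / (n - 2)
      # zero out pairs outside each variant's own window
      cols <- matrix(rng, nrow = length(jj), ncol = length(rng), byrow = TRUE)
      inwin <- cols >= lo[jj] & cols <= hi[jj]
      r2adj[!inwin] <- 0
      l2[vi[jj]] <- rowSums(r2adj)
    }
    # a monomorphic variant has no defined correlations; self-term only
    l2[vi[mono]] <- 1
  }
  out <- data.frame(chrom = v$chrom, id = v$id, pos = v$pos, l2 = l2,
                    stringsAsFactors = FALSE)
  attr(out, "n_reference") <- n
  class(out) <- c("ld_score_table", "data.frame")
  out
}

#' Write an LD score table in the common whitespace dialect
#'
#' @param l An \code{ld_score_table}.
#' @param path Output path (columns CHR, SNP, BP, L2).
#' @return Invisibly, \code{path}.
#' @export
write_ld_scores <- function(l, path) {
  utils::write.table(
    data.frame(CHR = l$chrom, SNP = l$id, BP = l$pos, L2 = l$l2),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.ldsc_blocks <- function(m, n_blocks) {
  n_blocks <- max(2L, min(n_blocks, floor(m / 2)))
  sort(rep_len(seq_len(n_blocks), m))
}

# weighted regression slope (and intercept if free = TRUE)
.wls_fit <- function(y, x, w, free) {
  if (free) {
    sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
    sxx <- sum(w * x^2); sxy <- sum(w * x * y)
    den <- sw * sxx - swx^2
    slope <- (sw * sxy - swx * swy) / den
    c(slope = slope, intercept = (swy * sxx - swx * sxy) / den)
  } else {
    c(slope = sum(w * x * y) / sum(w * x^2), intercept = NA_real_)
  }
}

.jackknife_se <- function(est) {
  B <- length(est)
  sqrt((B - 1) / B * sum((est - mean(est))^2))
}

#' Univariate LD score regression
#'
#' Weighted regression of association chi-square statistics on
#' \eqn{n l_j / m}; the slope estimates SNP-heritability. The intercept can
#' be estimated (\code{"free"}, its excess over 1 capturing confounding) or
#' constrained to its no-confounding value of 1 (\code{"constrained"}).
#'
#' @param stats \code{sumstats} with \code{chi_square} (or \code{beta} and
#'   \code{se}), ordered as the LD score table.
#' @param l An \code{ld_score_table} or numeric vector of LD scores.
#' @param n GWAS sample size.
#' @param m Number of variants (defaults to \code{length(l)}).
#' @param intercept \code{"free"} or \code{"constrained"} (to 1).
#' @param n_blocks Jackknife block count (default 200, reduced for small m).
#' @return list of class \code{ldsc_fit}: \code{h2}, \code{se},
#'   \code{intercept}, \code{intercept_se} (NA when constrained),
#'   \code{n_blocks}.
#' @export
ldsc_h2 <- function(stats, l, n, m = NULL,
                    intercept = c("free", "constrained"), n_blocks = 200) {
  intercept <- match.arg(intercept)
  l2 <- if (is.data.frame(l)) l$l2 else as.numeric(l)
  if (is.null(m)) m <- length(l2)
  if (m == 0) stop("no variants")
  chi2 <- if (!is.null(stats$chi_square)) stats$chi_square
          else (stats$beta / stats$se)^2
  stopifnot(length(chi2) == length(l2))
  ok <- is.finite(chi2) & is.finite(l2)
  chi2 <- chi2[ok]; l2 <- l2[ok]
  x <- n * l2 / m
  w <- 1 / pmax(l2, 1)
  free <- intercept == "free"
  y <- if (free) chi2 else chi2 - 1
  fit <- .wls_fit(y, x, w, free)
  blk <- .ldsc_blocks(length(y), n_blocks)
  jk <- vapply(unique(blk), function(b)
    .wls_fit(y[blk != b], x[blk != b], w[blk != b], free),
    numeric(2))
  structure(list(
    h2 = unname(fit["slope"]), se = .jackknife_se(jk[1, ]),
    intercept = if (free) unname(fit["intercept"]) else 1,
    intercept_se = if (free) .jackknife_se(jk[2, ]) else NA_real_,
    n_blocks = length(unique(blk)), constrained = !free
  ), class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat(sprintf("LDSC h2 = %.4f (SE %.4f); intercept %s (%s)\n",
              x$h2, x$se,
              formatC(x$intercept, digits = 3, format = "f"),
              if (x$constrained) "constrained" else
                sprintf("SE %.3f", x$intercept_se)))
  invisible(x)
}

#' Cross-trait LD score regression (genetic correlation)
#'
#' Regresses the per-variant z-score product of two GWAS on
#' \eqn{\sqrt{n_1 n_2}\, l_j / m}; the slope estimates the genetic
#' covariance, which is normalised by the two univariate LDSC heritabilities
#' to give the genetic correlation. The cross-trait intercept absorbs
#' sample-overlap confounding; with provably disjoint samples it can be
#' constrained to 0 (\code{"constrained"}), which also constrains the
#' univariate intercepts to 1. The whole ratio is jackknifed over blocks.
#'
#' @param stats1,stats2 \code{sumstats} on a shared, allele-aligned variant
#'   panel, ordered as \code{l}.
#' @param l LD score table or vector.
#' @param n1,n2 The two GWAS sample sizes.
#' @param intercept \code{"free"} or \code{"constrained"} (cross-trait
#'   intercept 0, univariate intercepts 1).
#' @param n_blocks Jackknife block count.
#' @return list of class \code{ldsc_rg}: \code{rg}, \code{se},
#'   \code{gcov}, \code{gcov_se}, \code{h2_1}, \code{h2_2},
#'   \code{intercept}, \code{n_blocks}.
#' @export
ldsc_rg <- function(stats1, stats2, l, n1, n2,
                    intercept = c("free", "constrained"), n_blocks = 200) {
  intercept <- match.arg(intercept)
  l2 <- if (is.data.frame(l)) l$l2 else as.numeric(l)
  m <- length(l2)
  z1 <- stats1$beta / stats1$se
  z2 <- stats2$beta / stats2$se
  stopifnot(length(z1) == m, length(z2) == m)
  ok <- is.finite(z1) & is.finite(z2) & is.finite(l2)
  z1 <- z1[ok]; z2 <- z2[ok]; l2 <- l2[ok]
  free <- intercept == "free"
  w <- 1 / pmax(l2, 1)
  x_co <- sqrt(n1 * n2) * l2 / m
  x_1 <- n1 * l2 / m
  x_2 <- n2 * l2 / m
  y_1 <- if (free) z1^2 else z1^2 - 1
  y_2 <- if (free) z2^2 else z2^2 - 1
  y_co <- z1 * z2

  est_rg <- function(keep) {
    co <- .wls_fit(y_co[keep], x_co[keep], w[keep], free)
    h1 <- .wls_fit(y_1[keep], x_1[keep], w[keep], free)["slope"]
    h2 <- .wls_fit(y_2[keep], x_2[keep], w[keep], free)["slope"]
    c(gcov = unname(co["slope"]),
      rg = unname(co["slope"]) / sqrt(max(h1, 1e-12) * max(h2, 1e-12)),
      h1 = unname(h1), h2 = unname(h2),
      icpt = unname(co["intercept"]))
  }
  all_fit <- est_rg(rep(TRUE, length(w)))
  if (all_fit["h1"] <= 0 || all_fit["h2"] <= 0)
    stop("non-positive LDSC heritability; genetic correlation undefined")
  blk <- .ldsc_blocks(length(w), n_blocks)
  jk <- vapply(unique(blk), function(b) est_rg(blk != b), numeric(5))
  structure(list(
    rg = unname(all_fit["rg"]), se = .jackknife_se(jk["rg", ]),
    gcov = unname(all_fit["gcov"]), gcov_se = .jackknife_se(jk["gcov", ]),
    h2_1 = unname(all_fit["h1"]), h2_2 = unname(all_fit["h2"]),
    intercept = if (free) unname(all_fit["icpt"]) else 0,
    intercept_se = if (free) .jackknife_se(jk["icpt", ]) else NA_real_,
    n_blocks = length(unique(blk)), constrained = !free
  ), class = "ldsc_rg")
}

#' @export
print.ldsc_rg <- function(x, ...) {
  cat(sprintf("LDSC rg = %.4f (SE %.4f), gcov %.4f; intercept %s\n",
              x$rg, x$se, x$gcov,
              if (x$constrained) "constrained to 0"
              else sprintf("%.3f (SE %.3f)", x$intercept, x$intercept_se)))
  invisible(x)
}
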