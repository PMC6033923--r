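# Per-SNP association and profile polygenic scoring.

#' Per-variant linear association scan
#'
#' Simple linear regression of an adjusted phenotype on each variant's
#' dosage (one variant at a time, missing dosages excluded per variant).
#' The phenotype is expected to be pre-adjusted for covariates with
#' \code{\link{residualize}}; for a case-control trait the residualised 0/1
#' phenotype is used, since the resulting per-allele effects feed a linear
#' profile score.
#'
#' @param d A \code{genotype_dataset}.
#' @param y_adjusted Numeric phenotype, one value per sample.
#' @return data.frame of class \code{sumstats} with columns \code{id},
#'   \code{allele1} (effect allele), \code{allele2}, \code{beta}, \code{se},
#'   \code{p}, \code{n}, \code{chi_square}. Variants with zero dosage
#'   variance get \code{NA} effects and are flagged in \code{note}.
#' @export
gwas_linear <- function(d, y_adjusted) {
  stopifnot(inherits(d, "genotype_dataset"),
            length(y_adjusted) == ncol(d$calls))
  x <- d$calls
  obs <- !is.na(x)
  x0 <- x; x0[!obs] <- 0
  nv <- rowSums(obs)
  y <- as.numeric(y_adjusted)
  sy <- as.vector(obs %*% y)
  syy <- as.vector(obs %*% y^2)
  sx <- rowSums(x0)
  sxx <- rowSums(x0 * x0)
  sxy <- as.vector(x0 %*% y)
  # per-variant centred sums over its non-missing samples
  Sxx <- sxx - sx^2 / nv
  Sxy <- sxy - sx * sy / nv
  Syy <- syy - sy^2 / nv
  ok <- nv > 2 & Sxx > 1e-12
  beta <- ifelse(ok, Sxy / Sxx, NA_real_)
  rss <- Syy - ifelse(ok, Sxy^2 / Sxx, 0)
  sigma2 <- rss / (nv - 2)
  se <- ifelse(ok, sqrt(pmax(sigma2, 0) / Sxx), NA_real_)
  tstat <- beta / se
  # a constant phenotype gives rss = 0 and t = 0/0; report beta 0, p 1
  degenerate <- ok & Syy <= 1e-12
  beta[degenerate] <- 0
  tstat[degenerate] <- 0
  se[degenerate] <- 0
  p <- ifelse(ok, 2 * stats::pt(-abs(tstat), df = nv - 2), NA_real_)
  p[degenerate] <- 1
  out <- data.frame(
    id = d$variants$id, allele1 = d$variants$allele1,
    allele2 = d$variants$allele2, beta = beta, se = se, p = p, n = nv,
    chi_square = tstat^2,
    note = ifelse(ok, "", "zero_dosage_variance"),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("sumstats", "data.frame"))
}

#' Read GWAS summary statistics from delimited text
#'
#' Accepts either the package's own columns (\code{id, allele1, allele2,
#' beta, se, p, n}) or the common public dialect (\code{SNP, A1, A2, OR,
#' SE, P}); odds ratios are converted to log odds on load (logged).
#'
#' @param path File path.
#' @return A \code{sumstats} data.frame.
#' @export
read_sumstats <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  nm <- tolower(names(tab))
  pick <- function(...) {
    for (cand in c(...)) { i <- match(cand, nm); if (!is.na(i)) return(i) }
    NA_integer_
  }
  id_i <- pick("id", "snp", "rsid")
  a1_i <- pick("allele1", "a1", "effect_allele")
  a2_i <- pick("allele2", "a2", "other_allele")
  se_i <- pick("se", "stderr")
  p_i <- pick("p", "pval", "p_value")
  n_i <- pick("n", "nobs")
  if (is.na(id_i) || is.na(a1_i) || is.na(a2_i))
    stop("summary statistics need id and allele columns")
  beta_i <- pick("beta", "b", "effect")
  if (is.na(beta_i)) {
    or_i <- pick("or", "odds_ratio")
    if (is.na(or_i)) stop("no effect column (beta or OR)")
    message("converting odds ratios to log scale")
    beta <- log(tab[[or_i]])
  } else beta <- tab[[beta_i]]
  out <- data.frame(
    id = tab[[id_i]], allele1 = toupper(tab[[a1_i]]),
    allele2 = toupper(tab[[a2_i]]), beta = beta,
    se = if (!is.na(se_i)) tab[[se_i]] else NA_real_,
    p = if (!is.na(p_i)) tab[[p_i]] else NA_real_,
    n = if (!is.na(n_i)) tab[[n_i]] else NA_integer_,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("sumstats", "data.frame"))
}

#' Write summary statistics to delimited text
#'
#' @param stats A \code{sumstats} data.frame.
#' @param path Output path (tab-separated, header row).
#' @return Invisibly, \code{path}.
#' @export
write_sumstats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Weighted-allele profile score
#'
#' Scores each target individual as \eqn{\sum_i \beta_i x_{ij}} over the
#' variants shared between the target panel and the summary statistics that
#' survive allele alignment (all of them: no p-value thresholding or LD
#' clumping, matching whole-genome profile scoring). Swap-aligned variants
#' contribute \eqn{\beta_i (2 - x_{ij})}; a missing dosage contributes the
#' variant's mean dosage times \eqn{\beta_i}, so scores stay comparable at
#' unequal call rates.
#'
#' @param target A \code{genotype_dataset} to score.
#' @param stats A \code{sumstats} table (effect allele = \code{allele1}).
#' @param alignment Optional \code{allele_alignment} of stats onto target;
#'   computed when omitted.
#' @param standardize Also return the z-scored profile (default TRUE).
#' @return data.frame of class \code{profile_score}: \code{id},
#'   \code{score}, \code{score_std}, \code{n_snps_scored},
#'   \code{n_missing_imputed}.
#' @export
profile_score <- function(target, stats, alignment = NULL,
                          standardize = TRUE) {
  stopifnot(inherits(target, "genotype_dataset"))
  stats <- stats[!is.na(stats$beta), , drop = FALSE]
  if (is.null(alignment))
    alignment <- align_alleles(target$variants, stats)
  keepable <- c("keep", "swap", "strand_flip", "swap_and_flip")
  kept <- alignment[alignment$action %in% keepable, , drop = FALSE]
  if (nrow(kept) == 0) stop("no scorable variants after alignment")

  vi <- match(kept$id, target$variants$id)
  si <- match(kept$id, stats$id)
  x <- target$calls[vi, , drop = FALSE]
  beta <- stats$beta[si]
  swap <- kept$action %in% c("swap", "swap_and_flip")
  # swap means the stats effect allele is the target's allele2
  x[swap, ] <- 2L - x[swap, , drop = FALSE]

  miss <- is.na(x)
  mean_dos <- rowMeans(x, na.rm = TRUE)
  mean_dos[is.nan(mean_dos)] <- 1             # all-missing variant: HWE mean
  xf <- x
  xf[miss] <- 0
  score <- drop(crossprod(xf, beta)) + drop(crossprod(miss, beta * mean_dos))
  n_imp <- colSums(miss)
  sd_s <- stats::sd(score)
  score_std <- if (standardize && sd_s > 0) (score - mean(score)) / sd_s
               else rep(NA_real_, length(score))
  structure(data.frame(id = sample_ids(target), score = score,
                       score_std = score_std,
                       n_snps_scored = nrow(kept),
                       n_missing_imputed = n_imp,
                       stringsAsFactors = FALSE),
            class = c("profile_score", "data.frame"))
}
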