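# Genotype and sample quality control.
#
# Thresholds follow the usual case-control GWAS conventions: every filter is
# applied with the strict/inclusive direction of its published wording
# ("call rate < 0.95 excluded" keeps a variant at exactly 0.95).

#' Quality-control thresholds
#'
#' Container for the QC cut-offs applied by \code{\link{filter_variants}} and
#' friends. Defaults are the standard values for combined case-control and
#' biobank panels: variant call rate 0.95, MAF 0.01, Hardy-Weinberg exact
#' p-value 1e-6 in controls and 1e-10 in cases (1e-7 for a single-stratum
#' quantitative cohort), sample call rate 0.98, pairwise genomic relatedness
#' 0.05, and ancestry outliers beyond 6 reference SDs on PC1/PC2.
#'
#' @param variant_call_rate_min,maf_min,hwe_p_min_controls,hwe_p_min_cases,hwe_p_min,sample_call_rate_min,relatedness_max,ancestry_sd_limit
#'   Numeric cut-offs; see Description.
#' @return A list of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(variant_call_rate_min = 0.95,
                          maf_min = 0.01,
                          hwe_p_min_controls = 1e-6,
                          hwe_p_min_cases = 1e-10,
                          hwe_p_min = 1e-7,
                          sample_call_rate_min = 0.98,
                          relatedness_max = 0.05,
                          ancestry_sd_limit = 6) {
  stopifnot(variant_call_rate_min >= 0, variant_call_rate_min <= 1,
            maf_min >= 0, maf_min <= 0.5,
            hwe_p_min_controls > 0, hwe_p_min_cases > 0, hwe_p_min > 0,
            sample_call_rate_min >= 0, sample_call_rate_min <= 1,
            relatedness_max > 0, ancestry_sd_limit > 0)
  structure(as.list(environment()), class = "qc_thresholds")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on observed genotype counts, conditioning on the
#' allele counts: the p-value is the total probability of all heterozygote
#' configurations no more probable than the observed one. Computed by the
#' stable ratio recurrence over heterozygote counts; symmetric under allele
#' relabelling. A monomorphic variant admits only one configuration and
#' returns 1 by convention.
#'
#' @param n_hom1 Count of allele1 homozygotes.
#' @param n_het Count of heterozygotes.
#' @param n_hom2 Count of allele2 homozygotes.
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) stop("no genotyped individuals")
  rare <- 2 * min(n_hom1, n_hom2) + n_het    # rare allele count
  if (rare == 0) return(1)                   # monomorphic
  probs <- .hwe_het_distribution(n, rare)
  obs <- probs[(n_het - rare %% 2) / 2 + 1]
  # relative tolerance guards ties against round-off
  sum(probs[probs <= obs * (1 + 1e-10)])
}

# Distribution of heterozygote counts given n diploids and `rare` copies of
# the rarer allele, under random union of gametes. Element i holds the
# probability of het count (rare %% 2) + 2*(i-1).
.hwe_het_distribution <- function(n, rare) {
  h0 <- rare %% 2
  het_max <- min(rare, 2 * n - rare)
  k <- (het_max - h0) / 2 + 1
  # start at the modal het count and fill outwards by the probability ratio
  mid <- round(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2 != h0) mid <- mid + 1
  mid <- min(max(mid, h0), het_max)
  probs <- numeric(k)
  at <- function(h) (h - h0) / 2 + 1
  probs[at(mid)] <- 1
  h <- mid
  while (h - 2 >= h0) {                      # downward recurrence
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    probs[at(h - 2)] <-
      probs[at(h)] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
    h <- h - 2
  }
  h <- mid
  while (h + 2 <= het_max) {                 # upward recurrence
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    probs[at(h + 2)] <-
      probs[at(h)] * 4 * hom_r * hom_c / ((h + 1) * (h + 2))
    h <- h + 2
  }
  probs / sum(probs)
}

.qc_report <- function(steps, dimension) {
  structure(list(steps = steps, dimension = dimension), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (", x$dimension, "):\n", sep = "")
  for (i in seq_len(nrow(x$steps)))
    cat(sprintf("  %-12s removed %6d, kept %6d\n", x$steps$step[i],
                x$steps$removed[i], x$steps$kept[i]))
  invisible(x)
}

.variant_genotype_counts <- function(calls) {
  cbind(hom1 = rowSums(calls == 2L, na.rm = TRUE),
        het  = rowSums(calls == 1L, na.rm = TRUE),
        hom2 = rowSums(calls == 0L, na.rm = TRUE))
}

#' Variant-level QC filters
#'
#' Applies, in order: variant call rate, minor allele frequency, and the
#' exact Hardy-Weinberg test. With case-control labels the HWE test is run
#' separately in controls (threshold \code{hwe_p_min_controls}) and cases
#' (\code{hwe_p_min_cases}); without labels a single-stratum test at
#' \code{hwe_p_min} is used. Each criterion recomputes its statistic on the
#' variants surviving the previous one, and all cut-offs are strict
#' (a variant exactly at a threshold is kept).
#'
#' @param d A \code{genotype_dataset}.
#' @param thresholds A \code{\link{qc_thresholds}} object.
#' @param case_status Optional per-sample vector (0 control / 1 case,
#'   order matching the dataset's samples).
#' @return list with elements \code{dataset} (filtered) and \code{report}
#'   (a \code{qc_report} itemising removals per criterion).
#' @export
filter_variants <- function(d, thresholds = qc_thresholds(),
                            case_status = NULL) {
  stopifnot(inherits(d, "genotype_dataset"))
  if (nrow(d$variants) == 0) stop("empty dataset")
  if (!is.null(case_status) && length(case_status) != ncol(d$calls))
    stop("case_status length must match sample count")
  keep <- rep(TRUE, nrow(d$variants))
  steps <- data.frame(step = character(), removed = integer(),
                      kept = integer(), stringsAsFactors = FALSE)
  add_step <- function(name, drop_now) {
    steps <<- rbind(steps, data.frame(step = name, removed = sum(drop_now),
                                      kept = sum(keep) - sum(drop_now)))
    keep[which(keep)[drop_now]] <<- FALSE
  }

  cr <- rowMeans(!is.na(d$calls[keep, , drop = FALSE]))
  add_step("call_rate", cr < thresholds$variant_call_rate_min)

  f <- rowMeans(d$calls[keep, , drop = FALSE], na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0                      # all-missing variant
  add_step("maf", maf < thresholds$maf_min)

  hwe_fail <- if (is.null(case_status)) {
    p <- .hwe_pvalues(d$calls[keep, , drop = FALSE])
    p < thresholds$hwe_p_min
  } else {
    ctl <- .hwe_pvalues(d$calls[keep, case_status == 0, drop = FALSE])
    cas <- .hwe_pvalues(d$calls[keep, case_status == 1, drop = FALSE])
    ctl < thresholds$hwe_p_min_controls | cas < thresholds$hwe_p_min_cases
  }
  add_step("hwe", hwe_fail)

  if (sum(keep) == 0)
    message("no variants survived QC")
  list(dataset = subset_genotypes(d, variants = keep),
       report = .qc_report(steps, "variants"))
}

.hwe_pvalues <- function(calls) {
  if (ncol(calls) == 0) return(rep(1, nrow(calls)))
  cnt <- .variant_genotype_counts(calls)
  vapply(seq_len(nrow(cnt)), function(i) {
    if (sum(cnt[i, ]) == 0) return(1)
    hwe_exact_test(cnt[i, 1], cnt[i, 2], cnt[i, 3])
  }, numeric(1))
}

#' Filter variants on a supplied per-variant quality score
#'
#' Pass-through filter for quality metrics produced upstream (imputation
#' INFO or r-squared, posterior-probability call quality): the package does
#' not re-implement imputation, it only applies the published cut-off to a
#' supplied column. Variants with missing quality are kept (logged).
#'
#' @param d A \code{genotype_dataset}.
#' @param quality Numeric vector, one value per variant.
#' @param min_quality Keep variants with \code{quality >= min_quality}.
#' @param label Filter name recorded in the report (default
#'   \code{"quality"}).
#' @return list with \code{dataset} and \code{report}, as
#'   \code{\link{filter_variants}}.
#' @export
filter_variants_by_quality <- function(d, quality, min_quality,
                                       label = "quality") {
  stopifnot(inherits(d, "genotype_dataset"),
            length(quality) == nrow(d$variants))
  keep <- is.na(quality) | quality >= min_quality
  if (anyNA(quality))
    message(sum(is.na(quality)), " variant(s) without a quality value kept")
  steps <- data.frame(step = label, removed = sum(!keep),
                      kept = sum(keep), stringsAsFactors = FALSE)
  list(dataset = subset_genotypes(d, variants = keep),
       report = .qc_report(steps, "variants"))
}

#' Sample call-rate filter
#'
#' Removes samples whose fraction of non-missing genotypes is below
#' \code{min_rate} (strict inequality; a sample exactly at the threshold is
#' kept).
#'
#' @param d A \code{genotype_dataset}.
#' @param min_rate Minimum fraction of called genotypes.
#' @return list with \code{dataset} and \code{report}, as
#'   \code{\link{filter_variants}}.
#' @export
filter_samples_by_call_rate <- function(d, min_rate = 0.98) {
  stopifnot(inherits(d, "genotype_dataset"))
  cr <- colMeans(!is.na(d$calls))
  keep <- cr >= min_rate
  steps <- data.frame(step = "sample_call_rate", removed = sum(!keep),
                      kept = sum(keep), stringsAsFactors = FALSE)
  list(dataset = subset_genotypes(d, samples = keep),
       report = .qc_report(steps, "samples"))
}

#' Ancestry outlier filter on principal components
#'
#' Keeps samples whose first two PC scores lie within \code{limit} reference
#' standard deviations of the reference mean (inclusive boundary).
#'
#' @param pcs Sample-by-k score matrix (k >= 2); rownames are sample ids.
#' @param reference_mean,reference_sd Length-k (or length-2) reference
#'   moments, e.g. from a European-ancestry reference panel.
#' @param limit Number of SDs allowed (default 6).
#' @return Character vector of kept sample ids (or kept indices when the
#'   matrix has no rownames).
#' @export
ancestry_filter <- function(pcs, reference_mean, reference_sd, limit = 6) {
  pcs <- as.matrix(pcs)
  stopifnot(ncol(pcs) >= 2, limit > 0)
  if (any(reference_sd[1:2] <= 0)) stop("reference sd must be positive")
  ok <- abs(pcs[, 1] - reference_mean[1]) <= limit * reference_sd[1] &
        abs(pcs[, 2] - reference_mean[2]) <= limit * reference_sd[2]
  if (!is.null(rownames(pcs))) rownames(pcs)[ok] else which(ok)
}

#' Prune related individuals within a cohort
#'
#' Greedy pruning of the relatedness graph: while any pair exceeds the
#' threshold, the individual with the most above-threshold partners is
#' removed, ties broken by a seeded uniform draw (one of a related pair is
#' removed at random, as in standard pipelines). The survivor set is
#' verified post hoc to contain no pair above the threshold.
#'
#' @param grm A \code{\link{compute_grm}} result (or bare symmetric matrix
#'   with dimnames).
#' @param threshold Maximum allowed off-diagonal relatedness (default 0.05).
#' @param seed Integer seed for tie-breaking.
#' @return Character vector of kept sample ids.
#' @export
prune_related <- function(grm, threshold = 0.05, seed = 1L) {
  A <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  ids <- if (inherits(grm, "grm")) grm$sample_ids else rownames(A)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(A)))
  adj <- A > threshold
  diag(adj) <- FALSE
  alive <- rep(TRUE, nrow(A))
  rng <- .seeded_rng(seed)
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    if (max(deg) == 0) break
    worst <- which(deg == max(deg))
    drop <- if (length(worst) == 1) worst else worst[
      floor(rng() * length(worst)) + 1]
    alive[drop] <- FALSE
    adj[drop, ] <- FALSE
    adj[, drop] <- FALSE
  }
  kept <- ids[alive]
  off <- A[alive, alive, drop = FALSE]
  diag(off) <- -Inf
  stopifnot(all(off <= threshold))           # post-hoc guarantee
  kept
}

# small deterministic uniform generator so pruning does not perturb the
# global .Random.seed
.seeded_rng <- function(seed) {
  state <- as.double(seed %% 2147483647)
  if (state <= 0) state <- 1
  function() {
    state <<- (state * 16807) %% 2147483647
    state / 2147483647
  }
}

#' Prune one cohort against another by cross-cohort relatedness
#'
#' Removes every cohort-B sample whose genomic relationship with any
#' cohort-A sample exceeds the threshold; cohort A is untouched (it is the
#' reference set whose composition is fixed).
#'
#' @param grm_cross Cross-block of the joint GRM: rows cohort A, columns
#'   cohort B (colnames are B sample ids).
#' @param threshold Maximum allowed cross relatedness (default 0.05).
#' @return Character vector of kept cohort-B ids (or indices without
#'   colnames).
#' @export
cross_cohort_prune <- function(grm_cross, threshold = 0.05) {
  M <- as.matrix(grm_cross)
  worst <- if (nrow(M) > 0) apply(M, 2, max) else rep(-Inf, ncol(M))
  ok <- worst <= threshold
  if (!is.null(colnames(M))) colnames(M)[ok] else which(ok)
}
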