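# Synthetic cohorts with the statistical structure the analyses assume:
# a liability-threshold case-control trait ascertained to fixed quotas, and
# a quantitative age-at-first-birth (AFB) trait whose younger and older
# strata have distinct genetic architectures, inducing a between-stratum
# genetic correlation below one.

#' Simulation configuration
#'
#' Defaults encode the emulated study design: a case-control cohort of
#' 1,500 cases and 1,500 controls ascertained from a 1%-prevalence
#' liability-threshold disease with SNP-heritability 0.3 of liability, and
#' an independent cohort of 5,000 women with AFB mean 26 whose younger
#' (< 26) and older (>= 26) strata have heritabilities 0.10 and 0.03 and a
#' between-stratum genetic correlation of 0.47; the disease trait
#' correlates -0.16 with the younger-AFB architecture and +0.14 with the
#' older one. Genotypes are 5,000 SNPs in LD blocks of 20 with
#' autoregressive haplotype correlation 0.7.
#'
#' @param n_case,n_control,n_target Sample sizes (target = AFB cohort).
#' @param m,m_causal Variant counts (total and causal).
#' @param maf_range Allele-frequency interval for simulated variants.
#' @param prevalence Disease prevalence K.
#' @param h2_liability Liability-scale SNP-heritability of the disease.
#' @param h2_afb_younger,h2_afb_older Within-stratum AFB heritabilities.
#' @param rg_liability_younger,rg_liability_older,rg_younger_older Pairwise
#'   genetic correlations among the three architectures; the implied 3x3
#'   correlation matrix must be positive semi-definite.
#' @param afb_mean,afb_sd Marginal AFB moments (years).
#' @param cutpoint Stratum boundary in years.
#' @param younger_fraction Expected fraction of women below the cutpoint.
#' @param stratum_means,stratum_sds Length-2 (younger, older) within-stratum
#'   AFB moments.
#' @param truncation Optional length-2 interval; AFB outside it is discarded.
#' @param relatedness_pairs Cross-cohort first-degree pairs to inject.
#' @param ld_block_size,ld_rho LD block length and within-block AR
#'   correlation of haplotypes.
#' @param seed Integer seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_case = 1500, n_control = 1500, n_target = 5000,
                       m = 5000, m_causal = 2000,
                       maf_range = c(0.05, 0.5),
                       prevalence = 0.01, h2_liability = 0.3,
                       h2_afb_younger = 0.10, h2_afb_older = 0.03,
                       rg_liability_younger = -0.16,
                       rg_liability_older = 0.14,
                       rg_younger_older = 0.47,
                       afb_mean = 26, afb_sd = 4.5, cutpoint = 26,
                       younger_fraction = 0.55,
                       stratum_means = c(22.5, 29.5),
                       stratum_sds = c(2.3, 2.8),
                       truncation = NULL, relatedness_pairs = 0,
                       ld_block_size = 20, ld_rho = 0.7, seed = 1L) {
  cfg <- as.list(environment())
  R <- matrix(c(1, rg_liability_younger, rg_liability_older,
                rg_liability_younger, 1, rg_younger_older,
                rg_liability_older, rg_younger_older, 1), 3, 3)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("implied genetic correlation matrix is not positive semi-definite")
  stopifnot(all(c(h2_liability, h2_afb_younger, h2_afb_older) >= 0),
            all(c(h2_liability, h2_afb_younger, h2_afb_older) <= 1),
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            prevalence > 0, prevalence < 1,
            m_causal >= 1, m_causal <= m)
  cfg$rg_matrix <- R
  structure(cfg, class = "sim_config")
}

# non-ambiguous allele pairs so simulated panels merge without strand drops
.allele_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                          "G", "A", "C", "A", "G", "T", "C", "T"),
                        ncol = 2, byrow = TRUE)

#' Simulate genotypes with block LD
#'
#' Draws 2n haplotypes per variant from a latent Gaussian that is AR(rho)
#' within LD blocks and independent across blocks, thresholded at each
#' variant's allele frequency; dosage is the sum of the two haplotypes.
#' Variants are placed 1 kb apart on one chromosome.
#'
#' @param n,m Sample and variant counts.
#' @param maf_range Frequencies drawn uniformly from this interval.
#' @param ld_block_size Variants per LD block (1 = independent variants).
#' @param ld_rho AR(1) correlation of the latent haplotype process; a
#'   vector is recycled over blocks, giving the panel heterogeneous LD
#'   (useful for LD-score work, where variation in LD scores identifies
#'   the regression intercept).
#' @param seed Integer seed (bit-reproducible output).
#' @param freqs Optional fixed allele-frequency vector (overrides
#'   \code{maf_range}); used to redraw individuals on an existing panel.
#' @param variants Optional variant table to reuse (ids/positions/alleles).
#' @param id_prefix Prefix for generated sample ids.
#' @param cohort Cohort label for the sample table.
#' @return A \code{genotype_dataset} with attribute \code{freqs} (the true
#'   allele-1 frequencies).
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5),
                               ld_block_size = 20, ld_rho = 0.7,
                               seed = 1L, freqs = NULL, variants = NULL,
                               id_prefix = "S", cohort = "sim") {
  stopifnot(m >= 1, n >= 1)
  if (!is.null(maf_range) && (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
                              maf_range[1] > maf_range[2]))
    stop("invalid maf_range")
  rs <- .new_rng(seed)
  p <- if (is.null(freqs)) rs$runif(m, maf_range[1], maf_range[2]) else freqs
  stopifnot(length(p) == m)
  thr <- stats::qnorm(p)

  calls <- matrix(0L, nrow = m, ncol = n)
  blocks <- split(seq_len(m), ceiling(seq_len(m) / ld_block_size))
  # ld_rho may be a vector (recycled over blocks) to give the panel
  # heterogeneous LD, e.g. for LD-score work where near-constant LD scores
  # would make the regression intercept unidentifiable
  rho_blk <- rep_len(ld_rho, length(blocks))
  for (hap in 1:2) {
    for (bi in seq_along(blocks)) {
      blkv <- blocks[[bi]]
      a <- rho_blk[bi]
      b <- sqrt(1 - a^2)
      E <- matrix(rs$rnorm(n * length(blkv)), nrow = n)
      Z <- E
      if (length(blkv) > 1 && a > 0)
        for (j in 2:length(blkv)) Z[, j] <- a * Z[, j - 1] + b * E[, j]
      H <- t(Z) < thr[blkv]                 # m_blk x n, TRUE = allele1
      calls[blkv, ] <- calls[blkv, ] + H
    }
  }

  if (is.null(variants)) {
    ap <- .allele_pairs[rs$sample_int(nrow(.allele_pairs), m), , drop = FALSE]
    variants <- data.frame(id = paste0("rs", seq_len(m)), chrom = "1",
                           pos = seq_len(m) * 1000L, allele1 = ap[, 1],
                           allele2 = ap[, 2], stringsAsFactors = FALSE)
  }
  samples <- data.frame(fid = cohort, iid = paste0(id_prefix, seq_len(n)),
                        sex = 2L, cohort = cohort, stringsAsFactors = FALSE)
  d <- genotype_dataset(variants, samples, calls)
  attr(d, "freqs") <- p
  d
}

# private RNG stream so simulations never disturb the global seed
.new_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, globalenv())
  with_state <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    out
  }
  list(runif = with_state(stats::runif),
       rnorm = with_state(stats::rnorm),
       sample_int = with_state(function(n, size, ...)
         sample.int(n, size, replace = size > n, ...)))
}

#' Draw correlated causal effect vectors for the three architectures
#'
#' Per causal variant, effects for (liability, younger-AFB, older-AFB) are
#' drawn from a trivariate normal whose correlation matrix carries the
#' target genetic correlations and whose per-trait variance is
#' \code{h2_t / m_causal} (on the standardised-genotype scale), so the
#' expected genetic variance of each standardised trait equals its target
#' heritability.
#'
#' @param config A \code{\link{sim_config}}.
#' @return list of class \code{sim_effects}: \code{causal_idx} (variant
#'   indices), \code{beta} (m_causal x 3 matrix, columns liability /
#'   younger / older).
#' @export
simulate_effects <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rs <- .new_rng(config$seed + 1000003L)
  mc <- config$m_causal
  causal_idx <- sort(rs$sample_int(config$m, mc))
  h2 <- c(config$h2_liability, config$h2_afb_younger, config$h2_afb_older)
  S <- diag(sqrt(h2 / mc)) %*% config$rg_matrix %*% diag(sqrt(h2 / mc))
  ch <- chol(S + diag(1e-14, 3))
  Z <- matrix(rs$rnorm(mc * 3), ncol = 3)
  beta <- Z %*% ch
  colnames(beta) <- c("liability", "younger", "older")
  structure(list(causal_idx = causal_idx, beta = beta, h2 = h2,
                 config = config),
            class = "sim_effects")
}

# genetic values on the standardised-genotype scale, using true frequencies
.genetic_values <- function(d, effects) {
  p <- attr(d, "freqs")
  ci <- effects$causal_idx
  x <- d$calls[ci, , drop = FALSE]
  w <- (x - 2 * p[ci]) / sqrt(2 * p[ci] * (1 - p[ci]))
  t(crossprod(w, effects$beta))              # 3 x n
}

#' Simulate an ascertained case-control cohort
#'
#' Liability = genetic value + normal residual scaled so the liability
#' variance is 1; an individual is a case when liability exceeds
#' \eqn{\Phi^{-1}(1-K)}. The population is sampled in batches until the
#' case and control quotas are filled, reproducing case oversampling
#' relative to the prevalence.
#'
#' @param effects A \code{\link{simulate_effects}} result.
#' @param config The same \code{sim_config}.
#' @return list: \code{genotypes} (ascertained cohort), \code{phenotypes}
#'   (data.frame id, status), \code{truth} (per-sample true liability
#'   genetic values and the causal effects used).
#' @export
simulate_case_control <- function(effects, config = effects$config) {
  rs <- .new_rng(config$seed + 2000003L)
  K <- config$prevalence
  thr <- stats::qnorm(1 - K)
  h2 <- config$h2_liability
  need_case <- config$n_case
  need_ctl <- config$n_control
  batch <- max(2000L, ceiling(need_case / K / 10))
  max_draws <- ceiling(5 * (need_case / K + need_ctl))
  drawn <- 0L
  acc <- list()
  freqs <- NULL
  batch_no <- 0L
  while ((need_case > 0 || need_ctl > 0) && drawn < max_draws) {
    batch_no <- batch_no + 1L
    d <- simulate_genotypes(batch, config$m, config$maf_range,
                            config$ld_block_size, config$ld_rho,
                            seed = config$seed + 37L * batch_no,
                            freqs = freqs,
                            id_prefix = paste0("B", batch_no, "_"),
                            cohort = "cc")
    if (is.null(freqs)) freqs <- attr(d, "freqs")
    g <- .genetic_values(d, effects)[1, ]
    lia <- g + rs$rnorm(batch) * sqrt(max(1 - h2, 0))
    is_case <- lia > thr
    take_case <- which(is_case)[seq_len(min(need_case, sum(is_case)))]
    take_ctl <- which(!is_case)[seq_len(min(need_ctl, sum(!is_case)))]
    take <- sort(c(take_case, take_ctl))
    if (length(take)) {
      keep <- subset_genotypes(d, samples = take)
      attr(keep, "freqs") <- freqs
      acc[[length(acc) + 1L]] <- list(d = keep, status = is_case[take],
                                      g = g[take])
    }
    need_case <- need_case - length(take_case)
    need_ctl <- need_ctl - length(take_ctl)
    drawn <- drawn + batch
  }
  if (need_case > 0 || need_ctl > 0)
    stop("case/control quota unreachable within draw budget")
  calls <- do.call(cbind, lapply(acc, function(a) a$d$calls))
  samples <- do.call(rbind, lapply(acc, function(a) a$d$samples))
  d <- genotype_dataset(acc[[1]]$d$variants, samples, calls)
  attr(d, "freqs") <- freqs
  status <- unlist(lapply(acc, `[[`, "status"))
  g <- unlist(lapply(acc, `[[`, "g"))
  # fix the output ratio exactly: reorder cases first then controls
  ord <- order(!status)
  d <- subset_genotypes(d, samples = ord)
  attr(d, "freqs") <- freqs
  status <- status[ord]; g <- g[ord]
  list(genotypes = d,
       phenotypes = data.frame(sample_id = sample_ids(d),
                               status = as.integer(status),
                               stringsAsFactors = FALSE),
       truth = list(g_liability = g, effects = effects,
                    prevalence = K, threshold = thr))
}

#' Simulate the AFB cohort with stratum-heterogeneous architecture
#'
#' Two-stage generative model: (i) a latent, almost entirely non-genetic
#' propensity assigns each woman to the younger or older stratum (so
#' architecture differences, not selection, drive the between-stratum
#' correlation); (ii) within her stratum, AFB = stratum mean +
#' sd * (sqrt(h2) * standardised stratum genetic value + sqrt(1-h2) *
#' residual). An optional truncation interval discards women with AFB
#' outside it.
#'
#' @param genotypes A \code{genotype_dataset} for the cohort (from
#'   \code{\link{simulate_genotypes}}, carrying true frequencies).
#' @param effects A \code{\link{simulate_effects}} result.
#' @param config The \code{sim_config}.
#' @return list: \code{phenotypes} (data.frame sample_id, afb, stratum),
#'   \code{truth} (true genetic values per architecture), \code{kept}
#'   (ids surviving truncation).
#' @export
simulate_afb_cohort <- function(genotypes, effects,
                                config = effects$config) {
  rs <- .new_rng(config$seed + 3000017L)
  n <- ncol(genotypes$calls)
  G <- .genetic_values(genotypes, effects)   # 3 x n
  gy <- G[2, ]; go <- G[3, ]
  # weakly genetic propensity: 1% of its variance from the mean architecture
  gsum <- gy + go
  gstd <- if (stats::sd(gsum) > 0) (gsum - mean(gsum)) / stats::sd(gsum)
          else numeric(n)
  prop <- sqrt(0.01) * gstd + sqrt(0.99) * rs$rnorm(n)
  younger <- prop < stats::qnorm(config$younger_fraction)
  if (!any(younger) || all(younger)) stop("empty AFB stratum")

  h2y <- config$h2_afb_younger; h2o <- config$h2_afb_older
  afb <- numeric(n)
  sdy <- max(stats::sd(gy), 1e-12); sdo <- max(stats::sd(go), 1e-12)
  gen_part <- numeric(n)
  gen_part[younger] <- sqrt(h2y) * gy[younger] / sdy
  gen_part[!younger] <- sqrt(h2o) * go[!younger] / sdo
  res_sd <- ifelse(younger, sqrt(1 - h2y), sqrt(1 - h2o))
  mu <- ifelse(younger, config$stratum_means[1], config$stratum_means[2])
  s <- ifelse(younger, config$stratum_sds[1], config$stratum_sds[2])
  afb <- mu + s * (gen_part + res_sd * rs$rnorm(n))
  # each woman's AFB must fall on her assigned side of the cutpoint, so the
  # observable strata carry exactly the configured architectures; residuals
  # of boundary-crossers are redrawn (a mild truncation of the residual)
  for (try in 1:40) {
    cross <- (younger & afb >= config$cutpoint) |
             (!younger & afb < config$cutpoint)
    if (!any(cross)) break
    afb[cross] <- mu[cross] +
      s[cross] * (gen_part[cross] + res_sd[cross] * rs$rnorm(sum(cross)))
  }
  eps <- 1e-3
  afb[younger & afb >= config$cutpoint] <- config$cutpoint - eps
  afb[!younger & afb < config$cutpoint] <- config$cutpoint + eps
  afb <- pmax(afb, 12)                       # biological floor

  kept <- rep(TRUE, n)
  if (!is.null(config$truncation))
    kept <- afb >= config$truncation[1] & afb <= config$truncation[2]
  ids <- sample_ids(genotypes)
  list(
    phenotypes = data.frame(
      sample_id = ids[kept], afb = afb[kept],
      stratum = ifelse(younger[kept], "younger", "older"),
      stringsAsFactors = FALSE),
    truth = list(g_younger = gy, g_older = go, g_liability = G[1, ],
                 assigned_younger = younger),
    kept = ids[kept]
  )
}

#' Inject first-degree relative pairs across two cohorts
#'
#' Overwrites the genotypes of \code{n_pairs} samples of cohort \code{b}
#' with simulated offspring of paired samples in cohort \code{a}: one
#' gamete sampled from the parent's genotype (heterozygous sites transmit
#' either allele with probability 1/2) plus one population haplotype drawn
#' at the panel frequencies. Expected cross-cohort genomic relationship of
#' a pair is 0.5.
#'
#' @param a,b \code{genotype_dataset}s on the same variant panel.
#' @param n_pairs Number of pairs (first samples of each cohort are used).
#' @param seed Integer seed.
#' @return list with modified \code{b} and \code{pairs} (data.frame of
#'   parent/offspring ids).
#' @export
inject_relatedness <- function(a, b, n_pairs, seed = 1L) {
  stopifnot(n_pairs <= min(ncol(a$calls), ncol(b$calls)))
  if (n_pairs == 0)
    return(list(b = b, pairs = data.frame(parent = character(),
                                          offspring = character())))
  rs <- .new_rng(seed)
  p <- attr(b, "freqs")
  if (is.null(p)) p <- allele_freq(b)
  m <- nrow(b$calls)
  for (k in seq_len(n_pairs)) {
    parent <- a$calls[, k]
    u <- rs$runif(m)
    transmitted <- ifelse(parent == 2L, 1L,
                          ifelse(parent == 1L, as.integer(u < 0.5), 0L))
    pop_hap <- as.integer(rs$runif(m) < p)
    b$calls[, k] <- transmitted + pop_hap
  }
  list(b = b,
       pairs = data.frame(parent = sample_ids(a)[seq_len(n_pairs)],
                          offspring = sample_ids(b)[seq_len(n_pairs)],
                          stringsAsFactors = FALSE))
}
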