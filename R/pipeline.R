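# md5 of the serialised configuration, via a temp file (tools::md5sum is
# file-based)
.hash_config <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "="), f)
  unname(tools::md5sum(f))
}

# End-to-end desk-scale replication pipeline:
# simulate -> QC -> merge -> GRM -> GREML -> GBLUP -> GWAS -> profile score
# -> U-shape regression -> LDSC. Every stage writes its artifact to disk and
# is logged in a JSON run manifest with checksums and wall times.

#' Run the full analysis pipeline on a simulated study
#'
#' Executes the seven analysis stages in fixed order on cohorts generated
#' from a \code{\link{sim_config}}, writing intermediate artifacts
#' (PLINK-1 trios, tab-separated tables, a GRM fileset) into \code{dir} and
#' returning the key results. Stage outputs are pure functions of the
#' configuration and its seed; re-running with the same configuration
#' reproduces them.
#'
#' @param config A \code{\link{sim_config}}.
#' @param dir Output directory (created if needed).
#' @param n_pcs Number of ancestry PCs used as covariates (default 10).
#' @param ld_window_kb LD score window (default 1000).
#' @param verbose Log stage progress to stderr.
#' @return list of class \code{pipeline_run}: per-stage results and the
#'   manifest (also serialised to \code{manifest.json}).
#' @export
run_pipeline <- function(config, dir = tempfile("pipeline"), n_pcs = 10,
                         ld_window_kb = 1000, verbose = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_flat <- unclass(config)[!vapply(config, is.matrix, logical(1))]
  manifest <- list(config = cfg_flat,
                   config_hash = .hash_config(cfg_flat),
                   seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("polygreml")),
                   stages = list())
  t_all <- proc.time()[3]
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- force(expr)
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[3] - t0, 2))
    say(name, " done (", round(proc.time()[3] - t0, 1), "s)")
    out
  }

  # -- simulate ---------------------------------------------------------
  sim <- stage("simulate", {
    eff <- simulate_effects(config)
    cc <- simulate_case_control(eff, config)
    tgt_geno <- simulate_genotypes(config$n_target, config$m,
                                   config$maf_range, config$ld_block_size,
                                   config$ld_rho,
                                   seed = config$seed + 5000011L,
                                   freqs = attr(cc$genotypes, "freqs"),
                                   variants = cc$genotypes$variants,
                                   id_prefix = "T", cohort = "afb")
    afb <- simulate_afb_cohort(tgt_geno, eff, config)
    if (config$relatedness_pairs > 0) {
      inj <- inject_relatedness(cc$genotypes, tgt_geno,
                                config$relatedness_pairs,
                                seed = config$seed + 7000003L)
      tgt_geno <- inj$b
    }
    write_plink(cc$genotypes, file.path(dir, "cc"))
    write_plink(tgt_geno, file.path(dir, "afb"))
    write_phenotype_table(cc$phenotypes, file.path(dir, "cc_pheno.tsv"))
    write_phenotype_table(afb$phenotypes, file.path(dir, "afb_pheno.tsv"))
    list(effects = eff, cc = cc, tgt_geno = tgt_geno, afb = afb)
  })

  # -- qc ---------------------------------------------------------------
  qc <- stage("qc", {
    thr <- qc_thresholds()
    cc_f <- filter_variants(sim$cc$genotypes, thr,
                            case_status = sim$cc$phenotypes$status)
    cc_s <- filter_samples_by_call_rate(cc_f$dataset,
                                        thr$sample_call_rate_min)
    tg_f <- filter_variants(sim$tgt_geno, thr)
    tg_s <- filter_samples_by_call_rate(tg_f$dataset, 0.95)
    merged <- merge_datasets(cc_s$dataset, tg_s$dataset)
    list(merged = merged,
         reports = list(cc_variants = cc_f$report, cc_samples = cc_s$report,
                        afb_variants = tg_f$report,
                        afb_samples = tg_s$report))
  })

  # -- grm --------------------------------------------------------------
  grm_res <- stage("grm", {
    g <- compute_grm(qc$merged)
    cc_ids <- sample_ids(qc$merged)[qc$merged$samples$cohort == "cc"]
    afb_ids <- setdiff(g$sample_ids, cc_ids)
    cross <- g$values[match(cc_ids, g$sample_ids),
                      match(afb_ids, g$sample_ids), drop = FALSE]
    colnames(cross) <- afb_ids
    # at desk-scale marker counts the GRM sampling noise can exceed the
    # published 0.05 cut-off; prune at the larger of the configured
    # threshold and 4.5 noise SDs so only genuine relatives are removed
    thr_cross <- max(qc_thresholds()$relatedness_max,
                     4.5 * stats::sd(as.vector(cross)))
    keep_b <- cross_cohort_prune(cross, thr_cross)
    keep <- c(cc_ids, keep_b)
    g <- subset_grm(g, keep)
    write_grm(g, file.path(dir, "merged"))
    pcs <- grm_pca(g, k = min(n_pcs, length(keep)))
    list(grm = g, pcs = pcs, cc_ids = cc_ids, afb_ids = keep_b)
  })
  g <- grm_res$grm

  # -- greml (trivariate) + gblup --------------------------------------
  greml_stage <- stage("greml", {
    pcs <- grm_res$pcs$scores
    cc_ids <- grm_res$cc_ids
    status <- sim$cc$phenotypes$status[match(cc_ids,
                                             sim$cc$phenotypes$sample_id)]
    ph <- sim$afb$phenotypes
    ph <- ph[ph$sample_id %in% grm_res$afb_ids, , drop = FALSE]
    stratum <- stratify_by_afb(ph$afb, config$cutpoint)
    mk_block <- function(trait, ids, y) {
      X <- cbind(1, pcs[match(ids, rownames(pcs)), seq_len(
        min(n_pcs, ncol(pcs))), drop = FALSE])
      phenotype_block(trait, ids, residualize(y, X))
    }
    blocks <- list(
      mk_block("scz", cc_ids, status),
      mk_block("afb_younger", ph$sample_id[stratum == "younger"],
               ph$afb[stratum == "younger"]),
      mk_block("afb_older", ph$sample_id[stratum == "older"],
               ph$afb[stratum == "older"])
    )
    fit <- fit_greml(g, blocks)
    s <- summary(fit)
    utils::write.table(cbind(component = rownames(s$components),
                             s$components),
                       file.path(dir, "variance_components.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # GBLUP scores for the quantitative cohort from the disease-only model
    fit1 <- fit_greml(g, blocks[[1]])
    pred <- predict(fit1, g, targets = grm_res$afb_ids)
    write_phenotype_table(
      data.frame(sample_id = pred$id, prs_gblup = pred$u),
      file.path(dir, "prs_gblup.tsv"))
    list(fit = fit, blup = pred)
  })
  greml_fit <- greml_stage$fit
  blup <- greml_stage$blup

  # -- gwas + profile score --------------------------------------------
  score <- stage("score", {
    cc_ids <- grm_res$cc_ids
    cc_geno <- subset_genotypes(qc$merged, samples = cc_ids)
    status <- sim$cc$phenotypes$status[match(cc_ids,
                                             sim$cc$phenotypes$sample_id)]
    pcs <- grm_res$pcs$scores
    X <- cbind(1, pcs[match(cc_ids, rownames(pcs)),
                      seq_len(min(n_pcs, ncol(pcs))), drop = FALSE])
    stats <- gwas_linear(cc_geno, residualize(status, X))
    write_sumstats(stats, file.path(dir, "scz_gwas.tsv"))
    tgt <- subset_genotypes(qc$merged, samples = grm_res$afb_ids)
    sc <- profile_score(tgt, stats)
    write_phenotype_table(
      data.frame(sample_id = sc$id, prs_score = sc$score_std),
      file.path(dir, "prs_score.tsv"))
    list(sumstats = stats, score = sc)
  })

  # -- ushape -----------------------------------------------------------
  ushape <- stage("ushape", {
    ph <- sim$afb$phenotypes
    ph <- ph[match(grm_res$afb_ids, ph$sample_id), , drop = FALSE]
    z <- response_transform(ph$afb)
    pcs <- grm_res$pcs$scores[match(ph$sample_id,
                                    rownames(grm_res$pcs$scores)),
                              seq_len(min(n_pcs, ncol(grm_res$pcs$scores))),
                              drop = FALSE]
    prs_g <- blup$u[match(ph$sample_id, blup$id)]
    prs_s <- score$score$score_std[match(ph$sample_id, score$score$id)]
    res <- list(
      gblup = regress_response_on_prs(z, prs_g, pcs),
      score = regress_response_on_prs(z, prs_s, pcs)
    )
    bins <- bin_prs_by_afb(scale(prs_g)[, 1], ph$afb)
    utils::write.table(bins, file.path(dir, "prs_by_afb_bin.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab <- data.frame(prs = names(res),
                      beta = vapply(res, `[[`, 0, "beta_prs"),
                      p = vapply(res, `[[`, 0, "p"),
                      r2_incremental = vapply(res, `[[`, 0, "r_squared"),
                      n = vapply(res, `[[`, 0L, "n"))
    utils::write.table(tab, file.path(dir, "ushape_regression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    c(res, list(bins = bins))
  })

  # -- ldsc -------------------------------------------------------------
  ldsc <- stage("ldsc", {
    lsc <- compute_ld_scores(qc$merged, window_kb = ld_window_kb)
    write_ld_scores(lsc, file.path(dir, "ldscores.tsv"))
    ph <- sim$afb$phenotypes
    ph <- ph[match(grm_res$afb_ids, ph$sample_id), , drop = FALSE]
    stratum <- stratify_by_afb(ph$afb, config$cutpoint)
    tgt <- subset_genotypes(qc$merged, samples = grm_res$afb_ids)
    pcs <- grm_res$pcs$scores[match(ph$sample_id,
                                    rownames(grm_res$pcs$scores)),
                              seq_len(min(n_pcs, ncol(grm_res$pcs$scores))),
                              drop = FALSE]
    fits <- lapply(c(younger = "younger", older = "older"), function(s) {
      sel <- stratum == s
      d_s <- subset_genotypes(tgt, samples = which(sel))
      y_adj <- residualize(ph$afb[sel], pcs[sel, , drop = FALSE])
      st <- gwas_linear(d_s, y_adj)
      ldsc_rg(score$sumstats, st, lsc, n1 = length(grm_res$cc_ids),
              n2 = sum(sel), intercept = "constrained")
    })
    tab <- data.frame(pair = paste0("scz:", names(fits)),
                      rg = vapply(fits, `[[`, 0, "rg"),
                      se = vapply(fits, `[[`, 0, "se"))
    utils::write.table(tab, file.path(dir, "ldsc_rg.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    fits
  })

  # -- manifest ---------------------------------------------------------
  files <- list.files(dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$files <- as.list(tools::md5sum(files))
  names(manifest$files) <- basename(files)
  manifest$total_seconds <- round(proc.time()[3] - t_all, 2)
  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(dir = dir, manifest = manifest, greml = greml_fit,
                 blup = blup, score = score, ushape = ushape, ldsc = ldsc,
                 qc = qc$reports),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline run:", x$manifest$n_stages, "stages in",
      x$manifest$total_seconds, "s ->", x$dir, "\n")
  s <- summary(x$greml)
  if (!is.null(s$rg)) { cat("GREML genetic correlations:\n"); print(s$rg) }
  cat(sprintf("U-shape regression on PRS-GBLUP: p = %.3g, R2 = %.3g\n",
              x$ushape$gblup$p, x$ushape$gblup$r_squared))
  invisible(x)
}
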