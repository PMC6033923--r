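# Synthetic-cohort generator: reproducibility, marginal structure, encoded
# genetic architecture, ascertainment and relatedness injection.

test_that("genotype simulation is bit-reproducible and respects marginals", {
  d1 <- simulate_genotypes(50, 100, seed = 7)
  d2 <- simulate_genotypes(50, 100, seed = 7)
  expect_identical(d1$calls, d2$calls)
  expect_identical(attr(d1, "freqs"), attr(d2, "freqs"))

  # fixed 0.5 frequency: mean dosage ~ 1
  d3 <- simulate_genotypes(600, 80, maf_range = c(0.5, 0.5), seed = 8)
  se <- stats::sd(rowMeans(d3$calls)) / sqrt(80)
  expect_lt(abs(mean(d3$calls) - 1), 3 * se)

  # block size 1: adjacent variants uncorrelated
  d4 <- simulate_genotypes(900, 60, ld_block_size = 1, seed = 9)
  r2 <- vapply(1:59, function(i)
    stats::cor(d4$calls[i, ], d4$calls[i + 1, ])^2, numeric(1))
  expect_lt(mean(r2), 3 / 900)              # null level ~ 1/n
  # with blocks, neighbours are correlated
  d5 <- simulate_genotypes(900, 60, ld_block_size = 20, ld_rho = 0.7,
                           seed = 9)
  r2b <- vapply(1:59, function(i)
    stats::cor(d5$calls[i, ], d5$calls[i + 1, ])^2, numeric(1))
  expect_gt(mean(r2b), 0.1)
  expect_error(simulate_genotypes(10, 5, maf_range = c(0, 0.6)), "maf_range")
})

test_that("effect simulation encodes the target correlation structure", {
  # perfect correlation: proportional effect vectors
  cfg1 <- sim_config(m = 300, m_causal = 300, rg_liability_younger = 1,
                     rg_liability_older = 1, rg_younger_older = 1, seed = 11)
  eff1 <- simulate_effects(cfg1)
  cors <- stats::cor(eff1$beta)
  expect_true(all(abs(cors - 1) < 1e-6))

  # zero correlation: empirical cross-trait correlations near 0
  cfg0 <- sim_config(m = 2000, m_causal = 2000, rg_liability_younger = 0,
                     rg_liability_older = 0, rg_younger_older = 0, seed = 12)
  eff0 <- simulate_effects(cfg0)
  c0 <- stats::cor(eff0$beta)[upper.tri(diag(3))]
  expect_true(all(abs(c0) < 3 / sqrt(2000)))

  # realised genetic variance matches the target heritability
  cfg <- sim_config(m = 500, m_causal = 500, h2_liability = 0.5, seed = 13)
  eff <- simulate_effects(cfg)
  d <- simulate_genotypes(800, 500, seed = 13)
  p <- attr(d, "freqs")
  w <- (d$calls - 2 * p) / sqrt(2 * p * (1 - p))
  gv <- drop(crossprod(w, eff$beta[, 1]))
  expect_lt(abs(stats::var(gv) - 0.5), 0.1)

  # an infeasible correlation matrix is rejected at construction
  expect_error(sim_config(rg_liability_younger = 0.9,
                          rg_liability_older = -0.9,
                          rg_younger_older = 0.9), "positive semi-definite")
})

test_that("case-control ascertainment fills quotas exactly and encodes a
           liability-threshold trait", {
  cfg <- sim_config(n_case = 120, n_control = 180, m = 150, m_causal = 150,
                    prevalence = 0.1, h2_liability = 0.5, seed = 21)
  eff <- simulate_effects(cfg)
  cc <- simulate_case_control(eff, cfg)
  expect_equal(sum(cc$phenotypes$status == 1), 120)
  expect_equal(sum(cc$phenotypes$status == 0), 180)
  expect_equal(ncol(cc$genotypes$calls), 300)
  # cases carry higher true genetic liability than controls
  expect_gt(mean(cc$truth$g_liability[cc$phenotypes$status == 1]),
            mean(cc$truth$g_liability[cc$phenotypes$status == 0]))
  # reproducible under the same config
  cc2 <- simulate_case_control(eff, cfg)
  expect_identical(cc2$genotypes$calls, cc$genotypes$calls)
})

test_that("a heritability-free disease yields calibrated association
           p-values", {
  cfg <- sim_config(n_case = 150, n_control = 150, m = 400, m_causal = 400,
                    prevalence = 0.5, h2_liability = 0, seed = 22)
  eff <- simulate_effects(cfg)
  eff$beta[] <- 0                            # no genetic effects at all
  cc <- simulate_case_control(eff, cfg)
  st <- gwas_linear(cc$genotypes, residualize(cc$phenotypes$status))
  ks <- suppressWarnings(stats::ks.test(st$p, "punif"))  # near-ties ok
  expect_gt(ks$p.value, 0.01)
})

test_that("AFB cohort: strata respect the cutpoint and encode stratum
           heritabilities", {
  cfg <- sim_config(n_target = 1200, m = 200, m_causal = 200,
                    h2_afb_younger = 0.4, h2_afb_older = 0.4, seed = 23)
  eff <- simulate_effects(cfg)
  d <- simulate_genotypes(1200, 200, seed = 24)
  afb <- simulate_afb_cohort(d, eff, cfg)
  ph <- afb$phenotypes
  expect_true(all(ph$afb[ph$stratum == "younger"] < 26))
  expect_true(all(ph$afb[ph$stratum == "older"] >= 26))
  expect_equal(nrow(ph), 1200)
  # younger fraction near the configured value
  expect_lt(abs(mean(ph$stratum == "younger") - 0.55), 0.05)
  # truncation switch restricts the returned sample
  cfg_t <- sim_config(n_target = 1200, m = 200, m_causal = 200,
                      truncation = c(26, Inf), seed = 23)
  afb_t <- simulate_afb_cohort(d, eff, cfg_t)
  expect_true(all(afb_t$phenotypes$afb >= 26))
  expect_lt(nrow(afb_t$phenotypes), 1200)
})

test_that("injected cross-cohort relatives show ~0.5 kinship and are broken
           by cross-cohort pruning", {
  a <- simulate_genotypes(40, 600, seed = 25, cohort = "a")
  b <- simulate_genotypes(40, 600, seed = 26, freqs = attr(a, "freqs"),
                          variants = a$variants, cohort = "b")
  inj <- inject_relatedness(a, b, n_pairs = 5, seed = 27)
  merged <- merge_datasets(a, inj$b)
  g <- compute_grm(merged)
  cross <- g$values[1:40, 41:80]
  injected <- diag(cross[1:5, 1:5])
  expect_lt(abs(mean(injected) - 0.5), 3 * stats::sd(injected) /
              sqrt(5) + 0.05)
  expect_true(all(abs(cross[6:40, 6:40]) < 0.4))
  colnames(cross) <- sample_ids(inj$b)
  kept <- cross_cohort_prune(cross, threshold = 0.05)
  expect_true(all(!sample_ids(inj$b)[1:5] %in% kept))
  # zero pairs leaves the dataset untouched
  inj0 <- inject_relatedness(a, b, 0)
  expect_identical(inj0$b$calls, b$calls)
})
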