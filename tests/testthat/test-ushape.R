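# Quadratic response transform and the PRS regression around it.

test_that("response transform evaluates the published polynomial exactly", {
  expect_equal(response_transform(0), 2.7214)          # printed intercept
  expect_equal(response_transform(26),
               2.7214 - 0.1105 * 26 + 0.0018 * 26^2)   # = 1.0652
  expect_equal(response_transform(26), 1.0652, tolerance = 1e-12)
  expect_error(response_transform(-1), ">= 0")
  # vertex: argmin over a fine grid matches the closed form 0.1105/0.0036
  grid <- seq(0, 60, by = 0.001)
  z <- response_transform(grid)
  expect_equal(grid[which.min(z)], 0.1105 / (2 * 0.0018), tolerance = 1e-3)
  # strictly decreasing before the vertex, increasing after (the U shape)
  expect_true(all(diff(z[grid < 30.69]) < 0))
  expect_true(all(diff(z[grid > 30.70]) > 0))
})

test_that("PRS regression matches a closed-form OLS oracle and reports
           incremental R-squared", {
  set.seed(91)
  n <- 300
  prs <- rnorm(n)
  covar <- cbind(age = rnorm(n), yob = rnorm(n))
  z <- 0.2 * prs + 0.5 * covar[, 1] + rnorm(n)
  res <- regress_response_on_prs(z, prs, covar, standardize_prs = FALSE)
  X1 <- cbind(1, covar, prs)
  bh <- solve(crossprod(X1), crossprod(X1, z))
  r1 <- z - X1 %*% bh
  df <- n - ncol(X1)
  se <- sqrt(sum(r1^2) / df * solve(crossprod(X1))[4, 4])
  expect_equal(res$beta_prs, bh[4], tolerance = 1e-9)
  expect_equal(res$se, se, tolerance = 1e-9)
  expect_equal(res$p, 2 * pt(-abs(bh[4] / se), df), tolerance = 1e-9)
  X0 <- cbind(1, covar)
  r0 <- z - X0 %*% solve(crossprod(X0), crossprod(X0, z))
  expect_equal(res$r_squared,
               (sum(r0^2) - sum(r1^2)) / sum((z - mean(z))^2),
               tolerance = 1e-9)

  # exact linear dependence without covariates: incremental R^2 = 1
  exact <- regress_response_on_prs(2 * prs + 1, prs)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
})

test_that("PRS regression p-values are uniform under a permutation null", {
  set.seed(92)
  n <- 250
  covar <- cbind(rnorm(n))
  z <- rnorm(n) + 0.3 * covar[, 1]
  prs <- rnorm(n)
  pvals <- vapply(1:200, function(i) {
    regress_response_on_prs(z, sample(prs), covar)$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("AFB stratification uses the inclusive older boundary", {
  g <- stratify_by_afb(c(25.99, 26, 26.01), cutpoint = 26)
  expect_equal(as.character(g), c("younger", "older", "older"))
  expect_warning(stratify_by_afb(c(30, 31), cutpoint = 26), "empty")
  # mean-recomputed cutpoint
  expect_equal(as.character(stratify_by_afb(c(20, 30, 25.2), "mean")),
               c("younger", "older", "older"))
})

test_that("PRS-by-AFB bins match a group-by oracle and handle degenerate
           bins", {
  set.seed(93)
  afb <- runif(200, 16, 42)
  prs <- rnorm(200)
  bins <- bin_prs_by_afb(prs, afb)
  expect_equal(bins$bin, c("<20", "20-<25", "25-<30", "30-<35", ">=35"))
  cuts <- cut(afb, c(0, 20, 25, 30, 35, Inf), right = FALSE)
  for (i in 1:5) {
    v <- prs[as.integer(cuts) == i]
    expect_equal(bins$n[i], length(v))
    expect_equal(bins$mean_prs[i], mean(v))
    expect_equal(bins$se[i], sd(v) / sqrt(length(v)))
  }
  # constant PRS: equal means, zero SE
  b2 <- bin_prs_by_afb(rep(1, 200), afb)
  expect_true(all(b2$mean_prs == 1))
  expect_true(all(b2$se == 0))
  # single-member bin reports missing SE
  b3 <- bin_prs_by_afb(c(0.5, 1, 2), c(18, 27, 28))
  expect_true(is.na(b3$se[b3$bin == "<20"]))
})

test_that("bin comparison equals the Welch formula oracle", {
  set.seed(94)
  a <- rnorm(40, 0, 1.3); b <- rnorm(25, 0.4, 0.7)
  expect_equal(compare_bins(a, b), oracle_welch(a, b), tolerance = 1e-10)
  expect_equal(compare_bins(a, a), 1)
  expect_lt(compare_bins(rnorm(1000), rnorm(1000, 1)), 1e-10)
  expect_error(compare_bins(1, b), "at least 2")
  expect_error(compare_bins(rep(1, 5), rep(2, 5)), "degenerate")
})

test_that("sensitivity adjustment behaves under orthogonal, collinear and
           missing extra covariates", {
  set.seed(95)
  n <- 400
  prs <- rnorm(n)
  z <- 0.3 * prs + rnorm(n)
  # extra covariates orthogonal to prs and z leave estimates unchanged
  extra <- data.frame(edu = rnorm(n), income = rnorm(n))
  base <- regress_response_on_prs(z, prs)
  adj <- sensitivity_adjust(z, prs, covariates = NULL, extra = extra)
  expect_equal(adj$beta_prs, base$beta_prs, tolerance = 0.05)
  # increasingly collinear extra covariate attenuates the PRS p-value
  ps <- vapply(c(0.9, 0.99, 0.999), function(r) {
    e2 <- data.frame(proxy = r * scale(prs)[, 1] +
                       sqrt(1 - r^2) * rnorm(n))
    sensitivity_adjust(z, prs, NULL, e2)$p
  }, numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_error(sensitivity_adjust(z, prs, NULL,
                                  data.frame(edu = rep(NA_real_, n))),
               "missing")
})

test_that("end-to-end pipeline detects strong pleiotropy and is calibrated
           under the global null", {
  run_chain <- function(seed, rg) {
    cfg <- sim_config(n_case = 300, n_control = 300, n_target = 900,
                      m = 150, m_causal = 150,
                      h2_afb_younger = 0.4, h2_afb_older = 0.4,
                      rg_liability_younger = -rg, rg_liability_older = rg,
                      rg_younger_older = 0.2, seed = seed)
    eff <- simulate_effects(cfg)
    cc <- simulate_case_control(eff, cfg)
    tg <- simulate_genotypes(cfg$n_target, cfg$m, cfg$maf_range,
                             cfg$ld_block_size, cfg$ld_rho,
                             seed = cfg$seed + 5000011L,
                             freqs = attr(cc$genotypes, "freqs"),
                             variants = cc$genotypes$variants,
                             id_prefix = "T", cohort = "afb")
    afb <- simulate_afb_cohort(tg, eff, cfg)
    merged <- merge_datasets(cc$genotypes, tg)
    grm <- compute_grm(merged)
    fit <- fit_greml(grm, phenotype_block("scz", cc$phenotypes$sample_id,
                                          cc$phenotypes$status),
                     tol = 1e-4)
    blup <- predict(fit, grm, targets = afb$phenotypes$sample_id)
    z <- response_transform(afb$phenotypes$afb)
    regress_response_on_prs(z, blup$u)$p
  }
  p_alt <- vapply(1:10, function(s) run_chain(6000 + s, 0.6), numeric(1))
  expect_gte(mean(p_alt < 0.05), 0.8)
  p_null <- vapply(1:10, function(s) run_chain(6100 + s, 0), numeric(1))
  expect_gte(mean(p_null > 0.05), 0.5)      # no systematic false signal
})
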