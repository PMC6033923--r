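# GREML core: residualisation, variance components, genetic correlations,
# Wald tests, liability transform.

test_that("residualize matches the normal-equations oracle", {
  set.seed(3)
  y <- rnorm(40)
  expect_equal(residualize(y), y - mean(y))
  X <- cbind(rnorm(40), rnorm(40))
  r <- residualize(y, X)
  Xi <- cbind(1, X)
  r_oracle <- y - Xi %*% solve(crossprod(Xi), crossprod(Xi, y))
  expect_equal(r, drop(r_oracle), tolerance = 1e-10)
  expect_lt(abs(mean(r)), 1e-12)
  # response inside the covariate span -> zero residuals
  y2 <- drop(Xi %*% c(1, 2, -1))
  expect_lt(max(abs(residualize(y2, X))), 1e-10)
  # collinear columns dropped with a warning
  expect_warning(residualize(y, cbind(X, X[, 1])), "collinear")
})

test_that("single-trait REML recovers simulated heritability and matches
           the restricted-likelihood grid oracle", {
  h2 <- 0.5
  d <- simulate_genotypes(600, 300, seed = 31)
  eff <- simulate_effects(sim_config(m = 300, m_causal = 300,
                                     h2_afb_younger = h2, seed = 31))
  g <- true_genetic_values(d, eff, "younger")
  set.seed(32)
  y <- sqrt(h2) * g + sqrt(1 - h2) * rnorm(600)
  grm <- compute_grm(d)
  fit <- fit_greml(grm, phenotype_block("t", sample_ids(d), y))
  est <- h2_estimates(fit)
  expect_lt(abs(est$h2 - h2), 2 * est$se)
  # gradient of the restricted likelihood is numerically zero at the optimum
  expect_lt(max(abs(fit$grad)), 1e-2)

  # small-n fit agrees with an exhaustive grid search (1e-3 resolution)
  d30 <- simulate_genotypes(30, 120, seed = 33)
  eff30 <- simulate_effects(sim_config(m = 120, m_causal = 120,
                                       h2_afb_younger = h2, seed = 33))
  set.seed(34)
  y30 <- true_genetic_values(d30, eff30, "younger") * 0.7 + rnorm(30)
  g30 <- compute_grm(d30)
  fit30 <- fit_greml(g30, phenotype_block("t", sample_ids(d30), y30))
  grid <- oracle_grid_reml(g30$values, y30)
  vp <- stats::var(y30)
  expect_lt(abs(coef(fit30)[1] - grid$vg), 2e-3 * vp)
  expect_lt(abs(coef(fit30)[2] - grid$ve), 2e-3 * vp)
  expect_lt(abs(fit30$logLik - grid$logLik), 1e-4)
})

test_that("null heritability is not declared significant too often", {
  # type-I error of the one-sided h2 Wald test at alpha = 0.05
  rej <- vapply(1:200, function(s) {
    d <- simulate_genotypes(150, 80, seed = 4000 + s)
    set.seed(9000 + s)
    y <- rnorm(150)
    fit <- fit_greml(compute_grm(d), phenotype_block("t", sample_ids(d), y),
                     tol = 1e-4)
    est <- h2_estimates(fit)
    (est$h2 / max(est$se, 1e-12)) > stats::qnorm(0.95)
  }, logical(1))
  expect_lt(mean(rej), 0.12)                # ~5% expected, allow 2x + noise
})

test_that("bivariate REML on disjoint cohorts recovers the genetic
           correlation and is invariant to phenotype rescaling", {
  cfg <- sim_config(m = 250, m_causal = 250, h2_afb_younger = 0.5,
                    h2_afb_older = 0.5, rg_liability_younger = 0,
                    rg_liability_older = 0, rg_younger_older = 0.5,
                    seed = 77)
  eff <- simulate_effects(cfg)
  d <- simulate_genotypes(900, 250, seed = 78)
  gy <- true_genetic_values(d, eff, "younger")
  go <- true_genetic_values(d, eff, "older")
  set.seed(79)
  idx1 <- 1:450; idx2 <- 451:900
  y1 <- sqrt(0.5) * gy[idx1] + sqrt(0.5) * rnorm(450)
  y2 <- sqrt(0.5) * go[idx2] + sqrt(0.5) * rnorm(450)
  ids <- sample_ids(d)
  grm <- compute_grm(d)
  fit <- fit_greml(grm, list(phenotype_block("a", ids[idx1], y1),
                             phenotype_block("b", ids[idx2], y2)))
  gc <- genetic_correlation(fit, "a", "b")
  expect_lt(abs(gc$rg - 0.5), 2.5 * gc$se)
  expect_gt(gc$se, 0)

  # rescaling one phenotype by a positive constant leaves rg unchanged
  fit2 <- fit_greml(grm, list(phenotype_block("a", ids[idx1], 3.7 * y1),
                              phenotype_block("b", ids[idx2], y2)))
  gc2 <- genetic_correlation(fit2, "a", "b")
  expect_equal(gc2$raw, gc$raw, tolerance = 1e-4)
})

test_that("genetic correlation edge cases behave per definition", {
  # construct a minimal fitted object by hand to isolate the algebra
  fit <- structure(list(
    theta = c(1, 1, 1, 0.5, 0.5), boundary = rep(FALSE, 5),
    ase = diag(1e-4, 5), traits = c("a", "b"),
    layout = polygreml:::.vc_layout(2)), class = "greml")
  names(fit$theta) <- polygreml:::.vc_names(fit$layout, fit$traits)
  fit$theta[3] <- 0
  expect_equal(genetic_correlation(fit, 1, 2)$rg, 0)
  fit$theta[3] <- 1
  expect_equal(genetic_correlation(fit, 1, 2)$rg, 1)
  fit$boundary[1] <- TRUE
  expect_error(genetic_correlation(fit, 1, 2), "undefined")
})

test_that("wald_test reproduces printed one-tail value and the normal CDF", {
  expect_equal(wald_test(0.5, 0.1, 0.5), 1)
  # printed worked example: estimate 0.14, SE 0.08, upper tail -> 0.04
  expect_equal(round(wald_test(0.14, 0.08, 0, tail = "upper"), 2), 0.04)
  # high-precision two-sided check for the heterogeneity test shape
  z <- (0.47 - 1) / 0.19
  expect_equal(wald_test(0.47, 0.19, 1), 2 * stats::pnorm(z),
               tolerance = 1e-12)
  expect_error(wald_test(1, 0), "positive")
})

test_that("observed-to-liability transform matches symbolic forms", {
  expect_equal(observed_to_liability_h2(0, 0.1, 0.3), 0)
  # K = P reduces to K(1-K)/phi(t)^2
  K <- 0.2; t <- qnorm(1 - K)
  expect_equal(observed_to_liability_h2(0.1, K, K),
               0.1 * K * (1 - K) / dnorm(t)^2)
  # independent high-precision recomputation at K=0.01, P=0.5
  h <- observed_to_liability_h2(0.2, 0.01, 0.5)
  t2 <- qnorm(0.99)
  expect_equal(h, 0.2 * 0.01^2 * 0.99^2 / (0.25 * dnorm(t2)^2),
               tolerance = 1e-12)
  expect_error(observed_to_liability_h2(0.2, 0, 0.5), "between")
})
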