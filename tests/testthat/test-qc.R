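# Variant/sample QC filters and the exact Hardy-Weinberg test.

test_that("HWE exact test matches enumeration oracle and conventions", {
  expect_equal(hwe_exact_test(1, 0, 0), 1)           # single individual
  expect_equal(hwe_exact_test(0, 2, 0), oracle_hwe(0, 2, 0))
  expect_equal(hwe_exact_test(57, 14, 50), oracle_hwe(57, 14, 50),
               tolerance = 1e-12)
  # symmetry under allele relabelling
  for (cfg in list(c(5, 10, 30), c(0, 7, 12), c(20, 1, 2))) {
    expect_equal(hwe_exact_test(cfg[1], cfg[2], cfg[3]),
                 hwe_exact_test(cfg[3], cfg[2], cfg[1]))
  }
  # monomorphic convention and error case
  expect_equal(hwe_exact_test(25, 0, 0), 1)
  expect_error(hwe_exact_test(0, 0, 0), "no genotyped")
  # random spot sweep against the oracle
  set.seed(5)
  for (i in 1:200) {
    n <- sample(2:120, 1)
    a <- sample(0:n, 1); h <- sample(0:(n - a), 1)
    expect_equal(hwe_exact_test(a, h, n - a - h), oracle_hwe(a, h, n - a - h),
                 tolerance = 1e-12)
  }
})

test_that("variant filters apply printed thresholds strictly and in order", {
  # 4 variants x 20 samples engineered around each boundary
  n <- 20
  calls <- rbind(
    c(rep(1L, 18), NA, NA),        # call rate 0.90 < 0.95 -> call_rate
    rep(c(0L, 1L), 10),            # fine
    c(1L, rep(0L, 19)),            # freq 1/40 = 0.025, MAF fine
    c(rep(2L, 10), rep(0L, 10))    # extreme HWE departure
  )
  d <- tiny_dataset(calls)
  thr <- qc_thresholds(variant_call_rate_min = 0.95, maf_min = 0.01,
                       hwe_p_min = 1e-4)
  res <- filter_variants(d, thr)
  expect_equal(res$dataset$variants$id, c("v2", "v3"))
  expect_equal(res$report$steps$step, c("call_rate", "maf", "hwe"))
  expect_equal(res$report$steps$removed, c(1L, 0L, 1L))
  # removals in the report reconcile with the dimension change
  expect_equal(sum(res$report$steps$removed),
               nrow(d$variants) - nrow(res$dataset$variants))

  # MAF exactly at the threshold is kept ("MAF < 0.01 excluded")
  n2 <- 50
  calls2 <- rbind(c(1L, rep(0L, n2 - 1)),   # MAF = 1/100 = 0.01 exactly
                  rep(c(0L, 2L), n2 / 2))
  res2 <- filter_variants(tiny_dataset(calls2),
                          qc_thresholds(maf_min = 0.01, hwe_p_min = 1e-30))
  expect_true("v1" %in% res2$dataset$variants$id)

  # filters are idempotent
  again <- filter_variants(res$dataset, thr)
  expect_equal(again$dataset$variants$id, res$dataset$variants$id)
  expect_equal(sum(again$report$steps$removed), 0L)
})

test_that("case/control HWE strata use their own thresholds", {
  set.seed(8)
  n <- 60
  status <- rep(c(0L, 1L), each = n / 2)
  # variant 1: HWE failure only among controls; variant 2: clean
  v1 <- c(rep(c(0L, 2L), n / 4), rbinom(n / 2, 2, 0.5))
  v2 <- rbinom(n, 2, 0.4)
  d <- tiny_dataset(rbind(v1, v2))
  res <- filter_variants(d, qc_thresholds(hwe_p_min_controls = 1e-3,
                                          hwe_p_min_cases = 1e-10),
                         case_status = status)
  expect_equal(res$dataset$variants$id, "v2")
  # identical data but the lenient case threshold applied to both strata
  res2 <- filter_variants(d, qc_thresholds(hwe_p_min_controls = 1e-30,
                                           hwe_p_min_cases = 1e-30),
                          case_status = status)
  expect_equal(nrow(res2$dataset$variants), 2)
})

test_that("supplied-quality filtering is a strict pass-through", {
  d <- tiny_dataset(matrix(1L, nrow = 4, ncol = 3))
  info <- c(0.9, 0.59, 0.6, NA)
  res <- filter_variants_by_quality(d, info, min_quality = 0.6)
  # the boundary value is kept, missing quality is kept (logged)
  expect_equal(res$dataset$variants$id, c("v1", "v3", "v4"))
  expect_equal(res$report$steps$removed, 1L)
})

test_that("sample call-rate filter keeps the inclusive boundary", {
  calls <- matrix(1L, nrow = 10, ncol = 3)
  calls[, 1] <- NA_integer_                 # all missing
  calls[1, 2] <- NA_integer_               # rate 0.9
  d <- tiny_dataset(calls)
  res <- filter_samples_by_call_rate(d, min_rate = 0.9)
  expect_equal(ncol(res$dataset$calls), 2)  # 0.9 kept, 0 removed
  expect_equal(res$report$steps$removed, 1L)
  full <- filter_samples_by_call_rate(d, min_rate = 1)
  expect_equal(ncol(full$dataset$calls), 1)
})

test_that("ancestry filter keeps samples within the SD limit inclusively", {
  pcs <- rbind(c(0, 0), c(7, 0), c(6, 0), c(0, -6.5), c(3, 3))
  rownames(pcs) <- paste0("s", 1:5)
  kept <- ancestry_filter(pcs, reference_mean = c(0, 0),
                          reference_sd = c(1, 1), limit = 6)
  expect_setequal(kept, c("s1", "s3", "s5"))  # exactly 6 SD is kept
  expect_error(ancestry_filter(pcs, c(0, 0), c(0, 1)), "positive")
})

test_that("relatedness pruning is minimal on chains, deterministic, and
           verified against the threshold", {
  # chain a-b, b-c related: removing b alone suffices
  A <- diag(3) ; A[1, 2] <- A[2, 1] <- 0.3; A[2, 3] <- A[3, 2] <- 0.4
  dimnames(A) <- list(letters[1:3], letters[1:3])
  kept <- prune_related(A, threshold = 0.05, seed = 1)
  expect_setequal(kept, c("a", "c"))
  # all pairs below the threshold: nothing removed
  B <- diag(4); B[upper.tri(B)] <- 0.04; B <- (B + t(B)) / 2; diag(B) <- 1
  dimnames(B) <- list(letters[1:4], letters[1:4])
  expect_equal(length(prune_related(B, 0.05, seed = 1)), 4)
  # a single related pair loses exactly one member, reproducibly
  C <- diag(2); C[1, 2] <- C[2, 1] <- 0.5
  dimnames(C) <- list(c("x", "y"), c("x", "y"))
  k1 <- prune_related(C, 0.05, seed = 3)
  expect_equal(length(k1), 1)
  expect_identical(prune_related(C, 0.05, seed = 3), k1)
})

test_that("cross-cohort pruning removes only offending B-samples", {
  M <- matrix(0, nrow = 3, ncol = 4,
              dimnames = list(NULL, paste0("b", 1:4)))
  expect_setequal(cross_cohort_prune(M, 0.05), paste0("b", 1:4))
  M[2, 3] <- 0.3
  expect_setequal(cross_cohort_prune(M, 0.05), c("b1", "b2", "b4"))
  # seeded fixture equals a per-column max scan
  set.seed(21)
  R <- matrix(rnorm(60, 0, 0.05), 5, 12,
              dimnames = list(NULL, paste0("b", 1:12)))
  expect_setequal(cross_cohort_prune(R, 0.05),
                  colnames(R)[apply(R, 2, max) <= 0.05])
})
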