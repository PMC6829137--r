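# Statistical layer: tau, dip statistic/test, size factors, BH, the NB
# differential test, mid-parent deviation and additivity classes.

test_that("tau matches hand-evaluated profiles and stays in [0, 1]", {
  expect_equal(tau(c(0, 0, 5)), 1)
  expect_equal(tau(c(2, 2, 2)), 0)
  expect_equal(tau(c(4, 1, 1)), 0.75)
  expect_true(is.na(tau(c(0, 0, 0))))
  expect_error(tau(5), "at least 2")
  expect_error(tau(c(-1, 2)), "non-negative")
  set.seed(11)
  for (i in 1:500) {
    x <- rexp(sample(2:12, 1)) * sample(c(1, 100), 1)
    expect_true(tau(x) >= 0 && tau(x) <= 1)
  }
  # flattening a single-condition profile toward constant decreases tau
  taus <- vapply(seq(0, 1, by = 0.1), function(a)
    tau(c(1, a, a, a)), 0)
  expect_true(all(diff(taus) <= 1e-12))
})

test_that("tau_matrix transforms, averages replicates, and subsets", {
  rpm <- rbind(F1 = c(3, 3, 0, 0), F2 = c(1, 1, 1, 1))
  colnames(rpm) <- paste0("L", 1:4)
  tm <- tau_matrix(rpm)
  expect_equal(tm[tm$feature == "F1", tau], 2 / 3)   # two of four libraries
  expect_equal(tm[tm$feature == "F2", tau], 0)
  md <- data.table(library_id = paste0("L", 1:4),
                   tissue = c("a", "a", "b", "b"))
  em <- structure(list(rpm = rpm, metadata = md), class = "expression_matrix")
  tg <- tau_matrix(em, group_by = "tissue")
  expect_identical(tg$n_conditions, c(2L, 2L))
  expect_equal(tg[tg$feature == "F1", tau], 1)
})

# dip values frozen from an independent reference implementation of
# Hartigan & Hartigan's algorithm, evaluated on fixed samples
dip_oracle_cases <- list(
  list(x = c(0, 1), dip = 0.25),
  list(x = c(1, 1, 1), dip = 0.166666666666667),
  list(x = c(0, 1, 5), dip = 0.166666666666667),
  list(x = c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1), dip = 0.25),
  list(x = c(0.837, 0.321, 0.680, 0.698, 0.457, 0.701, 0.416, 0.303, 0.877,
             0.119, 0.902, 0.953, 0.704, 0.516, 0.449, 0.842, 0.110),
       dip = 0.079025549613785),
  list(x = c(1.09, -0.54, -1.22, 1.04, -0.55, 0.90, -2.03, -0.55, 1.93, 0.47,
             1.83, 0.38, 1.34, -0.27, -0.13, -0.59, 0.39, 0.65, -0.03, 0.57,
             -0.87, -0.59, -0.19, 0.36, 0.90),
       dip = 0.074601226993865),
  list(x = c(0.579, -0.561, -0.847, -0.141, 0.549, -1.800, -0.771, -0.689,
             -2.106, -0.043, -0.502, 1.075, 1.335, -1.757, -0.903, 4.005,
             4.053, 4.132, 4.023, 4.280, 3.544, 4.256, 4.091, 3.594, 4.390,
             3.712, 3.808, 3.542, 3.650, 3.354),
       dip = 0.097040169133192),
  list(x = c(3, 2, 0, 3, 2, 2, 2, 0, 3, 3, 2, 1, 1, 0, 2, 1, 2, 0, 0, 2, 1,
             3, 1, 2, 1, 1, 0, 2, 1, 1, 2, 2, 0, 1, 1, 0, 1, 2, 0, 0),
       dip = 0.15),
  list(x = c(0.24, 0.12, 1.25, 0.30, 0.63, 1.29, 0.27, 1.30, 4.28, 0.59,
             0.16, 2.29, 0.49, 1.91, 0.49, 0.42, 1.39, 3.71, 3.52, 2.11,
             1.30, 0.02, 0.03, 1.32, 2.73, 0.68, 0.29, 0.29, 0.20, 0.61,
             1.41, 1.55, 2.65, 0.11, 0.17, 0.34, 0.76, 0.72, 0.20, 1.28,
             1.52, 0.64, 0.03, 1.18, 1.32, 2.62, 1.53, 1.38, 0.65, 1.74,
             1.53, 1.52, 0.02, 1.49, 1.35, 0.83, 0.88, 0.40, 5.59, 0.11),
       dip = 0.078448275862069)
)

test_that("dip statistic reproduces frozen reference values exactly", {
  for (case in dip_oracle_cases)
    expect_equal(dip_statistic(case$x), case$dip, tolerance = 1e-12)
})

test_that("dip statistic: bounds, invariance, and degenerate inputs", {
  set.seed(21)
  # any 2-point sample with distinct values gives exactly 0.25
  for (i in 1:20) expect_equal(dip_statistic(rnorm(2)), 0.25)
  # lower bound 1/(2n); affine invariance
  for (i in 1:300) {
    n <- sample(2:60, 1)
    x <- switch(sample(1:3, 1), runif(n), rnorm(n),
                sample(0:3, n, replace = TRUE))
    d <- dip_statistic(x)
    expect_true(d >= 1 / (2 * n) - 1e-15)
    expect_equal(dip_statistic(3.7 * x - 11), d, tolerance = 1e-12)
    expect_equal(dip_statistic(sample(x)), d, tolerance = 1e-12)
  }
  # balanced two-point mixtures sit at 0.25 for any size
  for (k in c(5, 50, 500))
    expect_equal(dip_statistic(c(rep(0, k), rep(1, k))), 0.25)
  expect_error(dip_statistic(3), "at least 2")
  expect_error(dip_statistic(c(1, NA)), "finite")
})

test_that("dip test separates bimodal from uniform and is seed-deterministic", {
  set.seed(31)
  bimodal <- c(rnorm(50, 0, 0.05), rnorm(50, 1, 0.05))
  unif <- runif(100)
  r1 <- dip_test(bimodal, n_sim = 500, seed = 7)
  r2 <- dip_test(bimodal, n_sim = 500, seed = 7)
  expect_identical(r1, r2)
  expect_lt(r1$p_value, 0.05)
  expect_false(r1$unimodal_call)                    # standard convention
  r1p <- dip_test(bimodal, n_sim = 500, seed = 7,
                  call_convention = "p_lt_alpha")
  expect_true(r1p$unimodal_call)                    # study's operational rule
  ru <- dip_test(unif, n_sim = 500, seed = 7)
  expect_gt(ru$p_value, 0.2)
  expect_true(ru$unimodal_call)
  # a precomputed null table gives the same p-value
  nt <- dip_null(100, 500, 7)
  expect_identical(dip_test(bimodal, null_table = nt, seed = 7)$p_value,
                   r1$p_value)
})

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10L, 20L, 30L, 20L, 40L, 60L), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("L1", "L2")))
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)))
  m2 <- cbind(L1 = c(5L, 8L, 100L), L2 = c(5L, 8L, 100L))
  expect_equal(unname(size_factors(m2)), c(1, 1))
  expect_equal(size_factors(m[c(3, 1, 2), ]), size_factors(m))
  expect_error(size_factors(matrix(c(0L, 1L, 1L, 0L), 2)), "positive")
})

test_that("size factors agree with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(41)
  for (i in 1:5) {
    m <- matrix(rnbinom(60, mu = 100, size = 5) + 1L, 10, 6,
                dimnames = list(sprintf("f%02d", 1:10), sprintf("L%d", 1:6)))
    expect_equal(unname(size_factors(m)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(m)),
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the literal step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"))
  set.seed(51)
  for (i in 1:200) {
    m <- sample(1:6, 1)
    p <- round(runif(m), 3)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # NA passthrough
  p <- c(0.01, NA, 0.5)
  a <- bh_adjust(p)
  expect_true(is.na(a[2]))
  expect_equal(a[c(1, 3)], oracle_bh(p[c(1, 3)]))
})

test_that("NB test: identical groups are ns, true fold changes are found", {
  set.seed(61)
  a <- matrix(rep(c(100L, 50L, 200L), 3), 3,
              dimnames = list(c("f1", "f2", "f3"), NULL))
  r <- nb_differential_test(a, a)
  expect_equal(r$log2fc, rep(0, 3))
  expect_identical(r$call, rep("ns", 3))
  # all-zero feature: NA p, ns call
  az <- rbind(a, f0 = 0L)
  r0 <- nb_differential_test(az, az)
  expect_true(is.na(r0[r0$feature == "f0", p]))
  expect_identical(r0[r0$feature == "f0", call], "ns")
  # 4-fold change with 6 vs 6 replicates, moderate dispersion
  hits <- 0L
  for (s in 1:30) {
    set.seed(s)
    base <- matrix(rnbinom(50 * 6, mu = 100, size = 10), 50, 6)
    trt <- matrix(rnbinom(50 * 6, mu = 100, size = 10), 50, 6)
    trt[1, ] <- rnbinom(6, mu = 400, size = 10)
    rownames(base) <- rownames(trt) <- sprintf("f%02d", 1:50)
    r <- nb_differential_test(base, trt)
    if (r[r$feature == "f01", call] == "up" &&
        r[r$feature == "f01", padj] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 27L)   # >= 90% of 30 seeds
})

test_that("DE calling applies the exact thresholds and exclusivity", {
  r <- data.table(feature = c("a", "b", "c", "d"),
                  base_mean_a = 1, base_mean_b = 1,
                  log2fc = c(1, 1, -2, 0.5),
                  p = c(0.001, 0.01, 0.001, 0.001),
                  padj = c(0.04, 0.05, 0.01, 0.01),
                  call = c("up", "ns", "down", "ns"))
  de <- call_de_families(r)
  expect_setequal(de$up_in_b, "a")       # padj 0.04, FC exactly 2 -> DE
  expect_setequal(de$up_in_a, "c")       # padj 0.05 exactly -> not DE ("b")
  de2 <- call_de_families(r, expressed_a = c("a", "c"),
                          expressed_b = c("c"))
  expect_setequal(de2$exclusive_a, "a")
  expect_identical(de2$exclusive_b, character(0))
})

test_that("mid-parent deviation and additivity classes behave as defined", {
  expect_equal(midparent_deviation(15, 10, 20, pseudocount = 0), 0)
  expect_equal(midparent_deviation(30, 10, 20, pseudocount = 0), 1)
  expect_lt(midparent_deviation(0, 10, 20), 0)
  expect_error(midparent_deviation(1, 0, 0, pseudocount = 0), "positive")
  mk <- function(calls) data.table(feature = c("x", "y", "z"), call = calls)
  cl <- classify_additivity(mk(c("up", "up", "down")),
                            mk(c("up", "ns", "down")))
  expect_identical(cl[cl$feature == "x", class], "above_both")
  expect_identical(cl[cl$feature == "y", class], "additive_range")
  expect_identical(cl[cl$feature == "z", class], "below_both")
  expect_warning(
    classify_additivity(mk(c("up", "up", "up")),
                        data.table(feature = c("x", "y"),
                                   call = c("up", "up"))),
    "skipped")
  tal <- nonadditive_counts(list(leaf = cl))
  expect_identical(tal$non_additive, 2L)
})

test_that("ril_segregation screens families and reports presence", {
  set.seed(71)
  rpm <- rbind(
    SEG = c(rep(0, 12), rep(80, 12) + rnorm(12)),   # bimodal, half present
    FLAT = rep(50, 24) + rnorm(24, sd = 4))
  colnames(rpm) <- sprintf("R%02d", 1:24)
  res <- ril_segregation(rpm, n_sim = 300, seed = 5)
  expect_equal(res[res$feature == "SEG", presence_fraction], 0.5)
  expect_false(res[res$feature == "SEG", unimodal])
  expect_true(res[res$feature == "FLAT", unimodal])
  expect_error(ril_segregation(rpm[, 1:10]), "at least 20")
  expect_warning(ril_segregation(rpm, families = c("SEG", "NOPE"),
                                 n_sim = 300, seed = 5), "absent")
})
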