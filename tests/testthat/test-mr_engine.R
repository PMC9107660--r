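test_that("greedy clumping honours p-value order, LD and distance", {
  ld <- simulate_ld_reference(30, 3, 0.9, seed = 1)
  snp_tab <- crosstrait:::ld_snp_table(ld)
  s <- crosstrait:::z_to_sumstats(rep(1, 30), snp_tab, 1e5, rep(0.3, 30), "t")
  # nothing below threshold: empty result
  expect_length(clump_instruments(s, ld, p_thresh = 5e-8), 0)

  # A best, B linked to A (same block, r2 >> 0.1), C independent block
  s$pval[] <- 1
  s$pval[s$rsid == "rs1"] <- 1e-10 # A
  s$pval[s$rsid == "rs2"] <- 1e-9  # B: r2 with A = 0.81
  s$pval[s$rsid == "rs11"] <- 1e-8 # C: different block
  kept <- clump_instruments(s, ld, p_thresh = 5e-8, r2_thresh = 0.1,
                            window_bp = 1e9)
  expect_setequal(kept, c("rs1", "rs11"))
  # with a permissive r2 threshold B survives too
  kept2 <- clump_instruments(s, ld, p_thresh = 5e-8, r2_thresh = 0.9,
                             window_bp = 1e9)
  expect_setequal(kept2, c("rs1", "rs2", "rs11"))
  # outside the physical window LD is ignored
  kept3 <- clump_instruments(s, ld, p_thresh = 5e-8, r2_thresh = 0.1,
                             window_bp = 10)
  expect_setequal(kept3, c("rs1", "rs2", "rs11"))
})

test_that("instrument classification reproduces the published bookkeeping", {
  tab <- simulate_instrument_table(seed = 1) # synthetic stand-in table
  cl <- classify_bw_instruments(tab$fetal, tab$maternal, tab$truth$rsid)
  counts <- attr(cl, "counts")
  expect_equal(unname(counts["fetal_specific"]), 63L, ignore_attr = TRUE)
  expect_equal(unname(counts["maternal_specific"]), 31L, ignore_attr = TRUE)
  expect_equal(unname(counts["both_same_direction"]), 26L, ignore_attr = TRUE)
  expect_equal(unname(counts["both_opposite_direction"]), 15L, ignore_attr = TRUE)
  expect_equal(unname(counts["unclassified"]), 71L, ignore_attr = TRUE)
  expect_length(attr(cl, "fetal_set"), 104L)    # 63 + 26 + 15
  expect_length(attr(cl, "maternal_set"), 72L)  # 31 + 26 + 15

  # sign rule and insignificance rule on constructed records
  f <- sumstats(data.frame(rsid = c("rs1", "rs2"), chrom = 1L, pos = 1:2,
                           a1 = "A", a2 = "G", beta = c(0.1, 0.01),
                           se = c(0.01, 0.05), n = 1e5))
  m <- sumstats(data.frame(rsid = c("rs1", "rs2"), chrom = 1L, pos = 1:2,
                           a1 = "A", a2 = "G", beta = c(-0.1, 0.01),
                           se = c(0.01, 0.05), n = 1e5))
  cl2 <- classify_bw_instruments(f, m, c("rs1", "rs2"))
  expect_equal(cl2$class, c("both_opposite_direction", "unclassified"))
  expect_warning(classify_bw_instruments(f, m, "rs9"), "missing")
})

test_that("IVW equals the weighted least squares oracle and reduces to Wald", {
  bx <- c(0.10, 0.20, 0.30); by <- c(0.04, 0.11, 0.14); sy <- c(0.01, 0.02, 0.01)
  f <- ivw(bx, by, sy)
  W <- diag(1 / sy^2)
  oracle <- solve(t(bx) %*% W %*% bx, t(bx) %*% W %*% by)[1, 1]
  expect_equal(f$beta, oracle, tolerance = 1e-10)
  # exact proportionality: slope exact, Q = 0
  fp <- ivw(bx, 0.5 * bx, sy)
  expect_equal(fp$beta, 0.5)
  expect_equal(fp$Q, 0)
  # single instrument: Wald ratio with se_y / |bx|
  f1 <- ivw(0.2, 0.1, 0.05)
  expect_equal(f1$beta, 0.5)
  expect_equal(f1$se, 0.25)
  expect_error(ivw(c(0, 0), c(1, 1), c(1, 1)), "zero")
  # order invariance and joint sign-flip equivariance
  o <- sample(3)
  expect_equal(ivw(bx[o], by[o], sy[o])$beta, f$beta)
  expect_equal(ivw(-bx, -by, sy)$beta, f$beta)
})

test_that("Egger fits exact linear pleiotropy and detects a planted intercept", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  fe <- mr_egger(bx, 0.02 + 0.5 * bx, rep(0.01, 4))
  expect_equal(fe$intercept, 0.02, tolerance = 1e-10)
  expect_equal(fe$beta, 0.5, tolerance = 1e-10)
  expect_error(mr_egger(bx[1:2], bx[1:2], rep(0.01, 2)), "3 instruments")

  # calibration: no pleiotropy gives uniform-ish intercept p
  p0 <- vapply(1:60, function(i) {
    d <- clean_instruments(J = 40, seed = 200 + i)
    mr_egger(d$bx, d$by, d$sy)$intercept_pval
  }, 0)
  expect_gt(ks.test(p0, "punif")$p.value, 0.01)

  # planted constant directional pleiotropy 0.03, 100 instruments: power > 0.8
  hits <- vapply(1:50, function(i) {
    set.seed(300 + i)
    bx <- runif(100, 0.05, 0.2)
    by <- 0.3 * bx + 0.03 + rnorm(100, 0, 0.01)
    f <- mr_egger(bx, by, rep(0.01, 100))
    c(f$intercept, f$intercept_pval < 0.05)
  }, c(0, 0))
  expect_equal(mean(hits[1, ]), 0.03, tolerance = 0.01)
  expect_gt(mean(hits[2, ]), 0.8)
})

test_that("weighted median interpolates the weighted CDF and resists invalid instruments", {
  expect_equal(crosstrait:::weighted_median_core(c(0.1, 0.2, 0.9), rep(1, 3)), 0.2)
  # all ratios identical: estimate c with tiny bootstrap se
  f <- weighted_median(c(0.1, 0.2, 0.4), c(0.05, 0.10, 0.20), rep(1e-6, 3),
                       n_boot = 50, seed = 1)
  expect_equal(f$beta, 0.5, tolerance = 1e-3)
  expect_lt(f$se, 1e-4)
  expect_warning(weighted_median(c(0, 0.1, 0.2, 0.3), rep(0.1, 4), rep(0.1, 4),
                                 n_boot = 10, seed = 1), "beta_x = 0")

  # 40% of instruments invalid with large positive pleiotropy
  est <- vapply(1:40, function(i) {
    set.seed(400 + i)
    J <- 50
    bx <- runif(J, 0.1, 0.3)
    pleio <- c(rep(0, 30), runif(20, 0.05, 0.15))
    by <- 0.3 * bx + pleio + rnorm(J, 0, 0.005)
    weighted_median(bx + rnorm(J, 0, 0.002), by, rep(0.005, J),
                    se_x = rep(0.002, J), n_boot = 200, seed = i)$beta
  }, 0)
  expect_lt(abs(mean(est) - 0.3), 0.05)
})

test_that("maximum likelihood matches Wald/IVW in its degenerate and asymptotic regimes", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  fm <- max_likelihood(bx, 0.5 * bx, rep(0.01, 4), rep(0.005, 4))
  expect_equal(fm$beta, 0.5, tolerance = 1e-4)
  # single instrument: Wald ratio
  f1 <- max_likelihood(0.2, 0.1, 0.05, 1e-12)
  expect_equal(f1$beta, 0.5, tolerance = 1e-6)
  # large-sample agreement with IVW under no pleiotropy
  d <- clean_instruments(J = 100, seed = 7, sx = 1e-4, sy = 0.005)
  fi <- ivw(d$bx, d$by, d$sy)
  fl <- max_likelihood(d$bx, d$by, d$sy, d$sx)
  expect_lt(abs(fl$beta - fi$beta), 2 * fi$se)
})

test_that("MR-PRESSO calibrates under the null and flags planted outliers", {
  # clean data: global p behaves like a uniform p-value
  p0 <- vapply(1:40, function(i) {
    d <- clean_instruments(J = 25, seed = 500 + i, sx = 0)
    # n_sim below J/sig: global test only, the outlier test has no power
    suppressWarnings(mr_presso(d$bx, d$by, d$sy, n_sim = 300, seed = i))$global_pval
  }, 0)
  expect_lt(mean(p0 < 0.05), 0.2)
  expect_gt(mean(p0), 0.3)

  # a single 10x-residual outlier among 30 is flagged nearly always
  hits <- vapply(1:40, function(i) {
    set.seed(600 + i)
    J <- 30
    bx <- runif(J, 0.05, 0.2)
    by <- 0.3 * bx + rnorm(J, 0, 0.01)
    by[7] <- by[7] + 10 * 0.01
    pr <- mr_presso(bx, by, rep(0.01, J), n_sim = 1000, seed = i)
    c(found = 7 %in% pr$outliers,
      err_corr = abs(pr$corrected$beta - 0.3),
      err_raw = abs(pr$raw$beta - 0.3))
  }, c(TRUE, 0, 0))
  expect_gte(mean(hits["found", ]), 0.95)
  # removing the outlier shrinks the mean absolute error of the estimate
  expect_lt(mean(hits["err_corr", ]), mean(hits["err_raw", ]))

  # nothing flagged: corrected estimate is identical to the raw IVW
  d <- clean_instruments(J = 20, seed = 3, sx = 0)
  pr <- mr_presso(d$bx, d$by, d$sy, n_sim = 500, seed = 4)
  if (length(pr$outliers) == 0) expect_identical(pr$corrected, pr$raw)
  expect_error(mr_presso(1:3 / 10, 1:3 / 10, rep(0.1, 3)), "4 instruments")
})

test_that("multivariable IVW recovers exact fits and reduces to IVW", {
  set.seed(10)
  bx1 <- runif(12, 0.05, 0.3); bx2 <- runif(12, 0.05, 0.3)
  by <- 0.3 * bx1 + 0.2 * bx2
  mv <- mvmr_ivw(cbind(A = bx1, B = bx2), by, rep(0.01, 12))
  expect_equal(mv$A$beta, 0.3, tolerance = 1e-10)
  expect_equal(mv$B$beta, 0.2, tolerance = 1e-10)
  # all-zero second exposure: rank-deficiency error naming the column
  expect_error(mvmr_ivw(cbind(A = bx1, B = rep(0, 12)), by, rep(0.01, 12)),
               "collinear: B")
  # single-exposure MVMR is exactly IVW (estimate and se)
  d <- clean_instruments(J = 15, seed = 11)
  fi <- ivw(d$bx, d$by, d$sy)
  m1 <- mvmr_ivw(cbind(X = d$bx), d$by, d$sy)$X
  expect_equal(m1$beta, fi$beta, tolerance = 1e-12)
  expect_equal(m1$se, fi$se, tolerance = 1e-12)
})

test_that("Bonferroni screening removes exactly the sub-threshold instruments", {
  keep <- bonferroni_filter(rep(1, 5))
  expect_true(all(keep))
  keep2 <- bonferroni_filter(c(1e-6, 0.2, 0.9), m = 100)
  expect_equal(attr(keep2, "removed"), 1L)
  # m = 1 reduces to plain p < 0.05 filtering
  keep3 <- bonferroni_filter(c(0.03, 0.07), m = 1)
  expect_equal(unclass(keep3)[1:2], c(FALSE, TRUE), ignore_attr = TRUE)
})

test_that("the analytical binary-outcome power formula behaves correctly", {
  # null effect returns the alpha/2 one-sided false-positive rate
  expect_equal(mr_power_binary(1e5, 0.3, 0.05, 1), 0.025, tolerance = 1e-10)
  # monotone in n, r2 and |log OR|
  n <- c(1e4, 5e4, 1e5, 5e5)
  expect_true(all(diff(mr_power_binary(n, 0.3, 0.02, 0.9)) > 0))
  r2 <- c(0.005, 0.01, 0.02, 0.05)
  expect_true(all(diff(mr_power_binary(1e5, 0.3, r2, 0.9)) > 0))
  or <- c(0.95, 0.9, 0.85, 0.8)
  expect_true(all(diff(mr_power_binary(1e5, 0.3, 0.02, or)) > 0))
  expect_error(mr_power_binary(1e5, 1.2, 0.05, 0.9), "K")
  expect_error(mr_power_binary(1e5, 0.3, 0, 0.9), "r2")
})

test_that("univariable estimators cover the truth at nominal rate on clean data", {
  res <- vapply(1:150, function(i) {
    d <- clean_instruments(J = 30, seed = 900 + i)
    ci_hit <- function(f) abs(f$beta - d$truth) <= 1.96 * f$se
    c(ivw = ci_hit(ivw(d$bx, d$by, d$sy)),
      egger = ci_hit(mr_egger(d$bx, d$by, d$sy)),
      wm = ci_hit(weighted_median(d$bx, d$by, d$sy, se_x = d$sx,
                                  n_boot = 200, seed = i)),
      ml = ci_hit(max_likelihood(d$bx, d$by, d$sy, d$sx)))
  }, c(TRUE, TRUE, TRUE, TRUE))
  cov <- rowMeans(res)
  for (m in names(cov)) expect_gt(cov[[m]], 0.88)
})
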