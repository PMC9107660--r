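test_that("LD reference has the stated block structure and LD scores", {
  # identity LD: every score is exactly 1
  ld0 <- simulate_ld_reference(12, 3, 0, seed = 1)
  expect_true(all(compute_ld_scores(ld0) == 1))

  # AR(1) block of 3 with rho = 0.5: middle SNP score 1 + 0.25 + 0.25
  ld1 <- simulate_ld_reference(3, 1, 0.5, seed = 1)
  expect_equal(unname(compute_ld_scores(ld1)[2]), 1.5)

  # invariants: scores >= 1, block SNP sets disjoint, unit diagonals
  ld <- simulate_ld_reference(200, 8, c(0.2, 0.8), seed = 2)
  expect_true(all(compute_ld_scores(ld) >= 1))
  ids <- unlist(lapply(ld$blocks, `[[`, "rsid"))
  expect_equal(anyDuplicated(ids), 0L)
  expect_true(all(vapply(ld$blocks, function(b) all(diag(b$R) == 1), TRUE)))

  expect_error(simulate_ld_reference(10, 2, 1.0), "block_rho")
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(m_snps = 200, n_blocks = 4)
  ld <- simulate_ld_reference(200, 4, 0.4, seed = 9)
  a <- simulate_paired_sumstats(ld, cfg, seed = 5)
  b <- simulate_paired_sumstats(ld, cfg, seed = 5)
  expect_identical(a, b)
  ch1 <- simulate_causal_chain(cfg, seed = 5)
  ch2 <- simulate_causal_chain(cfg, seed = 5)
  expect_identical(ch1, ch2)
  # the global RNG stream is not consumed
  set.seed(77); r1 <- rnorm(1)
  set.seed(77); invisible(simulate_paired_sumstats(ld, cfg, seed = 5)); r2 <- rnorm(1)
  expect_identical(r1, r2)
})

test_that("generated summary statistics satisfy the sumstats invariants and QC", {
  cfg <- sim_config(m_snps = 500, n_blocks = 10)
  ld <- simulate_ld_reference(500, 10, 0.5, seed = 3)
  sim <- simulate_paired_sumstats(ld, cfg, seed = 4)
  for (s in sim[c("trait1", "trait2")]) {
    expect_equal(nrow(qc_sumstats(s)), nrow(s)) # QC-clean by construction
    expect_equal(s$z, s$beta / s$se, tolerance = 1e-6)
    expect_true(all(s$pval > 0 & s$pval <= 1))
  }
})

test_that("paired simulation hits its generative moments", {
  ld <- study_ld()
  ell <- study_ell()
  # null case: regression of z1*z2 on l has slope compatible with 0
  sl <- vapply(1:30, function(i) {
    s <- simulate_paired_sumstats(ld, sim_config(rg_true = 0), seed = 400 + i)
    unname(coef(lm(I(s$trait1$z * s$trait2$z) ~ ell))[2])
  }, 0)
  expect_lt(abs(mean(sl)), 3 * sd(sl) / sqrt(length(sl)))

  # mean z^2 reflects 1 + n h2 l / M within Monte-Carlo error
  s <- simulate_paired_sumstats(ld, sim_config(), seed = 11)
  m <- ld$m_snps
  expected <- mean(1 + 50000 * 0.3 * ell / m)
  expect_equal(mean(s$trait1$z^2), expected, tolerance = 0.1)

  # perfect correlation: true effect vectors proportional
  s1 <- simulate_paired_sumstats(ld, sim_config(rg_true = 1), seed = 12)
  expect_equal(cor(s1$true_effects[, 1], s1$true_effects[, 2]), 1, tolerance = 1e-12)
})

test_that("fetal/maternal effects carry the requested correlation", {
  ld <- simulate_ld_reference(10000, 100, 0.3, seed = 21)
  fm <- simulate_fetal_maternal(ld, sim_config(m_snps = 10000, n_blocks = 100,
                                               fm_corr = -0.6), seed = 22)
  expect_equal(cor(fm$true_effects[, 1], fm$true_effects[, 2]), -0.6,
               tolerance = 0.05)
  fm0 <- simulate_fetal_maternal(ld, sim_config(m_snps = 10000, n_blocks = 100,
                                                fm_corr = 0), seed = 23)
  expect_lt(abs(cor(fm0$true_effects[, 1], fm0$true_effects[, 2])), 0.05)
  fm1 <- simulate_fetal_maternal(ld, sim_config(m_snps = 10000, n_blocks = 100,
                                                fm_corr = 1), seed = 24)
  expect_equal(cor(fm1$true_effects[, 1], fm1$true_effects[, 2]), 1,
               tolerance = 1e-12)
})

test_that("planted pleiotropic genes have labelled states and signed correlations", {
  pan <- independent_gene_panel()
  gm <- pan$gene_map[1:200]
  # frac 0: everything H00
  p0 <- plant_pleiotropic_genes(gm, pan$ld, frac_shared = 0, seed = 1)
  expect_true(all(p0$truth$state == "H00"))
  # states partition the gene set
  p <- plant_pleiotropic_genes(gm, pan$ld, frac_shared = 0.1,
                               frac_only1 = 0.2, frac_only2 = 0.2, seed = 2)
  expect_equal(sum(table(p$truth$state)), length(gm))
  # positive requested sign: per-gene true-effect correlation positive
  h11 <- p$truth$gene_id[p$truth$state == "H11"]
  rs <- vapply(h11, function(g) {
    rows <- match(gm[[g]], pan$snp_tab$rsid)
    cor(p$effects[rows, 1], p$effects[rows, 2])
  }, 0)
  expect_true(all(rs > 0))
  neg <- plant_pleiotropic_genes(gm, pan$ld, frac_shared = 0.1,
                                 effect_corr_sign = -1, seed = 3)
  h11n <- neg$truth$gene_id[neg$truth$state == "H11"]
  rsn <- vapply(h11n, function(g) {
    rows <- match(gm[[g]], pan$snp_tab$rsid)
    cor(neg$effects[rows, 1], neg$effects[rows, 2])
  }, 0)
  expect_true(all(rsn < 0))
})

test_that("causal chain effects follow the structural equations", {
  cfg <- sim_config(theta_xy = 0.05, theta_xm2 = 0.02)
  ch <- simulate_causal_chain(cfg, seed = 31)
  tr <- ch$truth
  i <- tr$direct != "M1" # SNPs without a direct M1 effect
  expect_equal(tr$b_m1[i], cfg$theta_xm1 * tr$b_x[i] + tr$gamma[i])
  j <- tr$direct != "M2"
  expect_equal(tr$b_m2[j], cfg$theta_m1m2 * tr$b_m1[j] + cfg$theta_xm2 * tr$b_x[j])
  expect_equal(tr$b_y, cfg$theta_m2y * tr$b_m2 + cfg$theta_xy * tr$b_x)
  # standard errors scale as 1/sqrt(n)
  expect_equal(unique(ch$M1$se), 1 / sqrt(cfg$n_m1))
  # planted outliers are flagged and inflated
  cho <- simulate_causal_chain(sim_config(outlier_frac = 0.05), seed = 32)
  expect_gt(sum(cho$truth$outlier), 0)
})

test_that("synthetic instrument table realizes its planted class composition", {
  tab <- simulate_instrument_table(seed = 5)
  cl <- classify_bw_instruments(tab$fetal, tab$maternal, tab$truth$rsid)
  expect_identical(cl$class, tab$truth$class)
})
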