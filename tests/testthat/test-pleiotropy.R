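test_that("null proportions are recovered under planted mixtures", {
  # global null: pi00 near 1
  sim0 <- simulate_gene_pvalue_pairs(5000, c(1, 0, 0, 0), seed = 1)
  c0 <- estimate_null_proportions(sim0$p1, sim0$p2)
  expect_equal(c0$pi00, 1, tolerance = 0.05)

  # trait 1 null, trait 2 with 30% signals: pi0(2) ~ 0.7, pi01 ~ 0.3
  sim <- simulate_gene_pvalue_pairs(5000, c(0.7, 0.3, 0, 0), seed = 2)
  cc <- estimate_null_proportions(sim$p1, sim$p2)
  expect_equal(cc$pi0_marginal[2], 0.7, tolerance = 0.05)
  expect_equal(cc$pi01, 0.3, tolerance = 0.05)
  expect_equal(cc$pi00 + cc$pi01 + cc$pi10 + cc$pi11, 1, tolerance = 1e-9)

  # degenerate: all p = 1 gives pure H00
  c1 <- suppressWarnings(estimate_null_proportions(rep(1, 200), rep(1, 200)))
  expect_equal(c1$pi00, 1, tolerance = 1e-6)

  expect_error(estimate_null_proportions(c(0, 0.5), c(0.5, 0.5)), "0, 1")
})

test_that("the mixture-null p-value formula evaluates exactly and is monotone", {
  comp <- list(pi00 = 0.85, pi01 = 0.07, pi10 = 0.07, pi11 = 0.01)
  # frozen from the closed form ((pi01+pi10) t + pi00 t^2) / (1 - pi11)
  expect_equal(maiup_test(0.009, 0.01, comp),
               (0.14 * 0.01 + 0.85 * 1e-4) / 0.99, tolerance = 1e-12)
  # pure-H00 limit: p = t^2
  expect_equal(maiup_test(0.2, 0.3, list(pi00 = 1, pi01 = 0, pi10 = 0)), 0.09)
  # boundary: t = 1 gives p = 1
  expect_equal(maiup_test(1, 0.4, comp), 1)
  # monotone in t, and never above t
  t <- seq(0.001, 1, by = 0.001)
  p <- maiup_test(t, t / 2, comp)
  expect_true(all(diff(p) > 0))
  expect_true(all(p <= t + 1e-12))
  expect_error(maiup_test(0.1, 0.1, list(pi00 = 0, pi01 = 0, pi10 = 0)),
               "null mass")
})

test_that("the mixture-null p-value matches the empirical max-P null CDF", {
  # oracle: empirical CDF of t = max(p1, p2) under the three-component null
  pi <- c(0.85, 0.07, 0.07, 0.01)
  set.seed(9)
  n <- 1e6
  state <- sample(c("H00", "H01", "H10"), n, TRUE, prob = pi[1:3])
  p1 <- runif(n); p2 <- runif(n)
  p1[state == "H10"] <- runif(sum(state == "H10"), 0, 1e-8) # non-null ~ 0
  p2[state == "H01"] <- runif(sum(state == "H01"), 0, 1e-8)
  tmax <- pmax(p1, p2)
  comp <- list(pi00 = pi[1], pi01 = pi[2], pi10 = pi[3])
  for (t0 in c(0.01, 0.05, 0.2)) {
    emp <- mean(tmax <= t0)
    expect_lt(abs(maiup_test(t0, t0, comp) - emp),
              3 * sqrt(emp / n) + 0.01 * emp)
  }
})

test_that("BH selection follows the step-up oracle", {
  q <- bh_fdr(c(0.01, 0.02, 0.03, 0.5))
  expect_equal(sum(q < 0.05), 3L)
  expect_equal(sum(bh_fdr(rep(1, 10)) < 0.05), 0L)
  p <- sort(runif(50))
  expect_true(all(diff(bh_fdr(p)) >= 0))
})

test_that("gene effect correlations recover planted proportionality and truth", {
  df <- toy_sumstats_df()
  s1 <- sumstats(df)
  s2 <- sumstats(within(df, beta <- 2 * beta))
  expect_equal(gene_effect_correlation(s1, s2, df$rsid)$r, 1)
  s3 <- sumstats(within(df, beta <- -beta))
  expect_equal(gene_effect_correlation(s1, s3, df$rsid)$r, -1)
  # too few shared SNPs or constant vectors flag an undefined r
  expect_true(is.na(gene_effect_correlation(s1, s2, df$rsid[1:2])$r))
  s4 <- sumstats(within(df, beta <- rep(0.1, 3)))
  expect_match(gene_effect_correlation(s1, s4, df$rsid)$flag, "constant")

  # planted +0.8 within-gene effect correlation is recovered from sumstats
  pan <- independent_gene_panel()
  gm50 <- pan$gene_map[1:40]
  pl <- plant_pleiotropic_genes(gm50, pan$ld, frac_shared = 1,
                                effect_corr = 0.8, effect_sd = 0.05, seed = 11)
  sim <- simulate_sumstats_from_effects(
    pan$ld, pl$effects, sim_config(m_snps = 5000, n_blocks = 500), seed = 12)
  rs <- vapply(names(gm50), function(g) {
    gene_effect_correlation(sim$trait1, sim$trait2, gm50[[g]])$r
  }, 0)
  expect_gt(mean(rs > 0), 0.9)
  expect_equal(mean(rs), 0.8, tolerance = 0.2)
})

test_that("set comparison reports intersections and sign concordance", {
  a <- data.frame(gene_id = c("g1", "g2", "g3"),
                  effect_corr = c(0.5, -0.2, 0.8))
  b <- data.frame(gene_id = c("g2", "g3", "g4"),
                  effect_corr = c(0.3, -0.6, 0.1))
  cmp <- compare_pleiotropic_sets(a, b)
  expect_setequal(cmp$shared_genes, c("g2", "g3"))
  expect_equal(unname(cmp$pos_fraction), c(2 / 3, 2 / 3))
  # disjoint sets: empty report, not an error
  d <- compare_pleiotropic_sets(a, data.frame(gene_id = "g9", effect_corr = 0.1))
  expect_equal(d$n_shared, 0L)
  # identical sets: cross-correlation 1
  i <- compare_pleiotropic_sets(a, a)
  expect_equal(i$cross_correlation, 1)
  # sign-flipped local effects give a strongly negative cross-correlation
  f <- compare_pleiotropic_sets(a, within(a, effect_corr <- -effect_corr))
  expect_equal(f$cross_correlation, -1)
})
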