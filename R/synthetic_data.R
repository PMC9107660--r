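#' Simulation configuration
#'
#' Bundles the generative parameters used by all synthetic-data generators:
#' a polygenic pair of traits under block LD (for LD score regression and
#' the gene-based stages) and an instrument-level causal chain
#' X -> M1 -> M2 -> Y (for the Mendelian-randomization and mediation
#' stages).  All generators are pure functions of (config, seed).
#'
#' Defaults emulate the study conditions of the motivating analysis: a
#' quantitative anthropometric exposure measured in a few-hundred-thousand
#' sample GWAS, a binary outcome on the log-odds scale, fetal- and
#' maternal-specific effect components that are negatively correlated, and
#' chain coefficients theta_XM1 = 0.09, theta_M1M2 = 0.11, theta_M2Y = 0.10
#' with no direct X -> Y effect.
#'
#' @param m_snps total SNP count of the genome-wide simulation.
#' @param n_blocks number of disjoint LD blocks.
#' @param block_rho AR(1) within-block LD parameter(s) in `[0, 1)`;
#'   a vector is recycled over blocks.  The default spreads the blocks
#'   over 0.1-0.9 so LD scores vary across the panel — without that
#'   variation the LD score regression slope is unidentified.
#' @param h2_1,h2_2 SNP heritabilities of the two traits in `[0, 1]`.
#' @param rg_true genetic correlation in `[-1, 1]`; may be a vector recycled
#'   over the 22 pseudo-chromosomes to plant chromosome-specific correlation.
#' @param n1,n2 GWAS sample sizes.
#' @param n_overlap shared individuals between the two GWASs.
#' @param rho_pheno phenotypic correlation among overlapping individuals.
#' @param fm_corr correlation of fetal- and maternal-specific true SNP
#'   effects in `[-1, 1]` (negative by default: the two components act in
#'   opposite directions).
#' @param theta_xm1,theta_m1m2,theta_m2y,theta_xy,theta_xm2 structural
#'   coefficients of the causal chain (log-odds scale for the binary Y).
#' @param n_inst_x,n_inst_m1,n_inst_m2 direct instruments per exposure.
#' @param n_x,n_m1,n_m2,n_y GWAS sample sizes of the four chain traits.
#' @param pleio_frac fraction of X instruments given horizontal pleiotropy
#'   on M1.
#' @param pleio_sd standard deviation of the horizontal-pleiotropy effects.
#' @param outlier_frac fraction of X instruments planted as outliers on Y.
#' @param outlier_mult residual inflation multiplier for planted outliers.
#' @param seed default seed used when a generator is not given one.
#' @return A `sim_config` list.
#' @export
sim_config <- function(m_snps = 5000L, n_blocks = 50L,
                       block_rho = seq(0.1, 0.9, length.out = n_blocks),
                       h2_1 = 0.3, h2_2 = 0.3, rg_true = 0.5,
                       n1 = 50000L, n2 = 50000L,
                       n_overlap = 0L, rho_pheno = 0,
                       fm_corr = -0.6,
                       theta_xm1 = 0.09, theta_m1m2 = 0.11,
                       theta_m2y = 0.10, theta_xy = 0, theta_xm2 = 0,
                       n_inst_x = 100L, n_inst_m1 = 100L, n_inst_m2 = 60L,
                       n_x = 264498L, n_m1 = 329345L, n_m2 = 69360L,
                       n_y = 266081L,
                       pleio_frac = 0, pleio_sd = 0.02,
                       outlier_frac = 0, outlier_mult = 10,
                       seed = 1L) {
  stopifnot(
    m_snps >= n_blocks, n_blocks >= 1,
    all(block_rho >= 0), all(block_rho < 1),
    h2_1 >= 0, h2_1 <= 1, h2_2 >= 0, h2_2 <= 1,
    all(abs(rg_true) <= 1), abs(fm_corr) <= 1,
    n_overlap <= min(n1, n2), abs(rho_pheno) <= 1,
    pleio_frac >= 0, pleio_frac <= 1, outlier_frac >= 0, outlier_frac <= 1
  )
  cfg <- as.list(environment())
  for (nm in c("n1", "n2", "n_overlap", "n_x", "n_m1", "n_m2", "n_y")) {
    cfg[[nm]] <- as.numeric(cfg[[nm]]) # avoid integer overflow in products
  }
  structure(cfg, class = "sim_config")
}

# Run code with a temporary RNG state; global .Random.seed is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate a block-structured LD reference
#'
#' Builds `n_blocks` disjoint LD blocks with AR(1) within-block SNP
#' correlations `R[j, k] = block_rho^|j - k|` and zero correlation across
#' blocks.  Blocks are assigned round-robin to 22 pseudo-chromosomes so
#' per-chromosome analyses are exercisable.  LD scores
#' `l_j = sum_k R[j, k]^2` (self included, so `l_j >= 1`) are precomputed.
#'
#' @param m_snps total SNPs; the remainder of `m_snps / n_blocks` is
#'   absorbed by the final block.
#' @param n_blocks number of blocks.
#' @param block_rho AR(1) parameter(s) in `[0, 1)`, recycled over blocks.
#' @param seed RNG seed (positions are jittered deterministically).
#' @return An `ld_reference` list: `blocks` (each with `chrom`, `rsid`,
#'   `pos`, `R`) and `ld_scores` (named per-SNP vector).
#' @export
simulate_ld_reference <- function(m_snps, n_blocks, block_rho, seed = 1L) {
  if (any(block_rho >= 1) || any(block_rho < 0)) stop("block_rho must be in [0, 1)")
  rho <- rep_len(block_rho, n_blocks)
  base <- m_snps %/% n_blocks
  sizes <- rep(base, n_blocks)
  sizes[n_blocks] <- sizes[n_blocks] + m_snps %% n_blocks
  chroms <- rep_len(1:22, n_blocks)

  with_seed(seed, {
    blocks <- vector("list", n_blocks)
    idx0 <- 0L
    pos_next <- stats::setNames(rep(1e6, 22), 1:22)
    for (b in seq_len(n_blocks)) {
      m <- sizes[b]
      ii <- abs(outer(seq_len(m), seq_len(m), "-"))
      R <- rho[b]^ii
      chrom <- chroms[b]
      pos <- as.integer(round(pos_next[chrom] + cumsum(stats::runif(m, 5e3, 2e4))))
      pos_next[chrom] <- max(pos) + 1e6
      rsid <- paste0("rs", idx0 + seq_len(m))
      blocks[[b]] <- list(chrom = chrom, rsid = rsid, pos = pos, R = R)
      idx0 <- idx0 + m
    }
    ld_scores <- unlist(lapply(blocks, function(bl) {
      stats::setNames(rowSums(bl$R^2), bl$rsid)
    }))
    structure(list(blocks = blocks, ld_scores = ld_scores, m_snps = m_snps),
              class = "ld_reference")
  })
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("LD reference: %d SNPs in %d blocks, mean LD score %.3f\n",
              x$m_snps, length(x$blocks), mean(x$ld_scores)))
  invisible(x)
}

# SNP table (rsid, chrom, pos, block, index-in-block) of an ld_reference
ld_snp_table <- function(ld) {
  do.call(rbind, lapply(seq_along(ld$blocks), function(b) {
    bl <- ld$blocks[[b]]
    data.frame(rsid = bl$rsid, chrom = bl$chrom, pos = bl$pos,
               block = b, k = seq_along(bl$rsid), stringsAsFactors = FALSE)
  }))
}

# Observed Z for two traits given true standardized effects B (m x 2):
# z_t = sqrt(n_t) R b_t + chol(R)' eta_t, with cross-trait noise
# correlation rho_ov within each SNP.  Returns an m x 2 matrix.
sim_z_from_effects <- function(ld, B, n1, n2, rho_ov = 0) {
  m <- ld$m_snps
  Z <- matrix(NA_real_, m, 2)
  idx0 <- 0L
  for (bl in ld$blocks) {
    mb <- nrow(bl$R)
    L <- chol(bl$R) # upper triangular: t(L) %*% L = R
    rows <- idx0 + seq_len(mb)
    e1 <- stats::rnorm(mb)
    e2 <- rho_ov * e1 + sqrt(1 - rho_ov^2) * stats::rnorm(mb)
    Z[rows, 1] <- sqrt(n1) * (bl$R %*% B[rows, 1]) + t(L) %*% e1
    Z[rows, 2] <- sqrt(n2) * (bl$R %*% B[rows, 2]) + t(L) %*% e2
    idx0 <- idx0 + mb
  }
  Z
}

# Dress a Z vector as a sumstats object on the per-allele scale
z_to_sumstats <- function(z, snp_tab, n, eaf, label, type = "quantitative") {
  scale <- 1 / sqrt(2 * eaf * (1 - eaf)) # standardized -> per-allele
  se <- scale / sqrt(n)
  alleles <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"), ncol = 2)
  pick <- 1 + (seq_along(z) %% 4)
  sumstats(data.frame(
    rsid = snp_tab$rsid, chrom = snp_tab$chrom, pos = snp_tab$pos,
    a1 = alleles[pick, 1], a2 = alleles[pick, 2],
    beta = z * se, se = se, n = n, z = z, eaf = eaf,
    stringsAsFactors = FALSE
  ), trait_label = label, trait_type = type)
}

#' Simulate a pair of polygenic GWAS summary-statistics sets
#'
#' Draws per-SNP standardized true effects (b1, b2) jointly normal with
#' `var(b_t) = h2_t / M` and `cov = rg_true * sqrt(h2_1 h2_2) / M`, then
#' generates observed Z statistics under block LD so that the LD score
#' regression moment model holds exactly:
#' `E[z1 z2] = sqrt(n1 n2) * rho_g * l_j / M + rho * n_overlap / sqrt(n1 n2)`.
#' Within-block noise is correlated according to R; across traits the noise
#' shares the sample-overlap correlation.  Betas and standard errors are
#' reported on the per-allele scale using simulated allele frequencies.
#'
#' `rg_true` may be a vector over the 22 pseudo-chromosomes to plant
#' chromosome-specific genetic correlation.
#'
#' @param ld [simulate_ld_reference()] output.
#' @param cfg [sim_config()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return List of two [sumstats] objects (`trait1`, `trait2`) plus
#'   `true_effects` (m x 2 matrix of standardized effects).
#' @export
simulate_paired_sumstats <- function(ld, cfg, seed = cfg$seed) {
  m <- ld$m_snps
  snp_tab <- ld_snp_table(ld)
  rg_chr <- rep_len(cfg$rg_true, 22)
  with_seed(seed, {
    rg_snp <- rg_chr[snp_tab$chrom]
    s1 <- sqrt(cfg$h2_1 / m)
    s2 <- sqrt(cfg$h2_2 / m)
    b1 <- stats::rnorm(m, 0, s1)
    b2 <- rg_snp * (s2 / s1) * b1 +
      sqrt(pmax(0, 1 - rg_snp^2)) * stats::rnorm(m, 0, s2)
    if (cfg$h2_1 == 0) { # degenerate: independent draw for trait 2
      b1 <- rep(0, m)
      b2 <- stats::rnorm(m, 0, s2)
    }
    B <- cbind(b1, b2)
    rho_ov <- cfg$rho_pheno * cfg$n_overlap / sqrt(cfg$n1 * cfg$n2)
    Z <- sim_z_from_effects(ld, B, cfg$n1, cfg$n2, rho_ov)
    eaf <- stats::runif(m, 0.05, 0.95)
    list(
      trait1 = z_to_sumstats(Z[, 1], snp_tab, cfg$n1, eaf, "trait1"),
      trait2 = z_to_sumstats(Z[, 2], snp_tab, cfg$n2, eaf, "trait2"),
      true_effects = B
    )
  })
}

#' Simulate fetal- and maternal-specific summary statistics
#'
#' Emits two summary-statistics sets for the same physical SNPs whose true
#' standardized effects are bivariate normal with correlation
#' `cfg$fm_corr`, emulating pre-decomposed fetal- and maternal-specific
#' components of a single trait (the decomposition itself is consumed as
#' given, not performed).
#'
#' @inheritParams simulate_paired_sumstats
#' @return List of two [sumstats] objects (`fetal`, `maternal`) plus
#'   `true_effects`.
#' @export
simulate_fetal_maternal <- function(ld, cfg, seed = cfg$seed) {
  m <- ld$m_snps
  snp_tab <- ld_snp_table(ld)
  with_seed(seed, {
    s1 <- sqrt(cfg$h2_1 / m)
    s2 <- sqrt(cfg$h2_2 / m)
    bf <- stats::rnorm(m, 0, s1)
    bm <- cfg$fm_corr * (s2 / s1) * bf +
      sqrt(max(0, 1 - cfg$fm_corr^2)) * stats::rnorm(m, 0, s2)
    B <- cbind(bf, bm)
    Z <- sim_z_from_effects(ld, B, cfg$n1, cfg$n2, 0)
    eaf <- stats::runif(m, 0.05, 0.95)
    list(
      fetal = z_to_sumstats(Z[, 1], snp_tab, cfg$n1, eaf, "fetal_specific"),
      maternal = z_to_sumstats(Z[, 2], snp_tab, cfg$n2, eaf, "maternal_specific"),
      true_effects = B
    )
  })
}

#' Plant pleiotropic genes into an annotation
#'
#' Assigns each gene one of the four joint hypothesis states — H00 (null
#' for both traits), H01 (null for trait 1 only), H10 (null for trait 2
#' only), H11 (associated with both, i.e. pleiotropic) — and draws true
#' standardized SNP effects accordingly.  SNPs of H11 genes carry bivariate
#' effects whose correlation has the requested sign; truth labels are
#' returned for calibration experiments.
#'
#' @param gene_map named list of per-gene rsID vectors (see
#'   [map_genes_to_snps()]).
#' @param ld LD reference covering the SNPs.
#' @param frac_shared fraction of genes planted as H11.
#' @param effect_corr_sign `+1` or `-1`: sign of the within-gene effect
#'   correlation of H11 genes.
#' @param frac_only1,frac_only2 fractions planted as H10 / H01.
#' @param effect_sd standardized per-SNP effect size in non-null genes.
#' @param effect_corr magnitude of the within-gene effect correlation.
#' @param seed RNG seed.
#' @return List: `truth` (data.frame gene_id, state), `effects` (m x 2
#'   matrix of true standardized effects aligned with the LD reference).
#' @export
plant_pleiotropic_genes <- function(gene_map, ld, frac_shared,
                                    effect_corr_sign = +1,
                                    frac_only1 = 0, frac_only2 = 0,
                                    effect_sd = 0.015, effect_corr = 0.8,
                                    seed = 1L) {
  stopifnot(frac_shared >= 0, frac_shared + frac_only1 + frac_only2 <= 1)
  genes <- names(gene_map)
  G <- length(genes)
  snp_tab <- ld_snp_table(ld)
  with_seed(seed, {
    states <- rep("H00", G)
    lab <- sample(G)
    n11 <- round(frac_shared * G)
    n10 <- round(frac_only1 * G)
    n01 <- round(frac_only2 * G)
    states[lab[seq_len(n11)]] <- "H11"
    if (n10 > 0) states[lab[n11 + seq_len(n10)]] <- "H10"
    if (n01 > 0) states[lab[n11 + n10 + seq_len(n01)]] <- "H01"
    rho <- sign(effect_corr_sign) * abs(effect_corr)
    B <- matrix(0, ld$m_snps, 2)
    for (g in seq_len(G)) {
      if (states[g] == "H00") next
      rows <- match(gene_map[[g]], snp_tab$rsid)
      rows <- rows[!is.na(rows)]
      k <- length(rows)
      if (k == 0L) next
      if (states[g] == "H11") {
        e1 <- stats::rnorm(k, 0, effect_sd)
        e2 <- rho * e1 + sqrt(1 - rho^2) * stats::rnorm(k, 0, effect_sd)
        B[rows, 1] <- B[rows, 1] + e1
        B[rows, 2] <- B[rows, 2] + e2
      } else if (states[g] == "H10") {
        B[rows, 1] <- B[rows, 1] + stats::rnorm(k, 0, effect_sd)
      } else {
        B[rows, 2] <- B[rows, 2] + stats::rnorm(k, 0, effect_sd)
      }
    }
    list(truth = data.frame(gene_id = genes, state = states,
                            stringsAsFactors = FALSE),
         effects = B)
  })
}

#' Simulate summary statistics for a pair of traits with planted effects
#'
#' Companion to [plant_pleiotropic_genes()]: turns a matrix of true
#' standardized effects into observed paired summary statistics under the
#' LD reference, using the same observation model as
#' [simulate_paired_sumstats()].
#'
#' @param ld LD reference.
#' @param effects m x 2 matrix of true standardized effects.
#' @param cfg [sim_config()] (sample sizes and overlap are used).
#' @param seed RNG seed.
#' @return List of two [sumstats] objects.
#' @export
simulate_sumstats_from_effects <- function(ld, effects, cfg, seed = cfg$seed) {
  snp_tab <- ld_snp_table(ld)
  with_seed(seed, {
    rho_ov <- cfg$rho_pheno * cfg$n_overlap / sqrt(cfg$n1 * cfg$n2)
    Z <- sim_z_from_effects(ld, effects, cfg$n1, cfg$n2, rho_ov)
    eaf <- stats::runif(ld$m_snps, 0.05, 0.95)
    list(trait1 = z_to_sumstats(Z[, 1], snp_tab, cfg$n1, eaf, "trait1"),
         trait2 = z_to_sumstats(Z[, 2], snp_tab, cfg$n2, eaf, "trait2"))
  })
}

#' Simulate paired gene-level p-values under a planted joint composition
#'
#' Direct p-value-level generator for calibrating the composite-null
#' pleiotropy test: each gene's joint state is drawn from
#' `(pi00, pi01, pi10, pi11)`; null-component p-values are uniform, signal
#' components come from a one-sided normal shift of size `mu`.
#'
#' @param G number of genes.
#' @param pi length-4 vector `(pi00, pi01, pi10, pi11)` summing to 1.
#' @param mu1,mu2 mean shift of the signal z-scores for trait 1 / trait 2.
#' @param seed RNG seed.
#' @return List: `p1`, `p2` (p-value vectors), `state` (per-gene labels).
#' @export
simulate_gene_pvalue_pairs <- function(G, pi = c(0.85, 0.07, 0.07, 0.01),
                                       mu1 = 3.5, mu2 = 3.5, seed = 1L) {
  stopifnot(length(pi) == 4, abs(sum(pi) - 1) < 1e-9, all(pi >= 0))
  with_seed(seed, {
    state <- sample(c("H00", "H01", "H10", "H11"), G, TRUE, prob = pi)
    sig1 <- state %in% c("H10", "H11") # trait 1 non-null
    sig2 <- state %in% c("H01", "H11")
    p1 <- stats::runif(G)
    p2 <- stats::runif(G)
    p1[sig1] <- stats::pnorm(stats::rnorm(sum(sig1), mu1), lower.tail = FALSE)
    p2[sig2] <- stats::pnorm(stats::rnorm(sum(sig2), mu2), lower.tail = FALSE)
    list(p1 = pmax(p1, .Machine$double.xmin),
         p2 = pmax(p2, .Machine$double.xmin), state = state)
  })
}

#' Simulate an instrument-level causal chain X -> M1 -> M2 -> Y
#'
#' Generates per-instrument true effects under the structural model
#' `b_M1 = theta_xm1 * b_X + gamma`, `b_M2 = theta_m1m2 * b_M1 +
#' theta_xm2 * b_X + direct_M2`, `b_Y = theta_m2y * b_M2 + theta_xy * b_X`
#' (log-odds scale for Y), where each SNP has a direct effect on exactly
#' one of X, M1 or M2 and `gamma` is optional horizontal pleiotropy on a
#' random fraction of X instruments.  Observed effects add independent
#' normal noise with standard errors `1/sqrt(n_trait)`; optional outlier
#' instruments get their observed Y effect inflated by `outlier_mult`
#' residual standard deviations.
#'
#' @param cfg [sim_config()].
#' @param seed RNG seed.
#' @return List of four [sumstats] objects (`X`, `M1`, `M2`, `Y`) over the
#'   same instruments, plus `truth`: data.frame of true effects, the SNP's
#'   direct trait, pleiotropy flags and outlier flags.
#' @export
simulate_causal_chain <- function(cfg, seed = cfg$seed) {
  jx <- cfg$n_inst_x; jm1 <- cfg$n_inst_m1; jm2 <- cfg$n_inst_m2
  J <- jx + jm1 + jm2
  with_seed(seed, {
    direct <- rep(c("X", "M1", "M2"), c(jx, jm1, jm2))
    mag <- stats::runif(J, 0.02, 0.06) * sample(c(-1, 1), J, TRUE)
    bX <- ifelse(direct == "X", mag, 0)
    gamma <- rep(0, J)
    if (cfg$pleio_frac > 0) {
      k <- which(direct == "X")
      pl <- sample(k, round(cfg$pleio_frac * length(k)))
      gamma[pl] <- stats::rnorm(length(pl), 0, cfg$pleio_sd)
    }
    bM1 <- cfg$theta_xm1 * bX + ifelse(direct == "M1", mag, 0) + gamma
    bM2 <- cfg$theta_m1m2 * bM1 + cfg$theta_xm2 * bX +
      ifelse(direct == "M2", mag, 0)
    bY <- cfg$theta_m2y * bM2 + cfg$theta_xy * bX

    se_x <- rep(1 / sqrt(cfg$n_x), J)
    se_m1 <- rep(1 / sqrt(cfg$n_m1), J)
    se_m2 <- rep(1 / sqrt(cfg$n_m2), J)
    se_y <- rep(1 / sqrt(cfg$n_y), J)
    ox <- bX + stats::rnorm(J, 0, se_x)
    om1 <- bM1 + stats::rnorm(J, 0, se_m1)
    om2 <- bM2 + stats::rnorm(J, 0, se_m2)
    oy <- bY + stats::rnorm(J, 0, se_y)

    outlier <- rep(FALSE, J)
    if (cfg$outlier_frac > 0) {
      k <- which(direct == "X")
      ol <- sample(k, max(1, round(cfg$outlier_frac * length(k))))
      outlier[ol] <- TRUE
      oy[ol] <- oy[ol] + cfg$outlier_mult * se_y[ol] * sample(c(-1, 1), length(ol), TRUE)
    }

    tab <- data.frame(
      rsid = paste0("rs", 90000000 + seq_len(J)),
      chrom = rep_len(1:22, J),
      pos = 1e6 + 1e4 * seq_len(J),
      a1 = "A", a2 = "G", stringsAsFactors = FALSE
    )
    mk <- function(beta, se, n, label, type = "quantitative") {
      sumstats(cbind(tab, data.frame(beta = beta, se = se, n = n)),
               trait_label = label, trait_type = type)
    }
    list(
      X = mk(ox, se_x, cfg$n_x, "birthweight"),
      M1 = mk(om1, se_m1, cfg$n_m1, "age_at_menarche"),
      M2 = mk(om2, se_m2, cfg$n_m2, "age_at_menopause"),
      Y = mk(oy, se_y, cfg$n_y, "breast_cancer", "binary"),
      truth = data.frame(rsid = tab$rsid, direct = direct,
                         b_x = bX, b_m1 = bM1, b_m2 = bM2, b_y = bY,
                         gamma = gamma, outlier = outlier,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Simulate a synthetic birthweight instrument table
#'
#' Builds a synthetic stand-in for a published fetal/maternal birthweight
#' instrument list: per-SNP fetal-specific and maternal-specific effects
#' whose significance patterns realize a requested class composition
#' (fetal-effect-only, maternal-effect-only, both with the same effect
#' direction, both with opposite directions, and unclassified SNPs that
#' reach significance for neither component).  The default composition
#' (63 / 31 / 26 / 15 / 71) mirrors the published instrument bookkeeping;
#' the table itself is entirely simulated — no real instrument data are
#' included.
#'
#' @param n_fetal_only,n_maternal_only,n_both_same,n_both_opposite,n_unclassified
#'   class sizes.
#' @param sig_thresh significance threshold the classes are planted
#'   against.
#' @param n_fetal,n_maternal GWAS sample sizes (set the standard errors).
#' @param seed RNG seed.
#' @return List of two [sumstats] objects (`fetal`, `maternal`) over the
#'   same SNPs, plus `truth` (the planted class per SNP).
#' @export
simulate_instrument_table <- function(n_fetal_only = 63L, n_maternal_only = 31L,
                                      n_both_same = 26L, n_both_opposite = 15L,
                                      n_unclassified = 71L,
                                      sig_thresh = 0.05,
                                      n_fetal = 264498L, n_maternal = 179360L,
                                      seed = 1L) {
  classes <- rep(
    c("fetal_specific", "maternal_specific", "both_same_direction",
      "both_opposite_direction", "unclassified"),
    c(n_fetal_only, n_maternal_only, n_both_same, n_both_opposite, n_unclassified)
  )
  J <- length(classes)
  se_f <- 1 / sqrt(n_fetal)
  se_m <- 1 / sqrt(n_maternal)
  z_sig <- stats::qnorm(sig_thresh / 2, lower.tail = FALSE)
  with_seed(seed, {
    # strongly significant vs clearly null z-scores per planted class
    z_hi <- function(k) (z_sig + 4 + abs(stats::rnorm(k)))
    z_lo <- function(k) stats::runif(k, -z_sig * 0.8, z_sig * 0.8)
    sgn <- sample(c(-1, 1), J, TRUE)
    zf <- zm <- numeric(J)
    for (cl in unique(classes)) {
      i <- which(classes == cl)
      k <- length(i)
      switch(cl,
        fetal_specific = { zf[i] <- sgn[i] * z_hi(k); zm[i] <- z_lo(k) },
        maternal_specific = { zm[i] <- sgn[i] * z_hi(k); zf[i] <- z_lo(k) },
        both_same_direction = { zf[i] <- sgn[i] * z_hi(k); zm[i] <- sgn[i] * z_hi(k) },
        both_opposite_direction = { zf[i] <- sgn[i] * z_hi(k); zm[i] <- -sgn[i] * z_hi(k) },
        unclassified = { zf[i] <- z_lo(k); zm[i] <- z_lo(k) }
      )
    }
    tab <- data.frame(
      rsid = paste0("rs", 80000000 + seq_len(J)),
      chrom = rep_len(1:22, J), pos = 2e6 + 5e4 * seq_len(J),
      a1 = "A", a2 = "G", stringsAsFactors = FALSE
    )
    list(
      fetal = sumstats(cbind(tab, data.frame(beta = zf * se_f, se = se_f, n = n_fetal)),
                       trait_label = "fetal_specific_birthweight"),
      maternal = sumstats(cbind(tab, data.frame(beta = zm * se_m, se = se_m, n = n_maternal)),
                          trait_label = "maternal_specific_birthweight"),
      truth = data.frame(rsid = tab$rsid, class = classes, stringsAsFactors = FALSE)
    )
  })
}
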