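#' Per-SNP LD scores of an LD reference
#'
#' `l_j = sum_k r2(j, k)` over SNP j's block, self-correlation included, so
#' `l_j >= 1` for every SNP that appears in its own score.
#'
#' @param ld `ld_reference` object.
#' @return Named numeric vector of LD scores.
#' @export
compute_ld_scores <- function(ld) {
  unlist(lapply(ld$blocks, function(bl) {
    stats::setNames(rowSums(bl$R^2), bl$rsid)
  }))
}

# Weighted regression y ~ 1 + x with per-jackknife-block sufficient
# statistics, so delete-one-block coefficient refits are O(1) each.
# Returns full-fit coefficients and a B x 2 matrix of deleted coefficients.
wls_blocks <- function(x, y, w, block_id) {
  X1 <- w; Xx <- w * x; Xxx <- w * x^2
  Xy <- w * y; Xxy <- w * x * y
  tot <- c(sum(X1), sum(Xx), sum(Xxx), sum(Xy), sum(Xxy))
  per <- cbind(
    rowsum(X1, block_id), rowsum(Xx, block_id), rowsum(Xxx, block_id),
    rowsum(Xy, block_id), rowsum(Xxy, block_id)
  )
  solve2 <- function(s) {
    # s = (Sw, Swx, Swxx, Swy, Swxy); solve 2x2 normal equations
    det <- s[1] * s[3] - s[2]^2
    a <- (s[3] * s[4] - s[2] * s[5]) / det # intercept
    b <- (s[1] * s[5] - s[2] * s[4]) / det # slope
    c(a, b)
  }
  full <- solve2(tot)
  del <- t(apply(per, 1, function(p) solve2(tot - p)))
  list(intercept = full[1], slope = full[2],
       del_intercept = del[, 1], del_slope = del[, 2])
}

# contiguous jackknife block labels for m SNPs
jackknife_blocks <- function(m, n_blocks) {
  n_blocks <- max(2L, min(n_blocks, m %/% 2L))
  sort(rep_len(seq_len(n_blocks), m))
}

# default number of jackknife blocks: 200, reduced for small panels
default_n_blocks <- function(m) max(2L, min(200L, m %/% 50L))

jackknife_se <- function(theta_del) {
  B <- length(theta_del)
  sqrt((B - 1) / B * sum((theta_del - mean(theta_del))^2))
}

#' Univariate LD score regression for SNP heritability
#'
#' Weighted regression of the squared Z statistics on `l_j * n / M` with a
#' free intercept; the slope estimates the SNP heritability and the
#' intercept absorbs confounding inflation.  The default two-step
#' weighting runs a first pass with `1 / l_j` (LD redundancy) and a second
#' pass that also downweights by the squared conditional variance of `z^2`
#' implied by the first-pass fit, `2 (int + n h2 l / M)^2` — without the
#' variance term, heavy-tailed high-LD SNPs dominate and the test
#' statistic is miscalibrated.  Standard errors come from a
#' delete-one-block jackknife over contiguous SNP blocks.
#'
#' @param s [sumstats] object after QC and region exclusion.
#' @param ell per-SNP LD scores aligned with `s` (named vector; matched by
#'   rsid when names are present).
#' @param n_blocks jackknife blocks; default 200, reduced to `M / 50` for
#'   small panels.  For block-simulated panels, choose at most the number
#'   of LD blocks so resampling units are independent.
#' @param M denominator SNP count; defaults to the number of regression
#'   SNPs.
#' @param weights `"two_step"` (default) or `"ld_only"` (single pass,
#'   weights `1 / l_j`).
#' @return List: `h2`, `se`, `intercept`, `intercept_se`, `n_snps`,
#'   `n_blocks`.
#' @export
ldsc_h2 <- function(s, ell, n_blocks = NULL, M = NULL,
                    weights = c("two_step", "ld_only")) {
  weights <- match.arg(weights)
  ell <- align_ld_scores(ell, s$rsid)
  m <- nrow(s)
  if (is.null(M)) M <- m
  if (is.null(n_blocks)) n_blocks <- default_n_blocks(m)
  if (m < 2 * n_blocks) stop("ldsc_h2: fewer than 2 SNPs per jackknife block")
  n <- stats::median(s$n)
  x <- ell * n / M
  w <- 1 / pmax(ell, 1)
  bid <- jackknife_blocks(m, n_blocks)
  fit <- wls_blocks(x, s$z^2, w, bid)
  if (weights == "two_step") {
    v <- pmax(fit$intercept, 0.5) + pmax(fit$slope, 0) * x
    fit <- wls_blocks(x, s$z^2, w / (2 * v^2), bid)
  }
  list(h2 = fit$slope, se = jackknife_se(fit$del_slope),
       intercept = fit$intercept,
       intercept_se = jackknife_se(fit$del_intercept),
       n_snps = m, n_blocks = max(bid))
}

#' Cross-trait LD score regression for genetic correlation
#'
#' Regresses the product of the two traits' Z statistics on
#' `l_j * sqrt(n1 n2) / M` with a free intercept (which absorbs sample
#' overlap), alongside the two univariate regressions, and reports the
#' genetic correlation `rg = gencov / sqrt(h2_1 * h2_2)`.  The standard
#' error of `rg` comes from delete-one-block jackknife refits of the full
#' ratio (all three regressions re-solved per deleted block); the p-value
#' is two-sided normal on `rg / se`.
#'
#' All three regressions use the two-step weights of [ldsc_h2()] by
#' default; the bivariate second-pass weight is
#' `1 / (l * (v1 v2 + cov^2))` with `v1`, `v2`, `cov` the first-pass
#' conditional moments of the two z scores and their product.
#'
#' The two summary-statistics sets must be harmonized to identical SNPs in
#' identical order (see [harmonize_pair()]).
#'
#' @param s1,s2 harmonized [sumstats] objects.
#' @param ell per-SNP LD scores aligned with the shared SNPs.
#' @param n_blocks jackknife blocks.
#' @param M denominator SNP count (default: regression SNP count).
#' @return An `ldsc_fit` list: `h2_1`, `h2_2`, `gencov`, `rg` (raw),
#'   `rg_reported` (clipped to `[-1, 1]`), `se_rg`, `pval_rg`,
#'   `intercept_biv`, `intercept_1`, `intercept_2`, `n_snps_used`,
#'   `n_blocks`, `flag` (NA or a reason the correlation is undefined).
#' @export
ldsc_rg <- function(s1, s2, ell, n_blocks = NULL, M = NULL,
                    weights = c("two_step", "ld_only")) {
  weights <- match.arg(weights)
  if (nrow(s1) != nrow(s2) || !all(s1$rsid == s2$rsid)) {
    stop("ldsc_rg: inputs must be harmonized to identical SNPs in identical order")
  }
  ell <- align_ld_scores(ell, s1$rsid)
  m <- nrow(s1)
  if (is.null(M)) M <- m
  if (is.null(n_blocks)) n_blocks <- default_n_blocks(m)
  if (m < 2 * n_blocks) stop("ldsc_rg: fewer than 2 SNPs per jackknife block")
  n1 <- stats::median(s1$n); n2 <- stats::median(s2$n)
  w <- 1 / pmax(ell, 1)
  bid <- jackknife_blocks(m, n_blocks)

  x1 <- ell * n1 / M; x2 <- ell * n2 / M; xc <- ell * sqrt(n1 * n2) / M
  f1 <- wls_blocks(x1, s1$z^2, w, bid)
  f2 <- wls_blocks(x2, s2$z^2, w, bid)
  fc <- wls_blocks(xc, s1$z * s2$z, w, bid)
  if (weights == "two_step") {
    v1 <- pmax(f1$intercept, 0.5) + pmax(f1$slope, 0) * x1
    v2 <- pmax(f2$intercept, 0.5) + pmax(f2$slope, 0) * x2
    # cross-term via the overall z correlation keeps the bivariate weights
    # proportional to the univariate ones when the two traits coincide
    cv <- stats::cor(s1$z, s2$z) * sqrt(v1 * v2)
    f1 <- wls_blocks(x1, s1$z^2, w / (2 * v1^2), bid)
    f2 <- wls_blocks(x2, s2$z^2, w / (2 * v2^2), bid)
    fc <- wls_blocks(xc, s1$z * s2$z, w / (v1 * v2 + cv^2), bid)
  }

  h2_1 <- f1$slope; h2_2 <- f2$slope; gencov <- fc$slope
  flag <- NA_character_
  if (h2_1 <= 0 || h2_2 <= 0) {
    flag <- "nonpositive heritability estimate; rg undefined"
    rg <- NA_real_; se_rg <- NA_real_; pval <- NA_real_
  } else {
    rg <- gencov / sqrt(h2_1 * h2_2)
    denom <- sqrt(pmax(f1$del_slope * f2$del_slope, 1e-12))
    rg_del <- fc$del_slope / denom
    se_rg <- jackknife_se(rg_del)
    pval <- 2 * stats::pnorm(-abs(rg / se_rg))
  }
  structure(list(
    h2_1 = h2_1, h2_2 = h2_2, gencov = gencov,
    rg = rg, rg_reported = if (is.na(rg)) NA_real_ else max(-1, min(1, rg)),
    se_rg = se_rg, pval_rg = pval,
    intercept_biv = fc$intercept, intercept_biv_se = jackknife_se(fc$del_intercept),
    intercept_1 = f1$intercept, intercept_2 = f2$intercept,
    n_snps_used = m, n_blocks = max(bid), flag = flag
  ), class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat(sprintf("LD score regression (%d SNPs, %d jackknife blocks)\n",
              x$n_snps_used, x$n_blocks))
  cat(sprintf("  h2 trait1 = %.4f, h2 trait2 = %.4f, gencov = %.4f\n",
              x$h2_1, x$h2_2, x$gencov))
  if (is.na(x$rg)) {
    cat("  rg undefined:", x$flag, "\n")
  } else {
    cat(sprintf("  rg = %.4f (se %.4f, P = %.3g); bivariate intercept %.4f\n",
                x$rg, x$se_rg, x$pval_rg, x$intercept_biv))
  }
  invisible(x)
}

#' Per-chromosome genetic correlation
#'
#' Applies [ldsc_rg()] within each chromosome and reports the estimate with
#' a 95% confidence interval `rg +/- 1.96 se`.  Chromosomes with fewer than
#' `2 * n_blocks_chrom` SNPs (blocks reduced per chromosome) are skipped
#' with a warning.
#'
#' @inheritParams ldsc_rg
#' @return data.frame: chrom, n_snps, rg, se, ci_lo, ci_hi, pval.
#' @export
ldsc_rg_by_chromosome <- function(s1, s2, ell, n_blocks = NULL,
                                  weights = "two_step") {
  ell <- align_ld_scores(ell, s1$rsid)
  out <- lapply(sort(unique(s1$chrom)), function(ch) {
    i <- which(s1$chrom == ch)
    nb <- default_n_blocks(length(i))
    if (!is.null(n_blocks)) nb <- min(n_blocks, nb)
    if (length(i) < 2 * nb || nb < 2) {
      warning("ldsc_rg_by_chromosome: chromosome ", ch, " skipped (too few SNPs)")
      return(NULL)
    }
    fit <- ldsc_rg(s1[i, ], s2[i, ], ell[i], n_blocks = nb, weights = weights)
    data.frame(chrom = ch, n_snps = length(i), rg = fit$rg, se = fit$se_rg,
               ci_lo = fit$rg - 1.96 * fit$se_rg,
               ci_hi = fit$rg + 1.96 * fit$se_rg, pval = fit$pval_rg)
  })
  do.call(rbind, out)
}

align_ld_scores <- function(ell, rsids) {
  if (!is.null(names(ell))) {
    miss <- !(rsids %in% names(ell))
    if (any(miss)) stop("LD scores missing for ", sum(miss), " SNP(s)")
    ell <- unname(ell[rsids])
  } else if (length(ell) != length(rsids)) {
    stop("unnamed LD score vector must match the SNP count")
  }
  as.numeric(ell)
}
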