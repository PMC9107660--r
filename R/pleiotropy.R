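#' Estimate the composite-null mixture proportions
#'
#' For paired gene p-values, estimates the proportions of the four joint
#' hypothesis states — H00 (both traits null), H01 (first null only), H10
#' (second null only), H11 (both non-null) — needed to calibrate the
#' intersection-union pleiotropy test.  Marginal null proportions are
#' estimated by the Storey counting estimator
#' `pi0(lambda) = #{p > lambda} / ((1 - lambda) G)` smoothed over a lambda
#' grid with a cubic smoothing spline (evaluated at the top of the grid;
#' falls back to the raw estimate at `lambda = 0.5` when smoothing is not
#' possible), and the joint composition follows by the product
#' decomposition `pi00 = pi0(1) pi0(2)`, etc., clipped and renormalized.
#'
#' @param p1,p2 equal-length p-value vectors in `(0, 1]`.
#' @param lambda_grid Storey grid (default 0.05 to 0.95 by 0.05).
#' @return A `null_composition` list: `pi00`, `pi01`, `pi10`, `pi11`,
#'   `pi0_marginal` (the two marginal estimates).
#' @export
estimate_null_proportions <- function(p1, p2,
                                      lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  check_pvals(p1); check_pvals(p2)
  if (length(p1) != length(p2)) stop("p1 and p2 must have equal length")
  if (length(p1) < 100) warning("fewer than 100 genes; null-proportion estimates are noisy")
  pi0_1 <- storey_pi0(p1, lambda_grid)
  pi0_2 <- storey_pi0(p2, lambda_grid)
  pi00 <- pi0_1 * pi0_2
  pi01 <- pi0_1 * (1 - pi0_2)
  pi10 <- (1 - pi0_1) * pi0_2
  pi11 <- max(0, 1 - pi00 - pi01 - pi10)
  pis <- pmin(pmax(c(pi00, pi01, pi10, pi11), 0), 1)
  pis <- pis / sum(pis)
  structure(list(pi00 = pis[1], pi01 = pis[2], pi10 = pis[3], pi11 = pis[4],
                 pi0_marginal = c(pi0_1, pi0_2)),
            class = "null_composition")
}

storey_pi0 <- function(p, lambda_grid) {
  G <- length(p)
  raw <- vapply(lambda_grid, function(l) sum(p > l) / ((1 - l) * G), 0)
  est <- tryCatch({
    fit <- stats::smooth.spline(lambda_grid, raw, df = 3)
    stats::predict(fit, x = max(lambda_grid))$y
  }, error = function(e) raw[which.min(abs(lambda_grid - 0.5))])
  min(1, max(est, 1 / G))
}

#' Composite-null intersection-union pleiotropy p-values
#'
#' The test statistic is `t = max(p1, p2)`; the null is the three-component
#' mixture of H00, H01 and H10.  Under H01 or H10 the maximum behaves like
#' the single remaining uniform p-value (CDF t); under H00 it is the
#' maximum of two independent uniforms (CDF t^2).  The mixture-null
#' p-value is therefore
#' `p = ((pi01 + pi10) t + pi00 t^2) / (pi00 + pi01 + pi10)`,
#' monotone in t and never larger than t.
#'
#' @param p1,p2 paired gene p-values.
#' @param composition [estimate_null_proportions()] output (or a list with
#'   pi00, pi01, pi10).
#' @return Numeric vector of composite-null p-values.
#' @export
maiup_test <- function(p1, p2, composition) {
  check_pvals(p1); check_pvals(p2)
  pi00 <- composition$pi00; pi01 <- composition$pi01; pi10 <- composition$pi10
  denom <- pi00 + pi01 + pi10
  if (denom <= 0) stop("maiup_test: null mass pi00 + pi01 + pi10 is zero")
  t <- pmax(p1, p2)
  pmin(1, ((pi01 + pi10) * t + pi00 * t^2) / denom)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate q-values via [stats::p.adjust()]; the
#' default selection rule downstream is `q < 0.05`.
#'
#' @param p p-values in `(0, 1]`.
#' @return q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  check_pvals(p)
  stats::p.adjust(p, method = "BH")
}

#' Local effect-size correlation of a gene between two traits
#'
#' Pearson correlation of the harmonized per-SNP effect sizes of the two
#' traits, restricted to the gene's member SNPs.  Requires at least 3
#' shared SNPs and non-constant effect vectors; otherwise the correlation
#' is undefined (NA) and flagged.
#'
#' @param s1,s2 harmonized [sumstats] objects (identical SNP order).
#' @param snp_ids member rsIDs of the gene.
#' @param min_snps minimum shared SNPs (default 3).
#' @return List: `r` (possibly NA), `n_local_snps`, `flag`.
#' @export
gene_effect_correlation <- function(s1, s2, snp_ids, min_snps = 3L) {
  i <- match(snp_ids, s1$rsid)
  i <- i[!is.na(i)]
  if (length(i) < min_snps) {
    return(list(r = NA_real_, n_local_snps = length(i), flag = "too few shared SNPs"))
  }
  b1 <- s1$beta[i]; b2 <- s2$beta[i]
  if (stats::sd(b1) == 0 || stats::sd(b2) == 0) {
    return(list(r = NA_real_, n_local_snps = length(i), flag = "constant effect vector"))
  }
  list(r = stats::cor(b1, b2), n_local_snps = length(i), flag = NA_character_)
}

#' Pleiotropy scan over paired gene-level results
#'
#' Joins per-gene p-values of the two traits (genomic-control-corrected
#' where available), estimates the null composition, computes
#' composite-null p-values and BH q-values, and annotates each gene with
#' its local effect-size correlation.  Genes absent from either trait's
#' gene-test results are excluded from the pleiotropy universe (logged).
#'
#' @param res1,res2 data.frames from [gene_test_all()] (+
#'   [genomic_control()]).
#' @param s1,s2 harmonized [sumstats] objects (for effect correlations);
#'   optional.
#' @param gene_map named list of per-gene rsIDs (needed when `s1`/`s2`
#'   given).
#' @param fdr selection level (default 0.05).
#' @return data.frame: gene_id, p1, p2, t, p_pleio, q, selected,
#'   effect_corr, n_local_snps; the estimated composition is attached as
#'   attribute `"composition"`.
#' @export
pleiotropy_scan <- function(res1, res2, s1 = NULL, s2 = NULL,
                            gene_map = NULL, fdr = 0.05) {
  shared <- intersect(res1$gene_id, res2$gene_id)
  dropped <- length(union(res1$gene_id, res2$gene_id)) - length(shared)
  if (dropped > 0) message("pleiotropy_scan: ", dropped,
                           " gene(s) absent from one trait excluded")
  p1 <- res1$pval_gc[match(shared, res1$gene_id)]
  p2 <- res2$pval_gc[match(shared, res2$gene_id)]
  comp <- estimate_null_proportions(p1, p2)
  pp <- maiup_test(p1, p2, comp)
  q <- bh_fdr(pp)
  out <- data.frame(
    gene_id = shared, p1 = p1, p2 = p2, t = pmax(p1, p2),
    p_pleio = pp, q = q, selected = q < fdr,
    effect_corr = NA_real_, n_local_snps = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (!is.null(s1) && !is.null(s2) && !is.null(gene_map)) {
    for (i in seq_len(nrow(out))) {
      ec <- gene_effect_correlation(s1, s2, gene_map[[out$gene_id[i]]])
      out$effect_corr[i] <- ec$r
      out$n_local_snps[i] <- ec$n_local_snps
    }
  }
  attr(out, "composition") <- comp
  out
}

#' Compare two sets of pleiotropic genes
#'
#' Intersects two pleiotropy result sets (e.g. the fetal-specific and
#' maternal-specific scans) by gene, correlates their local effect-size
#' correlations on the shared genes, and reports the fraction of selected
#' genes with positive effect correlation in each set.
#'
#' @param set_f,set_m data.frames from [pleiotropy_scan()], typically
#'   restricted to selected genes.
#' @return List: `shared_genes`, `n_shared`, `cross_correlation` (Pearson r
#'   of the two effect_corr vectors on shared genes; NA when < 3),
#'   `pos_fraction` (named length-2 vector).
#' @export
compare_pleiotropic_sets <- function(set_f, set_m) {
  shared <- intersect(set_f$gene_id, set_m$gene_id)
  rf <- set_f$effect_corr[match(shared, set_f$gene_id)]
  rm_ <- set_m$effect_corr[match(shared, set_m$gene_id)]
  ok <- is.finite(rf) & is.finite(rm_)
  cross <- if (sum(ok) >= 3) stats::cor(rf[ok], rm_[ok]) else NA_real_
  posfrac <- c(
    set1 = mean(set_f$effect_corr > 0, na.rm = TRUE),
    set2 = mean(set_m$effect_corr > 0, na.rm = TRUE)
  )
  list(shared_genes = shared, n_shared = length(shared),
       cross_correlation = cross, pos_fraction = posfrac)
}

check_pvals <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  invisible(TRUE)
}
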