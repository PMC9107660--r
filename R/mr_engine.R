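#' Greedy LD clumping of association signals
#'
#' Sorts candidate SNPs (those with `pval <= p_thresh`) by ascending
#' p-value and accepts a SNP iff its LD `r^2` with every already-accepted
#' SNP within `window_bp` on the same chromosome is below `r2_thresh`.
#' SNPs not covered by the LD reference are treated as independent (and
#' counted in a message).
#'
#' @param s [sumstats] object.
#' @param ld `ld_reference` or NULL (all SNPs treated as independent).
#' @param p_thresh p-value threshold for candidates (default 5e-8).
#' @param r2_thresh LD threshold (default 0.001).
#' @param window_bp physical window (default 1 Mb).
#' @return Character vector of accepted (index) rsIDs.
#' @export
clump_instruments <- function(s, ld = NULL, p_thresh = 5e-8,
                              r2_thresh = 0.001, window_bp = 1e6) {
  stopifnot(p_thresh > 0, r2_thresh >= 0, window_bp >= 0)
  cand <- s[s$pval <= p_thresh, , drop = FALSE]
  if (nrow(cand) == 0L) return(character(0))
  cand <- cand[order(cand$pval), , drop = FALSE]

  lookup <- NULL
  if (!is.null(ld)) {
    lookup <- ld_snp_table(ld)
    uncovered <- sum(!(cand$rsid %in% lookup$rsid))
    if (uncovered > 0) {
      message("clump_instruments: ", uncovered,
              " candidate(s) not in the LD reference; treated as independent")
    }
  }
  r2 <- function(id_a, id_b) {
    if (is.null(lookup)) return(0)
    a <- lookup[match(id_a, lookup$rsid), ]
    b <- lookup[match(id_b, lookup$rsid), ]
    if (is.na(a$block) || is.na(b$block) || a$block != b$block) return(0)
    ld$blocks[[a$block]]$R[a$k, b$k]^2
  }
  accepted <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in accepted) {
      if (cand$chrom[i] == cand$chrom[j] &&
          abs(cand$pos[i] - cand$pos[j]) <= window_bp &&
          r2(cand$rsid[i], cand$rsid[j]) >= r2_thresh) {
        ok <- FALSE
        break
      }
    }
    if (ok) accepted <- c(accepted, i)
  }
  cand$rsid[accepted]
}

#' Classify birthweight instruments by fetal/maternal effect pattern
#'
#' For each SNP, compares its fetal-specific and maternal-specific
#' association p-values against `sig_thresh`: significant for the fetal
#' component only gives `fetal_specific` (and symmetrically
#' `maternal_specific`); significant for both gives
#' `both_same_direction` or `both_opposite_direction` by the sign
#' agreement of the two effect estimates; significant for neither gives
#' `unclassified`.  The fetal instrument set is
#' `fetal_specific + both_*`, the maternal set
#' `maternal_specific + both_*`; unclassified SNPs belong to neither.
#'
#' @param fetal,maternal [sumstats] objects of the two decomposed effect
#'   components.
#' @param rsids SNPs to classify.
#' @param sig_thresh per-component significance threshold (default 0.05).
#' @return data.frame (rsid, class) with attributes `fetal_set` and
#'   `maternal_set` (rsID vectors) and `counts` (table of classes).
#' @export
classify_bw_instruments <- function(fetal, maternal, rsids, sig_thresh = 0.05) {
  fi <- match(rsids, fetal$rsid)
  mi <- match(rsids, maternal$rsid)
  cls <- character(length(rsids))
  for (k in seq_along(rsids)) {
    if (is.na(fi[k]) || is.na(mi[k])) {
      warning("classify_bw_instruments: ", rsids[k], " missing from an input")
      cls[k] <- "unclassified"
      next
    }
    fsig <- fetal$pval[fi[k]] < sig_thresh
    msig <- maternal$pval[mi[k]] < sig_thresh
    cls[k] <- if (fsig && !msig) "fetal_specific"
    else if (msig && !fsig) "maternal_specific"
    else if (fsig && msig) {
      if (sign(fetal$beta[fi[k]]) == sign(maternal$beta[mi[k]])) {
        "both_same_direction"
      } else "both_opposite_direction"
    } else "unclassified"
  }
  out <- data.frame(rsid = rsids, class = cls, stringsAsFactors = FALSE)
  both <- cls %in% c("both_same_direction", "both_opposite_direction")
  attr(out, "fetal_set") <- rsids[cls == "fetal_specific" | both]
  attr(out, "maternal_set") <- rsids[cls == "maternal_specific" | both]
  attr(out, "counts") <- table(factor(cls, levels = c(
    "fetal_specific", "maternal_specific", "both_same_direction",
    "both_opposite_direction", "unclassified"
  )))
  out
}

#' Build an instrument table from exposure and outcome summary statistics
#'
#' Harmonizes the pair, restricts to the given instruments, and returns
#' the per-SNP effect table consumed by the MR estimators.
#'
#' @param exposure,outcome [sumstats] objects.
#' @param rsids instrument rsIDs (default: all shared SNPs).
#' @return data.frame: rsid, beta_x, se_x, pval_x, beta_y, se_y, pval_y.
#' @export
make_instruments <- function(exposure, outcome, rsids = NULL) {
  h <- harmonize_pair(exposure, outcome)
  e <- h$exposure; o <- h$outcome
  if (!is.null(rsids)) {
    keep <- e$rsid %in% rsids
    e <- e[keep, , drop = FALSE]
    o <- o[keep, , drop = FALSE]
  }
  if (nrow(e) == 0L) stop("make_instruments: no instruments retained")
  data.frame(rsid = e$rsid, beta_x = e$beta, se_x = e$se, pval_x = e$pval,
             beta_y = o$beta, se_y = o$se, pval_y = o$pval,
             stringsAsFactors = FALSE)
}

mr_result <- function(method, beta, se, pval, n_inst, ...) {
  structure(c(list(method = method, beta = beta, se = se, pval = pval,
                   n_instruments = n_inst), list(...)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR %s: beta = %.4f (se %.4f), P = %.3g, %d instruments\n",
              x$method, x$beta, x$se, x$pval, x$n_instruments))
  invisible(x)
}

#' Inverse-variance weighted MR estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/se_y^2`:
#' `beta = sum(w bx by) / sum(w bx^2)`.  Cochran's Q is reported; under
#' the default multiplicative random-effects model the standard error is
#' inflated by `sqrt(Q / (J - 1))` when that exceeds 1.  A single
#' instrument reduces to the Wald ratio.
#'
#' @param beta_x,se_x exposure effects and standard errors (se_x unused by
#'   the estimator; accepted for interface symmetry).
#' @param beta_y,se_y outcome effects and standard errors.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate` with extras `Q`, `Q_df`, `Q_pval`.
#' @export
ivw <- function(beta_x, beta_y, se_y, se_x = NULL,
                model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  J <- length(beta_x)
  if (all(beta_x == 0)) stop("ivw: all exposure effects are zero")
  w <- 1 / se_y^2
  b <- sum(w * beta_x * beta_y) / sum(w * beta_x^2)
  se_fixed <- sqrt(1 / sum(w * beta_x^2))
  Q <- sum(w * (beta_y - b * beta_x)^2)
  Q_df <- max(J - 1L, 1L)
  se <- se_fixed
  if (model == "multiplicative_random" && J >= 2) {
    se <- se_fixed * sqrt(max(1, Q / Q_df))
  }
  mr_result(if (model == "fixed") "IVW_fixed" else "IVW", b, se,
            2 * stats::pnorm(-abs(b / se)), J,
            Q = Q, Q_df = Q_df,
            Q_pval = stats::pchisq(Q, Q_df, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted regression `beta_y = alpha + beta * beta_x` with weights
#' `1/se_y^2` after re-orienting instruments so every exposure effect is
#' non-negative (signs of beta_x and beta_y flipped jointly).  The slope
#' is the causal estimate; the intercept with its standard error and
#' p-value tests directional pleiotropy.  Coefficient standard errors use
#' the weighted residual variance floored at 1 (multiplicative
#' random-effects convention); p-values use a t distribution with J - 2
#' degrees of freedom.
#'
#' @inheritParams ivw
#' @return An `mr_estimate` with extras `intercept`, `intercept_se`,
#'   `intercept_pval`.
#' @export
mr_egger <- function(beta_x, beta_y, se_y, se_x = NULL) {
  J <- length(beta_x)
  if (J < 3) stop("mr_egger: at least 3 instruments required")
  flip <- sign(beta_x) < 0
  bx <- abs(beta_x)
  by <- ifelse(flip, -beta_y, beta_y)
  w <- 1 / se_y^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  coefs <- solve(XtWX, crossprod(X, w * by))
  resid <- by - X %*% coefs
  sigma2 <- max(1, sum(w * resid^2) / (J - 2))
  ses <- sqrt(diag(solve(XtWX)) * sigma2)
  tstat <- coefs / ses
  pvals <- 2 * stats::pt(-abs(tstat), df = J - 2)
  mr_result("Egger", coefs[2], ses[2], pvals[2], J,
            intercept = coefs[1], intercept_se = ses[1],
            intercept_pval = pvals[1])
}

# weighted median of values v with weights w (normalized), by linear
# interpolation of the weighted empirical CDF at 0.5
weighted_median_core <- function(v, w) {
  o <- order(v)
  v <- v[o]
  w <- w[o] / sum(w)
  cdf <- cumsum(w) - w / 2
  if (0.5 <= cdf[1]) return(v[1])
  if (0.5 >= cdf[length(cdf)]) return(v[length(v)])
  stats::approx(cdf, v, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' Per-instrument Wald ratios `by/bx` weighted by their inverse first-order
#' variance (`se_y^2 / bx^2`); the estimate is the weighted median
#' (linear interpolation of the weighted empirical CDF at 0.5), consistent
#' when valid instruments carry over half the weight.  The standard error
#' comes from a seeded parametric bootstrap resampling `beta_x` and
#' `beta_y` from normals.
#'
#' @inheritParams ivw
#' @param se_x exposure standard errors used only by the bootstrap
#'   (optional; 0 when NULL).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed bootstrap RNG seed.
#' @return An `mr_estimate`.
#' @export
weighted_median <- function(beta_x, beta_y, se_y, se_x = NULL,
                            n_boot = 1000L, seed = 1L) {
  drop <- beta_x == 0
  if (any(drop)) {
    warning("weighted_median: dropping ", sum(drop), " instrument(s) with beta_x = 0")
    beta_x <- beta_x[!drop]; beta_y <- beta_y[!drop]; se_y <- se_y[!drop]
    if (!is.null(se_x)) se_x <- se_x[!drop]
  }
  J <- length(beta_x)
  if (J < 3) stop("weighted_median: at least 3 instruments required")
  sx <- if (is.null(se_x)) rep(0, J) else se_x
  ratio <- beta_y / beta_x
  w <- beta_x^2 / se_y^2
  est <- weighted_median_core(ratio, w)
  boot <- with_seed(seed, {
    BX <- beta_x + sx * matrix(stats::rnorm(J * n_boot), J)
    BY <- beta_y + se_y * matrix(stats::rnorm(J * n_boot), J)
    vapply(seq_len(n_boot), function(i) {
      bx <- BX[, i]
      ok <- bx != 0
      weighted_median_core(BY[ok, i] / bx[ok], bx[ok]^2 / se_y[ok]^2)
    }, 0)
  })
  se <- stats::sd(boot)
  mr_result("weighted_median", est, se, 2 * stats::pnorm(-abs(est / se)), J)
}

#' Maximum-likelihood MR estimate
#'
#' Maximizes the joint normal likelihood of the observed
#' `(beta_x, beta_y)` around `(xi_j, beta * xi_j)` over the nuisance true
#' effects `xi_j` and the causal slope `beta`.  Profiling out `xi_j` gives
#' `-2 log L(beta) = sum (by - beta bx)^2 / (se_y^2 + beta^2 se_x^2)`,
#' optimized numerically from the IVW start; the standard error comes from
#' the observed information (numerical curvature) of the profile
#' likelihood.
#'
#' @inheritParams ivw
#' @param se_x exposure standard errors (required).
#' @return An `mr_estimate`.
#' @export
max_likelihood <- function(beta_x, beta_y, se_y, se_x) {
  J <- length(beta_x)
  if (J < 1) stop("max_likelihood: no instruments")
  nll <- function(b) 0.5 * sum((beta_y - b * beta_x)^2 / (se_y^2 + b^2 * se_x^2))
  start <- ivw(beta_x, beta_y, se_y)$beta
  width <- max(1, 10 * abs(start))
  opt <- stats::optimize(nll, interval = c(start - width, start + width))
  b <- opt$minimum
  h <- stats::optimHess(b, nll)
  if (!is.finite(h) || h <= 0) stop("max_likelihood: information matrix not positive; no convergence")
  se <- sqrt(1 / h[1, 1])
  mr_result("max_likelihood", b, se, 2 * stats::pnorm(-abs(b / se)), J)
}

#' MR-PRESSO global test, outlier test, and outlier-corrected estimate
#'
#' The observed residual sum of squares uses leave-one-out IVW slopes:
#' `RSS = sum w_j (by_j - b_(-j) bx_j)^2`.  Its null distribution is
#' simulated parametrically (`by_j ~ N(b_(-j) bx_j, se_y_j)`, exposure
#' effects optionally redrawn with `se_x`), giving an empirical global
#' p-value.  Each instrument's observed residual is compared with its own
#' simulated distribution for a per-SNP outlier p-value,
#' Bonferroni-adjusted across instruments; the corrected estimate is IVW
#' after removing flagged outliers (identical to the uncorrected IVW when
#' nothing is flagged).
#'
#' @inheritParams ivw
#' @param se_x optional exposure standard errors for the simulations.
#' @param n_sim parametric simulations (default 1000).  The smallest
#'   attainable Bonferroni-adjusted outlier p is `J / (n_sim + 1)`, so
#'   `n_sim` must exceed `J / sig` for the outlier test to have any power;
#'   a warning is issued otherwise.
#' @param seed RNG seed.
#' @param sig outlier significance level after Bonferroni (default 0.05).
#' @return List: `global_pval`, `outlier_pvals` (Bonferroni-adjusted, named
#'   by rsid position), `outliers` (indices), `raw` and `corrected`
#'   `mr_estimate`s.
#' @export
mr_presso <- function(beta_x, beta_y, se_y, se_x = NULL,
                      n_sim = 1000L, seed = 1L, sig = 0.05) {
  J <- length(beta_x)
  if (J < 4) stop("mr_presso: at least 4 instruments required")
  if (n_sim < J / sig) {
    warning("mr_presso: n_sim too small for the outlier test (min adjusted p = ",
            signif(J / (n_sim + 1), 3), " > sig); increase n_sim")
  }
  w <- 1 / se_y^2
  S_xy <- sum(w * beta_x * beta_y)
  S_xx <- sum(w * beta_x^2)
  b_loo <- (S_xy - w * beta_x * beta_y) / (S_xx - w * beta_x^2)
  obs_res <- w * (beta_y - b_loo * beta_x)^2
  rss_obs <- sum(obs_res)

  sims <- with_seed(seed, {
    BX <- if (is.null(se_x)) {
      matrix(beta_x, J, n_sim)
    } else {
      beta_x + se_x * matrix(stats::rnorm(J * n_sim), J)
    }
    BY <- b_loo * BX + se_y * matrix(stats::rnorm(J * n_sim), J)
    sxy <- colSums(w * BX * BY)
    sxx <- colSums(w * BX^2)
    BL <- (rep(sxy, each = J) - w * BX * BY) / (rep(sxx, each = J) - w * BX^2)
    w * (BY - BL * BX)^2 # J x n_sim matrix of simulated residuals
  })
  rss_sim <- colSums(sims)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  out_p_raw <- (1 + rowSums(sims >= obs_res)) / (n_sim + 1)
  out_p <- pmin(1, out_p_raw * J)
  outliers <- which(out_p < sig)
  raw <- ivw(beta_x, beta_y, se_y)
  corrected <- if (length(outliers) > 0 && length(outliers) < J - 1) {
    ivw(beta_x[-outliers], beta_y[-outliers], se_y[-outliers])
  } else {
    raw
  }
  list(global_pval = global_p, outlier_pvals = out_p, outliers = outliers,
       raw = raw, corrected = corrected)
}

#' Multivariable IVW MR
#'
#' Weighted multiple regression of outcome effects on the exposure effect
#' columns with no intercept and weights `1/se_y^2`, giving each
#' exposure's effect conditional on the others.  Coefficient standard
#' errors use the weighted residual variance floored at 1; p-values are
#' two-sided normal.  With a single exposure this reduces exactly to the
#' univariable IVW.
#'
#' @param beta_x_mat J x K matrix of instrument effects on the K exposures
#'   (column names label exposures).
#' @param beta_y,se_y outcome effects and standard errors.
#' @return List of `mr_estimate`s, one per exposure.
#' @export
mvmr_ivw <- function(beta_x_mat, beta_y, se_y) {
  X <- as.matrix(beta_x_mat)
  J <- nrow(X); K <- ncol(X)
  if (J < K + 1) stop("mvmr_ivw: need more instruments than exposures")
  qrX <- qr(X)
  if (qrX$rank < K) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):K]]
    stop("mvmr_ivw: exposure effect matrix is rank deficient (collinear: ",
         paste(bad, collapse = ", "), ")")
  }
  w <- 1 / se_y^2
  XtWX <- crossprod(X, w * X)
  coefs <- unname(drop(solve(XtWX, crossprod(X, w * beta_y))))
  resid <- beta_y - drop(X %*% coefs)
  sigma2 <- max(1, sum(w * resid^2) / max(J - K, 1))
  ses <- unname(sqrt(diag(solve(XtWX)) * sigma2))
  labels <- colnames(X)
  if (is.null(labels)) labels <- paste0("exposure", seq_len(K))
  out <- lapply(seq_len(K), function(k) {
    mr_result(paste0("MVMR_IVW[", labels[k], "]"), coefs[k], ses[k],
              2 * stats::pnorm(-abs(coefs[k] / ses[k])), J)
  })
  names(out) <- labels
  out
}

#' Bonferroni screen of candidate instruments
#'
#' Removes instruments whose screening p-value (association with the
#' outcome or a competing trait) is below `alpha / m`.
#'
#' @param screen_pvals per-instrument screening p-values.
#' @param m number of tests in the Bonferroni family (default: number of
#'   candidates).
#' @param alpha family-wise level (default 0.05).
#' @return Logical keep-vector with attribute `"removed"` (indices).
#' @export
bonferroni_filter <- function(screen_pvals, m = length(screen_pvals), alpha = 0.05) {
  keep <- !(screen_pvals < alpha / m)
  attr(keep, "removed") <- which(!keep)
  keep
}

#' Analytical power of two-sample MR with a binary outcome
#'
#' `power = Phi( sqrt(n r2 K (1 - K)) |log OR| - z_(1 - alpha/2) )` — the
#' standard normal approximation for the Wald test of the causal log odds
#' ratio, with `n` the outcome GWAS sample size, `K` its case fraction and
#' `r2` the variance of the exposure explained by the instruments.
#'
#' @param n outcome sample size.
#' @param K case fraction in `(0, 1)`.
#' @param r2 instrument variance explained in `(0, 1)`.
#' @param odds_ratio hypothesized causal OR per exposure unit.
#' @param alpha significance level (default 0.05).
#' @return Power in `[0, 1]`; vectorized over all arguments.
#' @export
mr_power_binary <- function(n, K, r2, odds_ratio, alpha = 0.05) {
  if (any(K <= 0 | K >= 1)) stop("mr_power_binary: K must be in (0, 1)")
  if (any(r2 <= 0 | r2 >= 1)) stop("mr_power_binary: r2 must be in (0, 1)")
  stopifnot(all(n > 0), all(odds_ratio > 0), all(alpha > 0), all(alpha < 1))
  ncp <- sqrt(n * r2 * K * (1 - K)) * abs(log(odds_ratio))
  stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
}
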