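# Shared fixtures, built once per test run.

# small sumstats table used by IO / QC tests
toy_sumstats_df <- function() {
  data.frame(
    rsid = c("rs1", "rs2", "rs3"),
    chrom = c(1L, 1L, 2L),
    pos = c(1000L, 2000L, 3000L),
    a1 = c("A", "G", "C"),
    a2 = c("G", "T", "T"),
    beta = c(0.10, -0.05, 0.02),
    se = c(0.02, 0.01, 0.04),
    n = c(10000, 10000, 10000),
    stringsAsFactors = FALSE
  )
}

# study-scale LD reference reused across LDSC tests (expensive to rebuild)
study_ld <- local({
  ld <- NULL
  function() {
    if (is.null(ld)) {
      cfg <- sim_config()
      ld <<- simulate_ld_reference(cfg$m_snps, cfg$n_blocks, cfg$block_rho,
                                   seed = 20)
    }
    ld
  }
})

study_ell <- local({
  ell <- NULL
  function() {
    if (is.null(ell)) ell <<- compute_ld_scores(study_ld())
    ell
  }
})

# LD panel of many small independent blocks with one gene per block, for
# calibration tests where genes must be independent draws
independent_gene_panel <- local({
  pan <- NULL
  function() {
    if (is.null(pan)) {
      ld <- simulate_ld_reference(5000, 500, seq(0.1, 0.9, length.out = 500),
                                  seed = 30)
      snp_tab <- crosstrait:::ld_snp_table(ld)
      gm <- lapply(split(snp_tab$rsid, snp_tab$block), function(x) x[2:8])
      names(gm) <- paste0("g", seq_along(gm))
      pan <<- list(ld = ld, gene_map = gm, snp_tab = snp_tab)
    }
    pan
  }
})

# clean instrument-level dataset for MR estimator tests
clean_instruments <- function(J = 30, beta = 0.3, seed = 1,
                              sx = 0.005, sy = 0.01) {
  set.seed(seed)
  bx <- stats::runif(J, 0.05, 0.2)
  by <- beta * bx + stats::rnorm(J, 0, sy)
  list(bx = bx + stats::rnorm(J, 0, sx), by = by,
       sx = rep(sx, J), sy = rep(sy, J), truth = beta)
}
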