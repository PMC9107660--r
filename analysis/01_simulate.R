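#!/usr/bin/env Rscript

# Stage 1 — build the synthetic study.
#
# Emulates the data layout of a summary-statistics study of birthweight and
# breast cancer: an LD reference of 50 blocks over 22 pseudo-chromosomes,
# fetal-specific and maternal-specific birthweight summary statistics whose
# true SNP effects are negatively correlated, a binary-outcome set sharing
# planted pleiotropic genes with both, an instrument-level causal chain
# birthweight -> age at menarche -> age at menopause -> breast cancer, and
# a synthetic instrument-classification table.  Everything is written as
# delimited text under results/sim/ for the downstream stages.

suppressMessages(library(crosstrait))
seed <- 20260919L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
ld <- simulate_ld_reference(cfg$m_snps, cfg$n_blocks, cfg$block_rho, seed)
# no binary outputs: downstream stages regenerate the LD reference by seed

# gene annotation: ~400 intervals of ~10 SNPs
snp_tab <- crosstrait:::ld_snp_table(ld)
gene_map <- crosstrait:::synthetic_gene_map(snp_tab, 400L, seed)
writeLines(
  vapply(names(gene_map), function(g) {
    paste(c(g, gene_map[[g]]), collapse = "\t")
  }, ""),
  file.path(out, "gene_map.tsv")
)

# fetal birthweight effects with planted pleiotropic genes shared with the
# outcome; maternal effects anticorrelated with the fetal ones (fm_corr)
pl <- plant_pleiotropic_genes(gene_map, ld, frac_shared = 0.05,
                              effect_corr_sign = +1, seed = seed + 1)
b_fetal <- pl$effects[, 1]
b_bc <- pl$effects[, 2]
set.seed(seed + 2)
b_maternal <- cfg$fm_corr * b_fetal +
  sqrt(1 - cfg$fm_corr^2) * sample(b_fetal) # same marginal scale, fm_corr link

pair_f <- simulate_sumstats_from_effects(ld, cbind(b_fetal, b_bc), cfg,
                                         seed = seed + 3)
pair_m <- simulate_sumstats_from_effects(ld, cbind(b_maternal, b_bc), cfg,
                                         seed = seed + 4)
write_sumstats(pair_f$trait1, file.path(out, "fetal_bw.tsv"))
write_sumstats(pair_f$trait2, file.path(out, "breast_cancer_f.tsv"))
write_sumstats(pair_m$trait1, file.path(out, "maternal_bw.tsv"))
write_sumstats(pair_m$trait2, file.path(out, "breast_cancer_m.tsv"))

# instrument-level chain and the synthetic classification table
chain <- simulate_causal_chain(cfg, seed = seed + 5)
for (tr in c("X", "M1", "M2", "Y")) {
  write_sumstats(chain[[tr]], file.path(out, paste0("chain_", tr, ".tsv")))
}
tab <- simulate_instrument_table(seed = seed + 6)
write_sumstats(tab$fetal, file.path(out, "instruments_fetal.tsv"))
write_sumstats(tab$maternal, file.path(out, "instruments_maternal.tsv"))

jsonlite::write_json(
  list(seed = seed,
       planted_pleiotropic_genes = pl$truth$gene_id[pl$truth$state == "H11"],
       chain_theta = cfg[c("theta_xm1", "theta_m1m2", "theta_m2y", "theta_xy")],
       fm_corr = cfg$fm_corr,
       instrument_truth = as.list(table(tab$truth$class))),
  file.path(out, "truth.json"), auto_unbox = TRUE, pretty = TRUE
)
cat("simulated study written to", out, "\n")
cat("planted pleiotropic genes:", sum(pl$truth$state == "H11"), "of",
    length(gene_map), "\n")
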