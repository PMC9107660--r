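#!/usr/bin/env Rscript

# Stage 5 — joint-significance mediation and the effect graph.
#
# Assembles the exposure -> mediator -> mediator -> outcome graph from the
# MR fits of stage 4, applies the joint-significance rule to the
# birthweight -> menarche -> menopause -> breast-cancer path, writes the
# verdicts and the DOT serialization, and checks the detection rate and
# global-null behavior over replicates.

suppressMessages(library(crosstrait))
seed <- 20260919L
sim_dir <- "results/sim"
out <- "results"

chain <- lapply(c(X = "chain_X.tsv", M1 = "chain_M1.tsv",
                  M2 = "chain_M2.tsv", Y = "chain_Y.tsv"), function(f) {
  read_sumstats(file.path(sim_dir, f))
})
graph <- chain_mr_analysis(chain, alpha = 0.05)
print(graph)
render_effect_graph(graph, file.path(out, "effect_graph.dot"))
jsonlite::write_json(
  list(alpha = graph$alpha, nodes = as.list(graph$nodes),
       paths = lapply(graph$paths, function(p) {
         list(edge_pvals = p$edge_pvals, verdict = p$verdict)
       })),
  file.path(out, "mediation.json"), auto_unbox = TRUE, pretty = TRUE,
  digits = NA, na = "null"
)

# operating characteristics over fresh replicates
cfg <- sim_config(seed = seed)
alt <- vapply(1:50, function(i) {
  chain_mr_analysis(simulate_causal_chain(cfg, seed = seed + 500 + i))$paths[[
    "X->M1->M2->Y"]]$verdict
}, TRUE)
null_cfg <- sim_config(theta_xm1 = 0, theta_m1m2 = 0, theta_m2y = 0)
nulls <- vapply(1:200, function(i) {
  chain_mr_analysis(simulate_causal_chain(null_cfg, seed = seed + 900 + i))$paths[[
    "X->M1->M2->Y"]]$verdict
}, TRUE)
cat(sprintf("mediation detected in %.0f%% of planted-chain replicates (50 reps)\n",
            100 * mean(alt)))
cat(sprintf("global-null mediation rate: %.4f (200 reps; alpha^3 = %.2e)\n",
            mean(nulls), 0.05^3))
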