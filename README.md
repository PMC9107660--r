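# crosstrait

Cross-trait genetic correlation, pleiotropy, Mendelian randomization and
mediation — from GWAS summary statistics alone.

## The problem

Epidemiology keeps finding traits that travel together — birthweight and
adult breast cancer is a classic, contested example — without being able
to say *why*: shared genetic background, a causal path, or a mediated
chain running through intermediate traits such as age at menarche and age
at menopause.  Individual-level data to settle this rarely exist in one
place, but genome-wide summary statistics usually do.  `crosstrait`
implements the complete summary-statistics toolkit for this question, for
statistical geneticists and genetic epidemiologists:

1. **Genetic correlation** by cross-trait LD score regression.  For SNP
   *j* with LD score ℓⱼ = Σₖ r²ⱼₖ,

       E[z₁ⱼ z₂ⱼ] = √(n₁n₂) ρ_g ℓⱼ / M  +  ρ n_s / √(n₁n₂),

   estimated by two-step weighted regression with a free intercept (which
   absorbs sample overlap), r_g = ρ̂_g/√(ĥ²₁ ĥ²₂), and delete-one-block
   jackknife standard errors of the full ratio — overall and per
   chromosome.
2. **Gene-based association**: the SNP-set statistic T = Σ zⱼ², whose null
   is Σ λᵢ χ²₁ with λᵢ the eigenvalues of the local LD matrix, with exact
   Imhof-inversion p-values (Satterthwaite approximation as fallback) and
   genomic-control correction when the inflation factor exceeds 1.05.
3. **Composite-null pleiotropy**: with t = max(p₁, p₂) per gene and
   mixture proportions π of the joint null states H00/H01/H10,

       p_pleio = [(π01 + π10) t + π00 t²] / (π00 + π01 + π10),

   calibrated by Storey-type null-proportion estimates, selected at
   BH-FDR 0.05, and annotated with local effect-size correlations.
4. **Two-sample MR**: greedy LD clumping, fetal/maternal instrument
   classification, IVW (fixed and multiplicative random effects),
   MR-Egger, weighted median, maximum likelihood, MR-PRESSO (global,
   outlier, corrected), multivariable IVW, a Bonferroni instrument
   screen, and an analytical binary-outcome power formula.
5. **Mediation** over the chain X → M1 → M2 → Y by the joint-significance
   rule: a path is mediated iff every edge's MR fit (with the
   multivariable adjustment scheme) is individually significant.

Because the consortium inputs of such analyses are not redistributable,
the package also ships seeded synthetic-data generators with block LD
that reproduce the statistical structure each stage assumes — the whole
pipeline is testable end to end without any external data.

## Worked example

```r
library(crosstrait)

# a synthetic study: 5000 SNPs in 50 LD blocks, two traits with h2 = 0.3
# and true genetic correlation 0.5, both GWAS at n = 50,000
cfg <- sim_config(rg_true = 0.5, seed = 1)
ld  <- simulate_ld_reference(cfg$m_snps, cfg$n_blocks, cfg$block_rho, seed = 1)
sim <- simulate_paired_sumstats(ld, cfg)
ldsc_rg(sim$trait1, sim$trait2, compute_ld_scores(ld), n_blocks = 50)
#> LD score regression (5000 SNPs, 50 jackknife blocks)
#>   h2 trait1 = 0.3545, h2 trait2 = 0.2883, gencov = 0.1932
#>   rg = 0.6044 (se 0.0820, P = 1.72e-13); bivariate intercept -0.4305
```

The estimate 0.60 ± 0.08 covers the planted 0.5 (single replicates
scatter with SE ≈ 0.08; across 200 replicates the mean is 0.50).  The
mediation stage, on an instrument-level causal chain with structural
coefficients θ = (0.09, 0.11, 0.10) and no direct effect:

```r
g <- chain_mr_analysis(simulate_causal_chain(cfg))
g
#> Mediation graph: birthweight / age_at_menarche / age_at_menopause / breast_cancer
#>   from to      beta       se      pval adjusted_for significant
#> 1    X M1  0.087331 0.004153 3.448e-98                     TRUE
#> 2    X  Y -0.002631 0.004678 5.738e-01                    FALSE
#> 3    X M2 -0.013759 0.009821 1.612e-01           M1       FALSE
#> 4   M1 M2  0.098066 0.009771 1.057e-23            X        TRUE
#> 5    X  Y -0.002122 0.004923 6.664e-01        M1,M2       FALSE
#> 6   M1  Y  0.002770 0.004934 5.745e-01         X,M2       FALSE
#> 7   M2  Y  0.096312 0.006222 4.846e-54         X,M1        TRUE
#>   path X->M1->M2->Y: mediation present
#>   path X->M1->Y: mediation absent
```

Each edge recovers its structural coefficient (0.087 ≈ θ_XM1 = 0.09,
0.098 ≈ θ_M1M2 = 0.11 after adjustment, 0.096 ≈ θ_M2Y = 0.10); the total
X → Y effect is correctly null (the whole effect flows through the
mediators), and the joint-significance rule declares the
X → M1 → M2 → Y path mediated.

## The analysis workflow

`analysis/` contains the numbered drivers of the full study narrative,
each a thin script over the package functions, writing its tables under
`results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | builds the synthetic study (LD panel, fetal/maternal trait pairs with planted pleiotropic genes, causal-chain instruments, instrument table) |
| `02_ldsc.R` | QC, harmonization, MHC-style exclusion, genetic correlation overall and per chromosome |
| `03_genes_pleiotropy.R` | gene-based tests, genomic control, pleiotropy scan at FDR 0.05, fetal-vs-maternal set comparison |
| `04_mr.R` | instrument classification, univariable MR suite + MR-PRESSO, multivariable IVW edges |
| `05_mediation.R` | joint-significance verdicts, DOT effect graph, detection/null-rate replicates |

Run them in order: `for f in analysis/0*.R; do Rscript "$f"; done`

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the models, the
weighting and jackknife choices, the mixture-null construction, every
tunable parameter with its default and rationale, what the synthetic
generators do and do not emulate, and known limitations.
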