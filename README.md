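# cistra

Integrative cistrome–epigenome–transcriptome analysis in R.

`cistra` asks the question a regulatory genomicist asks after mapping the
genome-wide binding sites of a chromatin factor (its *cistrome*): **what
does proximal binding of this factor do to gene expression, which
chromatin contexts modulate that effect, and which drugs target the
genes it governs?** It is written for analysts integrating peak calls
(ChIP-seq of a factor and a histone mark, open-chromatin assays such as
FAIRE-seq), bisulfite CpG methylation tables, RNA-seq expression and an
NCI-60-style drug-sensitivity panel.

## The statistics at the core

1. **Combinatorial promoter states.** Every gene's ±1 kb TSS window is
   flagged for factor binding (N), the histone mark (H) and open
   chromatin (F) — `t` if at least 25% of any peak's length falls inside
   the 2 kb window, else `f` — and for CpG methylation
   (C ∈ {l, h, f}: mean methylation of the window's CpGs below / at or
   above 30%, or no CpG detected). Leaving an axis "independent" (`i`)
   yields the 36-query sub-cistrome lattice
   {t,f,i}×{t,f,i}×{l,h,f,i} with N fixed.

2. **Bootstrap expression nulls.** For a gene subset *S* with mean
   Box-Cox-transformed expression m(S), the null is the distribution of
   m over B = 100,000 random same-size gene sets from a background
   (all protein-coding genes, or a matched background sharing the
   subset's H/F/C context with N = f). Empirical tails use the add-one
   rule, p = (1 + #{null ≥ obs}) / (B + 1), so p ≥ 1/(B+1) > 0 always.
   On/off composition (detected vs reproducibly undetected genes) is
   tested against the hypergeometric expectation.

3. **81-bin metagene model.** Genes ≥ 4100 bp are split into 40 × 100 bp
   bins centered on the TSS, one gene-body bin, and 40 × 100 bp bins
   centered on the TTS; per-bin mean binding signal (log(x+1)) is
   Pearson-correlated with log expression, bin by bin.

4. **Drug–gene enrichment.** Each drug's sensitivity Z-profile is
   correlated with every gene's expression Z-profile across the
   cell-line panel; genes at BH FDR ≤ 0.1 form the drug's positive and
   negative sets, and each set's overlap k with the cistrome genes K in
   the expression universe N is scored by the exact upper tail
   P(X ≥ k), X ~ Hypergeometric(N, K, n), BH-adjusted at FDR ≤ 0.01.

A synthetic-data generator plants all of this structure (bound genes
with shifted expression, a drug tracking cistrome-gene expression) so
the full pipeline runs and is tested without any external download.

## Worked example

```r
library(cistra)

cfg <- synthetic_config(seed = 1, n_genes = 1000, frac_bound = 0.15,
                        n_drugs = 20)
ds  <- generate_dataset(cfg)
res <- run_pipeline(ds, pipeline_params(bootstrap_B = 10000, seed = 1))

res$lambda
#> [1] -0.03

res$subset_results[res$subset_results$query == "t,i,i,i",
                   c("query", "n", "n_on", "observed_mean", "null_mean",
                     "ci_low", "ci_high", "p_upper")]
#>     query   n n_on observed_mean null_mean ci_low ci_high p_upper
#> 1 t,i,i,i 158  111          1.16     0.591  0.425   0.761   1e-04

res$drug_enrichment
#>   drug_id direction n_correlated n_cistrome overlap overlap_pct         p     adj_p
#> 1    D018  positive          158        158     137        86.7 2.74e-121 1.09e-120

ds$truth$planted_drug
#> [1] "D018"
```

Reading the output: the estimated Box-Cox exponent is ≈ 0 (log-normal
RPKM, as the generator plants). The parental cistrome query `t,i,i,i`
(bound genes, all other axes independent) covers 158 annotated genes
whose mean transformed expression, 1.16, sits far above the bootstrap
null (0.591, 95% CI [0.425, 0.761]); `p_upper = 1e-04` is the minimum
attainable at B = 10,000, i.e. no resampled gene set reached the
observed mean. The drug table recovers the planted drug D018: 137 of
its 158 positively correlated genes lie in the annotated cistrome
(86.7% overlap, adjusted p ≈ 1e-120). The per-bin correlation profile
(`res$bin_correlation`) peaks inside the TSS flank, where the generator
placed the binding signal.

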