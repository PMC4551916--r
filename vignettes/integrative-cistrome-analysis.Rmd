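---
title: "Relating a cistrome to chromatin state, expression and drug sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating a cistrome to chromatin state, expression and drug sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistra)
```

## The model

A cistrome — the genome-wide set of binding sites of a DNA-associated
protein, defined here by ChIP-seq peak calls — is, on its own, a list
of genomic intervals. `cistra` turns it into statistical statements by
integrating four layers around gene transcription start sites (TSS):

* **binding** of the factor of interest (axis N),
* a **histone mark** such as H3K9me3 (axis H),
* **open chromatin** from an assay such as FAIRE-seq (axis F),
* **CpG methylation** from bisulfite sequencing (axis C),

and relating the resulting promoter states to RNA-seq expression and to
drug sensitivity across a cell-line panel.

The package assumes peak calling, IDR reproducibility analysis and
RPKM quantification happened upstream; it consumes their standard text
outputs (broadPeak/narrowPeak/BED6, bedGraph-like methylation and
signal files, TSV tables). All coordinates are 0-based half-open (the
BED convention), chosen because every input format is BED-derived;
chromosome names are compared by exact string equality, with
`check_shared_chromosomes()` as the diagnostic for naming mismatches.

## Promoter state annotation

Each gene's promoter window is `[tss - flank, tss + flank)` with
`flank = 1000` bp; the TSS is the gene start on the plus strand and
the gene end on the minus strand, and unstranded genes are rejected.
Binding-type axes are flagged `t` when at least one peak overlaps the
window by at least 25% *of the peak's own length* — the denominator is
always the peak, never the window, so a peak much wider than the
window does not count by merely covering it. The boundary is
inclusive: exactly 25% is an overlap.

Before annotation, peaks of the factor are cleaned with
`filter_peaks()`: peaks longer than 100 kb *or* with signal value
below 2 are removed. Both conditions are applied as an OR because the
very-large and low-intensity tails are separate artifact modes of
broad-peak calling; the filter is idempotent and reports what it
removed.

Methylation replicates are merged first (`merge_methylation_replicates()`):
a CpG survives only when covered by at least 10 reads in *both*
replicates; the merged level is the arithmetic mean and the merged
coverage the minimum (the conservative choice of the two defensible
ones). The C axis is then `f` when no surviving CpG falls in the
window, `l` below 30% mean methylation, `h` at or above. The boundary
value of exactly 30% is classified high — the published description
("low < 30%, high > 30%") leaves the point mass unassigned, and a
deterministic single cut-point is preferable to an undefined state.

```{r states}
ds <- generate_dataset(synthetic_config(seed = 5, n_genes = 300,
                                        n_drugs = 3))
cpgs <- merge_methylation_replicates(ds$meth_rep1, ds$meth_rep2)
states <- annotate_states(ds$genes, filter_peaks(ds$factor_peaks),
                          ds$mark_peaks, ds$open_peaks, cpgs)
head(states)
```

### The sub-cistrome lattice

Queries over the axes use `t`/`f`/`i` (`i` = independent, matches
anything; C additionally takes `l`/`h`/`f`). With N fixed to `t`,
`enumerate_subsets()` emits the full 3 × 3 × 4 = 36-query lattice,
keeping empty subsets flagged rather than dropped. Wildcard
monotonicity (refining an `i` axis only shrinks a subset) and the
partition property (the concrete values of an axis split a wildcard
set exactly) are asserted as properties in the test suite. Published
analyses of this design sometimes quote larger sub-cistrome counts
that mix in additional derived lists; the lattice itself has 36
queries and nothing in this package asserts any other count.
`unique_subset_genes()` produces the mutually exclusive "unique" lists
(each query's genes minus the union of the other queries') used when
comparing annotation terms between overlapping subsets.

## Expression: on/off, Box-Cox, bootstrap

A gene is **on** when it passed reproducibility filtering and has an
RPKM value, **off** when it passed filtering but has none. RPKMs of on
genes are Box-Cox transformed; the exponent is estimated by profile
log-likelihood over a grid on $[-2, 2]$ with step 0.01, ties broken
toward 0 (the log transform). The grid is coarse enough to be fast and
fine enough that the discretization error (≤ 0.005) is far below the
sampling error of any realistic dataset.

`bootstrap_mean_test()` compares a subset's mean transformed
expression to B random same-size gene sets from a background. Draws
are made *without* replacement within a set — the null is "a random
gene signature of the same size", matching how the observed subset
arises — though classical with-replacement resampling is available via
`replace = TRUE`. Empirical tails use the add-one rule
$(1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$, so the reported
minimum is $1/(B+1)$ and zero never appears; the two-sided p is twice
the smaller tail, capped at 1. Ties within floating-point noise of the
observed mean count as ties, so the degenerate case subset =
background yields p = 1 exactly. Two backgrounds are supported: all
annotated protein-coding genes (the default) and a matched background
(`matched_background()`) of genes sharing the query's H/F/C context
with N = f, which isolates what the factor adds on top of a chromatin
context.

The on/off composition of a subset is scored by
`onoff_hypergeometric()`, the exact upper tail of the hypergeometric
distribution, computed in log-space (`hypergeom_tail()`) so that
extreme enrichments (p ~ 1e-150 and beyond) remain accurate.

## The 81-bin metagene model

`make_bins()` divides a gene into 40 × 100 bp bins spanning
`[tss - 2000, tss + 2000)`, one bin over the residual gene body, and
40 × 100 bp bins spanning `[tts - 2000, tts + 2000)`, ordered 5′→3′ in
gene orientation (minus-strand genes mirror so bin 1 is always most
5′). Genes shorter than 4100 bp — whose anchor windows would collide —
are excluded, not truncated. Per-bin signal is the mean of the
coverage track over the bin, with uncovered positions counting as 0,
then `log(x + 1)`; the pseudocount is required because empty bins are
legitimate and common. The gene-body bin is a plain mean over its full
residual length — no length renormalization, since the correlation
analysis is within-bin across genes, not across bins.
`per_bin_correlation()` then reports Pearson r and p per bin against
log expression; a constant bin column yields `NA` rather than an
error.

TSS-centered profile curves (`tss_profile()`) average feature coverage
per strand-oriented offset and normalize by the curve maximum — purely
a visualization convention. The methylation-versus-distance profile
fits a degree-3 polynomial: the lowest degree able to represent the
canonical asymmetric dip at the TSS.

## Drug sensitivity

`correlate_drug_genes()` correlates every drug's sensitivity Z-profile
with every gene's expression Z-profile over the shared cell lines,
using pairwise-complete observations with a minimum of 3 complete
pairs. FDR control is within-drug across genes by default (each drug's
gene set is its own discovery family; a global family is available
behind a flag). `build_drug_gene_sets()` splits significant genes by
correlation sign, and `rank_cistrome_enrichment()` scores each (drug,
direction) set's cistrome overlap by the exact hypergeometric upper
tail over the expression-matrix universe, BH-adjusting across all
tested rows. The universe is the expression matrix's gene set, with
the cistrome intersected into it — the only self-consistent choice
when cistrome annotation and panel expression cover different gene
catalogs. Any caller-side restriction (e.g. to approved compounds) is
applied before ranking, so the BH family is exactly the set of tests
actually run.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` plants every effect the pipeline is designed to
detect, with defaults chosen as the study conditions:

* **bound fraction 0.125** of genes get a factor peak centered within
  ±500 bp of the TSS — the proportion of protein-coding genes with
  proximal binding in a typical broad cistrome;
* **expression**: log-normal RPKM (so the estimated Box-Cox exponent
  is near 0 and the transform is exercised non-trivially), with bound
  genes' log-mean shifted by **delta = 0.75**; **74.8%** of genes are
  on, the rest have `NA` RPKM;
* **peaks**: log-normal lengths (median 3 kb, matching the few-kb
  average of broad peaks) and signals; planted TSS peaks get signal
  2 + log-normal so the planted cistrome survives the standard
  intensity filter, while background peaks drawn away from TSSs use
  unclipped distributions and give `filter_peaks()` real work;
* **methylation**: per-gene low (Beta(1, 9)) or high (Beta(6, 4))
  components observed through binomial reads at negative-binomial
  coverage (mean 30, dispersion 5) in two replicates sharing the
  latent levels;
* **panel**: 60 cell lines; bound genes load on a shared per-line
  factor, and one planted drug's sensitivity equals
  0.8 × (standardized mean bound-gene expression) plus noise.

Deliberately *not* emulated: genome sequence, read-level data,
copy-number structure, distal/enhancer binding, and correlated
co-occurrence between the mark/open-chromatin tracks and the factor
(they are independent by default). Passing tests on this generator
therefore demonstrates that the statistical machinery recovers planted
proximal-binding structure at realistic sizes and noise levels — not
that any particular biological claim holds in real data.

## Numerical and degenerate-input choices

* `hypergeom_tail()` accumulates `dhyper(log = TRUE)` terms via
  log-sum-exp; the lower tail of an impossible event (k below the
  support minimum) is 0.
* `bh_adjust()` is the standard step-up adjustment (delegated to
  `p.adjust`); tests verify it against the direct formula.
* Empty peak sets, zero-row CpG tables and empty subsets all have
  defined behaviour (flags all `f`, C all `f`, and an error,
  respectively). A `NULL` methylation input is an error — silently
  treating missing data as "no CpGs" would corrupt the C axis — which
  is why `run_pipeline()` aborts naming the stage when methylation is
  absent.
* `run_pipeline()` derives one bootstrap seed per catalog query from
  the master seed, so the full result table is reproducible
  bit-for-bit given (dataset, params).

## Problem sizes used in the checks

The test suite regenerates all fixtures in code at sizes chosen to
make each property measurable in seconds: bootstrap calibration uses
10,000 background genes, subsets of 200, B = 2000 and 500 repetitions;
planted-shift power and planted-bin recovery use 100 seeds; the
planted-drug end-to-end check uses 20 seeds of a 2000-gene, 50-drug,
60-line panel. B = 100,000 — the default a real analysis should use —
is exercised through smaller-B calls since the estimator is identical.

## Known limitations

* Only fixed-flank proximal windows: no nearest-gene or
  enhancer-assignment logic.
* IDR, peak calling and expression quantification are consumed, not
  computed.
* The bootstrap null treats genes as exchangeable within the chosen
  background; gene-length or GC confounding must be handled by
  choosing a matched background.
* `anchor_overlap_counts()` only counts interaction-anchor overlaps;
  it does not model interaction significance.
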