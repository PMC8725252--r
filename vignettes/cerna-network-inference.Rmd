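---
title: "Sign-stratified ceRNA network inference: models, parameters and design choices"
author: "ceRNAnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sign-stratified ceRNA network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ceRNAnet` screens for competing-endogenous-RNA (ceRNA) triplets in a
two-condition design. Under the sponge model, an lncRNA that carries
binding sites for a miRNA sequesters that miRNA and de-represses the
miRNA's mRNA targets. The observable signature in expression data is a
coherent sign pattern: in the UP stratum the lncRNA and mRNA rise on
induction while the shared miRNA falls; the DOWN stratum is the mirror
image. A candidate triplet must satisfy, simultaneously:

1. **Differential expression** of all three members with the correct
   signs: |signed fold change| > 2 and raw P < 0.05 (strict
   inequalities), from a pooled-variance two-sample t-test on log2
   values. Fold change is computed from the difference of log2 means,
   i.e. a geometric-mean ratio, the microarray convention and the only
   reading consistent with log-scale input. A fold change of exactly
   2.0 does not pass.
2. **Predicted binding** of the miRNA on both the lncRNA and the mRNA:
   a local duplex alignment score strictly above 160 and an estimated
   duplex free energy of at most −30 kcal/mol.
3. **Negative coexpression** of the miRNA with both targets (r < 0,
   P < 0.05 by default; the significance cut is this package's choice,
   as the screening rule itself only demands "negative").
4. **Strong positive lncRNA–mRNA coexpression**: Pearson r > 0.90 at
   P < 0.001, strict on both sides; r exactly 0.90 is excluded.

Passing triplets are assembled per stratum into a strictly tripartite
network with two drawn edge types (lncRNA–miRNA, miRNA–mRNA); the
lncRNA–mRNA correlation is triplet *evidence*, not a drawn edge,
matching the conventional rendering of such networks. Hub lncRNAs are
those with degree strictly exceeding 8 ("exceeding 8" is read literally:
degree 9 or more); their provenance triplets form the hub subnetwork.
The same provenance mechanism yields gene-set-anchored subnetworks
(e.g. all triplets whose mRNA belongs to an osteoblast-differentiation
term).

### Why correlations are pooled across conditions

All correlations are computed across the pooled samples of both
conditions. With realistic per-condition sample counts (a handful of
arrays per group) a within-condition correlation cannot reach P < 0.001
at all — at n = 3 per condition the t-transform has one degree of
freedom. Pooling is also what the ceRNA logic expects: the condition
shift itself is the dominant shared signal moving a sponge and its
target together. This is a documented interpretation, not a tunable.

### Degenerate inputs and tie-breaks

* Zero within-condition variance with equal means gives t = 0, p = 1;
  with unequal means it is reported as p = 0 plus a `degenerate` flag
  (and a warning) rather than an error, so that noiseless simulated
  limits flow through the pipeline.
* |r| = 1 is reported with p = 0; zero-variance features make a
  correlation undefined and the pair is skipped with a warning.
* The best binding site of a pair is chosen by higher score, then lower
  energy, then smaller target start — total determinism.
* All output tables are sorted lexicographically, so identical inputs
  and configuration yield byte-identical artifacts.

## Binding-site prediction

The alignment is a Smith–Waterman/Gotoh local alignment of the
*reversed* miRNA against the target, so the columns read 5'→3' on the
target and 3'→5' on the miRNA (an antiparallel duplex). Substitution
scores are +5 for Watson–Crick pairs, +2 for G:U wobble, −3 for a
mismatch; gaps cost −9 to open and −4 to extend. Substitution scores at
miRNA seed positions 2–8 are multiplied by 4, reflecting the dominant
contribution of seed pairing. The published screening rule fixes only
the two pass thresholds (score > 160, energy ≤ −30 kcal/mol); the
internal weights are this package's own defaults, all configurable
through `scoring_scheme()` and echoed in every run summary. The seed
multiplier default was set to 4 because it is the scale the miRanda
family of tools uses and because it places a perfect 22-nt duplex
(7·5·4 + 15·5 = 215) above the score threshold, which any sensible
scoring of a perfect site must do; a multiplier of 2 would cap perfect
sites at 145 and make the score threshold unsatisfiable.

Non-overlapping sites are reported greedily: the best site is found,
the target is split around it, and the flanks are re-searched. Because
the best alignment inside a sub-segment can never out-score the
segment's own best, pruning the recursion at the score threshold is
lossless for threshold-filtered consumers; `align_duplex()` retains all
positive-score local maxima when asked.

The free-energy estimate is a nearest-neighbour sum over consecutive
paired columns using a shipped 6×6 stacking table (`duplex_stack_table()`)
plus a duplex-initiation penalty of +4.09 kcal/mol. Watson–Crick/
Watson–Crick stacks carry published Turner 2004 ΔG37 values; stacks
involving G:U wobble carry approximate Turner-style values. Helix-end
A:U penalties, loop entropies and target-site accessibility are not
modelled: the estimate is a screening statistic, not a folding
prediction, and the screening rule it feeds uses a single coarse cut.
Mismatched or gapped columns contribute nothing and interrupt stacking,
so an isolated base pair scores only the initiation penalty and can
never pass the −30 kcal/mol cut.

## The synthetic benchmark and what it does (not) show

`simulation_config()` defines the emulated study: a balanced
two-condition design with `n_per_condition = 6` samples per arm,
40 planted triplets per stratum, a log2 effect of 2.5 (fold change
≈ 5.66) on planted features, and per-feature Gaussian noise of sd 0.4
log2 units; background features (150 lncRNA / 40 miRNA / 300 mRNA by
default) are condition-free noise around uniform baselines. Six samples
per condition is the smallest design in which the pooled-correlation
rule r > 0.90 with P < 0.001 (n = 12) is comfortably attainable.

Within a planted triplet, a per-sample latent factor is shared by the
three members with opposite sign on the miRNA. The coupling parameter
is the *fraction of the noise sd* loaded on that shared factor
(default 0.9), so each feature's marginal noise stays at `noise_sd`
while the expected pooled lncRNA–mRNA correlation is about 0.98 and the
miRNA's correlations with both partners are the mirror image. An
additive latent factor on top of the noise was rejected by design: it
inflates within-condition variance, which simultaneously weakens the
t-test and the correlation filter, and under the stated effect and
noise levels would make the default design internally inconsistent.

Sequences: each miRNA is a random 22-mer with GC fraction constrained
to [0.35, 0.65] (the realistic range — an AU-only duplex is too
unstable for any energy threshold); each planted target embeds the
exact reverse complement of its triplet's miRNA at a recorded position
in an otherwise random 500-nt sequence. Decoy targets are guaranteed to
contain no exact complement of length ≥ 8 nt to *any* miRNA. With
~120 miRNAs the forbidden 8-mer set is so dense that whole-sequence
rejection sampling essentially never terminates, so decoys are produced
by local repair: offending windows are point-mutated until the scan is
clean, with planted sites frozen. Gene sets: one term packed with 80%
planted upregulated mRNAs plus 50 uniform background terms.

The generator reproduces the statistical structure the screening
cascade assumes — sign patterns, coexpression strength, seed-exact
binding sites, an enriched term — but deliberately not microarray
probe effects, normalisation artefacts, secondary-structure
accessibility, or biological miRNA target-site taxonomy. Recovery
results on it therefore validate the *pipeline's logic and
implementation*, not the biological error rates to expect on real
arrays; with real data the published node counts additionally depend on
era-specific annotation and the exact external prediction tools, which
is why they are out of scope here.

## Enrichment

Over-representation uses the exact upper-tail hypergeometric test with
the expression platform (all assayable mRNAs) as universe — the
standard choice, and the only universe an analysis artifact can know.
The DAVID-style EASE adjustment (discounting one overlap gene) is
available as a flag; the exact test is the default for statistical
transparency. Reporting keeps raw P < 0.05 (matching the screening
convention of the source workflow) with BH q-values alongside, top 30
by default.

## Problem sizes used in the shipped checks

The bundled tests and the acceptance script run the default design
(6 + 6 samples, 40 triplets per stratum, ~490 background features,
500-nt targets) over ten seeds, plus exact-oracle comparisons on small
instances (alignment oracles up to 10×30 nt, exhaustive hypergeometric
enumeration up to N = 30, brute-force triplet assembly up to ~50
features per class). These sizes were chosen so the full benchmark
remains a few minutes of single-core compute while every filter
operates in its intended regime.

## Known limitations

* The alignment scoring is miRanda-*like*, not a bit-for-bit clone;
  published networks built with specific miRanda builds will not be
  reproduced exactly (the tool's non-threshold parameters were never
  published).
* The energy model omits accessibility and end effects (above).
* Hub extraction considers lncRNA hubs only, by design.
* Probe-level replicate collapsing is assumed done upstream; the
  readers reject missing values rather than imputing.
* The pipeline applies hub extraction to the finished networks
  (post-hoc); building the network from hub lncRNAs first is available
  by calling `extract_hub_subnetwork()` on intermediate results, and
  both orderings are exposed deliberately because workflow descriptions
  of this kind are ambiguous on the point.
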