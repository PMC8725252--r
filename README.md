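# ceRNAnet

Sign-stratified lncRNA–miRNA–mRNA competing-endogenous-RNA (ceRNA) network
inference from two-condition multi-omic expression data and transcript
sequences, with a synthetic-data generator that plants recoverable ground
truth for end-to-end benchmarking.

## The problem

In the ceRNA (miRNA-sponge) model, a long non-coding RNA that shares
miRNA binding sites with an mRNA competes for the shared miRNA pool and
thereby de-represses the mRNA. In a two-condition experiment (e.g. an
induced differentiation time point vs control) this model predicts
coherent *sign-stratified triplets*: an upregulated lncRNA, a
downregulated miRNA, and an upregulated mRNA — or the mirror image — in
which the miRNA binds both transcripts, the miRNA is negatively
coexpressed with both, and the lncRNA and mRNA are strongly positively
coexpressed. `ceRNAnet` implements this screening cascade as a reusable,
tested pipeline for anyone who has three expression matrices (lncRNA,
miRNA, mRNA; same samples) plus sequences, and wants the tripartite
networks, their hub lncRNAs, and enrichment-anchored subnetworks.

## The method

For each RNA class, features are screened by a pooled-variance two-sample
t-test on log2 values with the classic microarray filter

&nbsp;&nbsp;&nbsp;&nbsp;|signed fold change| > 2 and P < 0.05,

where the signed fold change is ±2^|Δ| for the difference Δ of log2
means. miRNA binding sites on candidate lncRNAs and mRNAs are predicted
with a seed-weighted Smith–Waterman local duplex alignment (reversed
miRNA vs target, Watson–Crick +5, G:U wobble +2, mismatch −3, affine
gaps −9/−4, seed positions 2–8 weighted ×4) plus a nearest-neighbour
duplex free-energy estimate from Turner-style stacking energies; a site
passes at score > 160 and ΔG ≤ −30 kcal/mol. Pairs are kept only when
the miRNA is significantly negatively correlated with the target across
all pooled samples, and a triplet additionally requires its lncRNA–mRNA
Pearson correlation r > 0.90 at P < 0.001. Passing triplets are
assembled into two strictly tripartite networks (UP and DOWN strata);
lncRNAs with degree > 8 define hub subnetworks, and each network's
mRNAs are tested for gene-set over-representation with the upper-tail
hypergeometric test (BH-adjusted q-values alongside raw p).

All thresholds are configurable via `run_config()` and echoed in the run
summary; the defaults above are the published screening values.

## Worked example

Simulate the default benchmark design (6 + 6 samples, 40 planted
triplets per stratum, log2 effect 2.5, noise sd 0.4), run the full
pipeline, and inspect the result:

```r
library(ceRNAnet)

cfg  <- simulation_config(seed = 1)
sim  <- simulate_expression(cfg)                 # bundle + ground truth
seqs <- simulate_sequences(cfg, sim$truth)       # FASTA-style sequences
gs   <- simulate_genesets(cfg, seqs$truth)       # GMT-style gene sets

run <- run_pipeline(sim$bundle, seqs$mirna_seqs, seqs$target_seqs,
                    gs$collection, run_config(), output_dir = "out")
print(run)
```

```
ceRNA pipeline run
  DE lncrna: 40 up / 40 down
  DE mirna : 40 up / 40 down
  DE mrna  : 40 up / 40 down
  predicted pairs: 166 (165 after anticorrelation filter)
  UP network: 41 triplets, 40 lncRNA / 40 miRNA / 40 mRNA nodes, 81 edges
  DOWN network: 44 triplets, 40 lncRNA / 40 miRNA / 40 mRNA nodes, 84 edges
```

Reading this: all 80 planted differential features per class were
recovered in the correct stratum; 166 (miRNA, target) pairs passed the
score/energy thresholds (the 160 planted arms plus a handful of
spurious alignments); and the two assembled networks contain all 80
planted triplets plus a few false positives that share the planted
condition shift. `run$networks$UP` is a `cerna_network` with nodes,
typed edges and triplet provenance; `summary(run$networks$UP)` lists
hub lncRNAs; `run$enrichment$UP$records` ranks the planted enriched
term first. `out/` holds the per-stage TSV tables, Cytoscape-compatible
SIF and GraphML exports, and `run_summary.json` with the full effective
parameter set.

Real data enter the same way through `read_expression()` (three TSV
matrices + a sample sheet), `read_rna_fasta()` and `read_gmt()`.

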