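# dualchip

Differential promoter-targeting analysis for paired ChIP experiments.

When two related chromatin factors — say, two RB-family corepressors
profiled by ChIP-exo — bind overlapping but non-identical sets of gene
promoters, the questions that follow are always the same: which genes
does each factor target, which are co-bound, which binding-site motifs
explain the observed enrichment, and do co-bound promoters carry
*stronger* motif sites than promoters bound by only one factor?
`dualchip` implements that analysis as a reusable, deterministic R
pipeline, together with a ground-truth synthetic data generator so every
stage can be validated end to end without external data.

## What it computes

* **Peak annotation** — each peak (anchor = summit, else midpoint) is
  assigned to the nearest TSS with a signed strand-aware distance and a
  `promoter` / `gene_body` / `intergenic` label (promoter window
  −1000..+100 bp).
* **Co-binding classes** — a promoter is bound when a peak anchor lies
  within 500 bp of the TSS; two factors' calls partition genes into
  `both` / `A_only` / `B_only` / `none`.
* **Promoter enrichment** — the max-average statistic over the 500 bp
  upstream of each TSS: max over sliding 50-bp windows of the mean
  coverage.
* **Motif sites and occupancy** — PWM scanning with exact site
  p-values under the i.i.d. background model (full enumeration for
  width ≤ 6, discretized dynamic programming otherwise), MAST-like
  site filter at p ≤ 0.0005, greedy non-overlapping site selection,
  and a sequence occupancy score
  O(S) = Σ<sub>windows, ±</sub> 2<sup>s − s<sub>max</sub></sup>.
* **Association screen** — per motif, Pearson correlation between
  occupancy and each factor's enrichment across the gene universe,
  categorized at r > 0.19 (high) and |r_A − r_B| < 0.04 (shared) /
  > 0.14 (differential).
* **Site-strength comparison** — pooled −log10 site p-values of
  co-bound vs single-factor promoters, one-sided Mann–Whitney U
  (exact for small untied samples), α = 0.05, with BH-FDR reported
  alongside.
* **Peak-set overlap** — anchors within 100 bp or intersecting
  intervals, with a hypergeometric genome-binning significance model.

See `vignettes/dualchip-methods.Rmd` for the models, assumptions and
design decisions.

## Worked example

Generate a synthetic dataset (one 200-kb chromosome, 100 genes, a
planted target motif with stronger sites in co-bound promoters, 20
decoy motifs) and run the full pipeline:

```r
library(dualchip)

ds  <- generate_dataset(synthetic_spec(seed = 7), dir = "demo_data")
cfg <- pipeline_config(
  genome   = ds$files[["genome"]],   genes  = ds$files[["genes"]],
  peaks    = c(A = ds$files[["peaks_A"]],    B = ds$files[["peaks_B"]]),
  coverage = c(A = ds$files[["coverage_A"]], B = ds$files[["coverage_B"]]),
  motifs   = ds$files[["motifs"]], outdir = "demo_out")
res <- run_pipeline(cfg)

attr(res$cobinding, "counts")
#>   both A_only B_only   none
#>     13      8     26     53

head(res$screen, 3)
#>   motif_id   r_A    r_B  delta category_A category_B delta_category
#> 1  planted 0.613  0.571 0.0425       high       high   intermediate
#> 2 decoy_15 0.200  0.244 0.0448       high       high   intermediate
#> 3 decoy_16 0.206 -0.144 0.3504       high   negative   differential

res$strength[res$strength$motif_id == "planted",
             c("n_cobound", "n_single", "U", "p_cobound_greater",
               "direction", "significant")]
#>   n_cobound n_single     U p_cobound_greater direction significant
#> 1        16       34 413.5          0.001273   cobound        TRUE
```

The planted motif tops the screen with high correlations for both
factors (its occupancy drives both coverage tracks), and the strength
test detects the planted differential: the 16 sites found in co-bound
promoters are stochastically stronger than the 34 in B-only promoters
(one-sided p = 0.0013). The peak-set overlap is likewise far above
chance: 13 of 21 factor-A peaks have a factor-B peak within 100 bp
against 0.8 expected (log10 p = −10.7). Checking the calls against the
generator's truth table:

```r
evaluate_recovery(res$cobinding, res$screen,
                  res$strength[res$strength$motif_id == "planted", ],
                  ds$truth, ds$planted_motif)$class_accuracy
#> [1] 1
```

Every output is also written to `demo_out/` as a TSV with a provenance
header, plus a `manifest.json` of md5 checksums; rerunning the same
config reproduces the checksums byte for byte. A thin CLI wrapping the
same functions lives at `inst/scripts/dualchip.R`
(`simulate`, `run-all`, and per-stage subcommands).

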