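---
title: "dualchip: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dualchip: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

`dualchip` compares how two chromatin factors assayed by ChIP (for
example two RB-family corepressors profiled by ChIP-exo in fly embryos)
target gene promoters, and asks which transcription-factor binding
motifs explain the observed binding. The pipeline has four analytical
stages on top of ordinary format I/O:

1. **Peak annotation and co-binding classification.** Each peak is
   reduced to an anchor point (its summit if recorded, else the
   interval midpoint) and assigned to the gene with the nearest TSS.
   A gene's promoter is called *bound* by a factor when some peak
   anchor falls within 500 bp of the TSS (inclusive, both directions),
   and the two factors' calls partition genes into
   `both` / `A_only` / `B_only` / `none`. A separate annotation window
   of −1000..+100 bp (relative, strand-aware) labels peaks
   `promoter` / `gene_body` / `intergenic`.

2. **Quantitative promoter enrichment.** For each gene, coverage in
   the 500 bp upstream of the TSS (strand-aware) is summarized as the
   *max-average* statistic: the maximum, over all sliding windows of
   width $w$ (step 1), of the mean per-base signal. For a promoter
   shorter than $w$ (truncation at a chromosome edge) the mean over
   the whole interval is used; an empty interval scores 0.

3. **Motif screen.** Each PWM in a library is scored against every
   promoter with a sequence-level *occupancy score*
   $$O(S) = \sum_{\text{windows } x \in S,\ \pm} 2^{\,s(x) - s_{\max}},$$
   the sum over both strands of relative affinities, where $s(x)$ is
   the log2-odds score of window $x$ and $s_{\max}$ the motif's
   maximum achievable score. The screen reports, per motif, the
   Pearson correlation between occupancy and each factor's promoter
   enrichment over the gene universe, categorized by fixed thresholds
   (high: $r > 0.19$; negative: $r < 0$) and by the between-factor
   difference $|r_A - r_B|$ (shared $< 0.04$, differential $> 0.14$).

4. **Site-strength comparison.** Motif *sites* are windows whose
   p-value under the i.i.d. background model is at most 0.0005.
   Overlapping sites within a promoter are resolved greedily by
   ascending p-value. Site p-values are transformed to $-\log_{10} p$
   and pooled across the promoters of the co-bound group and of the
   single-factor group; a one-sided Mann–Whitney U test asks whether
   co-bound promoters carry stochastically stronger sites, at
   $\alpha = 0.05$.

Peak-set agreement between the two factors is quantified as the number
of A peaks with a B anchor within 100 bp or an intersecting interval,
with significance from a hypergeometric genome-binning null (below).

# Site p-values

The null model is i.i.d. background sequence. For a motif of width
$\le 6$ the score distribution is enumerated exactly over all $4^w$
words. For wider motifs the per-position log-odds scores are quantized
to 1000 levels across the motif's score range and convolved position by
position — the classical dynamic-programming construction used by
MAST-family scanners. The scanner scores windows on the integer grid
used by the convolution, so reported p-values are exactly consistent
with the null distribution they came from; doubling the bin count moves
any p-value by less than 1/bins (property-tested). Reverse-strand
windows are scored with the reverse-complemented matrix, which gets its
own null distribution so asymmetric backgrounds are handled correctly.

Windows containing N are skipped by default (`n_policy =
"skip_window"`); the alternative `score_as_background` lets N contribute
a zero log-odds term. A MAST-style sequence-level E-value cap is
accepted in the configuration for compatibility but is deliberately a
no-op: only the site-level p-value threshold is load-bearing anywhere
downstream.

# The occupancy score as a deliberate simplification

The correlation screen needs one number per motif per promoter that
ranks sequences by predicted binding. A fitted thermodynamic occupancy
model (with free concentration and cooperativity parameters) is one way
to produce it; `dualchip` instead uses the parameter-free
relative-affinity sum above. With cooperativity absent and a single
motif considered at a time, the fitted model's output is a monotone
transform of summed Boltzmann weights, so the rank structure the screen
consumes is preserved while the result stays fully reproducible — no
training step, no initialization, no fitted constants. This is a
documented deviation, not an approximation claim: absolute occupancy
values are not comparable to any fitted model's output.

# Overlap significance: the binning null

HOMER-style overlap significance requires a null for "how many A peaks
would sit near B peaks by chance". The genome is divided into bins of
width twice the overlap threshold; with $a$ bins holding A anchors,
$b$ holding B anchors, and $N$ bins total, the number of shared bins
under independent placement is hypergeometric, and the upper tail is
reported as $\log_{10} p$. The model is validated against a
permutation null (uniform re-placement of B anchors, 1000 shuffles) and
agrees within 15% on informative configurations. One caveat is
property-tested explicitly: the bin grid is anchored at coordinate 0,
so coordinate-mirroring a dataset can move anchors across bin
boundaries and perturb $\log_{10} p$ slightly, while the overlap
*count* is exactly mirror-invariant.

# Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| promoter analysis window | 500 | bp upstream of TSS | enrichment, scanning, occupancy |
| annotation window | −1000..+100 | bp around TSS | promoter label for peaks |
| binding-call distance | 500 | bp, inclusive, symmetric | co-binding classification |
| overlap threshold | 100 | bp anchor distance | peak-set agreement |
| enrichment window $w$ | 50 | bp | sliding max-average; see below |
| site p-value cutoff | 0.0005 | — | MAST-like site filter |
| score bins | 1000 | levels/position | DP p-value discretization |
| screen thresholds | 0.19 / 0.04 / 0.14 | correlation | high / shared / differential |
| strength $\alpha$ | 0.05 | one-sided | Mann–Whitney threshold |

The sliding-window width has no canonical published value; 50 bp is an
order-of-magnitude match to high-resolution ChIP footprints, and the
choice is echoed into every output's provenance header so results are
interpretable. Sliding uses step 1 (the exact maximum) — promoters are
short enough that strided approximation would save nothing. Only full
windows are evaluated; the whole-interval mean is the fallback when the
interval itself is shorter than $w$.

Two conventions are resolved explicitly because upstream descriptions
leave them open: the 500-bp binding call is inclusive at the boundary
and symmetric around the TSS, and promoter sequences of minus-strand
genes are reverse-complemented before any motif work, so "upstream" is
always biologically upstream. The alternative (genome-forward
extraction) would score the two strands of the same physical sequence,
which the strand-symmetric scanner makes nearly — but not exactly —
equivalent; strand-oriented extraction is the biologically coherent
reading. Nearest-TSS ties break lexicographically by gene id for
determinism. In the strength comparison, sites are pooled across
promoters (sites are the sampled units); comparing per-promoter
summaries instead would weight promoters equally regardless of site
count and is not implemented.

# The synthetic data generator

`generate_dataset()` emulates the study design the analysis assumes:

* an i.i.d. background genome (default 200 kb, base composition
  0.3/0.2/0.2/0.3) carrying 100 non-overlapping genes on random strands;
* co-binding classes drawn per gene with fractions 0.20 (`both`),
  0.10 (`A_only`), 0.25 (`B_only`) — factor B targets roughly twice as
  many genes as factor A, matching the asymmetry the analysis is meant
  to resolve;
* one site of the target motif planted per bound promoter, sampled at
  temperature 0.35 (near-consensus) in co-bound promoters and 1.0 (the
  PWM's own entropy) in single-factor promoters — the planted
  differential the strength test should detect; site strand is random,
  exercising the reverse-complement path;
* per-factor coverage = Poisson(2) background plus Gaussian bumps
  (amplitude 20, sd 60 bp) centered on the planted site, not on the
  TSS, so the max-average statistic genuinely has to find the signal;
* peak calls at the true sites with ±50 bp uniform jitter and recorded
  summits.

Planted sites keep a margin of jitter + motif width from promoter
edges, so binding calls are exercised without boundary dropout; with
the default jitter this makes class recovery essentially
deterministic, which is intended — classification accuracy measures
coordinate bookkeeping, not luck. All randomness flows from one master
seed through per-stage child seeds, so changing, say, the coverage
parameters does not perturb the gene placement draw, and regeneration
is byte-identical.

What the generator does *not* emulate: read-level noise (no FASTQ),
ChIP-exo strand asymmetry, realistic genome composition (repeats, CpG
structure, real promoter base bias), overlapping or nested genes,
multiple sites per promoter, and motif co-occurrence structure.
Passing recovery tests therefore demonstrate that the pipeline's
statistics faithfully recover the structure they model — not that the
model captures everything in real ChIP data.

# Validation scales

The test suite and the acceptance script validate at fixed problem
sizes chosen as the package's reference conditions: 100 independent
datasets (100 genes / 200 kb each) for parameter recovery; 1000
repeats for the null calibration of the strength test; $10^6$
background windows per strand for scanner calibration; exhaustive
enumeration oracles at motif widths ≤ 6 and brute-force re-implementations
for window scores, sliding-window maxima, overlap counts,
hypergeometric tails and exact Mann–Whitney p-values.

# Known limitations

* The occupancy score is rank-faithful but not calibrated to any
  physical occupancy; only its correlations are interpreted.
* The overlap null ignores chromatin accessibility structure — as any
  uniform-genome null does — and its binning grid is
  coordinate-anchored (see above).
* With very small groups the one-sided Mann–Whitney p is discrete;
  the normal approximation with tie correction takes over beyond 20
  pooled observations, and heavy ties (discretized p-value grids) make
  the test mildly approximate there.
* Enrichment is raw coverage, not input-normalized; replicate merging
  and log-ratio enrichment are out of scope.
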