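---
title: "Clonal tracking of barcoded xenografts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal tracking of barcoded xenografts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrack)
```

# Overview

`clonetrack` analyses lentiviral cellular-barcoding experiments in
xenotransplanted leukaemia: unique DNA tags are integrated into individual
cells before transplant, and the barcode amplicon is sequenced from each
harvested organ. Because no public raw dataset accompanies this experimental
design, the package pairs its analysis pipeline with a full forward
simulator that produces reads *and* exact ground truth, so every stage of
the analysis can be validated against truth rather than against itself.

This vignette documents the models, the parameters that matter, the
numerical conventions, and what the simulation-based validation does and
does not establish about real data.

# The simulation model

## Library, transduction and founders

The barcode library is a uniform random sample of `n_library_tags` distinct
tags of `tag_length` nucleotides (default 100,000 tags of 30 nt), flanked
in the amplicon by fixed anchors (default 20 nt each). Real barcode oligo
designs vary and are often unpublished; since only anchor-delimited
extraction is exercised downstream, the layout is fully configurable and
the defaults are deliberately generic.

Each of the `dose` transplanted barcoded cells carries
$k \sim \text{Poisson}(\text{moi})$ integrations conditioned on $k \ge 1$.
The default `moi = 0.1` reflects the practice of capping transduction near
10% precisely to keep multiple integrations rare; a cell with $k$ tags
contributes its entire clone abundance to all $k$ tags, which is how
multi-integration cells distort real barcode counts. Engraftment is an
independent per-cell Bernoulli event with probability
`engraftment_probability` (default 0.1, inside the 1:2–1:29 range that
limiting-dilution estimates give for these leukaemias). There is no
cell–cell interaction: the observed insensitivity of engraftment to a 10×
excess of unlabelled carrier cells motivates modelling carriers as inert,
and the simulator accordingly never draws randomness for them (so the
dilution control is an exact invariance, which the tests assert).

## Organ growth: pooled versus niche

Every founder clone receives one log-normal whole-animal expansion factor
with coefficient of variation `growth_cv` (default 1.0; unitless). Organs
then differ only in how they sample the animal:

- **pooled** organs (spleen, spleen parts, meninges) are independent
  multinomial samples of `n_cells` cells (default $10^6$) from the
  whole-animal clone vector — the spleen filters the blood, so it sees the
  full repertoire;
- **niche** organs (individual femurs/tibias) are assembled from
  `n_niches` niches (default 5), each colonised by `niche_founders` clones
  (default 10) drawn proportionally to whole-animal abundance and then
  re-expanded with fresh independent log-normal factors.

The niche model is the minimal mechanism that produces focal clonal
dominance in single bones without giving any clone an intrinsic advantage:
dominance arises purely from which clones happen to colonise and expand in
each niche, so the dominant clones differ between bones and between
replicates. The defaults were fixed once as plausible study conditions, not
fitted to anything.

Serial transplants re-transplant `secondary_dose` cells drawn
multinomially from the parent spleen's clone abundances, each engrafting
with the same Bernoulli probability; recipients inherit the parent's
`lineage_id`.

## Sequencing reads

Per sample, `read_depth` reads of `anchor5 + tag + anchor3` are drawn with
probability proportional to clone abundance × a per-tag log-normal PCR
factor with log-SD `pcr_sigma` (default 0.5). The PCR factor is resampled
per sample, never per animal, so amplification bias can never masquerade as
heritable clone behaviour. Each base is substituted independently with
probability `substitution_rate` (default 0.001, a typical MiSeq
substitution rate; indels are not modelled — an indel-bearing read simply
fails anchor extraction). Finally each read is reassigned to a uniformly
chosen other sample of the same run with probability `hop_rate` (default
0.001), emulating index hopping; hopping conserves run totals. All
randomness flows from one root seed through named sub-streams (library,
per-mouse founders, per-mouse growth, per-sample reads, hopping), so stages
are independently reproducible and byte-identical under a fixed seed.

What the generator does **not** emulate: paired-end reads, base-quality
error profiles, indels, chimeric PCR products, growth kinetics over time
(only terminal abundances), and cell death after engraftment. Passing the
truth-recovery tests therefore shows the pipeline is correct under
substitution-dominated noise with known provenance; it does not certify
performance on data whose error modes violate these assumptions.

# The analysis pipeline

## Extraction

`extract_tags()` finds the 5' anchor allowing up to `max_anchor_mismatch`
substitutions (default 2, shared across both anchors), takes the next
`tag_length` bases as the tag, and requires the 3' anchor immediately
after. Among candidate anchor positions the best-scoring one wins, with
leftmost as tie-break; an exact leftmost occurrence is provably that
candidate, which gives a fast path, and remaining reads go through
`Biostrings::vmatchPattern`. Reads that are too short, contain non-ACGTN
characters, carry an `N` in the tag, or exceed the mismatch budget are
no-calls — counted but never corrected. No indel alignment is attempted,
keeping extraction linear in read length and faithful to the
substitution-dominated error model.

## Clone calling: three filters

1. **Detection threshold** (`min_frac`, default $10^{-4}$, i.e. 0.01% —
   the empirical detectability floor of this assay class): every retained
   barcode must comprise *strictly more than* `min_frac` of the sample's
   assigned reads. The total is fixed at the pre-filter assigned total,
   which makes lowest-count-first removal equivalent to a single cutoff
   and keeps the filter deterministic, order-free and idempotent. An
   iterative variant that re-normalises the total after each removal is
   available (`recompute_total = TRUE`); it can only be more permissive,
   and both are provided because published descriptions of the rule are
   ambiguous on this point.
2. **Single-base collapse** (`parent_ratio`, default 10): a tag is removed
   when a Hamming-distance-1 neighbour in the same sample has at least
   `parent_ratio` times its count. This is the directional-adjacency
   convention from UMI error correction, standing in for the manual
   curation of "single base changes from high-frequency barcodes".
   Decisions are made against the original counts in a single pass (no
   chaining), and removed reads are discarded rather than merged, because
   curation removes barcodes, it does not reassign reads. The ratio is
   configurable because any fixed ratio is a proxy for human judgement;
   distance-1 pairs that are genuine independent clones cannot be
   distinguished by any count rule.
3. **Cross-sample cleaning**: within one sequencing run, a tag is removed
   from a sample when a sample of a *different lineage* carries the
   identical tag at strictly higher frequency (count over assigned total).
   Samples sharing a lineage — a mouse and its serial-transplant
   descendants — are exempt, because they share barcodes legitimately;
   without the exemption every persistence analysis would delete its own
   signal. Frequency ties keep the tag everywhere (the rule reads "higher"
   strictly).

`call_clones()` applies the three filters in that order, logs every
removal (stage, sample, tag, reference value), and renormalises
frequencies over retained reads. All thresholds are referenced to the
pre-filter assigned totals, so each filter is a contraction and idempotent,
and on hop-free data the collapse and cross-sample stages commute (both
properties are asserted as tests).

## Statistics

- Gene diversity $H = 1 - \sum_i p_i^2$; between samples, on the union tag
  universe with zero-fill, $H_S$ = mean within-sample $H$, $H_T$ = $H$ of
  the equal-weight mean vector, and $G = (H_T - H_S)/H_T$, defined as 0
  when $H_T = 0$ (monomorphic identical samples have no subdivision).
  Equal-weight pooling without small-sample correction is the default
  since amplicon read depths are large; `correction = "unbiased"` applies
  the $n/(n-1)$ within-sample factor when sample sizes are small.
- The engrafting-cell frequency 1:N uses
  $N = \text{round}(\text{cells} \times \text{transduction} /
  \text{barcodes recovered})$ with round-half-up and a floor of 1 — the
  only rounding convention consistent with all eight published dose groups
  (quotients 15.1, 12.76, 6.45, 2.44, 6.27, 28.85, 7.09, 8.93 print as 15,
  13, 6, 2, 6, 29, 7, 9). For multi-mouse dose groups, "barcodes
  recovered" is the arithmetic mean across replicate spleens.
- Persistence and site sharing use a dominance cut (default 1%) in the
  reference sample and a detection floor (default 0.01%) in the compared
  samples; both are parameters, since published displays also use 2% and
  5% cuts.

# Numerical conventions and degenerate inputs

- Frequency vectors must sum to 1 within $10^{-6}$; renormalised clone
  tables satisfy this to $10^{-9}$.
- Empty results are values, not errors: a sample whose tags are all
  filtered yields an empty clone table with a complete filter log;
  `richness_metrics()` on an empty table returns zeros with a warning.
  Genuine contract violations (empty founder set, zero recovered barcodes,
  mixed tag lengths, multi-run input to the cross-sample filter) are
  errors that name the offending key or sample.
- TSV outputs use fixed column orders and lexicographically sorted tags,
  so reruns are byte-identical.
- Truncated Poisson draws use the inverse-CDF transform (bounded RNG use);
  substitution errors are drawn as a single without-replacement sample
  over the read × position grid, which is exact for independent per-base
  errors.

# Validation strategy and problem sizes

The test suite validates each stage against an independent oracle: binomial
moments for founder counts, $0.99^{30}$ for error-free tag fractions, a
sliding-window extraction oracle, an all-pairs collapse oracle, a
first-principles recomputation of $G$, and simulator read provenance for
the cross-sample filter. End-to-end, clone calling at read depth $10^6$
over 500 founders recovers exactly the founder tags above the 0.01%
threshold under error-free sequencing — defined as
`substitution_rate = 0`, `hop_rate = 0` *and* `pcr_sigma = 0`, since PCR
bias is itself sequencing noise that legitimately perturbs read
frequencies around the threshold — and stays within 2% of true richness at
1% substitution error. Spatial-drift properties use 100 replicate
truth-level simulations of 500 founders; dose–response uses the
100/1,000/10,000 sweep at read depth $10^5$. These sizes keep the full
suite within a few minutes while leaving Monte-Carlo margins wide.

# Known limitations

- The niche model is phenomenological: it reproduces stochastic focal
  dominance but is not calibrated to marrow anatomy; `n_niches` and
  `niche_founders` shape how extreme the dominance is.
- The collapse ratio cannot recover a genuine clone that is a single base
  away from a 10×-larger clone; with 30-nt random tags and realistic
  clone numbers such pairs are vanishingly rare in the library, but they
  can arise in low-complexity libraries.
- The cross-sample filter assumes contamination is rarer than signal; a
  tag genuinely shared by two lineages at similar frequencies (e.g. a
  library collision at high dose) will be kept in both, and at very
  different frequencies the minor one is lost.
- `G` is computed on called clone frequencies; heavy filtering truncates
  rare tags and therefore compresses diversity in all samples alike.
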