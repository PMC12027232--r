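---
title: "Selecting and validating RT-qPCR reference genes with refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and validating RT-qPCR reference genes with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(refstab)
```

## The problem

RT-qPCR quantifies a target gene's transcript level relative to one or more
*reference* (housekeeping) genes, assumed stably expressed across every
sample. That assumption fails often enough — across tissues, developmental
stages, and physiological stress — that reference genes must be validated for
each experimental system. `refstab` implements the full selection workflow as
it is practiced in non-model organisms (the bundled worked example comes from
a study of aging in male giant freshwater prawn, *Macrobrachium
rosenbergii*):

1. **screen** a transcriptome-wide TPM matrix for housekeeping-like
   candidates,
2. **score** candidate stability from qPCR Cq values with four established
   statistics (comparative ΔCt, geNorm, NormFinder, BestKeeper),
3. **aggregate** the four rankings into a comprehensive geometric-mean
   ranking and decide how many references suffice,
4. **normalize** target genes by 2^−ΔΔCt against the chosen references.

A seeded synthetic-data module generates TPM and Cq matrices with planted
stable and unstable genes, so every stage of the pipeline can be validated by
parameter recovery without any external data.

## Transcriptome screening

`apply_criteria()` applies four gates to a genes × samples TPM matrix with a
tissue-labelled annotation:

* **I. Detectability** — TPM > 0 in every sample of each required tissue
  (default: muscle, hepatopancreas, testis, heart). This is the strictest
  reading of "detectable"; `min_detect_fraction` relaxes it to a fraction of
  samples per tissue.
* **II. Low variance** — standard deviation of log2(TPM) < 1.
* **III. No outlying sample** — every sample's |log2(TPM) − mean log2(TPM)|
  < 2.
* **IV. High expression** — mean log2(TPM) > 5.

Survivors are then shortlisted by coefficient of variation
(CV = sd/mean of log2(TPM)) < 0.1. All summaries use the sample standard
deviation (n − 1): at the 2-decimal precision such tables are reported with,
the choice of denominator is immaterial, but the sample form is the standard
small-n convention.

Two details are deliberate:

* log2 is taken on raw TPM with **no pseudocount**. Criterion I already
  guarantees positivity for every gene that reaches criteria II–IV, so a
  pseudocount would only blur the statistics it feeds.
* The gates can be chained (`mode = "sequential"`, the default, which makes
  stage counts non-increasing) or evaluated independently on criterion I's
  survivors (`mode = "per_stage"`). Published stagewise counts are not always
  monotone — independent per-stage evaluation is the only reading consistent
  with such reports, so both modes are provided and the mode is recorded in
  the result.

`candidate_gene_stats()` ships the published 12-gene summary table from the
36-library *M. rosenbergii* screen (nine transcriptome-derived candidates
plus *eef1a*, *actb*, *gapdh*) as a worked example. Recomputing CV = sd/mean
from its printed means and SDs reproduces the printed CV column at 3-decimal
rounding for eleven of twelve rows; the *eif5a* row (0.60/6.02 → 0.100,
printed 0.099) differs by one unit in the last printed decimal, as expected
when a published table's CV was computed from unrounded summaries. The
package reports the recomputed value and leaves the bundled table as printed.

## The four stability statistics

The four methods are implemented from their source publications; all scores
are "lower = more stable".

**Comparative ΔCt** (`delta_ct_stability()`). For genes j, k the per-sample
difference ΔCt = Cq_j − Cq_k removes the shared RNA-load effect; gene j's
score is the mean over partners k of sd(ΔCt_jk), in cycles.

**geNorm** (`genorm()`). Cq is converted to relative quantities
Q = E^(minCq − Cq) (each gene's most abundant sample has Q = 1; the anchor is
the per-gene minimum Cq so Q ≤ 1). The M-value of a gene is the mean SD of
its pairwise log2 ratios; the gene with the largest M is excluded and M is
recomputed until the best pair remains. Exclusion ties are broken by removing
the lexicographically last gene id, for determinism. With all E = 2 the
initial M-values coincide exactly with the comparative ΔCt scores — a useful
cross-check asserted in the tests. The pairwise variation
V(n/n+1) = sd(log2(NF_n/NF_{n+1})), with NF_n the per-sample geometric mean
of Q over the n most stable genes, feeds
`pairwise_variation_cutoff()` (conventional threshold 0.15) to decide how
many reference genes suffice.

**BestKeeper** (`bestkeeper()`). Descriptive statistics on raw Cq: the
primary dispersion score is the mean absolute deviation around the arithmetic
mean (matching the original tool's "SD(±CP)" behaviour), with the classical
SD kept as a diagnostic; CV% = 100 × MAD / mean Cq; the BestKeeper index is
the per-sample geometric mean of all genes' Cq, and each gene's Pearson r
against the index is reported. A constant gene keeps its (best possible)
dispersion score of 0 while its correlation is flagged undefined.

**NormFinder** (`normfinder()`). Cq is treated as log2 abundance. Each sample
is centered by its mean Cq across genes (removing the RNA-load effect); per
gene i and group g the centered group mean m_ig and sample variance s²_ig
give the intergroup deviation c_ig = m_ig − mean_g(m_ig) and the stability
value

ρ_i = mean_g( |c_ig| + sqrt(s²_ig / n_g) ).

This is the direct variance decomposition **without** the original
publication's intergroup shrinkage step: at the small group counts typical of
validation panels the shrinkage mostly rescales ρ without reordering genes,
and the unshrunk form is transparent and exactly testable. With a single
group ρ_i reduces to the SD of the gene's centered values.

Missing Cq values are flagged explicitly (`NA`, never silent zeros) and
excluded pairwise/groupwise; any statistic computed on fewer than 3 values is
flagged unreliable in the diagnostics. Amplification efficiencies are
accepted either as base E (2.04) or as percentages (104.0 → E = 2.04; values
above 10 are interpreted as percent) and default to E = 2, since published
efficiencies (94–104% in the worked example) are rarely stated to have
entered the stability scoring.

## Comprehensive ranking

`comprehensive_ranking()` follows the RefFinder recipe: per-method scores
become average-tie ranks 1..G (`ranks_from_scores()`), and each gene's
comprehensive score is the unweighted geometric mean of its ranks — the
published description offers no weights, so none are invented. geNorm
contributes its exclusion-order ranking; its jointly-best pair enters as tied
rank 1.5 each by default (preserving the rank-sum invariant G(G+1)/2), with
`pair_rank = "split"` available since the alternative {1, 2} convention is
equally defensible and published figures cannot distinguish the two. Final
order is ascending comprehensive score with ties broken by ΔCt rank and then
gene id — an arbitrary but documented and deterministic choice.
`rank_across_conditions()` lays per-condition final ranks side by side with a
mean-rank summary, for reuse across tissues, stages, or stress conditions.

## 2^−ΔΔCt normalization

`ddct()` computes ΔCt = Cq_target − reference aggregate (single reference:
its own Cq; several: their arithmetic mean, i.e. the log of the geometric
mean of linear quantities), baselines against a calibrator sample or group
(group calibration uses the group's mean ΔCt, so the calibrator group's fold
changes have geometric mean 1), and reports fold = 2^−ΔΔCt. An
efficiency-corrected variant uses the target's stored base E instead of 2.
All fold changes are invariant to per-sample RNA-load shifts by construction.

## What the synthetic data emulates

`simulate_tpm()` plants four gene classes on the log2 scale
(value = base + tissue effect + noise; TPM = 2^value):

* *housekeeping* — base ~ U(5.5, 10), noise sd 0.5 **truncated at ±3σ**. The
  truncation is what lets the generator guarantee, not merely make probable,
  that every planted housekeeping gene passes all four criteria: deviations
  are capped at 1.5 < 2 (criterion III) and the sample SD stays below 1
  (criterion II). Untruncated normal noise would fail criterion III for a
  few gene × seed combinations in any large recovery experiment, which would
  say nothing about the screen itself.
* *tissue_variable* — the per-tissue effect vector is centered and rescaled
  so its per-sample dispersion is exactly `tissue_effect_sd` (default 2.0),
  structurally violating criterion II rather than probabilistically.
* *low_expressed* — base below 4, passing II–III but failing the mean floor.
* *tissue_restricted* — housekeeping-like but TPM = 0 in one designated
  tissue, failing criterion I.

Default dimensions (100 genes, 4 tissues × 9 samples = 36 libraries) mirror
a realistic screening design at desk scale; the default class mix (20
housekeeping / 80 violators) exercises every gate.

`simulate_cq()` generates Cq = base + load + shift + noise with a shared
per-sample load offset (sd 0.5 cycles — the component all four methods must
cancel), planted stable genes (noise sd 0.15 cycles, no shifts) and unstable
genes (noise sd 0.6 cycles plus per-group shifts of 1–2 cycles in random
direction, the first group serving as baseline). Defaults (6 + 6 genes, 3
groups × 6 replicates) mirror a three-condition validation panel with six
biological replicates. Each class draws from its own seeded sub-stream, so
enlarging one class leaves every other class's values bit-identical — frozen
fixtures survive config edits.

`recovery_experiment()` ties it together: simulate, score with all four
methods, aggregate, and ask whether the comprehensive top-k equals the
planted stable set. Under the default generator settings the comprehensive
ranking recovers the planted set in ≥ 95% of 200 seeded replicates, and the
sequential screen recovers the planted housekeeping set exactly in every one
of 50 seeds — the acceptance script recomputes both rates from scratch.

What the generators do **not** emulate: count noise and TPM normalization
artifacts of real RNA-seq, inter-run qPCR batch effects, technical-replicate
structure (the readers accept Cq values already collapsed across technical
triplicates, conventionally by their mean), pipetting outliers, or
efficiency drift. Passing recovery tests therefore demonstrates the
statistics and their implementation, not robustness to every artifact of
bench data.

## Numerical and design notes

* All serialization keeps 15 significant digits; write-then-read round-trips
  are exact, and reports are byte-identical across reruns (only the manifest
  timestamp changes).
* Delimiters are auto-detected between comma and tab (both occur in qPCR
  exports); labels are case-sensitive and matched exactly.
* Degenerate inputs: constant genes score 0 (best) everywhere, with
  undefined correlations flagged rather than invented; geNorm needs ≥ 3
  genes, ΔCt/BestKeeper ≥ 2, NormFinder ≥ 2 samples per group — violations
  raise immediate configuration errors.
* Problem sizes in the validation suites (5×8 to 12×18 panels, 200
  ranking replicates, 50 screening seeds) were chosen as the smallest sizes
  at which the planted effects are comfortably identifiable; they run in
  seconds on a laptop.

## A worked run

```{r example}
sim <- simulate_cq(cq_sim_config(seed = 7))
tab <- evaluate_stability(sim$cq)
head(tab, 4)

gn <- attr(tab, "method_results")$genorm
gn$best_pair
pairwise_variation_cutoff(gn)

fold <- ddct(sim$cq, target = "unstable_01",
             references = gn$best_pair, calibrator = "control")
aggregate(fold_change ~ group, fold, function(x) round(exp(mean(log(x))), 3))
```

The two planted stable genes ranked 1–2 here are exactly what the generator
planted; the fold-change table shows the calibrator group at geometric mean
1 and the planted condition shifts of the unstable target re-expressed as
fold changes.

## Known limitations

* The historical Excel implementations (geNorm VBA, BestKeeper spreadsheet,
  NormFinder add-in) differ in small conventions (dispersion statistic,
  shrinkage, tie handling); numeric parity with them is a non-goal, and
  marginal genes may rank differently than in outputs of those tools or of
  the RefFinder web service, whose internal re-implementations are not
  published.
* Screening operates on TPM as given; quantification upstream (and its
  biases) is out of scope, as are instrument-native run files (RDML etc.),
  melting-curve analysis and standard-curve efficiency estimation.
* No significance testing is attached to rank differences; the comprehensive
  ranking is a consensus heuristic, not an inferential procedure.
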