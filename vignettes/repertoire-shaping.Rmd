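---
title: "Models and methods: TCRβ repertoire shaping analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: TCRβ repertoire shaping analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repshape)
```

## The scientific problem

Early in gestation the enzyme TdT (terminal deoxynucleotidyl
transferase), which adds non-template nucleotides at V(D)J junctions, is
barely active. Fetal T-cell receptor β repertoires are therefore
enriched in *zero-insertion* clonotypes: short, germline-like CDR3
sequences that are easy to generate, recur across individuals (public
clonotypes), and often encode the same protein sequence through several
nucleotide routes (convergence). As TdT activity rises towards and after
birth, repertoires lengthen, diversify and individualize.

`repshape` provides the analysis toolchain for quantifying this shaping
— functionality partition, CDR3 length/insert statistics, convergence,
diversity, physicochemical CDR profiling, overlap geometry, V-usage and
depletion analysis, annotation matching, and nonparametric group
statistics — together with an explicit V(D)J recombination simulator so
that fetal-like and adult-like cohorts can be synthesized and every
analysis stage verified end to end without sequencing data.

## The generative model

A rearrangement is drawn as:

1. **Segments.** V, D, J from categorical weights (uniform by default).
2. **Deletions.** Independently at each junction-facing end, a
   truncated-geometric number of nucleotides
   $P(k) \propto q^k$, $k = 0..M$, renormalized over the truncated
   support. $M$ is the smaller of `max_deletion` and the nucleotides
   actually available: the conserved Cys codon of V and the Phe anchor
   codon of J always survive; D may be trimmed away entirely (the 3'
   support is conditioned on what the 5' trim left).
3. **Insertions.** Each junction receives a non-template run whose
   length is $0$ with probability $\pi_0$ and otherwise shifted
   geometric with parameter $p$ (mean $1/p$); inserted bases are i.i.d.
   from `nt_comp`. $\pi_0$ is the single interpretable TdT dial.
4. **Optional D skipping.** With probability `d_skip_prob` the D segment
   is omitted and the single V–J junction carries one insert run
   (default 0, keeping the scenario space minimal).
5. **Clone sizes.** Log-normal weights (sd `clone_size_sigma`) define a
   multinomial over which the requested UMIs are distributed.

The **generation probability** `pgen_nt()` of a sequence is the exact
sum of scenario probabilities over every (V, D, J, deletions,
insertions) decomposition consistent with it, found by enumerating V
prefixes, J suffixes and D placements with fragment probabilities
aggregated by realized string. It is validated in the test suite against
a brute-force oracle that carves candidate sequences by length
composition, against total-probability conservation on a fully
enumerable zero-insertion model, and against empirical frequencies of
$10^5$ simulated rearrangements. This is an intentionally small model —
a replacement for neither IGoR nor OLGA's full human TRB
parameterization — so absolute Pgen magnitudes are not comparable with
values computed under those tools; only in-model comparisons (e.g.
matched set vs repertoire mean) are meaningful.

### Preset parameters

The age presets encode only the TdT gradient; all other parameters are
shared. Values are this package's documented defaults (field-realistic
orders of magnitude, chosen once), not measured quantities:

| parameter | preterm_like | term_like | adult_like | meaning |
|---|---|---|---|---|
| `pi0` | 0.45 | 0.15 | 0.05 | P(zero-length insert run) per junction |
| `ins_p` | 0.3 | 0.3 | 0.3 | shifted-geometric run length, mean ≈ 3.3 nt |
| `q` | 0.4 | 0.4 | 0.4 | per-end deletion geometric parameter |
| `max_deletion` | 6 | 6 | 6 | cap per end, nt |
| `nt_comp` | GC-rich (0.2/0.3/0.3/0.2) | — | — | TdT is GC-biased |
| `clone_size_sigma` | 1.0 | 1.0 | 1.0 | log-normal clone-size dispersion |

With two junctions, a preterm-like zero-insert rearrangement fraction is
$\pi_0^2 \approx 0.2$ versus $0.0025$ adult-like — a deliberately strong,
unambiguous contrast for verification.

### What the simulator emulates, and what it does not

It reproduces: UMI-counted clonotype tables, age-dependent zero-insert
fraction and CDR3 length, V-usage bias (via segment weights), clone-size
dispersion, a realistic out-of-frame/stop fraction (no thymic selection
is applied inside the simulator, so roughly two thirds of raw
rearrangements are non-functional; the functionality filter models
selection downstream). It does **not** emulate: position-dependent
deletion profiles, P-nucleotides, segment-pair preferences, allele-level
variation, sequencing error, or the germline repertoire's true size —
the packaged library is synthetic (10 V genes / 8 families, 2 D, 3 J)
with invented CDR1/CDR2 sequences arranged so that TRBV4/TRBV7 families
score high on CDR2 binding strength. Passing tests therefore demonstrate
correctness of the *analysis machinery* and the *direction* of
ontogenic contrasts under the model, not biological effect sizes.

## Analysis definitions and numerical choices

* **Clonotype identity** is (V gene, CDR3nt, J gene) with alleles
  stripped on read; duplicate keys are aggregated by summing UMI
  counts, order-independently. Gene-level collapse is this package's convention: it makes
  V-matched overlap well defined and is robust to allele-call noise.
* **Functionality**: out-of-frame when CDR3nt length is not a multiple
  of 3 (this takes precedence), else stop-codon when the translation
  contains `*`, else functional. Out-of-frame sequences keep a
  codon-wise translation with `_` marking a trailing partial codon.
* **Convergence** = distinct CDR3nt / distinct CDR3aa among the 3000
  most abundant functional clonotypes; ties in the abundance ranking are
  broken lexicographically on CDR3nt so results are platform-stable.
* **Summary features** (length, insert size, zero-insert frequency)
  default to unique-clonotype weighting with UMI weighting available;
  the two weightings answer different questions (repertoire
  structure vs molecule mass), so both are exposed and the choice is
  part of the function signature.
* **Diversity**: observed richness and entropy (natural log) divided by
  `log(richness)`, defined as 0 for a single clonotype; computed after
  hypergeometric downsampling to a fixed UMI depth (4500 in
  `feature_table()` by default, matching common practice for
  depth normalization).
* **F2 overlap** aggregates frequencies by (V gene, CDR3aa) within the
  functional subset (renormalized) and sums geometric means over shared
  keys; distances are $-\log_{10}(\max(F2, 10^{-12}))$ — the floor keeps
  disjoint pairs finite (distance 12) so MDS stays defined.
* **MDS** is Torgerson double-centering (via `stats::cmdscale`) with a
  deterministic sign convention (largest-|coordinate| positive per axis)
  and zero-padding of non-positive eigendirections, flagged.
* **Feature PCA** z-scores each column (n−1 denominator), drops
  constant columns with a report, and uses the same sign convention;
  hierarchical clustering is average-linkage on Euclidean distances of
  z-scored rows (the linkage is not biologically constrained; average is the
  default and travels with the output).
* **Annotation matching**: same V gene, equal CDR3aa length, Hamming
  distance ≤ 1. "One mismatch" is interpreted as substitutions only —
  indels are excluded, which is the conventional reading in repertoire
  matching; a clonotype counts once per label.
* **Group statistics**: Kruskal–Wallis (tie-corrected, `stats::
  kruskal.test`) with Benjamini–Hochberg adjustment across the feature
  family, and a Dunn post-hoc (implemented here: no reference
  implementation ships with base R) BH-adjusted within its own pair
  set. BY is available where a more conservative adjustment is wanted;
  BH is the default.

## Verification problem sizes

The test suite and acceptance script size simulations so the whole
verification runs in minutes on one CPU: oracle equivalence on ≥ 50
sequences of a 2 V/1 D/2 J model with `max_deletion` 2; conservation on
the enumerable zero-insertion model; sampling consistency on $10^5$
rearrangements; $\pi_0^2$ recovery on $10^4$ draws per dial; cohort
direction checks on 10 + 10 samples of 1500 rearrangements / 3000 UMIs;
detection-rate replicates on 10 + 10 samples of 250 rearrangements /
600 UMIs (the preset contrast is large, so modest samples suffice);
null calibration on 2000 Kruskal–Wallis replicates.

## Known limitations

* Pgen magnitudes are model-relative (see above).
* The synthetic germline library is small; convergence and overlap
  levels are higher than real repertoires would show at equal depth
  because the scenario space is narrow. Directions, not levels, are the
  tested quantities.
* Insert-length laws are junction-symmetric and deletion laws
  position-independent — adequate for the TdT dial, not for
  sequence-level realism.
* `simulate_repertoire` records insert lengths from the generating
  scenario; when two scenarios collapse to one clonotype key the first
  scenario's annotation is kept, which can very slightly blur
  clonotype-level zero-insert frequencies (rearrangement-level
  quantities are exact).

## A minimal session

```{r example, eval = FALSE}
lib <- synthetic_segment_library()
model <- build_preset_model(lib, "preterm_like")
reps <- simulate(model, nsim = 3, seed = 1, n_rearrangements = 1500,
                 n_umis = 3000, age_group = "preterm")
feature_table(reps, diversity_depth = 500)
```
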