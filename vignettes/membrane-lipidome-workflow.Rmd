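---
title: "Membrane lipidome remodeling analysis with lipidshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane lipidome remodeling analysis with lipidshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidshift)
```

## The problem this package addresses

Halotolerant bacteria that persist in engineered subsurface systems —
the motivating case is *Halanaerobium* in hydraulically fractured shale —
remodel their plasma-membrane intact polar lipids (IPLs) as salinity,
nutrient residence time (hydraulic retention time, HRT) and growth mode
(planktonic vs biofilm) change. The raw observable is an LC-ESI-MS/MS
peak-intensity table: rows are lipid species written in shorthand
nomenclature, columns are culture samples, one table per ionization mode
(anionic glycerophospholipids PG/PE/PA/CL ionize in negative mode;
PC and the neutral glycerolipids and sphingolipids in positive mode).

`lipidshift` turns such tables into the quantities this field reasons
with: per-comparison differential-abundance calls, subclass and
headgroup-charge compositions, abundance-weighted membrane statistics
(double-bond index and mean chain length), hierarchical sample
clustering, PLS-DA, and a Monte-Carlo cross-validated random-forest
biomarker panel. A synthetic lipidome generator with planted ground
truth makes every stage testable without any external dataset.

## Shorthand nomenclature and charge classes

`parse_lipid_name()` implements the shorthand grammar used in practice:

* `PG(14:1/15:1)` — full chain annotation, one `carbons:double-bonds`
  term per chain slot. CL carries four slots, DG/TG three (a DG's third
  slot is canonically `0:0`), every other class two.
* `PG(18:1/0:0)_A` — an empty (`0:0`) slot beyond the class's canonical
  empty slots marks a **lyso** species; `_A`/`_B` are chromatographic
  isomer labels (identical structure, distinct feature IDs).
* `PG(35:1)` — a single term for a multi-slot class is a **sum
  composition**: totals are known, per-chain resolution is not.
* `HexCer(d18:2/16:1)` — the `d` prefix marks the sphingoid base. Only
  carbons and double bonds are modeled; hydroxylation state is not.
* `PE(16:0/18:1)/PE(16:1/18:0)` — an **ambiguous dual annotation**. The
  first annotation is primary for all metrics; alternates are retained
  for reporting. Printed alternates invariably share their totals, so
  metric values do not depend on this choice.

Headgroup net charge is a pure function of the class: PG, CL and PA are
anionic; PC and PE zwitterionic; DG, TG, Cer and HexCer neutral; lyso
variants inherit the parent assignment.

Two points were genuinely open and are fixed here as package policy:

* **Per-lipid chain length.** The mean-chain-length statistic needs one
  "hydrocarbon chain length" per lipid. We use the lipid's **total**
  acyl carbon count, because it is the only definition that also covers
  sum-composition species; a `per_chain_mean` basis (total / number of
  acyl chains) is available in `chain_summary()` and
  `mean_chain_length()` for users who prefer a per-chain reading.
* **Lyso semantics for DG.** A rule of the form "any `0:0` slot means
  lyso" would mark every diacylglycerol as lyso, since DG is written
  with three slots of which one is canonically empty. We therefore
  define lyso as *fewer filled chains than the class's canonical acyl
  count* (2 for the diacyl phospholipids, ceramides and DG; 3 for TG;
  4 for CL).

## Normalization

Two schemes are implemented, each serving a different question, and both
applied **separately per ionization mode** (the two modes are acquired
in separate runs and are not on a common intensity scale):

* `total_intensity_normalize()` divides each value by its
  (sample, mode)-block total. The result is a composition: within every
  sample each mode sums to 1. This is the scale for class
  relative-abundance and charge-profile summaries.
* `log2_median_normalize()` log2-transforms and subtracts each
  (sample, mode)-block's median log2 value, so every sample's
  within-mode median is exactly 0. This is the scale for differential
  testing, clustering and the multivariate models.

Missing measurements stay missing (they are never imputed to zero);
they are excluded from medians and contribute zero to block totals.
Nonpositive intensities are an error rather than silently offset — a
minimum-positive/2 substitution for exact zeros exists behind
`zero_substitute = TRUE` and is off by default.

A species identified in both modes has no principled reconciliation on
either scale, so `merge_modes()` treats a shared lipid ID as an error
rather than guessing.

## Differential abundance

`differential_table()` compares two disjoint sample groups per lipid
with the equal-variance Student's *t*-test (`welch = TRUE` switches to
Welch) and the log2 fold change, which on log2 data is a difference of
group means. A species is significant when `p < p_threshold` **and**
`|log2FC| > fc_threshold`; the conventional working thresholds are
(0.05, 1.5), with a stricter (0.01, 2.5) pass to isolate the most
discriminant species. Thresholds are interpreted on the **log2** scale
throughout. No multiple-testing correction is applied by default —
the criterion is a joint raw-p/effect-size filter — but
Benjamini–Hochberg is available via `adjust_p = TRUE`.

The sign convention is stored in every table: positive fold changes are
elevated in the second-listed group (`B_over_A`), so a "13% vs 20%
NaCl" comparison gives positive values to species elevated at 20%.
Lipids with fewer than two replicates in either group are flagged
untestable and excluded from counts. Degenerate inputs follow explicit
conventions (zero pooled variance: p = 1 when means agree, p = 0 with a
warning otherwise).

`subclass_composition()` and `summarize_counts()` produce the
per-subclass tallies, charge roll-ups and headline percentages used in
reporting; `round_percent()` encodes the reporting convention
(approximate figures to the nearest integer, exact ones to one
decimal). `anova_screen()` ranks lipids by one-way ANOVA p-value across
all groups (raw p; ties broken by F, then ID) to pick heatmap panels.

## Membrane statistics

For a stated lipid subset — canonically the differential species of a
comparison — the package computes two abundance-weighted means:

* **DBI** (double-bond index) = Σ dᵢwᵢ / Σ wᵢ, dᵢ = total double
  bonds of lipid *i*;
* **MCL** (mean chain length) = Σ Lᵢwᵢ / Σ wᵢ, Lᵢ = per-lipid chain
  length (total carbons by default).

The weights wᵢ are log2 intensities. Median-centered values can be
negative and break the weighted-mean reading, so
`membrane_indices()` takes the **raw-state** matrix and uses the mean
log2 raw intensity across the comparison's samples as the weight; a
min-shift policy for centered input exists behind `offset = TRUE` and
warns. Both statistics are weighted means, hence bounded by the
subset's extrema, invariant to rescaling all weights, and monotone in
the weight of the extreme species — properties the test suite checks on
random subsets. They are proxies for membrane unsaturation (fluidity)
and thickness, not biophysical simulations.

`charge_profile()` aggregates total-normalized abundances into
anionic / zwitterionic / neutral fractions per sample. The default
`core_classes` basis uses the conventional roll-up — anionic = PG + CL,
zwitterionic = PC + PE, neutral = DG + TG + sphingolipids — and
excludes PA entirely; `all_classes` includes PA with the anionic
fraction. PA is chemically anionic and every species record says so;
only this aggregation treats it as out of scope.

## Multivariate procedures

* `ward_cluster()` — agglomerative clustering of samples on Euclidean
  distances with the Ward.D2 update (`stats::hclust`), i.e. the
  squared-distance Lance–Williams recurrence on unsquared input. The
  test suite verifies the merge heights against an independent
  brute-force agglomeration. Dendrograms export as Newick via
  `cluster_newick()`.
* `plsda()` — two-class PLS-DA: NIPALS PLS1 regression of the 0/1 class
  indicator on the autoscaled matrix, two latent variables by default.
  Reported are in-fit R², leave-one-out classification accuracy
  (predicted indicator cut at 0.5) and leave-one-out Q² = 1 −
  PRESS/TSS.
* `rf_biomarker_mccv()` — the multivariate exploratory ROC procedure:
  per round, balanced subsampling (majority class downsampled to the
  minority size), a stratified 2/3 train / 1/3 validation split, a
  random forest fitted on the training portion to rank all features,
  and, per candidate panel size, a forest refitted on that round's
  top-ranked features and scored on the held-out third (ROC AUC of its
  class votes, Mann–Whitney formulation with ties at 1/2 —
  `roc_auc()`). The final ranking averages importance across rounds.
  Defaults — 100 rounds, 500 trees, `sqrt(p)` features per split, Gini
  importance, panel size 15 — are conventional choices recorded in the
  report; none is claimed to reproduce any particular external run.

## The synthetic generator: what it emulates, and what it does not

`simulate_lipidome()` draws raw intensities from a log-normal model:
`2^(baseline + delta·I(condition) + N(0, sigma))`, with per-lipid
baselines uniform on log2 [10, 25] (typical LC-MS dynamic range) and
within-group log2 noise `sigma = 0.5`. The default design mirrors the
motivating chemostat/biofilm experiments: salinity 7/13/20 % NaCl ×
HRT 19.2/24/48 h planktonic plus three biofilm conditions, 3 replicates
each (36 samples); `default_lipid_catalog()` supplies 194 unique
species across all subclasses, always embedding the observed-species
corpus (`reference_species_names()`). Planted effects are applied on
the log2 scale, so ground-truth fold changes are exact, and the truth
(IDs, contrasts, deltas, seed) is returned alongside. Missing values
are inserted completely at random and never wipe out a whole
(lipid, condition) group.

What the generator does **not** emulate: correlated lipids within a
pathway, heavy-tailed or intensity-dependent noise, batch and
retention-time drift, censored (limit-of-detection) missingness, or
adducts/isotopes. Passing tests therefore demonstrate that the
*procedures* are correct and calibrated under the model the statistics
assume — not that real shale lipidomes satisfy that model.

### An attenuation property worth knowing about

Median scaling estimates each sample's loading from its own lipids. If
a sizeable fraction of one mode's species shifts in one direction in
one condition, the shifted species drag that condition's medians with
them, and estimated fold changes attenuate accordingly. Under the
default synthetic conditions, planting a +3 log2 shift on 20 of 194
species (about 10% of each mode block) moves the treated samples'
block medians by ≈ 0.3 log2 units — exactly the expected
order-statistic displacement for a uniform [10, 25] baseline — so the
mean recovered fold change is ≈ 2.7, not 3, while detection sensitivity
is unaffected (the criterion margin is large). With sparse planting
(5 of 194) the attenuation is negligible and recovery is unbiased to
within sampling error. This is a property of median normalization
itself, worth remembering when many species respond in the same
direction, as in strong osmotic shifts.

## Numerical choices and problem sizes

* Determinism: every stochastic routine takes a seed;
  `rf_biomarker_mccv()` is bit-reproducible from its seed, and
  `run_pipeline()` re-runs byte-identically for a fixed config.
* Ties: ANOVA screening breaks p-value ties by descending F then
  lipid ID; per-round RF rankings break importance ties by feature
  name; `roc_auc()` uses midranks. Merge-order ties inside Ward
  clustering follow `stats::hclust`.
* Degenerate inputs have explicit outcomes rather than NaNs: all-zero
  normalization blocks, zero pooled variance, empty significant sets,
  single-class label vectors and unresolvable sample selectors all
  raise informative errors or documented conventions.
* The test suite exercises calibration at 2,000 null lipids (type-I
  rate and KS uniformity), recovery over 200 replicate simulations of
  the 194-lipid two-condition design, the biomarker procedure at
  18 vs 18 samples with 50 MCCV rounds, and oracle equivalences
  (brute-force Ward agglomeration, exhaustive AUC pair counting,
  numeric t-CDF integration) — sizes chosen so the whole suite runs in
  a few minutes on one core while leaving the statistical assertions
  well-powered.
* The biomarker permutation null averages the panel AUC over several
  independent relabellings (5 × 10 rounds): with three dozen samples
  and a strong planted signal, a single permutation retains chance
  overlap with the true labels and its AUC is dominated by that
  overlap, whereas the average over draws estimates the permutation
  null itself.

## Known limitations

* The parser covers the shorthand grammar of the nine classes above;
  ether linkages, oxidized lipids, adducts and full LIPID MAPS ontology
  are out of scope.
* Differential testing is two-group and unpaired; no mixed-effects or
  paired designs.
* DBI/MCL are weighted-mean proxies; no biophysical interpretation
  beyond "higher means more unsaturated / longer" is implied.
* Upstream LC-MS/MS processing (identification, alignment, gap
  filling) is assumed done; the package starts from intensity tables.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- list(
  simulate = list(
    n_lipids = 194, sigma = 0.5, seed = 1,
    effects = list(
      list(class = "PG", selector = list(salinity = 20), delta = 3)
    )
  ),
  comparisons = list(
    list(name = "salinity_13_vs_20",
         a = list(salinity = 13, growth_mode = "planktonic", hrt = 24),
         b = list(salinity = 20, growth_mode = "planktonic", hrt = 24))
  ),
  biomarker = list(labels = "growth_mode", panel_size = 15,
                   rounds = 100, seed = 2),
  output_dir = "lipidshift_run"
)
manifest <- run_pipeline(cfg)
names(manifest)
```

The bundle contains the differential CSV (volcano-ready columns),
membrane-index and biomarker JSONs, the per-sample charge-profile CSV,
the Newick dendrogram, the planted truth and a provenance record.
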