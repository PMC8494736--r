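---
title: "Detecting co-occurring and mutually exclusive mutated gene pairs"
author: "comutmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting co-occurring and mutually exclusive mutated gene pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In a tumor cohort, two genes whose mutations co-occur more often than their
individual frequencies predict may cooperate in tumorigenesis; two genes
mutated together *less* often than expected (mutual exclusivity) may sit in
the same pathway, mark distinct tumor subtypes, or form a synthetic-lethal
pair. Detecting either pattern is a conditional-independence question: the
null model must respect both how often each gene is mutated *and* how heavily
mutated each tumor is, because both vary over orders of magnitude. comutmap
implements a pipeline for this question aimed at cohorts of the size and
sparsity typical of pediatric cancer studies: a few hundred tumors per cancer
type, a handful of mutated genes per tumor.

## The statistics

**Substrate.** Everything operates on a binary gene-by-sample mutation matrix
built from a somatic variant table: an entry is 1 when the sample carries at
least one likely-functional SNV or small indel in the gene. Variants are
filtered by dialect-specific consequence keep-lists, hypermutator samples
(more than 225 coding mutations, counted *before* the functional filter so
silent variants are included) are removed, and genes mutated in fewer than
two samples are dropped. The 225 threshold is itself derived, not assumed:
`floor(10 mutations/Mb x 0.95 coverage x 23,698,355 bp / 1e6)`.

**Permutation test.** The null distribution of a pair's co-occurrence count
`co` is obtained from matrices drawn uniformly from the space of binary
matrices with exactly the observed row and column sums, via curveball trades
(repeatedly pick two genes at random and redeal the samples unique to either
one). With `N` permuted matrices the empirical P-values use the
add-one-to-both estimator

    p_co = (1 + #{i : co_i >= co_obs}) / (1 + N)
    p_me = (1 + #{i : co_i <= co_obs}) / (1 + N)

so p is never 0 and lies in `[1/(1+N), 1]`. In pan-cancer mode the counts are
pooled over cancer types but each type's sub-matrix is permuted
independently, so type-specific mutation-frequency differences cannot
masquerade as interactions.

**Weighted-resampling test.** A faster approximation redraws each gene's
mutated-sample set without replacement, with per-sample probabilities
proportional to mutation load, independently per gene and within each cancer
type. Sampling is by rejection from the load-proportional distribution
(skipping duplicates), which is exactly the sequential-renormalization
distribution. An adaptive ladder (default 100 to 1,000 to 10,000 resamples)
escalates a pair only while its interim P-value is below
`10 / resamples_so_far`, so the vast majority of uninteresting pairs cost
100 draws.

**Empirical FDR.** Both tests produce P-values that are discrete and biased
toward 1, so standard FDR procedures do not apply. Instead a null P-value
set `S_null` is built by scoring matrices that are themselves fixed-margin
permutations (100 pseudo-observed matrices for the permutation test; 300 for
the weighted-resampling test, whose null P-values are additionally
stratified into the three mutation-rate bin combinations low-low, low-high,
high-high, with "high" meaning mutated in at least 2% of samples). For an
observed value `P*`,

    FDR(P*) = V(P*) / R(P*),   V = prop(S_null <= P*) x n_observed,
    R = #{observed <= P*}

and the q-value is the minimum FDR over all observed P-values at or above
`P*`, capped at 1. FDR is computed separately per direction (and per bin
combination for the weighted test), with `n_observed` counted within the
same stratum. Candidates require `q < 0.2`, `p < 0.1` (strict) and, for the
co-occurrence direction only, at least three co-occurring samples.

**Replicates and high confidence.** The weighted-resampling analysis is run
ten times under distinct seeds; only pairs significant in at least nine runs
are high-confidence. The permutation test is run once (it is far more
expensive) and passes through.

**Mutation load association (MLA).** For each candidate gene a logistic
regression of its mutation indicator on the per-sample mutation load (the
matrix column sums, untransformed) gives `MLA = slope / SE(slope)`, a Wald
statistic. A mutually exclusive candidate is *suspect* when
`|MLA_a - MLA_b| > 3` and `max > 3`; a co-occurring candidate when both
exceed 3. Suspect pairs typically reflect subtype structure with
subtype-specific mutation loads rather than genetic interaction.

## Shared null draws in the weighted test

A fixed-margin permutation changes neither gene margins nor sample loads, so
the weighted-resampling null distribution of every pair is identical for the
observed matrix and all permuted matrices scored for the FDR null. comutmap
therefore accumulates one pool of null draws per pair (a co-count histogram
with a snapshot at every ladder rung) and scores all 301 matrices against
it; each matrix still follows its own escalation path and reads its
P-values from the snapshot of the rung where that path stopped, so every
reported P-value has the adaptive-ladder resolution it would have had from a
dedicated run. The cost of the 300-matrix null drops from hundreds of
adaptive analyses to roughly one. The price is that null P-values share
randomness across matrices, which leaves the FDR estimator's expectation
essentially unchanged and mildly increases its variance; the null-cohort
control (below) shows the realized false-positive behaviour.

## The resolution floor of the empirical FDR

With a resample cap of `N = 10,000` the smallest attainable P-value is
`1/(1+N) ~ 1e-4`. For a lone candidate at that floor, `R = 1` and
`V ~ prop(S_null at floor) x n_observed_in_stratum`, so the smallest
achievable FDR grows linearly with the number of pairs sharing the
candidate's stratum. Discreteness helps the exclusivity direction (a null
matrix can only reach the floor if its co-count undercuts *every* null
draw, which ties at zero make rare) much more than the co-occurrence
direction. Practically: in a stratum of several thousand high-frequency
pairs no single co-occurring candidate can reach `q < 0.2`, however strong.
This is a property of the method, not the implementation, and it is the
reason the synthetic cohorts below use a genuinely long-tailed gene-frequency
law — with unrealistically many high-frequency genes the method cannot
certify any co-occurrence.

## What the synthetic cohorts emulate

`generate_cohort()` draws per-gene background mutation frequencies from a
truncated Pareto law (shape 1, support `[1/n, 0.3]`): most genes are rare, a
minority are frequent, and at 300 samples the mean load is about four
mutated genes per tumor — the sparsity regime of pediatric cohorts.
Per-sample load multipliers are log-normal (sigma 0.6, mean 1), chosen to
mimic the dispersion of per-tumor mutated-gene counts. Optional structure:

* **Hypermutators** receive a fixed load multiplier (default 50) in place of
  their background draw; the emitted variant table scales per-entry
  functional variants and per-sample silent variants with the load
  multiplier, so hypermutators exceed the 225-count threshold almost surely
  while binary gene indicators saturate.
* **Subtypes** split a cancer type into groups with their own load
  multipliers and private genes mutated only within the group — the
  confounder that produces spurious exclusivity between genes of different
  subtypes.
* **Planted interactions**: mutual exclusivity clears double-mutants with a
  given probability (margins are depressed and reported, not re-balanced);
  co-occurrence redraws the two genes jointly from per-sample 2x2 tables
  with the marginal probabilities preserved and the joint mass multiplied by
  the lift, capped at the smaller margin where the product would exceed it.

Planting order is base sampling, then co-occurring pairs, then exclusive
pairs. The default planted co-occurring pair uses 15% marginal frequencies:
a design-time power analysis showed that at 300 samples and lift 4, margins
of 10% put the expected co-count (~12) too close to the load-inflated null
expectation (~4) to clear the FDR resolution floor, while 15% margins put it
at the P-value floor with FDR ~ 0.01-0.05.

What the generator does **not** emulate: mutational signatures, copy-number
or structural variants, gene length effects, panel composition biases,
inter-gene correlation beyond the planted pairs, or clinical covariates.
Passing the recovery tests therefore demonstrates that the statistics behave
as designed under their own assumptions, not that those assumptions hold in
any particular real cohort.

## Numerical and design choices

* Gene and sample order is canonical (alphabetical) everywhere; all pair
  tables enumerate unordered pairs in a fixed order, so runs are
  byte-reproducible under a seed.
* Curveball trades are counted as attempted gene-pair redeals. Conditioning
  on "successful" (swap-capable) pairs would bias the chain: the number of
  swappable pairs differs between states, which breaks detailed balance;
  the sampler is validated against exhaustive enumeration of small
  fixed-margin spaces. Defaults: burn-in 5x and thinning 1x the number of
  1-entries; analyses needing near-independent draws (the enumeration
  comparisons) use 5x thinning.
* Ties: `R(P*)` counts observed P-values `<= P*` inclusively; q-values are
  suffix minima and invariant to the order of duplicate P-values. FDR may
  exceed 1 before the q-step; only q is capped.
* The rate-bin boundary (2% of samples) is inclusive-high. A bin combination
  absent from every permuted matrix falls back to the pooled null of its
  direction rather than failing.
* Pre-test count filters (>= 3 mutually exclusive samples for the ME
  direction, >= 1 co-occurring sample for co) are applied in every mode and
  mirrored inside each permuted matrix when building null P-value sets; they
  only remove pairs that could never pass the selection thresholds.
* Pseudo-observed matrices are scored against an ensemble that includes
  themselves, shifting p by at most `1/(1+N)`.
* Degenerate inputs: a gene mutated in all samples yields `p_co = 1`; a
  two-gene matrix has its co-count fixed by the margins, so both P-values
  are 1; constant or separated logistic fits are reported with a reason code
  and excluded from suspect flagging rather than raising.
* MLA uses the load including the gene's own contribution (the convention of
  computing both marginals from the same matrix); `leave_one_out = TRUE` is
  available for sensitivity analysis. Note the self-contribution makes the
  null distribution of MLA wider than standard normal when loads are small;
  the calibration check in the test suite constructs a null in which the
  *total* load is independent of the gene.
* Overlapping-gene resolution sorts on annotation-quality keys; a full tie
  falls back to the alphabetically first symbol with a warning (the original
  voting scheme does not state a final tie-break).

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen so the full suite completes in
minutes: permutation ensembles of `N = 10^4` (the full-scale analysis uses
`10^6`; `N` only sharpens P-value resolution), synthetic cohorts of 300
samples by 200 genes, ten replicate runs, 300-permutation FDR nulls, and
exhaustive enumeration oracles on matrices up to 4 genes by 6 samples. The
down-sampling experiment uses sizes 50 and the full cohort with ten
replicates each.

## Known limitations

* The resolution floor discussion above: single strong co-occurring pairs in
  very large strata cannot reach `q < 0.2` at the 10,000-resample cap.
* The weighted-resampling null preserves sample loads only in expectation;
  its P-values have a slight directional tendency relative to the
  fixed-margin permutation null (lower for exclusivity, higher for
  co-occurrence). The two tests' P-values correlate at r > 0.98 on
  synthetic cohorts, and the candidate sets are compared, not merged.
* Per-type matrices receive their own singleton filtering, so a gene can be
  testable pan-cancer but absent from every per-type analysis.
* MLA flags load associations; it cannot distinguish subtype confounding
  from genuine load-coupled biology. Suspect pairs are annotations, not
  removals.
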