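---
title: "FDR-controlled peptide-identity propagation: models and design"
author: "pipecho"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FDR-controlled peptide-identity propagation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
assumptions the error control rests on, and where open design choices were
resolved.

## The hybrid competition model

Peptide-identity propagation fails in two distinguishable ways. A
*peak-matching error* attaches a (correct) donor identity to an MS1 trace
that belongs to another analyte or to noise. A *peptide-identification
error* propagates an identity that was already wrong at the database-search
stage. The package estimates both error classes with competitions that are
carried through the entire pipeline:

* Decoy donor peptides are treated identically to targets at every step
  (donor selection never looks at the label; the test suite asserts this by
  flipping all labels and checking donor membership is unchanged).
* Every donor is searched at two anchors per acceptor run: the predicted RT
  and a randomized RT obtained by mapping the retention time of a
  deliberately mismatched peptide of the donor run. A window anchored at a
  wrong-but-realistic elution time samples the same background of
  wrong-location traces that a peak-matching error would.

Two symmetry assumptions make the counts interpretable: an incorrect donor
identity is equally likely to be a target or a decoy peptide, and an
incorrect peak match is equally likely at the predicted as at the
randomized anchor. For a run's surviving candidates sorted by PEP, with
$T^p_k, T^r_k, D^p_k, D^r_k$ the cumulative predicted/randomized
target/decoy counts,

$$\widehat{\mathrm{FDR}}_k \;=\;
\frac{T^r_k + \max\{0,\; D^p_k - D^r_k\}}{T^p_k},$$

where $T^r_k$ estimates peak-matching errors, $D^p_k - D^r_k$ the
identification errors whose peaks were matched correctly (subtracting
$D^r_k$ avoids double counting; the maximum clamps chance excursions below
zero). Acceptance adds $+1$ to the numerator — the standard finite-sample
correction for competition-based FDR estimates — and reports the
predicted-RT target candidates among the top $k(\alpha) = \max\{k :
(1 + T^r_k + \max\{0, D^p_k - D^r_k\})/T^p_k \le \alpha\}$. Control is per
acceptor run; a consequence worth knowing is that nothing can be reported
from a run with fewer than $\lceil 1/\alpha \rceil$ surviving target
candidates, because the $+1$ alone exceeds the budget.

Monotone q-values are provided as the running minimum (from the deepest
rank) of the $+1$-adjusted estimate, so post-hoc thresholding reproduces
acceptance exactly.

### Donor selection

Donors are peptides whose peptide-level q-value passes $\alpha/5$, capped
globally at 0.01 (so requested FDRs of 1%, 2.5% and 5% give cutoffs 0.002,
0.005 and 0.01). The one-fifth heuristic limits how many identification
errors enter the candidate pool in the first place; it affects sensitivity
only — the estimator above does not depend on it. One donor is built per
(peptide, origin run); at propagation time, when several origin runs offer
the same peptide toward one acceptor, the highest-scoring donor is used, so
a peptide is reported at most once per acceptor run. Propagation targets
only runs with **no** MS2 detection of the peptide (any detection, at any
confidence, excludes the run).

## Tunable parameters

All RT units are seconds, mass tolerances ppm. Defaults live in
`pip_config()`:

| parameter | default | role |
|---|---|---|
| `ppm_tolerance` | 10 | peak-to-isotopologue matching tolerance |
| `min_envelope_cos` | 0.7 | minimum cosine between observed and theoretical envelope per scan |
| `max_isotopologues` | 5 | envelope length (monoisotopic included) |
| `initial_half_width` / `max_half_width` | 30 / 150 | RT search window; expansion step 30 s |
| `knn_anchors` | 10 | k of the nearest-anchor median-shift RT mapping |
| `min_anchors` | 10 | below this the mapping falls back to identity, with a warning |
| `min_mass_gap` / `max_mass_gap` | 5 / 11 Da | mass band for randomized-anchor sources |
| `min_rt_separation` | `2 * max_half_width` | minimum donor-to-source RT distance |
| `min_reference` | 20 | per-run calibration population size before pooling across runs |
| `min_for_ml` | 100 | candidate count below which PEP falls back to `1 - combined_score` |

The isotopic envelope is an averagine-style Poisson model with
$\lambda = 4.88 \times 10^{-4} \cdot m$: cheap, adequate for envelope
*plausibility* checking (we require a cosine, not a fit), and pluggable.
The RT mapping is a k-nearest-anchor median shift rather than a spline:
it reproduces constant shifts exactly, is robust to stray anchors, and
makes the monotonicity property easy to reason about. "Not too close" for
the randomized anchor is quantified as twice the maximal window half-width,
which guarantees the randomized window can never overlap the predicted one
— the randomized match is then a wrong location by construction. The
randomized source is redrawn per (donor, acceptor run) from a stream seeded
by the global seed and the pair's identity, so results do not depend on
iteration order.

### Scoring and rescoring

Five features are computed per matched trace: absolute ppm error of the
most-abundant isotopologue's neutral mass, log summed apex intensity,
absolute apex-to-anchor RT difference, apex envelope cosine, and
valid-scan count. Each is calibrated into $(0,1]$ as the fraction of a
reference population — traces unambiguously associated with MS2-detected
peptides of the same acceptor run ("unambiguous" = exactly one eligible
trace within the initial half-width of the MS2 RT) — at least as extreme,
floored at $1/(n+1)$ so that a single worst-in-reference feature penalises
but cannot veto the geometric-mean combined score.

Rescoring is Percolator-style: 3 cross-validation folds split **by donor
peptide** (a donor's predicted and randomized candidates never straddle
train/test), randomized-RT candidates as negatives, non-decoy predicted-RT
candidates inside the top 25% of *all* candidates (by combined score in
round 1, by previous PEP later) as positives, five rounds of
gradient-boosted trees, and an isotonic fit of the randomized-label
indicator against the held-out classifier score as the PEP. Because the
three fold models score on slightly different scales, each fold's held-out
scores are first normalised against that fold's own negatives (the
fraction of randomized-RT candidates they beat) before pooling — without
this, one fold's scale can dominate the next round's top-25% positive
selection. Only the
*ordering* of PEPs enters FDR control, so any monotone calibrator is
admissible. Decoys are scored like everyone else but never serve as
positives. If a training partition lacks either class, or fewer than
`min_for_ml` candidates exist, the fallback `pep = 1 - combined_score` is
used — small experiments lose a little ranking power, never error control.

Determinism everywhere: ties in the per-run sort break by combined score
then peptide string; trace ties by intensity then scan index; xgboost runs
single-threaded with a fixed seed.

## The entrapment FDP protocol

The two-proteome design measures the *realized* FDP of any propagation
tool. The entrapment database appends to each target protein half of a
shuffled copy of itself, with every K and R pinned in place so tryptic
cleavage structure is preserved; shuffled tryptic fragments colliding with
a real peptide of the target or exclusion proteomes are deleted (the
colliding substring is removed rather than re-shuffled — deterministic and
simple). "Half" is the first $\lfloor n/2 \rfloor$ residues of the
post-removal sequence. The scaling factor $S$ is recomputed from the
supplied databases as (unique entrapment + unique target peptides) /
unique entrapment peptides, never hard-coded.

In pure (single-species) runs, foreign-species propagations count directly
as peak-matching errors (`eFPE`), entrapment propagations scaled by $S$
estimate identification errors (`ePIE`), and the native peak-matching
error rate among correct-species propagations is measured by censoring:
500 peptides per run — detected below a 0.1% peptide-level q-value (we use
the peptide-level value, consistent with donor selection), human-only,
better-detected elsewhere, and with exactly one MS2 spectrum in the run —
have that spectrum replaced by a single peak at 150 m/z, and a propagation
landing more than 1% of the gradient away from the original apex (54 s on
a 90-min gradient) is a native peak error. Foreign peptides that were
themselves MS2-detected in pure runs are removed as suspected LC
carryover before counting.

## The spike-in window analysis

For each analyte, observed log2 fold change $O_{FC}$ is the difference of
condition means of log2 intensities (missing and zero values dropped;
median log-ratio normalization on non-spike analytes first). Candidate
window radii are the observed distances $|O_{FC} - E_{FC}|$ to the
expected spike fold change; the analysis reports the spike count inside
the **largest** radius at which the human fraction of in-window analytes
stays at or below the FDP target. The source text describes "the smallest
value for which no more than 5% are human", which conflicts with the goal
of maximising discoveries and with the accompanying illustration; we
implement the largest qualifying radius and note the discrepancy. The
expected fold change is supplied by the user, and humans are evaluated
against the same window (their distance from $E_{FC}$), since their true
change is zero.

## What the simulator emulates — and what it does not

`simulate_experiment()` generates analytes with uniform base RTs, per-run
affine warps plus Gaussian jitter, Gaussian elution peaks carrying
Poisson-averagine envelopes with ppm-scale mass jitter, noise traces, MS2
detections at a configurable probability, and two contaminant PSM classes
with identical q-value distributions: incorrect targets (claimed peptide
points at an absent analyte, or at a mass within a few ppm of a different
real analyte) and decoys. The 1:1 target:decoy split of contaminants and
the independence of wrong-location signal from either anchor realise the
two symmetry assumptions *by construction* — passing calibration tests on
these simulations therefore validates the counting machinery and the
pipeline plumbing, not the assumptions themselves on real data. Real
phenomena deliberately out of scope: peak tailing and co-elution shoulders,
dynamic-exclusion effects, chimeric MS2 spectra, charge-state envelope
interference, and systematic (non-affine) RT distortions.

Default study conditions (also the sizes used by the statistical tests):
4 runs, 2,000 analytes, 1,200 s gradient sampled every 2 s, 90% presence,
60% MS2 detection, 10% + 10% contamination, 400 noise traces per run.
Even with all planted noise removed, occasional *genuine* peak-matching
errors remain possible — two analytes can fall within the ppm tolerance of
each other by chance — which is why the "clean" limit is asserted as
near-zero rather than exactly zero. FDP control is verified over 50
simulation replicates at $\alpha \in \{0.01, 0.05\}$ (mean true FDP within
two standard errors of the target), power as the fraction of plantable
correct transfers recovered at $\alpha = 0.05$, and the entrapment
estimator against 20 replicates of a planted error composition.

## Known limitations

* Per-run control does not aggregate into a guarantee over the pooled
  experiment beyond a law-of-large-numbers argument.
* Donors without an eligible randomized-anchor source keep an unopposed
  predicted-RT candidate; they contribute to $T^p/D^p$ only. The fraction
  of unopposed donors is reported in the result object — it is small in
  dense experiments and grows as the donor-run peptide pool thins.
* The envelope validity check is a cosine threshold, not a full
  isotope-pattern fit; profile-mode data and ion mobility are out of
  scope (input is assumed centroided).
* Protein-level FDR and protein inference are out of scope; the rollup
  provided for the spike-in analysis is a plain per-run peptide sum.
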