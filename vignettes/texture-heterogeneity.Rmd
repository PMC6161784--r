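---
title: "Texture heterogeneity of PET lesions: model, phantom and screening methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture heterogeneity of PET lesions: model, phantom and screening methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetpet)
```

## The problem

In metastatic castration-resistant prostate cancer treated with
beta-emitting PSMA radioligands, roughly a third of patients show no PSA
decline. A pre-therapeutic marker of who will respond would spare those
patients an ineffective cycle. One candidate family of markers is the
*textural heterogeneity* of tracer uptake in baseline PSMA-PET lesions:
spatial disorder of uptake within a delineated lesion, summarized by
histogram and gray-level co-occurrence statistics.

`hetpet` implements that analysis end to end — lesion texture features,
patient-level aggregation, responder labelling from pre/post marker
changes, and Spearman/ROC screening — together with a synthetic phantom
cohort generator so the whole chain is testable without patient data.

## Texture model

Each lesion is a volume of interest (VOI): a binary mask on the PET grid
(nominally 5.3 × 5.3 × 5.0 mm voxels). From the raw SUVs of the in-mask
voxels we compute:

* **SUVmean** — the conventional comparator.
* **COV** — population standard deviation over mean of the raw SUVs.
  Invariant under positive rescaling of uptake but not under shifts; this
  shift sensitivity is inherent to the definition.

For the co-occurrence features the VOI is first quantized to `ng` equal
width gray levels spanning its own min–max SUV range (level
`floor((v - min)/width) + 1`, clamped to `1..ng`; a constant VOI maps to
level 1). Quantizing within the VOI makes every co-occurrence feature
invariant under affine rescaling of uptake, so calibration offsets between
scans drop out.

The **normalized gray-level co-occurrence matrix** (NGLCM) `p(i, j)`
accumulates level pairs over the 13 unique 3D directions at distance 1
(both orderings, so `p` is symmetric), counting only pairs with both
voxels inside the mask, normalized to sum to 1. Pooling all directions
into a single matrix — rather than averaging per-direction features —
makes the derived features exactly invariant under axis permutations and
flips of the grid. From `p`:

* **entropy** `-Σ p log2 p` (bits; 0 for a deterministic matrix, up to
  `2 log2(ng)` for a uniform one),
* **homogeneity** `Σ p/(1 + |i − j|)` (1 when neighbors always share a
  level),
* **contrast** `Σ (i − j)² p`.

**Size variation** is the one parameter with no published formula; its
prose description — the gray value change "when going to the next voxel" —
is implemented as a neighborhood gray-tone-difference statistic: the mean,
over in-mask voxels with at least one in-mask 26-neighbor, of
`|level(v) − mean level of its in-mask 26-neighbors|`. It is 0 for a
constant lesion and grows when intensity alternates voxel to voxel. This
is an interpretation, documented as such; whether the original
workstation used an NGTDM- or run-length-based quantity is not knowable
from its description.

Degenerate inputs are defined, not errors: a constant VOI yields COV 0,
entropy 0, homogeneity 1, contrast 0, size variation 0. A VOI whose every
voxel is isolated (no in-mask neighbor at the co-occurrence distance) has
no pair to count and raises an error. Lesions below a configurable voxel
floor (default 62 voxels ≈ 7.8 cm³ on a 5 mm grid, the smallest lesion
size the analysis is meant for) are flagged with a warning but still
computed.

Per patient and metastatic site (bone / lymph node / other), lesion
features are aggregated as the unweighted arithmetic mean over that
site's delineated lesions (up to three per site under the standard
protocol).

### Choosing the gray-level count

`ng = 64` is the package default, a common radiomics convention that
leaves entropy on a 0–12 bit scale. But the bin count must respect the
VOI size: with 64 levels, a 55–590-voxel lesion yields a 4096-cell matrix
holding only a few thousand pairs, so nearly every observed pair occupies
its own cell and entropy degenerates into a measure of pair count — that
is, of lesion volume — rather than of texture. The bundled analysis
workflow therefore extracts at `ng = 16`, where the matrix cells stay
populated across the whole lesion-size range and the feature–volume
independence that motivates these parameters actually holds. `ng` remains
a single configuration knob (`texture_config(ng = ...)`), and the
monotone-link and volume-independence properties in the test suite are
what certify a given choice.

## Response model

Treatment response is read off marker changes as `post − pre` for PSA,
alkaline phosphatase (AP) and bone alkaline phosphatase (bAP). A strictly
negative delta defines a responder; a delta of exactly zero is a
non-responder (response is defined by a decrease, so the boundary goes to
the non-responders). Summaries report counts, raw fractions and
percentages under both plain rounding and truncation, because published
cohort tables mix the two formats.

## Statistical screening

* **Spearman screen.** Every (site, feature) pair against every clinical
  delta; `rs` is the Pearson correlation of midranks, and the two-sided
  p-value uses the t approximation `t = rs sqrt((n−2)/(1−rs²))` on `n−2`
  degrees of freedom, the convention of mainstream clinical statistics
  packages; an exact permutation option exists for tiny n. No
  multiple-testing correction is applied — the screen mirrors how such
  exploratory analyses are reported — but the number of tests performed is
  part of the output so readers can judge the multiplicity themselves.
* **ROC / AUC.** For features passing `p < 0.05` against ΔPSA, the AUC is
  the Mann–Whitney probability (ties ½) that a random positive outscores
  a random negative, with the Hanley–McNeil standard error
  (`Q1 = A/(2−A)`, `Q2 = 2A²/(1+A)`) and a normal-approximation CI
  clipped to [0, 1] (clipping is flagged). Exact binomial intervals, as
  produced by some commercial packages, are not chased bit-for-bit.
* **Youden cutoff.** All candidate thresholds — midpoints between adjacent
  distinct scores plus sentinels beyond the range — are scanned for the
  maximum `J = sensitivity + specificity − 1`. The test direction
  (`score > cutoff` vs `score ≤ cutoff`) is chosen so the reported
  orientation has AUC ≥ 0.5. Ties in J break toward the smallest
  `|cutoff|`, deterministically, and all maximizing thresholds are
  reported.
* **Positive class.** Default is the *non-responder* (risk orientation:
  the test flags patients unlikely to benefit). This is the orientation
  under which published predictive values for this analysis type
  reproduce from their sensitivity/specificity and class sizes, e.g.
  sensitivity = specificity = 71.4% with 28 positives and 42 negatives
  gives PPV 62.5% and NPV 78.9%.
* **AND rule.** Two tests combine by declaring positive only when both
  are positive; under conditional independence
  `sens = s1·s2`, `spec = 1 − (1−sp1)(1−sp2)`.
* **Volume independence.** Pearson correlation plus OLS regression of
  each screened feature on lesion volume, guarding against texture
  features acting as size surrogates.

## The phantom cohort

The generator emulates the study conditions the analysis assumes, so
recovery of known ground truth is testable:

* **Cohort structure.** 70 patients; three bone lesions each (bone
  involvement universal), three lymph-node lesions with probability
  0.471, one to three other-site lesions with probability 0.214; lesion
  volumes uniform on 7.8–82.3 cm³, drawn independently of heterogeneity
  (so feature–volume independence holds by construction).
* **Lesion images.** An ellipsoidal mask of the requested volume — the
  `round(volume/voxel volume)` voxels closest in ellipsoidal distance to
  the center, guaranteeing the mask volume is within half a voxel of the
  request — embedded in background uptake (default SUV 1). In-mask voxels
  carry a Gaussian random field: white noise convolved with an isotropic
  Gaussian kernel whose width falls monotonically with the latent
  heterogeneity score `h` (σ = 0.3 + 2.2·logistic(−h) voxels), then
  rank-transformed to a uniform marginal and linearly rescaled to span
  0.5–1.5 × a lesion mean SUV drawn from 5–15, plus additive Gaussian
  noise (default SD 0.2 SUV). The rank transform is what makes the
  texture knob clean: it pins the marginal distribution, so quantized
  texture statistics respond to spatial correlation alone, and extracted
  entropy increases — and homogeneity decreases — strictly monotonically
  in `h`. Below a floor `h_min` (default −3) the field amplitude is zero:
  with zero noise the lesion is exactly constant, the degenerate anchor
  of the texture scale.
* **Outcome link.** A Gaussian copula ties `h` to ΔPSA: `z = ρ_P h +
  sqrt(1−ρ_P²) ε` with `ρ_P = 2 sin(π ρ_S/6)`, and ΔPSA is a strictly
  monotone quantile map of `Φ(z)` — sign set so `P(ΔPSA < 0)` equals the
  responder fraction target (default 0.60) exactly, magnitude lognormal
  (the marginal shape is not pinned down by published cohorts; any
  heavy-tailed choice serves, and it is configurable). Because the map is
  strictly monotone, the population Spearman correlation equals the
  target `ρ_S` exactly (default −0.33: more heterogeneous tumors show
  larger PSA declines). AP and bAP get their own, weaker links (default
  −0.10) and their own responder fractions (41/70, 39/70). Pre-therapy
  levels are lognormal with a floor ensuring `post = pre + Δ` stays
  positive; ECOG status is generated constant pre/post.
* **Degenerate targets error out.** `|ρ_S| ≥ 1` cannot be reached through
  a copula with independent noise and is rejected at spec construction.
* **Seeding.** All randomness flows from one integer seed; per-lesion
  streams and replicate indices perturb it deterministically
  (`(seed·48271 + stream·16807) mod 2³¹−1`), so any object — a lesion, a
  cohort, a replicate — is bit-reproducible in isolation, and the
  caller's RNG state is restored afterwards.
* **Fast path.** `generate_cohort_fast()` emits latents and clinical
  deltas straight from the copula, skipping image synthesis, for studies
  needing hundreds or thousands of replicates.

What the phantom does *not* emulate: scanner point-spread,
reconstruction artifacts, attenuation, partial-volume effects, lesion
shape irregularity, inter-lesion heterogeneity within a patient
(one `h` per patient), or any real PSMA biology. Passing tests certify
the pipeline's statistical machinery — not that textural features predict
response in real cohorts.

## Problem sizes used by the test suite

Statistical calibration tests run 500 fast-path replicates at n = 70
(copula mean-recovery within ±0.02, null p < 0.05 rate 5% ± 2%, mean
empirical AUC against a numerically integrated binormal closed form
within ±0.01). The image-path monotone link uses an 8-point `h` grid on
an 82 cm³ lesion with shape and noise held fixed. Oracle-equivalence
tests run 100 randomized trials each against brute-force enumerators
(co-occurrence pairs, neighborhood means, pairwise AUC, threshold scans).
End-to-end determinism is checked byte-for-byte on a written 5-patient
cohort. These sizes are the package's chosen balance between statistical
resolution and a test suite that stays pleasant to run.

## Known limitations

* Cutoffs and predictive values are apparent (resubstitution)
  performance; no cross-validation is attempted, mirroring the analysis
  type this package implements.
* The Spearman p-value's t approximation is inexact for very small n;
  use `exact = TRUE` there.
* COV is not shift-invariant; comparisons across differently calibrated
  scans should rely on the co-occurrence features.
* Masks are taken as given on the PET-native grid — no resampling,
  co-registration or delineation logic is in scope.
* NIfTI files carry no uptake-unit metadata; the unit tag is attached at
  read time by the caller, and decay correction is assumed upstream.
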