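# hetpet — texture heterogeneity of PET lesions for therapy-response screening

`hetpet` is an R package plus analysis workflow for asking whether the
*textural heterogeneity* of tracer uptake in baseline PET lesions predicts
response to radioligand therapy. The motivating setting is metastatic
castration-resistant prostate cancer treated with ¹⁷⁷Lu-PSMA, where a
substantial minority of patients show no PSA decline and a pre-therapeutic
selection marker would be valuable. It is written for imaging scientists
and biostatisticians who want the full chain — texture features, responder
labels, screening statistics — as tested, seedable code rather than a
workstation black box.

## What it computes

Per lesion (a binary VOI mask on the PET grid), from the raw SUVs and a
within-VOI min–max quantization to `ng` gray levels:

* **SUVmean**, and **COV** = σ/μ of the raw SUVs (population SD);
* a symmetric, direction-pooled 3D **normalized gray-level co-occurrence
  matrix** p(i,j) over the 13 unique distance-1 directions, and from it
  **entropy** −Σ p log₂ p, **homogeneity** Σ p/(1+|i−j|), and
  **contrast** Σ (i−j)² p;
* **size variation**, a neighborhood gray-tone-difference statistic:
  mean |level(v) − mean level of in-mask 26-neighbors|.

Lesion features are averaged per patient and metastatic site, responders
are defined by strictly negative post-minus-pre marker change (ΔPSA, ΔAP,
ΔbAP), and features are screened by Spearman correlation (two-sided t
approximation), ROC analysis with Mann–Whitney AUC and Hanley–McNeil
standard errors, Youden-index cutoffs (J = sens + spec − 1) with full
confusion metrics, AND-rule test combination, and a feature-vs-volume
independence check.

A synthetic **phantom cohort generator** provides ellipsoidal lesions
carrying Gaussian random-field textures whose fineness is driven by a
latent per-patient heterogeneity score, linked to clinical deltas through
a Gaussian copula with exact rank-scale calibration — so every stage of
the pipeline is testable against known ground truth without any patient
data. See `vignettes/texture-heterogeneity.Rmd` for the methods in full.

## Worked example

```r
library(hetpet)

# one synthetic 30 cm^3 lesion with fairly fine texture (h = 1.5)
sp  <- phantom_spec(seed = 7)
les <- generate_lesion_image(volume_cm3 = 30, heterogeneity_h = 1.5,
                             spec = sp, stream = 1)
f <- extract_features(les$volume, les$mask, texture_config(ng = 16))
round(unlist(f[c("n_voxels", "volume_cm3", "suv_mean", "cov", "entropy",
                 "homogeneity", "contrast", "size_variation")]), 4)
#>       n_voxels     volume_cm3       suv_mean            cov        entropy
#>       214.0000        30.0563         8.3381         0.2917         7.8143
#>    homogeneity       contrast size_variation
#>         0.3064        27.7906         2.9689

# Youden cutoff for a toy entropy-vs-response split
y <- youden_cutoff(c(5.4, 4.9, 5.6, 4.8, 5.9, 5.1, 4.6, 5.8),
                   c("nr","nr","r","nr","r","nr","nr","r"),
                   positive_class = "r")
#> cutoff > 5.50  J 1.00  sens 1.00 spec 1.00

# AND-rule combination of two published test profiles
cmb <- combined_and_rule(0.714, 0.714, 0.810, 0.571)
#> combined AND: sensitivity 57.83%, specificity 87.73%
```

The lesion occupies 214 voxels (30.06 cm³ at 5.3 × 5.3 × 5.0 mm spacing —
within half a voxel of the request). Its entropy of 7.81 bits sits near
the top of the 0–8 bit scale for 16 gray levels, as expected for a
fine-textured field, with correspondingly low homogeneity (0.31). In the
toy ROC, responders score strictly higher, so the threshold midway
between the classes separates them perfectly (J = 1). The AND rule trades
sensitivity (0.714 × 0.810 = 57.8%) for specificity
(1 − 0.286 × 0.429 = 87.7%).

## The analysis workflow

Numbered drivers under `analysis/` chain the full study on a simulated
cohort (override the seed with `HETPET_SEED`):

```sh
Rscript analysis/01_simulate_cohort.R   # 70-patient phantom -> results/cohort/
Rscript analysis/02_extract_features.R  # per-lesion + per-patient features
Rscript analysis/03_response.R          # deltas, responder summary
Rscript analysis/04_screen.R            # Spearman / ROC / Youden / AND tables
```

With the default seed this produces 351 VOIs (210 bone, 114 lymph node,
27 other) and 49/70 PSA responders; stage 4 writes correlation, ROC and
confusion tables under `results/screen/`. Whether the planted
heterogeneity–ΔPSA link (Spearman −0.33 in the population) reaches
significance in any single 70-patient draw depends on sampling — the
default draw falls short (bone entropy rs = −0.14, p = 0.25), a useful
reminder of the power available at this cohort size; the link's recovery
*in the mean* over hundreds of replicates is what the test suite
certifies.

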