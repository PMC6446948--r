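# pmnet

Resting-state network **integrity** analysis for two-group fMRI studies:
group independent component analysis, dual regression and template matching,
covariate-adjusted inference, cross-validated classification, and voxel-wise
TFCE permutation testing — with a synthetic-cohort generator so the whole
pipeline is testable without patient data.

## The scientific problem

Intrinsic connectivity networks such as the parietal memory network (PMN)
and the adjacent default mode network (DMN) can lose their canonical spatial
organization in degenerative disease. For each subject the package measures
how faithfully a network is expressed as the **network integrity**

    z = atanh(|r|),

the Fisher-Z transform of the absolute spatial correlation between the
subject's individual-level network map and the group-level template over the
brain mask. Lower `z` means a more distorted network. Integrity is computed
by two independent back-reconstruction routes — per-subject ICA followed by
greedy template matching, and dual regression — and compared between
patients and controls by multiple linear regression with age, sex, education
years, mean frame-wise displacement and gray-matter fraction as covariates,
with Cohen's d, leave-one-out cross-validated logistic classification
(ROC/AUC), and voxel-wise group inference by Freedman–Lane permutation with
threshold-free cluster enhancement (TFCE) inside mixture-model-thresholded
network regions.

The intended users are neuroimaging methodologists and clinical researchers
who want this widely used analysis design as tested, scriptable functions
rather than a chain of GUI tools.

## Worked example

Simulate a small cohort in which patients carry a planted spatial
degradation of the target network (`netA`), run the group decomposition,
and test the group difference:

```r
library(pmnet)

cfg     <- generator_config(n_patients = 12, n_controls = 12, seed = 42)
cohort  <- simulate_cohort(cfg)

concat    <- concat_and_normalize(cohort$series)
comps     <- spatial_ica(concat, MO = 10, seed = 42)
refs      <- template_set(cohort$truth$true_maps[cohort$truth$network_names, ])
templates <- select_networks(comps, refs)
templates$info
#> # A tibble: 3 × 4
#>   network component r_abs low_confidence
#>   <chr>       <int> <dbl> <lgl>
#> 1 netA            2 0.968 FALSE
#> 2 netB            1 0.971 FALSE
#> 3 netC            6 0.936 FALSE

ci  <- cohort_integrity(cohort$series, comps, templates, MO = 10, seed = 42)
cmp <- compare_integrity(ci$records, cohort$phenotypes,
                         network = "netA", method = "dual_regression", MO = 10)
cmp
#> <integrity_comparison netA / dual_regression / MO 10>
#>   patient 0.644 (0.160, n=12)  control 1.402 (0.066, n=12)
#>   group t = -15.336, p = 2.177e-11, Cohen's d = 6.190
```

The selection table says each reference network was matched to a group
component at high spatial correlation (`r_abs`), with no low-confidence
flags. The comparison shows patients' mean integrity for the degraded
network (0.644) far below controls' (1.402): the planted deficit is
recovered with a huge effect at this noise level. The same records feed the
classifier and the voxel-wise stage:

```r
cls <- loocv_logistic_auc(ci$records, cohort$phenotypes,
                          network = "netA", method = "dual_regression", MO = 10)
cls
#> <classification_result netA / dual_regression: LOOCV AUC = 1.000 (n = 24)>

autoplot(cmp)    # group boxplots;  autoplot(cls) draws the ROC curve
glance(cmp)      # one table row: means, SDs, t, p, Cohen's d
```

`run_pipeline(run_config(...))` orchestrates the full study design — a
model-order sweep, both methods, control networks, classification and
voxel-wise inference — into tidy report tables, and
`inst/cli/pmnet.R` exposes `generate` / `run` / `ica` / `stats` verbs for
shell use. `write_cohort()` / `read_bold()` handle the NIfTI + TSV on-disk
layout.

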