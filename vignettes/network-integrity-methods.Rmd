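---
title: "Resting-state network integrity: model, estimators, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state network integrity: model, estimators, and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmnet)
```

## The question the package answers

Resting-state fMRI decomposes into a reproducible set of intrinsic
connectivity networks. In degenerative disease, a network of interest — here
prototypically the parietal memory network (PMN), whose posterior parietal
hubs border the default mode network (DMN) — may lose its canonical spatial
organization. `pmnet` quantifies that loss per subject as **network
integrity**: the Fisher-Z transform of the absolute spatial correlation
between the subject's individual network map and a group-level template,

$$ z = \operatorname{atanh}(|r|), \qquad
   r = \operatorname{cor}\!\big(\text{subject map},\ \text{template}\big)
   \ \text{over in-mask voxels}. $$

Low integrity means the subject expresses a distorted version of the
canonical network. The statistic deliberately summarizes the network as a
whole; the voxel-wise stage (below) localizes where the distortion sits.

## The generative model and the two estimators

Everything rests on the linear mixing model of spatial ICA: the masked
time-by-voxel data of subject $s$ are
$X_s = \sum_k a_{sk}(t)\, m_{sk}(v) + \varepsilon$, a sum of spatial maps
weighted by time courses plus noise, with spatially independent,
non-Gaussian maps. Group templates come from **temporal-concatenation group
ICA**: each subject's series is demeaned and variance-normalized per voxel,
all subjects are stacked in time, the concatenated matrix is PCA-reduced to
a chosen model order (MO), and a symmetric fixed-point ICA maximizes the
non-Gaussianity of the spatial maps. Components representing the networks of
interest are selected by greedy absolute spatial correlation against
reference maps, without replacement; a selection below $|r| = 0.2$ is only
flagged, not rejected, as the automated stand-in for a visual check.

Individual-level maps are reconstructed by two routes, kept deliberately
independent so that agreement between them is evidence about the data rather
than the algorithm:

* **Template matching** — a fresh ICA per subject (at the same forced MO, or
  a per-subject evidence estimate under `MO = "auto"`), then the same greedy
  matching of subject components to the group templates. The matched
  component's correlation is the integrity.
* **Dual regression** — stage 1 regresses each time point's volume on *all*
  group component maps (structured-noise components included, so non-neural
  variance is modeled), giving per-component time courses; stage 2 regresses
  each voxel's series on those time courses, giving per-component subject
  maps. The selected networks' maps are correlated with their group
  templates.

Model-order selection uses the Laplace approximation to the model evidence
of a probabilistic PCA over the eigenspectrum (Minka's criterion), clipped
to $[2, \texttt{max\_order}]$. The package treats MO as an explicit
robustness parameter: the pipeline sweeps a configurable list and reports
every cell, because component splitting at high MO and component merging at
low MO both move the integrity statistic.

## Group inference

Per network, method, and MO, integrity is compared between groups by
ordinary least squares with the group indicator (1 = patient) plus age, sex,
education years, mean frame-wise displacement and gray-matter fraction as
covariates; the group coefficient's two-sided $t$ test is the primary
result. Cohen's $d$ is reported from the *unadjusted* group means with the
pooled SD — the adjusted and unadjusted effect summaries answer slightly
different questions, and the unadjusted one matches how such tables are
usually printed. Diagnostic value is summarized by leave-one-out
cross-validated logistic regression (integrity plus the same covariates);
the AUC of the held-out probabilities uses the rank formula with ties
counted one half, which equals the trapezoidal area under the empirical ROC.
Folds with perfect separation fall back to a ridge-stabilized IRLS fit
($\lambda = 10^{-6}$) with a warning rather than failing.

## Voxel-wise stage

The network region is defined by fitting a Gaussian (null) plus positive
Gamma (activation) mixture to the template map by EM and keeping voxels
whose posterior null probability — the local false-discovery rate — is below
0.05. EM runs at most 500 iterations to a $10^{-6}$ log-likelihood
tolerance with five deterministic jittered restarts; if the activation
component degenerates the function falls back to a $z > 3$ cut with a
warning. Inside the region, a per-voxel GLM (group + covariates) yields the
control-greater-than-patient $t$ field, which is enhanced by TFCE,

$$ \mathrm{TFCE}(p) = \sum_{h = dh,\,2dh,\dots}^{h_p} e(h,p)^{E}\, h^{H}\, dh, $$

with the canonical $E = 0.5$, $H = 2$, 26-connectivity and $dh =
\max/100$. Family-wise error is controlled by Freedman–Lane permutation:
covariates are regressed out, residualized rows are permuted (reduced-model
fits added back), and the maximum TFCE statistic over the region forms the
null; the unpermuted statistic is included, so the smallest attainable
corrected p is $1/(n_{\text{perm}}+1)$. The default is 5,000 permutations;
calibration tests use 500–1,000, which bounds the attainable p but does not
bias it.

## What the synthetic generator emulates — and what it does not

Real data for this design are rarely shareable, so the generator is a
first-class module, not a fixture. It plants, on a common 16×16×8 grid with
an ellipsoidal brain mask, three blob-union networks — two spatially
adjacent (sharing support, spatial correlation in $(0, 0.5)$, the PMN/DMN
analogue) and one disjoint control network — plus artifact-like structured
noise maps, band-limited (0.01–0.1 Hz) Gaussian-process time courses, and
white sensor noise. Patients receive a per-subject degradation fraction
$\delta \sim \mathrm{TN}(0.5, 0.1)$ on $[0,1]$ ($\delta_{\text{mean}} = 0$
is treated as the exact null, $\delta \equiv 0$): the target network's map
becomes $(1-\delta)\,m + \delta\,e$ with $e$ a smooth random field scaled to
the map's SD, so the deficit is spatial corruption — which a correlation
statistic must respond to — rather than amplitude scaling, which cancels in
correlation.

Choices that were genuinely open, and why they were fixed as they are:

* **Identifiability of every decomposed dimension.** Spatial ICA cannot
  converge on subspaces whose sources are Gaussian: the fixed-point
  iteration wanders indefinitely below any realistic tolerance. Smoothed
  Gaussian random fields *are* marginally Gaussian, so structured-noise maps
  are heavy-tailed (cubed smoothed fields), the per-subject corruption field
  $e$ is likewise heavy-tailed, and seven noise maps are planted so that the
  largest model order exercised in the tests (10) decomposes ten genuinely
  identifiable sources. Real scanner and physiological artifacts are
  spatially structured and non-Gaussian, so this is realism and numerical
  necessity pointing the same way.
* **Amplitude tiering.** Noise-map amplitudes step linearly from 0.8 to 0.6
  of the mean network-map SD: distinct amplitudes keep the PCA variance
  ranking unambiguous, so truncated decompositions retain whole sources
  instead of degenerate mixtures, while staying above the sensor-noise
  floor at the subject level.
* **Sensor noise `noise_sd = 0.8`** (time courses and network peaks are
  unit scale): strong enough that subject-level integrity is a genuinely
  noisy estimate, weak enough that every subject-level decomposition at the
  largest swept order remains identifiable.
* **Covariates.** Age, sex, education and mean FD are drawn per group from
  published AD/HC demographics (which are group-matched); the gray-matter
  fraction defaults to one common distribution for both groups. A default
  gray-matter group difference would leak group information through the
  covariate set and silently bias every null and control-network
  calibration; studies wanting that structural confound can configure
  per-group distributions.
* **Disjointness bound.** Two non-negative maps with disjoint supports on a
  small mask are necessarily slightly *negatively* correlated, so the
  control network's contract is a signed correlation below 0.1 plus a cap
  on support overlap, not an absolute-value bound.

The generator does **not** emulate registration error, head-motion
artifacts, physiological noise spectra, multi-site effects, spatial
autocorrelation of sensor noise, or hemodynamic convolution. Passing tests
therefore demonstrate that the estimators recover what the linear mixing
model plants, at desk scale — not that they are robust to everything real
data do.

## Numerical choices

* Fixed-point ICA: log-cosh contrast (Gaussian contrast available),
  symmetric decorrelation, tolerance $10^{-6}$, at most 1,000 iterations,
  up to 5 seeded random restarts; non-convergence is an error carrying the
  best-effort unmixing, never a silent result. Components are canonicalized
  (z-scored maps, non-negative skewness, explained-variance order) so runs
  are comparable.
* High-pass filtering is discrete-cosine-basis regression (all basis
  functions below the cutoff, plus the intercept), the deterministic drift
  model of standard fMRI GLM software.
* Correlations are computed over the brain mask only; out-of-mask zeros
  would inflate $r$.
* $|r|$ is clipped to $1 - 10^{-12}$ before `atanh`; saturated and
  constant-map records are flagged.
* Greedy matching breaks ties by lower component index, then lexicographic
  network name, making selection deterministic. Greedy can diverge from the
  sum-optimal assignment; the divergence case is documented and tested
  rather than "fixed", because the greedy rule is the one this literature
  actually uses.
* Dual-regression stage-1 time courses are variance-normalized by default
  (scale lands in the stage-2 maps; correlations are unaffected).
  Stage-2 *beta* maps are used for integrity, not z-stat maps.

## Problem sizes used by the test suite

All calibration checks run at sizes chosen to exercise the full pipeline on
a desktop: the default cohort is 36 patients + 43 controls on the 16×16×8
grid with 120 volumes; the type-I calibration uses 200 null cohorts of
20 + 20 subjects on a 12×12×6 grid with 60 volumes (dual regression against
the true maps, which needs no ICA); family-wise-error calibration uses 10
runs at 500 permutations; the planted-deficit recovery check uses 20
default-size cohorts across the model-order sweep {5, 8, 10}. Full study
scale — tens of thousands of in-mask voxels, a couple of hundred volumes,
model orders near 100, 5,000 permutations — is reachable through the same
functions and configuration, just not in a test run.

## Known limitations

* The integrity statistic conflates all forms of spatial deviation —
  including benign individual variability — into one number; the voxel-wise
  stage only partially disambiguates.
* Template matching at model orders below the true source count merges
  components; the control network can then be selected with low confidence
  (it is flagged, and its comparisons stay null, but its integrity level
  shifts with MO).
* The Gaussian-Gamma mixture threshold assumes a dominant null component
  and a positive activation tail; templates with heavy negative structure
  fall back to the $z > 3$ cut.
* LOOCV AUC on 79 subjects carries non-trivial variance; single-cohort AUC
  values should be read with that in mind.
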