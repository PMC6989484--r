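---
title: "Methods: the Disease State Index and its evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Disease State Index and its evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical method it
implements, the choices that had to be made where the method's usual verbal
description is silent, and what the synthetic-cohort validation does and
does not establish.

## The Disease State Index

The DSI is an ensemble of univariate empirical classifiers. For feature $i$
with $P$ positive and $N$ negative training values, the *fitness* of an
observed value $x$ is

$$f_i(x) = \frac{\mathrm{FN}_i(x)}{\mathrm{FN}_i(x) + \tfrac{P}{N}\,\mathrm{FP}_i(x)},$$

where $\mathrm{FN}_i(x)$ counts positives at or below $x$ and
$\mathrm{FP}_i(x)$ counts negatives above $x$, in *oriented* values (the
feature is flipped when its Mann–Whitney AUC against the labels is below
0.5, so that larger oriented values always point to the positive class).
Fitness estimates, roughly, the probability that a value at $x$ belongs to
the positive class once the classes are implicitly equalized in size by the
$P/N$ factor; it is a non-decreasing step function of $x$ with values in
$[0,1]$.

The *relevance* of a feature is the clamped Youden index of its own fitness
classifier evaluated on the training sample,
$R_i = \max\{\text{sens} + \text{spec} - 1,\, 0\}$, with a training subject
called positive when its fitness exceeds $0.5$. Relevance is both a
feature-quality readout and the feature's weight in the composite

$$\mathrm{DSI} = \frac{\sum_i R_i f_i}{\sum_i R_i}.$$

Features are grouped in a hierarchy (e.g. `mri/diffusion/global_md`); the
weighted average is applied recursively, each internal node contributing its
composite value and its own relevance (computed from the node's composite
training values against the same $0.5$ cut-off) to its parent. The root
composite is the final index; DSI $> 0.5$ classifies a subject positive.

Missing data are handled structurally: a missing feature is simply skipped
and the relevance weights are renormalized over the observed children of
every node. The package's test suite asserts the resulting identity
directly — scoring with a feature missing everywhere equals scoring with
that feature removed from the hierarchy.

### Numerical choices

The counting formula leaves a handful of edge cases open; the package fixes
them as follows, and the brute-force oracle in the test suite pins each one:

* **Tie side.** $\mathrm{FN}(x)$ uses $\le x$ and $\mathrm{FP}(x)$ uses
  $> x$: a value sitting exactly at a cut-off falls on the negative side.
  This makes fitness monotone non-decreasing and is self-consistent between
  fitness and relevance.
* **Gap between class supports.** There $\mathrm{FN} = \mathrm{FP} = 0$ and
  the formula is $0/0$; the package returns $0.5$, the maximally
  uninformative value.
* **Orientation ties.** A Mann–Whitney AUC of exactly $0.5$ orients the
  feature $+1$. The choice is inert: such a feature earns relevance $\approx 0$
  and vanishes from every weighted sum.
* **DSI exactly 0.5** classifies negative (only strict exceedance is
  positive).
* **Single-class features.** A feature with no observed values in one
  training class is unusable: relevance $0$, fitness constant $0.5$. A node
  whose observed children all have zero relevance has an undefined ($0/0$)
  composite and is treated as missing — consistent with the fact that a
  zero-relevance child is algebraically equivalent to no child at all.
* **Binary and ordinal features** (sex, education 1–7, smoking 0/1/2,
  lesion presence) pass through the same counting machinery; the formula
  only needs an ordering.

Because fitness is a step function, a *single-feature* DSI is a weakly (not
strictly) monotone transform of the feature: test values falling inside one
training step share a fitness value, so a midrank AUC of the index can
differ marginally from the AUC of the raw feature. The evaluation tests
account for this by recomputing per-split AUCs from the fitness primitives
rather than from the raw feature.

## The g-factor outcome

The general cognitive factor is the first unrotated principal component of
five baseline cognitive tests (Stroop interference, letter–digit
substitution, verbal fluency, delayed recall, pegboard), computed by
eigen-decomposition of the correlation matrix because the tests live on
incommensurate scales. Loadings have unit norm and the component is oriented
so the delayed-recall loading is positive (higher g = better cognition).
Subjects with an incomplete battery are excluded from the fit (listwise
deletion) and reported.

The baseline standardization and loadings are reused to score the follow-up
visit: a shared projection is the only choice under which the change in g is
interpretable as cognitive change rather than a change of coordinate system.
The annualized change $(g_{fu} - g_{base})/\Delta t$ is ranked and the
$\lfloor 0.05\,n \rfloor$ subjects with the steepest decline are labelled
positive. The floor rule was chosen over rounding as the deterministic,
conservative reading (at $n = 2542$ both give 127); exact ties at the
threshold are broken by ascending subject id for reproducibility.

## Evaluation protocol

Performance is estimated with repeated stratified 2-fold cross-validation:
each repetition splits the cohort into random halves preserving the class
ratio (per-class fold sizes differ by at most one), and **both** halves
serve as test set, so $r$ repetitions yield $2r$ AUC values (1000 at the
protocol default $r = 500$). The AUC is the Mann–Whitney probability with
ties counted $1/2$.

Per-split AUCs from repeated CV are positively correlated (training sets
overlap), so a naive $t$ interval on their mean would be anti-conservative.
The corrected resampled $t$ interval inflates the variance by
$\left(\tfrac{1}{kr} + \tfrac{n_2}{n_1}\right)$ with $n_2/n_1$ the
test/train size ratio (1 for 2-fold) and uses $kr - 1$ degrees of freedom.
Two experiments are compared by feeding their per-split AUC *differences*
(identical split sequences enforced) through the same interval; they differ
significantly when the interval excludes zero. The construction is
deliberately conservative, which the test suite demonstrates by simulation
on independent draws.

Four age-handling variants are protocol-fixed: (1) age in, no correction;
(2) age out, no correction; (3) age in, non-binary features except age
residualized on age; (4) age out, with residualization. Age correction is an
ordinary least-squares fit per feature, replacing values by residuals;
binary features are left untouched (determined by the metadata flag, not by
value inspection). By default the correction is fitted once on all subjects
(`scope = "full"`), mirroring the protocol's single-pass description — this
leaks only label-free information, but a leakage-safe `scope = "fold"`
refit-per-training-fold option is exposed because the choice is genuinely
open.

MRI feature selection thresholds the *whole-dataset* relevance of each MRI
feature at $t \in \{0, 0.01, \ldots, 0.1\}$ before the CV. Computing
selection relevance on the entire dataset (including future test subjects'
labels) is the protocol's stated choice and makes any AUC gain an upper
bound; in the corrected variants the relevance is computed on the
age-corrected values, since that is the view of the data the classifier will
see. If a threshold empties the MRI branch the branch simply drops out of
the hierarchy (the index tolerates absent branches); sweep cells whose
feature set empties entirely are reported as undefined.

Per-repetition relevance distributions pool the trained hierarchies of both
folds (two records per repetition); the protocol description does not fix
the fold handling, and pooling uses all available fits. The extreme-DSI
subgroup analysis restricts test subjects to DSI $< 0.2$ or $> 0.8$ and uses
the age-only index, whose scores actually spread across $[0,1]$; a
many-feature relevance-weighted average concentrates near $0.5$ and retains
almost nobody at those cut-offs.

## The synthetic cohort generator

The generator produces analysis-ready cohorts with the statistical structure
the analysis assumes, so every stage is testable without any external data.
Its defaults define the study conditions and are not tuning knobs:

* **Demographics.** Age from a truncated normal on $[45, 95]$ years with
  realized mean 60.9 and SD 9.1 — the underlying parameters are
  moment-matched so the *truncated* distribution hits these values exactly;
  55.6% female; follow-up interval $5.7 \pm 0.6$ years (truncated below at
  1 year).
* **Latent decline.** Each subject carries an annual change in g of
  $d_i = -0.02 - 0.0045\,( \mathrm{age}_i - 60.9) + \varepsilon_i$,
  $\varepsilon_i \sim N(0, 0.068)$ (g-units/year). These three constants
  were calibrated once against the anchor statistics of the emulated
  population — an overall decline SD near 0.08 g/yr, a 5%-tail threshold
  near $-0.18$ g/yr, and a positive group roughly a decade older than the
  controls — and then frozen.
* **Cognitive tests.** The five tests load on one latent cognition factor
  $G \sim N(0,1)$ with a common $|$loading$|$ of 0.53 on the z-scale
  (negative for the timed Stroop task) plus modest age slopes; together
  these make the first principal component explain roughly half of the test
  variance, the magnitude expected of a g-factor. Follow-up scores are
  baseline plus the loading-scaled decline times the follow-up interval, so
  the annualized delta-g is a positive multiple of $d_i$ and the 5% tail of
  delta-g coincides with the tail of the latent decline.
* **Biomarkers.** Clinical, genetic, gait and MRI features use the control
  population's means/SDs as anchors, with age slopes set once to plausible
  ageing rates (e.g. cerebrospinal fluid volume $+2$ mL/yr, white-matter
  volume $-1.5$ mL/yr, mean diffusivity $+0.003 \times 10^{-3}$ mm²/s/yr).
  The white-matter-lesion volume is log-normal (its population summaries are
  median/IQR), binary features follow age-dependent logits, education and
  smoking are ordinal.
* **Missingness** is MCAR per feature (5% for MRI and gait, 2% for most
  clinical features, none for age, sex and the cognitive tests). Structured
  missingness — e.g. masking the diffusion features of exactly 680 subjects
  — is produced only by `mask_subset_features()`, keeping the base generator
  simple and auditable.

By design, *age is the only planted outcome signal*: biomarkers depend on
age but not on the decline residual, and the latent cognition factor is
independent of decline. No inter-feature correlation beyond the shared age
and latent-G loadings is modelled. This is deliberate: it makes the
qualitative expectations sharp (age-corrected continuous features must carry
no signal; uncorrected age-loaded features must), and it gives the
generator a closed-form reference — `oracle_age_auc()` estimates by Monte
Carlo the AUC of age under the exact labelling rule, which the
cross-validated age-only DSI must recover.

What passing the synthetic-recovery checks does **not** show: performance on
real cohort data, where features correlate beyond age, carry independent
outcome signal, miss non-randomly, and where the decline threshold may need
to be age-dependent. The generator validates the *machinery* — the index,
the protocol, the intervals — not any clinical claim.

## Problem sizes and reproducibility

The test suite and the acceptance script work at the cohort size the
labelling arithmetic is defined on ($n = 2542$) but with reduced repetition
counts (10–100 repetitions instead of 500) — the corrected resampled
interval is valid for any $r$, and these sizes keep the full validation in
tens of seconds. Distributional checks use $n = 10^5$ draws; the
Monte-Carlo oracle uses $10^6$. All randomness flows from explicit integer
seeds through a pinned generator kind, and the pipeline writes every output
as plain CSV/JSON with a manifest of the child seeds, so any stage can be
reproduced in isolation.

## Known limitations

* Age correction is linear only; a log-normal feature with an age slope on
  the log scale retains a small nonlinear age component after linear
  residualization (visible as residual relevance of the lesion-volume
  feature in the corrected variants). Spline or log-scale correction is out
  of scope.
* The full sub-category hierarchy below the top level is a reconstruction
  from the feature roster's natural groupings; alternative groupings change
  the averaging structure and hence the index.
* The fitness step function is used as-is: no smoothing, interpolation, or
  probabilistic calibration of the index is attempted.
* Relevance-based selection on the entire dataset is optimistic by
  construction; the package mirrors it faithfully and exposes the
  leakage-safe correction scope only for the age regression, not for
  selection.
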