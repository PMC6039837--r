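---
title: "MEG network topology as a biomarker of VNS outcome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MEG network topology as a biomarker of VNS outcome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Vagus nerve stimulation (VNS) is a surgical option for drug-resistant
epilepsy, but roughly half of implanted patients do not achieve a 50%
seizure reduction, and no pre-operative test predicts who will respond.
`vnsnet` implements a resting-state MEG analysis built around the
hypothesis that the *topology* of the sensor-space functional network,
measured before implantation, separates eventual responders from
non-responders. The pipeline is: phase-locking-value (PLV) connectivity →
cost-thresholded binary graphs → three global graph measures → (a) twin
heritability and test–retest reliability of those measures, establishing
them as stable, biologically grounded traits, (b) group statistics, and
(c) a three-group naive Bayes classifier (non-responder / responder /
control).

Clinical and Human Connectome Project recordings cannot be redistributed,
so the package ships a synthetic-cohort module that emulates the features
of those data the pipeline actually consumes, making every stage testable
end to end.

## Connectivity model

For two sensors with instantaneous phases $\varphi_1(t), \varphi_2(t)$ at
frequency $f$, the phase-locking value is

$$\mathrm{PLV}_f = \bigl| \mathbb{E}\, e^{j(\varphi_1(t) - \varphi_2(t))} \bigr|,$$

estimated per 3-second epoch and averaged over epochs, then over the 1-Hz
bins of a band. The bin grid is 25 centres at 4–28 Hz; bins belong to
theta [4, 8), alpha [8, 12), beta [12, 30) by centre. (A 4–30 Hz grid in
1-Hz steps would contain 27 values; we keep the conventional 25-bin count
and the standard band edges, assigning centres 4..28.)

Phase extraction is a band-limited analytic signal: per epoch the spectrum
is restricted to the positive frequencies of the 1-Hz bin and
inverse-transformed; the instantaneous phase is the complex argument. This
is zero-phase by construction and exact on closed-form oracles (constant
slope for a sinusoid at the bin centre; constant lag $2\pi f \Delta t$ for
a delayed copy). We chose it over a narrow-band IIR filter plus Hilbert
transform because a 1-Hz passband at a 508.6 Hz sampling rate has a
normalized width of ~0.004, where transfer-function-form IIR designs are
numerically fragile; the FFT mask has no such pathology and is
substantially faster over epochs × bins × channels. A margin
(`edge_trim_s`, default 0.25 s) is trimmed from both ends of every epoch's
phase series before the PLV to suppress the filter's circular-wraparound
transients.

The estimator averages *per-epoch* PLVs rather than pooling samples across
epochs; the unit test distinguishing the two uses segments with opposite
constant lags, for which pooling cancels the phasors.

## Graph measures and thresholding

A connectivity matrix is binarized by retaining the top
$\lceil C \cdot m \rceil$ of its $m$ upper-triangle edges (ties at the
cutoff broken by ascending index, so the edge count is exact). The
analysis cost is fixed at $C = 0.10$ for all subjects and bands — the
value that maximizes the global cost efficiency

$$\mathrm{GCE} = E_C - C, \qquad
E_C = \frac{1}{n}\sum_{i \in N} \frac{\sum_{j \ne i} d_{ij}^{-1}}{n - 1},$$

derived once from a representative scan (`gce_scan()`, grid 0.01–0.50 in
steps of 0.01, first maximum on ties) and applied globally. On the
16-channel synthetic networks the GCE optimum falls at a higher cost
(~0.2) than on a 248-sensor array, as expected — cost efficiency scales
with network size — which is why the scan is reported but the fixed
10% convention is retained.

Three global measures are computed on the binary graph: Newman modularity
$Q$ (Louvain optimization, 100 seeded restarts, resolution 1, with the
trivial single-community partition as a floor so complete graphs return
exactly 0), transitivity $3 \times \text{triangles} / \text{paths of
length 2}$, and characteristic path length (mean shortest path over
reachable pairs; for disconnected graphs the reachable-pair fraction is
recorded rather than returning infinity). All three agree with exhaustive
brute-force oracles (all set partitions for $Q$; BFS for distances) on
every ≤ 8-node graph in the test suite. Graphs are binary: weighted CPL
conventions could not reproduce the magnitudes reported for this kind of
analysis under any normalization we identified, so the standard binary
definitions are used and a weighted mode is intentionally not offered.
Measures are computed per run and averaged across the three runs, except
in the reliability analysis, which consumes the per-run values.

## Heritability model

Graph features are traits in an AE variance-components model. With
$2\Phi$ the expected relatedness (1 for MZ co-twins, ½ for DZ co-twins
and siblings, 0 across families),

$$\Omega = 2\Phi\,\sigma_g^2 + I\,\sigma_e^2, \qquad
\sigma_p^2 = \sigma_g^2 + \sigma_e^2, \qquad
h^2 = \sigma_g^2 / \sigma_p^2.$$

The fit eigendecomposes $2\Phi$ once; in the rotated basis the covariance
is diagonal for any $h^2$, so the likelihood is profiled over $h^2 \in
[0, 1]$ with a bounded 1-D search (tolerance $10^{-6}$), a weighted GLS
fit of the fixed effects at each ratio, and an explicit comparison of the
interior optimum against both boundaries. Significance of $h^2$ is a
likelihood-ratio test of $\sigma_g^2 = 0$; because the null lies on the
boundary, $p = \tfrac12 P(\chi^2_1 \ge \Lambda)$. The decision threshold
is $p < 0.01$ uncorrected.

Traits are rank-based inverse-normal transformed (Blom offsets
$(r - 3/8)/(n + 1/4)$, ties sharing mean ranks) *before* the fit, and the
five covariates sex, age, age², age×sex, age²×sex enter as fixed effects
inside the ML fit; age is standardized internally for conditioning (the
fit is invariant to this linear reparameterization). Transforming first
and adjusting inside the fit follows the common variance-components
convention; the reported "variance explained by covariates" is the
covariates-only OLS $R^2$, labelled as such since the alternative
(full-model partition) is ambiguous. For pedigrees smaller than 15
individuals `h2_table()` drops the covariates — the 5-term design would
saturate a toy pedigree.

The model is deliberately AE only: no shared-environment (C) component,
environmental effects uncorrelated among family members. Null calibration
(1000 iid traits on the 89-individual design) gives a rejection rate of
~0.8% at the 1% threshold, and parameter recovery on 40 MZ + 40 DZ pairs
is unbiased to within ±0.1 across $h^2 \in \{0, 0.3, 0.6, 0.9\}$ — both
checks run in the acceptance suite.

## Reliability

Run-to-run reliability is the two-way-ANOVA intraclass correlation

$$\mathrm{ICC} = \frac{MS_b - MS_E}{MS_b + (k - 1) MS_E}, \qquad k = 3,$$

with $MS_b$ the between-subject mean square and $MS_E$ the residual after
removing subject and session main effects. Algebraically this is the
consistency form ICC(3,1), and it is implemented exactly as printed rather
than as an absolute-agreement variant. Ratings use the half-open bands
poor (< 0.2), fair [0.2, 0.4), moderate [0.4, 0.6), good [0.6, 0.8),
excellent (≥ 0.8). Negative ICCs are reported as computed and rated poor.
The two patient groups are pooled into one "patients" stratum, matching
the layout this analysis mirrors.

## Group statistics

Responder vs non-responder differences are tested per feature with a
two-way main-effects ANOVA over responding × sedation. Because variance
equality cannot be assumed in these small groups, the null distribution of
each factor's Type-II F statistic is built by bootstrap: resample the
residuals of the reduced model (the factor of interest removed) with
replacement, add them to the reduced-model fitted values, and re-fit
(10,000 resamples; $p = (1 + \#\{F^* \ge F\}) / (B + 1)$). The
interaction is omitted — the unbalanced 9/14 design with a sedation split
leaves near-empty interaction cells. Residual resampling under the
reduced model is one of several defensible bootstrap null constructions;
it was chosen because it preserves the nuisance factor's structure while
destroying the tested effect.

The nine features are corrected with Benjamini–Hochberg FDR at the 0.05
level; the step-up critical values $(i/m) \cdot 0.05$ are emitted next to
the adjusted p-values for transparency. Controls vs each patient group
use a two-sided rank test. A *paired* signed-rank test is not computable
between 89 controls and 14 or 9 patients, so the unpaired rank-sum
(Mann–Whitney) form is the default; a paired mode exists and errors on
unequal sizes.

Type-I calibration (200 null datasets at the 9/14 design, 500 resamples)
keeps the empirical rejection rate within [0.03, 0.07] at α = 0.05.

## Classification

A Gaussian naive Bayes classifier (empirical priors; per-class ML
variances floored at $10^{-9}$ × the largest feature variance; posterior
ties to the lexicographically first class) is evaluated under stratified
10-fold cross-validation. Stratification is required, not optional: with
9 non-responders among 37 subjects, unstratified folds can leave a class
absent from a training split, making the class-conditional fit ill-posed.
Feature sets mirror the four classifier variants: transitivity +
modularity in one band (2 features) or in all three bands (6). CPL is
excluded from the menu by design, following the feature selection of the
analysis this package mirrors (where CPL did not separate the patient
groups); in synthetic cohorts the global-coupling construction can make
CPL informative, but the menu is kept fixed.

Because the control pool exceeds the patient groups, each evaluation
repetition draws 14 controls without replacement, runs the
cross-validation on the 9/14/14 cohort, and accumulates the confusion
matrix (rows = actual classes, so each row sums to its class size),
one-vs-rest sensitivity/specificity/PPV/accuracy, and Mann–Whitney
one-vs-rest AUCs from the out-of-fold posteriors; 1000 repetitions are
averaged as real numbers and rounded only for display. Per-class
"accuracy" is one-vs-rest binary accuracy $(TP + TN)/n$; weighted
averages weight classes by size (9, 14, 14). Chance level for the
three-group problem is 33%; the label-permutation check in the acceptance
suite re-shuffles labels across repetitions (a single shuffled dataset
has ~7-point conditional accuracy noise at $n = 37$ and does not converge
to chance on its own).

## The synthetic cohort: what it emulates, and what it does not

Each channel is a sum of 25 narrow-band stochastic oscillations (one per
PLV bin). A component's phase is a Wiener process around its carrier with
increment variance set so the Lorentzian linewidth is 0.5 Hz (~1-Hz-wide
components). Per channel, the component at each frequency mixes three
phase sources with variance shares normalized to keep marginal variance
constant:

* a **module-shared** phase (share `within`) — all channels of a module
  lock together,
* a **globally shared** phase (share `global`, scaled per channel by a
  fixed hub-weight ramp 0.6–1.4) — the whole array locks onto one
  rhythm, most strongly at hub channels,
* an **independent** phase (the remainder).

A phase-mixture construction was chosen over a coupled-oscillator ODE
because the pipeline's ground truth *is* the phase-locking structure:
this construction controls expected PLV directly and generates minutes of
multichannel data in seconds.

Group profiles (defaults: within/global = 0.30/0.02 controls, 0.17/0.32
responders, 0.10/0.55 non-responders, with subject-level jitter 0.02/0.03)
were calibrated once so the downstream analysis reproduces the *ordering*
— modularity: controls > responders > non-responders; transitivity: the
reverse — not any published magnitudes, for which no effect sizes exist.
The mechanism matches the intuition the ordering encodes: strong global
coupling with hub heterogeneity merges the module structure (lower $Q$)
and concentrates the strongest connections on a cross-module core (higher
transitivity). Sedation is flagged on ~50% of patients but has no
simulated effect by default, mirroring the null sedation finding; an
`sedation_effect` knob exists for power experiments.

The twin module simulates $y = X\beta + g + e$ with $\mathrm{cov}(g) =
2\Phi \sigma_g^2$ drawn directly from the block structure (MZ co-twins
share $g$; DZ co-twins share an $N(0, \sigma_g^2/2)$ component),
$\sigma_g^2 = h^2$, $\sigma_e^2 = 1 - h^2$. The default pedigree is 19 MZ
+ 13 DZ pairs + 25 singletons (89 individuals). Twins share age; default
covariate effects are modest (sex 0.25, age 0.02/year) — enough to
exercise the covariate machinery without dominating the trait. Note the
MEG generator itself embeds no genetic effect, so the pipeline's
heritability stage on synthetic cohorts is a negative control; estimator
validation uses the twin-trait module's recovery loop instead.

What the generator does **not** emulate: sensor geometry and field
spread, physiological artifacts (eye-blink, cardiac, muscle), head
movement, interictal discharges, 1/f background spectra, and any
amplitude–phase coupling. Passing tests therefore demonstrate the
correctness and statistical calibration of the *analysis*, not that real
MEG data would yield the published effect sizes.

## Problem sizes and numerical choices

Defaults state the emulated study conditions: 248 channels, 508.6 Hz,
3 runs of 300 s (patients) / 360 s (controls). Tests and the analysis
scripts run the same code at reduced sizes chosen once as adequate for
their purpose: 16 channels in 4 modules, 36-s runs at 127.15 Hz
(Nyquist comfortably above the 30 Hz band edge; sample counts scale
1:4 with the full rate), theta-band-only where a single band suffices,
and `osc_freqs = 4:8` when only theta components are consumed. At these
sizes the full suite and the acceptance script each run in minutes on one
CPU while keeping every statistical property intact (the group-separation
property holds in ≥ 95% of 20 seeded replicates at n = 14 per group).

Other fixed numerical choices: epoch length 3 s with trailing partial
epochs discarded; Louvain restarts 100 (tests use 10–50; partitions on
≤ 16-node graphs converge far earlier); the threshold tie-break is
deterministic (ascending index) so densities are exact; bootstrap and CV
seeds derive from one master seed through a fixed
linear-congruential splitting scheme (`child_seed`), so any stage can be
re-run independently and reproduces byte-identical tables; all
randomness passes through `with_seed`, which restores the caller's RNG
state.

## Known limitations

* Sensor-space PLV is susceptible to volume conduction; no leakage
  correction (e.g. imaginary coherence or orthogonalization) is applied,
  matching the analysis this package implements.
* The binary-graph convention cannot reproduce path-length magnitudes
  reported under unstated normalizations; comparisons should be made on
  orderings and standardized effect sizes.
* The bootstrap ANOVA's null construction (reduced-model residual
  resampling) is one defensible choice among several; the exact published
  scheme is unstated.
* The classifier is validated by cross-validation only; no external
  validation cohort exists, synthetic or otherwise.
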