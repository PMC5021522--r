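---
title: "Models and methods behind bfpmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bfpmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfpmech)
```

`bfpmech` analyses biomembrane force probe (BFP) single-bond experiments on
receptors with force-unfoldable domains, with platelet GPIbα (leucine-rich
repeat domain, LRRD; juxtamembrane mechanosensitive domain, MSD) pulled by
VWF-A1 as the motivating system. This vignette is the package's own account
of its models, parameters, numerical choices, and limits.

## The measurement model

A BFP cycle drives the target cell through approach, impingement (a
compressive hold of ~20 pN for a contact time, default 2 s), and retraction.
Force is the probe-bead spring deflection times the spring constant
(default 0.3 pN/nm); retraction at constant speed yields a nominal loading
rate of `spring_constant * retraction_speed` (default 1000 pN/s, i.e.
~3.3 µm/s). Cycle outcomes are *no bond* (peak tensile force below
`min_force`, default 5 pN), *rupture* (bond breaks during the ramp), or
*lifetime* (clamp level reached; the lifetime runs from clamp attainment to
dissociation).

Unfolding appears as two signatures:

* **ramped** — a sudden stagnation or drop interrupting the linear ramp;
* **clamped** — an abrupt force drop during the hold that does not collapse
  to zero; the released length is (force drop)/(spring constant).

## The synthetic-data generator

The simulator (`sim_params()`, `simulate_cycle()`, `simulate_session()`)
replaces the instrument. Its defaults are the study conditions the analysis
assumes:

| parameter | default | unit | rationale |
|---|---|---|---|
| spring constant | 0.3 | pN/nm | standard BFP stiffness |
| ramp rate | 1000 | pN/s | nominal clamp-mode loading rate |
| clamp force | 25 | pN | the reference clamped condition |
| contact duration | 2 | s | protocol contact time |
| adhesion probability | 0.18 | – | infrequent-adhesion (<20%) regime |
| MSD unfolding rate k_u | 0.870 | 1/s | fitted 25 pN clamped rate |
| LRRD threshold force | N(12, 4²) | pN | reproduces unfolding at 5–20 pN |
| unfolding lengths | MSD N(20, 3²), LRRD N(36, 6²), both N(65, 7²) | nm | the three observed length modes |
| sample rate | 1000 | Hz | camera-rate force channel |
| force noise | 1 | pN | typical BFP thermal noise |
| idle between cycles | 1.4 | s | 50 cycles span ≈ 200 s |

Bond lifetimes are dual-exponential, with separate parameter sets depending
on whether the LRRD unfolded during the preceding ramp; clamped MSD
unfolding times are exponential at k_u and an event is realised when
t_u < t_b. Because the lifetime law is conditioned on LRRD unfolding, the
generator produces LRRD–MSD cooperativity mechanistically rather than by
construction of a 2×2 table.

**The lifetime parameter table.** The per-condition dual-exponential
parameters are shipped as `gpiba_kinetic_params()` and are a *synthetic
reconstruction*: the off-rate scales are set to plausible fast/slow values
for this bond (fast ~5 s⁻¹ and ~2 s⁻¹, slow 0.25 and 0.20 s⁻¹, with LRRD
unfolding prolonging lifetime), and the fast-pathway weights are then solved
in closed form (`solve_weight_for_pu()`) so that the joint-probability model
reproduces the reference clamped unfolding probabilities at 25 pN, 21.5%
(LRRD−) and 46.2% (LRRD+). Analyses that depend on the *shape* of the
lifetime distribution beyond these constraints should treat the table as
illustrative.

**Trace rendering.** The default tether model is a stiff-linkage
idealization: the bonded ramp rises at exactly the nominal rate, a ramped
unfolding drops the force by `k × length` instantly (floored at zero — the
retraction then takes up the released slack before the ramp resumes), and a
clamped unfolding drop is restored by the clamp feedback with a 0.5 s time
constant. This makes the unfolding length appear fully in the
extension/force jump, which is what the detectors measure. A compliant
tether (`tether = list(model = "wlc", Lc0, p)`) is available; it solves the
spring+WLC series force sample by sample and is used to exercise the
force-extension utilities. Session timing (the ≈200 s clock) always uses
the stiff-model segment durations.

**Calcium coupling.** `calcium_coupling()` encodes the triggering rule: an
α-type (spike) response follows the first clamped MSD unfolding event
provided the longest bond lifetime up to that cycle exceeds a threshold
(default 2 s); sessions with lifetime events but no qualifying trigger give
a low-amplitude β-type response; sessions without lifetime events stay
null. Trace shapes are parametric: α = latency, ~2 s rise, exponential
decay with 15 s half-life (peak increase drawn from 0.5–1.5 of baseline);
β = ~15 s gradual rise to 0.08–0.4 with 60 s half-decay; multiplicative
1% noise at 1 Hz. The shapes are qualitative stand-ins chosen so that the
amplitude classes match the null (<0.05) and α (mostly >0.5) boundaries;
real ratiometric calcium imaging (photobleaching, motion, indicator
kinetics) is not emulated, so passing tests demonstrate the analysis logic,
not robustness to imaging artifacts.

## Event detection

Segmentation (`segment_trace()`) works from the force channel alone:
retraction onset ends the compressive plateau; the tensile zero crossing is
refined by extrapolating the linear compressive unload to zero (robust for
soft tethers); clamp attainment requires the smoothed force to hold within
3 pN of the clamp level for 10 ms; dissociation requires < 2 pN sustained
for 5 ms. Bond calling uses a lightly despiked (5-point running median)
force so that short-lived low-force peaks are not smeared below threshold;
Savitzky–Golay smoothing (window 21 samples, order 3) is used elsewhere.

The ramped-kink detector flags intervals where the windowed slope of the
force (5 ms leading minus lagging mean) falls below `kink_threshold`
(default 0.3) of the reference loading rate for ≥ 3 ms. The reference is
the nominal ramp rate by default — exact for the stiff-tether model — with
a `"local"` (median observed slope) option for compliant tethers whose
loading rate is sub-nominal. Event onsets are fine-located at the steepest
single-sample force descent; the onset force comes from a short raw-data
line fit just before the drop (raw, because smoothed samples near the drop
are contaminated by spill-over); lengths are measured as the jump in
molecular extension (target minus probe displacement) between windows
before the drop and after re-tensioning, or as Δforce/k when position
channels are absent. The clamped detector is a windowed mean-difference
drop detector with the dissociation edge excluded and a positive post-drop
level required (a collapse to zero is dissociation, not unfolding).

With the default 1 pN noise at 1 kHz these choices give >95% recall and
precision with sub-2 nm median length error on labeled synthetic cycles
(the acceptance suite measures this on 1000 cycles). Lifetimes shorter
than the 10 ms attainment criterion are indistinguishable from ruptures
and are classified as such.

## Polymer elasticity and length classification

The Marko–Siggia worm-like chain is used throughout, with persistence
length fixed at 0.5 nm (unstructured polypeptide convention) and
k_BT = 4.28 pN·nm (310 K), both configurable; `fit_contour_length()` can
also co-estimate the persistence length, since whether the reference
analysis fitted it jointly is not documented. Contour lengths are fit with
Levenberg–Marquardt least squares (`minpack.lm`), with the lower bound
`Lc > max(length)` enforcing the model domain.

Unfolding-length ensembles are classified by kernel density estimation
(Sheather–Jones plug-in bandwidth; Gaussian and Epanechnikov kernels give
the same mode count on well-formed ensembles). Local maxima below 5%
prominence (rise above the separating valley, relative to the global mode)
are treated as bandwidth ripple and merged; this threshold separates true
modes (≥5% in trimodal ensembles of n ≈ 300) from ripple (≤2%) in the
regimes the package targets. Domain assignment uses fixed boundaries
b₁ = 28 nm and b₂ = 56 nm (ramped events: MSD below b₁, LRRD between, BOTH
above; clamped events are always MSD), with `calibrate_boundaries()`
deriving data-driven boundaries from KDE valleys when a calibration
ensemble is trimodal. The observed LRRD range (18–56 nm) overlaps the MSD
range; the fixed-boundary convention is therefore a documented tie-break,
not a claim about the original decision table. The Freedman–Diaconis bin
width defaults to type-7 (interpolated) quartiles; the quartile type is
exposed because discrete conventions change the answer on small samples.

Two estimators measure a single unfolding length from a force-extension
curve: the extension jump at the highest shared force of the two branches,
and the difference of WLC contour lengths fitted to the branches. They
agree to a few nm when the branches are sampled where the chain is
substantially extended; at low relative extension the jump method
under-reports (the released chain is not yet stretched), which is why the
contour-length difference is the rigorous option.

## Kinetics and the joint-probability model

The clamped time-to-unfold is exponential; its rate is estimated by the
reciprocal sample mean (MLE, exact gamma CI) or the log-survival slope.
Bond lifetimes are dual-exponential; `fit_dual_exponential()` maximizes the
likelihood directly with 10 random restarts (k₁ ≥ k₂ by convention) and
collapses to a single exponential — with a warning and `single = TRUE` —
when the rates merge, a weight vanishes, or the likelihood-ratio statistic
against the nested single exponential is below 4.

Assuming unfolding and dissociation are independent, the probability of
observing clamped unfolding before dissociation is the closed form
P_u = w₁·k_u/(k_u+k₁) + (1−w₁)·k_u/(k_u+k₂), equal to the volume of the
joint density over t_u < t_b (verified by quadrature to 10⁻⁴ over
randomized parameters, and against the simulator at n = 10⁴ cycles — the
two are mutual oracles). Force dependence of the unfolding rate follows
the Bell model, fitted by log-linear regression. Note the 25 pN rate
(0.870 s⁻¹) and the Bell pair (0.26 s⁻¹, 0.242 nm) are treated as two
separate reference results; they are not exactly mutually consistent at a
single k_BT and the package does not force them to agree. With only four
force levels and 5% rate noise, a single Bell fit's zero-force-rate
standard error is itself ~5%; recovery claims are therefore assessed on
replicate medians.

For pooled conditions in which few clamped unfoldings follow LRRD
unfolding (e.g. a slip-only mutant ligand), the lifetime fit is simply run
on the pooled sample — no LRRD± segregation.

## Cooperativity statistics

Independence of LRRD and MSD unfolding is tested with Pearson's χ² on the
2×2 occurrence table (expected counts from marginal products, 1 degree of
freedom, **no** continuity correction — the convention under which the
worked 25 pN table (14, 11, 25, 95) gives 13.01; the Yates-corrected value
differs and is deliberately not used). The cooperativity index
ΔP/P = P(both)/[P(MSD)·P(LRRD)] − 1 is zero under independence and
undefined when a marginal is zero (such conditions are flagged, not
tested). Category fractions carry multinomial standard errors
√[(n_i/n)(1−n_i/n)/n]. Under a Poisson bond-number model, an adhesion
frequency P_a implies a single-bond conditional probability
λe^(−λ)/(1−e^(−λ)) with λ = −ln(1−P_a); at P_a = 0.20 this is 89.3%, the
quantitative basis of the infrequent-adhesion design rule.

## Calcium linkage

Traces are normalized by the mean of an initial baseline window; onset is
the first rise above baseline + 5 baseline-noise s.d. sustained for
3 frames (the onset rule is not documented upstream; these are package
defaults). Types: null if the maximum increase is below 0.05; otherwise α
when spike-shaped (rise < 10 s and post-peak half-decay < 30 s), else β;
when the shape cannot be evaluated the 0.5 amplitude boundary decides —
the exact amplitude/shape precedence is genuinely open and both criteria
are exposed. Pre-onset lifetime statistics (t_max, Σt_i, mean) use
lifetimes *completed* before onset; the simulator's coupling places onset
after the triggering bond's dissociation so the triggering lifetime is
included. The ROC threshold on t_max minimizes FP+FN counts, resolving
ties toward the smaller (more sensitive) threshold; on simulated coupled
sessions it recovers the generating 2 s threshold within one grid step.

## Problem sizes and reproducibility

The shipped test-suite and acceptance-script sizes are chosen for precise
yet quick checks: 10⁴ draws for rate recovery (estimator s.e. ~1%), 10⁴
event-level cycles for the simulator-vs-closed-form oracle, 10³ rendered
traces for detector accuracy, 20-point curves for WLC recovery (force
noise 2 pN, the s.e.m. scale of averaged mechanics points, giving
contour-length errors at or below the reference fit uncertainties of
0.85/3.56 nm), and 120 event-level sessions for the ROC recovery. All
randomness flows from explicit seeds; sessions derive per-cycle substreams
deterministically, so every result is a pure function of (configuration,
seed).

## Known limitations

* The lifetime parameter table is calibrated, not measured (see above).
* The stiff-tether trace model omits tether compliance, drift, and bead
  tracking artifacts; detector accuracy figures apply to that model.
* Calcium traces are parametric shapes, not imaging data.
* Real-instrument condition counts (per-force frequencies across many
  platelets and ligands) depend on original recordings and are covered
  only by simulation-based pattern checks.
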