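---
title: "Granger-causal effective connectivity between resting-state networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Granger-causal effective connectivity between resting-state networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcnet)
```

## The scientific problem

Resting-state fMRI gives, for each participant, a multichannel time series:
one channel per large-scale brain network (the networks-of-interest, NOI),
sampled every TR = 2 s. *Functional* connectivity is the zero-lag
correlation between channels; *effective* connectivity asks a directional
question — does the past of network X improve prediction of network Y
beyond Y's own past? `gcnet` implements a group-comparison workflow around
that question: condition the time courses, estimate directed influence
between all ordered pairs of 14 canonical networks with Granger causality,
test group differences by label permutation with false-discovery-rate
control, summarize each group's directed graph by cost-thresholded
efficiency curves, and relate per-subject network strengths to behavioral
scales. A synthetic-data generator with known planted directed differences
makes every stage testable end to end without access to raw imaging data.

## Generative model and the GC statistic

Channels follow a vector autoregression (VAR) of order $p$:

$$x_t = \sum_{\ell=1}^{p} A_\ell\, x_{t-\ell} + \varepsilon_t,
\qquad \varepsilon_t \sim \mathcal N(0, \operatorname{diag}(\sigma^2)),$$

with stability enforced by requiring the companion-matrix spectral radius
to be below 1 (`var_spec()` rejects anything else and reports the radius).
For an ordered pair $(i, j)$, the pairwise Granger statistic compares a
restricted regression of $x_{j,t}$ on its own $p$ lags against an
unrestricted one that adds $i$'s lags:

$$F_{i \to j} = \frac{(\mathrm{RSS}_r - \mathrm{RSS}_u)/p}
                     {\mathrm{RSS}_u/(N - k_u)},$$

where $N$ counts regression rows and $k_u$ the unrestricted regressors
including the intercept. A *conditional* variant (all channels except $i$
in the restricted model) is available by flag; the two coincide exactly on
bivariate systems. F statistics, not log-F, are the analysis currency; a
log view exists for display only. Negative F arising from round-off is
clipped at zero with a warning counter.

Subjects are temporally concatenated within group before estimation, the
convention for group-level GC on component time courses. Lag windows never
span two subjects: `build_lagged_design()` drops any row whose $p$-lag
history crosses a subject boundary or touches a motion-censored time
point. Because of that, the Gram matrix of the group design is the sum of
per-subject Gram matrices, which is what makes the permutation tests cheap
— each relabeling only re-sums per-subject sufficient statistics rather
than refitting from raw data.

The lag order is configurable (default 1, matching the generator's lag-1
couplings) or selected by BIC over $p = 1..5$ on the concatenated series
(`select_order()`), with the same order forced on both groups so the
contrast is not confounded by unequal model complexity.

## Conditioning chain

The contract for BOLD-derived series, applied per subject *before*
concatenation (so no filter transient spans a boundary), is

drop 4 initial volumes → linear detrend → nuisance regression (6 motion
parameters, white-matter and CSF means, when supplied) → zero-phase
band-pass 0.008–0.15 Hz → z-normalization.

The filter is a 2nd-order Butterworth applied forward-backward
(`signal::filtfilt`): zero phase, so lag relationships are not shifted;
order kept low because single-subject series are short (146 points).
Two numerical facts about this chain are worth stating plainly:

* **It is not idempotent.** A Butterworth band-pass is not a projection;
  re-running the chain re-attenuates transition-band energy (about 12% RMS
  change on broadband input, dominated by the wide 0.15→0.25 Hz upper
  transition at TR = 2 s). Mid-band content is stable to within a few
  percent, and the non-filter steps are exactly idempotent; the tests
  assert precisely that.
* **Filtering blurs directed lag structure.** On synthetic VAR panels the
  band removes ~40% of the spectrum, and zero-phase (non-causal) filtering
  leaks future samples into the present; empirically this induces
  spurious reverse-direction group differences for strongly planted edges.
  For ground-truth recovery runs the filter is therefore off — the same
  rationale as generating with the hemodynamic response convolution off:
  both operations are temporal blurs that are part of BOLD realism, not of
  the directed-coupling estimand. For real volumetric data the full chain
  is the contract.

Motion censoring flags time points rather than interpolating them:
interpolation fabricates temporal structure that a lag-based statistic
would happily detect. Flagged points simply remove the regression rows
whose windows touch them. The "1 voxel/TR" censoring threshold is read as
framewise displacement above the 3.4 mm in-plane voxel size.

## Synthetic cohort: what it emulates and what it does not

`group_design()` defines the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_per_group` | 20 | subjects per group (the scaled test cohort; the reference study had 50/50) |
| `n_timepoints` | 150 | volumes per subject; 4 are dropped, leaving 146 |
| `tr_seconds` | 2.0 | sampling interval |
| base coupling | sparse random lag-1 | density 0.1, weights U(0.05, 0.15), diagonal U(0.2, 0.4), rescaled to spectral radius 0.7 |
| `delta_edges` | RECN→dDMN, dDMN→BGN, SMN→VSN, +0.15 | directed lag-1 increments applied to the SDI group only |
| `hrf` | off | canonical double-gamma convolution, available for realism runs |
| noise | `noise_sd = 1` Gaussian innovations | |

Choices and why:

* The three planted edges mirror the reported directed group findings
  among the 14 canonical networks; the +0.15 increment is a calibration
  choice — an effect size recoverable at 20 subjects per group — not an
  estimate of any empirical effect, whose true size is unknown.
* The shared base coupling is rescaled to radius 0.7 so both groups show
  plenty of genuine within-group connectivity while staying comfortably
  stationary; a cohort with connectivity only in the planted edges would
  make the recovery problem unrealistically easy.
* Subjects are independent realizations with no between-subject random
  effect, consistent with the exchangeability that temporal concatenation
  assumes.
* Behavioral scores are Gaussian and not integer-rounded; questionnaire
  discreteness is irrelevant to the regression machinery being tested.

What passing tests on this generator do *not* show: robustness to
hemodynamic variability between groups, physiological noise, motion
artifacts, scanner drift, or the spatial stage of real data (the
ICA/template path is tested on synthetic volumes with known blobs, not on
brain-shaped data). Indirect-path effects, however, are faithfully
present: with pairwise GC, a planted $X \to Y$ difference can propagate
through base couplings and occasionally produce a significant indirect
edge (e.g. $Z \to Y$ where $Z$ drives $X$); the recovery criterion
tolerates at most one such edge per run.

## Permutation inference

**Group contrast.** The per-edge statistic is the SDI-minus-control F
difference on the concatenated series. Subject labels are permuted
(group sizes preserved, default `n_perm = 2000`), both matrices are
recomputed at the fixed order, and the one-sided p-value is the percentile
position of the observed difference — the proportion of randomizations
at or above it. This is the classical randomization-test reading and
allows $p = 0$ when the observed difference exceeds every permuted one;
an `add_one` option gives the conservative $(1 + \#\{\text{null} \ge
\text{obs}\})/(1 + n_{\mathrm{perm}})$ rule instead, which bounds p away
from zero at the cost of making small FDR thresholds unreachable at
moderate permutation counts (at $n_{\mathrm{perm}} = 500$ the add-one
minimum of 1/501 already exceeds the BH rung $3q/m$ for 3 discoveries
among 182 tests at $q = 0.05$). Per-edge Monte Carlo standard errors
$\sqrt{p(1-p)/n_{\mathrm{perm}}}$ are reported, and a warning counts edges
whose call sits within 3 SEs of the BH threshold — the operational meaning
of "run more permutations until stable". Multiplicity is controlled by
Benjamini–Hochberg step-up over the 182 directed pairs; the default is
one-sided (SDI > control) with a two-sided option.

**Within-group edges.** The null for "does this edge exist at all inside
one group" is built from circular-shift surrogates: every channel of every
subject is rotated by an independent uniform offset of at least the lag
order. Shifting preserves each channel's autocorrelation exactly while
destroying cross-channel lag alignment — the correct null for a lag-based
statistic, where an i.i.d. bootstrap would destroy autocorrelation and
inflate false positives. Here the add-one rule is used (p ≥ 1/(1 +
n_perm)) with a per-edge threshold of 0.005.

## Graph efficiency

A GC matrix is thresholded at network cost $c$ by keeping the
$\lceil c \cdot n(n-1) \rceil$ largest off-diagonal entries as directed
edges (ties broken lexicographically, so edge sets are nested in $c$).
On the resulting binary digraph:

* global efficiency $= \frac{1}{n(n-1)} \sum_{i \ne j} 1/d_{ij}$ with
  $d_{ij}$ the directed shortest-path length (unreachable pairs
  contribute 0);
* local efficiency $=$ mean over nodes of the global efficiency of the
  subgraph induced by the node's in/out-neighbor union.

Graphs stay directed by default (GC is directed); a symmetrized mode
exists for comparison with undirected-metric conventions, as does a
choice of neighborhood rule. The default cost grid is 0.05–0.50 in steps
of 0.05. The group comparison statistic is the *area between curves*
(one number per metric, avoiding a second multiplicity layer), permuted
with the same label machinery; per-cost differences are reported
descriptively. Note a structural fact exploited by the tests: the cost
fixes the retained edge *count*, so only edge *placement* can move
efficiency — a group difference requires a topological contrast (e.g.
integrated vs modular strong couplings), not merely stronger weights.

## Networks-of-interest from volumes

For volumetric input the package provides the standard decomposition path:
per-subject PCA reduction of the time dimension (default 100 components,
capped at rank), a minimum-description-length estimator for the source
count (Wax–Kailath form: likelihood ratio of the trailing eigenvalues'
geometric to arithmetic mean plus a parameter penalty), group spatial ICA
(FastICA, logcosh contrast, via the `ica` package; maps z-scored, signs
aligned to non-negative skewness), greedy one-to-one template matching by
Pearson spatial correlation over an in-brain mask (ties broken by template
order — injectivity is required because each of the 14 symbols may label
at most one component), and dual-regression back-reconstruction (spatial
then temporal least squares, with a ridge fallback on collinearity). A
subject's network strength is the mean of its component map's beta
weights. Panel-only workflows bypass this module entirely; synthetic NOI
courses go straight to the GC stage, and per-subject channel standard
deviations stand in as the strength scalar.

## Behavioral module

Group comparisons are recomputed from published-style summary statistics
with the Welch t formula (equal group sizes make it coincide with the
pooled test, so the reproduction is insensitive to that choice);
Welch–Satterthwaite degrees of freedom; two-sided p. Strength-to-score
relations are simple one-predictor OLS regressions with Pearson r and
Bonferroni correction for a family of 8 network–scale pairs. The score
generator couples scales to network strengths as
$\text{score} = \mu_g + \sigma_g (r \sum_k s_k z_k + \sqrt{1 - K r^2}\,
\varepsilon)$ with signs $s_k$; a scale may couple to *several* networks
(impulsivity couples negatively to right-executive-control strength and
positively to dorsal-default-mode strength simultaneously), which is why
the coupling field is a list of (network, sign) pairs rather than a single
pair. One known non-reproduction is intentional: the published sex-ratio
p-value (0.869) for 22F/28M vs 25F/25M matches neither the corrected
(≈0.69) nor uncorrected (≈0.55) chi-squared test; both variants are
reported and neither is forced to match.

## Problem sizes and numerical choices

The test suite and acceptance checks run at deliberately scaled sizes
chosen as realistic-but-tractable study conditions: 20 subjects per group,
146 analyzed time points, 500 label permutations for recovery runs and
2000 for null-calibration runs, 20 replicate seeds for rate estimates, and
oracle comparisons on graphs of up to 6 nodes (exhaustive BFS) and 100
random bivariate GC cases at 1e-8 relative tolerance. Degenerate inputs
are rejected loudly rather than patched: non-stationary specs (with the
spectral radius in the message), constant channels in z-normalization,
all-censored series, singular lagged designs (with the condition number),
empty p-value vectors. Determinism is end to end: every generator and
every permutation test is a pure function of its seed, and identical
configurations produce byte-identical TSV outputs.

## Known limitations

* Pairwise GC does not distinguish direct from indirect influence;
  conditional GC is provided but needs more data per regression.
* GC on fMRI rests on temporal sampling far slower than neural events and
  on hemodynamic blurring; the generator can emulate the blur (double-
  gamma convolution) but not group-systematic hemodynamic differences.
* The permutation count bounds the resolution of small p-values; the
  Monte Carlo SE report and stability warning make that visible rather
  than hiding it.
* Human visual inspection of component maps (part of the original
  labeling workflow) is not modeled; template correlation alone decides.
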