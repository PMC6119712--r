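---
title: "Methods: psychometrics, group inference and lesion mapping in vmti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: psychometrics, group inference and lesion mapping in vmti}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmti)
```

## The scientific problem

Limb apraxia is a higher-order motor disorder, typically after left
hemispheric stroke, in which learned purposeful movements fail although
strength and sensation are intact. One candidate mechanism is a
breakdown of *visuo-motor temporal integration*: the comparison of the
predicted sensory consequences of one's own movement (the forward
model's motor prediction) against the visual feedback actually
received. A delayed-visual-feedback detection task probes this
directly: the patient moves (or is touched, or is moved passively), the
video image of their hand is delayed by a known amount, and the patient
answers "delayed" or "not delayed". Presenting three stimulation
conditions (tactile, passive movement, active movement) separates
visuo-tactile and visuo-proprioceptive integration from visuo-motor
integration proper, which only the active condition engages.

`vmti` implements the full analysis chain for such a study — the
psychometric model, the group-level statistical battery, and
lesion-behavior mapping — together with a synthetic cohort generator
that produces data with the coupling structure the analysis assumes.

## The psychometric model

Each patient x condition cell yields, at each delay
$t \in \{33, 100, 200, 300, 400, 500, 600\}$ ms, a detection
proportion from 7 forced-choice sets. A two-parameter logistic is
fitted to these proportions:

$$P(t) = \frac{1}{1 + \exp(-a\,[t - t_{DDT}])}$$

* $t_{DDT}$ (ms) is the **delay detection threshold** (DDT): the delay
  at which "delayed" and "not delayed" judgments are equally likely.
* $a$ (1/ms) is the **steepness**: the temporal precision of the
  judgment. Larger $a$ means a sharper transition.

Fitting minimises the unweighted residual sum of squares over the 7
observed proportions (the proportions are the observations; no
trial-level weighting), using a bounded Levenberg-Marquardt
least-squares optimiser with three starts
($(a, t_{DDT}) \in \{(0.01, 300), (0.005, 150), (0.05, 450)\}$) to
avoid local minima. Bounds are $a \in [10^{-4}, 1]$ /ms and
$t_{DDT} \in [0, 1200]$ ms; the threshold bound deliberately extends
to twice the largest tested delay because apraxic thresholds can lie
beyond 600 ms. Relative function/parameter tolerances are $10^{-8}$;
an optimiser return of "tolerances too tight" or "iteration cap with
residual sum of squares below $10^{-8}$" is treated as converged,
since both occur only when the solution is already at a minimum at
machine precision.

Curves that never or always report a delay leave both parameters
unidentified (any sufficiently extreme threshold fits equally well);
these are reported as failed fits with `NA` estimates rather than as
boundary values, and downstream group analyses list such patients as
excluded instead of silently dropping them. A trial-level Bernoulli
maximum-likelihood fit (`fit_psychometric_mle`) is provided as a
cross-check; it is not the default because the aggregated-proportion
least-squares fit is the convention this analysis chain follows.

## Group inference

The battery mirrors standard practice for a 22-patient, three-group
cohort (apraxic / pseudo-apraxic / unaffected, classified from a
12-point apraxia screen: 12 unaffected, 9–11 pseudo-apraxic, below 9
apraxic, below 5 severe):

* **Descriptives** use the population-SD convention (divisor $n$).
  This choice is forced by the published group tables this package
  reproduces: only divisor-$n$ standard deviations match them.
* **Kruskal-Wallis** on mid-ranks with the tie correction
  $H / (1 - \sum(t^3 - t)/(N^3 - N))$ (via `stats::kruskal.test`).
* **Pearson chi-square** without continuity correction for the
  sex-by-group table.
* **Mann-Whitney U and Wilcoxon signed-rank** use exact enumeration of
  the permutation distribution with mid-rank ties for small samples
  (combined $n \le 12$, or $\le 12$ nonzero pairs), and tie-corrected
  normal approximations above; zero differences are dropped. These are
  hand-implemented because the base distributions fall back to
  approximations whenever ties are present.
* **Split-plot ANOVA** (between: group; within: condition) uses the
  two-stage univariate partition: group is tested on subject means
  against subjects-within-groups; condition and group x condition are
  tested on subject-centred deviations with Type III drop-tests under
  sum contrasts against the subject x condition residual. With 22
  subjects, 3 groups and 3 conditions the dfs are (2, 19), (2, 38) and
  (4, 38). No sphericity correction is applied. Type III is used
  because the groups are unbalanced (9/6/7).
* **Post hocs**: Tukey-Kramer between groups within each condition
  (pooled within-condition error, df $N - g$), and paired t-tests
  between conditions within each group with **uncapped Bonferroni**
  adjustment ($p \times m$, reported even when above 1 — the
  convention of the source analyses, where adjusted values such as
  2.495 are printed as-is; capping is available as an option).
* **Spearman correlations** are Pearson correlations of mid-ranks with
  the $t$ approximation on $n - 2$ df, which is tie-safe.

## Lesion analyses

Lesion masks are binary volumes on one shared grid (NIfTI-1 on disk).
Spatial normalisation is assumed done upstream; an intensity window
(inclusive 100–255 by default) is available to binarize normalised
maps. The analyses are:

* **Overlap maps**: voxelwise counts of lesioned patients.
* **Subtraction maps**: apraxic-group overlap percentage minus
  comparison-group overlap percentage, as integer percentages.
  Rounding is toward zero (71.43 becomes 71, 57.14 becomes 57);
  half-up rounding is available as an option — both reproduce the
  worked values, truncation is the default.
* **VLSM**: at each voxel lesioned in at least 20% of the cohort (and
  with at least 2 patients on each side of the lesioned/intact split —
  the Brunner-Munzel variance is undefined for singletons), behavioral
  scores of lesioned vs intact patients are compared with the
  **Brunner-Munzel** test of the relative effect
  $\hat p = P(X < Y) + \tfrac12 P(X = Y)$, computed via the mid-rank
  identity $(\bar R_2 - (n_2+1)/2)/n_1$. Benjamini-Hochberg step-up
  FDR at $q = 0.05$ is applied over the included voxels only.

### Why VLSM calibrates p-values by permutation

The analytic Brunner-Munzel p comes from a $t$ distribution with
Satterthwaite-type df. At VLSM-typical split sizes (5–8 lesioned vs
14–17 intact) this approximation is anti-conservative in the far tail:
under a null with tied, screen-like scores about 3% of p-values fall
below 0.01 and the minimum analytic p can undercut the permutation
floor $2/\binom{N}{n_1}$ by orders of magnitude. Across hundreds of
included voxels, BH-FDR then declares false families at far above $q$.
`vlsm()` therefore calibrates the per-voxel p by permutation: for each
lesioned-count it builds the null distribution of the studentized
statistic from `n_perm` (default 1000) random reassignments of
patients, and reports $p = (1 + \#\{|T^*| \ge |T|\})/(n_{perm} + 1)$.
The draws come from a fixed internal stream, so identical inputs give
identical maps. The analytic $t$ p remains available via
`p_method = "t"`. Voxels sharing one lesioned-patient pattern (common
with blob-like lesions) are tested once and the result reused.

The z map is signed so that **positive z means lesioned patients score
lower**. Severity screens (higher = better) thus light up deleterious
voxels with positive z, while threshold-type scores (higher = worse,
e.g. the DDT) give negative z there — matching the reporting
convention of positive z thresholds for severity maps and negative
ones for threshold maps. z is recovered from the two-sided p as
$z = s\,\Phi^{-1}(1 - p/2)$.

Complete separation (both within-group rank variances zero without
ties) leaves the studentized statistic undefined; such voxels are
flagged and, in the analytic path, given the permutation floor
$2/\binom{N}{n_1}$ rather than dropped, since they are maximally
informative splits.

## The synthetic cohort generator

The generator is the package's test bed: it produces cohorts with the
statistical structure the analysis assumes, so every pipeline claim is
checked against known ground truth.

* **Patients.** Group sizes default to 7/6/9
  (apraxic/pseudo-apraxic/unaffected, 22 total). Screen subscores
  (imitation 0–7, gesture 0–5) are drawn uniformly from the pairs
  consistent with the group's total-score range; demographics are
  drawn per group from the reference cohort's means and
  population-SDs, clamped to plausible ranges (MMSE at least 25, the
  study's screening floor).
* **Psychometric ground truth.** Tactile and passive parameters are
  severity-independent: $t_{DDT} \sim \mathcal N(300, 40^2)$ ms and
  $a = 0.015 \cdot e^{\mathcal N(0, 0.2^2)}$ /ms for every group.
  Only the active condition is coupled to severity:
  $t_{DDT} = 300 + 25\,(12 - \text{total}) + \varepsilon$ ms and
  $a = 0.015\, e^{-0.12\,(12 - \text{total})}\eta$. The baseline of
  300 ms and steepness 0.015 /ms sit in the range reported for
  delayed-feedback detection in neurotypical adults; 25 ms per screen
  point and a 12% steepness loss per point were chosen once so that a
  fully apraxic patient (total 5 lost points ~ 7) shows a threshold
  extension of order 150–250 ms and a steepness reduction of roughly
  half — the qualitative pattern the analysis is meant to detect —
  while pseudo-apraxic patients stay within noise of the unaffected
  group.
* **Trials.** Within each of 7 sets per condition the 7 delays are
  presented in random order; responses are Bernoulli draws from the
  true logistic. 3 conditions x 7 delays x 7 sets = 147 trials per
  patient.
* **Lesions.** The grid is abstract (40 x 48 x 40 voxels, 4 mm), not
  stereotaxic space; the critical region is a configurable ellipsoid,
  not named anatomy. Each patient receives Poisson(2) random
  background ellipsoid blobs plus a severity-coupled core: the voxels
  of the critical region nearest its centre, sized so the damaged
  fraction is about $0.9\,(12-\text{total})/12$. Axis-aligned
  ellipsoids are the simplest shape family with controllable overlap;
  no claim about real lesion geometry is intended.
* **Seeding.** All randomness flows from one root seed; each stage
  (cohort, trials, lesions, VLSM permutations) draws from a stream
  derived by hashing a stage label onto the root seed modulo
  $2^{31}-1$ (`stream_seed`), so regenerating one stage never
  perturbs another and every result is bit-reproducible.

What the generator does **not** emulate: the hardware feedback latency
(33.71 ms in the original apparatus — the 33 ms level is treated as a
plain delay), experimenter variability in delivering stimuli, redone
error trials (complete designs are always produced), spatially
realistic lesion anatomy, and any dependence structure between
demographics and severity. Passing tests therefore show that the
*pipeline* recovers what it assumes, not that real lesions or real
patients behave this way.

## Numerical choices and degenerate inputs

* Psychometric fits: bounds and starts as above; boundary estimates
  are flagged (`boundary_hit`); all-0/all-1 curves fail explicitly.
* Kruskal-Wallis with every observation tied returns an explicit
  degenerate result (statistic 0, p 1) instead of NaN from the
  vanishing tie-correction denominator.
* Wilcoxon with all-zero differences and Spearman with zero rank
  variance raise errors.
* Brunner-Munzel with all values tied returns statistic 0, p 1,
  flagged degenerate.
* The BH step-up uses the largest $k$ with $p_{(k)} \le kq/V$; with no
  such $k$ nothing is significant and the critical p is `NA`.
* Subtraction rounding is toward zero by default (see above).
* The coverage rule is a weak inequality ($N/\text{cohort} \ge 0.20$),
  so a 19-patient cohort needs at least 4 lesioned patients per voxel.

## Problem sizes used in the shipped checks

The test-suite simulations run at the study's own scale (22 patients,
147 trials each, the default 40 x 48 x 40 grid) where the claim is
about that design, and at reduced scale elsewhere: psychometric
recovery uses 200 Monte-Carlo curves at 7 and 200 trials per level;
null FDR calibration uses 200 cohorts on a 14-cubed grid with denser
blobs (so included voxels exist); critical-region recovery uses 20
full-size cohorts; interaction power uses 60 simulated cohorts,
behavioral stage only. These sizes were chosen as the smallest at
which the binomial tolerances of the corresponding checks are
informative.

## Known limitations

* The split-plot ANOVA offers no sphericity correction; with 3
  conditions and these group sizes the univariate Type III analysis is
  the intended mirror of the source battery, not a general-purpose
  mixed-model tool (`lme4` is the right tool for unbalanced designs
  with missing cells).
* Permutation calibration makes the smallest attainable VLSM p equal
  to $1/(n_{perm}+1)$; with very few included voxels and very strong
  effects the implied z threshold saturates accordingly.
* The generator's severity coupling is linear in screen points lost;
  it is a device for power and recovery checks, not a cognitive model.
* Lesion volumes, not lesion location, drive the generator's
  behavioral coupling only through the critical-region fraction;
  real cohorts confound volume and location more heavily.
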