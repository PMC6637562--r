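---
title: "Differential phosphoproteome analysis of dual-stained 2-DE gels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential phosphoproteome analysis of dual-stained 2-DE gels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(phosphoRate)
```

## The measurement and the model

Two-dimensional gel electrophoresis (2-DE) resolves a protein extract into
spots by isoelectric point and molecular mass. When the same gel is stained
first with a phosphoprotein-specific fluorescent dye (Pro-Q Diamond) and then
post-stained for total protein (SYPRO Ruby), each matched spot yields two
densitometric volumes: a phospho volume $P$ and a total volume $T$. The
per-spot **phosphorylation rate**

$$PR = P/T$$

is the fundamental statistic: it normalises the phospho signal by the
protein amount in the same spot, so it is insensitive to differences in
spot abundance and (after per-image normalization) to image-level staining
and exposure differences. $PR$ is a ratio of two stains with unrelated
response factors, so it is not a stoichiometry; it is comparable *across
groups for the same spot*, which is all the downstream inference uses.
Values above 1 are legal; the package warns above 1.5 as a heuristic for
mismatched spots or saturated phospho signal.

A typical design — and the one the bundled reference dataset comes from — is
two groups (a stress-induced dark-firm-dry, "DFD", meat group and a normal
control group) with four biological replicate gels each. With $N = 4$,
parametric interval estimates for mean $PR$ are not credible, which
motivates the bootstrap machinery below.

## Preprocessing

**Total valid spot normalization** (`normalize_total_valid_spot()`): each
scanned image (one `(group, replicate, channel)` combination) is rescaled so
its detected spot volumes sum to a fixed reference, $10^6$ by default (the
ppm convention). The procedure is standard in gel densitometry; the constant
is arbitrary and cancels in $PR$. The operation is idempotent, and
pre-scaling any single image by a constant does not change its output.

**Reproducibility filter** (`reproducibility_filter()`): within each group,
a spot is kept only if detected on at least `min_reps = 2` of the replicate
gels. Detection is assessed on the total-protein channel — a spot must exist
reproducibly as a protein before its phosphorylation status is interpreted —
while phospho-channel presence is evaluated separately when counting
phospho-positive spots. Filtering is per-group: group-unique spots survive
on purpose.

**Fragment flagging** (`flag_fragment()`): a spot whose observed mass is
well below the theoretical full-length mass of its identified protein is a
degradation fragment. The comparison is standard; the cutoff is not, so the
package uses a documented default (`observed < 0.8 * theoretical`) and
returns "not evaluable" (spot retained) when no theoretical mass is known.

## Interval estimation and the significance call

For each spot and group the replicate $PR$ values are the $P/T$ ratios on
the replicates where the spot is present on the total channel; a replicate
with the spot present but no phospho signal contributes $PR = 0$; a group
with no phospho signal anywhere gets mean 0 and a not-applicable CI.

`bc_bootstrap_ci()` implements the bias-corrected (BC) percentile bootstrap
for the mean: draw `n_boot` resamples of size $N$ with replacement, let $p$
be the proportion of resample means strictly below the observed mean, set
$z_0 = \Phi^{-1}(p)$, and take the resample-mean quantiles at levels
$\Phi(2 z_0 \mp z_{(1+\gamma)/2})$ as the bounds for confidence level
$\gamma$. Numerical choices:

* $p$ is clamped to $[\tfrac{1}{2 n_{boot}}, 1 - \tfrac{1}{2 n_{boot}}]$ so
  $z_0$ stays finite when the resample distribution degenerates;
* ties at the observed mean are *not* half-counted — the bias-correction
  count is strictly-below by definition;
* an all-identical sample short-circuits to the degenerate interval
  $(v, v)$;
* quantiles are read from a smooth inverse CDF: the distinct resample means
  are placed at mid-mass (Hazen) plotting positions and linearly
  interpolated. At $N = 4$ the resample-mean distribution has at most 35
  atoms; an order-statistic quantile would be atom-valued, making the
  Monte-Carlo bounds a discontinuous function of the estimated CDF, whereas
  the interpolated inverse CDF converges smoothly (at rate
  $1/\sqrt{n_{boot}}$) to the bounds computed from exact enumeration of all
  $N^N$ equiprobable resamples. The test suite checks this agreement against
  an independent enumeration oracle.

The default `n_boot = 20000` follows the reference study's methods; its
results table footnote mentions 10,000 replicates, so the value is
configurable and echoed in all output metadata.

**Multiplicity.** Testing $m$ spots at family error rate $\alpha$ uses
Bonferroni-adjusted per-spot levels $1 - \alpha/m$
(`bonferroni_conf()`). $m$ defaults to the number of spots with phospho
signal in at least one group — one comparison per spot, which is how the
reference study frames its "32 of 59" significant set.

**The significance rule** (`significance_call()`) is interval-based:

* both group means zero → not evaluable;
* exactly one group zero → significant iff the nonzero group's adjusted
  lower bound excludes zero ($CL > 0$): the qualitative presence/absence
  case;
* both nonzero → significant iff the two adjusted intervals do not overlap.

The underlying study reports only that significance was assessed "by using"
the adjusted CIs, without stating the comparison operator. Non-overlap of
Bonferroni-adjusted intervals is the most conservative of the standard
choices and reproduces the structure of the published table (every
group-unique spot with a positive lower bound is significant); this
inference is a package convention, flagged here deliberately.

## Effect sizes

`fold_change()` computes $FC = PR_{treated}/PR_{control}$, with ratios below
one reported as negative reciprocals, so $|FC| \ge 1$ always and the sign
encodes direction. $FC$ is infinite for group-unique spots — which is
exactly why it is a poor summary for phosphoproteome comparisons, where most
changed spots are group-unique.

`relative_change()` computes $RC = DPR/|DPR_{max}|$, where
$DPR = PR_{treated} - PR_{control}$ and $DPR_{max}$ is the strongest
difference over the summarised spot set. $RC$ is bounded in $[-1, +1]$ for
shared and unique spots alike, is zero at no change, and the spot with the
strongest positive change gets $RC = +1$ exactly. Two conventions needed
fixing:

* *Scaling constant.* The statistic is defined with the "maximum observed
  $DPR$", but its defining bound $RC \in [-1, +1]$ forces the maximum in
  absolute value whenever the strongest change is a decrease. The package
  uses $\max |DPR|$, which coincides with the signed maximum when the
  strongest change is an increase — as in the reference dataset, so the
  published values reproduce exactly.
* *Universe.* $DPR_{max}$ is taken over the spots called significant
  (default), which reproduces the published effect table
  ($DPR_{max} = 0.94$); `rc_universe = "all"` widens it to every evaluable
  spot.

## Group-level statistics

`spot_group_counts()` decomposes the phospho-positive spot sets into shared
and group-unique spots and asserts the count identities.
`fisher_exact_two_tailed()` compares phospho-positive shares between groups
(standard sum-of-small-probabilities two-sided convention, computed by
`stats::fisher.test`). `mann_whitney_two_tailed()` compares the significant
spots' group-mean $PR$ columns (exact by enumeration for pooled $n \le 12$
without ties, otherwise normal approximation with tie and continuity
correction, via `stats::wilcox.test`). Both wrappers are cross-checked in
the tests against independent brute-force enumeration oracles.

## Clustering significant phosphoproteins

`rc_distance_matrix()` embeds each significant spot at its $|RC|$ value and
uses $d(i,j) = \bigl||RC_i| - |RC_j|\bigr|$ (default). The magnitude metric
is the one consistent with the reference study's clustering, whose
strong-change cluster mixes signs (a strong decrease clusters with strong
increases); a signed variant is available. Any 1-D embedding satisfies the
triangle inequality, and the two-cluster cut is always a contiguous split of
the sorted $|RC|$ values.

`upgma()` is an own implementation of unweighted pair-group average
clustering (no delegation to external clustering software, so tie-breaking
and heights are fully specified): merge
the closest pair, define cluster distances as the arithmetic mean of all
cross pairs (maintained by the size-weighted Lance–Williams update), set the
merge height to half the merge distance. Average linkage is monotone, so the
output is ultrametric. Ties are broken toward the pair earliest in sorted
label order — after canonical sorting, so the result is invariant to input
permutation; the original software's tie policy is unknown, which matters
only for exactly tied distances. The implementation is validated against a
brute-force re-averaging oracle and against `stats::hclust(method =
"average")` cophenetic distances, and exported to Newick with branch lengths
equal to height differences.

`cut_two_clusters()` removes the root; `cluster_mean_ci()` summarises each
cluster by its mean $|RC|$ with a BC-percentile bootstrap CI, by default at
99% (the reference figure's level; its text mentions Bonferroni-adjusted 95%
— both are supported via `conf`). Clusters are declared distinct when their
intervals do not overlap. Note the published cluster membership cannot be
reproduced exactly from published (rounded) $RC$ values: the printed values
place one spot on the wrong side of any 1-D split, so cluster membership is
a qualitative check only.

## The synthetic-data generator

`generate_spot_table()` emulates the study design so the whole pipeline can
be validated against known truth: per-spot lognormal baseline total volumes
(`baseline_log_mean = log(5000)`, `baseline_log_sd = 1`: spot volumes
spanning ~2 orders of magnitude), per-image multiplicative gel factors
(`gel_factor_sd = 0.1`, ~10% image-to-image variation), independent
multiplicative lognormal measurement noise with mean 1 (`noise_cv = 0.1`),
true per-spot phospho fractions per group, and per-replicate detection
dropout encoded as absent records (so the reproducibility filter is
exercised). The design reports no noise model for spot volumes, so these
distributional choices are stand-ins: positive, right-skewed, multiplicative
— the generic character of densitometric data. The generator does not
simulate gel images, spot shapes, spot-matching errors, or systematic
(e.g. mass-dependent) staining biases; passing recovery tests therefore
demonstrate statistical correctness of the pipeline, not robustness to
matching artifacts in real gels.

`scenario_preset("paper_like")` mirrors the reference study's dimensions:
314 matched spots, 4 replicates per group, 46/41 phospho-positive spots with
28 shared, true fractions taken from the bundled reference means, plus 27
shared spots with equal fractions (evenly spaced 0.10–0.62, a plausible
range for unchanged phospho spots). Ground-truth significance labels use a
configurable threshold `|Δ fraction| ≥ 0.1`.

Recovery experiments run the filter and analysis on the *raw* simulated
volumes, without total-valid-spot normalization: normalization rescales each
image to a fixed total and thereby multiplies every $PR$ by the image's
total/phospho composition ratio, which would change the units of the truth
fractions; simulated channels are already on a common scale. For real data,
where channel scales are arbitrary and image totals vary, normalization is
the first step.

## Validation experiment sizes

The shipped test suite uses desk-scale experiments chosen to make the Monte
Carlo error small relative to each assertion: bootstrap-oracle agreement
over 100 lognormal PR-scale quadruples at `n_boot = 20000` (±0.015 band
against exact 256-resample enumeration); coverage agreement between the
Monte-Carlo and enumeration CIs over 400 simulated N = 4 lognormal datasets;
parameter recovery over 50 seeds of the `paper_like` scenario (spots with
true $|\Delta PR| \ge 0.3$ must be called significant in ≥95% of cases,
spots with $\Delta PR = 0$ in ≤5%); and 50 seeds of a 20-spot scenario in
which exactly the five truly changed spots should be flagged.

## Known limitations

* The significance rule and the RC scaling/universe conventions are
  inferences from the structure of published tables, not stated procedure;
  both are configurable and prominently documented.
* Two-sided Fisher P-values depend on the two-sided convention; the package
  uses sum-of-small-probabilities, the dominant one.
* The bootstrap with $N = 4$ is honest but blunt: adjusted intervals are
  wide, and the qualitative ($CL > 0$) rule dominates the significant set
  whenever most changed spots are group-unique.
* No phosphosite-level inference, no abundance-proteome integration, no
  enrichment analysis: the scope ends at the spot-level statistics and
  clustering.
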