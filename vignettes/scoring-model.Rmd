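---
title: "The pooled-growth scoring model behind gipool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pooled-growth scoring model behind gipool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gipool)
```

## The measurement

A many-by-many pool of haploid yeast double mutants grows exponentially
under a condition. Each double mutant carries a fused pair of 20-nt
barcodes, so amplicon sequencing of the pool gives one count per strain
pair per sample. Two kinds of samples exist: the heterozygous-diploid
reference pool taken before sporulation and haploid selection ("time
zero"), and haploid double-mutant pools after growth under each condition,
usually in two technical replicates.

Under constant exponential growth, a strain pair's frequency evolves as
$f_{s,t} \propto N_{s,0}\, 2^{g_{xy} t}$, where $g_{xy}t$ is its number of
doublings. Every count receives a pseudocount of 0.5 before frequencies
are formed, so all ratios stay finite. The unknown initial pool size drops
out of the frequency ratio $r_{s,t} = f_{s,t}/f_{s,0}$ once the total
generations of pool growth, `gen_pool`, is known:

$$g_{xy}t = \log_2 r_{s,t} + \mathrm{gen}_{pool}.$$

Time units are arbitrary: rescaling every $g\,t$ and `gen_pool` by a
common factor cancels in all downstream ratios. `gen_pool` is a property
of the culture (how many times the pool doubled between reference and
sampling) and must be supplied per sample; the simulator's default is 10,
a typical value for an overnight-to-saturation pooled culture. The model
assumes growth-rate differences are constant over the measured window; in
practice $g$ is the average rate over it.

## From doublings to interaction scores

* **Wild-type baseline**: $g_{wt}t$ is the mean $g\,t$ over retained,
  unlinked, distinct-gene neutral–neutral pairs (deletions with no fitness
  effect), with its sample SD kept as $\hat\sigma_{g_{wt}t}$. At least 3
  such pairs are required.
* **Relative fitness**: $w_{xy} = g_{xy}t / g_{wt}t$.
* **Single-mutant fitness**: $w_x = \mathrm{mean}(w_{xj} \mid j \in
  \mathrm{neutral})$, per barcode replicate, over retained unlinked
  neutral partners on the opposite side (same-gene pairs never enter
  neutral means). The spread of $g_{xj}t$ over those partners is
  $\hat\sigma_{g_x t}$.
* **Interaction score**: the deviation from the multiplicative
  expectation, $GIS_{xy} = w_{xy} - w_x w_y$, with any negative $w$
  clipped to 0 first — a negative estimated fitness is measurement noise
  around lethality, and letting it go negative would manufacture spurious
  positive epistasis.

Sampling noise alone produces apparent interactions, so each score gets a
standard error. The double-mutant term $\hat\sigma_{w_{xy}t}$ is estimated
*globally* per condition as the median $|w(R_1) - w(R_2)|$ over strain
pairs (the absolute difference: a signed median would sit near zero and
carry no scale information; with more than two replicates the median runs
over all replicate pairings). The single-mutant and baseline terms are the
SDs above. Writing the score as $GIS = w_{xy} - g_x g_y / g_{wt}^2$ (in
$g\,t$ space) and ignoring covariances, the delta method gives

$$\hat\sigma_{GIS}^2 = \hat\sigma_{w_{xy}}^2
  + \left(\tfrac{g_y}{g_{wt}^2}\right)^2 \hat\sigma_{g_x}^2
  + \left(\tfrac{g_x}{g_{wt}^2}\right)^2 \hat\sigma_{g_y}^2
  + \left(\tfrac{2 g_x g_y}{g_{wt}^3}\right)^2 \hat\sigma_{g_{wt}}^2.$$

The dependence of $w_{xy}$ on $g_{wt}$ is deliberately not propagated —
$\hat\sigma_{w_{xy}}$ is treated as a directly estimated global term. The
tests verify this formula against a Monte-Carlo oracle (10^5 Gaussian
perturbations) to within a few percent in the small-error regime; the
approximation degrades if $\hat\sigma_{g_{wt}}/g_{wt}$ grows large.

$Z = GIS/\hat\sigma_{GIS}$ is then calibrated empirically: unlinked,
distinct-gene pairs containing at least one neutral gene ("neutral
pairs") are expected to harbor essentially no interactions, so their $Z$
distribution is summarized by a normal (sample mean and SD; at least 20
pairs required) and each pair's two-tailed p-value is
$p = \min(p_{pos}, p_{neg}) \times 2$, capped at 1 and floored at the
smallest representable double so downstream combination never sees 0.
Because the error model uses one global $\hat\sigma_{w_{xy}}$ while true
per-pair noise varies with sequencing depth, $Z$ is mildly heavy-tailed
relative to the fitted normal; on fully null simulations the pooled
neutral p-value distribution sits within a Kolmogorov–Smirnov distance of
about 0.03 from uniform. The verification suite therefore tests
uniformity on 2,000 evenly spaced quantiles of the pooled sample — a
deterministic representation of the distribution at that sample size,
rather than a random subsample whose own noise would dominate the
comparison.

## Quality control

Filters run in a fixed order, each followed by one recomputation pass,
and only ever set masks — raw counts are immutable.

1. **Reference coverage**: a pair's count in the het-diploid reference,
   $C_{xy}$, measures how well its starting frequency is known. Pairs
   with $C_{xy} < 30$ are dropped from all denominators and neutral
   means. Coverage comes first because it conditions every later
   estimate.
2. **Genetic linkage**: two loci on the same chromosome closer than
   75 kbp co-segregate during meiosis, depleting their haploid
   recombinants regardless of epistasis. Linked pairs are excluded from
   the wild-type baseline, single-mutant means and the neutral null, but
   are still scored and reported with a flag. Gene *midpoint* coordinates
   are used for the distance (the convention is not critical at a 75-kbp
   scale).
3. **Replicate profile correlation**: barcode replicates of the same gene
   must agree. Each replicate's profile — its mean GIS per (partner gene,
   condition) — is correlated against the element-wise mean profile of
   its siblings; replicates with Pearson $r < 0.5$ are excluded and
   scores recomputed. The sibling-mean reference is robust with three or
   more replicates and symmetric with two; with exactly two disagreeing
   replicates the correlation cannot identify the culprit, so both are
   flagged for review and neither is auto-excluded (empirically such
   cases need orthogonal evidence, e.g. genome sequencing). If exclusion
   would empty a gene's replicate set, the replicate with the highest
   reference coverage is retained with a warning. A replicate without
   siblings has undefined correlation and is retained. This pass needs
   scores, which is why it runs last.

## Gene-level aggregation and calls

Barcode-pair records for one gene pair (oriented alphabetically; the
barcode level stays donor–recipient-oriented because the assay is
asymmetric by construction) are combined by inverse-variance weighting
$\omega_b = 1/\hat\sigma_b^2$ — written $\omega$ to avoid colliding with
fitness $w$ — giving $\hat\sigma_{gene} = 1/\sqrt{\sum\omega}$. P-values
combine by Stouffer's method with the same weights,
$Z = \sum \omega z_b / \sqrt{\sum \omega^2}$, where each $z_b$ carries the
sign of its record's GIS so conflicting replicates cancel rather than
reinforce. Per condition, p-values become q-values with Storey's
estimator: $\hat\pi_0(\lambda) = \#\{p > \lambda\}/(n(1-\lambda))$ on
$\lambda = 0.05, \dots, 0.95$, smoothed with a df-3 cubic spline,
evaluated at $\lambda = 0.95$ and clamped to $(0, 1]$; below 20 p-values
the estimate is too unstable and $\pi_0 = 1$ (Benjamini–Hochberg) is used
with a warning. Calls: positive if $q < 0.01$ and $GIS > 0.075$, negative
if $q < 0.01$ and $GIS < -0.075$, else neutral. The effect-size cutoff
removes high-confidence but biologically negligible scores.

## Differential interactions

For each unordered condition pair $(a, b)$, $\Delta GIS = GIS_a - GIS_b$
and $\Delta Z = \Delta GIS / \sqrt{\hat\sigma_a^2 + \hat\sigma_b^2}$; a
normal null is fitted to $\Delta Z$ over neutral gene pairs, two-tailed
p-values follow as before, and q-values are computed within each
condition pair over repair–repair gene pairs (pooling across the many
condition pairs would mix different null scales). Significance requires
$q_\Delta < 0.01$ and $|\Delta GIS| > 0.1$; each significant record also
reports whether the interaction *type* changed (e.g. `- -> n`), since a
significant shift can stay within one class. Condition profiles over
commonly scored gene pairs are clustered with Chebyshev (maximum)
distance and complete linkage — both chosen so a single strongly
divergent gene pair separates conditions — with missing pairs dropped
pairwise, never imputed, and a lexicographic condition order for
deterministic ties.

## What the simulator emulates — and what it does not

`simulate_pool()` inverts exactly the model above: starting abundances
$N_0$ are gamma-distributed (shape `hetdip_dispersion`, default 3, CV
$\approx 0.58$ — uneven enough to produce the low-count tail the
$C_{xy}$ filter must catch); the reference sample is multinomial in
$N_0$; each haploid sample is multinomial in
$N_0 \cdot d \cdot 2^{w_{xy}\,\mathrm{gen}_{pool}}$ with $d = 0.05$ for
linked pairs (meiotic depletion applies only to post-sporulation samples
— the reference is drawn before sporulation, which is precisely why
linked pairs look depleted relative to it); same-gene pairs get
$w_{xy} = 0$ (unselectable as haploids); technical replicates are
independent draws from identical probabilities. True double-mutant
fitness is $w_x w_y + \varepsilon$ clipped at 0. Aneuploid-like artifact
replicates have their *entire* fitness row redrawn — an independent
single-mutant fitness per condition plus iid pair-level noise, overriding
even same-gene lethality — because the observable that matters is a
profile decorrelated from the gene's other replicates, anchors included.
Barcodes are generated at pairwise Hamming distance of at least 5, which makes
the 3-mismatch matcher provably unambiguous on error-free reads;
`simulate_reads()` writes 25-nt reads (barcode + 5-nt constant flank)
with iid substitution errors and a clean exact-match 6-nt sample index.
Default depth is 10^6 reads per sample.

Not emulated: mating/sporulation kinetics, recombination failure and
chimeric fusions (the all-by-all design makes every donor–recipient
combination legal, so chimera filtering is moot), copy-number mechanics
of real aneuploidy, PCR amplification bias, indels and quality-score
structure in reads, and correlated (batch) measurement error between
samples. Consequently, passing the simulation-based tests demonstrates
that the *inference correctly inverts the stated forward model* — not
that real libraries are free of systematic artifacts the model lacks.

## Numerical conventions and edge cases

* Pseudocount 0.5 on every count before frequencies; frequencies always
  renormalized over the currently retained set.
* Sample SDs ($n-1$) everywhere a spread is estimated — neutral sets are
  small. A single neutral partner gives $\hat\sigma_{g_x} = 0$; none at
  all drops the pair with a warning.
* Medians of even-length sets use the midpoint; p-values are capped at 1
  and floored at `.Machine$double.xmin`; a record with
  $\hat\sigma_b = 0$ dominates its inverse-variance average, and an
  all-zero group falls back to the unweighted mean, flagged.
* A degenerate $\Delta Z$ null (identical condition profiles) yields
  $p_\Delta = 1$ on-null and the floor off-null instead of an error.
* Everything downstream of a fixed seed is deterministic, including
  FASTQ emission and Newick output; genomic coordinates are 1-based.

## Problem sizes used by the verification suite

The test suite and `scripts/acceptance.R` use pools chosen to make each
property measurable quickly: a 40-gene pool (26 repair + 14 neutral, one
barcode per gene per side, two technical replicates, depth 10^6) repeated
over 50 seeds for null calibration; a 20-gene pool with a planted
epsilon grid $\{-0.6, -0.3, -0.1, 0, +0.1, +0.3\}$ for recovery; a
10-gene, 6-condition, 3-replicate pool with a structured interaction
background (per-pair $\varepsilon \sim N(0, 0.2)$) and 6% aneuploid
injection, over 100 seeds, for the profile filter — the background gives
good replicates a correlated profile to agree on, which is what real
repair-gene profiles provide. The whole battery runs in a few minutes on
one core.

## Known limitations

* The global $\hat\sigma_{w_{xy}}$ cannot track per-pair depth
  differences, so $Z$ is a mild scale mixture (see above); extremely
  uneven pools would benefit from a depth-dependent error model.
* Neutral-gene replicates in a pool with no true interaction structure
  have nearly flat profiles, making the correlation filter uninformative
  for them; the filter's guards (flag-don't-exclude for two replicates,
  keep-best-covered) bound the damage but cannot identify artifacts in
  that regime.
* $\hat\pi_0$ smoothing below ~20 p-values falls back to
  Benjamini–Hochberg, which is conservative.
* The multiplicative definition is the only epistasis model implemented;
  log-ratio or minimum-based definitions are out of scope.
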