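---
title: "Allelic age, sojourn times, and the Neighborhood-based Clock: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allelic age, sojourn times, and the Neighborhood-based Clock: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alleleClock)
```

## The model

`alleleClock` is built around one theoretical fact and one statistic that
exploits it.

The fact: conditional on its current population frequency, a selected
allele — deleterious or beneficial — is on average younger than a neutral
allele, and the difference comes mostly from selected alleles having spent
much less time at appreciable frequencies in the past. Under a
constant-size Wright–Fisher diffusion with genic selection (fitnesses
$1, 1+s, 1+2s$; no dominance), time in units of $2N$ generations and
$\gamma = 2Ns$, the scale function is
$S(y) = \left(1 - e^{-2\gamma y}\right)/(2\gamma)$, the infinitesimal
variance $b(y) = y(1-y)$, and $\psi(y) = e^{-2\gamma y}$. For an allele
observed now at frequency $x$ that arose as a new mutation ($p_0 \to 0$),
the expected time per unit frequency it has spent at frequency $y$ is

$$
t(y \mid x) =
\begin{cases}
\dfrac{2\, S(y)\,[S(1) - S(y)]}{S(1)\, b(y)\, \psi(y)}, & y \le x,\\[1.2em]
\dfrac{2\, S(x)\,[S(1) - S(y)]^2}{S(1)\,[S(1)-S(x)]\, b(y)\, \psi(y)}, & y \ge x,
\end{cases}
$$

the Green's function of the diffusion conditioned on present segregation
at $x$. The two branches join continuously at $y = x$. The mean age is
$\bar A(x) = \int_0^1 t(y \mid x)\,dy$. Three structural properties follow
and are enforced by the test suite: the density below $x$ is constant for
$\gamma = 0$ (a neutral allele spent equal time at every frequency below
its current one); density and age are exactly invariant under
$\gamma \to -\gamma$; and the neutral age reduces to
$-2\,[x/(1-x)]\ln x$. Both branches are evaluated via the absolute value
of $\gamma$ (legitimate by the symmetry) with all exponentials in log
space, which keeps the supported range $|\gamma| \le 200$ free of
overflow.

The statistic: the **Neighborhood-based Clock (NC)**. Both recombination
events detectable around a variant and rarer mutations arising on its
haplotype background accumulate with the time the allele has spent
segregating. For an index variant the package scans outward in each
direction over candidate variants and stops at the first that either

* shows **all four gametes** with the index (evidence of recombination
  between the sites), or
* is a **fully linked rarer variant**: its carrier haplotypes are a
  strict, non-empty subset of the index carriers — a mutation that arose
  later on the index haplotype.

With physical distances $d_{up}$ and $d_{down}$ to the two stops,
$\mathrm{NC} = \log_{10}(d_{up} + d_{down})$. Short distances mean the
neighborhood has been broken up many times — an old allele; long intact
neighborhoods mean youth. NC therefore *decreases* with true age, and a
class of deleterious variants shows *larger* NC than neutral variants at
the same minor allele count.

## Parameters and conventions

* **Selection scaling.** $\gamma = 2Ns$ with additive (genic) selection
  throughout; negative $\gamma$ is deleterious. This convention is stated
  here prominently because the $4Ns$ convention is equally common. The
  diffusion results are in units of $2N$ generations;
  `meanAge(units = "generations", nRef = )` converts with a reference
  diploid size.
* **Initial frequency** `p0`: the default 0 denotes the new-mutation limit
  — the case relevant for population variants. The general
  $p_0 > 0$ Green's function is exposed as an option.
* **Frequency grid**: `frequencyGrid(n = 2000, eps = 1e-6)` is log-spaced
  towards both endpoints, where the density has integrable singularities in
  shape. `sojournProfile()` cross-checks the trapezoidal integral of the
  gridded density against adaptive quadrature (`stats::integrate`,
  relative tolerance `1e-6`) and warns with the achieved agreement when the
  grid is too coarse for about `1e-3` relative accuracy.
* **Minor vs derived allele.** Carrier sets default to the minor allele of
  each variant (the stop rule speaks of variants *rarer* than the index);
  exact 50/50 sites deterministically take ALT as minor. With an
  ancestral-allele map attached, `mode = "derived"` restricts the analysis
  to polarized variants and uses derived-allele carriers instead.
* **Candidate filter.** Only non-singleton variants (MAC $\ge 2$) act as
  index variants and as candidates, matching the analysis convention that
  singletons carry no reliable haplotype information; `includeSingletons`
  turns them back on. A consequence worth knowing: a MAC-2 index can never
  be stopped by the subset rule (a strict non-empty subset of two carriers
  is a singleton), so MAC-2 stops are recombination signals only.
* **Distances** are absolute differences of 1-based positions to the
  stopping variant itself, not to an inferred recombination midpoint — the
  simplest reading of the physical-distance definition. A direction with
  no qualifying candidate before the contig end is **censored**; censored
  variants are reported with reasons but excluded from category statistics.
  The four-gamete test is applied directly between index and candidate;
  detecting recombination between intervening pairs would be an
  alternative reading and is not implemented.
* **Comparisons.** Effect sizes are
  $(\bar{NC}_{cat} - \bar{NC}_{syn}) / SD_{syn}$ with the synonymous
  (baseline) SD at the same MAC. p-values are one-sided Mann–Whitney
  (normal approximation with tie correction — NC values tie because
  distances are integers; the exact test is used only for small untied
  samples). Confidence intervals are 95% percentile bootstrap over 1000
  resamples of variants *within* each group; resampling within groups
  matches the percentile-CI usage, while label permutation (the other
  reading of "bootstrap permutations of variant labels") would produce a
  null distribution instead and is not what a CI requires. MAC classes
  2–6 are combined by Stouffer's weighted Z with $w_i = \sqrt{n_i}$,
  $n_i$ the compared-category variant count at MAC $i$ (the weighting
  variable is not pinned down by the source; sample size is the standard
  choice).

## The simulators

`simulateTrajectories()` runs vectorised binomial Wright–Fisher sampling
of unlinked sites: each new mutation enters at count 1 with its own
selection coefficient and its origin generation is recorded.
`schedule` mode introduces mutations continuously and reports the final
(sampling) generation — the natural way to ask "what ages do alleles at
2–4% sample frequency have today?". `absorption` mode follows a cohort to
loss or fixation and can record full occupancy (one row per
allele-generation), which is the most statistically efficient way to
estimate mean age per frequency bin: under stationary mutation influx,
every generation an allele spends in a bin is one draw from the
sampling-time ensemble. Standard errors are then clustered by allele.
`ageByFrequency()` uses 1% bins by default and emits empty bins with
`n = 0` rather than dropping them. The matching theoretical value for a
bin is `predictedAgeByFrequency()`: the occupancy-weighted average of
$\bar A(y)$ over the bin, not the bin-centre age — at 1% resolution the
two differ by a few percent, more than the Monte-Carlo error of a large
simulation.

`simulatePopulation()` is the individual-based engine (C++): diploid
individuals, haplotypes as position-sorted mutation lists, per-generation
fitness $\prod_\text{sites}(1 + s\,g)$ with $g \in \{0,1,2\}$
(multiplicative across sites, additive within a locus — the no-dominance
model of the theory), parent sampling proportional to fitness, meiosis
with Poisson crossovers at rate $\rho L/(4N)$ per gamete, and
infinite-sites mutation at continuous positions at rate $\theta L/(4N)$
per gamete. Fixed mutations are absorbed into the background and counted.
Each haplotype carries the subset of its mutations under selection
separately, so fitness evaluation scales with the selected load rather
than the total load. All randomness flows through R's RNG: a seed fully
determines the output, and stochastic entry points refuse to run without
one.

**Demography presets.** Expansion is exponential growth defined by a
(fold-increase, duration) pair — 100-fold over the final $0.05N$
generations, beginning $2N$ generations after burn-in under the default
$2.05N$ run; the bottleneck preset halves the population instantaneously
at the same time point and then grows at the same rate. The original
forward-simulation protocol expressed growth as a solver-specific rate
constant (156.48); the preset approximates that scenario's shape, it does
not replicate the solver's semantics. Simulation defaults are desk-scale
($N = 1000$, $\theta = \rho = 10^{-4}$ per site) rather than the
$N = 5000$–$10000$ of the original study; all protocol multipliers
(burn-in $10N$, run $2.05N$, events at $2N$, 70% of new mutations
selected) are preserved.

## The synthetic-data generator

`generatePanel()` emulates what a trio-phased population panel hands the
analyst: 188 phased haplotypes (94 unrelated parents), a contiguous
recombining region, a mix of neutral and deleterious variants, category
labels shaped like PolyPhen-2 output, a continuous damage score that
rank-correlates with $|\gamma|$, and an ancestral-allele map. Defaults:
$N = 200$ (desk-scale), one 1 Mb region, $\theta = \rho = 10^{-3}$ per
site, 70% of new mutations at $\gamma = -10$. The mutation density was
chosen to match the variant density of a human whole-genome panel of this
sample size (roughly one segregating site per ~350 bp in 188 haplotypes)
rather than the sparser rates used for the trajectory figures, because NC
scanning needs realistically dense candidates: at $10^{-4}$ per site
essentially every index variant in a desk-scale region is censored before
a stop is found. Region length matters the same way — real scans run
along whole chromosomes, so stop distances (typically tens of kb here)
are never truncated; in a 1 Mb synthetic region a minority of variants
(concentrated at MAC 2, where only recombination stops exist) still
censor, and tests treat censoring as reported missingness.

What the generator does **not** emulate: human demographic history and
linkage heterogeneity (recombination hotspots), exome structure and
codon-level mutation models, a distribution of selection coefficients
(each selected variant carries the same $\gamma$), genotyping or phasing
error, and ancestral-state misassignment (available only as an explicit
error-injection option, off by default). Passing end-to-end tests on these
panels therefore demonstrates that the statistics recover the age signal
the model generates — not that real data are free of the confounders
listed above.

The truth-label comparison in the acceptance suite contrasts the selected
class ($\gamma = -10$) with the neutral class directly. At minor allele
counts 2–6 in 188 haplotypes the standardized NC shifts are small
(the theory predicts age ratios of only ~1.4–1.7 at these frequencies),
so the class-level claims tested are the variant-count-weighted pooled
effect and the Stouffer-combined p-value across MAC 2–6, together with
negative NC–age rank correlation within every MAC; per-MAC effect-size
signs at a few hundred variants per cell are dominated by sampling noise
and are reported, not asserted.

## Numerical choices and degenerate inputs

* Quadrature: `stats::integrate` per branch with relative tolerance
  `1e-6`; non-convergence is an error naming the achieved tolerance.
* Large $|\gamma|$: log-space evaluation, documented range
  $|\gamma| \le 200$; $|\gamma| > 200$ is an error, not a silent loss of
  precision.
* Ties: exact 50/50 minor-allele ties go to ALT; rank ties in
  Mann–Whitney use the tie-corrected normal approximation; zero-variance
  inputs to the Spearman test return flagged `NA`s with a warning.
* Monomorphic columns cannot enter a panel's analyses (variants must be
  segregating; sample-monomorphic variants are dropped and counted when a
  panel is subsampled).
* Degenerate bootstrap resamples of a constant baseline (SD 0) contribute
  effect 0 rather than `NaN`.
* p-values of exactly 0 or 1 in the meta-analysis are clipped to
  `(1e-300, 1 - 1e-16)` with a warning.
* VCF ingestion drops — and counts, in `metadata()$exclusions` —
  multiallelic records, non-SNVs, records with any unphased or missing
  genotype, and duplicated positions; exclusion counts plus retained
  records always equal the input record count.

## Problem sizes used by the test and acceptance suites

Chosen as the package's own desk-scale protocol: diffusion checks on
closed forms are instantaneous; simulation-vs-theory uses $N = 1000$ with
$2 \times 10^6$ endpoint-sampled mutations over a $12N$-generation
stationary window (and $1.6 \times 10^7$ per demographic scenario for the
age-ordering comparison, sized for Mann–Whitney power at $p < 0.01$ in
the weakest, bottleneck, scenario); the NC oracle equivalence runs 200
random panels of up to 20 haplotypes and 50 variants; the end-to-end
pipeline pools 16 independent 1 Mb regions (16 Mb, ~6900 usable selected
and ~3800 neutral NC values at MAC 2–6).

## Known limitations

* The diffusion module is constant-size only; growing populations break
  the $\gamma \leftrightarrow -\gamma$ symmetry and are handled by
  simulation, not theory. Dominance ($h \ne 1/2$) is out of scope.
* NC censoring is a finite-region artifact; analyses of real chromosomes
  should treat contig edges the same way the package does (censor and
  count, never truncate silently).
* The discrete Wright–Fisher process deviates from the diffusion by
  $O(1/N)$; at $N = 1000$ this is a percent-level bias in binned mean
  ages, visible only to estimators with sub-percent Monte-Carlo error.
* `deleteriousFraction()` inherits the assumption that synonymous
  variants are strictly neutral; background selection or weak selection on
  synonymous sites would bias it downward.
* The NC statistic ranks classes of variants; it is not calibrated to
  date individual alleles in generations.
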