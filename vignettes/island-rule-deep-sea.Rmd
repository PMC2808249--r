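---
title: "Testing the island rule in deep-sea colonists: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the island rule in deep-sea colonists: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bathyrule)
options(bathyrule.quiet = TRUE)
```

## The question and the statistical problem

The island rule is the graded macroevolutionary trend in which large
colonists of isolated habitats evolve smaller body sizes and small colonists
larger ones, converging toward intermediate size. An analogous claim has
been made for marine gastropods colonizing the deep-sea benthos: comparing
each genus's deep-sea species against its shallow-water congeners, deep-sea
body sizes appear compressed toward the middle of the size range.

The standard test regresses the deep-sea size estimate $y$ of each genus on
the shallow-water estimate $x$ (both on a log scale) and asks, with an
ordinary-least-squares (OLS) fit and a t-test, whether the slope is below 1.
That test is statistically broken for this design. The shallow ("mainland")
lineages have evolved since the common ancestor of each genus, so $x$
carries lineage-specific drift variance of its own. Regression of $y$ on a
noisy $x$ attenuates the slope: $E[\hat b_{\mathrm{OLS}}] \approx
\sigma^2_A / (\sigma^2_A + \sigma^2_m)$, where $\sigma^2_A$ is the variance
of ancestral sizes across genera and $\sigma^2_m$ the shallow-lineage drift
variance. The OLS slope sits below 1 under a null with *no* deep/shallow
asymmetry at all, and the t-test rejects at a very high rate — a false
island-rule signal manufactured by regression to the mean.

`bathyrule` implements the corrected analysis:

* **Standardized-major-axis (SMA) regression**, the symmetric line fit
  $|b| = s_y / s_x$ with the sign of $r(x, y)$, appropriate when both axes
  carry error. Under the null of no effect the deep and shallow size
  distributions have equal spread and the SMA slope is 1.
* Its natural test statistic, the Pearson correlation $r(x+y,\; x-y)$.
  Since $\mathrm{cov}(x+y, x-y) = \mathrm{var}(x) - \mathrm{var}(y)$, the
  statistic is zero exactly when the spreads match, i.e. when the SMA slope
  is 1.
* A **within-genus permutation test**: deep/shallow labels are permuted
  within every genus, the genus pairs are rebuilt under the same balancing
  scheme, and the statistic is recomputed, giving a distribution-free null.
  The p-value is the proportion of permuted statistics at least as extreme
  as the observed one in its own direction, doubled for a two-tailed test
  and capped at 1 (an absolute-value tail is available as an option). The
  observed statistic is not added to the numerator or denominator; the
  p-value is a pure proportion of replicates.

## Pipeline and parameters

**Depth classification.** Species carry a maximum recorded shell length
(mm) and a shallowest/deepest recorded depth (m). Two rules classify them:

* *midpoint*: deep iff the depth-range midpoint exceeds the boundary
  (200 m by default — the average Atlantic shelf limit and the base of the
  photic zone); total, no exclusions. This liberal rule is the one under
  which the OLS artifact is demonstrated. The rule is deliberately read as
  "midpoint **above** 200 m means deep": the opposite reading would label
  deep-living species shallow.
* *strict*: shallow iff never recorded below the 200 m boundary; deep iff
  only recorded below a cutoff (200, 400, 600 or 800 m); everything else
  excluded. At the boundary, shallow uses $\le$ and deep strict $>$, so a
  species recorded exactly at 200 m is shallow and no species is ever in
  two categories. The deep sets nest as the cutoff rises.

Abyssal/bathypelagic sensitivity filters drop species whose ranges are
wholly (`range_min_exceeds`) or partly (`range_max_exceeds`) deeper than a
threshold (3000 m or 1000 m). Two exclusion counters are kept — all dropped
species, and dropped species that would otherwise have entered the analysis
(classified deep or shallow in a genus with both) — because either
convention is defensible; the analysis-scoped counter is the one reported
alongside results.

**Genus pairing.** Only genera with at least one deep and one shallow
member enter. Log sizes are `log10(shell length)`; means are taken after
the log transform to avoid bias, and every slope, statistic and p-value is
invariant to the log base (a tested property). Three balancing schemes:

* `all_means`: $x$ and $y$ are means over all shallow / deep congeners;
* `equalized`: the larger side is trimmed to the smaller side's count,
  removing the species that least separate the groups — the
  deepest-midpoint shallow species (or, symmetrically, shallowest-midpoint
  deep species). This greedy rule provably maximizes the difference in mean
  depth-range midpoints over all equal-size subset pairs, because the
  objective is a sum of per-species terms; a brute-force enumeration test
  guards the equivalence. It addresses the concern that fewer deep species
  per genus mechanically shrink the deep sample variance, mimicking
  convergence;
* `single_pair`: the one deep and one shallow species with maximal midpoint
  separation. The objective is separable, so this is the deepest-midpoint
  deep species paired with the shallowest-midpoint shallow species, and is
  implemented as equalization to one per side.

Midpoint ties are broken by smaller shell length, then lexicographic taxon
name — an arbitrary but deterministic choice, since no tie-break is implied
by the method's description. A minimum-count genus filter (e.g. at least 2
deep and 2 shallow species) is applied to **pre-equalization** counts: it is
a genus-inclusion criterion that precedes balancing, which is why the
balanced schemes can still be computed afterwards.

**Permutation settings.** The reference analysis uses 100,000 permutations;
the p-value's Monte-Carlo standard error at $p \approx 0.5$ is then about
0.003. Permutations re-run the full pairing scheme per replicate, including
equalization and single-pair re-selection — the selection is part of the
statistic, and freezing it would break the exchangeability argument.
Degenerate replicates (zero variance on a derived axis) are counted as
non-exceeding and tallied; an all-degenerate set is an error, as is a
degenerate observed statistic.

**Common-slope test.** To ask whether the convergence slope differs between
clades (e.g. Neogastropoda against all other gastropods), a
likelihood-ratio test compares one shared SMA slope against per-group
slopes. At a group's own SMA slope the residual axis $y - bx$ and fitted
axis $y + bx$ are exactly uncorrelated, so the statistic reduces to
$-\sum_i w_i \log(1 - r_i^2(\hat b))$ at the common slope $\hat b$
minimizing it, referred to $\chi^2_{k-1}$. The plain weights $w_i = n_i$
are the default; a Bartlett-type small-sample weight $n_i - 5/2$ is exposed
as a flag, since published implementations differ and the uncorrected ratio
is the cleaner baseline. The common slope is found by golden-section
minimization on the log-slope scale over a bracket spanning ten-fold beyond
the per-group slopes.

## The synthetic-data generator

Real species tables cannot be redistributed here, so every statistical
property is exercised on simulated tables with the structure the analysis
assumes. The generator is a two-branch genus star:

$$A_i \sim N(\mu, \sigma_A^2), \qquad
  X_i = A_i + m_i, \; m_i \sim N(0, \sigma_m^2), \qquad
  Y_i = \mu + \beta (A_i - \mu) + d_i, \; d_i \sim N(0, \sigma_d^2),$$

with species log sizes equal to their lineage value plus
$N(0, \sigma_w^2)$ noise, exponentiated to mm. $\beta$ is the island-rule
convergence slope ($\beta = 1$: null; $\beta < 1$: convergence). Defaults:
$\mu = 1.2$ (about a 16 mm shell, a typical gastropod scale),
$\sigma_A = 0.3$ (a 2-SD range of about 25-fold in length, matching the
spread of genus sizes in benthic data), $\sigma_m = \sigma_d = 0.1$,
$\sigma_w = 0.1$, species counts $n_{\text{shallow}} \sim 1 +
\mathrm{Pois}(3)$ and $n_{\text{deep}} \sim 1 + \mathrm{Pois}(1)$ —
reflecting that real genera typically contain fewer deep than shallow
species. Depth ranges are drawn so the strict classifier recovers the
intended labels exactly (shallow: min $\sim U(0, 50)$ m, width
$\sim U(10, 200 - \text{min})$; deep: min $\sim U(\text{cutoff}+50,
\text{cutoff}+1000)$, width $\sim U(50, 1500)$); an optional straddler
fraction gives ranges crossing the boundary, which the strict rule
excludes. The default straddler fraction is 0 so that classification
fidelity is exact unless deliberately degraded.

What the generator does **not** emulate: phylogenetic structure below or
above the genus (a full tree, unequal divergence times), size-biased
sampling of maxima, measurement error in depth ranges correlated with size,
and clade-specific responses. Passing tests on these tables therefore
validate the machinery and its statistical operating characteristics — not
the biological conclusion on any real fauna.

## Operating characteristics, and one subtlety

Three simulation studies anchor the test suite (sizes chosen to give
binomial intervals tight enough to be informative: 1000 replicate data
sets, 199 permutations per test — at which the doubled directional p-value
has exact size 0.05 for a continuous statistic):

1. **Type-I error.** Under the null where species within a genus are
   exchangeable (no branch drift, $\beta = 1$), the species-relabel
   permutation test holds its nominal 5% level.
2. **The OLS artifact.** Under the mainland-drift null ($\beta = 1$,
   $\sigma_m = \sigma_d = 0.3$, 100 genera) the OLS t-test against slope 1
   rejects essentially always (measured rate $\approx 1.0$; the mean OLS
   slope is $\approx 0.49$, matching the analytic attenuation
   $\sigma_A^2/(\sigma_A^2 + \sigma_m^2 + \sigma_w^2 E[1/n_s]) \approx
   0.49$), while the mean SMA slope stays at 1.
3. **Permutation validity under branch drift.** A subtlety surfaced by
   these calibrations: when congeners share a *branch-level* drift effect,
   the species within a genus are no longer exchangeable units — two
   shallow congeners are correlated through their shared $m_i$. The
   species-relabel permutation null then has too little spread and the test
   is mildly liberal (measured type-I error $\approx 0.13$ under drift SD
   0.3 — still an order of magnitude below the OLS rate). The relabeling
   that respects this null's symmetry is the **whole-group swap** (exchange
   each genus's complete deep and shallow sets with probability 1/2), which
   measures exactly nominal ($\approx 0.05$). `permutation_test()` exposes
   both via `relabel =`; the species relabeling is the default because it
   is the established procedure and the exact one when species are the
   exchangeable units. Users whose genera plausibly carry shared lineage
   effects should prefer `relabel = "group_swap"` or read the
   species-relabel p conservatively.

The OLS randomization study (`ols_randomization_study()`) makes the
artifact vivid on a single data set: labels are randomized (group swap by
default — "assigning whole species groups at random" — with species
relabeling as the alternative, since either reading of a randomization
demonstration is defensible), and the fraction of randomized data sets with
one-sided t support for slope $< 1$ at least as strong as the real data is
reported. Under a genuine strong effect this fraction is near 0; under the
drift null it is large (measured $\approx 0.5$ with the default generator),
showing the "significant" OLS trend is unexceptional.

## Numerical and design choices

* Log base 10 throughout; all inferential quantities are base-invariant
  (tested).
* Duplicate taxon names in input files keep the first occurrence with a
  warning; rows failing validation are dropped and counted by reason.
* Subspecies are independent records, never merged into their species.
* OLS p-values are two-sided, matching the permutation test's two-tailed
  convention; an exact fit on the 1:1 line gives $t = 0$, $p = 1$.
* The SMA slope sign follows $r(x, y)$; an exactly zero correlation gets
  sign $+1$ with a warning. The slope is returned whenever $x$ and $y$
  vary; only the test statistic degrades to `NA` (with a warning) when a
  derived axis is constant, e.g. on exactly anti-correlated data.
* Exhaustive permutation enumeration is available whenever the relabeling
  count is small (capped at $10^5$) and is tested against the Monte-Carlo
  path.
* The minimum-count filter is applied before the depth-exclusion switch is
  consulted, and both exclusion counters are exposed, because the original
  tabulations are ambiguous on both points.
* Seeded runs restore the caller's RNG state; identical seeds reproduce
  every p-value bit for bit. A single serial RNG stream is used; results
  are independent of any parallel machinery because there is none.

## Worked example

```{r example, eval = FALSE}
tab <- simulate_species_table(
  simulation_config(n_genera = 100, beta_effect = 0.8, seed = 7))
res <- run_analysis(tab, analysis_spec(depth_rule("strict"),
                                       n_permutations = 10000, seed = 7))
res          # SMA slope, permutation p, OLS slope, t-test p
run_table_suite(tab, "table1A", permute = FALSE)  # slope sweep
```

## Known limitations

* Genus membership is taken from the input table as-is; no taxonomy
  resolution and no phylogenetic correction below the genus level.
* No confidence intervals on the SMA elevation, and no major-axis or
  ranged-MA variants.
* The common-slope p-value is asymptotic ($\chi^2$); its small-sample
  behaviour is only guarded by the Monte-Carlo calibration at $n = 200$
  per group.
* The species-relabel permutation test assumes within-genus species
  exchangeability under the null; see the operating-characteristics section
  for what happens when that fails and which option to use instead.
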