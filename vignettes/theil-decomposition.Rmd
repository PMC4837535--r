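---
title: "Measuring allocation equity with the Theil index and its regional decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring allocation equity with the Theil index and its regional decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(theilequity)
```

## The measure

`theilequity` quantifies how equitably a divisible resource — here, health-care
institutions, health technical personnel, hospital beds and government health
investment — is allocated across geographic units relative to where people
live. For each unit $i$ let $p_i$ be its share of the population and $y_i$ its
share of the resource. The package computes the population-weighted Theil
index

$$T = \sum_{i=1}^{n} p_i \,\ln\frac{p_i}{y_i},$$

which is the mean log deviation, the $\mathrm{GE}(0)$ member of the
generalized-entropy family (sometimes written Theil-L). $T = 0$ exactly when
allocation is proportional to population ($y_i = p_i$ for all $i$); any
divergence makes $T > 0$ (Gibbs' inequality). Although the index is often
described as ranging from 0 to 1, it is in fact unbounded above — extreme
concentration of a resource in a low-population unit drives $T$ arbitrarily
high — and the package deliberately does not cap it, because capping would
break the decomposition identity below. We use the natural logarithm
throughout; changing the base only rescales $T$.

The population-weighted form was chosen over the resource-weighted Theil-T
($\sum_i y_i \ln(y_i/p_i)$) because only the former decomposes *exactly* with
population-share weights, which is what makes regional contribution rates
well defined.

## Exact within/between decomposition

Given a partition of the units into regions $g = 1,\dots,k$ with aggregate
shares $p_g = \sum_{i \in g} p_i$ and $y_g = \sum_{i \in g} y_i$,

$$T \;=\; \underbrace{\sum_g p_g\, t_g}_{T_\text{within}}
     \;+\; \underbrace{\sum_g p_g \ln\frac{p_g}{y_g}}_{T_\text{between}},
\qquad
t_g = \sum_{i \in g} \frac{p_i}{p_g}\,\ln\frac{p_i/p_g}{y_i/y_g}.$$

The identity is algebraic — each unit's term splits into a within part and a
between part by adding and subtracting $\ln(p_g/y_g)$ — so
`theil_decompose()` always reproduces an independently computed total to
floating-point accuracy, and the test suite asserts
$|T - (T_\text{within}+T_\text{between})| < 10^{-12}$ across a thousand random
panels. Contribution rates divide each component by $T$: a region contributes
$p_g t_g / T$, the between part $T_\text{between}/T$. When $T = 0$ every
contribution is reported as `NA` — undefined, not an arbitrary 0.

```{r decompose}
sh <- resource_shares(china_panel_2013(), "personnel")
dec <- theil_decompose(sh, china_partition())
dec
glance(dec)
```

## Share normalization conventions

`resource_shares()` by default normalizes both $p$ and $y$ over the units of
the slice, so each sums to one — the textbook definition, and the setting in
which all non-negativity and decomposition properties hold exactly.

Statistical-yearbook practice introduces a subtlety the package supports
explicitly: the published national population total can exceed the sum over
the provincial units, because some population (armed forces and other
centrally administered groups) is not attributed to any province. Analyses
published from such yearbooks divide provincial populations by the *national*
total. Passing `population_total` (and optionally `resource_total`)
reproduces that convention; $\sum_i p_i$ is then slightly below one and the
result carries a `reference_totals` attribute. For the packaged 2013 panel
the difference is material at the printed precision: the personnel index is
0.0113 under slice normalization and 0.0072 under the national-denominator
convention. Within-region values $t_g$ renormalize inside the region and are
therefore identical under both conventions. The decomposition identity holds
under either convention (it never uses $\sum_i p_i = 1$), but the
"zero iff proportional" and non-negativity guarantees apply only to the
default; with a reference denominator a small index can legitimately be
pulled slightly negative.

## Zero resource shares

A unit with people but none of a resource makes $T$ infinite; the statistic
is genuinely undefined there. The default is a hard error naming the units,
because silent infinities (or silent flooring) hide data problems. For
exploratory work an explicit opt-in `epsilon` floor (suggested value
`1e-12`) replaces zero shares and renormalizes $y$ back to its original sum,
and any result so produced is flagged with an `adjusted` attribute. Units
with $p_i = 0$ contribute zero, the continuous limit of $p \ln p$.

## Densities and trend surfaces

`density_table()` reports each unit's amount per 10,000 persons (populations
are stored in 10,000-person units, so the quotient is already on that scale)
and per 10,000 km². `extremal_ratio()` gives the max/min factor of a density
column together with the units attaining it; it requires strictly positive
inputs, is invariant to the density's scale, and on the packaged 2013 panel
the per-area personnel gap between Shanghai and Tibet exceeds a factor of
2600. `percent_change()` is plain relative growth on a positive baseline;
multi-year growth figures are conventionally computed on per-capita
densities, not raw totals, and the packaged national totals table carries
the published per-capita columns for exactly that purpose.

`theil_trend()` maps the index and, with a partition, the full decomposition
over every year-by-indicator slice of a panel, producing one national row
plus one row per region (so years × indicators × (1 + k) rows). A slice that
fails — say one indicator's total is zero in one year — is dropped with a
warning and recorded in the `problems` attribute rather than aborting the
rest. `autoplot()` draws the index-by-year lines, faceted by indicator;
`plot_contributions()` stacks the regional and between-region contribution
rates by year.

## The packaged 2013 panel

The package ships the 2013 cross-section of China's 31 provincial-level
units (Hong Kong, Macao and Taiwan excluded, following yearbook statistical
coverage), with the conventional east (11 units) / central (8) / west (12)
grouping. Absolute resource amounts were reconstructed as published
per-10,000-capita density × population; the reconstruction is validated by
the provincial sums, which match the published national totals to better
than 0.1% for institutions, personnel and beds. Two transcription decisions
are worth knowing: the source tables romanize both 山西 (Shanxi, central)
and 陕西 (Shaanxi, west) as "Shanxi", and the fixture distinguishes them by
population and land area; investment amounts inherit the coarse two-decimal
precision of the published per-capita column (values 0.05–0.13), so
investment-based indices carry up to ~10% reconstruction noise while the
other three indicators are precise to three significant figures or better.
Per-area comparisons for this panel uniformly use amounts per 10,000 km²;
max/min ratios are unaffected by that choice of scale.

Province-level inputs for 2009–2012 are not packaged (only national totals
are), so multi-year Theil trends for the real system are out of reach of
the shipped data; the synthetic generator covers that ground instead.

## The synthetic generator

`simulate_panel()` exists so that every pipeline stage — validation, shares,
decomposition, trends, the CLI — can be exercised without any download, and
so that the decomposition can be verified by *parameter recovery*: the two
components respond monotonically to two independent dials.

* Populations are log-normal (`population_dispersion` is the log-scale SD,
  default 0.9, matching the observed ~30-fold spread of Chinese province
  populations). Areas are log-normal as well. Both are constant across
  years.
* Within each region, a resource's unit shares are Dirichlet-distributed
  with mean equal to the within-region population shares and total
  concentration `alpha` ($\alpha_g$ per region). Large `alpha` pins
  allocation to population: for $n$ units the within term scales roughly
  like $(n-1)/(2\alpha)$, so the default `alpha = 250` yields within-region
  Theil terms of order 0.01–0.1, the range observed in the packaged real
  panel. At `alpha = 1e9` every indicator's index drops below $10^{-3}$.
* Each region's aggregate resource share is its population share tilted
  multiplicatively by `between_skew` and renormalized; a uniform skew makes
  the between term exactly zero, and the term grows monotonically in the
  skew magnitude (verified over 200-replicate sweeps).
* Defaults mirror the structure of the real system: 31 units, 3 regions,
  4 indicators, years 2009–2013, with per-indicator national totals of the
  observed order growing 5% per year.
* One integer seed drives all sampling through `withr::with_seed()`: output
  is byte-identical under a fixed seed and the global RNG state is never
  touched.

What the generator does *not* emulate: spatial autocorrelation, serially
correlated year-on-year allocation changes (years are redrawn
independently), reporting error, or any calibration to actual provincial
values outside the packaged 2013 cross-section. Passing tests on synthetic
panels therefore demonstrates the correctness of the estimators and the
steerability of the decomposition, not distributional realism.

## Numerical choices

* Identity checks (decomposition additivity, oracle agreement) use
  $10^{-12}$ absolute; share-sum checks use $10^{-9}$. Both sit well above
  double-precision rounding at $n \approx 31$ and far below the 3–4 decimals
  of any published value.
* $T$ and the between term are mathematically non-negative for normalized
  shares but can land within one ulp below zero in floating point; values in
  $(-10^{-12}, 0)$ are clamped to zero. Legitimately negative values under a
  reference denominator are orders of magnitude larger and pass through.
* Full double precision is kept everywhere internally and in CSV output;
  rounding to published precision happens only at presentation time.
* Region order is the stable first-appearance order of the partition file;
  unit order never affects any result beyond reporting order.

## Command-line use

The same operations are scriptable via the shipped entry point:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/theilequity.R", package="theilequity"))') \
  decompose --input panel.csv --partition china3 --indicator personnel --out out/
```

Subcommands `compute`, `decompose`, `trend` and `simulate` write tidy CSVs
(`theil.csv`, `decomposition.csv`, `trend.csv`, `panel.csv`/`partition.csv`)
and exit nonzero with a one-line diagnostic on any error; `--epsilon-floor`
and `--verbose` are available globally, and `simulate` accepts either flags
or a YAML scenario file.

## Known limitations

* The index compares *shares*; it is silent about absolute adequacy (a
  system can be perfectly proportional and uniformly under-resourced), and
  values are not directly comparable across systems with different numbers
  of units.
* Contribution rates are ratios of a decomposition of a single year's index;
  they do not identify causes.
* No sampling variability is quantified — the packaged data are a census of
  units, and the package reports no bootstrap intervals.
* The investment indicator of the packaged panel is reconstruction-limited
  (see above); its index should be read to about two significant figures.
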