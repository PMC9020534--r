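---
title: "The supply-demand framework for fertility: model, decomposition and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The supply-demand framework for fertility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fertdecomp)
```

## The model and its assumptions

The supply-demand view of fertility treats the observed total fertility
rate `F_o` as the outcome of three forces: the *supply* of births (natural
fertility `F_n`, the level that would prevail absent deliberate birth
control), the *demand* for births (wanted fertility `F_w`), and the degree
to which couples *implement* their preferences, summarised by the index

$$I_p = \frac{F_n - F_o}{F_n - F_w}.$$

Observed fertility is then the convex combination
$F_o = F_w I_p + F_n (1 - I_p)$, and unwanted fertility is
$F_u = (F_n - F_w)(1 - I_p)$, so that $F_o = F_w + F_u$ holds as an
accounting identity. Natural fertility is operationalised from
contraceptive prevalence `U` (married women currently using any method)
through the contraception index $C = 1 - 1.02\,U$ as $F_n = F_o / C$.

Assumptions worth keeping in view:

* **`F_n` is not fecundity.** It is observed fertility inflated by the
  contraception index only; other proximate determinants (postpartum
  amenorrhea, abortion, pathological sterility) are not modelled. Where
  they matter — long amenorrhea in particular — the index absorbs their
  effect and can leave the unit interval.
* **The 1.02 coefficient** in `C` is an empirical use-effectiveness and
  exposure adjustment inherited from the proximate-determinants
  tradition. It is exposed as an argument (`coef`) to document its
  provenance; the default is the standard value, and nothing in the
  package depends on changing it.
* **The index is a ratio of small differences.** When `F_n` is close to
  `F_w` the denominator is tiny and the index is volatile; when they are
  equal it is undefined. We treat `F_n <= F_w + 1e-6` as undefined
  (`FN_LE_FW`, error severity) rather than returning an unbounded value,
  because surfacing the degeneracy beats propagating infinities.

## Decomposition of fertility change

For two surveys at times 1 (earlier) and 2 (later), writing
$\Delta x = x_1 - x_2$ (so decline is positive) and $\bar x$ for the
arithmetic mean of the endpoints, the change in observed fertility splits
exactly as

$$\Delta F = \Delta F_w \,\bar I_p \;+\; \Delta I_p\,(\bar F_w - \bar F_n)
\;+\; \Delta F_n\,(1 - \bar I_p).$$

This is an algebraic identity, not an approximation: expanding
$F_o = F_w I_p + F_n(1-I_p)$ at both endpoints and pairing each difference
with the mean of its cofactor makes the cross terms cancel. The identity
holds **only** with arithmetic endpoint means — any other weighting leaves
a residual — which is why the package computes the means internally and
never accepts externally averaged mediators. Percent contributions are
`100 * component / ΔF`.

Two design choices here were genuinely open:

* **Sign convention.** `Δx = earlier − later`, so a fertility *decline* is
  positive and components that pushed fertility down are positive. The
  published national decomposition (a decline of 1.0 birth per woman
  reported as `+1`) forces this orientation.
* **Pairing.** `decompose_series()` pairs the first and last decomposable
  surveys by default, since published decade decompositions use window
  endpoints; consecutive-pair mode is available by option.
* **Index precision.** The index entering a decomposition is always
  recomputed from each record's full-precision values, never read back
  from 2-decimal display output; display rounding is one-way.

## Diagnostics instead of clamping

Published sub-national applications report implementation indices of
−0.09, 1.13 or 1.25 and discuss them as findings about the framework's
limits. The package follows that practice: out-of-range indices are
returned as computed, with warning diagnostics (`IP_BELOW_ZERO`,
`IP_ABOVE_ONE`) and footnote markers (`*`, `**`) in display tables.
Error-severity diagnostics (`FN_LE_FW`, `C_NONPOSITIVE`) leave derived
values `NA` and mark the record non-decomposable, but the record is
retained so reports show what failed and why. When both prevalence and a
printed natural fertility are supplied, the printed value wins (published
tables print `F_n`, not `U`) but is cross-checked against the
prevalence-derived value at 5% relative tolerance (`FN_U_INCONSISTENT`).

Percent contributions over a near-zero fertility change explode —
published stratified tables contain 708% and −671% exactly where the TFR
barely moved. Below `|ΔF| < 0.05` births per woman the percentages are
still computed (the source prints them, so we do too) but flagged
`UNSTABLE_PERCENT`; an exactly zero change yields `NA` percentages with an
error-severity flag. The 0.05 threshold is half a printed rounding unit of
the TFR, the smallest change distinguishable from rounding noise in a
1-decimal table.

## Display rounding

Tables print rates to 1 decimal and indices to 2, with ties rounded away
from zero. Base `round()` rounds half to even, so the package carries its
own `round_half_up()`, used only for display and for matching printed
values; all internal computation is full precision. A small epsilon keeps
decimal ties (stored fractionally below .5 in binary) on the
away-from-zero side; its only observable effect is on exact ties, where it
enforces the intended convention.

## The synthetic generator

Real inputs to this kind of analysis are registration-gated DHS
tabulations, so the package includes a generator producing multi-wave,
multi-stratum aggregate series with known ground truth. Per stratum it
draws trajectories for wanted fertility, natural fertility (or derives it
from a prevalence trajectory) and a true implementation index, computes
observed fertility through the forward model
$F = F_w I_p + F_n(1-I_p)$, then applies measurement noise and optional
1-decimal rounding. Defaults emulate a national East African series over
2000–2015: `F_w` 5.0 → 3.5 births per woman, prevalence 0.10 → 0.45,
natural fertility 8 → 9, index 0.45 → 0.85 along a logistic
(plateau-then-rise) path — magnitudes bracketing the published national
series. The logistic default mirrors the observed plateau-then-rise shape
of national index trends; linear is available.

Choices and their rationale:

* **Noise model.** Additive Gaussian on reported observed and wanted TFR
  (truncated to stay positive), none on prevalence by default: rate
  estimates carry sampling error, and prevalence error is second-order for
  what the framework's tests need. The published series carry no variance
  statements, so the default `noise_sd = 0.1` births per woman is a
  documented stand-in, not an estimate.
* **Strata heterogeneity** enters as per-stratum level offsets on the
  fertility trajectories, drawn once per seed (sd 0.3), mimicking the
  large within-country spread of real sub-national series.
* **Determinism.** The seed is part of the configuration; identical
  configuration gives bitwise-identical output (RNG state is scoped, not
  leaked).
* **`derive` mode** solves the forward model jointly with $F_n = F_o/C$,
  which is only consistent while $C > 1 - I_p$; infeasible combinations
  are refused before any generation.

What passing synthetic tests do and do not show: the generator emulates
trajectory shapes, table rounding and idealised sampling noise. It does
not emulate non-sampling error (rationalisation of wanted-fertility
reports, recall error), survey-design effects, or the other proximate
determinants — so exact recovery on synthetic data demonstrates the
pipeline's arithmetic is an exact inversion, not that real `I_p` estimates
are unbiased.

### Rounding sensitivity

Because printed tables round rates to 0.1, an index recomputed from a
printed row differs from one computed on unrounded estimates. The index is
monotone in each of its three arguments, so its exact range over all
perturbations within ±0.05 of each rate is attained at the 8 corners of
the perturbation box; `rounding_sensitivity()` enumerates them. On the
packaged national series this interval has half-width ≈ 0.01–0.03, which
is exactly the discrepancy pattern between recomputed and published
indices — the published values were evidently computed from unrounded
survey estimates, and the fixture documents this rather than fitting to
it. The same logic bounds the published decomposition components: on
printed inputs they reproduce within ±0.07 while their *sum* matches the
recomputed ΔF to machine precision.

## Problem sizes used in validation

The test suite exercises the exact identities on 10,000 random records,
antisymmetry and round-trips on thousands of pairs, and the
rounding-containment property on 1,000 seeded generator configurations of
3 waves each; the whole suite runs in well under a minute on one core.
These sizes were chosen to make the property checks dense in the valid
domain, not to estimate anything statistical.

## Known limitations

* Only deliberate contraception enters `C`; regions where other proximate
  determinants drive fertility will show distorted indices (the
  diagnostics make this visible, not correct).
* Wanted fertility is taken as reported; rationalisation and measurement
  error pass straight through to `I_p`.
* The alternative wanted-fertility shortcut from want-no-more proportions
  is implemented literally as published, but the published formula is
  internally inconsistent (the estimand appears on both sides); it always
  warns, is disabled in every pipeline default, and exists only so the
  printed arithmetic can be inspected.
* Multi-period path decompositions (sequential or integral) are out of
  scope; only the exact two-point mean-value form is provided.
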