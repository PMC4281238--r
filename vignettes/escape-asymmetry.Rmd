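---
title: "Measuring and modelling symmetry breaking in two-exit escape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling symmetry breaking in two-exit escape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antescape)
```

## The measurement problem

A group of `N` ants escaping a small circular cell through two symmetric
exits splits into `L` escaping left and `R` escaping right. The raw
*percentage difference in door use*, `Δ = 100·|L − R|/N`, cannot be read as
evidence of collective behaviour on its own, because independent escapers
produce positive Δ by chance: two independent ants split (2,0), (1,1) or
(0,2), so E[Δ] is 50%, not zero. The chance contribution falls like
`100·√(2/(πN))`, so any raw comparison across group sizes confounds
behaviour with arithmetic.

The package's core statistic removes the confound. With
`X ~ Binomial(N, 1/2)` the null expectation of Δ is the exact sum

$$E[\Delta_{rand}](N) = \sum_{k=0}^{N} \binom{N}{k} 2^{-N} \,
  \frac{100\,|2k - N|}{N},$$

and the *collective asymmetry* of an observed count is
`ΔC = Δ − E[Δ_rand](N)`. By construction the mean of ΔC over independent
fair-coin escapes is exactly zero at every `N`; positive average ΔC
therefore measures asymmetry *beyond* chance. Because
`E[(2X − N)²] = 4·Var(X) = N`, the null second moment is `10⁴/N` exactly,
and the null SD follows in closed form — `random_difference_sd()` uses it,
and `null_distribution()` exposes the full folded-binomial law.

Numerical notes: the binomial weights are evaluated as
`exp(lchoose(N, k) − N·log 2)`, which is accurate and overflow-free to `N`
of several thousand (tested to 1000 against the asymptotic form and to
`N ≤ 20` against brute-force enumeration of all `2^N` outcomes at `1e-9`).
The expectation is *not* strictly decreasing in `N`: the identity
`E|2X − n|` yields equal values in even/odd pairs (`50` at `N = 2` and
`N = 3`), so monotonicity holds in steps of two; `random_difference_sd(1)`
is clamped to exactly 0 against floating-point cancellation.

## Curve estimation over a trial table

Experimental group sizes cannot be fixed in advance, so the dependence of a
statistic on `N` is estimated by sorting trials by `N` (stable tie-break on
trial id, making results reproducible from the same file) and sliding a
window of `w` consecutive trials along the sorted order. Each *full* window
yields one curve point — no shrinking edge windows — with `x` the
within-window mean `N` (the observed `N` are irregular), `y` the window mean
of the statistic, and a spread equal to the standard error of that mean with
the `(w − 1)` SD denominator. `w = 31` is the default; 21–51 are all
reasonable and the package's tests verify the qualitative curve shape is
invariant across them. `sd_curve()` reuses the same windowing with the
sample SD as `y`, treating the window length as a free parameter since
nothing forces the SD to be computed in the same windows as the mean.

## The alarm-pheromone lattice model

Ants communicate alarm chemically rather than visually. The model places
`n` ants on an `L × L` square lattice (`L = 20`, so one locus is one body
length of 0.39 cm in an 8 cm cell; one time step is one locus at the
measured speed of 0.94 cm/s, ≈ 0.43 s). Per step, in order:

1. every active ant deposits η on its locus (co-located ants stack);
2. every locus loses κ, clamped at zero;
3. each ant, in index order, senses the *clipped* pheromone field over its
   Moore-8 neighbourhood (amounts above the perception threshold `T = 1`
   are indistinguishable and tie; ties are broken uniformly at random),
   turns by adding the sensed unit direction to its velocity componentwise
   through a sign quantiser, advances one locus with reflecting walls, and
   escapes if an exit locus is within its Moore range or underfoot.

Evaporation is specified physically through the fade-out time τ (seconds
for a locus at `T` to drain): `κ = T·Δt/τ` with `Δt = (8/20)/0.94 s`, so
τ = 60 s gives κ ≈ 0.0071. Defaults are η = 1/2, τ = 60 s, inside the
sensitivity grid η ∈ {1/2, 1/10}, τ ∈ {6, 60} s that the package's tests
explore; of those four combinations only (1/2, 60 s) produces the
rise-then-fall density dependence, which is why it is the default.

Design choices where the rules leave room (all config-exposed or documented
here):

* **Exit geometry.** Each 1 cm exit maps to ⌈1.0/0.4⌉ = 3 contiguous
  boundary loci centred on the left (column 0) and right (column `L−1`)
  edges. Detection-range escape means an ant is removed when within
  Chebyshev distance 1 of an exit locus.
* **Velocity rule.** New velocity = sign(previous + sensed direction),
  componentwise; an exact cancellation to (0,0) — disallowed, since ants
  move every step — keeps the previous heading. With nothing sensed the
  ant persists. This preserves persistence and turns toward pheromone.
* **Self-pheromone.** An ant's own locus is not in its detection range, so
  it is not attracted to its standing deposit; its trail in neighbouring
  loci does attract it.
* **Occupancy.** Multiple ants may share a locus ("one ant occupies one
  locus" fixes the spatial scale, not an exclusion rule).
* **Update scheme.** The field is updated synchronously and is fixed during
  the ant sweep; ants are processed in index order. A single RNG stream is
  consumed in a documented order (initialisation, then per step per ant,
  one draw per tied sensing event), so runs are reproducible by seed and
  the compiled runner is trajectory-identical to the R-level primitives —
  a property the tests check directly.
* **Reflection.** A component stepping off the lattice is negated and the
  position mirrored (from column 0 moving left, the ant lands on column 1
  moving right); corner hits reflect both components.

**Emergent behaviour worth knowing about.** The trail attraction that
produces symmetry breaking can also trap ants on their own saturated
trails: a lone ant fails to reach an exit within the 20 000-step default
cap in roughly half of runs at the default parameters. Such runs are
flagged `truncated`; `summarise_runs()` excludes them by default because
their escape totals are censored, but they can be included
(`exclude_truncated = FALSE`), which is unbiased for ΔC since left and
right remain exchangeable in the escaped subset. In the degenerate limit
η → 0 the field stays empty and each ant is a *deterministic* billiard
after initialisation — some orbits never meet an exit — so the
independent-walker null is recovered only over the ensemble of escaped
ants, not run by run.

The headline prediction is non-monotone: ΔC rises from small to
intermediate `n` (trails need traffic to form against evaporation) and
falls at large `n` (ubiquitous super-threshold pheromone is uninformative,
pushing ants back toward the random null). The rise is a small effect at
the default parameters — about one percentage point of ΔC from n = 10 to
n = 40 against a per-run SD near 24 — so the acceptance-level test uses
16 000 runs at those two group sizes (1 000 at n = 160, where the fall is
large), with the per-run step cap at 5 000 in these ensembles to keep the
suite fast; the package default cap stays 20 000. The sensitivity tests
check directions only: raising η toward `T` lowers ΔC at high density
(faster saturation), shortening τ lowers it at low density (trails cannot
accumulate); the τ = 6 s arm truncates in nearly all runs, so that
comparison includes truncated runs' escaped subsets.

## The Vicsek-like alignment model

The contrast model: `n` point particles in a disc of radius 4 cm move at
constant speed and blend headings with neighbours within radius `r`,

$$\mathbf{e}_i(t+1) \propto (1-\beta)\,\mathbf{e}_i(t) +
  \beta\,\langle \mathbf{e} \rangle_{r,i}(t),$$

normalised to unit length (kept unchanged if the blend cancels or no
neighbour is in range). The update is synchronous from time-`t` headings
and noise-free as printed — randomness enters only through initial
positions (uniform over the disc) and headings. Particles reflect
specularly off the wall and escape within 0.5 cm of either boundary exit
point (left at angle π, right at 0). Speed is 0.4 cm per step — one
body-scale hop, commensurate with the lattice model's step — and the
capture radius is half the 1 cm exit width; both are declared defaults, not
measured values, and are config-exposed.

With β = 0 (or r = 0) particles are independent and ΔC is statistically
zero — the model's own null, verified against the exact fair-coin
correction. With strong alignment (β = 0.8, r = 3.75 cm) the ensemble ΔC
*increases* with `n`: bigger groups align more globally and exit together.
This monotone increase, opposite to the pheromone model's rise-then-fall,
is the discriminating prediction, and the tests check both shapes at 500+
runs per group size. `vicsek_grid_sweep()` covers the β ∈ {0.2, 0.5, 0.8} ×
r ∈ {0.6, 2.0, 3.75} design.

## Synthetic trial tables

`generate_trials()` emulates the *statistical shape* of a two-exit escape
experiment, not ant behaviour: 291 trials with total counts `N` drawn from
[6, 269] (uniform by default; log-uniform available, and more realistic
when low-`N` resolution matters). The left/right split is fair-coin
binomial under the null, and under "collective" escape a beta-binomial:
`p ~ Beta(a, a)` with intra-class correlation `ρ = 1/(2a + 1)`, then
`n_left ~ Binomial(N, p)`. ρ is the single over-dispersion knob the
analysis layer actually consumes; ρ → 0 recovers the binomial exactly
(tested against exact probabilities), and every mode is left/right
exchangeable, so synthetic tables carry no hidden side bias.
`generate_rise_fall_table()` makes ρ density-dependent; the default profile
is a log-normal bump peaking at ρ = 0.3, N = 40 with width 0.5 on the log
scale, chosen to put the curve's peak at an intermediate group size and
decay to the null at both extremes of the `N` range.

What passing tests on these tables do *not* show: real escape counts are
not beta-binomial, their `N` distribution is not uniform, and consecutive
repetitions may be dependent through husbandry or arena residue. The
synthetic module validates the analysis pipeline's arithmetic and power,
nothing more. One practical interaction matters for test design: with 291
uniform-`N` trials, the lowest-`N` 51-trial window already spans `N` ≈ 6–50
and straddles the profile peak, so wide windows cannot resolve the rising
flank; the window-robustness test therefore uses log-uniform `N` (1 200
trials), which concentrates trials at small `N`.

## Known limitations

* The lattice velocity rule and sign quantiser are reconstructions
  consistent with the model's published verbal description; the exits'
  lattice placement is likewise a declared choice (3 centred boundary
  loci). Conclusions are robust at the qualitative-shape level the tests
  assert, not locus-for-locus.
* Self-trapping (above) means per-run escape totals at small `n` are
  censored at the step cap; ensemble statistics handle this by flagging,
  and both inclusion policies are available.
* The Vicsek variant has no angular noise, no body size, and no ant–ant
  collision; it is deliberately minimal, serving as the alignment-only
  contrast.
* The exact null assumes every escaped ant chooses a side independently
  with probability 1/2; it is not a generalised (p ≠ 1/2) or correlated
  null, and no hypothesis test beyond SEM/SD bands is provided.
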