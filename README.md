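# antescape

Exact statistics and agent-based simulators for **symmetry breaking in
collective escape through two exits**.

When a panicked group (here: fire ants, *Solenopsis invicta*, driven out of a
small circular cell by a repellent) can leave through two symmetrically
placed exits, the two exits are often used unequally. Quantifying that
asymmetry is subtle: even fully independent escapers split unevenly by
chance, and the size of that chance asymmetry depends strongly on group
size. This package provides the statistic that corrects for it, the analysis
layer that relates it to group size, and two competing agent-based models of
the behaviour, for researchers in collective animal behaviour who want to
analyse two-exit escape counts or probe the models' predictions.

## The statistics

For one repetition in which `L` ants escape left and `R` right
(`N = L + R`), the *percentage difference in door use* is

    Δ = 100 · |L − R| / N .

Under the *random null* — each ant independently escapes left with
probability 1/2, so `L ~ Binomial(N, 1/2)` — the expected difference is
positive and shrinks with N:

    E[Δ_rand](N) = Σₖ C(N,k) 2⁻ᴺ · 100 · |2k − N| / N ,

with `E[Δ²_rand](N) = 10⁴/N` exactly, giving the null SD in closed form.
The *collective asymmetry*

    ΔC = Δ − E[Δ_rand](N)

is zero on average for independent escapers at every group size, so a
systematically positive ΔC is evidence of collective symmetry breaking.
`random_difference_mean()` evaluates the sum exactly (log-domain binomial
coefficients, stable to N of several thousand): 50 for N = 2, 24.6 for
N = 10, 8.0 for N = 100.

Because N cannot be controlled in an escape experiment, the dependence of ΔC
on N is estimated by sorting trials by N and sliding a window (31 trials by
default) along the sorted sequence (`moving_average_curve()`, `sd_curve()`).

## The models

* **Alarm-pheromone lattice model** (`simulate_pheromone()`): ants on a
  20×20 lattice deposit a pheromone amount η per step, the field evaporates
  κ per locus per step, and each ant turns toward the largest perceived
  amount in its Moore-8 neighbourhood — perceived, because amounts above a
  threshold T are indistinguishable and tie. Escape happens on reaching
  either of two 3-locus exits. Trail-mediated attraction makes ΔC **rise
  then fall** with group size: saturation of the field at high density
  destroys the ants' ability to rank directions.
* **Vicsek-like alignment model** (`simulate_vicsek()`): point particles in
  a circular arena blend their heading with the mean heading of neighbours
  within radius r (weight β) and escape near two boundary exit points.
  Alignment makes ΔC **increase monotonically** with group size — the
  qualitative contrast that distinguishes the two mechanisms.

`generate_trials()` emits experiment-shaped synthetic trial tables (fair-coin
null, or beta-binomially over-dispersed with correlation ρ, optionally
density-dependent) for testing the analysis pipeline end to end.

## Worked example

```r
library(antescape)

round(random_difference_mean(c(2, 10, 100)), 1)
#> [1] 50.0 24.6  8.0

## a 291-trial synthetic experiment with density-dependent escape correlation
tt <- generate_rise_fall_table(n_trials = 291, seed = 42)
sign_counts(tt)
#> left right   tie
#>  130   159     2

cv <- moving_average_curve(tt, statistic = "delta_c", window = 31)
head(cv, 3)
#> Escape curve (moving average of delta_c), window 31, 3 points
#>   x_mean_n        y   spread window
#> 1 18.80645 13.87023 4.464973     31
#> 2 19.80645 16.60283 5.025518     31
#> 3 20.83871 16.57358 5.021952     31
pk <- which.max(cv$y)
sprintf("peak dC = %.1f +/- %.1f at mean N = %.0f", cv$y[pk], cv$spread[pk], cv$x_mean_n[pk])
#> [1] "peak dC = 39.3 +/- 4.9 at mean N = 50"

## the two models at n = 40, 200 runs each
round(summarise_runs(simulate_pheromone(40, 200, pheromone_config(), seed = 1)), 2)
#>   runs_used mean_delta mean_delta_c   se mean_n
#> 1       200      22.05         9.51 1.18     40
round(summarise_runs(simulate_vicsek(40, 200, vicsek_config(beta = 0.8), seed = 1)), 2)
#>   runs_used mean_delta mean_delta_c   se mean_n
#> 1       200      33.48        20.94 1.17     40
```

Reading the numbers: the synthetic table's left/right majorities (130 vs
159) are consistent with no side bias; its windowed collective asymmetry
peaks around N ≈ 50 and decays toward zero at large N. At n = 40 the
pheromone model shows a raw difference of 22% of which 12.5 points are
expected by chance, leaving ΔC ≈ 9.5; the strongly aligned Vicsek ensemble
is more than twice as asymmetric.

A command-line interface wrapping these functions (subcommands `null`,
`analyze`, `synth`, `sim-pheromone`, `sim-vicsek`, `sweep`) is installed at
`system.file("cli", "antescape.R", package = "antescape")`.

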