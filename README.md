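# burstcoast

Tools for the quantitative study of burst-and-coast swimming in small
schooling fish (e.g. the rummy-nose tetra *Hemigrammus rhodostomus*)
held in shallow circular arenas. Fish of this kind move in discrete
"kicks" — a brief acceleration with a heading change, followed by a
passive glide with exponentially decaying speed — which makes each kick
a natural behavioural decision and a trajectory a sequence of
stimulus–response pairs. The package implements the full loop around
that idea:

* **Simulation.** An event-driven stochastic model of kick decisions
  for one or two fish. At the *n*-th kick the heading changes by

  δφ = δφ_R(r_w) + δφ_W(r_w, θ_w) + δφ_Att(d, ψ, Δφ) + δφ_Ali(d, ψ, Δφ),

  a spontaneous Gaussian turn (scale γ_R, reduced near the wall), a
  wall-avoidance turn γ_W · O_w(θ_w) · exp(−(r_w/l_w)²), and separable
  attraction and alignment responses to a neighbour,
  F_Att(d)·O_Att(ψ)·E_Att(Δφ) and F_Ali(d)·O_Ali(Δφ)·E_Ali(ψ), with odd
  (O) and even (E) angular factors as left/right symmetry demands.
  Position updates follow the glide law l = v·τ₀·(1 − e^(−τ/τ₀)) with
  τ₀ = 0.8 s, and moves that would exit the arena are rejected and
  redrawn.
* **Segmentation.** Conversion of 50 Hz tracked positions into kick
  tables: centred-difference speed, Savitzky–Golay smoothing,
  acceleration-phase classification with merge/discard rules, activity
  selection, and per-kick variable extraction (length, duration,
  heading change, wall frame and pair frame).
* **Inference.** The measurement method at the package's core: bin the
  per-kick heading changes over the stimulus space, then factorize the
  binned response into parity-constrained products of one-variable
  tabulated functions by a damped weighted-least-squares fixed-point
  iteration — f_w(r_w)·O_w(θ_w) for the wall, a sum of attraction and
  alignment triples for pairs — with no smoothing or regularization.
* **Fits.** Parametric condensation of the tabulated factors into named
  parameters: the wall range l_w, the repulsion/attraction crossover d₀
  and range l_Att, the alignment range l_Ali, harmonic coefficients of
  the angular shapes, and the glide time τ₀.

Everything operates on plain data frames and returns tibbles, so the
stages chain with the pipe.

## Worked example: measuring the wall interaction from a closed loop

Simulate a single fish in the largest arena, reduce the kick log to a
binned wall response, factorize it, and fit the recovered factors:

```r
library(burstcoast)

params <- preset_params(n_fish = 1, radius_mm = 353)
kicks <- simulate_kicks(20000, params, seed = 1, n_burn = 500)

stats <- kick_statistics(kicks)
stats$summary[stats$summary$variable %in% c("tau_s", "l_mm", "r_w_mm"), ]
#> # A tibble: 3 × 5
#>   variable   mean   mode     sd bin_width
#>   <chr>     <dbl>  <dbl>  <dbl>     <dbl>
#> 1 tau_s     0.529  0.413  0.249     0.165
#> 2 l_mm     72.6   66.1   16.9       4.26
#> 3 r_w_mm   19.3   13.2   14.2       8.82

wall <- kicks |>
  symmetrize_kicks() |>
  bin_wall_response(min_count = 5) |>
  factorize_wall()
wall
#> <bc_factorization> wall response: f_wall, O_wall
#>   138 iterations, final error 5.40456, converged

fit_wall_range(factor_table(wall, "f_wall"))
#> <bc_fit> wall_range (converged)
#>   l_w_mm       54.8434
#>   amplitude    0.421435

fit_fourier(factor_table(wall, "O_wall"), parity = "odd", harmonics = 2)
#> <bc_fit> fourier_odd (converged)
#>   a2           0.835662
#>   amplitude    2.84868
```

Reading the numbers: the simulated fish kicks about twice per second
(mean inter-kick interval 0.53 s) with ~70 mm kicks, and spends most of
its time within ~20 mm of the wall — burst-and-coast motion cannot
escape a curved wall efficiently, so trajectories concentrate there.
The factorization, given only (r_w, θ_w, δφ) triples, recovers a wall
force with Gaussian range ≈ 55 mm (the generator used l_w = 60 mm) and
an angular shape sin θ_w·(1 + 0.84·cos 2θ_w) (the generator used a
0.7 modulation; the measured response also contains the extra avoidance
created by rejection of wall-crossing moves, which inflates the
modulation — see the methods vignette). `autoplot(wall)` draws the
tabulated factors; at 2×10⁵ kicks the recovery tightens to a few
percent on l_w.

The analogous two-fish loop uses `bin_pair_response()` +
`factorize_pair()` and the fits `fit_attraction_profile()`,
`fit_alignment_profile()` and `fit_fourier()`; see the methods
vignette (`vignettes/burstcoast-methods.Rmd`) for the model, the
estimation procedure, calibration choices and known biases.

A thin command-line wrapper over the same functions is installed at
`inst/cli/burstcoast.R` with subcommands `simulate`, `segment`,
`infer`, `fit` and `stats`.

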