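# encounternets

Mobility generates encounters: agents (or city dwellers) who repeatedly
visit the same place at the same time become linked, and those links
accumulate into a temporal *encounter network* — the substrate on which
epidemics, behaviours and acquaintance spread. `encounternets` is an R
package for studying that mobility-to-network connection from both
ends:

* **A solvable mobility model.** A discrete-time random walk over `N`
  fixed locations with transition probabilities
  `w(a→b) = Ω_ab / Σ_m Ω_am`, where the affinity is `Ω_ab = 1` for
  `l_ab ≤ R` (all neighbours within radius `R` equally likely) and
  `Ω_ab = (R/l_ab)^α` beyond — a rank model near, a gravity model far.
  Small `α` gives Lévy-flight-like exploration with hop-length density
  `P(l) ∝ l^−(α−1)`; `α → ∞` confines the walker to the random
  geometric graph of radius `R`, which is connected above
  `r_c = sqrt(log N / (π N))`.
* **Exact spectral analysis.** Stationary distribution in closed form
  (`p_b ∝ Σ_l Ω_bl`, by detailed balance), mean return times `1/p_a`,
  and mean first-passage / reach times from one symmetric
  eigendecomposition — cross-validated against a direct Monte Carlo
  first-passage oracle.
* **Encounter networks of many walkers.** Same-site-same-step
  encounters, links sustained by at least `c` encounters inside a
  sliding memory window `(t − M, t]`, and the time courses of the mean
  degree `⟨k(t)⟩` and mean clustering `⟨C(t)⟩ = mean((A³)_ii / k_i(k_i−1))`
  over ensembles of realizations.
* **A check-in pipeline.** Parsing of tab-separated geotagged check-in
  streams, pooled inter-event-time and displacement samples,
  maximum-likelihood power-law fits with a Kolmogorov–Smirnov scan for
  the lower cutoff (and a bounded-interval variant for shallow
  displacement exponents), hourly proximity co-coincidences between
  users at threshold `Δr`, cumulative encounter networks and
  largest-component summaries.
* **A synthetic city.** A check-in generator with planted Pareto gaps,
  truncated power-law displacements, shared hotspots and a daily-routine
  cohort, plus a quadratic brute-force co-coincidence oracle — so the
  entire empirical pipeline is testable offline.

## Worked example

```r
library(encounternets)

## --- the mobility model ---------------------------------------------
loc <- generate_locations(100, seed = 42)   # uniform sites in [0,1]^2
dm  <- pairwise_distances(loc)
k   <- levy_kernel(dm, alpha = 1, R = 0.05)
sp  <- spectral_solution(k)
sp
#> <spectral_solution> 100 modes, spectral gap 0.5219, tau = 108.4 steps
```

`tau = 108.4` is the global reach time: on average ~108 steps for this
long-range walker to first reach a site chosen at random, from a start
chosen at random. The same geometry under a nearly local strategy is
dramatically slower — `global_time()` at `alpha = 10` gives ~2.4 × 10⁶
steps, because `R = 0.05` sits below the connectivity radius
`rgg_critical_radius(100) ≈ 0.121` and long jumps are heavily
suppressed. The spectral reach times agree with direct simulation:

```r
mc <- mc_first_passage(k, target = 7, repeats = 1e4, seed = 1)
c(spectral = sp$tau_per_site[7], mc = mc$mean, se = mc$se)
#> spectral       mc       se
#>    88.13    88.57     0.88
```

## --- the check-in pipeline ------------------------------------------

```r
tab <- generate_checkins(synthetic_config(n_users = 60, duration_h = 240, seed = 7))
nrow(tab)
#> [1] 15561

fit_power_law(interevent_times(tab))
#> <power_law_fit> exponent 2.310, x_min 0.4667, KS 0.0148, n_tail = 6261
```

The fitted tail exponent 2.31 sits near the planted inter-event
exponent 2.5; the mixture with the routine cohort's scheduled gaps
shifts it slightly, and a roamer-only configuration recovers 2.5 to
within ±0.05 (that recovery is one of the checks in
`scripts/acceptance.R`).

```r
co <- hourly_cocoincidences(tab, delta_r = 100)   # same hour, within 100 m
co
#> <coincidence_table> 60 users, 266 co-located pairs, delta_r = 100 m

largest_component_summary(cumulative_network(co, min_contacts = 2))
#> $size           60
#> $edges          225
#> $mean_degree    7.5
#> $mean_clustering 0.478
#> $diameter       6
#> $mean_distance  2.65
```

A small world: 60 users, mean shortest path 2.65, clustering 0.48 —
the hotspot structure and daily routines concentrate encounters exactly
as shared venues do in real cities.

A thin command-line front end over these functions ships in
`inst/cli/encounternets.R` (subcommands `synth-locations`, `simulate`,
`spectra`, `encounters`, `synth-checkins`, `checkin-analyze`).

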