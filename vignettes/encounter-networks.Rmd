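---
title: "Encounter networks from long-range mobility: model, spectra and check-in analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encounter networks from long-range mobility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(encounternets)
```

## The problem

People move between a fixed set of places — homes, offices, restaurants,
gyms — and meeting someone means being at the same place at the same
time. Repeated co-locations are the raw material of contact networks,
which in turn drive epidemic spreading, diffusion of behaviour and the
formation of social ties. `encounternets` studies this mobility-to-network
pipeline twice over: with an exactly solvable random-walk model on fixed
spatial locations, and with an empirical pipeline for geotagged check-in
streams of the kind produced by location-based social networks.

## The mobility model

The substrate is a set of $N$ fixed sites with pairwise distances
$l_{ab}$ (uniform random points in the unit square by default;
`generate_locations()`, `pairwise_distances()`). A discrete-time walker
hops between sites with probability

$$w_{a\to b} = \frac{\Omega_{ab}}{\sum_m \Omega_{am}}, \qquad
\Omega_{ab} = \begin{cases} 1 & 0 \le l_{ab} \le R,\\
(R/l_{ab})^{\alpha} & l_{ab} > R.\end{cases}$$

Inside the neighbourhood radius $R$ every site (boundary included) is
equally likely — a rank-model regime where the chance of a particular
nearby site falls as $1/S$ with the number $S$ of neighbours. Beyond
$R$ the probability decays as a power of distance, a gravity-model
regime whose exponent $\alpha$ controls long jumps:

* $\alpha \to 0$: all sites equivalent, $w_{a\to b} = 1/N$ exactly;
* intermediate $\alpha$: Lévy-flight-like motion. On a dense site set
  the hop-length density follows $P(l) \propto l^{-(\alpha-1)}$ (an
  annulus at distance $l$ holds $\propto l\,\mathrm{d}l$ sites, each
  reached $\propto l^{-\alpha}$), truncated at large $l$ by the finite
  domain;
* $\alpha \to \infty$: purely local motion, handled symbolically
  (affinities exactly 0 or 1). The reachable set is then the random
  geometric graph of radius $R$, connected with high probability above
  $r_c = \sqrt{\log N / (\pi N)}$ (`rgg_critical_radius()`).

Two conventions matter and are explicit flags. **Self-hops**: the
affinity rule literally gives $\Omega_{aa} = 1$ (a site is inside its
own neighbourhood); the default keeps the self-term, and
`allow_self = FALSE` zeroes the diagonal before normalization. All
closed forms are evaluated under whichever convention is active.
**Metric**: planar Euclidean by default (Manhattan available as the L1
norm; no street routing). Geographic coordinates use great-circle
distances on a sphere of radius 6371 km, so metre thresholds are
reproducible; lat/lon are never projected.

## Exact spectral characterization

Because $\Omega$ is symmetric, the chain satisfies detailed balance and
its transition matrix is similar to a symmetric operator
$D^{1/2} W D^{-1/2}$ ($D$ = diagonal of affinity row sums). All
eigenvalues are real, $1 = \lambda_1 > \lambda_2 \ge \dots \ge
\lambda_N \ge -1$, and `spectral_solution()` obtains the right
eigenvectors and their duals from one symmetric eigendecomposition —
no general matrix inverse, which keeps the duals orthonormal to
round-off even for nearly degenerate spectra. From it:

* the stationary distribution has the closed form
  $p_b^\infty = \sum_l \Omega_{bl} / \sum_{lm} \Omega_{lm}$ — each
  site's share of total affinity;
* mean return times $\langle T_a \rangle = 1/p_a^\infty$ (Kac);
* mean first-passage times from the fundamental-matrix sum over the
  non-unit modes, $T(b \to a) = (G_{aa} - G_{ba})/p_a^\infty$ with
  $G = \sum_{m\ge 2} (1-\lambda_m)^{-1} \,|\phi_m\rangle\langle\bar\phi_m|$;
* per-site reach times $\tau_a$ — the mean steps to first reach $a$
  from a uniformly random start — and their average $\tau$, the scalar
  that ranks navigation strategies. Long-range strategies
  ($\alpha \le 1$) minimize $\tau$ and are insensitive to $R$; nearly
  local walks with small $R$ need orders of magnitude longer.

A design point worth recording: spectral reach-time formulas are easy
to get subtly wrong (index bookkeeping between eigenvectors and their
duals), so the package commits to the standard mean-first-passage
construction above and *validates it against an independent Monte Carlo
oracle* (`mc_first_passage()`), which simulates first arrivals directly
from uniform starts. The two agree within Monte Carlo error on every
instance in the test suite (20 random geometries, $N \le 30$, $10^4$
repeats each).

The start-equals-target convention is the other genuinely open choice:
"reach from a random start" counts 0 steps when the start already is
the target. The oracle and the spectral path share this convention; on
the two-site chain both reduce to the geometric closed form
$\tau = \tfrac12 (1/w)$.

## Encounter networks of many walkers

$N_w$ walkers move independently on the same kernel. Two walkers
*encounter* each other when they occupy the same site at the same step
(no distance tolerance in the simulator — spatial tolerance belongs to
the empirical pipeline where coordinates are continuous). Encounters at
$t = 0$ count; before the start there are none. A link $i \sim j$
exists at time $t$ if the half-open memory window $(t - M, t]$ holds at
least $c$ encounters of the pair; encounters at exactly $t - M$ have
just been forgotten. The adjacency $A(t)$ is symmetric, binary and
hollow, and with $M = \infty$ the rule degenerates to the cumulative
"at least $c$ encounters since $t = 0$" construction used for empirical
data, under which the edge set is monotone in $t$ and nested in $c$.

`encounter_curves()` tracks the mean degree
$\langle k(t)\rangle = \frac1{N_w}\sum_i k_i(t)$ and the mean local
clustering $\langle C(t)\rangle$, with
$C_i = (A^3)_{ii} / (k_i(k_i-1))$ for $k_i \ge 2$ and $C_i = 0$
otherwise. Windowed pair counts are maintained incrementally (events
entering at $t$, leaving at $t - M$), so the cost per step scales with
co-locations rather than with all pairs, and the matrix cube is taken
on sparse adjacencies. Ensemble curves average the *metrics* across
realizations at each $t$ — never metrics of an averaged matrix. Both
curves rise from an empty network and, once $t \gg M$, fluctuate about
a stationary plateau set by the balance of link creation and memory
loss; more local strategies (larger $\alpha$) concentrate walkers and
raise both plateaus. Note that "curves start at zero" is a theorem only
for $c \ge 2$: with $c = 1$, chance co-placements at $t = 0$ already
create links.

## The empirical check-in pipeline

`read_checkins()` parses tab-separated check-in streams (defaults match
the public Foursquare-style dump: user, venue, category, latitude,
longitude, timezone offset in minutes, UTC time string). Malformed rows
are counted and reported with line numbers, never silently dropped.
From a table the pipeline computes:

* **Inter-event times** $\tau$ (hours) and **displacements** $r$ (km),
  consecutive within each user's chronological stream and pooled across
  users — never across users.
* **Heavy-tail fits.** `fit_power_law()` implements the standard
  maximum-likelihood recipe for $P(x) \propto x^{-\gamma}$,
  $x \ge x_\mathrm{min}$: $\hat\gamma = 1 + n / \sum \ln(x_i/x_\mathrm{min})$
  with $x_\mathrm{min}$ chosen to minimize the Kolmogorov–Smirnov
  distance over candidate cutoffs (unique sample values, thinned to at
  most 500 log-spaced candidates; ties break to the smallest cutoff,
  i.e. the longest tail). `fit_power_law_range()` handles the shallow
  displacement exponents near 1, which are only normalizable on a
  bounded interval: the likelihood is normalized over $[lo, hi]$ and
  maximized numerically in one dimension.
* **Co-coincidences.** Two users co-coincide in an hour when both check
  in during that calendar hour at locations within $\Delta r$ metres
  (minimum over their check-in pairs in the hour). Hours are binned in
  each check-in's *local* time — daily routines are local-time
  phenomena, and the offsets travel with the data — with a
  `local_time = FALSE` switch for UTC binning. Each (pair, hour) counts
  at most once, whatever the number of within-range check-in pairs, so
  a pair's count $n$ reads as "hours co-located" and bursts of rapid
  check-ins cannot inflate it. Both choices are flags because the
  construction admits either reading; the defaults are the documented
  ones.
* **Networks.** Cumulative encounter networks at threshold $c$, their
  $\langle k(t)\rangle$/$\langle C(t)\rangle$ curves, and
  largest-component summaries (size, edges, mean degree, mean
  clustering, diameter, mean path length). Components and path lengths
  come from igraph; clustering uses the matrix-cube definition above,
  with degree-$\le 1$ nodes contributing 0.

## The synthetic generator

`generate_checkins()` emulates the statistical structure the pipeline
assumes, so everything is testable without any data download. Per
roaming user: a uniform home in a square city, gaps drawn
Pareto($\gamma$) above a floor, moves with truncated-power-law lengths
and uniform directions, each move snapping to the nearest shared
hotspot with probability $p_\mathrm{hotspot}$. A routine cohort instead
repeats a fixed daily schedule of hotspot visits (with ~20 m spatial
jitter and a random within-hour offset), which plants recurring
co-coincidences and a saturating cumulative network. Defaults, chosen
once as a plausible synthetic city: 200 users over 30 days in a 20 km
box; $\gamma = 2.5$ above 0.25 h (a clearly heavy but normalizable
tail); displacement exponent 1.5 on $[0.001, 10]$ km — deliberately
steeper than the $\approx 1.15$ seen in real city data, for comfortable
normalizability in recovery tests, with the shallow value available as
a parameter; 50 hotspots; $p_\mathrm{hotspot} = 0.5$; a 20 % routine
cohort with 3 daily slots; timezone offset −240 min. Identical config
and seed reproduce the byte-identical file.

What the generator does *not* emulate: venue-category semantics,
circadian and weekly activity rhythms for the roaming cohort,
user-level heterogeneity in check-in rates, and the strong spatial
clustering of real venues. Tests that pass on synthetic data therefore
validate the *mechanics* of the pipeline (binning, distances, counting,
fitting, network construction) and its statistical recovery of planted
laws — not any claim about real cities.

A quadratic brute-force oracle (`brute_force_cocoincidences()`, all
check-in pairs scanned directly, guarded at $10^4$ rows) must agree
exactly with the bin-grouped pipeline on every synthetic instance; the
suite checks 50 random configurations.

## Numerical choices and degenerate inputs

* Sampling uses inverse-CDF lookups on precomputed cumulative kernel
  rows; the last cumulative entry is pinned to 1 against rounding
  drift. Every walker in every realization draws from its own substream
  derived from the master seed, so ensembles are reproducible
  walker-by-walker and grow stably (adding walkers never changes
  earlier walkers' paths).
* $\alpha = \infty$ is symbolic (exact 0/1 affinities), never a large
  float; an isolated site under it raises an error naming the site, and
  a disconnected local kernel is rejected before any stationary or
  spectral quantity is computed.
* Eigendecomposition always goes through the symmetrized operator;
  the reach-time solver refuses chains whose unit eigenvalue is not
  simple.
* The Monte Carlo first-passage oracle caps chains at $10^6$ steps and
  raises rather than return a truncated mean.
* Duplicate locations are allowed ($l_{ab} = 0$ off-diagonal) and fall
  inside every neighbourhood.
* Statistical checks against the stationary law thin the simulated walk
  to several relaxation times ($\lceil 5/(1-\lambda_2)\rceil$ steps)
  before a chi-square test: successive states are autocorrelated, and
  the raw-count test would reject far too often for reasons that have
  nothing to do with the stationary distribution.
* Hop-length histograms use log-spaced bins (the natural scale for a
  power-law tail); zero-length hops are reported as a separate point
  mass. Scaling exponents are read off as the least-squares log-log
  slope over the decade $[R, 10R]$ — above the flat neighbourhood
  regime, below the scale where the finite domain truncates the tail.

## Problem sizes in the test suite

The suite validates the printed limits and statistical claims at these
scales, chosen so the whole suite runs in a couple of minutes while
leaving no estimate starved: stationary-law goodness of fit on a
$10^6$-step walk over 50 sites; hop-length scaling at 2000 sites and
$10^6$ hops per exponent; spectral-vs-Monte-Carlo reach times on 20
random geometries ($N \le 30$, $10^4$ repeats); encounter dynamics with
500 walkers on 100 sites over 200 steps and 10 ensemble realizations;
exponent recovery from $2 \times 10^5$ planted gaps and displacements;
and exact pipeline-vs-oracle agreement on tables of a few thousand
rows.

## Known limitations

* The model walks on a *fixed* site set; there are no continuous-space
  flights, time-varying kernels, or interactions between walkers, and
  no contagion dynamics on the resulting network.
* Largest-component statistics are not monotone in $\Delta r$ on sparse
  data: enlarging the radius can merge components and *lower* the
  component's mean degree even though every pair's co-coincidence count
  is non-decreasing. Only the dense-network regime shows the intuitive
  monotone behaviour.
* The KS-scan power-law fit inherits the usual caveats of tail fitting:
  with few tail points the cutoff estimate is noisy, and the scan
  requires at least 10 points above a candidate cutoff.
* Hour binning is calendar-based; events 1 minute apart straddling an
  hour boundary do not co-coincide. This is the construction's
  definition, not an accident, but worth remembering when choosing
  $\Delta r$ and thresholds.
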