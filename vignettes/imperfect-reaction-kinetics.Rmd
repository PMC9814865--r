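---
title: "Imperfect reaction kinetics in confinement: models, solvers and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imperfect reaction kinetics in confinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(confinedrxn)
```

## The problem

Most chemical encounters do not react: a reaction typically requires many
random meetings between reactants before it completes.  Inside a confining
volume — a cell, a microreactor — the kinetics of such *imperfect* reactions
are controlled jointly by transport (how long it takes the reactants to
meet) and by reactivity (how many meetings are needed).  `confinedrxn`
implements a complete modelling stack for this problem:

* **discrete models**: a continuous-time random walk on a network of `N`
  sites with one reactive site, which reacts at each visit with probability
  `p`;
* **continuum models**: Brownian motion in a confining domain with a
  spherical target that is either a penetrable *sink* (killing rate `k`) or
  an impenetrable, partially reactive surface (*Robin* reactivity `kappa`);
* the **asymptotic theory** that ties them together: in the large-volume
  limit the full distribution of the reaction time is determined by its
  mean alone, and it has the *same shape* as the first-passage-time
  distribution of the perfect reaction, rescaled.

## Discrete model

The walker waits an exponential time with rate `nu_i = w * degree(i)` at
site `i` and jumps to a uniform neighbour; the per-edge rate is `w = 1` by
default.  This waiting-time convention makes the stationary distribution
uniform (`q_i = 1/N`), which is the setting in which the Kac theorem gives
the mean return time to the target *exactly*:

> `mean return time = N / nu_0`, with `nu_0` the target's exit rate.

The reaction time from start `r` decomposes as a first passage plus a
geometric number (mean `(1-p)/p`) of independent return excursions.  Two
consequences, both exact on any finite network:

* mean decomposition: `<T_r(p)> = <tau_r> + ((1-p)/p) N / nu_0`;
* renewal identity in the Laplace domain:
  `F(s) = p F*(s) / (1 - (1-p) F1*(s))`.

**Timing convention.**  The Bernoulli trial is drawn on each arrival at the
target, and a successful reaction completes at the end of that residence,
so every visit contributes its residence time.  The first-passage time
likewise includes the residence on arrival, and the sampled return time
runs from a departure to the end of the next arrival's residence.  This is
the unique convention under which the decomposition above holds exactly —
we verified it symbolically on the two-state chain, where
`<T(p)> = 2/p` (per-edge rate 1).

The package computes these quantities three independent ways, which
cross-validate each other in the test suite:

1. event-driven Monte Carlo (`sample_reaction_times()`,
   `sample_return_times()`), exact for the continuous-time chain (no
   discretization error);
2. sparse linear solves for means and Laplace transforms
   (`exact_mean_reaction_time()`, `reaction_laplace()`);
3. dense eigendecomposition for full survival curves
   (`exact_survival()`, guarded at `N <= 1e4`; beyond that a fixed-Talbot
   numerical inversion of the sparse resolvent, `survival_talbot()`, is
   available).

For `p < 1` the transient generator is symmetrized by the similarity
transform built from the reversibility measure (`m_i = 1`,
`m_target = 1/(1-p)`), so the eigendecomposition is numerically stable.
At `p = 1` that measure degenerates; the implementation instead
diagonalizes the target-deleted (symmetric) block and convolves the final
exponential residence analytically.  When an arrival rate coincides with
`nu_0` the convolution weights are evaluated with a relative shift of
`1e-8`, which bounds the cancellation error of the resulting survival
values near `1e-8` — well below every tolerance used.

## Networks and exponents

Builders: `build_vicsek(f, g)` (trees, `N = (f+1)^g`, target at the
centre), `build_dual_sierpinski(g)` (`N = 3^g`, target at an apex),
`build_percolation(L, retain, seed)` (largest cluster of a bond-diluted
square lattice; the target is the retained site nearest the lattice
centre, ties broken by lowest index, a documented convention — there is
no canonical choice for a disordered cluster), and
`build_lattice_torus(side, dim)` for the noncompact case.  Scaling
exponents (`exponents_for()`) are literature constants — Vicsek
`d_f = ln(f+1)/ln 3`, `d_w = ln(3(f+1))/ln 3`; dual gasket
`d_f = ln 3/ln 2`, `d_w = ln 5/ln 2`; 2D critical percolation
`d_f = 91/48`, `d_w = 2.878` — and can be overridden with measured values.

Two structural details are easy to get wrong for these families.  First, attaching the `f` copies "corner to corner" necessarily
creates degree-2 joint vertices, so Vicsek trees of generation 2 and above
have degrees `{1, 2, f}` (a `{1, f}`-only 16-site tree is impossible: it
would need seven degree-3 vertices while four stars provide only four
centres).  Second, the 9-site dual gasket has eccentricity 3 from an apex,
not 4; both facts are asserted by hand-enumeration tests.

## Compact asymptotics

For compact walks (`d_w > d_f`) the mean reaction time obeys the two-term
law implemented in `mrt_compact()`:

> `<T_r(p)> ~ N r^(d_w-d_f)/nu_0 + N (1-p)/(p nu_0)`

a diffusion-controlled (DC) and a reaction-controlled (RC) part, balancing
at the crossover distance `l_c = ((1-p)/p)^(1/(d_w-d_f))`
(`crossover_length()`).  On the Vicsek tree `f = 6`, `g = 4` at
`p = 0.05` the exact (linear-solve) mean agrees with the two-term law to
better than 10% throughout `2 <= r <= 25`; beyond that the deviation
grows steadily (15% near `r = 30`, ~35% at the outermost shells near the
diameter 40), the expected saturation of a large-volume asymptotic at
the boundary of a finite structure.  Our tests assert the law inside the
scaling window `2 <= r <= 25` — which spans both the reaction-controlled
and diffusion-controlled regimes around `l_c = 19` — and treat the
boundary shells as reportable deviations, not failures.

The survival probability collapses, in rescaled coordinates
(`rescale_survival()`), onto the universal function
`Phi_nu` (`phi_universal()`), a series over the zeros of the Bessel
function `J_{-nu}` with `nu = d_f/d_w`.  Numerical notes:

* zeros are found by bracketed root search seeded with the McMahon
  asymptotic spacing and validated against the closed form
  `(k + 1/2) pi` at `nu = 1/2`;
* the series truncation is adaptive (last term below `1e-10` of the
  partial sum, at least 50 terms); the series converges slowly as
  `theta -> 0`, where the asymptotic form is not meaningful anyway;
* `phi_integral()` sums the termwise integrals and completes the slowly
  converging `k^(-1-2 nu)` tail with its analytic asymptotic form; the
  result equals 1 to better than `1e-6`, as it must for a limiting
  density.

**Validity regime.**  The collapse is a large-volume statement that
requires `p >> p* = N^(1 - d_w/d_f)` (`reactivity_threshold()`), the
reactivity below which the crossover length reaches the system size.  At
the sizes a dense eigensolver handles (`N <~ 3000`), `p = 0.05` sits at
or near `p*`: we measure sup-norm distances to `Phi_nu` on
`theta in [0.3, 3]` of 27–40% for the dual gasket at `g = 6, 7`
(`p*/p = 0.93, 0.56`) that shrink steadily with generation
(54%, 40%, 27%, 17% for `g = 5..8`) — reaching the few-percent collapse
quality seen in the perfect-reaction case requires `N ~ 1e5..1e6`,
which on deterministic fractals is the domain of recursive
eigen-constructions that this package deliberately does not implement
(the generic solver is exact at moderate `N`; asymptotics at large `N`
are probed by Monte Carlo).  At `p = 1` the same machinery collapses onto
`Phi_nu` to 0.3–2.3% already at `N ~ 700–2400` (7.7% at `N = 343`,
the smallest size we test).

## Noncompact asymptotics

For noncompact walks the first-passage density is asymptotically an atom
at zero plus a single exponential (`fpt_density_noncompact()`), and the
imperfect-reaction survival keeps that exponential shape with renormalized
parameters (`survival_noncompact_theory()`):

> `S(t) = (<T_r(p)>/<T(p)>_G) exp(-t/<T(p)>_G)`, with `S(0+) < 1`.

On the `16^3` periodic cubic lattice the exact slowest decay mode
(`survival_tail()`) matches `1/<T(p)>_G` and the prefactor matches
`<T_r>/<T>_G` to a few times `1e-4` — this is the sharpest validation in
the package.

## Continuum models

`mrt_sink()` and `mrt_robin()` implement the closed-form
`Phi(r) = <T(r)>/V` for `d = 1, 2, 3` (sink: cosh/sinh, Bessel-`I`, tanh
forms in `K = k a^2/D`; Robin: the Collins–Kimball-type forms in
`kappa`).  They are written in overflow-safe form (tanh and
exponentially scaled Bessel ratios), satisfy the defining boundary-value
problem to residuals below `1e-6` (`bvp_residual()`, with the interior
sink solution reconstructed as the bounded ODE solution matched at the
sink edge — required for the normalization integral and uniquely
determined by boundedness plus continuity), and obey the two limit laws:
both models converge to the perfect-absorber form at strong reactivity,
and they coincide under `kappa S_r = k V_r` at weak reactivity (within 2%
at `K = 1e-3` in every dimension).  The reaction-controlled time at
contact scales exactly as `kappa^-1` for surface reactivity but as
`k^-1/2` for the sink (penetration-length effect); the log-log slope
fitted over `K in [1e2, 1e4]` is -0.518, approaching -1/2 from below as
`K` grows.  In `d = 2` the mean grows logarithmically with the start
radius, so only differences, or values with a stated outer scale, are
physically meaningful; all comparisons in the package use them.

## Brownian dynamics

`sample_reaction_times_bd()` integrates the Euler scheme with Gaussian
increments (`sd = sqrt(2 D dt)` per axis) inside the ball or the two
star-shaped domains `A` (`f = 1.6 (1 + 0.5 cos^2 theta)`) and `B`
(`f = 1.6 (1 + 0.1 sin theta + 0.3 sin 3 theta)`), in 2D or as solids of
revolution in 3D.  Default time step `dt = 1e-4 a^2/D`.

* **Outer boundary**: specular reflection — the crossing point is
  located by bisection on the boundary level function and the overshoot
  is mirrored across the local tangent plane; a point still outside
  after mirroring (sharp concave spots of `B`) rejects the move.
  Walkers never end a step outside the domain.  A radial-mirror
  shortcut (reflecting `r` across `R f(theta)` along the ray) was
  evaluated and rejected: on the slanted patches of the 3D star-shaped
  domains it pumps walkers inward strongly enough to push the global
  mean reaction time *below* the reaction-limited bound `V/(k V_r)` —
  a physically impossible result that the specular rule removes.
* **Sink target**: penetrable; reaction with probability
  `1 - exp(-k dt)` per step inside.
* **Robin target**: impenetrable; an attempted crossing reflects radially
  and reacts with probability `kappa sqrt(pi dt / D)` — the standard
  `O(sqrt(dt))`-accurate surface-reaction rule.  The wrapper refuses time
  steps that push this probability (or `k dt`) above 0.5.
* **Target placement**: at the origin (the star centre of every domain),
  strictly interior with several radii of clearance; the default start
  position sits on the symmetry axis at `r = 6a` for the standard
  `R = 6a` geometry, both exposed as configuration.

Correctness is enforced against an *independent* radial finite-difference
oracle (`mrt_radial_fd()`, flux-conservative second-order scheme with
Robin/reflecting boundaries), not against the scheme's nominal order.
Measured bias of the Robin rule in a reflecting ball (`R = 6a`,
`kappa a/D = 1`, start `r = 3a`): -2.2% at `dt = 4e-4` and -1.2% at
`dt = 1e-4` — halving when `dt` is quartered, consistent with
`O(sqrt(dt))`.  Monte Carlo comparisons therefore use `3 SE` windows with
sample sizes that keep the statistical error above this bias.

The RNG is a xoshiro256++ stream with a 128-layer ziggurat normal
sampler, seeded from R's RNG, so `set.seed()` (or the `seed` arguments)
gives bit-for-bit reproducibility; a fresh stream is drawn per call.

## Problem sizes used in the shipped checks

The automated checks favour exact solvers wherever possible (linear
solves and eigendecompositions are deterministic and fast up to
`N ~ 4000`) and size Monte Carlo runs so a check completes in seconds to
a couple of minutes: `1e4–1e5` walkers on networks, `2.5e2–1.2e3`
Brownian walkers at `dt = 1e-4 a^2/D` with confining radii `R = 6a–10a`,
and deterministic finite-volume extrapolations (via the radial oracle) at
`R = 20a` where the closed forms are compared to their infinite-volume
limit.  The survival-collapse checks in the continuum run four
domain/dimension/reactivity combinations that jointly cover both domains,
both dimensions and both reactivity models.

## Known limitations

* The universal compact collapse is asserted quantitatively only in its
  validity regime (`p >> p*`); at dense-solver sizes the `p = 0.05`
  curves are demonstrably pre-asymptotic (see above).
* The Robin Brownian scheme is `O(sqrt(dt))`; high-precision continuum
  means should use the radial oracle or the closed forms.
* Percolation exponents are quenched-disorder averages; a single cluster
  realization at moderate `L` shows sample-to-sample scatter, so the
  percolation family is exercised structurally (construction, target
  convention, uniform stationarity) rather than through collapse
  tolerances.
* `<T>/V` in `d = 2` is defined only up to a domain-size term; the
  package always reports differences or uses the stated
  `T_G = V Phi(1) + tau_G` convention.
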