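---
title: "The limb-work model of quadrupedal footfall phasing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The limb-work model of quadrupedal footfall phasing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadgait)
```

## The question

Walking quadrupeds keep left and right limbs of each girdle half a stride out
of phase (a *symmetrical* gait), but the phasing between hind and fore limbs
varies widely. Two descriptors locate a gait in Hildebrand's gait space: the
**duty factor** (DF), the fraction of the stride a hind foot is on the
ground, and the **limb phase**, the percentage of the stride by which the
ipsilateral forefoot contact follows the hindfoot contact (25% = evenly
spaced footfalls, 50% = trot timing, 0/100% = pace timing). Observed walking
gaits cluster: slow, small or "cold-blooded" quadrupeds walk at DF near 0.8
with phases of 40-50%, while medium-to-large mammals walk at DF 0.6-0.75
with phases at or below 25%. Suspended, below-branch walkers (sloths) show
the reversed relationship. `quadgait` reproduces this structure from a
single principle: minimization of positive mechanical limb work.

## The model

Each limb applies mass-specific forces over its stance window, built from
sinusoids that vanish at touch-down and lift-off. With local stance time
$t \in [0, T_\mathrm{stance})$, $T_\mathrm{stance} = \mathrm{DF} \cdot
T_\mathrm{stride}$:

* **Vertical**: $F_z = A_z \sin(\pi t / T_\mathrm{stance})$. The amplitude
  supports body weight exactly: a half-sine averages $2/\pi$ of its
  amplitude over stance, so four limbs demand
  $A_z = \pi g / (8\,\mathrm{DF})$.
* **Fore-aft**: $F_x = s\,A_x \sin(2\pi t / T_\mathrm{stance}) + b\,
  A_{x,\mathrm{bias}} \sin(\pi t / T_\mathrm{stance})$. The full sine
  integrates to zero over stance; $s = -1$ for upright walking (each limb
  decelerates, then accelerates the body) and $s = +1$ for suspended
  progression, where limbs act in tension and the pattern reverses. The
  half-sine bias ($b = +1$ hind, $-1$ fore) gives the hindlimbs a net
  forward impulse exactly balanced by the forelimbs.
* **Medial**: $F_y = m\,A_y \sin(\pi t / T_\mathrm{stance})$, a small force
  toward the midline from every limb. With the $+y$ axis to the animal's
  left we take $m = -1$ for left limbs and $+1$ for right limbs; stride
  costs are invariant under the mirrored convention, which we verified
  numerically.

Amplitude ratios follow the model variants: $A_x / A_z = 0.2$ everywhere
(equivalent to a stance sweep angle near 30 degrees, see `stance_angle()`),
$A_{x,\mathrm{bias}} / A_z = 0.1$ in the biased variants, and
$A_y / A_z = 0.05$ in the full variant. Units are nondimensional: $g = 1$,
body mass 1, $T_\mathrm{stride} = 1$.

Center-of-mass velocities follow by integrating the summed limb forces
(minus gravity, vertically), subtracting each component's stride mean so
vertical and lateral velocities fluctuate about zero, and adding a mean
forward speed $V_0$ to the fore-aft component. The power demanded of one
limb is $P_\mathrm{limb} = \vec F_\mathrm{limb} \cdot \vec V_\mathrm{CoM}$,
with components cancelling *within* a limb before any rectification, and the
stride cost is

$$ W = \sum_\mathrm{limbs} \int_0^{T_\mathrm{stride}}
   \max(P_\mathrm{limb}, 0)\, dt. $$

Negative work by one limb cannot power positive work by another, and no
elastic recovery is assumed.

## The choice of mean forward speed

Any $V_0$ large enough to keep the instantaneous fore-aft velocity strictly
positive gives the same phase ranking of costs; we verified that the
minimizing phases at every duty factor are unchanged for fixed $V_0$
anywhere between 0.12 and 10 in model units. The default is therefore a
single fixed value, $V_0 = 0.25\,g\,T_\mathrm{stride}$ — a mid-range
dimensionless walking speed (for a horse at 1.4 m/s with a 1.1 s stride,
$v/(gT) \approx 0.13$). A value derived from the force fluctuations
themselves (for example, a multiple of the peak-to-peak fore-aft velocity
fluctuation) would be phase-dependent — the fluctuation nearly cancels at
high duty factors — and would distort comparisons across phases, so the
default is deliberately independent of the configuration. `stride_work_cost()`
accepts an explicit `mean_forward_speed` for sensitivity checks, and
`com_velocities()` raises an error, rather than silently clipping, if the
chosen speed fails to keep the fore-aft velocity positive.

## Cost surfaces and their minima

```{r surface, eval = FALSE}
surf <- compute_cost_surface("base")     # DF 0.55-0.95 x phase 0-99.5
plot(surf)                               # phase on x, DF descending on y
global_minimum_line(surf)
```

`compute_cost_surface()` normalizes each duty-factor row to [0, 1] for
display; minima are located on raw rows (the argmin is the same either way).
Ties within a relative tolerance of 1e-9 are reported as tie sets, never
broken arbitrarily: without medial forces the model is planar, so every
minimum at phase $P$ is exactly tied with $P + 50$.

The headline structure, recomputed by the test suite and by
`scripts/acceptance.R`:

* **Base variant**: minima at phases {25, 75} below a critical duty factor
  and {0, 50} above it. At low DF the body's vertical velocity is downward
  in early stance, and distributing footfalls evenly (25/75%) keeps limb
  forces closer to perpendicular to the center-of-mass velocity; at high DF
  overlapping limbs reverse the early-stance vertical velocity
  (`early_stance_vertical_velocity_sign()`), and synchronous timing (0/50%)
  becomes favorable.
* **Critical duty factor**: `critical_duty_factor()` bisects the family
  switch; 0.765 for the base variant (the cut-off is near, not exactly,
  0.75), and higher when the fore-aft amplitude ratio is raised.
* **Suspended (sloth) variant**: reversing the fore-aft force sign reverses
  the relationship — {25, 75} at high DF, {0, 50} at low DF.
* **Bias variant**: a hindward-forward / foreward-backward impulse pair
  shifts both troughs to lower phases (e.g. from 25 to about 21.5 at
  DF 0.65).
* **Full variant**: adding medial forces breaks the planar 50%-shift
  symmetry and tips the surface in favor of the lower trough.

On the full variant's surface the tipping is decisive at low-to-moderate
duty factors (at DF 0.7, crawling-like conditions, a 95% phase costs several
percent more than a 5% phase, matching the felt difficulty of near-pace
crawling with the hand leading). At duty factors above about 0.78 the
bias-shifted pace trough near phase 94 remains competitive: there phase 95
is locally cheap and the global row minimum can sit just above 50% in the
narrow family-transition zone (DF about 0.765-0.79, with margins under
0.2%). We verified this is not a numerical artifact: it persists across grid
refinement (2048 vs 8192 samples), the full range of valid forward speeds,
and medial amplitudes up to four times the default. The corresponding
acceptance test asserts the stronger, surface-wide form of the claim and
documents this region by failing there.

## Numerical choices

* Uniform circular time grid, 2048 samples per stride by default; on such a
  grid the trapezoid rule for a periodic integrand reduces to the sample
  mean times the period. Cost at (DF 0.7, phase 25) moves by less than
  0.1% when the grid doubles to 4096.
* Positive-work integrals clip the power series at zero, then integrate.
* Cumulative integrals use the trapezoidal rule (`pracma::cumtrapz`).
* Exact weight support is enforced analytically through the amplitude, not
  numerically: the grid-sampled stride-mean vertical force differs from $g$
  by the trapezoid error (~1e-7 relative), while the identity
  $4 A_z (2/\pi) \mathrm{DF} = g$ holds to machine precision.
* `critical_duty_factor()` bisects to 0.002 in DF, classifying each row by
  whether the global minimum is circularly nearer to {0, 50} or {25, 75}.
* Degenerate inputs are rejected: DF outside (0.5, 1), non-positive gravity
  or stride period, grids below 256 samples. Phases are circular (mod 100).

## The observational side

`duty_factor_from_events()` and `limb_phase_from_events()` compute
Hildebrand's metrics from timed contact/lift logs, averaging per-stride
values arithmetically, with the left hind limb as the conventional
reference. `load_species_table()` ships median walking gait parameters for
52 species. Two analysis choices were genuinely open and are fixed as
follows:

* **K-means features are z-score standardized** before the two-group split
  (seeded, 50 restarts): raw phase, on a percent scale, would otherwise
  dominate the Euclidean distance. On the packaged table the seeded split
  reproduces the printed groups exactly.
* **The regression is unweighted OLS on the 52 species medians** — the
  medians are the data actually tabulated; weighting by per-species
  observation counts would let two replicate-heavy species dominate. The
  packaged table yields phase (%) = 128.6 DF − 64.6.

```{r table, eval = FALSE}
tab <- load_species_table()
fit_phase_df_regression(tab)[c("slope", "intercept")]
table(kmeans_two_groups(tab, seed = 17), tab$group)
```

## The synthetic footfall generator

`generate_events()` emulates what video digitization of a walking quadruped
yields: contacts on the symmetrical-gait schedule, lifts one stance duration
later, and independent Gaussian jitter on every event time standing in for
frame-timing measurement error (draws are capped just under half the
smallest within-limb event gap, so orderings cannot invert).
`generate_species_ensemble()` draws per-species gait medians from Gaussian
group distributions — by default matching the observed two-cluster structure
(DF 0.80 / phase 44 versus DF 0.68 / phase 21, SDs 0.03 and 3) — with
out-of-range draws resampled rather than clipped.

What the generator does *not* emulate bounds what passing tests show: real
footfall sequences have within-stride correlation structure (speed drift,
left-right asymmetries, missing frames), per-species observation counts vary
(the table's zebra has 28, most species 1), and phase jitter can wrap at
0/100%. Round-trip and recovery tests therefore validate the estimators'
arithmetic and their robustness to independent timing noise, not their
behavior on noisy field video.

## Limitations

The model takes limb force profiles as given — independent of phase, speed
and duty factor — so it cannot address duty-factor selection, stance-angle
variation, grounded-running mechanics near DF 0.5, elastic energy recovery,
or muscle activation costs; lateral bending and belly or tail contact are
ignored. It evaluates the work implications of phasing alone. The observed
primate phasing near 75% is not the global minimum of any variant; it sits
in a local trough whose cost is only slightly above the global one, so an
energetic account alone cannot single it out.
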