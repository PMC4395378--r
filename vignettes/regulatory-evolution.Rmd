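---
title: "Fitness cliffs, phenotypic noise and the selection of channel expression levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitness cliffs, phenotypic noise and the selection of channel expression levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(axevolve)
```

## The question the model addresses

The squid giant axon expresses its voltage-gated sodium and potassium
channels at characteristic average peak conductances (about 120 and
36 mS/cm²).  Why these values?  Classic proposals invoke optimization of
conduction velocity or of the metabolic cost of the action potential.
`axevolve` implements an alternative population-genetics account:
channel expression is set by a *selection–mutation balance*.  Mutations
in promoters and cis-regulatory modules are biased toward weakening
regulatory function, so expression decays in the absence of selection;
qualitative failures of axonal physiology (conduction failure, a switch
in firing pattern) create *fitness cliffs* that remove low-expression
phenotypes; and phenotypic noise pushes the balance point away from the
cliff edge.  The package couples the two halves needed to study this
quantitatively: a biophysical axon model that maps conductances to
physiological performance, and a Wright–Fisher model of regulatory
evolution whose fitness functions are built from that map.

## The axon model

Membrane potential on a 10 cm unbranched cable obeys

$$C_m(t)\,\partial_t V \;=\; \frac{r}{2R_a}\,\partial_x^2 V
  - \bar G_K n^4 (V-E_K) - \bar G_{Na} m^3 h (V-E_{Na})
  - G_L (V-V_L) + I_{stim},$$

with first-order Hodgkin–Huxley kinetics for the gates $n, m, h$.  Two
modifications matter:

* **Potassium deactivation.**  $\beta_n = 0.125\,e^{-(V+65)/19.7}$
  (the Clay form) rather than the classic $e^{-(V+65)/80}$.  The
  stronger subthreshold potassium activation this produces is what makes
  the axon a single-spike (Type 3) system, as real squid axons are.
* **Gating capacitance.**  The sodium-channel gating charge contributes
  a voltage-dependent capacitance
  $C_g = 0.13\,(\bar G_{Na}/120)\,(1-m)$ µF/cm² on top of the bilayer's
  0.88 µF/cm².  Without it the conduction-velocity curve has no interior
  maximum in $\bar G_{Na}$; with it, adding channels eventually slows
  the spike.

All six rate constants carry a common factor $Q_{10} = 3^{(T-6.3)/10}$.
The leak reversal $V_L$ is fitted in closed form so that $-65$ mV is an
exact stationary state for any conductance pair (`solve_leak_potential()`);
an unstimulated cable drifts by less than $10^{-13}$ mV over 20 ms.

### Numerics

The solver (`simulate_axon()`, compiled) uses the staggered scheme of
Hines: gates are advanced on half steps with the exact exponential
update of the linear gate equation, the voltage implicitly by a
tridiagonal (Thomas) solve; ends are sealed.  The time-varying $C_m$ is
treated quasi-statically as the coefficient of $\partial_t V$, refreshed
from $m$ each step, exactly as the equation above is written.  Defaults
$\Delta t = 1$ µs, $\Delta x = 100$ µm; halving both changes the
measured velocity by well under 1% (asserted in the tests).  Rate
functions are tabulated on a 0.05 mV grid and linearly interpolated —
the standard trick in cable simulators — which changes velocities by
parts in $10^6$ and removes all transcendental calls from the inner
loop.  The removable singularities of $\alpha_n$ ($-55$ mV) and
$\alpha_m$ ($-40$ mV) evaluate by their analytic limits.

The stimulus is printed in the source equation as $I_{stim}/(2\pi r)$,
which lacks the length normalization a current *density* needs.  We
apply $I_{stim}/(2\pi r\,\Delta x)$ to the first compartment: the only
dimensionally consistent reading with membrane terms in mS/cm² and
µF/cm².  Since conduction velocity and all landscape boundaries are
independent of suprathreshold stimulus details (also asserted), the
choice only affects initiation.

### Operational readouts

`ap_metrics()` defines the physiological readouts used everywhere:
conduction success is an upward 0 mV crossing at 9.5 cm within the
window (30 ms at 26 °C); velocity comes from quadratically interpolated
spike-peak times at 2.5 and 7.5 cm (away from the stimulated and sealed
ends); sodium flux integrates $\bar G_{Na} m^3 h (V-E_{Na})$ at mid-axon
over the first spike; APD50/APD90 measure repolarization from the
mid-axon peak.  At high $\bar G_{Na}$ the proximal end can re-fire late
in a run, so all single-spike metrics are deliberately computed on the
*first* suprathreshold episode.

Excitability (`classify_excitability()`) follows the operational
definition of Type 3 firing: find the just-threshold *sustained* current
by bisection (1% relative tolerance), drive the cable with twice that
current for 100 ms, and count propagated spikes at 5 cm — one spike is
Type 3, two or more is Type 2.  The boundary this yields is protocol
dependent in an instructive way: with the sustained-rheobase reference
the switch at $\bar G_{Na} = 120$ sits at $\bar G_K = 22$ mS/cm²; using
twice the *brief-pulse* threshold instead pushes it above 28, and a
space-clamped patch gives 26.  We fix the sustained-rheobase cable
protocol because it is fully specified by quantities the model itself
defines.  One guard is needed at extreme phenotypes: at high
$\bar g_{Na}$ with very low $\bar g_K$ the fitted resting state is
effectively unstable — the cable fires on a $10^{-12}$ µA perturbation
and then sits depolarized.  Phenotypes whose rheobase falls below
$10^{-3}$ µA (three orders of magnitude under the normal 0.15–0.6 µA
range) are classified on the hyperexcitable Type 2 side and flagged
`spontaneous`, which keeps the Type 3 boundary monotone across the
landscape.

### The landscape and its discontinuities

`find_threshold()` bisects any predicate (conduction, Type 3) along one
conductance axis on a 1 mS/cm² grid, which provably matches a
brute-force unit-step scan (tested).  With the defaults the model yields
a minimum sodium conductance for 26 °C conduction of 68 mS/cm² at
$\bar G_K = 36$, an upper potassium edge of 121 mS/cm² at
$\bar G_{Na} = 120$, a conduction-velocity maximum at 430 mS/cm² (on the
5 mS/cm² sweep grid; the curve is flat to a few parts in $10^5$ between
420 and 440) lying 14% above the velocity at 120, and the Type 3
boundary at 22 mS/cm².  Two caveats belong with these numbers.  First,
boundary locations are sensitive to the effective kinetic rate scale:
warming the model by ~2.7 °C moves the sodium threshold to 81 and the
potassium edge to 88 simultaneously, so small differences in temperature
handling between implementations displace the whole 26 °C landscape
coherently.  Second, under the distal-crossing criterion the model
propagates low-amplitude but self-sustaining waves well below the point
where the full-sized spike is lost, and it does so down to
$\bar G_K = 0$, so the "failure to repolarize" edge at low potassium
conductance is not visible to this criterion at all.  Both sensitivities
are recorded as such rather than patched by ad-hoc criterion changes.

For two-dimensional fitness evaluation, `region_boundaries()` bisects
the boundaries at a handful of anchor values and interpolates linearly
between them (`fitness_region2d()` is then a pure lookup).  Per-anchor
bisection plus interpolation was chosen over a dense grid because a
single excitability classification costs tens of cable simulations and
the boundaries are smooth.

## The evolution model

Each channel gene is a diploid locus whose allele is a non-negative
integer: total promoter/CRM strength, i.e. the rate of mRNA production.
One allele unit is 5 mS/cm² of sodium or 2 mS/cm² of potassium
conductance, and the two alleles sum.  Each generation
(`next_generation()`):

1. two allele copies are drawn per locus from the parental pool of $2N$
   copies, *without replacement of the same copy*; the pool is restored
   between offspring, and loci are drawn independently;
2. each drawn copy mutates with probability $\mu = 10^{-2}$, one step
   down with probability 0.9 (mutation degrades regulatory function) or
   up with probability 0.1; the floor at 0 absorbs down-mutations;
3. the phenotype is the allele sum times the step, plus — when enabled —
   zero-centred binomial phenotypic noise
   $\text{step}\cdot(B(n,\tfrac12)-n/2)$, redrawn for every candidate
   and clamped at 0;
4. the candidate survives with probability equal to its fitness;
   rejected candidates are discarded entirely and redrawn until $N$
   offspring survive.

Noise widths follow the calibrated values: $n = 28$ (sd
$5\sqrt{28}/2 = 13.2$ mS/cm²) for sodium and $n = 16$ (sd 4.0) for
potassium in single-locus runs; $n = 48$ (sd 17.3) and $n = 20$ (sd 4.5)
in the concurrent two-locus runs.  Initial pools are
$B(6, \tfrac12)$-spread around the starting mean allele.  Trajectories
record the *genotype-determined* phenotype (noise is transient, attached
to individuals at the moment of selection); `final_histogram()` can
produce either the genotype-only or the noise-inclusive distribution.

Because rejected candidates are redrawn in full and noise is redrawn
with them, a candidate's noise never "sticks" across retries.  Whether
the original implementation redrew noise on retries is not documented
anywhere we could check; we chose redrawing because noise is phenotypic
— a property of the developing individual being tested — and the
alternative couples selection to stale random numbers.

### The exact transition law as oracle

For small populations the entire one-generation transition distribution
can be enumerated (`exact_transition_distribution()`): every ordered
draw of two copies, every mutation outcome of each, the fitness
acceptance of the pair, and the convolution of $N$ independent
accepted-pair draws.  A printed closed form for this chain treats the
$2N$ offspring copies as i.i.d. single alleles; in the simulated process
alleles arrive in pairs whose acceptance is joint, so we enumerate at
the pair level, which is the distribution the simulator actually
samples.  The test suite verifies the Monte-Carlo generation step
against this law at $N = 3$ across five mutation/selection settings
($10^5$ replicates each, three-standard-error bounds per outcome), plus
a from-first-principles brute-force enumeration at $N = 2$.

### Fitness functions

* `fitness_cliff(threshold)` — survival 1 at or above the threshold
  (inclusive: allele granularity makes boundary membership exact, and
  the choice moves equilibria by less than one allele step), 0 below.
  The plateau at exactly 1 keeps rejection sampling cheap; only the
  cliff's location matters at equilibrium.
* `fitness_velocity(curve, floor, cliff)` — the tabulated velocity curve
  affinely rescaled onto $[\text{floor}, 1]$ above the cliff.  The slope
  of the published analogue is not recoverable (its axis is magnified
  and unlabeled), so `floor` is an explicit calibration knob; the
  default 0.95 puts the run in the weak-selection regime where drift is
  visibly large, which is the qualitative point of that experiment.
  Equilibria under this and the two functions below are therefore
  calibration demonstrations, not sharp predictions.
* `fitness_velocity_cost(curve, cost_slope, ...)` — velocity minus a
  linear metabolic cost, renormalized to peak at 1; with the default
  slope equal to the velocity curve's tangent at 120 mS/cm² the optimum
  sits near the observed conductance by construction.
* `fitness_apd(curve, floor, cliff = 3)` — inverted, rescaled
  action-potential duration (shorter spikes are fitter) above a low-G_K
  cliff.
* `fitness_region2d(boundaries)` — indicator of
  {conducts at 26 °C} ∩ {Type 3}.

All constructors clamp to $[0,1]$ for every representable input,
including negative pre-clamp phenotypes, and reject scalings that would
leave the unit interval.

## What the generator does and does not emulate

The synthetic populations reproduce the study conditions exactly:
$N = 5000$ diploids, $\mu = 10^{-2}$, bias 0.9, the binomial noise
widths above, 5000–10000 generations.  They do *not* emulate linkage or
recombination within a locus, overlapping generations, mate choice,
dominance, a mechanistic sequence-level CRM model, or
temperature-acclimation physiology; the noise model is a single
stationary lump for what is biologically a mixture of trans-genetic and
developmental/environmental sources.  Passing tests therefore support
the claim that *this mechanism suffices* to stabilize expression levels
— not that real squid populations have these parameters.

## Problem sizes in the test and acceptance runs

The package's own acceptance checks use bisection at 1 mS/cm²
granularity for every boundary; evolutionary equilibria use three
replicates of 5000 generations at $N = 5000$ in the test suite and
10000 generations in the acceptance script (steady state is reached by
roughly generation 3000, so the two agree); the concurrent 2D run uses
4000 generations from three starting points.  The Markov-chain oracle
comparison uses $10^5$ one-generation replicates.  These sizes were
chosen as the smallest at which the quantities of interest are stable to
well within the tolerances being asserted.

## Known limitations

* The 26 °C conduction boundaries and the excitability boundary inherit
  the temperature-scale and protocol sensitivities described above;
  treat their absolute locations as model-version-specific.
* The low-G_K "repolarization failure" edge is invisible to the
  distal-crossing conduction criterion (see above); fitness cliffs
  placed at 3 mS/cm² (`fitness_apd`) take that value as an input rather
  than deriving it.
* Graded fitness functions carry free scaling constants; equilibria
  under them move with the calibration.
* Velocities are measured on a cable with sealed ends; the last
  half-centimetre is excluded from measurement sites, but extreme
  phenotypes outside the swept ranges extrapolate the landscape
  constantly rather than simulating anew.

```{r example}
# a compact end-to-end run: conduction cliff plus noise on the sodium locus
thr <- find_threshold("na", fixed = 36, predicate = "conducts",
                      TC = 26, bracket = c(40, 150))
cfg <- evolution_config(list(wf_locus("na", 5, 120, n_noise = 28)))
run <- run_evolution(cfg, fitness_cliff(thr), generations = 10000, seed = 1)
summary(run)
plot(run)
```
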