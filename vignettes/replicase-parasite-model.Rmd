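---
title: "The replicase-parasite multi-agent model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The replicase-parasite multi-agent model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpsim)
```

## The model

`rpsim` simulates a minimal RNA-world ecosystem of two molecular species on a
two-dimensional torus: **replicases** (R), RNA molecules with catalytic
replication activity, and **parasites** (P), RNA molecules that can only be
copied. Every molecule is an individual agent with a position, two scalar
attributes in $[0,1]$ — the *affinity towards replicases* $a$ and the
*folded-state probability* $l$ — and a remaining-lifetime clock. Molecules
diffuse by Brownian motion, decay, and bind pairwise into transient
catalyst-template **complexes**, the only context in which replication
happens. The torus avoids edge effects; one length unit corresponds to one
cell side of the lattice model this simulator is the off-lattice counterpart
of, so published rate constants transfer unchanged.

The kinetic scheme per complex: a template with attributes $(a, l)$ is bound
by a replicase with probability $\omega = a(1-l)$ per collision test; the
complex then races an exponential dissociation clock of rate $1-a$ against an
exponential replication clock of rate $K$. $K$ is set enormously large
($2.398\times 10^5$), so the replication time expires at the first clock
decrement: replication is effectively immediate (a Dirac-delta time), and the
only way it fails is dissociation striking first within the same step. Under
the scheduler's fixed ordering (dissociation is checked before the
replication clock ticks), the probability that a complex replicates rather
than dissociates is exactly
$$P(\text{replicate}) = e^{-(1-a)\,\Delta t},$$
which for the canonical parasite affinity $a = 0.55$ gives
$e^{-0.45} \approx 0.638$. This closed form is asserted by a Monte-Carlo test
in the suite and is a *contract* of the scheduler ordering, not an accident.

All first-order events (decay $d$, replication $K$, dissociation $1-a$) are
memoryless: waiting times are drawn once at creation via the inverse CDF
$t = -\ln(u)/k$, $u \sim U(0,1]$, and compared after whole-$\Delta t$
decrements. Diffusion follows
$\vec{x}(t+\Delta t) = \vec{x}(t) + \sqrt{2 D \Delta t}\,\vec{\xi}$ with
independent standard-normal components, wrapped onto the torus.

## One scheduler step

Each step, in order:

1. advance time by $\Delta t$;
2. decrement every running clock (free-molecule lifetimes, complex
   dissociation clocks, and — in the *ticking* decay mode — the lifetimes of
   complexed members);
3. remove free molecules whose lifetime expired; in ticking mode resolve
   in-complex decay (the expired member dies, the partner is freed at the
   complex position with its remaining clock);
4. shuffle a snapshot of all entities (free molecules and complexes) into a
   random processing order and rebuild the neighborhood grid;
5. process each snapshot entity in turn: a complex whose dissociation clock
   expired splits into its two members at the complex position; otherwise the
   entity takes a neighbor census (all entities strictly within the collision
   distance $r_c = 2r$, complexes counted as single points), is removed if it
   sees more than `n_max` neighbors (crowding), moves ($D$ for free
   molecules, $D'$ for complexes), and then either decrements its replication
   clock (complex; replication = offspring copy of the template, mutation,
   immediate dissociation) or attempts complex formation with the first
   neighbor from its shuffled pre-move census that is free, eligible (two
   parasites never bind) and passes the $\omega$ test;
6. entities created during a step occupy space immediately — they appear in
   later censuses within the same step — but act only from the next step.

Template selection follows the field's convention: if exactly one member of a
colliding pair is a parasite, the parasite is the template (whichever side
initiated); if both are replicases, the molecule that did *not* initiate is
the template. The catalyst is therefore always a replicase, which is asserted
as an invariant.

Mutation acts on the offspring only: per replication event, each mutable
attribute is independently perturbed with its probability $\mu$ by an
additive offset uniform on $[-\delta, +\delta]$, clamped to $[0,1]$. The
additive bounded kernel with clamping is the simplest model consistent with
smooth population-average drifts and with absorption at the attribute
boundaries when selection pushes an attribute to its extreme; $\delta$
defaults to 0.05 and is a configuration knob (and a sensitivity-analysis
axis), since only the qualitative statement "slightly changed" constrains it.

## Lattice-to-continuum conversion

The diffusion coefficients come from variance matching against the source
lattice model. A free lattice molecule moves to one of its 8 Moore
neighborhood cells (4 at squared distance 1, 4 at squared distance 2), so its
per-step displacement variance at move probability $p$ is $\tfrac{3}{2}p$;
equating with the Brownian $2D\Delta t$ gives $D = 3p/(4\Delta t)$, hence
$D = 0.75$ at $p = 1$, $\Delta t = 1$. A complexed lattice molecule moves
with half propensity and competes with replication, giving move probability
$p' = \frac{D_{CA}/2}{D_{CA}/2 + K_{CA}}$; the published center-of-mass
enumeration for the two-cell complex evaluates to exactly 1, so
$\sigma^2_C = 2p'$ and $D' = p'/\Delta t$, which reproduces the published
$D' = 0.0476$. The replication rate is deliberately *not* converted: it is
set extremely large on both sides to realize immediate replication. The
package exposes the enumerations themselves (`ca_single_move_variance`,
`ca_complex_move_variance`) so the identities can be asserted algebraically,
and the test suite additionally checks the free-molecule enumeration against
an independently simulated lattice walker.

## Design choices where the sources are ambiguous

Several implementation details are not fixed by the published description;
this section records the choices and the reasons.

**Decay of complexed molecules.** The prose description of unimolecular
reactions says decay applies to complexed and free molecules alike, with the
partner set free when a member decays; the scheduler pseudocode instead
stores member clocks at complex formation and *restores* them at
dissociation, which implies members do not age inside a complex. The two
readings are both implemented, one flag apart (`decay_mode = "ticking"` /
`"frozen"`). They are not dynamically equivalent: with the published decay
rate $d = 0.182$ (mean lifetime 5.5 steps) the ticking reading makes a pure
replicase population *unviable from any sparse start* — the maximum
per-capita birth rate of the paired replication cycle ($\approx 0.185$ per
step under instant re-pairing) barely exceeds the per-capita death rate
$1 - e^{-0.182} \approx 0.166$, and any search delay pushes net growth
negative, so founding populations collapse and none of the canonical
phenomena (the "explosion of life", wave formation, parameter sweeps with
surviving runs) can occur. Under the frozen reading the effective death rate
roughly halves (members spend much of their time bound) and the founding
bloom is explosive. The test suite demonstrates the contrast directly (a
founding replicase disc ignites under frozen decay and dies out under
ticking decay, all else equal). The package therefore defaults to
`"frozen"`; `"ticking"` remains available.

**Offspring placement.** "The offspring equals the template" is read as
including the position: offspring are placed at the complex position
(`offspring_offset = 0` by default; the offset and direction are
configurable). Placing the offspring inside the parental cluster increases
local crowding, which throttles front propagation for both species and
keeps parasite waves attached to their host waves longer than placement one
collision diameter away would; the offset remains a knob for sensitivity
analysis.

**Neighbor cap.** `n_max = 8` by default, the Moore-neighborhood capacity of
the source lattice whose one-molecule-per-cell crowding this rule emulates;
the value is otherwise unstated and is a configuration knob. With the default
radius, crowding caps local density near $n_{max}/(\pi r_c^2)\approx 2.5$
molecules per unit area.

**Census and crowding details.** The census radius is the collision distance;
strict inequality defines overlap (ties at exactly $r_c$ do not react — a
measure-zero event that must be fixed for determinism). A complex counts as
one agent in other entities' censuses, and an overcrowded complex is removed
with both members (two molecule deaths). The reaction loop consumes the
pre-move census; partners that meanwhile decayed or bound are skipped by a
liveness guard.

**Stabilization.** "The average stopped changing" is operationalized as a
trailing-window least-squares slope test (`detect_stabilization`): the
earliest window end from which every trailing window's absolute slope stays
below a tolerance through the end of the series (defaults at reference
scale: window $10^4$ steps, tolerance $10^{-6}$ per step). The published
criterion also mentions spatial uniformity of the agent groups; that half
would require a clustering statistic the sources do not define and is
deliberately not implemented.

## Determinism

Each run owns one xoshiro256++ stream seeded from the run seed. Every draw —
initial placement, initial lifetimes, the per-step entity shuffle, each free
molecule's neighbor-set shuffle, each Box-Muller move pair, each reaction
test, each clock initialization, each mutation decision and offset, each
offspring placement angle — consumes from this stream in the fixed order
documented in the engine source. A `(config, seed)` pair therefore
reproduces a run bit for bit on the same build, which the suite asserts, and
chunked stepping (for observers) is exactly equivalent to an uninterrupted
run. R's own RNG is never touched by the engine; the R-level kinetic
primitives (`sample_waiting_time`, `mutate_attribute`, ...) use R's RNG and
serve as independently seeded oracles in tests.

## Numerical choices and degenerate inputs

Clocks are real-valued (drawn from continuous exponentials) but decremented
in whole $\Delta t$ units; "expired" means $\le 0$. A template with $a = 1$
yields dissociation rate 0, represented as an infinite dissociation time
(the complex can only replicate, or lose a member to decay in ticking mode);
rate-0 waiting times generally map to $+\infty$, and `sample_waiting_time`
rejects non-positive rates at the API surface where a draw is demanded.
Uniform draws for waiting times live on $(0,1]$ by construction
($1 - U[0,1)$), so $\ln(0)$ never occurs and zero waiting times (from
$u = 1$) are legal. Positions are wrapped to the half-open fundamental
domain with a floating-point guard for the `x %% W == W` edge case.
Population standard deviations use the $n$ denominator (they are
descriptive, not inferential, and must be defined for $n = 1$). The
molecule-count ledger (births minus deaths) is asserted inside the engine at
every step and the run fails loudly on imbalance.

## What the simulations emulate, and at what scale

The published experiments track populations that reach millions of molecules
over up to 150k steps. This package's presets default to desk scale: the
reference configuration uses a $256^2$ arena with 2500 + 2500 molecules
started in two species-pure half-discs of radius 64 (`scaled = FALSE`), and
the scaled presets used by the test suite and the acceptance script reduce
the arena and populations further with experiment-specific step budgets
(`scaled = TRUE`; see `rp_preset`). The methods and observables are
identical at every scale; what changes with size is the *number of
independent wave domains* the torus can host. The traveling-wave /
explosion-of-life coexistence of replicases and parasites is a mesoscopic
phenomenon: host waves are consumed by parasite fronts and re-seeded by
escaping replicases, and global persistence relies on many such domains
being out of phase. At desk scale only a handful of domains fit, their
boom-bust cycles synchronize, and runs that would coexist at published scale
instead end with one species absorbing at zero within a few thousand steps.
Desk-scale survival outcomes are therefore conservative: extinction
boundaries of the parameter sweeps (which at full scale are driven by the
same local mechanisms) reproduce well, while long-horizon coexistence and
the attribute equilibria conditional on survival are only partially
reachable.

The study conditions used by the reproduction script
(`scripts/acceptance.R`) and the heavier test batteries, chosen once, are:
scaled presets on a $128^2$ torus with 1250 + 1250 molecules in a
radius-32 founding disc, ten independent seeds per configuration, step
budgets of 30000 (folding-evolution protocol) or 50000 (pinned-affinity and
full-coevolution protocols), and trailing-10000-step attribute averages
summarized as medians over seeds (surviving seeds when any survive). The
immutable-folding affinity sweep, whose expected outcome is extinction for
every initial affinity, runs at $80^2$ with 500 + 500 molecules over eleven
initial affinities and ten seeds; a smaller arena suffices there because
the sweep asserts only extinction and its timing.

What the synthetic worlds do *not* emulate: sequence-level genetics (attributes
are scalars; there is no genotype, no error threshold), resource or energy
limitation beyond the crowding cap, temperature- or length-dependent
kinetics, and any third species. Passing tests therefore demonstrate the
fidelity of the simulator's kinetics, scheduling and bookkeeping, and the
qualitative ecology of the replicase-parasite interaction at the stated
scales — not quantitative agreement with wet-lab RNA systems.

## Known limitations

* Single-threaded by contract: the single RNG stream is what makes runs
  reproducible; there is no parallel execution semantics.
* Fixed-step scheduling: events are resolved at $\Delta t$ resolution, not
  by an exact event queue; the race law above is exact *given* this
  discretization, which is the intended model.
* The complex center-of-mass variance enumeration is taken as published (it
  underpins the published $D'$); re-deriving it from the stated two-cell
  move rule gives a smaller constant, and the package deliberately follows
  the published calculus, which is the one the reference diffusion
  coefficients embody.
* At desk scale, long-horizon coexistence is systematically harder than at
  published scale (see above); conclusions about survival phase boundaries
  transfer, absolute survival times do not.
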