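---
title: "Cell-assembly agents in a four-room world: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-assembly agents in a four-room world: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cabot)
```

This vignette explains the models the package implements, the parameters
that matter and why their defaults are what they are, and the design choices
made where more than one reasonable construction existed.

## The spiking substrate

Neurons are discrete-time points.  At each 1 ms step a neuron's potential
relaxes toward its resting level with retention fraction
$\lambda \in (0,1]$, integrates arriving synaptic input and injections, and
fires when $v - a - f \ge \theta$, where $a$ is spike-rate adaptation and
$f$ fatigue (the FLIF variant).  On firing, $v$ resets, a refractory counter
starts, $a$ and $f$ increment, and the spike is delivered to every target
exactly `delay` steps later (`delay` $\ge 1$; there is no same-step
interaction).  Activation is dimensionless with resting $0$ and threshold
$1$ by default.  The update order (leak, then input, then threshold test
against the *pre-step* adaptation) is part of the contract: the closed-form
inter-spike interval under constant drive $I$,
$\mathrm{ISI} = \max\{k : I\tfrac{1-\lambda^k}{1-\lambda} \ge \theta\}$
bounded below by the refractory period, is tested against simulation.

The reference behaviors (ignition, persistence, gating) are all
threshold-level rather than waveform-level, which is why a linear
leaky integrate-and-fire neuron with adaptation suffices as the reference
model; the model kind is a per-population switch.

A consequence of leaky integration worth keeping in mind when reading the
calibrations below: sustained sub-threshold drive $I$ settles at
$I/(1-\lambda)$.  With the assembly default $\lambda = 0.2$ the gain is
$1.25$, so "sub-threshold" margins must be stated for the *integrated*
level, not the per-step drive.

## Binary cell assemblies

A binary cell assembly (CA) is five neurons, fully connected with weight
$0.3$ and delay 1.  Once all five fire in one step, each receives
$4 \times 0.3 = 1.2 \ge \theta$ every following step: ignition persists
indefinitely (tested to $10^4$ steps), and a never-stimulated assembly
stays silent.  `make_ca()` refuses parameter sets for which
$(n-1)w < \theta$, since no persistent state exists under delay $\ge 1$.
Extinction is strong transient inhibition (three steps of $-5$), after
which the recurrent loop is broken.

## FSAs made of assemblies

`make_fsa()` realizes a finite-state automaton with one CA per state.
A symbol is a transient input line (a three-step pulse on a five-neuron
block).  Each non-self transition $(s, a) \to s'$ has a two-neuron
coincidence detector that fires only when state drive and symbol drive
coincide (each alone is $0.65$, integrated $\approx 0.68 < 1$; together
$1.3$).  The detector launches a three-stage inhibitory cascade that
sweeps the whole state layer clear, and a delayed excitatory volley
(delay 8) that ignites the successor after the inhibition has passed.
Self-loops need no circuitry at all: the state simply persists, which is
exactly the self-loop semantics, so missing transitions default to
self-loops.  Transitions complete in about 10 steps; the settle window is
20 steps and symbols must be at least one settle window apart.  If two
symbols arrive in the same window the earlier injection wins; simultaneous
arrival is undefined and logged by callers.  The one-hot property (exactly
one state ignited at every post-settle checkpoint) and equivalence with a
symbolic automaton are property-tested over random machines.

## Timers

A timer is a synfire chain: one neuron per step, activity travelling down
the chain, ending after `duration` steps unless restarted.  Taps are
designated groups of the chain whose neurons gate other assemblies.  Tap
windows are exact by construction; the acceptance check allows a one
interval tolerance.

## The four-room world and its camera

The reference layout is a 24-by-24 cell grid with four 9-by-9 rooms at the
corners joined in a single cycle by four 2-cell-wide corridors.  Each room
holds one of the four shapes (pyramid or stalactite, red or blue), at the
room center; corridors are green.  Headings are the four compass
directions; actions are quarter turns, one-cell moves, and stop; blocked
moves are no-ops.  A world seed permutes the shape-to-room assignment.

The camera renders a deterministic, flat-shaded 20-by-20 RGB forward view:
shapes project to triangles (pyramid apex up, stalactite apex down) whose
apparent width falls off as $16/(d+1)$ with cell distance $d$, corridor
openings to green rectangles, and a wall directly ahead to a grey fill.
At distance $\ge 6$ cells a shape covers fewer than six pixels and its
apex orientation is no longer readable: the percept reports
`kind = "unknown"`.  This reproduces the distance-ambiguity failure mode
that drives the agent to approach before identifying.

Camera *capture* is noisy even though rendering is not: each lit pixel
drops out with probability `p_drop` (default 0.08, chosen once as a
plausible camera-transfer noise level).  Dropout at the minimum
discriminable size occasionally flips the apex-orientation read, which is
the mechanism behind shape-misidentification failures.

## Vision

`encode_frame()` maps pixels to one input neuron per (pixel, channel) and
schedules injections at the frame's delivery time.  In regular mode frames
arrive exactly every 30 ms; in jittered mode the interval is uniform on
[20, 40] ms; after a consumed frame, input ceases for a 100 ms processing
gap.  Feature maps comprise on-off and off-on center-surround responses at
granularities 3, 6 and 9 (stride 1; center is the inner third of the
kernel), oriented edge/angle maps, and per-colour presence masks.  The
percept reader takes colour from the dominant channel, position from the
horizontal third of the centroid, and kind from apex orientation (widest
row at the bottom means pyramid).  The agent's decision loop computes the
same percepts through a functionally equivalent reference stage rather
than spiking feature populations; both paths face the same percept tests.

## Language

The command grammar is a closed regular set of 24 sentences over a
20-token lexicon (`move` and `go` are synonyms; the compounds are
`move/go left/right`).  The parser is the FSA class applied to the
grammar's trie, with an explicit reject sink so that non-sentences and
continuations past an accept state are rejected.  Accept-state assemblies
project to goal and goal-parameter assemblies, so a successful parse
*ignites the goal*; a symbolic parse oracle must agree on the entire
sentence set.

## Planning

Goals, facts and actions are binary CAs; because binary assemblies cannot
carry the graded activations of a spreading-activation behavior network,
gating timers approximate them.  Facts ignite only when environmental
drive (a percept line, $0.65$ per member per step) coincides with a
gating-timer tap ($0.5$): each alone stays sub-threshold even after
integration.  The first timer's tap window (steps 101-135 of the cycle)
gates the visual fact set; a frame delivered later than step 135 — which
happens with probability $\approx 0.24$ under jittered timing and never
under regular timing — misses it.  The second timer then boosts the
proprioceptive facts (wall ahead, in corridor, room entered), and if
nothing ignites, a default pathway driven by the second timer's tail fires
the context's default action.  The default is move-forward; combined with
the wall-ahead rule (turn right at a wall) this makes unsighted search a
clockwise wall-follow — the agent turns right, walking, while looking for
the corridor.  Action assemblies are mutually inhibitory, so one decision
cycle commits at most one action; ties are prevented upstream by the
driver attending a single percept line per cycle with the fixed priority
identified > object position > wall, centre > left > right.

The explore and move-before behaviors are sequenced by a phase FSA
(identify, find-corridor, traverse).  Approach uses a staircase policy:
with quarter turns and a 90-degree field of view, turning while a target
is visible necessarily rotates it out of view, so the agent moves forward
while the target is in view and holds, as one-cycle iconic memory, the
side on which it disappeared, turning that way on the next cycle.
Corridor turn-around re-enters the identify phase, which relocates the
agent toward the room's shape before searching again — the recovery the
task needs after a traversal reversal.  Corridor search also applies
inhibition of return: green belonging only to the corridor just traversed
does not capture attention, so the search progresses around the room
cycle instead of shuttling back and forth through one corridor.  Without
it, the deterministic (noise-free) agent can enter a closed orbit between
two rooms.

One decision cycle occupies the 100 ms processing gap, the frame interval,
the gating windows, and a 200 ms action-execution period (the time the
environment takes to execute a move and the camera to re-acquire).  The
execution period is this package's constant, fixed before any batch
statistics were collected; it sets the overall cadence at roughly 0.4 s
per primitive move, the regime in which the four-room task is normally
run and measured.

## The cognitive map

Four room assemblies, four shape assemblies and a start marker live in
gated pools with all-to-all plastic projections (initial weight $0.02$,
bound $0.12$).  STDP is an exponential all-pairs kernel, potentiation
$0.02\,e^{-\Delta t/10}$ for pre-before-post, depression
$0.01\,e^{-\Delta t/10}$ for the reverse; the asymmetry makes sustained
co-firing net-potentiating, so one 40-step co-ignition window saturates a
pair at the bound.  The bound matters: integrated drive from a fully
learned partner is $5 \times 0.12 \times 1.25 = 0.75 < 1$, so a learned
association alone cannot ignite its target; retrieval opens one pool at a
time with a single-step gate boost of $0.35$ (a sustained boost would let
the room chain fire two sequence links at once).  The recall threshold
(pair mean weight $0.10$) sits between the initial weight and the
crossing weight $0.104$ implied by this arithmetic.

Sequence links chain rooms in *discovery order*, not the physical order of
traversal: after a corridor turn-around the agent re-enters a mapped room,
and physical-adjacency links would give one room two successors, breaking
the before-relation.  The before-relation is answered by a gated scan:
start marker to first room, then alternately retrieve the active room's
shape and step along the sequence links, with at most one room and one
shape assembly active at any checkpoint; the answer (the shape preceding
the target in the scan) is re-ignited as the map's final state.  Once four
associations exceed the recall threshold the map is complete and
`associate()` becomes a no-op: the agent can only explore once.

## Reinforcement rule selection

Antecedent assemblies project plastically to consequent assemblies
(initial $0.02$, bound $0.3$; five synapses at $0.3$ ignite a consequent
outright).  An Explore population fires at an elevated rate whenever an
antecedent is present and drives consequents with a per-window uniform
noise level on $[0.35, 0.75]$ drawn from the trial's seeded stream — the
argmax crosses threshold first and winner-take-all inhibition keeps the
selection unique.  A correct selection activates Value externally, which
suppresses Explore ($-3$ per step), and applies the reward-gated updates:
$+0.06$ on the active pair, $-0.04$ from the antecedent to the other
consequents.  A wrong selection gets a small transient increase
($+0.01$), no Value, and a strong hold-down ($-3.5$ per step, enough to
beat recurrence plus a trained drive) for the rest of the trial while
another consequent is tried.  Every rewarded trial therefore moves the
correct pair up and the others down; the only attractors are the pairings
the reward rule defines, and flipping the rule mid-run re-converges in a
few dozen trials (the re-convergence bound is recorded by the tests, not
asserted from outside).

## The closed loop and its statistics

The environment advances only when an action assembly ignites, so
simulated neural time (the step counter) is decoupled from wall-clock
time.  Episodes parse each command with the neural parser, dispatch to the
matching controller, and classify failures from the event log: a halt in
the wrong room (or a wrong association en route) is a misidentification
failure; a timeout with the trailing fifty moves confined to one room is
circling.  Success on the two-command script means halting, within the
200 s budget, in the room that actually precedes the target shape's room
in the agent's own exploration order.

Batch statistics in this package are computed at a 10-episode smoke scale
per timing mode (matched seeds across modes share the camera-noise
stream, with jitter drawn from a separate stream), which is the problem
size used by the tests and the acceptance script.

## What the synthetic world does and does not show

The generated world reproduces the structural difficulties of the task —
narrow corridors that are hard to find and easy to reverse out of, shapes
that cannot be told apart at range, input timing that can starve the
gating window — under a schematic renderer and discrete kinematics.  It
has no continuous dynamics, no texture, no lighting, and a single fixed
geometry per seed, so passing tests here demonstrates the neural
machinery's correctness and the task-level failure modes, not performance
on physical-camera input.

## Numerical choices and degenerate inputs

All weight calibrations are stated above in integrated-drive terms; the
spike threshold test uses a $10^{-9}$ tolerance, and the simulator retires
neurons whose state has relaxed to within $10^{-9}$ of rest (snapping them
to rest), which is far below every threshold margin in the package.
Degenerate inputs are rejected eagerly: assemblies that cannot persist,
timers whose duration is not a multiple of their interval, transitions
over unknown states, worlds whose corridors do not form a single cycle,
schedules addressing unknown neurons.  Blocked moves and failed episodes
are outcomes, not errors.
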