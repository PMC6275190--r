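# cabot

Closed-loop spiking cell-assembly agents in a four-room grid world.

`cabot` is an R package for building cognitive agents out of spiking
neurons.  Its substrate is a discrete-time point-neuron simulator (leaky
integrate-and-fire with adaptation, plus a fatiguing variant) with delayed
spike delivery and spike-timing-dependent plasticity.  On top of it sit
three neural abstract data types and the subsystems of a complete embodied
agent:

- **Binary cell assemblies** — five mutually excitatory neurons; once all
  fire, they re-fire each other indefinitely (*ignition*), giving a
  two-state memory element.
- **Finite-state automata** whose states are cell assemblies: presenting a
  symbol while state *s* is ignited extinguishes *s* and ignites
  δ(*s*, *a*) via coincidence detectors and an inhibitory sweep.
- **Synfire-chain timers** whose taps gate other assemblies during defined
  windows.

The agent lives in a four-room world connected in a cycle by green
corridors, each room holding one of four shapes (red/blue ×
pyramid/stalactite).  It parses typed commands with a regular-grammar
neural parser (a parse *ignites* the goal assembly), extracts shape,
colour and position percepts from a noisy 20×20 camera, selects one action
per decision cycle through timer-gated goal/fact/action assemblies, learns
a spatial cognitive map of room–shape associations by STDP during
exploration, and answers "the room before the room with the red
stalactite" by gated recall over the learned map.  A reward-gated
rule-selection network (antecedents, consequents, Explore and Value
subnets) learns stimulus–response rules from reinforcement and re-learns
them when the rule changes.

Visual input timing is configurable: *regular* (a frame exactly every
30 ms) or *jittered* (uniform on 20–40 ms), with a ~100 ms processing gap
after each consumed frame; jitter can starve the fact-gating window, which
is what degrades task performance in that mode.

## A worked example

```r
library(cabot)

agent <- assemble_agent()
agent
#> <cabot_agent> 3369 neurons, 27946 synapses
#>   vision language planning   cogmap    total
#>     1200     1458      666       45     3369

res <- run_episode(agent, episode_config(
  c("explore", "move to the room before the room with the red stalactite"),
  duration_s = 200, mode = "regular", seed = 5))
res
#> <cabot_episode> regular mode seed 5: success, 187 moves, completed at 79.0 s
res$visit_rooms
#> [1] "NW" "SW" "SE" "NE"
res$map
#> [1] "red_pyramid" "blue_stalactite" "red_stalactite" "blue_pyramid"
```

The agent explored the four rooms (visit order above), associated each
room with the shape it identified there, recalled that the room before the
red stalactite's room holds the blue stalactite, traversed the world
checking shapes, and halted in the correct room after 79.0 simulated
seconds and 187 primitive moves.  `write_episode(res, "out/")` writes `result.json`,
the move trace (TSV and an ASCII map in the style of a top-down plot with
`S` at the start and `M` at the move command), the event log, and the
learned map.

Batches with per-run seeds:

```r
b <- run_batch(n = 10, base_seed = 1, mode = "regular")
b
#> <cabot_batch> 10/10 successful; median completion 83.0 s; moves 187-198
```

A command-line wrapper is installed at `inst/cli/cabot`:

```sh
Rscript inst/cli/cabot run --commands "explore; move to the room before the room with the red stalactite" \
    --mode regular --duration-s 200 --seed 5 --out out/
Rscript inst/cli/cabot batch --runs 10 --seed 1 --out out/
Rscript inst/cli/cabot build-world --seed 3 --out world.yaml
```

## Documentation

The methods vignette (`vignettes/cabot-methods.Rmd`) describes the neuron
model and its update order, the assembly/FSA/timer constructions and their
calibrations, the world and camera, the timer-gated planning scheme, the
cognitive map's plasticity arithmetic, the reinforcement dynamics, and the
known limitations of the synthetic world.
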