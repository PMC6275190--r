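# The planning subsystem: goal assemblies set by the parser, fact
# assemblies gated by synfire timers, action assemblies selected through
# coincidence detectors, and a phase FSA sequencing the explore /
# move-before behaviors.  Facts only ignite when environmental drive (a
# percept line, sub-threshold on its own) coincides with a gating-timer tap
# (also sub-threshold): this is the timer approximation of spreading
# activation in a behavior-selection network.

PLAN_FACTS <- c("obj_left", "obj_right", "obj_center",
                "id_red_pyramid", "id_blue_pyramid", "id_red_stalactite",
                "id_blue_stalactite",
                "corridor_left", "corridor_right", "corridor_center",
                "wall_ahead", "in_corridor", "room_entered")
PLAN_VISUAL_FACTS <- PLAN_FACTS[1:10]
PLAN_PROP_FACTS <- PLAN_FACTS[11:13]   # proprioceptive / kinesthetic senses
PLAN_ACTIONS <- c("turn_left", "turn_right", "move_forward", "move_backward")
PLAN_GOALS <- c("stop", "explore", "move_before", "turn_toward",
                "approach_box", "move_forward", "move_backward",
                "turn_left", "turn_right", "move_left", "move_right")
PLAN_PARAMS <- c("tgt_red", "tgt_blue", "tgt_pyramid", "tgt_stalactite")
PLAN_PHASES <- c("idle", "identify", "find_corridor", "traverse", "done")
PHASE_SYMBOLS <- c("start_task", "identified_done", "corridor_entered",
                   "entered_new_room", "entered_old_room", "task_done",
                   "reset_phase")

# segment-1 layout (steps within a decision cycle): the gating timer starts
# at step 1; the processing gap occupies the first ~100 steps; the frame is
# delivered at 100 + interval; the visual tap window is steps 101..135, so
# a late (jittered) frame can miss it
GATE1_DURATION <- 140L
GATE1_TAPS <- 20:26          # interval 5: neurons 101..135
GATE2_DURATION <- 100L
GATE2_PROP_TAPS <- 0:6       # neurons 1..35
GATE2_DEFAULT_TAPS <- 12:17  # neurons 61..90
SEG1_STEPS <- 150L
SEG2_STEPS <- 100L
FRAME_VISIBLE_STEPS <- 30L   # a delivered frame drives its lines for 30 ms
# Simulated time for a committed action to execute in the environment and
# the camera to re-acquire: together with the gap, gating and settle times
# this fixes the overall cadence at roughly 0.4 s per primitive move.
ACTION_EXEC_STEPS <- 200L

LINE_W <- 0.13    # percept line -> fact member (sum 0.65: sub-threshold)
TAP_W <- 0.5      # gating tap neuron -> fact member
CONJ_IN_W <- 0.13 # assembly member -> coincidence detector
CONJ_TAP_W <- 0.65
CONJ_OUT_W <- 0.6

fact_pop <- function(f) paste0("fact.", f)
line_pop <- function(f) paste0("line.", f)
act_pop <- function(a) paste0("act.", a)
goal_pop <- function(g) paste0("goal.", g)

# a 2-neuron coincidence detector driven by two assemblies (or an assembly
# and a set of timer tap neurons), projecting to a target assembly
add_conj <- function(net, id, a_pop, b_pop, target_pop,
                     b_neurons = NULL, out_w = CONJ_OUT_W, out_delay = 1L) {
  add_population(net, id, 2L, conj_params())
  add_projection(net, paste0(id, ".a"), a_pop, id,
                 rep(1:5, 2), rep(1:2, each = 5), CONJ_IN_W)
  if (is.null(b_neurons)) {
    add_projection(net, paste0(id, ".b"), b_pop, id,
                   rep(1:5, 2), rep(1:2, each = 5), CONJ_IN_W)
  } else {
    add_projection(net, paste0(id, ".b"), b_pop, id,
                   rep(b_neurons, 2), rep(1:2, each = length(b_neurons)),
                   CONJ_TAP_W)
  }
  if (!is.null(target_pop))
    add_projection(net, paste0(id, ".out"), id, target_pop,
                   rep(1:2, each = 5), rep(1:5, 2), out_w, out_delay)
  invisible(net)
}

#' Assemble the full agent network
#'
#' Builds, on a single network, every subsystem and the projections between
#' them: the neural command parser (language), goal and goal-parameter
#' assemblies driven by the parser's accept states, the phase FSA, the
#' percept lines and gated fact assemblies (vision-to-planning), the action
#' assemblies with winner-take-all inhibition, the gating and compound
#' timers, the retina input populations, and the cognitive map with its
#' plastic projections (planning-to-cognitive-map).  Each subsystem is
#' independently testable before assembly; the agent is their union plus
#' inter-subsystem synapses.
#'
#' @param config an [agent_config()].
#' @return an object of class `cabot_agent`.
#' @export
assemble_agent <- function(config = agent_config()) {
  net <- network(step_ms = 1)
  subsystems <- config$subsystems

  # retina input populations (one neuron per pixel per channel)
  for (ch in c("retina_r", "retina_g", "retina_b"))
    add_population(net, ch, FRAME_W * FRAME_H, conj_params())

  parser <- build_parser(net)

  for (g in c(PLAN_GOALS, PLAN_PARAMS)) make_ca(net, 5, id = goal_pop(g))

  accept_goal <- list(
    A_stop = "stop", A_explore = "explore",
    A_turn_left = "turn_left", A_turn_right = "turn_right",
    A_move_forward = "move_forward", A_move_backward = "move_backward",
    A_move_left = "move_left", A_move_right = "move_right",
    A_toward_pyramid = c("turn_toward", "tgt_pyramid"),
    A_toward_stalactite = c("turn_toward", "tgt_stalactite"),
    A_box = "approach_box",
    A_before_red_pyramid = c("move_before", "tgt_red", "tgt_pyramid"),
    A_before_red_stalactite = c("move_before", "tgt_red", "tgt_stalactite"),
    A_before_blue_pyramid = c("move_before", "tgt_blue", "tgt_pyramid"),
    A_before_blue_stalactite = c("move_before", "tgt_blue", "tgt_stalactite"))
  for (acc in names(accept_goal))
    for (g in accept_goal[[acc]])
      add_projection(net, sprintf("lang.%s.%s", acc, g),
                     paste0("parser.s.", acc), goal_pop(g),
                     rep(1:5, each = 5), rep(1:5, 5), 0.24)

  phase_tr <- data.frame(
    state = c("idle", "identify", "find_corridor", "traverse", "traverse",
              "identify", PLAN_PHASES),
    symbol = c("start_task", "identified_done", "corridor_entered",
               "entered_new_room", "entered_old_room", "task_done",
               rep("reset_phase", length(PLAN_PHASES))),
    next_state = c("identify", "find_corridor", "traverse", "identify",
                   "identify", "done", rep("idle", length(PLAN_PHASES))),
    stringsAsFactors = FALSE)
  phase <- make_fsa(net, PLAN_PHASES, PHASE_SYMBOLS, phase_tr, "idle",
                    id = "phase")

  # percept lines and fact assemblies
  for (f in PLAN_FACTS) {
    add_population(net, line_pop(f), 5L, conj_params())
    make_ca(net, 5, id = fact_pop(f))
    add_projection(net, paste0("lf.", f), line_pop(f), fact_pop(f),
                   rep(1:5, each = 5), rep(1:5, 5), LINE_W)
  }

  # action assemblies with winner-take-all inhibition
  for (a in PLAN_ACTIONS) make_ca(net, 5, id = act_pop(a))
  for (a in PLAN_ACTIONS) for (b in setdiff(PLAN_ACTIONS, a))
    add_projection(net, sprintf("wta.%s.%s", a, b), act_pop(a), act_pop(b),
                   rep(1:5, each = 5), rep(1:5, 5), -0.4)

  # gating timers: taps gate visual facts (gate1), proprioceptive facts and
  # the per-phase default pathway (gate2)
  gate1 <- make_timer(net, GATE1_DURATION, 5L, GATE1_TAPS, id = "gate1")
  gate2 <- make_timer(net, GATE2_DURATION, 5L,
                      c(GATE2_PROP_TAPS, GATE2_DEFAULT_TAPS), id = "gate2")
  g1_neurons <- unlist(lapply(GATE1_TAPS, timer_tap_neurons, timer = gate1))
  g2_prop <- unlist(lapply(GATE2_PROP_TAPS, timer_tap_neurons, timer = gate2))
  g2_def <- unlist(lapply(GATE2_DEFAULT_TAPS, timer_tap_neurons, timer = gate2))
  for (f in PLAN_VISUAL_FACTS)
    add_projection(net, paste0("g1.", f), "gate1", fact_pop(f),
                   rep(g1_neurons, each = 5), rep(1:5, length(g1_neurons)),
                   TAP_W)
  for (f in PLAN_PROP_FACTS)
    add_projection(net, paste0("g2.", f), "gate2", fact_pop(f),
                   rep(g2_prop, each = 5), rep(1:5, length(g2_prop)), TAP_W)

  # (context, fact) -> action coincidence detectors
  rules <- list(
    c("phase.s.identify", "obj_left", "turn_left"),
    c("phase.s.identify", "obj_right", "turn_right"),
    c("phase.s.identify", "obj_center", "move_forward"),
    c("phase.s.identify", "wall_ahead", "turn_right"),
    c("phase.s.find_corridor", "corridor_left", "turn_left"),
    c("phase.s.find_corridor", "corridor_right", "turn_right"),
    c("phase.s.find_corridor", "corridor_center", "move_forward"),
    c("phase.s.find_corridor", "wall_ahead", "turn_right"),
    c("phase.s.traverse", "wall_ahead", "turn_right"),
    c(goal_pop("turn_toward"), "obj_left", "turn_left"),
    c(goal_pop("turn_toward"), "obj_right", "turn_right"),
    c(goal_pop("approach_box"), "obj_left", "turn_left"),
    c(goal_pop("approach_box"), "obj_right", "turn_right"),
    c(goal_pop("approach_box"), "obj_center", "move_forward"),
    c(goal_pop("approach_box"), "wall_ahead", "turn_right"))
  for (k in seq_along(rules)) {
    r <- rules[[k]]
    add_conj(net, sprintf("rule%02d", k), r[1], fact_pop(r[2]), act_pop(r[3]))
  }
  # per-context default action, driven by the tail taps of gate2
  # the default action is move_forward; with the wall_ahead -> turn_right
  # rule this makes unsighted search a clockwise wall-follow (turning right
  # while looking for the corridor)
  defaults <- list(
    c("phase.s.identify", "move_forward"),
    c("phase.s.find_corridor", "move_forward"),
    c("phase.s.traverse", "move_forward"),
    c(goal_pop("turn_toward"), "turn_right"),
    c(goal_pop("approach_box"), "turn_right"))
  for (k in seq_along(defaults)) {
    d <- defaults[[k]]
    add_conj(net, sprintf("def%02d", k), d[1], "gate2", act_pop(d[2]),
             b_neurons = g2_def)
  }
  # primitive goals drive their action directly
  for (a in PLAN_ACTIONS)
    add_projection(net, paste0("prim.", a), goal_pop(a), act_pop(a),
                   rep(1:5, each = 5), rep(1:5, 5), 0.24)
  # compound goals: a two-tap timer sequences turn then step
  comp <- make_timer(net, 70L, 35L, c(0L, 1L), id = "comp")
  c0 <- timer_tap_neurons(comp, 0L); c1 <- timer_tap_neurons(comp, 1L)
  add_conj(net, "comp.l0", goal_pop("move_left"), "comp",
           act_pop("turn_left"), b_neurons = c0)
  add_conj(net, "comp.l1", goal_pop("move_left"), "comp",
           act_pop("move_forward"), b_neurons = c1)
  add_conj(net, "comp.r0", goal_pop("move_right"), "comp",
           act_pop("turn_right"), b_neurons = c0)
  add_conj(net, "comp.r1", goal_pop("move_right"), "comp",
           act_pop("move_forward"), b_neurons = c1)

  cogmap <- if ("cogmap" %in% subsystems) build_cogmap(net) else NULL

  structure(list(net = net, parser = parser, phase = phase,
                 cogmap = cogmap, gate1 = gate1, gate2 = gate2, comp = comp,
                 config = config), class = "cabot_agent")
}

#' @export
print.cabot_agent <- function(x, ...) {
  counts <- subsystem_counts(x)
  cat("<cabot_agent>", x$net$n, "neurons,", length(x$net$syn_w), "synapses\n")
  print(counts)
  invisible(x)
}

#' Per-subsystem neuron counts of an assembled agent
#'
#' @param agent a `cabot_agent`.
#' @return named integer vector.
#' @export
subsystem_counts <- function(agent) {
  pops <- agent$net$pops
  grp <- function(prefixes) sum(vapply(pops[grepl(prefixes, names(pops))],
                                       `[[`, integer(1), "size"))
  c(vision = grp("^retina_"),
    language = grp("^parser\\."),
    planning = grp("^(goal\\.|phase\\.|fact\\.|line\\.|act\\.|gate|comp|rule|def|wta|prim)"),
    cogmap = grp("^map\\."),
    total = agent$net$n)
}

#' Deterministic signature of a network's structure
#'
#' A cheap rolling checksum over population sizes, synapse endpoints,
#' weights and delays; two assemblies from the same configuration produce
#' the same signature.
#'
#' @param net a `cabot_network`.
#' @return a character scalar.
#' @export
network_signature <- function(net) {
  acc <- 0
  fold <- function(acc, x) {
    for (v in x) acc <- (acc * 31 + (as.double(v) * 1e4) %% 1e9) %% 2147483647
    acc
  }
  acc <- fold(acc, vapply(net$pops, `[[`, integer(1), "size"))
  acc <- fold(acc, net$syn_pre); acc <- fold(acc, net$syn_post)
  acc <- fold(acc, net$syn_w); acc <- fold(acc, net$syn_d)
  sprintf("%d-%d-%.0f", net$n, length(net$syn_w), acc)
}

#' Agent configuration
#'
#' @param world world seed (integer) or a [world_spec()] list; `NULL` for the
#'   reference layout.
#' @param subsystems subsystems to assemble; omitting `"cogmap"` yields an
#'   agent valid for primitive commands only (explore is rejected).
#' @param p_drop camera dropout probability (see [capture_frame()]).
#' @return an `agent_config` list.
#' @export
agent_config <- function(world = NULL, subsystems = c("vision", "language",
                                                      "planning", "cogmap"),
                         p_drop = 0.08) {
  structure(list(world = world, subsystems = subsystems, p_drop = p_drop),
            class = "agent_config")
}
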