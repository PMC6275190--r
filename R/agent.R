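# Closed-loop episode driver.  The environment advances only when an action
# assembly ignites (loose coupling): each decision cycle starts the gating
# timer, waits out the processing gap, delivers a (possibly jittered,
# possibly noisy) camera frame onto the percept lines, and lets the network
# select an action; the driver applies the action to the world and the next
# cycle sees the consequences.  Simulated time is the network's step count
# (1 ms per step) and is decoupled from wall-clock time.

#' Episode configuration
#'
#' @param commands character vector of command strings; each is parsed (by
#'   the neural parser) and executed when the previous command's goal has
#'   completed.
#' @param duration_s simulated-time budget in seconds (default 200).
#' @param mode visual input timing: `"regular"` or `"jittered"`.
#' @param seed integer; seeds every random stream of the episode (camera
#'   noise, input jitter) via [derive_seed()].
#' @param record `"none"` (default) or `"full"` (keep all decision-cycle
#'   and cognitive-map spike records in the result).
#' @return an `episode_config` list.
#' @export
episode_config <- function(commands = c("explore",
                                        "move to the room before the room with the red stalactite"),
                           duration_s = 200, mode = c("regular", "jittered"),
                           seed = 1L, record = c("none", "full")) {
  mode <- match.arg(mode)
  record <- match.arg(record)
  stopifnot(duration_s > 0)
  structure(list(commands = commands, duration_s = duration_s, mode = mode,
                 seed = as.integer(seed), record = record),
            class = "episode_config")
}

ID_FACTS <- paste0("id_", c("red_pyramid", "blue_pyramid",
                            "red_stalactite", "blue_stalactite"))

ep_new <- function(agent, episode) {
  ep <- new.env(parent = emptyenv())
  ep$agent <- agent; ep$net <- agent$net
  ep$world <- build_world(agent$config$world %||% world_spec())
  ep$pose <- with(ep$world$start, agent_pose(x, y, heading))
  ep$mode <- episode$mode
  ep$retina <- retina_config(mode = episode$mode)
  ep$p_drop <- agent$config$p_drop
  ep$t0 <- agent$net$state$t               # episode time is relative
  ep$limit <- ep$t0 + as.integer(episode$duration_s * 1000)
  ep$trace <- list(); ep$events <- list(); ep$moves <- 0L
  ep$records <- list(); ep$keep <- identical(episode$record, "full")
  ep$visit_rooms <- character(0)
  ep$assoc <- character(0)                 # committed shape per visited room
  ep$current_room <- room_at(ep$world, ep$pose$x, ep$pose$y)
  ep$phase_mirror <- "idle"
  ep$mem_side <- list()
  ep$streams <- list()
  for (nm in c("capture", "timing"))
    ep$streams[[nm]] <- derive_seed(episode$seed, nm)
  if (!is.null(agent$cogmap)) agent$cogmap$trace$keep <- ep$keep
  ep
}

# seeded, named random streams: each draw swaps in the stream's RNG state
ep_draw <- function(ep, name, fn) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  st <- ep$streams[[name]]
  if (is.integer(st) && length(st) == 1L) set.seed(st)
  else assign(".Random.seed", st, globalenv())
  out <- fn()
  ep$streams[[name]] <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out
}

ep_event <- function(ep, event, detail = "") {
  ep$events[[length(ep$events) + 1L]] <-
    data.frame(t = ep$net$state$t - ep$t0, event = event, detail = detail,
               stringsAsFactors = FALSE)
}

ep_time_left <- function(ep) ep$net$state$t < ep$limit

run_seg <- function(ep, steps, sched = NULL) {
  rec <- spike_record(ep$net, run_raw(ep$net, steps, sched))
  if (ep$keep) ep$records[[length(ep$records) + 1L]] <- rec
  rec
}

facts_on <- function(rec, window = 60L) {
  on <- vapply(PLAN_FACTS, function(f)
    pop_ignited(rec, fact_pop(f), 5L, window), logical(1))
  PLAN_FACTS[on]
}

action_on <- function(rec, window = 80L) {
  hit <- character(0); first <- integer(0)
  for (a in PLAN_ACTIONS) {
    if (pop_ignited(rec, act_pop(a), 5L, window)) {
      hit <- c(hit, a)
      first <- c(first, min(rec$step[rec$population == act_pop(a)]))
    }
  }
  if (!length(hit)) return(NULL)
  hit[which.min(first)]
}

sched_extinguish_pops <- function(net, pops, step = 1L) {
  do.call(rbind, lapply(pops, function(p)
    sched_block(net, p, 1:5, step + 0:2, CA_EXTINGUISH)))
}

ep_clear_cycle <- function(ep) {
  if (is.null(ep$clear_sched))
    ep$clear_sched <- sched_extinguish_pops(
      ep$net, c(vapply(PLAN_FACTS, fact_pop, ""),
                vapply(PLAN_ACTIONS, act_pop, "")))
  run_seg(ep, 8L, ep$clear_sched)
}

ep_clear_goals <- function(ep) {
  sched <- sched_extinguish_pops(ep$net,
                                 vapply(c(PLAN_GOALS, PLAN_PARAMS), goal_pop, ""))
  run_seg(ep, 8L, sched)
}

wall_ahead_geom <- function(world, pose) {
  h <- HEADINGS[[pose$heading]]
  !is_walkable(world, pose$x + h[1], pose$y + h[2])
}

# Which visual percept line gets attention this cycle.  With a 90-degree
# field of view and 90-degree turns, turning while a target is visible
# always rotates it out of view, so the approach policy is a staircase:
# while the target is visible the agent closes in (the "ahead" line), and
# the side on which it slips out of view is held for one cycle as iconic
# memory, driving a corrective turn when it disappears.  turn_toward keeps
# the literal left/right semantics (its task is orienting, not approach).
attend_visual <- function(ep, context, percept, goal_kind = NULL) {
  mem_turn <- function(kind_key, present, position) {
    if (present) {
      ep$mem_side[[kind_key]] <-
        if (position %in% c("left", "right")) position else NULL
      return("center")
    }
    side <- ep$mem_side[[kind_key]]
    ep$mem_side[[kind_key]] <- NULL
    side
  }
  if (context %in% c("identify", "approach_box")) {
    if (percept$object_present && context == "identify" &&
        percept$kind != "unknown")
      return(paste0("id_", percept$color, "_", percept$kind))
    dir <- mem_turn("obj", percept$object_present, percept$position)
    if (!is.null(dir)) return(paste0("obj_", dir))
    return(NULL)
  }
  if (context == "turn_toward") {
    if (!percept$object_present) return(NULL)
    if (!is.null(goal_kind) &&
        !percept$kind %in% c("unknown", goal_kind)) return(NULL)
    return(paste0("obj_", percept$position))
  }
  if (context == "find_corridor") {
    dir <- mem_turn("corr", percept$corridor_present,
                    percept$corridor_position)
    if (!is.null(dir)) return(paste0("corridor_", dir))
  }
  NULL
}

ep_trace_row <- function(ep, action, mark = "") {
  ep$trace[[length(ep$trace) + 1L]] <-
    data.frame(t = ep$net$state$t - ep$t0, x = ep$pose$x, y = ep$pose$y,
               heading = ep$pose$heading, action = action, mark = mark,
               stringsAsFactors = FALSE)
}

# one decision cycle: gap -> frame -> gated facts -> action -> environment
decision_cycle <- function(ep, context, goal_kind = NULL) {
  net <- ep$net
  interval <- if (ep$mode == "regular") ep$retina$frame_interval
  else ep_draw(ep, "timing", function() sample_frame_interval(ep$retina))
  arr <- 100L + as.integer(interval)
  frame <- render_frame(ep$world, ep$pose)
  cap <- ep_draw(ep, "capture", function() capture_frame(frame, ep$p_drop))
  percept <- frame_percept(cap)
  # inhibition of return: while searching for a corridor, green belonging
  # only to the corridor just traversed does not capture attention, which
  # keeps the search moving around the cycle instead of shuttling back
  if (context == "find_corridor" && percept$corridor_present &&
      !is.null(ep$last_corridor)) {
    seen <- visible_corridors(ep$world, ep$pose)
    if (length(seen) && all(seen == ep$last_corridor)) {
      percept$corridor_present <- FALSE
      percept$corridor_position <- NA_character_
    }
  }
  vis <- attend_visual(ep, context, percept, goal_kind)
  # an obstacle directly ahead takes attention away from a blocked approach
  if (!is.null(vis) && grepl("_center$", vis) && wall_ahead_geom(ep$world, ep$pose))
    vis <- NULL

  sched1 <- sched_timer_start(ep$agent$gate1, 1L)
  if (!is.null(vis)) {
    to <- min(arr + FRAME_VISIBLE_STEPS - 1L, SEG1_STEPS)
    sched1 <- rbind(sched1,
                    sched_block(net, line_pop(vis), 1:5, arr:to, CA_IGNITE))
  }
  rec1 <- run_seg(ep, SEG1_STEPS, sched1)
  facts <- facts_on(rec1)
  act <- action_on(rec1)
  if (is.null(act) && !any(facts %in% ID_FACTS)) {
    # second timer: boost the proprioceptive fact set; on continued failure
    # the default pathway fires
    sched2 <- sched_timer_start(ep$agent$gate2, 1L)
    prop <- character(0)
    if (wall_ahead_geom(ep$world, ep$pose)) prop <- c(prop, "wall_ahead")
    if (!is.na(corridor_at(ep$world, ep$pose$x, ep$pose$y)))
      prop <- c(prop, "in_corridor")
    if (isTRUE(ep$entered_room_flag)) prop <- c(prop, "room_entered")
    for (p in prop)
      sched2 <- rbind(sched2, sched_block(net, line_pop(p), 1:5,
                                          1:GATE2_DURATION, CA_IGNITE))
    rec2 <- run_seg(ep, SEG2_STEPS, sched2)
    facts <- union(facts, facts_on(rec2))
    act <- action_on(rec2)
  }
  ep$entered_room_flag <- FALSE
  moved_room <- NULL
  if (!is.null(act)) {
    if (act %in% c("turn_left", "turn_right"))
      ep$mem_side <- list()      # iconic memory is only valid across steps
    old_corr <- corridor_at(ep$world, ep$pose$x, ep$pose$y)
    ep$pose <- apply_action(ep$world, ep$pose, act)
    ep$moves <- ep$moves + 1L
    ep_trace_row(ep, act)
    new_room <- room_at(ep$world, ep$pose$x, ep$pose$y)
    if (!is.na(new_room) && !identical(new_room, ep$current_room)) {
      moved_room <- new_room
      ep$entered_room_flag <- TRUE
      if (!is.na(old_corr)) ep$last_corridor <- old_corr
    }
  }
  ep_clear_cycle(ep)
  if (!is.null(act)) run_seg(ep, ACTION_EXEC_STEPS)
  list(percept = percept, facts = facts, action = act, arrival = arr,
       entered_room = moved_room)
}

present_phase <- function(ep, symbol) {
  rec <- fsa_present(ep$agent$phase, symbol)
  if (ep$keep) ep$records[[length(ep$records) + 1L]] <- rec
  st <- fsa_state(ep$agent$phase, rec)
  if (length(st) == 1) ep$phase_mirror <- st
  else ep_event(ep, "phase_anomaly", paste(st, collapse = ","))
  invisible(st)
}

reset_phase <- function(ep) {
  present_phase(ep, "reset_phase")
}

# handle a room change: during exploration, update the visit order and
# learn sequence links, and treat re-entry (corridor turn-around) as a
# recovery back to corridor search; during a move-before traversal every
# entered room is checked, so re-entries also go to identification
handle_room_entry <- function(ep, new_room, learning) {
  ep$current_room <- new_room
  if (!learning) {
    ep_event(ep, "entered_room", new_room)
    present_phase(ep, "entered_new_room")
  } else if (new_room %in% ep$visit_rooms) {
    ep_event(ep, "entered_old_room", new_room)
    present_phase(ep, "entered_old_room")
  } else {
    ep$visit_rooms <- c(ep$visit_rooms, new_room)
    # sequence links chain rooms in discovery order (the order the map's
    # "room before" relation encodes), which stays a single chain even when
    # the agent backtracks through an already-mapped room on the way
    if (!is.null(ep$agent$cogmap) && length(ep$visit_rooms) >= 2)
      learn_sequence(ep$agent$cogmap, length(ep$visit_rooms) - 1L,
                     length(ep$visit_rooms))
    ep_event(ep, "entered_new_room", new_room)
    present_phase(ep, "entered_new_room")
  }
}

#' Explore controller
#'
#' Runs the exploration behavior on an assembled agent whose `explore` goal
#' is active: per room, identify the shape (associating it into the
#' cognitive map), turn right to look for a corridor, traverse it, and
#' repeat until all four rooms are mapped.  A second `explore` after the map
#' is complete only wanders (the agent can only explore once).  Failure
#' (timeout, circling) is an episode outcome, not an error.
#'
#' @param ep internal episode state (created by [run_episode()]).
#' @return `TRUE` on completion, `FALSE` on timeout.
#' @keywords internal
explore_controller <- function(ep) {
  map <- ep$agent$cogmap
  if (is.null(map)) {
    ep_event(ep, "command_rejected", "explore requires the cogmap subsystem")
    return(NA)
  }
  if (map_complete(map)) {
    ep_event(ep, "explore_ignored", "map already complete; explore once only")
    return(TRUE)
  }
  ep$visit_rooms <- ep$current_room
  ep$assoc <- setNames(NA_character_, ep$current_room)
  learn_sequence(map, "start", 1L)
  present_phase(ep, "start_task")
  while (ep_time_left(ep)) {
    ph <- ep$phase_mirror
    res <- decision_cycle(ep, ph)
    idf <- intersect(res$facts, ID_FACTS)
    if (ph == "identify" && length(idf)) {
      shape <- sub("^id_", "", idf[1])
      ridx <- match(ep$current_room, ep$visit_rooms)
      if (is.na(ep$assoc[ep$current_room])) {
        truth <- with(ep$world$shapes,
                      shape_label(color[room == ep$current_room],
                                  kind[room == ep$current_room]))
        if (!identical(shape, truth))
          ep_event(ep, "misidentified", paste(ep$current_room, shape,
                                              "truth", truth))
        associate(map, ridx, shape)
        ep$assoc[ep$current_room] <- shape
        ep_event(ep, "associated", paste(ep$current_room, shape))
      }
      if (sum(!is.na(ep$assoc)) >= 4L) {
        present_phase(ep, "task_done")
        ep_event(ep, "explore_complete", "")
        return(TRUE)
      }
      present_phase(ep, "identified_done")
      next
    }
    if (!is.null(res$entered_room)) {
      handle_room_entry(ep, res$entered_room, learning = TRUE)
      next
    }
    if (ph == "find_corridor" &&
        !is.na(corridor_at(ep$world, ep$pose$x, ep$pose$y))) {
      ep_event(ep, "corridor_entered",
               corridor_at(ep$world, ep$pose$x, ep$pose$y))
      present_phase(ep, "corridor_entered")
    }
  }
  ep_event(ep, "timeout", "explore unfinished")
  FALSE
}

#' Move-before controller
#'
#' With a complete cognitive map, recalls the shape in the room before the
#' target shape's room and traverses the environment checking each room's
#' shape until the recalled predecessor shape is identified, then halts.
#'
#' @param ep internal episode state.
#' @param target `c(color, kind)`.
#' @return `TRUE` when the agent halts (rightly or wrongly), `FALSE` on
#'   timeout, `NA` if the map is incomplete.
#' @keywords internal
move_before_controller <- function(ep, target) {
  map <- ep$agent$cogmap
  if (is.null(map) || !map_complete(map)) {
    ep_event(ep, "command_rejected", "move_before requires a complete map")
    return(NA)
  }
  pred <- suppressWarnings(recall_before(map, target))
  if (is.null(pred)) {
    ep_event(ep, "recall_failure", paste(target, collapse = " "))
    return(NA)
  }
  ep_event(ep, "recalled_predecessor", pred$shape)
  reset_phase(ep)
  present_phase(ep, "start_task")
  checked_here <- FALSE
  while (ep_time_left(ep)) {
    ph <- ep$phase_mirror
    res <- decision_cycle(ep, ph)
    idf <- intersect(res$facts, ID_FACTS)
    if (ph == "identify" && length(idf)) {
      shape <- sub("^id_", "", idf[1])
      ep_event(ep, "checked_shape", paste(ep$current_room, shape))
      if (identical(shape, pred$shape)) {
        present_phase(ep, "task_done")
        ep_event(ep, "halted", ep$current_room)
        return(TRUE)
      }
      present_phase(ep, "identified_done")
      next
    }
    if (!is.null(res$entered_room)) {
      handle_room_entry(ep, res$entered_room, learning = FALSE)
      next
    }
    if (ph == "find_corridor" &&
        !is.na(corridor_at(ep$world, ep$pose$x, ep$pose$y)))
      present_phase(ep, "corridor_entered")
  }
  ep_event(ep, "timeout", "move_before unfinished")
  FALSE
}

# primitive and compound command execution
prim_controller <- function(ep, goal) {
  rec <- run_seg(ep, 10L)
  act <- action_on(rec, window = 10L)
  ok <- identical(act, goal)
  if (!is.null(act)) {
    ep$pose <- apply_action(ep$world, ep$pose, act)
    ep$moves <- ep$moves + 1L
    ep_trace_row(ep, act)
  }
  ep_clear_goals(ep); ep_clear_cycle(ep)
  ok
}

compound_controller <- function(ep, goal) {
  expect <- list(move_left = c("turn_left", "move_forward"),
                 move_right = c("turn_right", "move_forward"))[[goal]]
  acts <- character(0)
  run_seg(ep, 2L, sched_timer_start(ep$agent$comp, 1L))
  for (half in 1:2) {
    rec <- run_seg(ep, 34L)
    act <- action_on(rec, window = 34L)
    if (!is.null(act)) {
      acts <- c(acts, act)
      ep$pose <- apply_action(ep$world, ep$pose, act)
      ep$moves <- ep$moves + 1L
      ep_trace_row(ep, act)
    }
    ep_clear_cycle(ep)
  }
  ep_clear_goals(ep)
  identical(acts, expect)
}

orient_controller <- function(ep, goal, kind = NULL, max_cycles = 60L) {
  for (i in seq_len(max_cycles)) {
    if (!ep_time_left(ep)) break
    frame <- render_frame(ep$world, ep$pose)
    percept <- frame_percept(frame)
    done <- percept$object_present && percept$position == "center" &&
      (goal == "turn_toward" || percept$apparent_size >= 12)
    if (done) { ep_clear_goals(ep); ep_clear_cycle(ep); return(TRUE) }
    decision_cycle(ep, goal, goal_kind = kind)
  }
  ep_clear_goals(ep); ep_clear_cycle(ep)
  FALSE
}

#' Drive the gated fact cascade once
#'
#' Stand-alone version of one decision cycle's fact gating, for testing and
#' inspection: starts the first gating timer and injects the given percept
#' lines; if no fact ignites, the second timer boosts the proprioceptive
#' set, and on continued failure the context's default pathway fires.  The
#' caller is responsible for having a context (phase or goal) assembly
#' ignited; without one, no conjunction can drive an action, and without a
#' timer no fact can ignite no matter the percept drive.
#'
#' @param agent an [assemble_agent()] agent.
#' @param visual_line name of the attended visual percept line (or `NULL`).
#' @param prop_lines character vector of proprioceptive lines active this
#'   cycle.
#' @param arrival frame delivery step within the cycle (default 130, the
#'   regular-mode value).
#' @return list with `facts` (ignited fact assemblies), `action` (ignited
#'   action assembly or `NULL`) and `record` (the spike record).
#' @export
gate_facts <- function(agent, visual_line = NULL, prop_lines = character(0),
                       arrival = 130L) {
  net <- agent$net
  sched1 <- sched_timer_start(agent$gate1, 1L)
  if (!is.null(visual_line)) {
    to <- min(arrival + FRAME_VISIBLE_STEPS - 1L, SEG1_STEPS)
    sched1 <- rbind(sched1, sched_block(net, line_pop(visual_line), 1:5,
                                        arrival:to, CA_IGNITE))
  }
  rec1 <- spike_record(net, run_raw(net, SEG1_STEPS, sched1))
  facts <- facts_on(rec1)
  act <- action_on(rec1)
  recs <- list(rec1)
  if (is.null(act) && !any(facts %in% ID_FACTS)) {
    sched2 <- sched_timer_start(agent$gate2, 1L)
    for (p in prop_lines)
      sched2 <- rbind(sched2, sched_block(net, line_pop(p), 1:5,
                                          1:GATE2_DURATION, CA_IGNITE))
    rec2 <- spike_record(net, run_raw(net, SEG2_STEPS, sched2))
    facts <- union(facts, facts_on(rec2))
    act <- action_on(rec2)
    recs <- c(recs, list(rec2))
  }
  rec <- do.call(rbind, recs)
  attr(rec, "t_end") <- attr(recs[[length(recs)]], "t_end")
  sched <- sched_extinguish_pops(net, c(vapply(PLAN_FACTS, fact_pop, ""),
                                        vapply(PLAN_ACTIONS, act_pop, "")))
  run_raw(net, 8L, sched)
  list(facts = facts, action = act, record = rec)
}

#' Select an action from a context and a fact
#'
#' Stand-alone action selection: ignites the given fact assembly while the
#' context (phase state or goal) assembly is ignited, lets the coincidence
#' detectors drive the action layer, and reads out the single ignited
#' action.  Simultaneously ignited facts are resolved by the action layer's
#' winner-take-all inhibition (first ignition wins; the fixed priority
#' center > left > right is realized by the driver attending one line per
#' cycle).
#'
#' @param agent an [assemble_agent()] agent.
#' @param context a phase name (`"identify"`, `"find_corridor"`,
#'   `"traverse"`) or goal name (`"turn_toward"`, `"approach_box"`, ...).
#' @param fact a fact name from the planning fact set.
#' @return the selected action name, or `NULL` when the pairing drives no
#'   action.
#' @export
select_action <- function(agent, context, fact) {
  net <- agent$net
  ctx_pop <- if (context %in% PLAN_PHASES) paste0("phase.s.", context)
  else goal_pop(context)
  sched <- rbind(sched_block(net, ctx_pop, 1:5, 1L, CA_IGNITE),
                 sched_block(net, fact_pop(fact), 1:5, 1L, CA_IGNITE))
  rec <- spike_record(net, run_raw(net, 20L, sched))
  act <- action_on(rec, window = 20L)
  sched <- rbind(sched_extinguish_pops(net, c(ctx_pop, fact_pop(fact),
                                              vapply(PLAN_ACTIONS, act_pop, ""))))
  run_raw(net, 8L, sched)
  act
}

# read the goal and parameter assemblies ignited right now
read_goals <- function(ep) {
  rec <- run_seg(ep, 5L)
  on <- vapply(c(PLAN_GOALS, PLAN_PARAMS), function(g)
    pop_ignited(rec, goal_pop(g), 5L, 5L), logical(1))
  names(on)[on]
}

#' Run one closed-loop episode
#'
#' Parses each command with the neural parser (igniting the goal assembly
#' through the language-to-planning projections), dispatches to the matching
#' controller, and collects the move trace, event log, per-command outcomes
#' and (optionally) spike records.  An unparseable command aborts the
#' episode with a diagnostic.  For the two-command explore / move-before
#' script, success means the agent halts, within the time budget, in the
#' room that actually precedes the target shape's room in its own
#' exploration order.
#'
#' @param agent an [assemble_agent()] agent (fresh: weights and state are
#'   mutated in place).
#' @param episode an [episode_config()].
#' @return an object of class `cabot_episode`: list with `success`,
#'   `moves`, `completion_s`, `command_results`, `trace`, `events`,
#'   `failure_cause`, `visit_rooms`, `map` (learned pairs), `mode`, `seed`,
#'   and `records` when requested.
#' @export
run_episode <- function(agent, episode = episode_config()) {
  ep <- ep_new(agent, episode)
  fsa_start(agent$phase)          # phase FSA begins in its idle state
  results <- list()
  aborted <- FALSE
  wrong_room <- FALSE
  for (ci in seq_along(episode$commands)) {
    cmd <- episode$commands[ci]
    if (!ep_time_left(ep)) break
    pr <- parse_command(cmd, agent$parser)
    if (!pr$accepted) {
      ep_event(ep, "parse_error", paste0("'", cmd, "': ", pr$reason))
      results[[ci]] <- FALSE; names(results)[ci] <- cmd; aborted <- TRUE
      break
    }
    fsa_reset(agent$parser)      # accept state off; the goal assembly persists
    ep_event(ep, "command", paste(cmd, "->", pr$goal))
    if (ci > 1 && pr$goal == "move_before")
      if (nrow_trace <- length(ep$trace))
        ep$trace[[nrow_trace]]$mark <- "M"
    ok <- switch(pr$goal,
      stop = { ep_clear_goals(ep); TRUE },
      explore = { r <- explore_controller(ep); ep_clear_goals(ep); reset_phase(ep); r },
      move_before = {
        r <- move_before_controller(ep, c(pr$color, pr$kind))
        if (isTRUE(r)) {
          truth_room <- ep$world$shapes$room[
            ep$world$shapes$color == pr$color & ep$world$shapes$kind == pr$kind]
          k <- match(truth_room, ep$visit_rooms)
          correct <- if (is.na(k) || length(ep$visit_rooms) < 4) FALSE else
            identical(ep$current_room, ep$visit_rooms[(k - 2) %% 4 + 1])
          if (!correct) wrong_room <- TRUE
          ep_event(ep, "halt_evaluated",
                   if (correct) "correct room" else "wrong room")
          r <- correct
        }
        ep_clear_goals(ep); reset_phase(ep)
        isTRUE(r)
      },
      turn_toward = { r <- orient_controller(ep, "turn_toward", pr$kind); r },
      approach_box = { r <- orient_controller(ep, "approach_box"); r },
      move_left = , move_right = compound_controller(ep, pr$goal),
      prim_controller(ep, pr$goal))
    results[[ci]] <- isTRUE(ok); names(results)[ci] <- cmd
    if (is.na(ok)) { aborted <- TRUE; break }
  }
  success <- length(results) == length(episode$commands) &&
    all(unlist(results))
  completion_s <- if (success) (ep$net$state$t - ep$t0) / 1000 else NA_real_
  trace <- if (length(ep$trace)) do.call(rbind, ep$trace) else
    data.frame(t = integer(0), x = integer(0), y = integer(0),
               heading = character(0), action = character(0),
               mark = character(0))
  if (nrow(trace)) trace$mark[1] <- ifelse(trace$mark[1] == "", "S", trace$mark[1])
  events <- if (length(ep$events)) do.call(rbind, ep$events) else
    data.frame(t = integer(0), event = character(0), detail = character(0))
  cause <- classify_failure(ep, success, aborted, wrong_room, events, trace)
  out <- list(success = success, moves = ep$moves,
              completion_s = completion_s,
              command_results = results, trace = trace, events = events,
              failure_cause = cause, visit_rooms = ep$visit_rooms,
              map = if (!is.null(agent$cogmap)) map_pairs(agent$cogmap) else NULL,
              mode = episode$mode, seed = episode$seed,
              duration_s = episode$duration_s,
              world = ep$world)
  if (ep$keep) {
    recs <- ep$records
    if (!is.null(agent$cogmap)) recs <- c(recs, agent$cogmap$trace$records)
    out$records <- recs
  }
  class(out) <- "cabot_episode"
  out
}

classify_failure <- function(ep, success, aborted, wrong_room, events, trace) {
  if (success) return(NA_character_)
  if (aborted) return("aborted")
  if (wrong_room || any(events$event == "misidentified") &&
      any(events$event == "halted")) return("misidentification")
  # timeout: circling if the agent's trailing moves loop within one room or
  # shuttle between a single pair of rooms through the same corridor
  if (nrow(trace) > 50) {
    tail_rooms <- vapply(seq(max(1, nrow(trace) - 50), nrow(trace)),
                         function(i) room_at(ep$world, trace$x[i], trace$y[i]) %||%
                           NA_character_, character(1))
    if (length(unique(stats::na.omit(tail_rooms))) <= 2) return("circling")
  }
  if (any(events$event == "misidentified")) return("misidentification")
  "timeout"
}

#' @export
print.cabot_episode <- function(x, ...) {
  cat(sprintf("<cabot_episode> %s mode seed %d: %s, %d moves%s\n",
              x$mode, x$seed, if (x$success) "success" else
                paste0("failure (", x$failure_cause, ")"),
              x$moves,
              if (!is.na(x$completion_s))
                sprintf(", completed at %.1f s", x$completion_s) else ""))
  invisible(x)
}

#' Run a batch of episodes
#'
#' Episode `i` uses seed `base_seed + i` on a freshly assembled agent; the
#' summary is reproducible given `base_seed`.
#'
#' @param config an [agent_config()].
#' @param n number of runs.
#' @param base_seed integer base seed.
#' @param commands,mode,duration_s passed to [episode_config()].
#' @return a `cabot_batch` list: `summary` data frame (one row per run),
#'   `success_count`, `completion_times`, `move_counts`, `causes`.
#' @export
run_batch <- function(config = agent_config(), n = 10, base_seed = 1,
                      commands = episode_config()$commands,
                      mode = "regular", duration_s = 200) {
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    agent <- assemble_agent(config)
    res <- run_episode(agent, episode_config(commands, duration_s, mode,
                                             seed = base_seed + i))
    rows[[i]] <- data.frame(run = i, seed = base_seed + i,
                            success = res$success, moves = res$moves,
                            completion_s = res$completion_s,
                            cause = res$failure_cause %||% NA_character_,
                            stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  structure(list(summary = summary,
                 success_count = sum(summary$success),
                 completion_times = summary$completion_s[summary$success],
                 move_counts = summary$moves,
                 causes = summary$cause[!summary$success]),
            class = "cabot_batch")
}

#' @export
print.cabot_batch <- function(x, ...) {
  cat(sprintf("<cabot_batch> %d/%d successful; median completion %.1f s; moves %d-%d\n",
              x$success_count, nrow(x$summary),
              stats::median(x$completion_times),
              min(x$move_counts), max(x$move_counts)))
  invisible(x)
}

#' Write episode artifacts
#'
#' Writes `result.json`, `trace.tsv`, `map.json`, `events.tsv`, an ASCII
#' trace map, and (when records were kept) `spikes.tsv`.
#'
#' @param result a `cabot_episode`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_episode <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(success = result$success, moves = result$moves,
                            completion_s = result$completion_s,
                            failure_cause = result$failure_cause,
                            mode = result$mode, seed = result$seed,
                            visit_rooms = result$visit_rooms,
                            commands = lapply(result$command_results, isTRUE)),
                       file.path(dir, "result.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  write_trace(result$trace, file.path(dir, "trace.tsv"))
  utils::write.table(result$events, file.path(dir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$map))
    jsonlite::write_json(as.list(setNames(result$map, paste0("room", 1:4))),
                         file.path(dir, "map.json"), auto_unbox = TRUE,
                         na = "null")
  writeLines(format_trace(result$world, result$trace),
             file.path(dir, "trace_map.txt"))
  if (!is.null(result$records))
    write_spikes(do.call(rbind, result$records), file.path(dir, "spikes.tsv"))
  invisible(dir)
}
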