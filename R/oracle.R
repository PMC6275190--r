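# Pure-R reference controller: the same attention, gating, action-selection
# and phase logic as the neural driver, with no neurons.  Used as the
# independent oracle for controller equivalence tests (with perfect
# percepts, the neural agent's room-visit sequence must match).

ORACLE_RULES <- list(
  identify = c(obj_left = "turn_left", obj_right = "turn_right",
               obj_center = "move_forward", wall_ahead = "turn_right"),
  find_corridor = c(corridor_left = "turn_left", corridor_right = "turn_right",
                    corridor_center = "move_forward", wall_ahead = "turn_right"),
  traverse = c(wall_ahead = "turn_right"))
ORACLE_DEFAULTS <- c(identify = "move_forward", find_corridor = "move_forward",
                     traverse = "move_forward")

symbolic_episode <- function(world, commands = episode_config()$commands,
                             max_cycles = 2000L) {
  if (!inherits(world, "cabot_world")) world <- build_world(world)
  ep <- new.env(parent = emptyenv())
  ep$world <- world
  ep$pose <- with(world$start, agent_pose(x, y, heading))
  ep$mem_side <- list()
  ep$current_room <- room_at(world, ep$pose$x, ep$pose$y)
  visit <- ep$current_room
  assoc <- setNames(NA_character_, ep$current_room)
  moves <- 0L
  phase <- "identify"
  target_pred <- NULL
  results <- logical(0)
  for (cmd in commands) {
    pr <- parse_oracle(cmd)
    if (!pr$accepted) { results <- c(results, FALSE); break }
    if (pr$goal == "explore") {
      phase <- "identify"
      done <- FALSE
    } else if (pr$goal == "move_before") {
      if (sum(!is.na(assoc)) < 4) { results <- c(results, FALSE); break }
      tgt <- shape_label(pr$color, pr$kind)
      k <- match(tgt, assoc[visit])
      if (is.na(k)) { results <- c(results, FALSE); break }
      target_pred <- unname(assoc[visit][(k - 2) %% 4 + 1])
      phase <- "identify"
      done <- FALSE
    } else { results <- c(results, TRUE); next }

    for (cyc in seq_len(max_cycles)) {
      percept <- frame_percept(render_frame(world, ep$pose))
      if (phase == "find_corridor" && percept$corridor_present &&
          !is.null(ep$last_corridor)) {
        seen <- visible_corridors(world, ep$pose)
        if (length(seen) && all(seen == ep$last_corridor)) {
          percept$corridor_present <- FALSE
          percept$corridor_position <- NA_character_
        }
      }
      vis <- attend_visual(ep, phase, percept)
      if (!is.null(vis) && grepl("_center$", vis) &&
          wall_ahead_geom(world, ep$pose)) vis <- NULL
      act <- NULL
      if (!is.null(vis) && grepl("^id_", vis)) {
        shape <- sub("^id_", "", vis)
        if (is.null(target_pred)) {          # exploring
          if (is.na(assoc[ep$current_room])) assoc[ep$current_room] <- shape
          if (sum(!is.na(assoc)) >= 4) { done <- TRUE; break }
          phase <- "find_corridor"
        } else {                              # checking
          if (identical(shape, target_pred)) { done <- TRUE; break }
          phase <- "find_corridor"
        }
        next
      }
      if (!is.null(vis)) {
        act <- unname(ORACLE_RULES[[phase]][vis])
      } else if (wall_ahead_geom(world, ep$pose)) {
        act <- "turn_right"
      } else {
        act <- unname(ORACLE_DEFAULTS[phase])
      }
      if (is.na(act) || is.null(act)) act <- unname(ORACLE_DEFAULTS[phase])
      if (act %in% c("turn_left", "turn_right")) ep$mem_side <- list()
      old_corr <- corridor_at(world, ep$pose$x, ep$pose$y)
      ep$pose <- apply_action(world, ep$pose, act)
      moves <- moves + 1L
      room <- room_at(world, ep$pose$x, ep$pose$y)
      if (!is.na(room) && !identical(room, ep$current_room)) {
        if (!is.na(old_corr)) ep$last_corridor <- old_corr
        ep$current_room <- room
        if (is.null(target_pred) && !room %in% visit) {
          visit <- c(visit, room)
          if (is.na(match(room, names(assoc)))) assoc[room] <- NA_character_
        }
        phase <- "identify"
        next
      }
      if (phase == "find_corridor" &&
          !is.na(corridor_at(world, ep$pose$x, ep$pose$y)))
        phase <- "traverse"
    }
    results <- c(results, isTRUE(done))
    if (!isTRUE(done)) break
  }
  list(success = length(results) == length(commands) && all(results),
       visit_rooms = visit, assoc = assoc, moves = moves,
       final_room = ep$current_room)
}
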