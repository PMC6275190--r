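# Spatial cognitive map: four room assemblies, four shape assemblies (one
# per colour-kind pair) and a start marker, all-to-all plastic projections
# among them, learned by the STDP rule during exploration.  Gating keeps at
# most one room and one shape assembly active at any checkpoint; retrieval
# opens one pool at a time with a sub-threshold gate boost so that only a
# learned association can ignite its target.

MAP_SHAPES <- c("red_pyramid", "blue_pyramid", "red_stalactite",
                "blue_stalactite")
# Member neurons integrate sustained input with steady-state gain
# 1/(1 - membrane_decay) = 1.25, so a fully learned block drive of
# 5 * w_max = 0.6 settles at 0.75: below threshold on its own, above it
# with the 0.35 gate boost.  Unlearned drive (0.25) stays far below even
# when boosted.
MAP_W0 <- 0.02          # initial plastic weight
MAP_WMAX <- 0.12        # bound: integrated 5*w_max stays sub-threshold
MAP_BOOST <- 0.35       # retrieval gate boost per member per step
MAP_RECALL_THR <- 0.10  # pair mean weight above which recall succeeds

shape_label <- function(color, kind) paste(color, kind, sep = "_")

#' Build a cognitive map on a network
#'
#' Adds the room, shape and start-marker assemblies and the plastic
#' projections among them (rooms to shapes, shapes to rooms, room-sequence
#' links, start marker to rooms).  Weights start low; one co-ignition
#' window under the STDP rule drives a pair above the recall threshold.
#'
#' @param net a [network()].
#' @param id population id prefix.
#' @return an object of class `cabot_cogmap`.
#' @export
build_cogmap <- function(net, id = "map") {
  rooms_pop <- paste0(id, ".rooms"); shapes_pop <- paste0(id, ".shapes")
  start_pop <- paste0(id, ".start")
  add_population(net, rooms_pop, 20L, ca_params())
  add_population(net, shapes_pop, 20L, ca_params())
  add_population(net, start_pop, 5L, ca_params())
  block <- function(i) (i - 1L) * 5L + 1:5
  # intra-assembly wiring inside each 5-neuron block
  for (pop in c(rooms_pop, shapes_pop)) {
    pre <- integer(0); post <- integer(0)
    for (b in 1:4) for (i in block(b)) for (j in setdiff(block(b), i)) {
      pre <- c(pre, i); post <- c(post, j)
    }
    add_projection(net, paste0(pop, ".intra"), pop, pop, pre, post, CA_INTRA_W)
  }
  add_projection(net, paste0(start_pop, ".intra"), start_pop, start_pop,
                 rep(1:5, each = 4),
                 unlist(lapply(1:5, function(i) setdiff(1:5, i))), CA_INTRA_W)
  all_cross <- function() {
    g <- expand.grid(pre = 1:20, post = 1:20)
    g[((g$pre - 1) %/% 5) != ((g$post - 1) %/% 5), ]   # across blocks only
  }
  g <- expand.grid(pre = 1:20, post = 1:20)
  add_projection(net, paste0(id, ".rs"), rooms_pop, shapes_pop,
                 g$pre, g$post, MAP_W0, 1L, "stdp_hebbian", MAP_WMAX)
  add_projection(net, paste0(id, ".sr"), shapes_pop, rooms_pop,
                 g$pre, g$post, MAP_W0, 1L, "stdp_hebbian", MAP_WMAX)
  gc <- all_cross()
  add_projection(net, paste0(id, ".rr"), rooms_pop, rooms_pop,
                 gc$pre, gc$post, MAP_W0, 1L, "stdp_hebbian", MAP_WMAX)
  g2 <- expand.grid(pre = 1:5, post = 1:20)
  add_projection(net, paste0(id, ".or"), start_pop, rooms_pop,
                 g2$pre, g2$post, MAP_W0, 1L, "stdp_hebbian", MAP_WMAX)
  trace <- new.env(parent = emptyenv())
  trace$keep <- FALSE; trace$records <- list()
  structure(list(net = net, id = id, rooms_pop = rooms_pop,
                 shapes_pop = shapes_pop, start_pop = start_pop,
                 stdp = stdp_params(), trace = trace),
            class = "cabot_cogmap")
}

map_block <- function(i) (i - 1L) * 5L + 1:5
map_shape_index <- function(shape) match(shape, MAP_SHAPES)

sched_pool <- function(map, pop, block_i, steps, val)
  sched_block(map$net, pop, map_block(block_i), steps, val)

extinguish_map <- function(map, settle = 6L) {
  sched <- rbind(
    sched_block(map$net, map$rooms_pop, 1:20, 1:3, CA_EXTINGUISH),
    sched_block(map$net, map$shapes_pop, 1:20, 1:3, CA_EXTINGUISH),
    sched_block(map$net, map$start_pop, 1:5, 1:3, CA_EXTINGUISH))
  run_raw(map$net, settle, sched)
  invisible(map)
}

map_note <- function(map, rec) {
  if (isTRUE(map$trace$keep))
    map$trace$records[[length(map$trace$records) + 1L]] <- rec
  rec
}

# which 5-neuron block of a pool is ignited in the record's final window
ignited_block <- function(map, pop, record, window = 6L) {
  which(vapply(1:4, function(b)
    pop_ignited(record, pop, 20L, window, members = map_block(b)), logical(1)))
}

#' Mean learned weight between a room and a shape assembly
#'
#' @param map a `cabot_cogmap`.
#' @param room room index (1..4, exploration order).
#' @param shape a shape label (`"red_pyramid"`, ...).
#' @return mean synaptic weight of the room-to-shape block.
#' @export
map_weight <- function(map, room, shape) {
  projection_weight(map$net, paste0(map$id, ".rs"),
                    pre = map_block(room), post = map_block(map_shape_index(shape)))
}

#' Associate a room with a shape
#'
#' Co-ignites the room and shape assemblies for a fixed learning window and
#' applies the STDP rule to the plastic projections, driving the pair's
#' weights above the recall threshold while leaving all other pairings
#' unchanged.  Once the map is complete the operation is a no-op (the agent
#' can only explore once); a gating violation (another map assembly still
#' ignited when called) is an error.
#'
#' @param map a `cabot_cogmap`.
#' @param room room index in exploration order (1..4).
#' @param shape shape label or `c(color, kind)`.
#' @param window co-ignition window in steps.
#' @return `TRUE` if an association was learned, `FALSE` if the map was
#'   already complete, invisibly.
#' @export
associate <- function(map, room, shape, window = 40L) {
  if (length(shape) == 2) shape <- shape_label(shape[1], shape[2])
  si <- map_shape_index(shape)
  if (is.na(si)) stop("input error: unknown shape '", shape, "'")
  if (map_complete(map)) return(invisible(FALSE))
  probe <- spike_record(map$net, run_raw(map$net, 6L))
  if (length(ignited_block(map, map$rooms_pop, probe)) ||
      length(ignited_block(map, map$shapes_pop, probe)))
    stop("gating violation: another room or shape assembly is still ignited")
  sched <- rbind(sched_pool(map, map$rooms_pop, room, 1L, CA_IGNITE),
                 sched_pool(map, map$shapes_pop, si, 1L, CA_IGNITE))
  rec <- map_note(map, spike_record(map$net, run_raw(map$net, window, sched)))
  apply_plasticity(map$net, paste0(map$id, ".rs"), rec, rec, map$stdp)
  apply_plasticity(map$net, paste0(map$id, ".sr"), rec, rec, map$stdp)
  extinguish_map(map)
  invisible(TRUE)
}

# learn a directed room-sequence link (or start -> first room) by ordered
# ignition: the earlier assembly fires before the later one, so the STDP
# rule potentiates the forward link and depresses the backward one
learn_sequence <- function(map, from_room, to_room, lead = 20L) {
  from_sched <- if (identical(from_room, "start"))
    sched_block(map$net, map$start_pop, 1:5, 1L, CA_IGNITE)
  else sched_pool(map, map$rooms_pop, from_room, 1L, CA_IGNITE)
  ext <- if (identical(from_room, "start"))
    sched_block(map$net, map$start_pop, 1:5, lead + 1:3, CA_EXTINGUISH)
  else sched_pool(map, map$rooms_pop, from_room, lead + 1:3, CA_EXTINGUISH)
  sched <- rbind(from_sched, ext,
                 sched_pool(map, map$rooms_pop, to_room, lead + 5L, CA_IGNITE))
  rec <- map_note(map, spike_record(map$net, run_raw(map$net, lead + 25L, sched)))
  proj <- if (identical(from_room, "start")) paste0(map$id, ".or")
          else paste0(map$id, ".rr")
  apply_plasticity(map$net, proj, rec, rec, map$stdp)
  extinguish_map(map)
  invisible(map)
}

#' Is the cognitive map complete?
#'
#' `TRUE` iff every room has a shape association whose mean weight exceeds
#' the recall threshold.
#'
#' @param map a `cabot_cogmap`.
#' @return logical flag.
#' @export
map_complete <- function(map) {
  all(vapply(1:4, function(r)
    max(vapply(MAP_SHAPES, function(s) map_weight(map, r, s), numeric(1))) >
      MAP_RECALL_THR, logical(1)))
}

#' Read the learned room-to-shape assignment
#'
#' @param map a `cabot_cogmap`.
#' @return character vector of length 4: the argmax shape label per room
#'   (NA where no association exceeds the recall threshold).
#' @export
map_pairs <- function(map) {
  vapply(1:4, function(r) {
    w <- vapply(MAP_SHAPES, function(s) map_weight(map, r, s), numeric(1))
    if (max(w) > MAP_RECALL_THR) MAP_SHAPES[which.max(w)] else NA_character_
  }, character(1))
}

#' Recall the shape in the room before a target shape
#'
#' Gated neural retrieval: the start marker is ignited and the gate opens
#' the room pool, igniting the first room; the scan then alternates between
#' opening the shape pool (retrieving the active room's learned shape) and
#' stepping to the next room along the learned sequence links, never letting
#' two rooms or two shapes be active at a checkpoint.  When the retrieved
#' shape matches the target, the shape retrieved in the previous room is the
#' answer; it is re-ignited as the final state of the map.
#'
#' @param map a `cabot_cogmap`.
#' @param target shape label or `c(color, kind)`.
#' @return list with `color`, `kind`, `shape` (label) and `sequence` (the
#'   four retrieved labels in scan order), or `NULL` with a warning when the
#'   map is incomplete or the target is never retrieved (recall failure).
#' @export
recall_before <- function(map, target) {
  if (length(target) == 2) target <- shape_label(target[1], target[2])
  if (!map_complete(map)) {
    warning("recall failure: cognitive map incomplete")
    return(NULL)
  }
  extinguish_map(map)
  # a single-step gate boost, applied only after the source assembly's drive
  # has integrated: a sustained boost would let retrieval chain two sequence
  # links at once
  gate <- function(pop, at = 8L)
    sched_block(map$net, pop, 1:20, at, MAP_BOOST)
  # stage 1: start marker + room gate -> first room ignites
  sched <- rbind(sched_block(map$net, map$start_pop, 1:5, 1L, CA_IGNITE),
                 gate(map$rooms_pop),
                 sched_block(map$net, map$start_pop, 1:5, 21:23, CA_EXTINGUISH))
  rec <- map_note(map, spike_record(map$net, run_raw(map$net, 26L, sched)))
  room <- ignited_block(map, map$rooms_pop, rec)
  if (length(room) != 1) { warning("recall failure: no unique first room"); return(NULL) }
  shapes_seen <- character(0)
  for (i in 1:4) {
    # open the shape pool: the active room retrieves its shape
    rec <- map_note(map, spike_record(map$net, run_raw(map$net, 26L, gate(map$shapes_pop))))
    sh <- ignited_block(map, map$shapes_pop, rec)
    if (length(sh) != 1) { warning("recall failure: no unique shape for room ", i); return(NULL) }
    shapes_seen <- c(shapes_seen, MAP_SHAPES[sh])
    # close the shape pool again
    run_raw(map$net, 8L, sched_pool(map, map$shapes_pop, sh, 1:3, CA_EXTINGUISH))
    if (i < 4) {
      # step to the next room along the sequence links, then release the old
      sched <- rbind(gate(map$rooms_pop),
                     sched_pool(map, map$rooms_pop, room, 11:13, CA_EXTINGUISH))
      rec <- map_note(map, spike_record(map$net, run_raw(map$net, 26L, sched)))
      nxt <- setdiff(ignited_block(map, map$rooms_pop, rec), room)
      if (length(nxt) != 1) { warning("recall failure: no unique successor room"); return(NULL) }
      room <- nxt
    }
  }
  extinguish_map(map)
  k <- match(target, shapes_seen)
  if (is.na(k)) { warning("recall failure: target shape not in map"); return(NULL) }
  ans <- shapes_seen[(k - 2) %% 4 + 1]
  # final state: the answer shape assembly ignited
  run_raw(map$net, 6L,
          sched_pool(map, map$shapes_pop, match(ans, MAP_SHAPES), 1L, CA_IGNITE))
  parts <- strsplit(ans, "_")[[1]]
  list(color = parts[1], kind = parts[2], shape = ans, sequence = shapes_seen)
}
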