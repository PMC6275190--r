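# The planning subsystem: gated facts, action selection, and the explore /
# move-before controllers.  Network-level properties are checked on full
# spike records; controller behavior against the pure-R reference
# controller.

agent_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- assemble_agent()
    cache
  }
})

test_that("percept lines alone never ignite a fact (gating soundness)", {
  agent <- assemble_agent()
  net <- agent$net
  # drive the obj_left line hard for a long time, with no gating timer
  sched <- cabot:::sched_block(net, "line.obj_left", 1:5, 1:300, 1.3)
  rec <- cabot:::spike_record(net, cabot:::run_raw(net, 320, sched))
  expect_false(cabot:::pop_ignited(rec, "fact.obj_left", 5, 300))
  # with the gating timer, the same drive ignites the fact in the tap window
  out <- gate_facts(agent, visual_line = "obj_left")
  expect_true("obj_left" %in% out$facts)
  steps <- out$record$step[out$record$population == "fact.obj_left"]
  t0 <- min(out$record$step) - 1
  expect_gte(min(steps) - t0, 101)   # inside the first tap window
  expect_lte(min(steps) - t0, 140)
})

test_that("a late frame misses the visual tap and falls through to the default", {
  agent <- agent_fixture()
  # context: identify phase ignited
  cabot:::run_raw(agent$net, 3,
                  cabot:::sched_block(agent$net, "phase.s.identify", 1:5, 1,
                                      cabot:::CA_IGNITE))
  hit <- gate_facts(agent, visual_line = "obj_right", arrival = 130L)
  expect_true("obj_right" %in% hit$facts)
  expect_equal(hit$action, "turn_right")
  miss <- gate_facts(agent, visual_line = "obj_right", arrival = 145L)
  expect_false("obj_right" %in% miss$facts)
  expect_equal(miss$action, "move_forward")   # identify-phase default
  # no stimulation at all through both timers: default action fires
  none <- gate_facts(agent)
  expect_length(none$facts, 0)
  expect_equal(none$action, "move_forward")
  cabot:::run_raw(agent$net, 8, cabot:::sched_extinguish_pops(
    agent$net, "phase.s.identify"))
})

test_that("proprioceptive facts are boosted by the second timer", {
  agent <- agent_fixture()
  out <- gate_facts(agent, prop_lines = c("wall_ahead", "in_corridor"))
  expect_true(all(c("wall_ahead", "in_corridor") %in% out$facts))
})

test_that("the action mapping matches its table, one action per pairing", {
  agent <- agent_fixture()
  cases <- list(
    c("identify", "obj_left", "turn_left"),
    c("identify", "obj_right", "turn_right"),
    c("identify", "obj_center", "move_forward"),
    c("find_corridor", "corridor_left", "turn_left"),
    c("find_corridor", "corridor_center", "move_forward"),
    c("traverse", "wall_ahead", "turn_right"),
    c("turn_toward", "obj_left", "turn_left"),
    c("turn_toward", "obj_right", "turn_right"))
  for (cs in cases)
    expect_equal(select_action(agent, cs[1], cs[2]), cs[3],
                 info = paste(cs[1], cs[2]))
  # pairings with no wired consequence select nothing
  expect_null(select_action(agent, "identify", "room_entered"))
  expect_null(select_action(agent, "traverse", "obj_left"))
})

test_that("goal assemblies drive primitive actions directly", {
  agent <- agent_fixture()
  for (a in cabot:::PLAN_ACTIONS) {
    net <- agent$net
    cabot:::run_raw(net, 2, cabot:::sched_block(net, cabot:::goal_pop(a),
                                                1:5, 1, cabot:::CA_IGNITE))
    rec <- cabot:::spike_record(net, cabot:::run_raw(net, 10))
    expect_equal(cabot:::action_on(rec, 10), a)
    cabot:::run_raw(net, 8, cabot:::sched_extinguish_pops(
      net, c(cabot:::goal_pop(a), vapply(cabot:::PLAN_ACTIONS,
                                         cabot:::act_pop, ""))))
  }
})

test_that("no decision cycle emits two actions (single-action invariant)", {
  agent <- assemble_agent(agent_config(p_drop = 0))
  res <- run_episode(agent, episode_config("explore", duration_s = 40,
                                           seed = 2, record = "full"))
  acts <- vapply(cabot:::PLAN_ACTIONS, cabot:::act_pop, "")
  for (rec in res$records) {
    on <- vapply(acts, function(p) cabot:::pop_ignited(rec, p, 5, 6),
                 logical(1))
    expect_lte(sum(on), 1)
  }
  expect_gt(res$moves, 10)
})

test_that("facts only ignite inside gating-timer windows over a full episode", {
  agent <- assemble_agent(agent_config(p_drop = 0))
  res <- run_episode(agent, episode_config("explore", duration_s = 30,
                                           seed = 2, record = "full"))
  all_rec <- do.call(rbind, res$records)
  tap1 <- all_rec$population == "gate1" & all_rec$neuron %in% 101:135
  tap2 <- all_rec$population == "gate2" & all_rec$neuron %in% 1:35
  gate_steps <- sort(unique(all_rec$step[tap1 | tap2]))
  fact_pops <- vapply(cabot:::PLAN_FACTS, cabot:::fact_pop, "")
  onsets <- tapply(all_rec$step[all_rec$population %in% fact_pops],
                   all_rec$population[all_rec$population %in% fact_pops],
                   min)
  for (t in onsets) {
    # a fact's first spike must coincide with an active gating tap (+-2 ms)
    expect_true(any(abs(gate_steps - t) <= 2),
                info = paste("fact onset at", t))
  }
})

test_that("the neural controller's room-visit sequence matches the reference controller", {
  for (ws in c(1, 2, 3)) {
    agent <- assemble_agent(agent_config(world = ws, p_drop = 0))
    neural <- run_episode(agent, episode_config("explore", duration_s = 200,
                                                seed = 1))
    symbolic <- cabot:::symbolic_episode(build_world(ws), "explore")
    expect_true(neural$success, info = paste("world", ws))
    expect_equal(neural$visit_rooms, symbolic$visit_rooms,
                 info = paste("world", ws))
  }
})

test_that("a successful explore uses well over one hundred primitive moves", {
  agent <- assemble_agent(agent_config(p_drop = 0))
  res <- run_episode(agent, episode_config("explore", duration_s = 200,
                                           seed = 3))
  expect_true(res$success)
  expect_gt(res$moves, 100)
})
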