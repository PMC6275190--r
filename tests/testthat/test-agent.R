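test_that("assembly is deterministic and reports per-subsystem counts", {
  a1 <- assemble_agent()
  a2 <- assemble_agent()
  expect_identical(network_signature(a1$net), network_signature(a2$net))
  counts <- subsystem_counts(a1)
  expect_equal(unname(counts["vision"]), 1200)   # 20x20x3 retina
  expect_gt(counts["language"], 0)
  expect_gt(counts["planning"], 0)
  expect_gt(counts["cogmap"], 0)
  expect_equal(unname(counts["total"]), a1$net$n)
})

test_that("an agent without the cogmap rejects explore but runs primitives", {
  agent <- assemble_agent(agent_config(subsystems = c("vision", "language",
                                                      "planning")))
  res <- run_episode(agent, episode_config("move forward", duration_s = 5,
                                           seed = 1))
  expect_true(res$success)
  res2 <- run_episode(agent, episode_config("explore", duration_s = 5,
                                            seed = 1))
  expect_false(res2$success)
  expect_true(any(res2$events$event == "command_rejected"))
})

test_that("an empty script is a vacuous success and bad commands abort", {
  agent <- assemble_agent()
  res <- run_episode(agent, episode_config(character(0), duration_s = 2,
                                           seed = 1))
  expect_true(res$success)
  expect_equal(res$moves, 0)
  res2 <- run_episode(assemble_agent(),
                      episode_config("flip the pancake", duration_s = 2,
                                     seed = 1))
  expect_false(res2$success)
  expect_equal(res2$failure_cause, "aborted")
  expect_true(any(res2$events$event == "parse_error"))
})

test_that("identical seeds reproduce an episode exactly; jitter diversifies", {
  r1 <- run_episode(assemble_agent(),
                    episode_config("explore", duration_s = 25, seed = 9))
  r2 <- run_episode(assemble_agent(),
                    episode_config("explore", duration_s = 25, seed = 9))
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$events, r2$events)
  # distinct seeds under jittered timing give distinct traces
  j1 <- run_episode(assemble_agent(),
                    episode_config("explore", duration_s = 25, seed = 9,
                                   mode = "jittered"))
  j2 <- run_episode(assemble_agent(),
                    episode_config("explore", duration_s = 25, seed = 10,
                                   mode = "jittered"))
  expect_false(identical(j1$trace$action, j2$trace$action))
})

test_that("every environment change corresponds to one ignited action assembly", {
  agent <- assemble_agent(agent_config(p_drop = 0))
  res <- run_episode(agent, episode_config("explore", duration_s = 20,
                                           seed = 4, record = "full"))
  expect_gt(res$moves, 5)
  all_rec <- do.call(rbind, res$records)
  for (a in cabot:::PLAN_ACTIONS) {
    traced <- sum(res$trace$action == a)
    # count distinct ignition episodes of the action assembly: runs of
    # firing separated by silence
    st <- sort(unique(all_rec$step[all_rec$population == cabot:::act_pop(a)]))
    ignitions <- if (!length(st)) 0 else sum(diff(c(-10, st)) > 5)
    expect_equal(ignitions, traced, info = a)
  }
})

test_that("turn_toward centres the named shape", {
  # stand in the SE room, stalactite to the east: agent must end facing it
  cfg <- agent_config(p_drop = 0)
  agent <- assemble_agent(cfg)
  ep_cfg <- episode_config("turn toward the stalactite", duration_s = 30,
                           seed = 1)
  ep <- cabot:::ep_new(agent, ep_cfg)
  ep$pose <- agent_pose(15, 18, "S")   # shape at (18, 18): to the left
  fsa_start(agent$phase)
  pr <- parse_command("turn toward the stalactite", agent$parser)
  fsa_reset(agent$parser)
  ok <- cabot:::orient_controller(ep, "turn_toward", pr$kind)
  expect_true(ok)
  pc <- frame_percept(render_frame(ep$world, ep$pose))
  expect_true(pc$object_present)
  expect_equal(pc$position, "center")
})

test_that("batches are reproducible and a single run matches run_episode", {
  b1 <- run_batch(n = 2, base_seed = 50, commands = "move left",
                  duration_s = 5)
  b2 <- run_batch(n = 2, base_seed = 50, commands = "move left",
                  duration_s = 5)
  expect_identical(b1$summary, b2$summary)
  single <- run_episode(assemble_agent(),
                        episode_config("move left", duration_s = 5,
                                       seed = 51))
  expect_equal(b1$summary$success[1], single$success)
  expect_equal(b1$summary$moves[1], single$moves)
  expect_equal(b1$summary$completion_s[1], single$completion_s)
})

test_that("the agent explores once; later move commands keep working", {
  agent <- assemble_agent(agent_config(p_drop = 0))
  res <- run_episode(agent, episode_config(
    c("explore", "explore",
      "move to the room before the room with the red stalactite",
      "move to the room before the room with the blue pyramid"),
    duration_s = 200, seed = 1))
  expect_true(res$success)
  # the second explore is ignored (the map cannot be relearned) ...
  expect_true(any(res$events$event == "explore_ignored"))
  expect_equal(sum(res$events$event == "explore_complete"), 1)
  # ... and both move commands executed and were evaluated
  expect_equal(sum(res$events$event == "halt_evaluated"), 2)
})

test_that("episode artifacts are written as plain-text files", {
  agent <- assemble_agent()
  res <- run_episode(agent, episode_config("move left", duration_s = 5,
                                           seed = 1))
  dir <- tempfile()
  write_episode(res, dir)
  expect_true(file.exists(file.path(dir, "result.json")))
  expect_true(file.exists(file.path(dir, "trace.tsv")))
  expect_true(file.exists(file.path(dir, "trace_map.txt")))
  js <- jsonlite::read_json(file.path(dir, "result.json"))
  expect_true(js$success)
  expect_equal(js$moves, 2)
})

test_that("network and world configurations round-trip through YAML", {
  path <- system.file("extdata", "example-network.yaml", package = "cabot")
  skip_if(path == "", "example config not installed")
  net <- read_network_config(path)
  expect_equal(net$n, 10)
  expect_equal(net$projections$ba$plasticity, "stdp_hebbian")
  wpath <- tempfile(fileext = ".yaml")
  write_world_config(world_spec(), wpath)
  w <- read_world_config(wpath)
  expect_s3_class(w, "cabot_world")
  expect_identical(w$shapes$room, build_world()$shapes$room)
})
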