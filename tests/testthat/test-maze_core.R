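test_that("default configuration carries the printed apparatus values", {
  cfg <- default_maze_config()
  expect_identical(cfg$n_arms, 8L)
  expect_equal(cfg$arm_length, 46)
  expect_equal(cfg$arm_width, 9)
  expect_equal(cfg$center_diameter, 28)
  expect_equal(cfg$session_duration, 600)
  expect_equal(cfg$center_timeout, 20)
  expect_equal(cfg$pellet_mass, 20)
  expect_equal(cfg$light_intensity, 400)
  counts <- table(cfg$arm_roles)
  expect_true(all(counts[c("POSITIVE", "NEGATIVE",
                           "NEAR_POSITIVE", "NEAR_NEGATIVE")] == 2))
})

test_that("role-layout invariants are enforced", {
  # positive pair not adjacent
  expect_error(maze_config(arm_roles = c(
    "POSITIVE", "NEAR_POSITIVE", "POSITIVE", "NEAR_NEGATIVE",
    "NEGATIVE", "NEGATIVE", "NEAR_NEGATIVE", "NEAR_POSITIVE")),
    "adjacent")
  # negatives not opposite the positives
  expect_error(maze_config(arm_roles = c(
    "POSITIVE", "POSITIVE", "NEGATIVE", "NEGATIVE",
    "NEAR_POSITIVE", "NEAR_NEGATIVE", "NEAR_NEGATIVE", "NEAR_POSITIVE")),
    "opposite")
  # wrong multiset
  expect_error(maze_config(arm_roles = rep("POSITIVE", 8)), "exactly")
  # bad end zone
  expect_error(maze_config(end_zone_length = 0), "end_zone_length")
  expect_error(maze_config(end_zone_length = 50), "end_zone_length")
  # rotations of the default layout are all valid
  for (shift in 0:7) {
    roles <- default_arm_roles()[(((0:7) + shift) %% 8) + 1]
    expect_s3_class(maze_config(arm_roles = roles), "maze_config")
  }
})

test_that("open_arms distinguishes training from test", {
  cfg <- default_maze_config()
  tr <- open_arms("TRAINING", cfg)
  expect_setequal(tr, c(arms_with_role("POSITIVE", cfg),
                        arms_with_role("NEGATIVE", cfg)))
  expect_identical(open_arms("TEST", cfg), 0:7)
})

test_that("configuration round-trips through the JSON config file", {
  cfg <- maze_config(end_zone_length = 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_maze_config(cfg, path)
  expect_equal(read_maze_config(path), cfg)
})

# --- contingency engine: the five worked transition examples -----------

step_seq <- function(events, config, mode = "TEST") {
  replay_contingencies(events, config, mode)
}

test_that("session starts with the overhead light on", {
  cfg <- default_maze_config()
  st <- contingency_step(initial_contingency_state(),
                         maze_event(0, "SESSION_START"), cfg)
  expect_true(st$state$light_on)
})

test_that("reaching a positive arm end turns the light off and dispenses", {
  cfg <- default_maze_config()
  pos <- arms_with_role("POSITIVE", cfg)[1]
  r <- step_seq(rbind(
    maze_event(0, "SESSION_START"),
    maze_event(5, "ENTER_ARM", pos),
    maze_event(8, "REACH_END", pos)), cfg)
  expect_false(r$state$light_on)
  expect_identical(r$state$pellets_dispensed, 1L)
  acts <- r$log$action[r$log$time == 8]
  expect_setequal(acts, c("LIGHT_OFF", "DISPENSE_PELLET"))
})

test_that("negative arm: entry restores light, end triggers noise until exit", {
  cfg <- default_maze_config()
  pos <- arms_with_role("POSITIVE", cfg)[1]
  neg <- arms_with_role("NEGATIVE", cfg)[1]
  ev <- rbind(
    maze_event(0, "SESSION_START"),
    maze_event(2, "ENTER_ARM", pos),
    maze_event(4, "REACH_END", pos),   # light now off
    maze_event(6, "EXIT_ARM", pos),
    maze_event(7, "ENTER_CENTER"),
    maze_event(9, "ENTER_ARM", neg),
    maze_event(11, "REACH_END", neg),
    maze_event(14, "EXIT_ARM", neg))
  r <- step_seq(ev, cfg)
  expect_identical(r$log$action[r$log$time == 9], "LIGHT_ON")
  expect_identical(r$log$action[r$log$time == 11], "NOISE_ON")
  expect_identical(r$log$action[r$log$time == 14], "NOISE_OFF")
  expect_true(r$state$light_on)   # light stays on after noise stops
  expect_false(r$state$noise_on)
})

test_that("20-s centre dwell after leaving a positive arm restores the light", {
  cfg <- default_maze_config()
  pos <- arms_with_role("POSITIVE", cfg)
  ev <- rbind(
    maze_event(0, "SESSION_START"),
    maze_event(2, "ENTER_ARM", pos[1]),
    maze_event(4, "REACH_END", pos[1]),
    maze_event(6, "EXIT_ARM", pos[1]),
    maze_event(7, "ENTER_CENTER"),
    maze_event(40, "SESSION_END"))
  r <- step_seq(ev, cfg)
  on_row <- r$log[r$log$action == "LIGHT_ON" & r$log$time > 0, ]
  expect_equal(on_row$time, 27)  # armed at 7, expires 20 s later
  expect_true(r$state$light_on)

  # cancelled by re-entering an arm before expiry; light stays off
  ev2 <- rbind(
    maze_event(0, "SESSION_START"),
    maze_event(2, "ENTER_ARM", pos[1]),
    maze_event(4, "REACH_END", pos[1]),
    maze_event(6, "EXIT_ARM", pos[1]),
    maze_event(7, "ENTER_CENTER"),
    maze_event(15, "ENTER_ARM", pos[2]),
    maze_event(60, "SESSION_END"))
  r2 <- step_seq(ev2, cfg)
  expect_false(r2$state$light_on)
  expect_false(any(r2$log$action == "LIGHT_ON" & r2$log$time > 0))
})

test_that("ambiguous arms trigger nothing in TEST mode", {
  cfg <- default_maze_config()
  nn <- arms_with_role("NEAR_NEGATIVE", cfg)[1]
  ev <- rbind(
    maze_event(0, "SESSION_START"),
    maze_event(2, "ENTER_ARM", nn),
    maze_event(4, "REACH_END", nn),
    maze_event(6, "EXIT_ARM", nn))
  r <- step_seq(ev, cfg, mode = "TEST")
  expect_identical(nrow(r$log), 1L)  # only the session-start LIGHT_ON
  expect_identical(r$state$pellets_dispensed, 0L)
  expect_false(r$state$noise_on)
})

# --- contingency engine: invariants ------------------------------------

test_that("training mode rejects ambiguous-arm events", {
  cfg <- default_maze_config()
  np <- arms_with_role("NEAR_POSITIVE", cfg)[1]
  ev <- rbind(maze_event(0, "SESSION_START"), maze_event(2, "ENTER_ARM", np))
  expect_error(step_seq(ev, cfg, mode = "TRAINING"), "ambiguous")
})

test_that("inconsistent event order raises a protocol error naming the event", {
  cfg <- default_maze_config()
  expect_error(step_seq(rbind(maze_event(0, "SESSION_START"),
                              maze_event(1, "REACH_END", 0L)), cfg),
               "t=1.*REACH_END")
  expect_error(step_seq(rbind(maze_event(0, "SESSION_START"),
                              maze_event(1, "EXIT_ARM", 0L)), cfg),
               "EXIT_ARM without")
  expect_error(step_seq(rbind(maze_event(0, "SESSION_START"),
                              maze_event(1, "ENTER_ARM", 0L),
                              maze_event(2, "ENTER_ARM", 1L)), cfg),
               "while still in arm")
  expect_error(step_seq(rbind(maze_event(5, "SESSION_START"),
                              maze_event(1, "ENTER_ARM", 0L)), cfg),
               "out of order")
})

test_that("only the first REACH_END per visit triggers actions", {
  cfg <- default_maze_config()
  pos <- arms_with_role("POSITIVE", cfg)[1]
  ev <- rbind(
    maze_event(0, "SESSION_START"),
    maze_event(2, "ENTER_ARM", pos),
    maze_event(4, "REACH_END", pos),
    maze_event(5, "REACH_END", pos),   # same visit: no-op
    maze_event(6, "EXIT_ARM", pos),
    maze_event(7, "ENTER_CENTER"),
    maze_event(8, "ENTER_ARM", pos),
    maze_event(9, "REACH_END", pos))   # new visit: dispenses again
  r <- step_seq(ev, cfg)
  expect_identical(r$state$pellets_dispensed, 2L)
  expect_identical(sum(r$log$action == "DISPENSE_PELLET"), 2L)
})

test_that("replay is a pure function: pellets count positive REACH_ENDs and light is bistable", {
  cfg <- default_maze_config()
  for (seed in 1:5) {
    sim <- simulate_session(agent_params(seed = seed), "TEST", cfg,
                            session_index = 7, make_track = FALSE)
    r1 <- replay_contingencies(sim$events, cfg, "TEST")
    r2 <- replay_contingencies(sim$events, cfg, "TEST")
    expect_identical(r1$log, r2$log)
    expect_identical(r1$state, r2$state)
    pos <- arms_with_role("POSITIVE", cfg)
    n_pos_reach <- sum(sim$events$kind == "REACH_END" & sim$events$arm %in% pos)
    expect_identical(r1$state$pellets_dispensed, n_pos_reach)
    # noise strictly paired: every NOISE_ON followed by NOISE_OFF or session end
    expect_lte(abs(sum(r1$log$action == "NOISE_ON") -
                     sum(r1$log$action == "NOISE_OFF")), 1L)
  }
})

test_that("light stays off absent negative arms and centre dwells", {
  cfg <- default_maze_config()
  pos <- arms_with_role("POSITIVE", cfg)
  ev <- rbind(
    maze_event(0, "SESSION_START"),
    maze_event(2, "ENTER_ARM", pos[1]),
    maze_event(4, "REACH_END", pos[1]),
    maze_event(6, "EXIT_ARM", pos[1]),
    maze_event(6.5, "ENTER_CENTER"),
    maze_event(10, "ENTER_ARM", pos[2]),
    maze_event(12, "REACH_END", pos[2]),
    maze_event(14, "EXIT_ARM", pos[2]),
    maze_event(14.5, "ENTER_CENTER"),
    maze_event(20, "ENTER_ARM", pos[1]),
    maze_event(30, "EXIT_ARM", pos[1]))
  r <- step_seq(ev, cfg)
  expect_false(r$state$light_on)
  # exactly one LIGHT_OFF (first positive reach); moving between positive
  # arms does not re-trigger the light
  expect_identical(sum(r$log$action == "LIGHT_OFF"), 1L)
})
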