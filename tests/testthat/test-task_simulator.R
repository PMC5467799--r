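phase_I_cfg <- default_protocol()[[1]]
phase_II_cfg <- default_protocol()[[2]]
phase_III_cfg <- default_protocol()[[3]]

test_that("responses are rewarded per the contingency and schedule corrections", {
  amb <- opstrat:::trial_spec("ambiguous", NA)
  expect_true(evaluate_response(amb, "L", phase_III_cfg)$rewarded)
  expect_true(evaluate_response(amb, "R", phase_III_cfg)$rewarded)

  hc <- opstrat:::trial_spec("hc_stay", "top")  # top cue -> left correct
  wrong_I <- evaluate_response(hc, "R", phase_I_cfg)
  expect_false(wrong_I$rewarded)
  expect_true(wrong_I$next_is_correction)
  wrong_III <- evaluate_response(hc, "R", phase_III_cfg)
  expect_false(wrong_III$rewarded)
  expect_false(wrong_III$next_is_correction)
  expect_true(evaluate_response(hc, "L", phase_I_cfg)$rewarded)
})

test_that("transition rules fire in priority order", {
  # enforced flip: after 3 identical positions the next free draw flips
  state <- opstrat:::new_session_state()
  state$ref_side <- "L"; state$run_pos <- "top"; state$run_len <- 3L
  set.seed(1)
  for (i in 1:20) {
    drawn <- draw_next_trial(phase_I_cfg, state)
    expect_equal(drawn$spec$target, "bottom")
    expect_equal(drawn$spec$origin, "forced")
  }
  # pending correction repeats the previous cue position
  state <- opstrat:::new_session_state()
  state$ref_side <- "L"
  state$pending_correction <- opstrat:::trial_spec("hc_shift", "bottom")
  drawn <- draw_next_trial(phase_I_cfg, state)
  expect_equal(drawn$spec$target, "bottom")
  expect_true(drawn$spec$is_correction)
  # pending insertions emit high-contrast stay trials at the reference side
  state <- opstrat:::new_session_state()
  state$ref_side <- "R"; state$pending_stays <- 2L
  drawn <- draw_next_trial(phase_II_cfg, state)
  expect_equal(drawn$spec$type, "hc_stay")
  expect_equal(drawn$spec$correct_sides, "R")
  expect_equal(drawn$state$pending_stays, 1L)
})

test_that("every shift trial in phase II is followed by two inserted stay trials", {
  set.seed(5)
  ag <- make_agent(agent_cue_rule(1))  # never errs, so no corrections interleave
  sess <- run_session(ag, phase_II_cfg)
  shifts <- which(sess$trial_type %in% c("hc_shift", "lc_shift") &
                    sess$origin == "free")
  for (i in shifts) {
    follow <- sess[i + c(1, 2), ]
    follow <- follow[!is.na(follow$day), ]
    expect_true(all(follow$origin == "insertion" &
                      follow$trial_type == "hc_stay"))
  }
})

test_that("correction trials repeat the failed trial and reward a shifted response", {
  set.seed(8)
  ag <- make_agent(agent_outcome_table(p_stay_win = 0.5, p_stay_lose = 0))
  for (rep in 1:5) {
    sess <- run_session(ag, phase_I_cfg)
    corr <- which(sess$is_correction)
    expect_gt(length(corr), 0)
    prev_target <- target_position(sess$top_brightness, sess$bottom_brightness)
    for (i in corr) {
      expect_equal(prev_target[i], prev_target[i - 1])
      expect_equal(sess$correct_sides[i], sess$correct_sides[i - 1])
    }
    # a lose-shift agent always shifts after the error, so every correction
    # trial is rewarded
    expect_true(all(sess$rewarded[corr]))
    # with corrections enabled there are never two consecutive unrewarded
    # trials with different cue positions
    both_lost <- which(!sess$rewarded[-1] & !sess$rewarded[-nrow(sess)]) + 1
    expect_true(all(prev_target[both_lost] == prev_target[both_lost - 1]))
  }
})

test_that("free draws follow the configured distribution", {
  set.seed(3)
  ag <- make_agent(agent_random())
  draws <- character(0)
  while (length(draws) < 4000) {
    sess <- run_session(ag, phase_III_cfg)
    draws <- c(draws, sess$trial_type[sess$origin == "free"])
  }
  n <- length(draws)
  for (type in c("hc_shift", "lc_shift", "lc_stay", "ambiguous")) {
    p_hat <- mean(draws == type)
    expect_lt(abs(p_hat - 0.125), 3 * sqrt(0.125 * 0.875 / n))
  }
  expect_lt(abs(mean(draws == "hc_stay") - 0.5), 3 * sqrt(0.5 * 0.5 / n))
})

test_that("sessions have the configured length and are seed-reproducible", {
  ag1 <- make_agent(agent_side_bias(0.7))
  set.seed(21); s1 <- run_session(ag1, phase_I_cfg)
  set.seed(21); s2 <- run_session(make_agent(agent_side_bias(0.7)), phase_I_cfg)
  expect_equal(nrow(s1), 40)
  expect_identical(s1, s2)
  expect_equal(nrow(run_session(ag1, phase_II_cfg)), 50)
  expect_equal(nrow(run_session(ag1, phase_III_cfg)), 100)
})

test_that("side-bias agents reproduce their configured left rate", {
  set.seed(4)
  ag <- make_agent(agent_side_bias(0.7))
  resp <- character(0)
  for (i in 1:50) resp <- c(resp, run_session(ag, phase_III_cfg)$response)
  expect_lt(abs(mean(resp == "L") - 0.7),
            3 * sqrt(0.7 * 0.3 / length(resp)))
})

test_that("protocol progression follows the accuracy criterion and caps", {
  perfect <- run_protocol(make_agent(agent_cue_rule(1)), seed = 2)
  # two sessions at 100% end phase I immediately; phase II likewise
  expect_equal(sum(unique(perfect[, c("phase", "day")])$phase == "I"), 2)
  expect_equal(sum(unique(perfect[, c("phase", "day")])$phase == "II"), 2)
  expect_equal(sum(unique(perfect[, c("phase", "day")])$phase == "III"), 20)

  capped <- run_protocol(make_agent(agent_random()),
                         protocol = default_protocol(phase_I_cap = 15,
                                                     phase_II_cap = 3,
                                                     phase_III_sessions = 2),
                         seed = 3)
  expect_equal(sum(unique(capped[, c("phase", "day")])$phase == "I"), 15)

  re <- run_protocol(make_agent(agent_cue_rule(1)), seed = 2)
  expect_identical(perfect, re)
})

test_that("random agents perform at chance on phase I", {
  set.seed(6)
  ag <- make_agent(agent_random())
  acc <- replicate(60, cue_accuracy(run_session(ag, phase_I_cfg) |>
                                      tibble::add_column(animal_id = "x",
                                                         group = "g",
                                                         .before = 1)))
  expect_lt(abs(mean(acc) - 0.5), 0.04)
})

test_that("rl agents follow softmax choice with learned values", {
  # a large-beta cue agent that has learned value 1 for the correct pair
  # behaves like a perfect cue-rule follower
  spec <- agent_rl(rl_model_spec("cue", "hybrid"),
                   rl_params(kappa = 1, eta = 0, beta_I = 50))
  ag <- make_agent(spec)
  ag$state$V <- matrix(c(1, 0, 0, 1), 2, 2)  # top->L, bottom->R
  ctx <- list(day = 1, phase = "I", target = "top", contrast = "high",
              prev_response = NA, prev_rewarded = NA)
  expect_gt(ag$choose(ctx), 0.999)
  ctx$target <- "bottom"
  expect_lt(ag$choose(ctx), 0.001)
  # learning moves the chosen pair's value toward the obtained reward
  ag2 <- make_agent(agent_rl(rl_model_spec("cue", "hybrid"),
                             rl_params(kappa = 0.5, eta = 0.25, beta_I = 2)))
  ag2$learn(ctx, "R", TRUE)   # bottom-cue/right, rewarded
  expect_equal(ag2$state$V[2, 2], 0.5)          # 0 + 0.5 * 1 * (1 - 0)
  expect_equal(ag2$state$alpha, 1)              # |delta| = 1 keeps alpha at 1
})
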