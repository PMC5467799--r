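test_that("cue accuracy is the rewarded fraction of the selection", {
  tr <- toy_trials(c("L", "L", "R", "LR"), c("L", "R", "R", "L"))
  expect_equal(cue_accuracy(tr), 2 / 3)          # ambiguous excluded
  expect_equal(cue_accuracy(tr, include_ambiguous = TRUE), 3 / 4)
  expect_equal(cue_accuracy(toy_trials(rep("L", 5), rep("L", 5))), 1)
  expect_true(is.na(cue_accuracy(tr, phase = "III")))
  # 32 correct of 40 is the progression-criterion scale
  tr40 <- toy_trials(rep("L", 40), c(rep("L", 32), rep("R", 8)))
  expect_equal(cue_accuracy(tr40), 0.8)
})

test_that("outcome-rule frequencies use win/lose denominators and are complementary", {
  # win contexts at trials 2, 3, 5 (two stays, one shift); one lose context
  # at trial 4 (a shift)
  tr <- toy_trials(c("L", "L", "R", "R", "L"),
                   c("L", "L", "L", "R", "L"))
  freq <- outcome_rule_frequencies(tr)
  expect_equal(freq$frequency[freq$rule == "win-stay"], 2 / 3)
  expect_equal(freq$frequency[freq$rule == "win-shift"], 1 / 3)
  expect_equal(freq$frequency[freq$rule == "lose-shift"], 1)
  # no losses: lose pair undefined, win pair defined
  all_win <- toy_trials(rep("L", 4), rep("L", 4))
  freq2 <- outcome_rule_frequencies(all_win)
  expect_true(all(is.na(freq2$frequency[3:4])))
  expect_equal(freq2$frequency[1], 1)
})

test_that("complementarity holds on simulated streams and frequencies match the policy", {
  set.seed(9)
  co <- simulate_cohort(agent_outcome_table(p_stay_win = 0.58,
                                            p_stay_lose = 0.5),
                        n_animals = 1, protocol = fixed_protocol(n_III = 30),
                        master_seed = 13)
  freq <- outcome_rule_frequencies(co)
  expect_equal(freq$frequency[1] + freq$frequency[2], 1)
  expect_equal(freq$frequency[3] + freq$frequency[4], 1)
  n_win <- freq$n_context[1]
  # configured 42% win-shift vs 58% win-stay recovered within 3 SE
  expect_lt(abs(freq$frequency[freq$rule == "win-shift"] - 0.42),
            3 * sqrt(0.42 * 0.58 / n_win))
})

test_that("rule reward probabilities are reinforcements over applications", {
  tr <- toy_trials(c("L", "R", "R", "R"), c("L", "R", "L", "R"))
  # trial 2: win-shift rewarded; trial 3: win-shift unrewarded;
  # trial 4: lose-shift rewarded
  rew <- rule_reward_probabilities(tr)
  expect_equal(rew$p_reward[rew$rule == "win-shift"], 1 / 2)
  expect_equal(rew$p_reward[rew$rule == "lose-shift"], 1)
  expect_true(is.na(rew$p_reward[rew$rule == "win-stay"]))
  # lose-shift responses on phase I correction trials are always rewarded
  set.seed(10)
  co <- simulate_cohort(agent_outcome_table(0.5, 0), n_animals = 1,
                        protocol = fixed_protocol(n_I = 10), master_seed = 3)
  ann <- annotate_trials(co)
  corr <- ann[ann$is_correction & ann$outcome_rule == "lose-shift", ]
  expect_gt(nrow(corr), 20)
  expect_equal(mean(corr$rewarded), 1)
})

test_that("reward probabilities converge to generating contingencies", {
  # on phase III free-draw structure, win-stay pays exactly when the next
  # trial is a stay trial; check convergence of p(reward | win-stay) to the
  # empirical stay rate after wins
  set.seed(11)
  co <- simulate_cohort(agent_outcome_table(1, 0.5), n_animals = 1,
                        protocol = fixed_protocol(n_III = 20), master_seed = 5)
  ann <- annotate_trials(co)
  ws <- ann[!is.na(ann$outcome_rule) & ann$outcome_rule == "win-stay", ]
  stay_frac <- mean(ws$stay_shift == "stay" | ws$correct_sides == "LR",
                    na.rm = TRUE)
  rew <- rule_reward_probabilities(ann)
  expect_equal(rew$p_reward[rew$rule == "win-stay"], stay_frac,
               tolerance = 1e-10)
})

test_that("binomial test matches exact enumeration for n <= 20", {
  enum_p <- function(k, n, p0) {
    # upper-tail enumeration straight from the mass function
    sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - (k:n)))
  }
  for (n in c(5, 12, 20)) {
    for (k in c(0, floor(n / 2), n)) {
      expect_equal(binomial_test(k, n, 0.5, side = "greater"),
                   enum_p(k, n, 0.5), tolerance = 1e-12)
    }
  }
  expect_equal(binomial_test(10, 10, 0.5, side = "greater"), 2^-10)
  expect_equal(binomial_test(10, 20, 0.5, side = "two.sided"), 1,
               tolerance = 1e-6)
  expect_error(binomial_test(0, 0), "n >= 1")
})

test_that("2x2 chi-square matches the direct Pearson formula", {
  res <- chi_square_2x2(rbind(c(11, 1), c(4, 8)))
  expect_equal(res$statistic, 8.711, tolerance = 1e-3)
  expect_equal(res$p_value, 0.003, tolerance = 0.05)
  expect_equal(chi_square_2x2(rbind(c(5, 5), c(5, 5)))$statistic, 0)
  # brute-force Pearson formula
  tab <- rbind(c(12, 0), c(10, 2))
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  expect_equal(chi_square_2x2(tab)$statistic, sum((tab - e)^2 / e))
  expect_true(is.na(chi_square_2x2(rbind(c(0, 0), c(1, 2)))$statistic))
})

test_that("fisher transform of correlations behaves at the anchors", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(fisher_corr(x, x)$r, 1)
  expect_equal(fisher_corr(x, x)$z, Inf)
  y <- c(2, 1, 4, 3, 5)
  fc <- fisher_corr(x, y)
  expect_equal(fc$z, atanh(fc$r))
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  expect_true(is.na(fisher_corr(x, rep(1, 5))$r))
})

test_that("day metrics assemble one consistent row per animal and day", {
  set.seed(12)
  co <- simulate_cohort(agent_cue_rule(0.85), n_animals = 2,
                        protocol = fixed_protocol(n_I = 2, n_III = 2),
                        master_seed = 8)
  dm <- day_metrics(co)
  expect_equal(nrow(dm), 8)
  expect_true(all(dm$n_trials == rep(c(40, 40, 100, 100), 2)))
  ok <- !is.na(dm$f_win_stay)
  expect_equal(dm$f_win_stay[ok] + dm$f_win_shift[ok], rep(1, sum(ok)))
  one <- annotate_trials(co) |> dplyr::filter(animal_id == "m01", day == 1)
  expect_equal(dm$accuracy[1], cue_accuracy(one))
})
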