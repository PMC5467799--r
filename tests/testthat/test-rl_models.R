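test_that("the hybrid update follows the prediction-error rule", {
  v <- list(V = matrix(0.5, 2, 2), alpha = 0.8)
  par <- rl_params(kappa = 0.5, eta = 0.25)
  out <- rl_update(v, 1, 1, 1, par, "hybrid")
  expect_equal(out$delta, 0.5)
  expect_equal(out$V[1, 1], 0.7)          # 0.5 + 0.5 * 0.8 * 0.5
  expect_equal(out$alpha, 0.725)          # 0.75 * 0.8 + 0.25 * 0.5
  expect_equal(out$V[1, 2], 0.5)          # untouched pairs stay put

  # full-step identity: V = 0, alpha = 1, kappa = 1, r = 1
  v0 <- list(V = matrix(0, 2, 2), alpha = 1)
  out2 <- rl_update(v0, 2, 1, 1, rl_params(kappa = 1, eta = 0.3), "hybrid")
  expect_equal(out2$V[2, 1], 1)
  expect_equal(out2$alpha, 1)             # |delta| = 1 regardless of eta

  # eta = 0 freezes the associability
  out3 <- rl_update(v, 1, 2, 0, rl_params(kappa = 0.7, eta = 0), "hybrid")
  expect_equal(out3$alpha, 0.8)

  # the rw rule never touches the associability
  out4 <- rl_update(v, 1, 1, 1, rl_params(kappa = 0.5, eta = 0.9), "rw")
  expect_equal(out4$alpha, 0.8)
  expect_error(rl_update(v, 1, 1, 1, rl_params(kappa = 2), "hybrid"),
               "kappa")
})

test_that("values and associability stay in [0, 1] for rewards in {0, 1}", {
  set.seed(14)
  for (rep in 1:20) {
    par <- rl_params(kappa = runif(1), eta = runif(1))
    v <- list(V = matrix(runif(4), 2, 2), alpha = runif(1))
    for (t in 1:200) {
      v <- rl_update(v, sample(2, 1), sample(2, 1), sample(0:1, 1), par,
                     sample(c("hybrid", "hybrid_fixed", "rw"), 1))
      expect_true(all(v$V >= 0 & v$V <= 1))
      expect_true(v$alpha >= 0 && v$alpha <= 1)
    }
  }
})

test_that("softmax choice probabilities are correct, stable and shift-invariant", {
  expect_equal(choice_probabilities(c(0.3, 0.9), 0), c(0.5, 0.5))
  expect_equal(choice_probabilities(c(0.6, 0.2), 2)[1],
               1 / (1 + exp(-0.8)))
  expect_equal(choice_probabilities(c(0.6, 0.2), 2),
               choice_probabilities(c(10.6, 10.2), 2))
  expect_gt(choice_probabilities(c(1, 0), 500)[1], 1 - 1e-10)
  expect_equal(sum(choice_probabilities(c(700, -700), 1)), 1)
})

test_that("model states select the brighter cue or the previous outcome", {
  trials <- annotate_trials(toy_trials(c("L", "R", "LR", "L"),
                                       c("L", "L", "R", "R"),
                                       phase = "III",
                                       contrast = c("high", "low", "high", "high")))
  cue <- rl_model_spec("cue")
  out <- rl_model_spec("outcome")
  expect_equal(state_of(trials, cue), c("top", "bottom", NA, "top"))
  expect_equal(state_of(trials, out), c(NA, "win", "lose", "win"))
})

test_that("likelihood is T*log(2) when all inverse temperatures are zero", {
  set.seed(15)
  co <- simulate_cohort(agent_random(), n_animals = 1,
                        protocol = fixed_protocol(n_I = 2, n_III = 2),
                        master_seed = 2)
  for (fam in c("cue", "outcome")) {
    spec <- rl_model_spec(fam, "hybrid")
    rec <- opstrat:::prepare_record(annotate_trials(co), fam)
    par <- rl_params(kappa = runif(1), eta = runif(1), beta_I = 0,
                     beta_II = 0, beta_III = 0)
    expect_equal(rl_nll(par, annotate_trials(co), spec), rec$n * log(2))
  }
})

test_that("likelihood kernel matches a brute-force forward pass", {
  for (seed in 1:8) {
    rec <- random_record(10, seed)
    par <- rl_params(kappa = runif(1), eta = runif(1),
                     beta_I = runif(1, 0, 5), beta_II = runif(1, 0, 5),
                     beta_III = runif(1, 0, 5))
    for (rule in c("hybrid", "hybrid_fixed", "rw")) {
      expect_equal(nll_kernel(par, rec, rule),
                   nll_bruteforce(par, rec, rule), tolerance = 1e-12)
    }
  }
  # and on a real simulated record via the full preparation path
  set.seed(16)
  co <- annotate_trials(
    simulate_cohort(agent_random(), n_animals = 1,
                    protocol = fixed_protocol(n_III = 1), master_seed = 4))
  for (fam in c("cue", "outcome")) {
    rec <- opstrat:::prepare_record(co, fam)
    par <- rl_params(kappa = 0.4, eta = 0.3, beta_I = 1, beta_II = 2,
                     beta_III = 3)
    expect_equal(rl_nll(par, co, rl_model_spec(fam, "hybrid")),
                 nll_bruteforce(par, rec, "hybrid"), tolerance = 1e-10)
  }
})

test_that("hybrid with eta = 0 equals pure RW at rate kappa * alpha0", {
  for (seed in 1:5) {
    rec <- random_record(50, seed + 100)
    kappa <- runif(1); alpha0 <- runif(1, 0.2, 1)
    par_h <- rl_params(kappa = kappa, eta = 0, beta_I = 2, beta_II = 1,
                       beta_III = 3)
    par_rw <- rl_params(kappa = kappa * alpha0, eta = 0.99, beta_I = 2,
                        beta_II = 1, beta_III = 3)
    expect_equal(nll_kernel(par_h, rec, "hybrid", alpha0 = alpha0),
                 nll_kernel(par_rw, rec, "rw", alpha0 = 1), tolerance = 1e-12)
  }
})

test_that("ambiguous trials update the outcome model but enter no likelihood", {
  trials <- toy_trials(c("L", "LR", "L", "L"), c("L", "L", "L", "L"),
                       phase = "III")
  rec <- opstrat:::prepare_record(annotate_trials(trials), "outcome")
  expect_equal(rec$include, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(rec$state[2], 1L)   # win context still drives the update
  rec_cue <- opstrat:::prepare_record(annotate_trials(trials), "cue")
  expect_equal(rec_cue$include, rec$include)  # same n across families
  expect_true(is.na(rec_cue$state[2]))
})

test_that("the outcome model is invariant to relabeling left and right", {
  set.seed(17)
  co <- annotate_trials(
    simulate_cohort(agent_outcome_table(0.7, 0.3), n_animals = 1,
                    protocol = fixed_protocol(n_I = 3), master_seed = 9))
  flip <- function(x) ifelse(x == "L", "R", "L")
  co2 <- co
  co2$response <- flip(co$response)
  co2$correct_sides <- flip(co$correct_sides)
  tmp <- co2$top_brightness
  co2$top_brightness <- co2$bottom_brightness
  co2$bottom_brightness <- tmp
  co2 <- annotate_trials(co2[, opstrat:::trial_columns()])
  par <- rl_params(kappa = 0.4, eta = 0.2, beta_I = 2)
  spec <- rl_model_spec("outcome", "hybrid")
  expect_equal(rl_nll(par, co, spec), rl_nll(par, co2, spec))
})

test_that("multistart fitting is deterministic and beats a parameter grid", {
  set.seed(18)
  co <- annotate_trials(simulate_cohort(
    agent_rl(rl_model_spec("cue"), rl_params(kappa = 0.4, eta = 0.3,
                                             beta_I = 3)),
    n_animals = 1, protocol = fixed_protocol(n_I = 10), master_seed = 21))
  spec <- rl_model_spec("cue", "hybrid")
  f1 <- rl_fit(co, spec, n_starts = 8, seed = 5)
  f2 <- rl_fit(co, spec, n_starts = 8, seed = 5)
  expect_identical(f1$params, f2$params)
  expect_equal(-f1$logLik, min(f1$starts$nll))
  # the optimum beats a coarse grid search over (kappa, beta_I) with the
  # other parameters pinned at the fitted values
  grid <- expand.grid(kappa = seq(0.05, 1, by = 0.05),
                      beta = seq(0.25, 10, by = 0.25))
  rec <- opstrat:::prepare_record(co, "cue")
  grid_nll <- mapply(function(k, b) {
    par <- f1$params; par$kappa <- k; par$beta_I <- b
    rl_nll(par, NULL, spec, record = rec)
  }, grid$kappa, grid$beta)
  expect_lte(-f1$logLik, min(grid_nll) + 1e-6)
})
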