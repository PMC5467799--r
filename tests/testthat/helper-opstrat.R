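# Shared fixtures: toy trial streams built in code, compact protocols, and
# independent brute-force oracles used against the package's fast paths.

# Build a valid trial tibble from correct sides and responses. Brightness is
# reconstructed from the correct side (top cue -> left response), with "LR"
# giving an ambiguous 50/50 trial.
toy_trials <- function(correct_sides, response,
                       phase = "I", day = 1L, animal_id = "a1",
                       group = "g", is_correction = FALSE,
                       contrast = "high") {
  n <- length(correct_sides)
  phase <- rep_len(phase, n)
  day <- rep_len(as.integer(day), n)
  contrast <- rep_len(contrast, n)
  top <- bottom <- numeric(n)
  for (i in seq_len(n)) {
    if (correct_sides[i] == "LR") {
      top[i] <- bottom[i] <- 50
    } else {
      tgt_top <- correct_sides[i] == "L"
      top[i] <- if (tgt_top) 85 else if (contrast[i] == "low") 20 else 0
      bottom[i] <- if (!tgt_top) 85 else if (contrast[i] == "low") 20 else 0
    }
  }
  idx <- stats::ave(seq_len(n), paste(animal_id, day), FUN = seq_along)
  tibble::tibble(
    animal_id = rep_len(animal_id, n), group = rep_len(group, n),
    phase = phase, day = day, trial_index = as.integer(idx),
    top_brightness = top, bottom_brightness = bottom,
    correct_sides = correct_sides, response = response,
    rewarded = mapply(grepl, response, correct_sides, USE.NAMES = FALSE),
    is_correction = rep_len(is_correction, n)
  )
}

# Fixed-length protocol: no progression criterion, so trial counts are exact.
fixed_protocol <- function(n_I = 0, n_II = 0, n_III = 0) {
  proto <- default_protocol()
  out <- list()
  caps <- c(n_I, n_II, n_III)
  for (i in 1:3) {
    if (caps[i] > 0) {
      cfg <- proto[[i]]
      cfg$criterion_accuracy <- NA
      cfg$max_sessions <- caps[i]
      out[[length(out) + 1]] <- cfg
    }
  }
  out
}

# Brute-force forward pass of the hybrid RW/PH likelihood, written directly
# from the update and softmax definitions; used as the oracle for the
# package's likelihood kernel.
nll_bruteforce <- function(params, rec, rule = "hybrid", v0 = 0, alpha0 = 1) {
  V <- matrix(v0, 2, 2)
  alpha <- alpha0
  beta <- c(params$beta_I, params$beta_II, params$beta_III)
  kappa <- if (rule == "hybrid_fixed") 1 else params$kappa
  nll <- 0
  for (t in seq_along(rec$state)) {
    s <- rec$state[t]; a <- rec$action[t]
    if (is.na(s) || is.na(a)) next
    if (rec$include[t]) {
      b <- beta[rec$phase[t]]
      p <- exp(b * V[s, a]) / (exp(b * V[s, 1]) + exp(b * V[s, 2]))
      nll <- nll - log(p)
    }
    delta <- rec$reward[t] - V[s, a]
    V[s, a] <- V[s, a] + kappa * alpha * delta
    if (rule != "rw") alpha <- (1 - params$eta) * alpha + params$eta * abs(delta)
  }
  nll
}

# Random short record in the kernel's raw form (states, actions, rewards,
# phases, inclusion flags) for property tests.
random_record <- function(n, seed) {
  set.seed(seed)
  list(state = sample(c(1L, 2L, NA), n, replace = TRUE, prob = c(.45, .45, .1)),
       action = sample(1:2, n, replace = TRUE),
       reward = sample(0:1, n, replace = TRUE),
       phase = sort(sample(1:3, n, replace = TRUE)),
       include = c(FALSE, rep(TRUE, n - 1)))
}

# Call the likelihood kernel on a raw record through the exported rl_nll()
# by faking its prepared-record hook.
nll_kernel <- function(params, rec, rule = "hybrid", v0 = 0, alpha0 = 1) {
  spec <- rl_model_spec("cue", rule, v0 = v0, alpha0 = alpha0)
  rec$n <- sum(rec$include)
  rl_nll(params, trials = NULL, model_spec = spec, record = rec)
}
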