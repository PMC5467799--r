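#' Generative model of the three-phase two-choice touchscreen task
#'
#' The simulator reproduces the trial-transition structure the analysis
#' assumes: phase I presents high-contrast trials with correction trials
#' after errors and an enforced cue-position flip after three identical
#' positions in a row; phase II adds low-contrast shift trials and inserts
#' two high-contrast stay trials after every shift trial; phase III adds
#' ambiguous (both-rewarded) probe trials, drops correction trials, and
#' inserts one high-contrast stay trial after every non-stay trial. Freely
#' drawn trial types follow the configured phase distribution.
#'
#' @name task_simulator
NULL

# Cue brightness in percent: high-contrast target alone, low-contrast target
# with a dim distractor on the opposite position, ambiguous probes equally lit.
.BRIGHT_TARGET <- 85
.BRIGHT_DISTRACTOR <- 20
.BRIGHT_AMBIGUOUS <- 50

.TRIAL_TYPES <- c("hc_stay", "hc_shift", "lc_stay", "lc_shift", "ambiguous")

#' Phase configuration
#'
#' Bundles the parameters that define one task phase: session length, the
#' free-draw distribution over trial types, whether errors trigger correction
#' trials, how many high-contrast stay trials are inserted after a non-stay
#' trial, the enforced-flip run length, and the progression rule.
#'
#' @param phase `"I"`, `"II"` or `"III"`.
#' @param session_length trials per session.
#' @param draw named numeric vector of free-draw probabilities over
#'   `r paste(.TRIAL_TYPES, collapse = ", ")` (missing names mean 0); must
#'   sum to 1.
#' @param corrections logical; repeat the cue position after errors until the
#'   correct response occurs.
#' @param post_shift_stays number of high-contrast stay trials inserted after
#'   each non-stay (shift or ambiguous) trial.
#' @param max_same_position_run free draws flip the cue position after this
#'   many identical positions in a row (`Inf` disables the rule).
#' @param criterion_accuracy,criterion_days session accuracy and number of
#'   consecutive sessions required to progress (`NA` accuracy means the phase
#'   runs for a fixed number of sessions).
#' @param max_sessions session cap for the phase.
#' @return a `phase_config` list.
#' @export
phase_config <- function(phase,
                         session_length,
                         draw,
                         corrections,
                         post_shift_stays = 0,
                         max_same_position_run = Inf,
                         criterion_accuracy = 0.8,
                         criterion_days = 2,
                         max_sessions = Inf) {
  stopifnot(phase %in% .PHASES, session_length >= 1)
  bad <- setdiff(names(draw), .TRIAL_TYPES)
  if (length(bad)) stop("unknown trial types in draw: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (any(draw < 0) || abs(sum(draw) - 1) > 1e-9) {
    stop("free-draw probabilities must be nonnegative and sum to 1",
         call. = FALSE)
  }
  p <- setNames(numeric(length(.TRIAL_TYPES)), .TRIAL_TYPES)
  p[names(draw)] <- draw
  structure(
    list(phase = phase, session_length = as.integer(session_length),
         draw = p, draw_cdf = cumsum(p), corrections = corrections,
         post_shift_stays = as.integer(post_shift_stays),
         max_same_position_run = max_same_position_run,
         criterion_accuracy = criterion_accuracy,
         criterion_days = as.integer(criterion_days),
         max_sessions = max_sessions),
    class = "phase_config")
}

#' Default three-phase protocol
#'
#' Phase I: 40-trial sessions of high-contrast stay/shift trials drawn with
#' equal probability, correction trials, enforced flip after 3 identical
#' positions, progression at >= 80% accuracy on 2 consecutive sessions with a
#' 70-session cap. Phase II: 50-trial sessions, stay probability .5 and
#' high-/low-contrast shift .25 each, correction trials, 2 inserted stay
#' trials after each shift trial, same criterion with a 14-session cap.
#' Phase III: 20 fixed sessions of 100 trials, no corrections, 1 inserted
#' stay trial after each non-stay trial, free draws at .5 for high-contrast
#' stay and .125 for each other type.
#'
#' @param phase_I_cap session cap for phase I.
#' @param phase_II_cap session cap for phase II.
#' @param phase_III_sessions fixed number of phase III sessions.
#' @return list of [phase_config()]s, in task order.
#' @export
default_protocol <- function(phase_I_cap = 70, phase_II_cap = 14,
                             phase_III_sessions = 20) {
  list(
    phase_config("I", 40, c(hc_stay = .5, hc_shift = .5),
                 corrections = TRUE, post_shift_stays = 0,
                 max_same_position_run = 3, max_sessions = phase_I_cap),
    phase_config("II", 50, c(hc_stay = .5, hc_shift = .25, lc_shift = .25),
                 corrections = TRUE, post_shift_stays = 2,
                 max_sessions = phase_II_cap),
    phase_config("III", 100,
                 c(hc_stay = .5, hc_shift = .125, lc_shift = .125,
                   lc_stay = .125, ambiguous = .125),
                 corrections = FALSE, post_shift_stays = 1,
                 criterion_accuracy = NA, max_sessions = phase_III_sessions)
  )
}

# Cue rule: mapping from cue position to rewarded side.
.CUE_MAP <- c(top = "L", bottom = "R")

position_for_side <- function(side) names(.CUE_MAP)[match(side, .CUE_MAP)]

# Build the concrete cue configuration for a trial type at a given target
# position. Ambiguous trials ignore the position argument.
trial_spec <- function(type, target, is_correction = FALSE, origin = "free") {
  if (type == "ambiguous") {
    list(type = type, target = NA_character_,
         top = .BRIGHT_AMBIGUOUS, bottom = .BRIGHT_AMBIGUOUS,
         correct_sides = "LR", is_correction = FALSE, origin = origin)
  } else {
    hc <- type %in% c("hc_stay", "hc_shift")
    top <- if (target == "top") .BRIGHT_TARGET else if (hc) 0 else .BRIGHT_DISTRACTOR
    bottom <- if (target == "bottom") .BRIGHT_TARGET else if (hc) 0 else .BRIGHT_DISTRACTOR
    list(type = type, target = target, top = top, bottom = bottom,
         correct_sides = unname(.CUE_MAP[target]),
         is_correction = is_correction, origin = origin)
  }
}

#' Evaluate a response to a trial
#'
#' @param spec a trial spec as produced by the trial generator.
#' @param side the response, `"L"` or `"R"`.
#' @param phase_cfg the [phase_config()] in force.
#' @return list with `rewarded` (response in the trial's correct sides; both
#'   sides are rewarded on ambiguous trials) and `next_is_correction`
#'   (unrewarded and the phase runs correction trials).
#' @export
evaluate_response <- function(spec, side, phase_cfg) {
  if (side != "L" && side != "R") stop("side must be L or R", call. = FALSE)
  rewarded <- spec$correct_sides == "LR" || side == spec$correct_sides
  list(rewarded = rewarded,
       next_is_correction = !rewarded && isTRUE(phase_cfg$corrections))
}

# Fresh transition state for a session: no reference side, no pending
# correction or insertions, empty position run.
new_session_state <- function() {
  list(ref_side = NA_character_, pending_correction = NULL,
       pending_stays = 0L, run_pos = NA_character_, run_len = 0L)
}

#' Draw the next trial of a session
#'
#' Applies the transition rules in priority order: a pending correction trial
#' repeats the previous cue configuration; pending post-shift insertions emit
#' high-contrast stay trials; in phase I the cue position is flipped after
#' `max_same_position_run` identical positions; otherwise the trial type is a
#' free draw from the phase distribution. The first trial of a session (no
#' reference side yet) presents a high-contrast cue at a uniformly drawn
#' position.
#'
#' @param phase_cfg a [phase_config()].
#' @param state session transition state (see [run_session()]); `NULL` starts
#'   a fresh session.
#' @return list with `spec` (the drawn trial) and the updated `state`.
#' @export
draw_next_trial <- function(phase_cfg, state = NULL) {
  if (is.null(state)) state <- new_session_state()
  if (!is.null(state$pending_correction)) {
    prev <- state$pending_correction
    spec <- trial_spec(prev$type, prev$target, is_correction = TRUE,
                       origin = "correction")
    return(list(spec = spec, state = state))
  }
  if (state$pending_stays > 0L) {
    state$pending_stays <- state$pending_stays - 1L
    spec <- trial_spec("hc_stay", position_for_side(state$ref_side),
                       origin = "insertion")
    return(list(spec = spec, state = state))
  }
  if (is.na(state$ref_side)) {
    target <- if (runif(1) < 0.5) "top" else "bottom"
    return(list(spec = trial_spec("hc_stay", target, origin = "first"),
                state = state))
  }
  if (is.finite(phase_cfg$max_same_position_run) &&
      state$run_len >= phase_cfg$max_same_position_run) {
    target <- other_position(state$run_pos)
    type <- if (unname(.CUE_MAP[target]) == state$ref_side) "hc_stay" else "hc_shift"
    return(list(spec = trial_spec(type, target, origin = "forced"),
                state = state))
  }
  # inverse-CDF draw; noticeably faster than sample() in this inner loop
  type <- .TRIAL_TYPES[which.max(runif(1) <= phase_cfg$draw_cdf)]
  if (type == "ambiguous") {
    return(list(spec = trial_spec("ambiguous", NA), state = state))
  }
  side <- if (endsWith(type, "stay")) state$ref_side else other_side(state$ref_side)
  list(spec = trial_spec(type, position_for_side(side)), state = state)
}

# Advance the transition state after a completed trial.
advance_state <- function(state, spec, response, rewarded, phase_cfg) {
  pos <- if (is.na(spec$target)) NA_character_ else spec$target
  if (!is.na(pos)) {
    state$run_len <- if (identical(state$run_pos, pos)) state$run_len + 1L else 1L
    state$run_pos <- pos
  }
  if (!rewarded && isTRUE(phase_cfg$corrections)) {
    state$pending_correction <- spec
  } else {
    state$pending_correction <- NULL
  }
  # Non-stay trials (shift or ambiguous probe) owe the configured number of
  # inserted high-contrast stay trials; corrections and insertions never
  # re-trigger the rule.
  if (spec$origin %in% c("free", "forced") &&
      !endsWith(spec$type, "stay") && phase_cfg$post_shift_stays > 0L) {
    state$pending_stays <- phase_cfg$post_shift_stays
  }
  state$ref_side <- if (spec$correct_sides == "LR") response else spec$correct_sides
  state
}

#' Run one session of an agent on the task
#'
#' Plays `phase_cfg$session_length` trials: the trial generator draws each
#' trial, the agent chooses a side given its context (current cue, previous
#' response and outcome, day), and the response is evaluated for reward and
#' correction scheduling. Agent internal state (e.g. learned values) is
#' mutated in place and persists across sessions; the trial-transition state
#' starts fresh each session.
#'
#' @param agent an agent from [make_agent()].
#' @param phase_cfg a [phase_config()].
#' @param day session day index (passed to day-dependent agents).
#' @return tibble of trials with simulator annotation columns `trial_type`
#'   and `origin` (`free`, `forced`, `insertion`, `correction`, `first`).
#' @export
run_session <- function(agent, phase_cfg, day = 1L) {
  n <- phase_cfg$session_length
  top <- bottom <- numeric(n)
  correct_sides <- response <- type <- origin <- character(n)
  rewarded <- is_correction <- logical(n)
  state <- new_session_state()
  prev_response <- NA_character_
  prev_rewarded <- NA
  for (i in seq_len(n)) {
    drawn <- draw_next_trial(phase_cfg, state)
    spec <- drawn$spec
    state <- drawn$state
    ctx <- list(day = day, phase = phase_cfg$phase, target = spec$target,
                contrast = if (spec$type == "ambiguous") "ambiguous"
                           else if (startsWith(spec$type, "hc")) "high" else "low",
                prev_response = prev_response, prev_rewarded = prev_rewarded)
    p_left <- agent$choose(ctx)
    side <- if (runif(1) < p_left) "L" else "R"
    ev <- evaluate_response(spec, side, phase_cfg)
    agent$learn(ctx, side, ev$rewarded)
    top[i] <- spec$top; bottom[i] <- spec$bottom
    correct_sides[i] <- spec$correct_sides
    response[i] <- side
    rewarded[i] <- ev$rewarded
    is_correction[i] <- spec$is_correction
    type[i] <- spec$type; origin[i] <- spec$origin
    state <- advance_state(state, spec, side, ev$rewarded, phase_cfg)
    prev_response <- side
    prev_rewarded <- ev$rewarded
  }
  tibble::new_tibble(list(
    phase = rep(phase_cfg$phase, n), day = rep(as.integer(day), n),
    trial_index = seq_len(n),
    top_brightness = top, bottom_brightness = bottom,
    correct_sides = correct_sides, response = response, rewarded = rewarded,
    is_correction = is_correction, trial_type = type, origin = origin
  ), nrow = n)
}

session_accuracy <- function(session) {
  keep <- session$correct_sides != "LR"
  if (!any(keep)) return(NA_real_)
  mean(session$rewarded[keep])
}

#' Run an agent through a full multi-phase protocol
#'
#' Sessions are played day by day. Phases with a progression criterion end
#' once accuracy reaches `criterion_accuracy` on `criterion_days` consecutive
#' sessions, or at `max_sessions`; phases with `criterion_accuracy = NA` run
#' exactly `max_sessions` sessions. Agent state carries across sessions and
#' phases.
#'
#' @param agent an agent from [make_agent()].
#' @param protocol list of [phase_config()]s (default [default_protocol()]).
#' @param animal_id,group identifiers stamped on the output.
#' @param seed optional integer seed for this animal's trial stream.
#' @return a cohort tibble for one simulated animal (with `trial_type` and
#'   `origin` annotations).
#' @export
run_protocol <- function(agent, protocol = default_protocol(),
                         animal_id = "sim1", group = "sim", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  day <- 0L
  out <- vector("list", 0L)
  for (cfg in protocol) {
    streak <- 0L
    n_sessions <- 0L
    repeat {
      day <- day + 1L
      n_sessions <- n_sessions + 1L
      sess <- run_session(agent, cfg, day = day)
      out[[length(out) + 1L]] <- sess
      if (is.na(cfg$criterion_accuracy)) {
        if (n_sessions >= cfg$max_sessions) break
      } else {
        acc <- session_accuracy(sess)
        streak <- if (!is.na(acc) && acc >= cfg$criterion_accuracy) streak + 1L else 0L
        if (streak >= cfg$criterion_days || n_sessions >= cfg$max_sessions) break
      }
    }
  }
  trials <- dplyr::bind_rows(out)
  tibble::tibble(animal_id = animal_id, group = group, trials)
}

#' Simulate a cohort of animals
#'
#' Each animal gets a fresh agent built from its spec and an independent
#' RNG stream derived from the master seed and the animal index, so cohorts
#' are reproducible and animals independent.
#'
#' @param agent_specs list of agent specs (see [make_agent()]), one per
#'   animal, or a single spec recycled for all animals.
#' @param n_animals number of animals when a single spec is given.
#' @param protocol list of [phase_config()]s.
#' @param groups group label per animal (recycled).
#' @param master_seed integer master seed.
#' @param id_prefix prefix for generated animal ids.
#' @return a cohort tibble.
#' @export
simulate_cohort <- function(agent_specs, n_animals = NULL,
                            protocol = default_protocol(),
                            groups = "sim", master_seed = 1L,
                            id_prefix = "m") {
  if (inherits(agent_specs, "agent_spec")) {
    stopifnot(!is.null(n_animals))
    agent_specs <- rep(list(agent_specs), n_animals)
  }
  n <- length(agent_specs)
  groups <- rep_len(groups, n)
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    agent <- make_agent(agent_specs[[i]])
    cohort[[i]] <- run_protocol(
      agent, protocol,
      animal_id = sprintf("%s%02d", id_prefix, i), group = groups[i],
      seed = animal_seed(master_seed, i))
  }
  dplyr::bind_rows(cohort)
}

# Per-animal seed derived from the master seed; kept within 32-bit range.
animal_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 1009 + 7919 * i) %% .Machine$integer.max)
}
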