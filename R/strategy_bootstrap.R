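#' Agent-based bootstrap null distributions for rule-consistent behaviour
#'
#' Tests, per animal, the null hypothesis that cue-rule performance is fully
#' explained by a pure outcome-based (or pure cue-based) response policy:
#' artificial agents sample actions with the animal's own day-specific
#' conditional response probabilities while facing the same generative task
#' structure on the same number of days and trials, yielding a null
#' distribution of per-day accuracy on stay and shift trials. Days on which
#' the animal's observed accuracy leaves the percentile band count as
#' escapes, assessed by an upper-tail binomial test.
#'
#' @name strategy_bootstrap
NULL

# Stay/shift label within one session: a trial is a stay trial when its
# single correct side repeats the previous trial's reference side (previous
# correct side, or the chosen side after an ambiguous trial).
stay_shift_within <- function(correct_sides, response) {
  cs <- ifelse(correct_sides %in% c("L", "R"), correct_sides, NA_character_)
  ref <- dplyr::lag(ifelse(is.na(cs), response, cs))
  ifelse(is.na(ref) | is.na(cs), NA_character_,
         ifelse(cs == ref, "stay", "shift"))
}

# Per-day accuracy on stay and on shift trials (non-ambiguous only),
# classified within day so observed animals and replicate agents are scored
# identically.
day_class_accuracy <- function(trials) {
  split(trials, trials$day) |>
    lapply(function(d) {
      lab <- stay_shift_within(d$correct_sides, d$response)
      acc <- function(cls) {
        i <- !is.na(lab) & lab == cls
        if (!any(i)) NA_real_ else mean(d$rewarded[i])
      }
      tibble::tibble(day = d$day[1], phase = d$phase[1],
                     n_trials = nrow(d),
                     acc_stay = acc("stay"), acc_shift = acc("shift"))
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$day)
}

#' Infer an animal's day-specific response probabilities
#'
#' For the outcome family: per day, the probability of repeating the
#' previous response after a rewarded (win) and after an unrewarded (lose)
#' trial. For the cue family: per day, cue position and contrast class, the
#' probability of a left response. Contexts unobserved on a day are absent
#' from the table and fall back to `fallback` inside the agent.
#'
#' @param trials one animal's trials.
#' @param family `"outcome"` or `"cue"`.
#' @return a day-probability table suitable for [agent_outcome_table()] or
#'   [agent_cue_table()].
#' @export
infer_day_probabilities <- function(trials, family = c("outcome", "cue")) {
  family <- match.arg(family)
  stopifnot(nrow(trials) > 0, length(unique(trials$animal_id)) == 1)
  if (family == "outcome") {
    split(trials, trials$day) |>
      lapply(function(d) {
        prev_resp <- dplyr::lag(d$response)
        prev_rew <- dplyr::lag(d$rewarded)
        stay <- d$response == prev_resp
        p_ctx <- function(rew) {
          i <- !is.na(prev_rew) & prev_rew == rew
          if (!any(i)) NA_real_ else mean(stay[i])
        }
        tibble::tibble(day = d$day[1], p_stay_win = p_ctx(TRUE),
                       p_stay_lose = p_ctx(FALSE))
      }) |>
      dplyr::bind_rows()
  } else {
    if (!"contrast" %in% names(trials)) trials <- annotate_trials(trials)
    trials |>
      dplyr::group_by(.data$day, .data$target, .data$contrast) |>
      dplyr::summarise(p_left = mean(.data$response == "L"), .groups = "drop")
  }
}

# Day-by-day schedule mirroring an animal's record: phase and trial count
# per day, with the phase's standard transition rules.
mirror_schedule <- function(trials, protocol = default_protocol()) {
  phases <- vapply(protocol, `[[`, character(1), "phase")
  split(trials, trials$day) |>
    lapply(function(d) {
      cfg <- protocol[[match(d$phase[1], phases)]]
      cfg$session_length <- nrow(d)
      list(day = d$day[1], cfg = cfg)
    }) |>
    unname()
}

#' Run the strategy bootstrap for one animal
#'
#' Each replicate plays a probability-table agent of the requested family
#' through the generative task for the animal's own schedule (same days,
#' same phases, same trial counts), using the animal's inferred day-specific
#' response probabilities. Per day and per trial class (stay/shift) the
#' replicate accuracies give a percentile confidence band; days on which the
#' observed accuracy leaves the band under the escape policy are counted and
#' assessed against a binomial null.
#'
#' The default escape policy is one-sided above the band with
#' \eqn{\alpha = .05} for the outcome-family bootstrap (does the animal beat
#' the best outcome-only agent?), and two-sided with \eqn{\alpha = .10} for
#' the cue-family bootstrap.
#'
#' @param trials one animal's trials.
#' @param family `"outcome"` or `"cue"`: the strategy family of the null.
#' @param n_replicates bootstrap replicates (default 1000).
#' @param level band coverage (default 0.90).
#' @param policy `"above"`, `"below"` or `"either"`; `NULL` picks the family
#'   default.
#' @param alpha per-day escape probability under the null for the binomial
#'   assessment; `NULL` picks the policy default (`level` tail mass).
#' @param protocol phase templates supplying the transition rules.
#' @param fallback probability for contexts unobserved on a day.
#' @param probs optional day-probability table to drive the replicate agent
#'   (as returned by [infer_day_probabilities()]); by default inferred from
#'   the animal's record, which is the standard analysis path. Passing the
#'   table of a known generating policy isolates band calibration from
#'   inference noise in coverage studies.
#' @param seed integer seed; replicates use independent derived streams.
#' @return a `bootstrap_result`: `per_day` tibble (observed accuracies, band
#'   bounds, escape flag per day), `escape_days`, `n_assessable`, `p_value`,
#'   `escaped` (overall verdict at the binomial .05 level), plus settings.
#' @export
run_bootstrap <- function(trials, family = c("outcome", "cue"),
                          n_replicates = 1000, level = 0.90, policy = NULL,
                          alpha = NULL, protocol = default_protocol(),
                          fallback = 0.5, probs = NULL, seed = 1L) {
  family <- match.arg(family)
  if (n_replicates < 2) stop("need at least 2 replicates", call. = FALSE)
  stopifnot(level > 0, level < 1)
  if (is.null(policy)) policy <- if (family == "outcome") "above" else "either"
  policy <- match.arg(policy, c("above", "below", "either"))
  if (is.null(alpha)) {
    alpha <- if (policy == "either") 1 - level else (1 - level) / 2
  }
  if (is.null(probs)) probs <- infer_day_probabilities(trials, family)
  spec <- if (family == "outcome") {
    agent_outcome_table(probs, fallback = fallback)
  } else {
    agent_cue_table(probs, fallback = fallback)
  }
  schedule <- mirror_schedule(trials, protocol)
  n_days <- length(schedule)
  days <- vapply(schedule, `[[`, numeric(1), "day")
  rep_stay <- rep_shift <- matrix(NA_real_, n_replicates, n_days)
  for (r in seq_len(n_replicates)) {
    set.seed(animal_seed(seed, r))
    agent <- make_agent(spec)
    for (d in seq_len(n_days)) {
      sess <- run_session(agent, schedule[[d]]$cfg, day = schedule[[d]]$day)
      lab <- stay_shift_within(sess$correct_sides, sess$response)
      i_stay <- !is.na(lab) & lab == "stay"
      i_shift <- !is.na(lab) & lab == "shift"
      rep_stay[r, d] <- if (any(i_stay)) mean(sess$rewarded[i_stay]) else NA
      rep_shift[r, d] <- if (any(i_shift)) mean(sess$rewarded[i_shift]) else NA
    }
  }
  q_lo <- (1 - level) / 2
  band <- function(m, q) apply(m, 2, quantile, probs = q, na.rm = TRUE,
                               names = FALSE)
  obs <- day_class_accuracy(trials)
  stopifnot(identical(as.numeric(obs$day), as.numeric(days)))
  per_day <- tibble::tibble(
    day = obs$day, phase = obs$phase, n_trials = obs$n_trials,
    obs_stay = obs$acc_stay, obs_shift = obs$acc_shift,
    lower_stay = band(rep_stay, q_lo), upper_stay = band(rep_stay, 1 - q_lo),
    mean_stay = colMeans(rep_stay, na.rm = TRUE),
    lower_shift = band(rep_shift, q_lo), upper_shift = band(rep_shift, 1 - q_lo),
    mean_shift = colMeans(rep_shift, na.rm = TRUE)
  )
  assess <- escape_assessment(
    observed = cbind(per_day$obs_stay, per_day$obs_shift),
    lower = cbind(per_day$lower_stay, per_day$lower_shift),
    upper = cbind(per_day$upper_stay, per_day$upper_shift),
    policy = policy, alpha = alpha)
  per_day$escape <- assess$escape_flags
  structure(
    list(family = family, per_day = per_day,
         escape_days = assess$escape_days,
         n_assessable = assess$n_assessable,
         p_value = assess$p_value,
         escaped = !is.na(assess$p_value) && assess$p_value < 0.05,
         n_replicates = n_replicates, level = level, policy = policy,
         alpha = alpha, seed = seed),
    class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "%s-rule bootstrap: %d/%d days outside the %.0f%% band (policy %s)\n",
    x$family, x$escape_days, x$n_assessable, 100 * x$level, x$policy))
  cat(sprintf("  binomial p = %.4g (alpha = %.3g, %d replicates)\n",
              x$p_value, x$alpha, x$n_replicates))
  invisible(x)
}

#' Count band escapes and assess them against a binomial null
#'
#' A day is assessable when at least one trial class has both an observed
#' accuracy and a band; it escapes when any assessable class falls outside
#' the band in the direction the policy admits. The p-value is the upper
#' binomial tail \eqn{P(X \ge \mathrm{escapes})} with
#' \eqn{X \sim B(\mathrm{assessable\ days}, \alpha)}.
#'
#' @param observed,lower,upper numeric matrices, days x trial classes.
#' @param policy `"above"`, `"below"` or `"either"`.
#' @param alpha per-day escape probability under the null.
#' @return list with `escape_flags` (per day, `NA` when not assessable),
#'   `escape_days`, `n_assessable`, `p_value`.
#' @export
escape_assessment <- function(observed, lower, upper,
                              policy = c("above", "below", "either"),
                              alpha = 0.05) {
  policy <- match.arg(policy)
  observed <- as.matrix(observed); lower <- as.matrix(lower)
  upper <- as.matrix(upper)
  defined <- !is.na(observed) & !is.na(lower) & !is.na(upper)
  out <- matrix(FALSE, nrow(observed), ncol(observed))
  above <- defined & observed > upper
  below <- defined & observed < lower
  out[defined] <- switch(policy,
                         above = above[defined],
                         below = below[defined],
                         either = (above | below)[defined])
  assessable <- rowSums(defined) > 0
  flags <- ifelse(assessable, rowSums(out) > 0, NA)
  n_assess <- sum(assessable)
  escapes <- sum(flags, na.rm = TRUE)
  p <- if (n_assess == 0) NA_real_ else
    pbinom(escapes - 1, n_assess, alpha, lower.tail = FALSE)
  list(escape_flags = flags, escape_days = escapes,
       n_assessable = n_assess, p_value = p)
}

#' Compare escape counts between two groups
#'
#' 2x2 chi-square (uncorrected) on the numbers of animals that did and did
#' not escape their bootstrap bands in each group.
#'
#' @param escaped_a,escaped_b logical per-animal escape flags.
#' @return as [chi_square_2x2()], plus the underlying table.
#' @export
group_escape_comparison <- function(escaped_a, escaped_b) {
  counts <- rbind(c(sum(escaped_a), sum(!escaped_a)),
                  c(sum(escaped_b), sum(!escaped_b)))
  dimnames(counts) <- list(c("group_a", "group_b"), c("escaped", "stayed"))
  c(chi_square_2x2(counts), list(table = counts))
}

#' Serialize a bootstrap result
#'
#' Writes the per-day table (band bounds, observed accuracies, escape flags)
#' as CSV and the summary (escape count, p-value, settings, seed) as JSON.
#'
#' @param result a `bootstrap_result`.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return `result`, invisibly.
#' @export
write_bootstrap <- function(result, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "bootstrap_result"))
  if (!is.null(csv_path)) {
    readr::write_csv(result$per_day, csv_path, progress = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      result[c("family", "escape_days", "n_assessable", "p_value", "escaped",
               "n_replicates", "level", "policy", "alpha", "seed")],
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
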