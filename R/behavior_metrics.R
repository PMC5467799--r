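#' Descriptive strategy metrics on trial logs
#'
#' Cue-rule accuracy (fraction of rewarded responses), outcome-rule
#' frequencies (win-stay/win-shift and lose-stay/lose-shift as fractions of
#' previous-win and previous-lose trials), per-rule reward probabilities
#' (how often applying a rule paid off), and the elementary per-animal
#' inferential procedures: exact binomial tests against chance, 2x2
#' chi-square comparisons and Fisher-z transformed correlations.
#'
#' @name behavior_metrics
NULL

#' Cue-rule accuracy of a trial selection
#'
#' Fraction of rewarded responses. Ambiguous trials (both sides correct, so
#' accuracy is uninformative) are excluded unless requested; correction
#' trials are included unless excluded.
#'
#' @param trials cohort or single-animal trials.
#' @param phase,day,stay_shift,contrast optional filters (values to keep);
#'   `stay_shift`/`contrast` require annotation, which is added when absent.
#' @param include_ambiguous include both-rewarded probe trials.
#' @param include_corrections include correction trials.
#' @return the proportion correct, or `NA` when the selection is empty.
#' @export
cue_accuracy <- function(trials, phase = NULL, day = NULL, stay_shift = NULL,
                         contrast = NULL, include_ambiguous = FALSE,
                         include_corrections = TRUE) {
  if (!"stay_shift" %in% names(trials)) trials <- annotate_trials(trials)
  keep <- rep(TRUE, nrow(trials))
  if (!is.null(phase)) keep <- keep & trials$phase %in% phase
  if (!is.null(day)) keep <- keep & trials$day %in% day
  if (!is.null(stay_shift)) keep <- keep & trials$stay_shift %in% stay_shift
  if (!is.null(contrast)) keep <- keep & trials$contrast %in% contrast
  if (!include_ambiguous) keep <- keep & trials$correct_sides != "LR"
  if (!include_corrections) keep <- keep & !trials$is_correction
  if (!any(keep)) return(NA_real_)
  mean(trials$rewarded[keep])
}

.OUTCOME_RULES <- c("win-stay", "win-shift", "lose-stay", "lose-shift")

#' Outcome-rule application frequencies
#'
#' Counts how often each of the four outcome rules was applied and expresses
#' stay/shift responses relative to the number of previous-win and
#' previous-lose trials, so that win-stay + win-shift = 1 and lose-stay +
#' lose-shift = 1 whenever the denominators are nonzero. Trials without a
#' defined previous trial are skipped.
#'
#' @param trials one stream of trials (annotated or raw).
#' @return tibble with `rule`, `n_applied`, `n_context` (win or lose trials)
#'   and `frequency` (`NA` when the context never occurred).
#' @export
outcome_rule_frequencies <- function(trials) {
  if (!"outcome_rule" %in% names(trials)) trials <- annotate_trials(trials)
  rules <- trials$outcome_rule[!is.na(trials$outcome_rule)]
  applied <- setNames(tabulate(match(rules, .OUTCOME_RULES), 4), .OUTCOME_RULES)
  context <- ifelse(startsWith(.OUTCOME_RULES, "win"),
                    sum(applied[1:2]), sum(applied[3:4]))
  tibble::tibble(
    rule = .OUTCOME_RULES,
    n_applied = as.integer(applied),
    n_context = as.integer(context),
    frequency = ifelse(context > 0, applied / context, NA_real_)
  )
}

#' Reward probability of each outcome rule
#'
#' For each rule, the number of times applying it was rewarded divided by
#' the number of times it was applied — the reward rate of the rule from the
#' animal's perspective. Rules never applied get `NA`.
#'
#' @inheritParams outcome_rule_frequencies
#' @return tibble with `rule`, `n_applied`, `n_rewarded`, `p_reward`.
#' @export
rule_reward_probabilities <- function(trials) {
  if (!"outcome_rule" %in% names(trials)) trials <- annotate_trials(trials)
  ok <- !is.na(trials$outcome_rule)
  rule <- factor(trials$outcome_rule[ok], levels = .OUTCOME_RULES)
  applied <- table(rule)
  rewarded <- tapply(trials$rewarded[ok], rule, sum, default = 0)
  tibble::tibble(
    rule = .OUTCOME_RULES,
    n_applied = as.integer(applied),
    n_rewarded = as.integer(rewarded),
    p_reward = unname(ifelse(applied > 0,
                             rewarded / as.integer(applied), NA_real_))
  )
}

#' Per-animal, per-day metric table
#'
#' One row per animal x day: trial counts, cue accuracy overall and split by
#' stay/shift and contrast class, outcome-rule frequencies and per-rule
#' reward probabilities. Suitable as input to external ANOVA tooling.
#'
#' @param trials a cohort tibble.
#' @param include_corrections include correction trials in accuracies.
#' @return a tibble, one row per animal and day.
#' @export
day_metrics <- function(trials, include_corrections = TRUE) {
  trials <- annotate_trials(trials)
  split(trials, list(trials$animal_id, trials$day), drop = TRUE) |>
    lapply(function(d) {
      freq <- outcome_rule_frequencies(d)
      rew <- rule_reward_probabilities(d)
      acc <- function(...) cue_accuracy(d, ...,
                                        include_corrections = include_corrections)
      tibble::tibble(
        animal_id = d$animal_id[1], group = d$group[1], day = d$day[1],
        phase = d$phase[1], n_trials = nrow(d),
        accuracy = acc(),
        accuracy_stay = acc(stay_shift = "stay"),
        accuracy_shift = acc(stay_shift = "shift"),
        accuracy_hc = acc(contrast = "high"),
        accuracy_lc = acc(contrast = "low"),
        f_win_stay = freq$frequency[1], f_win_shift = freq$frequency[2],
        f_lose_stay = freq$frequency[3], f_lose_shift = freq$frequency[4],
        p_rew_win_stay = rew$p_reward[1], p_rew_win_shift = rew$p_reward[2],
        p_rew_lose_stay = rew$p_reward[3], p_rew_lose_shift = rew$p_reward[4]
      )
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$animal_id, .data$day)
}

#' Exact binomial test against a reference probability
#'
#' @param k number of successes.
#' @param n number of trials (>= 1).
#' @param p0 reference success probability.
#' @param side `"greater"`, `"less"` or `"two.sided"`.
#' @return the exact binomial p-value.
#' @export
binomial_test <- function(k, n, p0 = 0.5,
                          side = c("greater", "less", "two.sided")) {
  side <- match.arg(side)
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1", call. = FALSE)
  stopifnot(p0 > 0, p0 < 1)
  binom.test(k, n, p = p0, alternative = side)$p.value
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction by default, matching the convention of the
#' escape-count comparisons this package produces.
#'
#' @param counts 2x2 matrix of nonnegative counts.
#' @param correct apply the Yates continuity correction.
#' @return list with `statistic`, `p_value`, `df`; statistic and p are `NA`
#'   when a margin is zero.
#' @export
chi_square_2x2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    return(list(statistic = NA_real_, p_value = NA_real_, df = 1L))
  }
  res <- suppressWarnings(chisq.test(counts, correct = correct))
  list(statistic = unname(res$statistic), p_value = res$p.value, df = 1L)
}

#' Pearson correlation with Fisher z-transform
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return list with `r` and `z = atanh(r)`; both `NA` when either series
#'   has zero variance, `z` infinite when `|r| = 1`.
#' @export
fisher_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, z = NA_real_))
  }
  r <- cor(x, y)
  if (abs(r) > 1 - 1e-12) r <- sign(r)  # guard rounding at perfect correlation
  list(r = r, z = atanh(r))
}
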