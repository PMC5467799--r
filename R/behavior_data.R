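#' Trial-level data model for two-choice operant logs
#'
#' A cohort is a tibble with one row per trial and the columns
#' `animal_id`, `group`, `phase` (`"I"`, `"II"`, `"III"`), `day`,
#' `trial_index` (1-based within session), `top_brightness`,
#' `bottom_brightness` (percent in \[0, 100\]), `correct_sides`
#' (`"L"`, `"R"` or `"LR"` for ambiguous trials), `response` (`"L"`/`"R"`),
#' `rewarded` (logical) and `is_correction` (logical). Contrast class and
#' target position are always derived from the two brightness values and
#' never stored, so they cannot fall out of sync with the cues.
#'
#' @name behavior_data
NULL

#' Classify the cue contrast of a trial
#'
#' High contrast: exactly one cue lit. Low contrast: both lit with unequal
#' brightness. Ambiguous: both lit at equal brightness.
#'
#' @param top_brightness,bottom_brightness cue brightness in percent.
#' @return character vector in `c("high", "low", "ambiguous")`.
#' @export
contrast_class <- function(top_brightness, bottom_brightness) {
  stopifnot(all(top_brightness >= 0 & top_brightness <= 100),
            all(bottom_brightness >= 0 & bottom_brightness <= 100))
  n_lit <- (top_brightness > 0) + (bottom_brightness > 0)
  if (any(n_lit == 0)) stop("trial with no lit cue", call. = FALSE)
  dplyr::case_when(
    n_lit == 1 ~ "high",
    top_brightness != bottom_brightness ~ "low",
    TRUE ~ "ambiguous"
  )
}

#' Position of the strictly brighter cue
#'
#' @inheritParams contrast_class
#' @return `"top"`, `"bottom"`, or `NA` for ambiguous trials.
#' @export
target_position <- function(top_brightness, bottom_brightness) {
  dplyr::case_when(
    top_brightness > bottom_brightness ~ "top",
    bottom_brightness > top_brightness ~ "bottom",
    TRUE ~ NA_character_
  )
}

single_correct_side <- function(correct_sides) {
  ifelse(correct_sides %in% c("L", "R"), correct_sides, NA_character_)
}

#' Stay/shift classification of one trial given its predecessor
#'
#' A trial is a *stay* trial when its (single) correct side equals the
#' reference side carried over from the previous trial, and a *shift* trial
#' when it is the opposite side. The reference side is the previous trial's
#' correct side; after an ambiguous trial (both sides correct) it is the side
#' the animal actually chose, which was rewarded. The label is undefined on
#' the first trial of an animal's record and on ambiguous current trials.
#'
#' @param current,previous one-row data frames (or lists) with the trial
#'   columns; `previous` may be `NULL`.
#' @return `"stay"`, `"shift"` or `"undefined"`.
#' @export
classify_stay_shift <- function(current, previous) {
  if (is.null(previous)) return("undefined")
  if (!identical(as.character(current$animal_id),
                 as.character(previous$animal_id))) {
    stop("cannot classify stay/shift across different animals", call. = FALSE)
  }
  ref <- reference_side(previous)
  cur <- single_correct_side(current$correct_sides)
  if (is.na(ref) || is.na(cur)) return("undefined")
  if (cur == ref) "stay" else "shift"
}

# The side a stay trial would repeat: the previous correct side, or, after an
# ambiguous trial, the (rewarded) side the animal chose.
reference_side <- function(previous) {
  side <- single_correct_side(previous$correct_sides)
  ifelse(is.na(side), previous$response, side)
}

#' Outcome-rule classification of a response
#'
#' Labels the current response as win/lose x stay/shift relative to the
#' previous trial: win/lose from whether the previous trial was rewarded,
#' stay/shift from whether the response repeats the previous response.
#'
#' @param previous one-row data frame or list for the previous trial, or
#'   `NULL` for the first trial of a record.
#' @param response the current trial's response, `"L"` or `"R"`.
#' @return one of `"win-stay"`, `"win-shift"`, `"lose-stay"`, `"lose-shift"`,
#'   `"undefined"`.
#' @export
classify_outcome_rule <- function(previous, response) {
  if (is.null(previous)) return("undefined")
  stopifnot(response %in% .SIDES)
  wl <- if (isTRUE(as.logical(previous$rewarded))) "win" else "lose"
  ss <- if (response == previous$response) "stay" else "shift"
  paste(wl, ss, sep = "-")
}

#' Annotate a cohort with derived per-trial classifications
#'
#' Adds, per trial: `contrast`, `target` (brighter cue position),
#' `correct_side` (single side or `NA` for ambiguous), `prev_response`,
#' `prev_rewarded`, `stay_shift` and `outcome_rule`. Labels involving the
#' previous trial are `NA` on each animal's first trial. Trials are ordered
#' by animal, day and trial index.
#'
#' @param trials a cohort tibble (see [behavior_data]).
#' @return the cohort with annotation columns appended.
#' @export
annotate_trials <- function(trials) {
  validate_trials(trials)
  trials |>
    dplyr::arrange(.data$animal_id, .data$day, .data$trial_index) |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::mutate(
      contrast = contrast_class(.data$top_brightness, .data$bottom_brightness),
      target = target_position(.data$top_brightness, .data$bottom_brightness),
      correct_side = single_correct_side(.data$correct_sides),
      prev_response = dplyr::lag(.data$response),
      prev_rewarded = dplyr::lag(.data$rewarded),
      .ref_side = dplyr::lag(
        ifelse(is.na(single_correct_side(.data$correct_sides)),
               .data$response, single_correct_side(.data$correct_sides))),
      stay_shift = dplyr::case_when(
        is.na(.data$.ref_side) | is.na(.data$correct_side) ~ NA_character_,
        .data$correct_side == .data$.ref_side ~ "stay",
        TRUE ~ "shift"
      ),
      outcome_rule = dplyr::case_when(
        is.na(.data$prev_response) ~ NA_character_,
        TRUE ~ paste(ifelse(.data$prev_rewarded, "win", "lose"),
                     ifelse(.data$response == .data$prev_response,
                            "stay", "shift"),
                     sep = "-")
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".ref_side")
}

trial_columns <- function() {
  c("animal_id", "group", "phase", "day", "trial_index",
    "top_brightness", "bottom_brightness", "correct_sides",
    "response", "rewarded", "is_correction")
}

#' Validate the invariants of a cohort of trials
#'
#' Checks column presence, value alphabets, the reward contingency
#' (`rewarded` iff `response` is in `correct_sides`), that correction trials
#' occur only in phases I and II, strictly increasing trial indices within a
#' session, and non-decreasing phase over days within each animal. Errors
#' name the offending row.
#'
#' @param trials a cohort tibble.
#' @return the validated tibble, invisibly.
#' @export
validate_trials <- function(trials) {
  missing <- setdiff(trial_columns(), names(trials))
  if (length(missing)) {
    stop("missing trial columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_row <- function(what, idx) {
    stop(sprintf("invalid trial data (%s) at row %d", what, idx[1]),
         call. = FALSE)
  }
  if (nrow(trials) == 0) return(invisible(trials))
  chk <- function(ok, what) if (any(!ok)) bad_row(what, which(!ok))
  chk(trials$phase %in% .PHASES, "phase not in I/II/III")
  chk(trials$correct_sides %in% c("L", "R", "LR"), "correct_sides")
  chk(trials$response %in% .SIDES, "response not L/R")
  chk(is.finite(trials$day) & trials$day >= 1, "day")
  chk(is.finite(trials$trial_index) & trials$trial_index >= 1, "trial_index")
  chk(trials$top_brightness >= 0 & trials$top_brightness <= 100 &
        trials$bottom_brightness >= 0 & trials$bottom_brightness <= 100,
      "brightness outside [0, 100]")
  hit <- mapply(grepl, trials$response, trials$correct_sides)
  chk(as.logical(trials$rewarded) == hit,
      "rewarded flag inconsistent with correct_sides")
  chk(!(as.logical(trials$is_correction) & trials$phase == "III"),
      "correction trial in phase III")
  by_sess <- split(seq_len(nrow(trials)),
                   paste(trials$animal_id, trials$day, sep = "\r"))
  for (idx in by_sess) {
    ti <- trials$trial_index[idx]
    if (any(diff(ti) <= 0)) bad_row("non-increasing trial_index", idx[-1][diff(ti) <= 0])
  }
  by_animal <- split(seq_len(nrow(trials)), trials$animal_id)
  for (idx in by_animal) {
    ord <- idx[order(trials$day[idx], trials$trial_index[idx])]
    ph <- match(trials$phase[ord], .PHASES)
    if (any(diff(ph) < 0)) bad_row("phase decreasing over days", ord[-1][diff(ph) < 0])
  }
  invisible(trials)
}

#' Read a cohort of trials from CSV
#'
#' Reads the tidy trial-log dialect (UTF-8, header, comma-separated; see
#' [behavior_data]) and validates every trial invariant. Parse failures
#' report the offending row.
#'
#' @param path file path.
#' @return a validated cohort tibble ordered by animal, day, trial index.
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      animal_id = readr::col_character(),
      group = readr::col_character(),
      phase = readr::col_character(),
      day = readr::col_integer(),
      trial_index = readr::col_integer(),
      top_brightness = readr::col_double(),
      bottom_brightness = readr::col_double(),
      correct_sides = readr::col_character(),
      response = readr::col_character(),
      rewarded = readr::col_integer(),
      is_correction = readr::col_integer()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  prob <- readr::problems(trials)
  if (nrow(prob) > 0) {
    stop(sprintf("parse error at line %d: %s", prob$row[1] + 1L,
                 prob$expected[1]), call. = FALSE)
  }
  trials$rewarded <- as.logical(trials$rewarded)
  trials$is_correction <- as.logical(trials$is_correction)
  validate_trials(trials)
  dplyr::arrange(trials, .data$animal_id, .data$day, .data$trial_index)
}

#' Write a cohort of trials to CSV
#'
#' Writes the canonical trial-log columns (simulator annotation columns are
#' dropped). `write_trials()` followed by [read_trials()] is the identity on
#' valid cohorts.
#'
#' @param trials a cohort tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  out <- trials[, trial_columns()]
  out$rewarded <- as.integer(out$rewarded)
  out$is_correction <- as.integer(out$is_correction)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
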