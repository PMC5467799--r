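#' Behavioural agents
#'
#' Agents map a trial context to a probability of responding left, and may
#' learn from feedback. Five families are provided: outcome-table agents
#' conditioning only on the previous outcome (win/lose), cue-table agents
#' conditioning only on the current cue (position x contrast, per day),
#' reinforcement-learning agents sampling from the softmax of their learned
#' values, constant side-bias agents, and random agents.
#'
#' @name agents
NULL

agent_spec <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "agent_spec")
}

#' Agent specifications
#'
#' @description
#' * `agent_random()`: responds left with probability 0.5 on every trial.
#' * `agent_side_bias(p_left)`: responds left with a constant probability,
#'   ignoring all context.
#' * `agent_outcome_table(p_stay_win, p_stay_lose)`: after a rewarded trial
#'   repeats its previous response with probability `p_stay_win`, after an
#'   unrewarded trial with `p_stay_lose`; uniform on the first trial of a
#'   session. Probabilities may be scalars or per-day tables (data frame with
#'   columns `day`, `p_stay_win`, `p_stay_lose`); days missing from the table
#'   fall back to `fallback`.
#' * `agent_cue_table(table, fallback)`: responds left with probability
#'   `p_left` looked up by day, cue position and contrast class from `table`
#'   (columns `day`, `target`, `contrast`, `p_left`; `target` is `NA` for
#'   ambiguous trials). Missing contexts fall back to `fallback`.
#' * `agent_cue_rule(p_correct)`: responds to the side indicated by the
#'   brighter cue with probability `p_correct` (uniform on ambiguous trials);
#'   the idealised cue-rule follower.
#' * `agent_rl(model_spec, params)`: chooses by softmax over the learned
#'   values of the current state's two actions and updates them from reward
#'   feedback (see [rl_model_spec()] and [rl_params()]).
#'
#' @param p_left probability of a left response.
#' @param p_stay_win,p_stay_lose stay probabilities after wins and losses.
#' @param table per-day cue-response probability table.
#' @param fallback probability used for contexts absent from a table.
#' @param p_correct probability of following the cue rule.
#' @param model_spec,params RL model specification and parameters.
#' @return an `agent_spec` for [make_agent()].
#' @export
agent_random <- function() agent_spec("random")

#' @rdname agent_random
#' @export
agent_side_bias <- function(p_left) {
  stopifnot(p_left >= 0, p_left <= 1)
  agent_spec("side_bias", p_left = p_left)
}

#' @rdname agent_random
#' @export
agent_outcome_table <- function(p_stay_win, p_stay_lose, fallback = 0.5) {
  if (is.data.frame(p_stay_win)) {
    tab <- p_stay_win
    stopifnot(all(c("day", "p_stay_win", "p_stay_lose") %in% names(tab)))
    agent_spec("outcome_table", table = tab, fallback = fallback)
  } else {
    stopifnot(p_stay_win >= 0, p_stay_win <= 1,
              p_stay_lose >= 0, p_stay_lose <= 1)
    agent_spec("outcome_table",
               table = data.frame(day = NA_integer_,
                                  p_stay_win = p_stay_win,
                                  p_stay_lose = p_stay_lose),
               fallback = fallback)
  }
}

#' @rdname agent_random
#' @export
agent_cue_table <- function(table, fallback = 0.5) {
  stopifnot(all(c("day", "target", "contrast", "p_left") %in% names(table)))
  if (any(table$p_left < 0 | table$p_left > 1)) {
    stop("cue-table probabilities must lie in [0, 1]", call. = FALSE)
  }
  agent_spec("cue_table", table = table, fallback = fallback)
}

#' @rdname agent_random
#' @export
agent_cue_rule <- function(p_correct = 1) {
  stopifnot(p_correct >= 0, p_correct <= 1)
  agent_spec("cue_rule", p_correct = p_correct)
}

#' @rdname agent_random
#' @export
agent_rl <- function(model_spec, params) {
  stopifnot(inherits(model_spec, "rl_model_spec"))
  validate_rl_params(params, model_spec)
  agent_spec("rl", model_spec = model_spec, params = params)
}

#' Instantiate an agent from its specification
#'
#' Builds a fresh agent with its own internal state. The agent is a list
#' with `choose(ctx)` returning the probability of a left response in the
#' given context, and `learn(ctx, response, rewarded)` consuming feedback
#' (a no-op for non-learning agents). The context carries `day`, `phase`,
#' `target` (brighter-cue position or `NA`), `contrast`, `prev_response`
#' and `prev_rewarded`.
#'
#' @param spec an `agent_spec`.
#' @return an agent.
#' @export
make_agent <- function(spec) {
  stopifnot(inherits(spec, "agent_spec"))
  switch(spec$kind,
    random = list(kind = "random",
                  choose = function(ctx) 0.5,
                  learn = function(ctx, response, rewarded) invisible(NULL)),
    side_bias = list(kind = "side_bias",
                     choose = function(ctx) spec$p_left,
                     learn = function(ctx, response, rewarded) invisible(NULL)),
    outcome_table = make_outcome_table_agent(spec),
    cue_table = make_cue_table_agent(spec),
    cue_rule = list(
      kind = "cue_rule",
      choose = function(ctx) {
        if (is.na(ctx$target)) return(0.5)
        if (unname(.CUE_MAP[ctx$target]) == "L") spec$p_correct else 1 - spec$p_correct
      },
      learn = function(ctx, response, rewarded) invisible(NULL)),
    rl = make_rl_agent(spec),
    stop("unknown agent kind: ", spec$kind, call. = FALSE)
  )
}

make_outcome_table_agent <- function(spec) {
  tab <- spec$table
  fallback <- spec$fallback
  # hashed per-day lookup keeps the per-trial cost flat in the table size
  env <- new.env(parent = emptyenv(), size = max(2L, nrow(tab)))
  day_wide <- all(is.na(tab$day))
  for (i in seq_len(nrow(tab))) {
    key <- if (day_wide) "all" else as.character(tab$day[i])
    assign(key, c(win = tab$p_stay_win[i], lose = tab$p_stay_lose[i]), envir = env)
  }
  list(
    kind = "outcome_table",
    choose = function(ctx) {
      if (is.na(ctx$prev_response)) return(0.5)
      key <- if (day_wide) "all" else as.character(ctx$day)
      pr <- if (exists(key, envir = env, inherits = FALSE)) get(key, envir = env)
            else c(win = NA_real_, lose = NA_real_)
      p_stay <- if (isTRUE(ctx$prev_rewarded)) pr[["win"]] else pr[["lose"]]
      if (is.na(p_stay)) p_stay <- fallback
      if (ctx$prev_response == "L") p_stay else 1 - p_stay
    },
    learn = function(ctx, response, rewarded) invisible(NULL)
  )
}

make_cue_table_agent <- function(spec) {
  tab <- spec$table
  fallback <- spec$fallback
  env <- new.env(parent = emptyenv(), size = max(2L, nrow(tab)))
  keys <- paste(tab$day, tab$target, tab$contrast)
  for (i in seq_len(nrow(tab))) assign(keys[i], tab$p_left[i], envir = env)
  list(
    kind = "cue_table",
    choose = function(ctx) {
      key <- paste(ctx$day, ctx$target, ctx$contrast)
      v <- if (exists(key, envir = env, inherits = FALSE)) get(key, envir = env)
           else NA_real_
      if (is.na(v)) fallback else v
    },
    learn = function(ctx, response, rewarded) invisible(NULL)
  )
}

make_rl_agent <- function(spec) {
  ms <- spec$model_spec
  par <- spec$params
  env <- new.env(parent = emptyenv())
  env$V <- matrix(ms$v0, 2, 2)  # rows: states, cols: actions
  env$alpha <- ms$alpha0
  # cue family: states top/bottom, actions L/R
  # outcome family: states win/lose, actions stay/shift
  state_idx <- function(ctx) {
    if (ms$family == "cue") {
      if (is.na(ctx$target)) NA_integer_ else match(ctx$target, .POSITIONS)
    } else {
      if (is.na(ctx$prev_response)) NA_integer_
      else if (isTRUE(ctx$prev_rewarded)) 1L else 2L
    }
  }
  list(
    kind = "rl",
    choose = function(ctx) {
      s <- state_idx(ctx)
      if (is.na(s)) return(0.5)
      beta <- par[[paste0("beta_", ctx$phase)]]
      v <- env$V[s, ]
      p1 <- 1 / (1 + exp(-beta * (v[1] - v[2])))
      if (ms$family == "cue") {
        p1  # action 1 = L
      } else {
        # action 1 = stay: p(L) depends on which side staying means
        if (ctx$prev_response == "L") p1 else 1 - p1
      }
    },
    learn = function(ctx, response, rewarded) {
      s <- state_idx(ctx)
      if (is.na(s)) return(invisible(NULL))
      a <- if (ms$family == "cue") match(response, .SIDES)
           else if (response == ctx$prev_response) 1L else 2L
      kappa <- if (ms$rule == "hybrid_fixed") 1 else par$kappa
      delta <- as.numeric(rewarded) - env$V[s, a]
      env$V[s, a] <- env$V[s, a] + kappa * env$alpha * delta
      if (ms$rule != "rw") env$alpha <- (1 - par$eta) * env$alpha + par$eta * abs(delta)
      invisible(NULL)
    },
    state = env
  )
}
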