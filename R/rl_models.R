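#' Reinforcement-learning models of cue-rule and outcome-rule learning
#'
#' Two model families track the values of four state-action pairs each: the
#' *cue* family conditions on the brighter cue's position (top/bottom) with
#' actions left/right; the *outcome* family conditions on the previous
#' trial's outcome (win/lose) with actions stay/shift. Values are updated by
#' a hybrid Rescorla-Wagner/Pearce-Hall rule
#' \deqn{V_{t+1}(s,a) = V_t(s,a) + \kappa \alpha_t \delta, \quad
#'       \delta = r_t - V_t(s,a)}
#' with associability
#' \deqn{\alpha_t = (1-\eta)\alpha_{t-1} + \eta |\delta|,}
#' and choices follow a softmax with a separate inverse temperature
#' \eqn{\beta_k} per task phase. Reduced variants fix \eqn{\kappa = 1}
#' (`hybrid_fixed`) or keep the associability constant (`rw`, a pure
#' Rescorla-Wagner learner with rate \eqn{\kappa \alpha_0}).
#'
#' @name rl_models
NULL

.RL_RULES <- c("hybrid", "hybrid_fixed", "rw")

#' Specify an RL model
#'
#' @param family `"cue"` (states top/bottom, actions L/R) or `"outcome"`
#'   (states win/lose, actions stay/shift).
#' @param rule `"hybrid"` (free \eqn{\kappa} and \eqn{\eta}),
#'   `"hybrid_fixed"` (\eqn{\kappa = 1}), or `"rw"` (constant associability;
#'   \eqn{\eta} unused).
#' @param v0 initial value of every state-action pair.
#' @param alpha0 initial associability.
#' @param beta_max upper optimisation bound for the inverse temperatures.
#' @return an `rl_model_spec`.
#' @export
rl_model_spec <- function(family = c("cue", "outcome"),
                          rule = c("hybrid", "hybrid_fixed", "rw"),
                          v0 = 0, alpha0 = 1, beta_max = 50) {
  family <- match.arg(family)
  rule <- match.arg(rule)
  stopifnot(v0 >= 0, v0 <= 1, alpha0 >= 0, alpha0 <= 1, beta_max > 0)
  structure(list(family = family, rule = rule, v0 = v0, alpha0 = alpha0,
                 beta_max = beta_max,
                 id = paste(family, rule, sep = "_")),
            class = "rl_model_spec")
}

#' RL model parameters
#'
#' @param kappa global learning rate in \[0, 1\].
#' @param eta associability update weight in \[0, 1\].
#' @param beta_I,beta_II,beta_III inverse temperatures (> 0; 0 allowed for
#'   diagnostics) for the three task phases.
#' @return a named parameter list.
#' @export
rl_params <- function(kappa = 0.5, eta = 0.5,
                      beta_I = 1, beta_II = 1, beta_III = 1) {
  list(kappa = kappa, eta = eta,
       beta_I = beta_I, beta_II = beta_II, beta_III = beta_III)
}

validate_rl_params <- function(params, spec = NULL) {
  with(params, {
    if (kappa < 0 || kappa > 1) stop("kappa outside [0, 1]", call. = FALSE)
    if (eta < 0 || eta > 1) stop("eta outside [0, 1]", call. = FALSE)
    if (any(c(beta_I, beta_II, beta_III) < 0)) {
      stop("inverse temperatures must be nonnegative", call. = FALSE)
    }
  })
  invisible(params)
}

#' Model state of a trial
#'
#' @param current annotated current trial (one row of [annotate_trials()]
#'   output, or a list with `target`/`prev_rewarded`).
#' @param model_spec an [rl_model_spec()].
#' @return for the cue family, the brighter cue's position (`"top"`/
#'   `"bottom"`, `NA` on ambiguous trials); for the outcome family, `"win"`
#'   or `"lose"` from the previous trial's reward (`NA` on an animal's first
#'   trial).
#' @export
state_of <- function(current, model_spec) {
  if (model_spec$family == "cue") {
    current$target
  } else {
    ifelse(is.na(current$prev_rewarded), NA_character_,
           ifelse(current$prev_rewarded, "win", "lose"))
  }
}

#' One hybrid Rescorla-Wagner/Pearce-Hall value update
#'
#' Updates only the visited state-action pair: \eqn{\delta = r - V(s,a)},
#' \eqn{V(s,a) \mathrel{+}= \kappa \alpha_t \delta}, then (for hybrid rules)
#' \eqn{\alpha_{t+1} = (1-\eta)\alpha_t + \eta|\delta|}. The `rw` rule keeps
#' the associability constant. With rewards in \{0, 1\} and
#' \eqn{V_0, \alpha_0 \in [0,1]}, values and associability stay in \[0, 1\].
#'
#' @param values list with `V` (2 x 2 matrix, states x actions) and `alpha`.
#' @param state,action 1-based indices into the value table.
#' @param r reward, 0 or 1.
#' @param params an [rl_params()] list.
#' @param rule update rule (see [rl_model_spec()]).
#' @return updated `values` with the last prediction error in `delta`.
#' @export
rl_update <- function(values, state, action, r, params,
                      rule = c("hybrid", "hybrid_fixed", "rw")) {
  rule <- match.arg(rule)
  validate_rl_params(params)
  stopifnot(r %in% c(0, 1))
  kappa <- if (rule == "hybrid_fixed") 1 else params$kappa
  delta <- r - values$V[state, action]
  values$V[state, action] <- values$V[state, action] + kappa * values$alpha * delta
  if (rule != "rw") {
    values$alpha <- (1 - params$eta) * values$alpha + params$eta * abs(delta)
  }
  values$delta <- delta
  values
}

#' Softmax choice probabilities over a state's two actions
#'
#' \eqn{p(a|s) = e^{\beta V(s,a)} / \sum_l e^{\beta V(s,l)}}; overflow-safe
#' and invariant to adding a constant to both values.
#'
#' @param v numeric vector of the state's action values.
#' @param beta inverse temperature (>= 0; 0 gives the uniform distribution).
#' @return probabilities summing to 1.
#' @export
choice_probabilities <- function(v, beta) {
  stopifnot(beta >= 0)
  z <- beta * (v - max(v))
  exp(z) / sum(exp(z))
}

# Translate one animal's annotated trials into the integer streams the
# likelihood kernel consumes. Ambiguous trials and the animal's first trial
# are excluded from the likelihood of BOTH families so the trial count n is
# identical across models; trials with a defined state still drive updates
# (in particular, ambiguous trials update the outcome model).
prepare_record <- function(trials, family) {
  stopifnot(length(unique(trials$animal_id)) == 1)
  if (!"target" %in% names(trials)) trials <- annotate_trials(trials)
  first <- seq_len(nrow(trials)) == 1L
  ambiguous <- trials$correct_sides == "LR"
  include <- !first & !ambiguous
  if (family == "cue") {
    state <- match(trials$target, .POSITIONS)
    action <- match(trials$response, .SIDES)
    action[is.na(state)] <- NA_integer_
  } else {
    state <- ifelse(is.na(trials$prev_rewarded), NA_integer_,
                    ifelse(trials$prev_rewarded, 1L, 2L))
    action <- ifelse(is.na(trials$prev_response), NA_integer_,
                     ifelse(trials$response == trials$prev_response, 1L, 2L))
  }
  list(state = as.integer(state), action = as.integer(action),
       reward = as.numeric(trials$rewarded),
       phase = match(trials$phase, .PHASES),
       include = include, n = sum(include))
}

#' Negative log-likelihood of an animal's choices under an RL model
#'
#' Runs the value-learning forward pass over the animal's full trial stream
#' (values and associability carry over across sessions and phases; only the
#' phase-specific \eqn{\beta_k} switches) and sums \eqn{-\log p(a_t|s_t)}
#' over included trials. Ambiguous trials and the first trial are excluded
#' from the likelihood of both families; ambiguous trials still update
#' outcome-family values.
#'
#' @param params an [rl_params()] list.
#' @param trials one animal's trials (annotated or raw).
#' @param model_spec an [rl_model_spec()].
#' @param record optional pre-built record from the internal preparation
#'   step, to avoid re-annotation in tight loops.
#' @return the negative log-likelihood (scalar).
#' @export
rl_nll <- function(params, trials, model_spec, record = NULL) {
  validate_rl_params(params)
  if (is.null(record)) record <- prepare_record(trials, model_spec$family)
  if (record$n == 0) stop("no trials enter the likelihood", call. = FALSE)
  beta <- c(params$beta_I, params$beta_II, params$beta_III)
  rl_nll_cpp(record$state, record$action, record$reward, record$phase,
             record$include, params$kappa, params$eta, beta,
             model_spec$v0, model_spec$alpha0,
             match(model_spec$rule, .RL_RULES) - 1L)
}

# Free parameters per rule; fixed ones are pinned in the objective.
free_params <- function(rule) {
  switch(rule,
         hybrid = c("kappa", "eta", "beta_I", "beta_II", "beta_III"),
         hybrid_fixed = c("eta", "beta_I", "beta_II", "beta_III"),
         rw = c("kappa", "beta_I", "beta_II", "beta_III"))
}

#' Fit an RL model to one animal by multistart maximum likelihood
#'
#' Bounded quasi-Newton (`L-BFGS-B`) minimisation of [rl_nll()] from
#' `n_starts` random initial points: \eqn{\kappa, \eta} drawn uniformly in
#' \[0, 1\], inverse temperatures log-uniformly in \[0.01, `beta_max`\]. The
#' best converged start wins. The full hybrid rule has 5 free parameters,
#' the fixed-\eqn{\kappa} hybrid and the pure Rescorla-Wagner rule 4 each.
#'
#' @param trials one animal's trials.
#' @param model_spec an [rl_model_spec()].
#' @param n_starts number of random initial points (default 100).
#' @param seed integer seed making the start set reproducible.
#' @return a `FitResult` list: `model_id`, `params` (full parameter list,
#'   fixed values included), `logLik`, `n` (likelihood trials), `k` (free
#'   parameter count), `bic`, `starts` (per-start diagnostics), `seed`.
#' @export
rl_fit <- function(trials, model_spec, n_starts = 100, seed = 1L) {
  stopifnot(n_starts >= 1)
  record <- prepare_record(trials, model_spec$family)
  if (record$n == 0) stop("no trials enter the likelihood", call. = FALSE)
  free <- free_params(model_spec$rule)
  is_beta <- startsWith(free, "beta")
  lower <- ifelse(is_beta, 1e-4, 0)
  upper <- ifelse(is_beta, model_spec$beta_max, 1)
  obj <- function(x) {
    par <- rl_params(kappa = 1, eta = 0)
    par[free] <- as.list(x)
    rl_nll(par, trials = NULL, model_spec, record = record)
  }
  set.seed(seed)
  inits <- matrix(NA_real_, n_starts, length(free))
  for (j in seq_along(free)) {
    inits[, j] <- if (is_beta[j]) {
      exp(runif(n_starts, log(0.01), log(model_spec$beta_max)))
    } else runif(n_starts)
  }
  starts <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      optim(inits[s, ], obj, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    starts[[s]] <- if (is.null(fit)) {
      list(value = Inf, par = inits[s, ], convergence = NA_integer_)
    } else fit[c("value", "par", "convergence")]
  }
  values <- vapply(starts, `[[`, numeric(1), "value")
  if (all(!is.finite(values))) {
    stop("all optimisation starts failed", call. = FALSE)
  }
  best <- starts[[which.min(values)]]
  params <- rl_params(kappa = 1, eta = 0)
  params[free] <- as.list(best$par)
  logLik <- -best$value
  k <- length(free)
  structure(
    list(model_id = model_spec$id, family = model_spec$family,
         rule = model_spec$rule, params = params, logLik = logLik,
         n = record$n, k = k, bic = bic(logLik, k, record$n),
         n_starts = n_starts,
         starts = tibble::tibble(
           nll = values,
           convergence = vapply(starts, `[[`, numeric(1), "convergence")),
         seed = seed),
    class = "rl_fit")
}

#' @export
print.rl_fit <- function(x, ...) {
  cat(sprintf("RL fit: %s  (n = %d trials, %d starts)\n",
              x$model_id, x$n, x$n_starts))
  cat(sprintf("  logLik = %.2f, BIC = %.2f\n", x$logLik, x$bic))
  cat("  params:",
      paste(sprintf("%s = %.3f", names(x$params), unlist(x$params)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Fit one model to every animal of a cohort
#'
#' @param trials a cohort tibble.
#' @param model_spec an [rl_model_spec()].
#' @inheritParams rl_fit
#' @return named list of `FitResult`s, one per animal.
#' @export
rl_fit_cohort <- function(trials, model_spec, n_starts = 100, seed = 1L) {
  trials <- annotate_trials(trials)
  by_animal <- split(trials, trials$animal_id)
  fits <- vector("list", length(by_animal))
  names(fits) <- names(by_animal)
  for (i in seq_along(by_animal)) {
    fits[[i]] <- rl_fit(by_animal[[i]], model_spec, n_starts = n_starts,
                        seed = animal_seed(seed, i))
  }
  fits
}
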