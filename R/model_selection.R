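#' Bayesian model selection across animals
#'
#' Log model evidence is approximated per animal by \eqn{-BIC/2}; the
#' population distribution over model frequencies \eqn{\pi_m} is then
#' estimated by random-effects Bayesian model selection: a variational
#' scheme that alternates per-animal posterior model assignments (from the
#' evidences and digamma-adjusted Dirichlet parameters) with
#' re-accumulation of the Dirichlet counts. Exceedance probabilities give
#' the posterior probability that one model is the most frequent in the
#' population (reducing to a Beta tail in the two-model case).
#'
#' @name model_selection
NULL

#' Bayesian Information Criterion
#'
#' \eqn{BIC = -2 \log L + k \log n}; \eqn{-BIC/2} approximates the log model
#' evidence.
#'
#' @param log_likelihood maximised log-likelihood.
#' @param k number of free parameters.
#' @param n number of trials entering the likelihood.
#' @return the BIC value.
#' @export
bic <- function(log_likelihood, k, n) {
  stopifnot(k >= 0)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  -2 * log_likelihood + k * log(n)
}

#' Collect an evidence matrix from fits
#'
#' @param fits list of lists of `FitResult`s: one element per model, each a
#'   per-animal list as returned by [rl_fit_cohort()]; or a named list of
#'   numeric per-animal evidence vectors.
#' @return matrix animals x models of approximate log evidences (-BIC/2).
#' @export
evidence_matrix <- function(fits) {
  if (is.list(fits[[1]]) && inherits(fits[[1]][[1]], "rl_fit")) {
    models <- names(fits)
    animals <- names(fits[[1]])
    L <- sapply(fits, function(f) {
      stopifnot(identical(names(f), animals))
      -vapply(f, `[[`, numeric(1), "bic") / 2
    })
    dimnames(L) <- list(animals, models)
    L
  } else {
    do.call(cbind, fits)
  }
}

#' Random-effects Bayesian model selection
#'
#' Variational estimation of the Dirichlet posterior over population model
#' frequencies. Starting from the prior counts \eqn{\alpha_0}, each
#' iteration computes unnormalised per-animal assignment weights
#' \eqn{u_{nm} \propto \exp(L_{nm} + \psi(\alpha_m) - \psi(\sum_j \alpha_j))},
#' normalises them per animal, accumulates \eqn{\alpha_m = \alpha_{0m} +
#' \sum_n g_{nm}}, and repeats to convergence. Only evidence differences
#' within an animal matter.
#'
#' @param evidence matrix animals x models of log model evidences (use
#'   [evidence_matrix()]), with at least 2 models.
#' @param alpha0 Dirichlet prior count per model (default 1, uniform).
#' @param tol convergence tolerance on the Dirichlet parameters.
#' @param max_iter iteration cap; non-convergence is flagged, not silent.
#' @return a `bms_result`: `alpha` (Dirichlet parameters), `expected`
#'   (posterior model probabilities \eqn{E[\pi_m] = \alpha_m / \sum \alpha}),
#'   `xp` (exceedance probabilities), `assignments` (per-animal posterior
#'   weights), `converged`, `iterations`.
#' @export
bms <- function(evidence, alpha0 = 1, tol = 1e-6, max_iter = 1e4) {
  evidence <- as.matrix(evidence)
  m <- ncol(evidence)
  if (m < 2) stop("need at least 2 models", call. = FALSE)
  if (any(!is.finite(evidence))) stop("non-finite evidences", call. = FALSE)
  stopifnot(alpha0 > 0)
  alpha <- rep(alpha0, m)
  converged <- FALSE
  iter <- 0L
  g <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    lu <- sweep(evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lu <- lu - apply(lu, 1, max)
    g <- exp(lu) / rowSums(exp(lu))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  structure(
    list(alpha = setNames(alpha, colnames(evidence)),
         expected = setNames(alpha / sum(alpha), colnames(evidence)),
         xp = exceedance(setNames(alpha, colnames(evidence))),
         assignments = g, converged = converged, iterations = iter),
    class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects BMS over", length(x$alpha), "models",
      if (!x$converged) "(NOT converged)" else "", "\n")
  tab <- rbind(alpha = x$alpha, expected = x$expected, exceedance = x$xp)
  print(round(tab, 4))
  invisible(x)
}

#' Exceedance probabilities of a Dirichlet distribution
#'
#' Probability that each model's population frequency exceeds all others'.
#' With two models this is the closed-form Beta tail
#' \eqn{P(\pi_1 > 0.5)} with \eqn{\pi_1 \sim Beta(\alpha_1, \alpha_2)};
#' with more models it is estimated by seeded Monte-Carlo Dirichlet
#' sampling.
#'
#' @param alpha Dirichlet parameters (all > 0).
#' @param n_samples Monte-Carlo draws for > 2 models.
#' @param seed RNG seed for the Monte-Carlo branch.
#' @return exceedance probabilities, summing to 1.
#' @export
exceedance <- function(alpha, n_samples = 1e6, seed = 1L) {
  stopifnot(all(alpha > 0))
  m <- length(alpha)
  if (m == 2) {
    p1 <- pbeta(0.5, alpha[1], alpha[2], lower.tail = FALSE)
    return(setNames(c(p1, 1 - p1), names(alpha)))
  }
  exceedance_mc(alpha, n_samples, seed)
}

# Monte-Carlo Dirichlet estimate of the exceedance probabilities; also the
# cross-check route for the two-model closed form.
exceedance_mc <- function(alpha, n_samples = 1e6, seed = 1L) {
  m <- length(alpha)
  set.seed(seed)
  draws <- matrix(rgamma(n_samples * m, shape = rep(alpha, each = n_samples)),
                  n_samples, m)
  winner <- max.col(draws, ties.method = "first")
  setNames(tabulate(winner, m) / n_samples, names(alpha))
}

#' Compare update rules by averaging BIC across model families
#'
#' For each animal and update rule, the BIC values of the cue and outcome
#' models are averaged and \eqn{-\overline{BIC}/2} is taken as that rule's
#' log evidence; the resulting animals x rules evidence matrix is passed to
#' [bms()].
#'
#' @param fits nested list `fits[[family]][[rule]]`, each a per-animal list
#'   of `FitResult`s with families `cue`/`outcome` and a common set of
#'   rules.
#' @param ... passed on to [bms()].
#' @return list with `evidence` (animals x rules) and `bms`.
#' @export
compare_update_rules <- function(fits, ...) {
  stopifnot(all(c("cue", "outcome") %in% names(fits)))
  rules <- names(fits$cue)
  if (!identical(sort(rules), sort(names(fits$outcome)))) {
    stop("cue and outcome fits cover different update rules", call. = FALSE)
  }
  animals <- names(fits$cue[[1]])
  ev <- matrix(NA_real_, length(animals), length(rules),
               dimnames = list(animals, rules))
  for (r in rules) {
    for (a in animals) {
      for (fam in c("cue", "outcome")) {
        if (is.null(fits[[fam]][[r]][[a]])) {
          stop(sprintf("missing fit: family %s, rule %s, animal %s",
                       fam, r, a), call. = FALSE)
        }
      }
      mean_bic <- mean(c(fits$cue[[r]][[a]]$bic, fits$outcome[[r]][[a]]$bic))
      ev[a, r] <- -mean_bic / 2
    }
  }
  list(evidence = ev, bms = bms(ev, ...))
}
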