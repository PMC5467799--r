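#' End-to-end analysis pipeline
#'
#' Configuration-driven orchestration of the full workflow: simulate a
#' cohort (or read one from CSV), compute per-day strategy metrics, run the
#' outcome- and cue-family bootstraps per animal, fit the RL models, and
#' select among them by random-effects BMS. Every output embeds the master
#' seed and a hash of the configuration so runs are reproducible and
#' auditable.
#'
#' @name pipeline
NULL

#' Build a run configuration
#'
#' @param seed master seed for every source of randomness.
#' @param cohort list: `n_animals`, `group`, and `agent` (a list with `kind`
#'   and the kind's parameters, see [agent_from_config()]); or a list of
#'   such lists for a multi-group cohort.
#' @param protocol list: `phase_I_cap`, `phase_II_cap`,
#'   `phase_III_sessions` (see [default_protocol()]).
#' @param bootstrap list: `replicates`, `level`, `families`.
#' @param fit list: `starts`, `families`, `rules`.
#' @param bms list: `prior`, `tol`.
#' @return a validated `run_config`.
#' @export
run_config <- function(seed = 1L,
                       cohort = list(n_animals = 12, group = "sim",
                                     agent = list(kind = "cue_rule",
                                                  p_correct = 0.9)),
                       protocol = list(),
                       bootstrap = list(replicates = 1000, level = 0.9,
                                        families = c("outcome", "cue")),
                       fit = list(starts = 100,
                                  families = c("cue", "outcome"),
                                  rules = "hybrid"),
                       bms = list(prior = 1, tol = 1e-6)) {
  cfg <- list(seed = as.integer(seed), cohort = cohort, protocol = protocol,
              bootstrap = bootstrap, fit = fit, bms = bms)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$seed))
  groups <- if (!is.null(cfg$cohort$agent)) list(cfg$cohort) else cfg$cohort
  for (g in groups) {
    if (is.null(g$n_animals) || g$n_animals < 1) {
      stop("config: each cohort group needs n_animals >= 1", call. = FALSE)
    }
    agent_from_config(g$agent)  # validates the agent spec
  }
  protocol_from_config(cfg$protocol)
  bs <- cfg$bootstrap
  if (!is.null(bs$level) && (bs$level <= 0 || bs$level >= 1)) {
    stop("config: bootstrap level must lie in (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path configuration file; format chosen by extension.
#' @return a validated `run_config`.
#' @export
load_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(cfg)
}

#' Build an agent spec from a configuration list
#'
#' `kind` selects the family; remaining entries are its parameters:
#' `random`; `side_bias` (`p_left`); `cue_rule` (`p_correct`);
#' `outcome_table` (`p_stay_win`, `p_stay_lose`); `rl` (`family`, `rule`,
#' `kappa`, `eta`, `beta_I`, `beta_II`, `beta_III`, optional `v0`,
#' `alpha0`).
#'
#' @param agent a named list with at least `kind`.
#' @return an `agent_spec`.
#' @export
agent_from_config <- function(agent) {
  if (is.null(agent$kind)) stop("config: agent needs a kind", call. = FALSE)
  switch(agent$kind,
    random = agent_random(),
    side_bias = agent_side_bias(agent$p_left),
    cue_rule = agent_cue_rule(agent$p_correct %||% 1),
    outcome_table = agent_outcome_table(agent$p_stay_win, agent$p_stay_lose),
    rl = {
      ms <- rl_model_spec(agent$family, agent$rule %||% "hybrid",
                          v0 = agent$v0 %||% 0, alpha0 = agent$alpha0 %||% 1)
      par <- rl_params(kappa = agent$kappa %||% 0.5,
                       eta = agent$eta %||% 0.5,
                       beta_I = agent$beta_I %||% 1,
                       beta_II = agent$beta_II %||% 1,
                       beta_III = agent$beta_III %||% 1)
      agent_rl(ms, par)
    },
    stop("config: unknown agent kind: ", agent$kind, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

protocol_from_config <- function(p) {
  default_protocol(phase_I_cap = p$phase_I_cap %||% 70,
                   phase_II_cap = p$phase_II_cap %||% 14,
                   phase_III_sessions = p$phase_III_sessions %||% 20)
}

#' Stable hash of a configuration
#'
#' FNV-1a over the canonical JSON serialisation; identical configurations
#' always map to the same hexadecimal digest, which is stamped on every
#' pipeline output.
#'
#' @param cfg a `run_config` (or any serialisable list).
#' @return an 8-hex-digit character digest.
#' @export
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits, keeping everything in
    # integer range
    h <- h - h %% 256 + bitwXor(h %% 256, b)
    # 32-bit modular multiply in doubles: split to keep products < 2^53
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  # render the 32-bit digest as hex (h may exceed integer range, so split)
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Simulate a cohort from a configuration
#'
#' @param cfg a `run_config`.
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @return the cohort tibble, with the manifest (seed, config hash, row
#'   count) attached as attribute `manifest`; files `cohort.csv` and
#'   `cohort_manifest.json` when `out_dir` is given.
#' @export
cmd_simulate <- function(cfg, out_dir = NULL) {
  cfg <- validate_run_config(cfg)
  protocol <- protocol_from_config(cfg$protocol)
  groups <- if (!is.null(cfg$cohort$agent)) list(cfg$cohort) else cfg$cohort
  specs <- list(); labels <- character(0)
  for (g in groups) {
    specs <- c(specs, rep(list(agent_from_config(g$agent)), g$n_animals))
    labels <- c(labels, rep(g$group %||% "sim", g$n_animals))
  }
  cohort <- simulate_cohort(specs, protocol = protocol, groups = labels,
                            master_seed = cfg$seed)
  manifest <- list(seed = cfg$seed, config_hash = config_hash(cfg),
                   n_animals = length(specs), n_trials = nrow(cohort))
  attr(cohort, "manifest") <- manifest
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(cohort, file.path(out_dir, "cohort.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "cohort_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  cohort
}

#' Analyse a cohort end to end
#'
#' Runs per-day metrics, per-animal bootstraps for the configured strategy
#' families, RL fits for the configured model families and update rules,
#' and random-effects BMS over the model families (using the first
#' configured rule). When several update rules are configured, the
#' BIC-averaging rule comparison is run as well.
#'
#' @param cohort a cohort tibble or a path to a trial-log CSV.
#' @param cfg a `run_config`.
#' @param out_dir output directory; `NULL` to skip writing.
#' @return list with `metrics`, `bootstrap` (per family: per-animal
#'   results, escape flags, and the group comparison when two groups are
#'   present), `fits`, `bms`, `rule_comparison` (or `NULL`), `manifest`.
#' @export
cmd_analyze <- function(cohort, cfg, out_dir = NULL) {
  cfg <- validate_run_config(cfg)
  if (is.character(cohort)) {
    if (!file.exists(cohort)) stop("cohort file not found: ", cohort,
                                   call. = FALSE)
    cohort <- read_trials(cohort)
  }
  cohort <- annotate_trials(cohort)
  protocol <- protocol_from_config(cfg$protocol)
  metrics <- day_metrics(cohort)

  by_animal <- split(cohort, cohort$animal_id)
  bs_cfg <- cfg$bootstrap
  bootstrap <- list()
  for (fam in bs_cfg$families %||% c("outcome", "cue")) {
    res <- lapply(seq_along(by_animal), function(i) {
      run_bootstrap(by_animal[[i]], family = fam,
                    n_replicates = bs_cfg$replicates %||% 1000,
                    level = bs_cfg$level %||% 0.9, protocol = protocol,
                    seed = animal_seed(cfg$seed, i))
    })
    names(res) <- names(by_animal)
    escaped <- vapply(res, `[[`, logical(1), "escaped")
    groups <- vapply(by_animal, function(d) d$group[1], character(1))
    comparison <- if (length(unique(groups)) == 2) {
      g <- unique(groups)
      group_escape_comparison(escaped[groups == g[1]], escaped[groups == g[2]])
    }
    bootstrap[[fam]] <- list(results = res, escaped = escaped,
                             comparison = comparison)
  }

  fit_cfg <- cfg$fit
  rules <- fit_cfg$rules %||% "hybrid"
  families <- fit_cfg$families %||% c("cue", "outcome")
  fits <- list()
  for (fam in families) {
    fits[[fam]] <- list()
    for (rule in rules) {
      spec <- rl_model_spec(fam, rule)
      fits[[fam]][[rule]] <- rl_fit_cohort(
        cohort, spec, n_starts = fit_cfg$starts %||% 100, seed = cfg$seed)
    }
  }
  family_fits <- lapply(fits, `[[`, rules[[1]])
  bms_res <- if (length(families) >= 2) {
    bms(evidence_matrix(family_fits), alpha0 = cfg$bms$prior %||% 1,
        tol = cfg$bms$tol %||% 1e-6)
  }
  rule_cmp <- if (length(rules) >= 2 && length(families) == 2) {
    compare_update_rules(fits, alpha0 = cfg$bms$prior %||% 1)
  }
  manifest <- list(seed = cfg$seed, config_hash = config_hash(cfg))
  out <- list(metrics = metrics, bootstrap = bootstrap, fits = fits,
              bms = bms_res, rule_comparison = rule_cmp, manifest = manifest)
  if (!is.null(out_dir)) write_analysis(out, cfg, out_dir)
  out
}

write_analysis <- function(out, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(out$metrics, file.path(out_dir, "day_metrics.csv"),
                   progress = FALSE)
  for (fam in names(out$bootstrap)) {
    b <- out$bootstrap[[fam]]
    for (id in names(b$results)) {
      stem <- file.path(out_dir, sprintf("bootstrap_%s_%s", fam, id))
      write_bootstrap(b$results[[id]],
                      csv_path = paste0(stem, ".csv"),
                      json_path = paste0(stem, ".json"))
    }
  }
  fit_rows <- list()
  for (fam in names(out$fits)) {
    for (rule in names(out$fits[[fam]])) {
      for (id in names(out$fits[[fam]][[rule]])) {
        f <- out$fits[[fam]][[rule]][[id]]
        fit_rows[[length(fit_rows) + 1L]] <-
          c(list(animal_id = id, model = f$model_id), f$params,
            list(logLik = f$logLik, n = f$n, k = f$k, bic = f$bic))
      }
    }
  }
  jsonlite::write_json(fit_rows, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(out$bms)) {
    fam_fits <- lapply(out$fits, `[[`, 1L)
    ev <- evidence_matrix(fam_fits)
    readr::write_csv(
      tibble::as_tibble(ev, rownames = "animal_id"),
      file.path(out_dir, "evidence.csv"), progress = FALSE)
    jsonlite::write_json(
      list(alpha = as.list(out$bms$alpha),
           expected = as.list(out$bms$expected),
           exceedance = as.list(out$bms$xp),
           converged = out$bms$converged, manifest = out$manifest),
      file.path(out_dir, "bms.json"), auto_unbox = TRUE, digits = NA)
  }
  writeLines(render_report(out), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

render_report <- function(out) {
  lines <- c("Strategy analysis report",
             sprintf("seed %d, config %s", out$manifest$seed,
                     out$manifest$config_hash), "")
  for (fam in names(out$bootstrap)) {
    b <- out$bootstrap[[fam]]
    lines <- c(lines, sprintf("%s-rule bootstrap escapes: %d/%d animals",
                              fam, sum(b$escaped), length(b$escaped)))
    if (!is.null(b$comparison)) {
      lines <- c(lines, sprintf("  group comparison: chi2 = %.2f, p = %.4g",
                                b$comparison$statistic, b$comparison$p_value))
    }
  }
  if (!is.null(out$bms)) {
    lines <- c(lines, "", "Model selection (expected posterior | exceedance):")
    for (m in names(out$bms$expected)) {
      lines <- c(lines, sprintf("  %s: %.3f | %.3f", m,
                                out$bms$expected[[m]], out$bms$xp[[m]]))
    }
  }
  lines
}

#' Simulate and analyse in one call
#'
#' @param cfg a `run_config` (or a path to one).
#' @param out_dir output directory; `NULL` returns results without writing.
#' @return as [cmd_analyze()], plus the simulated `cohort`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  cohort <- cmd_simulate(cfg, out_dir = out_dir)
  res <- cmd_analyze(cohort, cfg, out_dir = out_dir)
  c(list(cohort = cohort), res)
}
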