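#' Configure a full scoring-comparison experiment
#'
#' Bundles everything one Monte Carlo experiment needs: the cohort design,
#' the number of replicate cohorts, the item-sharing scenarios, the measures
#' to score and fit, the Rasch and LCGA settings and the master seed. Within
#' a replicate every scenario is applied to a copy of the *same* simulated
#' cohort, so scenarios share identical underlying data, and the
#' `"theta_sim"` benchmark arm (LCGA on the error-free simulated latent
#' values) is fitted once per replicate since masking cannot affect it.
#'
#' @param design a [study_design()] (its own scenario is ignored; scenarios
#'   are applied per arm).
#' @param n_replicates number of replicate cohorts.
#' @param scenarios character vector of scenario names (or list of
#'   [scenario_mask()] objects).
#' @param measures subset of `"raw"`, `"standardised"`, `"theta_est"`,
#'   `"theta_sim"`.
#' @param rasch_method difficulty estimator for the `theta_est` arm
#'   (`"cml"` or `"mml"`), re-estimated per replicate and scenario.
#' @param person_method person scorer (`"eap"` by default: the posterior-mean
#'   factor score; `"wle"` or `"ml"` selectable).
#' @param k,n_starts,max_iter,rel_tol,residual_variance LCGA settings, see
#'   [fit_lcga()].
#' @param seed master seed; per-replicate seeds are derived from it so
#'   results do not depend on execution order or worker count.
#' @param workers parallel workers for [run_experiment()] (forked; 1 = serial).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(design = study_design(),
                              n_replicates = 200,
                              scenarios = c("complete", "seven_difficult",
                                            "seven_easy", "four_items"),
                              measures = c("raw", "standardised",
                                           "theta_est", "theta_sim"),
                              rasch_method = c("cml", "mml"),
                              person_method = c("eap", "wle", "ml"),
                              k = 3, n_starts = 20, max_iter = 500,
                              rel_tol = 1e-7,
                              residual_variance = "per_time",
                              seed = 1, workers = 1) {
  stopifnot(inherits(design, "study_design"), n_replicates >= 1)
  measures <- match.arg(measures, several.ok = TRUE)
  if (is.character(scenarios)) scenarios <- as.list(scenarios)
  structure(list(
    design = design, n_replicates = as.integer(n_replicates),
    scenarios = scenarios, measures = measures,
    rasch_method = match.arg(rasch_method),
    person_method = match.arg(person_method),
    k = k, n_starts = n_starts, max_iter = max_iter, rel_tol = rel_tol,
    residual_variance = residual_variance,
    seed = as.integer(seed), workers = workers
  ), class = "experiment_config")
}

scenario_name <- function(s) if (inherits(s, "scenario_mask")) s$name else s

measure_scores <- function(cohort, measure, config) {
  switch(measure,
    raw = score_raw(cohort),
    standardised = score_standardised(cohort),
    theta_est = person_scores(
      cohort,
      estimate_difficulties(cohort, method = config$rasch_method),
      method = config$person_method),
    theta_sim = score_theta_sim(cohort),
    abort(sprintf("unknown measure '%s'.", measure),
          class = "raschtraj_invalid_input")
  )
}

fit_and_evaluate <- function(scores, truth, config, fit_seed) {
  fit <- fit_lcga(scores, k = config$k, n_starts = config$n_starts,
                  max_iter = config$max_iter, rel_tol = config$rel_tol,
                  residual_variance = config$residual_variance,
                  seed = fit_seed)
  ev <- evaluate_classification(assign_classes(fit), truth, fit)
  ev$loglik <- fit$loglik
  ev$converged <- fit$converged
  ev
}

#' Run one replicate of the experiment
#'
#' Simulates one cohort, applies every configured scenario to a copy of it,
#' computes every configured measure, fits LCGA to each and evaluates the
#' classification against the simulated groups. The benchmark `theta_sim`
#' measure is fitted once (reported under scenario `"complete"`). Failures in
#' a single (scenario, measure) cell are recorded in the `error` column, not
#' fatal. Fully deterministic given the configuration and index.
#'
#' @param config an [experiment_config()].
#' @param index replicate number in `1..n_replicates`.
#' @param rep_seed optional explicit replicate seed (derived from the master
#'   seed by default).
#' @return a tibble with one row per fitted cell: `replicate`, `scenario`,
#'   `measure`, `pcc`, `kappa`, `entropy`, `group_pcc` (list-column),
#'   `loglik`, `converged`, `error`.
#' @export
run_replicate <- function(config, index, rep_seed = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(rep_seed)) {
    rep_seed <- derive_seeds(config$seed, config$n_replicates)[index]
  }
  base_design <- config$design
  base_design$scenario <- scenario_mask("complete",
                                        n_items = base_design$n_items,
                                        n_times = base_design$n_times)
  cohort <- simulate_cohort(base_design, seed = rep_seed)
  truth <- cohort$group

  cells <- list()
  add_cell <- function(scenario, measure, body) {
    row <- tryCatch(body(), error = function(e) {
      tibble::tibble(pcc = NA_real_, kappa = NA_real_, entropy = NA_real_,
                     group_pcc = list(NULL), loglik = NA_real_,
                     converged = NA, error = conditionMessage(e))
    })
    if (!"error" %in% names(row)) row$error <- NA_character_
    row <- tibble::add_column(row,
      replicate = index, scenario = scenario, measure = measure, .before = 1)
    cells[[length(cells) + 1]] <<- row
  }

  if ("theta_sim" %in% config$measures) {
    add_cell("complete", "theta_sim", function() {
      fit_and_evaluate(score_theta_sim(cohort), truth, config, rep_seed)
    })
  }
  item_measures <- setdiff(config$measures, "theta_sim")
  for (scen in config$scenarios) {
    if (length(item_measures) == 0) break
    masked <- apply_scenario(cohort, if (inherits(scen, "scenario_mask")) scen
                             else scenario_mask(scen,
                                                n_items = base_design$n_items,
                                                n_times = base_design$n_times))
    for (measure in item_measures) {
      add_cell(scenario_name(scen), measure, function() {
        fit_and_evaluate(measure_scores(masked, measure, config),
                         truth, config, rep_seed)
      })
    }
  }
  dplyr::bind_rows(cells)
}

#' Run the full Monte Carlo experiment
#'
#' Runs [run_replicate()] for every replicate (optionally on forked workers;
#' results are keyed by replicate index and identical for any worker count),
#' aggregates the performance criteria with 95% confidence intervals, and
#' optionally writes report files.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory; when given, [write_experiment()] is
#'   called on the result.
#' @param progress print a dot per replicate.
#' @return an object of class `lcga_experiment`: `replicates` (per-cell
#'   tibble), `summary` (criterion means with CIs), `group_summary` (per-group
#'   mean %CC) and `config`.
#' @export
run_experiment <- function(config, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- derive_seeds(config$seed, config$n_replicates)
  one <- function(i) {
    if (progress) cat(".")
    run_replicate(config, i, rep_seed = seeds[i])
  }
  reps <- if (config$workers > 1) {
    parallel::mclapply(seq_len(config$n_replicates), one,
                       mc.cores = config$workers)
  } else {
    lapply(seq_len(config$n_replicates), one)
  }
  if (progress) cat("\n")
  replicates <- dplyr::bind_rows(reps)
  ok <- replicates[is.na(replicates$error), ]
  out <- structure(list(
    replicates = replicates,
    summary = aggregate_replicates(ok),
    group_summary = aggregate_group_pcc(ok),
    config = config,
    seeds = seeds
  ), class = "lcga_experiment")
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

#' @export
print.lcga_experiment <- function(x, ...) {
  cat(sprintf("<lcga_experiment> %d replicates, %d fitted cells (%d failed)\n",
              x$config$n_replicates, nrow(x$replicates),
              sum(!is.na(x$replicates$error))))
  print(format_table1(x$summary))
  invisible(x)
}

#' Format an experiment summary as a report-ready grid
#'
#' One row per criterion and scenario, one column per measure, each cell
#' `mean [ci_low - ci_high]`.
#'
#' @param summary the `summary` tibble of an `lcga_experiment`.
#' @return a tibble of formatted strings.
#' @export
format_table1 <- function(summary) {
  s <- summary
  digits <- ifelse(s$criterion == "pcc", 1, 3)
  s$cell <- sprintf("%.*f [%.*f - %.*f]", digits, s$mean, digits, s$ci_low,
                    digits, s$ci_high)
  tidyr::pivot_wider(s[c("criterion", "scenario", "measure", "cell")],
                     names_from = "measure", values_from = "cell")
}

#' Write experiment report files
#'
#' Writes `results.csv` (per-replicate criteria), `summary.csv` (tidy means
#' and CIs), `group_pcc.csv` (per-group mean %CC), `table1.md` (formatted
#' grid) and `run_log.json` (configuration, seeds and session versions).
#'
#' @param experiment an `lcga_experiment`.
#' @param dir output directory (created if needed).
#' @return the experiment, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "lcga_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- experiment$replicates
  flat$group_pcc <- NULL
  write.csv(flat, file.path(dir, "results.csv"), row.names = FALSE)
  write.csv(experiment$summary, file.path(dir, "summary.csv"),
            row.names = FALSE)
  write.csv(experiment$group_summary, file.path(dir, "group_pcc.csv"),
            row.names = FALSE)
  tab <- format_table1(experiment$summary)
  lines <- c(paste0("| ", paste(names(tab), collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|"),
             apply(tab, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
  writeLines(lines, file.path(dir, "table1.md"))
  cfg <- experiment$config
  log <- list(
    n_replicates = cfg$n_replicates,
    scenarios = vapply(cfg$scenarios, scenario_name, character(1)),
    measures = cfg$measures,
    rasch_method = cfg$rasch_method,
    person_method = cfg$person_method,
    lcga = list(k = cfg$k, n_starts = cfg$n_starts, max_iter = cfg$max_iter,
                rel_tol = cfg$rel_tol,
                residual_variance = cfg$residual_variance),
    master_seed = cfg$seed,
    replicate_seeds = experiment$seeds,
    r_version = R.version.string,
    failed_cells = sum(!is.na(experiment$replicates$error))
  )
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(experiment)
}

#' Plot per-group classification accuracy by scenario and measure
#'
#' The per-group view shows how evenly the misclassifications spread over the
#' trajectory groups: sum-score measures tend to lose the "increasing" group
#' as items are erased, while the Rasch latent-variable score stays balanced.
#'
#' @param object an `lcga_experiment`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot lcga_experiment
#' @export
autoplot.lcga_experiment <- function(object, ...) {
  df <- object$group_summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$mean_pcc,
                                   colour = .data$group,
                                   group = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = "item-sharing scenario",
                  y = "mean % correctly classified",
                  colour = "true group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the design's latent mean trajectories
#'
#' @param design a [study_design()].
#' @return a ggplot of the group mean trajectories.
#' @export
plot_trajectory_groups <- function(design) {
  m <- group_means_matrix(design)
  df <- tidyr::expand_grid(group = rownames(m), time = seq_len(ncol(m)))
  df$mean <- m[cbind(match(df$group, rownames(m)), df$time)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean,
                                   colour = .data$group)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "collection time", y = "latent mean",
                  colour = "trajectory group") +
    ggplot2::theme_minimal()
}
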