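#' Rasch item response function
#'
#' Probability of a positive response given a person level `theta` and an item
#' difficulty `delta` under the one-parameter logistic (Rasch) model:
#' `exp(theta - delta) / (1 + exp(theta - delta))`. Computed through
#' [stats::plogis()], so it is numerically stable for large `|theta - delta|`.
#'
#' @param theta person level(s) on the latent scale.
#' @param delta item difficulty(ies) on the same scale.
#' @return response probabilities, recycled over the longer argument.
#' @examples
#' irf(0, 0)     # 0.5
#' irf(1, 0)     # exp(1) / (1 + exp(1))
#' @export
irf <- function(theta, delta) {
  if (any(!is.finite(theta)) || any(!is.finite(delta))) {
    abort("`theta` and `delta` must be finite.", class = "raschtraj_invalid_input")
  }
  plogis(theta - delta)
}

#' Simulate a cohort from the longitudinal Rasch model
#'
#' Latent levels for each subject are drawn from the subject's group-specific
#' multivariate normal distribution (group mean trajectory, covariance shared
#' by all groups), and each binary item response is an independent Bernoulli
#' draw with probability [irf()] of the subject's latent level at that time
#' and the item's difficulty. The design's item-sharing scenario is then
#' applied, erasing the designed-missing cells.
#'
#' @param design a [study_design()].
#' @param seed optional integer seed; when given, the simulation is fully
#'   reproducible and the caller's RNG state is left untouched.
#' @return an object of class `sim_cohort` with elements `theta` (N x T matrix
#'   of true latent levels), `group` (factor of true group labels),
#'   `responses` (N x T x J integer array, `NA` at erased cells), `design` and
#'   `seed`.
#' @examples
#' cohort <- simulate_cohort(study_design(groups =
#'   default_trajectory_groups(size = 50)), seed = 1)
#' cohort
#' @export
simulate_cohort <- function(design, seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  body <- function() {
    T <- design$n_times
    J <- design$n_items
    mu <- group_means_matrix(design)
    Sigma <- latent_covariance(design)
    sizes <- design$groups$size
    theta <- do.call(rbind, lapply(seq_len(nrow(mu)), function(g) {
      MASS::mvrnorm(sizes[g], mu[g, ], Sigma)
    }))
    if (sizes[1] == 1) theta <- matrix(theta, ncol = T)  # mvrnorm drops dims
    N <- nrow(theta)
    group <- factor(rep(design$groups$group, sizes),
                    levels = design$groups$group)
    delta <- design$item_bank$difficulty
    responses <- array(NA_integer_, c(N, T, J),
                       dimnames = list(NULL, paste0("t", seq_len(T)),
                                       paste0("i", seq_len(J))))
    for (t in seq_len(T)) {
      p <- irf(matrix(theta[, t], N, J), matrix(delta, N, J, byrow = TRUE))
      responses[, t, ] <- (matrix(runif(N * J), N, J) < p) + 0L
    }
    cohort <- structure(
      list(theta = theta, group = group, responses = responses,
           design = design, seed = seed),
      class = "sim_cohort"
    )
    apply_scenario(cohort, design$scenario)
  }
  if (is.null(seed)) body() else withr::with_seed(as.integer(seed), body())
}

#' Apply an item-sharing scenario to a simulated cohort
#'
#' Sets the responses at the scenario's erased (item, time) cells to missing
#' and leaves every other cell untouched, so different scenarios applied to
#' the same cohort share identical underlying data.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param scenario a [scenario_mask()] or a scenario name.
#' @return the cohort with the scenario applied (and recorded in its design).
#' @export
apply_scenario <- function(cohort, scenario) {
  stopifnot(inherits(cohort, "sim_cohort"))
  J <- cohort$design$n_items
  T <- cohort$design$n_times
  if (!inherits(scenario, "scenario_mask")) {
    scenario <- scenario_mask(scenario, n_items = J, n_times = T)
  } else {
    validate_mask(scenario, J, T)
  }
  e <- scenario$erased
  if (nrow(e) > 0) {
    for (r in seq_len(nrow(e))) {
      cohort$responses[, e$time[r], e$item[r]] <- NA_integer_
    }
  }
  for (t in seq_len(T)) {
    if (all(is.na(cohort$responses[, t, ]))) {
      abort_scenario(sprintf("all items are missing at time %d after masking.", t))
    }
  }
  cohort$design$scenario <- scenario
  cohort
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d subjects x %d times x %d items (scenario: %s)\n",
              nrow(x$theta), x$design$n_times, x$design$n_items,
              x$design$scenario$name))
  print(table(x$group))
  invisible(x)
}

#' Long-format view of a simulated cohort
#'
#' @param x a `sim_cohort`.
#' @param what `"responses"` for one row per (subject, time, item) with the
#'   binary response (`NA` when erased), or `"theta"` for one row per
#'   (subject, time) with the true latent level.
#' @param ... unused.
#' @return a tibble.
#' @method as_tibble sim_cohort
#' @export
as_tibble.sim_cohort <- function(x, ..., what = c("responses", "theta")) {
  what <- match.arg(what)
  N <- nrow(x$theta)
  T <- x$design$n_times
  if (what == "theta") {
    return(tibble::tibble(
      subject_id = rep(seq_len(N), T),
      group = rep(x$group, T),
      time = rep(seq_len(T), each = N),
      theta = as.vector(x$theta)
    ))
  }
  J <- x$design$n_items
  tibble::tibble(
    subject_id = rep(seq_len(N), T * J),
    group = rep(x$group, T * J),
    time = rep(rep(seq_len(T), each = N), J),
    item = rep(seq_len(J), each = N * T),
    response = as.integer(x$responses)
  )
}

#' Write / read a cohort as long-format CSV
#'
#' `write_cohort()` writes two plain CSV files: responses in long format
#' (subject_id, group, time, item, response with empty cells for designed
#' missingness) and true latent levels (subject_id, group, time, theta).
#' `read_cohort()` rebuilds a `sim_cohort` from them; user data with unknown
#' truth may omit the theta file.
#'
#' @param cohort a `sim_cohort`.
#' @param responses_file,theta_file file paths.
#' @param design optional [study_design()] recorded on the rebuilt cohort; a
#'   minimal design matching the data's dimensions is constructed otherwise.
#' @return `write_cohort()` the input, invisibly; `read_cohort()` a
#'   `sim_cohort` (with `theta` all `NA` when no theta file is given).
#' @export
write_cohort <- function(cohort, responses_file, theta_file = NULL) {
  write.csv(as_tibble.sim_cohort(cohort, what = "responses"),
            responses_file, row.names = FALSE, na = "")
  if (!is.null(theta_file)) {
    write.csv(as_tibble.sim_cohort(cohort, what = "theta"),
              theta_file, row.names = FALSE)
  }
  invisible(cohort)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(responses_file, theta_file = NULL, design = NULL) {
  long <- read.csv(responses_file)
  subjects <- sort(unique(long$subject_id))
  times <- sort(unique(long$time))
  items <- sort(unique(long$item))
  N <- length(subjects); T <- length(times); J <- length(items)
  responses <- array(NA_integer_, c(N, T, J))
  idx <- cbind(match(long$subject_id, subjects), match(long$time, times),
               match(long$item, items))
  responses[idx] <- as.integer(long$response)
  first <- long[!duplicated(long$subject_id), ]
  group <- factor(first$group[match(subjects, first$subject_id)])
  theta <- matrix(NA_real_, N, T)
  if (!is.null(theta_file)) {
    th <- read.csv(theta_file)
    theta[cbind(match(th$subject_id, subjects), match(th$time, times))] <- th$theta
  }
  if (is.null(design)) {
    sizes <- as.integer(table(group))
    groups <- tibble::tibble(group = levels(group), size = sizes)
    for (t in seq_len(T)) groups[[paste0("t", t)]] <- 0
    design <- suppressWarnings(study_design(
      n_times = T, n_items = J, groups = groups, scenario = "complete"))
  }
  structure(list(theta = theta, group = group, responses = responses,
                 design = design, seed = NULL),
            class = "sim_cohort")
}

#' Read a study design from a YAML configuration file
#'
#' Keys: `times`, `items`, `groups` (list of name/size/means), `variance`,
#' `correlations`, `difficulties` (vector or `"auto"`), `scenario` (name or
#' list with `erased` pairs), `erased_times`, `seed`.
#'
#' @param path path to a YAML file.
#' @return a list with elements `design` and `seed`.
#' @export
read_design_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  n_times <- cfg$times %||% 4
  groups <- purrr::map_dfr(cfg$groups, function(g) {
    row <- tibble::tibble(group = g$name, size = as.integer(g$size))
    for (t in seq_len(n_times)) row[[paste0("t", t)]] <- g$means[[t]]
    row
  })
  difficulties <- cfg$difficulties
  if (is.null(difficulties) || identical(difficulties, "auto")) difficulties <- NULL
  scen <- cfg$scenario %||% "complete"
  if (is.list(scen)) {
    erased <- purrr::map_dfr(scen$erased,
                             ~tibble::tibble(item = .x[[1]], time = .x[[2]]))
    scen <- scenario_mask("custom", erased = erased,
                          n_items = cfg$items %||% 10, n_times = n_times)
  }
  design <- study_design(
    n_times = n_times,
    n_items = cfg$items %||% 10,
    groups = groups,
    latent_variance = cfg$variance %||% 0.3,
    correlations = unlist(cfg$correlations %||% c(0.8, 0.7, 0.6)),
    difficulties = unlist(difficulties),
    scenario = scen,
    erased_times = unlist(cfg$erased_times %||% c(3, 4))
  )
  list(design = design, seed = cfg$seed)
}
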