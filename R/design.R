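#' Build an item bank of time-invariant difficulties
#'
#' Difficulties default to evenly spaced percentiles of the standard normal
#' distribution, `qnorm(j / (n_items + 1))`, which places the items
#' symmetrically about zero on the logit scale. For the default 10-item bank
#' the three easiest items span \[-1.34, -0.60\] and the three hardest span
#' \[0.60, 1.34\].
#'
#' @param n_items number of items (at least 2).
#' @param difficulties optional explicit numeric vector of difficulties on the
#'   logit scale; overrides the percentile rule.
#' @return a tibble with columns `item` and `difficulty`.
#' @examples
#' item_bank(10)
#' @export
item_bank <- function(n_items = 10, difficulties = NULL) {
  if (is.null(difficulties)) {
    if (!is.numeric(n_items) || length(n_items) != 1 || n_items < 2) {
      abort_design("`n_items` must be a single integer >= 2.")
    }
    n_items <- as.integer(n_items)
    difficulties <- qnorm(seq_len(n_items) / (n_items + 1))
  } else {
    if (!is.numeric(difficulties) || any(!is.finite(difficulties)) ||
        length(difficulties) < 2) {
      abort_design("`difficulties` must be a finite numeric vector of length >= 2.")
    }
    n_items <- length(difficulties)
  }
  tibble::tibble(item = seq_len(n_items), difficulty = difficulties)
}

#' Default trajectory groups
#'
#' Three groups of equal size: a stable low group (latent mean -1 at every
#' time), a stable high group (+1 at every time) and an increasing group whose
#' mean rises linearly from -0.5 to 1 across the collection times.
#'
#' @param n_times number of collection times.
#' @param size subjects per group.
#' @return a tibble with columns `group`, `size` and one mean column per time
#'   (`t1`, `t2`, ...).
#' @export
default_trajectory_groups <- function(n_times = 4, size = 1000) {
  means <- rbind(
    low        = rep(-1, n_times),
    high       = rep(1, n_times),
    increasing = seq(-0.5, 1, length.out = n_times)
  )
  out <- tibble::tibble(group = rownames(means), size = as.integer(size))
  for (t in seq_len(n_times)) out[[paste0("t", t)]] <- means[, t]
  out
}

#' Define the study design of a simulated cohort
#'
#' Gathers everything the longitudinal Rasch simulator needs: the number of
#' collection times and items, the latent trajectory groups, the latent
#' variance and lag correlations (shared by all groups), the item bank and an
#' item-sharing scenario.
#'
#' @param n_times number of collection times T.
#' @param n_items number of binary items J per questionnaire.
#' @param groups tibble as returned by [default_trajectory_groups()]: columns
#'   `group`, `size` and `t1`..`tT` latent means.
#' @param latent_variance latent variance at each time (a single positive
#'   number).
#' @param correlations vector of length `n_times - 1` giving the latent
#'   correlation at lag 1, 2, ... between collection times.
#' @param difficulties optional explicit item difficulties; defaults to the
#'   normal-percentile bank of [item_bank()].
#' @param scenario an item-sharing scenario: a name accepted by
#'   [scenario_mask()] or a mask object.
#' @param erased_times collection times at which scenario items are erased
#'   when `scenario` is given by name.
#' @return an object of class `study_design`.
#' @examples
#' design <- study_design()
#' design
#' @export
study_design <- function(n_times = 4,
                         n_items = 10,
                         groups = default_trajectory_groups(n_times),
                         latent_variance = 0.3,
                         correlations = c(0.8, 0.7, 0.6),
                         difficulties = NULL,
                         scenario = "complete",
                         erased_times = c(3, 4)) {
  n_times <- as.integer(n_times)
  bank <- item_bank(n_items, difficulties)
  n_items <- nrow(bank)
  if (!is.numeric(latent_variance) || length(latent_variance) != 1 ||
      latent_variance <= 0) {
    abort_design("`latent_variance` must be a single positive number.")
  }
  if (length(correlations) != n_times - 1) {
    abort_design(sprintf(
      "`correlations` must give one value per lag 1..%d.", n_times - 1))
  }
  mean_cols <- paste0("t", seq_len(n_times))
  if (!all(c("group", "size", mean_cols) %in% names(groups))) {
    abort_design("`groups` must have columns group, size and t1..tT.")
  }
  if (any(groups$size <= 0)) abort_design("group sizes must be positive.")
  if (!inherits(scenario, "scenario_mask")) {
    scenario <- scenario_mask(scenario, times = erased_times,
                              n_items = n_items, n_times = n_times)
  } else {
    validate_mask(scenario, n_items, n_times)
  }
  design <- structure(
    list(
      n_times = n_times,
      n_items = n_items,
      groups = tibble::as_tibble(groups[c("group", "size", mean_cols)]),
      latent_variance = latent_variance,
      correlations = correlations,
      item_bank = bank,
      scenario = scenario
    ),
    class = "study_design"
  )
  latent_covariance(design)  # validates positive definiteness
  design
}

group_means_matrix <- function(design) {
  m <- as.matrix(design$groups[paste0("t", seq_len(design$n_times))])
  rownames(m) <- design$groups$group
  m
}

#' Latent covariance matrix implied by a study design
#'
#' Entry (t, t') is `latent_variance * correlation[|t - t'|]` with unit
#' correlation on the diagonal. The matrix must be positive definite.
#'
#' @param design a [study_design()].
#' @return a `n_times` x `n_times` covariance matrix.
#' @export
latent_covariance <- function(design) {
  T <- design$n_times
  v <- design$latent_variance
  rho <- design$correlations
  S <- diag(T) ## correlation scale
  for (t in seq_len(T)) for (s in seq_len(T)) {
    if (t != s) S[t, s] <- rho[abs(t - s)]
  }
  S <- v * S
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(abs(ev))) {
    abort_design("The implied latent covariance matrix is not positive definite.")
  }
  S
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d times x %d items, N = %d\n",
              x$n_times, x$n_items, sum(x$groups$size)))
  cat(sprintf("  latent variance %.3g, lag correlations %s\n",
              x$latent_variance, paste(x$correlations, collapse = "/")))
  cat(sprintf("  scenario: %s (%d erased item-time cells)\n",
              x$scenario$name, nrow(x$scenario$erased)))
  invisible(x)
}

#' Item-sharing scenario masks
#'
#' A scenario erases chosen items at chosen collection times, mimicking a
#' questionnaire change during follow-up. Built-in scenarios for a 10-item
#' bank: `"complete"` (nothing erased), `"seven_difficult"` (the three easiest
#' items 1, 2, 4 erased, leaving seven fairly difficult shared items),
#' `"seven_easy"` (the mirror: items 7, 9, 10 erased) and `"four_items"` (the
#' union, leaving the four mid-difficulty items 3, 5, 6 and 8 shared).
#'
#' @param scenario scenario name, or `"custom"` with `erased` supplied.
#' @param erased optional data frame with columns `item` and `time` listing
#'   erased cells (used for custom scenarios).
#' @param times collection times at which built-in scenario items are erased.
#' @param n_items,n_times design dimensions used for validation.
#' @return an object of class `scenario_mask`.
#' @examples
#' scenario_mask("four_items")
#' @export
scenario_mask <- function(scenario = c("complete", "seven_difficult",
                                       "seven_easy", "four_items", "custom"),
                          erased = NULL, times = c(3, 4),
                          n_items = 10, n_times = 4) {
  scenario <- match.arg(scenario)
  if (is.null(erased)) {
    items <- switch(scenario,
      complete        = integer(0),
      seven_difficult = c(1L, 2L, 4L),
      seven_easy      = n_items + 1L - c(1L, 2L, 4L),
      four_items      = sort(c(c(1L, 2L, 4L), n_items + 1L - c(1L, 2L, 4L))),
      custom          = abort_scenario("a custom scenario needs `erased`.")
    )
    erased <- tidyr::expand_grid(item = items, time = as.integer(times))
  } else {
    if (!all(c("item", "time") %in% names(erased))) {
      abort_scenario("`erased` must have columns `item` and `time`.")
    }
    erased <- tibble::as_tibble(erased[c("item", "time")])
    erased$item <- as.integer(erased$item)
    erased$time <- as.integer(erased$time)
    erased <- dplyr::distinct(erased)
  }
  mask <- structure(
    list(name = scenario, erased = erased,
         n_items = as.integer(n_items), n_times = as.integer(n_times)),
    class = "scenario_mask"
  )
  validate_mask(mask, n_items, n_times)
  mask
}

validate_mask <- function(mask, n_items, n_times) {
  e <- mask$erased
  if (nrow(e) == 0) return(invisible(mask))
  if (any(e$item < 1 | e$item > n_items) || any(e$time < 1 | e$time > n_times)) {
    abort_scenario("erased cells fall outside the design (item or time out of range).")
  }
  per_time <- table(factor(e$time, levels = seq_len(n_times)))
  if (any(per_time >= n_items)) {
    abort_scenario("a scenario may not erase every item at a collection time.")
  }
  if (length(unique(e$item)) >= n_items) {
    abort_scenario("the shared-item set (items never erased) must be non-empty.")
  }
  invisible(mask)
}

#' @export
print.scenario_mask <- function(x, ...) {
  cat(sprintf("<scenario_mask> %s: %d erased cells", x$name, nrow(x$erased)))
  if (nrow(x$erased) > 0) {
    cat(sprintf(" (items %s at times %s)",
                paste(sort(unique(x$erased$item)), collapse = ","),
                paste(sort(unique(x$erased$time)), collapse = ",")))
  }
  cat("\n")
  invisible(x)
}
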