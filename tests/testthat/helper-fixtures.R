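## small designs and cached cohorts shared across test files

tiny_design <- function(size = 40, ...) {
  study_design(groups = default_trajectory_groups(size = size), ...)
}

## one small cohort, built once per test run
.fixtures <- new.env(parent = emptyenv())

tiny_cohort <- function() {
  if (is.null(.fixtures$tiny)) {
    .fixtures$tiny <- simulate_cohort(tiny_design(), seed = 101)
  }
  .fixtures$tiny
}

## one full-size cohort (default design) for recovery checks
full_cohort <- function() {
  if (is.null(.fixtures$full)) {
    .fixtures$full <- simulate_cohort(study_design(), seed = 202)
  }
  .fixtures$full
}

## hand-built cohort with prescribed responses (complete, no missingness)
manual_cohort <- function(responses, theta = NULL) {
  dm <- dim(responses)
  groups <- default_trajectory_groups(n_times = dm[2], size = dm[1])[1, ]
  design <- study_design(n_times = dm[2], n_items = dm[3], groups = groups,
                         correlations = rep(0.5, dm[2] - 1))
  if (is.null(theta)) theta <- matrix(0, dm[1], dm[2])
  structure(list(theta = theta,
                 group = factor(rep("low", dm[1])),
                 responses = responses, design = design, seed = NULL),
            class = "sim_cohort")
}
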