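#' Items shared by all questionnaire versions
#'
#' The shared set contains the items with no designed missingness at any
#' collection time; it is the only information usable for the raw score when
#' the questionnaire changed during follow-up.
#'
#' @param cohort a `sim_cohort`.
#' @return integer vector of shared item indices.
#' @export
shared_items <- function(cohort) {
  stopifnot(inherits(cohort, "sim_cohort"))
  ever_missing <- apply(is.na(cohort$responses), 3, any)
  shared <- which(!ever_missing)
  if (length(shared) == 0) {
    abort("No item is observed at every collection time; the raw score is undefined.",
          class = "raschtraj_scoring")
  }
  shared
}

new_scores <- function(tbl, measure, items_used) {
  structure(tbl, measure = measure, items_used = items_used,
            class = c("traj_scores", class(tbl)))
}

#' Raw score over shared items
#'
#' The raw score at each time is the plain sum of a subject's responses over
#' the items shared by every questionnaire version (see [shared_items()]);
#' items available at only some times are discarded.
#'
#' @param cohort a `sim_cohort`.
#' @return a score tibble (class `traj_scores`) with columns `subject_id`,
#'   `group`, `time`, `score` and attributes `measure = "raw"` and
#'   `items_used`.
#' @export
score_raw <- function(cohort) {
  shared <- shared_items(cohort)
  T <- cohort$design$n_times
  N <- dim(cohort$responses)[1]
  mat <- vapply(seq_len(T), function(t) {
    rowSums(cohort$responses[, t, shared, drop = FALSE])
  }, numeric(N))
  new_scores(score_tibble(mat, cohort), "raw",
             rep(list(shared), T))
}

#' Per-time standardised score
#'
#' At each collection time the sum over *all* items observed at that time is
#' computed, then centred by that time's sample mean and divided by that
#' time's sample standard deviation (denominator N - 1). Unlike the raw
#' score, items present at only some times contribute at the times where they
#' are present; the per-time standardisation implicitly assumes a stable
#' population mean over time.
#'
#' @param cohort a `sim_cohort`.
#' @return a score tibble with `measure = "standardised"`.
#' @export
score_standardised <- function(cohort) {
  T <- cohort$design$n_times
  N <- dim(cohort$responses)[1]
  items_used <- vector("list", T)
  mat <- matrix(NA_real_, N, T)
  for (t in seq_len(T)) {
    obs <- which(!apply(is.na(cohort$responses[, t, , drop = FALSE]), 3, all))
    items_used[[t]] <- obs
    sums <- rowSums(cohort$responses[, t, obs, drop = FALSE], na.rm = TRUE)
    s <- sd(sums)
    if (!is.finite(s) || s == 0 || length(unique(sums)) < 2) {
      abort(sprintf("scores at time %d are constant; standardisation is degenerate.", t),
            class = "raschtraj_degenerate_score")
    }
    mat[, t] <- (sums - mean(sums)) / s
  }
  new_scores(score_tibble(mat, cohort), "standardised", items_used)
}

#' True simulated latent levels as a score
#'
#' Exposes the simulated latent values as a score table, the benchmark arm of
#' the experiment: applying LCGA to these values shows the best classification
#' achievable with no measurement error. Unaffected by item-sharing scenarios.
#'
#' @param cohort a `sim_cohort` (must carry simulated `theta`).
#' @return a score tibble with `measure = "theta_sim"`.
#' @export
score_theta_sim <- function(cohort) {
  if (anyNA(cohort$theta)) {
    abort("this cohort carries no simulated latent values.",
          class = "raschtraj_scoring")
  }
  new_scores(score_tibble(cohort$theta, cohort), "theta_sim",
             rep(list(integer(0)), cohort$design$n_times))
}

score_tibble <- function(mat, cohort) {
  N <- nrow(mat); T <- ncol(mat)
  tibble::tibble(
    subject_id = rep(seq_len(N), T),
    group = rep(cohort$group, T),
    time = rep(seq_len(T), each = N),
    score = as.vector(mat)
  )
}

## wide N x T matrix from a long score tibble, rows ordered by subject_id
scores_wide <- function(scores) {
  stopifnot(all(c("subject_id", "time", "score") %in% names(scores)))
  wide <- tidyr::pivot_wider(
    scores[c("subject_id", "time", "score")],
    names_from = "time", values_from = "score", names_sort = TRUE)
  wide <- dplyr::arrange(wide, .data$subject_id)
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$subject_id
  mat
}

#' @export
print.traj_scores <- function(x, ...) {
  cat(sprintf("<traj_scores> measure: %s\n", attr(x, "measure")))
  NextMethod()
}

#' Write a score table as a wide CSV
#'
#' One row per subject with columns `subject_id`, `group`, `s_t1`..`s_tT`.
#'
#' @param scores a score tibble.
#' @param file output path.
#' @export
write_scores <- function(scores, file) {
  mat <- scores_wide(scores)
  out <- tibble::tibble(subject_id = as.integer(rownames(mat)))
  if ("group" %in% names(scores)) {
    first <- scores[!duplicated(scores$subject_id), ]
    out$group <- first$group[match(out$subject_id, first$subject_id)]
  }
  colnames(mat) <- paste0("s_t", seq_len(ncol(mat)))
  write.csv(cbind(out, mat), file, row.names = FALSE)
  invisible(scores)
}
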