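#' Match LCGA classes to true groups and build the confusion table
#'
#' Mixture class labels are arbitrary (label switching), so assigned classes
#' are matched to the true trajectory groups by the permutation of class
#' labels that maximises the diagonal agreement, searched exhaustively over
#' all K! permutations; ties keep the first permutation in lexicographic
#' order (class order in an `lcga_fit` already follows ascending trajectory
#' level, making this deterministic).
#'
#' @param assigned integer/factor vector of assigned classes (or a tibble from
#'   [assign_classes()], whose `class` column is used).
#' @param truth factor of true group labels, same length.
#' @return an object of class `class_match`: `permutation` (new label of each
#'   original class), `confusion` (rows = true group, columns = matched
#'   class), `matched` (relabelled assignments) and `n`.
#' @export
match_classes <- function(assigned, truth) {
  if (is.data.frame(assigned)) assigned <- assigned$class
  truth <- as.factor(truth)
  k <- nlevels(truth)
  if (is.factor(assigned)) assigned <- as.integer(assigned)
  assigned <- as.integer(assigned)
  if (any(assigned < 1 | assigned > k)) {
    abort(sprintf("assigned classes must be integers in 1..%d.", k),
          class = "raschtraj_invalid_input")
  }
  if (length(assigned) != length(truth)) {
    abort("`assigned` and `truth` must have the same length.",
          class = "raschtraj_invalid_input")
  }
  truth_i <- as.integer(truth)
  perms <- permutations_of(k)
  agree <- apply(perms, 1, function(p) sum(p[assigned] == truth_i))
  best <- perms[which.max(agree), ]
  matched <- best[assigned]
  confusion <- table(truth = truth, assigned = factor(matched, levels = seq_len(k)))
  structure(list(permutation = best, confusion = unclass(confusion),
                 matched = matched, n = length(truth)),
            class = "class_match")
}

#' @export
print.class_match <- function(x, ...) {
  cat(sprintf("<class_match> %d subjects, %%CC = %.1f\n",
              x$n, percent_correct(x)))
  print(x$confusion)
  invisible(x)
}

conf_of <- function(x) {
  if (inherits(x, "class_match")) x$confusion else as.matrix(x)
}

#' Percentage of correctly classified subjects
#'
#' `100 * trace / N` of the matched confusion table.
#'
#' @param x a [match_classes()] result or a square confusion matrix
#'   (rows = truth, columns = matched assignment).
#' @return percentage in \[0, 100\].
#' @export
percent_correct <- function(x) {
  conf <- conf_of(x)
  100 * sum(diag(conf)) / sum(conf)
}

#' Per-group percentage correctly classified
#'
#' @param x as in [percent_correct()].
#' @return a tibble with columns `group` and `pcc` (`NA` for an empty group).
#' @export
group_percent_correct <- function(x) {
  conf <- conf_of(x)
  totals <- rowSums(conf)
  tibble::tibble(
    group = rownames(conf) %||% as.character(seq_len(nrow(conf))),
    pcc = unname(ifelse(totals > 0, 100 * diag(conf) / totals, NA_real_))
  )
}

#' Cohen's kappa for a matched confusion table
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the expected
#' agreement `p_e` from the marginal products. Conventional reading: below
#' 0.6 poor-to-moderate, 0.6-0.8 substantial, above 0.8 almost perfect.
#'
#' @param x as in [percent_correct()].
#' @return kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(x) {
  conf <- conf_of(x)
  n <- sum(conf)
  if (n == 0) abort("empty table.", class = "raschtraj_invalid_input")
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  if (pe >= 1 - 1e-15) {
    abort("expected agreement is 1; kappa is undefined.",
          class = "raschtraj_undefined_kappa")
  }
  (po - pe) / (1 - pe)
}

#' Evaluate one LCGA classification against the simulated truth
#'
#' Matches classes to groups, then computes the percentage correctly
#' classified (overall and per true group), Cohen's kappa and — when the
#' posterior matrix is given — the relative entropy of the classification.
#'
#' @param assigned assigned classes (vector or [assign_classes()] tibble).
#' @param truth true group factor.
#' @param posteriors optional N x K posterior matrix or `lcga_fit`.
#' @return a one-row tibble: `pcc`, `kappa`, `entropy` and a `group_pcc`
#'   list-column holding the per-group tibble.
#' @export
evaluate_classification <- function(assigned, truth, posteriors = NULL) {
  m <- match_classes(assigned, truth)
  tibble::tibble(
    pcc = percent_correct(m),
    kappa = cohens_kappa(m),
    entropy = if (!is.null(posteriors)) relative_entropy(posteriors) else NA_real_,
    group_pcc = list(group_percent_correct(m))
  )
}

#' Aggregate per-replicate criteria with normal-approximation 95% CIs
#'
#' @param replicates a tibble with columns `scenario`, `measure` and the
#'   per-replicate criteria `pcc`, `kappa`, `entropy` (as produced by
#'   [run_replicate()]).
#' @return a tidy tibble: `criterion`, `scenario`, `measure`, `mean`,
#'   `ci_low`, `ci_high`, `n_replicates`.
#' @export
aggregate_replicates <- function(replicates) {
  long <- tidyr::pivot_longer(
    replicates[c("scenario", "measure", "pcc", "kappa", "entropy")],
    cols = c("pcc", "kappa", "entropy"),
    names_to = "criterion", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$criterion, .data$scenario, .data$measure),
    mean = mean(.data$value),
    hw = precision_halfwidth(stats::sd(.data$value), dplyr::n()),
    n_replicates = dplyr::n(),
    .groups = "drop")
  out$ci_low <- out$mean - out$hw
  out$ci_high <- out$mean + out$hw
  out[c("criterion", "scenario", "measure", "mean", "ci_low", "ci_high",
        "n_replicates")]
}

#' Mean per-group percentage correctly classified over replicates
#'
#' @param replicates as in [aggregate_replicates()], with the `group_pcc`
#'   list-column.
#' @return a tibble: `scenario`, `measure`, `group`, `mean_pcc`.
#' @export
aggregate_group_pcc <- function(replicates) {
  long <- tidyr::unnest(
    replicates[c("scenario", "measure", "group_pcc")], "group_pcc")
  dplyr::summarise(
    dplyr::group_by(long, .data$scenario, .data$measure, .data$group),
    mean_pcc = mean(.data$pcc), .groups = "drop")
}

#' Half-width of a normal-approximation 95% confidence interval
#'
#' `1.96 * sd / sqrt(n)`: the precision attached to a Monte Carlo mean of
#' `n` replicates whose per-replicate standard deviation is `sd`. Used to
#' choose the number of simulated datasets for a target accuracy.
#'
#' @param sd per-replicate standard deviation.
#' @param n number of replicates.
#' @return the CI half-width.
#' @examples
#' precision_halfwidth(0.011, 200)  # ~0.0015, i.e. +/-0.15 percentage points
#' @export
precision_halfwidth <- function(sd, n) {
  stopifnot(sd >= 0, n >= 1)
  1.96 * sd / sqrt(n)
}
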