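#' Fit a latent class growth analysis by multi-start EM
#'
#' Fits a finite mixture of `k` linear growth trajectories to a subjects-by-
#' times score table: class k has mean `intercept_k + slope_k * time_code`,
#' within-class growth-factor variances are fixed at zero (LCGA, not a growth
#' mixture model) and the residual variances are shared across classes —
#' time-specific by default, optionally constant. The observed-data
#' log-likelihood is maximised by EM from several starting points (a k-means
#' partition of the subject score vectors plus random responsibility draws);
#' the best converged start is kept. Classes are reported in increasing order
#' of their mean fitted trajectory level, so the "low / increasing / high"
#' labelling is deterministic.
#'
#' @param scores a score tibble (columns `subject_id`, `time`, `score`;
#'   `group` carried through if present) with no missing cells.
#' @param k number of latent classes.
#' @param time_codes numeric codes for the collection times; default
#'   `0, 1, ..., T-1` so the intercept is the first-time level.
#' @param residual_variance `"per_time"` (default) or `"constant"`.
#' @param n_starts number of EM starts (first is k-means seeded).
#' @param max_iter maximum EM iterations per start.
#' @param rel_tol relative log-likelihood convergence tolerance.
#' @param seed optional seed making the starts reproducible.
#' @return an object of class `lcga_fit`: mixture weights, per-class intercept
#'   and slope, residual variances, an N x k posterior matrix, log-likelihood
#'   (with its per-iteration trace for the best start), relative entropy,
#'   iteration count and convergence flag.
#' @examples
#' cohort <- simulate_cohort(study_design(groups =
#'   default_trajectory_groups(size = 60)), seed = 2)
#' fit <- fit_lcga(score_theta_sim(cohort), n_starts = 3, seed = 2)
#' tidy(fit)
#' @export
fit_lcga <- function(scores, k = 3, time_codes = NULL,
                     residual_variance = c("per_time", "constant"),
                     n_starts = 20, max_iter = 500, rel_tol = 1e-7,
                     seed = NULL) {
  residual_variance <- match.arg(residual_variance)
  Y <- scores_wide(scores)
  if (anyNA(Y)) abort("scores must have no missing cells.",
                      class = "raschtraj_invalid_input")
  N <- nrow(Y); T <- ncol(Y)
  if (k < 1) abort("`k` must be at least 1.", class = "raschtraj_invalid_input")
  if (N < k) abort("need at least as many subjects as classes.",
                   class = "raschtraj_invalid_input")
  if (is.null(time_codes)) time_codes <- seq_len(T) - 1
  if (length(time_codes) != T || is.unsorted(time_codes, strictly = TRUE)) {
    abort("`time_codes` must be strictly increasing, one per time.",
          class = "raschtraj_invalid_input")
  }

  run <- function() {
    best <- NULL
    any_converged <- FALSE
    for (s in seq_len(n_starts)) {
      W <- em_start(Y, k, kmeans_start = (s == 1))
      fit <- em_lcga(Y, W, time_codes, residual_variance, max_iter, rel_tol)
      if (fit$converged) any_converged <- TRUE
      if (is.null(best) ||
          (fit$loglik > best$loglik && (fit$converged || !best$converged))) {
        fit$best_start <- s
        best <- fit
      }
      if (k == 1) break  # single class: EM is deterministic
    }
    if (!any_converged && k > 1) {
      abort(sprintf("no EM start converged within %d iterations.", max_iter),
            class = "raschtraj_convergence")
    }
    best
  }
  best <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())

  ## deterministic class order: ascending mean fitted trajectory
  ord <- order(rowMeans(best$mu))
  mu <- best$mu[ord, , drop = FALSE]
  coefs <- best$ab[ord, , drop = FALSE]
  post <- best$W[, ord, drop = FALSE]
  weights <- colMeans(post)  # EM fixed point: weights are posterior means

  fit <- structure(list(
    k = k,
    weights = weights,
    coefficients = tibble::tibble(
      class = seq_len(k), weight = weights,
      intercept = coefs[, 1], slope = coefs[, 2]),
    mean_trajectories = mu,
    residual_variances = best$sig2,
    posteriors = post,
    loglik = best$loglik,
    loglik_trace = best$trace,
    entropy = if (k > 1) relative_entropy(post) else NA_real_,
    n_iter = best$n_iter,
    converged = best$converged,
    best_start = best$best_start,
    degenerate = any(weights < 1 / N),
    time_codes = time_codes,
    subject_id = as.integer(rownames(Y)),
    group = if ("group" %in% names(scores)) {
      first <- scores[!duplicated(scores$subject_id), ]
      first$group[match(as.integer(rownames(Y)), first$subject_id)]
    },
    measure = attr(scores, "measure") %||% "score",
    n = N
  ), class = "lcga_fit")
  fit
}

em_start <- function(Y, k, kmeans_start) {
  N <- nrow(Y)
  if (k == 1) return(matrix(1, N, 1))
  if (kmeans_start) {
    km <- kmeans(Y, k, nstart = 5)
    W <- matrix(0, N, k)
    W[cbind(seq_len(N), km$cluster)] <- 1
    return(W)
  }
  W <- matrix(rexp(N * k), N, k)
  W / rowSums(W)
}

em_lcga <- function(Y, W, x, residual_variance, max_iter, rel_tol) {
  N <- nrow(Y); T <- ncol(Y); k <- ncol(W)
  X <- cbind(1, x)
  sig2 <- rep(var(as.vector(Y)), T)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  ab <- matrix(0, k, 2)
  mu <- matrix(0, k, T)
  pi_k <- colMeans(W)
  for (it in seq_len(max_iter)) {
    ## M-step (conditional maximisations: growth coefficients, then variances)
    pi_k <- colMeans(W)
    for (kk in seq_len(k)) {
      w <- W[, kk]; sw <- sum(w)
      A <- matrix(0, 2, 2); b <- c(0, 0)
      for (t in seq_len(T)) {
        A <- A + (sw / sig2[t]) * tcrossprod(X[t, ])
        b <- b + (sum(w * Y[, t]) / sig2[t]) * X[t, ]
      }
      ab[kk, ] <- solve(A, b)
      mu[kk, ] <- as.vector(X %*% ab[kk, ])
    }
    if (residual_variance == "per_time") {
      for (t in seq_len(T)) {
        sig2[t] <- sum(W * (Y[, t] - matrix(mu[, t], N, k, byrow = TRUE))^2) / N
      }
    } else {
      tot <- 0
      for (t in seq_len(T)) {
        tot <- tot + sum(W * (Y[, t] - matrix(mu[, t], N, k, byrow = TRUE))^2)
      }
      sig2 <- rep(tot / (N * T), T)
    }
    ## E-step
    logd <- matrix(log(pi_k), N, k, byrow = TRUE)
    for (kk in seq_len(k)) {
      for (t in seq_len(T)) {
        logd[, kk] <- logd[, kk] +
          dnorm(Y[, t], mu[kk, t], sqrt(sig2[t]), log = TRUE)
      }
    }
    mx <- apply(logd, 1, max)
    li <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(li)
    W <- exp(logd - li)
    trace <- c(trace, ll)
    if (it > 1 && ll - ll_old <= rel_tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(W = W, ab = ab, mu = mu, sig2 = sig2, loglik = ll, trace = trace,
       n_iter = length(trace), converged = converged)
}

#' Relative entropy of a posterior classification
#'
#' `1 - sum(-p * log(p)) / (N log K)`: 1 when every subject is assigned with
#' certainty, 0 when every posterior is uniform. `p log p` is taken as 0 at
#' `p = 0`.
#'
#' @param posteriors an N x K posterior matrix (rows summing to 1) or an
#'   `lcga_fit`.
#' @return a number in \[0, 1\].
#' @export
relative_entropy <- function(posteriors) {
  if (inherits(posteriors, "lcga_fit")) posteriors <- posteriors$posteriors
  p <- as.matrix(posteriors)
  if (ncol(p) < 2) {
    abort("relative entropy is undefined for a single class.",
          class = "raschtraj_undefined_entropy")
  }
  plogp <- ifelse(p > 0, p * log(p), 0)
  1 - sum(-plogp) / (nrow(p) * log(ncol(p)))
}

#' Modal class assignment
#'
#' Assigns each subject to the class with the highest posterior probability;
#' ties are broken toward the lower class index.
#'
#' @param fit an `lcga_fit`.
#' @return a tibble with columns `subject_id`, `class` and `posterior` (the
#'   winning probability).
#' @export
assign_classes <- function(fit) {
  stopifnot(inherits(fit, "lcga_fit"))
  cl <- max.col(fit$posteriors, ties.method = "first")
  tibble::tibble(
    subject_id = fit$subject_id,
    class = cl,
    posterior = fit$posteriors[cbind(seq_along(cl), cl)]
  )
}

#' @export
print.lcga_fit <- function(x, ...) {
  cat(sprintf("<lcga_fit> %d-class linear LCGA on %s (N = %d)\n",
              x$k, x$measure, x$n))
  cat(sprintf("  loglik %.2f after %d EM iterations (start %d%s)\n",
              x$loglik, x$n_iter, x$best_start,
              if (x$converged) ", converged" else ", NOT converged"))
  if (!is.na(x$entropy)) cat(sprintf("  relative entropy %.3f\n", x$entropy))
  print(x$coefficients)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy per-class LCGA parameters
#'
#' @param x an `lcga_fit`.
#' @param ... unused.
#' @return a tibble with one row per class: `class`, `weight`, `intercept`,
#'   `slope`.
#' @method tidy lcga_fit
#' @export
tidy.lcga_fit <- function(x, ...) x$coefficients

#' One-row LCGA fit summary
#'
#' @param x an `lcga_fit`.
#' @param ... unused.
#' @method glance lcga_fit
#' @export
glance.lcga_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, n = x$n, loglik = x$loglik, entropy = x$entropy,
    n_iter = x$n_iter, converged = x$converged, best_start = x$best_start,
    degenerate = x$degenerate
  )
}

#' Scores augmented with class assignments and posteriors
#'
#' @param x an `lcga_fit`.
#' @param ... unused.
#' @return a tibble with one row per subject: `subject_id`, `group` (when
#'   known), `.class` and posterior probability columns `.p1`..`.pk`.
#' @method augment lcga_fit
#' @export
augment.lcga_fit <- function(x, ...) {
  out <- assign_classes(x)
  names(out)[names(out) == "class"] <- ".class"
  out$posterior <- NULL
  if (!is.null(x$group)) out <- tibble::add_column(out, group = x$group, .after = 1)
  post <- tibble::as_tibble(x$posteriors, .name_repair = ~paste0(".p", seq_along(.x)))
  dplyr::bind_cols(out, post)
}

#' Plot fitted class mean trajectories
#'
#' @param object an `lcga_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot lcga_fit
#' @export
autoplot.lcga_fit <- function(object, ...) {
  df <- tidyr::expand_grid(class = seq_len(object$k),
                           time = seq_along(object$time_codes))
  df$mean <- object$mean_trajectories[cbind(df$class, df$time)]
  df$weight <- object$weights[df$class]
  df$class <- factor(df$class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean,
                                   colour = .data$class)) +
    ggplot2::geom_line(ggplot2::aes(linewidth = .data$weight)) +
    ggplot2::geom_point() +
    ggplot2::scale_linewidth(range = c(0.4, 1.6), guide = "none") +
    ggplot2::labs(x = "collection time", y = paste("mean", object$measure),
                  colour = "class",
                  title = sprintf("%d-class linear LCGA on %s",
                                  object$k, object$measure)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
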