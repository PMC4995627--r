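#' Elementary symmetric functions of item easiness parameters
#'
#' For easiness values `eps[j] = exp(-delta[j])`, the order-r elementary
#' symmetric function is the sum of products of `eps` over all r-subsets of
#' items; it is the kernel of the conditional likelihood of a Rasch response
#' pattern given its raw score. Computed by the stable summation recursion.
#'
#' @param eps positive finite easiness values.
#' @return numeric vector `(gamma_0, ..., gamma_J)`.
#' @examples
#' elementary_symmetric(c(1, 1, 1))  # binomial coefficients 1 3 3 1
#' @export
elementary_symmetric <- function(eps) {
  if (length(eps) == 0) return(1)
  if (any(!is.finite(eps)) || any(eps <= 0)) {
    abort("`eps` must be positive and finite.", class = "raschtraj_invalid_input")
  }
  J <- length(eps)
  g <- c(1, rep(0, J))
  for (j in seq_len(J)) {
    g[2:(j + 1)] <- g[2:(j + 1)] + eps[j] * g[1:j]
  }
  g
}

## gamma^{(j)}_r for each left-out item j: row j holds orders 0..m-1
esf_without_one <- function(eps) {
  m <- length(eps)
  out <- matrix(0, m, m)
  for (j in seq_len(m)) out[j, ] <- elementary_symmetric(eps[-j])[seq_len(m)]
  out
}

log1pexp <- function(x) {
  out <- x
  lo <- x <= 37
  out[lo] <- log1p(exp(x[lo]))
  out
}

## Pool subject-time records and summarise by observed item set.
## Each element: items (indices), tot (item totals), score_cnt (counts of raw
## scores 0..m), n (number of records).
pool_records <- function(cohort) {
  N <- dim(cohort$responses)[1]
  T <- cohort$design$n_times
  J <- cohort$design$n_items
  recs <- matrix(cohort$responses, N * T, J)
  obs <- !is.na(recs)
  keep <- rowSums(obs) > 0
  recs <- recs[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  key <- apply(obs, 1, function(z) paste(which(z), collapse = ","))
  lapply(split(seq_along(key), key), function(rows) {
    items <- which(obs[rows[1], ])
    y <- recs[rows, items, drop = FALSE]
    sc <- rowSums(y)
    list(items = items, tot = colSums(y),
         score_cnt = tabulate(sc + 1L, length(items) + 1L),
         n = length(rows))
  })
}

cml_loglik <- function(d, sets) {
  ll <- 0
  for (s in sets) {
    eps <- exp(-d[s$items])
    g <- elementary_symmetric(eps)
    ll <- ll + sum(-d[s$items] * s$tot) -
      sum(s$score_cnt * log(g))
  }
  ll
}

cml_grad_hess <- function(d, sets, J) {
  grad <- rep(0, J)
  H <- matrix(0, J, J)
  for (s in sets) {
    items <- s$items
    m <- length(items)
    eps <- exp(-d[items])
    g <- elementary_symmetric(eps)
    g1 <- esf_without_one(eps)
    grad[items] <- grad[items] - s$tot
    for (r in seq_len(m)) {            # raw scores 1..m (0 contributes nothing)
      n_r <- s$score_cnt[r + 1]
      if (n_r == 0) next
      pij <- eps * g1[, r] / g[r + 1]  # P(Y_j = 1 | raw score r)
      grad[items] <- grad[items] + n_r * pij
      pijk <- matrix(0, m, m)
      if (r >= 2 && m >= 2) {
        for (j in seq_len(m - 1)) for (k in (j + 1):m) {
          gjk <- elementary_symmetric(eps[-c(j, k)])
          pijk[j, k] <- pijk[k, j] <- eps[j] * eps[k] * gjk[r - 1] / g[r + 1]
        }
      }
      diag(pijk) <- pij
      cov_r <- pijk - tcrossprod(pij)
      H[items, items] <- H[items, items] - n_r * cov_r
    }
  }
  list(grad = grad, hess = H)
}

gh_rule <- function(n = 21) pracma::gaussHermite(n)

## log integral of exp(r*theta) * prod_j 1/(1+exp(theta-delta_j)) against a
## N(mu, sigma^2) density, for r = 0..m, by Gauss-Hermite quadrature
log_score_integrals <- function(delta, mu, sigma, gh) {
  theta <- mu + sqrt(2) * sigma * gh$x
  base <- -vapply(theta, function(th) sum(log1pexp(th - delta)), numeric(1))
  lw <- log(gh$w) - 0.5 * log(pi)
  vapply(0:length(delta), function(r) {
    lf <- lw + r * theta + base
    mx <- max(lf)
    mx + log(sum(exp(lf - mx)))
  }, numeric(1))
}

mml_loglik <- function(d, mu, sigma, sets, gh) {
  ll <- 0
  for (s in sets) {
    li <- log_score_integrals(d[s$items], mu, sigma, gh)
    ll <- ll + sum(-d[s$items] * s$tot) + sum(s$score_cnt * li)
  }
  ll
}

#' Estimate Rasch item difficulties with across-time equality constraints
#'
#' Every subject-by-time record is pooled into one calibration (its responses
#' over the items observed at that time), which enforces a single
#' time-invariant difficulty per item — the longitudinal anchoring that makes
#' latent-variable scores comparable across questionnaire versions. Two
#' estimators are available: conditional maximum likelihood (CML), which
#' conditions each record on its raw score and eliminates the person levels,
#' solved by Newton-Raphson with elementary symmetric functions; and marginal
#' maximum likelihood (MML) with a normal latent distribution per record,
#' integrated by Gauss-Hermite quadrature. Difficulties are anchored by a
#' sum-to-zero constraint over all items.
#'
#' @param cohort a `sim_cohort` (any scenario applied).
#' @param method `"cml"` (default) or `"mml"`.
#' @param tol convergence tolerance on the gradient norm (CML).
#' @param max_iter maximum Newton iterations (CML).
#' @param gh_nodes Gauss-Hermite nodes for MML.
#' @return a tibble of class `rasch_difficulties` with columns `item`,
#'   `difficulty`, `se`, and attributes `method`, `anchoring`, `loglik`,
#'   `n_records`.
#' @export
estimate_difficulties <- function(cohort, method = c("cml", "mml"),
                                  tol = 1e-8, max_iter = 100, gh_nodes = 21) {
  method <- match.arg(method)
  J <- cohort$design$n_items
  sets <- pool_records(cohort)

  tot <- rep(0, J); n_obs <- rep(0, J)
  for (s in sets) {
    tot[s$items] <- tot[s$items] + s$tot
    n_obs[s$items] <- n_obs[s$items] + s$n
  }
  if (any(n_obs == 0)) {
    abort(sprintf("item(s) %s are never observed.",
                  paste(which(n_obs == 0), collapse = ", ")),
          class = "raschtraj_inestimable_item")
  }
  extreme <- which(tot == 0 | tot == n_obs)
  if (length(extreme) > 0) {
    abort(sprintf(
      "item(s) %s have all-0 or all-1 responses; their difficulty is inestimable.",
      paste(extreme, collapse = ", ")), class = "raschtraj_inestimable_item")
  }

  A <- rbind(diag(J - 1), rep(-1, J - 1))  # sum-to-zero parametrisation

  if (method == "cml") {
    d <- rep(0, J)
    ll <- cml_loglik(d, sets)
    converged <- FALSE
    n_iter <- 0
    for (it in seq_len(max_iter)) {
      n_iter <- it
      gh <- cml_grad_hess(d, sets, J)
      g9 <- crossprod(A, gh$grad)
      H9 <- crossprod(A, gh$hess %*% A)
      if (sqrt(sum(g9^2)) < tol) { converged <- TRUE; break }
      step <- solve(H9, g9)
      if (sqrt(sum(step^2)) < 1e-10) { converged <- TRUE; break }
      lam <- 1
      repeat {   # step halving keeps the CL increasing (up to rounding noise)
        d_new <- d - lam * as.vector(A %*% step)
        ll_new <- cml_loglik(d_new, sets)
        if (is.finite(ll_new) && ll_new >= ll - 1e-9 * max(1, abs(ll))) break
        lam <- lam / 2
        if (lam < 1e-8) break
      }
      d <- d_new; ll <- ll_new
    }
    if (!converged) {
      gh <- cml_grad_hess(d, sets, J)
      g9 <- crossprod(A, gh$grad)
      if (sqrt(sum(g9^2)) < tol) converged <- TRUE
    }
    if (!converged) {
      abort(sprintf(
        "CML did not converge in %d iterations (gradient norm %.2e).",
        max_iter, sqrt(sum(g9^2))), class = "raschtraj_convergence")
    }
    info9 <- -crossprod(A, cml_grad_hess(d, sets, J)$hess %*% A)
    V <- A %*% solve(info9) %*% t(A)
    se <- sqrt(pmax(diag(V), 0))
    extra <- list()
  } else {
    gh <- gh_rule(gh_nodes)
    fn <- function(p) {
      d <- as.vector(A %*% p[seq_len(J - 1)])
      mml_loglik(d, p[J], exp(p[J + 1]), sets, gh)
    }
    fit <- optim(rep(0, J + 1), fn, method = "BFGS", hessian = TRUE,
                 control = list(fnscale = -1, maxit = 500, reltol = 1e-12))
    if (fit$convergence != 0) {
      abort(sprintf("MML did not converge (optim code %d).", fit$convergence),
            class = "raschtraj_convergence")
    }
    d <- as.vector(A %*% fit$par[seq_len(J - 1)])
    ll <- fit$value
    Vfull <- tryCatch(solve(-fit$hessian), error = function(e) {
      matrix(NA_real_, J + 1, J + 1)
    })
    V <- A %*% Vfull[seq_len(J - 1), seq_len(J - 1)] %*% t(A)
    se <- sqrt(pmax(diag(V), 0))
    n_iter <- fit$counts[["function"]]
    converged <- TRUE
    extra <- list(latent_mean = fit$par[J], latent_sd = exp(fit$par[J + 1]))
  }

  out <- tibble::tibble(item = seq_len(J), difficulty = d, se = se)
  structure(out,
            class = c("rasch_difficulties", class(out)),
            method = toupper(method), anchoring = "sum-to-zero over all items",
            loglik = ll, n_records = sum(vapply(sets, `[[`, 0, "n")),
            n_iter = n_iter, converged = converged, latent = extra)
}

#' @export
print.rasch_difficulties <- function(x, ...) {
  cat(sprintf("<rasch_difficulties> %s, %s (%d pooled records)\n",
              attr(x, "method"), attr(x, "anchoring"), attr(x, "n_records")))
  NextMethod()
}

#' Latent level estimate for a raw score on a fixed item set
#'
#' Under the Rasch model the raw score is sufficient for the person level
#' given the item set, so scoring reduces to a map from raw score to theta.
#' `"ml"` solves `sum(y - P) = 0` (undefined at perfect scores); `"wle"` adds
#' Warm's bias correction term `I'(theta) / (2 I(theta))`, which keeps the
#' estimate finite at raw scores of 0 or all-correct; `"eap"` is the posterior
#' mean under a normal prior.
#'
#' @param raw_score vector of raw scores, each in `0..length(difficulties)`.
#' @param difficulties item difficulties of the observed set (possibly empty
#'   for EAP, which then returns the prior mean).
#' @param method `"wle"`, `"ml"` or `"eap"`.
#' @param prior_mean,prior_sd normal prior for EAP.
#' @param gh_nodes Gauss-Hermite nodes for EAP.
#' @return numeric vector of latent level estimates.
#' @examples
#' estimate_theta(2, qnorm(1:4 / 5), "wle")  # symmetric bank, half right -> 0
#' @export
estimate_theta <- function(raw_score, difficulties,
                           method = c("wle", "ml", "eap"),
                           prior_mean = 0, prior_sd = 1, gh_nodes = 41) {
  method <- match.arg(method)
  m <- length(difficulties)
  if (any(raw_score < 0 | raw_score > m)) {
    abort("raw scores must lie in 0..number of items.",
          class = "raschtraj_invalid_input")
  }
  if (m == 0) {
    if (method != "eap") {
      abort("only EAP is defined with zero observed items.",
            class = "raschtraj_infinite_estimate")
    }
    return(rep(prior_mean, length(raw_score)))
  }
  if (method == "ml" && any(raw_score == 0 | raw_score == m)) {
    abort(paste("ML person estimates are infinite at perfect raw scores;",
                "use method = 'wle' or 'eap'."),
          class = "raschtraj_infinite_estimate")
  }
  map <- vapply(sort(unique(raw_score)), function(r) {
    switch(method,
      ml = uniroot(function(th) r - sum(irf(th, difficulties)),
                   c(-35, 35), tol = 1e-10)$root,
      wle = uniroot(function(th) {
        p <- irf(th, difficulties)
        info <- sum(p * (1 - p))
        dinfo <- sum(p * (1 - p) * (1 - 2 * p))
        r - sum(p) + dinfo / (2 * info)
      }, c(-35, 35), tol = 1e-10)$root,
      eap = {
        gh <- gh_rule(gh_nodes)
        theta <- prior_mean + sqrt(2) * prior_sd * gh$x
        lf <- log(gh$w) + r * theta -
          vapply(theta, function(th) sum(log1pexp(th - difficulties)), numeric(1))
        w <- exp(lf - max(lf))
        sum(theta * w) / sum(w)
      })
  }, numeric(1))
  map[match(raw_score, sort(unique(raw_score)))]
}

#' Latent variable scores per subject and time
#'
#' Computes the Rasch latent-variable score for every subject at every
#' collection time, over the items observed at that time, using a shared set
#' of (time-invariant) item difficulties — so the latent scale is identical at
#' every time and scores are longitudinally comparable even when the
#' questionnaire changed. The default scorer is the expected a posteriori
#' (EAP) estimate — the posterior mean under a per-time normal prior whose
#' mean and variance are estimated by marginal maximum likelihood from that
#' time's records with the difficulties held fixed; this is the factor score
#' that maximum-likelihood IRT software reports for categorical items, and it
#' is finite at extreme raw scores. Warm's weighted likelihood estimate (WLE,
#' less shrinkage, no prior) and plain ML are available.
#'
#' @param cohort a `sim_cohort`.
#' @param difficulties a [estimate_difficulties()] result, a bare numeric
#'   vector of difficulties for all items, or `NULL` to estimate them by CML
#'   from the cohort itself.
#' @param method `"eap"` (default), `"wle"` or `"ml"`.
#' @param gh_nodes Gauss-Hermite nodes for EAP priors and scores.
#' @return a score tibble with `measure = "theta_est"`.
#' @export
person_scores <- function(cohort, difficulties = NULL,
                          method = c("eap", "wle", "ml"), gh_nodes = 41) {
  method <- match.arg(method)
  if (is.null(difficulties)) difficulties <- estimate_difficulties(cohort)
  if (is.data.frame(difficulties)) {
    delta <- difficulties$difficulty[order(difficulties$item)]
  } else {
    delta <- as.numeric(difficulties)
  }
  J <- cohort$design$n_items
  if (length(delta) != J) {
    abort("difficulties must cover every item in the design.",
          class = "raschtraj_invalid_input")
  }
  N <- dim(cohort$responses)[1]
  T <- cohort$design$n_times
  mat <- matrix(NA_real_, N, T)
  items_used <- vector("list", T)
  for (t in seq_len(T)) {
    obs <- which(!apply(is.na(cohort$responses[, t, , drop = FALSE]), 3, all))
    items_used[[t]] <- obs
    sc <- rowSums(cohort$responses[, t, obs, drop = FALSE])
    if (method == "eap") {
      cnt <- tabulate(sc + 1L, length(obs) + 1L)
      gh <- gh_rule(21)
      fn <- function(p) {
        sum(cnt * log_score_integrals(delta[obs], p[1], exp(p[2]), gh))
      }
      pr <- optim(c(0, 0), fn, control = list(fnscale = -1, reltol = 1e-10))
      mat[, t] <- estimate_theta(sc, delta[obs], "eap",
                                 prior_mean = pr$par[1],
                                 prior_sd = exp(pr$par[2]),
                                 gh_nodes = gh_nodes)
    } else {
      mat[, t] <- estimate_theta(sc, delta[obs], method)
    }
  }
  new_scores(score_tibble(mat, cohort), "theta_est", items_used)
}
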