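make_scores <- function(Y) {
  tibble::tibble(
    subject_id = rep(seq_len(nrow(Y)), ncol(Y)),
    time = rep(seq_len(ncol(Y)), each = nrow(Y)),
    score = as.vector(Y)
  )
}

test_that("single-class fit with constant variance equals the OLS solution", {
  set.seed(71)
  Y <- matrix(rnorm(200 * 4, rep(1:4, each = 200)), 200, 4)
  fit <- fit_lcga(make_scores(Y), k = 1, residual_variance = "constant",
                  rel_tol = 1e-12)
  # closed-form oracle: pooled OLS of score on time code, MLE variance
  df <- data.frame(y = as.vector(Y), x = rep(0:3, each = 200))
  ols <- lm(y ~ x, data = df)
  s2 <- mean(residuals(ols)^2)
  ll <- sum(dnorm(df$y, fitted(ols), sqrt(s2), log = TRUE))
  expect_equal(unname(coef(ols)),
               c(fit$coefficients$intercept, fit$coefficients$slope),
               tolerance = 1e-8)
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
})

test_that("single-class fit with per-time variances matches a direct optimiser", {
  set.seed(72)
  Y <- matrix(rnorm(150 * 4, rep(c(0, 1, 2, 3), each = 150),
                    rep(c(0.5, 1, 1.5, 2), each = 150)), 150, 4)
  fit <- fit_lcga(make_scores(Y), k = 1, rel_tol = 1e-12)
  nll <- function(p) {
    mu <- p[1] + p[2] * (0:3)
    -sum(sapply(1:4, function(t) {
      sum(dnorm(Y[, t], mu[t], exp(p[2 + t]), log = TRUE))
    }))
  }
  oracle <- optim(c(0, 0, rep(0, 4)), nll, method = "BFGS",
                  control = list(reltol = 1e-14))
  expect_equal(fit$loglik, -oracle$value, tolerance = 1e-6)
})

test_that("widely separated flat classes are recovered essentially exactly", {
  set.seed(73)
  mu <- c(-10, 0, 10)
  Y <- matrix(rnorm(90 * 4, rep(mu, each = 30), 0.01), 90, 4)
  fit <- fit_lcga(make_scores(Y), k = 3, n_starts = 3, seed = 73)
  expect_equal(fit$coefficients$intercept, mu, tolerance = 0.01)
  expect_equal(fit$coefficients$slope, rep(0, 3), tolerance = 0.01)
  expect_true(all(apply(fit$posteriors, 1, max) > 0.999))
  expect_equal(fit$weights, rep(1 / 3, 3), tolerance = 1e-6)
})

test_that("the EM log-likelihood never decreases and posteriors are proper", {
  co <- tiny_cohort()
  for (measure in list(score_theta_sim(co), score_raw(co))) {
    fit <- fit_lcga(measure, n_starts = 4, seed = 11)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8 * abs(fit$loglik)))
    expect_equal(unname(rowSums(fit$posteriors)), rep(1, fit$n),
                 tolerance = 1e-12)
    expect_equal(unname(colMeans(fit$posteriors)), unname(fit$weights))
    expect_true(fit$converged)
  }
})

test_that("classes are reported in ascending trajectory order", {
  fit <- fit_lcga(score_theta_sim(tiny_cohort()), n_starts = 4, seed = 3)
  expect_true(!is.unsorted(rowMeans(fit$mean_trajectories)))
})

test_that("relative entropy matches direct summation", {
  one_hot <- diag(3)[rep(1:3, 10), ]
  expect_equal(relative_entropy(one_hot), 1)
  uniform <- matrix(1 / 3, 30, 3)
  expect_equal(relative_entropy(uniform), 0)
  p <- matrix(rep(c(0.5, 0.25, 0.25), each = 20), 20, 3)
  oracle <- 1 - 20 * (0.5 * log(2) + 2 * 0.25 * log(4)) / (20 * log(3))
  expect_equal(relative_entropy(p), oracle)
  expect_error(relative_entropy(matrix(1, 5, 1)),
               class = "raschtraj_undefined_entropy")
})

test_that("modal assignment breaks ties toward the lower class", {
  fake <- structure(list(
    posteriors = rbind(c(0.1, 0.7, 0.2), c(1, 0, 0), c(0.5, 0.5, 0)),
    subject_id = 1:3), class = "lcga_fit")
  got <- assign_classes(fake)
  expect_equal(got$class, c(2L, 1L, 1L))
  expect_equal(got$posterior, c(0.7, 1, 0.5))
})

test_that("different start orders change labels only, not fit quality", {
  co <- tiny_cohort()
  s <- score_theta_sim(co)
  f1 <- fit_lcga(s, n_starts = 4, seed = 1)
  f2 <- fit_lcga(s, n_starts = 4, seed = 999)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$entropy, f2$entropy, tolerance = 1e-6)
  expect_equal(f1$coefficients$intercept, f2$coefficients$intercept,
               tolerance = 1e-4)
})

test_that("LCGA on the true latent values identifies the design structure", {
  # The working model ignores the 0.8 within-class lag correlations, so the
  # ML component means are pushed apart from the generating means (the fitted
  # likelihood must beat the generating parameters under the working model);
  # the qualitative structure — flat low, increasing middle, flat high, equal
  # weights — is what the fit is expected to recover.
  co <- full_cohort()
  Y <- co$theta
  fit <- fit_lcga(score_theta_sim(co), n_starts = 5, seed = 17)
  truth <- rbind(rep(-1, 4), c(-0.5, 0, 0.5, 1), rep(1, 4))  # ascending order
  mu <- rbind(rep(-1, 4), c(-0.5, 0, 0.5, 1), rep(1, 4))
  ll_truth <- sum(log(rowSums(sapply(1:3, function(k) {
    (1 / 3) * apply(sapply(1:4, function(t) {
      dnorm(Y[, t], mu[k, t], sqrt(0.3))
    }), 1, prod)
  }))))
  expect_gt(fit$loglik, ll_truth)
  expect_lt(max(abs(fit$mean_trajectories - truth)), 0.35)
  expect_lt(abs(fit$coefficients$slope[1]), 0.1)         # low class is flat
  expect_lt(abs(fit$coefficients$slope[3]), 0.1)         # high class is flat
  expect_gt(fit$coefficients$slope[2], 0.25)             # middle class rises
  expect_equal(fit$weights, rep(1 / 3, 3), tolerance = 0.15)
})

test_that("fit accessors expose tidy summaries", {
  fit <- fit_lcga(score_theta_sim(tiny_cohort()), n_starts = 3, seed = 5)
  td <- tidy(fit)
  expect_equal(names(td), c("class", "weight", "intercept", "slope"))
  gl <- glance(fit)
  expect_equal(gl$k, 3)
  expect_true(gl$converged)
  au <- augment(fit)
  expect_equal(nrow(au), fit$n)
  expect_true(all(c(".class", ".p1", ".p3") %in% names(au)))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("invalid score tables are rejected", {
  s <- make_scores(matrix(rnorm(20), 5, 4))
  s$score[3] <- NA
  expect_error(fit_lcga(s), class = "raschtraj_invalid_input")
  expect_error(fit_lcga(make_scores(matrix(rnorm(8), 2, 4)), k = 3),
               class = "raschtraj_invalid_input")
})
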