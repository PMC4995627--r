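test_that("elementary symmetric functions match enumeration", {
  expect_equal(elementary_symmetric(c(1, 1, 1)), c(1, 3, 3, 1))
  expect_equal(elementary_symmetric(2), c(1, 2))

  # exhaustive-pattern oracle on 6 items
  set.seed(31)
  eps <- exp(runif(6, -1.5, 1.5))
  patterns <- as.matrix(expand.grid(rep(list(0:1), 6)))
  oracle <- sapply(0:6, function(r) {
    rows <- patterns[rowSums(patterns) == r, , drop = FALSE]
    sum(apply(rows, 1, function(y) prod(eps^y)))
  })
  expect_equal(elementary_symmetric(eps), oracle)
  expect_error(elementary_symmetric(c(1, -1)),
               class = "raschtraj_invalid_input")
})

test_that("CML estimates maximise the enumeration-based conditional likelihood", {
  co <- simulate_cohort(tiny_design(size = 80, n_items = 6,
                                    difficulties = qnorm(1:6 / 7)), seed = 55)
  est <- estimate_difficulties(co, method = "cml")

  # oracle: direct optimisation of the conditional log-likelihood computed by
  # exhaustive enumeration of response patterns (no ESF recursion)
  recs <- matrix(co$responses, ncol = 6)
  scores <- rowSums(recs)
  patterns <- as.matrix(expand.grid(rep(list(0:1), 6)))
  cloglik <- function(d9) {
    d <- c(d9, -sum(d9))
    eps <- exp(-d)
    denom <- sapply(0:6, function(r) {
      rows <- patterns[rowSums(patterns) == r, , drop = FALSE]
      sum(apply(rows, 1, function(y) prod(eps^y)))
    })
    sum(recs %*% (-d)) - sum(log(denom[scores + 1]))
  }
  oracle <- optim(rep(0, 5), cloglik, method = "BFGS",
                  control = list(fnscale = -1, reltol = 1e-14))
  expect_equal(est$difficulty, c(oracle$par, -sum(oracle$par)),
               tolerance = 1e-5)
  expect_equal(sum(est$difficulty), 0, tolerance = 1e-10)
})

test_that("CML recovers the generating difficulties on a full cohort", {
  est <- estimate_difficulties(full_cohort())   # 12,000 pooled records
  truth <- qnorm(1:10 / 11)
  expect_lt(max(abs(est$difficulty - truth)), 0.1)
  expect_lt(mean(abs(est$difficulty - truth)), 0.05)
  expect_true(all(is.finite(est$se)) && all(est$se > 0))
})

test_that("all items stay estimable under the four_items scenario", {
  co <- apply_scenario(tiny_cohort(), "four_items")
  est <- estimate_difficulties(co)
  expect_equal(nrow(est), 10)
  expect_true(all(is.finite(est$difficulty)) && all(is.finite(est$se)))
})

test_that("CML estimates are invariant to a latent location shift", {
  g <- default_trajectory_groups(size = 1000)
  g[paste0("t", 1:4)] <- g[paste0("t", 1:4)] + 0.5
  shifted <- simulate_cohort(study_design(groups = g), seed = 202)
  a <- estimate_difficulties(full_cohort())$difficulty
  b <- estimate_difficulties(shifted)$difficulty
  expect_lt(max(abs(a - b)), 0.1)
})

test_that("MML and CML difficulty estimates agree", {
  co <- full_cohort()
  cml <- estimate_difficulties(co, "cml")
  mml <- estimate_difficulties(co, "mml")
  joint_se <- sqrt(cml$se^2 + mml$se^2)
  expect_true(all(abs(cml$difficulty - mml$difficulty) < 2 * joint_se))
})

test_that("constant items are reported as inestimable by name", {
  co <- tiny_cohort()
  co$responses[, , 2] <- 0L
  expect_error(estimate_difficulties(co), "2",
               class = "raschtraj_inestimable_item")
})

test_that("WLE matches a grid-search maximiser of the penalised likelihood", {
  delta <- c(-1.2, -0.4, 0.1, 0.8, 1.5)
  grid <- seq(-8, 8, by = 5e-4)
  info <- function(th) rowSums(sapply(delta, function(d) {
    p <- plogis(th - d); p * (1 - p)
  }))
  for (r in 0:5) {
    pen <- r * grid -
      rowSums(sapply(delta, function(d) log1p(exp(grid - d)))) +
      0.5 * log(info(grid))
    oracle <- grid[which.max(pen)]
    expect_equal(estimate_theta(r, delta, "wle"), oracle, tolerance = 1e-3)
  }
})

test_that("person estimators respect symmetry, priors and perfect scores", {
  sym <- qnorm(1:4 / 5)
  expect_equal(estimate_theta(2, sym, "wle"), 0, tolerance = 1e-8)
  expect_equal(estimate_theta(2, sym, "ml"), 0, tolerance = 1e-8)
  expect_equal(estimate_theta(0, numeric(0), "eap"), 0)
  expect_equal(estimate_theta(0, numeric(0), "eap", prior_mean = 0.7), 0.7)
  expect_error(estimate_theta(4, sym, "ml"),
               class = "raschtraj_infinite_estimate")
  expect_error(estimate_theta(0, sym, "ml"),
               class = "raschtraj_infinite_estimate")
  expect_true(is.finite(estimate_theta(0, sym, "wle")))
  # EAP shrinks toward the prior mean relative to WLE
  expect_lt(abs(estimate_theta(4, sym, "eap")), abs(estimate_theta(4, sym, "wle")))
})

test_that("person estimates increase strictly with the raw score", {
  delta <- qnorm(1:10 / 11)
  for (m in c("wle", "eap")) {
    th <- estimate_theta(0:10, delta, m)
    expect_true(all(diff(th) > 0))
  }
  expect_true(all(diff(estimate_theta(1:9, delta, "ml")) > 0))
})

test_that("person scores cover every subject-time on the same latent scale", {
  co <- apply_scenario(tiny_cohort(), "four_items")
  est <- estimate_difficulties(co)
  ps <- person_scores(co, est, method = "wle")
  expect_equal(attr(ps, "measure"), "theta_est")
  expect_true(all(is.finite(ps$score)))
  expect_equal(nrow(ps), nrow(co$theta) * 4)
  # within a time, theta_est is a strictly increasing function of the raw sum
  for (t in c(1, 3)) {
    obs <- which(!apply(is.na(co$responses[, t, , drop = FALSE]), 3, all))
    sums <- rowSums(co$responses[, t, obs, drop = FALSE])
    th <- ps$score[ps$time == t]
    agg <- tapply(th, sums, unique)
    expect_true(all(diff(unlist(agg)) > 0))
  }
})

test_that("WLE scores from disjoint item halves estimate the same level", {
  co <- full_cohort()
  delta <- qnorm(1:10 / 11)
  odd <- c(1, 3, 5, 7, 9); even <- c(2, 4, 6, 8, 10)
  s_odd <- estimate_theta(rowSums(co$responses[, 1, odd]), delta[odd], "wle")
  s_even <- estimate_theta(rowSums(co$responses[, 1, even]), delta[even], "wle")
  # specific objectivity: both halves are unbiased for the same theta
  expect_lt(abs(mean(s_odd - s_even)), 0.05)
  expect_lt(abs(coef(lm(s_odd ~ co$theta[, 1]))[2] -
                coef(lm(s_even ~ co$theta[, 1]))[2]), 0.1)
})

test_that("EAP person scores use marginally estimated per-time priors", {
  co <- tiny_cohort()
  ps <- person_scores(co, qnorm(1:10 / 11), method = "eap")
  expect_true(all(is.finite(ps$score)))
  # shrinkage: EAP spread no larger than WLE spread
  wle <- person_scores(co, qnorm(1:10 / 11), method = "wle")
  expect_lt(sd(ps$score), sd(wle$score))
})
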