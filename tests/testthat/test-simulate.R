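test_that("the item response function matches its closed form", {
  expect_equal(irf(0.7, 0.7), 0.5)
  expect_equal(irf(1, 0), exp(1) / (1 + exp(1)))
  expect_equal(irf(-2, 1), plogis(-3))
  lo <- irf(-50, 0)
  expect_true(lo > 0 && lo < 1e-20 && is.finite(lo))
  expect_true(is.finite(irf(50, 0)) && irf(50, 0) <= 1)
  expect_error(irf(NA, 0), class = "raschtraj_invalid_input")
})

test_that("simulation is reproducible from the seed", {
  d <- tiny_design()
  a <- simulate_cohort(d, seed = 5)
  b <- simulate_cohort(d, seed = 5)
  expect_identical(a$responses, b$responses)
  expect_identical(a$theta, b$theta)
  c <- simulate_cohort(d, seed = 6)
  expect_false(identical(a$responses, c$responses))
})

test_that("cohort dimensions and group counts follow the design", {
  co <- full_cohort()
  expect_equal(dim(co$responses), c(3000, 4, 10))
  expect_equal(unname(table(co$group)), array(c(1000L, 1000L, 1000L)))
  expect_equal(levels(co$group), c("low", "high", "increasing"))
})

test_that("latent trajectories have the designed group means", {
  co <- full_cohort()
  # MC tolerance: 4 standard errors of a mean of 1000 draws with variance 0.3
  tol <- 4 * sqrt(0.3 / 1000)
  mu <- rbind(rep(-1, 4), rep(1, 4), c(-0.5, 0, 0.5, 1))
  for (g in 1:3) {
    th <- co$theta[as.integer(co$group) == g, ]
    expect_true(all(abs(colMeans(th) - mu[g, ]) < tol))
  }
})

test_that("within-group lag correlations of theta match the design", {
  co <- full_cohort()
  for (lag in 1:3) {
    rho <- c(0.8, 0.7, 0.6)[lag]
    obs <- sapply(levels(co$group), function(g) {
      th <- co$theta[co$group == g, ]
      mean(sapply(seq_len(4 - lag), function(t) cor(th[, t], th[, t + lag])))
    })
    expect_true(all(abs(obs - rho) < 0.03),
                info = sprintf("lag %d: %s", lag, paste(round(obs, 3), collapse = " ")))
  }
})

test_that("item marginals agree with a quadrature oracle", {
  co <- full_cohort()
  gh <- pracma::gaussHermite(41)
  delta <- co$design$item_bank$difficulty
  for (g in c("low", "high")) {
    mu_g <- if (g == "low") -1 else 1
    th <- mu_g + sqrt(2 * 0.3) * gh$x
    for (j in c(1, 5, 10)) {
      oracle <- sum(gh$w * plogis(th - delta[j])) / sqrt(pi)
      obs <- mean(co$responses[co$group == g, 1, j])
      mc_se <- sqrt(oracle * (1 - oracle) / 1000)
      expect_lt(abs(obs - oracle), 3.5 * mc_se)
    }
  }
})

test_that("scenario masking erases exactly the designed cells", {
  co <- tiny_cohort()
  m <- apply_scenario(co, "seven_difficult")
  expect_true(all(is.na(m$responses[, 3:4, c(1, 2, 4)])))
  keep <- !is.na(m$responses)
  expect_identical(m$responses[keep], co$responses[keep])
  expect_equal(sum(is.na(m$responses)), nrow(co$theta) * 2 * 3)

  identity <- apply_scenario(co, "complete")
  expect_identical(identity$responses, co$responses)
})

test_that("masking every item at a time is rejected", {
  co <- tiny_cohort()
  first9 <- scenario_mask("custom",
                          erased = tidyr::expand_grid(item = 1:9, time = 1))
  masked <- apply_scenario(co, first9)
  last1 <- scenario_mask("custom",
                         erased = tibble::tibble(item = 10, time = 1))
  expect_error(apply_scenario(masked, last1),
               class = "raschtraj_invalid_scenario")
})

test_that("cohorts round-trip through long-format CSV", {
  co <- simulate_cohort(tiny_design(size = 10, scenario = "four_items"), seed = 9)
  rf <- tempfile(fileext = ".csv"); tf <- tempfile(fileext = ".csv")
  write_cohort(co, rf, tf)
  back <- read_cohort(rf, tf)
  expect_equal(unname(back$responses), unname(co$responses))
  expect_equal(back$theta, co$theta, ignore_attr = TRUE)
  expect_equal(as.character(back$group), as.character(co$group))
})

test_that("designs round-trip through YAML config", {
  cfg <- tempfile(fileext = ".yml")
  writeLines(c(
    "times: 4", "items: 10", "variance: 0.3",
    "correlations: [0.8, 0.7, 0.6]",
    "groups:",
    "  - {name: low, size: 20, means: [-1, -1, -1, -1]}",
    "  - {name: high, size: 20, means: [1, 1, 1, 1]}",
    "scenario: four_items", "seed: 7"), cfg)
  got <- read_design_config(cfg)
  expect_s3_class(got$design, "study_design")
  expect_equal(got$design$scenario$name, "four_items")
  expect_equal(got$design$groups$size, c(20L, 20L))
  expect_equal(got$seed, 7)
})
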