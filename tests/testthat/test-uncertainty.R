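test_that("ratio-of-differences propagation reproduces the mixing-ratio SD", {
  pr <- propagate_ratio_of_differences(mq(3417, 279), mq(2693, 196),
                                       mq(10899, 420))
  expect_equal(pr$value, 0.088228, tolerance = 1e-4)
  # independent-occurrence convention: the published-convention SD
  expect_lt(abs(pr$sd - 0.0417), 0.0005)

  # correlated alternative is smaller (shared baseline partially cancels)
  prc <- propagate_ratio_of_differences(mq(3417, 279), mq(2693, 196),
                                        mq(10899, 420), correlated_b = TRUE)
  expect_lt(prc$sd, pr$sd)

  # exact inputs give an exact result
  pr0 <- propagate_ratio_of_differences(mq(3417), mq(2693), mq(10899))
  expect_equal(pr0$sd, 0)
  expect_error(propagate_ratio_of_differences(mq(1, 1), mq(2, 1), mq(2, 1)),
               "degenerate denominator")
})

test_that("each convention agrees with its own Monte-Carlo counterpart", {
  a <- mq(3417, 279); b <- mq(2693, 196); c <- mq(10899, 420)
  indep <- propagate_ratio_of_differences(a, b, c)
  mc_split <- monte_carlo("ratio_of_differences_split", list(a, b, b, c),
                          n_draws = 2e5, seed = 101)
  expect_equal(indep$sd, mc_split$sd, tolerance = 0.03)

  corr <- propagate_ratio_of_differences(a, b, c, correlated_b = TRUE)
  mc_shared <- monte_carlo("basalt_fraction", list(a, b, c),
                           n_draws = 2e5, seed = 101)
  expect_equal(corr$sd, mc_shared$sd, tolerance = 0.03)
})

test_that("delta-method propagation matches closed forms and flags misuse", {
  # d/dp [m p/(1-p)] = m/(1-p)^2; documents the ~60 t/ha first-order SD
  mb <- propagate_through("basalt_mass", list(mq(1200, 0), mq(0.0881, 0.0417)))
  expect_equal(mb$value, basalt_mass(1200, 0.0881))
  expect_equal(mb$sd, 1200 / (1 - 0.0881)^2 * 0.0417, tolerance = 1e-6)
  expect_gt(mb$sd, 55)  # far from a "± 5" scale

  cdr0 <- propagate_through("cdr_potential",
                            list(mq(0.3), mq(0.1), mq(31009), mq(70664),
                                 mq(200)))
  expect_equal(cdr0$sd, 0)

  expect_error(propagate_through("no_such_op", list(mq(1))), "unknown operation")
  expect_error(propagate_through("basalt_mass", list(mq(1))), "takes 2 inputs")
})

test_that("analytic and Monte-Carlo SDs agree within 3 MC standard errors", {
  set.seed(21)
  n_draws <- 2e4
  mc_se <- function(s) s / sqrt(2 * (n_draws - 1))
  cases <- list()
  for (i in 1:6) {
    ti_s <- runif(1, 2000, 4000)
    ti_b <- runif(1, 8000, 15000)
    p <- runif(1, 0.03, 0.3)
    cases[[length(cases) + 1]] <- list(
      "basalt_fraction",
      list(mq(expected_cation(ti_b, ti_s, p), 0.02 * ti_s),
           mq(ti_s, 0.02 * ti_s), mq(ti_b, 0.02 * ti_b)))
    cases[[length(cases) + 1]] <- list(
      "basalt_mass", list(mq(1200, 24), mq(p, 0.03 * p)))
    cases[[length(cases) + 1]] <- list(
      "cdr_potential",
      list(mq(runif(1, 0.1, 0.6), 0.01), mq(runif(1, 0.05, 0.3), 0.01),
           mq(31009, 600), mq(70664, 1400), mq(200, 4)))
  }
  for (k in seq_along(cases)) {
    op <- cases[[k]][[1]]; inp <- cases[[k]][[2]]
    an <- propagate_through(op, inp)
    mc <- monte_carlo(op, inp, n_draws = n_draws, seed = 300 + k)
    expect_lt(abs(an$sd - mc$sd), 3 * mc_se(mc$sd) + 0.003 * mc$sd,
              label = paste("op", op, "case", k))
  }
})

test_that("scaling all input SDs by k scales the analytic output SD by k", {
  inp <- list(mq(3417, 279), mq(2693, 196), mq(10899, 420))
  s1 <- propagate_through("basalt_fraction", inp)$sd
  inp2 <- lapply(inp, function(q) mq(q$value, 2.5 * q$sd))
  expect_equal(propagate_through("basalt_fraction", inp2)$sd, 2.5 * s1,
               tolerance = 1e-9)
})

test_that("Monte-Carlo is a deterministic, seed-reproducible oracle", {
  inp <- list(mq(3417, 279), mq(2693, 196), mq(10899, 420))
  m1 <- monte_carlo("basalt_fraction", inp, n_draws = 5e4, seed = 7)
  m2 <- monte_carlo("basalt_fraction", inp, n_draws = 5e4, seed = 7)
  expect_identical(m1$value, m2$value)
  expect_identical(m1$sd, m2$sd)

  # zero-noise fixed point, both methods
  exact <- list(mq(3417), mq(2693), mq(10899))
  expect_equal(monte_carlo("basalt_fraction", exact, 1e4, seed = 1)$sd, 0)
  expect_equal(propagate_through("basalt_fraction", exact)$sd, 0)
  expect_equal(monte_carlo("basalt_fraction", exact, 1e4, seed = 1)$value,
               (3417 - 2693) / (10899 - 2693))

  # caller's RNG stream is untouched
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(monte_carlo("basalt_fraction", inp, 1e4, seed = 5))
  expect_identical(rnorm(3), before)

  expect_error(monte_carlo("basalt_fraction", inp, n_draws = 10, seed = 1),
               "at least 1000")
  # frequent precondition failure is reported, not averaged over
  expect_error(
    monte_carlo("basalt_mass", list(mq(1200, 0), mq(0.99, 0.2)),
                n_draws = 1e4, seed = 2),
    "failed")
})
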