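test_that("recurrence probability escalates geometrically", {
  p <- model_params()
  expect_equal(recurrence_prob(1, p), 0.1181)
  expect_equal(recurrence_prob(5, p), 0.1181 * 1.019^4)
  expect_equal(recurrence_prob(5, p), 0.12735, tolerance = 2e-4)
  flat <- model_params(recur_rr_per_year = 1)
  expect_equal(recurrence_prob(1:20, flat), rep(0.1181, 20))
  expect_error(recurrence_prob(0, p), ">= 1")
  # capped at 1 far in the future
  expect_equal(recurrence_prob(500, p), 1)
})

test_that("survivor reallocation spreads mass to equal-or-worse states", {
  expect_equal(reallocate_survivors("mrs01"),
               c(mrs01 = 1 / 3, mrs23 = 1 / 3, mrs45 = 1 / 3))
  expect_equal(reallocate_survivors("mrs23"),
               c(mrs01 = 0, mrs23 = 0.5, mrs45 = 0.5))
  expect_equal(reallocate_survivors("mrs45"),
               c(mrs01 = 0, mrs23 = 0, mrs45 = 1))
  expect_equal(unname(rowSums(reallocate_survivors())), rep(1, 3))
  expect_error(reallocate_survivors("death"), "alive")
})

test_that("the dead state is absorbing with no flows", {
  st <- markov_step(c(0, 0, 0, 1), year_index = 1, age = 64)
  expect_equal(unname(st$occupancy), c(0, 0, 0, 1))
  expect_equal(st$cycle_cost, 0)
  expect_equal(st$cycle_qaly, 0)
})

test_that("with no recurrence and no mortality, QALY flow is the utility mix", {
  p <- model_params(recur_rate = 0)
  occ <- c(0.5, 0.3, 0.15, 0.05)
  st <- markov_step(occ, 1, age = 64, params = p,
                    life_table = null_life_table(p))
  expect_equal(unname(st$occupancy), occ, tolerance = 1e-12)
  expect_equal(st$cycle_qaly, 0.80 * 0.5 + 0.58 * 0.3 + 0.28 * 0.15,
               tolerance = 1e-12)
})

test_that("one cycle from full health matches hand-computed flows", {
  # r = 0.1181, fatality 0.2101, no background mortality
  p <- model_params()
  st <- markov_step(c(1, 0, 0, 0), 1, age = 64, params = p,
                    life_table = null_life_table(p))
  dead <- 0.1181 * 0.2101
  surv <- 0.1181 * (1 - 0.2101)
  expect_equal(dead, 0.02481, tolerance = 2e-4)
  expect_equal(unname(st$occupancy),
               c(1 - 0.1181 + surv / 3, surv / 3, surv / 3, dead),
               tolerance = 1e-12)
  expect_equal(st$recurrent_deaths, dead, tolerance = 1e-12)
})

test_that("occupancy stays a distribution and death is monotone", {
  set.seed(31)
  w <- default_time_windows()
  for (arm in c("tpa", "control")) {
    out <- pooled_arm_outcomes(w, arm)
    tr <- run_cohort(arm, out)
    occ <- as.matrix(tr[, c("mrs01", "mrs23", "mrs45", "death")])
    expect_equal(unname(rowSums(occ)), rep(1, nrow(occ)), tolerance = 1e-9)
    expect_true(all(diff(tr$death) >= -1e-12))
    expect_true(all(diff(tr$cum_cost_disc) >= 0))
    expect_true(all(diff(tr$cum_qaly_disc) >= 0))
  }
  # random parameter perturbations keep mass conserved
  for (i in 1:10) {
    p <- model_params(
      recur_rate = runif(1, 0, 0.5),
      recur_case_fatality = runif(1, 0, 1),
      hr_mrs45 = runif(1, 2.04, 6)
    )
    out <- pooled_arm_outcomes(w, "tpa")
    tr <- run_cohort("tpa", out, p)
    occ <- as.matrix(tr[, c("mrs01", "mrs23", "mrs45", "death")])
    expect_equal(unname(rowSums(occ)), rep(1, nrow(occ)), tolerance = 1e-9)
    expect_true(all(diff(tr$death) >= -1e-12))
  }
})

test_that("zero discount rates reproduce plain undiscounted sums", {
  p <- model_params(disc_cost = 0, disc_outcome = 0)
  out <- pooled_arm_outcomes(default_time_windows(), "tpa")
  tr <- run_cohort("tpa", out, p)
  expect_equal(tr$cum_cost_disc[nrow(tr)], sum(tr$cycle_cost),
               tolerance = 1e-9)
  expect_equal(tr$cum_qaly_disc[nrow(tr)], sum(tr$cycle_qaly),
               tolerance = 1e-9)
})

test_that("an immortal fully-healthy cohort accrues exactly H QALYs", {
  p <- model_params(recur_rate = 0, disc_cost = 0, disc_outcome = 0,
                    utility_mrs01 = 1, utility_mrs23 = 1, utility_mrs45 = 1)
  tr <- run_cohort("control", degenerate_outcome("mrs01"), p,
                   life_table = null_life_table(p))
  hs <- horizon_summary(tr, c(1, 2, 10, 30))
  expect_equal(hs$qaly, c(1, 2, 10, 30), tolerance = 1e-9)
})

test_that("horizon summaries pro-rate the final annual cycle by 0.75", {
  out <- pooled_arm_outcomes(default_time_windows(), "tpa")
  tr <- run_cohort("tpa", out)
  h1 <- horizon_summary(tr, 1)
  expect_equal(h1$cost, tr$disc_cost[1] + 0.75 * tr$disc_cost[2],
               tolerance = 1e-9)
  expect_equal(h1$qaly, tr$disc_qaly[1] + 0.75 * tr$disc_qaly[2],
               tolerance = 1e-9)
  h2 <- horizon_summary(tr, 2)
  expect_equal(h2$qaly,
               sum(tr$disc_qaly[1:2]) + 0.75 * tr$disc_qaly[3],
               tolerance = 1e-9)
  expect_error(horizon_summary(tr, 31), "between")
})

test_that("QALYs respond monotonically to utilities and recurrence", {
  out <- pooled_arm_outcomes(default_time_windows(), "tpa")
  qaly_at <- function(params) {
    horizon_summary(run_cohort("tpa", out, params), 30)$qaly
  }
  base <- qaly_at(model_params())
  expect_gt(qaly_at(model_params(utility_mrs23 = 0.70)), base)
  expect_gt(qaly_at(model_params(utility_mrs45 = 0.36)), base)
  worse <- model_params(recur_rate = 0.25)
  expect_lt(qaly_at(worse), base)
  dead_frac <- function(params) {
    tr <- run_cohort("tpa", out, params)
    tr$death[nrow(tr)]
  }
  expect_gt(dead_frac(worse), dead_frac(model_params()))
})

test_that("cycle-0 accrual is 0.25 years at 90-day state utilities", {
  out <- pooled_arm_outcomes(default_time_windows(), "control")
  tr <- run_cohort("control", out)
  p <- model_params()
  expect_equal(tr$cycle_qaly[1],
               0.25 * (out$p_mrs01 * 0.80 + out$p_mrs23 * 0.58 +
                         out$p_mrs45 * 0.28),
               tolerance = 1e-12)
  expect_equal(tr$cycle_cost[1], first_cycle_cost(out, "control", p),
               tolerance = 1e-9)
})
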