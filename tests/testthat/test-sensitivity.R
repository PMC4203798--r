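test_that("a degenerate range returns the base-case ICER on both sides", {
  cfg <- base_config()
  i <- cfg$specs$name == "cost_sich_addon"
  cfg$specs$low[i] <- cfg$specs$base[i]
  cfg$specs$high[i] <- cfg$specs$base[i]
  entry <- one_way("cost_sich_addon", cfg)
  base <- run_base_case(cfg, horizons = 30, utilities = "base")$icer
  expect_equal(entry$icer_at_low, base, tolerance = 1e-9)
  expect_equal(entry$icer_at_high, base, tolerance = 1e-9)
  expect_equal(entry$spread, 0)
})

test_that("one-way sweeps move the ICER in the expected direction", {
  cfg <- base_config()
  base <- run_base_case(cfg, horizons = 30, utilities = "base")$icer
  orw <- one_way("or_mrs01_w2", cfg)
  expect_gt(orw$icer_at_low, base)   # weaker treatment effect -> worse ICER
  expect_lt(orw$icer_at_high, base)
  ann <- one_way("cost_annual_mrs25", cfg)
  expect_gt(ann$icer_at_low, base)   # cheaper disabled care -> fewer offsets
  expect_lt(ann$icer_at_high, base)
  expect_error(one_way("no_such_param", cfg), "Unknown")
})

test_that("window-level odds-ratio sweeps only touch their own window", {
  cfg <- base_config()
  spec <- cfg$specs[cfg$specs$name == "or_mrs01_w2", ]
  mod <- tpacea:::set_spec_value(cfg$windows, cfg$params, spec, 1.12)
  expect_equal(mod$windows$or_mrs01, c(2.55, 1.12, 1.34))
  expect_equal(mod$windows$or_death, cfg$windows$or_death)
})

test_that("tornado sorts by spread and keeps failed entries flagged", {
  tor <- run_owsa(base_config())
  expect_s3_class(tor, "tornado")
  expect_equal(nrow(tor), nrow(base_config()$specs))
  expect_true(all(diff(tor$spread[!is.na(tor$spread)]) <= 1e-9))
  expect_true(all(c("icer_at_low", "icer_at_high", "failed") %in%
                    names(tor)))
  expect_true(is.finite(attr(tor, "base_icer")))
  # the hr_mrs01 upper bound (1.2) violates the hazard-ratio ordering
  # against hr_mrs23 (1.19), so that entry is flagged rather than dropped
  expect_true(tor$failed[tor$param == "hr_mrs01"])
})

test_that("PSA draws have the specified moments", {
  cfg <- base_config()
  cmp <- tpacea:::psa_compile(cfg)
  set.seed(51)
  n <- 20000
  i <- which(cmp$scalar_names == "utility_mrs45")
  u45 <- rbeta(n, cmp$shape1[i], cmp$shape2[i])
  se <- sd(u45) / sqrt(n)
  expect_lt(abs(mean(u45) - 0.28), 3 * se)
  expect_true(all(u45 >= 0 & u45 <= 1))
  j <- which(cmp$scalar_names == "cost_tpa_addon")
  cost <- rlnorm(n, cmp$meanlog[j], cmp$sdlog[j])
  expect_true(all(cost > 0))
  med_se <- 1.2533 * sd(cost) / sqrt(n)  # asymptotic SE of a median
  expect_lt(abs(median(cost) - 10830), 3 * med_se)
  # full joint draws respect domains
  set.seed(52)
  for (k in 1:20) {
    d <- draw_psa_params(cfg)
    expect_true(all(d$windows$p_mrs01 + d$windows$p_mrs23 +
                      d$windows$p_mrs45 + d$windows$p_death - 1 < 1e-12))
    expect_true(all(d$windows$p_sich > 0 & d$windows$p_sich < 1))
    expect_true(d$params$hr_mrs01 <= d$params$hr_mrs23)
  }
})

test_that("degenerate distributions make every draw the base case", {
  cfg <- degenerate_config()
  set.seed(53)
  d <- draw_psa_params(cfg)
  expect_equal(unclass(d$params), unclass(cfg$params))
  expect_equal(as.data.frame(d$windows), as.data.frame(cfg$windows))
  psa <- run_psa(25, seed = 9, config = cfg)
  base <- run_base_case(cfg, horizons = 30, utilities = "base")
  expect_equal(psa$points$delta_cost, rep(base$delta_cost, 25),
               tolerance = 1e-9)
  expect_equal(psa$points$delta_qaly, rep(base$delta_qaly, 25),
               tolerance = 1e-9)
  # CEAC is a step function at the base-case ICER
  expect_equal(psa$ceac$probability,
               as.numeric(psa$ceac$wtp > base$icer))
})

test_that("the PSA is bitwise reproducible given its seed", {
  a <- run_psa(40, seed = 123)
  b <- run_psa(40, seed = 123)
  expect_identical(a$points, b$points)
  expect_identical(a$ceac, b$ceac)
  c <- run_psa(40, seed = 124)
  expect_false(identical(a$points, c$points))
})

test_that("CEAC bounds, limits and monotonicity hold", {
  set.seed(61)
  pts <- tibble::tibble(delta_cost = rnorm(500, 5000, 8000),
                        delta_qaly = runif(500, 0.05, 0.8))
  curve <- ceac(pts, c(0, 1e4, 5e4, 1e5, 1e9))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  expect_equal(curve$probability[1], mean(pts$delta_cost < 0))
  # all gains positive -> non-decreasing in wtp, limit = 1
  expect_true(all(diff(curve$probability) >= 0))
  expect_equal(curve$probability[5], mean(pts$delta_qaly > 0))
  dom <- tibble::tibble(delta_cost = -abs(rnorm(100)),
                        delta_qaly = runif(100))
  expect_equal(ceac(dom, c(0, 35100, 105000))$probability, rep(1, 3))
  expect_error(ceac(dom[0, ], 0), "non-empty")
})

test_that("dominant draws are cost-effective at every positive threshold", {
  psa <- run_psa(300, seed = 71)
  pos <- psa$ceac$wtp > 0
  expect_true(all(psa$ceac$probability[pos] >= psa$frac_dominant - 1e-12))
  expect_equal(nrow(psa$points), 300)
  pr <- prob_cost_effective(psa)
  expect_named(pr, c("35100", "105000"))
  g <- glance(psa)
  expect_equal(g$n_draws, 300)
})

test_that("wtp grid includes both GDP-based thresholds exactly", {
  grid <- default_wtp_grid()
  expect_true(all(c(35100, 105000) %in% grid))
  expect_false(is.unsorted(grid))
})

test_that("sensitivity plots build without error", {
  tor <- run_owsa(base_config())
  expect_s3_class(ggplot2::autoplot(tor), "ggplot")
  psa <- run_psa(60, seed = 5)
  expect_s3_class(ggplot2::autoplot(psa), "ggplot")
  expect_s3_class(plot_ceac(psa), "ggplot")
  tr <- run_cohort("tpa", pooled_arm_outcomes(default_time_windows(), "tpa"))
  expect_s3_class(ggplot2::autoplot(tr), "ggplot")
})
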