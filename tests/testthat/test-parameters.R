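test_that("default parameter set reproduces the published base-case inputs", {
  p <- model_params()
  expect_equal(p$recur_rate, 0.1181)
  expect_equal(p$recur_rr_per_year, 1.019)
  expect_equal(p$recur_case_fatality, 0.2101)
  expect_equal(c(p$hr_mrs01, p$hr_mrs23, p$hr_mrs45), c(1, 1.19, 2.04))
  expect_equal(p$mort_anchor_rate_lo, 0.0089)
  expect_equal(p$mort_anchor_rate_hi, 0.1654)
  expect_equal(p$cost_tpa_addon, 10830)
  expect_equal(c(p$utility_mrs01, p$utility_mrs23, p$utility_mrs45,
                 p$utility_death), c(0.80, 0.58, 0.28, 0))
  expect_equal(c(p$disc_cost, p$disc_outcome), c(0.03, 0.03))
  expect_equal(c(p$start_age, p$horizon_years), c(63, 30))
})

test_that("sensitivity manifest matches the frozen base/range table", {
  # every uncertain input appears exactly once, with its published base
  # value and plausible range
  frozen <- tibble::tribble(
    ~name,                 ~base,   ~low,    ~high,   ~dist,
    "recur_rate",          0.1181,  0.1123,  0.1241,  "beta",
    "recur_rr_per_year",   1.019,   1.014,   1.024,   "lognormal",
    "recur_case_fatality", 0.2101,  0.1887,  0.2316,  "beta",
    "hr_mrs01",            1,       1.0,     1.2,     "lognormal",
    "hr_mrs23",            1.19,    1.1,     1.3,     "lognormal",
    "hr_mrs45",            2.04,    1.4,     3.0,     "lognormal",
    "cost_tpa_addon",      10830,   8385,    12630,   "lognormal",
    "cost_sich_addon",     2300,    500,     4800,    "lognormal",
    "cost_hosp_mrs01",     9526,    5502,    11994,   "lognormal",
    "cost_hosp_mrs25",     12595,   6922,    16516,   "lognormal",
    "cost_hosp_mrs6",      10794,   5072,    14267,   "lognormal",
    "cost_annual_mrs01",   6773,    2028,    8639,    "lognormal",
    "cost_annual_mrs25",   10305,   2592,    12959,   "lognormal",
    "utility_mrs01",       0.80,    0.80,    0.95,    "beta",
    "utility_mrs23",       0.58,    0.56,    0.78,    "beta",
    "utility_mrs45",       0.28,    0.05,    0.36,    "beta",
    "utility_death",       0,       0,       0,       "fixed",
    "disc_cost",           0.03,    0.03,    0.08,    "beta",
    "disc_outcome",        0.03,    0.024,   0.036,   "beta",
    "or_mrs01_w1",         2.55,    1.44,    4.52,    "lognormal",
    "or_mrs01_w2",         1.64,    1.12,    2.40,    "lognormal",
    "or_mrs01_w3",         1.34,    1.06,    1.68,    "lognormal",
    "or_death_w1",         0.78,    0.41,    1.48,    "lognormal",
    "or_death_w2",         1.13,    0.70,    1.82,    "lognormal",
    "or_death_w3",         1.22,    0.87,    1.71,    "lognormal",
    "or_sich_w1",          8.23,    2.39,    28.32,   "lognormal",
    "or_sich_w2",          8.23,    2.39,    28.32,   "lognormal",
    "or_sich_w3",          3.61,    1.76,    7.38,    "lognormal"
  )
  specs <- param_specs()
  expect_setequal(specs$name, frozen$name)
  expect_equal(anyDuplicated(specs$name), 0L)
  m <- specs[match(frozen$name, specs$name), c("name", "base", "low",
                                               "high", "dist")]
  expect_equal(as.data.frame(m), as.data.frame(frozen))
})

test_that("window table carries the printed shares and distributions", {
  w <- default_time_windows()
  expect_equal(w$share, c(0.0568, 0.6113, 0.3319))
  expect_equal(sum(w$share), 1)
  expect_equal(w$p_mrs01[2], 0.4711, tolerance = 1e-6)
  expect_equal(w$p_sich, c(0.0469, 0.0305, 0.0535))
  # early-window sICH odds ratio mirrors the 1.5-3 h estimate
  expect_equal(w$or_sich[1], w$or_sich[2])
  for (i in 1:3) {
    expect_equal(w$p_mrs01[i] + w$p_mrs23[i] + w$p_mrs45[i] + w$p_death[i],
                 1, tolerance = 1e-12)
  }
})

test_that("normalize_distribution rescales and rejects bad input", {
  expect_equal(normalize_distribution(c(0.5397, 0.2381, 0.0952, 0.1270)),
               c(0.5397, 0.2381, 0.0952, 0.1270))
  expect_equal(normalize_distribution(c(0.25, 0.25, 0.25, 0.25)),
               rep(0.25, 4))
  expect_equal(normalize_distribution(c(2, 1, 1, 0)), c(0.5, 0.25, 0.25, 0))
  expect_error(normalize_distribution(c(-0.1, 1.1)), ">= 0")
  expect_error(normalize_distribution(c(0, 0)), "positive")
})

test_that("empty config yields the full default set", {
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  cfg <- load_config(empty)
  expect_equal(cfg$params$recur_rate, 0.1181)
  expect_equal(cfg$windows, default_time_windows())
  expect_equal(nrow(cfg$provenance), 0)
})

test_that("config overrides pass through and record provenance", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("discounting:", "  disc_cost: 0.0"), f)
  cfg <- load_config(f)
  expect_equal(cfg$params$disc_cost, 0)
  expect_equal(cfg$params$disc_outcome, 0.03)
  expect_equal(cfg$provenance$key, "discounting.disc_cost")
})

test_that("invalid values and unknown keys are rejected by name", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("utilities:", "  utility_mrs45: 1.2"), f)
  expect_error(load_config(f), "utility_mrs45")
  writeLines(c("utilities:", "  utility_mrs99: 0.5"), f)
  expect_error(load_config(f), "utility_mrs99")
  writeLines(c("typo_section:", "  x: 1"), f)
  expect_error(load_config(f), "typo_section")
  writeLines("not valid: [yaml", f)
  expect_error(load_config(f), "parse")
  expect_error(load_config("/nonexistent/file.yaml"), "not found")
})

test_that("serializing then re-loading a config round-trips exactly", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("markov:", "  recur_rate: 0.125",
               "costs:", "  cost_tpa_addon: 9000"), f)
  cfg <- load_config(f)
  g <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, g)
  cfg2 <- load_config(g)
  expect_equal(unclass(cfg2$params), unclass(cfg$params))
  expect_equal(as.data.frame(cfg2$windows), as.data.frame(cfg$windows))
})

test_that("parameter invariants are enforced", {
  expect_error(model_params(utility_death = 0.1), "utility_death")
  expect_error(model_params(hr_mrs23 = 3), "hr_mrs01 <= hr_mrs23")
  expect_error(model_params(cost_tpa_addon = -1), ">= 0")
  expect_error(model_params(nonsense = 1), "Unknown")
  expect_error(model_params(mort_anchor_rate_hi = 0.001),
               "mort_anchor_rate_hi")
})

test_that("currency helper converts at the fixed 2011 rate", {
  expect_equal(cny_to_usd(6500), 1000)
})

test_that("the shipped example config loads to the base case", {
  f <- system.file("extdata", "example-config.yaml", package = "tpacea")
  cfg <- load_config(f)
  expect_equal(unclass(cfg$params), unclass(model_params()))
  expect_equal(cfg$psa$divisor, 3.92)
})
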