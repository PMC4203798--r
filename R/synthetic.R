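# Synthetic patient-level data. Two jobs: (1) generate patient tables with
# the same marginal structure as the treated cohort the model summarizes,
# for parameter-recovery studies; (2) an individual-level microsimulation
# that mirrors the cohort engine event-for-event, used as an independent
# oracle for its expected values.

#' Simulate synthetic 90-day patient records
#'
#' Draws patients with the cohort's descriptive structure: age normal with
#' mean 63.48 and SD 11.34 truncated to \[18, 95\], 39.01% female, an
#' onset-to-needle window drawn by cohort share, a 90-day mRS state drawn
#' from the requested arm's window-specific distribution, and an sICH
#' indicator at the window's arm-specific rate. Age, sex and NIHSS are
#' descriptive only — the cohort model conditions on none of them.
#'
#' @param n Number of patients.
#' @param arm `"tpa"` or `"control"` (control distributions derived per
#'   window, see [control_distribution()]).
#' @param windows Window table, default [default_time_windows()].
#' @param seed Integer seed for reproducibility.
#' @inheritParams control_distribution
#' @return A tibble with columns `id`, `age`, `female`, `nihss`, `window`,
#'   `mrs90` (one of `"mrs01"`, `"mrs23"`, `"mrs45"`, `"death"`), `sich`.
#' @examples
#' simulate_patients(5, "tpa", seed = 1)
#' @export
simulate_patients <- function(n, arm = c("tpa", "control"),
                              windows = default_time_windows(), seed,
                              method = c("ratio", "odds")) {
  arm <- match.arg(arm)
  method <- match.arg(method)
  if (n < 1) abort("n must be >= 1")
  if (!missing(seed)) set.seed(seed)
  dist <- if (arm == "tpa") windows else control_distribution(windows, method)

  age <- rnorm(n, 63.48, 11.34)
  while (any(bad <- age < 18 | age > 95)) {
    age[bad] <- rnorm(sum(bad), 63.48, 11.34)
  }
  win_idx <- sample.int(nrow(windows), n, replace = TRUE,
                        prob = windows$share)
  pmat <- as.matrix(dist[, c("p_mrs01", "p_mrs23", "p_mrs45", "p_death")])
  mrs <- integer(n)
  for (i in seq_len(nrow(windows))) {
    idx <- which(win_idx == i)
    if (length(idx)) {
      mrs[idx] <- sample.int(4, length(idx), replace = TRUE, prob = pmat[i, ])
    }
  }
  tibble(
    id = seq_len(n),
    age = age,
    female = rbinom(n, 1, 0.3901),
    nihss = pmin(round(stats::rlnorm(n, log(11), 0.55)), 42),
    window = windows$label[win_idx],
    mrs90 = .states[mrs],
    sich = rbinom(n, 1, dist$p_sich[win_idx])
  )
}

#' Estimate window-level 90-day inputs from patient records
#'
#' Maximum-likelihood (empirical frequency) estimates of each window's
#' outcome distribution and sICH rate, with Wilson 95% confidence intervals
#' per outcome probability.
#'
#' @param patients A patient tibble from [simulate_patients()] (needs
#'   `window`, `mrs90`, `sich`).
#' @param conf Confidence level for the intervals.
#' @return A tibble with one row per window x quantity (`p_mrs01`,
#'   `p_mrs23`, `p_mrs45`, `p_death`, `p_sich`): columns `window`,
#'   `quantity`, `estimate`, `conf_low`, `conf_high`, `n`.
#' @examples
#' pts <- simulate_patients(500, "tpa", seed = 7)
#' estimate_inputs(pts)
#' @export
estimate_inputs <- function(patients, conf = 0.95) {
  wins <- unique(patients$window)
  if (any(!table(patients$window) > 0)) abort("Empty window stratum")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  wilson <- function(k, n) {
    p <- k / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    c(lo = max(0, ctr - hw), hi = min(1, ctr + hw))
  }
  purrr::map_dfr(wins, function(wlab) {
    sub <- patients[patients$window == wlab, ]
    n <- nrow(sub)
    counts <- c(
      p_mrs01 = sum(sub$mrs90 == "mrs01"),
      p_mrs23 = sum(sub$mrs90 == "mrs23"),
      p_mrs45 = sum(sub$mrs90 == "mrs45"),
      p_death = sum(sub$mrs90 == "death"),
      p_sich = sum(sub$sich)
    )
    purrr::map_dfr(names(counts), function(q) {
      ci <- wilson(counts[[q]], n)
      tibble(window = wlab, quantity = q, estimate = counts[[q]] / n,
             conf_low = ci[["lo"]], conf_high = ci[["hi"]], n = n)
    })
  })
}

#' Individual-level microsimulation oracle for the cohort engine
#'
#' Simulates each patient's trajectory by drawing every transition the
#' cohort engine computes in expectation — recurrence, recurrence case
#' fatality, survivor reallocation, non-stroke death — as Bernoulli or
#' categorical events, with identical probabilities and the identical
#' event ordering (recurrence first; recurrent-stroke survivors skip
#' non-stroke mortality that cycle). Per-patient discounted costs and QALYs
#' accumulate exactly as in [run_cohort()], including the 90-day cycle and
#' the 0.75 pro-rating of the final annual cycle.
#'
#' Because it shares no code path with the cohort engine's expected-value
#' recursion, agreement of its means with the cohort totals (within Monte
#' Carlo error) validates the engine.
#'
#' @inheritParams run_cohort
#' @param horizon_years Horizon in years.
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed.
#' @return A list: `mean_cost`, `mean_qaly`, `se_cost`, `se_qaly`,
#'   `n_patients`, `seed`, and `trajectories` (final state tabulation).
#' @examples
#' out <- pooled_arm_outcomes(default_time_windows(), "tpa")
#' microsim_oracle("tpa", out, horizon_years = 2, n_patients = 500, seed = 3)
#' @export
microsim_oracle <- function(arm = c("tpa", "control"), outcome90,
                            params = model_params(),
                            life_table = build_life_table(params),
                            horizon_years = params$horizon_years,
                            n_patients, seed) {
  arm <- match.arg(arm)
  if (n_patients < 1) abort("n_patients must be >= 1")
  if (!missing(seed)) set.seed(seed)
  n <- n_patients
  p0 <- c(outcome90$p_mrs01, outcome90$p_mrs23, outcome90$p_mrs45,
          outcome90$p_death)
  util <- c(params$utility_mrs01, params$utility_mrs23,
            params$utility_mrs45, params$utility_death)
  hosp <- c(params$cost_hosp_mrs01, params$cost_hosp_mrs25,
            params$cost_hosp_mrs25, params$cost_hosp_mrs6)
  ann <- c(params$cost_annual_mrs01, params$cost_annual_mrs25,
           params$cost_annual_mrs25, 0)
  hr <- c(params$hr_mrs01, params$hr_mrs23, params$hr_mrs45)

  state <- sample.int(4, n, replace = TRUE, prob = p0)
  sich <- rbinom(n, 1, outcome90$p_sich)
  cost <- hosp[state] + (arm == "tpa") * params$cost_tpa_addon +
    sich * params$cost_sich_addon
  qaly <- 0.25 * util[state]

  for (y in seq_len(horizon_years)) {
    wt <- if (y == horizon_years) 0.75 else 1
    dfc <- wt / (1 + params$disc_cost)^y
    dfq <- wt / (1 + params$disc_outcome)^y
    age <- min(params$start_age + y, max(life_table$age))
    q <- life_table$q[match(age, life_table$age)]
    alive <- state != 4L
    if (!any(alive)) break
    r <- recurrence_prob(y, params)

    recur <- alive & (runif(n) < r)
    dies_rec <- recur & (runif(n) < params$recur_case_fatality)
    surv_rec <- recur & !dies_rec
    # reallocation: uniform over states of equal or greater disability
    if (any(surv_rec)) {
      s <- state[surv_rec]
      new_s <- s
      new_s[s == 1L] <- sample.int(3, sum(s == 1L), replace = TRUE)
      new_s[s == 2L] <- sample(2:3, sum(s == 2L), replace = TRUE)
      # s == 3 stays 3
      cost[surv_rec] <- cost[surv_rec] + hosp[new_s] * dfc
      state[surv_rec] <- new_s
    }
    if (any(dies_rec)) {
      cost[dies_rec] <- cost[dies_rec] + params$cost_hosp_mrs6 * dfc
      state[dies_rec] <- 4L
    }
    nonrec <- alive & !recur
    if (any(nonrec)) {
      q_state <- 1 - (1 - q)^hr[state[nonrec]]
      dies_ns <- nonrec
      dies_ns[nonrec] <- runif(sum(nonrec)) < q_state
      state[dies_ns] <- 4L
    }
    alive_end <- state != 4L
    cost[alive_end] <- cost[alive_end] + ann[state[alive_end]] * dfc
    qaly[alive_end] <- qaly[alive_end] + util[state[alive_end]] * dfq
  }
  list(
    mean_cost = mean(cost), mean_qaly = mean(qaly),
    se_cost = stats::sd(cost) / sqrt(n),
    se_qaly = stats::sd(qaly) / sqrt(n),
    n_patients = n, seed = if (missing(seed)) NA_integer_ else seed,
    final_states = table(factor(.states[state], levels = .states))
  )
}
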