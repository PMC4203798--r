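# Markov cohort engine. One 90-day decision-tree cycle (cycle 0) seeds the
# state occupancy; annual cycles then apply, in order: recurrent stroke with
# its case fatality and survivor reallocation, then non-stroke mortality on
# the non-recurring mass. Costs and QALYs accrue per cycle and are
# discounted from the first annual cycle onwards.

#' Annual stroke recurrence probability for a given model year
#'
#' The base recurrence rate escalates multiplicatively with each life-year:
#' `recur_rate * recur_rr_per_year^(year_index - 1)`, capped at 1.
#'
#' @param year_index Annual cycle index, `>= 1` (year 1 is the first annual
#'   cycle after the 90-day decision-tree cycle).
#' @param params A [model_params()] object.
#' @return Recurrence probability for that year.
#' @examples
#' recurrence_prob(1, model_params())   # 0.1181
#' recurrence_prob(5, model_params())   # 0.1181 * 1.019^4
#' @export
recurrence_prob <- function(year_index, params = model_params()) {
  if (any(year_index < 1)) abort("year_index must be >= 1")
  pmin(params$recur_rate * params$recur_rr_per_year^(year_index - 1), 1)
}

#' Post-recurrence reallocation of surviving patients
#'
#' Survivors of a recurrent stroke are reallocated equally among the
#' disability categories of equal or greater severity: from mRS 0-1 to each
#' of the three alive states with weight 1/3; from mRS 2-3 to mRS 2-3 and
#' mRS 4-5 with weight 1/2 each; from mRS 4-5 they remain in mRS 4-5.
#' Functional state never improves.
#'
#' @param from_state One of `"mrs01"`, `"mrs23"`, `"mrs45"`, or `NULL` to
#'   return the full 3x3 reallocation matrix (rows = origin, columns =
#'   destination; rows sum to 1).
#' @return A named length-3 probability vector over the alive states, or the
#'   matrix when `from_state` is `NULL`.
#' @examples
#' reallocate_survivors("mrs23")
#' reallocate_survivors()
#' @export
reallocate_survivors <- function(from_state = NULL) {
  m <- rbind(
    mrs01 = c(1 / 3, 1 / 3, 1 / 3),
    mrs23 = c(0, 1 / 2, 1 / 2),
    mrs45 = c(0, 0, 1)
  )
  colnames(m) <- .alive_states
  if (is.null(from_state)) return(m)
  if (!from_state %in% .alive_states) {
    abort("from_state must be an alive state (mrs01, mrs23, mrs45)")
  }
  m[from_state, ]
}

# Plain-list engine shared by run_cohort(), the sensitivity analyses and the
# reproduction pipeline. Returns undiscounted and discounted per-cycle flows;
# callers assemble tibbles or summaries. `q_by_year` is the non-stroke death
# probability at age start_age + y for y = 1..horizon.
cohort_engine <- function(p0, p_sich, arm, params, q_by_year, horizon) {
  occ <- as.numeric(p0)
  if (abs(sum(occ) - 1) > 1e-9) abort("Initial occupancy must sum to 1")
  hr <- c(params$hr_mrs01, params$hr_mrs23, params$hr_mrs45)
  util <- c(params$utility_mrs01, params$utility_mrs23, params$utility_mrs45,
            params$utility_death)
  c_ann <- c(params$cost_annual_mrs01, params$cost_annual_mrs25,
             params$cost_annual_mrs25)
  realloc <- reallocate_survivors()

  cost0 <- params$cost_hosp_mrs01 * occ[1] +
    params$cost_hosp_mrs25 * (occ[2] + occ[3]) +
    params$cost_hosp_mrs6 * occ[4] +
    (arm == "tpa") * params$cost_tpa_addon +
    p_sich * params$cost_sich_addon
  qaly0 <- 0.25 * sum(occ * util)

  occ_mat <- matrix(0, horizon + 1, 4,
                    dimnames = list(NULL, .states))
  occ_mat[1, ] <- occ
  flow_cost <- flow_qaly <- rec_events <- rec_deaths <- ns_deaths <-
    numeric(horizon)

  for (y in seq_len(horizon)) {
    r <- recurrence_prob(y, params)
    alive <- occ[1:3]
    recurring <- alive * r
    deaths_rec <- sum(recurring) * params$recur_case_fatality
    survivors <- recurring * (1 - params$recur_case_fatality)
    arrivals <- as.numeric(survivors %*% realloc)
    stay <- alive * (1 - r)
    q_state <- 1 - (1 - q_by_year[y])^hr
    deaths_ns <- sum(stay * q_state)
    new_alive <- arrivals + stay * (1 - q_state)
    occ <- c(new_alive, occ[4] + deaths_rec + deaths_ns)
    occ_mat[y + 1, ] <- occ

    flow_cost[y] <- sum(new_alive * c_ann) +
      deaths_rec * params$cost_hosp_mrs6 +
      arrivals[1] * params$cost_hosp_mrs01 +
      (arrivals[2] + arrivals[3]) * params$cost_hosp_mrs25
    flow_qaly[y] <- sum(new_alive * util[1:3])
    rec_events[y] <- sum(recurring)
    rec_deaths[y] <- deaths_rec
    ns_deaths[y] <- deaths_ns
  }
  years <- seq_len(horizon)
  list(
    cost0 = cost0, qaly0 = qaly0, occ = occ_mat,
    flow_cost = flow_cost, flow_qaly = flow_qaly,
    disc_cost = flow_cost / (1 + params$disc_cost)^years,
    disc_qaly = flow_qaly / (1 + params$disc_outcome)^years,
    rec_events = rec_events, rec_deaths = rec_deaths, ns_deaths = ns_deaths
  )
}

#' Advance the cohort by one annual Markov cycle
#'
#' Applies one year of transitions to a state-occupancy vector: recurrence
#' (with case fatality and survivor reallocation) first, then non-stroke
#' mortality on the non-recurring mass; recurrent-stroke survivors are not
#' additionally exposed to non-stroke death within the same cycle.
#'
#' @param occ Occupancy 4-vector over \{mRS 0-1, mRS 2-3, mRS 4-5, dead\},
#'   summing to 1.
#' @param year_index Annual cycle index (`>= 1`); sets the recurrence rate.
#' @param age Cohort age during the cycle; sets the non-stroke mortality.
#' @param params A [model_params()] object.
#' @param life_table Life table from [build_life_table()]; defaults to one
#'   built from `params`.
#' @return A list with `occupancy` (new 4-vector), `cycle_cost` and
#'   `cycle_qaly` (undiscounted flows for the year), and expected
#'   `recurrences`, `recurrent_deaths`, `nonstroke_deaths`.
#' @examples
#' markov_step(c(1, 0, 0, 0), year_index = 1, age = 64)
#' @export
markov_step <- function(occ, year_index, age, params = model_params(),
                        life_table = build_life_table(params)) {
  if (abs(sum(occ) - 1) > 1e-9) abort("Occupancy must sum to 1")
  q <- life_table$q[match(pmin(age, max(life_table$age)), life_table$age)]
  if (is.na(q)) abort("Age outside the life table")
  # delegate to the engine for a single cycle at the given year's rates
  p <- unclass(params)
  p$recur_rate <- recurrence_prob(year_index, params)
  p$recur_rr_per_year <- 1
  p <- structure(p, class = "tpa_params")
  eng <- cohort_engine(occ, p_sich = 0, arm = "control", params = p,
                       q_by_year = q, horizon = 1)
  list(
    occupancy = eng$occ[2, ],
    cycle_cost = eng$flow_cost[1],
    cycle_qaly = eng$flow_qaly[1],
    recurrences = eng$rec_events[1],
    recurrent_deaths = eng$rec_deaths[1],
    nonstroke_deaths = eng$ns_deaths[1]
  )
}

#' Run the cohort model for one arm
#'
#' Propagates a treatment arm from its 90-day outcome distribution through
#' annual Markov cycles to the horizon. Cycle 0 spans days 0-90: occupancy is
#' the 90-day distribution, cost is the undiscounted index-hospitalization
#' cost (see [first_cycle_cost()]) and QALY accrual is 0.25 years at the
#' 90-day state utilities. Annual cycle `y` runs at age `start_age + y` and
#' its flows are discounted by `(1 + rate)^-y`.
#'
#' @param arm `"tpa"` or `"control"`.
#' @param outcome90 An `arm_outcome` row from [pooled_arm_outcomes()].
#' @param params A [model_params()] object.
#' @param life_table Life table from [build_life_table()]; defaults to one
#'   built from `params`.
#' @param horizon_years Number of annual cycles to run (default from
#'   `params`).
#' @return A `cohort_trace` tibble, one row per cycle (cycle 0 = the 90-day
#'   cycle), with state occupancies, undiscounted and discounted cycle
#'   flows, cumulative discounted cost and QALYs, and expected recurrence /
#'   death events.
#' @seealso [horizon_summary()] for cumulative values at exact year marks.
#' @examples
#' out <- pooled_arm_outcomes(default_time_windows(), "tpa")
#' trace <- run_cohort("tpa", out)
#' tail(trace, 1)[, c("cum_cost_disc", "cum_qaly_disc")]
#' @export
run_cohort <- function(arm = c("tpa", "control"), outcome90,
                       params = model_params(),
                       life_table = build_life_table(params),
                       horizon_years = params$horizon_years) {
  arm <- match.arg(arm)
  if (horizon_years < 1) abort("horizon_years must be >= 1")
  p0 <- c(outcome90$p_mrs01, outcome90$p_mrs23, outcome90$p_mrs45,
          outcome90$p_death)
  ages <- params$start_age + seq_len(horizon_years)
  q_by_year <- life_table$q[match(pmin(ages, max(life_table$age)),
                                  life_table$age)]
  if (anyNA(q_by_year)) abort("Life table does not cover the horizon")
  eng <- cohort_engine(p0, outcome90$p_sich, arm, params, q_by_year,
                       horizon_years)
  out <- tibble(
    cycle = 0:horizon_years,
    age = c(params$start_age, ages),
    mrs01 = eng$occ[, 1], mrs23 = eng$occ[, 2], mrs45 = eng$occ[, 3],
    death = eng$occ[, 4],
    cycle_cost = c(eng$cost0, eng$flow_cost),
    cycle_qaly = c(eng$qaly0, eng$flow_qaly),
    disc_cost = c(eng$cost0, eng$disc_cost),
    disc_qaly = c(eng$qaly0, eng$disc_qaly),
    recurrences = c(0, eng$rec_events),
    recurrent_deaths = c(0, eng$rec_deaths),
    nonstroke_deaths = c(0, eng$ns_deaths)
  )
  out$cum_cost_disc <- cumsum(out$disc_cost)
  out$cum_qaly_disc <- cumsum(out$disc_qaly)
  out$arm <- arm
  class(out) <- c("cohort_trace", class(out))
  out
}

#' Cumulative discounted totals at an exact year mark
#'
#' The cycle grid (90 days, then annual cycles) does not land on integer
#' years, so an `H`-year horizon is read as: cycle 0 (0.25 years), annual
#' cycles 1 through `H - 1` in full, plus 0.75 of annual cycle `H`'s
#' discounted flows — covering exactly `H` years. For `H = 1` this reduces
#' to cycle 0 plus three quarters of the first annual cycle.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param horizons Integer year marks; each must be at most the number of
#'   annual cycles in the trace.
#' @return A tibble with columns `arm`, `horizon_years`, `cost`, `qaly`
#'   (cumulative discounted values at each mark).
#' @export
horizon_summary <- function(trace, horizons) {
  n_annual <- max(trace$cycle)
  if (any(horizons < 1) || any(horizons > n_annual)) {
    abort("Each horizon must lie between 1 and the trace's annual cycles")
  }
  purrr::map_dfr(horizons, function(h) {
    full <- trace$cycle <= (h - 1)
    tibble(
      arm = trace$arm[1],
      horizon_years = h,
      cost = sum(trace$disc_cost[full]) + 0.75 * trace$disc_cost[h + 1],
      qaly = sum(trace$disc_qaly[full]) + 0.75 * trace$disc_qaly[h + 1]
    )
  })
}

# Fast path used by the sensitivity module: totals only, no tibbles.
# Returns c(cost, qaly) at each requested horizon for one arm.
engine_totals <- function(p0, p_sich, arm, params, q_by_year, horizons) {
  H <- max(horizons)
  eng <- cohort_engine(p0, p_sich, arm, params, q_by_year, H)
  dc <- c(eng$cost0, eng$disc_cost)
  dq <- c(eng$qaly0, eng$disc_qaly)
  t(vapply(horizons, function(h) {
    c(cost = sum(dc[seq_len(h)]) + 0.75 * dc[h + 1],
      qaly = sum(dq[seq_len(h)]) + 0.75 * dq[h + 1])
  }, numeric(2)))
}
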