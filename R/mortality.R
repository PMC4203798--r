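# Age-specific non-stroke mortality. The source life table is summarized by
# two printed anchor rates (age 63 and age 93); intermediate ages are
# reconstructed by interpolation and disability states are penalized on the
# hazard scale.

#' Build the age-specific non-stroke mortality schedule
#'
#' Reconstructs annual non-stroke death probabilities for every age the
#' cohort can reach, from the two anchor values in the parameter set
#' (0.0089 at age 63 and 0.1654 at age 93 in the base case).
#'
#' @param params A [model_params()] object.
#' @param method Interpolation between the anchors. `"log_linear"` (default)
#'   interpolates linearly in log rate, i.e. a constant annual growth factor,
#'   matching the roughly exponential (Gompertz-like) rise of adult mortality
#'   hazards with age. `"linear"` interpolates the probabilities directly and
#'   exists for sensitivity checks.
#' @return A `life_table` tibble with columns `age` and `q` (annual
#'   non-stroke death probability), covering `start_age` through
#'   `start_age + horizon_years`. Ages beyond the upper anchor keep the
#'   anchor rate (flat extrapolation); all values are capped below 1.
#' @examples
#' lt <- build_life_table(model_params())
#' lt$q[lt$age == 63]   # 0.0089
#' lt$q[lt$age == 78]   # geometric midpoint, sqrt(0.0089 * 0.1654)
#' @export
build_life_table <- function(params = model_params(),
                             method = c("log_linear", "linear")) {
  method <- match.arg(method)
  a0 <- params$mort_anchor_age_lo
  a1 <- params$mort_anchor_age_hi
  q0 <- params$mort_anchor_rate_lo
  q1 <- params$mort_anchor_rate_hi
  ages <- seq(params$start_age, params$start_age + params$horizon_years)
  aa <- pmin(pmax(ages, a0), a1)  # flat beyond both anchors
  q <- switch(method,
    log_linear = q0 * exp((aa - a0) * log(q1 / q0) / (a1 - a0)),
    linear = q0 + (aa - a0) * (q1 - q0) / (a1 - a0)
  )
  q <- pmin(q, 1 - 1e-12)
  out <- tibble(age = ages, q = q)
  class(out) <- c("life_table", class(out))
  out
}

#' Adjust a mortality probability by a state-specific hazard ratio
#'
#' Applies the hazard ratio on the hazard scale via the complement-power
#' formula `1 - (1 - q)^hr`, so the result stays a valid probability for any
#' positive hazard ratio (naive multiplication `q * hr` can exceed 1).
#'
#' @param q_age Annual death probability, in (0, 1).
#' @param hr Hazard ratio, `>= 0`.
#' @return Adjusted annual death probability in `[0, 1)`, increasing in
#'   `hr`, equal to `q_age` at `hr = 1`.
#' @examples
#' state_mortality(0.0089, 2.04)
#' @export
state_mortality <- function(q_age, hr) {
  if (any(q_age <= 0) || any(q_age >= 1)) abort("q_age must lie in (0, 1)")
  if (any(hr < 0)) abort("hr must be >= 0")
  1 - (1 - q_age)^hr
}

#' Export-ready life table with per-state mortality columns
#'
#' @param params A [model_params()] object.
#' @inheritParams build_life_table
#' @return A tibble with columns `age`, `q_nonstroke`, `q_mrs01`, `q_mrs23`,
#'   `q_mrs45` (the anchor schedule adjusted by each state's hazard ratio).
#' @export
state_life_table <- function(params = model_params(),
                             method = c("log_linear", "linear")) {
  lt <- build_life_table(params, method)
  tibble(
    age = lt$age,
    q_nonstroke = lt$q,
    q_mrs01 = state_mortality(lt$q, params$hr_mrs01),
    q_mrs23 = state_mortality(lt$q, params$hr_mrs23),
    q_mrs45 = state_mortality(lt$q, params$hr_mrs45)
  )
}
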