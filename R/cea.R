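# Incremental cost-effectiveness: ICER, dominance classification, net
# monetary benefit, and the base-case pipeline tying the decision tree and
# the Markov engine together.

#' Incremental cost-effectiveness of tPA versus control
#'
#' @param control,tpa Numeric vectors `c(cost, qaly)` — cumulative
#'   discounted totals for each arm — or one-row tibbles/lists with `cost`
#'   and `qaly` elements.
#' @param horizon_years Optional horizon annotation carried into the result.
#' @return A `cea_result` tibble with per-arm totals, `delta_cost`,
#'   `delta_qaly`, `icer` (CNY per QALY; `-Inf`/`Inf` when `delta_qaly` is
#'   0) and `dominance` (`"dominant"` when tPA is cheaper and more
#'   effective, `"dominated"` when costlier and less effective, otherwise
#'   `"none"`).
#' @examples
#' icer(control = c(114350, 4.571), tpa = c(120880, 4.993))
#' @export
icer <- function(control, tpa, horizon_years = NA_integer_) {
  cv <- as_cost_qaly(control)
  tv <- as_cost_qaly(tpa)
  dc <- tv[["cost"]] - cv[["cost"]]
  dq <- tv[["qaly"]] - cv[["qaly"]]
  ratio <- if (dq == 0) sign(dc) * Inf else dc / dq
  dominance <- if (dc < 0 && dq > 0) "dominant"
  else if (dc > 0 && dq < 0) "dominated"
  else "none"
  out <- tibble(
    horizon_years = horizon_years,
    cost_control = cv[["cost"]], cost_tpa = tv[["cost"]],
    qaly_control = cv[["qaly"]], qaly_tpa = tv[["qaly"]],
    delta_cost = dc, delta_qaly = dq,
    icer = ratio, dominance = dominance
  )
  class(out) <- c("cea_result", class(out))
  out
}

as_cost_qaly <- function(x) {
  if (is.numeric(x) && length(x) == 2) {
    v <- c(cost = unname(x[[1]]), qaly = unname(x[[2]]))
    if (!is.null(names(x)) && all(c("cost", "qaly") %in% names(x))) {
      v <- c(cost = unname(x[["cost"]]), qaly = unname(x[["qaly"]]))
    }
    return(v)
  }
  if (!is.null(x$cost) && !is.null(x$qaly)) {
    return(c(cost = x$cost[[1]], qaly = x$qaly[[1]]))
  }
  abort("Arm totals must be c(cost, qaly) or have $cost and $qaly")
}

#' Net monetary benefit of tPA at a willingness-to-pay threshold
#'
#' `wtp * delta_qaly - delta_cost`; positive exactly when tPA is
#' cost-effective at that threshold. Affine and strictly increasing in `wtp`
#' whenever the QALY gain is positive.
#'
#' @param result A `cea_result` from [icer()] (or any list with
#'   `delta_cost` and `delta_qaly`).
#' @param wtp Willingness to pay, CNY per QALY, `>= 0`. Vectorized.
#' @return Net monetary benefit in CNY.
#' @examples
#' r <- icer(c(114350, 4.571), c(120880, 4.993))
#' nmb(r, wtp = 105000)
#' @export
nmb <- function(result, wtp) {
  if (any(wtp < 0)) abort("wtp must be >= 0")
  wtp * result$delta_qaly[[1]] - result$delta_cost[[1]]
}

#' Run the base-case analysis end to end
#'
#' Builds both arms' pooled 90-day distributions, runs the Markov cohort for
#' each, and reports per-horizon discounted costs, QALYs, and the
#' incremental comparison — the deterministic analysis underlying every
#' downstream sensitivity run.
#'
#' @param config A configuration list from [load_config()]; defaults to the
#'   built-in base case.
#' @param horizons Integer year marks to report (default 1, 2 and 30).
#' @param utilities `"base"` for the base-case state utilities
#'   (0.80/0.58/0.28), `"upper"` for the upper-range set (0.95/0.78/0.36),
#'   or `"both"` to tabulate the two side by side. Short-horizon per-arm
#'   QALY levels depend visibly on this choice; increments much less so.
#' @param method Odds-ratio back-transformation passed to
#'   [pooled_arm_outcomes()].
#' @param interp Life-table interpolation passed to [build_life_table()].
#' @return A `basecase_result`: a tibble with one row per horizon (x utility
#'   set when `"both"`) carrying per-arm costs/QALYs, increments, the ICER
#'   and the dominance label, plus attributes `traces` (named list of
#'   `cohort_trace`s per utility set) and `outcomes` (the pooled 90-day
#'   distributions).
#' @examples
#' run_base_case(horizons = c(2, 30))
#' @export
run_base_case <- function(config = load_config(), horizons = c(1, 2, 30),
                          utilities = c("base", "upper", "both"),
                          method = c("ratio", "odds"),
                          interp = c("log_linear", "linear")) {
  utilities <- match.arg(utilities)
  method <- match.arg(method)
  interp <- match.arg(interp)
  sets <- switch(utilities, base = "base", upper = "upper",
                 both = c("base", "upper"))
  out_tpa <- pooled_arm_outcomes(config$windows, "tpa", method)
  out_ctl <- pooled_arm_outcomes(config$windows, "control", method)

  traces <- list()
  rows <- purrr::map_dfr(sets, function(uset) {
    params <- if (uset == "upper") upper_utility_params(config$params)
    else config$params
    lt <- build_life_table(params, interp)
    tr_t <- run_cohort("tpa", out_tpa, params, lt)
    tr_c <- run_cohort("control", out_ctl, params, lt)
    traces[[uset]] <<- list(tpa = tr_t, control = tr_c)
    ht <- horizon_summary(tr_t, horizons)
    hc <- horizon_summary(tr_c, horizons)
    res <- purrr::map_dfr(seq_along(horizons), function(i) {
      icer(control = c(hc$cost[i], hc$qaly[i]),
           tpa = c(ht$cost[i], ht$qaly[i]),
           horizon_years = horizons[i])
    })
    dplyr::mutate(res, utility_set = uset, .before = 1)
  })
  if (utilities != "both") rows$utility_set <- NULL
  attr(rows, "traces") <- traces
  attr(rows, "outcomes") <- dplyr::bind_rows(out_tpa, out_ctl)
  class(rows) <- c("basecase_result", class(rows))
  rows
}

#' @export
print.basecase_result <- function(x, ...) {
  cat("Base-case cost-effectiveness (discounted, 2011 CNY)\n\n")
  print(summary_table(x), n = Inf)
  invisible(x)
}

#' Per-arm summary in the conventional published layout
#'
#' Reshapes a [run_base_case()] result into the conventional published
#' layout: one row per horizon and arm with QALYs, cost, and the ICER on
#' the tPA row.
#'
#' @param result A `basecase_result`.
#' @return A tibble with columns (`utility_set`,) `horizon_years`, `arm`,
#'   `qalys`, `cost_cny`, `icer_cny_per_qaly`.
#' @export
summary_table <- function(result) {
  has_set <- "utility_set" %in% names(result)
  base <- if (has_set) result else dplyr::mutate(result, utility_set = "base")
  out <- purrr::map_dfr(seq_len(nrow(base)), function(i) {
    r <- base[i, ]
    tibble(
      utility_set = r$utility_set,
      horizon_years = r$horizon_years,
      arm = c("control", "tpa"),
      qalys = c(r$qaly_control, r$qaly_tpa),
      cost_cny = c(r$cost_control, r$cost_tpa),
      icer_cny_per_qaly = c(NA_real_, r$icer)
    )
  })
  if (!has_set) out$utility_set <- NULL
  out
}

#' @rdname tidy
#' @param x A `cea_result` or `basecase_result`.
#' @param ... Unused.
#' @export
tidy.cea_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy and glance methods for model results
#'
#' `tidy()` returns the result as a plain tibble (one row per horizon for
#' base-case results); `glance()` condenses a base-case run to its
#' longest-horizon increments and ICER.
#'
#' @name tidy
#' @export
tidy.basecase_result <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x))
  attr(out, "traces") <- NULL
  attr(out, "outcomes") <- NULL
  out
}

#' @rdname tidy
#' @export
glance.basecase_result <- function(x, ...) {
  r <- x[which.max(x$horizon_years), ]
  tibble(
    horizon_years = r$horizon_years,
    delta_cost = r$delta_cost,
    delta_qaly = r$delta_qaly,
    icer = r$icer,
    dominance = r$dominance
  )
}
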