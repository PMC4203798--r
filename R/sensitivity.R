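# Sensitivity analyses. One-way: every manifest parameter swept across its
# plausible range with all else at base, tornado-ranked by ICER spread.
# Probabilistic: joint Monte Carlo over beta (probabilities, utilities) and
# lognormal (costs, ratio-scale parameters) distributions, yielding the
# cost-effectiveness plane and acceptability curve.

# Recompute the deterministic ICER at one horizon for given windows/params.
deterministic_icer <- function(windows, params, horizon = 30,
                               method = "ratio", interp = "log_linear") {
  out_t <- pooled_arm_outcomes(windows, "tpa", method)
  out_c <- pooled_arm_outcomes(windows, "control", method)
  lt <- build_life_table(params, interp)
  ages <- params$start_age + seq_len(horizon)
  q <- lt$q[match(pmin(ages, max(lt$age)), lt$age)]
  tt <- engine_totals(c(out_t$p_mrs01, out_t$p_mrs23, out_t$p_mrs45,
                        out_t$p_death), out_t$p_sich, "tpa", params, q,
                      horizon)
  tc <- engine_totals(c(out_c$p_mrs01, out_c$p_mrs23, out_c$p_mrs45,
                        out_c$p_death), out_c$p_sich, "control", params, q,
                      horizon)
  icer(control = tc[1, ], tpa = tt[1, ], horizon_years = horizon)
}

# Set one manifest parameter (scalar or window-level odds ratio) to `value`.
set_spec_value <- function(windows, params, spec_row, value) {
  if (is.na(spec_row$window)) {
    p <- unclass(params)
    p[[spec_row$name]] <- value
    params <- validate_params(structure(p, class = "tpa_params"))
  } else {
    i <- match(spec_row$window, windows$label)
    windows[[spec_row$target]][i] <- value
    # keep the CI bracket valid when the point estimate is pushed outside it
    windows[[paste0(spec_row$target, "_lo")]][i] <-
      min(windows[[paste0(spec_row$target, "_lo")]][i], value)
    windows[[paste0(spec_row$target, "_hi")]][i] <-
      max(windows[[paste0(spec_row$target, "_hi")]][i], value)
  }
  list(windows = windows, params = params)
}

#' One-way sensitivity of the ICER to a single parameter
#'
#' Re-runs the full deterministic model twice with the named parameter at
#' its low and high range bound (everything else at base case) and reports
#' both ICERs. Window-level odds-ratio parameters perturb only their own
#' window.
#'
#' @param spec_name Parameter name, a row of `config$specs` (see
#'   [param_specs()]).
#' @param config Configuration from [load_config()].
#' @param horizon Horizon in years (sensitivity analyses use the long-term
#'   30-year model).
#' @inheritParams run_base_case
#' @return A one-row tibble: `param`, `low`, `high`, `icer_at_low`,
#'   `icer_at_high`, `spread` (absolute ICER range width), `failed` (TRUE
#'   when an extreme produced an invalid model; its ICER is `NA`, the entry
#'   is kept).
#' @examples
#' one_way("cost_annual_mrs25", load_config())
#' @export
one_way <- function(spec_name, config = load_config(), horizon = 30,
                    method = c("ratio", "odds"),
                    interp = c("log_linear", "linear")) {
  method <- match.arg(method)
  interp <- match.arg(interp)
  spec <- config$specs[config$specs$name == spec_name, ]
  if (nrow(spec) != 1) abort(paste0("Unknown parameter: ", spec_name))
  at <- function(value) {
    tryCatch({
      mod <- set_spec_value(config$windows, config$params, spec, value)
      deterministic_icer(mod$windows, mod$params, horizon, method, interp)$icer
    }, error = function(e) NA_real_)
  }
  lo <- at(spec$low)
  hi <- at(spec$high)
  tibble(
    param = spec$name, low = spec$low, high = spec$high,
    icer_at_low = lo, icer_at_high = hi,
    spread = abs(hi - lo),
    failed = is.na(lo) || is.na(hi)
  )
}

#' Tornado analysis: one-way sweeps over every uncertain parameter
#'
#' Applies [one_way()] to each row of the parameter manifest and returns the
#' entries sorted by decreasing ICER spread — the order of the bars in a
#' tornado diagram. Degenerate ranges (low = high) produce zero spread and
#' sort last.
#'
#' @inheritParams one_way
#' @return A `tornado` tibble (columns as in [one_way()]), sorted by
#'   `spread` descending; plot with [ggplot2::autoplot()].
#' @export
run_owsa <- function(config = load_config(), horizon = 30,
                     method = c("ratio", "odds"),
                     interp = c("log_linear", "linear")) {
  method <- match.arg(method)
  interp <- match.arg(interp)
  out <- purrr::map_dfr(config$specs$name, one_way, config = config,
                        horizon = horizon, method = method, interp = interp)
  out <- dplyr::arrange(out, dplyr::desc(.data$spread))
  base <- deterministic_icer(config$windows, config$params, horizon,
                             method, interp)$icer
  attr(out, "base_icer") <- base
  class(out) <- c("tornado", class(out))
  out
}

# Beta parameters by method of moments; NULL when infeasible.
beta_moments <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) return(NULL)
  v <- sd^2
  if (v >= mean * (1 - mean)) return(NULL)
  k <- mean * (1 - mean) / v - 1
  list(shape1 = mean * k, shape2 = (1 - mean) * k)
}

# Precompute every sampling constant so a PSA draw is a handful of
# vectorized RNG calls. Shapes depend only on the manifest, not the draw.
psa_compile <- function(config) {
  specs <- config$specs
  divisor <- config$psa$divisor
  scalar <- specs[is.na(specs$window), ]
  kind <- character(nrow(scalar))
  sh1 <- sh2 <- ml <- sl <- numeric(nrow(scalar))
  for (i in seq_len(nrow(scalar))) {
    s <- scalar[i, ]
    if (s$dist == "fixed" || s$low == s$high) {
      kind[i] <- "fixed"
    } else if (s$dist == "lognormal") {
      kind[i] <- "lognormal"
      ml[i] <- log(s$base)
      sl[i] <- (log(s$high) - log(s$low)) / divisor
    } else {
      bm <- beta_moments(s$base, (s$high - s$low) / divisor)
      if (is.null(bm)) {
        warn(paste0("Beta moments infeasible for '", s$name,
                    "'; falling back to uniform(low, high)"),
             class = "tpacea_beta_fallback", .frequency = "once",
             .frequency_id = s$name)
        kind[i] <- "uniform"
      } else {
        kind[i] <- "beta"
        sh1[i] <- bm$shape1
        sh2[i] <- bm$shape2
      }
    }
  }
  w <- config$windows
  n_eff <- config$psa$n_source * w$share
  pmat <- as.matrix(w[, c("p_mrs01", "p_mrs23", "p_mrs45", "p_death")])
  ors <- specs[!is.na(specs$window), ]
  or_target <- matrix(
    c(w$or_mrs01, w$or_death, w$or_sich), nrow = nrow(w),
    dimnames = list(w$label, c("or_mrs01", "or_death", "or_sich"))
  )
  or_sl <- matrix(0, nrow(w), 3,
                  dimnames = dimnames(or_target))
  for (i in seq_len(nrow(ors))) {
    j <- match(ors$window[i], w$label)
    or_sl[j, ors$target[i]] <- (log(ors$high[i]) - log(ors$low[i])) / divisor
  }
  list(
    scalar_names = scalar$name, kind = kind, base = scalar$base,
    low = scalar$low, high = scalar$high,
    shape1 = sh1, shape2 = sh2, meanlog = ml, sdlog = sl,
    share = w$share, labels = w$label,
    p_alpha = pmat * n_eff, p_beta = (1 - pmat) * n_eff,
    sich_alpha = w$p_sich * n_eff, sich_beta = (1 - w$p_sich) * n_eff,
    or_meanlog = log(or_target), or_sdlog = or_sl,
    window_model = config$psa$window_model,
    base_params = unclass(config$params),
    base_pmat = pmat, base_sich = w$p_sich
  )
}

# One joint draw from a compiled sampler. Returns plain numerics: the
# scalar parameter list, a 3x4 window outcome matrix, sICH rates, and a
# 3x3 odds-ratio matrix.
psa_draw <- function(cmp) {
  v <- cmp$base
  ib <- cmp$kind == "beta"
  il <- cmp$kind == "lognormal"
  iu <- cmp$kind == "uniform"
  v[ib] <- rbeta(sum(ib), cmp$shape1[ib], cmp$shape2[ib])
  v[il] <- rlnorm(sum(il), cmp$meanlog[il], cmp$sdlog[il])
  v[iu] <- runif(sum(iu), cmp$low[iu], cmp$high[iu])
  p <- cmp$base_params
  p[cmp$scalar_names] <- as.list(v)
  # hazard-ratio draws are independent; restore the monotone ordering the
  # state definition implies rather than rejecting the draw
  hrs <- pmax(sort(c(p$hr_mrs01, p$hr_mrs23, p$hr_mrs45)), 1)
  p$hr_mrs01 <- hrs[1]
  p$hr_mrs23 <- hrs[2]
  p$hr_mrs45 <- hrs[3]

  if (cmp$window_model == "fixed") {
    pmat <- cmp$base_pmat
    sich <- cmp$base_sich
  } else {
    raw <- if (cmp$window_model == "dirichlet") {
      matrix(stats::rgamma(length(cmp$p_alpha), shape = cmp$p_alpha),
             nrow = nrow(cmp$p_alpha))
    } else {
      matrix(rbeta(length(cmp$p_alpha), cmp$p_alpha, cmp$p_beta),
             nrow = nrow(cmp$p_alpha))
    }
    pmat <- raw / rowSums(raw)
    sich <- rbeta(length(cmp$sich_alpha), cmp$sich_alpha, cmp$sich_beta)
  }
  ors <- matrix(
    rlnorm(length(cmp$or_meanlog), cmp$or_meanlog, cmp$or_sdlog),
    nrow = nrow(cmp$or_meanlog), dimnames = dimnames(cmp$or_meanlog)
  )
  list(params = p, pmat = pmat, sich = sich, ors = ors)
}

# Pool the drawn (or base) window inputs into both arms and return
# c(delta_cost, delta_qaly) at `horizon`, without tibble overhead.
fast_delta <- function(d, share, q_by_year, horizon, method) {
  pmat <- d$pmat
  back <- function(p, or) {
    if (method == "ratio") p / or
    else {
      o <- (p / (1 - p)) / or
      o / (1 + o)
    }
  }
  c01 <- back(pmat[, 1], d$ors[, "or_mrs01"])
  cd <- back(pmat[, 4], d$ors[, "or_death"])
  rem <- 1 - c01 - cd
  if (any(c01 >= 1) || any(cd >= 1) || any(rem < 0)) {
    abort("Back-transformed window distribution invalid")
  }
  split <- pmat[, 2] + pmat[, 3]
  cmat <- cbind(c01, rem * pmat[, 2] / split, rem * pmat[, 3] / split, cd)
  cs <- back(d$sich, d$ors[, "or_sich"])
  p_t <- as.numeric(share %*% pmat)
  p_c <- as.numeric(share %*% cmat)
  tt <- engine_totals(p_t, sum(share * d$sich), "tpa", d$params,
                      q_by_year, horizon)
  tc <- engine_totals(p_c, sum(share * cs), "control", d$params,
                      q_by_year, horizon)
  c(tt[1, "cost"] - tc[1, "cost"], tt[1, "qaly"] - tc[1, "qaly"])
}

#' Sample one joint parameter draw for probabilistic sensitivity analysis
#'
#' Scalar parameters follow their manifest family: `beta` by method of
#' moments with mean at the base case and the range read as a central 95%
#' interval (`sd = (high - low) / divisor`, divisor 3.92 by default);
#' `lognormal` with log-scale median at the base case and
#' `sdlog = (log(high) - log(low)) / divisor`; `fixed` stays at base. A
#' beta whose moment solution is infeasible falls back to
#' `uniform(low, high)` with a warning. Window-level 90-day outcome vectors
#' are drawn as beta margins (or gamma margins under the Dirichlet option)
#' with effective sample size `n_source * share` and renormalized to sum
#' to 1; sICH rates are beta with the same effective size. All draws are
#' mutually independent and consume the current RNG stream.
#'
#' @param config Configuration from [load_config()] (carries the manifest
#'   and the PSA settings `divisor`, `window_model`, `n_source`).
#' @return A list with sampled `windows` (tibble) and `params`
#'   ([model_params()] object).
#' @export
draw_psa_params <- function(config = load_config()) {
  cmp <- psa_compile(config)
  d <- psa_draw(cmp)
  w <- config$windows
  pcols <- c("p_mrs01", "p_mrs23", "p_mrs45", "p_death")
  w[, pcols] <- d$pmat
  w$p_sich <- d$sich
  for (tgt in colnames(d$ors)) {
    w[[tgt]] <- d$ors[, tgt]
    w[[paste0(tgt, "_lo")]] <- pmin(w[[paste0(tgt, "_lo")]], w[[tgt]])
    w[[paste0(tgt, "_hi")]] <- pmax(w[[paste0(tgt, "_hi")]], w[[tgt]])
  }
  params <- validate_params(structure(d$params, class = "tpa_params"))
  list(windows = w, params = params)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo over the joint parameter distribution: each draw samples
#' every uncertain input (see [draw_psa_params()]), reruns both arms of the
#' deterministic model to the horizon, and records the incremental cost and
#' QALYs. Draws that produce an invalid model (e.g. back-transformed
#' probabilities outside \[0, 1\]) are resampled and counted; more than 1%
#' failures aborts the run.
#'
#' @param n_draws Number of simulations (the published analysis uses
#'   10,000).
#' @param seed Integer seed; the run is fully reproducible given the seed,
#'   which is recorded in the result.
#' @param config Configuration from [load_config()].
#' @param horizon Horizon in years (30 for the long-term analysis).
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve;
#'   defaults to 0 to 200,000 CNY in 1,000-CNY steps plus the two
#'   GDP-per-capita thresholds 35,100 and 105,000 exactly.
#' @inheritParams run_base_case
#' @return A `psa_result` list: `points` (tibble `draw`, `delta_cost`,
#'   `delta_qaly`), `ceac` (tibble `wtp`, `probability`), `frac_dominant`,
#'   `n_draws`, `n_resampled`, `seed`, `base` (the deterministic
#'   `cea_result` at the same horizon).
#' @examples
#' psa <- run_psa(n_draws = 50, seed = 1)
#' psa$frac_dominant
#' @export
run_psa <- function(n_draws, seed, config = load_config(), horizon = 30,
                    wtp_grid = default_wtp_grid(),
                    method = c("ratio", "odds"),
                    interp = c("log_linear", "linear")) {
  if (n_draws < 1) abort("n_draws must be >= 1")
  method <- match.arg(method)
  interp <- match.arg(interp)
  set.seed(seed)
  cmp <- psa_compile(config)
  lt <- build_life_table(config$params, interp)
  ages <- config$params$start_age + seq_len(horizon)
  q_by_year <- lt$q[match(pmin(ages, max(lt$age)), lt$age)]
  dc <- dq <- numeric(n_draws)
  n_resampled <- 0L
  max_fail <- max(10, ceiling(0.01 * n_draws))
  for (i in seq_len(n_draws)) {
    repeat {
      res <- tryCatch(
        fast_delta(psa_draw(cmp), cmp$share, q_by_year, horizon, method),
        error = function(e) NULL
      )
      if (!is.null(res)) break
      n_resampled <- n_resampled + 1L
      if (n_resampled > max_fail) {
        abort("More than 1% of PSA draws failed; model inputs inconsistent")
      }
    }
    dc[i] <- res[1]
    dq[i] <- res[2]
  }
  points <- tibble(draw = seq_len(n_draws), delta_cost = dc, delta_qaly = dq)
  out <- list(
    points = points,
    ceac = ceac(points, wtp_grid),
    frac_dominant = mean(dc < 0 & dq > 0),
    n_draws = n_draws,
    n_resampled = n_resampled,
    seed = seed,
    base = deterministic_icer(config$windows, config$params, horizon,
                              method, interp)
  )
  class(out) <- "psa_result"
  out
}

#' Default willingness-to-pay grid
#'
#' 0 to 200,000 CNY per QALY in 1,000-CNY steps, with the 1x and 3x 2011
#' GDP-per-capita thresholds (35,100 and 105,000) included exactly.
#'
#' @return Sorted numeric vector of WTP values.
#' @export
default_wtp_grid <- function() {
  sort(unique(c(seq(0, 200000, by = 1000), 35100, 105000)))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of simulation points with
#' positive net monetary benefit `wtp * delta_qaly - delta_cost > 0`.
#'
#' @param points Tibble with columns `delta_cost` and `delta_qaly` (e.g.
#'   `psa$points`).
#' @param wtp_grid Numeric vector of WTP thresholds.
#' @return A tibble with columns `wtp` and `probability`.
#' @examples
#' pts <- tibble::tibble(delta_cost = c(-1, 5), delta_qaly = c(0.1, 0.2))
#' ceac(pts, c(0, 50, 100))
#' @export
ceac <- function(points, wtp_grid = default_wtp_grid()) {
  if (nrow(points) == 0) abort("points must be non-empty")
  tibble(
    wtp = wtp_grid,
    probability = vapply(
      wtp_grid,
      function(w) mean(w * points$delta_qaly - points$delta_cost > 0),
      numeric(1)
    )
  )
}

#' Probability that tPA is cost-effective at given thresholds
#'
#' Convenience lookup into a PSA's acceptability curve.
#'
#' @param psa A `psa_result` from [run_psa()].
#' @param wtp Threshold(s) in CNY per QALY; must be on the PSA's grid.
#' @return Named numeric vector of probabilities.
#' @export
prob_cost_effective <- function(psa, wtp = c(35100, 105000)) {
  i <- match(wtp, psa$ceac$wtp)
  if (anyNA(i)) abort("wtp value not on the PSA's grid")
  setNames(psa$ceac$probability[i],
           format(wtp, trim = TRUE, scientific = FALSE))
}

#' @export
print.psa_result <- function(x, ...) {
  cat("Probabilistic sensitivity analysis:", x$n_draws, "draws (seed",
      paste0(x$seed, ")\n"))
  cat(sprintf("  dominant (cheaper & more effective): %.1f%%\n",
              100 * x$frac_dominant))
  for (w in c(35100, 105000)) {
    if (w %in% x$ceac$wtp) {
      cat(sprintf("  cost-effective at WTP %s CNY/QALY: %.1f%%\n",
                  format(w, big.mark = ","),
                  100 * x$ceac$probability[x$ceac$wtp == w]))
    }
  }
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.psa_result <- function(x, ...) x$points

#' @rdname tidy
#' @export
glance.psa_result <- function(x, ...) {
  tibble(
    n_draws = x$n_draws,
    frac_dominant = x$frac_dominant,
    p_ce_35100 = x$ceac$probability[match(35100, x$ceac$wtp)],
    p_ce_105000 = x$ceac$probability[match(105000, x$ceac$wtp)],
    mean_delta_cost = mean(x$points$delta_cost),
    mean_delta_qaly = mean(x$points$delta_qaly),
    seed = x$seed
  )
}
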