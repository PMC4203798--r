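# Shared fixtures. Everything is built in code; no stored data.

base_config <- function() load_config()

# A life table that is numerically zero everywhere, for deterministic
# no-mortality scenarios (q must be positive for build_life_table, so this
# is constructed directly).
null_life_table <- function(params = model_params()) {
  tibble::tibble(
    age = seq(params$start_age, params$start_age + params$horizon_years),
    q = 1e-300
  )
}

degenerate_outcome <- function(state = "mrs01", arm = "control",
                               p_sich = 0) {
  p <- c(mrs01 = 0, mrs23 = 0, mrs45 = 0, death = 0)
  p[state] <- 1
  tibble::tibble(arm = arm, p_mrs01 = p[["mrs01"]], p_mrs23 = p[["mrs23"]],
                 p_mrs45 = p[["mrs45"]], p_death = p[["death"]],
                 p_sich = p_sich)
}

# Config in which every manifest parameter is pinned to its base value and
# window distributions are not sampled: the PSA becomes deterministic.
degenerate_config <- function() {
  cfg <- load_config()
  cfg$specs$low <- cfg$specs$base
  cfg$specs$high <- cfg$specs$base
  cfg$specs$dist <- "fixed"
  cfg$psa$window_model <- "fixed"
  cfg
}
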