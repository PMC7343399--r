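# Shared fixtures: small configurations and quiet fitting helpers.
# Everything is generated in code; no data files.

tiny_config <- function(seed = 1, ...) {
  sim_config(n_individuals = 8, n_dates = 8, trials_per_observer = 4,
             seed = seed, ...)
}

# fits at test scale emit convergence warnings by design (short chains);
# silence them -- convergence behaviour has its own tests
quiet_fit <- function(...) suppressWarnings(fit_univariate(...))
quiet_bifit <- function(...) suppressWarnings(fit_bivariate(...))

# configuration with effectively no random structure and tiny noise, for
# near-deterministic limits
degenerate_config <- function(seed = 1, sigma = 1e-6, intercept_vod = 1.06,
                              intercept_fid = 0.67) {
  beta_vod <- setNames(numeric(12), names(sim_config()$beta_vod))
  beta_vod["intercept"] <- intercept_vod
  beta_fid <- setNames(numeric(11), names(sim_config()$beta_fid))
  beta_fid["intercept"] <- intercept_fid
  sim_config(
    n_individuals = 6, n_dates = 6, trials_per_observer = 3,
    beta_vod = beta_vod, beta_fid = beta_fid, sd_date = 0,
    individual_sds = list(vod = rep(0, 5), fid = rep(0, 5)),
    cross_response_corr = 0,
    sigma = c(vod = sigma, fid = sigma),
    covariate_frequencies = list(
      compatibility = c(engaged = 1, looking = 0, not_engaged_not_looking = 0),
      habitat_open = 0, height_ground = 0, neighbor_rate = 0,
      neighbor_fled_first = 0, external_event = 0,
      response_category = c(alarm_bark = 0, flight_to_refuge = 0,
                            rapid_flight = 0, displacement_with_geck = 0,
                            passive_displacement = 1, flinch_before_flight = 0,
                            not_displaced = 0, not_displaced_threatens = 0)),
    seed = seed)
}
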