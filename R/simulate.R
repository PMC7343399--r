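# Synthetic trial-data generator.
#
# The generator emulates a repeated flight-initiation-distance (FID) sampling
# design on a habituated group: each individual is approached `trials_per_observer`
# times by each of two observers (one familiar, one unfamiliar), at most twice
# per sampling day, with the start distance (SD) spanning the protocol range.
# Responses are log-normal with a date random intercept and a correlated
# individual-level block (intercept, envelope-covariate slope, observer,
# trial number, observer x trial number), and the distance envelope
# 0 < FID <= VOD < SD is enforced by truncation.
#
# Distance geometry: VODD = SD - VOD (distance covered before the animal
# orients) and VODI = VOD - FID (distance between orientation and flight).
# The source design never states these algebraically; this package adopts the
# definitions above throughout.

#' Canonical behavioral response categories
#'
#' The eight behavioral responses recorded after each approach, ordered from
#' most predator-like to least threatened.
#'
#' @return Character vector of length 8.
#' @export
response_categories <- function() {
  c("alarm_bark", "flight_to_refuge", "rapid_flight",
    "displacement_with_geck", "passive_displacement",
    "flinch_before_flight", "not_displaced", "not_displaced_threatens")
}

# Within-response correlation of the individual block (intercept, envelope
# slope, observer, trial number, observer x trial number), posterior means
# from the fitted study group.  Both matrices are positive definite as printed.
.default_corr_vod <- matrix(c(
  1.00,  0.57,  0.21, -0.68,  0.35,
  0.57,  1.00,  0.16, -0.30,  0.29,
  0.21,  0.16,  1.00, -0.17, -0.05,
  -0.68, -0.30, -0.17,  1.00, -0.47,
  0.35,  0.29, -0.05, -0.47,  1.00), 5, 5)

.default_corr_fid <- matrix(c(
  1.00,  0.26,  0.04, -0.46, -0.12,
  0.26,  1.00,  0.16, -0.25, -0.36,
  0.04,  0.16,  1.00, -0.39, -0.05,
  -0.46, -0.25, -0.39,  1.00, -0.13,
  -0.12, -0.36, -0.05, -0.13,  1.00), 5, 5)

.vod_terms <- c("intercept", "vodd", "looking", "not_engaged_not_looking",
                "open", "ground", "n_neighbors", "neighbor_fled_first",
                "external_event", "observer_unfamiliar", "trial_number",
                "observer_unfamiliar:trial_number")

.fid_terms <- c("intercept", "vodi", "engaged", "open", "ground",
                "n_neighbors", "neighbor_fled_first", "external_event",
                "observer_unfamiliar", "trial_number",
                "observer_unfamiliar:trial_number")

.block_terms <- function(response) {
  env <- if (response == "vod") "vodd" else "vodi"
  c("intercept", env, "observer_unfamiliar", "trial_number",
    "observer_unfamiliar:trial_number")
}

#' Simulation configuration
#'
#' Bundles the generative truth for a synthetic trial dataset: design sizes,
#' fixed-effect coefficients on the log scale, variance components, the
#' within-response correlation of the individual random-effect block, the
#' among-individual (cross-response) intercept correlation, and covariate
#' frequencies.  Defaults mirror the study design this package emulates:
#' 69 individuals x 2 observers x 12 trials over 58 dates, start distances
#' uniform on 2.5-33.8 m, and fixed effects / variance components at the
#' fitted posterior means of the study group.
#'
#' @param n_individuals Number of focal individuals.
#' @param n_dates Number of sampling dates available for scheduling.
#' @param trials_per_observer Trials per individual per observer.
#' @param observers Length-2 labels; the first is the familiar (reference)
#'   observer.
#' @param sd_range_m Start-distance range in meters, `c(low, high)` with
#'   `0 < low < high`.
#' @param beta_vod,beta_fid Named fixed-effect vectors on the log scale; see
#'   `fidtrait:::.vod_terms` / `fidtrait:::.fid_terms` for the required names.
#' @param sd_date Date random-intercept SD (log scale).
#' @param individual_sds List with elements `vod` and `fid`, each a length-5
#'   nonnegative vector of individual-block SDs (intercept, envelope slope,
#'   observer, trial number, observer x trial number).
#' @param individual_corr List with elements `vod` and `fid`, each a 5x5
#'   correlation matrix for the individual block.
#' @param cross_response_corr Among-individual intercept correlation between
#'   the two responses, in `[-1, 1]`.
#' @param sigma Named residual SDs on the log scale, `c(vod = , fid = )`.
#' @param covariate_frequencies List of category probabilities: `compatibility`
#'   (named length-3 simplex), `habitat_open`, `height_ground`,
#'   `neighbor_fled_first`, `external_event` (probabilities), `neighbor_rate`
#'   (Poisson mean for the number of neighbors within 5 m), and
#'   `response_category` (named length-8 simplex over [response_categories()]).
#' @param seed Integer seed; the configuration plus the seed fully determine
#'   the dataset.
#'
#' @return An object of class `fid_sim_config` (a named list).
#' @seealso [simulate_trials()], [build_design()]
#' @export
sim_config <- function(n_individuals = 69,
                       n_dates = 58,
                       trials_per_observer = 12,
                       observers = c("familiar", "unfamiliar"),
                       sd_range_m = c(2.5, 33.8),
                       beta_vod = c(intercept = 1.06, vodd = -0.02,
                                    looking = 0.21, not_engaged_not_looking = 0.11,
                                    open = 0.15, ground = 0.06,
                                    n_neighbors = -0.05, neighbor_fled_first = 0.08,
                                    external_event = 0.02, observer_unfamiliar = -0.04,
                                    trial_number = -0.01,
                                    `observer_unfamiliar:trial_number` = 0.01),
                       beta_fid = c(intercept = 0.67, vodi = -0.04,
                                    engaged = 0.14, open = 0.12, ground = 0.12,
                                    n_neighbors = -0.08, neighbor_fled_first = 0,
                                    external_event = 0.01, observer_unfamiliar = -0.14,
                                    trial_number = -0.02,
                                    `observer_unfamiliar:trial_number` = 0.02),
                       sd_date = 0.14,
                       individual_sds = list(vod = c(0.24, 0.04, 0.09, 0.01, 0.01),
                                             fid = c(0.49, 0.06, 0.18, 0.01, 0.01)),
                       individual_corr = list(vod = .default_corr_vod,
                                              fid = .default_corr_fid),
                       cross_response_corr = 0.875,
                       sigma = c(vod = 0.31, fid = 0.36),
                       covariate_frequencies = list(
                         compatibility = c(engaged = 0.40, looking = 0.35,
                                           not_engaged_not_looking = 0.25),
                         habitat_open = 0.50,
                         height_ground = 0.85,
                         neighbor_rate = 1.2,
                         neighbor_fled_first = 0.15,
                         external_event = 0.05,
                         response_category = c(
                           alarm_bark = 0, flight_to_refuge = 0, rapid_flight = 0,
                           displacement_with_geck = 16 / 1656,
                           passive_displacement = 1637 / 1656,
                           flinch_before_flight = 3 / 1656,
                           not_displaced = 0, not_displaced_threatens = 0)),
                       seed = 42L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_dates = as.integer(n_dates),
              trials_per_observer = as.integer(trials_per_observer),
              observers = observers, sd_range_m = sd_range_m,
              beta_vod = beta_vod, beta_fid = beta_fid, sd_date = sd_date,
              individual_sds = individual_sds,
              individual_corr = individual_corr,
              cross_response_corr = cross_response_corr, sigma = sigma,
              covariate_frequencies = covariate_frequencies,
              seed = as.integer(seed))
  class(cfg) <- "fid_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants of a [sim_config()] object: positive
#' design sizes, a valid start-distance range, nonnegative SDs, symmetric
#' positive-semidefinite unit-diagonal correlation matrices, a cross-response
#' correlation in `[-1, 1]`, and probability vectors that are simplexes.
#'
#' @param config A `fid_sim_config`.
#' @return `config`, invisibly, or an error describing the violated invariant.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "fid_sim_config"))
  with(config, {
    if (n_individuals < 1 || trials_per_observer < 1 || n_dates < 1)
      stop("design sizes must be positive integers")
    if (length(observers) != 2 || anyDuplicated(observers))
      stop("exactly two distinct observers are required")
    if (!(sd_range_m[1] > 0 && sd_range_m[1] < sd_range_m[2]))
      stop("sd_range_m must satisfy 0 < low < high")
    if (sd_date < 0 || any(sigma <= 0)) stop("sd_date must be >= 0 and sigma > 0")
    for (r in c("vod", "fid")) {
      s <- individual_sds[[r]]
      if (length(s) != 5 || any(s < 0))
        stop("individual_sds$", r, " must be 5 nonnegative values")
      C <- individual_corr[[r]]
      if (!isTRUE(all.equal(C, t(C))) || any(abs(diag(C) - 1) > 1e-8))
        stop("individual_corr$", r, " must be symmetric with unit diagonal")
      if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
        stop("individual_corr$", r, " is not positive semidefinite")
    }
    if (abs(cross_response_corr) > 1)
      stop("cross_response_corr must lie in [-1, 1]")
    cf <- covariate_frequencies
    if (abs(sum(cf$compatibility) - 1) > 1e-8)
      stop("compatibility probabilities must sum to 1")
    if (abs(sum(cf$response_category) - 1) > 1e-8)
      stop("response_category probabilities must sum to 1")
    if (!all(names(cf$response_category) %in% response_categories()))
      stop("unknown response_category labels in covariate_frequencies")
  })
  invisible(config)
}

#' Joint individual-level covariance implied by a configuration
#'
#' Builds the 10x10 covariance of the shared individual block (five terms per
#' response).  The two responses are coupled through a single shared factor on
#' the intercept innovations, so that the among-individual intercept
#' correlation equals `cross_response_corr` exactly while the within-response
#' correlation matrices are preserved; the construction is positive
#' semidefinite for any `|cross_response_corr| <= 1`.
#'
#' @param config A `fid_sim_config`.
#' @return List with `cov` (10x10 covariance), `corr` (10x10 correlation) and
#'   `sds` (length-10 SDs, VOD block first).
#' @export
joint_individual_cov <- function(config) {
  Cv <- config$individual_corr$vod
  Cf <- config$individual_corr$fid
  rho <- config$cross_response_corr
  cross <- rho * Cv[, 1] %*% t(Cf[, 1])
  corr <- rbind(cbind(Cv, cross), cbind(t(cross), Cf))
  sds <- c(config$individual_sds$vod, config$individual_sds$fid)
  cov <- diag(sds) %*% corr %*% diag(sds)
  dimnames(cov) <- dimnames(corr) <-
    list(nm <- c(paste0("vod_", .block_terms("vod")),
                 paste0("fid_", .block_terms("fid"))), nm)
  list(cov = cov, corr = corr, sds = setNames(sds, nm))
}

.trial_columns <- c("individual_id", "date_id", "observer", "trial_number",
                    "sd_m", "vod_m", "fid_m", "vodd_m", "vodi_m",
                    "compatibility", "engaged", "habitat", "height",
                    "n_neighbors", "neighbor_fled_first", "external_event_5min",
                    "response_category")

# Design skeleton: balanced (individual x observer x trial) rows with dates
# and covariates but no distance responses.  Assumes the RNG state is already
# set by the caller.
build_design_impl <- function(config) {
  validate_sim_config(config)
  n_ind <- config$n_individuals
  tpo <- config$trials_per_observer
  if (config$n_dates < tpo) {
    stop("scheduling infeasible: ", 2 * tpo, " trials per individual at a ",
         "maximum of two trials per individual per day need at least ", tpo,
         " dates, but n_dates = ", config$n_dates,
         " (binding constraint: two-per-day cap)")
  }
  date_labels <- as.character(as.Date("2017-10-01") + seq_len(config$n_dates) - 1)
  ind_labels <- sprintf("ind_%03d", seq_len(n_ind))

  # Per individual: interleave the two observers so trial t for both observers
  # shares a sampling day (two trials per day, the cap), and stagger start
  # days across individuals.
  per_ind <- function(i) {
    slot <- rep(seq_len(tpo), each = 2)
    offset <- floor((i - 1) * config$n_dates / n_ind)
    tibble::tibble(
      individual_id = ind_labels[i],
      date_id = date_labels[((offset + slot - 1) %% config$n_dates) + 1],
      observer = rep(config$observers, times = tpo),
      trial_number = slot)
  }
  des <- dplyr::bind_rows(lapply(seq_len(n_ind), per_ind))
  n <- nrow(des)

  cf <- config$covariate_frequencies
  compat <- sample(names(cf$compatibility), n, replace = TRUE,
                   prob = cf$compatibility)
  n_neigh <- rpois(n, cf$neighbor_rate)
  des <- dplyr::mutate(
    des,
    sd_m = runif(n, config$sd_range_m[1], config$sd_range_m[2]),
    compatibility = compat,
    engaged = compat == "engaged",
    habitat = ifelse(runif(n) < cf$habitat_open, "open", "closed"),
    height = ifelse(runif(n) < cf$height_ground, "ground", "above_ground"),
    n_neighbors = n_neigh,
    neighbor_fled_first = n_neigh > 0 & runif(n) < cf$neighbor_fled_first,
    external_event_5min = runif(n) < cf$external_event,
    response_category = sample(names(cf$response_category), n, replace = TRUE,
                               prob = cf$response_category))
  des
}

#' Build a balanced trial design (no responses)
#'
#' Generates the trial skeleton of a simulated dataset: every individual
#' appears exactly `trials_per_observer` times per observer with trial numbers
#' `1:trials_per_observer`, scheduled over dates so that no individual is
#' approached more than twice on one day, with contextual covariates and start
#' distances drawn from the configured frequencies.  Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per planned trial (no `vod_m`/`fid_m`).
#' @export
build_design <- function(config) {
  withr::with_seed(config$seed, build_design_impl(config))
}

# Inverse-CDF draw from a log-normal truncated to (0, upper]; errors when the
# truncation mass underflows (the retry cap has already been spent).
.rlnorm_trunc <- function(meanlog, sdlog, upper, context) {
  p_up <- plnorm(upper, meanlog, sdlog)
  bad <- which(p_up <= 0 | !is.finite(p_up))
  if (length(bad)) {
    stop("truncation failure after retry cap: row ", bad[1],
         " has meanlog = ", signif(meanlog[bad[1]], 4),
         ", sdlog = ", signif(sdlog, 4),
         ", upper bound = ", signif(upper[bad[1]], 4), " (", context, ")")
  }
  qlnorm(runif(length(meanlog), 0, p_up), meanlog, sdlog)
}

# Rejection sampling of exp(meanlog + eps) on (0, upper] with a retry cap,
# then an inverse-CDF fallback for the stragglers.
.sample_envelope <- function(meanlog, sdlog, upper, context, max_retry = 1000) {
  n <- length(meanlog)
  out <- exp(meanlog + rnorm(n, 0, sdlog))
  todo <- which(out >= upper | out <= 0)
  tries <- 0
  while (length(todo) && tries < max_retry) {
    out[todo] <- exp(meanlog[todo] + rnorm(length(todo), 0, sdlog))
    todo <- todo[out[todo] >= upper[todo] | out[todo] <= 0]
    tries <- tries + 1
  }
  if (length(todo)) {
    out[todo] <- .rlnorm_trunc(meanlog[todo], sdlog, upper[todo], context)
  }
  out
}

# Linear predictor shared by the generator; `envelope_value` may be NULL to
# obtain the envelope-free part, and `include_random = FALSE` gives the
# covariate-only predictor (used for the draft draws, so the provisional
# envelope covariate stays exogenous to the random effects).
.sim_lp <- function(des, beta, block, d_date, U, date_idx, ind_idx,
                    envelope_value = NULL, include_random = TRUE) {
  obs <- as.numeric(des$observer == des$.observer_unfamiliar_label)
  tn <- des$trial_number
  lp <- beta[["intercept"]] +
    beta[["open"]] * (des$habitat == "open") +
    beta[["ground"]] * (des$height == "ground") +
    beta[["n_neighbors"]] * des$n_neighbors +
    beta[["neighbor_fled_first"]] * des$neighbor_fled_first +
    beta[["external_event"]] * des$external_event_5min +
    beta[["observer_unfamiliar"]] * obs +
    beta[["trial_number"]] * tn +
    beta[["observer_unfamiliar:trial_number"]] * obs * tn
  if ("looking" %in% names(beta)) {
    lp <- lp + beta[["looking"]] * (des$compatibility == "looking") +
      beta[["not_engaged_not_looking"]] *
        (des$compatibility == "not_engaged_not_looking")
  } else {
    lp <- lp + beta[["engaged"]] * des$engaged
  }
  if (include_random) {
    lp <- lp + d_date[date_idx] +
      U[cbind(ind_idx, block[1])] +
      U[cbind(ind_idx, block[3])] * obs +
      U[cbind(ind_idx, block[4])] * tn +
      U[cbind(ind_idx, block[5])] * obs * tn
  }
  if (!is.null(envelope_value)) {
    env_name <- if ("looking" %in% names(beta)) "vodd" else "vodi"
    lp <- lp + (beta[[env_name]] + U[cbind(ind_idx, block[2])]) * envelope_value
  }
  lp
}

#' Simulate a constrained-envelope trial dataset
#'
#' Draws a full synthetic dataset from a [sim_config()]: correlated individual
#' random effects, date intercepts, log-normal VOD truncated to `(0, SD)`, and
#' log-normal FID truncated to `(0, VOD]`, so every row satisfies the envelope
#' `0 < FID <= VOD < SD`.  The envelope covariates are handled as follows: a
#' draft response drawn with independent noise provides a provisional
#' VODD/VODI that enters the generative linear predictor (keeping the
#' covariate exogenous), and after truncation the exact values
#' `VODD = SD - VOD` and `VODI = VOD - FID` are recomputed and stored, so
#' fitted models only ever see internally consistent rows.
#'
#' With `envelope = "none"` no truncation is applied and the *provisional*
#' (exogenous) envelope covariate is stored instead; rows may then violate the
#' envelope.  This mode exists for calibration studies where the generative
#' law must match the fitted likelihood exactly; see the methods vignette.
#'
#' @param config A [sim_config()].
#' @param envelope `"truncate"` (default) enforces the envelope;
#'   `"none"` disables it.
#' @return A tibble of trials (one row each) with the generative truth attached
#'   as attribute `"fid_truth"`; retrieve it with [sim_truth()].
#' @examples
#' cfg <- sim_config(n_individuals = 4, n_dates = 6, trials_per_observer = 3,
#'                   seed = 1)
#' d <- simulate_trials(cfg)
#' all(d$fid_m <= d$vod_m & d$vod_m < d$sd_m)
#' @export
simulate_trials <- function(config, envelope = c("truncate", "none")) {
  envelope <- match.arg(envelope)
  withr::with_seed(config$seed, {
    des <- build_design_impl(config)
    n <- nrow(des)
    n_ind <- config$n_individuals
    jc <- joint_individual_cov(config)
    U <- matrix(rnorm(n_ind * 10), n_ind, 10) %*% chol_psd(jc$cov)
    colnames(U) <- colnames(jc$cov)
    d_vod <- rnorm(config$n_dates, 0, config$sd_date)
    d_fid <- rnorm(config$n_dates, 0, config$sd_date)

    date_levels <- sort(unique(des$date_id))
    date_idx <- match(des$date_id, date_levels)
    ind_idx <- match(des$individual_id, sprintf("ind_%03d", seq_len(n_ind)))
    des$.observer_unfamiliar_label <- config$observers[2]

    # VOD ------------------------------------------------------------------
    lp0 <- .sim_lp(des, config$beta_vod, 1:5, d_vod, U, date_idx, ind_idx,
                   include_random = FALSE)
    draft_vod <- if (envelope == "truncate")
      .rlnorm_trunc(lp0, config$sigma[["vod"]], des$sd_m, "draft VOD")
    else pmin(exp(lp0 + rnorm(n, 0, config$sigma[["vod"]])),
              0.999 * des$sd_m)  # keep the covariate on its (0, SD) support
    prov_vodd <- des$sd_m - draft_vod
    lp_vod <- .sim_lp(des, config$beta_vod, 1:5, d_vod, U, date_idx, ind_idx,
                      envelope_value = prov_vodd)
    if (envelope == "truncate") {
      vod <- .sample_envelope(lp_vod, config$sigma[["vod"]], des$sd_m, "VOD")
      vodd <- des$sd_m - vod
    } else {
      vod <- exp(lp_vod + rnorm(n, 0, config$sigma[["vod"]]))
      vodd <- prov_vodd
    }

    # FID ------------------------------------------------------------------
    lp0f <- .sim_lp(des, config$beta_fid, 6:10, d_fid, U, date_idx, ind_idx,
                    include_random = FALSE)
    draft_fid <- if (envelope == "truncate")
      .rlnorm_trunc(lp0f, config$sigma[["fid"]], vod, "draft FID")
    else pmin(exp(lp0f + rnorm(n, 0, config$sigma[["fid"]])), 0.999 * vod)
    prov_vodi <- vod - draft_fid
    lp_fid <- .sim_lp(des, config$beta_fid, 6:10, d_fid, U, date_idx, ind_idx,
                      envelope_value = prov_vodi)
    if (envelope == "truncate") {
      fid <- .sample_envelope(lp_fid, config$sigma[["fid"]], vod, "FID")
      vodi <- vod - fid
    } else {
      fid <- exp(lp_fid + rnorm(n, 0, config$sigma[["fid"]]))
      vodi <- prov_vodi
    }

    des$.observer_unfamiliar_label <- NULL
    out <- dplyr::mutate(des, vod_m = vod, fid_m = fid,
                         vodd_m = vodd, vodi_m = vodi)
    out <- dplyr::select(out, dplyr::all_of(.trial_columns))
    truth <- list(
      u = tibble::as_tibble(cbind(
        tibble::tibble(individual_id = sprintf("ind_%03d", seq_len(n_ind))),
        tibble::as_tibble(U))),
      date_effects = tibble::tibble(date_id = date_levels,
                                    vod = d_vod[seq_along(date_levels)],
                                    fid = d_fid[seq_along(date_levels)]),
      beta_vod = config$beta_vod, beta_fid = config$beta_fid,
      sigma = config$sigma, sd_date = config$sd_date,
      individual_cov = jc$cov, config = config, envelope = envelope)
    attr(out, "fid_truth") <- truth
    out
  })
}

# Cholesky factor that tolerates semi-definite inputs (zero SDs are allowed).
chol_psd <- function(S) {
  ev <- eigen(S, symmetric = TRUE)
  v <- pmax(ev$values, 0)
  t(ev$vectors %*% (t(ev$vectors) * sqrt(v)))
}

#' Generative truth attached to a simulated dataset
#'
#' @param data A tibble produced by [simulate_trials()].
#' @return A list with the latent individual effects (`u`), date effects,
#'   fixed-effect vectors, variance components and the configuration used.
#' @export
sim_truth <- function(data) {
  truth <- attr(data, "fid_truth")
  if (is.null(truth)) stop("no generative truth attached; was this dataset ",
                           "produced by simulate_trials()?")
  truth
}

#' Split trials by trial-number parity
#'
#' Partitions a trial table into even- and odd-numbered trials, the split-half
#' device used to validate the among-individual correlation on independent
#' subsets of the data.
#'
#' @param data A trial tibble with a `trial_number` column.
#' @return A list with tibbles `even` and `odd`; their union is the input and
#'   their intersection is empty.
#' @export
split_by_trial_parity <- function(data) {
  if (nrow(data) == 0) stop("cannot split an empty trial table")
  list(even = dplyr::filter(data, .data$trial_number %% 2 == 0),
       odd = dplyr::filter(data, .data$trial_number %% 2 == 1))
}

#' Variance components and ICC implied by a simulation configuration
#'
#' Computes, for one response, the latent-scale variance components that the
#' generative configuration implies over the realized design: the fixed-effect
#' variance (population variance of the true linear predictor across rows),
#' the individual-block variance (mean over rows of the quadratic form
#' `z' Sigma z`), the date variance and the residual variance, together with
#' the implied enhanced-agreement ICC.  This is the recovery target for
#' simulation-based checks of [enhanced_icc()].
#'
#' @param data A simulated dataset with truth attached.
#' @param response `"vod"` or `"fid"`.
#' @param include_fixed Include the fixed-effect variance in the denominator
#'   (the enhanced-agreement convention)?
#' @return One-row tibble with `v_individual`, `v_date`, `v_fixed`,
#'   `v_residual` and `icc`.
#' @export
implied_icc <- function(data, response = c("vod", "fid"), include_fixed = TRUE) {
  response <- match.arg(response)
  truth <- sim_truth(data)
  cfg <- truth$config
  spec <- model_spec(response)
  dm <- build_design_matrices(data, spec)
  beta <- if (response == "vod") truth$beta_vod else truth$beta_fid
  lp <- as.vector(dm$X %*% beta[colnames(dm$X)])
  v_fixed <- mean(lp^2) - mean(lp)^2
  blk <- if (response == "vod") 1:5 else 6:10
  Sg <- truth$individual_cov[blk, blk]
  M <- crossprod(dm$Z) / nrow(dm$Z)
  v_ind <- sum(Sg * M)
  v_date <- truth$sd_date^2
  v_res <- truth$sigma[[response]]^2
  denom <- v_ind + v_date + v_res + if (include_fixed) v_fixed else 0
  tibble::tibble(response = response, v_individual = v_ind, v_date = v_date,
                 v_fixed = v_fixed, v_residual = v_res,
                 icc = v_ind / denom)
}

#' Write / read trial data as CSV
#'
#' Column order is fixed and documented (`fidtrait:::.trial_columns`); date
#' labels are ISO-8601.
#'
#' @param data Trial tibble.
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` returns
#'   a tibble with the canonical column order and types.
#' @export
write_trials <- function(data, path) {
  write.csv(data[, .trial_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.trial_columns, names(d))
  if (length(missing)) stop("trial CSV is missing columns: ",
                            paste(missing, collapse = ", "))
  tibble::as_tibble(d[, .trial_columns])
}

#' Check the trial-record invariants
#'
#' Verifies the distance envelope `0 < FID <= VOD < SD`, the envelope
#' identities `VODD = SD - VOD` and `VODI = VOD - FID`, trial-number bounds and
#' per-(individual, observer, trial) uniqueness, and that `neighbor_fled_first`
#' never holds with zero neighbors.
#'
#' @param data Trial tibble.
#' @return `TRUE` invisibly, or an error naming the violated invariant.
#' @export
validate_trials <- function(data) {
  with(data, {
    if (any(fid_m <= 0 | fid_m > vod_m | vod_m >= sd_m))
      stop("envelope violated: need 0 < FID <= VOD < SD on every row")
    if (any(abs(vodd_m - (sd_m - vod_m)) > 1e-8))
      stop("vodd_m must equal sd_m - vod_m")
    if (any(abs(vodi_m - (vod_m - fid_m)) > 1e-8))
      stop("vodi_m must equal vod_m - fid_m")
    if (any(trial_number < 1 | trial_number != round(trial_number)))
      stop("trial_number must be a positive integer")
    if (any(n_neighbors == 0 & neighbor_fled_first))
      stop("neighbor_fled_first requires at least one neighbor")
  })
  if (anyDuplicated(data[, c("individual_id", "observer", "trial_number")]))
    stop("duplicated (individual, observer, trial_number) rows")
  invisible(TRUE)
}

#' Write / read a simulation configuration as YAML
#'
#' @param config A `fid_sim_config`.
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly; `read_sim_config()`
#'   returns a validated `fid_sim_config`.
#' @export
write_sim_config <- function(config, path) {
  ser <- unclass(config)
  ser$individual_corr <- lapply(ser$individual_corr, function(m)
    apply(m, 1, c, simplify = FALSE))
  # named vectors survive the YAML round trip as maps
  for (f in c("beta_vod", "beta_fid", "sigma"))
    ser[[f]] <- as.list(ser[[f]])
  ser$individual_sds <- lapply(ser$individual_sds, as.list)
  ser$covariate_frequencies$compatibility <-
    as.list(ser$covariate_frequencies$compatibility)
  ser$covariate_frequencies$response_category <-
    as.list(ser$covariate_frequencies$response_category)
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$individual_corr <- lapply(raw$individual_corr, function(rows) {
    do.call(rbind, lapply(rows, unlist))
  })
  for (f in c("beta_vod", "beta_fid", "sigma"))
    raw[[f]] <- unlist(raw[[f]])
  raw$individual_sds <- lapply(raw$individual_sds, unlist)
  cf <- raw$covariate_frequencies
  cf$compatibility <- unlist(cf$compatibility)
  cf$response_category <- unlist(cf$response_category)
  raw$covariate_frequencies <- cf
  do.call(sim_config, raw)
}
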