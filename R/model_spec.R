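# Model specification and design-matrix construction.
#
# Both responses share the same structure: treatment-coded fixed effects with
# references engaged / closed habitat / above-ground / familiar observer, an
# observer x trial-number interaction, a date random intercept, and a
# correlated individual block (intercept, envelope-covariate slope, observer,
# trial number, observer x trial number).  The envelope covariate is VODD for
# the VOD model and VODI for the FID model; compatibility appears only in the
# VOD model and engaged only in the FID model.

#' Specify a univariate trial model
#'
#' @param response `"vod"` or `"fid"`.
#' @return A `fid_model_spec` with the ordered fixed terms, the random
#'   structure (date intercept plus the correlated individual block), the
#'   log-normal family and the prior description.
#' @export
model_spec <- function(response = c("vod", "fid")) {
  response <- match.arg(response)
  spec <- list(
    response = response,
    response_col = paste0(response, "_m"),
    fixed_terms = if (response == "vod") .vod_terms else .fid_terms,
    block_terms = .block_terms(response),
    family = "lognormal",
    priors = list(beta = "normal(0, 100)",
                  scalar_sd = "half-student-t(3, 0, 10)",
                  individual_block = "huang-wand(nu = 2, scale = 10)"))
  class(spec) <- "fid_model_spec"
  spec
}

#' @export
print.fid_model_spec <- function(x, ...) {
  cat("<fid_model_spec> ", toupper(x$response), " ~ ",
      paste(setdiff(x$fixed_terms, "intercept"), collapse = " + "),
      " + (1 | date) + (", paste(x$block_terms, collapse = " + "),
      " | individual)\n", sep = "")
  invisible(x)
}

# Display names matching the published table layout.
.pretty_names <- c(
  intercept = "Intercept", vodd = "VODD", vodi = "VODI",
  looking = "Looking", not_engaged_not_looking = "Not engaged not looking",
  engaged = "Engaged", open = "Open (Habitat)", ground = "Ground (Height)",
  n_neighbors = "Number of neighbors",
  neighbor_fled_first = "Neighbor flee first",
  external_event = "External factors within 5 min",
  observer_unfamiliar = "Unfamiliar observer (AB)",
  trial_number = "Trial number",
  `observer_unfamiliar:trial_number` = "Unfamiliar observer (AB): Trial number")

#' Build fixed and random design matrices for a trial model
#'
#' Treatment contrasts with references engaged / closed / above-ground /
#' familiar observer; the interaction column is the unfamiliar-observer
#' indicator times the raw trial number (1-12, not centered).  The random
#' index maps rows onto date and individual levels.
#'
#' @param data Trial tibble (no missing values in model terms).
#' @param spec A [model_spec()].
#' @return List with `X` (fixed matrix, columns in spec order), `Z` (individual
#'   random-covariate matrix: intercept, envelope covariate, observer, trial
#'   number, interaction), `ind`/`date` (1-based level indices),
#'   `ind_levels`/`date_levels`, `y` (response vector) and `warnings`
#'   (constant-column and sparse-individual notes, recorded in fit metadata).
#' @export
build_design_matrices <- function(data, spec) {
  stopifnot(inherits(spec, "fid_model_spec"))
  needed <- c("individual_id", "date_id", "observer", "trial_number",
              "habitat", "height", "n_neighbors", "neighbor_fled_first",
              "external_event_5min",
              if (spec$response == "vod") c("compatibility", "vodd_m")
              else c("engaged", "vodi_m"))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) stop("data is missing columns: ",
                                 paste(missing_cols, collapse = ", "))
  sub <- data[, unique(c(needed, intersect(spec$response_col, names(data))))]
  if (anyNA(sub)) stop("missing values in model terms are not allowed")

  check_levels <- function(col, allowed) {
    extra <- setdiff(unique(data[[col]]), allowed)
    if (length(extra)) stop("unseen ", col, " level(s): ",
                            paste(extra, collapse = ", "),
                            " (allowed: ", paste(allowed, collapse = ", "), ")")
  }
  check_levels("habitat", c("open", "closed"))
  check_levels("height", c("ground", "above_ground"))
  if (spec$response == "vod")
    check_levels("compatibility",
                 c("engaged", "looking", "not_engaged_not_looking"))

  obs_levels <- sort(unique(data$observer))
  if (length(obs_levels) > 2) stop("more than two observer levels")
  # reference = familiar when present, else first level
  if ("familiar" %in% obs_levels)
    obs_levels <- c("familiar", setdiff(obs_levels, "familiar"))
  obs <- if (length(obs_levels) == 2) as.numeric(data$observer == obs_levels[2])
         else rep(0, nrow(data))

  env <- if (spec$response == "vod") data$vodd_m else data$vodi_m
  n <- nrow(data)
  X <- cbind(
    intercept = rep(1, n),
    env = env,
    if (spec$response == "vod") cbind(
      looking = as.numeric(data$compatibility == "looking"),
      not_engaged_not_looking =
        as.numeric(data$compatibility == "not_engaged_not_looking"))
    else cbind(engaged = as.numeric(data$engaged)),
    open = as.numeric(data$habitat == "open"),
    ground = as.numeric(data$height == "ground"),
    n_neighbors = as.numeric(data$n_neighbors),
    neighbor_fled_first = as.numeric(data$neighbor_fled_first),
    external_event = as.numeric(data$external_event_5min),
    observer_unfamiliar = obs,
    trial_number = as.numeric(data$trial_number),
    `observer_unfamiliar:trial_number` = obs * as.numeric(data$trial_number))
  colnames(X)[2] <- if (spec$response == "vod") "vodd" else "vodi"
  X <- X[, spec$fixed_terms, drop = FALSE]

  Z <- cbind(intercept = rep(1, n), env = env, observer_unfamiliar = obs,
             trial_number = as.numeric(data$trial_number),
             `observer_unfamiliar:trial_number` = obs * data$trial_number)
  colnames(Z)[2] <- colnames(X)[2]

  warnings <- character()
  const <- colnames(X)[-1][apply(X[, -1, drop = FALSE], 2, function(v)
    length(unique(v)) == 1)]
  if (length(const))
    warnings <- c(warnings, paste0("constant fixed-effect column(s): ",
                                   paste(const, collapse = ", ")))
  ind_levels <- sort(unique(data$individual_id))
  sparse <- names(which(table(data$individual_id) < 2))
  if (length(sparse))
    warnings <- c(warnings,
                  paste0("individual(s) with < 2 trials (retained, partial ",
                         "pooling applies): ", paste(sparse, collapse = ", ")))
  date_levels <- sort(unique(data$date_id))

  list(X = X, Z = Z,
       ind = match(data$individual_id, ind_levels),
       date = match(data$date_id, date_levels),
       ind_levels = ind_levels, date_levels = date_levels,
       y = if (spec$response_col %in% names(data)) data[[spec$response_col]]
           else NULL,
       warnings = warnings)
}
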