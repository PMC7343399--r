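# broom-style tidiers and the published-table summary layout.

.block_pretty <- c(intercept = "Intercept", vodd = "VODD", vodi = "VODI",
                   observer_unfamiliar = "ObserverAB",
                   trial_number = "TrialNo",
                   `observer_unfamiliar:trial_number` = "ObserverAB:TrialNo")

.pretty_block <- function(nm) {
  # strip an optional response prefix from joint block names
  core <- sub("^(vod|fid)_", "", nm)
  pre <- ifelse(grepl("^(vod|fid)_", nm), paste0(toupper(substr(nm, 1, 3)), " "), "")
  paste0(pre, .block_pretty[core])
}

.param_summary <- function(fit) {
  pd <- fit$param_draws
  tibble::tibble(
    parameter = colnames(pd),
    estimate = colMeans(pd),
    est_error = apply(pd, 2, sd),
    l95 = apply(pd, 2, quantile, 0.025),
    u95 = apply(pd, 2, quantile, 0.975)) |>
    dplyr::left_join(fit$diagnostics, by = "parameter")
}

#' Tidy a fitted trial model
#'
#' @param x A `fid_fit`.
#' @param effects `"fixed"` (default), `"ran_pars"` (SDs and correlations) or
#'   `"all"`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high` (95 percent quantile interval), `rhat`, `ess_bulk`,
#'   `ess_tail`.
#' @method tidy fid_fit
#' @export
tidy.fid_fit <- function(x, effects = c("fixed", "ran_pars", "all"), ...) {
  effects <- match.arg(effects)
  s <- .param_summary(x)
  is_fixed <- grepl("^(vod_|fid_)?b_", s$parameter)
  keep <- switch(effects, fixed = is_fixed, ran_pars = !is_fixed,
                 all = rep(TRUE, nrow(s)))
  out <- s[keep, ]
  dplyr::rename(out, term = "parameter", std.error = "est_error",
                conf.low = "l95", conf.high = "u95")
}

#' Glance at a fitted trial model
#'
#' @param x A `fid_fit`.
#' @param ... Unused.
#' @return One-row tibble with sizes, sampler settings, the worst Rhat /
#'   smallest bulk ESS and the convergence flag.
#' @method glance fid_fit
#' @export
glance.fid_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$meta$n_obs,
    n_individuals = length(x$dm[[1]]$ind_levels),
    n_dates = length(x$dm[[1]]$date_levels),
    chains = x$meta$chains,
    draws = nrow(x$param_draws),
    max_rhat = max(x$diagnostics$rhat),
    min_ess_bulk = min(x$diagnostics$ess_bulk),
    converged = x$converged)
}

#' Published-style coefficient summary table
#'
#' One row per population-level parameter, family parameter, and group-level
#' SD / correlation, in the layout of the study's model-summary tables:
#' posterior mean, posterior SD, 95 percent interval bounds, Rhat and
#' bulk/tail ESS, grouped into population-level, family-specific, date and
#' individual-identity sections with the published row labels
#' (e.g. `"Unfamiliar observer (AB)"`, `"sd(ObserverAB:TrialNo)"`).
#'
#' @param fit A `fid_fit`.
#' @return Tibble with columns `response`, `group`, `parameter`, `estimate`,
#'   `est_error`, `l95`, `u95`, `rhat`, `bulk_ess`, `tail_ess`.
#' @export
summarize_fit <- function(fit) {
  s <- .param_summary(fit)
  n_date <- length(fit$dm[[1]]$date_levels)
  n_ind <- length(fit$dm[[1]]$ind_levels)
  multi <- length(fit$specs) > 1
  rows <- purrr::map_dfr(seq_len(nrow(s)), function(i) {
    p <- s$parameter[i]
    resp <- if (multi && grepl("^(vod|fid)_", p)) substr(p, 1, 3)
            else names(fit$specs)[1]
    core <- sub("^(vod|fid)_", "", p)
    if (grepl("^b_", core)) {
      grp <- "Population-level effects"
      lab <- unname(.pretty_names[sub("^b_", "", core)])
    } else if (core == "sigma") {
      grp <- "Family specific (log-normal)"
      lab <- "Sigma"
    } else if (core == "sd_date") {
      grp <- sprintf("Date (%d levels)", n_date)
      lab <- "sd(Intercept)"
    } else if (grepl("^sd_ind_", core)) {
      grp <- sprintf("Individual identity (%d levels)", n_ind)
      lab <- paste0("sd(", .pretty_block(sub("^sd_ind_", "", p)), ")")
    } else {
      grp <- sprintf("Individual identity (%d levels)", n_ind)
      pair <- strsplit(sub("^cor_ind_", "", p), "__")[[1]]
      lab <- paste0("cor(", .pretty_block(pair[1]), ",",
                    .pretty_block(pair[2]), ")")
    }
    tibble::tibble(response = resp, group = grp, parameter = lab)
  })
  dplyr::bind_cols(rows,
                   dplyr::select(s, "estimate", "est_error", "l95", "u95"),
                   tibble::tibble(rhat = s$rhat, bulk_ess = s$ess_bulk,
                                  tail_ess = s$ess_tail))
}
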