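# Posterior fitting of the log-normal mixed models.
#
# The response is modelled as log y ~ Normal(X beta + date intercept +
# Z u[individual], sigma) -- a log-normal observation model whose latent scale
# is Gaussian, so all full conditionals are conjugate and the posterior is
# explored with a blocked Gibbs sampler (see src/gibbs.cpp).  Priors follow
# the analysis this package implements: Normal(0, 100) on fixed effects,
# half-Student-t(3, 10) on the date and residual SDs, and a marginally
# noninformative Huang-Wand prior on the correlated individual block (uniform
# marginal correlations, half-t marginal SDs).

.default_chains <- 4L
.default_iter <- 2000L
.default_warmup <- 500L

.fit_gibbs <- function(data, specs, chains, iter, warmup, seed,
                       include_individual = TRUE) {
  stopifnot(iter > warmup, chains >= 1)
  dms <- lapply(specs, function(s) build_design_matrices(data, s))
  ys <- lapply(seq_along(specs), function(r) {
    y <- dms[[r]]$y
    if (is.null(y)) stop("response column ", specs[[r]]$response_col,
                         " not found in data")
    if (any(y <= 0)) stop("log-normal responses must be strictly positive")
    log(y)
  })
  Xs <- lapply(dms, `[[`, "X")
  Zs <- lapply(dms, `[[`, "Z")
  ind <- dms[[1]]$ind
  date <- dms[[1]]$date
  n_ind <- length(dms[[1]]$ind_levels)
  n_date <- length(dms[[1]]$date_levels)

  keep <- iter - warmup
  run_chain <- function(c_id) {
    withr::with_seed((seed + 7919L * c_id) %% .Machine$integer.max, {
      gibbs_lmm_cpp(ys, Xs, Zs, ind - 1L, date - 1L, n_ind, n_date,
                    include_individual, beta_sd = 100,
                    scalar_nu = 3, scalar_A = 10,
                    block_nu = 2, block_A = 10,
                    n_iter = as.integer(iter), n_warmup = as.integer(warmup))
    })
  }
  t0 <- Sys.time()
  chains_out <- lapply(seq_len(chains), run_chain)
  runtime <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  resp_names <- vapply(specs, `[[`, "", "response")
  q_each <- vapply(Zs, ncol, 0L)
  block_names <- unlist(lapply(seq_along(specs), function(r) {
    nm <- colnames(Zs[[r]])
    if (length(specs) > 1) paste0(resp_names[r], "_", nm) else nm
  }))
  q_tot <- sum(q_each)

  # stack chains
  stack <- function(get) do.call(rbind, lapply(chains_out, get))
  draws <- list(
    beta = lapply(seq_along(specs), function(r) {
      b <- stack(function(ch) ch$beta[[r]])
      colnames(b) <- colnames(Xs[[r]])
      b
    }),
    sigma = stack(function(ch) ch$sigma),
    tau = stack(function(ch) ch$tau),
    Sigma = if (include_individual) stack(function(ch) ch$Sigma) else NULL,
    U = if (include_individual) {
      arr <- array(NA_real_, c(n_ind, q_tot, keep * chains))
      for (c_id in seq_len(chains))
        arr[, , (c_id - 1) * keep + seq_len(keep)] <- chains_out[[c_id]]$U
      dimnames(arr) <- list(dms[[1]]$ind_levels, block_names, NULL)
      arr
    } else NULL,
    d = lapply(seq_along(specs), function(r) stack(function(ch) ch$d[[r]])))
  names(draws$beta) <- resp_names
  names(draws$d) <- resp_names
  colnames(draws$sigma) <- colnames(draws$tau) <- resp_names

  # scalar summaries for diagnostics, as iterations x chains arrays
  diag_params <- list()
  for (r in seq_along(specs)) {
    pre <- if (length(specs) > 1) paste0(resp_names[r], "_") else ""
    B <- draws$beta[[r]]
    for (j in seq_len(ncol(B)))
      diag_params[[paste0(pre, "b_", colnames(B)[j])]] <- B[, j]
    diag_params[[paste0(pre, "sigma")]] <- draws$sigma[, r]
    diag_params[[paste0(pre, "sd_date")]] <- draws$tau[, r]
  }
  if (include_individual) {
    SD <- sqrt(draws$Sigma[, (seq_len(q_tot) - 1) * q_tot + seq_len(q_tot),
                           drop = FALSE])
    for (k in seq_len(q_tot))
      diag_params[[paste0("sd_ind_", block_names[k])]] <- SD[, k]
    for (k in seq_len(q_tot - 1)) for (l in (k + 1):q_tot) {
      ckl <- draws$Sigma[, (l - 1) * q_tot + k] / (SD[, k] * SD[, l])
      diag_params[[paste0("cor_ind_", block_names[k], "__",
                          block_names[l])]] <- ckl
    }
  }
  param_draws <- do.call(cbind, diag_params)
  diagnostics <- purrr::map_dfr(seq_len(ncol(param_draws)), function(j) {
    d <- mcmc_diagnostics(matrix(param_draws[, j], nrow = keep, ncol = chains))
    tibble::tibble(parameter = colnames(param_draws)[j],
                   rhat = d[["rhat"]], ess_bulk = d[["ess_bulk"]],
                   ess_tail = d[["ess_tail"]])
  })
  converged <- all(is.finite(diagnostics$rhat)) &&
    max(diagnostics$rhat) <= 1.01 && min(diagnostics$ess_bulk) >= 400
  meta_warnings <- unlist(lapply(dms, `[[`, "warnings"))
  fit <- structure(list(
    specs = setNames(specs, resp_names),
    data = data, dm = setNames(dms, resp_names),
    include_individual = include_individual,
    block_names = block_names, q_each = setNames(q_each, resp_names),
    draws = draws, param_draws = param_draws,
    chain_id = rep(seq_len(chains), each = keep),
    diagnostics = diagnostics, converged = converged,
    meta = list(chains = chains, iter = iter, warmup = warmup, seed = seed,
                n_obs = nrow(data), runtime_s = runtime,
                design_warnings = meta_warnings,
                priors = specs[[1]]$priors)),
    class = "fid_fit")
  if (!converged) {
    warning(sprintf(paste0("fit did not meet the convergence criteria ",
                           "(max Rhat = %.3f, min bulk ESS = %.0f); ",
                           "inspect $diagnostics before using the posterior"),
                    max(diagnostics$rhat), min(diagnostics$ess_bulk)),
            call. = FALSE)
  }
  fit
}

#' Fit a univariate log-normal mixed model
#'
#' Samples the posterior of the VOD or FID model: log-normal response, the
#' full fixed-effect structure of [model_spec()], a date random intercept and
#' a correlated five-term individual block.  Returns draws, per-parameter
#' convergence diagnostics (split-Rhat, bulk/tail ESS) and everything needed
#' to compute pointwise log-likelihoods lazily via [pointwise_loglik()].
#'
#' @param data Trial tibble.
#' @param spec A [model_spec()]; defaults to the VOD model.
#' @param chains,iter,warmup Sampler settings. The defaults (4 chains, 2000
#'   iterations of which 500 warmup) are desk-scale settings; increase for
#'   final inference.
#' @param seed Integer seed (each chain derives its own stream).
#' @param include_individual Set `FALSE` to drop the entire individual block
#'   (the reduced model used for identity stacking).
#' @return A `fid_fit`.  The convergence flag (`$converged`, Rhat <= 1.01 and
#'   bulk ESS >= 400 on every parameter) is also surfaced by [glance()]; a
#'   non-converged fit is returned with a structured warning, never silently.
#' @export
fit_univariate <- function(data, spec = model_spec("vod"),
                           chains = .default_chains, iter = .default_iter,
                           warmup = .default_warmup, seed = 1L,
                           include_individual = TRUE) {
  .fit_gibbs(data, list(spec), chains, iter, warmup, seed, include_individual)
}

#' Fit the bivariate log-normal mixed model
#'
#' Joint model for VOD and FID sharing a single ten-term individual-level
#' block (all correlations between the two responses' individual terms are
#' estimated, in particular the two intercepts), with separate date intercepts
#' and residual SDs per response and conditionally independent residuals.
#'
#' @inheritParams fit_univariate
#' @param vod_spec,fid_spec The per-response [model_spec()]s.
#' @return A `fid_fit` with two responses; pass it to
#'   [among_individual_correlation()] for the convergent-validity correlation.
#' @export
fit_bivariate <- function(data, vod_spec = model_spec("vod"),
                          fid_spec = model_spec("fid"),
                          chains = .default_chains, iter = .default_iter,
                          warmup = .default_warmup, seed = 1L) {
  .fit_gibbs(data, list(vod_spec, fid_spec), chains, iter, warmup, seed, TRUE)
}

#' Pointwise log-likelihood matrix of a fit
#'
#' Evaluates, for every retained posterior draw and every observation used in
#' fitting, the log-normal log density of the observed response (including the
#' Jacobian of the log transform) at that draw's parameters.  For a bivariate
#' fit the columns are the VOD observations followed by the FID observations.
#'
#' @param fit A `fid_fit`.
#' @param response Optional response name to restrict the columns.
#' @return Matrix, draws by observations.
#' @export
pointwise_loglik <- function(fit, response = NULL) {
  resps <- names(fit$specs)
  if (!is.null(response)) {
    if (!response %in% resps) stop("fit has no response ", response)
    resps <- response
  }
  out <- lapply(resps, function(r) t(.loglik_one(fit, r)))
  out <- do.call(cbind, out)
  if (!is.null(out)) dimnames(out) <- NULL
  out
}

# n x S matrix of log densities for one response
.loglik_one <- function(fit, r) {
  dm <- fit$dm[[r]]
  y <- dm$y
  B <- fit$draws$beta[[r]]
  MU <- dm$X %*% t(B)                                   # n x S
  MU <- MU + t(fit$draws$d[[r]])[dm$date, , drop = FALSE]
  if (fit$include_individual) {
    off <- c(0, cumsum(fit$q_each))[match(r, names(fit$specs))]
    for (k in seq_len(ncol(dm$Z))) {
      MU <- MU + dm$Z[, k] * fit$draws$U[dm$ind, off + k, ]
    }
  }
  sig <- fit$draws$sigma[, r]
  ly <- log(y)
  SW <- matrix(sig, nrow(MU), length(sig), byrow = TRUE)
  -ly - log(SW) - 0.5 * log(2 * pi) - (ly - MU)^2 / (2 * SW^2)
}

#' Draw from the model priors (no data)
#'
#' Data-free draws from the prior: fixed effects Normal(0, 100), scalar SDs
#' half-Student-t(3, 10), individual-block SDs half-t(2, 10).  Used for
#' prior-predictive sanity checks.
#'
#' @param spec A [model_spec()].
#' @param n Number of draws.
#' @param seed Seed.
#' @return Tibble of draws, one column per parameter.
#' @export
sample_prior <- function(spec = model_spec("vod"), n = 1000, seed = 1L) {
  withr::with_seed(seed, {
    fixed <- matrix(rnorm(n * length(spec$fixed_terms), 0, 100), n)
    colnames(fixed) <- paste0("b_", spec$fixed_terms)
    scal <- matrix(abs(stats::rt(n * 2, df = 3)) * 10, n)
    colnames(scal) <- c("sd_date", "sigma")
    blk <- matrix(abs(stats::rt(n * length(spec$block_terms), df = 2)) * 10, n)
    colnames(blk) <- paste0("sd_ind_", spec$block_terms)
    tibble::as_tibble(cbind(fixed, scal, blk))
  })
}

#' @export
print.fid_fit <- function(x, ...) {
  cat("<fid_fit> ", paste(toupper(names(x$specs)), collapse = " + "),
      if (!x$include_individual) " (individual block removed)", "\n",
      "  ", x$meta$n_obs, " observations, ",
      length(x$dm[[1]]$ind_levels), " individuals, ",
      length(x$dm[[1]]$date_levels), " dates\n",
      "  ", x$meta$chains, " chains x ", x$meta$iter - x$meta$warmup,
      " kept draws; max Rhat = ", sprintf("%.3f", max(x$diagnostics$rhat)),
      "; converged: ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Conditional-effect curves from a fit
#'
#' Response-scale predictions over a grid of one focal term (by default the
#' observer x trial-number interaction), holding every other covariate at its
#' reference level (categorical) or mean (numeric) and setting the random
#' effects to zero.  Per draw the expected response `exp(mu + sigma^2 / 2)` is
#' computed; the curve is the posterior mean with 2.5/97.5 percent quantile
#' bands.
#'
#' @param fit A `fid_fit`.
#' @param term Focal term: `"observer_unfamiliar:trial_number"`, a numeric
#'   covariate name, or a categorical term of the model specification.
#' @param response Response to predict (defaults to the first).
#' @param grid_n Grid size for numeric covariates.
#' @return Tibble with the grid columns, `estimate`, `lower`, `upper`.
#' @export
conditional_effects <- function(fit, term = "observer_unfamiliar:trial_number",
                                response = NULL, grid_n = 50) {
  response <- response %||% names(fit$specs)[1]
  spec <- fit$specs[[response]]
  if (!term %in% c(spec$fixed_terms, "compatibility", "habitat", "height"))
    stop("term ", dQuote(term), " is not in the ", toupper(response),
         " model specification")
  dm <- fit$dm[[response]]
  Xbar <- colMeans(dm$X)
  env_name <- spec$fixed_terms[2]

  base_row <- setNames(rep(0, ncol(dm$X)), colnames(dm$X))
  base_row["intercept"] <- 1
  base_row[env_name] <- Xbar[env_name]
  base_row["n_neighbors"] <- Xbar["n_neighbors"]
  base_row["trial_number"] <- Xbar["trial_number"]

  if (term == "observer_unfamiliar:trial_number") {
    grid <- tidyr::expand_grid(observer = c("familiar", "unfamiliar"),
                               trial_number = 1:12)
    Xn <- t(vapply(seq_len(nrow(grid)), function(i) {
      r <- base_row
      ob <- as.numeric(grid$observer[i] == "unfamiliar")
      r["observer_unfamiliar"] <- ob
      r["trial_number"] <- grid$trial_number[i]
      r["observer_unfamiliar:trial_number"] <- ob * grid$trial_number[i]
      r
    }, base_row))
  } else if (term %in% c("compatibility", "habitat", "height", "engaged",
                         "looking", "not_engaged_not_looking", "open",
                         "ground", "neighbor_fled_first", "external_event")) {
    lv <- switch(term,
                 compatibility = c("engaged", "looking", "not_engaged_not_looking"),
                 habitat = c("closed", "open"), height = c("above_ground", "ground"),
                 c("reference", term))
    grid <- tibble::tibble(level = lv)
    Xn <- t(vapply(lv, function(l) {
      r <- base_row
      if (l %in% colnames(dm$X)) r[l] <- 1
      r
    }, base_row))
  } else {
    vals <- seq(min(dm$X[, term]), max(dm$X[, term]), length.out = grid_n)
    grid <- tibble::tibble(!!term := vals)
    Xn <- t(vapply(vals, function(v) {
      r <- base_row
      r[term] <- v
      if (term == "trial_number")
        r["observer_unfamiliar:trial_number"] <-
          r["observer_unfamiliar"] * v
      r
    }, base_row))
  }
  B <- fit$draws$beta[[response]]
  sig <- fit$draws$sigma[, response]
  MU <- Xn %*% t(B)
  PRED <- exp(MU + matrix(sig^2 / 2, nrow(MU), length(sig), byrow = TRUE))
  dplyr::bind_cols(grid, tibble::tibble(
    estimate = rowMeans(PRED),
    lower = apply(PRED, 1, quantile, 0.025),
    upper = apply(PRED, 1, quantile, 0.975)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
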