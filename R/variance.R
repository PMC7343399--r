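# Variance decomposition on the latent (log) scale.
#
# All components live on the log scale, where the variance components of a
# log-normal model are defined: the individual block contributes through the
# observed covariate values (random slopes enter via the quadratic form
# z' Sigma z averaged over rows), the date intercept through its variance,
# the fixed effects through the population variance of the linear predictor
# over the fitted rows, and the residual through sigma^2.

#' Per-draw variance components of a fit
#'
#' For every retained draw and response computes `v_individual` (mean over
#' rows of `z' Sigma z` for that draw's individual covariance), `v_date`
#' (date-intercept variance), `v_fixed` (population variance of `X beta`
#' across the fitted rows) and `v_residual` (`sigma^2`).
#'
#' @param fit A `fid_fit` with the individual block included.
#' @param check_convergence Error on a non-converged fit unless `FALSE`.
#' @return A `fid_varcomp` tibble with columns `draw`, `chain`, `response`,
#'   `v_individual`, `v_date`, `v_fixed`, `v_residual`.
#' @export
variance_components <- function(fit, check_convergence = FALSE) {
  if (!fit$include_individual)
    stop("fit has no individual block; variance decomposition needs one")
  if (check_convergence && !fit$converged)
    stop("fit did not converge; pass check_convergence = FALSE to override")
  q_tot <- sum(fit$q_each)
  offs <- c(0, cumsum(fit$q_each))
  out <- purrr::map_dfr(seq_along(fit$specs), function(r) {
    dm <- fit$dm[[r]]
    B <- fit$draws$beta[[r]]
    Xc <- sweep(dm$X, 2, colMeans(dm$X))
    A <- crossprod(Xc) / nrow(dm$X)             # population covariance of X
    v_fixed <- rowSums((B %*% A) * B)
    M <- crossprod(dm$Z) / nrow(dm$Z)
    q <- ncol(dm$Z)
    idx <- as.vector(outer(offs[r] + seq_len(q), offs[r] + seq_len(q),
                           function(i, j) (j - 1) * q_tot + i))
    v_ind <- as.vector(fit$draws$Sigma[, idx, drop = FALSE] %*% as.vector(M))
    tibble::tibble(draw = seq_along(v_ind), chain = fit$chain_id,
                   response = names(fit$specs)[r],
                   v_individual = v_ind,
                   v_date = fit$draws$tau[, r]^2,
                   v_fixed = v_fixed,
                   v_residual = fit$draws$sigma[, r]^2)
  })
  class(out) <- c("fid_varcomp", class(out))
  out
}

#' Enhanced-agreement repeatability (ICC)
#'
#' Per-draw intraclass correlation
#' `v_individual / (v_individual + v_date + v_fixed + v_residual)`, i.e. the
#' proportion of latent-scale variance attributable to consistent
#' among-individual differences after accounting for observation date and
#' (by default) the fixed-effect structure -- the enhanced-agreement
#' convention.  Summarized by the posterior mean and 95 percent HDI.
#'
#' @param components A [variance_components()] tibble.
#' @param include_fixed Include `v_fixed` in the denominator (default); set
#'   `FALSE` for the agreement variant conditioned on the fixed effects.
#' @param mass HDI probability mass.
#' @return A `fid_icc` tibble, one row per response: `mean`, `hdi_low`,
#'   `hdi_high`, `n_draws`, `n_excluded` (zero-denominator draws are excluded
#'   with a count, never propagated as NaN).  Posterior samples are attached
#'   as the attribute `"samples"` (a named list).
#' @export
enhanced_icc <- function(components, include_fixed = TRUE, mass = 0.95) {
  stopifnot(inherits(components, "fid_varcomp"))
  if (nrow(components) == 0) stop("empty variance-component table")
  samples <- list()
  out <- purrr::map_dfr(split(components, components$response), function(d) {
    denom <- d$v_individual + d$v_date + d$v_residual +
      if (include_fixed) d$v_fixed else 0
    bad <- denom <= 0
    icc <- d$v_individual[!bad] / denom[!bad]
    if (length(icc) < 2)
      stop("fewer than 2 draws with positive total variance for response ",
           d$response[1])
    samples[[d$response[1]]] <<- icc
    tibble::tibble(response = d$response[1], grouping = "individual_id",
                   mean = mean(icc),
                   hdi_low = hdi(icc, mass)[["low"]],
                   hdi_high = hdi(icc, mass)[["high"]],
                   n_draws = length(icc), n_excluded = sum(bad))
  })
  stopifnot(all(unlist(samples) >= 0 & unlist(samples) <= 1))
  attr(out, "samples") <- samples
  class(out) <- c("fid_icc", class(out))
  out
}

#' Among-individual correlation between VOD and FID
#'
#' From a bivariate fit, builds the posterior of the among-individual
#' correlation by dividing the covariance between the two responses'
#' individual intercepts by the product of the square roots of their
#' variances, standardizing the covariance to `[-1, 1]` (the
#' convergent-validity statistic).
#'
#' @param fit A bivariate `fid_fit`.
#' @param mass HDI probability mass.
#' @return A one-row `fid_corr` tibble (`mean`, `hdi_low`, `hdi_high`,
#'   `n_draws`, `n_excluded`) with the posterior samples attached as
#'   attribute `"samples"`.
#' @export
among_individual_correlation <- function(fit, mass = 0.95) {
  if (length(fit$specs) != 2 || !fit$include_individual)
    stop("among-individual correlation needs a bivariate fit with a shared ",
         "individual block")
  q_tot <- sum(fit$q_each)
  i <- 1L
  j <- fit$q_each[[1]] + 1L
  v1 <- fit$draws$Sigma[, (i - 1) * q_tot + i]
  v2 <- fit$draws$Sigma[, (j - 1) * q_tot + j]
  cv <- fit$draws$Sigma[, (j - 1) * q_tot + i]
  bad <- v1 <= 0 | v2 <= 0
  r <- cv[!bad] / sqrt(v1[!bad] * v2[!bad])
  stopifnot(all(r >= -1 - 1e-8 & r <= 1 + 1e-8))
  r <- pmin(pmax(r, -1), 1)
  out <- tibble::tibble(parameter = "cor(vod_intercept, fid_intercept)",
                        mean = mean(r),
                        hdi_low = hdi(r, mass)[["low"]],
                        hdi_high = hdi(r, mass)[["high"]],
                        n_draws = length(r), n_excluded = sum(bad))
  attr(out, "samples") <- r
  class(out) <- c("fid_corr", class(out))
  out
}

#' Per-individual conditional modes
#'
#' Point estimates of each individual's random-intercept deviation (the BLUP
#' analogues): by default the posterior mean of the intercept deviation,
#' which is the stable summary for MCMC output; a kernel-density posterior
#' mode is available via `method = "mode"`.
#'
#' @param fit A `fid_fit` with the individual block.
#' @param trait Response name; `NULL` returns every response, in wide format
#'   for a bivariate fit (ready for a convergent-validity scatter).
#' @param method `"mean"` (default) or `"mode"`.
#' @return Tibble `individual_id` plus one estimate column per trait.
#' @export
conditional_modes <- function(fit, trait = NULL, method = c("mean", "mode")) {
  method <- match.arg(method)
  if (!fit$include_individual) stop("fit has no individual block")
  traits <- names(fit$specs)
  if (!is.null(trait)) {
    if (!trait %in% traits) stop("trait ", dQuote(trait),
                                 " absent from fit (has: ",
                                 paste(traits, collapse = ", "), ")")
    traits <- trait
  }
  offs <- c(0, cumsum(fit$q_each))
  est <- lapply(traits, function(tr) {
    r <- match(tr, names(fit$specs))
    dev <- fit$draws$U[, offs[r] + 1L, ]       # individuals x draws
    if (method == "mean") rowMeans(dev)
    else apply(dev, 1, function(x) {
      d <- density(x)
      d$x[which.max(d$y)]
    })
  })
  out <- tibble::tibble(individual_id = dimnames(fit$draws$U)[[1]])
  for (k in seq_along(traits)) out[[traits[k]]] <- est[[k]]
  out
}
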