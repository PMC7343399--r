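# Pointwise out-of-sample predictive accuracy (PSIS-LOO) and log-score
# stacking of Bayesian predictive distributions.
#
# Leave-one-out expected log predictive densities are approximated by
# importance sampling with ratios 1/p(y_i | theta_s); the raw ratios are
# regularized by replacing the largest ~20 percent with expected order
# statistics of a generalized Pareto distribution (GPD) fitted to the tail,
# whose shape k-hat doubles as a reliability diagnostic (k-hat > 0.7 flags an
# unreliable observation).  Stacking weights maximize the summed log score of
# the convex combination of the models' predictive densities on the simplex.

# Profile-posterior GPD fit (Zhang & Stephens 2009) with the usual
# weakly-informative shape regularization for small tails.
.gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  b <- 1 / x[n] +
    (1 - sqrt(m / (seq_len(m) - 0.5))) / (prior_bs * x[ceiling(n / 4 + 0.5)])
  k_of <- function(bi) mean(log1p(-bi * x))
  ks <- vapply(b, k_of, 0)
  l <- n * (log(-b / ks) - ks - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(l - l[j])), 0)
  b_hat <- sum(b * w)
  k_hat <- k_of(b_hat)
  sigma <- -k_hat / b_hat
  k_reg <- (n * k_hat + 10 * 0.5) / (n + 10)  # weak prior pull toward 0.5
  list(khat = k_reg, sigma = sigma)
}

.qgpd <- function(p, khat, sigma) {
  if (abs(khat) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-khat * log1p(-p)) / khat
}

#' Pareto-smoothed importance weights
#'
#' Normalizes a vector of importance log-ratios after replacing the largest
#' ~20 percent (at least 5) by expected order statistics of a generalized
#' Pareto distribution fitted to the tail.  A degenerate tail (all ratios
#' equal) is reported with `khat = NA` ("undefined tail") and unsmoothed
#' normalized weights.
#'
#' @param log_ratios Numeric vector of at least 2 finite log importance
#'   ratios (one per posterior draw).
#' @param tail_frac Fraction of draws treated as the tail (default 0.2,
#'   floored at 5 draws).
#' @return List with `weights` (normalized, summing to 1), `log_weights`
#'   (normalized on the log scale), `khat` and `n_tail`.
#' @export
psis_smooth <- function(log_ratios, tail_frac = 0.2) {
  lr <- log_ratios
  if (length(lr) < 2 || any(!is.finite(lr)))
    stop("psis_smooth needs >= 2 finite log-ratios")
  S <- length(lr)
  lr <- lr - max(lr)
  norm_out <- function(lw, khat, M) {
    lw <- lw - max(lw)
    w <- exp(lw)
    w <- w / sum(w)
    list(weights = w, log_weights = log(w), khat = khat, n_tail = M)
  }
  M <- max(5, floor(tail_frac * S))
  if (S < 10 || M >= S) return(norm_out(lr, NA_real_, 0L))
  ord <- order(lr)
  cutoff <- lr[ord[S - M]]
  tail_lw <- lr[ord[(S - M + 1):S]]
  exceed <- exp(tail_lw) - exp(cutoff)
  if (max(exceed) - min(exceed) < 1e-12 || max(exceed) <= 0)
    return(norm_out(lr, NA_real_, M))
  fitgpd <- .gpd_fit(exceed)
  smoothed <- log(exp(cutoff) +
                    .qgpd((seq_len(M) - 0.5) / M, fitgpd$khat, fitgpd$sigma))
  smoothed <- pmin(smoothed, max(lr))   # never exceed the largest raw ratio
  lw <- lr
  lw[ord[(S - M + 1):S]] <- smoothed
  norm_out(lw, fitgpd$khat, M)
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' PSIS-LOO expected log predictive density
#'
#' Approximates leave-one-out cross-validation for a fitted model from its
#' pointwise log-likelihood matrix: per observation the importance ratios are
#' the reciprocal likelihood draws, PSIS-smoothed, and
#' `elpd_i = log sum_s w_s p(y_i | theta_s)`.  Observations with Pareto
#' `khat > threshold` are counted and surfaced.
#'
#' @param fit A `fid_fit`, or a draws-by-observations log-likelihood matrix.
#' @param response Optional response restriction (see [pointwise_loglik()]).
#' @param khat_threshold Reliability threshold for the Pareto shape
#'   (default 0.7).
#' @return A `fid_loo`: list with `pointwise` (tibble `elpd`, `khat`),
#'   `elpd`, `se`, `n_obs` and `n_high_khat`.
#' @export
loo_elpd <- function(fit, response = NULL, khat_threshold = 0.7) {
  ll <- if (is.matrix(fit)) fit else pointwise_loglik(fit, response)
  if (is.null(ll)) stop("no pointwise log-likelihood available")
  n <- ncol(ll)
  pw <- vapply(seq_len(n), function(i) {
    ps <- psis_smooth(-ll[, i])
    c(elpd = .logsumexp(ps$log_weights + ll[, i]), khat = ps$khat)
  }, c(elpd = 0, khat = 0))
  pointwise <- tibble::tibble(elpd = pw["elpd", ], khat = pw["khat", ])
  out <- list(pointwise = pointwise,
              elpd = sum(pointwise$elpd),
              se = sqrt(n * var(pointwise$elpd)),
              n_obs = n,
              khat_threshold = khat_threshold,
              n_high_khat = sum(pointwise$khat > khat_threshold, na.rm = TRUE))
  class(out) <- "fid_loo"
  out
}

#' @export
print.fid_loo <- function(x, ...) {
  cat("<fid_loo> elpd = ", sprintf("%.1f", x$elpd),
      " (SE ", sprintf("%.1f", x$se), "), n = ", x$n_obs,
      "; khat > ", x$khat_threshold, ": ", x$n_high_khat, "\n", sep = "")
  invisible(x)
}

#' Log-score stacking weights
#'
#' Simplex weights maximizing `sum_i log sum_k w_k exp(elpd_ik)` -- the
#' leave-one-out log score of the stacked predictive distribution.  The
#' objective is concave; it is maximized over a softmax parameterization with
#' analytic gradients to a tight tolerance.  A flat objective (models with
#' identical pointwise elpd) returns uniform weights by the documented tie
#' rule.
#'
#' @param loo_results List of `fid_loo` objects (or a numeric matrix of
#'   pointwise elpd values, observations by models) over identical
#'   observation sets.
#' @param tol Gradient tolerance for the optimizer.
#' @return Named numeric simplex weights (nonnegative, summing to 1).
#' @export
stacking_weights <- function(loo_results, tol = 1e-8) {
  if (is.matrix(loo_results)) {
    lpd <- loo_results
  } else {
    ns <- vapply(loo_results, function(l) l$n_obs, 0L)
    if (length(unique(ns)) != 1)
      stop("models were evaluated on different numbers of observations: ",
           paste(ns, collapse = ", "))
    lpd <- do.call(cbind, lapply(loo_results, function(l) l$pointwise$elpd))
  }
  K <- ncol(lpd)
  if (K < 2) stop("stacking needs at least two models")
  shift <- apply(lpd, 1, max)
  P <- exp(lpd - shift)                       # n x K, rowwise-rescaled
  obj_grad <- function(theta) {
    w <- exp(c(theta, 0))
    w <- w / sum(w)
    den <- as.vector(P %*% w)
    gw <- colSums(P / den)                    # d obj / d w_k
    g <- w[-K] * (gw[-K] - sum(gw * w))       # softmax chain rule
    list(obj = sum(log(den)), grad = g, w = w)
  }
  res <- optim(rep(0, K - 1),
               fn = function(th) -obj_grad(th)$obj,
               gr = function(th) -obj_grad(th)$grad,
               method = "BFGS",
               control = list(maxit = 1000, reltol = tol * 1e-4))
  w <- obj_grad(res$par)$w
  w <- pmax(w, 0)
  w <- w / sum(w)
  names(w) <- colnames(lpd) %||% names(loo_results) %||%
    paste0("model", seq_len(K))
  w
}

#' Is individual identity predictive? Stacking comparison
#'
#' Fits the maximal model and the same model with the entire individual block
#' removed, computes PSIS-LOO for both, and stacks their predictive
#' distributions.  A with-identity weight near 1 means the model including
#' individual identity predicts essentially every observation better.
#'
#' @param data Trial tibble.
#' @param spec A [model_spec()].
#' @param chains,iter,warmup,seed Sampler settings passed to
#'   [fit_univariate()].
#' @return Tibble with one row per model (`with_identity`,
#'   `without_identity`): `elpd`, `se`, `n_high_khat`, `weight` (summing
#'   to 1).  The two `fid_loo` objects are attached as attribute `"loos"`.
#' @export
compare_identity_models <- function(data, spec = model_spec("vod"),
                                    chains = 2, iter = 1200, warmup = 400,
                                    seed = 1L) {
  fit_with <- fit_univariate(data, spec, chains, iter, warmup, seed)
  fit_without <- fit_univariate(data, spec, chains, iter, warmup, seed,
                                include_individual = FALSE)
  loos <- list(with_identity = loo_elpd(fit_with),
               without_identity = loo_elpd(fit_without))
  w <- stacking_weights(loos)
  out <- tibble::tibble(
    model = names(loos),
    elpd = vapply(loos, `[[`, 0, "elpd"),
    se = vapply(loos, `[[`, 0, "se"),
    n_high_khat = vapply(loos, `[[`, 0L, "n_high_khat"),
    weight = as.numeric(w[names(loos)]))
  attr(out, "loos") <- loos
  out
}
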