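# MCMC diagnostics: rank-normalized split-Rhat, bulk/tail effective sample
# sizes (Geyer initial-monotone-sequence estimator on split chains), and the
# highest density interval.  Inputs are iterations x chains matrices.

.split_chains <- function(m) {
  h <- floor(nrow(m) / 2)
  cbind(m[seq_len(h), , drop = FALSE],
        m[(nrow(m) - h + 1):nrow(m), , drop = FALSE])
}

.z_scale <- function(m) {
  r <- rank(m, ties.method = "average")
  matrix(qnorm((r - 3 / 8) / (length(m) + 1 / 4)), nrow(m), ncol(m))
}

.rhat_basic <- function(m) {
  m <- .split_chains(m)
  n <- nrow(m)
  if (n < 2) return(NA_real_)
  W <- mean(apply(m, 2, var))
  B <- n * var(colMeans(m))
  if (W < .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.ess_basic <- function(m) {
  m <- .split_chains(m)
  n <- nrow(m)
  nc <- ncol(m)
  if (n < 4) return(NA_real_)
  # per-chain autocovariance via FFT, lags 0..n-1
  acovs <- apply(m, 2, function(x) {
    x <- x - mean(x)
    M <- 2^ceiling(log2(2 * n))
    f <- stats::fft(c(x, rep(0, M - n)))
    Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (M * n)
  })
  W <- mean(apply(m, 2, var))
  var_plus <- mean(acovs[1, ]) * n / (n - 1)
  if (nc > 1) var_plus <- var_plus + var(colMeans(m))
  if (var_plus < .Machine$double.eps) return(n * nc)
  rho <- 1 - (W - rowMeans(acovs)) / var_plus  # rho[t + 1] is lag t
  # Geyer initial monotone positive sequence over pairs (rho_0 + rho_1), ...
  np <- floor(n / 2) - 1
  P <- rho[seq(1, 2 * np - 1, 2)] + rho[seq(2, 2 * np, 2)]
  k <- which(P <= 0)[1]
  k <- if (is.na(k)) np else max(1L, k - 1L)
  P[seq_len(k)] <- cummin(P[seq_len(k)])
  tau <- max(-1 + 2 * sum(P[seq_len(k)]), 1e-8)
  min(n * nc / tau, n * nc * log10(n * nc))
}

#' Split-Rhat and effective sample sizes for a draws matrix
#'
#' Rank-normalized split-Rhat (the maximum of the bulk and folded variants),
#' bulk ESS on rank-normalized draws, and tail ESS (the smaller ESS of the
#' 5 and 95 percent quantile-exceedance indicators).
#'
#' @param m Numeric matrix, iterations by chains.
#' @return Named numeric: `rhat`, `ess_bulk`, `ess_tail`.
#' @export
mcmc_diagnostics <- function(m) {
  m <- as.matrix(m)
  if (diff(range(m)) < .Machine$double.eps) {
    return(c(rhat = 1, ess_bulk = length(m), ess_tail = length(m)))
  }
  folded <- abs(m - median(m))
  rhat <- max(.rhat_basic(.z_scale(m)), .rhat_basic(.z_scale(folded)))
  ess_bulk <- .ess_basic(.z_scale(m))
  q <- quantile(m, c(0.05, 0.95))
  tail_ess <- function(ind) {
    if (diff(range(ind)) < .Machine$double.eps) return(length(m))
    .ess_basic(.z_scale(ind))
  }
  ess_tail <- min(tail_ess(1 * (m <= q[1])), tail_ess(1 * (m >= q[2])))
  c(rhat = rhat, ess_bulk = ess_bulk, ess_tail = ess_tail)
}

#' Highest density interval of a posterior sample
#'
#' The narrowest contiguous interval containing `ceiling(mass * n)` of the
#' sorted samples.
#'
#' @param samples Numeric vector of at least two finite draws.
#' @param mass Probability mass, in (0, 1).
#' @return Named numeric `c(low, high)` with `low <= high`.
#' @examples
#' hdi(rnorm(1e4))
#' @export
hdi <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 2) stop("hdi needs at least 2 finite samples")
  if (!(mass > 0 && mass < 1)) stop("mass must be in (0, 1)")
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(low = x[1], high = x[n]))
  w <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(w)
  c(low = x[i], high = x[i + m - 1])
}
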