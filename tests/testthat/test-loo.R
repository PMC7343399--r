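test_that("psis returns uniform weights for a degenerate tail", {
  ps <- psis_smooth(rep(0.3, 100))
  expect_equal(ps$weights, rep(1 / 100, 100))
  expect_true(is.na(ps$khat))  # undefined-tail sentinel
  expect_equal(sum(ps$weights), 1)
})

test_that("gpd shape is recovered from simulated generalized Pareto tails", {
  for (shape in c(0.1, 0.4)) {
    u <- withr::with_seed(round(100 * shape), runif(4000))
    x <- ((1 - u)^(-shape) - 1) / shape
    expect_equal(fidtrait:::.gpd_fit(x)$khat, shape, tolerance = 0.1)
  }
})

test_that("psis weights are permutation-equivariant and sum to one", {
  lr <- withr::with_seed(3, rt(800, df = 5))
  ps <- psis_smooth(lr)
  expect_equal(sum(ps$weights), 1)
  perm <- withr::with_seed(4, sample(800))
  ps2 <- psis_smooth(lr[perm])
  expect_equal(ps2$weights, ps$weights[perm], tolerance = 1e-12)
  expect_equal(ps2$khat, ps$khat)
})

test_that("single-observation elpd matches the quadrature oracle", {
  # y ~ N(theta, 1), theta ~ N(0, 0.1^2): LOO elpd of the single observation
  # is the log marginal likelihood, available by quadrature
  y <- 0.7
  post_var <- 1 / (1 / 0.01 + 1)
  post_mean <- post_var * y
  theta <- withr::with_seed(5, rnorm(2e5, post_mean, sqrt(post_var)))
  ll <- matrix(dnorm(y, theta, 1, log = TRUE), ncol = 1)
  res <- loo_elpd(ll)
  oracle <- log(integrate(function(t) dnorm(y, t, 1) * dnorm(t, 0, 0.1),
                          -2, 2, rel.tol = 1e-12)$value)
  expect_equal(res$elpd, oracle, tolerance = 1e-3)
})

test_that("elpd is additive over duplicated observations", {
  d <- simulate_trials(tiny_config(seed = 15))
  f <- quiet_fit(d, model_spec("vod"), chains = 1, iter = 400, warmup = 150,
                 seed = 2)
  ll <- pointwise_loglik(f)
  l1 <- loo_elpd(ll)
  l2 <- loo_elpd(cbind(ll, ll))
  expect_equal(l2$elpd, 2 * l1$elpd, tolerance = 1e-9)
  expect_equal(l2$pointwise$elpd[seq_len(ncol(ll))], l1$pointwise$elpd)
  expect_equal(nrow(l1$pointwise), ncol(ll))
  expect_error(loo_elpd(list()), "log-likelihood")
})

test_that("stacking weight is 1 for a pointwise-dominant model", {
  n <- 40
  base <- withr::with_seed(6, rnorm(n, -1.5, 0.3))
  lpd <- cbind(a = base + 0.4, b = base)  # a better at every observation
  w <- stacking_weights(lpd)
  expect_equal(unname(w["a"]), 1, tolerance = 1e-4)
  expect_equal(sum(w), 1)
  expect_true(all(w >= 0))
})

test_that("identical models split the stacking weight by the tie rule", {
  lpd <- matrix(rep(withr::with_seed(7, rnorm(25)), 2), ncol = 2)
  expect_equal(unname(stacking_weights(lpd)), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("three-model stacking matches an exhaustive grid search", {
  lpd <- withr::with_seed(8, matrix(rnorm(15, -1, 0.8), 5, 3))
  w <- stacking_weights(lpd)
  # grid over the simplex at step 0.001
  g <- seq(0, 1, by = 0.001)
  grid <- expand.grid(w1 = g, w2 = g)
  grid <- grid[grid$w1 + grid$w2 <= 1, ]
  W <- cbind(grid$w1, grid$w2, 1 - grid$w1 - grid$w2)
  P <- exp(lpd)
  obj <- rowSums(log(W %*% t(P)))
  best <- W[which.max(obj), ]
  expect_equal(unname(w), unname(best), tolerance = 0.01)
  # local optimality: no pure model beats the returned weights
  obj_at <- function(wv) sum(log(P %*% wv))
  for (k in 1:3) {
    e <- numeric(3); e[k] <- 1
    expect_gte(obj_at(w) + 1e-6, obj_at(e))
  }
})

test_that("stacking rejects mismatched observation sets", {
  d <- simulate_trials(tiny_config(seed = 16))
  f <- quiet_fit(d, model_spec("vod"), chains = 1, iter = 250, warmup = 100,
                 seed = 2)
  l1 <- loo_elpd(f)
  l2 <- loo_elpd(pointwise_loglik(f)[, 1:10])
  expect_error(stacking_weights(list(l1, l2)), "different numbers")
})

test_that("identity comparison returns a two-model simplex report", {
  d <- simulate_trials(tiny_config(seed = 17))
  cmp <- suppressWarnings(compare_identity_models(
    d, model_spec("fid"), chains = 1, iter = 400, warmup = 150, seed = 3))
  expect_equal(nrow(cmp), 2)
  expect_setequal(cmp$model, c("with_identity", "without_identity"))
  expect_equal(sum(cmp$weight), 1)
  expect_true(all(cmp$weight >= 0))
  loos <- attr(cmp, "loos")
  expect_s3_class(loos$with_identity, "fid_loo")
})
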