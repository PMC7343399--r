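# A fitted object with draws overwritten by known values makes the variance
# decomposition checkable against hand computations.
small_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      d <- simulate_trials(tiny_config(seed = 11))
      fit <<- quiet_fit(d, model_spec("vod"), chains = 1, iter = 220,
                        warmup = 100, seed = 2)
    }
    fit
  }
})

test_that("individual variance equals the quadratic-form oracle", {
  f <- small_fit()
  q <- 5
  # one synthetic draw: intercept SD 0.3, envelope-slope SD 0.1, corr 0.5
  Sg <- diag(c(0.3, 0.1, 0, 0, 0))
  C <- diag(5); C[1, 2] <- C[2, 1] <- 0.5
  Sg <- Sg %*% C %*% Sg
  f$draws$Sigma <- matrix(as.vector(Sg), 1, q * q)
  f$draws$beta$vod <- f$draws$beta$vod[1, , drop = FALSE]
  f$draws$sigma <- f$draws$sigma[1, , drop = FALSE]
  f$draws$tau <- f$draws$tau[1, , drop = FALSE]
  f$chain_id <- 1L
  vc <- variance_components(f)
  Z <- f$dm$vod$Z
  oracle <- mean(vapply(seq_len(nrow(Z)), function(n)
    drop(Z[n, ] %*% Sg %*% Z[n, ]), 0))
  expect_equal(vc$v_individual, oracle, tolerance = 1e-10)

  # intercept-only block with SD s: v_individual = s^2 exactly
  f$draws$Sigma <- matrix(as.vector(diag(c(0.36, 0, 0, 0, 0))), 1, q * q)
  expect_equal(variance_components(f)$v_individual, 0.36, tolerance = 1e-12)

  # zero coefficient vector: no fixed-effect variance
  f$draws$beta$vod[] <- 0
  expect_equal(variance_components(f)$v_fixed, 0, tolerance = 1e-12)
})

test_that("icc reduces to the closed-form ratio on constant draws", {
  f <- small_fit()
  q <- 5
  n_draws <- 4
  f$draws$Sigma <- matrix(rep(as.vector(diag(c(0.5, 0, 0, 0, 0))^2), each = n_draws),
                          n_draws, q * q)
  f$draws$Sigma[, 1] <- 0.5  # v_individual = 0.5 per draw
  f$draws$beta$vod <- matrix(0, n_draws, ncol(f$dm$vod$X),
                             dimnames = list(NULL, colnames(f$dm$vod$X)))
  f$draws$tau <- matrix(0.5, n_draws, 1, dimnames = list(NULL, "vod"))
  f$draws$sigma <- matrix(0.5, n_draws, 1, dimnames = list(NULL, "vod"))
  f$chain_id <- rep(1L, n_draws)
  vc <- variance_components(f)
  # v_date = v_residual = 0.25, v_fixed = 0 -> icc = 0.5 / 1.0
  icc <- enhanced_icc(vc)
  expect_equal(icc$mean, 0.5, tolerance = 1e-12)
  expect_equal(unname(icc$hdi_low), 0.5, tolerance = 1e-12)

  # no individual variance -> icc identically zero
  f0 <- f
  f0$draws$Sigma[] <- 0
  expect_equal(enhanced_icc(variance_components(f0))$mean, 0)

  # all-zero denominator draws are excluded with a count, not NaN
  fz <- f
  fz$draws$Sigma[] <- 0
  fz$draws$tau[] <- 0
  fz$draws$sigma[] <- 0
  fz$draws$Sigma[c(2, 4), 1] <- 0.3  # two informative draws survive
  iccz <- enhanced_icc(variance_components(fz))
  expect_equal(iccz$n_excluded, 2)
  expect_equal(iccz$n_draws, 2)
  expect_false(anyNA(iccz$mean))

  # the without-fixed variant has a larger or equal denominator effect
  f$draws$beta$vod[, "vodd"] <- 1
  vc2 <- variance_components(f)
  expect_lte(enhanced_icc(vc2)$mean, enhanced_icc(vc2, include_fixed = FALSE)$mean)
})

test_that("icc is invariant to a multiplicative shift of the response", {
  d <- simulate_trials(tiny_config(seed = 12))
  d2 <- d
  d2$vod_m <- d2$vod_m * 3  # constant shift of log(VOD)
  f1 <- quiet_fit(d, model_spec("vod"), chains = 2, iter = 700, warmup = 300,
                  seed = 2)
  f2 <- quiet_fit(d2, model_spec("vod"), chains = 2, iter = 700, warmup = 300,
                  seed = 2)
  i1 <- enhanced_icc(variance_components(f1))$mean
  i2 <- enhanced_icc(variance_components(f2))$mean
  expect_equal(i1, i2, tolerance = 0.06)
})

test_that("among-individual correlation standardizes covariance to [-1, 1]", {
  d <- simulate_trials(tiny_config(seed = 13))
  f <- quiet_bifit(d, chains = 1, iter = 250, warmup = 100, seed = 2)
  r <- among_individual_correlation(f)
  smp <- attr(r, "samples")
  expect_true(all(smp >= -1 & smp <= 1))

  # synthetic draws at the boundary cases
  q <- 10
  f2 <- f
  Sg <- diag(q) * 0.2
  f2$draws$Sigma <- matrix(rep(as.vector(Sg), each = 3), 3, q * q)
  f2$chain_id <- rep(1L, 3)
  expect_equal(among_individual_correlation(f2)$mean, 0)

  Sg[1, 6] <- Sg[6, 1] <- 0.2  # cov = sqrt(v1 v2): Cauchy-Schwarz boundary
  f2$draws$Sigma <- matrix(rep(as.vector(Sg), each = 3), 3, q * q)
  expect_equal(among_individual_correlation(f2)$mean, 1)

  expect_error(among_individual_correlation(small_fit()), "bivariate")
})

test_that("conditional modes are one estimate per individual, centred at 0", {
  d <- simulate_trials(tiny_config(seed = 14))
  f <- quiet_bifit(d, chains = 1, iter = 400, warmup = 150, seed = 2)
  cm <- conditional_modes(f)
  expect_equal(nrow(cm), 8)
  expect_named(cm, c("individual_id", "vod", "fid"))
  expect_equal(mean(cm$vod), 0, tolerance = 0.15)
  cm_one <- conditional_modes(f, trait = "fid")
  expect_equal(nrow(cm_one), 8)
  cm_mode <- conditional_modes(f, method = "mode")
  expect_equal(dim(cm_mode), dim(cm))
  expect_error(conditional_modes(f, trait = "latency"), "absent")
})
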