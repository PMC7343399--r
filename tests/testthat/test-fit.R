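test_that("posterior matches an independent MCMC oracle on a reduced model", {
  # random-intercept log-normal model, fitted both by the package sampler
  # (intercept-only individual block) and by JAGS with matched priors
  set.seed(42)
  n_ind <- 8; n_date <- 6; n <- 160
  ind <- sample(n_ind, n, TRUE); date <- sample(n_date, n, TRUE)
  x <- runif(n, 0, 2)
  u <- rnorm(n_ind, 0, 0.4); dd <- rnorm(n_date, 0, 0.15)
  y <- exp(1 + 0.3 * x + u[ind] + dd[date] + rnorm(n, 0, 0.3))
  X <- cbind(1, x)

  res <- withr::with_seed(7, fidtrait:::gibbs_lmm_cpp(
    list(log(y)), list(X), list(matrix(1, n, 1)), ind - 1L, date - 1L,
    n_ind, n_date, TRUE, 100, 3, 10, 2, 10, 12000, 2000))

  mod <- "model{
    for(i in 1:n){ ly[i] ~ dnorm(b0 + b1*x[i] + u[ind[i]] + d[date[i]], prec) }
    for(j in 1:J){ u[j] ~ dnorm(0, precu) }
    for(k in 1:K){ d[k] ~ dnorm(0, precd) }
    b0 ~ dnorm(0, 1e-4); b1 ~ dnorm(0, 1e-4)
    sig ~ dt(0, 0.01, 3) T(0,); prec <- 1/(sig*sig)
    tau ~ dt(0, 0.01, 3) T(0,); precd <- 1/(tau*tau)
    sdu ~ dt(0, 0.01, 2) T(0,); precu <- 1/(sdu*sdu)
  }"
  jm <- rjags::jags.model(
    textConnection(mod),
    data = list(ly = log(y), x = x, ind = ind, date = date,
                n = n, J = n_ind, K = n_date),
    n.chains = 2, n.adapt = 1500, quiet = TRUE)
  js <- as.matrix(rjags::coda.samples(jm, c("b0", "b1", "sig", "tau", "sdu"),
                                      8000))

  expect_lt(abs(mean(res$beta[[1]][, 1]) - mean(js[, "b0"])), 0.06)
  expect_lt(abs(mean(res$beta[[1]][, 2]) - mean(js[, "b1"])), 0.02)
  expect_lt(abs(mean(res$sigma) - mean(js[, "sig"])), 0.01)
  expect_lt(abs(mean(res$tau) - mean(js[, "tau"])), 0.03)
  expect_lt(abs(mean(sqrt(res$Sigma[, 1])) - mean(js[, "sdu"])), 0.08)
  expect_lt(abs(sd(res$beta[[1]][, 2]) - sd(js[, "b1"])), 0.01)
})

test_that("near-deterministic limit recovers the generative coefficients", {
  cfg <- degenerate_config(seed = 3, sigma = 0.05)
  cfg$covariate_frequencies <- sim_config()$covariate_frequencies
  cfg$beta_vod <- sim_config()$beta_vod
  cfg$n_individuals <- 12L; cfg$n_dates <- 10L; cfg$trials_per_observer <- 6L
  d <- simulate_trials(cfg, envelope = "none")
  f <- quiet_fit(d, model_spec("vod"), chains = 2, iter = 800, warmup = 300,
                 seed = 2)
  td <- tidy(f)
  truth <- cfg$beta_vod[sub("^b_", "", td$term)]
  expect_true(all(abs(td$estimate - truth) < 3 * pmax(td$std.error, 0.005)))
})

test_that("pointwise log-likelihood matches a direct density evaluation", {
  d <- simulate_trials(tiny_config(seed = 4))
  f <- quiet_fit(d, model_spec("vod"), chains = 1, iter = 200, warmup = 100,
                 seed = 2)
  ll <- pointwise_loglik(f)
  expect_equal(dim(ll), c(100, nrow(d)))
  dm <- f$dm$vod
  for (s in c(1, 37, 100)) {
    for (i in c(1, 17, nrow(d))) {
      mu <- sum(dm$X[i, ] * f$draws$beta$vod[s, ]) +
        f$draws$d$vod[s, dm$date[i]] +
        sum(dm$Z[i, ] * f$draws$U[dm$ind[i], , s])
      expect_equal(ll[s, i],
                   dlnorm(dm$y[i], mu, f$draws$sigma[s, "vod"], log = TRUE),
                   tolerance = 1e-8)
    }
  }
})

test_that("prior draws match the stated prior moments", {
  pr <- sample_prior(model_spec("vod"), n = 20000, seed = 1)
  fixed <- as.matrix(pr[, startsWith(names(pr), "b_")])
  expect_equal(mean(colMeans(fixed)), 0, tolerance = 2)
  expect_equal(mean(apply(fixed, 2, sd)), 100, tolerance = 3)
  # half-t(3, 10) median is 10 * qt(0.75, 3) = 7.65
  expect_equal(median(pr$sigma), 10 * qt(0.75, 3), tolerance = 0.5)
})

test_that("row order does not change posterior summaries beyond MC error", {
  d <- simulate_trials(tiny_config(seed = 5))
  f1 <- quiet_fit(d, model_spec("vod"), chains = 2, iter = 700, warmup = 300,
                  seed = 2)
  perm <- withr::with_seed(1, sample(nrow(d)))
  f2 <- quiet_fit(d[perm, ], model_spec("vod"), chains = 2, iter = 700,
                  warmup = 300, seed = 3)
  t1 <- tidy(f1); t2 <- tidy(f2)
  expect_equal(t1$estimate, t2$estimate,
               tolerance = 1e-12 + max(4 * t1$std.error / sqrt(50)))
})

test_that("non-convergence is flagged and warned about, never silent", {
  d <- simulate_trials(tiny_config(seed = 6))
  expect_warning(
    f <- fit_univariate(d, model_spec("vod"), chains = 2, iter = 30,
                        warmup = 10, seed = 1),
    "convergence")
  expect_false(f$converged)
  expect_true(all(is.finite(f$diagnostics$rhat)))
})

test_that("univariate and bivariate fits agree on fixed effects", {
  d <- simulate_trials(tiny_config(seed = 7))
  fu <- quiet_fit(d, model_spec("vod"), chains = 2, iter = 800, warmup = 300,
                  seed = 2)
  fb <- quiet_bifit(d, chains = 2, iter = 800, warmup = 300, seed = 2)
  bu <- colMeans(fu$draws$beta$vod)
  bb <- colMeans(fb$draws$beta$vod)
  se <- apply(fu$draws$beta$vod, 2, sd)
  expect_true(all(abs(bu - bb) < 4 * pmax(se, 0.01)))
})

test_that("conditional effects hold non-focal terms fixed", {
  d <- simulate_trials(tiny_config(seed = 8))
  f <- quiet_fit(d, model_spec("vod"), chains = 1, iter = 300, warmup = 100,
                 seed = 2)
  # single retained draw and zeroed interaction: observer curves exactly
  # parallel on the log scale
  f1 <- f
  keep <- 1L
  f1$draws$beta$vod <- f1$draws$beta$vod[keep, , drop = FALSE]
  f1$draws$beta$vod[, "observer_unfamiliar:trial_number"] <- 0
  f1$draws$sigma <- f1$draws$sigma[keep, , drop = FALSE]
  ce <- conditional_effects(f1)
  gap <- log(ce$estimate[ce$observer == "unfamiliar"]) -
    log(ce$estimate[ce$observer == "familiar"])
  expect_equal(diff(range(gap)), 0, tolerance = 1e-10)

  # grid of one point: band is that point's prediction interval
  ce2 <- conditional_effects(f, term = "n_neighbors", grid_n = 1)
  expect_equal(nrow(ce2), 1)
  expect_lte(ce2$lower, ce2$estimate)
  expect_gte(ce2$upper, ce2$estimate)

  expect_error(conditional_effects(f, term = "engaged"), "not in the")
})

test_that("summary table follows the published layout", {
  d <- simulate_trials(tiny_config(seed = 9))
  f <- quiet_fit(d, model_spec("vod"), chains = 1, iter = 300, warmup = 100,
                 seed = 2)
  s <- summarize_fit(f)
  expect_equal(sum(s$group == "Population-level effects"), 12)
  expect_true(any(grepl("^Date", s$group) & s$parameter == "sd(Intercept)"))
  expect_true(any(grepl("^Individual identity", s$group) &
                    s$parameter == "sd(Intercept)"))
  expect_true(any(s$parameter == "Unfamiliar observer (AB)"))
  expect_true(all(s$l95 <= s$u95))
  expect_true(all(c("rhat", "bulk_ess", "tail_ess") %in% names(s)))
})
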