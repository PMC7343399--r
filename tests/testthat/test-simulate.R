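test_that("balanced design has the expected size, counts and schedule", {
  cfg <- sim_config(seed = 1)
  des <- build_design(cfg)
  expect_equal(nrow(des), 1656)  # 69 individuals x 2 observers x 12 trials
  counts <- dplyr::count(des, individual_id, observer)
  expect_true(all(counts$n == 12))
  expect_setequal(unique(des$trial_number), 1:12)
  per_day <- dplyr::count(des, individual_id, date_id)
  expect_lte(max(per_day$n), 2)
  expect_equal(length(unique(des$date_id)), 58)

  mini <- sim_config(n_individuals = 1, n_dates = 2, trials_per_observer = 1,
                     seed = 1)
  dm <- build_design(mini)
  expect_equal(nrow(dm), 2)
  expect_equal(dm$trial_number, c(1L, 1L))
})

test_that("identical config and seed give byte-identical datasets", {
  cfg <- tiny_config(seed = 3)
  expect_identical(simulate_trials(cfg), simulate_trials(cfg))
  expect_identical(build_design(cfg), build_design(cfg))
})

test_that("infeasible scheduling is reported with the binding constraint", {
  cfg <- tiny_config()
  cfg$n_dates <- 2L  # < trials_per_observer, two-per-day cap binds
  expect_error(build_design(cfg), "two-per-day cap")
})

test_that("every simulated row honours the distance envelope", {
  # property over random configurations
  for (s in 1:6) {
    cfg <- sim_config(n_individuals = 5 + s, n_dates = 10,
                      trials_per_observer = 3,
                      sd_range_m = c(runif(1, 1, 4), runif(1, 15, 40)),
                      seed = 100 + s)
    d <- simulate_trials(cfg)
    expect_true(all(d$fid_m > 0 & d$fid_m <= d$vod_m & d$vod_m < d$sd_m))
    expect_equal(d$vodd_m, d$sd_m - d$vod_m)
    expect_equal(d$vodi_m, d$vod_m - d$fid_m)
    expect_true(validate_trials(d))
  }
  # and at the full study scale
  d <- simulate_trials(sim_config(seed = 2))
  expect_true(all(d$fid_m > 0 & d$fid_m <= d$vod_m & d$vod_m < d$sd_m))
})

test_that("neighbor_fled_first never occurs without neighbors", {
  d <- simulate_trials(sim_config(seed = 5))
  expect_false(any(d$n_neighbors == 0 & d$neighbor_fled_first))
})

test_that("degenerate limit: no random structure gives vod = exp(intercept)", {
  d <- simulate_trials(degenerate_config(seed = 2), envelope = "none")
  expect_equal(d$vod_m, rep(exp(1.06), nrow(d)), tolerance = 1e-4)
  expect_equal(d$fid_m, rep(exp(0.67), nrow(d)), tolerance = 1e-4)
})

test_that("mean of log VOD converges to the intercept without covariates", {
  cfg <- degenerate_config(seed = 4, sigma = 0.3)
  cfg$n_individuals <- 40L
  cfg$trials_per_observer <- 12L
  cfg$n_dates <- 30L
  d <- simulate_trials(cfg, envelope = "none")
  mc_se <- 0.3 / sqrt(nrow(d))
  expect_equal(mean(log(d$vod_m)), 1.06, tolerance = 4 * mc_se)
})

test_that("truncation failure reports the offending row parameters", {
  cfg <- degenerate_config(seed = 1, sigma = 0.05, intercept_vod = 25)
  expect_error(simulate_trials(cfg), "truncation failure")
})

test_that("parity split partitions the data and is idempotent", {
  d <- simulate_trials(tiny_config(seed = 6))
  sp <- split_by_trial_parity(d)
  expect_equal(nrow(sp$even) + nrow(sp$odd), nrow(d))
  expect_true(all(sp$even$trial_number %% 2 == 0))
  expect_true(all(sp$odd$trial_number %% 2 == 1))
  expect_equal(nrow(dplyr::intersect(sp$even, sp$odd)), 0)
  resplit <- split_by_trial_parity(sp$odd)
  expect_equal(nrow(resplit$even), 0)
  expect_identical(resplit$odd, sp$odd)
  only1 <- dplyr::filter(d, trial_number == 1)
  sp1 <- split_by_trial_parity(only1)
  expect_equal(nrow(sp1$even), 0)
  expect_identical(sp1$odd, only1)
  expect_error(split_by_trial_parity(d[0, ]), "empty")
  # balanced 12-trial study design halves exactly
  full <- build_design(sim_config(seed = 1))
  spf <- split_by_trial_parity(full)
  expect_equal(nrow(spf$even), 828)
  expect_equal(nrow(spf$odd), 828)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(sd_range_m = c(5, 2)), "sd_range_m")
  expect_error(sim_config(cross_response_corr = 1.2), "cross_response_corr")
  bad_corr <- diag(5); bad_corr[1, 2] <- bad_corr[2, 1] <- 1.5
  expect_error(sim_config(individual_corr = list(vod = bad_corr,
                                                 fid = diag(5))),
               "positive semidefinite")
  expect_error(sim_config(individual_sds = list(vod = rep(-1, 5),
                                                fid = rep(0, 5))),
               "nonnegative")
})

test_that("joint individual covariance preserves blocks and the coupling", {
  cfg <- sim_config(seed = 1)
  jc <- joint_individual_cov(cfg)
  expect_equal(jc$corr[1, 6], 0.875)
  expect_equal(jc$corr[1:5, 1:5], cfg$individual_corr$vod,
               ignore_attr = TRUE)
  ev <- eigen(jc$corr, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("trial CSV and config YAML round-trip faithfully", {
  cfg <- tiny_config(seed = 8)
  d <- simulate_trials(cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trials(d, csv)
  d2 <- read_trials(csv)
  expect_equal(d2, d, tolerance = 1e-12, ignore_attr = TRUE)

  yml <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, yml)
  cfg2 <- read_sim_config(yml)
  expect_equal(cfg2$beta_vod, cfg$beta_vod)
  expect_equal(cfg2$individual_corr$vod, cfg$individual_corr$vod,
               ignore_attr = TRUE)
  expect_identical(simulate_trials(cfg2)$vod_m, simulate_trials(cfg)$vod_m)
})

test_that("trial-record validation catches envelope violations", {
  d <- simulate_trials(tiny_config(seed = 9))
  bad <- d
  bad$fid_m[1] <- bad$vod_m[1] + 1
  expect_error(validate_trials(bad), "envelope")
  bad2 <- d
  bad2$vodd_m[3] <- bad2$vodd_m[3] + 0.5
  expect_error(validate_trials(bad2), "vodd_m")
  bad3 <- dplyr::bind_rows(d, d[1, ])
  expect_error(validate_trials(bad3), "duplicated")
})
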