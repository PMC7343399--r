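test_that("threat profiles reproduce the classification table", {
  p <- classify_response("Alarm bark")
  expect_equal(p$equivalent_to_predator, "yes")
  expect_equal(p$equivalent_to_social_threat, "no")
  expect_equal(p$minimal_threat, "no")
  expect_equal(p$no_threat, "no")

  p <- classify_response("Animal passively displaces")
  expect_equal(unlist(p[, 3:6], use.names = FALSE),
               c("no", "yes", "yes", "no"))

  # explicitly uncertain rows stay three-state, never collapsed
  p <- classify_response("flinch_before_flight")
  expect_true(all(unlist(p[, 3:6]) == "ambiguous"))

  # every category maps to at least one non-"no" column
  tbl <- threat_profiles()
  expect_equal(nrow(tbl), 8)
  expect_true(all(apply(tbl[, 3:6], 1, function(r) any(r != "no"))))
})

test_that("classification is a pure, normalizing lookup", {
  expect_identical(classify_response("  ALARM   BARK "),
                   classify_response("alarm_bark"))
  expect_identical(classify_response("rapid_flight"),
                   classify_response("rapid_flight"))
  expect_error(classify_response("sitting quietly"), "valid categories")
})

test_that("response tally reproduces the published percentages", {
  d <- tibble::tibble(response_category = rep(
    c("passive_displacement", "displacement_with_geck", "flinch_before_flight"),
    c(1637, 16, 3)))
  tl <- tally_responses(d)
  expect_equal(sum(tl$n), 1656)
  get <- function(cat) tl$percent[tl$response_category == cat]
  expect_identical(get("passive_displacement"), 98.85)
  expect_identical(get("displacement_with_geck"), 0.97)
  expect_identical(get("flinch_before_flight"), 0.18)
  # zero-count categories are reported explicitly
  expect_equal(tl$n[tl$response_category == "alarm_bark"], 0)
  # unrounded percentages sum to exactly 100
  expect_equal(sum(100 * tl$n / sum(tl$n)), 100)
})

test_that("tally handles single-category and empty tables", {
  one <- tibble::tibble(response_category = "rapid_flight")
  t1 <- tally_responses(one)
  expect_equal(t1$percent[t1$response_category == "rapid_flight"], 100)
  expect_true(attr(t1, "percentages_defined"))

  t0 <- tally_responses(one[0, ])
  expect_true(all(t0$n == 0))
  expect_true(all(is.na(t0$percent)))
  expect_false(attr(t0, "percentages_defined"))

  expect_error(tally_responses(tibble::tibble(response_category = "tail_up")),
               "unknown")
})

test_that("percentage rounding is half-up to two decimals", {
  expect_equal(fidtrait:::round_half_up(0.125, 2), 0.13)
  expect_equal(fidtrait:::round_half_up(98.845, 2), 98.85)
})
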