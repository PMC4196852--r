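test_that("aggregate tallies patient records exactly", {
  recs <- data.frame(group_label = "group1",
                     n_benign_excisions = c(1L, 2L, 1L),
                     has_melanoma = FALSE,
                     sddi_registered = FALSE,
                     attended_3month = FALSE,
                     attended_12month = FALSE,
                     stringsAsFactors = FALSE)
  st <- aggregate_cohort(recs)$group1
  expect_equal(st$n_unnecessary_patients, 3)
  expect_equal(st$n_multi_patients, 1)
  expect_equal(st$total_unnecessary_excisions, 4)
  expect_equal(st$n_melanomas, 0)

  empty <- aggregate_cohort(recs[0, ])$group1
  expect_true(all(unlist(unclass(empty)[-1]) == 0))
})

test_that("invalid patient records are rejected with row numbers", {
  recs <- data.frame(group_label = c("group1", "group1"),
                     n_benign_excisions = 1L,
                     has_melanoma = FALSE,
                     sddi_registered = c(FALSE, TRUE),  # group1 never registers
                     attended_3month = FALSE,
                     attended_12month = FALSE,
                     stringsAsFactors = FALSE)
  expect_error(validate_patient_records(recs), "rows: 2")
  recs$sddi_registered <- FALSE
  recs$attended_12month <- c(TRUE, FALSE)  # attendance without registration
  expect_error(validate_patient_records(recs), "rows: 1")
  expect_error(aggregate_cohort(recs[, -2]), "lack columns")
})

test_that("patient records round-trip through CSV", {
  recs <- generate_cohort(default_generator_config("group2", "exact_counts"))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(recs, path, row.names = FALSE)
  back <- read_patient_records(path)
  expect_equal(back, recs)
})

test_that("cohort statistics enforce their invariants", {
  expect_error(cohort_stats("group1", 10, 11, 0, 11, 0), "exceeds n_screened")
  expect_error(cohort_stats("group1", 10, 5, 6, 5, 0),
               "exceeds n_unnecessary")
  expect_error(cohort_stats("group1", 10, 5, 0, 4, 0),
               "below n_unnecessary")
  expect_error(cohort_stats("group2", 10, 0, 0, 0, 0,
                            n_sddi_registered = 2, n_attended_3month = 1,
                            n_attended_12month = 2), "attendance")
})

test_that("parameter construction matches the published distribution table", {
  ps1 <- build_parameter_set(group1_observed_stats())
  p <- ps1$params
  expect_equal(p$n_unnecessary$mean, 533)
  expect_equal(c(p$n_unnecessary$lower, p$n_unnecessary$upper), c(490, 577))
  expect_equal(p$prop_multi$a, 33)
  expect_equal(p$prop_multi$b, 500)
  expect_equal(round(p$prop_multi$mean, 2), 0.06)
  expect_equal(round(c(p$prop_multi$lower, p$prop_multi$upper), 2),
               c(0.04, 0.08))
  expect_equal(p$avg_excisions$a, 570)
  expect_equal(p$avg_excisions$b, 533)
  expect_equal(round(p$avg_excisions$mean, 2), 1.07)
  expect_equal(round(c(p$avg_excisions$lower, p$avg_excisions$upper), 2),
               c(0.98, 1.16))
  expect_equal(c(p$n_melanomas$lower, p$n_melanomas$upper), c(54, 87))
  # OD-only arm has no SDDI distributions
  expect_true(p$n_registered$fixed && p$n_registered$a == 0)

  ps2 <- build_parameter_set(group2_observed_stats())
  q <- ps2$params
  expect_equal(c(q$n_unnecessary$lower, q$n_unnecessary$upper), c(62, 96))
  expect_equal(c(q$n_melanomas$lower, q$n_melanomas$upper), c(21, 44))
  expect_equal(c(q$n_registered$lower, q$n_registered$upper), c(103, 146))
  expect_equal(q$prop_12month$a, 90)
  expect_equal(q$prop_12month$b, 34)
  expect_equal(round(q$prop_12month$mean, 2), 0.73)
  expect_equal(round(c(q$prop_12month$lower, q$prop_12month$upper), 2),
               c(0.64, 0.80))
  # SDDI arm: multi-excision proportion degenerate at 0, average at 1
  expect_true(q$prop_multi$fixed && q$prop_multi$a == 0)
  expect_true(q$avg_excisions$fixed && q$avg_excisions$a == 1)
  expect_true(q$prop_3month$fixed && q$prop_3month$a == 1)

  expect_error(build_parameter_set(cohort_stats("group1", 0, 0, 0, 0, 0)),
               "n_screened")
})

test_that("analytic means match Monte Carlo draws and ranges bracket them", {
  ps <- c(build_parameter_set(group1_observed_stats())$params,
          build_parameter_set(group2_observed_stats())$params)
  set.seed(31)
  n <- 1e5
  for (p in ps) {
    expect_lte(p$lower, p$mean)
    expect_gte(p$upper, p$mean)
    if (p$fixed) next
    draws <- sddicost:::sample_param(p, n)
    sd_analytic <- switch(p$dist,
      binom = sqrt(p$a * p$b * (1 - p$b)),
      beta = sqrt(p$a * p$b / ((p$a + p$b)^2 * (p$a + p$b + 1))),
      gamma = sqrt(p$a) / p$b,
      pois = sqrt(p$a),
      pois_trunc = sqrt(p$a))
    expect_lt(abs(mean(draws) - p$mean), 4 * sd_analytic / sqrt(n))
  }
})

test_that("exact synthetic cohorts aggregate back to the published statistics", {
  for (stats in list(group1_observed_stats(), group2_observed_stats())) {
    cfg <- exact_config_from_stats(stats)
    agg <- aggregate_cohort(generate_cohort(cfg))[[stats$group]]
    expect_equal(unclass(agg), unclass(stats))
  }
})
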