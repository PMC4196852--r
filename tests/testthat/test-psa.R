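test_that("plug-in evaluation at parameter means reproduces the published components", {
  out <- iteration_outcome(draw_at_means())
  expect_equal(out[["excision_group1"]], PLUGIN$excision_g1)
  expect_equal(out[["pathology_group1"]], PLUGIN$pathology_g1)
  expect_equal(out[["excision_group2"]], PLUGIN$excision_g2)
  expect_equal(out[["pathology_group2"]], PLUGIN$pathology_g2)
  expect_equal(out[["sddi_group2"]], PLUGIN$sddi_g2)
  expect_equal(out[["total_group1"]], PLUGIN$total_g1)
  expect_equal(out[["difference"]],
               PLUGIN$total_g1 / 70 - PLUGIN$total_g2 / 32)
})

test_that("empty cohorts cost nothing", {
  d <- draw_at_means()
  d$group1[] <- c(0, 0, 1, 1, 0, 0, 0)
  d$group2[] <- c(0, 0, 1, 1, 0, 0, 0)
  out <- iteration_outcome(d)
  expect_true(all(out == 0))
})

test_that("seeded runs are bit-identical and respect n_iterations", {
  a <- run_psa(n_iterations = 300, seed = 99)
  b <- run_psa(n_iterations = 300, seed = 99)
  expect_identical(a$draws, b$draws)
  expect_identical(a$outcomes, b$outcomes)
  expect_false(identical(a$draws, run_psa(n_iterations = 300, seed = 98)$draws))
  single <- run_psa(n_iterations = 1, seed = 5)
  expect_equal(nrow(single$outcomes), 1L)
  expect_error(run_psa(n_iterations = 0), ">= 1")
})

test_that("running the PSA does not disturb the caller's RNG stream", {
  set.seed(424)
  before <- .Random.seed
  invisible(run_psa(n_iterations = 50, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("draw matrix has the eight sampled parameters in declaration order", {
  res <- run_psa(n_iterations = 5, seed = 3)
  expect_equal(colnames(res$draws),
               c("P unnec ex OD", "Multi unnec ex", "N unnec ex", "Mela OD",
                 "P unnec ex SDDI", "Mela SDDI", "P ctrl T0", "P ctrl 12 M"))
  expect_true(all(res$draws[, "Mela OD"] >= 1))
  expect_true(all(res$draws[, "Mela SDDI"] >= 1))
})

test_that("melanoma draws are zero-truncated with negligible moment shift", {
  # truncation moves the Poisson mean by a factor 1/(1 - exp(-lambda))
  for (lambda in c(32, 70))
    expect_lt((lambda / (1 - exp(-lambda)) - lambda) / lambda, 1e-12)
  # truncation is actually enforced at a rate where zeros are common
  small <- build_parameter_set(cohort_stats("group1", 10, 0, 0, 0,
                                            n_melanomas = 1))
  set.seed(8)
  draws <- sddicost:::sample_param(small$params$n_melanomas, 5000)
  expect_true(all(draws >= 1))
  # and the truncated mean matches its analytic value lambda/(1-exp(-lambda))
  expect_lt(abs(mean(draws) - 1 / (1 - exp(-1))), 4 * sqrt(1 / 5000))
})

test_that("group totals are linear in the parameters: PSA means match plug-in", {
  res <- paper_psa()
  n <- res$n_iterations
  for (pair in list(c("total_group1", PLUGIN$total_g1),
                    c("excision_group1", PLUGIN$excision_g1),
                    c("excision_group2", PLUGIN$excision_g2),
                    c("pathology_group1", PLUGIN$pathology_g1),
                    c("sddi_group2", PLUGIN$sddi_g2),
                    c("total_group2", PLUGIN$total_g2))) {
    x <- res$outcomes[, pair[1]]
    expect_lt(abs(mean(x) - as.numeric(pair[2])),
              4 * stats::sd(x) / sqrt(n))
  }
})

test_that("per-melanoma means show the Jensen gap over the ratio of means", {
  res <- paper_psa()
  out <- res$outcomes
  for (g in c("group1", "group2")) {
    ratio_of_means <- mean(out[, paste0("total_", g)]) /
      mean(res$draws[, if (g == "group1") "Mela OD" else "Mela SDDI"])
    expect_gt(mean(out[, paste0("per_melanoma_", g)]), ratio_of_means)
  }
})

test_that("the OD-only arm is more expensive in well over 90% of iterations", {
  expect_gt(prop_group1_more_expensive(paper_psa()), 0.90)
})

test_that("summaries use interpolated percentiles and handle degenerate vectors", {
  res <- fake_psa_result(draws = matrix(rnorm(200), 100),
                         outcomes = cbind(difference = 1:100))
  s <- summarize_psa(res)
  d <- s[s$outcome == "difference", ]
  expect_equal(d$ci_low, 3.475)       # hand-computed interpolated order stat
  expect_equal(d$ci_high, 97.525)
  expect_equal(d$one_sided_low, 5.95)
  expect_equal(d$one_sided_high, 100)
  expect_equal(attr(s, "prop_positive"), 1)

  const <- fake_psa_result(draws = matrix(rnorm(20), 10),
                           outcomes = cbind(difference = rep(7, 10)))
  sc <- summarize_psa(const)
  dc <- sc[sc$outcome == "difference", ]
  expect_true(all(unlist(dc[, -1]) == 7))
  empty <- fake_psa_result(matrix(numeric(0), 0, 2),
                           cbind(difference = numeric(0)))
  expect_error(summarize_psa(empty), "empty")
})

test_that("summary difference rows equal group1 minus group2 row-wise", {
  res <- run_psa(n_iterations = 400, seed = 11)
  expect_equal(res$outcomes[, "difference"],
               res$outcomes[, "per_melanoma_group1"] -
                 res$outcomes[, "per_melanoma_group2"])
  s <- summarize_psa(res)
  m <- function(nm) s$mean[s$outcome == nm]
  expect_equal(m("difference_total"), m("total_group1") - m("total_group2"),
               tolerance = 1e-9)
})
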