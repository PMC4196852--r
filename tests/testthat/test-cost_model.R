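costs <- default_unit_costs()

test_that("excision pathway cost reproduces the tariff decomposition", {
  # frozen expected values, each re-derivable from the billing-event oracle
  cases <- list(list(1L, TRUE, 141.92),
                list(1L, FALSE, 135.53),
                list(0L, TRUE, 0),
                list(2L, FALSE, 162.58))
  for (cs in cases) {
    expect_equal(excision_pathway_cost(cs[[1]], cs[[2]], costs), cs[[3]],
                 tolerance = 1e-9)
    expect_equal(excision_pathway_cost(cs[[1]], cs[[2]], costs),
                 oracle_patient_bill(cs[[1]], cs[[2]], costs),
                 tolerance = 1e-12)
  }
  expect_equal(excision_pathway_cost(0:2, FALSE, costs),
               c(0, 135.53, 162.58))
  expect_error(excision_pathway_cost(-1, TRUE, costs), "non-negative")
  expect_error(excision_pathway_cost(1.5, TRUE, costs), "integer")
})

test_that("pathology block bills once per patient plus two stains per IHC case", {
  expect_equal(pathology_block_cost(79, 32, costs), 6525.82)
  expect_equal(pathology_block_cost(0, 0, costs), 0)
  expect_equal(pathology_block_cost(533, 70, costs), 36614.06)
  expect_equal(pathology_block_cost(533, 70, costs),
               oracle_pathology_bill(533, 70, costs))
  expect_error(pathology_block_cost(-1, 0, costs), "non-negative")
})

test_that("SDDI follow-up bills consultation plus exam per attended visit", {
  expect_equal(sddi_followup_cost(124, 1, 90 / 124, costs), 17609.80)
  expect_equal(sddi_followup_cost(0, 1, 1, costs), 0)
  expect_equal(sddi_followup_cost(1, 1, 0, costs), 104.20)
  # integer-attendance cohorts agree with per-visit enumeration
  expect_equal(sddi_followup_cost(124, 1, 90 / 124, costs),
               oracle_sddi_bill(124, 124, 90, costs))
  expect_error(sddi_followup_cost(10, 1, 1.2, costs), "\\[0, 1\\]")
  expect_error(sddi_followup_cost(10, -0.1, 1, costs), "\\[0, 1\\]")
})

test_that("default tariff table satisfies its invariants", {
  expect_true(all(unlist(unclass(costs)) > 0))
  expect_equal(costs$excision_additional, costs$excision_first / 2)
  expect_error(unit_cost_table(1, 1, 1, 1, 1, 1, 1, -1), "non-negative")
})

test_that("cost operations are monotone, additive and homogeneous", {
  set.seed(71)
  for (rep in 1:25) {
    ct <- random_costs()
    n <- sample(0:5, 1)
    flag <- sample(c(TRUE, FALSE), 1)
    # per-billing-event enumeration oracle
    expect_equal(excision_pathway_cost(n, flag, ct),
                 oracle_patient_bill(n, flag, ct), tolerance = 1e-12)
    np <- sample(0:50, 1); ni <- sample(0:20, 1)
    expect_equal(pathology_block_cost(np, ni, ct),
                 oracle_pathology_bill(np, ni, ct), tolerance = 1e-12)
    # monotone in every count/proportion argument
    expect_gte(excision_pathway_cost(n + 1, flag, ct),
               excision_pathway_cost(n, flag, ct))
    expect_gte(pathology_block_cost(np + 1, ni, ct),
               pathology_block_cost(np, ni, ct))
    p3 <- runif(1); p12 <- runif(1)
    expect_gte(sddi_followup_cost(10, min(p3 + 0.1, 1), p12, ct),
               sddi_followup_cost(10, p3, p12, ct))
    # homogeneity: scaling every tariff by k scales every output by k
    k <- runif(1, 0.5, 3)
    scaled <- do.call(unit_cost_table,
                      lapply(unclass(ct), function(v) v * k))
    expect_equal(excision_pathway_cost(n, flag, scaled),
                 k * excision_pathway_cost(n, flag, ct), tolerance = 1e-12)
    expect_equal(sddi_followup_cost(7, p3, p12, scaled),
                 k * sddi_followup_cost(7, p3, p12, ct), tolerance = 1e-12)
  }
})

test_that("pathway breakdown sums its components and rejects negatives", {
  b <- pathway_cost_breakdown(100.5, 20.25, 3)
  expect_equal(b$total,
               b$excision_component + b$pathology_component +
                 b$sddi_component, tolerance = 1e-9)
  expect_error(pathway_cost_breakdown(-1, 0, 0), "non-negative")
})

test_that("observed extra-costs reproduce the published arithmetic", {
  g1 <- observed_extra_costs(group1_observed_stats(), costs)
  expect_equal(g1$breakdown$excision_component, 76536.01)
  expect_equal(g1$breakdown$pathology_component, 36614.06)
  expect_equal(g1$breakdown$sddi_component, 0)
  g2 <- observed_extra_costs(group2_observed_stats(), costs)
  expect_equal(g2$breakdown$excision_component, 10706.87)
  expect_equal(g2$breakdown$pathology_component, 6525.82)
  expect_equal(g2$breakdown$sddi_component, 17609.80)
  expect_equal(g1$mnm_denominator, 570 / 70)
  expect_equal(g2$mnm_denominator, 79 / 32)
})

test_that("unit costs load from JSON with defaults for absent keys", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"sddi_exam": 30.00}', path)
  ct <- read_unit_costs(path)
  expect_equal(ct$sddi_exam, 30)
  expect_equal(ct$pathology, costs$pathology)
  writeLines('{"not_a_tariff": 1}', path)
  expect_error(read_unit_costs(path), "unknown unit-cost keys")
})
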