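# Independent brute-force oracles used by the property tests. These
# enumerate billing events line by line and must stay independent of the
# closed-form arithmetic in the package.

# Every tariff line item billed for one patient whose n_exc same-day
# excisions all turn out benign (pathology excluded).
oracle_patient_bill <- function(n_exc, bill_od, costs) {
  if (n_exc == 0) return(0)
  events <- c(costs$dermatologist_consult,               # decision consult
              if (bill_od) costs$optical_dermoscopy,     # OD exam fee
              costs$dermatologist_consult,               # excision session
              costs$excision_first,
              rep(costs$excision_additional, n_exc - 1),
              costs$gp_consult)                          # stitch removal
  sum(events)
}

# Pathology block by per-event enumeration: one pathology fee per patient,
# two stain fees per IHC case.
oracle_pathology_bill <- function(n_patients, n_ihc, costs) {
  sum(rep(costs$pathology, n_patients)) +
    sum(rep(costs$immunohistochemistry_per_stain, 2 * n_ihc))
}

# SDDI follow-up by per-visit enumeration for integer attendance counts.
oracle_sddi_bill <- function(n_registered, n_3month, n_12month, costs) {
  visit <- costs$dermatologist_consult + costs$sddi_exam
  sum(rep(visit, n_registered + n_3month + n_12month))
}

# A random (non-default) tariff table for homogeneity/oracle properties.
random_costs <- function() {
  v <- round(stats::runif(8, 1, 120), 2)
  unit_cost_table(v[1], v[2], v[3], v[4], v[5], v[6], v[7], v[8])
}

# Squared multiple correlation computed from the covariance matrix, the
# independent oracle for the importance regression's R-squared.
oracle_r_squared <- function(x, y) {
  s_xx <- stats::cov(x)
  s_xy <- stats::cov(x, y)
  drop(t(s_xy) %*% solve(s_xx, s_xy)) / stats::var(y)
}

# Hand-built draw at the published parameter means (plug-in evaluation).
draw_at_means <- function() {
  list(group1 = c(n_unnecessary = 533, prop_multi = 33 / 533,
                  avg_excisions = 570 / 533, n_melanomas = 70,
                  n_registered = 0, prop_3month = 0, prop_12month = 0),
       group2 = c(n_unnecessary = 79, prop_multi = 0, avg_excisions = 1,
                  n_melanomas = 32, n_registered = 124, prop_3month = 1,
                  prop_12month = 90 / 124))
}

# Minimal psa_result wrapper so summary/importance operations can be tested
# on hand-constructed outcome vectors.
fake_psa_result <- function(draws, outcomes) {
  n <- nrow(outcomes)
  full <- matrix(0, n, length(sddicost:::outcome_names),
                 dimnames = list(NULL, sddicost:::outcome_names))
  full[, colnames(outcomes)] <- outcomes
  structure(list(draws = draws, outcomes = full,
                 params = NULL, costs = default_unit_costs(),
                 seed = 0L, n_iterations = n),
            class = "psa_result")
}
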