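#' Billing-pathway cost of a benign-excision patient
#'
#' Cost of the standard excision pathway for one patient whose suspicious
#' lesions are excised the same day and turn out benign. The pathway is:
#' a first consultation at which the decision to excise is taken (optionally
#' with an optical dermoscopy examination billed on top), a second
#' consultation at which the excision is performed, the surgical fees (first
#' excision at full tariff, each further same-day excision at the reduced
#' tariff), and a general practitioner visit for stitch removal. Pathology
#' is billed separately (see [pathology_block_cost()]).
#'
#' @param n_excisions_same_day Number of lesions excised in the session
#'   (non-negative integer; 0 returns 0). May be a vector.
#' @param bill_optical_dermoscopy Should the optical dermoscopy fee be billed
#'   at the first consultation? In the published comparison it is billed in
#'   the optical-dermoscopy-only arm (Group 1) and not in the SDDI arm.
#' @param costs A [unit_cost_table()].
#'
#' @return Cost in euros, same length as `n_excisions_same_day`.
#' @export
#' @examples
#' excision_pathway_cost(1, TRUE)   # 141.92 under the 2012 tariffs
#' excision_pathway_cost(1, FALSE)  # 135.53
excision_pathway_cost <- function(n_excisions_same_day,
                                  bill_optical_dermoscopy,
                                  costs = default_unit_costs()) {
  n <- check_count(n_excisions_same_day, "n_excisions_same_day",
                   allow_vector = TRUE)
  check_flag(bill_optical_dermoscopy, "bill_optical_dermoscopy")
  stopifnot(inherits(costs, "unit_cost_table"))
  base <- 2 * costs$dermatologist_consult + costs$gp_consult +
    if (bill_optical_dermoscopy) costs$optical_dermoscopy else 0
  ifelse(n == 0, 0,
         base + costs$excision_first + (n - 1) * costs$excision_additional)
}

#' Pathology and immunohistochemistry block cost
#'
#' Pathology is billed once per patient-session however many lesions were
#' excised. Immunohistochemistry (two immunostains: HMB45 plus a melanocytic
#' antibody cocktail) is assumed performed on as many benign naevi as there
#' were melanomas in the group, so `n_ihc_cases` is typically the group's
#' melanoma count.
#'
#' @param n_patients_with_benign_pathology Patients with at least one benign
#'   lesion sent to pathology (non-negative integer, vectorised).
#' @param n_ihc_cases Benign cases receiving the two-immunostain work-up
#'   (non-negative integer, vectorised).
#' @param costs A [unit_cost_table()].
#' @return Cost in euros.
#' @export
#' @examples
#' pathology_block_cost(79, 32)  # 6525.82
pathology_block_cost <- function(n_patients_with_benign_pathology,
                                 n_ihc_cases,
                                 costs = default_unit_costs()) {
  np <- check_count(n_patients_with_benign_pathology,
                    "n_patients_with_benign_pathology", allow_vector = TRUE)
  ni <- check_count(n_ihc_cases, "n_ihc_cases", allow_vector = TRUE)
  stopifnot(inherits(costs, "unit_cost_table"))
  np * costs$pathology + ni * 2 * costs$immunohistochemistry_per_stain
}

#' SDDI follow-up cost
#'
#' Each attended monitoring visit is billed as a dermatologist consultation
#' plus the SDDI examination fee. The canonical visit schedule is: an
#' inclusion visit (all registered patients), a 3-month visit (a proportion
#' `prop_3month` of registered patients, 1 in the published cohort), and a
#' 12-month visit (`prop_12month` of registered patients — the registered
#' cohort, not the still-monitored subset, is the denominator).
#'
#' @param n_registered Patients registered for SDDI monitoring at inclusion
#'   (non-negative integer, vectorised).
#' @param prop_3month Proportion attending the 3-month visit, in `[0, 1]`.
#' @param prop_12month Proportion attending the 12-month visit, in `[0, 1]`.
#' @param costs A [unit_cost_table()].
#' @return Cost in euros.
#' @export
#' @examples
#' sddi_followup_cost(124, 1, 90 / 124)  # 17609.80
sddi_followup_cost <- function(n_registered,
                               prop_3month,
                               prop_12month,
                               costs = default_unit_costs()) {
  n <- check_count(n_registered, "n_registered", allow_vector = TRUE)
  p3 <- check_fraction(prop_3month, "prop_3month", allow_vector = TRUE)
  p12 <- check_fraction(prop_12month, "prop_12month", allow_vector = TRUE)
  stopifnot(inherits(costs, "unit_cost_table"))
  visit <- costs$dermatologist_consult + costs$sddi_exam
  n * visit * (1 + p3 + p12)
}

#' Component breakdown of a pathway cost
#'
#' Bundles the three extra-cost components tracked by the model — excision
#' (consultations, dermoscopy exams, surgery, GP visit), pathology
#' (pathology plus immunohistochemistry) and SDDI follow-up — together with
#' their total.
#'
#' @param excision_component,pathology_component,sddi_component Component
#'   costs in euros, each non-negative.
#' @return An object of class `pathway_cost_breakdown`.
#' @export
pathway_cost_breakdown <- function(excision_component,
                                   pathology_component,
                                   sddi_component = 0) {
  comp <- c(excision = excision_component, pathology = pathology_component,
            sddi = sddi_component)
  if (any(!is.finite(comp)) || any(comp < 0))
    stop("cost components must be finite and non-negative", call. = FALSE)
  structure(list(excision_component = excision_component,
                 pathology_component = pathology_component,
                 sddi_component = sddi_component,
                 total = excision_component + pathology_component +
                   sddi_component),
            class = "pathway_cost_breakdown")
}

#' @export
print.pathway_cost_breakdown <- function(x, ...) {
  cat(sprintf("Excisions  %12.2f\nPathology  %12.2f\nSDDI       %12.2f\nTotal      %12.2f\n",
              x$excision_component, x$pathology_component, x$sddi_component,
              x$total))
  invisible(x)
}

#' Observed extra-costs of a cohort
#'
#' Deterministic (plug-in) extra-cost accounting for one study arm from its
#' observed sufficient statistics: every benign-excision patient is billed
#' one excision pathway, every multi-excision patient one additional reduced
#' excision fee, the pathology block covers all benign-excision patients with
#' immunohistochemistry on as many cases as there were melanomas, and SDDI
#' visits are billed per the canonical schedule.
#'
#' @param stats A [cohort_stats()] object.
#' @param costs A [unit_cost_table()].
#' @return A list with the [pathway_cost_breakdown()], the extra-cost per
#'   melanoma diagnosed, and the melanoma to non-melanoma excision ratio
#'   (`mnm_denominator`: benign excisions per melanoma, the "1/x" figure).
#' @export
#' @examples
#' observed_extra_costs(group2_observed_stats())
observed_extra_costs <- function(stats, costs = default_unit_costs()) {
  stopifnot(inherits(stats, "cohort_stats"))
  bill_od <- stats$n_sddi_registered == 0  # OD fee billed in the OD-only arm
  excision <- stats$n_unnecessary_patients *
    excision_pathway_cost(1, bill_od, costs) +
    stats$n_multi_patients * costs$excision_additional
  pathology <- pathology_block_cost(stats$n_unnecessary_patients,
                                    stats$n_melanomas, costs)
  p3 <- if (stats$n_sddi_registered > 0)
    stats$n_attended_3month / stats$n_sddi_registered else 0
  p12 <- if (stats$n_sddi_registered > 0)
    stats$n_attended_12month / stats$n_sddi_registered else 0
  sddi <- sddi_followup_cost(stats$n_sddi_registered, p3, p12, costs)
  breakdown <- pathway_cost_breakdown(excision, pathology, sddi)
  list(
    breakdown = breakdown,
    per_melanoma = if (stats$n_melanomas > 0)
      breakdown$total / stats$n_melanomas else NA_real_,
    mnm_denominator = if (stats$n_melanomas > 0)
      stats$total_unnecessary_excisions / stats$n_melanomas else NA_real_
  )
}
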