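#' Per-group observed sufficient statistics
#'
#' The eight counts that summarise one study arm and fully determine both
#' the deterministic cost accounting and the parameter distributions of the
#' probabilistic sensitivity analysis.
#'
#' @param group Arm label, `"group1"` (optical dermoscopy only) or
#'   `"group2"` (optical dermoscopy with selective SDDI).
#' @param n_screened Patients examined for melanoma detection.
#' @param n_unnecessary_patients Patients with at least one benign
#'   ("unnecessary") excision.
#' @param n_multi_patients Patients with more than one same-day benign
#'   excision.
#' @param total_unnecessary_excisions Total benign excisions.
#' @param n_melanomas Melanomas diagnosed.
#' @param n_sddi_registered Patients registered for SDDI monitoring at
#'   inclusion (0 in the OD-only arm).
#' @param n_attended_3month,n_attended_12month Registered patients attending
#'   the 3-month and 12-month monitoring visits.
#'
#' @return An object of class `cohort_stats`.
#' @seealso [group1_observed_stats()], [group2_observed_stats()],
#'   [aggregate_cohort()], [build_parameter_set()]
#' @export
cohort_stats <- function(group,
                         n_screened,
                         n_unnecessary_patients,
                         n_multi_patients,
                         total_unnecessary_excisions,
                         n_melanomas,
                         n_sddi_registered = 0,
                         n_attended_3month = 0,
                         n_attended_12month = 0) {
  group <- match.arg(group, c("group1", "group2"))
  x <- list(group = group,
            n_screened = check_count(n_screened, "n_screened"),
            n_unnecessary_patients =
              check_count(n_unnecessary_patients, "n_unnecessary_patients"),
            n_multi_patients =
              check_count(n_multi_patients, "n_multi_patients"),
            total_unnecessary_excisions =
              check_count(total_unnecessary_excisions,
                          "total_unnecessary_excisions"),
            n_melanomas = check_count(n_melanomas, "n_melanomas"),
            n_sddi_registered =
              check_count(n_sddi_registered, "n_sddi_registered"),
            n_attended_3month =
              check_count(n_attended_3month, "n_attended_3month"),
            n_attended_12month =
              check_count(n_attended_12month, "n_attended_12month"))
  if (x$n_unnecessary_patients > x$n_screened)
    stop("n_unnecessary_patients exceeds n_screened", call. = FALSE)
  if (x$n_multi_patients > x$n_unnecessary_patients)
    stop("n_multi_patients exceeds n_unnecessary_patients", call. = FALSE)
  if (x$total_unnecessary_excisions < x$n_unnecessary_patients)
    stop("total_unnecessary_excisions below n_unnecessary_patients",
         call. = FALSE)
  if (x$n_attended_3month > x$n_sddi_registered ||
      x$n_attended_12month > x$n_attended_3month)
    stop("attendance counts must satisfy 12-month <= 3-month <= registered",
         call. = FALSE)
  structure(x, class = "cohort_stats")
}

#' Published observed statistics, optical-dermoscopy-only arm
#'
#' 7,434 patients screened over one year; 533 patients with benign
#' excisions (33 of them multi-excision, 570 benign excisions in total) and
#' 70 melanomas.
#'
#' @return A [cohort_stats()].
#' @export
group1_observed_stats <- function() {
  cohort_stats("group1",
               n_screened = 7434,
               n_unnecessary_patients = 533,
               n_multi_patients = 33,
               total_unnecessary_excisions = 570,
               n_melanomas = 70)
}

#' Published observed statistics, selective-SDDI arm
#'
#' 1,926 patients screened; 79 patients with one benign excision each, 32
#' melanomas, 124 patients registered for SDDI monitoring of whom all
#' attended the 3-month visit and 90 the 12-month visit.
#'
#' @return A [cohort_stats()].
#' @export
group2_observed_stats <- function() {
  cohort_stats("group2",
               n_screened = 1926,
               n_unnecessary_patients = 79,
               n_multi_patients = 0,
               total_unnecessary_excisions = 79,
               n_melanomas = 32,
               n_sddi_registered = 124,
               n_attended_3month = 124,
               n_attended_12month = 90)
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat("Cohort statistics (", x$group, ")\n", sep = "")
  for (nm in setdiff(names(x), "group"))
    cat(sprintf("  %-28s %6d\n", nm, x[[nm]]))
  invisible(x)
}

# ---- patient records ------------------------------------------------------

patient_record_columns <- c("group_label", "n_benign_excisions",
                            "has_melanoma", "sddi_registered",
                            "attended_3month", "attended_12month")

#' Validate a patient-record table
#'
#' A patient-record table has one row per screened patient with columns
#' `group_label` (`"group1"`/`"group2"`), `n_benign_excisions` (count),
#' and logical `has_melanoma`, `sddi_registered`, `attended_3month`,
#' `attended_12month`. Invariants: group1 patients are never
#' SDDI-registered, and attendance flags require registration.
#'
#' @param records A data frame of patient records.
#' @return The validated data frame, invisibly.
#' @export
validate_patient_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(patient_record_columns, names(records))
  if (length(missing_cols))
    stop("patient records lack columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0) return(invisible(records))
  bad_group <- !records$group_label %in% c("group1", "group2")
  check_count(records$n_benign_excisions, "n_benign_excisions",
              allow_vector = TRUE)
  bad_reg <- records$group_label == "group1" & records$sddi_registered
  bad_attend <- (!records$sddi_registered) &
    (records$attended_3month | records$attended_12month)
  bad_order <- records$attended_12month & !records$attended_3month
  bad <- which(bad_group | bad_reg | bad_attend | bad_order)
  if (length(bad))
    stop("invalid patient records at rows: ",
         paste(utils::head(bad, 20), collapse = ", "),
         if (length(bad) > 20) " ..." else "", call. = FALSE)
  invisible(records)
}

#' Read patient records from CSV
#'
#' One row per patient, columns as in [validate_patient_records()].
#'
#' @param path Path to a CSV file.
#' @return A validated patient-record data frame.
#' @export
read_patient_records <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in c("has_melanoma", "sddi_registered", "attended_3month",
               "attended_12month"))
    if (nm %in% names(records)) records[[nm]] <- as.logical(records[[nm]])
  validate_patient_records(records)
  records
}

#' Aggregate patient records into per-group cohort statistics
#'
#' Exact tallies: `n_unnecessary_patients` counts patients with at least one
#' benign excision, `n_multi_patients` those with more than one,
#' `total_unnecessary_excisions` sums the per-patient counts, and the SDDI
#' counts tally registration and attendance flags.
#'
#' @param records A patient-record data frame (see
#'   [validate_patient_records()]); may contain one or both groups.
#' @return A named list of [cohort_stats()], one entry per group present
#'   (all-zero statistics for an empty input, keyed `"group1"`).
#' @export
#' @examples
#' recs <- generate_cohort(default_generator_config("group2"), seed = 1)
#' aggregate_cohort(recs)$group2
aggregate_cohort <- function(records) {
  validate_patient_records(records)
  if (nrow(records) == 0) {
    return(list(group1 = cohort_stats("group1", 0, 0, 0, 0, 0)))
  }
  groups <- sort(unique(records$group_label))
  out <- lapply(groups, function(g) {
    r <- records[records$group_label == g, , drop = FALSE]
    benign <- r$n_benign_excisions
    cohort_stats(
      g,
      n_screened = nrow(r),
      n_unnecessary_patients = sum(benign >= 1),
      n_multi_patients = sum(benign > 1),
      total_unnecessary_excisions = sum(benign),
      n_melanomas = sum(r$has_melanoma),
      n_sddi_registered = sum(r$sddi_registered),
      n_attended_3month = sum(r$attended_3month),
      n_attended_12month = sum(r$attended_12month)
    )
  })
  names(out) <- groups
  out
}
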