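#' Unit-cost tariff table
#'
#' Container for the eight reimbursement tariffs (in euros) that drive all
#' cost arithmetic in the model: consultations, excision surgery, pathology,
#' immunohistochemistry, optical dermoscopy and the sequential digital
#' dermoscopy imaging (SDDI) examination.
#'
#' The bundled defaults ([default_unit_costs()]) are the official Belgian
#' 2012 tariffs. Under those defaults a second (or third) same-day excision
#' is billed at half the first-excision fee; user-supplied tables are not
#' required to preserve that relationship.
#'
#' @param dermatologist_consult Dermatologist's consultation fee.
#' @param gp_consult General practitioner's consultation fee (stitch removal
#'   and scar check after surgery).
#' @param excision_first Cutaneous tumour excision with suture, first lesion
#'   of the session.
#' @param excision_additional Each further same-day excision.
#' @param pathology Pathology fee, billed once per patient-session regardless
#'   of the number of lesions.
#' @param immunohistochemistry_per_stain Fee per immunostain.
#' @param optical_dermoscopy Optical dermoscopy examination fee.
#' @param sddi_exam Sequential digital dermoscopy imaging examination fee
#'   (added on top of the consultation fee at each monitoring visit).
#'
#' @return An object of class `unit_cost_table` (a named list of
#'   non-negative numeric scalars; a zero switches a fee off, e.g. when
#'   modelling a non-reimbursed SDDI examination).
#' @seealso [default_unit_costs()], [read_unit_costs()]
#' @export
#' @examples
#' costs <- default_unit_costs()
#' costs$excision_first
unit_cost_table <- function(dermatologist_consult,
                            gp_consult,
                            excision_first,
                            excision_additional,
                            pathology,
                            immunohistochemistry_per_stain,
                            optical_dermoscopy,
                            sddi_exam) {
  x <- list(
    dermatologist_consult = dermatologist_consult,
    gp_consult = gp_consult,
    excision_first = excision_first,
    excision_additional = excision_additional,
    pathology = pathology,
    immunohistochemistry_per_stain = immunohistochemistry_per_stain,
    optical_dermoscopy = optical_dermoscopy,
    sddi_exam = sddi_exam
  )
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("unit cost `", nm, "` must be a single non-negative number",
           call. = FALSE)
    x[[nm]] <- as.numeric(v)
  }
  structure(x, class = "unit_cost_table")
}

#' Default Belgian 2012 tariffs
#'
#' The official 2012 Belgian unit costs, in euros, used throughout the
#' published analysis.
#'
#' @return A [unit_cost_table()].
#' @export
default_unit_costs <- function() {
  unit_cost_table(
    dermatologist_consult = 28.88,
    gp_consult = 23.67,
    excision_first = 54.10,
    excision_additional = 27.05,
    pathology = 62.02,
    immunohistochemistry_per_stain = 25.41,
    optical_dermoscopy = 6.39,
    sddi_exam = 23.22
  )
}

#' Read a unit-cost table from a JSON file
#'
#' Keys mirror the [unit_cost_table()] field names; absent keys fall back to
#' the bundled Belgian 2012 defaults, unknown keys are an error.
#'
#' @param path Path to a JSON file.
#' @return A [unit_cost_table()].
#' @export
read_unit_costs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unit_costs_from_list(raw)
}

# Merge a plain list of overrides onto the default tariffs.
unit_costs_from_list <- function(raw) {
  defaults <- unclass(default_unit_costs())
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown unit-cost keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults[names(raw)] <- raw
  do.call(unit_cost_table, defaults)
}

#' @export
print.unit_cost_table <- function(x, ...) {
  cat("Unit-cost tariff table (EUR)\n")
  for (nm in names(x)) cat(sprintf("  %-32s %8.2f\n", nm, x[[nm]]))
  invisible(x)
}
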