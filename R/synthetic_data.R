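#' Synthetic-cohort generator configuration
#'
#' Describes the patient-level data-generating process whose aggregation
#' yields the sufficient statistics the model consumes: each screened
#' patient independently has an unnecessary (benign) excision with
#' probability `p_unnecessary`; excised patients are multi-excision with
#' probability `p_multi_given_unnecessary` (a multi-excision patient has a
#' third same-day excision with probability `p_third_excision`, otherwise
#' two); melanoma patients are generated disjointly from the benign-excision
#' patients with an expected count of `melanoma_rate` per cohort; remaining
#' patients are registered for SDDI monitoring with probability
#' `p_register`, all registered patients attend the 3-month visit, and each
#' attends the 12-month visit with probability `p_attend_12month`.
#'
#' In `"exact_counts"` mode the generator emits a deterministic record list
#' whose tallies equal the rounded expected counts (and, if
#' `n_excisions_total` is given, distributes third excisions among
#' multi-excision patients to hit that total exactly). In `"stochastic"`
#' mode every quantity is drawn from the sampling distribution above.
#'
#' @param group `"group1"` or `"group2"`.
#' @param n_screened Cohort size (positive integer).
#' @param p_unnecessary Probability a screened patient has a benign excision.
#' @param p_multi_given_unnecessary Probability an excised patient has more
#'   than one same-day excision (OD-only arm; 0 in the SDDI arm).
#' @param p_third_excision Probability a multi-excision patient has three
#'   rather than two excisions (stochastic mode).
#' @param melanoma_rate Expected melanomas per cohort (Poisson).
#' @param p_register Probability a screened patient who is neither excised
#'   nor a melanoma case is registered for SDDI monitoring.
#' @param p_attend_12month Probability a registered patient attends the
#'   12-month visit.
#' @param n_excisions_total Optional exact-mode target for the total number
#'   of benign excisions.
#' @param mode `"stochastic"` or `"exact_counts"`.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(group,
                             n_screened,
                             p_unnecessary,
                             p_multi_given_unnecessary = 0,
                             p_third_excision = 0,
                             melanoma_rate = 0,
                             p_register = 0,
                             p_attend_12month = 0,
                             n_excisions_total = NULL,
                             mode = c("stochastic", "exact_counts")) {
  group <- match.arg(group, c("group1", "group2"))
  mode <- match.arg(mode)
  n_screened <- check_count(n_screened, "n_screened")
  if (n_screened < 1) stop("n_screened must be positive", call. = FALSE)
  check_fraction(p_unnecessary, "p_unnecessary")
  check_fraction(p_multi_given_unnecessary, "p_multi_given_unnecessary")
  check_fraction(p_third_excision, "p_third_excision")
  check_fraction(p_register, "p_register")
  check_fraction(p_attend_12month, "p_attend_12month")
  if (!is.numeric(melanoma_rate) || melanoma_rate < 0)
    stop("melanoma_rate must be a non-negative number", call. = FALSE)
  if (group == "group1" && (p_register > 0))
    stop("group1 cohorts cannot register patients for SDDI", call. = FALSE)
  if (!is.null(n_excisions_total))
    n_excisions_total <- check_count(n_excisions_total, "n_excisions_total")
  structure(list(group = group, n_screened = n_screened,
                 p_unnecessary = p_unnecessary,
                 p_multi_given_unnecessary = p_multi_given_unnecessary,
                 p_third_excision = p_third_excision,
                 melanoma_rate = melanoma_rate,
                 p_register = p_register,
                 p_attend_12month = p_attend_12month,
                 n_excisions_total = n_excisions_total,
                 mode = mode),
            class = "generator_config")
}

#' Generator configurations calibrated to the published cohorts
#'
#' Group 1: 7,434 screened, benign-excision probability 533/7434,
#' multi-excision probability 33/533 with a third excision for 4/33 of
#' multi-excision patients (so the expected benign-excision total is 570),
#' 70 expected melanomas. Group 2: 1,926 screened, benign-excision
#' probability 79/1926, 32 expected melanomas, registration probability
#' 124/1815 among the remaining patients, 12-month attendance 90/124.
#'
#' @param group `"group1"` or `"group2"`.
#' @param mode Generation mode, as in [generator_config()].
#' @return A [generator_config()].
#' @export
default_generator_config <- function(group = c("group1", "group2"),
                                     mode = c("stochastic", "exact_counts")) {
  group <- match.arg(group)
  mode <- match.arg(mode)
  if (group == "group1") {
    generator_config("group1", n_screened = 7434,
                     p_unnecessary = 533 / 7434,
                     p_multi_given_unnecessary = 33 / 533,
                     p_third_excision = 4 / 33,
                     melanoma_rate = 70,
                     n_excisions_total = 570,
                     mode = mode)
  } else {
    generator_config("group2", n_screened = 1926,
                     p_unnecessary = 79 / 1926,
                     melanoma_rate = 32,
                     p_register = 124 / (1926 - 79 - 32),
                     p_attend_12month = 90 / 124,
                     n_excisions_total = 79,
                     mode = mode)
  }
}

#' Exact-mode configuration reproducing given cohort statistics
#'
#' Inverts [aggregate_cohort()]: builds a [generator_config()] whose
#' `"exact_counts"` cohort aggregates back to `stats` exactly. Requires all
#' registered patients to have attended the 3-month visit (the published
#' situation); other 3-month patterns are not representable.
#'
#' @param stats A [cohort_stats()] object.
#' @return A [generator_config()] in `"exact_counts"` mode.
#' @export
exact_config_from_stats <- function(stats) {
  stopifnot(inherits(stats, "cohort_stats"))
  if (stats$n_attended_3month != stats$n_sddi_registered)
    stop("exact mode requires full 3-month attendance", call. = FALSE)
  remainder <- stats$n_screened - stats$n_unnecessary_patients -
    stats$n_melanomas
  if (remainder < stats$n_sddi_registered)
    stop("not enough non-excised patients to register for SDDI",
         call. = FALSE)
  generator_config(
    group = stats$group,
    n_screened = stats$n_screened,
    p_unnecessary = stats$n_unnecessary_patients / stats$n_screened,
    p_multi_given_unnecessary =
      if (stats$n_unnecessary_patients > 0)
        stats$n_multi_patients / stats$n_unnecessary_patients else 0,
    melanoma_rate = stats$n_melanomas,
    p_register = if (remainder > 0) stats$n_sddi_registered / remainder else 0,
    p_attend_12month = if (stats$n_sddi_registered > 0)
      stats$n_attended_12month / stats$n_sddi_registered else 0,
    n_excisions_total = stats$total_unnecessary_excisions,
    mode = "exact_counts")
}

#' Generate a synthetic patient-level cohort
#'
#' @param config A [generator_config()].
#' @param seed Optional integer seed (stochastic mode); the global RNG
#'   stream is used when `NULL`.
#' @return A patient-record data frame (see [validate_patient_records()])
#'   with one row per screened patient.
#' @export
#' @examples
#' recs <- generate_cohort(default_generator_config("group1", "exact_counts"))
#' aggregate_cohort(recs)$group1
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed, kind = "Mersenne-Twister")
  }
  if (config$mode == "exact_counts")
    generate_exact(config)
  else
    generate_stochastic(config)
}

generate_exact <- function(config) {
  n <- config$n_screened
  n_unnec <- as.integer(round(n * config$p_unnecessary))
  n_multi <- as.integer(round(n_unnec * config$p_multi_given_unnecessary))
  n_mel <- as.integer(round(config$melanoma_rate))
  total <- if (!is.null(config$n_excisions_total)) config$n_excisions_total
           else n_unnec + n_multi  # every multi patient gets the minimal 2
  extra <- total - n_unnec
  if (extra < n_multi || extra > 2L * n_multi)
    stop("infeasible exact counts: ", total, " total excisions cannot be ",
         "spread over ", n_unnec, " patients with ", n_multi,
         " multi-excision patients (2 or 3 excisions each)", call. = FALSE)
  n_triple <- extra - n_multi          # multi patients with 3 excisions
  remainder <- n - n_unnec - n_mel
  if (remainder < 0)
    stop("infeasible exact counts: excised plus melanoma patients exceed ",
         "n_screened", call. = FALSE)
  n_reg <- as.integer(round(remainder * config$p_register))
  if (n_reg > remainder)
    stop("infeasible exact counts: more registered than eligible patients",
         call. = FALSE)
  n_12 <- as.integer(round(n_reg * config$p_attend_12month))
  excisions <- c(rep(3L, n_triple), rep(2L, n_multi - n_triple),
                 rep(1L, n_unnec - n_multi))
  new_records(
    group = config$group,
    n_benign = c(excisions, integer(n_mel), integer(remainder)),
    melanoma = c(rep(FALSE, n_unnec), rep(TRUE, n_mel),
                 rep(FALSE, remainder)),
    registered = c(rep(FALSE, n_unnec + n_mel), rep(TRUE, n_reg),
                   rep(FALSE, remainder - n_reg)),
    attended_12 = c(rep(FALSE, n_unnec + n_mel), rep(TRUE, n_12),
                    rep(FALSE, remainder - n_12)))
}

generate_stochastic <- function(config) {
  n <- config$n_screened
  unnec <- stats::rbinom(n, 1L, config$p_unnecessary) == 1L
  n_unnec <- sum(unnec)
  multi <- logical(n)
  multi[unnec] <- stats::rbinom(n_unnec, 1L,
                                config$p_multi_given_unnecessary) == 1L
  third <- logical(n)
  third[multi] <- stats::rbinom(sum(multi), 1L,
                                config$p_third_excision) == 1L
  n_benign <- integer(n)
  n_benign[unnec] <- 1L
  n_benign[multi] <- 2L
  n_benign[third] <- 3L
  # melanoma patients are disjoint from benign-excision patients
  n_mel <- stats::rpois(1L, config$melanoma_rate)
  candidates <- which(!unnec)
  if (n_mel > length(candidates))
    stop("melanoma draw exceeds the number of non-excised patients",
         call. = FALSE)
  melanoma <- logical(n)
  melanoma[candidates[seq_len(n_mel)]] <- TRUE
  registered <- logical(n)
  eligible <- !unnec & !melanoma
  registered[eligible] <- stats::rbinom(sum(eligible), 1L,
                                        config$p_register) == 1L
  attended_12 <- logical(n)
  attended_12[registered] <- stats::rbinom(sum(registered), 1L,
                                           config$p_attend_12month) == 1L
  new_records(config$group, n_benign, melanoma, registered, attended_12)
}

new_records <- function(group, n_benign, melanoma, registered, attended_12) {
  data.frame(group_label = group,
             n_benign_excisions = as.integer(n_benign),
             has_melanoma = melanoma,
             sddi_registered = registered,
             attended_3month = registered,   # full 3-month attendance
             attended_12month = attended_12,
             stringsAsFactors = FALSE)
}
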