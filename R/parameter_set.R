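#' Construct the PSA parameter distributions from cohort statistics
#'
#' Builds, for one study arm, the sampling distributions propagated through
#' the decision tree by the probabilistic sensitivity analysis:
#'
#' * number of patients with unnecessary excisions —
#'   `Binomial(n_screened, n_unnecessary / n_screened)`;
#' * proportion of patients with more than one unnecessary excision —
#'   `Beta(n_multi, n_unnecessary - n_multi)` (successes/failures, no prior
#'   pseudo-counts), degenerate at 0 when no multi-excision patients were
#'   observed;
#' * average number of unnecessary excisions per patient —
#'   `Gamma(shape = total_excisions, rate = n_unnecessary)`, degenerate at 1
#'   when every patient had a single excision;
#' * number of excised melanomas — `Poisson(n_melanomas)`, zero-truncated at
#'   sampling time so per-melanoma ratios stay defined;
#' * number of patients registered for SDDI — `Poisson(n_registered)`
#'   (absent in the OD-only arm);
#' * proportion followed up at 3–6 months — fixed at 1;
#' * proportion followed up at 12 months —
#'   `Beta(n_attended_12month, n_registered - n_attended_12month)` (the
#'   registered cohort is the denominator).
#'
#' All parameters are treated as mutually independent. For each distribution
#' the analytic mean and central 95% range (2.5th/97.5th percentiles) are
#' exposed for reporting.
#'
#' @param stats A [cohort_stats()] object.
#' @return An object of class `parameter_set`: a list of parameter
#'   descriptors in declaration order, each with a `name`, a short `label`
#'   (as used on the tornado graph), a distribution spec and summaries.
#' @export
#' @examples
#' build_parameter_set(group1_observed_stats())
build_parameter_set <- function(stats) {
  stopifnot(inherits(stats, "cohort_stats"))
  od_arm <- stats$group == "group1"
  suffix <- if (od_arm) "OD" else "SDDI"
  params <- list()

  if (stats$n_screened == 0)
    stop("cannot build parameter set: n_screened is zero", call. = FALSE)
  params$n_unnecessary <- param_spec(
    "n_unnecessary", paste("P unnec ex", suffix), "binom",
    a = stats$n_screened,
    b = stats$n_unnecessary_patients / stats$n_screened)

  if (stats$n_multi_patients > 0) {
    if (stats$n_unnecessary_patients == stats$n_multi_patients)
      stop("cannot build parameter set: zero Beta failure count for prop_multi",
           call. = FALSE)
    params$prop_multi <- param_spec(
      "prop_multi", "Multi unnec ex", "beta",
      a = stats$n_multi_patients,
      b = stats$n_unnecessary_patients - stats$n_multi_patients)
    if (stats$n_unnecessary_patients == 0)
      stop("cannot build parameter set: zero denominator for avg_excisions",
           call. = FALSE)
    params$avg_excisions <- param_spec(
      "avg_excisions", "N unnec ex", "gamma",
      a = stats$total_unnecessary_excisions,
      b = stats$n_unnecessary_patients)
  } else {
    params$prop_multi <- param_spec("prop_multi", "Multi unnec ex",
                                    "fixed", a = 0)
    params$avg_excisions <- param_spec("avg_excisions", "N unnec ex",
                                       "fixed", a = 1)
  }

  params$n_melanomas <- param_spec(
    "n_melanomas", paste("Mela", suffix), "pois_trunc",
    a = stats$n_melanomas)

  if (stats$n_sddi_registered > 0) {
    params$n_registered <- param_spec(
      "n_registered", "P ctrl T0", "pois", a = stats$n_sddi_registered)
    params$prop_3month <- param_spec("prop_3month", "P ctrl 3 M",
                                     "fixed", a = 1)
    n12 <- stats$n_attended_12month
    if (n12 == 0 || n12 == stats$n_sddi_registered) {
      params$prop_12month <- param_spec(
        "prop_12month", "P ctrl 12 M", "fixed",
        a = n12 / stats$n_sddi_registered)
    } else {
      params$prop_12month <- param_spec(
        "prop_12month", "P ctrl 12 M", "beta",
        a = n12, b = stats$n_sddi_registered - n12)
    }
  } else {
    params$n_registered <- param_spec("n_registered", "P ctrl T0",
                                      "fixed", a = 0)
    params$prop_3month <- param_spec("prop_3month", "P ctrl 3 M",
                                     "fixed", a = 0)
    params$prop_12month <- param_spec("prop_12month", "P ctrl 12 M",
                                      "fixed", a = 0)
  }

  structure(list(group = stats$group, params = params),
            class = "parameter_set")
}

# One parameter descriptor: analytic mean and central 95% range computed at
# construction. The zero-truncation correction for Poisson melanoma counts
# is below machine precision at the rates used (e^-32) and is ignored in the
# reported summaries.
param_spec <- function(name, label, dist, a, b = NULL) {
  mean_ <- switch(dist,
    binom = a * b,
    beta = a / (a + b),
    gamma = a / b,
    pois = a,
    pois_trunc = if (a > 0) a / (1 - exp(-a)) else stop(
      "zero-truncated Poisson requires a positive rate", call. = FALSE),
    fixed = a)
  q <- function(p) switch(dist,
    binom = stats::qbinom(p, a, b),
    beta = stats::qbeta(p, a, b),
    gamma = stats::qgamma(p, shape = a, rate = b),
    pois = stats::qpois(p, a),
    pois_trunc = stats::qpois(p, a),
    fixed = rep(a, length(p)))
  rng <- q(c(0.025, 0.975))
  list(name = name, label = label, dist = dist, a = a, b = b,
       fixed = dist == "fixed", mean = mean_,
       lower = rng[1], upper = rng[2])
}

# Draw n values from one parameter descriptor using the global RNG stream.
sample_param <- function(p, n = 1L) {
  switch(p$dist,
    binom = stats::rbinom(n, p$a, p$b),
    beta = stats::rbeta(n, p$a, p$b),
    gamma = stats::rgamma(n, shape = p$a, rate = p$b),
    pois = stats::rpois(n, p$a),
    pois_trunc = {
      x <- stats::rpois(n, p$a)
      while (any(x < 1)) {              # redraw until >= 1
        i <- which(x < 1)
        x[i] <- stats::rpois(length(i), p$a)
      }
      x
    },
    fixed = rep(p$a, n))
}

#' Default parameter sets for the published two-arm comparison
#'
#' @return A list with elements `group1` and `group2`, each a
#'   [build_parameter_set()] result for the published observed statistics.
#' @export
default_parameter_sets <- function() {
  list(group1 = build_parameter_set(group1_observed_stats()),
       group2 = build_parameter_set(group2_observed_stats()))
}

#' Summarise a parameter set
#'
#' @param object A `parameter_set`.
#' @param ... Unused.
#' @return A data frame with one row per parameter: name, tornado label,
#'   distribution, hyperparameters, mean and central 95% range.
#' @export
summary.parameter_set <- function(object, ...) {
  rows <- lapply(object$params, function(p) {
    data.frame(name = p$name, label = p$label, dist = p$dist,
               a = p$a, b = if (is.null(p$b)) NA_real_ else p$b,
               mean = p$mean, lower = p$lower, upper = p$upper,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("PSA parameter set (", x$group, ")\n", sep = "")
  print(summary(x), digits = 4)
  invisible(x)
}
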