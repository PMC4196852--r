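#' Load a run configuration
#'
#' Reads a JSON configuration with (all optional) sections `unit_costs`,
#' `group1`, `group2`, `psa` (`n_iterations`, `seed`) and `output`
#' (`directory`, `formats`). Absent keys fall back to the published
#' defaults — the Belgian 2012 tariffs, the observed two-arm cohort
#' statistics, and 10,000 iterations — so an empty (or `NULL`) configuration
#' reproduces the published analysis. Unknown keys are an error.
#'
#' @param path Path to a JSON file, or `NULL` for the full defaults.
#' @return An object of class `run_config` with elements `unit_costs`,
#'   `group1`, `group2`, `psa` and `output`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list()
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw) || length(raw) == 0) raw <- list()
  known <- c("unit_costs", "group1", "group2", "psa", "output")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  stats_from <- function(raw_stats, defaults) {
    fields <- setdiff(names(unclass(defaults)), "group")
    if (is.null(raw_stats)) raw_stats <- list()
    unknown <- setdiff(names(raw_stats), fields)
    if (length(unknown))
      stop("unknown cohort keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    merged <- unclass(defaults)
    merged[names(raw_stats)] <- raw_stats
    do.call(cohort_stats, merged)
  }
  psa_defaults <- list(n_iterations = 10000, seed = 1L)
  out_defaults <- list(directory = ".", formats = c("csv", "json"))
  psa_raw <- if (is.null(raw$psa)) list() else raw$psa
  out_raw <- if (is.null(raw$output)) list() else raw$output
  unknown <- c(setdiff(names(psa_raw), names(psa_defaults)),
               setdiff(names(out_raw), names(out_defaults)))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  psa_defaults[names(psa_raw)] <- psa_raw
  out_defaults[names(out_raw)] <- out_raw
  if (!all(out_defaults$formats %in% c("csv", "json")))
    stop("output formats must be a subset of {csv, json}", call. = FALSE)

  structure(list(unit_costs = unit_costs_from_list(raw$unit_costs),
                 group1 = stats_from(raw$group1, group1_observed_stats()),
                 group2 = stats_from(raw$group2, group2_observed_stats()),
                 psa = psa_defaults,
                 output = out_defaults),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Parameter-set construction, PSA, summary and variable-importance
#' analysis for a [load_config()] configuration. Run metadata (seed,
#' iteration count, configuration checksum) is logged to standard error.
#'
#' @param config A `run_config` (default: the published analysis).
#' @return A list with `config`, the `psa_result`, the `psa_summary`, the
#'   `importance_table`, and the per-arm observed (plug-in) extra-costs.
#' @export
run_analysis <- function(config = load_config()) {
  stopifnot(inherits(config, "run_config"))
  log_msg("run: seed=", config$psa$seed,
          " iterations=", config$psa$n_iterations,
          " config_checksum=", config_checksum(unclass(config)))
  params <- list(group1 = build_parameter_set(config$group1),
                 group2 = build_parameter_set(config$group2))
  result <- run_psa(params, config$unit_costs,
                    n_iterations = config$psa$n_iterations,
                    seed = config$psa$seed)
  list(config = config,
       result = result,
       summary = summarize_psa(result),
       importance = fit_importance(result),
       observed = list(group1 = observed_extra_costs(config$group1,
                                                     config$unit_costs),
                       group2 = observed_extra_costs(config$group2,
                                                     config$unit_costs)))
}

#' Write the analysis report files
#'
#' Emits, into `out_dir`:
#' * `summary_table.csv` — the simulated-cost table (rows: Excisions,
#'   Pathology, Follow-up by SDDI, Total, Total/melanoma diagnosed; one
#'   column block per arm plus the between-arm difference), money rounded
#'   to the nearest euro with the displayed Total recomputed from the
#'   rounded components so the columns add up;
#' * `difference_distribution.csv` — the raw per-iteration per-melanoma
#'   cost differences (histogram data);
#' * `tornado.csv` — label, standardized coefficient and absolute-value
#'   rank per parameter;
#' * `metrics.json` — means, the proportion of iterations with the OD-only
#'   arm more expensive, and the importance R-squared.
#'
#' @param summary A [summarize_psa()] result.
#' @param importance A [fit_importance()] result.
#' @param out_dir Output directory (created if needed).
#' @param result Optional `psa_result` supplying the difference
#'   distribution; omitted from the report when `NULL`.
#' @param formats Subset of `c("csv", "json")`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(summary, importance, out_dir,
                         result = NULL, formats = c("csv", "json")) {
  stopifnot(inherits(summary, "psa_summary"),
            inherits(importance, "importance_table"))
  if (!all(formats %in% c("csv", "json")))
    stop("formats must be a subset of {csv, json}", call. = FALSE)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- character(0)

  if ("csv" %in% formats) {
    tab <- summary_report_table(summary)
    p <- file.path(out_dir, "summary_table.csv")
    utils::write.csv(tab, p, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(out_dir, "tornado.csv")
    utils::write.csv(tornado_table(importance), p, row.names = FALSE)
    paths <- c(paths, p)
    if (!is.null(result)) {
      p <- file.path(out_dir, "difference_distribution.csv")
      utils::write.csv(
        data.frame(difference = result$outcomes[, "difference"]),
        p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  if ("json" %in% formats) {
    means <- stats::setNames(summary$mean, summary$outcome)
    metrics <- list(
      n_iterations = attr(summary, "n_iterations"),
      seed = attr(summary, "seed"),
      proportion_group1_more_expensive = attr(summary, "prop_positive"),
      mean_difference_per_melanoma = unname(means[["difference"]]),
      means = as.list(means),
      importance_r_squared = attr(importance, "r_squared"))
    p <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(metrics, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# Assemble the published-style simulated-cost table, money rounded to the
# nearest euro; each displayed Total is the sum of its displayed components.
summary_report_table <- function(summary) {
  g <- function(nm) summary[summary$outcome == nm, , drop = FALSE]
  component_rows <- rbind(
    cbind(row = "Excisions", block("group1", g("excision_group1")),
          block("group2", g("excision_group2")),
          block("difference", g("difference_excisions"), one_sided = TRUE)),
    cbind(row = "Pathology", block("group1", g("pathology_group1")),
          block("group2", g("pathology_group2")),
          block("difference", g("difference_pathology"), one_sided = TRUE)),
    cbind(row = "Follow-up by SDDI", block("group1", g("sddi_group1")),
          block("group2", g("sddi_group2")),
          block("difference", g("difference_sddi"), one_sided = TRUE)))
  total_row <- cbind(row = "Total",
                     block("group1", g("total_group1")),
                     block("group2", g("total_group2")),
                     block("difference", g("difference_total"),
                           one_sided = TRUE))
  # display-layer reconciliation: rounded components must sum to the total
  for (col in c("group1_mean", "group2_mean", "difference_mean"))
    total_row[[col]] <- sum(component_rows[[col]])
  per_mel <- cbind(row = "Total/melanoma diagnosed",
                   block("group1", g("per_melanoma_group1")),
                   block("group2", g("per_melanoma_group2")),
                   block("difference", g("difference"), one_sided = TRUE))
  rbind(component_rows, total_row, per_mel)
}

block <- function(prefix, row, one_sided = FALSE) {
  lo <- if (one_sided) row$one_sided_low else row$ci_low
  hi <- if (one_sided) row$one_sided_high else row$ci_high
  out <- data.frame(mean = round(row$mean), ci_low = round(lo),
                    ci_high = round(hi))
  names(out) <- paste(prefix, names(out), sep = "_")
  out
}
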