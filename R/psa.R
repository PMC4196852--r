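#' Draw one set of parameter values
#'
#' Samples every parameter of both arms once, in declaration order (all
#' Group 1 parameters, then all Group 2 parameters), from the global RNG
#' stream. Fixed (degenerate) parameters contribute their point value and
#' consume no random numbers; zero-truncated Poisson melanoma counts are
#' redrawn until at least 1.
#'
#' @param params A list with elements `group1` and `group2`, each a
#'   [build_parameter_set()] result (default: the published distributions).
#' @return A list with named numeric vectors `group1` and `group2` (all
#'   parameter values) and `sampled` (the stochastic parameters only, named
#'   by their tornado labels, in declaration order).
#' @export
#' @examples
#' set.seed(1)
#' sample_draw()$sampled
sample_draw <- function(params = default_parameter_sets()) {
  check_two_arm_params(params)
  sampled <- numeric(0)
  values <- lapply(params, function(ps) {
    v <- vapply(ps$params, function(p) {
      if (p$fixed) p$a else sample_param(p, 1L)
    }, numeric(1))
    names(v) <- vapply(ps$params, `[[`, "", "name")
    v
  })
  for (g in names(params)) {
    stoch <- !vapply(params[[g]]$params, `[[`, TRUE, "fixed")
    s <- values[[g]][stoch]
    names(s) <- vapply(params[[g]]$params[stoch], `[[`, "", "label")
    sampled <- c(sampled, s)
  }
  list(group1 = values$group1, group2 = values$group2, sampled = sampled)
}

check_two_arm_params <- function(params) {
  if (!is.list(params) || !all(c("group1", "group2") %in% names(params)) ||
      !inherits(params$group1, "parameter_set") ||
      !inherits(params$group2, "parameter_set"))
    stop("`params` must be a list with parameter_set elements `group1` and `group2`",
         call. = FALSE)
  invisible(params)
}

outcome_names <- c("excision_group1", "pathology_group1", "sddi_group1",
                   "total_group1",
                   "excision_group2", "pathology_group2", "sddi_group2",
                   "total_group2",
                   "per_melanoma_group1", "per_melanoma_group2",
                   "difference")

#' Decision-tree outcome for one parameter draw
#'
#' Applies the billing pathway to one sampled parameter vector. Per arm:
#' the excision component bills every unnecessary-excision patient one
#' standard pathway (with the optical dermoscopy fee in the OD-only arm)
#' plus, in expectation, one reduced additional-excision fee per
#' multi-excision patient (`n_unnecessary * prop_multi`); the pathology
#' component bills pathology per patient and two immunostains per melanoma
#' equivalent; the SDDI component bills the canonical visit schedule. Totals
#' are divided by the arm's melanoma draw to give extra-cost per melanoma
#' diagnosed; `difference` is Group 1 minus Group 2 per-melanoma cost. The
#' sampled average number of excisions per patient is recorded for the
#' importance analysis but does not enter the cost arithmetic, whose
#' multi-excision surcharge runs off `prop_multi`.
#'
#' @param draw A draw from [sample_draw()].
#' @param costs A [unit_cost_table()].
#' @return Named numeric vector of the per-iteration outcomes (component
#'   costs, totals, per-melanoma costs, difference).
#' @export
iteration_outcome <- function(draw, costs = default_unit_costs()) {
  g1 <- arm_components(draw$group1, bill_od = TRUE, costs)
  g2 <- arm_components(draw$group2, bill_od = FALSE, costs)
  if (draw$group1[["n_melanomas"]] < 1 || draw$group2[["n_melanomas"]] < 1)
    stop("internal error: melanoma draw below 1 reached the cost model",
         call. = FALSE)
  pm1 <- g1[["total"]] / draw$group1[["n_melanomas"]]
  pm2 <- g2[["total"]] / draw$group2[["n_melanomas"]]
  out <- c(g1[c("excision", "pathology", "sddi", "total")],
           g2[c("excision", "pathology", "sddi", "total")],
           pm1, pm2, pm1 - pm2)
  names(out) <- outcome_names
  out
}

arm_components <- function(v, bill_od, costs) {
  n_unnec <- v[["n_unnecessary"]]
  excision <- n_unnec * excision_pathway_cost(1, bill_od, costs) +
    n_unnec * v[["prop_multi"]] * costs$excision_additional
  # IHC is performed on benign naevi, one per melanoma, so the stained-case
  # count can never exceed the number of benign-excision patients
  pathology <- pathology_block_cost(n_unnec,
                                    min(v[["n_melanomas"]], n_unnec), costs)
  sddi <- sddi_followup_cost(v[["n_registered"]], v[["prop_3month"]],
                             v[["prop_12month"]], costs)
  c(excision = excision, pathology = pathology, sddi = sddi,
    total = excision + pathology + sddi)
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of the parameter distributions through the
#' decision-tree cost model. Sampling is iteration-major (every parameter is
#' drawn once per iteration before the next iteration starts) from a single
#' Mersenne-Twister stream seeded with `seed`, so the draw sequence — and
#' hence the whole result — is reproducible bit-for-bit.
#'
#' @param params Two-arm parameter list as in [sample_draw()].
#' @param costs A [unit_cost_table()].
#' @param n_iterations Number of iterations (default 10,000).
#' @param seed Integer seed.
#' @return An object of class `psa_result` with the `n_iterations x 8`
#'   matrix of stochastic parameter `draws` (columns named by tornado
#'   labels, in declaration order), the matrix of per-iteration `outcomes`,
#'   and the run metadata.
#' @export
#' @examples
#' res <- run_psa(n_iterations = 200, seed = 42)
#' summarize_psa(res)
run_psa <- function(params = default_parameter_sets(),
                    costs = default_unit_costs(),
                    n_iterations = 10000,
                    seed = 1L) {
  check_two_arm_params(params)
  n_iterations <- check_count(n_iterations, "n_iterations")
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  first <- sample_draw(params)
  draws <- matrix(NA_real_, n_iterations, length(first$sampled),
                  dimnames = list(NULL, names(first$sampled)))
  outcomes <- matrix(NA_real_, n_iterations, length(outcome_names),
                     dimnames = list(NULL, outcome_names))
  draws[1L, ] <- first$sampled
  outcomes[1L, ] <- iteration_outcome(first, costs)
  if (n_iterations > 1L) {
    for (i in 2:n_iterations) {
      d <- sample_draw(params)
      draws[i, ] <- d$sampled
      outcomes[i, ] <- iteration_outcome(d, costs)
    }
  }
  structure(list(draws = draws, outcomes = outcomes, params = params,
                 costs = costs, seed = as.integer(seed),
                 n_iterations = n_iterations),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("PSA result: ", x$n_iterations, " iterations, seed ", x$seed, "\n",
      "mean difference per melanoma: ",
      round(mean(x$outcomes[, "difference"]), 1), " EUR\n", sep = "")
  invisible(x)
}

#' Proportion of iterations with Group 1 more expensive
#'
#' @param result A [run_psa()] result.
#' @return Fraction of iterations with a strictly positive per-melanoma cost
#'   difference (Group 1 minus Group 2).
#' @export
prop_group1_more_expensive <- function(result) {
  stopifnot(inherits(result, "psa_result"))
  mean(result$outcomes[, "difference"] > 0)
}

#' Summarise a PSA result
#'
#' For every outcome: Monte Carlo mean and two-sided 95% credibility
#' interval (2.5th/97.5th percentiles, linear interpolation between order
#' statistics). Between-arm difference rows (per component, total, and per
#' melanoma) additionally carry the one-sided upper 95% interval (5th
#' percentile and maximum). The proportion of iterations in which the
#' OD-only arm is more expensive is attached as attribute `prop_positive`.
#'
#' @param result A non-empty [run_psa()] result.
#' @return A `psa_summary` data frame (one row per outcome; columns
#'   `outcome`, `mean`, `ci_low`, `ci_high`, `one_sided_low`,
#'   `one_sided_high`).
#' @export
summarize_psa <- function(result) {
  stopifnot(inherits(result, "psa_result"))
  if (nrow(result$outcomes) == 0)
    stop("empty PSA result", call. = FALSE)
  out <- result$outcomes
  diffs <- cbind(
    difference_excisions = out[, "excision_group1"] - out[, "excision_group2"],
    difference_pathology = out[, "pathology_group1"] - out[, "pathology_group2"],
    difference_sddi = out[, "sddi_group1"] - out[, "sddi_group2"],
    difference_total = out[, "total_group1"] - out[, "total_group2"])
  all_out <- cbind(out, diffs)
  q <- function(x, p) stats::quantile(x, p, type = 7, names = FALSE)
  rows <- lapply(colnames(all_out), function(nm) {
    x <- all_out[, nm]
    one_sided <- nm == "difference" || startsWith(nm, "difference_")
    data.frame(outcome = nm,
               mean = mean(x),
               ci_low = q(x, 0.025),
               ci_high = q(x, 0.975),
               one_sided_low = if (one_sided) q(x, 0.05) else NA_real_,
               one_sided_high = if (one_sided) max(x) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(res,
            prop_positive = prop_group1_more_expensive(result),
            n_iterations = result$n_iterations,
            seed = result$seed,
            class = c("psa_summary", "data.frame"))
}

#' @rdname summarize_psa
#' @param object,... Method arguments (`object` is the `psa_result`).
#' @export
summary.psa_result <- function(object, ...) summarize_psa(object)

#' @export
print.psa_summary <- function(x, ...) {
  cat("PSA summary (", attr(x, "n_iterations"), " iterations, seed ",
      attr(x, "seed"), ")\n", sep = "")
  print.data.frame(x, digits = 6, row.names = FALSE)
  cat(sprintf("Proportion of iterations with Group 1 more expensive: %.1f%%\n",
              100 * attr(x, "prop_positive")))
  invisible(x)
}
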