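#' Standardize a numeric vector
#'
#' Subtracts the mean and divides by the sample (n-1 denominator) standard
#' deviation, the first step of the standardized-regression variable
#' importance analysis.
#'
#' @param values Numeric vector of length at least 2.
#' @return Numeric vector with mean 0 and sample standard deviation 1.
#' @export
#' @examples
#' standardize(c(1, 2, 3))  # -1 0 1
standardize <- function(values) {
  if (!is.numeric(values) || length(values) < 2L || anyNA(values))
    stop("`values` must be a numeric vector of length >= 2 without NAs",
         call. = FALSE)
  s <- stats::sd(values)
  if (s == 0)
    stop("cannot standardize a constant vector (zero standard deviation)",
         call. = FALSE)
  (values - mean(values)) / s
}

#' Variable-importance analysis of a PSA result
#'
#' Regresses the standardized primary outcome (per-melanoma cost
#' difference) on the standardized sampled parameters by ordinary least
#' squares. The absolute standardized coefficients measure how many
#' standard deviations the outcome moves per standard deviation of each
#' input; the fit's R-squared measures how much of the outcome variance the
#' linear metamodel captures. Constant parameter columns are dropped with a
#' warning. The regression is fitted with an intercept (numerically ~0
#' after centring), which is excluded from the reported coefficients.
#'
#' @param result A [run_psa()] result with at least 2 iterations.
#' @param outcome Outcome column to analyse (default `"difference"`).
#' @return An object of class `importance_table`: a data frame with columns
#'   `parameter` (tornado label), `coefficient` and `abs_rank` (rank by
#'   absolute coefficient, ties broken by parameter declaration order), with
#'   the fit's `r_squared` as an attribute.
#' @export
#' @examples
#' res <- run_psa(n_iterations = 500, seed = 7)
#' fit_importance(res)
fit_importance <- function(result, outcome = "difference") {
  stopifnot(inherits(result, "psa_result"))
  if (nrow(result$draws) < 2L)
    stop("importance analysis requires at least 2 iterations", call. = FALSE)
  if (!outcome %in% colnames(result$outcomes))
    stop("unknown outcome: ", outcome, call. = FALSE)
  x <- result$draws
  keep <- apply(x, 2L, stats::sd) > 0
  if (any(!keep)) {
    warning("dropping constant parameter column(s): ",
            paste(colnames(x)[!keep], collapse = ", "), call. = FALSE)
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) == 0L)
    stop("no non-constant parameter columns to regress on", call. = FALSE)
  zx <- apply(x, 2L, standardize)
  zy <- standardize(result$outcomes[, outcome])
  qrx <- qr(cbind(1, zx))
  if (qrx$rank < ncol(zx) + 1L) {
    dropped <- colnames(zx)[qrx$pivot[seq.int(qrx$rank + 1L, ncol(zx) + 1L)] - 1L]
    stop("singular design: collinear parameter column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, zx), zy)
  coefs <- fit$coefficients[-1L]
  r2 <- 1 - sum(fit$residuals^2) / sum(zy^2)  # zy is centred
  ord <- order(-abs(coefs), seq_along(coefs))
  rank <- integer(length(coefs))
  rank[ord] <- seq_along(coefs)
  structure(data.frame(parameter = colnames(zx),
                       coefficient = unname(coefs),
                       abs_rank = rank,
                       stringsAsFactors = FALSE),
            r_squared = r2,
            class = c("importance_table", "data.frame"))
}

#' Tornado report rows
#'
#' Orders an importance table by decreasing absolute coefficient (ties
#' broken by parameter declaration order), the order in which a tornado
#' graph draws its bars.
#'
#' @param imp An [fit_importance()] result.
#' @return The reordered `importance_table`.
#' @export
tornado_table <- function(imp) {
  stopifnot(inherits(imp, "importance_table"))
  out <- imp[order(imp$abs_rank), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, r_squared = attr(imp, "r_squared"),
            class = class(imp))
}

#' @export
print.importance_table <- function(x, ...) {
  cat("Standardized-regression variable importance (R-squared = ",
      round(attr(x, "r_squared"), 4), ")\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
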