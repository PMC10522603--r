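#' Fit receptor-enriched multifactorial causal models for a cohort
#'
#' Fits one linear dynamical factor model per subject and per biological
#' factor: the finite-difference rate of change of each factor is regressed
#' on the states of all factors, receptor-by-factor interactions, direct
#' receptor densities and the connectome propagation term (plus an
#' intercept). With 6 factors and 15 receptors each model has 113
#' coefficients, 678 per subject across factors.
#'
#' @param cohort A [cohort()].
#' @param receptor_subset `NULL` fits the full model; `character(0)` the
#'   restricted neuroimaging-only model (8 columns); a single receptor label
#'   the single-receptor model (15 columns).
#' @param states_at Predictor-state convention, `"start"` (forward
#'   difference, default) or `"midpoint"`.
#' @param normalize_imaging If `TRUE` (default), imaging values are pooled
#'   z-scored per modality before fitting. Set `FALSE` when the cohort is
#'   already on the modeling scale (e.g. synthetic cohorts generated on the
#'   z-scale) and raw-scale coefficient recovery is of interest.
#' @param factors Factors to fit (default: all).
#'
#' @return An object of class `remcm`: per subject x factor
#'   [fit_factor_model()] results, an `r_squared` subject-by-factor matrix
#'   and a record of any failed fits.
#' @seealso [summary.remcm()], [coef.remcm()], [validate_remcm()],
#'   [stable_mechanisms()], [symptom_axes()], [influence_map()]
#' @export
remcm <- function(cohort, receptor_subset = NULL,
                  states_at = c("start", "midpoint"),
                  normalize_imaging = TRUE, factors = NULL) {
  states_at <- match.arg(states_at)
  stopifnot(inherits(cohort, "remcm_cohort"))
  if (normalize_imaging) cohort <- zscore_imaging(cohort)
  receptors <- zscore_receptors(cohort$receptors)
  factors <- factors %||% cohort$factor_names
  ids <- names(cohort$subjects)
  fits <- list()
  failures <- list()
  r2 <- matrix(NA_real_, length(ids), length(factors),
               dimnames = list(ids, factors))
  for (id in ids) {
    fits[[id]] <- list()
    for (f in factors) {
      res <- tryCatch({
        d <- build_design_matrix(cohort$subjects[[id]], f, receptors,
                                 cohort$connectome,
                                 receptor_subset = receptor_subset,
                                 states_at = states_at)
        fit_factor_model(d)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[paste(id, f, sep = "|")]] <- conditionMessage(res)
      } else {
        fits[[id]][[f]] <- res
        r2[id, f] <- res$r_squared
      }
    }
  }
  structure(
    list(fits = fits, r_squared = r2, subject_ids = ids,
         factor_names = factors, receptor_subset = receptor_subset,
         receptor_names = colnames(receptors), states_at = states_at,
         failures = failures),
    class = "remcm"
  )
}

model_kind <- function(x) {
  rs <- x$receptor_subset
  if (is.null(rs)) "full"
  else if (length(rs) == 0) "restricted (neuroimaging-only)"
  else if (length(rs) == 1) paste0("single-receptor (", rs, ")")
  else paste0("receptor subset (", paste(rs, collapse = ", "), ")")
}

#' @export
print.remcm <- function(x, ...) {
  cat("re-MCM fits:", length(x$subject_ids), "subjects x",
      length(x$factor_names), "factors;", model_kind(x), "model\n")
  cat(sprintf("  median R^2 = %.3f\n", stats::median(x$r_squared, na.rm = TRUE)))
  if (length(x$failures)) {
    cat("  skipped fits:", length(x$failures), "\n")
  }
  invisible(x)
}

#' Summarize per-factor explained variance
#'
#' @param object An [remcm()] fit.
#' @param ... Unused.
#' @return A data frame with per-factor mean, SD, median and range of the
#'   subject-level coefficients of determination.
#' @export
summary.remcm <- function(object, ...) {
  r2 <- object$r_squared
  out <- data.frame(
    factor = colnames(r2),
    mean_r2 = colMeans(r2, na.rm = TRUE),
    sd_r2 = apply(r2, 2, stats::sd, na.rm = TRUE),
    median_r2 = apply(r2, 2, stats::median, na.rm = TRUE),
    min_r2 = apply(r2, 2, min, na.rm = TRUE),
    max_r2 = apply(r2, 2, max, na.rm = TRUE),
    n_fits = colSums(!is.na(r2)),
    row.names = NULL
  )
  class(out) <- c("summary.remcm", "data.frame")
  attr(out, "kind") <- model_kind(object)
  attr(out, "n_failures") <- length(object$failures)
  attr(out, "failures") <- object$failures
  out
}

#' @export
print.summary.remcm <- function(x, ...) {
  cat("Per-factor R^2 of the", attr(x, "kind"), "re-MCM models\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  if (attr(x, "n_failures") > 0) {
    cat("Skipped fits:\n")
    msg <- attr(x, "failures")
    for (nm in names(msg)) cat(" ", nm, ":", msg[[nm]], "\n")
  }
  invisible(x)
}

#' Coefficients of a cohort fit
#'
#' @param object An [remcm()] fit.
#' @param scale `"standardized"` (coefficients of the standardized
#'   predictors, interpretable as relative effect sizes) or `"raw"`
#'   (back-transformed to the un-standardized predictor scale).
#' @param ... Unused.
#' @return A `subject x (factor * parameter)` matrix; column names combine
#'   target factor and predictor label as `"<factor>|<term>"`. Coefficients
#'   of skipped fits are `NA`.
#' @export
coef.remcm <- function(object, scale = c("standardized", "raw"), ...) {
  scale <- match.arg(scale)
  labels <- unlist(lapply(object$factor_names, function(m) {
    ft <- object$fits[[1]][[m]]
    lab <- if (!is.null(ft)) ft$labels
           else design_labels(object$factor_names,
                              object$receptor_subset %||% object$receptor_names)
    paste0(m, "|", lab)
  }))
  out <- matrix(NA_real_, length(object$subject_ids), length(labels),
                dimnames = list(object$subject_ids, labels))
  for (id in object$subject_ids) {
    row <- unlist(lapply(object$factor_names, function(m) {
      ft <- object$fits[[id]][[m]]
      if (is.null(ft)) return(rep(NA_real_, length(labels) / length(object$factor_names)))
      if (scale == "standardized") ft$alpha else ft$alpha_raw
    }))
    out[id, ] <- row
  }
  out
}

#' @export
residuals.remcm <- function(object, ...) {
  lapply(object$fits, function(sf) lapply(sf, residuals))
}

#' @export
fitted.remcm <- function(object, ...) {
  lapply(object$fits, function(sf) lapply(sf, fitted))
}

#' Histogram of subject-level explained variance per factor
#'
#' The per-factor distribution of model R-squared across subjects, one panel
#' per biological factor.
#'
#' @param x An [remcm()] fit.
#' @param breaks Passed to [graphics::hist()].
#' @param ... Further arguments passed to [graphics::hist()].
#' @export
plot.remcm <- function(x, breaks = 10, ...) {
  fn <- x$factor_names
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(fn)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (f in fn) {
    graphics::hist(x$r_squared[, f], breaks = breaks, main = f,
                   xlab = expression(R^2), col = "grey80", border = "white", ...)
  }
  invisible(x)
}
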