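#' Nested F-test between a full and a restricted factor model
#'
#' Compares two OLS fits on identical rows, the restricted model's columns
#' nested in the full model's:
#' `F = ((RSS_r - RSS_f) / (p_f - p_r)) / (RSS_f / (n - p_f))`, with the
#' p-value from the F distribution on `(p_f - p_r, n - p_f)` degrees of
#' freedom (model sizes taken as the fitted ranks).
#'
#' @param full,restricted [fit_factor_model()] results on the same rows.
#' @return A list with `F`, `p`, and the degrees of freedom `df1`, `df2`.
#' @export
nested_f_test <- function(full, restricted) {
  if (full$n_rows != restricted$n_rows) {
    stop("full and restricted fits must use the same rows")
  }
  if (restricted$rank >= full$rank) {
    stop("restricted model must have fewer parameters than the full model")
  }
  n <- full$n_rows
  df1 <- full$rank - restricted$rank
  df2 <- n - full$rank
  if (df2 <= 0) stop("no residual degrees of freedom for the full model")
  Fstat <- ((restricted$rss - full$rss) / df1) / (full$rss / df2)
  Fstat <- max(Fstat, 0)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Shuffle receptor maps across regions
#'
#' Each receptor column is independently permuted across regions, preserving
#' its value multiset while destroying the spatial correspondence between
#' receptor density and imaging data.
#'
#' @param receptors A [receptor_matrix()].
#' @param seed Optional integer seed.
#' @return A [receptor_matrix()] of the same shape.
#' @export
permute_receptor_matrix <- function(receptors, seed = NULL) {
  m <- unclass(receptors)
  with_seed(seed, {
    for (j in seq_len(ncol(m))) {
      m[, j] <- m[sample.int(nrow(m)), j]
    }
  })
  out <- receptor_matrix(m)
  rownames(out) <- rownames(receptors)
  out
}

#' Permutation test of the receptor contribution to model fit
#'
#' The observed full-model R-squared for one subject and factor is compared
#' with a null distribution obtained by refitting the model with randomly
#' permuted receptor maps (all receptor columns shuffled across regions,
#' independently per column and per iteration). Nothing but the injected
#' receptor matrix differs between the observed and null fits. The p-value
#' follows the add-one convention
#' `p = (1 + #\{null R^2 >= observed\}) / (n_perm + 1)` (one-sided:
#' improvement only).
#'
#' @param cohort A [cohort()] with imaging already on the modeling scale or
#'   `normalize_imaging = TRUE`.
#' @param subject Subject id.
#' @param factor Factor label.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @param states_at Design convention, as in [build_design_matrix()].
#' @param normalize_imaging Standardize imaging first (default `TRUE`).
#' @return A list with `p`, `observed_r2`, `null_r2` and `n_dropped` (null
#'   iterations whose fit failed).
#' @export
permutation_test_r2 <- function(cohort, subject, factor, n_perm = 1000,
                                seed = NULL, states_at = "start",
                                normalize_imaging = TRUE) {
  stopifnot(inherits(cohort, "remcm_cohort"))
  if (normalize_imaging) cohort <- zscore_imaging(cohort)
  receptors <- zscore_receptors(cohort$receptors)
  ts <- cohort$subjects[[subject]]
  if (is.null(ts)) stop("unknown subject: ", subject)
  fit_r2 <- function(rmat) {
    d <- build_design_matrix(ts, factor, rmat, cohort$connectome,
                             receptor_subset = NULL, states_at = states_at)
    fit_factor_model(d, leverage = FALSE)$r_squared
  }
  observed <- fit_r2(receptors)
  seeds <- child_seeds(seed, n_perm)
  null_r2 <- rep(NA_real_, n_perm)
  for (b in seq_len(n_perm)) {
    null_r2[b] <- tryCatch(
      fit_r2(permute_receptor_matrix(receptors, seed = seeds[[b]])),
      error = function(e) NA_real_)
  }
  dropped <- sum(is.na(null_r2))
  ok <- null_r2[!is.na(null_r2)]
  p <- (1 + sum(ok >= observed)) / (length(ok) + 1)
  list(p = p, observed_r2 = observed, null_r2 = null_r2, n_dropped = dropped)
}

#' Combine p-values with Fisher's method
#'
#' `chi2 = -2 sum(log p)` on `2 * length(p)` degrees of freedom.
#' Zero p-values (impossible under the add-one permutation convention) are
#' clipped with a warning.
#'
#' @param p_values Vector of p-values in `(0, 1]`.
#' @param clip Value substituted for zero entries (default
#'   `.Machine$double.xmin`).
#' @return A list with `chi2`, `df` and `combined_p`.
#' @export
fishers_method <- function(p_values, clip = .Machine$double.xmin) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  if (any(p_values == 0)) {
    warning("zero p-values clipped; add-one permutation p-values cannot be 0")
    p_values[p_values == 0] <- clip
  }
  chi2 <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(chi2 = chi2, df = df,
       combined_p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Validate the receptor contribution across a cohort
#'
#' For every subject and factor, runs the nested F-test of the full
#' (receptor-enriched) against the restricted (neuroimaging-only) model and,
#' optionally, the permuted-receptor-map R-squared permutation test;
#' summarizes per factor the fraction of significant subjects and Fisher's
#' combined statistic over the permutation p-values.
#'
#' @param cohort A [cohort()].
#' @param n_perm Permutations per subject/factor for the R-squared test;
#'   `0` skips the permutation test.
#' @param alpha Significance level for the per-subject tests.
#' @param seed Optional integer seed.
#' @param states_at,normalize_imaging As in [remcm()].
#' @return An object of class `remcm_validation`: a per-fit data frame
#'   (`$tests`) and a per-factor summary (`$by_factor`).
#' @export
validate_remcm <- function(cohort, n_perm = 1000, alpha = 0.05, seed = NULL,
                           states_at = "start", normalize_imaging = TRUE) {
  stopifnot(inherits(cohort, "remcm_cohort"))
  if (normalize_imaging) cohort <- zscore_imaging(cohort)
  full <- remcm(cohort, receptor_subset = NULL, states_at = states_at,
                normalize_imaging = FALSE)
  restr <- remcm(cohort, receptor_subset = character(0), states_at = states_at,
                 normalize_imaging = FALSE)
  rows <- list()
  seeds <- child_seeds(seed, length(full$subject_ids) * length(full$factor_names))
  k <- 0
  for (id in full$subject_ids) {
    for (f in full$factor_names) {
      k <- k + 1
      ff <- full$fits[[id]][[f]]
      rf <- restr$fits[[id]][[f]]
      if (is.null(ff) || is.null(rf)) next
      ft <- nested_f_test(ff, rf)
      perm_p <- NA_real_
      if (n_perm > 0) {
        perm_p <- permutation_test_r2(cohort, id, f, n_perm = n_perm,
                                      seed = seeds[[k]], states_at = states_at,
                                      normalize_imaging = FALSE)$p
      }
      rows[[k]] <- data.frame(
        subject_id = id, factor = f, F = ft$F, f_p = ft$p,
        r2_full = ff$r_squared, r2_restricted = rf$r_squared,
        perm_p = perm_p, n_perm = n_perm)
    }
  }
  tests <- do.call(rbind, rows)
  by_factor <- do.call(rbind, lapply(split(tests, tests$factor), function(d) {
    fisher <- if (all(is.na(d$perm_p))) list(chi2 = NA_real_, combined_p = NA_real_)
              else fishers_method(d$perm_p[!is.na(d$perm_p)])
    data.frame(factor = d$factor[1],
               frac_f_significant = mean(d$f_p < alpha),
               frac_perm_significant = mean(d$perm_p < alpha),
               fisher_chi2 = fisher$chi2,
               fisher_p = fisher$combined_p,
               n_subjects = nrow(d))
  }))
  rownames(by_factor) <- NULL
  structure(list(tests = tests, by_factor = by_factor, alpha = alpha),
            class = "remcm_validation")
}

#' @export
print.remcm_validation <- function(x, ...) {
  cat("re-MCM validation (alpha =", x$alpha, ")\n")
  print.data.frame(x$by_factor, digits = 3, row.names = FALSE)
  invisible(x)
}
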