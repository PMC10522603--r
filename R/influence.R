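#' Internally studentized residuals of a factor model
#'
#' `r_i / (sigma_hat * sqrt(1 - h_i))`, with `h_i` the row leverage from the
#' fit's QR factorization and `sigma_hat^2 = RSS / df`. Rows with leverage
#' numerically equal to one fall back to plain z-scoring of the residuals
#' (flagged); a fit with zero residual variance returns zeros (flagged).
#'
#' @param fit A [fit_factor_model()] result.
#' @return Numeric vector of studentized residuals with optional
#'   `attr(, "flag")`.
#' @export
studentize_residuals <- function(fit) {
  r <- fit$residuals
  df <- fit$df_residual
  sigma2 <- fit$rss / max(df, 1)
  if (sigma2 < 1e-24 * max(1, mean(fit$fitted^2))) {
    out <- rep(0, length(r))
    attr(out, "flag") <- "zero residual variance"
    return(out)
  }
  h <- pmin(fit$leverage, 1)
  bad <- h >= 1 - 1e-8
  out <- numeric(length(r))
  out[!bad] <- r[!bad] / sqrt(sigma2 * (1 - h[!bad]))
  if (any(bad)) {
    out[bad] <- (r[bad] - mean(r)) / max(stats::sd(r), 1e-12)
    attr(out, "flag") <- "leverage ~ 1 rows z-scored"
  }
  out
}

#' Regional Wilcoxon rank-sum statistic of residual improvement
#'
#' Rank-sum (with midranks for ties) of the restricted model's absolute
#' studentized residuals within the combined sample of both models' absolute
#' studentized residuals for one region. Larger values mean the restricted
#' model's residuals rank higher, i.e. the receptor-enriched model improves
#' the fit there. Identical samples sit at the null mean
#' `n1 (n1 + n2 + 1) / 2`.
#'
#' @param restricted_resid Studentized residuals of the neuroimaging-only
#'   model pooled for the region.
#' @param single_resid Studentized residuals of the single-receptor model
#'   pooled for the same region.
#' @return The rank-sum statistic (scalar).
#' @export
regional_wilcoxon <- function(restricted_resid, single_resid) {
  x <- abs(restricted_resid); y <- abs(single_resid)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  rk <- rank(c(x, y))
  sum(rk[seq_along(x)])
}

#' Regional receptor-influence map
#'
#' For one receptor and target factor: fits the single-receptor and the
#' neuroimaging-only models for every subject, pools internally studentized
#' residuals per region across subjects and intervals, and computes the
#' per-region Wilcoxon rank-sum statistic of restricted-model versus
#' single-receptor-model absolute residuals. A null distribution is obtained
#' by region-shuffling the receptor's density map and refitting the
#' single-receptor models (the restricted models carry no receptor terms and
#' are reused). The map reports the z-score of the observed statistic
#' against its permutation null and flags regions whose one-sided empirical
#' add-one p-value falls below `alpha`.
#'
#' @param cohort A [cohort()].
#' @param receptor Receptor label.
#' @param factor Target factor label.
#' @param n_perm Number of permuted maps (>= 100).
#' @param alpha Significance level for the flag.
#' @param seed Optional integer seed.
#' @param states_at,normalize_imaging As in [remcm()].
#' @return A data frame of class `remcm_influence` with columns `region`,
#'   `w`, `null_mean`, `null_sd`, `z`, `p`, `significant`.
#' @export
influence_map <- function(cohort, receptor, factor, n_perm = 1000,
                          alpha = 0.05, seed = NULL, states_at = "start",
                          normalize_imaging = TRUE) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  stopifnot(inherits(cohort, "remcm_cohort"))
  if (!receptor %in% colnames(cohort$receptors)) {
    stop("unknown receptor: ", receptor)
  }
  if (normalize_imaging) cohort <- zscore_imaging(cohort)
  receptors <- zscore_receptors(cohort$receptors)
  regions <- cohort$region_names

  pooled_resid <- function(rmat, subset) {
    vals <- lapply(cohort$subjects, function(ts) {
      d <- build_design_matrix(ts, factor, rmat, cohort$connectome,
                               receptor_subset = subset,
                               states_at = states_at)
      ft <- fit_factor_model(d)
      list(region = d$rows$region, r = studentize_residuals(ft))
    })
    split(unlist(lapply(vals, `[[`, "r")),
          factor(unlist(lapply(vals, `[[`, "region")), levels = regions))
  }

  restr <- pooled_resid(receptors, character(0))
  obs <- pooled_resid(receptors, receptor)
  w_obs <- vapply(regions, function(i) {
    regional_wilcoxon(restr[[i]], obs[[i]])
  }, numeric(1))

  seeds <- child_seeds(seed, n_perm)
  w_null <- matrix(NA_real_, n_perm, length(regions),
                   dimnames = list(NULL, regions))
  for (b in seq_len(n_perm)) {
    rp <- permute_receptor_matrix(receptors, seed = seeds[[b]])
    nullr <- pooled_resid(rp, receptor)
    w_null[b, ] <- vapply(regions, function(i) {
      regional_wilcoxon(restr[[i]], nullr[[i]])
    }, numeric(1))
  }
  mu <- colMeans(w_null)
  sdv <- apply(w_null, 2, stats::sd)
  z <- rep(NA_real_, length(regions))
  ok <- sdv > 0
  z[ok] <- (w_obs[ok] - mu[ok]) / sdv[ok]
  p <- vapply(seq_along(regions), function(i) {
    (1 + sum(w_null[, i] >= w_obs[i])) / (n_perm + 1)
  }, numeric(1))
  out <- data.frame(region = regions, w = w_obs, null_mean = mu,
                    null_sd = sdv, z = z, p = p,
                    significant = p < alpha, row.names = NULL)
  class(out) <- c("remcm_influence", "data.frame")
  attr(out, "receptor") <- receptor
  attr(out, "factor") <- factor
  attr(out, "n_perm") <- n_perm
  out
}

#' @export
print.remcm_influence <- function(x, ...) {
  cat(sprintf("Receptor influence map: %s on %s (%d permutations)\n",
              attr(x, "receptor"), attr(x, "factor"), attr(x, "n_perm")))
  cat(sprintf("  %d of %d regions significant; z range [%.2f, %.2f]\n",
              sum(x$significant, na.rm = TRUE), nrow(x),
              min(x$z, na.rm = TRUE), max(x$z, na.rm = TRUE)))
  invisible(x)
}
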