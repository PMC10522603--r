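#' Rates of clinical decline
#'
#' The OLS slope of each assessment's scores against examination time
#' (score units per year), using whichever visits are non-missing.
#' Assessments with fewer than two non-missing visits get `NA` and are
#' flagged.
#'
#' @param record A [clinical_record()].
#' @return Named numeric vector of slopes; missing-assessment flags in
#'   `attr(, "missing")`.
#' @export
clinical_slopes <- function(record) {
  sc <- record$scores
  tt <- record$exam_times
  out <- rep(NA_real_, nrow(sc))
  names(out) <- rownames(sc)
  for (a in seq_len(nrow(sc))) {
    ok <- !is.na(sc[a, ])
    if (sum(ok) < 2) next
    x <- tt[ok]; y <- sc[a, ok]
    out[a] <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  attr(out, "missing") <- names(out)[is.na(out)]
  out
}

#' Adjust a feature matrix for covariates and z-score
#'
#' Each column is replaced by its residual from an OLS regression on an
#' intercept plus the covariates, then z-scored (population SD). Columns
#' whose residuals are degenerate (numerically constant, e.g. a feature
#' exactly linear in a covariate) are dropped with a warning and recorded in
#' `attr(, "dropped")`.
#'
#' @param x Numeric `subject x feature` matrix.
#' @param covariates Numeric `subject x k` covariate matrix (complete).
#' @return The adjusted, z-scored matrix.
#' @export
adjust_covariates <- function(x, covariates) {
  x <- as.matrix(x); covariates <- as.matrix(covariates)
  stopifnot(nrow(x) == nrow(covariates))
  if (anyNA(covariates)) stop("covariates must be complete")
  Z <- cbind(1, covariates)
  if (qr(Z)$rank < ncol(Z)) stop("rank-deficient covariate matrix")
  res <- x - Z %*% solve(crossprod(Z), crossprod(Z, x))
  sds <- apply(res, 2, pop_sd)
  ref <- apply(abs(x), 2, max)
  degenerate <- sds < 1e-10 * pmax(1, ref)
  if (any(degenerate)) {
    warning(sum(degenerate),
            " feature(s) degenerate after covariate adjustment; dropped: ",
            paste(utils::head(colnames(x)[degenerate], 5), collapse = ", "),
            if (sum(degenerate) > 5) ", ...")
  }
  out <- res[, !degenerate, drop = FALSE]
  out <- sweep(out, 2, apply(out, 2, pop_sd), "/")
  attr(out, "dropped") <- colnames(x)[degenerate]
  out
}

#' SVD of the mechanism-symptom cross-covariance
#'
#' Decomposes `C = t(X) Y / (n - 1)` as `C = U S V'`; per-component
#' covariance explained is `s_i^2 / sum(s^2)` (squared-singular-value
#' convention; `explained = "linear"` uses `s_i / sum(s)`), and the
#' projection correlation is the Pearson correlation between the latent
#' scores `X u_i` and `Y v_i`.
#'
#' @param X Subject-by-mechanism matrix (column-centered; typically
#'   [adjust_covariates()] output).
#' @param Y Subject-by-symptom matrix, rows aligned with `X`.
#' @param explained Covariance-explained convention.
#' @return An object of class `remcm_axes` with `U`, `V`, `d`,
#'   `covariance_explained` and `projection_r`.
#' @export
cross_covariance_svd <- function(X, Y, explained = c("squared", "linear")) {
  explained <- match.arg(explained)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have aligned rows")
  if (nrow(X) < 3) stop("at least 3 subjects are required")
  n <- nrow(X)
  C <- crossprod(X, Y) / (n - 1)
  K <- min(dim(C))
  s <- svd(C, nu = K, nv = K)
  proj_r <- vapply(seq_len(K), function(i) {
    stats::cor(X %*% s$u[, i], Y %*% s$v[, i])
  }, numeric(1))
  ce <- if (explained == "squared") s$d[seq_len(K)]^2 / sum(s$d^2)
        else s$d[seq_len(K)] / sum(s$d)
  structure(
    list(U = structure(s$u, dimnames = list(colnames(X), NULL)),
         V = structure(s$v, dimnames = list(colnames(Y), NULL)),
         d = s$d[seq_len(K)], covariance_explained = ce,
         projection_r = proj_r, n = n, explained = explained),
    class = "remcm_axes"
  )
}

# Orthogonal Procrustes rotation Q minimizing ||M Q - ref||_F.
procrustes_rotation <- function(ref, M) {
  s <- svd(crossprod(M, ref))
  s$u %*% t(s$v)
}

# Align a permuted/bootstrapped SVD to reference symptom loadings V_ref:
# the rotation is computed on the (well-conditioned) symptom side and
# applied to both sides; aligned singular values are the column norms of the
# rotated, singular-value-weighted mechanism loadings.
align_svd <- function(V_ref, U_p, d_p, V_p) {
  Q <- procrustes_rotation(V_ref, V_p)
  Lu <- U_p %*% (diag(d_p, length(d_p)) %*% Q)
  d_al <- sqrt(colSums(Lu^2))
  list(U = U_p %*% Q, V = V_p %*% Q, d = d_al)
}

#' Permutation test for latent mechanism-symptom axes
#'
#' Shuffles the mapping between subjects' mechanism vectors and symptom
#' vectors (rows of `Y`), recomputes the cross-covariance SVD, aligns each
#' permuted decomposition to the observed axes by orthogonal Procrustes
#' rotation of the symptom-side loadings, and records the aligned singular
#' values. Per-component p-values follow the add-one convention and are
#' family-wise-error corrected against the null distribution of the largest
#' aligned singular value (max-statistic correction).
#'
#' @param X,Y As in [cross_covariance_svd()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional integer seed.
#' @param axes Optional precomputed observed [cross_covariance_svd()].
#' @return A list with `p` (FWE-corrected, per component), `p_uncorrected`,
#'   and the `null_max` vector.
#' @export
permutation_test_axes <- function(X, Y, n_perm = 1000, seed = NULL,
                                  axes = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  axes <- axes %||% cross_covariance_svd(X, Y)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); K <- length(axes$d)
  null_d <- matrix(NA_real_, n_perm, K)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      Yp <- Y[sample.int(n), , drop = FALSE]
      sp <- svd(crossprod(X, Yp) / (n - 1), nu = K, nv = K)
      null_d[b, ] <- align_svd(axes$V, sp$u, sp$d[seq_len(K)],
                               sp$v)$d
    }
  })
  null_max <- apply(null_d, 1, max)
  p_fwe <- vapply(seq_len(K), function(i) {
    (1 + sum(null_max >= axes$d[i])) / (n_perm + 1)
  }, numeric(1))
  p_unc <- vapply(seq_len(K), function(i) {
    (1 + sum(null_d[, i] >= axes$d[i])) / (n_perm + 1)
  }, numeric(1))
  list(p = p_fwe, p_uncorrected = p_unc, null_max = null_max, null_d = null_d)
}

#' Bootstrap stability of axis loadings
#'
#' Resamples subjects with replacement, recomputes and Procrustes-aligns the
#' cross-covariance SVD, and summarizes per-loading percentile confidence
#' intervals (stable when the interval excludes zero) and bootstrap ratios
#' (original loading over the replicate SD, capped at 1e6 with a degeneracy
#' flag). Resamples with fewer than 3 distinct subjects are redrawn.
#'
#' @param X,Y As in [cross_covariance_svd()].
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param level Confidence level of the percentile intervals.
#' @param seed Optional integer seed.
#' @param axes Optional precomputed observed decomposition.
#' @return A list with `stable_U`, `stable_V` (logical matrices),
#'   `ratio_U`, `ratio_V`, and the interval bounds.
#' @export
bootstrap_stability <- function(X, Y, n_boot = 1000, level = 0.95,
                                seed = NULL, axes = NULL) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  axes <- axes %||% cross_covariance_svd(X, Y)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); K <- length(axes$d)
  Ub <- array(NA_real_, c(dim(axes$U), n_boot))
  Vb <- array(NA_real_, c(dim(axes$V), n_boot))
  redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(idx)) >= 3) break
        redraws <- redraws + 1L
      }
      sp <- svd(crossprod(X[idx, , drop = FALSE], Y[idx, , drop = FALSE]) / (n - 1),
                nu = K, nv = K)
      al <- align_svd(axes$V, sp$u, sp$d[seq_len(K)], sp$v)
      Ub[, , b] <- al$U
      Vb[, , b] <- al$V
    }
  })
  if (redraws > 0) message(redraws, " bootstrap resamples redrawn (<3 distinct subjects)")
  qlo <- (1 - level) / 2; qhi <- 1 - qlo
  summarize <- function(orig, arr) {
    lo <- apply(arr, c(1, 2), stats::quantile, probs = qlo)
    hi <- apply(arr, c(1, 2), stats::quantile, probs = qhi)
    sdv <- apply(arr, c(1, 2), stats::sd)
    degen <- sdv < abs(orig) / 1e6
    ratio <- orig / pmax(sdv, abs(orig) / 1e6)
    list(stable = lo > 0 | hi < 0, lower = lo, upper = hi,
         ratio = ratio, degenerate = degen)
  }
  su <- summarize(axes$U, Ub)
  sv <- summarize(axes$V, Vb)
  list(stable_U = su$stable, stable_V = sv$stable,
       ratio_U = su$ratio, ratio_V = sv$ratio,
       lower_U = su$lower, upper_U = su$upper,
       lower_V = sv$lower, upper_V = sv$upper,
       degenerate_U = su$degenerate, degenerate_V = sv$degenerate,
       level = level, n_boot = n_boot)
}

#' Per-parameter variance attribution along an axis
#'
#' The share of one latent component carried by each mechanism parameter:
#' `U_ij^2` normalized over the included (by default the bootstrap-stable)
#' parameters of component `i`; shares sum to one within the component.
#' Optionally aggregates shares by parameter group, scaled by the
#' component's covariance-explained fraction.
#'
#' @param axes A [cross_covariance_svd()] result.
#' @param component Component index.
#' @param stable Optional logical mask over parameters (e.g. a column of
#'   [bootstrap_stability()]`$stable_U`); default: all parameters.
#' @param grouping Optional map with columns `parameter`, `family` (e.g.
#'   [receptor_grouping()] with labels matched to `rownames(axes$U)`).
#' @return A list with `share` (named, sums to 1 over included parameters)
#'   and, when grouped, `group_share` (share of total covariance per group).
#' @export
variance_per_parameter <- function(axes, component, stable = NULL,
                                   grouping = NULL) {
  u <- axes$U[, component]
  inc <- stable %||% rep(TRUE, length(u))
  if (!any(inc)) {
    warning("no stable parameters for component ", component)
    return(list(share = numeric(0), group_share = NULL))
  }
  share <- numeric(length(u))
  names(share) <- rownames(axes$U)
  share[inc] <- u[inc]^2 / sum(u[inc]^2)
  out <- list(share = share[inc])
  if (!is.null(grouping)) {
    fam <- grouping$family[match(names(share)[inc], grouping$parameter)]
    if (anyNA(fam)) {
      stop("unmapped parameter label(s): ",
           paste(names(share)[inc][is.na(fam)], collapse = ", "))
    }
    gs <- tapply(share[inc], fam, sum) * axes$covariance_explained[component]
    out$group_share <- gs
  }
  out
}

#' Mechanism-symptom axes analysis for a fitted cohort
#'
#' End-to-end wrapper: extracts the subject-by-678 coefficient matrix from a
#' cohort fit, computes per-subject clinical decline slopes, adjusts both
#' sides for baseline age, education and sex, z-scores, and runs the
#' cross-covariance SVD with permutation significance and bootstrap
#' stability.
#'
#' @param fit An [remcm()] full-model fit.
#' @param cohort The [cohort()] that was fitted (must carry clinical
#'   records).
#' @param n_perm,n_boot Permutation/bootstrap iterations (default 1000
#'   each).
#' @param level Bootstrap confidence level.
#' @param seed Optional integer seed.
#' @param explained Covariance-explained convention, see
#'   [cross_covariance_svd()].
#' @return An object of class `remcm_axes_analysis` bundling the observed
#'   axes, permutation p-values, bootstrap masks and the adjusted matrices.
#' @export
symptom_axes <- function(fit, cohort, n_perm = 1000, n_boot = 1000,
                         level = 0.95, seed = NULL,
                         explained = c("squared", "linear")) {
  explained <- match.arg(explained)
  stopifnot(inherits(fit, "remcm"), inherits(cohort, "remcm_cohort"))
  if (is.null(cohort$clinical)) stop("cohort carries no clinical records")
  Xraw <- coef(fit)
  ids <- rownames(Xraw)[stats::complete.cases(coef(fit))]
  Xraw <- Xraw[ids, , drop = FALSE]
  Yraw <- t(vapply(cohort$clinical[ids], clinical_slopes,
                   numeric(nrow(cohort$clinical[[1]]$scores))))
  keep <- !apply(is.na(Yraw), 1, any)
  if (!all(keep)) {
    message(sum(!keep), " subject(s) dropped: incomplete clinical slopes")
  }
  ids <- ids[keep]
  Xraw <- Xraw[keep, , drop = FALSE]; Yraw <- Yraw[keep, , drop = FALSE]
  covs <- t(vapply(cohort$clinical[ids], function(r) r$covariates, numeric(3)))
  X <- adjust_covariates(Xraw, covs)
  Y <- adjust_covariates(Yraw, covs)
  axes <- cross_covariance_svd(X, Y, explained = explained)
  seeds <- child_seeds(seed, 2)
  perm <- permutation_test_axes(X, Y, n_perm = n_perm, seed = seeds[[1]],
                                axes = axes)
  boot <- bootstrap_stability(X, Y, n_boot = n_boot, level = level,
                              seed = seeds[[2]], axes = axes)
  structure(
    list(axes = axes, permutation = perm, bootstrap = boot,
         X = X, Y = Y, subject_ids = ids),
    class = "remcm_axes_analysis"
  )
}

#' @export
print.remcm_axes_analysis <- function(x, ...) {
  K <- length(x$axes$d)
  cat("Mechanism-symptom latent axes (", x$axes$n, " subjects)\n", sep = "")
  df <- data.frame(
    component = seq_len(K),
    singular_value = x$axes$d,
    covariance_explained = x$axes$covariance_explained,
    projection_r = x$axes$projection_r,
    p_fwe = x$permutation$p)
  print.data.frame(utils::head(df, 5), digits = 3, row.names = FALSE)
  if (K > 5) cat("  ... (", K - 5, " more components)\n", sep = "")
  invisible(x)
}
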