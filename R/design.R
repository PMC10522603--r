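#' Predictor labels of a factor model
#'
#' Column labels of the design matrix for one target factor, in canonical
#' order: the direct factor terms, the receptor-by-factor interaction terms,
#' the direct receptor terms, the connectome propagation term, and the
#' intercept. With 6 factors and 15 receptors this is
#' 6 + 90 + 15 + 1 + 1 = 113 columns.
#'
#' @param factor_names Character vector of factor labels.
#' @param receptor_names Character vector of receptor labels (possibly a
#'   subset, or empty for the neuroimaging-only model).
#' @return Character vector of predictor labels.
#' @export
design_labels <- function(factor_names = factor_labels(),
                          receptor_names = receptor_labels()) {
  ix <- if (length(receptor_names)) {
    as.vector(vapply(factor_names,
                     function(n) paste0("ix:", n, ":", receptor_names),
                     character(length(receptor_names))))
  } else character(0)
  c(paste0("fac:", factor_names), ix,
    if (length(receptor_names)) paste0("rec:", receptor_names),
    "prop", "(Intercept)")
}

# Label of one coefficient of the stacked per-subject parameter vector.
mech_labels <- function(factor_names = factor_labels(),
                        receptor_names = receptor_labels()) {
  as.vector(vapply(factor_names, function(m) {
    paste0(m, "|", design_labels(factor_names, receptor_names))
  }, character(length(design_labels(factor_names, receptor_names)))))
}

#' Finite-difference rate of change of one factor
#'
#' For each consecutive visit pair `(t', t)` the local rate
#' `(S(t) - S(t')) / (t - t')`, per region.
#'
#' @param ts A [subject_ts()].
#' @param factor Target factor label.
#' @return A list with `rates` (`region x interval` matrix), `midpoints`
#'   (interval midpoint times) and `dt` (interval lengths, years).
#' @export
compute_rate_of_change <- function(ts, factor) {
  f <- match(factor, ts$factor_names)
  if (is.na(f)) stop("unknown factor: ", factor)
  tt <- ts$visit_times
  if (length(tt) < 2) stop("at least 2 visits are required")
  dt <- diff(tt)
  if (any(dt == 0)) stop("duplicate visit times give a zero-length interval")
  s <- ts$values[, f, , drop = TRUE]
  rates <- (s[, -1, drop = FALSE] - s[, -length(tt), drop = FALSE]) /
    rep(dt, each = nrow(s))
  list(rates = rates, midpoints = (tt[-1] + tt[-length(tt)]) / 2, dt = dt)
}

#' Connectome propagation term
#'
#' The net spread of one factor's pathology into each region along the
#' symmetric connectome: `p_i = sum_j C_ij (S_j - S_i)`. Over a symmetric
#' connectome the unweighted sum of `p` over regions telescopes to zero.
#'
#' @param ts A [subject_ts()].
#' @param factor Factor label.
#' @param conn A [connectome()] over the same regions.
#' @param visit Visit index at which the states are taken.
#' @return Numeric region vector.
#' @export
compute_propagation <- function(ts, factor, conn, visit) {
  f <- match(factor, ts$factor_names)
  if (is.na(f)) stop("unknown factor: ", factor)
  w <- unclass(conn)
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-12, check.attributes = FALSE))) {
    stop("propagation requires a symmetric connectome")
  }
  s <- ts$values[, f, visit]
  as.vector(w %*% s) - s * rowSums(w)
}

#' Build the per-subject, per-factor design matrix
#'
#' Assembles the linear-model predictors for the rate of change of one
#' target factor: states of all factors at the interval's start visit (or the
#' visit-pair midpoint average), receptor-by-factor interaction terms formed
#' from z-scored receptor densities, direct receptor terms, and the
#' propagation term, stacked over `region x interval` rows. All non-intercept
#' columns are standardized (mean 0, population SD 1) over rows; centers and
#' scales are retained so coefficients can be mapped back to the raw scale.
#'
#' @param ts A [subject_ts()] (values on the z-scored imaging scale).
#' @param factor Target factor label.
#' @param receptors A z-scored [receptor_matrix()].
#' @param conn A [connectome()].
#' @param receptor_subset `NULL` for all receptors (full model),
#'   `character(0)` for the neuroimaging-only restricted model, or a subset
#'   of receptor labels (a single label gives the single-receptor model).
#' @param states_at `"start"` evaluates predictor states at the interval's
#'   start visit (forward difference); `"midpoint"` averages the two visits.
#' @return An object of class `remcm_design`: list with `X`, `y`, `labels`,
#'   `center`, `scale`, `degenerate`, and row metadata.
#' @export
build_design_matrix <- function(ts, factor, receptors, conn,
                                receptor_subset = NULL,
                                states_at = c("start", "midpoint")) {
  states_at <- match.arg(states_at)
  fn <- ts$factor_names
  m <- match(factor, fn)
  if (is.na(m)) stop("unknown factor: ", factor)
  rsel <- if (is.null(receptor_subset)) colnames(receptors) else receptor_subset
  if (length(rsel) && !all(rsel %in% colnames(receptors))) {
    stop("unknown receptor(s): ",
         paste(setdiff(rsel, colnames(receptors)), collapse = ", "))
  }
  R <- length(ts$region_names)
  V <- length(ts$visit_times)
  nI <- V - 1
  rc <- compute_rate_of_change(ts, factor)
  y <- as.vector(rc$rates)

  rec <- unclass(receptors)[ts$region_names, rsel, drop = FALSE]
  state_at <- function(v) {
    if (states_at == "start") ts$values[, , v, drop = TRUE]
    else (ts$values[, , v, drop = TRUE] + ts$values[, , v + 1, drop = TRUE]) / 2
  }
  direct <- do.call(rbind, lapply(seq_len(nI), state_at))
  prop <- unlist(lapply(seq_len(nI), function(v) {
    s <- if (states_at == "start") ts$values[, m, v]
         else (ts$values[, m, v] + ts$values[, m, v + 1]) / 2
    w <- unclass(conn)
    as.vector(w %*% s) - s * rowSums(w)
  }))
  rec_rows <- rec[rep(seq_len(R), nI), , drop = FALSE]
  K <- length(rsel)
  inter <- if (K) {
    cols <- lapply(seq_along(fn), function(n) rec_rows * direct[, n])
    do.call(cbind, cols)
  } else NULL

  X <- cbind(direct, inter, if (K) rec_rows, prop, 1)
  labels <- design_labels(fn, rsel)
  colnames(X) <- labels
  p <- ncol(X)
  # standardize all non-intercept columns (population SD)
  mu <- colMeans(X)
  s <- sqrt(colMeans(X^2) - mu^2)
  mu[p] <- 0; s[p] <- 1  # intercept untouched
  degenerate <- s < 1e-12
  s[degenerate] <- 1
  X <- sweep(X, 2, mu, "-")
  X <- sweep(X, 2, s, "/")
  X[, degenerate] <- 0
  X[, p] <- 1
  center <- mu; scale <- s
  structure(
    list(X = X, y = y, labels = labels, center = center, scale = scale,
         degenerate = degenerate, factor = factor,
         receptor_subset = rsel, states_at = states_at,
         rows = list(region = rep(ts$region_names, nI),
                     interval = rep(seq_len(nI), each = R)),
         subject_id = ts$subject_id),
    class = "remcm_design"
  )
}

#' Fit one factor model by ordinary least squares
#'
#' Fits the standardized design by OLS. Columns that are degenerate or
#' near-collinear (absolute correlation above 0.9999 with an earlier column)
#' are pruned and reported with zero coefficients. The coefficient of
#' determination uses the subject-wise mean of the rate targets over all
#' regions and intervals, and is stored unclipped.
#'
#' @param design A `remcm_design` from [build_design_matrix()].
#' @param leverage Compute row leverages (needed for
#'   [studentize_residuals()]); can be switched off in permutation loops
#'   that only use the fit's R-squared.
#' @return An object of class `remcm_factor_fit` with standardized and
#'   raw-scale coefficients, residuals, leverages, `r_squared`, `rss` and
#'   degrees of freedom.
#' @export
fit_factor_model <- function(design, leverage = TRUE) {
  X <- design$X; y <- design$y
  n <- nrow(X); p <- ncol(X)
  if (n <= p) {
    stop("under-determined fit: ", n, " rows for ", p,
         " columns; use a restricted receptor subset or more visits/regions")
  }
  keep <- !design$degenerate
  # prune near-collinear duplicates among the kept non-intercept columns;
  # columns are standardized, so the correlation is just crossprod(X)/n
  kept_idx <- which(keep & design$labels != "(Intercept)")
  if (length(kept_idx) > 1) {
    cc <- crossprod(X[, kept_idx, drop = FALSE]) / n
    drop <- logical(length(kept_idx))
    for (a in seq_along(kept_idx)[-1]) {
      if (any(abs(cc[a, seq_len(a - 1)]) > 0.9999 & !drop[seq_len(a - 1)])) {
        drop[a] <- TRUE
      }
    }
    keep[kept_idx[drop]] <- FALSE
  }
  fit <- stats::lm.fit(X[, keep, drop = FALSE], y)
  alpha_std <- numeric(p)
  names(alpha_std) <- design$labels
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  alpha_std[keep] <- cf
  pruned <- design$labels[!keep | (keep & seq_len(p) %in%
                                     which(keep)[is.na(fit$coefficients)])]
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  # leverages from the QR factorization of the retained columns
  rank <- fit$rank
  h <- NULL
  if (leverage) {
    Q <- qr.qy(fit$qr, diag(1, n, rank))
    h <- rowSums(Q^2)
  }
  # raw-scale coefficients: invert the column standardization
  nonint <- design$labels != "(Intercept)"
  alpha_raw <- alpha_std
  alpha_raw[nonint] <- alpha_std[nonint] / design$scale[nonint]
  alpha_raw["(Intercept)"] <- alpha_std["(Intercept)"] -
    sum(alpha_std[nonint] * design$center[nonint] / design$scale[nonint])
  structure(
    list(subject_id = design$subject_id, factor = design$factor,
         alpha = alpha_std, alpha_raw = alpha_raw,
         residuals = res, fitted = fit$fitted.values, leverage = h,
         r_squared = r2, rss = rss, tss = tss,
         n_rows = n, n_params = p, rank = rank,
         df_residual = n - rank, pruned = pruned,
         receptor_subset = design$receptor_subset,
         labels = design$labels, rows = design$rows),
    class = "remcm_factor_fit"
  )
}

#' @export
print.remcm_factor_fit <- function(x, ...) {
  cat("re-MCM factor model: subject", x$subject_id, "factor", x$factor, "\n")
  cat(sprintf("  %d rows, %d predictors (rank %d), R^2 = %.4f\n",
              x$n_rows, x$n_params, x$rank, x$r_squared))
  if (length(x$pruned)) {
    cat("  pruned columns:", paste(x$pruned, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.remcm_factor_fit <- function(object, scale = c("standardized", "raw"), ...) {
  scale <- match.arg(scale)
  if (scale == "standardized") object$alpha else object$alpha_raw
}

#' @export
residuals.remcm_factor_fit <- function(object, ...) object$residuals

#' @export
fitted.remcm_factor_fit <- function(object, ...) object$fitted
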