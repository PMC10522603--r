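#' Identify mechanisms stable across subjects
#'
#' For each (factor, parameter) pair, computes the confidence interval for
#' the across-subject mean coefficient; a mechanism is "stable" when the
#' interval excludes zero. The default interval is the t-interval; a
#' bootstrap percentile interval is available. Within each factor, the mean
#' absolute coefficients of the stable mechanisms are normalized to shares
#' summing to one. No multiple-testing correction is applied across the
#' parameters; the confidence level is the only screen.
#'
#' @param fit An [remcm()] fit, or a `subject x parameter` coefficient
#'   matrix with `"<factor>|<term>"` column names.
#' @param level Confidence level (default 0.99).
#' @param method `"t"` or `"bootstrap"` (percentile).
#' @param n_boot Bootstrap replicates when `method = "bootstrap"`.
#' @param scale Coefficient scale when `fit` is an [remcm()] object.
#' @param seed Optional integer seed (bootstrap only).
#' @return A data frame of class `remcm_stability` with columns `factor`,
#'   `parameter`, `mean`, `lower`, `upper`, `stable`, `mean_abs`, `share`.
#' @export
stable_mechanisms <- function(fit, level = 0.99,
                              method = c("t", "bootstrap"), n_boot = 1000,
                              scale = "standardized", seed = NULL) {
  method <- match.arg(method)
  x <- if (inherits(fit, "remcm")) coef(fit, scale = scale) else as.matrix(fit)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 2) stop("at least 2 subjects with complete fits are required")
  if (n < 5) warning("fewer than 5 subjects; stability intervals are fragile")
  lab <- strsplit(colnames(x), "|", fixed = TRUE)
  fac <- vapply(lab, `[`, "", 1)
  par <- vapply(lab, `[`, "", 2)
  mu <- colMeans(x)
  if (method == "t") {
    se <- apply(x, 2, stats::sd) / sqrt(n)
    tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
    lower <- mu - tq * se
    upper <- mu + tq * se
  } else {
    qs <- with_seed(seed, {
      idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
      means <- idx
      means <- t(apply(idx, 1, function(ii) colMeans(x[ii, , drop = FALSE])))
      apply(means, 2, stats::quantile,
            probs = c((1 - level) / 2, 1 - (1 - level) / 2))
    })
    lower <- qs[1, ]; upper <- qs[2, ]
  }
  stable <- lower > 0 | upper < 0
  mean_abs <- colMeans(abs(x))
  share <- numeric(length(mu))
  for (f in unique(fac)) {
    sel <- fac == f & stable
    tot <- sum(mean_abs[sel])
    if (tot > 0) share[sel] <- mean_abs[sel] / tot
  }
  out <- data.frame(factor = fac, parameter = par, mean = mu,
                    lower = lower, upper = upper, stable = stable,
                    mean_abs = mean_abs, share = share, row.names = NULL)
  class(out) <- c("remcm_stability", "data.frame")
  attr(out, "level") <- level
  attr(out, "method") <- method
  attr(out, "n_subjects") <- n
  out
}

#' @export
print.remcm_stability <- function(x, n = 10, ...) {
  lvl <- attr(x, "level")
  if (!is.null(lvl)) {
    cat(sprintf("Stable re-MCM mechanisms (%s interval, level %.3g, %d subjects)\n",
                attr(x, "method"), lvl, attr(x, "n_subjects")))
  }
  cat(sprintf("  %d of %d parameters stable; top by within-factor share:\n",
              sum(x$stable), nrow(x)))
  top <- as.data.frame(x)[order(-x$share), , drop = FALSE]
  print.data.frame(utils::head(top, n), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Default grouping of model parameters
#'
#' Maps every predictor label to a receptor family ("glutamate", "GABA",
#' "acetylcholine", "noradrenaline", "serotonin", "dopamine") or a
#' non-receptor class ("factor" for direct factor terms, "network" for
#' propagation, "baseline" for the intercept), and to a mechanism class
#' ("direct-factor", "interaction", "direct-receptor", "propagation",
#' "intercept"). The receptor-to-family map ships as a versioned YAML under
#' `inst/extdata/receptor_families.yaml`.
#'
#' @param factor_names,receptor_names Labels.
#' @param families Optional named list mapping family name to receptor
#'   labels (default: read from the shipped YAML).
#' @return A data frame with columns `parameter`, `family`, `class`.
#' @export
receptor_grouping <- function(factor_names = factor_labels(),
                              receptor_names = receptor_labels(),
                              families = NULL) {
  if (is.null(families)) {
    families <- yaml::read_yaml(
      system.file("extdata", "receptor_families.yaml", package = "remcm"))$families
  }
  fam_of <- function(k) {
    hit <- names(families)[vapply(families, function(v) k %in% v, TRUE)]
    if (!length(hit)) stop("receptor '", k, "' has no family mapping")
    hit[1]
  }
  labs <- design_labels(factor_names, receptor_names)
  fam <- character(length(labs)); cls <- character(length(labs))
  for (i in seq_along(labs)) {
    l <- labs[i]
    if (startsWith(l, "fac:")) { fam[i] <- "factor"; cls[i] <- "direct-factor" }
    else if (startsWith(l, "ix:")) {
      fam[i] <- fam_of(sub("^ix:[^:]+:", "", l)); cls[i] <- "interaction"
    } else if (startsWith(l, "rec:")) {
      fam[i] <- fam_of(sub("^rec:", "", l)); cls[i] <- "direct-receptor"
    } else if (l == "prop") { fam[i] <- "network"; cls[i] <- "propagation" }
    else { fam[i] <- "baseline"; cls[i] <- "intercept" }
  }
  data.frame(parameter = labs, family = fam, class = cls)
}

#' Grouped effect sizes of stable mechanisms
#'
#' Sums the mean absolute coefficients of stable mechanisms within each
#' (factor, family) group and normalizes within factor, the tabular analogue
#' of a receptor-by-factor effect summary. Factors without any stable
#' mechanism are reported with share 0 and flagged.
#'
#' @param stability A [stable_mechanisms()] table.
#' @param grouping A parameter-to-family map as from [receptor_grouping()].
#' @return A data frame with columns `factor`, `family`, `share`,
#'   `n_stable`, `any_stable`.
#' @export
effect_size_summary <- function(stability, grouping = receptor_grouping()) {
  unmapped <- setdiff(unique(stability$parameter), grouping$parameter)
  if (length(unmapped)) {
    stop("unmapped parameter label(s): ", paste(unmapped, collapse = ", "))
  }
  fam <- grouping$family[match(stability$parameter, grouping$parameter)]
  out <- list()
  for (f in unique(stability$factor)) {
    sel <- stability$factor == f & stability$stable
    tot <- sum(stability$mean_abs[sel])
    fams <- sort(unique(grouping$family))
    for (g in fams) {
      gsel <- sel & fam == g
      out[[paste(f, g)]] <- data.frame(
        factor = f, family = g,
        share = if (tot > 0) sum(stability$mean_abs[gsel]) / tot else 0,
        n_stable = sum(gsel), any_stable = tot > 0)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
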