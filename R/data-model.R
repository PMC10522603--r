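#' Canonical factor and receptor labels
#'
#' The six imaging-derived biological factors (gray matter density, fALFF,
#' DAT-SPECT uptake, fractional anisotropy, mean diffusivity, t1/t2 ratio) and
#' the fifteen neurotransmitter receptor types used throughout the package.
#' ASCII-safe spellings are used for receptor names (e.g. `alpha4beta2` for
#' the nicotinic receptor, `5HT1A`/`5HT2` for the serotonergic receptors).
#'
#' @return A character vector of labels.
#' @export
factor_labels <- function() c("GM", "fALFF", "DAT", "FA", "MD", "t1t2")

#' @rdname factor_labels
#' @export
receptor_labels <- function() {
  c("AMPA", "NMDA", "kainate", "GABAA", "GABAB", "BZ",
    "M1", "M2", "M3", "alpha4beta2", "alpha1", "alpha2",
    "5HT1A", "5HT2", "D1")
}

#' Per-subject longitudinal regional imaging series
#'
#' Container for one subject's regional values of several biological factors
#' over imaging visits, i.e. the state variables \eqn{S_{m,i}(t)} of the
#' dynamical model.
#'
#' @param subject_id Subject identifier (scalar character).
#' @param values Numeric array `region x factor x visit`; all values finite.
#' @param visit_times Numeric vector of visit times in years since baseline,
#'   strictly increasing, one per visit.
#' @param region_names,factor_names Optional dimension labels; taken from
#'   `dimnames(values)` when present.
#'
#' @return An object of class `subject_ts`.
#' @export
subject_ts <- function(subject_id, values, visit_times,
                       region_names = NULL, factor_names = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  region_names <- region_names %||% dimnames(values)[[1]] %||%
    sprintf("R%03d", seq_len(dim(values)[1]))
  factor_names <- factor_names %||% dimnames(values)[[2]] %||%
    factor_labels()[seq_len(dim(values)[2])]
  if (length(visit_times) != dim(values)[3]) {
    stop("visit_times length must match the third dimension of values")
  }
  if (any(diff(visit_times) <= 0)) {
    stop("visit_times must be strictly increasing")
  }
  if (length(visit_times) < 2) stop("at least 2 visits are required")
  if (dim(values)[2] < 2) stop("at least 2 factors are required")
  if (!all(is.finite(values))) {
    stop("all imaging values must be finite; incomplete imaging is not supported")
  }
  dimnames(values) <- list(region_names, factor_names, NULL)
  structure(
    list(subject_id = as.character(subject_id), values = values,
         visit_times = as.numeric(visit_times),
         region_names = region_names, factor_names = factor_names),
    class = "subject_ts"
  )
}

#' Regional receptor-density matrix
#'
#' @param densities Numeric `region x receptor` matrix without missing
#'   entries; row names are region labels.
#' @param receptor_names Optional column labels (default: column names of
#'   `densities`, else the canonical 15 receptor labels).
#'
#' @return An object of class `receptor_matrix` (a numeric matrix).
#' @export
receptor_matrix <- function(densities, receptor_names = NULL) {
  densities <- as.matrix(densities)
  receptor_names <- receptor_names %||% colnames(densities) %||%
    receptor_labels()[seq_len(ncol(densities))]
  if (anyNA(densities) || !all(is.finite(densities))) {
    stop("receptor densities must be complete and finite")
  }
  colnames(densities) <- receptor_names
  if (is.null(rownames(densities))) {
    rownames(densities) <- sprintf("R%03d", seq_len(nrow(densities)))
  }
  class(densities) <- c("receptor_matrix", class(matrix()))
  densities
}

#' Symmetric anatomical connectivity matrix
#'
#' @param weights Square numeric matrix of nonnegative connection weights;
#'   must be symmetric with a zero diagonal.
#'
#' @return An object of class `connectome` (a numeric matrix).
#' @export
connectome <- function(weights) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("connectome must be square")
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-12,
                        check.attributes = FALSE))) {
    stop("connectome must be symmetric (the propagation model assumes symmetric connectivity)")
  }
  if (any(weights < 0)) stop("connectome weights must be nonnegative")
  if (any(abs(diag(weights)) > 0)) stop("connectome diagonal must be zero")
  if (is.null(rownames(weights))) {
    rownames(weights) <- colnames(weights) %||%
      sprintf("R%03d", seq_len(nrow(weights)))
  }
  colnames(weights) <- rownames(weights)
  class(weights) <- c("connectome", class(matrix()))
  weights
}

#' Per-subject longitudinal clinical record
#'
#' Scores of the 11 clinical assessments over visits, with examination times
#' (years) and baseline covariates. Missing scores are allowed; an assessment
#' needs at least two non-missing visits to admit a decline slope.
#'
#' @param subject_id Subject identifier.
#' @param scores Numeric `assessment x visit` matrix; `NA` allowed.
#' @param exam_times Increasing numeric vector of exam times in years.
#' @param covariates Named numeric vector with elements `age`, `education`,
#'   `sex` (binary code).
#'
#' @return An object of class `clinical_record`.
#' @export
clinical_record <- function(subject_id, scores, exam_times, covariates) {
  scores <- as.matrix(scores)
  if (length(exam_times) != ncol(scores)) {
    stop("exam_times length must match the number of score columns")
  }
  if (any(diff(exam_times) <= 0)) stop("exam_times must be increasing")
  need <- c("age", "education", "sex")
  if (!all(need %in% names(covariates))) {
    stop("covariates must contain: ", paste(need, collapse = ", "))
  }
  if (is.null(rownames(scores))) rownames(scores) <- assessment_labels()[seq_len(nrow(scores))]
  structure(
    list(subject_id = as.character(subject_id), scores = scores,
         exam_times = as.numeric(exam_times),
         covariates = covariates[need]),
    class = "clinical_record"
  )
}

#' @rdname factor_labels
#' @export
assessment_labels <- function() {
  c("BJLOT", "GDS", "HVLT", "LNS", "NP1", "NP2", "NP3",
    "MoCA", "SF", "STAIAD", "SDM")
}

#' Assemble and validate a cohort
#'
#' Bundles the imaging series, clinical records, receptor matrix and
#' connectome, checking that region labels agree exactly (string identity, no
#' positional matching) and that subject identifiers are unique and matched
#' between the imaging and clinical lists.
#'
#' @param subjects List of [subject_ts()] objects.
#' @param receptors A [receptor_matrix()].
#' @param connectome A [connectome()].
#' @param clinical Optional list of [clinical_record()] objects (one per
#'   imaging subject, matched by `subject_id`).
#'
#' @return An object of class `remcm_cohort`.
#' @export
cohort <- function(subjects, receptors, connectome, clinical = NULL) {
  stopifnot(length(subjects) >= 1)
  regions <- subjects[[1]]$region_names
  for (s in subjects) {
    bad <- union(setdiff(s$region_names, regions), setdiff(regions, s$region_names))
    if (length(bad)) {
      stop("region labels differ between subjects: ", paste(bad, collapse = ", "))
    }
  }
  check_regions <- function(lbls, what) {
    bad <- union(setdiff(lbls, regions), setdiff(regions, lbls))
    if (length(bad)) {
      stop("region labels of ", what, " do not match the imaging regions: ",
           paste(bad, collapse = ", "))
    }
  }
  check_regions(rownames(receptors), "receptor matrix")
  check_regions(rownames(connectome), "connectome")
  # align row order to the imaging region order
  receptors <- receptor_matrix(unclass(receptors)[regions, , drop = FALSE])
  cw <- unclass(connectome)[regions, regions, drop = FALSE]
  class(cw) <- c("connectome", class(matrix()))
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stop("subject ids must be unique")
  names(subjects) <- ids
  if (!is.null(clinical)) {
    cids <- vapply(clinical, function(r) r$subject_id, character(1))
    if (anyDuplicated(cids)) stop("clinical subject ids must be unique")
    miss <- setdiff(ids, cids)
    extra <- setdiff(cids, ids)
    if (length(miss) || length(extra)) {
      stop("imaging and clinical subject ids are not matched; missing: ",
           paste(miss, collapse = ", "), "; unmatched: ",
           paste(extra, collapse = ", "))
    }
    names(clinical) <- cids
    clinical <- clinical[ids]
  }
  structure(
    list(subjects = subjects, receptors = receptors, connectome = cw,
         clinical = clinical, region_names = regions,
         factor_names = subjects[[1]]$factor_names),
    class = "remcm_cohort"
  )
}

#' @export
print.remcm_cohort <- function(x, ...) {
  cat("remcm cohort:", length(x$subjects), "subjects,",
      length(x$region_names), "regions,",
      length(x$factor_names), "factors,",
      ncol(x$receptors), "receptors\n")
  cat("  visits per subject:",
      paste(range(vapply(x$subjects, function(s) length(s$visit_times), 1L)),
            collapse = "-"), "\n")
  cat("  clinical records:", if (is.null(x$clinical)) "none" else length(x$clinical), "\n")
  invisible(x)
}

#' Z-score imaging values per modality
#'
#' Standardizes each biological factor (modality) by the pooled mean and
#' population SD across all regions, visits and (by default) subjects of that
#' modality, so that one scale applies cohort-wide and between-subject
#' severity differences are preserved. `scope = "subject"` standardizes
#' within each subject instead.
#'
#' @param cohort A [cohort()].
#' @param scope `"pooled"` (default) or `"subject"`.
#' @return The cohort with standardized imaging values; the applied centers
#'   and scales are stored in `attr(, "imaging_scaling")`.
#' @export
zscore_imaging <- function(cohort, scope = c("pooled", "subject")) {
  scope <- match.arg(scope)
  fn <- cohort$factor_names
  scaling <- list()
  if (scope == "pooled") {
    for (f in seq_along(fn)) {
      pool <- unlist(lapply(cohort$subjects, function(s) s$values[, f, ]))
      mu <- mean(pool); sd <- pop_sd(pool)
      if (sd < .Machine$double.eps * max(1, abs(mu))) {
        stop("degenerate input: modality '", fn[f], "' has zero pooled variance")
      }
      for (i in seq_along(cohort$subjects)) {
        cohort$subjects[[i]]$values[, f, ] <-
          (cohort$subjects[[i]]$values[, f, ] - mu) / sd
      }
      scaling[[fn[f]]] <- c(center = mu, scale = sd)
    }
  } else {
    for (i in seq_along(cohort$subjects)) {
      for (f in seq_along(fn)) {
        v <- cohort$subjects[[i]]$values[, f, ]
        mu <- mean(v); sd <- pop_sd(v)
        if (sd < .Machine$double.eps * max(1, abs(mu))) {
          stop("degenerate input: modality '", fn[f], "' constant for subject ",
               cohort$subjects[[i]]$subject_id)
        }
        cohort$subjects[[i]]$values[, f, ] <- (v - mu) / sd
      }
    }
  }
  attr(cohort, "imaging_scaling") <- scaling
  cohort
}

#' Z-score receptor densities across regions
#'
#' Each receptor column is normalized by its mean and population SD across
#' regions; idempotent on already-normalized input.
#'
#' @param receptors A [receptor_matrix()].
#' @return A [receptor_matrix()] with column mean 0 and SD 1.
#' @export
zscore_receptors <- function(receptors) {
  m <- unclass(receptors)
  for (j in seq_len(ncol(m))) {
    s <- pop_sd(m[, j])
    if (s < .Machine$double.eps * max(1, abs(mean(m[, j])))) {
      stop("degenerate input: receptor '", colnames(m)[j],
           "' is constant across regions")
    }
    m[, j] <- (m[, j] - mean(m[, j])) / s
  }
  receptor_matrix(m)
}

req_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("format error in ", what, " table: missing column(s) ",
         paste(miss, collapse = ", "))
  }
}

#' Read a cohort from plain-text files
#'
#' File dialects: imaging is a long-format CSV with columns
#' `subject_id,factor,region,visit_time,value`; receptors a TSV whose first
#' column is `region` followed by one named column per receptor; the
#' connectome a square TSV with region labels as header and first column;
#' clinical a long CSV `subject_id,assessment,exam_time,score` plus a
#' covariates CSV `subject_id,age,education,sex`. Values are stored raw
#' (un-normalized); apply [zscore_imaging()] / [zscore_receptors()] for the
#' modeling views.
#'
#' @param imaging_path,receptor_path,connectome_path Paths to the imaging,
#'   receptor and connectome tables.
#' @param clinical_path,covariates_path Optional paths to the clinical score
#'   and covariate tables.
#' @param time_unit `"years"` (default) or `"months"`; month columns are
#'   converted to years on load.
#' @return A validated [cohort()].
#' @export
read_cohort <- function(imaging_path, receptor_path, connectome_path,
                        clinical_path = NULL, covariates_path = NULL,
                        time_unit = c("years", "months")) {
  time_unit <- match.arg(time_unit)
  tconv <- if (time_unit == "months") 1 / 12 else 1
  img <- utils::read.csv(imaging_path, stringsAsFactors = FALSE)
  req_cols(img, c("subject_id", "factor", "region", "visit_time", "value"), "imaging")
  rec <- utils::read.delim(receptor_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  req_cols(rec, "region", "receptor")
  recm <- as.matrix(rec[, setdiff(names(rec), "region"), drop = FALSE])
  rownames(recm) <- rec$region
  conn <- as.matrix(utils::read.delim(connectome_path, row.names = 1,
                                      check.names = FALSE))
  colnames(conn) <- rownames(conn)

  subjects <- lapply(split(img, img$subject_id), function(d) {
    # visit order is taken as given in the file; subject_ts() rejects
    # non-monotone times rather than silently reordering them
    visits <- unique(d$visit_time) * tconv
    fns <- unique(d$factor)
    rgs <- unique(d$region)
    arr <- array(NA_real_, c(length(rgs), length(fns), length(visits)),
                 dimnames = list(rgs, fns, NULL))
    arr[cbind(match(d$region, rgs), match(d$factor, fns),
              match(d$visit_time * tconv, visits))] <- d$value
    if (anyNA(arr)) {
      stop("imaging table for subject ", d$subject_id[1],
           " is incomplete; every region x factor x visit cell is required")
    }
    subject_ts(d$subject_id[1], arr, visits)
  })

  clinical <- NULL
  if (!is.null(clinical_path)) {
    if (is.null(covariates_path)) stop("covariates_path is required with clinical_path")
    cl <- utils::read.csv(clinical_path, stringsAsFactors = FALSE)
    req_cols(cl, c("subject_id", "assessment", "exam_time", "score"), "clinical")
    cv <- utils::read.csv(covariates_path, stringsAsFactors = FALSE)
    req_cols(cv, c("subject_id", "age", "education", "sex"), "covariates")
    clinical <- lapply(split(cl, cl$subject_id), function(d) {
      times <- unique(d$exam_time) * tconv
      asmt <- unique(d$assessment)
      sc <- matrix(NA_real_, length(asmt), length(times),
                   dimnames = list(asmt, NULL))
      sc[cbind(match(d$assessment, asmt), match(d$exam_time * tconv, times))] <- d$score
      row <- cv[cv$subject_id == d$subject_id[1], ]
      if (nrow(row) != 1) stop("covariates missing for subject ", d$subject_id[1])
      clinical_record(d$subject_id[1], sc, times,
                      c(age = row$age, education = row$education, sex = row$sex))
    })
  }
  cohort(subjects, receptor_matrix(recm), connectome(conn), clinical)
}

#' Write a cohort to plain-text files
#'
#' Inverse of [read_cohort()]; numeric fields round-trip to full double
#' precision.
#'
#' @param cohort A [cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(imaging = file.path(dir, "imaging.csv"),
             receptors = file.path(dir, "receptors.tsv"),
             connectome = file.path(dir, "connectome.tsv"))
  img <- do.call(rbind, lapply(cohort$subjects, function(s) {
    g <- expand.grid(region = s$region_names, factor = s$factor_names,
                     visit_time = s$visit_times, stringsAsFactors = FALSE)
    data.frame(subject_id = s$subject_id, factor = g$factor, region = g$region,
               visit_time = g$visit_time, value = as.vector(s$values))
  }))
  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  img$value <- fmt(img$value)
  img$visit_time <- fmt(img$visit_time)
  utils::write.csv(img, paths["imaging"], row.names = FALSE, quote = FALSE)
  rec <- data.frame(region = rownames(cohort$receptors),
                    apply(unclass(cohort$receptors), 2, fmt),
                    check.names = FALSE)
  utils::write.table(rec, paths["receptors"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  cw <- apply(unclass(cohort$connectome), 2, fmt)
  rownames(cw) <- rownames(cohort$connectome)
  utils::write.table(cw, paths["connectome"], sep = "\t", quote = FALSE,
                     col.names = NA)
  if (!is.null(cohort$clinical)) {
    paths["clinical"] <- file.path(dir, "clinical.csv")
    paths["covariates"] <- file.path(dir, "covariates.csv")
    cl <- do.call(rbind, lapply(cohort$clinical, function(r) {
      g <- expand.grid(assessment = rownames(r$scores),
                       exam_time = r$exam_times, stringsAsFactors = FALSE)
      data.frame(subject_id = r$subject_id, assessment = g$assessment,
                 exam_time = fmt(g$exam_time), score = fmt(as.vector(r$scores)))
    }))
    cl <- cl[cl$score != "NA", ]
    utils::write.csv(cl, paths["clinical"], row.names = FALSE, quote = FALSE)
    cv <- do.call(rbind, lapply(cohort$clinical, function(r) {
      data.frame(subject_id = r$subject_id, age = fmt(r$covariates["age"]),
                 education = fmt(r$covariates["education"]),
                 sex = r$covariates["sex"])
    }))
    utils::write.csv(cv, paths["covariates"], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Load an analysis configuration
#'
#' Reads a YAML configuration (paths, seed, iteration counts, thresholds) and
#' merges it over package defaults; all effective settings are reported via
#' `message()` so runs are self-documenting.
#'
#' @param path Optional path to a YAML file; `NULL` returns the defaults.
#' @return A named list of settings.
#' @export
remcm_config <- function(path = NULL) {
  defaults <- list(
    seed = 1L, n_perm = 1000L, n_boot = 1000L,
    stability_level = 0.99, bootstrap_level = 0.95,
    euler_dt = 0.01, zscore_scope = "pooled",
    states_at = "start", covariance_explained = "squared",
    time_unit = "years"
  )
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  message("remcm configuration: ",
          paste(names(cfg), vapply(cfg, function(v) paste(v, collapse = ","),
                                   character(1)),
                sep = "=", collapse = "; "))
  cfg
}
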