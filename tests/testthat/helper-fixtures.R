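# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A tiny hand-built cohort: 5 regions, 3 factors, 3 visits, 2 subjects.
tiny_cohort <- function() cached("tiny", function() {
  set.seed(404)
  R <- 5; fn <- c("GM", "fALFF", "DAT")
  mk <- function(id) {
    arr <- array(rnorm(R * 3 * 3), c(R, 3, 3),
                 dimnames = list(sprintf("R%03d", 1:R), fn, NULL))
    subject_ts(id, arr, c(0, 0.5, 1.1))
  }
  rec <- receptor_matrix(matrix(rnorm(R * 4), R,
                                dimnames = list(sprintf("R%03d", 1:R),
                                                c("AMPA", "NMDA", "GABAA", "D1"))))
  w <- matrix(runif(R * R), R); w <- w + t(w); diag(w) <- 0
  dimnames(w) <- list(sprintf("R%03d", 1:R), sprintf("R%03d", 1:R))
  cl <- lapply(c("a", "b"), function(id) {
    sc <- matrix(rnorm(11 * 3), 11, dimnames = list(assessment_labels(), NULL))
    clinical_record(id, sc, c(0, 0.5, 1.1),
                    c(age = 60 + rnorm(1), education = 14, sex = 1))
  })
  cohort(list(mk("a"), mk("b")), rec, connectome(w), cl)
})

# Small simulated cohort able to carry the full 113-column model:
# 4 subjects, 40 regions, 5 visits.
small_sim <- function() cached("small_sim", function() {
  simulate_cohort(n_subjects = 4, n_regions = 40,
                  visit_schedule = seq(0, 2, 0.5), seed = 101)
})

# Reference-geometry cohort (95 regions, 4 visits) with clinical records.
study_sim <- function() cached("study_sim", function() {
  simulate_cohort(n_subjects = 20, seed = 2024)
})

study_fit <- function() cached("study_fit", function() {
  remcm(study_sim()$cohort, normalize_imaging = FALSE)
})

# Truth-based mechanism/symptom matrices for axis tests (no imaging fits).
axes_xy <- function(n_subjects = 80, seed = 5150, clinical_noise = 0.5) {
  tr <- generate_ground_truth(n_subjects, seed = seed)
  recs <- generate_clinical_from_axes(tr, noise_sd = clinical_noise,
                                      seed = seed + 1L)
  X0 <- t(vapply(seq_len(n_subjects),
                 function(i) as.vector(t(tr$subject_alpha[i, , , drop = TRUE])),
                 numeric(length(tr$labels) * length(tr$factor_names))))
  colnames(X0) <- rownames(tr$latent$mechanism)
  covs <- t(vapply(recs, function(r) r$covariates, numeric(3)))
  X <- suppressWarnings(adjust_covariates(X0, covs))
  Y <- adjust_covariates(attr(recs, "slopes"), covs)
  list(X = X, Y = Y, truth = tr)
}

# Independent rank-sum oracle by pairwise counting (never calls rank()):
# midrank of v in the combined sample is #{c < v} + (#{c == v} + 1)/2,
# summed over the first sample's absolute values.
wilcoxon_oracle <- function(x, y) {
  x <- abs(x); y <- abs(y)
  n1 <- length(x)
  sum(outer(x, x, "<")) + sum(outer(y, x, "<")) +
    (sum(outer(x, x, "==")) + sum(outer(y, x, "=="))) / 2 + n1 / 2
}
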