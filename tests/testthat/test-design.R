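test_that("finite-difference rates follow the visit schedule", {
  arr <- array(0, c(3, 2, 4), dimnames = list(c("r1", "r2", "r3"),
                                              c("GM", "FA"), NULL))
  arr[, 1, ] <- matrix(c(0, 1, 1.5, 1.5), 3, 4, byrow = TRUE)
  arr[, 2, ] <- 2  # constant factor
  ts <- subject_ts("s", arr, c(0, 0.5, 1, 2))
  rc <- compute_rate_of_change(ts, "GM")
  expect_identical(dim(rc$rates), c(3L, 3L))
  expect_equal(rc$rates[1, ], c(2, 1, 0), ignore_attr = TRUE)
  expect_equal(compute_rate_of_change(ts, "FA")$rates, matrix(0, 3, 3),
               ignore_attr = TRUE)
  expect_error(compute_rate_of_change(ts, "MD"), "unknown factor")
})

test_that("propagation matches its definition and telescopes to zero", {
  # 2 regions, C12 = 2, S = (0, 1): p = (2, -2)
  w <- connectome(matrix(c(0, 2, 2, 0), 2,
                         dimnames = list(c("r1", "r2"), c("r1", "r2"))))
  arr <- array(0, c(2, 2, 2), dimnames = list(c("r1", "r2"), c("GM", "FA"), NULL))
  arr[, 1, 1] <- c(0, 1)
  ts <- subject_ts("s", arr, c(0, 0.5))
  expect_equal(compute_propagation(ts, "GM", w, 1), c(2, -2),
               ignore_attr = TRUE)
  # uniform states: zero vector
  arr[, 1, 1] <- 3
  expect_equal(compute_propagation(subject_ts("s", arr, c(0, 0.5)), "GM", w, 1),
               c(0, 0), ignore_attr = TRUE)
  # random 5-region instance against a double-loop oracle
  set.seed(9)
  R <- 5
  wm <- matrix(runif(R * R), R); wm <- wm + t(wm); diag(wm) <- 0
  dimnames(wm) <- list(paste0("r", 1:R), paste0("r", 1:R))
  a5 <- array(rnorm(R * 2 * 2), c(R, 2, 2),
              dimnames = list(paste0("r", 1:R), c("GM", "FA"), NULL))
  ts5 <- subject_ts("s", a5, c(0, 1))
  p <- compute_propagation(ts5, "GM", connectome(wm), 2)
  oracle <- vapply(1:R, function(i) {
    sum(vapply(1:R, function(j) wm[i, j] * (a5[j, 1, 2] - a5[i, 1, 2]),
               numeric(1)))
  }, numeric(1))
  expect_equal(p, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(abs(sum(p)), 1e-10)
  # asymmetric connectivity is rejected
  wbad <- wm; wbad[1, 2] <- wbad[1, 2] + 1
  expect_error(compute_propagation(ts5, "GM", structure(wbad, class = "connectome"), 1),
               "symmetric")
})

test_that("design matrices have the canonical column structure", {
  sim <- small_sim()
  ts <- sim$cohort$subjects[[1]]
  rec <- zscore_receptors(sim$cohort$receptors)
  d_full <- build_design_matrix(ts, "GM", rec, sim$cohort$connectome)
  d_restr <- build_design_matrix(ts, "GM", rec, sim$cohort$connectome,
                                 receptor_subset = character(0))
  d_one <- build_design_matrix(ts, "GM", rec, sim$cohort$connectome,
                               receptor_subset = "kainate")
  expect_identical(ncol(d_full$X), 113L)
  expect_identical(ncol(d_restr$X), 8L)
  expect_identical(ncol(d_one$X), 15L)
  expect_identical(nrow(d_full$X), 40L * 4L)
  # all non-intercept columns standardized
  nonint <- d_full$labels != "(Intercept)"
  expect_true(all(abs(colMeans(d_full$X[, nonint])) < 1e-10))
  sds <- apply(d_full$X[, nonint], 2, function(x) sqrt(mean((x - mean(x))^2)))
  expect_true(all(abs(sds - 1) < 1e-10))
  # interaction columns are receptor-by-state products before standardization
  j <- which(d_full$labels == "ix:FA:D1")
  raw <- rep(unclass(rec)[, "D1"], 4) *
    as.vector(vapply(1:4, function(v) ts$values[, "FA", v], numeric(40)))
  expect_equal(d_full$X[, j], (raw - mean(raw)) / sqrt(mean((raw - mean(raw))^2)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("OLS fit recovers exact targets and matches the normal equations", {
  sim <- small_sim()
  ts <- sim$cohort$subjects[[1]]
  rec <- zscore_receptors(sim$cohort$receptors)
  d <- build_design_matrix(ts, "MD", rec, sim$cohort$connectome,
                           receptor_subset = "M2")
  # exact linear target: R^2 = 1 and coefficients recovered
  beta <- rnorm(ncol(d$X))
  d2 <- d
  d2$y <- as.vector(d$X %*% beta)
  ft <- fit_factor_model(d2)
  expect_equal(ft$r_squared, 1, tolerance = 1e-10)
  expect_equal(ft$alpha, beta, tolerance = 1e-8, ignore_attr = TRUE)
  # mean-centered target orthogonal to every non-intercept column: R^2 = 0
  set.seed(1)
  y <- rnorm(nrow(d$X))
  Q <- qr(cbind(d$X))
  d3 <- d
  d3$y <- qr.resid(Q, y)
  ft0 <- fit_factor_model(d3)
  expect_equal(ft0$r_squared, 0, tolerance = 1e-10)
  # random instance against the normal-equations oracle
  set.seed(2)
  d$y <- rnorm(nrow(d$X))
  ft2 <- fit_factor_model(d)
  oracle <- solve(crossprod(d$X), crossprod(d$X, d$y))
  expect_equal(ft2$alpha, as.vector(oracle), tolerance = 1e-8,
               ignore_attr = TRUE)
  # residuals orthogonal to the design
  expect_lt(max(abs(crossprod(d$X, ft2$residuals))), 1e-6 * nrow(d$X))
  # raw-scale back-transform reproduces fitted values on raw predictors
  expect_equal(ft2$fitted,
               as.vector(sweep(sweep(d$X, 2, d$scale, "*"), 2, d$center, "+") %*%
                           ft2$alpha_raw),
               tolerance = 1e-8)
})

test_that("under-determined designs are refused with advice", {
  sim <- simulate_cohort(n_subjects = 1, n_regions = 20,
                         visit_schedule = c(0, 0.5, 1), seed = 55)
  ts <- sim$cohort$subjects[[1]]
  rec <- zscore_receptors(sim$cohort$receptors)
  d <- build_design_matrix(ts, "GM", rec, sim$cohort$connectome)
  expect_error(fit_factor_model(d), "restricted")
  # the restricted model still fits
  dr <- build_design_matrix(ts, "GM", rec, sim$cohort$connectome,
                            receptor_subset = character(0))
  expect_s3_class(fit_factor_model(dr), "remcm_factor_fit")
})

test_that("cohort fits satisfy nested dominance and counts", {
  sim <- small_sim()
  full <- remcm(sim$cohort, normalize_imaging = FALSE)
  restr <- remcm(sim$cohort, receptor_subset = character(0),
                 normalize_imaging = FALSE)
  one <- remcm(sim$cohort, receptor_subset = "GABAA",
               normalize_imaging = FALSE)
  expect_identical(sum(!is.na(full$r_squared)), 4L * 6L)
  expect_true(all(full$r_squared >= one$r_squared - 1e-10))
  expect_true(all(one$r_squared >= restr$r_squared - 1e-10))
  cf <- coef(full)
  expect_identical(dim(cf), c(4L, 678L))
  expect_false(anyNA(cf))
  # near-noiseless discrete cohort is explained almost perfectly
  simc <- simulate_cohort(n_subjects = 2, n_regions = 40,
                          visit_schedule = seq(0, 2, 0.5), seed = 66,
                          method = "discrete", noise_sd = 1e-4)
  fitc <- remcm(simc$cohort, normalize_imaging = FALSE)
  expect_gt(median(fitc$r_squared), 0.99)
})
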