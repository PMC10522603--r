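test_that("receptor-map generator yields z-scored, seed-stable maps", {
  r1 <- generate_receptor_maps(50, 6, smoothness = 0.4, seed = 3)
  r2 <- generate_receptor_maps(50, 6, smoothness = 0.4, seed = 3)
  expect_identical(unclass(r1), unclass(r2))
  expect_true(all(abs(colMeans(unclass(r1))) < 1e-8))
  sds <- apply(unclass(r1), 2, function(x) sqrt(mean((x - mean(x))^2)))
  expect_true(all(abs(sds - 1) < 1e-8))
  expect_error(generate_receptor_maps(50, smoothness = 1), "smoothness")
  expect_error(generate_receptor_maps(3), "n_regions")
  # smoothness 0: lag-1 spatial autocorrelation is near zero
  r0 <- generate_receptor_maps(200, 5, smoothness = 0, seed = 11)
  lag1 <- apply(unclass(r0), 2, function(x) cor(x[-1], x[-length(x)]))
  expect_true(all(abs(lag1) < 0.2))
  # positive smoothness induces clear neighbor correlation
  rs <- generate_receptor_maps(200, 5, smoothness = 0.7, seed = 11)
  lag1s <- apply(unclass(rs), 2, function(x) cor(x[-1], x[-length(x)]))
  expect_true(mean(lag1s) > 0.4)
})

test_that("connectome generator respects symmetry, density and seeds", {
  c1 <- generate_connectome(50, density = 0.2, seed = 9)
  expect_identical(unclass(c1), t(unclass(c1)))
  expect_true(all(diag(unclass(c1)) == 0))
  expect_true(all(unclass(c1) >= 0))
  ut <- unclass(c1)[upper.tri(unclass(c1))]
  frac <- mean(ut > 0)
  # binomial 99% band around 0.2 for choose(50,2) = 1225 draws
  band <- qbinom(c(0.005, 0.995), length(ut), 0.2) / length(ut)
  expect_gte(frac, band[1])
  expect_lte(frac, band[2])
  full <- generate_connectome(10, density = 1, seed = 2)
  expect_true(all(unclass(full)[upper.tri(unclass(full))] > 0))
  expect_error(generate_connectome(10, density = 0), "density")
})

test_that("ground truth is sparse with mean-preserving subject deviations", {
  tr <- generate_ground_truth(60, seed = 12)
  expect_true(all(rowSums(tr$support) <= 0.2 * length(tr$labels)))
  expect_identical(dim(tr$subject_alpha), c(60L, 6L, 113L))
  # across-subject mean of each coefficient matches the population value
  # within a few standard errors
  devs <- vapply(seq_len(6), function(m) {
    est <- colMeans(tr$subject_alpha[, m, ])
    se <- apply(tr$subject_alpha[, m, ], 2, sd) / sqrt(60)
    max(abs(est - tr$population_alpha[m, ]) / pmax(se, 1e-12))
  }, numeric(1))
  expect_true(all(devs < 5))
  # intercept has no generative counterpart
  expect_true(all(tr$subject_alpha[, , "(Intercept)"] == 0))
  # receptor-free truth places no mass on receptor terms
  trf <- generate_ground_truth(10, receptor_terms = FALSE, seed = 1)
  reccols <- grepl("^(ix|rec):", trf$labels)
  expect_true(all(trf$subject_alpha[, , reccols] == 0))
})

test_that("trajectories honour degenerate and conservation limits", {
  rec <- generate_receptor_maps(12, 4, seed = 5)
  conn <- generate_connectome(12, 0.5, seed = 6)
  tr <- generate_ground_truth(2, receptor_names = colnames(rec), seed = 7,
                              noise_sd = 0)
  # all-zero coefficients: trajectories constant at baseline
  tr0 <- tr
  tr0$population_alpha[] <- 0
  tr0$subject_alpha[] <- 0
  ts0 <- simulate_trajectories(tr0, rec, conn, c(0, 0.5, 1), seed = 8,
                               noise_sd = 0)
  expect_equal(ts0[[1]]$values[, , 3], ts0[[1]]$values[, , 1], tolerance = 1e-12)
  # propagation-only dynamics conserve the regional sum of each factor
  trp <- tr0
  trp$subject_alpha[, , "prop"] <- 0.05
  tsp <- simulate_trajectories(trp, rec, conn, c(0, 0.5, 1), seed = 8,
                               noise_sd = 0)
  sums <- apply(tsp[[1]]$values, c(2, 3), sum)
  for (m in 1:6) {
    expect_equal(sums[m, 2], sums[m, 1], tolerance = 1e-8)
    expect_equal(sums[m, 3], sums[m, 1], tolerance = 1e-8)
  }
})

test_that("discrete-mode rates reproduce the model right-hand side", {
  rec <- generate_receptor_maps(15, 4, seed = 15)
  conn <- generate_connectome(15, 0.5, seed = 16)
  tr <- generate_ground_truth(1, receptor_names = colnames(rec), seed = 17,
                              noise_sd = 0)
  ts <- simulate_trajectories(tr, rec, conn, c(0, 0.5, 1, 1.5), seed = 18,
                              method = "discrete", noise_sd = 0)
  tr <- attr(ts, "truth")
  op <- remcm:::build_operator(tr$subject_alpha[1, , , drop = TRUE], rec, conn,
                               tr$factor_names, tr$receptor_names)
  s <- ts[[1]]$values
  for (v in 1:3) {
    svec <- as.vector(s[, , v])
    rate <- as.vector(op$A %*% svec) + op$c
    fd <- as.vector((s[, , v + 1] - s[, , v]) / 0.5)
    expect_equal(fd, rate, tolerance = 1e-9)
  }
  # euler integration converges linearly in the sub-step
  run <- function(dt) simulate_trajectories(tr, rec, conn, c(0, 0.5, 1, 1.5),
                                            seed = 18, method = "euler",
                                            euler_dt = dt,
                                            noise_sd = 0)[[1]]$values
  ref <- run(0.001)
  errs <- vapply(c(0.05, 0.01, 0.002), function(dt) max(abs(run(dt) - ref)),
                 numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_gt(errs[1] / errs[2], 2)   # roughly first-order in dt
})

test_that("simulation guards reject unstable or ill-posed requests", {
  rec <- generate_receptor_maps(10, 3, seed = 1)
  conn <- generate_connectome(10, 0.5, seed = 2)
  tr <- generate_ground_truth(1, receptor_names = colnames(rec), seed = 3)
  expect_error(simulate_trajectories(tr, rec, conn, c(0, 0.5, 1),
                                     euler_dt = 0.2), "euler_dt")
  expect_error(simulate_trajectories(tr, rec, conn, c(0, 0.5),
                                     seed = 1), "3 visits")
  expect_error(simulate_trajectories(tr, rec, conn, c(0, 0.5, 1),
                                     noise_model = "process"), "discrete")
  # the spectral guard rescales explosive coefficients and says so
  trx <- tr
  trx$subject_alpha[, , "fac:GM"] <- 8
  expect_message(simulate_trajectories(trx, rec, conn, c(0, 0.5, 1), seed = 4),
                 "spectral guard")
})

test_that("planted clinical axes reproduce slopes and rank structure", {
  tr <- generate_ground_truth(40, seed = 31)
  recs <- generate_clinical_from_axes(tr, noise_sd = 0, covariate_effect = 0,
                                      seed = 32)
  planted <- attr(recs, "slopes")
  got <- t(vapply(recs, clinical_slopes, numeric(11)))
  expect_equal(unname(got), unname(planted), tolerance = 1e-10)
  # noiseless slopes built from planted axes give a rank-limited
  # cross-covariance with the generating parameters
  X <- t(vapply(seq_len(40), function(i) as.vector(t(tr$subject_alpha[i, , ])),
                numeric(678)))
  Xz <- apply(X, 2, function(x) if (sd(x) < 1e-14) 0 * x else (x - mean(x)) / sd(x))
  C <- crossprod(Xz, scale(planted, scale = FALSE)) / 39
  sv <- svd(C)$d
  expect_gt(sv[2], 1e-6)
  expect_lt(sv[3] / sv[1], 0.05)
})

test_that("cohort simulation is deterministic and carries matched clinical", {
  a <- simulate_cohort(n_subjects = 3, n_regions = 20, seed = 77,
                       visit_schedule = c(0, 0.5, 1))
  b <- simulate_cohort(n_subjects = 3, n_regions = 20, seed = 77,
                       visit_schedule = c(0, 0.5, 1))
  expect_identical(a$cohort$subjects[[2]]$values, b$cohort$subjects[[2]]$values)
  expect_identical(a$truth$subject_alpha, b$truth$subject_alpha)
  expect_identical(names(a$cohort$subjects), names(a$cohort$clinical))
})
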