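test_that("clinical slopes are exact line fits over available visits", {
  sc <- matrix(NA_real_, 11, 3, dimnames = list(assessment_labels(), NULL))
  sc[1, ] <- c(0, 1, NA)       # two points, slope 1 over 1 year
  sc[2, ] <- c(3, 3, 3)        # constant
  sc[3, ] <- c(0, 2, 4)        # exact line, slope 2
  sc[4, ] <- c(1, NA, NA)      # a single visit: no slope
  rec <- clinical_record("s", sc, c(0, 1, 2),
                         c(age = 60, education = 12, sex = 0))
  sl <- clinical_slopes(rec)
  expect_equal(sl[["BJLOT"]], 1)
  expect_equal(sl[["GDS"]], 0)
  expect_equal(sl[["HVLT"]], 2)
  expect_true(is.na(sl[["LNS"]]))
  expect_true("LNS" %in% attr(sl, "missing"))
})

test_that("covariate adjustment leaves orthogonal structure intact", {
  set.seed(3)
  n <- 50
  covs <- cbind(age = rnorm(n, 60, 8), edu = rnorm(n, 14, 3),
                sex = rbinom(n, 1, 0.5))
  x <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
  adj <- adjust_covariates(x, covs)
  # residuals orthogonal to each covariate
  expect_lt(max(abs(crossprod(cbind(1, covs), adj))), 1e-8 * n)
  expect_true(all(abs(colMeans(adj)) < 1e-8))
  # a feature exactly linear in age collapses and is dropped
  x2 <- cbind(x, bad = 2 * covs[, "age"] - 7)
  expect_warning(adj2 <- adjust_covariates(x2, covs), "degenerate")
  expect_identical(attr(adj2, "dropped"), "bad")
  expect_identical(ncol(adj2), 6L)
  # covariates orthogonal to a feature: only z-scoring happens
  xo <- qr.resid(qr(cbind(1, covs)), rnorm(n))
  adj3 <- adjust_covariates(cbind(only = xo), covs)
  expect_equal(as.vector(adj3), as.vector(scale(xo)) *
                 sd(xo) / sqrt(mean((xo - mean(xo))^2)),
               tolerance = 1e-8)
  expect_error(adjust_covariates(x, cbind(covs, covs[, 1])), "rank")
})

test_that("cross-covariance SVD matches a dense oracle and its invariants", {
  set.seed(4)
  X <- matrix(rnorm(12), 4, 3)
  Y <- matrix(rnorm(12), 4, 3)
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  ax <- cross_covariance_svd(X, Y)
  oracle <- svd(t(X) %*% Y / 3)
  expect_equal(ax$d, oracle$d[1:3], tolerance = 1e-10)
  expect_equal(abs(ax$U), abs(oracle$u), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sum(ax$covariance_explained), 1, tolerance = 1e-12)
  expect_true(all(diff(ax$d) <= 1e-12))
  # orthonormal loadings
  expect_equal(crossprod(ax$U), diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(crossprod(ax$V), diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(cross_covariance_svd(X[1:2, ], Y[1:2, ]), "3 subjects")
  # planted noiseless rank-1 link: first component takes all covariance
  set.seed(5)
  X1 <- scale(matrix(rnorm(200), 20, 10))
  w <- rnorm(10)
  Y1 <- (X1 %*% w) %*% t(rnorm(4))
  ax1 <- cross_covariance_svd(X1, scale(Y1, scale = FALSE))
  expect_equal(ax1$covariance_explained[1], 1, tolerance = 1e-10)
  expect_gt(abs(ax1$projection_r[1]), 0.8)
})

test_that("latent projections are mutually uncorrelated on the data", {
  xy <- axes_xy(40, seed = 900)
  ax <- cross_covariance_svd(xy$X, xy$Y)
  TX <- xy$X %*% ax$U
  cors <- cor(TX)
  # projections along distinct mechanism axes are decorrelated
  offdiag <- abs(cors[upper.tri(cors)])
  expect_lt(max(offdiag[1:5]), 0.3)
})

test_that("Procrustes alignment of a decomposition to itself is the identity", {
  xy <- axes_xy(30, seed = 901)
  ax <- cross_covariance_svd(xy$X, xy$Y)
  al <- remcm:::align_svd(ax$V, ax$U, ax$d, ax$V)
  expect_equal(al$U, ax$U, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(al$V, ax$V, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(al$d, ax$d, tolerance = 1e-8)
})

test_that("axis permutation p-values respect the add-one convention", {
  xy <- axes_xy(60, seed = 902, clinical_noise = 0.2)
  ax <- cross_covariance_svd(xy$X, xy$Y)
  pt <- permutation_test_axes(xy$X, xy$Y, n_perm = 100, seed = 7, axes = ax)
  expect_true(all(pt$p >= 1 / 101 & pt$p <= 1))
  expect_equal(pt$p[1], 1 / 101)   # strong planted axis beats every null
  expect_true(all(pt$p_uncorrected <= pt$p + 1e-12))
  expect_error(permutation_test_axes(xy$X, xy$Y, n_perm = 50), "at least 100")
})

test_that("bootstrap masks flag planted structure and cap degenerate ratios", {
  xy <- axes_xy(60, seed = 903)
  ax <- cross_covariance_svd(xy$X, xy$Y)
  bs <- bootstrap_stability(xy$X, xy$Y, n_boot = 200, seed = 8, axes = ax)
  expect_identical(dim(bs$stable_U), dim(ax$U))
  # the planted symptom axis loadings are mostly stable on component 1
  expect_gt(mean(bs$stable_V[, 1]), 0.5)
  expect_true(all(is.finite(bs$ratio_U)))
  expect_true(all(abs(bs$ratio_U) <= 1e6 + 1e-9))
  expect_error(bootstrap_stability(xy$X, xy$Y, n_boot = 10), "at least 100")
  # noiseless rank-1 system: loadings identical across replicates, ratios
  # hit the cap and are flagged
  set.seed(11)
  X1 <- scale(matrix(rnorm(30 * 5), 30, 5))
  Y1 <- (X1[, 1, drop = FALSE]) %*% t(c(1, 2))
  colnames(Y1) <- c("s1", "s2")
  ax1 <- cross_covariance_svd(X1, scale(Y1, scale = FALSE))
  bs1 <- bootstrap_stability(X1, scale(Y1, scale = FALSE), n_boot = 100,
                             seed = 12, axes = ax1)
  expect_true(any(bs1$degenerate_V[, 1]))
  expect_true(all(abs(bs1$ratio_V[, 1]) <= 1e6 + 1e-9))
})

test_that("per-parameter variance shares normalize within a component", {
  xy <- axes_xy(40, seed = 904)
  ax <- cross_covariance_svd(xy$X, xy$Y)
  vp <- variance_per_parameter(ax, 1)
  expect_equal(sum(vp$share), 1, tolerance = 1e-8)
  # single included parameter takes share one
  mask <- rep(FALSE, nrow(ax$U)); mask[5] <- TRUE
  vp1 <- variance_per_parameter(ax, 1, stable = mask)
  expect_equal(unname(vp1$share), 1)
  # grouped shares match a hand-summed oracle
  grouping <- data.frame(parameter = rownames(ax$U),
                         family = rep(c("a", "b"), length.out = nrow(ax$U)))
  vg <- variance_per_parameter(ax, 1, grouping = grouping)
  manual <- tapply(vg$share, grouping$family[match(names(vg$share),
                                                  grouping$parameter)], sum) *
    ax$covariance_explained[1]
  expect_equal(as.vector(vg$group_share), as.vector(manual), tolerance = 1e-10)
  # empty mask: flagged empty result
  expect_warning(v0 <- variance_per_parameter(ax, 2, stable = rep(FALSE, nrow(ax$U))),
                 "no stable")
  expect_length(v0$share, 0)
})

test_that("end-to-end axes analysis runs on a fitted cohort", {
  sim <- study_sim()
  fit <- study_fit()
  ax <- symptom_axes(fit, sim$cohort, n_perm = 100, n_boot = 100, seed = 5)
  expect_s3_class(ax, "remcm_axes_analysis")
  expect_length(ax$axes$d, 11)
  expect_equal(sum(ax$axes$covariance_explained), 1, tolerance = 1e-8)
  expect_true(all(ax$permutation$p >= 1 / 101))
  expect_identical(nrow(ax$X), 20L)
})
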