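#' Generate spatially smooth synthetic receptor maps
#'
#' Each receptor column is a draw from a correlated multivariate normal over
#' a ring-lattice region graph (neighbor correlation equal to `smoothness`,
#' decaying geometrically with ring distance), then z-scored across regions.
#' Pairwise inter-receptor correlations are checked to stay below 0.9;
#' offending columns are redrawn.
#'
#' @param n_regions Number of regions (>= 4).
#' @param n_receptors Number of receptor maps (default 15).
#' @param smoothness Neighbor correlation in `[0, 1)`; 0 gives spatially
#'   independent maps.
#' @param seed Optional integer seed.
#' @param region_names,receptor_names Optional labels.
#' @return A z-scored [receptor_matrix()].
#' @export
generate_receptor_maps <- function(n_regions, n_receptors = 15,
                                   smoothness = 0.3, seed = NULL,
                                   region_names = NULL, receptor_names = NULL) {
  if (n_regions < 4) stop("n_regions must be at least 4")
  if (smoothness < 0 || smoothness >= 1) stop("smoothness must be in [0, 1)")
  region_names <- region_names %||% sprintf("R%03d", seq_len(n_regions))
  receptor_names <- receptor_names %||% receptor_labels()[seq_len(n_receptors)]
  with_seed(seed, {
    L <- NULL
    if (smoothness > 0) {
      d <- outer(seq_len(n_regions), seq_len(n_regions), function(i, j) {
        dd <- abs(i - j); pmin(dd, n_regions - dd)  # ring distance
      })
      S <- smoothness^d
      L <- chol(S + diag(1e-10, n_regions))
    }
    draw <- function() {
      z <- stats::rnorm(n_regions)
      if (!is.null(L)) z <- as.vector(t(L) %*% z)
      (z - mean(z)) / pop_sd(z)
    }
    m <- matrix(0, n_regions, n_receptors,
                dimnames = list(region_names, receptor_names))
    for (k in seq_len(n_receptors)) {
      for (try in 1:50) {
        m[, k] <- draw()
        if (k == 1 ||
            max(abs(stats::cor(m[, k], m[, seq_len(k - 1), drop = FALSE]))) < 0.9) break
        if (try == 50) stop("could not draw receptor maps with pairwise |cor| < 0.9")
      }
    }
    receptor_matrix(m)
  })
}

#' Generate a random symmetric connectome
#'
#' Off-diagonal edges are present independently with probability `density`
#' and carry gamma-distributed positive weights; the matrix is symmetric
#' with a zero diagonal.
#'
#' @param n_regions Number of regions.
#' @param density Expected off-diagonal nonzero fraction, in `(0, 1]`.
#' @param seed Optional integer seed.
#' @param region_names Optional region labels.
#' @return A [connectome()].
#' @export
generate_connectome <- function(n_regions, density = 0.3, seed = NULL,
                                region_names = NULL) {
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  region_names <- region_names %||% sprintf("R%03d", seq_len(n_regions))
  with_seed(seed, {
    w <- matrix(0, n_regions, n_regions,
                dimnames = list(region_names, region_names))
    ut <- upper.tri(w)
    ne <- sum(ut)
    present <- stats::rbinom(ne, 1, density) == 1
    vals <- numeric(ne)
    vals[present] <- stats::rgamma(sum(present), shape = 2, rate = 2)
    w[ut] <- vals
    w <- w + t(w)
    connectome(w)
  })
}

#' Generate ground-truth model coefficients for a synthetic cohort
#'
#' Draws a sparse population coefficient vector per factor (by default 15
#' nonzero mechanisms out of 113: the factor's own decay term, the
#' propagation term, and 13 further mechanisms drawn at random), then
#' subject-level coefficients as the population values plus correlated
#' deviations. Deviations live on the population support and have a low-rank
#' latent structure across subjects (`latent_dim` shared modes plus small
#' independent jitter), emulating correlated individual differences in
#' mechanism strength. The planted mechanism/symptom axes used to generate
#' clinical decline are derived from the first `n_axes` latent modes.
#'
#' @param n_subjects Number of subjects.
#' @param factor_names,receptor_names Labels (defaults: the canonical 6 and
#'   15).
#' @param n_nonzero Nonzero mechanisms per factor (default 15).
#' @param receptor_terms If `FALSE`, the support excludes every receptor
#'   interaction and direct receptor term: a receptor-free generator for
#'   null-calibration studies.
#' @param effect_range Magnitude range of nonzero coefficients (per year).
#' @param decay_range Magnitude range of each factor's own (negative) decay
#'   term.
#' @param prop_range Range of the propagation coefficient.
#' @param latent_dim Number of shared latent modes of subject deviations.
#' @param n_axes Number of planted mechanism-symptom axes (<= `latent_dim`).
#' @param axis_strength Strength (slope units per SD of latent score) of each
#'   planted axis.
#' @param deviation_sd Scale of the shared low-rank subject deviations.
#' @param jitter_sd SD of independent per-coefficient subject jitter.
#' @param noise_sd Default observation noise scale for trajectories.
#' @param seed Optional integer seed.
#' @return An object of class `remcm_truth`.
#' @export
generate_ground_truth <- function(n_subjects,
                                  factor_names = factor_labels(),
                                  receptor_names = receptor_labels(),
                                  n_nonzero = 15,
                                  receptor_terms = TRUE,
                                  effect_range = c(0.04, 0.10),
                                  decay_range = c(0.4, 0.8),
                                  prop_range = c(0.005, 0.02),
                                  latent_dim = 3, n_axes = 2,
                                  axis_strength = c(1.0, 0.6),
                                  deviation_sd = 0.3, jitter_sd = 0.01,
                                  noise_sd = 0.05, seed = NULL) {
  stopifnot(n_axes <= latent_dim, length(axis_strength) >= n_axes)
  labels <- design_labels(factor_names, receptor_names)
  nf <- length(factor_names); p <- length(labels)
  with_seed(seed, {
    pop <- matrix(0, nf, p, dimnames = list(factor_names, labels))
    support <- matrix(FALSE, nf, p, dimnames = list(factor_names, labels))
    for (m in seq_len(nf)) {
      self <- paste0("fac:", factor_names[m])
      pop[m, self] <- -stats::runif(1, decay_range[1], decay_range[2])
      pop[m, "prop"] <- stats::runif(1, prop_range[1], prop_range[2])
      support[m, c(self, "prop")] <- TRUE
      eligible <- setdiff(labels, c(self, "prop", "(Intercept)"))
      if (!receptor_terms) {
        eligible <- grep("^fac:", eligible, value = TRUE)
      }
      extra <- sample(eligible, min(max(n_nonzero - 2, 0), length(eligible)))
      pop[m, extra] <- sample(c(-1, 1), length(extra), replace = TRUE) *
        stats::runif(length(extra), effect_range[1], effect_range[2])
      support[m, extra] <- TRUE
    }
    # latent subject deviations live on the support excluding the propagation
    # coefficient, whose scale (~0.01/yr) is far below the other mechanisms';
    # additive deviations of the shared scale would routinely flip it negative
    # (anti-diffusion) and destabilize the dynamics. It gets a proportional
    # jitter instead.
    sup <- support
    sup[, "prop"] <- FALSE
    sup_idx <- which(as.vector(t(sup)))  # indices in the stacked 678 space
    ns <- length(sup_idx)
    q <- min(latent_dim, ns)
    # disjoint latent modules with random signs: rows orthonormal and column
    # norms equal, so each planted axis is an eigendirection of the subject
    # parameter correlation and survives column-wise z-scoring undistorted
    grp <- sample(rep(seq_len(q), length.out = ns))
    lam <- matrix(0, q, ns)
    for (a in seq_len(q)) {
      members <- which(grp == a)
      lam[a, members] <- sample(c(-1, 1), length(members), replace = TRUE) /
        sqrt(length(members))
    }
    z <- matrix(stats::rnorm(n_subjects * q), n_subjects, q)
    jit <- matrix(stats::rnorm(n_subjects * ns, sd = jitter_sd), n_subjects, ns)
    dev_sup <- deviation_sd * (z %*% lam) + jit
    popvec <- as.vector(t(pop))  # stacked factor-major (678)
    prop_jit <- matrix(stats::rnorm(n_subjects * nf, sd = 0.3), n_subjects, nf)
    subject_alpha <- array(0, c(n_subjects, nf, p),
                           dimnames = list(NULL, factor_names, labels))
    for (i in seq_len(n_subjects)) {
      v <- popvec
      v[sup_idx] <- v[sup_idx] + dev_sup[i, ]
      am <- matrix(v, nf, p, byrow = TRUE)
      pc <- match("prop", labels)
      am[, pc] <- am[, pc] * (1 + prop_jit[i, ])
      subject_alpha[i, , ] <- am
    }
    mech_u <- matrix(0, nf * p, n_axes,
                     dimnames = list(mech_labels(factor_names, receptor_names), NULL))
    for (a in seq_len(n_axes)) {
      u <- numeric(nf * p)
      u[sup_idx] <- lam[a, ]
      mech_u[, a] <- u / sqrt(sum(u^2))
    }
    sym_v <- qr.Q(qr(matrix(stats::rnorm(11 * n_axes), 11, n_axes)))
    rownames(sym_v) <- assessment_labels()
    structure(
      list(population_alpha = pop, subject_alpha = subject_alpha,
           support = support,
           latent = list(mechanism = mech_u, symptom = sym_v,
                         strength = axis_strength[seq_len(n_axes)]),
           factor_names = factor_names, receptor_names = receptor_names,
           labels = labels, noise_sd = noise_sd,
           deviation_sd = deviation_sd, jitter_sd = jitter_sd,
           receptor_terms = receptor_terms, seed = seed),
      class = "remcm_truth"
    )
  })
}

#' @export
print.remcm_truth <- function(x, ...) {
  cat("re-MCM ground truth:", dim(x$subject_alpha)[1], "subjects,",
      length(x$factor_names), "factors,", length(x$labels),
      "coefficients per factor\n")
  cat("  nonzero mechanisms per factor:",
      paste(rowSums(x$support), collapse = ", "), "\n")
  cat("  planted axes:", ncol(x$latent$mechanism),
      "(strengths", paste(x$latent$strength, collapse = ", "), ")\n")
  invisible(x)
}

# Full system operator A (stacked state: factor blocks of length R) and
# constant forcing c for one subject's coefficient matrix alpha (nf x p).
build_operator <- function(alpha, receptors, conn, factor_names, receptor_names) {
  R <- nrow(receptors); nf <- length(factor_names)
  rec <- unclass(receptors)
  w <- unclass(conn)
  lap <- w - diag(rowSums(w))
  A <- matrix(0, nf * R, nf * R)
  cc <- numeric(nf * R)
  for (m in seq_len(nf)) {
    mi <- (m - 1) * R + seq_len(R)
    for (n in seq_len(nf)) {
      b <- rep(alpha[m, paste0("fac:", factor_names[n])], R)
      for (k in receptor_names) {
        b <- b + alpha[m, paste0("ix:", factor_names[n], ":", k)] * rec[, k]
      }
      ni <- (n - 1) * R + seq_len(R)
      A[cbind(mi, ni)] <- A[cbind(mi, ni)] + b
    }
    A[mi, mi] <- A[mi, mi] + alpha[m, "prop"] * lap
    f <- numeric(R)
    for (k in receptor_names) {
      f <- f + alpha[m, paste0("rec:", k)] * rec[, k]
    }
    cc[mi] <- f
  }
  list(A = A, c = cc)
}

#' Simulate longitudinal factor trajectories
#'
#' Integrates the linear receptor-mediated dynamics forward from standard
#' normal baseline states and records them at the visit schedule.
#' `method = "euler"` uses explicit Euler sub-steps of length `euler_dt`;
#' `method = "discrete"` takes one step per inter-visit interval, so the
#' finite-difference rates of the recorded data satisfy the regression model
#' exactly (useful for parameter-recovery studies free of integrator error).
#' `noise_model = "observation"` adds i.i.d. Gaussian noise to the recorded
#' states; `"process"` (discrete method only) perturbs the rates themselves,
#' the error model under which the model's F-test is exact.
#'
#' A spectral guard estimates the exponential growth of the dynamics over the
#' simulated horizon and rescales all coefficients (with a message) if
#' trajectories would grow more than 50-fold; the effective truth is returned
#' in `attr(, "truth")`.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param receptors A z-scored [receptor_matrix()].
#' @param conn A [connectome()].
#' @param visit_schedule Visit times in years (>= 3 visits).
#' @param euler_dt Euler sub-step in years; must be at most one tenth of the
#'   smallest inter-visit gap.
#' @param noise_sd Noise scale (default `truth$noise_sd`).
#' @param seed Optional integer seed.
#' @param method `"euler"` or `"discrete"` (see Details).
#' @param noise_model `"observation"` or `"process"`.
#' @param influence_plant Optional list
#'   `list(factor=, source=, receptor=, regions=, beta=)` adding a
#'   region-restricted receptor-mediated interaction to the dynamics, for
#'   regional-influence recovery studies.
#' @return A list of [subject_ts()]; the (possibly rescaled) generating truth
#'   is attached as `attr(, "truth")`.
#' @export
simulate_trajectories <- function(truth, receptors, conn,
                                  visit_schedule = c(0, 0.5, 1, 1.5),
                                  euler_dt = 0.01, noise_sd = NULL,
                                  seed = NULL,
                                  method = c("euler", "discrete"),
                                  noise_model = c("observation", "process"),
                                  influence_plant = NULL) {
  method <- match.arg(method)
  noise_model <- match.arg(noise_model)
  noise_sd <- noise_sd %||% truth$noise_sd
  if (length(visit_schedule) < 3) stop("at least 3 visits are required")
  gaps <- diff(visit_schedule)
  if (any(gaps <= 0)) stop("visit_schedule must be strictly increasing")
  if (method == "euler" && euler_dt > min(gaps) / 10 + 1e-12) {
    stop("euler_dt must be at most one tenth of the smallest inter-visit gap")
  }
  if (noise_model == "process" && method != "discrete") {
    stop("process noise is defined for the discrete method only")
  }
  fn <- truth$factor_names
  rn <- truth$receptor_names
  R <- nrow(receptors)
  N <- dim(truth$subject_alpha)[1]
  horizon <- max(visit_schedule) - min(visit_schedule)

  ops <- lapply(seq_len(N), function(i) {
    build_operator(truth$subject_alpha[i, , , drop = TRUE], receptors, conn, fn, rn)
  })
  if (!is.null(influence_plant)) {
    ip <- influence_plant
    m <- match(ip$factor, fn); n <- match(ip$source, fn)
    rk <- unclass(receptors)[, ip$receptor]
    for (i in seq_len(N)) {
      idx <- cbind((m - 1) * R + ip$regions, (n - 1) * R + ip$regions)
      ops[[i]]$A[idx] <- ops[[i]]$A[idx] + ip$beta * rk[ip$regions]
    }
  }
  # spectral guard: probe the homogeneous dynamics over the horizon and
  # rescale all coefficients if trajectories would grow more than 50-fold
  probe_growth <- function(A) {
    dtp <- min(gaps) / 20
    nstep <- ceiling(horizon / dtp)
    g <- 0
    for (k in 1:2) {
      s <- stats::rnorm(nrow(A)); s <- s / sqrt(sum(s^2))
      for (step in seq_len(nstep)) s <- s + (horizon / nstep) * as.vector(A %*% s)
      g <- max(g, sqrt(sum(s^2)))
    }
    g
  }
  gmax <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                    max(vapply(ops, function(o) probe_growth(o$A), numeric(1))))
  scale_fac <- 1
  if (is.finite(gmax) && gmax > 50) {
    scale_fac <- log(50) / log(gmax)
    message(sprintf(
      "spectral guard: rescaling coefficients by %.3f to bound trajectory growth",
      scale_fac))
    truth$population_alpha <- truth$population_alpha * scale_fac
    truth$subject_alpha <- truth$subject_alpha * scale_fac
    ops <- lapply(ops, function(o) list(A = o$A * scale_fac, c = o$c * scale_fac))
  }

  out <- with_seed(seed, {
    lapply(seq_len(N), function(i) {
      A <- ops[[i]]$A; cc <- ops[[i]]$c
      s <- stats::rnorm(length(cc))
      rec_states <- matrix(NA_real_, length(cc), length(visit_schedule))
      rec_states[, 1] <- s
      for (v in seq_along(gaps)) {
        gap <- gaps[v]
        if (method == "discrete") {
          rate <- as.vector(A %*% s) + cc
          if (noise_model == "process") {
            rate <- rate + stats::rnorm(length(s), sd = noise_sd)
          }
          s <- s + gap * rate
        } else {
          nstep <- ceiling(gap / euler_dt - 1e-9)
          dt <- gap / nstep
          for (step in seq_len(nstep)) {
            s <- s + dt * (as.vector(A %*% s) + cc)
            if (any(abs(s) > 1e6)) {
              stop("trajectory divergence: |state| exceeded 1e6; use smaller coefficients")
            }
          }
        }
        rec_states[, v + 1] <- s
      }
      obs <- rec_states
      if (noise_model == "observation" && noise_sd > 0) {
        obs <- obs + stats::rnorm(length(obs), sd = noise_sd)
      }
      arr <- array(0, c(R, length(fn), length(visit_schedule)),
                   dimnames = list(rownames(receptors), fn, NULL))
      for (m in seq_along(fn)) {
        arr[, m, ] <- obs[(m - 1) * R + seq_len(R), ]
      }
      subject_ts(sprintf("S%03d", i), arr, visit_schedule)
    })
  })
  attr(out, "truth") <- truth
  attr(out, "alpha_rescale") <- scale_fac
  out
}

#' Generate clinical records with planted mechanism-symptom axes
#'
#' Per-subject rates of clinical decline are built as a low-rank function of
#' the (z-scored) model parameters: each planted axis contributes its
#' strength times the standardized latent mechanism score times the symptom
#' loading vector. A mild covariate dependence (baseline age, education,
#' sex) and Gaussian noise are added to the slopes, which are then converted
#' to per-visit scores along exact lines so that [clinical_slopes()] recovers
#' them.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param params Optional `subject x 678` parameter matrix (default: the
#'   truth's own subject coefficients, stacked factor-major).
#' @param noise_sd SD of the slope noise (score units per year).
#' @param exam_times Exam times in years.
#' @param covariate_effect Scale of the covariate contribution to slopes.
#' @param seed Optional integer seed.
#' @return A list of [clinical_record()]; the planted slope matrix is
#'   attached as `attr(, "slopes")`.
#' @export
generate_clinical_from_axes <- function(truth, params = NULL, noise_sd = 0.5,
                                        exam_times = c(0, 0.5, 1, 1.5),
                                        covariate_effect = 0.2, seed = NULL) {
  N <- dim(truth$subject_alpha)[1]
  if (is.null(params)) {
    params <- t(vapply(seq_len(N),
                       function(i) as.vector(t(truth$subject_alpha[i, , , drop = TRUE])),
                       numeric(length(truth$labels) * length(truth$factor_names))))
  }
  U <- truth$latent$mechanism
  V <- truth$latent$symptom
  strength <- truth$latent$strength
  stopifnot(nrow(U) == ncol(params))
  with_seed(seed, {
    Xz <- params
    for (j in seq_len(ncol(Xz))) {
      s <- pop_sd(Xz[, j])
      Xz[, j] <- if (s < 1e-12) 0 else (Xz[, j] - mean(Xz[, j])) / s
    }
    age <- stats::rnorm(N, 62, 8)
    education <- pmax(8, round(stats::rnorm(N, 15, 3)))
    sex <- stats::rbinom(N, 1, 0.6)
    cov_std <- cbind((age - mean(age)) / pop_sd(age),
                     (education - mean(education)) / pop_sd(education),
                     sex - mean(sex))
    gamma <- matrix(stats::rnorm(3 * nrow(V), sd = covariate_effect), 3, nrow(V))
    slopes <- matrix(0, N, nrow(V), dimnames = list(NULL, rownames(V)))
    for (a in seq_len(ncol(U))) {
      t_a <- as.vector(Xz %*% U[, a])
      sda <- pop_sd(t_a)
      if (sda > 1e-12) t_a <- (t_a - mean(t_a)) / sda
      slopes <- slopes + strength[a] * outer(t_a, V[, a])
    }
    slopes <- slopes + cov_std %*% gamma
    if (noise_sd > 0) {
      slopes <- slopes + matrix(stats::rnorm(length(slopes), sd = noise_sd),
                                nrow(slopes))
    }
    baseline <- matrix(stats::rnorm(N * nrow(V)), N)
    recs <- lapply(seq_len(N), function(i) {
      sc <- outer(as.vector(baseline[i, ]), rep(1, length(exam_times))) +
        outer(as.vector(slopes[i, ]), exam_times)
      rownames(sc) <- rownames(V)
      clinical_record(sprintf("S%03d", i), sc, exam_times,
                      c(age = age[i], education = education[i], sex = sex[i]))
    })
    attr(recs, "slopes") <- slopes
    recs
  })
}

#' Simulate a complete synthetic cohort with known ground truth
#'
#' Convenience wrapper wiring together the receptor-map, connectome,
#' coefficient, trajectory and clinical generators. The defaults define the
#' package's reference fixture: 20 subjects, 95 regions, 15 receptors, 4
#' visits 0.5 years apart, observation noise 0.05 on the z-scored imaging
#' scale — the regional and longitudinal geometry of the cohorts this
#' analysis is designed for. The 113-column full model needs more rows than
#' columns, so any fixture must provide `regions x intervals > 113`; 95
#' regions and 3 intervals give 285 rows (172 residual degrees of freedom).
#'
#' @param n_subjects,n_regions,n_receptors Cohort dimensions.
#' @param visit_schedule Imaging visit times (years).
#' @param smoothness,density Receptor-map smoothness and connectome density.
#' @param noise_sd Imaging noise scale.
#' @param clinical_noise_sd Clinical slope noise (score units/year).
#' @param seed Integer seed (drives every generator).
#' @param ... Passed to [generate_ground_truth()].
#' @inheritParams simulate_trajectories
#' @return A list with elements `cohort` (a [cohort()]) and `truth` (the
#'   effective [generate_ground_truth()] object).
#' @export
simulate_cohort <- function(n_subjects = 20, n_regions = 95, n_receptors = 15,
                            visit_schedule = c(0, 0.5, 1, 1.5),
                            smoothness = 0.3, density = 0.3,
                            noise_sd = 0.05, clinical_noise_sd = 0.5,
                            seed = 1, method = "euler", euler_dt = 0.01,
                            noise_model = "observation",
                            influence_plant = NULL, ...) {
  seeds <- child_seeds(seed, 5)
  rec <- generate_receptor_maps(n_regions, n_receptors, smoothness,
                                seed = seeds[[1]])
  conn <- generate_connectome(n_regions, density, seed = seeds[[2]])
  truth <- generate_ground_truth(
    n_subjects,
    receptor_names = colnames(rec),
    noise_sd = noise_sd, seed = seeds[[3]], ...)
  subjects <- simulate_trajectories(truth, rec, conn, visit_schedule,
                                    euler_dt = euler_dt, seed = seeds[[4]],
                                    method = method, noise_model = noise_model,
                                    influence_plant = influence_plant)
  truth <- attr(subjects, "truth")
  clinical <- generate_clinical_from_axes(truth, noise_sd = clinical_noise_sd,
                                          seed = seeds[[5]])
  list(cohort = cohort(subjects, rec, conn, clinical), truth = truth)
}
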