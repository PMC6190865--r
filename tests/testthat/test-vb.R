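test_that("VB fit is deterministic and its free-energy trace ascends", {
  set.seed(101)
  X <- build_design(rep(c("UP", "AP", "UU", "AU"), each = 6), opposition_model())
  y <- rnorm(24)
  f1 <- vb_fit(y, X)
  f2 <- vb_fit(y, X)
  expect_identical(f1$free_energy, f2$free_energy)
  expect_gte(min(diff(f1$trace$values)), -1e-8)
  expect_true(f1$trace$converged)
})

test_that("converged F lower-bounds the exact log evidence with a small gap", {
  # 20-trial toy with a genuine effect; oracle = marginalising the
  # coefficients analytically and integrating the noise precision numerically
  set.seed(202)
  labels <- rep(c("UP", "AP", "UU", "AU"), each = 5)
  X <- build_design(labels, opposition_model())$matrix
  priors <- vb_priors()
  for (rep_i in 1:3) {
    y <- as.vector(X %*% c(0.8, 0.3)) + rnorm(20, sd = 0.7)
    fit <- vb_fit(y, X, priors, tol = 1e-8, max_iter = 512)
    exact <- exact_log_evidence(y, X, priors)
    expect_lte(fit$free_energy, exact + 1e-6)
    expect_lt(exact - fit$free_energy, 0.1)
    expect_gte(min(diff(fit$trace$values)), -1e-8)
  }
})

test_that("VB fit validates input and warns when it hits the iteration cap", {
  X <- cbind(rnorm(10), 1)
  expect_error(vb_fit(c(rnorm(9), NA), X), "non-finite")
  expect_error(vb_fit(rnorm(9), X), "nrow")
  expect_error(vb_fit(rnorm(10), X, tol = 0), "tol")
  expect_warning(f <- vb_fit(rnorm(10), X, tol = 1e-12, max_iter = 2), "converge")
  expect_false(f$trace$converged)
  expect_true(is.finite(f$free_energy))
})

test_that("log Bayes factors behave like log-evidence differences", {
  expect_equal(log_bayes_factor(3.2, 3.2), 0)
  expect_equal(log_bayes_factor(1, 4), -log_bayes_factor(4, 1))
  expect_equal(log_bayes_factor(log(20) + 5, 5), log(20))
  expect_error(log_bayes_factor(Inf, 1), "finite")
})

test_that("rescaling data with matched priors leaves the log Bayes factor unchanged", {
  set.seed(77)
  labels <- rep(c("UP", "AP", "UU", "AU"), each = 8)
  Xo <- build_design(labels, opposition_model())$matrix
  Xi <- build_design(labels, interaction_model())$matrix
  y <- as.vector(Xo %*% c(0.5, 0.2)) + rnorm(32, sd = 0.8)
  pr <- vb_priors()
  lbf <- function(yy, pp) {
    vb_fit(yy, Xo, pp, tol = 1e-9, max_iter = 512)$free_energy -
      vb_fit(yy, Xi, pp, tol = 1e-9, max_iter = 512)$free_energy
  }
  cc <- 10
  pr_scaled <- vb_priors(coeff_precision = pr$coeff_precision / cc^2,
                         noise_shape = pr$noise_shape,
                         noise_rate = pr$noise_rate * cc^2)
  expect_equal(lbf(y, pr), lbf(cc * y, pr_scaled), tolerance = 1e-5)
})

test_that("Gaussian KL divergence matches the closed form and an integral oracle", {
  expect_equal(kl_gaussian(0, 1, 0, 1), 0)
  expect_equal(kl_gaussian(1, 1, 0, 1), 0.5)
  # numerical integration oracle for an asymmetric case
  q <- function(x) dnorm(x, 0.3, sqrt(2))
  p <- function(x) dnorm(x, -0.5, sqrt(0.7))
  num <- integrate(function(x) q(x) * (log(q(x)) - log(p(x))), -12, 12)$value
  expect_equal(kl_gaussian(0.3, 2, -0.5, 0.7), num, tolerance = 1e-6)
  # non-negativity over random parameters
  set.seed(5)
  for (i in 1:20) {
    expect_gte(kl_gaussian(rnorm(1), rexp(1), rnorm(1), rexp(1)), 0)
  }
  expect_error(kl_gaussian(0, 0, 0, 1), "positive")
})

test_that("evidence maps favour the generating model at effect voxels", {
  sim <- tiny_group(n_subjects = 4, assignments = c(1, 1, 2, 2),
                    noise_sd = 0.3, effect_size = 3, seed = 55)
  images <- lapply(sim$datasets, build_scalp_time_volumes, grid_size = c(12, 12))
  specs <- list(opposition_model(), interaction_model())
  maps <- evidence_maps(images, specs, smooth_fwhm = 0)
  eff <- sim$truth$effect_region
  for (s in 1:4) {
    k_true <- sim$truth$subject_assignments[s]
    lbf <- maps$evidences[s, k_true, eff] - maps$evidences[s, 3 - k_true, eff]
    expect_gt(mean(lbf > 0), 0.9)  # generating model wins at nearly all effect voxels
  }
  # null voxels: mean log Bayes factor near zero
  null_vox <- intersect(which(maps$mask), setdiff(which(maps$mask), sim$truth$halo_region))
  nb <- maps$evidences[, 1, null_vox] - maps$evidences[, 2, null_vox]
  expect_lt(abs(mean(nb)), 0.2)
})

test_that("identical subjects yield identical evidence rows; grids must match", {
  sim <- tiny_group(n_subjects = 1, seed = 66)
  img <- build_scalp_time_volumes(sim$datasets[[1]], c(12, 12))
  specs <- list(opposition_model(), interaction_model())
  maps <- evidence_maps(list(img, img), specs, smooth_fwhm = 0)
  expect_equal(maps$evidences[1, , ], maps$evidences[2, , ])
  img2 <- build_scalp_time_volumes(sim$datasets[[1]], c(10, 10))
  expect_error(evidence_maps(list(img, img2), specs), "common grid")
})

test_that("Gaussian smoothing has the stated identity, fixed point and width", {
  set.seed(8)
  v <- array(rnorm(6 * 6 * 6), c(6, 6, 6))
  expect_equal(smooth_map(v, 0), v)
  const <- array(3, c(6, 6, 6))
  expect_equal(smooth_map(const, 1.5), const, tolerance = 1e-12)
  # FWHM = 2*sqrt(2 log 2) voxels corresponds to sigma = 1 voxel: the impulse
  # response falls to exp(-1/2) of its peak one voxel away
  d <- array(0, c(21, 21, 21)); d[11, 11, 11] <- 1
  s <- smooth_map(d, fwhm = 2 * sqrt(2 * log(2)))
  expect_equal(s[12, 11, 11] / s[11, 11, 11], exp(-0.5), tolerance = 1e-10)
  expect_equal(s[11, 13, 11] / s[11, 11, 11], exp(-2), tolerance = 1e-10)
  expect_error(smooth_map(v, -1), "non-negative")
  # mask-aware: constants stay constant near the mask edge
  m <- array(TRUE, c(6, 6, 6)); m[1:2, , ] <- FALSE
  cm <- array(NA_real_, c(6, 6, 6)); cm[m] <- 2
  sm <- smooth_map(cm, 2, mask = m)
  expect_equal(sm[m], rep(2, sum(m)), tolerance = 1e-12)
  expect_true(all(is.na(sm[!m])))
})
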