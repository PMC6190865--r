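#' Priors for the variational Bayesian GLM
#'
#' The per-voxel model is `y = X w + e`, `e ~ N(0, 1/lambda)`, with a
#' zero-mean Gaussian prior on the coefficients, `w ~ N(0, I / coeff_precision)`,
#' and a Gamma prior on the noise precision, `lambda ~ Gamma(noise_shape,
#' noise_rate)`. Defaults are weakly informative.
#'
#' @param coeff_precision Prior precision of each regression coefficient.
#' @param noise_shape,noise_rate Gamma prior (shape, rate) on the noise
#'   precision.
#' @return A list of class `vb_priors`.
#' @export
vb_priors <- function(coeff_precision = 1e-3, noise_shape = 1e-3, noise_rate = 1e-3) {
  stopifnot(coeff_precision > 0, noise_shape > 0, noise_rate > 0)
  structure(list(coeff_precision = coeff_precision,
                 noise_shape = noise_shape, noise_rate = noise_rate),
            class = "vb_priors")
}

# Vectorised mean-field VB for many voxels sharing one design.
# Y: n x V response matrix; X: n x p design. Factorised posterior
# q(w) q(lambda) optimised by coordinate ascent; the free energy
#   F = E[log p(y|w,lambda)] - KL(q(w)||p(w)) - KL(q(lambda)||p(lambda))
# is a monotone lower bound on the log model evidence. Uses the
# eigendecomposition of X'X so the per-voxel posterior covariance
# (s0 I + E[lambda] X'X)^{-1} is elementwise in the rotated basis.
vb_fit_matrix <- function(Y, X, priors = vb_priors(), tol = 1e-4,
                          max_iter = 128L, keep_trace = FALSE) {
  Y <- as.matrix(Y)
  n <- nrow(Y); V <- ncol(Y); p <- ncol(X)
  s0 <- priors$coeff_precision
  a0 <- priors$noise_shape; b0 <- priors$noise_rate

  eg <- eigen(crossprod(X), symmetric = TRUE)
  Q <- eg$vectors; d <- pmax(eg$values, 0)
  G <- crossprod(Q, crossprod(X, Y))              # p x V rotated X'y
  yty <- colSums(Y^2)

  a <- a0 + n / 2
  Elam <- rep(a0 / b0, V)
  F_prev <- rep(-Inf, V)
  trace_vals <- if (keep_trace) matrix(NA_real_, max_iter, V) else NULL
  dF <- rep(Inf, V)
  it <- 0L
  const_lik <- -n / 2 * log(2 * pi)

  repeat {
    it <- it + 1L
    denom <- s0 + outer(d, Elam)                  # p x V
    Stilde <- 1 / denom
    mt <- Stilde * G * rep(Elam, each = p)        # rotated posterior mean
    trS <- colSums(Stilde)
    logdetS <- -colSums(log(denom))
    mm <- colSums(mt^2)
    mAm <- colSums(d * mt^2)
    trSA <- colSums(d * Stilde)
    mXty <- colSums(mt * G)
    Eres <- yty - 2 * mXty + mAm + trSA           # E||y - Xw||^2

    b <- b0 + Eres / 2
    Elam <- a / b
    Eloglam <- digamma(a) - log(b)

    Elik <- n / 2 * Eloglam + const_lik - Elam / 2 * Eres
    KLw <- 0.5 * (s0 * (trS + mm) - p - p * log(s0) - logdetS)
    KLlam <- (a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
      a0 * (log(b) - log(b0)) + a * (b0 - b) / b
    F_now <- Elik - KLw - KLlam

    if (keep_trace) trace_vals[it, ] <- F_now
    dF <- F_now - F_prev
    F_prev <- F_now
    if (all(abs(dF) < tol) || it >= max_iter) break
  }

  list(F = F_prev, converged = abs(dF) < tol, n_iter = it,
       mean_rotated = mt, rotation = Q, Stilde = Stilde,
       noise_shape = a, noise_rate = b,
       trace = if (keep_trace) trace_vals[seq_len(it), , drop = FALSE] else NULL)
}

#' Fit a Bayesian GLM to one voxel by variational Bayes
#'
#' Mean-field variational inference for `y = X w + e` with a Gaussian prior
#' on `w` and a Gamma prior on the noise precision. The factorised posterior
#' `q(w) q(lambda)` is optimised by coordinate ascent; the returned free
#' energy `F` is a lower bound on the log model evidence, tightened at every
#' iteration (the trace is non-decreasing), and is the quantity used as the
#' approximate log evidence in model selection.
#'
#' @param y Numeric vector of per-trial amplitudes at one voxel.
#' @param X A [build_design()] result or a numeric trials x regressors matrix.
#' @param priors A [vb_priors()].
#' @param tol Convergence tolerance on the change in F (nats).
#' @param max_iter Maximum number of coordinate-ascent iterations.
#' @return An object of class `vb_glm_fit`: posterior means, marginal
#'   precisions and covariance of the coefficients, the Gamma posterior of
#'   the noise precision, the free energy `F`, and the per-iteration trace.
#' @export
vb_fit <- function(y, X, priors = vb_priors(), tol = 1e-4, max_iter = 128L) {
  if (inherits(X, "bms_design")) X <- X$matrix
  X <- as.matrix(X)
  if (any(!is.finite(y))) stop("non-finite values in `y`.", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X).", call. = FALSE)
  if (length(y) < 3L) stop("need at least 3 trials.", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive.", call. = FALSE)

  fit <- vb_fit_matrix(matrix(y, ncol = 1), X, priors, tol, max_iter, keep_trace = TRUE)
  if (!fit$converged[1]) {
    warning("VB did not converge within ", max_iter, " iterations.", call. = FALSE)
  }
  Q <- fit$rotation
  S <- Q %*% (fit$Stilde[, 1] * t(Q))             # posterior covariance of w
  m <- as.vector(Q %*% fit$mean_rotated[, 1])
  names(m) <- colnames(X) %||% paste0("x", seq_along(m))
  structure(list(coeff_mean = m,
                 coeff_precision = 1 / diag(S),
                 coeff_cov = S,
                 noise_shape = fit$noise_shape,
                 noise_rate = fit$noise_rate[1],
                 free_energy = fit$F[1],
                 trace = list(values = fit$trace[, 1],
                              converged = fit$converged[1],
                              n_iter = fit$n_iter),
                 priors = priors),
            class = "vb_glm_fit")
}

#' @export
print.vb_glm_fit <- function(x, ...) {
  cat("<vb_glm_fit> F = ", format(x$free_energy, digits = 6), " nats after ",
      x$trace$n_iter, " iterations (",
      if (x$trace$converged) "converged" else "not converged", ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.vb_glm_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coeff_mean),
                 estimate = unname(x$coeff_mean),
                 std.error = sqrt(diag(x$coeff_cov)))
}

#' @export
glance.vb_glm_fit <- function(x, ...) {
  tibble::tibble(free_energy = x$free_energy,
                 noise_precision = x$noise_shape / x$noise_rate,
                 n_iter = x$trace$n_iter,
                 converged = x$trace$converged)
}

#' Log Bayes factor between two log evidences
#'
#' @param evidence_a,evidence_b Log model evidences (nats).
#' @return `evidence_a - evidence_b`, the log Bayes factor of model a over b.
#' @export
log_bayes_factor <- function(evidence_a, evidence_b) {
  if (any(!is.finite(evidence_a)) || any(!is.finite(evidence_b))) {
    stop("log evidences must be finite.", call. = FALSE)
  }
  evidence_a - evidence_b
}

#' Kullback-Leibler divergence between univariate Gaussians
#'
#' Closed form of `KL(q || p)` for `q = N(q_mean, q_var)` and
#' `p = N(p_mean, p_var)`; non-negative, zero iff the distributions match.
#'
#' @param q_mean,q_var Mean and variance of q.
#' @param p_mean,p_var Mean and variance of p.
#' @return KL divergence in nats.
#' @export
kl_gaussian <- function(q_mean, q_var, p_mean, p_var) {
  if (any(q_var <= 0) || any(p_var <= 0)) {
    stop("variances must be positive.", call. = FALSE)
  }
  0.5 * (log(p_var / q_var) + (q_var + (q_mean - p_mean)^2) / p_var - 1)
}

#' Per-voxel log model evidence maps for a group
#'
#' For every subject, candidate model and in-mask voxel, fits the VB GLM to
#' the per-trial voxel amplitudes against the model's condition-weight
#' regressor and stores the converged free energy as the approximate log
#' model evidence. Evidence images are optionally smoothed with a mask-aware
#' Gaussian kernel, the stated spatial regularisation of the mapping method.
#'
#' @param images List of [voxel_image_set()] objects, one per subject, on a
#'   common grid and mask.
#' @param specs List of [model_spec()] objects.
#' @param priors A [vb_priors()].
#' @param tol,max_iter VB convergence controls.
#' @param smooth_fwhm Gaussian FWHM in voxel units applied to each evidence
#'   image (scalar or per-axis); 0 disables smoothing. Default 1.
#' @param subject_ids Optional subject identifiers.
#' @return An object of class `log_evidence_maps`: `evidences`
#'   (subjects x models x voxels, NA outside the mask), `mask`, `grid_meta`,
#'   `model_names`, `subject_ids`, `dim3`.
#' @export
evidence_maps <- function(images, specs, priors = vb_priors(), tol = 1e-4,
                          max_iter = 128L, smooth_fwhm = 1, subject_ids = NULL) {
  stopifnot(length(images) >= 1L, length(specs) >= 1L)
  dims <- lapply(images, function(s) dim(s$volumes)[1:3])
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("subjects' volumes are not on a common grid.", call. = FALSE)
  }
  masks <- vapply(images, function(s) paste(which(s$mask), collapse = ","), character(1))
  if (length(unique(masks)) != 1L) {
    stop("subjects' masks differ; evidence maps need identical masks.", call. = FALSE)
  }
  cond_sets <- lapply(images, function(s) sort(unique(s$condition_labels)))
  if (length(unique(vapply(cond_sets, paste, character(1), collapse = ","))) != 1L) {
    stop("subjects have different condition label sets.", call. = FALSE)
  }
  dim3 <- dims[[1]]
  mask <- images[[1]]$mask
  in_mask <- which(mask)
  S <- length(images); K <- length(specs)
  if (is.null(subject_ids)) subject_ids <- seq_len(S)
  model_names <- vapply(specs, `[[`, character(1), "name")

  evid <- array(NA_real_, dim = c(S, K, prod(dim3)))
  for (s in seq_len(S)) {
    set <- images[[s]]
    n_trials <- dim(set$volumes)[4]
    Y <- t(matrix(set$volumes, nrow = prod(dim3))[in_mask, , drop = FALSE])
    if (any(!is.finite(Y))) {
      stop("non-finite in-mask voxel values for subject ", subject_ids[s],
           "; sanitize or re-mask first.", call. = FALSE)
    }
    for (k in seq_len(K)) {
      X <- build_design(set$condition_labels, specs[[k]])$matrix
      fit <- vb_fit_matrix(Y, X, priors, tol, max_iter)
      Fv <- fit$F
      if (any(smooth_fwhm > 0)) {
        v <- array(NA_real_, dim3); v[in_mask] <- Fv
        v <- smooth_map(v, fwhm = smooth_fwhm, mask = mask)
        Fv <- v[in_mask]
      }
      evid[s, k, in_mask] <- Fv
    }
  }
  structure(list(evidences = evid, mask = mask,
                 grid_meta = images[[1]]$grid_meta,
                 model_names = model_names, subject_ids = subject_ids,
                 dim3 = dim3),
            class = "log_evidence_maps")
}

#' @export
print.log_evidence_maps <- function(x, ...) {
  cat("<log_evidence_maps> ", length(x$subject_ids), " subjects x ",
      length(x$model_names), " models (", paste(x$model_names, collapse = ", "),
      ") on a ", paste(x$dim3, collapse = "x"), " grid, ",
      sum(x$mask), " in-mask voxels\n", sep = "")
  invisible(x)
}

#' Mask-aware Gaussian smoothing of a volume
#'
#' Separable Gaussian convolution with `sigma = fwhm / sqrt(8 log 2)` per
#' axis. Smoothing is renormalised by the smoothed mask so in-mask values
#' near the mask edge are weighted averages of in-mask neighbours only;
#' out-of-mask voxels stay `NA`. `fwhm = 0` is the identity.
#'
#' @param volume 3-D numeric array (NA allowed outside the mask).
#' @param fwhm Full width at half maximum per axis, in the same units as
#'   `voxel_size` (recycled to length 3).
#' @param voxel_size Physical voxel size per axis (default 1, i.e. `fwhm`
#'   is in voxel units).
#' @param mask Logical array of valid voxels; default the finite voxels.
#' @return Smoothed volume, same shape, NA outside the mask.
#' @export
smooth_map <- function(volume, fwhm, voxel_size = c(1, 1, 1), mask = NULL) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  fwhm <- rep_len(as.numeric(fwhm), 3L)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(fwhm < 0)) stop("`fwhm` must be non-negative.", call. = FALSE)
  if (is.null(mask)) mask <- is.finite(volume)
  if (all(fwhm == 0)) {
    volume[!mask] <- NA_real_
    return(volume)
  }
  sigma <- fwhm / voxel_size / sqrt(8 * log(2))
  num <- volume
  num[!mask] <- 0
  den <- array(as.numeric(mask), dim(volume))
  for (axis in 1:3) {
    if (sigma[axis] <= 0) next
    num <- convolve_axis(num, gauss_kernel(sigma[axis]), axis)
    den <- convolve_axis(den, gauss_kernel(sigma[axis]), axis)
  }
  out <- num / den
  out[!mask] <- NA_real_
  out
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# 1-D convolution along `axis` of a 3-D array, zero padding at the edges
convolve_axis <- function(arr, kernel, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  L <- d[1]; r <- (length(kernel) - 1L) / 2L
  band <- matrix(0, L, L)
  for (off in -r:r) {
    i <- seq_len(L)
    j <- i + off
    ok <- j >= 1L & j <= L
    band[cbind(i[ok], j[ok])] <- kernel[off + r + 1L]
  }
  out <- band %*% matrix(a, nrow = L)
  a <- array(out, d)
  aperm(a, order(perm))
}

#' Write and read per-subject per-model log-evidence NIfTI images
#'
#' Files are named `LogEv_<subject>_<model>.nii`; out-of-mask voxels are
#' stored as NaN. A JSON sidecar carries grid metadata and names.
#'
#' @param maps A `log_evidence_maps` object.
#' @param dir Directory.
#' @return `write_evidence_maps()` returns the paths invisibly;
#'   `read_evidence_maps()` returns a `log_evidence_maps`.
#' @export
write_evidence_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "log_evidence_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in seq_along(maps$subject_ids)) {
    for (k in seq_along(maps$model_names)) {
      v <- array(maps$evidences[s, k, ], maps$dim3)
      v[!maps$mask] <- NaN
      p <- file.path(dir, sprintf("LogEv_%s_%s.nii", maps$subject_ids[s],
                                  maps$model_names[k]))
      img <- RNifti::asNifti(v)
      RNifti::pixdim(img) <- maps$grid_meta$voxel_size
      RNifti::writeNifti(img, p)
      paths <- c(paths, p)
    }
  }
  jsonlite::write_json(list(grid_meta = maps$grid_meta,
                            model_names = maps$model_names,
                            subject_ids = maps$subject_ids,
                            dim3 = maps$dim3),
                       file.path(dir, "evidence_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_evidence_maps
#' @export
read_evidence_maps <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "evidence_meta.json"),
                              simplifyVector = TRUE)
  dim3 <- as.integer(meta$dim3)
  S <- length(meta$subject_ids); K <- length(meta$model_names)
  evid <- array(NA_real_, c(S, K, prod(dim3)))
  mask <- NULL
  for (s in seq_len(S)) {
    for (k in seq_len(K)) {
      p <- file.path(dir, sprintf("LogEv_%s_%s.nii", meta$subject_ids[s],
                                  meta$model_names[k]))
      v <- as.array(RNifti::readNifti(p))
      if (!identical(dim(v), dim3)) stop("shape mismatch in ", p, call. = FALSE)
      m <- is.finite(v)
      mask <- if (is.null(mask)) m else mask & m
      evid[s, k, ] <- as.vector(v)
    }
  }
  evid[, , !as.vector(mask)] <- NA_real_
  structure(list(evidences = evid, mask = array(mask, dim3),
                 grid_meta = meta$grid_meta, model_names = meta$model_names,
                 subject_ids = meta$subject_ids, dim3 = dim3),
            class = "log_evidence_maps")
}
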