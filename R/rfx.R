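#' Random-effects Bayesian model selection over a group
#'
#' Inverts the hierarchical model in which group model frequencies `r` carry
#' a Dirichlet prior `Dir(alpha0)`, each subject's generating model is a
#' multinomial draw from `r`, and each subject contributes a log model
#' evidence per candidate model. The variational fixed point iterates
#' \deqn{u_{nk} = \exp(\ln p(y_n|m_k) + \psi(\alpha_k) - \psi(\sum_j \alpha_j))}
#' \deqn{\beta_k = \sum_n u_{nk} / \sum_j u_{nj}, \qquad \alpha = \alpha_0 + \beta}
#' until the Dirichlet parameters stabilise. `u` rows are computed in the
#' log domain with the per-row maximum subtracted before exponentiation
#' (exact, by shift invariance of the update).
#'
#' @param log_evidences Numeric subjects x models matrix of log model
#'   evidences (nats).
#' @param alpha0 Dirichlet prior counts (scalar or length K, all > 0);
#'   default 1 ("no models seen a priori").
#' @param tol Convergence tolerance on `max |delta alpha|`.
#' @param max_iter Iteration cap.
#' @return An object of class `bms_dirichlet`: `alpha`, `alpha0`, `beta`
#'   (expected data counts), `u_normalised` (subjects x models posterior
#'   model assignments), `n_subjects`, `n_iter`, `converged`.
#' @export
rfx_update <- function(log_evidences, alpha0 = 1, tol = 1e-6, max_iter = 10000L) {
  lme <- as.matrix(log_evidences)
  N <- nrow(lme); K <- ncol(lme)
  if (N < 1L || K < 2L) stop("need >= 1 subject and >= 2 models.", call. = FALSE)
  if (any(!is.finite(lme))) stop("non-finite log evidences.", call. = FALSE)
  alpha0 <- rep_len(as.numeric(alpha0), K)
  if (any(alpha0 <= 0)) stop("`alpha0` must be positive.", call. = FALSE)

  alpha <- alpha0
  it <- 0L; converged <- FALSE
  u <- matrix(NA_real_, N, K)
  repeat {
    it <- it + 1L
    lnu <- sweep(lme, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lnu <- lnu - apply(lnu, 1, max)
    u <- exp(lnu)
    u <- u / rowSums(u)
    beta <- colSums(u)
    alpha_new <- alpha0 + beta
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged) {
    warning("rfx_update reached max_iter without converging (last delta alpha = ",
            format(delta, digits = 3), ").", call. = FALSE)
  }
  model_names <- colnames(lme) %||% paste0("model", seq_len(K))
  structure(list(alpha = setNames(alpha, model_names),
                 alpha0 = setNames(alpha0, model_names),
                 beta = setNames(alpha - alpha0, model_names),
                 u_normalised = u, n_subjects = N,
                 n_iter = it, converged = converged),
            class = "bms_dirichlet")
}

#' @export
print.bms_dirichlet <- function(x, ...) {
  cat("<bms_dirichlet> N = ", x$n_subjects, ", ", length(x$alpha),
      " models, ", x$n_iter, " iterations\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.bms_dirichlet <- function(x, ...) {
  tibble::tibble(model = names(x$alpha),
                 alpha0 = unname(x$alpha0),
                 data_counts = unname(x$beta),
                 alpha = unname(x$alpha),
                 posterior_prob = unname(posterior_model_probabilities(x)))
}

#' @export
glance.bms_dirichlet <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_models = length(x$alpha),
                 n_iter = x$n_iter, converged = x$converged)
}

#' Posterior model probabilities from a Dirichlet posterior
#'
#' The expected group frequency of model k under `Dir(alpha)`:
#' `r_k = alpha_k / sum(alpha)` — the probability that model k generated the
#' data of a randomly selected subject. These are the values a posterior
#' probability map (PPM) displays per voxel.
#'
#' @param dp A `bms_dirichlet` or a positive numeric vector of alphas.
#' @return Named probability vector summing to 1.
#' @export
posterior_model_probabilities <- function(dp) {
  alpha <- if (inherits(dp, "bms_dirichlet")) dp$alpha else as.numeric(dp)
  if (any(alpha <= 0)) stop("alpha must be positive.", call. = FALSE)
  alpha / sum(alpha)
}

#' Exceedance probabilities from a Dirichlet posterior
#'
#' The probability that model k's group frequency exceeds every other
#' model's: `phi_k = P(r_k > r_j for all j != k | alpha)`. For K = 2 this is
#' computed in closed form from the Beta distribution
#' (`phi_1 = P(Beta(alpha_1, alpha_2) > 1/2)`); for K > 2 by Monte-Carlo
#' sampling of the Dirichlet with a fixed seed. These are the values an
#' exceedance probability map (EPM) displays per voxel.
#'
#' @param dp A `bms_dirichlet` or a positive numeric alpha vector.
#' @param n_samples Monte-Carlo draws for K > 2 (default 1e6).
#' @param seed Seed for the Monte-Carlo path.
#' @return Named probability vector summing to 1 (exactly for K = 2, within
#'   Monte-Carlo error otherwise); attribute `mc_se` carries the standard
#'   error per component (0 for the closed form).
#' @export
exceedance_probabilities <- function(dp, n_samples = 1e6, seed = 1) {
  alpha <- if (inherits(dp, "bms_dirichlet")) dp$alpha else as.numeric(dp)
  if (any(alpha <= 0)) stop("alpha must be positive.", call. = FALSE)
  K <- length(alpha)
  nm <- names(alpha) %||% paste0("model", seq_len(K))
  if (K == 2L) {
    phi1 <- pbeta(0.5, alpha[1], alpha[2], lower.tail = FALSE)
    out <- setNames(c(phi1, 1 - phi1), nm)
    attr(out, "mc_se") <- c(0, 0)
    return(out)
  }
  if (n_samples < 1e4) {
    warning("fewer than 1e4 Monte-Carlo draws; attained s.e. about ",
            format(sqrt(0.25 / n_samples), digits = 2), call. = FALSE)
  }
  set.seed(seed)
  counts <- integer(K)
  chunk <- 1e5
  done <- 0
  while (done < n_samples) {
    m <- min(chunk, n_samples - done)
    g <- matrix(rgamma(m * K, shape = rep(alpha, each = m)), m, K)
    win <- max.col(g, ties.method = "first")
    counts <- counts + tabulate(win, K)
    done <- done + m
  }
  phi <- counts / n_samples
  out <- setNames(phi, nm)
  attr(out, "mc_se") <- sqrt(phi * (1 - phi) / n_samples)
  out
}

#' Convert a two-model Bayes factor to a posterior model probability
#'
#' Under uniform model priors, `P(m1 | y) = BF / (1 + BF)`. The conventional
#' strong-evidence landmark BF = 20 maps to a posterior probability of
#' 20/21, just above 0.95.
#'
#' @param bf Bayes factor(s), > 0 (Inf allowed; maps to 1).
#' @return Posterior probability of the favoured model.
#' @export
bayes_factor_to_posterior <- function(bf) {
  if (any(is.na(bf)) || any(bf <= 0)) {
    stop("`bf` must be positive.", call. = FALSE)
  }
  ifelse(is.infinite(bf), 1, bf / (1 + bf))
}

#' Fixed-effects group Bayes factor (log domain)
#'
#' The group Bayes factor is the product of per-subject Bayes factors —
#' fixed-effects inference that assumes every subject's data came from the
#' same model. Returned in the log domain:
#' `sum_n (ln p(y_n | k_a) - ln p(y_n | k_b))`.
#'
#' @param log_evidences Subjects x models matrix (nats).
#' @param k_a,k_b Model column indices (or names) to compare.
#' @return Log group Bayes factor of `k_a` over `k_b` (nats).
#' @export
group_bayes_factor <- function(log_evidences, k_a = 1, k_b = 2) {
  lme <- as.matrix(log_evidences)
  if (any(!is.finite(lme))) stop("non-finite log evidences.", call. = FALSE)
  sum(lme[, k_a] - lme[, k_b])
}

#' Voxel-wise random-effects model selection maps
#'
#' Runs the Dirichlet fixed point independently at every in-mask voxel of a
#' group log-evidence map and fills posterior probability (PPM) and
#' exceedance probability (EPM) volumes per model. No spatial coupling is
#' applied at the group stage; spatial regularisation, if any, comes from
#' smoothing the evidence images beforehand.
#'
#' @param maps A `log_evidence_maps` object.
#' @param alpha0 Dirichlet prior counts (default 1).
#' @param tol Convergence tolerance on `max |delta alpha|` across voxels.
#' @param max_iter Iteration cap.
#' @param n_samples Monte-Carlo draws per voxel for the EPM when K > 2
#'   (K = 2 uses the closed Beta form).
#' @param seed Seed for the Monte-Carlo EPM path.
#' @param keep_subject_posteriors Keep the subjects x models x voxels
#'   assignment array (memory-heavy; default FALSE).
#' @return An object of class `bms_result` with `alpha`, `ppm`, `epm`
#'   (models x voxels matrices, NA outside the mask), `mask`, `dim3`,
#'   `grid_meta`, `model_names`, and run metadata.
#' @export
voxelwise_bms <- function(maps, alpha0 = 1, tol = 1e-6, max_iter = 10000L,
                          n_samples = 1e6, seed = 1,
                          keep_subject_posteriors = FALSE) {
  stopifnot(inherits(maps, "log_evidence_maps"))
  in_mask <- which(maps$mask)
  if (length(in_mask) == 0L) stop("no in-mask voxels.", call. = FALSE)
  evid <- maps$evidences[, , in_mask, drop = FALSE]
  if (any(!is.finite(evid))) {
    stop("non-finite log evidence at in-mask voxel(s); no silent imputation — ",
         "sanitize or re-mask first.", call. = FALSE)
  }
  S <- dim(evid)[1]; K <- dim(evid)[2]; V <- dim(evid)[3]
  alpha0 <- rep_len(as.numeric(alpha0), K)
  if (any(alpha0 <= 0)) stop("`alpha0` must be positive.", call. = FALSE)

  alpha <- matrix(alpha0, K, V)
  it <- 0L; converged <- FALSE
  u <- NULL
  repeat {
    it <- it + 1L
    dg <- digamma(alpha) - rep(digamma(colSums(alpha)), each = K)   # K x V
    lnu <- evid + aperm(array(dg, c(K, V, S)), c(3, 1, 2))
    rowmax <- lnu[, 1, , drop = FALSE]
    for (k in seq_len(K)[-1]) rowmax <- pmax(rowmax, lnu[, k, , drop = FALSE])
    u <- exp(lnu - array(rowmax[, rep(1, K), ], dim(lnu)))
    tot <- u[, 1, ]
    for (k in seq_len(K)[-1]) tot <- tot + u[, k, ]
    for (k in seq_len(K)) u[, k, ] <- u[, k, ] / tot
    beta <- apply(u, c(2, 3), sum)                                  # K x V
    alpha_new <- alpha0 + beta
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged) {
    warning("voxelwise_bms reached max_iter without full convergence.", call. = FALSE)
  }

  ppm_in <- alpha / rep(colSums(alpha), each = K)
  if (K == 2L) {
    phi1 <- pbeta(0.5, alpha[1, ], alpha[2, ], lower.tail = FALSE)
    epm_in <- rbind(phi1, 1 - phi1)
  } else {
    epm_in <- matrix(NA_real_, K, V)
    for (v in seq_len(V)) {
      epm_in[, v] <- exceedance_probabilities(alpha[, v], n_samples = n_samples,
                                              seed = child_seed(seed, v))
    }
  }

  Vfull <- prod(maps$dim3)
  expand <- function(m) {
    out <- matrix(NA_real_, K, Vfull)
    out[, in_mask] <- m
    rownames(out) <- maps$model_names
    out
  }
  structure(list(alpha = expand(alpha), ppm = expand(ppm_in), epm = expand(epm_in),
                 mask = maps$mask, dim3 = maps$dim3, grid_meta = maps$grid_meta,
                 model_names = maps$model_names, n_subjects = S,
                 alpha0 = alpha0, n_iter = it, converged = converged,
                 n_samples = if (K > 2) n_samples else NA_real_, seed = seed,
                 subject_posteriors = if (keep_subject_posteriors) u else NULL),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result> ", x$n_subjects, " subjects, ", length(x$model_names),
      " models on a ", paste(x$dim3, collapse = "x"), " grid (",
      sum(x$mask), " in-mask voxels), ", x$n_iter, " iterations\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @export
glance.bms_result <- function(x, ...) {
  in_mask <- which(x$mask)
  tibble::tibble(model = x$model_names,
                 mean_ppm = rowMeans(x$ppm[, in_mask, drop = FALSE]),
                 max_ppm = apply(x$ppm[, in_mask, drop = FALSE], 1, max),
                 mean_epm = rowMeans(x$epm[, in_mask, drop = FALSE]),
                 n_voxels = length(in_mask))
}

#' @export
tidy.bms_result <- function(x, ...) {
  in_mask <- which(x$mask)
  ijk <- arrayInd(in_mask, x$dim3)
  base <- tibble::tibble(voxel = rep(in_mask, times = length(x$model_names)),
                         i = rep(ijk[, 1], times = length(x$model_names)),
                         j = rep(ijk[, 2], times = length(x$model_names)),
                         k = rep(ijk[, 3], times = length(x$model_names)),
                         model = rep(x$model_names, each = length(in_mask)))
  base$alpha <- as.vector(t(x$alpha[, in_mask, drop = FALSE]))
  base$ppm <- as.vector(t(x$ppm[, in_mask, drop = FALSE]))
  base$epm <- as.vector(t(x$epm[, in_mask, drop = FALSE]))
  base
}

#' Extract one model's probability volume from a BMS result
#'
#' @param result A `bms_result`.
#' @param model Model name or index.
#' @param type `"ppm"`, `"epm"` or `"alpha"`.
#' @return 3-D array (NA outside the mask).
#' @export
prob_volume <- function(result, model = 1, type = c("ppm", "epm", "alpha")) {
  stopifnot(inherits(result, "bms_result"))
  type <- match.arg(type)
  if (is.character(model)) model <- match(model, result$model_names)
  if (is.na(model)) stop("unknown model.", call. = FALSE)
  array(result[[type]][model, ], result$dim3)
}

#' Write BMS result volumes and a run report
#'
#' Writes `PPM_<model>.nii`, `EPM_<model>.nii` and `alpha_<model>.nii` plus a
#' JSON report with tolerances, iteration counts and seeds.
#'
#' @param result A `bms_result`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_bms_result <- function(result, dir) {
  stopifnot(inherits(result, "bms_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(result$model_names)) {
    for (type in c("ppm", "epm", "alpha")) {
      v <- prob_volume(result, k, type)
      v[!result$mask] <- NaN
      img <- RNifti::asNifti(v)
      RNifti::pixdim(img) <- result$grid_meta$voxel_size
      RNifti::writeNifti(img, file.path(dir, sprintf(
        "%s_%s.nii", c(ppm = "PPM", epm = "EPM", alpha = "alpha")[type],
        result$model_names[k])))
    }
  }
  jsonlite::write_json(list(n_subjects = result$n_subjects,
                            model_names = result$model_names,
                            alpha0 = result$alpha0,
                            n_iter = result$n_iter,
                            converged = result$converged,
                            n_samples = result$n_samples,
                            seed = result$seed),
                       file.path(dir, "bms_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
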