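#' Simulate a heterogeneous group of epoched M/EEG datasets
#'
#' Generates one epoched dataset per subject under a known ground truth:
#' each subject's data are produced by one of the candidate condition-weight
#' models. The trial amplitude at channel `ch` and sample `t` is
#' `intercept + effect_size * weight(condition) * g(ch) * h(t) + N(0, noise_sd^2)`
#' where `g` is 1 on a block of effect channels (0 elsewhere) and `h` is 1
#' inside the effect time window. Channels sit on a regular `channel_layout`
#' grid over the unit square, so the voxels whose scalp interpolation is
#' supported entirely by effect channels form a contiguous spatial blob;
#' those voxel indices (crossed with the effect window) are recorded as the
#' ground-truth effect region, and partially supported voxels as a halo.
#'
#' Each subject has an independent child random stream derived from the root
#' seed, so adding subjects never changes earlier subjects' data.
#'
#' @param n_subjects Number of subjects (default 21, a typical EEG cohort).
#' @param n_trials_per_condition Trials per condition per subject.
#' @param conditions Character vector of condition labels (>= 2).
#' @param model_specs List of [model_spec()] objects (>= 1), the candidate
#'   models; every condition must be mapped by every model.
#' @param assignments Optional integer vector: generating model index per
#'   subject. Default: drawn uniformly per subject.
#' @param effect_size Amplitude units per unit covariate weight.
#' @param noise_sd Standard deviation of the additive channel noise (>= 0).
#' @param intercept Baseline amplitude common to all channels.
#' @param grid_size Scalp grid `(nx, ny)` used to define the voxel-space
#'   ground truth (default 32 x 32).
#' @param n_time Number of peristimulus samples (default 80).
#' @param time_axis Peristimulus times in ms (default 0..395 ms at 200 Hz).
#' @param effect_time Integer sample indices of the effect window
#'   (default 10 samples).
#' @param channel_layout Channels-per-side of the square channel grid
#'   (default 8, i.e. 64 channels).
#' @param effect_channel_block Integer rows/columns (on the channel grid) of
#'   the effect block; default the central 2 x 2 block, whose fully supported
#'   voxel footprint is about 5 x 5 on a 32 x 32 grid.
#' @param seed Root seed (integer).
#' @return A `bms_simulation`: list with `datasets` (list of [eeg_dataset()])
#'   and `truth` (assignments, effect channels, voxel-space effect region and
#'   halo, parameters, seed).
#' @export
simulate_group <- function(n_subjects = 21,
                           n_trials_per_condition = 30,
                           conditions = c("UP", "AP", "UU", "AU"),
                           model_specs = list(opposition_model(), interaction_model()),
                           assignments = NULL,
                           effect_size = 1,
                           noise_sd = 1,
                           intercept = 0,
                           grid_size = c(32, 32),
                           n_time = 80,
                           time_axis = NULL,
                           effect_time = 31:40,
                           channel_layout = 8,
                           effect_channel_block = NULL,
                           seed = 1) {
  if (length(conditions) < 2L) stop("need at least two conditions.", call. = FALSE)
  if (length(model_specs) < 1L) stop("need at least one model.", call. = FALSE)
  if (n_trials_per_condition < 1L) stop("need at least one trial per condition.", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative.", call. = FALSE)
  for (spec in model_specs) {
    stopifnot(inherits(spec, "bms_model_spec"))
    missing_cond <- setdiff(conditions, names(spec$weights))
    if (length(missing_cond) > 0L) {
      stop("model '", spec$name, "' does not map condition(s): ",
           paste(missing_cond, collapse = ", "), call. = FALSE)
    }
  }
  K <- length(model_specs)
  if (!is.null(assignments)) {
    assignments <- as.integer(assignments)
    if (length(assignments) != n_subjects || any(assignments < 1L | assignments > K)) {
      stop("`assignments` must give one model index in 1..", K,
           " per subject.", call. = FALSE)
    }
  }
  if (is.null(time_axis)) time_axis <- seq(0, by = 5, length.out = n_time)
  n_time <- length(time_axis)
  if (any(effect_time < 1L | effect_time > n_time)) {
    stop("`effect_time` indices outside the time axis.", call. = FALSE)
  }

  # regular channel grid over the unit square
  side <- channel_layout
  coord <- seq(0, 1, length.out = side)
  channel_positions <- cbind(rep(coord, times = side), rep(coord, each = side))
  if (is.null(effect_channel_block)) {
    mid <- floor(side / 2)
    effect_channel_block <- c(mid, mid + 1L)
  }
  in_block <- function(i) i %in% effect_channel_block
  ch_row <- rep(seq_len(side), times = side)
  ch_col <- rep(seq_len(side), each = side)
  effect_channels <- which(in_block(ch_row) & in_block(ch_col))

  # voxel-space ground truth from the interpolation support
  itp <- scalp_interpolator(channel_positions, grid_size)
  full <- vapply(itp$support, function(s) length(s) > 0 && all(s %in% effect_channels),
                 logical(1))
  partial <- vapply(itp$support, function(s) length(s) > 0 && any(s %in% effect_channels),
                    logical(1)) & !full
  n_vox_spatial <- grid_size[1] * grid_size[2]
  effect_region <- as.vector(outer(which(full), (effect_time - 1L) * n_vox_spatial, "+"))
  halo_spatial <- which(partial)
  halo_region <- as.vector(outer(which(full | partial),
                                 (seq_len(n_time) - 1L) * n_vox_spatial, "+"))

  n_trials <- n_trials_per_condition * length(conditions)
  labels <- rep(conditions, each = n_trials_per_condition)
  g_ch <- as.numeric(seq_len(side^2) %in% effect_channels)
  h_t <- as.numeric(seq_len(n_time) %in% effect_time)

  datasets <- vector("list", n_subjects)
  if (is.null(assignments)) assignments <- rep(NA_integer_, n_subjects)
  for (n in seq_len(n_subjects)) {
    set.seed(child_seed(seed, n))
    if (is.na(assignments[n])) assignments[n] <- sample.int(K, 1L)
    w <- model_specs[[assignments[n]]]$weights[labels]           # per trial
    mean_arr <- intercept +
      effect_size * outer(outer(unname(w), g_ch), h_t)           # trials x ch x time
    noise <- array(rnorm(length(mean_arr), sd = noise_sd), dim = dim(mean_arr))
    datasets[[n]] <- eeg_dataset(mean_arr + noise, channel_positions,
                                 time_axis, labels, subject_id = n)
  }

  truth <- list(subject_assignments = assignments,
                model_names = vapply(model_specs, `[[`, character(1), "name"),
                effect_channels = effect_channels,
                effect_spatial = which(full),
                halo_spatial = halo_spatial,
                effect_region = effect_region,
                halo_region = halo_region,
                effect_time = effect_time,
                grid_size = grid_size,
                n_time = n_time,
                effect_size = effect_size,
                noise_sd = noise_sd,
                intercept = intercept,
                seed = seed)
  structure(list(datasets = datasets, truth = truth,
                 model_specs = model_specs, conditions = conditions),
            class = "bms_simulation")
}

#' @export
print.bms_simulation <- function(x, ...) {
  cat("<bms_simulation> ", length(x$datasets), " subjects, ",
      length(x$model_specs), " candidate models\n", sep = "")
  cat("  assignments:", paste(table(factor(x$truth$subject_assignments,
                                           levels = seq_along(x$model_specs))),
                              collapse = " / "), "\n")
  cat("  effect: ", length(x$truth$effect_spatial), " spatial voxels x ",
      length(x$truth$effect_time), " samples, effect size ",
      x$truth$effect_size, ", noise sd ", x$truth$noise_sd, "\n", sep = "")
  invisible(x)
}

# deterministic per-subject child seed, independent of n_subjects
child_seed <- function(root, n) {
  as.integer((as.numeric(root) + 104729 * as.numeric(n)) %% 2147483629)
}

#' Simulate a single-voxel group log-evidence matrix
#'
#' Direct fixture for group-level random-effects model selection: each
#' subject's generating model is drawn from `true_frequencies`, and that
#' model's log evidence exceeds the others' by draws centred on
#' `evidence_scale` (each entry gets independent `N(0, noise_sd^2)` jitter,
#' so `evidence_scale = 0` yields uninformative rows).
#'
#' @param n_subjects Number of subjects.
#' @param true_frequencies Probability vector over the K candidate models.
#' @param evidence_scale Log-evidence advantage (nats) of the generating model.
#' @param noise_sd Jitter s.d. on each log evidence (default 1 nat).
#' @param seed Root seed; subjects use independent child streams.
#' @return List of class `bms_sim_evidence` with `log_evidences`
#'   (subjects x models), `assignments`, and the generating parameters.
#' @export
simulate_log_evidences <- function(n_subjects, true_frequencies,
                                   evidence_scale = 3, noise_sd = 1, seed = 1) {
  true_frequencies <- as.numeric(true_frequencies)
  if (any(true_frequencies < 0)) stop("negative model frequency.", call. = FALSE)
  if (abs(sum(true_frequencies) - 1) > 1e-8) {
    stop("`true_frequencies` must sum to 1.", call. = FALSE)
  }
  K <- length(true_frequencies)
  if (K < 2L) stop("need at least two models.", call. = FALSE)
  lme <- matrix(0, n_subjects, K)
  assignments <- integer(n_subjects)
  for (n in seq_len(n_subjects)) {
    set.seed(child_seed(seed, n))
    assignments[n] <- sample.int(K, 1L, prob = true_frequencies)
    lme[n, ] <- evidence_scale * (seq_len(K) == assignments[n]) +
      rnorm(K, sd = noise_sd)
  }
  colnames(lme) <- paste0("model", seq_len(K))
  structure(list(log_evidences = lme, assignments = assignments,
                 true_frequencies = true_frequencies,
                 evidence_scale = evidence_scale, noise_sd = noise_sd,
                 seed = seed),
            class = "bms_sim_evidence")
}

#' Write a simulated group to disk
#'
#' One NIfTI array file (trials x channels x time) plus a trial table per
#' subject, and a JSON sidecar holding the ground truth.
#'
#' @param sim A `bms_simulation`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "bms_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (n in seq_along(sim$datasets)) {
    ds <- sim$datasets[[n]]
    RNifti::writeNifti(RNifti::asNifti(ds$data),
                       file.path(dir, sprintf("subject_%02d_epochs.nii", n)))
    utils::write.table(
      data.frame(trial = seq_along(ds$condition_labels),
                 condition = ds$condition_labels),
      file.path(dir, sprintf("subject_%02d_trials.tsv", n)),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(
    data.frame(channel = seq_len(nrow(sim$datasets[[1]]$channel_positions)),
               x = sim$datasets[[1]]$channel_positions[, 1],
               y = sim$datasets[[1]]$channel_positions[, 2]),
    file.path(dir, "channel_positions.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(time_ms = sim$datasets[[1]]$time_axis),
    file.path(dir, "time_axis.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
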