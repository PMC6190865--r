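#' Construct an epoched M/EEG dataset
#'
#' Container for epoched single-trial data: a trials x channels x time
#' amplitude array (microvolts), 2-D scalp coordinates per channel
#' (normalised units), a peristimulus time axis (ms) and one condition
#' label per trial.
#'
#' @param data Numeric array, trials x channels x time.
#' @param channel_positions Numeric matrix, channels x 2.
#' @param time_axis Numeric vector of peristimulus times (ms), one per sample.
#' @param condition_labels Character vector, one per trial.
#' @param subject_id Optional identifier.
#' @return An object of class `eeg_dataset`.
#' @export
eeg_dataset <- function(data, channel_positions, time_axis, condition_labels,
                        subject_id = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  channel_positions <- as.matrix(channel_positions)
  d <- dim(data)
  if (nrow(channel_positions) != d[2] || ncol(channel_positions) != 2L) {
    stop("`channel_positions` must be a (channels x 2) matrix matching dim(data)[2].",
         call. = FALSE)
  }
  if (length(time_axis) != d[3]) {
    stop("`time_axis` length must equal dim(data)[3].", call. = FALSE)
  }
  if (length(condition_labels) != d[1]) {
    stop("`condition_labels` length must equal the number of trials.", call. = FALSE)
  }
  structure(list(data = data,
                 channel_positions = channel_positions,
                 time_axis = as.numeric(time_axis),
                 condition_labels = as.character(condition_labels),
                 subject_id = subject_id),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_dataset>", if (!is.null(x$subject_id)) paste0(" subject ", x$subject_id), "\n",
      sep = "")
  cat("  ", d[1], " trials x ", d[2], " channels x ", d[3], " samples (",
      min(x$time_axis), "..", max(x$time_axis), " ms)\n", sep = "")
  cat("  conditions:", paste(sort(unique(x$condition_labels)), collapse = ", "), "\n")
  invisible(x)
}

# Piecewise-linear scalp interpolator: Delaunay triangulation of the channel
# layout, barycentric weights at each grid node. Returns the (grid x channels)
# weight matrix once so repeated trials/time-points are a single matrix product.
scalp_interpolator <- function(channel_positions, grid_size) {
  pos <- as.matrix(channel_positions)
  if (nrow(pos) < 3L) {
    stop("scalp interpolation needs at least 3 channels.", call. = FALSE)
  }
  if (anyDuplicated(round(pos, 12))) {
    stop("duplicate channel positions.", call. = FALSE)
  }
  centred <- sweep(pos, 2, colMeans(pos))
  if (qr(centred)$rank < 2L) {
    stop("channel positions are collinear; cannot triangulate the scalp.", call. = FALSE)
  }
  nx <- grid_size[1]; ny <- grid_size[2]
  gx <- seq(min(pos[, 1]), max(pos[, 1]), length.out = nx)
  gy <- seq(min(pos[, 2]), max(pos[, 2]), length.out = ny)
  pts <- cbind(rep(gx, times = ny), rep(gy, each = nx))

  tm <- interp::tri.mesh(pos[, 1], pos[, 2])
  loc <- interp::tri.find(tm, pts[, 1], pts[, 2])
  idx <- cbind(loc$i1, loc$i2, loc$i3)
  bc <- loc$bc
  # point location returns valid vertex indices (with tr = 0) for grid nodes
  # exactly on a triangle edge or vertex; only truly-outside points get idx 0
  inside <- idx[, 1] > 0
  # numerical slop at hull edges: clamp tiny negative weights, renormalise
  bc[bc > -1e-6 & bc < 0] <- 0
  bc <- bc / rowSums(bc)

  W <- matrix(0, nrow = nx * ny, ncol = nrow(pos))
  row_in <- which(inside)
  for (v in 1:3) {
    ij <- cbind(row_in, idx[row_in, v])
    W[ij] <- W[ij] + bc[row_in, v]
  }
  list(weights = W,
       mask = matrix(inside, nx, ny),
       grid_x = gx, grid_y = gy,
       support = lapply(seq_len(nx * ny), function(i) {
         if (!inside[i]) integer(0) else idx[i, bc[i, ] > 1e-9]
       }))
}

#' Interpolate channel amplitudes onto a scalp grid
#'
#' Piecewise-linear (barycentric) interpolation of per-channel values on a
#' Delaunay triangulation of the channel layout. Grid nodes outside the
#' convex hull of the channels are masked out rather than extrapolated;
#' interpolation is exact at channel locations and reproduces any affine
#' field `a + b*x + c*y` on the interior.
#'
#' @param channel_values Numeric vector, one amplitude per channel.
#' @param channel_positions Channels x 2 coordinate matrix.
#' @param grid_size Integer pair `(nx, ny)`.
#' @return A list with `grid` (nx x ny matrix, `NA` outside the mask) and
#'   `mask` (nx x ny logical).
#' @export
interpolate_scalp <- function(channel_values, channel_positions, grid_size = c(32, 32)) {
  if (length(channel_values) != nrow(as.matrix(channel_positions))) {
    stop("one value per channel required.", call. = FALSE)
  }
  if (any(!is.finite(channel_values))) {
    stop("non-finite channel values.", call. = FALSE)
  }
  itp <- scalp_interpolator(channel_positions, grid_size)
  g <- as.vector(itp$weights %*% channel_values)
  g[!as.vector(itp$mask)] <- NA_real_
  list(grid = matrix(g, grid_size[1], grid_size[2]), mask = itp$mask)
}

#' Construct a set of per-trial voxel volumes
#'
#' @param volumes 4-D numeric array `(nx, ny, nz, n_trials)` on a shared grid.
#' @param mask 3-D logical array of valid voxels.
#' @param grid_meta List describing the grid: `voxel_size`, `origin`, `axes`,
#'   `space` (`"scalp-time"` or `"source"`).
#' @param condition_labels One label per volume.
#' @return An object of class `voxel_image_set`.
#' @export
voxel_image_set <- function(volumes, mask, grid_meta, condition_labels) {
  stopifnot(is.array(volumes), length(dim(volumes)) == 4L)
  dv <- dim(volumes)
  if (!is.array(mask) || !identical(dim(mask), dv[1:3])) {
    stop("`mask` must be a 3-D logical array matching the volume grid.", call. = FALSE)
  }
  if (length(condition_labels) != dv[4]) {
    stop("one condition label per volume required.", call. = FALSE)
  }
  structure(list(volumes = volumes, mask = array(as.logical(mask), dv[1:3]),
                 grid_meta = grid_meta,
                 condition_labels = as.character(condition_labels)),
            class = "voxel_image_set")
}

#' @export
print.voxel_image_set <- function(x, ...) {
  dv <- dim(x$volumes)
  cat("<voxel_image_set> ", dv[4], " volumes of ", dv[1], "x", dv[2], "x", dv[3],
      " (", x$grid_meta$space %||% "unknown", " space), ",
      sum(x$mask), " in-mask voxels\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build per-trial scalp-time voxel volumes from epoched data
#'
#' Every trial becomes one 3-D volume: the first two axes are the
#' interpolated scalp grid and the third axis is peristimulus time, ordered
#' from the earliest to the latest sample. The spatial mask (grid nodes
#' inside the channel hull) is identical for all trials and all time slices.
#'
#' @param dataset An [eeg_dataset()].
#' @param grid_size Integer pair `(nx, ny)`; default the conventional 32 x 32
#'   scalp raster.
#' @return A [voxel_image_set()] with one volume per trial.
#' @export
build_scalp_time_volumes <- function(dataset, grid_size = c(32, 32)) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  d <- dim(dataset$data)
  n_trials <- d[1]; n_ch <- d[2]; n_time <- d[3]
  if (n_trials == 0L) stop("empty dataset: no trials.", call. = FALSE)
  if (is.unsorted(dataset$time_axis, strictly = TRUE)) {
    stop("`time_axis` must be strictly increasing.", call. = FALSE)
  }
  itp <- scalp_interpolator(dataset$channel_positions, grid_size)
  # channels x (trials*time), trial index fastest
  vals <- matrix(aperm(dataset$data, c(2, 1, 3)), nrow = n_ch)
  g <- itp$weights %*% vals                       # (nx*ny) x (trials*time)
  vol <- array(g, dim = c(grid_size[1], grid_size[2], n_trials, n_time))
  vol <- aperm(vol, c(1, 2, 4, 3))                # nx, ny, time, trial
  out_mask <- !as.vector(itp$mask)
  if (any(out_mask)) {
    vol_flat <- matrix(vol, nrow = grid_size[1] * grid_size[2])
    vol_flat[out_mask, ] <- NA_real_
    vol <- array(vol_flat, dim = dim(vol))
  }
  dt <- if (n_time > 1) diff(dataset$time_axis[1:2]) else 1
  grid_meta <- list(
    space = "scalp-time",
    voxel_size = c(diff(itp$grid_x[1:2]), diff(itp$grid_y[1:2]), dt),
    origin = c(itp$grid_x[1], itp$grid_y[1], dataset$time_axis[1]),
    axes = c("scalp-x", "scalp-y", "time-ms"))
  mask3 <- array(rep(as.vector(itp$mask), n_time),
                 dim = c(grid_size[1], grid_size[2], n_time))
  voxel_image_set(vol, mask3, grid_meta, dataset$condition_labels)
}

#' Replace NaN voxels by zero in a source-space volume
#'
#' Source reconstructions commonly code voxels outside the cortical support
#' as NaN; downstream voxel-wise model selection expects finite values.
#' All NaN (and NA) voxels are set to zero; finite values are untouched and
#' the number of replacements is reported.
#'
#' @param volume Numeric array.
#' @return The volume with NaNs replaced, with attribute `n_replaced`.
#' @export
sanitize_source_map <- function(volume) {
  bad <- !is.finite(volume)
  if (all(bad) && length(volume) > 0L) {
    warning("volume contains no finite voxels; returning all zeros.", call. = FALSE)
  }
  n <- sum(bad)
  if (n > 0L) {
    volume[bad] <- 0
    message("sanitize_source_map: replaced ", n, " non-finite voxel(s) with 0.")
  }
  attr(volume, "n_replaced") <- n
  volume
}

#' Write and read voxel image sets as NIfTI-1 volumes
#'
#' One `.nii` file per trial volume; voxels outside the mask are stored as
#' NaN so they cannot be mistaken for measured zeros. Grid metadata goes to
#' a JSON sidecar and condition labels to a tab-separated trial table, making
#' the round trip lossless up to float32 storage precision.
#'
#' @param set A [voxel_image_set()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return `write_volumes()` returns the written volume paths, invisibly.
#' @export
write_volumes <- function(set, dir, prefix = "trial") {
  stopifnot(inherits(set, "voxel_image_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dv <- dim(set$volumes)
  mask_flat <- !as.vector(set$mask)
  paths <- character(dv[4])
  for (i in seq_len(dv[4])) {
    v <- set$volumes[, , , i]
    v[mask_flat] <- NaN
    img <- RNifti::asNifti(v)
    RNifti::pixdim(img) <- set$grid_meta$voxel_size
    paths[i] <- file.path(dir, sprintf("%s_%04d.nii", prefix, i))
    RNifti::writeNifti(img, paths[i])
  }
  jsonlite::write_json(set$grid_meta, file.path(dir, paste0(prefix, "_grid.json")),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(trial = seq_len(dv[4]), condition = set$condition_labels),
    file.path(dir, paste0(prefix, "_trials.tsv")),
    sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' @rdname write_volumes
#' @param paths Character vector of NIfTI paths, or a directory written by
#'   `write_volumes()`.
#' @param prefix2 Prefix used when `paths` is a directory (matches `prefix`).
#' @export
read_volumes <- function(paths, prefix2 = "trial") {
  grid_meta <- NULL; labels <- NULL
  if (length(paths) == 1L && dir.exists(paths)) {
    dir <- paths
    paths <- sort(list.files(dir, pattern = paste0("^", prefix2, "_\\d+\\.nii$"),
                             full.names = TRUE))
    gj <- file.path(dir, paste0(prefix2, "_grid.json"))
    if (file.exists(gj)) grid_meta <- jsonlite::read_json(gj, simplifyVector = TRUE)
    tt <- file.path(dir, paste0(prefix2, "_trials.tsv"))
    if (file.exists(tt)) labels <- utils::read.delim(tt)$condition
  }
  if (length(paths) == 0L) stop("no NIfTI volumes found.", call. = FALSE)
  vols <- lapply(paths, function(p) {
    a <- as.array(RNifti::readNifti(p))
    if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
    a
  })
  shapes <- vapply(vols, function(a) paste(dim(a), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1L) {
    stop("inconsistent volume shapes across files: ",
         paste(unique(shapes), collapse = " vs "), call. = FALSE)
  }
  arr <- array(unlist(vols), dim = c(dim(vols[[1]]), length(vols)))
  mask <- is.finite(vols[[1]])
  for (a in vols[-1]) mask <- mask & is.finite(a)
  if (is.null(grid_meta)) {
    pd <- RNifti::pixdim(RNifti::readNifti(paths[1]))
    grid_meta <- list(space = "unknown", voxel_size = pd[seq_len(3)],
                      origin = c(0, 0, 0), axes = c("x", "y", "z"))
  }
  if (is.null(labels)) labels <- rep(NA_character_, length(vols))
  voxel_image_set(arr, mask, grid_meta, labels)
}
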