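#' Threshold a probability volume
#'
#' A voxel is supra-threshold iff its probability strictly exceeds the
#' threshold and it lies inside the mask (following the usual "> 75%" /
#' "> 50%" display conventions for scalp-time and source maps).
#'
#' @param prob_volume 3-D numeric array of probabilities.
#' @param threshold Probability in `[0, 1]`.
#' @param mask Optional logical array; defaults to the finite voxels.
#' @return Logical 3-D array.
#' @export
threshold_map <- function(prob_volume, threshold, mask = NULL) {
  stopifnot(is.array(prob_volume), length(dim(prob_volume)) == 3L)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    stop("`threshold` must be a probability in [0, 1].", call. = FALSE)
  }
  if (is.null(mask)) mask <- is.finite(prob_volume)
  out <- !is.na(prob_volume) & prob_volume > threshold & mask
  array(out, dim(prob_volume))
}

conn_offsets <- function(connectivity) {
  base <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  base <- base[rowSums(abs(base)) > 0, ]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(base)) == 1,
                 "18" = rowSums(abs(base)) <= 2,
                 "26" = rep(TRUE, nrow(base)),
                 stop("`connectivity` must be 6, 18 or 26.", call. = FALSE))
  off <- as.matrix(base[keep, ])
  # keep one direction per pair; undirected edges
  off[off[, 3] > 0 | (off[, 3] == 0 & (off[, 2] > 0 | (off[, 2] == 0 & off[, 1] > 0))), ,
      drop = FALSE]
}

#' Extract supra-threshold clusters from a binary volume
#'
#' Labels connected components under face (6), face+edge (18) or
#' face+edge+corner (26) connectivity, drops components smaller than
#' `min_size`, and reports each cluster's extent `K_E`, peak value and peak
#' coordinates (grid indices, plus physical coordinates when grid metadata
#' is supplied). Clusters are sorted by size descending with a deterministic
#' lexicographic tie-break on the peak index.
#'
#' @param binary_volume Logical 3-D array (NA treated as FALSE).
#' @param connectivity 6, 18 or 26.
#' @param min_size Minimum cluster extent in voxels (clusters below are
#'   dropped; 0 keeps everything).
#' @param values Optional numeric array (e.g. the probability map) used to
#'   locate and report cluster peaks.
#' @param grid_meta Optional grid metadata (`origin`, `voxel_size`) for
#'   physical peak coordinates.
#' @return A tibble with columns `cluster`, `size`, `peak_value`,
#'   `peak_i/j/k` and, when metadata is given, `peak_x/y/z`.
#' @export
extract_clusters <- function(binary_volume, connectivity = 6, min_size = 0,
                             values = NULL, grid_meta = NULL) {
  stopifnot(is.array(binary_volume), length(dim(binary_volume)) == 3L)
  d <- dim(binary_volume)
  bin <- !is.na(binary_volume) & binary_volume
  vox <- which(bin)
  empty <- tibble::tibble(cluster = integer(0), size = integer(0),
                          peak_value = numeric(0), peak_i = integer(0),
                          peak_j = integer(0), peak_k = integer(0))
  if (length(vox) == 0L) return(empty)

  coords <- arrayInd(vox, d)
  id <- match(vox, vox)                 # 1..n in voxel order
  offs <- conn_offsets(connectivity)
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    nb <- sweep(coords, 2, off, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb_lin <- (nb[ok, 3] - 1) * d[1] * d[2] + (nb[ok, 2] - 1) * d[1] + nb[ok, 1]
    hit <- match(nb_lin, vox)
    src <- which(ok)[!is.na(hit)]
    dst <- hit[!is.na(hit)]
    if (length(src)) edges <- rbind(edges, cbind(src, dst))
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership

  vals <- if (is.null(values)) rep(1, length(vox)) else values[vox]
  rows <- lapply(unique(memb), function(m) {
    members <- which(memb == m)
    size <- length(members)
    # peak: highest value, ties broken by smallest linear index
    best <- members[order(-vals[members], vox[members])][1]
    list(size = size, peak_value = vals[best], peak_lin = vox[best],
         peak = coords[best, ])
  })
  tab <- tibble::tibble(
    size = vapply(rows, function(r) r$size, numeric(1)),
    peak_value = vapply(rows, function(r) r$peak_value, numeric(1)),
    peak_lin = vapply(rows, function(r) r$peak_lin, numeric(1)),
    peak_i = vapply(rows, function(r) r$peak[1], numeric(1)),
    peak_j = vapply(rows, function(r) r$peak[2], numeric(1)),
    peak_k = vapply(rows, function(r) r$peak[3], numeric(1)))
  tab <- tab[tab$size >= max(min_size, 1), , drop = FALSE]
  tab <- tab[order(-tab$size, tab$peak_lin), , drop = FALSE]
  if (nrow(tab) == 0L) return(empty)
  tab$cluster <- seq_len(nrow(tab))
  out <- tab[, c("cluster", "size", "peak_value", "peak_i", "peak_j", "peak_k")]
  if (!is.null(grid_meta) && !is.null(grid_meta$origin)) {
    phys <- sweep(sweep(as.matrix(out[, c("peak_i", "peak_j", "peak_k")]) - 1,
                        2, grid_meta$voxel_size[1:3], "*"),
                  2, grid_meta$origin[1:3], "+")
    out$peak_x <- unname(phys[, 1])
    out$peak_y <- unname(phys[, 2])
    out$peak_z <- unname(phys[, 3])
  }
  out
}

#' Threshold, cluster and report a BMS result
#'
#' For every model: thresholds that model's probability map, extracts
#' clusters, and (optionally) writes thresholded NIfTI masks, delimited
#' cluster tables, and per-time-slice PNG panels for scalp-time results.
#'
#' @param result A `bms_result`.
#' @param threshold Display probability threshold (strict `>`).
#' @param type Map to report: `"ppm"` (default) or `"epm"`.
#' @param min_size Minimum cluster extent.
#' @param connectivity Cluster connectivity (6, 18 or 26).
#' @param out_dir Optional directory to write masks, tables and panels to.
#' @return A list of class `bms_report`: `clusters` (one tibble, with a
#'   `model` column), `tables` (list of per-model tibbles), `threshold`,
#'   and the binary maps.
#' @export
bms_report <- function(result, threshold = 0.75, type = c("ppm", "epm"),
                       min_size = 0, connectivity = 6, out_dir = NULL) {
  stopifnot(inherits(result, "bms_result"))
  type <- match.arg(type)
  tables <- list(); binaries <- list()
  for (k in seq_along(result$model_names)) {
    nm <- result$model_names[k]
    vol <- prob_volume(result, k, type)
    bin <- threshold_map(vol, threshold, mask = result$mask)
    tab <- extract_clusters(bin, connectivity = connectivity, min_size = min_size,
                            values = vol, grid_meta = result$grid_meta)
    tab$model <- nm
    tables[[nm]] <- tab
    binaries[[nm]] <- bin
  }
  combined <- dplyr::bind_rows(tables)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in result$model_names) {
      img <- RNifti::asNifti(array(as.numeric(binaries[[nm]]), result$dim3))
      RNifti::pixdim(img) <- result$grid_meta$voxel_size
      RNifti::writeNifti(img, file.path(out_dir, sprintf("thresh_%s_%s.nii", type, nm)))
      utils::write.table(tables[[nm]],
                         file.path(out_dir, sprintf("clusters_%s_%s.tsv", type, nm)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      if (identical(result$grid_meta$space, "scalp-time")) {
        p <- autoplot(result, model = nm, type = type, threshold = threshold)
        grDevices::png(file.path(out_dir, sprintf("slices_%s_%s.png", type, nm)),
                       width = 1600, height = 1200, res = 150)
        print(p)
        grDevices::dev.off()
      }
    }
    utils::write.table(combined, file.path(out_dir, sprintf("clusters_%s_all.tsv", type)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  structure(list(clusters = combined, tables = tables, binary = binaries,
                 threshold = threshold, type = type, min_size = min_size,
                 connectivity = connectivity),
            class = "bms_report")
}

#' @export
print.bms_report <- function(x, ...) {
  cat("<bms_report> threshold > ", x$threshold, " (", x$type, "), min size ",
      x$min_size, ", connectivity ", x$connectivity, "\n", sep = "")
  print(x$clusters)
  invisible(x)
}

#' Plot probability-map slices of a BMS result
#'
#' Renders per-time-slice (third axis) 2-D panels of one model's posterior
#' or exceedance probability map; voxels below `threshold` are blanked when
#' a threshold is supplied.
#'
#' @param object A `bms_result`.
#' @param model Model name or index.
#' @param type `"ppm"` or `"epm"`.
#' @param slices Integer vector of third-axis slices (default: up to 12,
#'   evenly spaced).
#' @param threshold Optional display threshold (strict `>`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bms_result <- function(object, model = 1, type = c("ppm", "epm"),
                                slices = NULL, threshold = NULL, ...) {
  type <- match.arg(type)
  vol <- prob_volume(object, model, type)
  d <- dim(vol)
  if (is.null(slices)) {
    slices <- unique(round(seq(1, d[3], length.out = min(12, d[3]))))
  }
  df <- do.call(rbind, lapply(slices, function(s) {
    data.frame(i = rep(seq_len(d[1]), d[2]),
               j = rep(seq_len(d[2]), each = d[1]),
               slice = s, prob = as.vector(vol[, , s]))
  }))
  if (!is.null(threshold)) df$prob[df$prob <= threshold] <- NA_real_
  nm <- if (is.character(model)) model else object$model_names[model]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$prob)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~slice) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90",
                                  name = toupper(type)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0(toupper(type), ": ", nm),
                  x = "scalp x", y = "scalp y") +
    ggplot2::theme_minimal()
}
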