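#' Detection parameters for probability-map segmentation
#'
#' The defaults are the calibrated operating point of the workflow: voxels
#' with nucleus probability of at least 0.80 form candidate objects, and
#' connected components (26-connectivity) smaller than 8 voxels are
#' discarded (~3.3 um^3 at the 0.743 um larval voxel size).
#'
#' @param threshold probability threshold in (0, 1).
#' @param min_voxels minimum component size, voxels (>= 1).
#' @param connectivity 6 or 26.
#' @return object of class `detection_params`.
#' @export
detection_params <- function(threshold = 0.80, min_voxels = 8L,
                             connectivity = 26L) {
  if (!(threshold > 0 && threshold < 1)) stop("`threshold` must be in (0,1)")
  if (min_voxels < 1) stop("`min_voxels` must be >= 1")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  structure(list(threshold = threshold, min_voxels = as.integer(min_voxels),
                 connectivity = as.integer(connectivity)),
            class = "detection_params")
}

#' Segment nuclei from a probability volume
#'
#' Thresholds the probability map at `params$threshold`, labels connected
#' components at the configured connectivity, drops components below the
#' size filter, and returns per-object voxel sets with world centroids,
#' volumes and elongations. An empty result is legitimate.
#'
#' @param p a `probability_volume` (from [classify_plane()] /
#'   [combine_probabilities()]) or a bare 3D probability array.
#' @param params a [detection_params()].
#' @param voxel_size_um voxel size; defaults to the probability volume's.
#' @return object of class `nucleus_set`: list with `table` (data.frame: id,
#'   x_um, y_um, z_um, n_voxels, volume_um3, elongation) and `voxels`
#'   (list of integer matrices, columns z,y,x).
#' @export
segment_nuclei <- function(p, params = detection_params(),
                           voxel_size_um = NULL) {
  if (inherits(p, "probability_volume")) {
    if (is.null(voxel_size_um)) voxel_size_um <- p$voxel_size_um
    p <- p$p
  }
  if (is.null(voxel_size_um)) stop("`voxel_size_um` required for array input")
  stopifnot(inherits(params, "detection_params"))
  d <- dim(p)
  mask <- p >= params$threshold
  lab <- .cc_label3d(as.vector(mask), as.integer(d), params$connectivity)
  sizes <- tabulate(lab)
  keep <- which(sizes >= params$min_voxels)
  voxels <- vector("list", length(keep))
  if (length(keep)) {
    sel <- which(lab %in% keep)
    co <- arrayInd(sel, d)
    grp <- match(lab[sel], keep)
    o <- order(grp, method = "radix")
    co <- co[o, , drop = FALSE]
    ends <- cumsum(sizes[keep])
    starts <- c(1L, head(ends, -1L) + 1L)
    for (i in seq_along(keep)) {
      v <- co[starts[i]:ends[i], , drop = FALSE]
      colnames(v) <- c("z", "y", "x")
      voxels[[i]] <- v
    }
  }
  tab <- data.frame(
    id = seq_along(voxels),
    x_um = vapply(voxels, function(v) mean(v[, 3] - 1), numeric(1)) * voxel_size_um,
    y_um = vapply(voxels, function(v) mean(v[, 2] - 1), numeric(1)) * voxel_size_um,
    z_um = vapply(voxels, function(v) mean(v[, 1] - 1), numeric(1)) * voxel_size_um,
    n_voxels = vapply(voxels, nrow, integer(1)))
  tab$volume_um3 <- tab$n_voxels * voxel_size_um^3
  tab$elongation <- vapply(voxels, elongation, numeric(1))
  if (nrow(tab) == 0L)
    tab <- data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                      z_um = numeric(), n_voxels = integer(),
                      volume_um3 = numeric(), elongation = numeric())
  structure(list(table = tab, voxels = voxels, voxel_size_um = voxel_size_um),
            class = "nucleus_set")
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf("<nucleus_set> %d objects @ %.4g um/voxel\n",
              nrow(x$table), x$voxel_size_um))
  invisible(x)
}

#' @export
as.data.frame.nucleus_set <- function(x, ...) x$table

#' Match detected against reference centroids
#'
#' Greedy one-to-one matching by ascending pair distance (ties broken by
#' reference index then detection index); pairs farther apart than
#' `match_radius_um` stay unmatched. Matched pairs are true positives,
#' unmatched references false negatives, unmatched detections false
#' positives; precision, recall and the F1 score are derived. The default
#' radius of 3 um is about the radius of a typical ~13 um^3 brain nucleus.
#'
#' @param detected n x 3 matrix of detected centroids (x, y, z um) or a
#'   `nucleus_set`.
#' @param reference m x 3 matrix of reference (e.g. ground-truth or
#'   manually annotated) centroids.
#' @param match_radius_um maximum centroid distance of a valid match (> 0).
#' @return object of class `match_result`: list with counts `TP`, `FP`,
#'   `FN`, the matched `pairs` (detection, reference, distance), and
#'   `precision`, `recall`, `f1`.
#' @export
match_detections <- function(detected, reference, match_radius_um = 3) {
  if (match_radius_um <= 0) stop("`match_radius_um` must be positive")
  if (inherits(detected, "nucleus_set"))
    detected <- as.matrix(detected$table[, c("x_um", "y_um", "z_um")])
  detected <- as.matrix(detected); reference <- as.matrix(reference)
  nd <- nrow(detected); nt <- nrow(reference)
  pairs <- data.frame(detection = integer(), reference = integer(),
                      distance_um = numeric())
  if (nd > 0 && nt > 0) {
    D <- sqrt(outer(rowSums(detected^2), rowSums(reference^2), "+") -
                2 * detected %*% t(reference))
    D[!is.finite(D)] <- 0
    cand <- which(D <= match_radius_um, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(D[cand], cand[, 2], cand[, 1], method = "radix")
      cand <- cand[ord, , drop = FALSE]
      used_d <- logical(nd); used_t <- logical(nt)
      keep <- integer(0)
      for (i in seq_len(nrow(cand))) {
        di <- cand[i, 1]; ti <- cand[i, 2]
        if (!used_d[di] && !used_t[ti]) {
          used_d[di] <- TRUE; used_t[ti] <- TRUE
          keep <- c(keep, i)
        }
      }
      pairs <- data.frame(detection = cand[keep, 1], reference = cand[keep, 2],
                          distance_um = D[cand[keep, , drop = FALSE]])
    }
  }
  TP <- nrow(pairs); FP <- nd - TP; FN <- nt - TP
  structure(list(TP = TP, FP = FP, FN = FN, pairs = pairs,
                 precision = if (TP + FP > 0) TP / (TP + FP) else NaN,
                 recall = if (TP + FN > 0) TP / (TP + FN) else NaN,
                 f1 = if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN)
                      else NaN),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d  FP %d  FN %d | precision %.3f recall %.3f F1 %.3f\n",
              x$TP, x$FP, x$FN, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Calibrate the probability threshold by F1 score
#'
#' Runs segment -> match -> F1 for every threshold in the grid and returns
#' the full curve plus the argmax (ties towards the smallest threshold),
#' balancing precision against recall.
#'
#' @param p a `probability_volume` or 3D array.
#' @param reference reference centroids (m x 3, um); must be non-empty.
#' @param thresholds threshold grid in (0, 1).
#' @param params a [detection_params()] supplying size filter and
#'   connectivity (its threshold is overridden by the grid).
#' @param voxel_size_um voxel size for array input.
#' @param match_radius_um matching radius, um.
#' @return list with `best_threshold`, `best_f1` and `curve` (data.frame:
#'   threshold, TP, FP, FN, precision, recall, f1).
#' @export
optimize_threshold <- function(p, reference, thresholds = seq(0.5, 0.95, 0.05),
                               params = detection_params(),
                               voxel_size_um = NULL, match_radius_um = 3) {
  if (length(thresholds) == 0) stop("empty threshold grid")
  reference <- as.matrix(reference)
  if (nrow(reference) == 0)
    stop("empty reference set: recall (hence F1) is undefined")
  rows <- lapply(sort(thresholds), function(th) {
    pr <- params; pr$threshold <- th
    det <- segment_nuclei(p, pr, voxel_size_um)
    m <- match_detections(det, reference, match_radius_um)
    data.frame(threshold = th, TP = m$TP, FP = m$FP, FN = m$FN,
               precision = m$precision, recall = m$recall, f1 = m$f1)
  })
  curve <- do.call(rbind, rows)
  i <- which.max(curve$f1)
  list(best_threshold = curve$threshold[i], best_f1 = curve$f1[i],
       curve = curve)
}

#' End-to-end nucleus detection on a volume
#'
#' The full calibrated pipeline: train one random-forest voxel classifier
#' per orthogonal plane from sparse labels, classify every slice of each
#' plane, fuse the three probability maps by voxelwise product, and segment
#' with the threshold/size filter.
#'
#' @param volume a [volume3d()].
#' @param labels a [sparse_labels()] with both classes.
#' @param params a [detection_params()].
#' @param spec a [feature_spec()].
#' @param n_trees trees per forest.
#' @param seed RNG seed (forest training).
#' @return list with `nuclei` (a `nucleus_set`), `p_total` and `p_plane`
#'   (the per-plane probability volumes).
#' @export
detect_nuclei <- function(volume, labels, params = detection_params(),
                          spec = feature_spec(), n_trees = 100L, seed = 1L) {
  models <- lapply(1:3, function(ax)
    train_classifier(volume, labels, axis = ax, spec = spec,
                     n_trees = n_trees, seed = seed + ax))
  probs <- lapply(1:3, function(ax) classify_plane(volume, models[[ax]], ax))
  p_total <- combine_probabilities(probs[[1]], probs[[2]], probs[[3]])
  list(nuclei = segment_nuclei(p_total, params), p_total = p_total,
       p_plane = probs)
}
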