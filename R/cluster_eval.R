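# Scoring a reconstruction against the simulated ground truth:
# condition difference -> window average -> top-fraction threshold ->
# adjacency clustering -> TP/FP/FN classification -> metrics.

#' Windowed condition difference map
#'
#' Per-dipole difference between the ERP-condition and noise-condition evoked
#' current source density, averaged over the analysis window (inclusive sample
#' endpoints).
#'
#' @param erp_evoked,noise_evoked `source_estimate` objects on the same source
#'   space and time axis.
#' @param window 2-vector, window of interest in ms post-stimulus (default
#'   `c(100, 220)`).
#' @return numeric vector, one value per dipole.
#' @export
condition_difference <- function(erp_evoked, noise_evoked,
                                 window = c(100, 220)) {
  stopifnot(inherits(erp_evoked, "source_estimate"),
            inherits(noise_evoked, "source_estimate"))
  if (!identical(dim(erp_evoked$csd), dim(noise_evoked$csd)) ||
      !identical(erp_evoked$source_space_id, noise_evoked$source_space_id)) {
    stop_invalid("evoked estimates must share source space and time axis")
  }
  t <- erp_evoked$t0 + (seq_len(ncol(erp_evoked$csd)) - 1) * 1000 / erp_evoked$fs
  sel <- which(t >= window[1] & t <= window[2])
  if (length(sel) == 0 || window[1] < min(t) || window[2] > max(t)) {
    stop_invalid("analysis window [", window[1], ", ", window[2],
                 "] ms lies outside the epoch")
  }
  rowMeans(erp_evoked$csd[, sel, drop = FALSE] -
           noise_evoked$csd[, sel, drop = FALSE])
}

#' Threshold a difference map to its strongest fraction
#'
#' Keeps exactly `ceiling(fraction * n)` dipoles: the largest by signed value,
#' ties broken by ascending dipole index for determinism.  An all-equal input
#' still returns that many dipoles (by tie-break) with a warning.
#'
#' @param values per-dipole difference values.
#' @param fraction fraction to keep, in (0, 1) (default 0.05).
#' @return logical mask over dipoles.
#' @export
threshold_top_fraction <- function(values, fraction = 0.05) {
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    stop_invalid("fraction must lie in (0, 1)")
  }
  n <- length(values)
  k <- ceiling(fraction * n)
  if (max(values) == min(values)) {
    warning("all difference values are equal; the active set is an index tie-break")
  }
  ord <- order(-values, seq_len(n))
  mask <- logical(n)
  mask[ord[seq_len(k)]] <- TRUE
  mask
}

#' Group active dipoles into spatial-adjacency clusters
#'
#' Two active dipoles are adjacent if their distance is strictly below
#' `adjacency_mm`; clusters are the connected components of the adjacency
#' graph, and components with fewer than `min_size` dipoles are dropped.
#' Cluster centers are unweighted centroids of the member positions
#' (amplitude-weighted centroids available via `weights`), and cluster volume
#' is the member count times the grid's per-dipole volume.
#'
#' @param mask logical vector of active dipoles (from
#'   [threshold_top_fraction()]).
#' @param sources the [source_space][make_source_space] the mask lives on.
#' @param adjacency_mm adjacency distance in mm (default 5).
#' @param min_size minimum cluster size to retain (default 5).
#' @param weights optional per-dipole non-negative weights (e.g. the
#'   difference map) for amplitude-weighted centroids; `NULL` for unweighted.
#' @return an object of class `cluster_set`: `clusters` (list of dipole index
#'   vectors), `centers` (meters), `volumes_mm3`, `sizes`, and the parameters
#'   used.
#' @export
cluster_adjacent <- function(mask, sources, adjacency_mm = 5, min_size = 5,
                             weights = NULL) {
  stopifnot(inherits(sources, "source_space"))
  if (!is.finite(adjacency_mm) || adjacency_mm <= 0) {
    stop_invalid("adjacency_mm must be > 0")
  }
  idx <- which(mask)
  n <- length(idx)
  comp <- integer(0)
  if (n > 0) {
    pos <- sources$positions[idx, , drop = FALSE] * 1000  # mm
    # union-find over pairs closer than the adjacency distance
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    D <- as.matrix(stats::dist(pos))
    for (i in seq_len(n - 1)) {
      for (j in which(D[i, ] < adjacency_mm)) {
        if (j <= i) next
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
    comp <- vapply(seq_len(n), find, 1L)
  }
  groups <- split(idx, comp)
  groups <- groups[lengths(groups) >= min_size]
  groups <- unname(groups[order(vapply(groups, min, 1L))])
  centers <- t(vapply(groups, function(g) {
    p <- sources$positions[g, , drop = FALSE]
    if (is.null(weights)) colMeans(p)
    else colSums(p * weights[g]) / sum(weights[g])
  }, numeric(3)))
  if (length(groups) == 0) centers <- matrix(numeric(0), 0, 3)
  structure(list(
    clusters = groups,
    centers = centers,
    sizes = lengths(groups),
    volumes_mm3 = lengths(groups) * sources$per_dipole_volume,
    params = list(adjacency_mm = adjacency_mm, min_size = min_size,
                  weighted = !is.null(weights))
  ), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters (sizes: %s)\n", length(x$clusters),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Classify clusters against the simulated ROIs
#'
#' Center-to-center rule: an ROI with at least one cluster within
#' `max_dist_mm` is a true positive, otherwise a false negative; a cluster
#' within `max_dist_mm` of no ROI is a false positive.  One cluster within
#' range of several ROIs validates all of them (counts are ROI-level for
#' TP/FN and cluster-level for FP).
#'
#' @param clusters a [cluster_set][cluster_adjacent].
#' @param roi_centers 4 x 3 matrix of simulated ROI centers (meters).
#' @param max_dist_mm classification radius in mm; 10, 30 or 50 in the
#'   standard analysis (default 30).
#' @return list with `tp`, `fn`, `fp`, the per-ROI hit flags (`roi_hit`), and
#'   the ROI-by-cluster distance matrix in mm (`dist_mm`).
#' @export
classify_clusters <- function(clusters, roi_centers, max_dist_mm = 30) {
  stopifnot(inherits(clusters, "cluster_set"))
  roi_centers <- as.matrix(roi_centers)
  n_roi <- nrow(roi_centers)
  n_cl <- length(clusters$clusters)
  if (n_cl == 0) {
    D <- matrix(numeric(0), n_roi, 0)
  } else {
    D <- 1000 * sqrt(outer(rowSums(roi_centers^2),
                           rowSums(clusters$centers^2), "+") -
                     2 * roi_centers %*% t(clusters$centers))
    D[!is.finite(D)] <- 0
  }
  roi_hit <- if (n_cl == 0) rep(FALSE, n_roi) else
    apply(D <= max_dist_mm, 1, any)
  cl_matched <- if (n_cl == 0) logical(0) else apply(D <= max_dist_mm, 2, any)
  list(tp = sum(roi_hit), fn = sum(!roi_hit), fp = sum(!cl_matched),
       roi_hit = roi_hit, dist_mm = D, max_dist_mm = max_dist_mm)
}

#' Compute sensitivity, precision, localization error and spatial dispersion
#'
#' Sensitivity is `tp / (tp + fn)` over ROIs and precision `tp / (tp + fp)`
#' (ROI-level TPs against cluster-level FPs, as the classification rule
#' defines them).  Localization error and spatial dispersion are computed per
#' true-positive ROI over its qualifying clusters (those within
#' `max_dist_mm`): the error is the mean center-to-center distance, and the
#' dispersion is `(sum of qualifying cluster volumes - ROI volume) / ROI
#' volume`.  Means over the TP ROIs are reported; with no TPs both are `NA`,
#' and with no clusters at all precision is `NA` (undefined, not zero).
#'
#' @param classification output of [classify_clusters()].
#' @param clusters the [cluster_set][cluster_adjacent] that was classified.
#' @param roi_volumes_mm3 per-ROI simulated volumes (mm^3).
#' @return an object of class `eval_result` with fields `tp`, `fn`, `fp`,
#'   `sensitivity`, `precision`, `localization_error_mm` (mean) and
#'   `per_roi_locerr_mm`, `spatial_dispersion` (mean) and
#'   `per_roi_dispersion`, `max_dist_mm`, `n_clusters`.
#' @export
compute_metrics <- function(classification, clusters, roi_volumes_mm3) {
  cl <- classification
  n_roi <- length(cl$roi_hit)
  per_le <- rep(NA_real_, n_roi)
  per_sd <- rep(NA_real_, n_roi)
  for (r in which(cl$roi_hit)) {
    qual <- which(cl$dist_mm[r, ] <= cl$max_dist_mm)
    per_le[r] <- mean(cl$dist_mm[r, qual])
    per_sd[r] <- (sum(clusters$volumes_mm3[qual]) - roi_volumes_mm3[r]) /
      roi_volumes_mm3[r]
  }
  structure(list(
    tp = cl$tp, fn = cl$fn, fp = cl$fp,
    sensitivity = if (cl$tp + cl$fn > 0) cl$tp / (cl$tp + cl$fn) else NA_real_,
    precision = if (cl$tp + cl$fp > 0) cl$tp / (cl$tp + cl$fp) else NA_real_,
    localization_error_mm = if (cl$tp > 0) mean(per_le, na.rm = TRUE) else NA_real_,
    per_roi_locerr_mm = per_le,
    spatial_dispersion = if (cl$tp > 0) mean(per_sd, na.rm = TRUE) else NA_real_,
    per_roi_dispersion = per_sd,
    max_dist_mm = cl$max_dist_mm,
    n_clusters = length(clusters$clusters)
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> tp %d fn %d fp %d | sens %.3g prec %.3g | locerr %.3g mm | disp %.3g (max_dist %g mm)\n",
    x$tp, x$fn, x$fp, x$sensitivity, x$precision, x$localization_error_mm,
    x$spatial_dispersion, x$max_dist_mm))
  invisible(x)
}

#' Evaluation parameters
#'
#' @param window analysis window in ms post-stimulus.
#' @param fraction strongest-difference fraction kept by the threshold.
#' @param adjacency_mm cluster adjacency distance in mm.
#' @param min_size minimum retained cluster size.
#' @param max_dist_mm TP/FP classification radius in mm.
#' @param weighted_centers use amplitude-weighted cluster centroids.
#' @return a list of parameters for [evaluate_reconstruction()].
#' @export
eval_params <- function(window = c(100, 220), fraction = 0.05,
                        adjacency_mm = 5, min_size = 5, max_dist_mm = 30,
                        weighted_centers = FALSE) {
  list(window = window, fraction = fraction, adjacency_mm = adjacency_mm,
       min_size = min_size, max_dist_mm = max_dist_mm,
       weighted_centers = weighted_centers)
}

#' Score a reconstruction against the simulated ground truth
#'
#' Deterministic composition of the evaluation pipeline: condition difference
#' over the analysis window, top-fraction threshold, adjacency clustering,
#' TP/FP/FN classification against the true ROI centers, and the metrics.
#' `max_dist_mm` may be a vector, in which case thresholding and clustering
#' are done once and a list of results (one per radius) is returned.
#'
#' @param erp_evoked,noise_evoked per-condition evoked `source_estimate`s on
#'   the reconstruction source space.
#' @param truth a [resolved_network][resolve_network] on the *generating*
#'   source space: supplies the true ROI centers and volumes.
#' @param sources the reconstruction [source_space][make_source_space].
#' @param params an [eval_params()] list.
#' @return an `eval_result`, or a named list of them when `params$max_dist_mm`
#'   has several entries.
#' @export
evaluate_reconstruction <- function(erp_evoked, noise_evoked, truth, sources,
                                    params = eval_params()) {
  stopifnot(inherits(truth, "resolved_network"),
            inherits(sources, "source_space"))
  diffmap <- condition_difference(erp_evoked, noise_evoked, params$window)
  mask <- threshold_top_fraction(diffmap, params$fraction)
  clusters <- cluster_adjacent(mask, sources, params$adjacency_mm,
                               params$min_size,
                               weights = if (params$weighted_centers)
                                 pmax(diffmap, 0) else NULL)
  one <- function(md) {
    compute_metrics(classify_clusters(clusters, truth$centers, md),
                    clusters, truth$volumes_mm3)
  }
  mds <- params$max_dist_mm
  if (length(mds) == 1) return(one(mds))
  out <- lapply(mds, one)
  names(out) <- paste0("max_dist_", mds)
  out
}
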