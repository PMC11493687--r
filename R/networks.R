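# Four-region ERP network presets.
#
# Each network activates four regions of interest (ROIs), two per hemisphere,
# mirrored across the midsagittal plane.  Anatomical region names are mapped
# to fixed angular positions on the source sphere (head coordinates: +x right,
# +y anterior, +z superior) that preserve the qualitative depth/coverage
# contrasts of the named areas: occipital regions sit posteriorly, inferior
# temporal regions laterally and low (near the edge of the electrode cap),
# inferior frontal regions anteriorly and slightly low, supramarginal regions
# superior-laterally.

.roi_directions <- local({
  d <- rbind(
    occipital_pole       = c(0.12, -0.97, -0.15),
    inferior_temporal    = c(0.85, -0.30, -0.43),
    inferior_frontal     = c(0.62,  0.77, -0.08),
    supramarginal        = c(0.65, -0.32,  0.69)
  )
  d / sqrt(rowSums(d^2))
})

roi_direction <- function(region, hemisphere = c("lh", "rh")) {
  hemisphere <- match.arg(hemisphere)
  dir <- .roi_directions[region, ]
  if (hemisphere == "lh") dir[1] <- -dir[1]
  dir
}

.network_tables <- list(
  temporo_occipital = list(
    c("occipital_pole", "lh"), c("occipital_pole", "rh"),
    c("inferior_temporal", "lh"), c("inferior_temporal", "rh")),
  fronto_parietal = list(
    c("inferior_frontal", "rh"), c("inferior_frontal", "lh"),
    c("supramarginal", "lh"), c("supramarginal", "rh")),
  fronto_occipital = list(
    c("occipital_pole", "lh"), c("occipital_pole", "rh"),
    c("inferior_frontal", "rh"), c("inferior_frontal", "lh")),
  temporo_parietal = list(
    c("inferior_temporal", "lh"), c("inferior_temporal", "rh"),
    c("supramarginal", "lh"), c("supramarginal", "rh"))
)

#' Names of the built-in four-ROI network presets
#' @return character vector of preset names.
#' @export
network_names <- function() names(.network_tables)

#' Build a four-ROI ERP network specification
#'
#' Returns the standard activation pattern: the first two ROIs (one per
#' hemisphere) start at 100 and 110 ms post-stimulus at full amplitude, the
#' third and fourth start at 120 ms at 80% amplitude.  ROI centers are given
#' as unit directions; they are bound to absolute positions on a dipole grid
#' by [resolve_network()].
#'
#' @param name one of [network_names()], or `"custom"` together with `rois`.
#' @param rois for `"custom"`: a list of exactly 4 lists with fields `name`,
#'   `direction` (3-vector, will be normalized), and optionally `onset` (ms),
#'   `amplitude_scale`, `radius_mm`.
#' @return an object of class `network_spec` with a 4-element `rois` list
#'   (fields `name`, `direction`, `onset`, `amplitude_scale`, `radius_mm`).
#' @examples
#' net <- network_spec("fronto_occipital")
#' sapply(net$rois, `[[`, "onset")
#' @export
network_spec <- function(name, rois = NULL) {
  onsets <- c(100, 110, 120, 120)
  scales <- c(1, 1, 0.8, 0.8)
  if (identical(name, "custom")) {
    if (is.null(rois) || length(rois) != 4) {
      stop_invalid("custom networks need exactly 4 ROIs")
    }
    rois <- lapply(seq_along(rois), function(k) {
      r <- rois[[k]]
      dir <- as.numeric(r$direction)
      if (length(dir) != 3 || !all(is.finite(dir)) || all(dir == 0)) {
        stop_invalid("ROI direction must be a nonzero finite 3-vector")
      }
      list(name = if (!is.null(r$name)) r$name else sprintf("roi%d", k),
           direction = dir / vec_norm(dir),
           onset = if (!is.null(r$onset)) r$onset else onsets[k],
           amplitude_scale = if (!is.null(r$amplitude_scale)) r$amplitude_scale else scales[k],
           radius_mm = if (!is.null(r$radius_mm)) r$radius_mm else 10)
    })
  } else {
    if (!name %in% names(.network_tables)) {
      stop_invalid("unknown network '", name, "'; available: ",
                   paste(network_names(), collapse = ", "), ", custom")
    }
    tab <- .network_tables[[name]]
    rois <- lapply(seq_along(tab), function(k) {
      list(name = paste(tab[[k]][1], tab[[k]][2], sep = "_"),
           direction = roi_direction(tab[[k]][1], tab[[k]][2]),
           onset = onsets[k], amplitude_scale = scales[k], radius_mm = 10)
    })
  }
  for (r in rois) {
    if (r$radius_mm <= 0 || r$onset < 0 ||
        r$amplitude_scale <= 0 || r$amplitude_scale > 1) {
      stop_invalid("ROI fields out of range (radius > 0, onset >= 0, ",
                   "amplitude_scale in (0, 1])")
    }
  }
  structure(list(name = name, rois = rois), class = "network_spec")
}

#' Bind a network to a source space
#'
#' Scales each ROI's unit direction to the grid radius and selects the member
#' dipoles within the ROI radius.  The result carries everything evaluation
#' needs about the ground truth: absolute centers, member dipole sets and ROI
#' volumes (member count times the grid's per-dipole volume).
#'
#' @param network a [network_spec].
#' @param sources a [source_space][make_source_space].
#' @return an object of class `resolved_network`: `centers` (4 x 3, meters),
#'   `dipole_sets` (list of index vectors), `volumes_mm3`, `onsets`,
#'   `amplitude_scales`, `radius_mm`, plus the originating `network` name and
#'   `source_space_id`.
#' @export
resolve_network <- function(network, sources) {
  stopifnot(inherits(network, "network_spec"), inherits(sources, "source_space"))
  centers <- t(vapply(network$rois, function(r) r$direction * sources$radius,
                      numeric(3)))
  sets <- lapply(seq_len(4), function(k) {
    select_roi_dipoles(sources, list(center = centers[k, ],
                                     radius_mm = network$rois[[k]]$radius_mm))
  })
  structure(list(
    network = network$name,
    centers = centers,
    dipole_sets = sets,
    volumes_mm3 = vapply(sets, length, 1L) * sources$per_dipole_volume,
    onsets = vapply(network$rois, `[[`, 0, "onset"),
    amplitude_scales = vapply(network$rois, `[[`, 0, "amplitude_scale"),
    radius_mm = vapply(network$rois, `[[`, 0, "radius_mm"),
    roi_names = vapply(network$rois, `[[`, "", "name"),
    source_space_id = sources$id
  ), class = "resolved_network")
}

#' Select the dipoles belonging to a spherical ROI
#'
#' Returns exactly the indices of dipoles whose Euclidean distance to the ROI
#' center is at most the ROI radius.
#'
#' @param sources a [source_space][make_source_space].
#' @param roi a list with `center` (3-vector, meters) and `radius_mm`.
#' @return integer vector of dipole indices (non-empty).
#' @export
select_roi_dipoles <- function(sources, roi) {
  stopifnot(inherits(sources, "source_space"))
  center <- as.numeric(roi$center)
  radius_m <- roi$radius_mm / 1000
  d2 <- rowSums(sweep(sources$positions, 2, center)^2)
  idx <- which(d2 <= radius_m^2)
  if (length(idx) == 0) {
    stop_empty_roi("ROI at (", paste(signif(center, 3), collapse = ", "),
                   ") m with radius ", roi$radius_mm,
                   " mm selects no dipoles on this grid")
  }
  idx
}
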