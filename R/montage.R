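# Electrode montages on the outer surface of a spherical head model.

#' Create a quasi-uniform electrode montage
#'
#' Places `n_sensors` electrodes on the upper portion of a sphere of radius
#' `outer_radius` using a Fibonacci lattice restricted to polar angles
#' 0--120 degrees, emulating the coverage of a high-density EEG cap (no face or
#' neck electrodes).  The default of 128 sensors mirrors a 128-channel
#' recording system.  The azimuthal phase of the lattice is drawn from `seed`,
#' so the montage is deterministic given `(n_sensors, seed)`.
#'
#' @param n_sensors number of electrodes, at least 8.
#' @param outer_radius scalp radius in meters.
#' @param seed integer seed fixing the azimuthal orientation of the lattice.
#' @return an object of class `eeg_montage`: a list with `labels` (unique
#'   sensor names), `positions` (`n_sensors` x 3 matrix, meters), and the
#'   `outer_radius` and `seed` used.
#' @examples
#' mon <- make_montage(32, 0.1, seed = 1)
#' range(sqrt(rowSums(mon$positions^2)))  # all on the 0.1 m sphere
#' @export
make_montage <- function(n_sensors = 128, outer_radius = 0.10, seed = 1L) {
  if (length(n_sensors) != 1 || is.na(n_sensors) || n_sensors < 8) {
    stop_invalid("n_sensors must be at least 8 (got ", n_sensors, ")")
  }
  if (length(outer_radius) != 1 || !is.finite(outer_radius) || outer_radius <= 0) {
    stop_invalid("outer_radius must be a positive length in meters")
  }
  n_sensors <- as.integer(n_sensors)
  phase <- with_seed(seed, stats::runif(1, 0, 2 * pi))
  # polar cap from the vertex down to 120 degrees: z in [cos(120deg), 1]
  unit <- fibonacci_points(n_sensors, z_range = c(cos(2 * pi / 3), 1), phase = phase)
  structure(list(
    labels = sprintf("E%03d", seq_len(n_sensors)),
    positions = unit * outer_radius,
    outer_radius = outer_radius,
    seed = as.integer(seed),
    id = sprintf("montage_n%d_s%d", n_sensors, as.integer(seed))
  ), class = "eeg_montage")
}

#' Project a montage onto a different outer-shell radius
#'
#' Keeps sensor directions (and labels) fixed and rescales positions so each
#' electrode lies on the sphere of radius `outer_radius`.  Used to carry a
#' shared cap across subjects whose scalp radii differ.
#'
#' @param montage an `eeg_montage`.
#' @param outer_radius new scalp radius in meters.
#' @return an `eeg_montage` on the new radius (same `id`: sensor identity is
#'   defined by labels and lattice seed, not by the head it sits on).
#' @export
project_montage <- function(montage, outer_radius) {
  stopifnot(inherits(montage, "eeg_montage"))
  if (!is.finite(outer_radius) || outer_radius <= 0) {
    stop_invalid("outer_radius must be a positive length in meters")
  }
  montage$positions <- unit_rows(montage$positions) * outer_radius
  montage$outer_radius <- outer_radius
  montage
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d sensors on r = %.3f m (seed %d)\n",
              length(x$labels), x$outer_radius, x$seed))
  invisible(x)
}

#' Write a montage to a plain-text CSV file
#'
#' Columns `label,x,y,z` with positions in meters and a header row.
#'
#' @param montage an `eeg_montage`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(montage, path) {
  stopifnot(inherits(montage, "eeg_montage"))
  df <- data.frame(label = montage$labels,
                   x = montage$positions[, 1],
                   y = montage$positions[, 2],
                   z = montage$positions[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a montage from a plain-text CSV file
#'
#' Expects columns `label,x,y,z` (meters) with a header row, as written by
#' [write_montage()].
#'
#' @param path input file path.
#' @return an `eeg_montage`.
#' @export
read_montage <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop_invalid("montage file must have columns label,x,y,z")
  }
  if (anyDuplicated(df$label)) stop_invalid("montage labels must be unique")
  pos <- as.matrix(df[, c("x", "y", "z")])
  if (!all(is.finite(pos))) stop_invalid("montage positions must be finite")
  r <- row_norms(pos)
  structure(list(
    labels = as.character(df$label),
    positions = pos,
    outer_radius = stats::median(r),
    seed = NA_integer_,
    id = sprintf("montage_file_n%d", nrow(df))
  ), class = "eeg_montage")
}
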