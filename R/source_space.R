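# Dipole source grids on a spherical surface inside the brain compartment.

#' Create a quasi-uniform dipole source space
#'
#' Places dipoles on the sphere of radius `eccentricity * r_brain` (the
#' spherical stand-in for a cortical sheet at fixed depth) with approximately
#' the requested spacing, using a full-sphere Fibonacci lattice.  The dipole
#' count is `round(4 pi r^2 / spacing^2)` so the average surface area per
#' dipole is `spacing^2`; `per_dipole_volume` is `spacing^3` so that
#' volume-based dispersion metrics remain computable on a surface grid.
#'
#' @param model a [shell_model][make_shell_model]; the innermost radius is the
#'   brain compartment boundary.
#' @param spacing nominal inter-dipole spacing in millimeters (default 3).
#' @param eccentricity fraction of the brain radius at which the dipole shell
#'   sits, in (0, 1); must leave a 1 mm margin to the brain boundary.
#' @param max_sources resource cap on the dipole count.
#' @return an object of class `source_space`: `positions`
#'   (`n x 3`, meters), `radius` (meters), `nominal_spacing` (mm),
#'   `per_dipole_volume` (mm^3), and a provenance `id`.
#' @examples
#' ss <- make_source_space(make_shell_model("bem_default"), spacing = 8)
#' nrow(ss$positions)
#' @export
make_source_space <- function(model, spacing = 3, eccentricity = 0.85,
                              max_sources = 50000L) {
  stopifnot(inherits(model, "shell_model"))
  if (!is.finite(spacing) || spacing <= 0) stop_invalid("spacing must be > 0 mm")
  if (!is.finite(eccentricity) || eccentricity <= 0 || eccentricity >= 1) {
    stop_invalid("eccentricity must lie in (0, 1)")
  }
  r_brain <- model$radii[1]
  r_src <- eccentricity * r_brain
  if (r_src > r_brain - 0.001) {
    stop_invalid("source shell violates the 1 mm margin to the brain boundary")
  }
  n <- round(4 * pi * (r_src * 1000)^2 / spacing^2)
  if (n > max_sources) {
    stop_resource("requested spacing yields ", n, " dipoles, above the cap of ",
                  max_sources)
  }
  unit <- fibonacci_points(n, z_range = c(-1, 1))
  structure(list(
    positions = unit * r_src,
    radius = r_src,
    nominal_spacing = spacing,
    per_dipole_volume = spacing^3,
    id = sprintf("srcspace_n%d_r%.6f", n, r_src)
  ), class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space> %d dipoles on r = %.1f mm (nominal %.1f mm spacing)\n",
              nrow(x$positions), 1000 * x$radius, x$nominal_spacing))
  invisible(x)
}

#' Morph per-dipole values onto a template source grid
#'
#' Nearest-neighbor transfer on angular distance: both grids are normalized to
#' the unit sphere and each template dipole receives the value of the closest
#' subject dipole.  No values are invented or smoothed; identical grids map to
#' the identity.
#'
#' @param values numeric vector, one value per subject dipole.
#' @param subject_sources,template_sources [source_space][make_source_space]
#'   objects on spherical grids.
#' @return numeric vector, one value per template dipole.
#' @export
morph_to_template <- function(values, subject_sources, template_sources) {
  stopifnot(inherits(subject_sources, "source_space"),
            inherits(template_sources, "source_space"))
  ns <- nrow(subject_sources$positions)
  nt <- nrow(template_sources$positions)
  if (ns == 0 || nt == 0) stop_invalid("source spaces must be non-empty")
  if (length(values) != ns) {
    stop_invalid("length(values) must equal the subject dipole count")
  }
  us <- unit_rows(subject_sources$positions)
  ut <- unit_rows(template_sources$positions)
  out <- numeric(nt)
  chunk <- max(1L, floor(2e7 / ns))  # bound the nt x ns dot-product matrix
  for (start in seq(1L, nt, by = chunk)) {
    idx <- start:min(nt, start + chunk - 1L)
    D <- ut[idx, , drop = FALSE] %*% t(us)     # cosine similarity
    out[idx] <- values[max.col(D, ties.method = "first")]
  }
  out
}
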