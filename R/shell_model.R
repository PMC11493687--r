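# Concentric-shell head geometries and conductivity presets.

# Conductivities in S/m, listed innermost to outermost shell.  The two
# four-shell presets carry the gray-matter, CSF, compact-bone and scalp values
# of the corresponding volume-conduction parameter sets (a meta-analysis set
# and a common software default set); the three-shell preset is the classic
# BEM triple with no CSF compartment.
.shell_presets <- list(
  fem_meta = list(
    conductivities = c(brain = 0.47, csf = 1.71, skull = 0.006, scalp = 0.41),
    n_shells = 4L,
    description = "4-shell (brain/CSF/skull/scalp), meta-analysis conductivities"
  ),
  fem_default = list(
    conductivities = c(brain = 0.33, csf = 1.79, skull = 0.008, scalp = 0.43),
    n_shells = 4L,
    description = "4-shell (brain/CSF/skull/scalp), software-default conductivities"
  ),
  bem_default = list(
    conductivities = c(brain = 0.33, skull = 0.006, scalp = 0.33),
    n_shells = 3L,
    description = "3-shell (brain/skull/scalp), no CSF"
  )
)

# Default shell radii (meters) following common spherical-head conventions.
.default_radii <- list(`3` = c(0.087, 0.092, 0.100),
                       `4` = c(0.083, 0.087, 0.092, 0.100))

#' Named conductivity presets for shell models
#'
#' @return a named list; each entry has `conductivities` (S/m, innermost to
#'   outermost), `n_shells` and a short `description`.
#' @export
shell_presets <- function() .shell_presets

#' Create a concentric-shell head model
#'
#' Builds the forward-physics substrate of the package: a set of concentric
#' spherical shells with per-shell isotropic conductivities.  Four-shell models
#' (brain/CSF/skull/scalp) act as the "detailed" head models that account for
#' cerebrospinal fluid; three-shell models (brain/skull/scalp) are the
#' "simple" analogue that cannot.
#'
#' @param preset one of `"fem_meta"`, `"fem_default"`, `"bem_default"`; see
#'   [shell_presets()].
#' @param radii strictly increasing outer radii of the shells in meters,
#'   innermost first; count must match the preset (4 for `fem_*`, 3 for
#'   `bem_default`).  Defaults to 87/92/100 mm (3-shell) or 83/87/92/100 mm
#'   (4-shell).
#' @return an object of class `shell_model` with fields `radii`,
#'   `conductivities`, `name`, `n_shells`.
#' @examples
#' make_shell_model("bem_default")
#' make_shell_model("fem_meta", c(0.083, 0.087, 0.092, 0.100))
#' @export
make_shell_model <- function(preset = "fem_meta", radii = NULL) {
  if (!preset %in% names(.shell_presets)) {
    stop_invalid("unknown preset '", preset, "'; available: ",
                 paste(names(.shell_presets), collapse = ", "))
  }
  p <- .shell_presets[[preset]]
  if (is.null(radii)) radii <- .default_radii[[as.character(p$n_shells)]]
  if (length(radii) != p$n_shells) {
    stop_invalid("preset '", preset, "' needs ", p$n_shells,
                 " radii, got ", length(radii))
  }
  if (any(!is.finite(radii)) || any(radii <= 0) || any(diff(radii) <= 0)) {
    stop_invalid("radii must be finite, positive and strictly increasing")
  }
  structure(list(
    radii = as.numeric(radii),
    conductivities = unname(p$conductivities),
    shell_names = names(p$conductivities),
    name = preset,
    n_shells = p$n_shells
  ), class = "shell_model")
}

#' Collapse a four-shell model to its three-shell analogue
#'
#' Removes the CSF compartment: the brain is extended outward to the old CSF
#' boundary and the `bem_default` conductivities are assigned.  This mirrors
#' the construction of a simple three-surface model on the same head geometry.
#'
#' @param model a 4-shell `shell_model`.
#' @return a 3-shell `shell_model` with preset `bem_default`.
#' @export
collapse_to_bem <- function(model) {
  stopifnot(inherits(model, "shell_model"))
  if (model$n_shells != 4L) stop_invalid("collapse_to_bem expects a 4-shell model")
  make_shell_model("bem_default", radii = model$radii[2:4])
}

#' @export
print.shell_model <- function(x, ...) {
  cat(sprintf("<shell_model> %s: %d shells\n", x$name, x$n_shells))
  for (i in seq_len(x$n_shells)) {
    cat(sprintf("  %-6s r = %.1f mm, sigma = %.3f S/m\n",
                x$shell_names[i], 1000 * x$radii[i], x$conductivities[i]))
  }
  invisible(x)
}
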