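# Synthetic subject cohorts: per-subject head geometries plus a template
# model built from the cohort-mean radii, emulating a study population with
# individual anatomies and an average-anatomy head model.

#' Generate a synthetic subject cohort with a template model
#'
#' Each subject's shell radii are the base radii scaled by independent
#' lognormal factors (`sdlog = radius_jitter_sd`), re-sorted to remain
#' strictly increasing.  The template model uses the arithmetic mean of the
#' subject radii (exact).  All subjects share one electrode cap, projected
#' onto each subject's own scalp radius, and a dipole grid at the same nominal
#' spacing on their own brain compartment.
#'
#' For every subject (and for the template) leadfields are computed for the
#' requested model `variants`: the detailed 4-shell model under both
#' conductivity presets and the 3-shell collapse without CSF.  The detailed
#' `fem_meta` model doubles as the generating forward model in simulations.
#'
#' @param n_subjects number of subjects, at least 2 (default 18).
#' @param base_radii 4-shell base radii in meters, innermost first.
#' @param radius_jitter_sd lognormal sd of the per-shell radius jitter, in
#'   \[0, 0.15\] (default 0.05).
#' @param cap_rotation_sd_deg sd (degrees) of the per-subject cap placement
#'   error: each subject's electrode cap is rigidly rotated about a random
#'   axis by an angle drawn from `N(0, sd)` before projection onto their
#'   scalp.  Subject-specific models use the true (rotated) positions, while
#'   the template model assumes the standard unrotated cap, emulating the
#'   electrode co-registration component of template-model error.  Default 5.
#' @param preset generating conductivity preset, `"fem_meta"` or
#'   `"fem_default"`.
#' @param montage shared [eeg_montage][make_montage]; projected per subject.
#' @param spacing dipole grid spacing in mm.
#' @param eccentricity source-shell depth as a fraction of the brain radius.
#' @param seed integer seed; the cohort is deterministic given it.
#' @param variants character subset of
#'   `c("fem_meta", "fem_default", "bem")` naming the per-head leadfields to
#'   compute (default all three).
#' @return an object of class `subject_cohort`: `subjects` (list of per-subject
#'   records with `models`, `sources`, `montage`, `leadfields`, `radii`,
#'   `jitter_factors`), `template` (same structure), the shared `montage`,
#'   `seed` and generation parameters.
#' @export
make_cohort <- function(n_subjects = 18L,
                        base_radii = c(0.083, 0.087, 0.092, 0.100),
                        radius_jitter_sd = 0.05,
                        cap_rotation_sd_deg = 5,
                        preset = "fem_meta",
                        montage = make_montage(),
                        spacing = 3,
                        eccentricity = 0.85,
                        seed = 1L,
                        variants = c("fem_meta", "fem_default", "bem")) {
  if (n_subjects < 2) stop_invalid("n_subjects must be at least 2")
  if (!is.finite(radius_jitter_sd) || radius_jitter_sd < 0 ||
      radius_jitter_sd > 0.15) {
    stop_invalid("radius_jitter_sd must lie in [0, 0.15]")
  }
  if (!is.finite(cap_rotation_sd_deg) || cap_rotation_sd_deg < 0) {
    stop_invalid("cap_rotation_sd_deg must be non-negative")
  }
  if (!preset %in% c("fem_meta", "fem_default")) {
    stop_invalid("generating preset must be one of fem_meta, fem_default")
  }
  if (length(base_radii) != 4) stop_invalid("base_radii must have 4 shells")
  variants <- match.arg(variants, c("fem_meta", "fem_default", "bem"),
                        several.ok = TRUE)
  stopifnot(inherits(montage, "eeg_montage"))

  draws <- with_seed(seed, {
    factors <- matrix(
      exp(stats::rnorm(n_subjects * 4L, mean = 0, sd = radius_jitter_sd)),
      nrow = n_subjects, ncol = 4L)
    rotations <- lapply(seq_len(n_subjects), function(s) {
      axis <- stats::rnorm(3)
      axis <- axis / vec_norm(axis)
      rotation_matrix(axis, stats::rnorm(1, 0, cap_rotation_sd_deg) * pi / 180)
    })
    list(factors = factors, rotations = rotations)
  })
  factors <- draws$factors
  subject_radii <- t(apply(factors, 1, function(f) sort(base_radii * f)))
  template_radii <- colMeans(subject_radii)

  build_head <- function(radii, cap_rotation = NULL) {
    models <- list()
    if ("fem_meta" %in% variants || preset == "fem_meta") {
      models$fem_meta <- make_shell_model("fem_meta", radii)
    }
    if ("fem_default" %in% variants || preset == "fem_default") {
      models$fem_default <- make_shell_model("fem_default", radii)
    }
    if ("bem" %in% variants) {
      models$bem <- make_shell_model("bem_default", radii[2:4])
    }
    mon <- montage
    if (!is.null(cap_rotation)) {
      mon$positions <- mon$positions %*% t(cap_rotation)
    }
    mon <- project_montage(mon, radii[4])
    # one grid per head, defined on the detailed geometry's brain compartment
    src <- make_source_space(models[[if (preset %in% names(models)) preset else 1L]],
                             spacing = spacing, eccentricity = eccentricity)
    lf <- lapply(models, function(m) compute_leadfield(m, mon, src))
    list(models = models, montage = mon, sources = src, leadfields = lf,
         radii = radii)
  }

  subjects <- lapply(seq_len(n_subjects), function(s) {
    head <- build_head(subject_radii[s, ], draws$rotations[[s]])
    head$jitter_factors <- factors[s, ]
    head$cap_rotation <- draws$rotations[[s]]
    head$subject <- s
    head
  })
  template <- build_head(template_radii)

  structure(list(
    subjects = subjects,
    template = template,
    montage = montage,
    seed = as.integer(seed),
    params = list(n_subjects = n_subjects, base_radii = base_radii,
                  radius_jitter_sd = radius_jitter_sd,
                  cap_rotation_sd_deg = cap_rotation_sd_deg, preset = preset,
                  spacing = spacing, eccentricity = eccentricity,
                  variants = variants)
  ), class = "subject_cohort")
}

#' @export
print.subject_cohort <- function(x, ...) {
  cat(sprintf(
    "<subject_cohort> %d subjects + template (jitter sd %.3f, preset %s, seed %d)\n",
    length(x$subjects), x$params$radius_jitter_sd, x$params$preset, x$seed))
  invisible(x)
}
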