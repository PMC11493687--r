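# Analytic EEG forward solution for a current dipole in a multilayer
# conductive sphere.
#
# In each shell the harmonic-n radial profile is A r^n + B r^-(n+1).  The
# dipole in the innermost shell contributes a known singular coefficient; the
# interface conditions (continuity of potential and of radial current) give a
# 2x2 transfer matrix per interface, and the no-current condition at the outer
# surface closes the system.  Radii are normalized to the outer radius before
# the recursion so all powers stay well scaled.

# Per-harmonic outer-surface gain for a unit singular coefficient in shell 1.
# Returns F_n, n = 1..n_max, such that the surface potential is
#   V = sum_n F_n * x^(n-1) / (4 pi sigma_1 R^2) *
#         [ n m_r P_n(u) + (m_t . r_e_hat) P_n'(u) ]
# with x = b/R the relative dipole depth and u the cosine of the angle between
# dipole position and electrode.
shell_gain_coefs <- function(radii, conductivities, n_max = 200L) {
  M <- length(radii)
  rho <- radii / radii[M]
  n <- seq_len(n_max)
  # running transfer-matrix product, stored as four vectors over n
  T11 <- rep(1, n_max); T12 <- rep(0, n_max)
  T21 <- rep(0, n_max); T22 <- rep(1, n_max)
  if (M > 1) {
    for (j in seq_len(M - 1)) {
      a2n1 <- rho[j]^(2 * n + 1)
      s <- conductivities[j]; sp <- conductivities[j + 1]
      den <- (2 * n + 1) * sp
      m11 <- (n * s + (n + 1) * sp) / den
      m12 <- ((n + 1) * (sp - s) / a2n1) / den
      m21 <- (n * (sp - s) * a2n1) / den
      m22 <- ((n + 1) * s + n * sp) / den
      t11 <- m11 * T11 + m12 * T21; t12 <- m11 * T12 + m12 * T22
      t21 <- m21 * T11 + m22 * T21; t22 <- m21 * T12 + m22 * T22
      T11 <- t11; T12 <- t12; T21 <- t21; T22 <- t22
    }
  }
  # outer boundary (normalized radius 1): n A_M = (n + 1) B_M
  A1 <- ((n + 1) * T22 - n * T12) / (n * T11 - (n + 1) * T21)
  (T11 * A1 + T12) + (T21 * A1 + T22)
}

# Legendre polynomials P_n(u) and derivatives P_n'(u) by upward recurrence.
# u may be a vector or matrix; returns a list of two [length(u) x n_max]
# matrices.  Used only for scalar/small cases; the leadfield path runs the
# recurrence in-place without storing all orders.
legendre_table <- function(u, n_max) {
  u <- as.numeric(u)
  P <- matrix(0, length(u), n_max)
  dP <- matrix(0, length(u), n_max)
  P[, 1] <- u; dP[, 1] <- 1
  if (n_max >= 2) {
    Pm1 <- rep(1, length(u)); Pc <- u
    dPm1 <- rep(0, length(u)); dPc <- rep(1, length(u))
    for (n in 1:(n_max - 1)) {
      Pn1 <- ((2 * n + 1) * u * Pc - n * Pm1) / (n + 1)
      dPn1 <- dPm1 + (2 * n + 1) * Pc
      Pm1 <- Pc; Pc <- Pn1; dPm1 <- dPc; dPc <- dPn1
      P[, n + 1] <- Pc; dP[, n + 1] <- dPc
    }
  }
  list(P = P, dP = dP)
}

#' Scalp potential of a current dipole in a multilayer sphere
#'
#' Evaluates the Legendre-series solution for the electric potential generated
#' by a current dipole inside the innermost shell of a concentric-shell head
#' model, at an electrode on the outer surface.  The series is truncated
#' adaptively: summation stops once a term contributes less than `tol` of the
#' accumulated value (hard cap `n_max` terms).  The returned value is the raw
#' (reference-free) potential in volts; referencing is applied at the
#' leadfield level.
#'
#' @param dipole_position 3-vector, meters; strictly inside the innermost shell.
#' @param dipole_moment 3-vector, ampere-meters.
#' @param model a [shell_model][make_shell_model].
#' @param electrode_position 3-vector on the outer shell surface (within
#'   1e-6 m).
#' @param tol relative truncation tolerance for the series.
#' @param n_max hard cap on the number of Legendre terms.
#' @return scalar potential in volts.
#' @export
sphere_potential <- function(dipole_position, dipole_moment, model,
                             electrode_position, tol = 1e-10, n_max = 200L) {
  stopifnot(inherits(model, "shell_model"))
  p <- as.numeric(dipole_position); m <- as.numeric(dipole_moment)
  e <- as.numeric(electrode_position)
  if (length(p) != 3 || length(m) != 3 || length(e) != 3 ||
      any(!is.finite(c(p, m, e)))) {
    stop_invalid("positions and moment must be finite 3-vectors")
  }
  R <- model$radii[model$n_shells]
  b <- vec_norm(p)
  if (b >= model$radii[1]) {
    stop_invalid("dipole must lie strictly inside the innermost shell")
  }
  if (abs(vec_norm(e) - R) > 1e-6) {
    stop_invalid("electrode must lie on the outer shell surface (within 1e-6 m)")
  }
  if (all(m == 0)) return(0)

  Fn <- shell_gain_coefs(model$radii, model$conductivities, n_max)
  reh <- e / vec_norm(e)
  if (b > 0) r0h <- p / b else r0h <- c(0, 0, 1)  # dipole at center: any axis
  x <- b / R
  u <- sum(r0h * reh)
  m_r <- sum(m * r0h)
  mt <- m - m_r * r0h
  mte <- sum(mt * reh)

  # series with adaptive stop
  total <- 0
  Pm1 <- 1; Pc <- u; dPm1 <- 0; dPc <- 1
  xpow <- 1  # x^(n-1)
  small_run <- 0L
  for (n in seq_len(n_max)) {
    term <- Fn[n] * xpow * (n * m_r * Pc + mte * dPc)
    total <- total + term
    if (n >= 10 && abs(term) < tol * max(abs(total), .Machine$double.xmin)) {
      small_run <- small_run + 1L
      if (small_run >= 2L) break
    } else small_run <- 0L
    # advance recurrences to order n + 1
    Pn1 <- ((2 * n + 1) * u * Pc - n * Pm1) / (n + 1)
    dPn1 <- dPm1 + (2 * n + 1) * Pc
    Pm1 <- Pc; Pc <- Pn1; dPm1 <- dPc; dPc <- dPn1
    xpow <- xpow * x
  }
  total / (4 * pi * model$conductivities[1] * R^2)
}

#' Compute an average-referenced leadfield matrix
#'
#' Evaluates the multilayer-sphere forward solution for every source dipole and
#' electrode, for the three canonical unit moments (x, y, z) of each source.
#' Columns for the three moments of a source are contiguous.  The matrix is
#' average referenced: each column sums to zero.
#'
#' All electrodes must lie on the model's outer shell surface; use
#' [project_montage()] first when carrying a shared cap across head geometries.
#'
#' @param model a [shell_model][make_shell_model].
#' @param montage an [eeg_montage][make_montage] on the model's outer surface.
#' @param sources a [source_space][make_source_space] inside the innermost
#'   shell.
#' @param tol relative truncation tolerance of the Legendre series.
#' @param n_max hard cap on series terms.
#' @return an object of class `leadfield`: list with `gain`
#'   (`n_sensors x 3 n_sources`, V per A.m), `reference = "average"`, and
#'   provenance ids (`source_space_id`, `montage_id`, `shell_model_id`).
#' @export
compute_leadfield <- function(model, montage, sources, tol = 1e-10,
                              n_max = 200L) {
  stopifnot(inherits(model, "shell_model"), inherits(montage, "eeg_montage"),
            inherits(sources, "source_space"))
  R <- model$radii[model$n_shells]
  if (any(abs(row_norms(montage$positions) - R) > 1e-6)) {
    stop_invalid("montage does not lie on the model's outer shell; ",
                 "project it with project_montage() first")
  }
  pos <- sources$positions
  b <- row_norms(pos)
  if (any(b >= model$radii[1])) {
    stop_invalid("all sources must lie strictly inside the innermost shell")
  }
  n_src <- nrow(pos); n_e <- nrow(montage$positions)
  reh <- unit_rows(montage$positions)           # n_e x 3
  r0h <- unit_rows(pos)                          # n_src x 3
  U <- r0h %*% t(reh)                            # cos(angle), n_src x n_e

  Fn <- shell_gain_coefs(model$radii, model$conductivities, n_max)
  x <- b / R                                     # per-source relative depth
  # choose truncation from the largest depth present
  xmax <- max(x)
  cn_max <- abs(Fn) * xmax^(seq_len(n_max) - 1) * seq_len(n_max)
  keep <- which(cn_max > tol * max(cumsum(cn_max)))
  n_use <- min(n_max, max(10L, if (length(keep)) max(keep) + 2L else 10L))

  # accumulate S1 = sum_n c_n n P_n(U), S2 = sum_n c_n P_n'(U) with
  # c_n = F_n x^(n-1), by running the Legendre recurrence on the full matrix.
  S1 <- matrix(0, n_src, n_e); S2 <- matrix(0, n_src, n_e)
  Pm1 <- matrix(1, n_src, n_e); Pc <- U
  dPm1 <- matrix(0, n_src, n_e); dPc <- matrix(1, n_src, n_e)
  xpow <- rep(1, n_src)                          # x^(n-1), per source
  for (n in seq_len(n_use)) {
    cn <- Fn[n] * xpow
    S1 <- S1 + (cn * n) * Pc
    S2 <- S2 + cn * dPc
    if (n < n_use) {
      Pn1 <- ((2 * n + 1) * U * Pc - n * Pm1) / (n + 1)
      dPn1 <- dPm1 + (2 * n + 1) * Pc
      Pm1 <- Pc; Pc <- Pn1; dPm1 <- dPc; dPc <- dPn1
      xpow <- xpow * x
    }
  }
  scale <- 1 / (4 * pi * model$conductivities[1] * R^2)
  gain <- matrix(0, n_e, 3L * n_src)
  for (k in 1:3) {
    # moment e_k: radial part (e_k . r0h) and tangential part
    # (e_k - (e_k . r0h) r0h) . reh = reh[, k] - r0h[, k] * U
    Tk <- sweep(-(r0h[, k] * U), 2, reh[, k], "+")
    Gk <- r0h[, k] * S1 + Tk * S2
    gain[, seq(k, by = 3, length.out = n_src)] <- t(Gk) * scale
  }
  gain <- sweep(gain, 2, colMeans(gain))  # average reference
  structure(list(
    gain = gain,
    reference = "average",
    n_sensors = n_e,
    n_sources = n_src,
    source_space_id = sources$id,
    montage_id = montage$id,
    shell_model_id = model$name
  ), class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d sensors x %d sources (model %s, %s reference)\n",
              x$n_sensors, x$n_sources, x$shell_model_id, x$reference))
  invisible(x)
}
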