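# Independent oracles and shared fixtures for the test suite.
#
# The homogeneous-sphere dipole potential below is a closed form obtained by
# summing the Legendre series with generating functions; it shares no code
# with the transfer-matrix solver in the package and serves as its oracle in
# the equal-conductivity limit.

homogeneous_sphere_potential <- function(dipole_position, dipole_moment,
                                         radius, sigma, electrode_position) {
  p <- as.numeric(dipole_position); m <- as.numeric(dipole_moment)
  e <- as.numeric(electrode_position)
  b <- sqrt(sum(p^2))
  reh <- e / sqrt(sum(e^2))
  r0h <- if (b > 0) p / b else c(0, 0, 1)
  x <- b / radius
  u <- sum(r0h * reh)
  m_r <- sum(m * r0h)
  mt <- m - m_r * r0h
  mte <- sum(mt * reh)
  g <- sqrt(1 - 2 * x * u + x^2)        # |r_e - r_0| / R
  d <- 1 - x * u + g
  radial <- 2 * (u - x) / g^3 + if (x > 0) (1 / g - 1) / x else 0
  tangential <- 2 / g^3 + (1 + g) / (g * d)
  (m_r * radial + mte * tangential) / (4 * pi * sigma * radius^2)
}

# small shared fixtures, built once per test run
fixture_env <- new.env()

small_setup <- function() {
  if (is.null(fixture_env$lf)) {
    fixture_env$model <- make_shell_model("fem_meta")
    fixture_env$montage <- make_montage(64, 0.1, seed = 1)
    fixture_env$sources <- make_source_space(fixture_env$model, spacing = 10)
    fixture_env$lf <- compute_leadfield(fixture_env$model, fixture_env$montage,
                                        fixture_env$sources)
  }
  fixture_env
}

# a tiny simulated epoch set reused across simulator/inverse tests
sim_setup <- function() {
  if (is.null(fixture_env$epochs)) {
    fx <- small_setup()
    net <- resolve_network(network_spec("fronto_occipital"), fx$sources)
    fixture_env$net <- net
    fixture_env$epochs <- simulate_epochs(
      net, fx$lf, fx$sources,
      sim_config(snr_db = -5, seed = 11))
  }
  fixture_env
}

row_norms_test <- function(m) sqrt(rowSums(m^2))

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), .Machine$double.eps),
            tol)
}
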