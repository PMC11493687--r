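# Montages, shell models, the multilayer-sphere forward solution, source
# grids, leadfields, cohorts and template morphing.

test_that("montage construction places sensors on the upper sphere", {
  mon <- make_montage(128, 0.10, seed = 1)
  expect_length(unique(mon$labels), 128)
  expect_true(all(abs(row_norms_test(mon$positions) - 0.10) < 1e-12))
  # upper-cap coverage: no sensor below 120 degrees polar angle
  expect_true(all(mon$positions[, 3] >= 0.10 * cos(2 * pi / 3) - 1e-12))
  # determinism given (n, seed); different seed rotates the cap
  expect_identical(mon$positions, make_montage(128, 0.10, seed = 1)$positions)
  expect_false(identical(mon$positions, make_montage(128, 0.10, seed = 2)$positions))
})

test_that("minimum montage keeps sensors well separated", {
  mon <- make_montage(8, 0.10, seed = 1)
  d <- as.matrix(dist(mon$positions))
  diag(d) <- Inf
  expect_gt(min(d), 0.02)  # > 2 cm between any two of 8 sensors
})

test_that("montage and shell-model preconditions are enforced", {
  expect_error(make_montage(7, 0.10, seed = 1), class = "erplocsim_invalid_argument")
  expect_error(make_montage(128, -1), class = "erplocsim_invalid_argument")
  expect_error(make_shell_model("nope"), class = "erplocsim_invalid_argument")
  expect_error(make_shell_model("fem_meta", c(0.087, 0.092, 0.100)),
               class = "erplocsim_invalid_argument")
  expect_error(make_shell_model("bem_default", c(0.100, 0.092, 0.087)),
               class = "erplocsim_invalid_argument")
})

test_that("conductivity presets carry the published tissue values", {
  bem <- make_shell_model("bem_default", c(0.087, 0.092, 0.100))
  expect_equal(bem$conductivities, c(0.33, 0.006, 0.33))
  meta <- make_shell_model("fem_meta", c(0.083, 0.087, 0.092, 0.100))
  expect_equal(meta$conductivities, c(0.47, 1.71, 0.006, 0.41))
  expect_equal(meta$conductivities[2], 1.71)  # CSF shell
  dflt <- make_shell_model("fem_default")
  expect_equal(dflt$conductivities, c(0.33, 1.79, 0.008, 0.43))
})

test_that("multilayer solver matches the closed-form homogeneous sphere", {
  mod <- make_shell_model("fem_meta")
  mod$conductivities <- rep(0.33, 4)  # homogeneous limit
  set.seed(7)
  for (i in 1:100) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2)) * runif(1, 0.001, 0.080)
    m <- rnorm(3) * 1e-9
    e <- rnorm(3); e <- e / sqrt(sum(e^2)) * 0.100
    v <- sphere_potential(d, m, mod, e)
    v0 <- homogeneous_sphere_potential(d, m, 0.100, 0.33, e)
    expect_rel_equal(v, v0, 1e-6)
  }
})

test_that("forward solution is linear, rotation-equivariant, and convergent", {
  mod <- make_shell_model("fem_meta")
  set.seed(21)
  for (i in 1:20) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2)) * runif(1, 0.01, 0.08)
    m <- rnorm(3); e <- rnorm(3); e <- e / sqrt(sum(e^2)) * 0.1
    v <- sphere_potential(d, m, mod, e)
    # linearity in the moment
    expect_equal(sphere_potential(d, 2 * m, mod, e), 2 * v)
    expect_identical(sphere_potential(d, c(0, 0, 0), mod, e), 0)
    # spherical symmetry: common rotation leaves the potential unchanged
    rot <- qr.Q(qr(matrix(rnorm(9), 3)))
    vr <- sphere_potential(c(rot %*% d), c(rot %*% m), mod, c(rot %*% e))
    expect_rel_equal(vr, v, 1e-10)
  }
  # doubling the truncation order changes nothing at default tolerance
  d <- c(0.02, 0.03, 0.05); m <- c(1, -2, 0.5) * 1e-9; e <- c(0, 0, 0.1)
  v100 <- sphere_potential(d, m, mod, e, tol = 0, n_max = 100)
  v200 <- sphere_potential(d, m, mod, e, tol = 0, n_max = 200)
  expect_rel_equal(v200, v100, 1e-8)
})

test_that("forward preconditions reject bad geometry", {
  mod <- make_shell_model("bem_default")
  expect_error(sphere_potential(c(0, 0, 0.09), c(0, 0, 1e-9), mod, c(0, 0, 0.1)),
               class = "erplocsim_invalid_argument")  # dipole outside brain
  expect_error(sphere_potential(c(0, 0, 0.05), c(0, 0, 1e-9), mod, c(0, 0, 0.09)),
               class = "erplocsim_invalid_argument")  # electrode off surface
})

test_that("source grids are dense, uniform and inside the brain", {
  mod <- make_shell_model("bem_default")  # r_brain = 87 mm
  ss <- make_source_space(mod, spacing = 3)
  n_expect <- 4 * pi * (0.85 * 87)^2 / 9
  expect_lt(abs(nrow(ss$positions) - n_expect) / n_expect, 0.15)
  expect_true(all(row_norms_test(ss$positions) < mod$radii[1] - 0.001))
  expect_equal(ss$per_dipole_volume, 27)

  coarse <- make_source_space(mod, spacing = 8)
  d <- as.matrix(dist(coarse$positions * 1000))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_true(all(nn >= 5.6 & nn <= 10.4))  # every NN within 30% of nominal
})

test_that("source-grid preconditions and resource cap are enforced", {
  mod <- make_shell_model("bem_default")
  expect_error(make_source_space(mod, spacing = 3, eccentricity = 0.995),
               class = "erplocsim_invalid_argument")
  expect_error(make_source_space(mod, spacing = 0.5),
               class = "erplocsim_resource_limit")
})

test_that("leadfields are average-referenced, linear and depth-sensitive", {
  fx <- small_setup()
  lf <- fx$lf
  cn <- sqrt(colSums(lf$gain^2))
  expect_true(all(abs(colSums(lf$gain)) < 1e-12 * cn))
  expect_true(all(is.finite(lf$gain)) && all(cn > 0))
  # linearity: doubled moment doubles the sensor pattern
  b1 <- lf$gain[, 1:3] %*% c(1, 2, 3)
  b2 <- lf$gain[, 1:3] %*% c(2, 4, 6)
  expect_equal(b2, 2 * b1)
  # a deeper source (same angles) produces a weaker signal
  deep <- make_source_space(fx$model, spacing = 10, eccentricity = 0.5)
  lfd <- compute_leadfield(fx$model, fx$montage, deep)
  expect_gt(mean(sqrt(colSums(lf$gain^2))), mean(sqrt(colSums(lfd$gain^2))))
})

test_that("lower skull conductivity changes the leadfield but keeps referencing", {
  fx <- small_setup()
  mod_hi <- make_shell_model("fem_default")          # skull 0.008
  mod_lo <- mod_hi; mod_lo$conductivities[3] <- 0.006
  lf_hi <- compute_leadfield(mod_hi, fx$montage, fx$sources)
  lf_lo <- compute_leadfield(mod_lo, fx$montage, fx$sources)
  relchange <- max(abs(lf_hi$gain - lf_lo$gain)) / max(abs(lf_hi$gain))
  expect_gt(relchange, 0)
  cn <- sqrt(colSums(lf_lo$gain^2))
  expect_true(all(abs(colSums(lf_lo$gain)) < 1e-12 * cn))
})

test_that("cohorts are deterministic and template radii are the exact mean", {
  mon <- make_montage(16, seed = 3)
  co <- make_cohort(n_subjects = 3, radius_jitter_sd = 0.05, montage = mon,
                    spacing = 20, seed = 7, variants = "fem_meta")
  co2 <- make_cohort(n_subjects = 3, radius_jitter_sd = 0.05, montage = mon,
                     spacing = 20, seed = 7, variants = "fem_meta")
  expect_identical(co$subjects[[2]]$radii, co2$subjects[[2]]$radii)
  expect_identical(co$subjects[[1]]$leadfields$fem_meta$gain,
                   co2$subjects[[1]]$leadfields$fem_meta$gain)
  co3 <- make_cohort(n_subjects = 3, radius_jitter_sd = 0.05, montage = mon,
                     spacing = 20, seed = 8, variants = "fem_meta")
  expect_false(identical(co$subjects[[1]]$radii, co3$subjects[[1]]$radii))
  radii_mat <- t(sapply(co$subjects, `[[`, "radii"))
  expect_identical(co$template$radii, colMeans(radii_mat))
})

test_that("zero jitter collapses every subject onto the template", {
  mon <- make_montage(16, seed = 3)
  co <- make_cohort(n_subjects = 2, radius_jitter_sd = 0,
                    cap_rotation_sd_deg = 0, montage = mon,
                    spacing = 20, seed = 5, variants = c("fem_meta", "bem"))
  for (s in co$subjects) {
    expect_lt(max(abs(s$leadfields$fem_meta$gain -
                      co$template$leadfields$fem_meta$gain)), 1e-12)
    expect_lt(max(abs(s$leadfields$bem$gain -
                      co$template$leadfields$bem$gain)), 1e-12)
  }
})

test_that("morphing is the identity on identical grids and conserves constants", {
  fx <- small_setup()
  ss <- fx$sources
  v <- rnorm(nrow(ss$positions))
  expect_identical(morph_to_template(v, ss, ss), v)
  # constant field stays constant across different grids
  mod <- fx$model
  ss2 <- make_source_space(mod, spacing = 14)
  expect_equal(morph_to_template(rep(3.5, nrow(ss$positions)), ss, ss2),
               rep(3.5, nrow(ss2$positions)))
  # single nonzero dipole lands on exactly the angular nearest neighbors
  v1 <- numeric(nrow(ss$positions)); v1[10] <- 2
  out <- morph_to_template(v1, ss, ss2)
  u_t <- ss2$positions / sqrt(rowSums(ss2$positions^2))
  u_s <- ss$positions / sqrt(rowSums(ss$positions^2))
  nn <- apply(u_t %*% t(u_s), 1, which.max)
  expect_identical(which(out != 0), which(nn == 10))
})
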