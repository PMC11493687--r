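# Difference maps, thresholding, adjacency clustering, TP/FP/FN
# classification and the derived metrics.

make_est <- function(csd, fs = 250, t0 = -200, id = "ss_test") {
  structure(list(csd = csd, fs = fs, t0 = t0, condition = "erp",
                 source_space_id = id), class = "source_estimate")
}

test_that("condition difference averages the right window", {
  n <- 50; ns <- 250
  erp <- make_est(matrix(1, n, ns)); noi <- make_est(matrix(1, n, ns))
  expect_identical(condition_difference(erp, noi), rep(0, n))
  # a single dipole raised by c over the whole window scores c
  erp2 <- erp; erp2$csd[7, ] <- erp2$csd[7, ] + 2.5
  d <- condition_difference(erp2, noi)
  expect_equal(d[7], 2.5); expect_identical(d[-7], rep(0, n - 1))
  # the [100, 220] ms window at 250 Hz covers exactly 31 samples, inclusive
  t <- -200 + (0:(ns - 1)) * 4
  sel <- t >= 100 & t <= 220
  expect_identical(sum(sel), 31L)
  erp3 <- erp; erp3$csd[3, sel] <- erp3$csd[3, sel] + 1
  erp3$csd[3, !sel] <- 99  # outside the window: must not contribute
  expect_equal(condition_difference(erp3, noi)[3], 1)
  expect_error(condition_difference(erp, noi, window = c(700, 900)),
               class = "erplocsim_invalid_argument")
})

test_that("top-fraction threshold is exact, deterministic and scale-invariant", {
  set.seed(8)
  v100 <- rnorm(100)
  m <- threshold_top_fraction(v100, 0.05)
  expect_identical(sum(m), 5L)
  v1000 <- rnorm(1000)
  m2 <- threshold_top_fraction(v1000, 0.05)
  expect_identical(which(m2), sort(order(v1000, decreasing = TRUE)[1:50]))
  expect_identical(threshold_top_fraction(3 * v1000, 0.05), m2)
  # all-equal input: tie-break by ascending index, with a warning
  expect_warning(m3 <- threshold_top_fraction(rep(0, 100), 0.05))
  expect_identical(which(m3), 1:5)
  expect_error(threshold_top_fraction(v100, 1.5),
               class = "erplocsim_invalid_argument")
})

test_that("adjacency clustering finds blobs, drops isolated actives", {
  mod <- make_shell_model("bem_default")
  ss <- make_source_space(mod, spacing = 3)
  # two active blobs around dipoles far apart
  c1 <- ss$positions[10, ]; far <- which.max(colSums((t(ss$positions) - c1)^2))
  b1 <- select_roi_dipoles(ss, list(center = c1, radius_mm = 8))
  b2 <- select_roi_dipoles(ss, list(center = ss$positions[far, ], radius_mm = 8))
  mask <- logical(nrow(ss$positions)); mask[c(b1, b2)] <- TRUE
  cl <- cluster_adjacent(mask, ss)
  expect_identical(length(cl$clusters), 2L)
  expect_setequal(unlist(cl$clusters), c(b1, b2))
  expect_equal(cl$volumes_mm3, cl$sizes * 27)
  # 4 isolated actives (pairwise beyond adjacency) yield no retained cluster
  iso <- c(1L, far, which.max(ss$positions[, 3]), which.min(ss$positions[, 3]))
  mask2 <- logical(nrow(ss$positions)); mask2[iso] <- TRUE
  expect_identical(length(cluster_adjacent(mask2, ss)$clusters), 0L)
})

test_that("min_size boundary retains a blob of exactly five dipoles", {
  # synthetic 1-D chain grid: 5 mutually-reachable dipoles 3 mm apart
  pos <- cbind(seq(0, by = 0.003, length.out = 5) - 0.04, 0, 0)
  ss <- structure(list(positions = pos, radius = 0.07, nominal_spacing = 3,
                       per_dipole_volume = 27, id = "chain"),
                  class = "source_space")
  cl <- cluster_adjacent(rep(TRUE, 5), ss, adjacency_mm = 5, min_size = 5)
  expect_identical(length(cl$clusters), 1L)
  expect_identical(cl$sizes, 5L)
  # one dipole fewer falls below min_size
  ss4 <- ss; ss4$positions <- pos[1:4, ]
  expect_identical(length(cluster_adjacent(rep(TRUE, 4), ss4)$clusters), 0L)
})

test_that("clustering equals a graph connected-components oracle", {
  skip_if_not_installed("igraph")
  mod <- make_shell_model("bem_default")
  ss <- make_source_space(mod, spacing = 6)
  n <- nrow(ss$positions)
  set.seed(13)
  for (trial in 1:200) {
    k <- sample(20:120, 1)
    active <- sample(n, k)
    mask <- logical(n); mask[active] <- TRUE
    adj_mm <- sample(c(5, 7, 9, 12), 1)
    min_size <- sample(1:5, 1)
    cl <- cluster_adjacent(mask, ss, adjacency_mm = adj_mm, min_size = min_size)
    D <- as.matrix(dist(ss$positions[active, ] * 1000))
    g <- igraph::graph_from_adjacency_matrix(D < adj_mm, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    oracle <- split(active, comp)
    oracle <- oracle[lengths(oracle) >= min_size]
    oracle <- unname(oracle[order(vapply(oracle, min, 1L))])
    expect_identical(lapply(cl$clusters, sort), lapply(oracle, sort))
  }
})

test_that("classification applies the distance rule, including double hits", {
  ss <- structure(list(positions = matrix(0, 1, 3), radius = 0.07,
                       nominal_spacing = 3, per_dipole_volume = 27, id = "x"),
                  class = "source_space")
  mk_clusters <- function(centers, sizes) {
    structure(list(clusters = lapply(sizes, seq_len), centers = centers,
                   sizes = sizes, volumes_mm3 = sizes * 27,
                   params = list()), class = "cluster_set")
  }
  rois <- rbind(c(0, 0, 0), c(0.05, 0, 0), c(0, 0.05, 0), c(0.05, 0.05, 0))
  # three ROIs each with a cluster 15 mm away, no extra clusters
  cl <- mk_clusters(rbind(c(0.015, 0, 0), c(0.065, 0, 0), c(0, 0.065, 0)),
                    c(5L, 5L, 5L))
  r <- classify_clusters(cl, rois, 30)
  expect_identical(c(r$tp, r$fn, r$fp), c(3L, 1L, 0L))
  # one cluster equidistant (25 mm) from two ROIs validates both
  cl2 <- mk_clusters(matrix(c(0.025, 0, 0), 1), 5L)
  r2 <- classify_clusters(cl2, rois[1:2, ], 30)
  expect_identical(c(r2$tp, r2$fn, r2$fp), c(2L, 0L, 0L))
  # a cluster far from every ROI is a false positive
  cl3 <- mk_clusters(matrix(c(0, 0, 0.2), 1), 5L)
  r3 <- classify_clusters(cl3, rois, 30)
  expect_identical(c(r3$tp, r3$fn, r3$fp), c(0L, 4L, 1L))
})

test_that("metrics implement their defining ratios", {
  mk <- function(tp, fn, fp, roi_hit, D, volumes, sizes) {
    cl <- structure(list(clusters = lapply(sizes, seq_len),
                         centers = matrix(0, length(sizes), 3), sizes = sizes,
                         volumes_mm3 = volumes, params = list()),
                    class = "cluster_set")
    compute_metrics(list(tp = tp, fn = fn, fp = fp, roi_hit = roi_hit,
                         dist_mm = D, max_dist_mm = 30), cl,
                    roi_volumes_mm3 = rep(27 * 10, length(roi_hit)))
  }
  # one of four ROIs missed
  D <- matrix(100, 4, 3); D[1, 1] <- 10; D[2, 2] <- 20; D[3, 3] <- 5
  r <- mk(3L, 1L, 0L, c(TRUE, TRUE, TRUE, FALSE), D, rep(270, 3), rep(10L, 3))
  expect_equal(r$sensitivity, 0.75)
  expect_equal(r$localization_error_mm, mean(c(10, 20, 5)))
  expect_equal(r$spatial_dispersion, 0)  # cluster volume equals ROI volume
  # two of four reconstructed
  D2 <- matrix(100, 4, 2); D2[1, 1] <- 0; D2[2, 2] <- 12
  r2 <- mk(2L, 2L, 0L, c(TRUE, TRUE, FALSE, FALSE), D2, c(270, 540), c(10L, 20L))
  expect_equal(r2$sensitivity, 0.5)
  expect_equal(r2$per_roi_locerr_mm[1], 0)
  expect_equal(r2$per_roi_dispersion[2], (540 - 270) / 270)
  # precision undefined (NA, not zero) when there are no clusters at all
  r3 <- mk(0L, 4L, 0L, rep(FALSE, 4), matrix(100, 4, 0), numeric(0), integer(0))
  expect_true(is.na(r3$precision))
  expect_true(is.na(r3$localization_error_mm))
  expect_equal(r3$sensitivity, 0)
})

test_that("full evaluation is deterministic and monotone in max_dist", {
  fx <- sim_setup()
  cov <- estimate_noise_covariance(fx$epochs)
  op <- eloreta_weights(whiten(fx$lf, cov), alpha = 1 / 9)
  ev <- condition_csd_evoked(fx$epochs, op)
  res <- evaluate_reconstruction(ev$erp, ev$noise, fx$net, fx$sources,
                                 eval_params(adjacency_mm = 11,
                                             max_dist_mm = c(10, 30, 50)))
  res2 <- evaluate_reconstruction(ev$erp, ev$noise, fx$net, fx$sources,
                                  eval_params(adjacency_mm = 11,
                                              max_dist_mm = c(10, 30, 50)))
  expect_identical(res, res2)
  tps <- sapply(res, `[[`, "tp"); fps <- sapply(res, `[[`, "fp")
  expect_true(all(diff(tps) >= 0))
  expect_true(all(diff(fps) <= 0))
  for (r in res) {
    expect_identical(r$tp + r$fn, 4L)
    expect_true(r$sensitivity >= 0 && r$sensitivity <= 1)
    expect_true(is.na(r$precision) || (r$precision >= 0 && r$precision <= 1))
  }
})
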