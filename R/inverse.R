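# Noise covariance estimation, pre-whitening, and the eLORETA inverse.

#' Estimate the sensor noise covariance
#'
#' Sample covariance over the selected samples: all samples of the noise-only
#' epochs (default), or the pre-stimulus windows of all epochs.  Diagonal
#' loading `loading * mean(diag)` is added, which guarantees positive
#' definiteness.
#'
#' @param epochs an [epoch_set].
#' @param source `"noise_epochs"` or `"prestim"`.
#' @param loading diagonal loading fraction (default 0.05).
#' @return an object of class `noise_cov`: `matrix`
#'   (`n_sensors x n_sensors`), `n_samples_used`, `loading`, `source`.
#' @export
estimate_noise_covariance <- function(epochs,
                                      source = c("noise_epochs", "prestim"),
                                      loading = 0.05) {
  stopifnot(inherits(epochs, "epoch_set"))
  source <- match.arg(source)
  if (loading < 0) stop_invalid("loading must be non-negative")
  d <- dim(epochs$data)
  if (source == "noise_epochs") {
    idx <- which(epochs$condition == "noise")
    if (length(idx) == 0) stop_invalid("no noise-only epochs available")
    X <- do.call(rbind, lapply(idx, function(e) t(epochs$data[e, , ])))
  } else {
    t <- epoch_time(epochs)
    pre <- which(t < 0)
    if (length(pre) == 0) stop_invalid("no pre-stimulus samples available")
    X <- do.call(rbind, lapply(seq_len(d[1]),
                               function(e) t(epochs$data[e, , pre])))
  }
  n <- nrow(X)
  if (n <= d[2] && loading == 0) {
    stop_invalid("only ", n, " samples for ", d[2], " sensors: the covariance ",
                 "is rank deficient; use a nonzero diagonal loading")
  }
  X <- sweep(X, 2, colMeans(X))
  C <- crossprod(X) / (n - 1)
  C <- C + diag(loading * mean(diag(C)), d[2])
  structure(list(matrix = C, n_samples_used = n, loading = loading,
                 source = source),
            class = "noise_cov")
}

# inverse symmetric matrix square root via eigendecomposition
inv_sqrt_sym <- function(C, rtol = 1e-12) {
  e <- eigen(C, symmetric = TRUE)
  vals <- e$values
  if (any(vals <= rtol * max(vals))) {
    stop_numeric("covariance is not positive definite; increase the loading")
  }
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

#' Pre-whiten a leadfield with a noise covariance
#'
#' Multiplies the gain matrix by the inverse matrix square root of the noise
#' covariance, so that noise with that covariance becomes identity-covariance
#' in the whitened sensor space.
#'
#' @param leadfield a [leadfield][compute_leadfield].
#' @param cov a [noise_cov][estimate_noise_covariance].
#' @return the whitened `leadfield` (reference tag `"whitened"`), with the
#'   whitener matrix attached as the `whitener` element.
#' @export
whiten <- function(leadfield, cov) {
  stopifnot(inherits(leadfield, "leadfield"), inherits(cov, "noise_cov"))
  if (nrow(cov$matrix) != leadfield$n_sensors) {
    stop_invalid("covariance dimension does not match the leadfield")
  }
  Wm <- inv_sqrt_sym(cov$matrix)
  leadfield$gain <- Wm %*% leadfield$gain
  leadfield$reference <- "whitened"
  leadfield$whitener <- Wm
  leadfield
}

#' Pre-whiten epoch data with a noise covariance
#'
#' @param epochs an [epoch_set].
#' @param cov a [noise_cov][estimate_noise_covariance].
#' @return the whitened [epoch_set].
#' @export
whiten_data <- function(epochs, cov) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(cov, "noise_cov"))
  Wm <- inv_sqrt_sym(cov$matrix)
  for (e in seq_len(dim(epochs$data)[1])) {
    epochs$data[e, , ] <- Wm %*% epochs$data[e, , ]
  }
  epochs$meta$whitened <- TRUE
  epochs
}

#' Compute the eLORETA inverse operator
#'
#' Iterates the eLORETA per-source symmetric 3x3 weight blocks
#' `W_i <- [K_i' (K W^-1 K' + a H)^+ K_i]^(1/2)` to their fixed point, with
#' `H` the average-reference centering operator and the regularization scaled
#' by `trace(K W^-1 K') / n_sensors` each iteration (so a common rescaling of
#' the data and leadfield leaves the solution's shape unchanged).  The
#' resolvent kernel `W^-1 K' (K W^-1 K' + a H)^+` maps whitened sensor data to
#' source moments.
#'
#' For conditioning, the leadfield is internally rescaled to unit median
#' column norm; current source density output is therefore in arbitrary units.
#'
#' @param whitened_leadfield a [whiten]ed leadfield (a raw average-referenced
#'   leadfield is accepted for noise-free use).
#' @param alpha regularization fraction (default 1/9, an evoked-data
#'   signal-to-noise prior of 3).
#' @param tol convergence tolerance on the maximum relative weight change.
#' @param max_iter iteration cap.
#' @return an object of class `inverse_operator`: `weights` (3x3xS array),
#'   `kernel` (`3S x n_sensors`), `alpha`, `iterations_run`, `converged`,
#'   `rel_changes`, `whitener` (or `NULL`), and provenance ids.  When the
#'   iteration does not converge the operator is still returned with
#'   `converged = FALSE` and a warning.
#' @export
eloreta_weights <- function(whitened_leadfield, alpha = 1 / 9, tol = 1e-6,
                            max_iter = 100L) {
  stopifnot(inherits(whitened_leadfield, "leadfield"))
  if (alpha < 0) stop_invalid("alpha must be non-negative")
  K <- whitened_leadfield$gain
  scale <- stats::median(sqrt(colSums(K^2)))
  if (!is.finite(scale) || scale <= 0) stop_numeric("degenerate leadfield")
  fit <- eloreta_fit_cpp(K / scale, alpha, tol, as.integer(max_iter))
  if (!fit$converged) {
    warning(sprintf(
      "eLORETA iteration did not converge in %d iterations (last relative change %.3g)",
      fit$iterations, utils::tail(fit$rel_changes, 1)))
  }
  structure(list(
    weights = fit$weights,
    kernel = fit$kernel / scale,
    alpha = alpha,
    iterations_run = fit$iterations,
    converged = fit$converged,
    rel_changes = fit$rel_changes,
    whitener = whitened_leadfield$whitener,
    source_space_id = whitened_leadfield$source_space_id,
    montage_id = whitened_leadfield$montage_id,
    shell_model_id = whitened_leadfield$shell_model_id,
    n_sources = whitened_leadfield$n_sources,
    n_sensors = whitened_leadfield$n_sensors
  ), class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf(
    "<inverse_operator> eLORETA, %d sources, alpha = %.4g, %d iterations (%s)\n",
    x$n_sources, x$alpha, x$iterations_run,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

new_source_estimate <- function(csd, fs, t0, condition, source_space_id) {
  structure(list(csd = csd, fs = fs, t0 = t0, condition = condition,
                 source_space_id = source_space_id),
            class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat(sprintf("<source_estimate> %d sources x %d samples (%s)\n",
              nrow(x$csd), ncol(x$csd), x$condition))
  invisible(x)
}

#' Apply an inverse operator to epochs
#'
#' Whitens each epoch with the operator's own whitener (if any) and computes
#' the per-sample current source density: the Euclidean norm of the estimated
#' 3-vector dipole moment at every source, discarding orientation.
#'
#' @param epochs an [epoch_set] of raw (unwhitened) data.
#' @param op an [inverse_operator][eloreta_weights].
#' @return a list of `source_estimate` objects, one per epoch, each with the
#'   epoch's condition label.
#' @export
apply_inverse <- function(epochs, op) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(op, "inverse_operator"))
  if (dim(epochs$data)[2] != op$n_sensors) {
    stop_invalid("epoch sensor count does not match the inverse operator")
  }
  lapply(seq_len(dim(epochs$data)[1]), function(e) {
    X <- epochs$data[e, , , drop = FALSE]
    dim(X) <- dim(epochs$data)[2:3]
    if (!is.null(op$whitener)) X <- op$whitener %*% X
    new_source_estimate(csd_epoch_cpp(op$kernel, X), epochs$fs, epochs$t0,
                        epochs$condition[e], op$source_space_id)
  })
}

#' Average per-epoch source estimates within conditions
#'
#' Pointwise mean of the per-epoch current source density, separately for each
#' condition label.
#'
#' @param estimates a list of `source_estimate` objects (from
#'   [apply_inverse()]).
#' @return a named list with one `source_estimate` per condition present.
#' @export
condition_evoked <- function(estimates) {
  if (length(estimates) == 0) stop_invalid("no estimates supplied")
  conds <- vapply(estimates, `[[`, "", "condition")
  out <- lapply(unique(conds), function(cc) {
    idx <- which(conds == cc)
    csd <- Reduce(`+`, lapply(estimates[idx], `[[`, "csd")) / length(idx)
    e1 <- estimates[[idx[1]]]
    new_source_estimate(csd, e1$fs, e1$t0, cc, e1$source_space_id)
  })
  names(out) <- unique(conds)
  out
}

#' Condition-averaged CSD without storing per-epoch estimates
#'
#' Memory-lean equivalent of [apply_inverse()] followed by
#' [condition_evoked()]: epochs are reconstructed one at a time and their CSD
#' accumulated into per-condition means.
#'
#' @param epochs an [epoch_set].
#' @param op an [inverse_operator][eloreta_weights].
#' @return a named list of `source_estimate` objects, one per condition.
#' @export
condition_csd_evoked <- function(epochs, op) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(op, "inverse_operator"))
  if (dim(epochs$data)[2] != op$n_sensors) {
    stop_invalid("epoch sensor count does not match the inverse operator")
  }
  conds <- unique(epochs$condition)
  sums <- list(); counts <- list()
  for (e in seq_len(dim(epochs$data)[1])) {
    X <- epochs$data[e, , , drop = FALSE]
    dim(X) <- dim(epochs$data)[2:3]
    if (!is.null(op$whitener)) X <- op$whitener %*% X
    csd <- csd_epoch_cpp(op$kernel, X)
    cc <- epochs$condition[e]
    if (is.null(sums[[cc]])) { sums[[cc]] <- csd; counts[[cc]] <- 1L }
    else { sums[[cc]] <- sums[[cc]] + csd; counts[[cc]] <- counts[[cc]] + 1L }
  }
  out <- lapply(conds, function(cc) {
    new_source_estimate(sums[[cc]] / counts[[cc]], epochs$fs, epochs$t0, cc,
                        op$source_space_id)
  })
  names(out) <- conds
  out
}
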