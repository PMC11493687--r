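# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`, then
#' restores the previous RNG state so callers' random streams are unaffected.
#' With `seed = NULL` the code runs against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic per-cell seed derivation.  Mixes the master seed with small
# factor indices through a Weyl-style integer hash; result is always a
# non-negative integer below 2^31 so it is a valid R seed on every platform.
derive_seed <- function(master_seed, ...) {
  parts <- c(as.numeric(master_seed), as.numeric(c(...)))
  h <- 0
  for (p in parts) {
    # 2654435761 is the Knuth multiplicative-hash constant; arithmetic done in
    # doubles and reduced mod 2^31 - 1, which doubles represent exactly.
    h <- (h * 2654435761 + p * 40503 + 97) %% 2147483647
  }
  as.integer(h)
}

vec_norm <- function(x) sqrt(sum(x^2))

row_norms <- function(m) sqrt(rowSums(m^2))

unit_rows <- function(m) m / row_norms(m)

# Quasi-uniform points on the unit sphere (or a polar cap of it) via the
# Fibonacci lattice.  `z_range` gives the inclusive range of z = cos(polar
# angle) to cover; the full sphere is c(-1, 1).
fibonacci_points <- function(n, z_range = c(-1, 1), phase = 0) {
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n)
  z <- z_range[2] - (i - 0.5) / n * (z_range[2] - z_range[1])
  phi <- phase + i * golden
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
}

# Rodrigues rotation matrix about a unit axis.
rotation_matrix <- function(axis, angle) {
  k <- axis / vec_norm(axis)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("erplocsim_invalid_argument", "error")))
}

stop_resource <- function(...) {
  stop(errorCondition(paste0(...), class = c("erplocsim_resource_limit", "error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("erplocsim_numerical_error", "error")))
}

stop_provenance <- function(...) {
  stop(errorCondition(paste0(...), class = c("erplocsim_provenance_error", "error")))
}

stop_empty_roi <- function(...) {
  stop(errorCondition(paste0(...), class = c("erplocsim_empty_roi", "error")))
}
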