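# Internal helpers shared across modules.

#' Flatten a landmark array to a wide coordinate matrix
#'
#' Converts an `n x L x 3` landmark array into an `n x 3L` matrix with
#' per-landmark interleaved columns `x1, y1, z1, ..., xL, yL, zL` — the layout
#' used by the wide CSV format and by all regression stages.
#'
#' @param shapes Numeric array `n x L x 3` (or a single `L x 3` configuration).
#' @return Numeric matrix `n x 3L`, row names preserved.
#' @export
shapes_to_matrix <- function(shapes) {
  if (length(dim(shapes)) == 2L) {
    shapes <- array(shapes, dim = c(1L, nrow(shapes), 3L))
  }
  n <- dim(shapes)[1L]
  L <- dim(shapes)[2L]
  out <- matrix(aperm(shapes, c(3L, 2L, 1L)), nrow = n, ncol = 3L * L,
                byrow = TRUE)
  rownames(out) <- dimnames(shapes)[[1L]]
  out
}

#' Rebuild a landmark array from a wide coordinate matrix
#'
#' Inverse of [shapes_to_matrix()].
#'
#' @param m Numeric matrix `n x 3L` with interleaved `x, y, z` columns.
#' @return Numeric array `n x L x 3`.
#' @export
matrix_to_shapes <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  n <- nrow(m)
  L <- ncol(m) / 3L
  if (L != floor(L)) stop("column count ", ncol(m), " is not a multiple of 3")
  arr <- aperm(array(t(m), dim = c(3L, L, n)), c(3L, 2L, 1L))
  dimnames(arr) <- list(rownames(m), NULL, c("x", "y", "z"))
  arr
}

# Single L x 3 configuration from an n x L x 3 array.
config_at <- function(shapes, i) {
  matrix(shapes[i, , ], ncol = 3L, dimnames = list(NULL, c("x", "y", "z")))
}

# Stack a list of L x 3 configurations into n x L x 3.
stack_configs <- function(configs, ids = NULL) {
  n <- length(configs)
  L <- nrow(configs[[1L]])
  arr <- array(NA_real_, dim = c(n, L, 3L),
               dimnames = list(ids, NULL, c("x", "y", "z")))
  for (i in seq_len(n)) arr[i, , ] <- configs[[i]]
  arr
}

# Deterministic per-unit substream seed derived from a global seed.
# Keeps every derived seed a valid positive 32-bit integer so subsetting a
# cohort never reshuffles another individual's draws.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 69621) %% 2147483629 + 1)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number")
  if (positive && x <= 0) stop("'", name, "' must be > 0")
  invisible(x)
}
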