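# Symmetrization and generalized Procrustes superimposition (with scaling)
# of dense landmark configurations. Shape-only analysis: translation,
# rotation and centroid size are removed; centroid size is recorded before
# scaling so it can enter the covariate model.

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks to their
#' centroid — the standard size measure in geometric morphometrics.
#'
#' @param config `L x 3` numeric matrix.
#' @return Non-negative scalar, in the configuration's length units.
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 3L) stop("need at least 3 landmarks")
  if (!all(is.finite(config))) stop("non-finite coordinates")
  ctr <- colMeans(config)
  s <- sqrt(sum(sweep(config, 2L, ctr)^2))
  if (s == 0) warning("all landmarks coincident: centroid size 0")
  s
}

#' Reflect a configuration and relabel bilateral landmarks
#'
#' Negates the `x` coordinates and permutes landmarks by the template's
#' bilateral pairing, so that each index again denotes the same anatomical
#' point on the mirrored face. The operation is an involution.
#'
#' @param config `L x 3` matrix.
#' @param template A `face_template` supplying the pairing.
#' @return `L x 3` matrix.
#' @export
reflect_and_pair <- function(config, template) {
  if (nrow(config) != nrow(template$coordinates))
    stop("configuration has ", nrow(config), " landmarks; template has ",
         nrow(template$coordinates))
  refl <- config
  refl[, 1L] <- -refl[, 1L]
  refl[template$pairing, , drop = FALSE]
}

#' Symmetrize a configuration
#'
#' Averages a configuration with its reflected-and-relabeled copy, removing
#' bilateral asymmetry. The output is an exact fixed point of
#' [reflect_and_pair()] and the operation is idempotent.
#'
#' @inheritParams reflect_and_pair
#' @return `L x 3` bilaterally symmetric matrix.
#' @export
symmetrize <- function(config, template) {
  (config + reflect_and_pair(config, template)) / 2
}

#' Symmetrize every configuration in a cohort
#'
#' @param shapes `n x L x 3` array.
#' @param template A `face_template`.
#' @return `n x L x 3` array of symmetrized configurations.
#' @export
symmetrize_cohort <- function(shapes, template) {
  out <- shapes
  for (i in seq_len(dim(shapes)[1L]))
    out[i, , ] <- symmetrize(config_at(shapes, i), template)
  out
}

# Optimal rotation (no reflection) carrying A onto B: minimizes ||A R - B||_F
# over SO(3).
opa_rotation <- function(A, B) {
  M <- crossprod(A, B)
  sv <- svd(M)
  d <- sign(det(sv$u) * det(sv$v))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Full Procrustes distance between two configurations
#'
#' Centers and scales both configurations to unit centroid size, rotates the
#' first onto the second optimally (rotations only), and returns the
#' Frobenius norm of the difference.
#'
#' @param a,b `L x 3` matrices.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  a <- sweep(a, 2L, colMeans(a)); a <- a / sqrt(sum(a^2))
  b <- sweep(b, 2L, colMeans(b)); b <- b / sqrt(sum(b^2))
  sqrt(sum((a %*% opa_rotation(a, b) - b)^2))
}

#' Project a displacement field onto the Procrustes tangent space
#'
#' Removes from a per-landmark displacement field the components that a
#' similarity-only superimposition cannot represent as shape change: the
#' three translations, the three infinitesimal rotations of the reference,
#' and the scaling direction (the reference itself). What remains is the
#' part of the field that is recoverable as shape variation after
#' generalized Procrustes alignment with scaling, so ground-truth
#' deformations should be projected this way before being compared with
#' effects estimated from aligned shapes.
#'
#' @param field `L x 3` displacement field.
#' @param reference `L x 3` reference configuration at which the tangent
#'   space is taken (template or mean shape).
#' @return `L x 3` projected field.
#' @export
tangent_projection <- function(field, reference) {
  X0 <- sweep(as.matrix(reference), 2L, colMeans(reference))
  L <- nrow(X0)
  zero <- rep(0, L)
  one <- rep(1, L)
  gen <- function(A) as.vector(X0 %*% A)
  basis <- cbind(c(one, zero, zero), c(zero, one, zero), c(zero, zero, one),
                 as.vector(X0),
                 gen(rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 0))),
                 gen(rbind(c(0, 0, -1), c(0, 0, 0), c(1, 0, 0))),
                 gen(rbind(c(0, 0, 0), c(0, 0, -1), c(0, 1, 0))))
  Q <- qr.Q(qr(basis))
  v <- as.vector(as.matrix(field))
  out <- matrix(v - Q %*% crossprod(Q, v), ncol = 3L)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Generalized Procrustes analysis with scaling
#'
#' Iterative superimposition of a cohort: each configuration is centered and
#' scaled to unit centroid size, rotated to the current mean by the optimal
#' orthogonal rotation (reflections disallowed), the mean recomputed and
#' rescaled to unit size, until the root-mean-square change of the mean falls
#' below `tol`. The converged frame is anchored by rotating everything so the
#' mean is optimally aligned with the initial orientation of the anchor
#' configuration (lexicographically smallest id, or row 1 if unnamed), making
#' results reproducible across runs and invariant to row order.
#'
#' @param shapes `n x L x 3` array (ids in rownames).
#' @param scale Remove size (default TRUE; FALSE keeps raw centroid sizes).
#' @param tol Convergence tolerance on the mean (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @return Object of class `gpa_fit`: `shapes` (aligned array), `mean_shape`
#'   (`L x 3`, unit centroid size), `centroid_sizes` (pre-scaling sizes),
#'   `iterations`, `converged`.
#' @export
gpa <- function(shapes, scale = TRUE, tol = 1e-8, max_iter = 100L) {
  n <- dim(shapes)[1L]
  L <- dim(shapes)[2L]
  if (n < 2L) stop("GPA needs at least 2 configurations")
  if (L < 3L) stop("GPA needs at least 3 landmarks")
  ids <- dimnames(shapes)[[1L]]

  sizes <- numeric(n)
  configs <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config_at(shapes, i)
    cfg <- sweep(cfg, 2L, colMeans(cfg))
    sizes[i] <- sqrt(sum(cfg^2))
    if (sizes[i] == 0)
      stop("degenerate configuration for individual ",
           if (is.null(ids)) i else ids[i], ": zero centroid size")
    if (svd(cfg, nu = 0, nv = 0)$d[3L] < 1e-12 * sizes[i])
      stop("degenerate (rank < 3) configuration for individual ",
           if (is.null(ids)) i else ids[i])
    if (scale) cfg <- cfg / sizes[i]
    configs[[i]] <- cfg
  }

  # frame anchor: the configuration with the lexicographically smallest id
  # (row 1 if unnamed), so the output frame is independent of row order
  anchor <- if (is.null(ids)) 1L else order(ids)[1L]
  first0 <- configs[[anchor]]
  mean_shape <- first0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n))
      configs[[i]] <- configs[[i]] %*% opa_rotation(configs[[i]], mean_shape)
    new_mean <- Reduce(`+`, configs) / n
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")

  # anchor the frame: align the mean to the first configuration's initial
  # orientation, then carry every configuration along
  R0 <- opa_rotation(mean_shape, first0 / sqrt(sum(first0^2)))
  mean_shape <- mean_shape %*% R0
  for (i in seq_len(n)) configs[[i]] <- configs[[i]] %*% R0

  structure(list(shapes = stack_configs(configs, ids),
                 mean_shape = mean_shape, centroid_sizes = sizes,
                 iterations = iter, converged = converged),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("Generalized Procrustes superimposition\n")
  cat("  configurations :", dim(x$shapes)[1L], "x", dim(x$shapes)[2L],
      "landmarks\n")
  cat("  iterations     :", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  centroid sizes :", sprintf("%.4g .. %.4g", min(x$centroid_sizes),
                                    max(x$centroid_sizes)), "\n")
  invisible(x)
}
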