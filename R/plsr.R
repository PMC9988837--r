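# Partial least squares regression (PLS2, SIMPLS algorithm) of a landmark
# coordinate block on predictors, and the correction stages built on it:
# covariate correction, genetic-ancestry correction via leading genetic PCs,
# and single-PC (leave-one-out) facial effects.
#
# Predictors are standardized internally (heterogeneous units: years, cm, kg,
# +/-1 codes); responses are centered only (homogeneous landmark units).
# With n_components equal to the number of predictors and a full-rank design,
# the PLSR coefficients coincide with multivariate ordinary least squares,
# which makes the default deterministic and oracle-checkable.

#' Fit a PLS2 regression of a response block on predictors
#'
#' SIMPLS fit of `Y` (n x q, centered internally) on `X` (n x p, standardized
#' internally). The default `n_components = ncol(X)` reproduces ordinary
#' least squares on full-rank designs.
#'
#' @param X Numeric predictor matrix `n x p` (a data.frame is accepted).
#' @param Y Numeric response matrix `n x q` (e.g. an `n x 3L` coordinate
#'   matrix from [shapes_to_matrix()]).
#' @param n_components Number of latent components, at most `min(p, n - 1)`.
#' @return Object of class `plsr_fit` with elements `predictor_names`,
#'   `x_mean`, `x_scale`, `y_mean`, `coefficients` (p x q, on the
#'   standardized-X scale), `n_components`.
#' @export
fit_plsr <- function(X, Y, n_components = ncol(X)) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("X and Y row counts differ")
  if (n <= p) stop("need n > p (got n = ", n, ", p = ", p, ")")
  if (n_components < 1L || n_components > min(p, n - 1L))
    stop("n_components must lie in [1, min(p, n-1)]")
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2L, stats::sd)
  zero_var <- which(x_sd == 0)
  if (length(zero_var))
    stop("predictor '", colnames(X)[zero_var[1L]],
         "' has zero variance; drop it before fitting")
  Xs <- sweep(sweep(X, 2L, x_mean), 2L, x_sd, "/")
  y_mean <- colMeans(Y)
  Y0 <- sweep(Y, 2L, y_mean)

  rk <- qr(Xs)$rank
  A <- n_components
  if (rk < A) {
    warning("design has rank ", rk, " < n_components = ", A,
            "; reducing to ", rk, " components")
    A <- rk
  }

  S <- crossprod(Xs, Y0)
  Rm <- matrix(0, p, A)
  Qm <- matrix(0, ncol(Y), A)
  V <- matrix(0, p, A)
  used <- 0L
  for (a in seq_len(A)) {
    sv <- svd(S, nu = 1L, nv = 0L)
    if (sv$d[1L] < 1e-12) break
    r <- sv$u[, 1L]
    t_sc <- Xs %*% r
    nt <- sqrt(sum(t_sc^2))
    if (nt < 1e-12) break
    t_sc <- t_sc / nt
    r <- r / nt
    p_a <- crossprod(Xs, t_sc)
    q_a <- crossprod(Y0, t_sc)
    v <- p_a
    if (a > 1L) v <- v - V[, seq_len(used), drop = FALSE] %*%
        crossprod(V[, seq_len(used), drop = FALSE], p_a)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    used <- used + 1L
    Rm[, used] <- r; Qm[, used] <- q_a; V[, used] <- v
    S <- S - v %*% crossprod(v, S)
  }
  if (used < A)
    warning("component extraction stopped at ", used, " of ", A)
  B <- Rm[, seq_len(used), drop = FALSE] %*%
    t(Qm[, seq_len(used), drop = FALSE])

  structure(list(predictor_names = colnames(X), x_mean = x_mean,
                 x_scale = x_sd, y_mean = y_mean, coefficients = B,
                 n_components = used, n = n),
            class = "plsr_fit")
}

#' @export
predict.plsr_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2L, object$x_mean), 2L, object$x_scale, "/")
  sweep(Xs %*% object$coefficients, 2L, object$y_mean, "+")
}

#' @export
coef.plsr_fit <- function(object, ...) {
  # coefficients on the raw predictor scale
  sweep(object$coefficients, 1L, object$x_scale, "/")
}

#' @export
print.plsr_fit <- function(x, ...) {
  cat("PLSR fit (SIMPLS):", length(x$predictor_names), "predictors ->",
      ncol(x$coefficients), "responses,", x$n_components, "components, n =",
      x$n, "\n")
  invisible(x)
}

#' Build the covariate design matrix
#'
#' Assembles the standard covariate block: sex, age, age-squared (derived
#' from age when absent, to absorb residual nonlinear age effects), height,
#' weight, centroid size and camera system (two systems coded -1 / +1).
#'
#' @param covariates Data frame with columns `sex, age, height, weight,
#'   camera` and optionally `age_squared`.
#' @param centroid_sizes Optional numeric vector appended as `centroid_size`.
#' @return Numeric design matrix, one row per individual.
#' @export
covariate_design <- function(covariates, centroid_sizes = NULL) {
  cv <- covariates
  if (is.null(cv$age_squared)) cv$age_squared <- cv$age^2
  cols <- c("sex", "age", "age_squared", "height", "weight", "camera")
  X <- as.matrix(cv[, cols])
  if (!is.null(centroid_sizes)) X <- cbind(X, centroid_size = centroid_sizes)
  rownames(X) <- cv$id
  X
}

#' Correct a cohort of shapes for predictor effects
#'
#' Regresses the landmark coordinate block on `X` via PLSR and replaces each
#' configuration with its residual plus the cohort mean shape, removing the
#' modeled effects while preserving the grand mean.
#'
#' @param shapes `n x L x 3` array (typically the aligned shapes of a
#'   [gpa()] fit) or a `gpa_fit`.
#' @param X Predictor matrix with rownames matching the shape ids.
#' @param n_components Passed to [fit_plsr()]; defaults to `ncol(X)`.
#' @return Object of class `corrected_cohort`: `shapes` (corrected array),
#'   `model` (the `plsr_fit`), `grand_mean` (`L x 3`).
#' @export
correct_shapes <- function(shapes, X, n_components = ncol(X)) {
  if (inherits(shapes, "gpa_fit")) shapes <- shapes$shapes
  Y <- shapes_to_matrix(shapes)
  X <- as.matrix(X)
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    stop("predictor ids do not match shape ids")
  fit <- fit_plsr(X, Y, n_components)
  corrected <- Y - stats::predict(fit, X) +
    matrix(fit$y_mean, nrow(Y), ncol(Y), byrow = TRUE)
  rownames(corrected) <- rownames(Y)
  structure(list(shapes = matrix_to_shapes(corrected), model = fit,
                 grand_mean = matrix(fit$y_mean, ncol = 3L, byrow = TRUE,
                                     dimnames = list(NULL, c("x", "y", "z")))),
            class = "corrected_cohort")
}

#' @export
print.corrected_cohort <- function(x, ...) {
  cat("Covariate-corrected cohort:", dim(x$shapes)[1L], "individuals x",
      dim(x$shapes)[2L], "landmarks\n")
  cat("  predictors removed:",
      paste(x$model$predictor_names, collapse = ", "), "\n")
  invisible(x)
}

#' Correct for genetic ancestry via the leading genetic PCs
#'
#' PLSR of the (already covariate-corrected) shapes on the first `k` genetic
#' PCs; the per-individual displacement before minus after correction is the
#' genetic facial ancestry effect. Per-region mean effect fields are computed
#' when labels are supplied.
#'
#' @param corrected A `corrected_cohort` (or `n x L x 3` array).
#' @param pcs `n x K` genetic PC score matrix.
#' @param k Number of leading PCs to correct for (default 4, the standard
#'   ancestry-correction protocol).
#' @param labels Optional factor of region labels for per-region means.
#' @return List of class `ancestry_correction`: `corrected`
#'   (`corrected_cohort` after ancestry removal), `effect` with
#'   `per_individual` (`n x L x 3`) and, when labels are given, `per_region`
#'   (`R x L x 3`).
#' @export
ancestry_correct <- function(corrected, pcs, k = 4L, labels = NULL) {
  if (k < 1L) stop("k must be >= 1")
  if (k > ncol(pcs)) stop("k = ", k, " exceeds available PCs (", ncol(pcs), ")")
  shapes <- if (inherits(corrected, "corrected_cohort")) corrected$shapes
            else corrected
  X <- as.matrix(pcs[, seq_len(k), drop = FALSE])
  # constant PC columns carry no ancestry information: drop them; with none
  # left the correction is a no-op with an identically zero effect field
  keep_cols <- apply(X, 2L, stats::sd) > 0
  if (!all(keep_cols)) {
    X <- X[, keep_cols, drop = FALSE]
    if (ncol(X) == 0L) {
      grand <- matrix_to_shapes(colMeans(shapes_to_matrix(shapes)))[1L, , ]
      out <- structure(list(shapes = shapes, model = NULL,
                            grand_mean = grand),
                       class = "corrected_cohort")
      effect <- list(per_individual = array(0, dim = dim(shapes),
                                            dimnames = dimnames(shapes)))
      if (!is.null(labels)) {
        labels <- as.factor(labels)
        effect$per_region <- array(
          0, dim = c(nlevels(labels), dim(shapes)[2L], 3L),
          dimnames = list(levels(labels), NULL, c("x", "y", "z")))
      }
      return(structure(list(corrected = out, effect = effect, k = k),
                       class = "ancestry_correction"))
    }
  }
  out <- correct_shapes(shapes, X)
  eff <- shapes_to_matrix(shapes) - shapes_to_matrix(out$shapes)
  effect <- list(per_individual = matrix_to_shapes(eff))
  if (!is.null(labels)) {
    labels <- as.factor(labels)
    per_region <- array(0, dim = c(nlevels(labels), dim(out$shapes)[2L], 3L),
                        dimnames = list(levels(labels), NULL,
                                        c("x", "y", "z")))
    for (r in levels(labels)) {
      rows <- which(labels == r)
      per_region[r, , ] <- matrix_to_shapes(
        colMeans(eff[rows, , drop = FALSE]))[1L, , ]
    }
    effect$per_region <- per_region
  }
  structure(list(corrected = out, effect = effect, k = k),
            class = "ancestry_correction")
}

#' Facial effect of a single genetic PC
#'
#' Difference between ancestry correction using all `k` leading PCs and using
#' the same set with one PC left out: what the excluded PC alone contributes
#' to the correction.
#'
#' @param corrected A `corrected_cohort` (covariates removed, ancestry not).
#' @param pcs `n x K` genetic PC scores.
#' @param exclude Index (1..k) of the PC whose effect is sought.
#' @param k Number of leading PCs in the full correction (default 4).
#' @return List with `per_individual` (`n x L x 3`) and `mean_field`
#'   (`L x 3`, cohort mean effect).
#' @export
single_pc_effect <- function(corrected, pcs, exclude, k = 4L) {
  if (exclude < 1L || exclude > k)
    stop("exclude must lie in 1..", k)
  full <- ancestry_correct(corrected, pcs, k)
  reduced_shapes <- if (k == 1L) {
    if (inherits(corrected, "corrected_cohort")) corrected$shapes else corrected
  } else {
    ancestry_correct(corrected,
                     pcs[, setdiff(seq_len(k), exclude), drop = FALSE],
                     k = k - 1L)$corrected$shapes
  }
  diff <- shapes_to_matrix(full$corrected$shapes) -
    shapes_to_matrix(reduced_shapes)
  list(per_individual = matrix_to_shapes(diff),
       mean_field = matrix_to_shapes(colMeans(diff))[1L, , ])
}

#' Exaggerate an effect field on a base face
#'
#' `base + factor * effect` — used only for visual export (4x for regional
#' effects, 8x for single-PC effects); statistics are never computed on
#' exaggerated faces.
#'
#' @param base_face `L x 3` base configuration.
#' @param effect `L x 3` displacement field.
#' @param factor Exaggeration multiplier.
#' @return `L x 3` configuration.
#' @export
exaggerate <- function(base_face, effect, factor) {
  if (!all(is.finite(base_face)) || !all(is.finite(effect)))
    stop("non-finite input")
  base_face + factor * effect
}
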