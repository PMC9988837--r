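# Permutation testing of the shape variance explained by predictor sets.
# Shape variation is first reduced by PCA of the landmark coordinates
# (components retained up to a cumulative-variance threshold, scores
# normalized to unit variance with eigenvalues kept for back-weighting);
# the observed total R-squared of a predictor set is then compared with a
# permutation null built by re-pairing predictors with shapes.

#' PCA reduction of a shape cohort
#'
#' PCA of the centered landmark-coordinate matrix; retains the smallest
#' number of components whose cumulative variance fraction reaches
#' `var_threshold`. Scores are stored unit-variance-normalized, with the
#' component variances (eigenvalues) retained so variance-weighted statistics
#' can be recovered exactly.
#'
#' @param shapes `n x L x 3` array, `corrected_cohort`, or `n x 3L` matrix.
#' @param var_threshold Cumulative variance fraction to retain (default
#'   0.96).
#' @return Object of class `shape_pca`: `loadings` (3L x m), `eigenvalues`
#'   (m component variances), `scores` (n x m, unit variance), `center`,
#'   `m_retained`, `var_threshold`, `total_variance`.
#' @export
shape_pca <- function(shapes, var_threshold = 0.96) {
  if (inherits(shapes, "corrected_cohort")) shapes <- shapes$shapes
  Y <- if (length(dim(shapes)) == 3L) shapes_to_matrix(shapes) else
    as.matrix(shapes)
  n <- nrow(Y)
  if (n < 3L) stop("need at least 3 individuals")
  if (var_threshold <= 0 || var_threshold > 1)
    stop("var_threshold must lie in (0, 1]")
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2L, ctr)
  sv <- svd(Yc, nu = 0L)
  ev <- sv$d^2 / (n - 1L)
  keep <- ev > max(ev) * 1e-12
  ev <- ev[keep]
  V <- sv$v[, keep, drop = FALSE]
  frac <- cumsum(ev) / sum(ev)
  m <- which(frac >= var_threshold - 1e-12)[1L]
  V <- V[, seq_len(m), drop = FALSE]
  ev_m <- ev[seq_len(m)]
  scores <- Yc %*% V
  scores <- sweep(scores, 2L, sqrt(ev_m), "/")  # unit variance
  colnames(scores) <- paste0("shapePC", seq_len(m))
  structure(list(loadings = V, eigenvalues = ev_m, scores = scores,
                 center = ctr, m_retained = m,
                 var_threshold = var_threshold, total_variance = sum(ev),
                 all_eigenvalues = ev),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("Shape PCA:", x$m_retained, "components retained (",
      sprintf("%.1f%%", 100 * sum(x$eigenvalues) / x$total_variance),
      "of variance, threshold",
      sprintf("%.0f%%", 100 * x$var_threshold), ")\n")
  invisible(x)
}

# Fast per-component R^2 of the least-squares fit of unit-variance scores on
# X. Full-component PLSR coincides with this fit, so the permutation loop
# uses the direct least-squares path.
r2_components <- function(X, scores) {
  Xc <- sweep(X, 2L, colMeans(X))
  qr_x <- qr(Xc)
  fitted <- qr.fitted(qr_x, sweep(scores, 2L, colMeans(scores)))
  colSums(fitted^2) / colSums(sweep(scores, 2L, colMeans(scores))^2)
}

#' Total shape variance explained by a predictor set
#'
#' Regresses the retained (unit-variance) shape-PC scores on the predictors
#' (full-component PLSR, equal to least squares) and aggregates per-component
#' R-squared values. In `"eigenvalue"` mode components are weighted by their
#' variances, so the statistic reads as the fraction of retained facial
#' variation explained; `"unit"` mode weights components equally, matching
#' the unit-variance-normalized scores.
#'
#' @param X Predictor matrix `n x q`.
#' @param pca A [shape_pca()].
#' @param weighting `"eigenvalue"` (default) or `"unit"`.
#' @return Fraction in \[0, 1\].
#' @export
total_r2 <- function(X, pca, weighting = c("eigenvalue", "unit")) {
  weighting <- match.arg(weighting)
  X <- as.matrix(X)
  if (nrow(X) != nrow(pca$scores)) stop("X rows must match PCA scores")
  if (ncol(X) >= nrow(X)) stop("need q < n predictors")
  if (any(apply(X, 2L, stats::sd) == 0)) stop("zero-variance predictor")
  r2 <- r2_components(X, pca$scores)
  if (weighting == "eigenvalue")
    sum(pca$eigenvalues * r2) / sum(pca$eigenvalues)
  else mean(r2)
}

#' Permutation test of shape variance explained
#'
#' Builds a null distribution for [total_r2()] by breaking the pairing
#' between predictors and shapes `B` times and recomputing the statistic.
#' The default scheme permutes the rows of the predictor block jointly
#' (exchangeable under the global null); `"freedman_lane"` permutes the
#' response residuals from a nuisance model (intercept-only by default,
#' where the two schemes coincide in distribution). The p-value uses the
#' add-one rule, so it is bounded below by `1/(B + 1)`.
#'
#' @param X Predictor matrix `n x q`.
#' @param pca A [shape_pca()].
#' @param B Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param weighting Passed to [total_r2()].
#' @param scheme `"rows"` (default) or `"freedman_lane"`.
#' @param nuisance Optional nuisance design for the Freedman-Lane scheme.
#' @param keep_null Retain the null statistics (default FALSE).
#' @return Object of class `perm_test`: `r2_observed`, `p_value`, `B`,
#'   `seed`, `scheme`, optionally `r2_null`.
#' @export
permutation_test <- function(X, pca, B = 10000L, seed = 1L,
                             weighting = c("eigenvalue", "unit"),
                             scheme = c("rows", "freedman_lane"),
                             nuisance = NULL, keep_null = FALSE) {
  weighting <- match.arg(weighting)
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  n <- nrow(X)
  if (B < 1L) stop("B must be >= 1")
  if (n < 5L) warning("n < 5: permutation null resolution is poor")
  w <- if (weighting == "eigenvalue")
    pca$eigenvalues / sum(pca$eigenvalues) else
      rep(1 / length(pca$eigenvalues), length(pca$eigenvalues))
  obs <- sum(w * r2_components(X, pca$scores))

  scores <- pca$scores
  if (scheme == "freedman_lane") {
    Z <- if (is.null(nuisance)) matrix(1, n, 1L) else
      cbind(1, as.matrix(nuisance))
    qz <- qr(Z)
    fitted_z <- qr.fitted(qz, scores)
    resid_z <- scores - fitted_z
  }

  set.seed(seed)
  null <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n)
    if (scheme == "rows") {
      null[b] <- sum(w * r2_components(X[idx, , drop = FALSE], scores))
    } else {
      ystar <- fitted_z + resid_z[idx, , drop = FALSE]
      null[b] <- sum(w * r2_components(X, ystar))
    }
  }
  p <- (1 + sum(null >= obs)) / (B + 1)
  structure(list(r2_observed = obs, p_value = p, B = B, seed = seed,
                 scheme = scheme, weighting = weighting,
                 r2_null = if (keep_null) null else NULL),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s, %s weighting): R^2 = %.4f, p = %.4g (B = %d)\n",
    x$scheme, x$weighting, x$r2_observed, x$p_value, x$B))
  invisible(x)
}

#' Permutation tests across regional groups and predictor sets
#'
#' Re-runs the shape PCA and permutation test within each group of regions
#' (e.g. all regions, each region alone, each pair), for each genetic PC
#' individually and optionally for a joint set — producing the familiar
#' PCs-by-groups p-value table.
#'
#' @param pcs `n x K` genetic PC score matrix.
#' @param shapes `n x L x 3` array or `corrected_cohort`.
#' @param labels Factor of region labels, length n.
#' @param groups Named list of character vectors of region labels; defaults
#'   to all regions combined, every pair, and every single region.
#' @param pc_list Integer vector of PCs to test individually (default
#'   `1:min(20, K)`).
#' @param combined Integer vector of PCs tested jointly as one set, or NULL.
#' @param B,seed,var_threshold,weighting Passed through to the test.
#' @return Data frame of class `subgroup_tests` with columns `group`,
#'   `predictors`, `n`, `m_retained`, `r2`, `p`.
#' @export
subgroup_tests <- function(pcs, shapes, labels, groups = NULL,
                           pc_list = NULL, combined = NULL, B = 10000L,
                           seed = 1L, var_threshold = 0.96,
                           weighting = "eigenvalue") {
  if (inherits(shapes, "corrected_cohort")) shapes <- shapes$shapes
  labels <- as.factor(labels)
  pcs <- as.matrix(pcs)
  if (is.null(pc_list)) pc_list <- seq_len(min(20L, ncol(pcs)))
  if (is.null(groups)) {
    regs <- levels(labels)
    groups <- list(ALL = regs)
    if (length(regs) > 2L) {
      prs <- utils::combn(regs, 2L, simplify = FALSE)
      for (p in prs) groups[[paste(p, collapse = "-")]] <- p
    }
    for (r in regs) groups[[r]] <- r
  }
  rows <- list()
  for (g in names(groups)) {
    keep <- labels %in% groups[[g]]
    n_g <- sum(keep)
    sets <- c(as.list(pc_list),
              if (!is.null(combined)) list(combined))
    if (n_g < 5L) {
      for (s in sets)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, predictors = paste0("PC", paste(s, collapse = "+")),
          n = n_g, m_retained = NA_integer_, r2 = NA_real_, p = NA_real_)
      next
    }
    pca_g <- shape_pca(shapes[keep, , , drop = FALSE], var_threshold)
    for (s in sets) {
      pt <- permutation_test(pcs[keep, s, drop = FALSE], pca_g, B = B,
                             seed = derive_seed(seed, length(rows) + 1L),
                             weighting = weighting)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, predictors = paste0("PC", paste(s, collapse = "+")),
        n = n_g, m_retained = pca_g$m_retained, r2 = pt$r2_observed,
        p = pt$p_value)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("subgroup_tests", "data.frame")
  out
}

#' Reshape subgroup test results to a PCs-by-groups p-value table
#'
#' @param x A `subgroup_tests` data frame.
#' @return Data frame, rows = predictor sets, columns = groups, entries = p.
#' @export
pvalue_table <- function(x) {
  stats::reshape(x[, c("group", "predictors", "p")], direction = "wide",
                 idvar = "predictors", timevar = "group")
}
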