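# Regional consensus faces: per-region mean configurations of the
# covariate-corrected, Procrustes-aligned cohort, and the consensus-based
# ancestry correction (indicator or admixture-weighted) built on them.
# A consensus face describes a population, not an individual, so a store can
# be shared across research groups.

#' Build regional consensus faces
#'
#' Runs a generalized Procrustes alignment over the full covariate-corrected
#' cohort (a shared frame is required for subtraction), then averages the
#' member configurations of each region. The grand mean of the aligned
#' cohort is stored as the reference average face.
#'
#' @param corrected A `corrected_cohort` or `n x L x 3` array (covariates
#'   removed, ancestry not).
#' @param labels Factor of region labels, length n.
#' @param align Re-run GPA over the corrected cohort first (default TRUE).
#' @param min_members Advisory minimum per region (default 30, the size at
#'   which facial averages become robust); smaller regions trigger a warning.
#' @return Object of class `consensus_store`: `faces` (named list of
#'   `L x 3`), `n_members` (named), `grand_mean` (`L x 3`), `aligned`
#'   (`n x L x 3` cohort used for averaging).
#' @export
build_consensus <- function(corrected, labels, align = TRUE,
                            min_members = 30L) {
  shapes <- if (inherits(corrected, "corrected_cohort")) corrected$shapes
            else corrected
  labels <- as.factor(labels)
  if (dim(shapes)[1L] != length(labels))
    stop("labels length must match cohort size")
  counts <- table(labels)
  if (any(counts < 2L))
    stop("region '", names(counts)[counts < 2L][1L],
         "' has fewer than 2 members")
  if (any(counts < min_members))
    warning("regions below the advisory minimum of ", min_members,
            " members: ",
            paste(names(counts)[counts < min_members], collapse = ", "))
  if (align) shapes <- gpa(shapes)$shapes
  m <- shapes_to_matrix(shapes)
  faces <- lapply(levels(labels), function(r)
    matrix_to_shapes(colMeans(m[labels == r, , drop = FALSE]))[1L, , ])
  names(faces) <- levels(labels)
  structure(list(faces = faces, n_members = as.vector(counts),
                 regions = levels(labels),
                 grand_mean = matrix_to_shapes(colMeans(m))[1L, , ],
                 aligned = shapes),
            class = "consensus_store")
}

#' @export
print.consensus_store <- function(x, ...) {
  cat("Consensus store:", length(x$faces), "regional faces (",
      paste(sprintf("%s: n=%d", x$regions, x$n_members), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Consensus-face ancestry correction of one configuration
#'
#' Subtracts the individual's regional consensus face and adds back the
#' average face, leaving within-region variation untouched while removing
#' the regional (phenotypic ancestry) component.
#'
#' @param face `L x 3` configuration, in the store's aligned frame.
#' @param region Region label.
#' @param store A `consensus_store`.
#' @return `L x 3` corrected configuration.
#' @export
consensus_correct <- function(face, region, store) {
  if (!region %in% names(store$faces))
    stop("unknown region '", region, "'")
  face - store$faces[[region]] + store$grand_mean
}

#' Admixture-weighted consensus correction
#'
#' Subtracts the admixture-weighted blend of regional consensus faces
#' instead of a single region's face, so admixed individuals are corrected
#' towards their own mixture of ancestries. Reduces exactly to
#' [consensus_correct()] when `q_row` is an indicator.
#'
#' @param face `L x 3` configuration.
#' @param q_row Named or ordered admixture weights, one per stored region,
#'   summing to 1.
#' @param store A `consensus_store`.
#' @return `L x 3` corrected configuration.
#' @export
weighted_consensus_correct <- function(face, q_row, store) {
  R <- length(store$faces)
  if (length(q_row) != R)
    stop("expected ", R, " weights, got ", length(q_row))
  if (abs(sum(q_row) - 1) > 1e-6)
    stop("weights must sum to 1 (got ", format(sum(q_row)), ")")
  if (!is.null(names(q_row))) q_row <- q_row[names(store$faces)]
  blend <- 0
  for (r in seq_len(R)) blend <- blend + q_row[[r]] * store$faces[[r]]
  face - blend + store$grand_mean
}

#' Apply consensus correction to a whole cohort
#'
#' @param store A `consensus_store` (its `aligned` cohort is corrected).
#' @param labels Factor of region labels (indicator mode).
#' @param q Optional `n x R` admixture matrix; when given, the weighted
#'   correction is used instead of the per-region indicator.
#' @return `n x L x 3` array of consensus-corrected configurations.
#' @export
consensus_correct_cohort <- function(store, labels = NULL, q = NULL) {
  shapes <- store$aligned
  n <- dim(shapes)[1L]
  out <- shapes
  if (is.null(q)) {
    labels <- as.factor(labels)
    if (length(labels) != n) stop("labels length must match cohort")
    for (i in seq_len(n))
      out[i, , ] <- consensus_correct(config_at(shapes, i),
                                      as.character(labels[i]), store)
  } else {
    if (nrow(q) != n) stop("q rows must match cohort")
    for (i in seq_len(n))
      out[i, , ] <- weighted_consensus_correct(config_at(shapes, i),
                                               q[i, ], store)
  }
  out
}

#' Re-test genetic PCs after consensus correction
#'
#' Applies the consensus correction to the cohort and re-runs the per-PC
#' permutation tests, reporting p-values before and after side by side —
#' the check of whether regional genetic PCs still explain facial variation
#' once phenotypic ancestry has been removed.
#'
#' @param corrected A `corrected_cohort` (covariates removed).
#' @param pcs `n x K` genetic PC scores.
#' @param labels Region labels.
#' @param q Optional admixture matrix for weighted correction.
#' @param pc_list PCs to test (default 1..min(20, K)).
#' @param B,seed,var_threshold Permutation-test settings.
#' @return Data frame with columns `predictors`, `p_before`, `p_after`,
#'   `r2_before`, `r2_after`; the consensus-corrected cohort is attached as
#'   attribute `"corrected_shapes"`.
#' @export
retest_after_consensus <- function(corrected, pcs, labels, q = NULL,
                                   pc_list = NULL, B = 10000L, seed = 1L,
                                   var_threshold = 0.96) {
  pcs <- as.matrix(pcs)
  if (is.null(pc_list)) pc_list <- seq_len(min(20L, ncol(pcs)))
  store <- build_consensus(corrected, labels)
  after_shapes <- consensus_correct_cohort(store, labels = labels, q = q)
  grp <- list(ALL = levels(as.factor(labels)))
  before <- subgroup_tests(pcs, store$aligned, labels, groups = grp,
                           pc_list = pc_list, B = B, seed = seed,
                           var_threshold = var_threshold)
  after <- subgroup_tests(pcs, after_shapes, labels, groups = grp,
                          pc_list = pc_list, B = B, seed = seed,
                          var_threshold = var_threshold)
  out <- data.frame(predictors = before$predictors,
                    p_before = before$p, p_after = after$p,
                    r2_before = before$r2, r2_after = after$r2)
  attr(out, "corrected_shapes") <- after_shapes
  attr(out, "store") <- store
  out
}
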