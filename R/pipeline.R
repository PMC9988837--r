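# End-to-end drivers: the genetic-PC route (select -> symmetrize -> GPA ->
# covariate correction -> ancestry correction -> permutation tables ->
# effect maps) and the consensus route (covariate-corrected cohort ->
# consensus store -> consensus correction -> re-test -> method comparison).
# Both routes share the covariate-corrected cohort and are deterministic
# given the configured seed.

#' Pipeline configuration
#'
#' Collects the protocol constants of the analysis in one validated object:
#' 4 ancestry PCs for correction, 20 PCs for the visualization base face,
#' a 96% shape-PCA variance threshold, 10,000 permutations, 186 individuals
#' per region, and 4x / 8x exaggeration for regional and single-PC effect
#' exports. Scaled-down runs override the relevant fields.
#'
#' @param k_ancestry_pcs PCs used for ancestry correction (default 4).
#' @param k_visual_pcs PCs removed for the visualization base face
#'   (default 20).
#' @param var_threshold Shape-PCA retained-variance fraction (default 0.96).
#' @param B Permutations (default 10000).
#' @param n_per_region Regional subsample size (default 186).
#' @param exaggeration Named list `regional` (default 4) and `single_pc`
#'   (default 8).
#' @param pc_list PCs tested individually (default 1:20, capped at K).
#' @param seed Integer seed.
#' @param output_dir Optional directory for exported artifacts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(k_ancestry_pcs = 4L, k_visual_pcs = 20L,
                            var_threshold = 0.96, B = 10000L,
                            n_per_region = 186L,
                            exaggeration = list(regional = 4, single_pc = 8),
                            pc_list = NULL, seed = 1L, output_dir = NULL) {
  if (k_ancestry_pcs > k_visual_pcs)
    stop("k_ancestry_pcs must not exceed k_visual_pcs")
  structure(list(k_ancestry_pcs = as.integer(k_ancestry_pcs),
                 k_visual_pcs = as.integer(k_visual_pcs),
                 var_threshold = var_threshold, B = as.integer(B),
                 n_per_region = as.integer(n_per_region),
                 exaggeration = exaggeration, pc_list = pc_list,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

# Shared front end of both routes: regional selection, symmetrization, GPA,
# covariate correction.
prepare_cohort <- function(cohort, cfg) {
  if (cfg$k_visual_pcs > ncol(cohort$pcs))
    stop("k_visual_pcs exceeds available genetic PCs")
  asg <- assign_max_region(cohort$q)
  asg <- median_threshold_filter(asg)
  asg <- balanced_subsample(asg, n_target = cfg$n_per_region,
                            seed = cfg$seed)
  keep <- which(asg$selected)
  cohort <- subset_cohort(cohort, keep)
  labels <- droplevels(asg$region[keep])

  sym <- symmetrize_cohort(cohort$shapes, cohort$template)
  fit <- gpa(sym)
  X <- covariate_design(cohort$covariates,
                        centroid_sizes = fit$centroid_sizes)
  corrected <- correct_shapes(fit, X)
  list(cohort = cohort, labels = labels, assignment = asg, gpa = fit,
       corrected = corrected)
}

#' Run the genetic-PC analysis route
#'
#' Full protocol on one cohort: regional selection from admixture
#' proportions, symmetrization, Procrustes superimposition, PLSR covariate
#' correction, ancestry correction with the leading genetic PCs,
#' permutation-test tables across regional groupings, and per-landmark
#' effect maps (maximum ancestry shift, per-region normal displacement).
#'
#' @param cohort A `synthetic_cohort` (or compatible list with `shapes`,
#'   `covariates`, `pcs`, `q`, `template`).
#' @param cfg A [pipeline_config()].
#' @return List of class `pc_route_report`: `prep` (shared intermediates),
#'   `ancestry` (the [ancestry_correct()] result), `perm_table`
#'   (subgroup tests), `max_shift`, `regional_maps`, `base_face`,
#'   `manifest` (files written, if `output_dir` set).
#' @export
run_genetic_pc_route <- function(cohort, cfg = pipeline_config()) {
  prep <- prepare_cohort(cohort, cfg)
  pcs <- prep$cohort$pcs
  pc_list <- cfg$pc_list
  if (is.null(pc_list)) pc_list <- seq_len(min(20L, ncol(pcs)))

  anc <- ancestry_correct(prep$corrected, pcs, k = cfg$k_ancestry_pcs,
                          labels = prep$labels)
  perm_table <- subgroup_tests(pcs, prep$corrected, prep$labels,
                               pc_list = pc_list,
                               combined = seq_len(cfg$k_ancestry_pcs),
                               B = cfg$B, seed = cfg$seed,
                               var_threshold = cfg$var_threshold)
  max_shift <- max_ancestry_shift(prep$corrected$shapes,
                                  anc$corrected$shapes)

  # visualization base face: cohort mean after also removing the first
  # k_visual_pcs genetic PCs
  vis <- ancestry_correct(prep$corrected, pcs, k = cfg$k_visual_pcs)
  base_face <- matrix_to_shapes(
    colMeans(shapes_to_matrix(vis$corrected$shapes)))[1L, , ]

  normals <- vertex_normals(base_face, prep$cohort$template$triangles)
  regional_maps <- lapply(levels(prep$labels), function(r) {
    eff <- matrix(anc$effect$per_region[r, , ], ncol = 3L)
    face_r <- exaggerate(base_face, eff, cfg$exaggeration$regional)
    list(effect = eff,
         exaggerated_face = face_r,
         normal_displacement = normal_displacement(base_face,
                                                   base_face + eff, normals))
  })
  names(regional_maps) <- levels(prep$labels)

  manifest <- character(0)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(perm_table,
                     file.path(cfg$output_dir, "perm_table.csv"),
                     row.names = FALSE)
    write_scalar_map(prep$cohort$template, max_shift,
                     file.path(cfg$output_dir, "max_ancestry_shift"))
    for (r in names(regional_maps))
      write_scalar_map(prep$cohort$template,
                       regional_maps[[r]]$normal_displacement,
                       file.path(cfg$output_dir,
                                 paste0("displacement_", r)))
    manifest <- list.files(cfg$output_dir, full.names = TRUE)
  }

  structure(list(prep = prep, ancestry = anc, perm_table = perm_table,
                 max_shift = max_shift, regional_maps = regional_maps,
                 base_face = base_face, config = cfg, manifest = manifest),
            class = "pc_route_report")
}

#' Run the consensus-correction analysis route
#'
#' Consensus protocol on the same covariate-corrected cohort as the
#' genetic-PC route: builds regional consensus faces, applies the
#' (optionally admixture-weighted) consensus correction, re-tests the
#' genetic PCs, and compares the consensus-derived regional faces with the
#' genetic-PC-derived ones via displacement and angle maps.
#'
#' @param cohort A `synthetic_cohort`.
#' @param cfg A [pipeline_config()].
#' @param weighted Use admixture-weighted consensus correction (default
#'   FALSE: indicator correction by assigned region).
#' @param pc_report Optional `pc_route_report` computed on the same cohort
#'   and config; when supplied its intermediates are reused so both routes
#'   share the identical covariate-corrected cohort.
#' @return List of class `consensus_route_report`: `store`, `retest`
#'   (before/after p-values), `comparison` (per-region displacement/angle
#'   maps vs the PC route), `manifest`.
#' @export
run_consensus_route <- function(cohort, cfg = pipeline_config(),
                                weighted = FALSE, pc_report = NULL) {
  if (is.null(pc_report)) pc_report <- run_genetic_pc_route(cohort, cfg)
  prep <- pc_report$prep
  pcs <- prep$cohort$pcs
  pc_list <- cfg$pc_list
  if (is.null(pc_list)) pc_list <- seq_len(min(20L, ncol(pcs)))

  retest <- retest_after_consensus(prep$corrected, pcs, prep$labels,
                                   q = if (weighted) prep$cohort$q else NULL,
                                   pc_list = pc_list, B = cfg$B,
                                   seed = cfg$seed,
                                   var_threshold = cfg$var_threshold)
  store <- attr(retest, "store")

  pc_faces <- lapply(names(pc_report$regional_maps), function(r)
    pc_report$base_face + pc_report$regional_maps[[r]]$effect)
  names(pc_faces) <- names(pc_report$regional_maps)
  cons_faces <- lapply(store$regions, function(r)
    pc_report$base_face + (store$faces[[r]] - store$grand_mean))
  names(cons_faces) <- store$regions
  comparison <- compare_correction_methods(pc_faces, cons_faces,
                                           pc_report$base_face,
                                           prep$cohort$template$triangles)

  manifest <- character(0)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(retest),
                     file.path(cfg$output_dir, "consensus_retest.csv"),
                     row.names = FALSE)
    for (r in names(comparison))
      write_scalar_map(prep$cohort$template,
                       comparison[[r]]$normal_displacement,
                       file.path(cfg$output_dir,
                                 paste0("method_comparison_", r)))
    manifest <- list.files(cfg$output_dir, full.names = TRUE)
  }

  structure(list(store = store, retest = retest, comparison = comparison,
                 pc_report = pc_report, config = cfg, manifest = manifest),
            class = "consensus_route_report")
}
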