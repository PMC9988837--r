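# Synthetic cohort generator. Emulates the statistical structure of a
# multi-region facial cohort: regional mean-shape deformations, linear
# covariate effects, genetic PC scores whose leading axes track region,
# Dirichlet admixture proportions concentrated on the true region, and
# landmark-level Gaussian noise. Ground truth is stored so downstream
# recovery can be tested exactly.

#' Default per-region mean loadings of the leading genetic PCs
#'
#' Rows are PCs, columns regions (North, South, East, West). PC1 contrasts
#' South against North/West, PC2 is an East-West gradient, PC3 a weak
#' North-West contrast, PC4 carries no regional signal — the qualitative
#' structure of leading genetic ancestry PCs within Europe.
#'
#' @return 4 x 4 numeric matrix.
#' @export
default_pc_loadings <- function() {
  m <- rbind(
    PC1 = c(North = -1, South = 2, East = 0, West = -1),
    PC2 = c(North = 0, South = 0, East = 2, West = -2),
    PC3 = c(North = 1, South = 0, East = 0, West = -1),
    PC4 = c(North = 0, South = 0, East = 0, West = 0)
  )
  m
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of the generator. Defaults describe the
#' emulated study conditions: four regional subpopulations, 186 individuals
#' per region, face-scale template units, smooth localized regional
#' deformations, and 20 genetic PCs of which the first three carry regional
#' signal.
#'
#' @param n_per_region Individuals per region (default 186).
#' @param regions Ordered region labels.
#' @param region_effect_scale Peak amplitude of the regional deformation
#'   fields, template units (default 2).
#' @param covariate_effects Named numeric vector of per-covariate field
#'   amplitudes in template units per unit predictor; names among
#'   `sex, age, height, weight, camera`.
#' @param n_shape_modes Number of smooth individual-variation modes.
#' @param mode_scale Amplitude of individual-variation modes, template units.
#' @param noise_sd Landmark-level Gaussian noise SD, template units.
#' @param pc_region_loadings `K0 x R` matrix of mean PC score per region
#'   (at least 4 rows); defaults to [default_pc_loadings()].
#' @param n_pcs Total number of genetic PCs generated (default 20); PCs
#'   beyond `nrow(pc_region_loadings)` are pure standard normal noise.
#' @param dirichlet_concentration Dirichlet mass on the true region (default
#'   12; off-region components get mass 1).
#' @param seed Integer seed driving the hierarchical random stream.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_region = 186L,
                          regions = c("North", "South", "East", "West"),
                          region_effect_scale = 2,
                          covariate_effects = c(sex = 0.8, age = 0.02,
                                                height = 0.03, weight = 0.02,
                                                camera = 0.2),
                          n_shape_modes = 5L,
                          mode_scale = 0.6,
                          noise_sd = 0.5,
                          pc_region_loadings = NULL,
                          n_pcs = 20L,
                          dirichlet_concentration = 12,
                          seed = 1L) {
  if (is.null(pc_region_loadings)) {
    pc_region_loadings <- default_pc_loadings()
    colnames(pc_region_loadings) <- regions
  }
  pc_region_loadings <- as.matrix(pc_region_loadings)
  if (nrow(pc_region_loadings) < 4L)
    stop("pc_region_loadings must have at least 4 PC rows")
  if (ncol(pc_region_loadings) != length(regions))
    stop("pc_region_loadings must have one column per region")
  if (n_per_region < 2L) stop("n_per_region must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (dirichlet_concentration <= 0) stop("dirichlet_concentration must be > 0")
  if (n_pcs < nrow(pc_region_loadings))
    stop("n_pcs must be >= nrow(pc_region_loadings)")
  structure(list(n_per_region = as.integer(n_per_region), regions = regions,
                 region_effect_scale = region_effect_scale,
                 covariate_effects = covariate_effects,
                 n_shape_modes = as.integer(n_shape_modes),
                 mode_scale = mode_scale, noise_sd = noise_sd,
                 pc_region_loadings = pc_region_loadings,
                 n_pcs = as.integer(n_pcs),
                 dirichlet_concentration = dirichlet_concentration,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Smooth Gaussian-bump displacement field on the template surface,
# symmetrized so injected effects survive bilateral symmetrization.
# Normalized to unit peak displacement magnitude before scaling.
smooth_field <- function(template, n_bumps = 3L) {
  coords <- template$coordinates
  L <- nrow(coords)
  width <- template$extent / 4
  field <- matrix(0, L, 3L)
  centers <- sample.int(L, n_bumps, replace = TRUE)
  for (b in seq_len(n_bumps)) {
    dir <- stats::rnorm(3L)
    dir <- dir / sqrt(sum(dir^2))
    d2 <- rowSums((coords - matrix(coords[centers[b], ], L, 3L,
                                   byrow = TRUE))^2)
    field <- field + exp(-d2 / (2 * width^2)) %o% dir
  }
  # make bilaterally symmetric: average with reflected-and-paired copy
  refl <- field
  refl[, 1L] <- -refl[, 1L]
  field <- (field + refl[template$pairing, , drop = FALSE]) / 2
  peak <- max(sqrt(rowSums(field^2)))
  if (peak > 0) field <- field / peak
  field
}

#' Generate a synthetic landmark cohort with known ground truth
#'
#' Each individual's configuration is
#' `template + region deformation + sum of covariate effects + individual
#' low-rank modes + landmark noise`. Genetic PC scores are the region's mean
#' loading plus unit Gaussian noise; admixture rows are Dirichlet with the
#' configured mass on the true region. A hierarchical seed stream (one
#' substream per individual) makes the cohort reproducible and stable under
#' subsetting.
#'
#' @param cfg A [cohort_config()].
#' @param template A [make_template()] template.
#' @return Object of class `synthetic_cohort`: list with `shapes`
#'   (`n x L x 3` array, ids in rownames), `covariates` (data.frame with
#'   `id, sex, age, age_squared, height, weight, camera`), `pcs` (`n x K`),
#'   `q` (`n x R`), `true_region` (factor), `true_region_effect`
#'   (`R x L x 3`), `true_covariate_effects` (named list of `L x 3`),
#'   `template`, `config`.
#' @export
generate_cohort <- function(cfg, template) {
  stopifnot(inherits(cfg, "cohort_config"), inherits(template, "face_template"))
  L <- nrow(template$coordinates)
  if (cfg$n_shape_modes > 3L * L)
    stop("n_shape_modes exceeds 3L: degenerate covariance")
  R <- length(cfg$regions)
  n <- cfg$n_per_region * R
  K0 <- nrow(cfg$pc_region_loadings)

  # --- structural draws (fields), under the global seed -------------------
  set.seed(cfg$seed)
  # regional deformations are pure shape changes: project out the
  # similarity-transform components (the emulated study's regional groups
  # did not differ in centroid size or pose, only in shape), renormalize to
  # unit peak, then center across regions so the grand mean is the template
  raw <- lapply(seq_len(R), function(r) {
    f <- tangent_projection(smooth_field(template), template$coordinates)
    peak <- max(sqrt(rowSums(f^2)))
    if (peak > 0) f <- f / peak
    f
  })
  mean_field <- Reduce(`+`, raw) / R
  region_effect <- array(0, dim = c(R, L, 3L),
                         dimnames = list(cfg$regions, NULL, c("x", "y", "z")))
  for (r in seq_len(R))
    region_effect[r, , ] <- (raw[[r]] - mean_field) * cfg$region_effect_scale

  cov_names <- names(cfg$covariate_effects)
  cov_fields <- lapply(cov_names, function(nm)
    smooth_field(template) * cfg$covariate_effects[[nm]])
  names(cov_fields) <- cov_names

  mode_fields <- lapply(seq_len(cfg$n_shape_modes), function(m)
    smooth_field(template) * cfg$mode_scale)

  # --- per-individual substreams ------------------------------------------
  true_region <- factor(rep(cfg$regions, each = cfg$n_per_region),
                        levels = cfg$regions)
  ids <- sprintf("id%04d", seq_len(n))
  shapes <- array(NA_real_, dim = c(n, L, 3L),
                  dimnames = list(ids, NULL, c("x", "y", "z")))
  covariates <- data.frame(id = ids, sex = NA_real_, age = NA_real_,
                           age_squared = NA_real_, height = NA_real_,
                           weight = NA_real_, camera = NA_real_,
                           stringsAsFactors = FALSE)
  pcs <- matrix(NA_real_, n, cfg$n_pcs,
                dimnames = list(ids, paste0("PC", seq_len(cfg$n_pcs))))
  q <- matrix(NA_real_, n, R, dimnames = list(ids, cfg$regions))

  for (i in seq_len(n)) {
    set.seed(derive_seed(cfg$seed, i))
    r <- as.integer(true_region[i])
    sex <- sample(c(-1, 1), 1L)
    age <- stats::runif(1L, 18, 65)
    height <- stats::rnorm(1L, 170, 10)
    weight <- stats::rnorm(1L, 75, 15)
    camera <- sample(c(-1, 1), 1L)
    covariates[i, -1L] <- c(sex, age, age^2, height, weight, camera)

    config <- template$coordinates + region_effect[r, , ]
    # centered covariate contributions so the grand mean stays near template
    config <- config + cov_fields$sex * sex +
      cov_fields$age * (age - 41.5) +
      cov_fields$height * (height - 170) +
      cov_fields$weight * (weight - 75) +
      cov_fields$camera * camera
    if (cfg$n_shape_modes > 0L) {
      mscore <- stats::rnorm(cfg$n_shape_modes)
      for (m in seq_len(cfg$n_shape_modes))
        config <- config + mode_fields[[m]] * mscore[m]
    }
    if (cfg$noise_sd > 0)
      config <- config + matrix(stats::rnorm(3L * L, sd = cfg$noise_sd), L, 3L)
    shapes[i, , ] <- config

    load <- c(cfg$pc_region_loadings[, r], rep(0, cfg$n_pcs - K0))
    pcs[i, ] <- load + stats::rnorm(cfg$n_pcs)

    alpha <- rep(1, R)
    alpha[r] <- cfg$dirichlet_concentration
    g <- stats::rgamma(R, shape = alpha)
    q[i, ] <- g / sum(g)
  }

  structure(list(shapes = shapes, covariates = covariates, pcs = pcs, q = q,
                 true_region = true_region, true_region_effect = region_effect,
                 true_covariate_effects = cov_fields, template = template,
                 config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic landmark cohort\n")
  cat("  individuals :", dim(x$shapes)[1L], "(",
      paste(levels(x$true_region), collapse = ", "), ")\n")
  cat("  landmarks   :", dim(x$shapes)[2L], "\n")
  cat("  genetic PCs :", ncol(x$pcs), "\n")
  cat("  noise SD    :", x$config$noise_sd, "template units\n")
  invisible(x)
}

#' Ground-truth regional deformation field
#'
#' Accessor for the deformation field injected for one region. The fields sum
#' to zero across regions, so the cohort grand mean equals the template.
#'
#' @param cohort A `synthetic_cohort`.
#' @param region Region label.
#' @return `L x 3` displacement field.
#' @export
true_effect_map <- function(cohort, region) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!region %in% dimnames(cohort$true_region_effect)[[1L]])
    stop("unknown region '", region, "'")
  matrix(cohort$true_region_effect[region, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Subset a synthetic cohort by individual
#'
#' Keeps all per-individual components aligned. Because each individual has
#' its own seed substream, a subset's shapes are identical to the same rows of
#' the full cohort.
#'
#' @param cohort A `synthetic_cohort`.
#' @param keep Integer or logical index over individuals.
#' @return A `synthetic_cohort` restricted to `keep`.
#' @export
subset_cohort <- function(cohort, keep) {
  cohort$shapes <- cohort$shapes[keep, , , drop = FALSE]
  cohort$covariates <- cohort$covariates[keep, , drop = FALSE]
  cohort$pcs <- cohort$pcs[keep, , drop = FALSE]
  cohort$q <- cohort$q[keep, , drop = FALSE]
  cohort$true_region <- cohort$true_region[keep]
  cohort
}
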