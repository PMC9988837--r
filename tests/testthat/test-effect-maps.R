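flat_grid <- function() {
  tpl <- test_template()
  face <- tpl$coordinates
  face[, 3L] <- 0
  list(face = face, tri = tpl$triangles)
}

test_that("vertex normals: flat grid, winding flip, isolated vertices", {
  fg <- flat_grid()
  nrm <- vertex_normals(fg$face, fg$tri)
  expect_lt(max(abs(sweep(nrm, 2L, c(0, 0, 1)))), 1e-12)
  flipped <- vertex_normals(fg$face, fg$tri[, c(1L, 3L, 2L)])
  expect_equal(flipped, -nrm, tolerance = 1e-12)
  expect_error(vertex_normals(fg$face, fg$tri[-(1:2), ]),
               "isolated vertex")
})

test_that("vertex normals align with radial directions on a sphere patch", {
  # spherical cap parameterized on a grid, radius 1
  nth <- 25L; nph <- 25L
  th <- seq(0.35 * pi, 0.65 * pi, length.out = nth)   # polar
  ph <- seq(0.35 * pi, 0.65 * pi, length.out = nph)   # azimuth
  g <- expand.grid(th = th, ph = ph)
  face <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  idx <- function(r, c) (c - 1L) * nth + r
  tris <- list()
  for (c in seq_len(nph - 1L)) for (r in seq_len(nth - 1L)) {
    tris[[length(tris) + 1L]] <- c(idx(r, c), idx(r, c + 1L),
                                   idx(r + 1L, c + 1L))
    tris[[length(tris) + 1L]] <- c(idx(r, c), idx(r + 1L, c + 1L),
                                   idx(r + 1L, c))
  }
  tri <- do.call(rbind, tris)
  nrm <- vertex_normals(face, tri)
  # fix overall orientation, then compare with the analytic radial normal
  if (sum(nrm * face) < 0) nrm <- -nrm
  cosang <- pmin(1, pmax(-1, rowSums(nrm * face)))
  expect_lt(max(acos(abs(cosang)) * 180 / pi), 5)
})

test_that("normal displacement is the signed normal component", {
  fg <- flat_grid()
  nrm <- vertex_normals(fg$face, fg$tri)
  lifted <- fg$face
  lifted[, 3L] <- lifted[, 3L] + 0.3
  expect_equal(normal_displacement(fg$face, lifted, nrm), rep(0.3, 100L),
               tolerance = 1e-12)
  expect_equal(normal_displacement(fg$face, fg$face, nrm), rep(0, 100L))
  # purely tangential shifts are invisible to the map
  tangent <- fg$face
  tangent[, 1L] <- tangent[, 1L] + 1.7
  expect_equal(normal_displacement(fg$face, tangent, nrm), rep(0, 100L),
               tolerance = 1e-12)
  expect_error(normal_displacement(fg$face, lifted, nrm * 2), "unit length")
  # linearity in the displacement
  set.seed(1)
  d1 <- matrix(rnorm(300), 100L); d2 <- matrix(rnorm(300), 100L)
  expect_equal(normal_displacement(fg$face, fg$face + d1 + d2, nrm),
               normal_displacement(fg$face, fg$face + d1, nrm) +
                 normal_displacement(fg$face, fg$face + d2, nrm),
               tolerance = 1e-10)
  expect_true(all(abs(normal_displacement(fg$face, fg$face + d1, nrm)) <=
                    sqrt(rowSums(d1^2)) + 1e-12))
})

test_that("angle differences satisfy the canonical identities", {
  a <- rbind(c(1, 0, 0), c(1, 1, 0), c(0, 0, 2))
  expect_equal(angle_difference(a, a), rep(0, 3L), tolerance = 1e-5)
  expect_equal(angle_difference(a, -a), rep(180, 3L), tolerance = 1e-5)
  b <- rbind(c(0, 1, 0), c(1, -1, 0), c(3, 0, 0))
  expect_equal(angle_difference(a, b), c(90, 90, 90), tolerance = 1e-8)
  # scale invariance in both arguments
  set.seed(2)
  u <- matrix(rnorm(30), 10L); v <- matrix(rnorm(30), 10L)
  expect_equal(angle_difference(u, v), angle_difference(5 * u, 0.1 * v),
               tolerance = 1e-10)
  # sub-threshold vectors have undefined direction -> 0
  z <- matrix(0, 3L, 3L)
  z[1L, 1L] <- 1e-12
  expect_equal(angle_difference(a, z), rep(0, 3L))
})

test_that("maximum ancestry shift matches the hand example", {
  before <- array(0, c(3L, 5L, 3L))
  after <- before
  after[2L, 4L, ] <- c(3, 4, 0)  # displacement of norm 5
  shift <- max_ancestry_shift(before, after)
  expect_equal(shift, c(0, 0, 0, 5, 0))
  expect_equal(max_ancestry_shift(before, before), rep(0, 5L))
  # permutation invariance over individuals and dominance over the mean
  perm <- c(3L, 1L, 2L)
  expect_equal(max_ancestry_shift(before[perm, , ], after[perm, , ]), shift)
  mean_shift <- colMeans(sqrt(apply((before - after)^2, c(1L, 2L), sum)))
  expect_true(all(shift >= mean_shift - 1e-12))
  expect_error(max_ancestry_shift(before, after[, 1:4, ]), "mismatch")
})

test_that("single-individual max shift equals the mean shift", {
  set.seed(3)
  b <- array(rnorm(1 * 8 * 3), c(1L, 8L, 3L))
  a <- b + array(rnorm(24, sd = 0.2), c(1L, 8L, 3L))
  d <- sqrt(rowSums((matrix(a[1, , ], ncol = 3) -
                       matrix(b[1, , ], ncol = 3))^2))
  expect_equal(max_ancestry_shift(b, a), d)
})

test_that("method comparison maps are zero for identical methods", {
  tpl <- test_template()
  set.seed(4)
  base <- tpl$coordinates
  faces <- list(North = base + matrix(rnorm(300, sd = 0.1), 100L),
                South = base + matrix(rnorm(300, sd = 0.1), 100L))
  cmp <- compare_correction_methods(faces, faces, base, tpl$triangles)
  for (r in names(cmp)) {
    expect_equal(cmp[[r]]$normal_displacement, rep(0, 100L))
    expect_equal(cmp[[r]]$angle_difference, rep(0, 100L), tolerance = 1e-5)
  }
  expect_error(compare_correction_methods(faces, faces["North"], base,
                                          tpl$triangles), "region sets")
})

test_that("methods agree when PCs fully encode regions, disagree when not", {
  tpl <- cached("tpl60", make_template(L = 63, extent = 100))
  run_both <- function(loading_scale, seed) {
    load <- default_pc_loadings() * loading_scale
    colnames(load) <- c("North", "South", "East", "West")
    cfg <- cohort_config(n_per_region = 60L, pc_region_loadings = load,
                         noise_sd = 0.15, mode_scale = 0.15, seed = seed)
    co <- generate_cohort(cfg, tpl)
    fit <- gpa(symmetrize_cohort(co$shapes, tpl))
    cc <- correct_shapes(fit, covariate_design(co$covariates,
                                               fit$centroid_sizes))
    anc <- ancestry_correct(cc, co$pcs, k = 4L, labels = co$true_region)
    store <- build_consensus(cc, co$true_region, align = FALSE,
                             min_members = 10L)
    gm <- store$grand_mean
    out <- list()
    for (r in levels(co$true_region)) {
      pc_eff <- matrix(anc$effect$per_region[r, , ], ncol = 3L)
      cons_eff <- store$faces[[r]] - gm
      out[[r]] <- c(diff_rms = sqrt(mean((pc_eff - cons_eff)^2)),
                    eff_rms = sqrt(mean(cons_eff^2)))
    }
    out
  }
  # PCs fully encode regional structure: per-region maps nearly coincide
  ratios_strong <- unlist(lapply(11:15, function(s) {
    res <- run_both(loading_scale = 8, seed = s)
    vapply(res, function(x) x[["diff_rms"]] / x[["eff_rms"]], numeric(1L))
  }))
  expect_lt(median(ratios_strong), 0.10)
  # regional effect invisible to the PCs: consensus captures what PCs miss
  ratios_null <- unlist(lapply(11:15, function(s) {
    res <- run_both(loading_scale = 0, seed = s)
    vapply(res, function(x) x[["diff_rms"]] / x[["eff_rms"]], numeric(1L))
  }))
  expect_gt(median(ratios_null), 0.5)
})

test_that("effect maps round trip through the scalar-map exporter", {
  tpl <- test_template()
  set.seed(5)
  vals <- rnorm(100L)
  base <- file.path(withr::local_tempdir(), "map")
  paths <- write_scalar_map(tpl, vals, base)
  expect_equal(read_scalar_map(paths[["csv"]]), vals, tolerance = 1e-9)
})
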