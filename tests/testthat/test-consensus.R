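two_per_region_store <- function() {
  # two identical individuals per region, distinct across regions
  tpl <- tiny_template()
  regions <- c("A", "B")
  set.seed(1)
  faces <- list(A = tpl$coordinates + matrix(rnorm(27, sd = 0.05), 9L),
                B = tpl$coordinates + matrix(rnorm(27, sd = 0.05), 9L))
  arr <- array(NA_real_, c(4L, 9L, 3L),
               dimnames = list(c("a1", "a2", "b1", "b2"), NULL, NULL))
  arr[1L, , ] <- faces$A; arr[2L, , ] <- faces$A
  arr[3L, , ] <- faces$B; arr[4L, , ] <- faces$B
  list(shapes = arr, labels = factor(c("A", "A", "B", "B")), faces = faces)
}

test_that("consensus of identical members is the shared shape exactly", {
  fx <- two_per_region_store()
  store <- suppressWarnings(build_consensus(fx$shapes, fx$labels,
                                            align = FALSE))
  expect_equal(store$faces$A, unname(fx$faces$A) * 1, ignore_attr = TRUE)
  expect_equal(store$faces$B, unname(fx$faces$B) * 1, ignore_attr = TRUE)
  expect_equal(store$grand_mean, (store$faces$A + store$faces$B) / 2,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("with no regional effect all consensus faces match the grand mean", {
  tpl <- test_template()
  cfg <- cohort_config(n_per_region = 30L, region_effect_scale = 0,
                       covariate_effects = c(sex = 0, age = 0, height = 0,
                                             weight = 0, camera = 0),
                       n_shape_modes = 0L, noise_sd = 0.4, seed = 13L)
  co <- generate_cohort(cfg, tpl)
  store <- build_consensus(co$shapes, co$true_region, align = FALSE)
  bound <- 3 * 0.4 / sqrt(30)
  for (r in names(store$faces))
    expect_lt(mean(sqrt(rowSums((store$faces[[r]] -
                                   store$grand_mean)^2))), bound)
})

test_that("regional consensus converges to template plus injected effect", {
  tpl <- test_template()
  cfg <- cohort_config(n_per_region = 60L,
                       covariate_effects = c(sex = 0, age = 0, height = 0,
                                             weight = 0, camera = 0),
                       n_shape_modes = 0L, noise_sd = 0.5, seed = 17L)
  co <- generate_cohort(cfg, tpl)
  store <- build_consensus(co$shapes, co$true_region, align = FALSE)
  for (r in levels(co$true_region)) {
    target <- tpl$coordinates + true_effect_map(co, r)
    err <- mean(sqrt(rowSums((store$faces[[r]] - target)^2)))
    expect_lt(err, 3 * 0.5 / sqrt(60))
  }
})

test_that("consensus correction removes between-region means exactly", {
  co <- test_cohort()
  store <- build_consensus(co$shapes, co$true_region, min_members = 10L)
  corrected <- consensus_correct_cohort(store, labels = co$true_region)
  m <- shapes_to_matrix(corrected)
  region_means <- do.call(rbind, lapply(levels(co$true_region), function(r)
    colMeans(m[co$true_region == r, , drop = FALSE])))
  gm <- matrix(shapes_to_matrix(store$grand_mean), nrow = 1L)
  for (i in seq_len(nrow(region_means)))
    expect_lt(max(abs(region_means[i, ] - gm)), 1e-10)
  # a face equal to its consensus corrects to the grand mean exactly
  out <- consensus_correct(store$faces$South, "South", store)
  expect_equal(out, store$grand_mean, tolerance = 1e-15)
  expect_error(consensus_correct(store$faces$South, "Atlantis", store),
               "unknown region")
})

test_that("weighted correction: indicator, uniform and admixed behaviour", {
  co <- test_cohort()
  store <- build_consensus(co$shapes, co$true_region, min_members = 10L)
  face <- matrix(store$aligned[5L, , ], ncol = 3L)
  # indicator weights reproduce the unweighted correction bitwise
  ind <- c(North = 0, South = 1, East = 0, West = 0)
  expect_identical(weighted_consensus_correct(face, ind, store),
                   consensus_correct(face, "South", store))
  # uniform weights with balanced regions: blend equals the grand mean
  unif <- rep(1 / 4, 4L)
  out_u <- weighted_consensus_correct(face, unif, store)
  blend <- Reduce(`+`, store$faces) / 4
  expect_lt(max(abs(blend - store$grand_mean)), 1e-10)
  expect_lt(max(abs(out_u - face)), 1e-10)
  # linearity in q
  qa <- c(0.7, 0.1, 0.1, 0.1); qb <- c(0.1, 0.3, 0.3, 0.3)
  lhs <- weighted_consensus_correct(face, 0.5 * qa + 0.5 * qb, store)
  rhs <- 0.5 * weighted_consensus_correct(face, qa, store) +
    0.5 * weighted_consensus_correct(face, qb, store)
  expect_lt(max(abs(lhs - rhs)), 1e-12)
  expect_error(weighted_consensus_correct(face, c(0.5, 0.5, 0.5, 0.5),
                                          store), "sum to 1")
})

test_that("a 50/50 admixed face is best corrected by its weighted blend", {
  tpl <- test_template()
  co <- test_cohort()
  store <- build_consensus(co$shapes, co$true_region, align = FALSE,
                           min_members = 10L)
  set.seed(3)
  admixed <- tpl$coordinates +
    0.5 * true_effect_map(co, "North") + 0.5 * true_effect_map(co, "South") +
    matrix(rnorm(300, sd = 0.05), 100L)
  gm <- store$grand_mean
  d_weighted <- sqrt(sum((weighted_consensus_correct(
    admixed, c(0.5, 0.5, 0, 0), store) - gm)^2))
  d_north <- sqrt(sum((consensus_correct(admixed, "North", store) - gm)^2))
  d_south <- sqrt(sum((consensus_correct(admixed, "South", store) - gm)^2))
  expect_lt(d_weighted, d_north)
  expect_lt(d_weighted, d_south)
})

test_that("consensus faces are invariant to cohort row order", {
  co <- subset_cohort(test_cohort(), c(1:10, 21:30, 41:50, 61:70))
  store1 <- build_consensus(co$shapes, co$true_region,
                            min_members = 2L)
  set.seed(4)
  perm <- sample(40L)
  store2 <- build_consensus(co$shapes[perm, , ], co$true_region[perm],
                            min_members = 2L)
  for (r in names(store1$faces))
    expect_lt(max(abs(store1$faces[[r]] - store2$faces[[r]])), 1e-8)
})

test_that("consensus store guards membership minima", {
  fx <- two_per_region_store()
  expect_warning(build_consensus(fx$shapes, fx$labels, align = FALSE),
                 "advisory minimum")
  bad <- factor(c("A", "A", "A", "B"))
  expect_error(suppressWarnings(build_consensus(fx$shapes, bad,
                                                align = FALSE)),
               "fewer than 2")
})

test_that("consensus correction is a near no-op on ancestry-free cohorts", {
  tpl <- test_template()
  cfg <- cohort_config(n_per_region = 25L, region_effect_scale = 0,
                       pc_region_loadings = matrix(0, 4L, 4L),
                       n_shape_modes = 0L, noise_sd = 0.4, seed = 19L)
  co <- generate_cohort(cfg, tpl)
  store <- build_consensus(co$shapes, co$true_region, align = FALSE,
                           min_members = 10L)
  corrected <- consensus_correct_cohort(store, labels = co$true_region)
  shift <- sqrt(mean((corrected - store$aligned)^2))
  spread <- sqrt(mean(sweep(shapes_to_matrix(store$aligned), 2L,
                            colMeans(shapes_to_matrix(store$aligned)))^2))
  expect_lt(shift, 0.25 * spread)
})
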