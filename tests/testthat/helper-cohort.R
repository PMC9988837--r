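# Shared fixtures, built in code and memoised per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

tiny_template <- function() cached("tpl9", make_template(L = 9, extent = 1))

test_template <- function() cached("tpl100", make_template(L = 100, extent = 100))

# Default-condition cohort at reduced scale (20 per region, 100 landmarks).
test_cohort <- function() cached("cohort_default", {
  generate_cohort(cohort_config(n_per_region = 20L, seed = 101L),
                  test_template())
})

# Noise-free cohort with every effect switched off: shapes equal the template.
null_cohort <- function() cached("cohort_null", {
  cfg <- cohort_config(n_per_region = 5L, region_effect_scale = 0,
                       covariate_effects = c(sex = 0, age = 0, height = 0,
                                             weight = 0, camera = 0),
                       n_shape_modes = 0L, noise_sd = 0, seed = 11L)
  generate_cohort(cfg, test_template())
})

# Hand-built minimal template for permutation-oracle style checks:
# 3 landmarks, pairing (1 <-> 3, 2 self).
three_landmark_template <- function() {
  structure(list(
    coordinates = rbind(c(-1, 0, 0), c(0, 1, 0), c(1, 0, 0)),
    triangles = matrix(c(1L, 3L, 2L), ncol = 3L),
    pairing = c(3L, 2L, 1L),
    grid = c(nr = 1L, nc = 3L), extent = 2),
    class = "face_template")
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3L)
  qd <- qr(m)
  R <- qr.Q(qd) %*% diag(sign(diag(qr.R(qd))))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

# Apply a random similarity transform (rotation, translation, scale) to a
# configuration.
random_similarity <- function(config, scale_range = c(0.5, 2)) {
  s <- runif(1L, scale_range[1L], scale_range[2L])
  t_vec <- rnorm(3L, sd = 10)
  s * config %*% random_rotation() +
    matrix(t_vec, nrow(config), 3L, byrow = TRUE)
}

expect_all_close <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}
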