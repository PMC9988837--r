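test_that("noiseless univariate regression is recovered exactly", {
  set.seed(1)
  x <- matrix(rnorm(50), ncol = 1L, dimnames = list(NULL, "x"))
  b <- c(2.5, -1, 0.3)
  Y <- x %*% matrix(b, nrow = 1L)
  fit <- fit_plsr(x, Y)
  expect_equal(unname(coef(fit)), matrix(b, nrow = 1L), tolerance = 1e-10)
  expect_equal(unname(predict(fit, x)), unname(Y), tolerance = 1e-10)
})

test_that("full-component PLSR equals the normal-equations OLS solution", {
  set.seed(2)
  n <- 80L
  X <- cbind(a = rnorm(n), b = runif(n), c = rnorm(n, sd = 4))
  Y <- matrix(rnorm(n * 12L), n)
  fit <- fit_plsr(X, Y, n_components = 3L)
  # OLS oracle via the normal equations on centered data
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  B_ols <- solve(crossprod(Xc), crossprod(Xc, Yc))
  expect_lt(max(abs(coef(fit) - B_ols)), 1e-6)
})

test_that("reduced-component univariate fit matches mixOmics PLS", {
  skip_if_not_installed("mixOmics")
  set.seed(3)
  n <- 60L
  X <- matrix(rnorm(n * 5L), n, dimnames = list(NULL, paste0("x", 1:5)))
  y <- matrix(X %*% c(1, -2, 0.5, 0, 0) + rnorm(n), ncol = 1L,
              dimnames = list(NULL, "y"))
  mine <- fit_plsr(X, y, n_components = 2L)
  ref <- mixOmics::pls(X, y, ncomp = 2L, mode = "regression")
  pred_ref <- predict(ref, X)$predict[, 1L, 2L]
  expect_equal(unname(predict(mine, X)[, 1L]), unname(pred_ref),
               tolerance = 1e-6)
})

test_that("design validation: constant columns, component bounds, rank", {
  set.seed(4)
  X <- cbind(a = rnorm(20), b = rep(1, 20))
  Y <- matrix(rnorm(40), 20)
  expect_error(fit_plsr(X, Y), "zero variance")
  X2 <- cbind(a = rnorm(20), b = rnorm(20))
  expect_error(fit_plsr(X2, Y, n_components = 3L), "n_components")
  X3 <- cbind(a = rnorm(20), b = 0)
  X3 <- cbind(X3, c = X3[, "a"] * 2 + 3)  # collinear
  X3[, "b"] <- rnorm(20)
  expect_warning(fit_plsr(X3, Y, n_components = 3L), "rank")
})

test_that("correction leaves unrelated shapes untouched and is idempotent", {
  set.seed(5)
  n <- 40L
  X <- cbind(u = rnorm(n), v = rnorm(n))
  Y0 <- matrix(rnorm(n * 30L), n)
  # make Y exactly orthogonal to the centered predictors
  Xc <- sweep(X, 2L, colMeans(X))
  Y <- Y0 - Xc %*% solve(crossprod(Xc), crossprod(Xc, Y0))
  shapes <- matrix_to_shapes(Y)
  cc <- suppressWarnings(correct_shapes(shapes, X))
  expect_lt(max(abs(cc$shapes - shapes)), 1e-10)
  # idempotence: a second pass changes nothing beyond numerical noise
  cc2 <- suppressWarnings(correct_shapes(cc$shapes, X))
  expect_lt(max(abs(cc2$shapes - cc$shapes)), 1e-8)
})

test_that("corrected shapes decorrelate from predictors; mean preserved", {
  co <- test_cohort()
  sym <- symmetrize_cohort(co$shapes, co$template)
  fit <- gpa(sym)
  X <- covariate_design(co$covariates, fit$centroid_sizes)
  cc <- correct_shapes(fit, X)
  Yc <- shapes_to_matrix(cc$shapes)
  keep <- apply(Yc, 2L, stats::sd) > 1e-12
  r <- abs(cor(X, Yc[, keep]))
  expect_lt(max(r), 1e-6)
  expect_lt(max(abs(colMeans(Yc) -
                      colMeans(shapes_to_matrix(fit$shapes)))), 1e-8)
})

test_that("an injected sex effect is removed by covariate correction", {
  tpl <- test_template()
  cfg <- cohort_config(n_per_region = 30L, region_effect_scale = 0,
                       covariate_effects = c(sex = 1.5, age = 0, height = 0,
                                             weight = 0, camera = 0),
                       n_shape_modes = 0L, noise_sd = 0.3, seed = 77L)
  co <- generate_cohort(cfg, tpl)
  X <- covariate_design(co$covariates)
  m <- shapes_to_matrix(co$shapes)
  male <- co$covariates$sex > 0
  gap_before <- max(abs(colMeans(m[male, ]) - colMeans(m[!male, ])))
  cc <- correct_shapes(co$shapes, X)
  mc <- shapes_to_matrix(cc$shapes)
  gap_after <- max(abs(colMeans(mc[male, ]) - colMeans(mc[!male, ])))
  # residual group gap is pure noise: 3 SE of a mean difference at n ~ 60
  se <- 0.3 * sqrt(1 / sum(male) + 1 / sum(!male))
  expect_gt(gap_before, 10 * se)
  expect_lt(gap_after, 3 * se * 1.5)  # max over 300 coords, mild allowance
})

test_that("ancestry correction recovers the injected regional effect", {
  co <- test_cohort()
  sym <- symmetrize_cohort(co$shapes, co$template)
  fit <- gpa(sym)
  X <- covariate_design(co$covariates, fit$centroid_sizes)
  cc <- correct_shapes(fit, X)
  anc <- ancestry_correct(cc, co$pcs, k = 4L, labels = co$true_region)
  truth <- true_effect_map(co, "South")
  got <- matrix(anc$effect$per_region["South", , ], ncol = 3L)
  expect_gt(cor(as.vector(truth), as.vector(got)), 0.75)
  # k = 4 is the default protocol width
  expect_equal(anc$k, 4L)
  expect_error(ancestry_correct(cc, co$pcs, k = 0L), "k must be")
  expect_error(ancestry_correct(cc, co$pcs, k = 99L), "exceeds")
})

test_that("all-zero PCs produce an identically zero ancestry effect", {
  co <- subset_cohort(test_cohort(), 1:10)
  zero_pcs <- matrix(0, 10L, 4L)
  anc <- ancestry_correct(co$shapes, zero_pcs, k = 4L)
  expect_equal(max(abs(anc$effect$per_individual)), 0)
  expect_identical(anc$corrected$shapes, co$shapes)
})

test_that("single-PC effects: noise PC is null, orthogonal PCs decompose", {
  set.seed(6)
  n <- 60L
  L <- 30L
  # orthonormalize four predictors in-sample
  raw <- matrix(rnorm(n * 4L), n)
  pcs <- qr.Q(qr(sweep(raw, 2L, colMeans(raw))))
  colnames(pcs) <- paste0("PC", 1:4)
  field <- matrix(rnorm(3L * L), L)
  base <- matrix(rnorm(3L * L, sd = 3), L)
  shapes <- array(NA_real_, c(n, L, 3L))
  for (i in seq_len(n))  # only PC1 and PC2 move the shape
    shapes[i, , ] <- base + pcs[i, 1L] * field + pcs[i, 2L] * field[, 3:1] +
      matrix(rnorm(3L * L, sd = 0.01), L)
  eff4 <- single_pc_effect(shapes, pcs, exclude = 4L, k = 4L)
  expect_lt(sqrt(mean(eff4$mean_field^2)), 0.01)
  # orthogonal in-sample PCs: single-PC effects sum to the total effect
  anc <- ancestry_correct(shapes, pcs, k = 4L)
  total <- shapes_to_matrix(shapes) -
    shapes_to_matrix(anc$corrected$shapes)
  summed <- 0
  for (e in 1:4)
    summed <- summed +
      shapes_to_matrix(single_pc_effect(shapes, pcs, e, k = 4L)$per_individual)
  # effect of excluding PC e is (reduced - full) of the correction; with
  # orthogonal predictors the four exclusions tile the full correction
  expect_lt(max(abs(summed + total)) / max(abs(total)), 1e-6)
  expect_error(single_pc_effect(shapes, pcs, exclude = 5L, k = 4L),
               "exclude")
})

test_that("exaggeration is an affine map with the protocol factors", {
  base <- matrix(rnorm(30), 10L)
  eff <- matrix(rnorm(30), 10L)
  expect_equal(exaggerate(base, eff, 0), base)
  expect_equal(exaggerate(base, eff, 1), base + eff)
  expect_equal(exaggerate(base, eff, 4) - base, 4 * eff)
  expect_equal(exaggerate(base, eff, 8) - base, 8 * eff)
  expect_error(exaggerate(base, eff * NA, 2), "non-finite")
})

test_that("regional effect recovery improves with cohort size", {
  tpl <- cached("tpl60", make_template(L = 63, extent = 100))
  err_at_n <- function(n_per, seeds) {
    vapply(seeds, function(s) {
      co <- generate_cohort(cohort_config(n_per_region = n_per, seed = s),
                            tpl)
      cc <- correct_shapes(co$shapes, covariate_design(co$covariates))
      anc <- ancestry_correct(cc, co$pcs, k = 4L, labels = co$true_region)
      truth <- true_effect_map(co, "South")
      got <- matrix(anc$effect$per_region["South", , ], ncol = 3L)
      # compare in the common scale-free way: normalized fields
      mean(sqrt(rowSums((truth / sqrt(sum(truth^2)) -
                           got / sqrt(sum(got^2)))^2)))
    }, numeric(1L))
  }
  seeds <- 201:210
  expect_lt(median(err_at_n(32L, seeds)), median(err_at_n(8L, seeds)))
})
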