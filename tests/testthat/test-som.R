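test_that("standardize centres and scales gene rows, dropping constants", {
  vals <- matrix(c(1, 2, 3, 4,
                   5, 5, 5, 5,
                   0, 1, 0, 1), nrow = 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"),
                                 c("s1", "s2", "s3", "s4")))
  ann <- toy_study()$annotations
  study <- expression_study(vals, ann)
  expect_message(std <- standardize(study), "1 constant")
  expect_equal(nrow(std$values), 2)
  expect_equal(rowMeans(std$values), c(g1 = 0, g3 = 0))
  expect_equal(apply(std$values, 1, sd), c(g1 = 1, g3 = 1))
  # idempotent up to numerics
  expect_equal(standardize(std)$values, std$values)
  allconst <- expression_study(matrix(1, 2, 4,
                                      dimnames = list(c("a", "b"),
                                                      ann$sample_id)), ann)
  expect_error(standardize(allconst), "constant")
})

test_that("training pulls all weights onto a single shared gene vector", {
  ann <- toy_study()$annotations
  g0 <- c(-1.1618950, 0.7744633, -1.1618950, 1.5493267)  # standardized
  vals <- matrix(rep(g0, each = 40), nrow = 40,
                 dimnames = list(sprintf("g%02d", 1:40), ann$sample_id))
  study <- expression_study(vals, ann)
  grid <- som_grid(rows = 3, cols = 3, delta = 0.05, sigma = 3, seed = 2)
  trained <- train_som(study, grid, epochs = 60)
  err <- apply(trained$weights, 1, function(w) sqrt(sum((w - g0)^2)))
  expect_lt(max(err), 1e-3)
})

test_that("two planted clusters each claim nodes within their hulls", {
  ann <- data.frame(sample_id = sprintf("s%d", 1:8),
                    treatment = rep(c("treated", "control"), each = 4),
                    sex = rep(c("F", "M"), 4), stringsAsFactors = FALSE)
  up <- rep(c(1, -1), c(4, 4))
  dn <- -up
  vals <- withr::with_seed(3, rbind(
    matrix(rep(up, each = 30), 30) + rnorm(240, sd = 0.05),
    matrix(rep(dn, each = 30), 30) + rnorm(240, sd = 0.05)))
  dimnames(vals) <- list(sprintf("g%02d", 1:60), ann$sample_id)
  study <- standardize(expression_study(vals, ann))
  trained <- train_som(study, som_grid(rows = 4, cols = 4, delta = 0.05,
                                       seed = 4), epochs = 50)
  # both clusters claim at least one node, and the claimed nodes sit
  # inside the cluster hulls (nodes balanced between the two opposite
  # attractors can remain between them)
  d_up <- colSums((t(trained$weights) - up)^2)
  d_dn <- colSums((t(trained$weights) - dn)^2)
  expect_gt(sum(d_up < d_dn), 0)
  expect_gt(sum(d_dn < d_up), 0)
  expect_lt(min(d_up), 0.5)
  expect_lt(min(d_dn), 0.5)
})

test_that("zero epochs returns the seeded random initialisation", {
  study <- standardize(generate_expression_study(
    study_design(n_genes = 30, seed = 1))$study)
  g <- som_grid(rows = 3, cols = 3, seed = 42)
  t0 <- train_som(study, g, epochs = 0)
  W <- withr::with_seed(42L, matrix(rnorm(9 * 17), nrow = 9))
  expect_equal(unname(t0$weights), W)
  # reproducibility with training
  t1 <- train_som(study, g, epochs = 3)
  t2 <- train_som(study, g, epochs = 3)
  expect_identical(t1$weights, t2$weights)
})

test_that("node regression flags covariate-aligned weights and nulls", {
  ann <- toy_study()$annotations
  x <- c(1, 1, 0, 0)
  grid <- som_grid(rows = 2, cols = 2, seed = 1)
  grid$weights <- rbind(rep(2, 4),          # constant -> Z = 0
                        x,                  # aligned -> max |Z|
                        c(0.1, -0.2, 0.15, 0),
                        -x)
  colnames(grid$weights) <- ann$sample_id
  grid$samples <- ann$sample_id
  grid$epochs <- 1L
  m <- regress_weights(grid, "treatment", ann)
  z <- as.vector(t(unclass(m)))
  expect_equal(z[1], 0)
  expect_true(which.max(abs(z)) %in% c(2, 4))
  expect_true(all(is.finite(z)))
  expect_equal(z[2], -z[4])
  expect_error(regress_weights(grid, "bogus", ann), "bogus")
})

test_that("permutation p is calibrated, powered, and label-symmetric", {
  # null: covariate independent of expression
  synth <- generate_expression_study(study_design(
    n_genes = 300, effect_fraction = 0, sex_fraction = 0, seed = 21))
  std <- standardize(synth$study)
  pt <- permutation_significance(std, "treatment", n_perm = 200, seed = 3,
                                 mode = "regress",
                                 grid = som_grid(seed = 5), epochs = 5)
  expect_gt(pt$p, 0.01)

  # power: strong planted treatment effect
  synth2 <- generate_expression_study(study_design(
    n_genes = 300, effect_fraction = 0.2, effect_size = 3, seed = 22))
  std2 <- standardize(synth2$study)
  pt2 <- permutation_significance(std2, "treatment", n_perm = 500,
                                  seed = 4, mode = "regress",
                                  grid = som_grid(seed = 5), epochs = 5)
  expect_lte(pt2$p, 0.01)

  # swapping which group is "treated" leaves p unchanged
  ann_sw <- std2$annotations
  ann_sw$treatment <- ifelse(ann_sw$treatment == "treated", "control",
                             "treated")
  std_sw <- expression_study(std2$values, ann_sw)
  pt_sw <- permutation_significance(std_sw, "treatment", n_perm = 500,
                                    seed = 4, mode = "regress",
                                    grid = som_grid(seed = 5), epochs = 5)
  expect_equal(pt_sw$p, pt2$p)

  # add-one convention bounds p away from 0 and 1
  expect_gte(pt$p, 1 / 201)
  expect_lte(pt$p, 1)
  expect_error(permutation_significance(std, "treatment", n_perm = 10),
               "n_perm")
})

test_that("retrain mode agrees with regress mode on a strong effect", {
  synth <- generate_expression_study(study_design(
    n_genes = 150, effect_fraction = 0.3, effect_size = 4, seed = 30))
  std <- standardize(synth$study)
  pt <- permutation_significance(std, "treatment", n_perm = 100, seed = 6,
                                 mode = "retrain",
                                 grid = som_grid(rows = 5, cols = 5,
                                                 seed = 7), epochs = 3)
  expect_lte(pt$p, 0.05)
})

test_that("residualizing a covariate removes its variance only", {
  ann <- toy_study()$annotations
  sex_ind <- as.numeric(ann$sex == "F")
  ortho <- c(1, 1, -1, -1)          # orthogonal to sex (F,M,F,M), mean 0
  vals <- rbind(g1 = sex_ind, g2 = ortho)
  colnames(vals) <- ann$sample_id
  study <- expression_study(vals, ann)
  res <- residualize(study, "sex")
  expect_equal(unname(res$values["g1", ]), rep(0, 4))
  expect_equal(unname(res$values["g2", ]), ortho)
  expect_error(residualize(
    expression_study(vals, transform(ann, sex = "F")), "sex"),
    "not binary")
})

test_that("residualizing sex kills the sex map but keeps the treatment map", {
  # moderate effects keep node scores far from the saturation regime in
  # which a weight equals the covariate indicator exactly; the max-node
  # statistic is averaged over a few map seeds to damp training noise
  sexes <- c(rep(c("F", "M"), length.out = 7),
             rep(c("F", "M"), length.out = 10))
  synth <- generate_expression_study(study_design(
    n_genes = 800, effect_fraction = 0.1, effect_size = 1.2,
    sex_fraction = 0.1, sex_effect_size = 2.5, sex_assignment = sexes,
    seed = 32))
  std <- standardize(synth$study)
  res <- standardize(residualize(synth$study, "sex"))
  max_z <- function(s, cov, seed) {
    tr <- train_som(s, som_grid(rows = 8, cols = 8, seed = seed),
                    epochs = 5)
    max(abs(regress_weights(tr, cov, s$annotations)))
  }
  pre_sex <- mean(vapply(8:10, function(s) max_z(std, "sex", s), 0))
  post_sex <- mean(vapply(8:10, function(s) max_z(res, "sex", s), 0))
  pre_tr <- mean(vapply(8:10, function(s) max_z(std, "treatment", s), 0))
  post_tr <- mean(vapply(8:10, function(s) max_z(res, "treatment", s), 0))
  expect_lt(post_sex, 0.05 * pre_sex)
  expect_gt(post_tr, 0.9 * pre_tr)
})

test_that("updates contract the best-matching weight toward the gene", {
  # one presentation: BMU distance must not increase
  ann <- toy_study()$annotations
  vals <- matrix(c(2, -1, 0.5, 1), 1, dimnames = list("g1", ann$sample_id))
  study <- expression_study(vals, ann)
  grid <- som_grid(rows = 3, cols = 3, delta = 0.5, seed = 9)
  t0 <- train_som(study, grid, epochs = 0)
  t1 <- train_som(study, grid, epochs = 1)
  d0 <- apply(t0$weights, 1, function(w) sum((w - vals[1, ])^2))
  d1 <- apply(t1$weights, 1, function(w) sum((w - vals[1, ])^2))
  expect_true(all(d1 <= d0 + 1e-12))
  expect_true(all(is.finite(t1$weights)))
})
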