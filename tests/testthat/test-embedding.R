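test_that("distance model maps correlations through the chord transform", {
  target <- null_profile(3000, seed = 50, name = "target")
  lib <- generate_drug_library(target, 3, c(1, -1, 0), seed = 51)
  model <- build_distance_model(target, lib)
  # drug identical to target: c = 1, radius = f(2) = 1 (maximal)
  expect_equal(unname(model$r0[1]), 1)
  # sign-flipped drug: c = -1, radius f(0) = 0 -> plots at the centre
  expect_equal(unname(model$r0[2]), 0)
  # identical drugs are at drug-drug distance f(0) = 0
  lib2 <- list(lib[[1]],
               gene_profile(lib[[1]]$z, name = "copy"), lib[[3]])
  model2 <- build_distance_model(target, lib2)
  expect_equal(model2$d[1, 2], 0)
  expect_equal(model2$d[1, 1], 0)
  # symmetry and bounds
  expect_equal(model$d, t(model$d))
  expect_true(all(model$d >= 0 & model$d <= 1, na.rm = TRUE))
  # the half transform is the linear variant
  mh <- build_distance_model(target, lib, transform = "half")
  expect_equal(unname(mh$r0[1]), 1)
  expect_equal(unname(mh$r0[2]), 0)
})

test_that("stress is the exact sum over available pairs", {
  # plant 3 points with known coordinates; their chord distances give 0
  r <- c(1, 2, 1.5)
  theta <- c(0.3, 2.0, 4.4)
  x <- r * cos(theta); y <- r * sin(theta)
  d <- as.matrix(stats::dist(cbind(x, y)))
  model <- distance_model(d, r0 = stats::setNames(r, c("a", "b", "c")))
  expect_equal(stress(list(radius = r, theta = theta), model), 0)
  # perturbing one distance adds exactly the squared residual
  d2 <- d; d2[1, 2] <- d2[2, 1] <- d2[1, 2] + 0.25
  model2 <- distance_model(d2, model$r0)
  expect_equal(stress(list(radius = r, theta = theta), model2), 0.25^2)
  # single drug: no pairs, zero stress
  m1 <- distance_model(matrix(0, 1, 1), c(a = 1))
  expect_equal(stress(list(radius = 1, theta = 0.7), m1), 0)
})

test_that("the analytic angle gradient matches finite differences", {
  withr::with_seed(52, {
    for (rep in 1:5) {
      k <- 10
      r <- runif(k, 0.2, 1.5)
      theta <- runif(k, 0, 2 * pi)
      cmat <- matrix(runif(k * k, -1, 1), k)
      cmat <- (cmat + t(cmat)) / 2
      d <- sqrt((1 - cmat) / 2); diag(d) <- 0
      model <- distance_model(d, stats::setNames(r, paste0("d", 1:k)))
      g <- sigreverse:::stress_gradient(r, theta, model$d)
      fd <- fd_stress_gradient(r, theta, model$d, model)
      expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)
    }
  })
})

test_that("a two-drug layout recovers the closed-form pi separation", {
  model <- distance_model(matrix(c(0, 2, 2, 0), 2),
                          c(a = 1, b = 1))
  layout <- optimize_layout(model, seed = 1, tol = 1e-14,
                            max_iter = 50000)
  sep <- abs(layout$theta[1] - layout$theta[2]) %% (2 * pi)
  sep <- min(sep, 2 * pi - sep)
  expect_lt(abs(sep - pi), 1e-3)
  expect_equal(layout$radius, c(1, 1))
})

test_that("a consistent planar configuration is recovered to tiny stress", {
  withr::with_seed(53, {
    k <- 3
    r <- runif(k, 0.3, 1.2)
    theta0 <- runif(k, 0, 2 * pi)
    x <- r * cos(theta0); y <- r * sin(theta0)
    d <- as.matrix(stats::dist(cbind(x, y)))
  })
  model <- distance_model(d, stats::setNames(r, paste0("d", 1:k)))
  layout <- optimize_layout(model, seed = 2, tol = 1e-14,
                            max_iter = 20000, restarts = 8)
  expect_lt(layout$stress, 1e-6 * sum(d^2))
})

test_that("radii are preserved, rotation leaves stress unchanged, runs repeat", {
  target <- null_profile(3000, seed = 54, name = "t")
  lib <- generate_drug_library(target, 8,
                               seq(-0.9, 0.9, length.out = 8), seed = 55)
  model <- build_distance_model(target, lib)
  layout <- optimize_layout(model, seed = 3, restarts = 2, max_iter = 500)
  expect_equal(layout$radius, unname(model$r0))
  # global rotation invariance
  rot <- list(radius = layout$radius, theta = layout$theta + 1.234)
  expect_equal(stress(rot, model), layout$stress, tolerance = 1e-9)
  # reproducibility
  layout2 <- optimize_layout(model, seed = 3, restarts = 2, max_iter = 500)
  expect_identical(layout$theta, layout2$theta)
  # monotone trend: late stress no worse than early
  tr <- layout$trace
  n10 <- max(1, floor(length(tr) / 10))
  expect_lte(stats::median(utils::tail(tr, n10)),
             stats::median(utils::head(tr, n10)))
})

test_that("all-zero radii return immediately with angles irrelevant", {
  model <- distance_model(matrix(c(0, 0.5, 0.5, 0), 2), c(a = 0, b = 0))
  layout <- optimize_layout(model, seed = 4)
  expect_equal(layout$x, c(0, 0))
  expect_equal(layout$stress, 0.25)     # d12 mismatch is irreducible
  expect_length(layout$trace, 1)
})

test_that("missing pairs are excluded and unplaceable drugs dropped", {
  d <- matrix(c(0, NA, NA, 0), 2)
  model <- distance_model(d, c(a = 0.5, b = 0.5))
  layout <- optimize_layout(model, seed = 5)
  expect_equal(layout$stress, 0)

  target <- null_profile(2000, seed = 56, name = "t")
  lib <- generate_drug_library(target, 3, c(0.8, -0.8, 0), seed = 57)
  # a drug with no shared significant features with anything
  dull <- gene_profile(stats::setNames(rep(0.1, 2000), names(target$z)),
                       name = "dull")
  expect_warning(model2 <- build_distance_model(target, c(lib, list(dull))),
                 "dull")
  expect_equal(nrow(model2$d), 3)
})
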