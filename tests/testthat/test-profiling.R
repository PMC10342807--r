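test_that("differential Z matches a per-gene lm oracle and its edge cases", {
  synth <- generate_expression_study(study_design(
    n_genes = 60, effect_fraction = 0.2, effect_size = 2, seed = 12))
  prof <- differential_profile(synth$study)
  expect_equal(unname(prof$z), unname(lm_oracle_z(synth$study)),
               tolerance = 1e-10)

  # gene identical in both groups -> Z = 0; near-separating gene -> |Z| > 5
  ann <- synth$study$annotations
  vals <- rbind(flat = rep(3, 17),
                sep = as.numeric(ann$treatment == "treated") +
                  withr::with_seed(1, rnorm(17, sd = 0.01)))
  colnames(vals) <- ann$sample_id
  st <- expression_study(vals, ann)
  z <- differential_profile(st)$z
  expect_equal(unname(z["flat"]), 0)
  expect_gt(abs(z["sep"]), 5)
  expect_gt(z["sep"], 0)   # positive = higher in treated

  # confounded design errors naming the collinear column
  ann2 <- ann
  ann2$sex <- ifelse(ann2$treatment == "treated", "F", "M")
  expect_error(differential_profile(expression_study(vals, ann2)),
               "sex")
})

test_that("differential Z flips sign when group labels swap", {
  synth <- generate_expression_study(study_design(
    n_genes = 40, effect_fraction = 0.3, seed = 13))
  prof <- differential_profile(synth$study)
  ann <- synth$study$annotations
  ann$treatment <- ifelse(ann$treatment == "treated", "control", "treated")
  flipped <- differential_profile(expression_study(synth$study$values, ann))
  expect_equal(flipped$z, -prof$z)

  # and is invariant under sample permutation
  perm <- withr::with_seed(2, sample(17))
  st_perm <- expression_study(synth$study$values[, perm],
                              synth$study$annotations[perm, ])
  expect_equal(differential_profile(st_perm)$z, prof$z)
})

test_that("mean planted-gene |Z| matches the small-n Monte Carlo oracle", {
  # oracle: direct lm() fits over replicate studies, same design
  des <- function(seed) study_design(n_genes = 120, effect_fraction = 0.25,
                                     effect_size = 2, seed = seed)
  impl <- sapply(1:15, function(s) {
    synth <- generate_expression_study(des(s))
    mean(abs(differential_profile(synth$study)$z[synth$affected_genes]))
  })
  oracle <- sapply(1:15, function(s) {
    synth <- generate_expression_study(des(s))
    mean(abs(lm_oracle_z(synth$study)[synth$affected_genes]))
  })
  expect_equal(mean(impl), mean(oracle), tolerance = 1e-8)
  expect_equal(mean(impl), 4.1, tolerance = 0.5)  # effect / se at 7v10
})

test_that("probe collapse keeps the maximal-magnitude Z per gene", {
  probes <- gene_profile(c(p1 = 1.2, p2 = -3.4, p3 = 0.5, p4 = 2.0,
                           p5 = -2.0), name = "probes")
  map <- c(p1 = "GA", p2 = "GA", p3 = "GB", p4 = "GC", p5 = "GC")
  out <- suppressMessages(collapse_probes(probes, map))
  expect_equal(out$z[["GA"]], -3.4)
  expect_equal(out$z[["GB"]], 0.5)
  # |Z| tie, opposite signs: first probe in input order wins, tie reported
  expect_message(out2 <- collapse_probes(probes, map), "tie")
  expect_equal(out2$z[["GC"]], 2.0)

  # single probe per gene is the identity; unmapped probes are dropped
  one <- suppressMessages(collapse_probes(probes, c(p2 = "GX")))
  expect_equal(one$z, c(GX = -3.4))
  expect_error(collapse_probes(probes, character(0)), "empty")
  expect_error(collapse_probes(probes, c(q9 = "GZ")), "no probe")

  # never increases records, never alters retained values
  expect_lte(length(out$z), length(probes$z))
  expect_true(all(out$z %in% probes$z))
})

test_that("composite combines as sum over sqrt(k) with missing as zero", {
  p <- function(z, nm) gene_profile(z, name = nm)
  same <- lapply(1:4, function(i) p(c(a = 1.5, b = -2), paste0("s", i)))
  comp <- composite_profile(same)
  expect_equal(comp$z, c(a = 3, b = -4))          # sqrt(4) * z
  expect_equal(unname(comp$k), c(4L, 4L))

  single <- composite_profile(list(p(c(a = 0.7), "only")))
  expect_equal(single$z, c(a = 0.7))

  # gene in 1 of 4 profiles with Z = 2 -> composite 2 / sqrt(4) = 1
  four <- c(same[1:3], list(p(c(a = 1.5, b = -2, extra = 2), "s4")))
  comp4 <- composite_profile(four)
  expect_equal(comp4$z[["extra"]], 1)
  expect_equal(unname(comp4$k["extra"]), 1L)
  expect_error(composite_profile(list()), "at least one")
})

test_that("composite of independent null profiles stays standard normal", {
  fam <- generate_profile_family(profile_family_design(
    n_genes = 10000, n_profiles = 12, shared_fraction = 0, seed = 14))
  comp <- composite_profile(fam)
  expect_equal(stats::sd(comp$z), 1, tolerance = 0.05)
  expect_equal(mean(comp$z), 0, tolerance = 0.05)
})

test_that("threshold counts use strict inequality and match the null rate", {
  zero <- gene_profile(c(a = 0, b = 0), "zero")
  tc0 <- threshold_counts(zero)
  expect_equal(tc0$n_up + tc0$n_down, 0)

  prof <- gene_profile(c(A = 2.5, B = -2.1, C = 1.9, D = 2.0), "toy")
  tc <- threshold_counts(prof, 2)
  expect_identical(tc$up, "A")          # D = 2.0 excluded when strict
  expect_identical(tc$down, "B")
  tc_ge <- threshold_counts(prof, 2, strict = FALSE)
  expect_setequal(tc_ge$up, c("A", "D"))

  # standard-normal null: expected tail count 2 * N * pnorm(-2)
  null <- null_profile(15699, seed = 15)
  tcn <- threshold_counts(null)
  expected <- 2 * 15699 * stats::pnorm(-2)
  sd3 <- 3 * sqrt(2 * 15699 * stats::pnorm(-2) * (1 - 2 * stats::pnorm(-2)))
  expect_lt(abs(tcn$n_up + tcn$n_down - expected), sd3)
})
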