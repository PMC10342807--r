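# Seeded generators that emulate the statistical structure the analysis
# assumes: a two-group expression study with a sparse additive treatment
# effect and a sex effect on Gaussian noise; families of correlated disease
# Z profiles sharing a common signal; random pathway collections; and a
# compound library with planted (anti-)correlates of a target profile.
# Every generator returns its ground truth alongside the data and is
# bit-reproducible for a fixed seed.

#' Design of a synthetic two-group expression study
#'
#' Defaults mirror a treated-versus-control brain study of 7 treated
#' (3 female, 4 male) and 10 control (6 female, 4 male) animals with a
#' sparse additive treatment effect on unit Gaussian noise.
#'
#' @param n_genes Number of genes.
#' @param n_treated,n_control Group sizes (total must be >= 4).
#' @param sex_assignment Optional character vector of `"F"`/`"M"` of length
#'   `n_treated + n_control` (treated samples first). Default assigns
#'   3F/4M-like and 6F/4M-like proportions to the two groups.
#' @param effect_fraction Proportion of genes carrying the treatment effect.
#' @param effect_size Additive expression shift in treated samples.
#' @param sex_effect_size Additive shift in female samples for the
#'   sex-affected genes.
#' @param sex_fraction Proportion of genes carrying the sex effect; drawn
#'   disjoint from the treatment-affected genes so the two signals are
#'   separable.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian noise.
#' @param seed Integer seed.
#' @return A list of class `StudyDesign`.
#' @export
study_design <- function(n_genes = 2000, n_treated = 7, n_control = 10,
                         sex_assignment = NULL, effect_fraction = 0.05,
                         effect_size = 2, sex_effect_size = 1,
                         sex_fraction = 0.1, noise_sd = 1, seed = 1) {
  n <- n_treated + n_control
  if (n_treated < 1 || n_control < 1)
    stop("both groups need at least one sample")
  if (n < 4) stop("need at least 4 samples in total")
  if (effect_fraction < 0 || effect_fraction > 1)
    stop("effect_fraction must lie in [0, 1]")
  if (sex_fraction < 0 || sex_fraction > 1)
    stop("sex_fraction must lie in [0, 1]")
  if (effect_fraction + sex_fraction > 1)
    stop("effect_fraction + sex_fraction must not exceed 1 ",
         "(affected gene sets are disjoint)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (is.null(sex_assignment)) {
    nf_tr <- round(3 / 7 * n_treated)
    nf_ct <- round(6 / 10 * n_control)
    sex_assignment <- c(rep(c("F", "M"), c(nf_tr, n_treated - nf_tr)),
                        rep(c("F", "M"), c(nf_ct, n_control - nf_ct)))
  }
  if (length(sex_assignment) != n || !all(sex_assignment %in% c("F", "M")))
    stop("sex_assignment must be 'F'/'M' of length n_treated + n_control")
  structure(list(n_genes = n_genes, n_treated = n_treated,
                 n_control = n_control, sex_assignment = sex_assignment,
                 effect_fraction = effect_fraction, effect_size = effect_size,
                 sex_effect_size = sex_effect_size,
                 sex_fraction = sex_fraction, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "StudyDesign")
}

#' Generate a synthetic expression study with known affected genes
#'
#' A random `effect_fraction` of genes carries an additive `effect_size`
#' shift in the treated samples; a disjoint `sex_fraction` of genes carries
#' an additive `sex_effect_size` shift in female samples; everything else is
#' i.i.d. Gaussian noise.
#'
#' @param design A [study_design()].
#' @return A list of class `SyntheticStudy` with elements `study` (an
#'   [expression_study()]), `affected_genes` (treatment ground truth) and
#'   `sex_genes` (sex-effect ground truth).
#' @export
generate_expression_study <- function(design) {
  stopifnot(inherits(design, "StudyDesign"))
  withr::with_seed(design$seed, {
    n <- design$n_treated + design$n_control
    genes <- sprintf("G%05d", seq_len(design$n_genes))
    samples <- c(sprintf("T%02d", seq_len(design$n_treated)),
                 sprintf("C%02d", seq_len(design$n_control)))
    vals <- matrix(stats::rnorm(design$n_genes * n, sd = design$noise_sd),
                   nrow = design$n_genes,
                   dimnames = list(genes, samples))
    n_eff <- round(design$effect_fraction * design$n_genes)
    n_sex <- round(design$sex_fraction * design$n_genes)
    pick <- sample.int(design$n_genes, n_eff + n_sex)
    affected <- genes[pick[seq_len(n_eff)]]
    sex_genes <- genes[pick[n_eff + seq_len(n_sex)]]
    treated_cols <- seq_len(design$n_treated)
    vals[affected, treated_cols] <-
      vals[affected, treated_cols] + design$effect_size
    female_cols <- which(design$sex_assignment == "F")
    if (length(female_cols) && length(sex_genes))
      vals[sex_genes, female_cols] <-
        vals[sex_genes, female_cols] + design$sex_effect_size
    ann <- data.frame(
      sample_id = samples,
      treatment = rep(c("treated", "control"),
                      c(design$n_treated, design$n_control)),
      sex = design$sex_assignment,
      stringsAsFactors = FALSE)
    structure(list(study = expression_study(vals, ann),
                   affected_genes = affected, sex_genes = sex_genes,
                   design = design),
              class = "SyntheticStudy")
  })
}

#' Design of a family of correlated Z profiles
#'
#' Emulates a set of disease differential-expression profiles from distinct
#' studies that share a common biological signal: each profile is
#' `sqrt(shared_fraction)` times a common standard-Gaussian signal plus
#' `sqrt(1 - shared_fraction)` times independent standard-Gaussian noise, so
#' the expected pairwise Pearson correlation equals `shared_fraction`.
#'
#' @param n_genes Genes per profile before dropout.
#' @param n_profiles Number of profiles (>= 1).
#' @param shared_fraction Proportion of variance from the common signal,
#'   in \[0, 1\].
#' @param missing_fraction Proportion of genes absent from each profile,
#'   in \[0, 1).
#' @param seed Integer seed.
#' @return A list of class `ProfileFamilyDesign`.
#' @export
profile_family_design <- function(n_genes = 10000, n_profiles = 12,
                                  shared_fraction = 0.5,
                                  missing_fraction = 0, seed = 1) {
  if (n_profiles < 1) stop("n_profiles must be >= 1")
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]")
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must lie in [0, 1)")
  structure(list(n_genes = n_genes, n_profiles = n_profiles,
                 shared_fraction = shared_fraction,
                 missing_fraction = missing_fraction,
                 seed = as.integer(seed)),
            class = "ProfileFamilyDesign")
}

#' Generate a family of correlated Z profiles
#'
#' @param design A [profile_family_design()].
#' @param common_signal Optional named numeric vector supplying the shared
#'   signal (e.g. the negative of a treatment profile, to emulate a disease
#'   family the treatment reverses); standardized internally to unit scale.
#'   Default: a fresh standard-Gaussian signal.
#' @return List of [gene_profile()]s; the common signal is attached as
#'   attribute `common_signal`. Missing genes are absent from a profile
#'   (not zero) — the composite operation owns the missing-to-zero rule.
#' @export
generate_profile_family <- function(design, common_signal = NULL) {
  stopifnot(inherits(design, "ProfileFamilyDesign"))
  if (!is.null(common_signal) &&
      (length(common_signal) != design$n_genes ||
         is.null(names(common_signal))))
    stop("common_signal must be a named vector of length n_genes")
  withr::with_seed(design$seed, {
    if (is.null(common_signal)) {
      genes <- sprintf("G%05d", seq_len(design$n_genes))
      common <- stats::rnorm(design$n_genes)
      names(common) <- genes
    } else {
      genes <- names(common_signal)
      common <- as.vector(scale(common_signal))
      names(common) <- genes
    }
    a <- sqrt(design$shared_fraction)
    b <- sqrt(1 - design$shared_fraction)
    profiles <- lapply(seq_len(design$n_profiles), function(i) {
      z <- a * common + b * stats::rnorm(design$n_genes)
      names(z) <- genes
      if (design$missing_fraction > 0) {
        drop <- sample.int(design$n_genes,
                           round(design$missing_fraction * design$n_genes))
        z <- z[-drop]
      }
      gene_profile(z, name = sprintf("family_%02d", i))
    })
    attr(profiles, "common_signal") <- common
    profiles
  })
}

#' Generate a random gene-set collection
#'
#' Emulates a canonical-pathway collection: set sizes uniform on
#' `size_range`, members sampled uniformly without replacement from the
#' universe.
#'
#' @param n_sets Number of sets.
#' @param size_range Length-2 integer vector `c(min, max)`; max must not
#'   exceed the universe size.
#' @param universe Character vector of candidate genes (non-empty).
#' @param seed Integer seed.
#' @return A [gene_set_collection()].
#' @export
generate_gene_set_collection <- function(n_sets, size_range, universe,
                                         seed = 1) {
  if (!length(universe)) stop("empty universe")
  size_range <- as.integer(size_range)
  if (length(size_range) != 2 || size_range[1] < 1 ||
      size_range[1] > size_range[2])
    stop("size_range must be c(min, max) with 1 <= min <= max")
  if (size_range[2] > length(universe))
    stop("maximum set size exceeds universe size")
  withr::with_seed(as.integer(seed), {
    sizes <- size_range[1] + sample.int(size_range[2] - size_range[1] + 1L,
                                        n_sets, replace = TRUE) - 1L
    sets <- lapply(sizes, function(k) universe[sample.int(length(universe), k)])
    names(sets) <- sprintf("SET%04d", seq_len(n_sets))
    gene_set_collection(sets, rep("synthetic", n_sets))
  })
}

#' Generate a compound profile library with planted correlations
#'
#' Each compound profile is `rho * target + sqrt(1 - rho^2) * noise` for its
#' planted correlation `rho`, with standard-Gaussian noise, so the realised
#' Pearson correlation with the target is within sampling error of `rho`.
#' Emulates a drug-induced expression-profile library screened against a
#' disease target.
#'
#' @param target A [gene_profile()]; treated as the disease signature.
#' @param n_drugs Number of compound profiles.
#' @param planted_correlations Numeric vector in \[-1, 1\], recycled to
#'   `n_drugs`.
#' @param seed Integer seed.
#' @return List of [gene_profile()]s with attribute `planted_rho`.
#' @export
generate_drug_library <- function(target, n_drugs, planted_correlations,
                                  seed = 1) {
  stopifnot(inherits(target, "GeneProfile"))
  rho <- rep_len(planted_correlations, n_drugs)
  if (any(abs(rho) > 1)) stop("planted correlations must lie in [-1, 1]")
  withr::with_seed(as.integer(seed), {
    drugs <- lapply(seq_len(n_drugs), function(i) {
      z <- rho[i] * target$z +
        sqrt(1 - rho[i]^2) * stats::rnorm(length(target$z))
      names(z) <- names(target$z)
      gene_profile(z, name = sprintf("drug_%03d", i))
    })
    attr(drugs, "planted_rho") <- rho
    drugs
  })
}

#' Write a synthetic study and its ground truth to a directory
#'
#' Writes the expression matrix, the sample annotations and a two-column
#' gene/label truth table (`treatment`, `sex` or `none`).
#'
#' @param synth A `SyntheticStudy` from [generate_expression_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_study <- function(synth, dir) {
  stopifnot(inherits(synth, "SyntheticStudy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("expression.tsv", "annotations.tsv",
                            "truth.tsv"))
  write_expression(synth$study, paths[1], paths[2])
  genes <- rownames(synth$study$values)
  lab <- rep("none", length(genes))
  lab[genes %in% synth$affected_genes] <- "treatment"
  lab[genes %in% synth$sex_genes] <- "sex"
  write_tsv_commented(data.frame(gene = genes, label = lab), paths[3])
  invisible(paths)
}
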