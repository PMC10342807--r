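# Differential Z profiles and their combination. A profile is the vector
# of per-gene Z scores (coefficient / standard error) from an ordinary
# least-squares fit of expression on treatment plus covariates; alternative
# probes for a gene are collapsed to the one with maximal |Z|; profiles
# from independent studies combine Stouffer-style into a composite that is
# standard normal per gene under the null.

#' Covariate-adjusted differential Z profile of a study
#'
#' Fits, per gene, expression ~ treatment + covariates by ordinary least
#' squares and returns the treatment-coefficient Z score (estimate divided
#' by its standard error). Positive Z means higher expression in treated
#' samples.
#'
#' @param study An [expression_study()].
#' @param outcome Annotation column defining the contrast
#'   (default `"treatment"`; level `"treated"` codes 1).
#' @param covariates Character vector of annotation columns adjusted for
#'   (default `"sex"`); use `character(0)` for an unadjusted fit.
#' @param name Profile label.
#' @return A [gene_profile()]. Genes with zero residual variance get Z = 0
#'   when the estimate is also 0.
#' @export
differential_profile <- function(study, outcome = "treatment",
                                 covariates = "sex", name = "differential") {
  stopifnot(inherits(study, "ExpressionStudy"))
  ann <- study$annotations
  x_out <- covariate_indicator(ann, outcome)
  if (min(table(x_out)) < 2) stop("need >= 2 samples per outcome level")
  X <- cbind(intercept = 1, outcome = x_out)
  for (cv in covariates)
    X <- cbind(X, covariate_indicator(ann, cv))
  colnames(X) <- c("intercept", outcome, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  Y <- t(study$values)                       # samples x genes
  coef <- qr.coef(qx, Y)
  res <- Y - X %*% coef
  df <- nrow(X) - ncol(X)
  if (df < 1) stop("no residual degrees of freedom")
  sigma2 <- colSums(res^2) / df
  xtxinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * xtxinv[2, 2])
  z <- ifelse(se > 0, coef[2, ] / se, 0)
  names(z) <- rownames(study$values)
  gene_profile(z, name = name)
}

#' Collapse probe-level Z scores to genes
#'
#' Maps probes to genes and keeps, per gene, the Z of the probe with the
#' largest absolute value (sign preserved). On an exact |Z| tie the probe
#' occurring first in the input order is retained and the tie reported.
#' Unmapped probes are dropped with a message.
#'
#' @param probe_profile A [gene_profile()] keyed by probe IDs.
#' @param mapping Named character vector probe -> gene
#'   (see [read_mapping()]).
#' @param name Label of the collapsed profile.
#' @return A [gene_profile()] keyed by gene IDs.
#' @export
collapse_probes <- function(probe_profile, mapping, name = NULL) {
  stopifnot(inherits(probe_profile, "GeneProfile"))
  if (!length(mapping)) stop("empty probe-to-gene mapping")
  probes <- names(probe_profile$z)
  gene <- unname(mapping[probes])
  mapped <- !is.na(gene) & gene != ""
  if (!any(mapped)) stop("no probe in the profile is covered by the mapping")
  if (any(!mapped))
    message(sprintf("collapse_probes: dropped %d unmapped probe(s)",
                    sum(!mapped)))
  z <- probe_profile$z[mapped]
  gene <- gene[mapped]
  ord <- seq_along(z)                       # stable: first probe wins ties
  best <- tapply(ord, gene, function(idx) idx[which.max(abs(z[idx]))])
  ties <- tapply(ord, gene, function(idx)
    length(idx) > 1 && sum(abs(z[idx]) == max(abs(z[idx]))) > 1)
  if (any(unlist(ties)))
    message(sprintf("collapse_probes: |Z| tie(s) in %d gene(s), first probe kept",
                    sum(unlist(ties))))
  out <- z[unlist(best)]
  names(out) <- names(best)
  if (is.null(name)) name <- probe_profile$name
  gene_profile(out, name = name)
}

#' Stouffer composite of Z profiles
#'
#' Combines k profiles gene-wise as `sum(Z) / sqrt(k)` where k is the total
#' number of profiles; a gene absent from a profile contributes 0 and the
#' denominator does not shrink, so the composite of independent standard
#' normal profiles is itself standard normal per gene. The number of
#' profiles actually containing each gene is recorded.
#'
#' @param profiles Non-empty list of [gene_profile()]s.
#' @param name Label of the composite.
#' @return Object of class `c("CompositeProfile", "GeneProfile")` with an
#'   extra element `k`: per-gene count of contributing profiles.
#' @export
composite_profile <- function(profiles, name = "composite") {
  if (!length(profiles)) stop("need at least one profile")
  stopifnot(all(vapply(profiles, inherits, TRUE, "GeneProfile")))
  genes <- unique(unlist(lapply(profiles, function(p) names(p$z))))
  zsum <- numeric(length(genes))
  k <- integer(length(genes))
  names(zsum) <- names(k) <- genes
  for (p in profiles) {
    zsum[names(p$z)] <- zsum[names(p$z)] + p$z
    k[names(p$z)] <- k[names(p$z)] + 1L
  }
  out <- gene_profile(zsum / sqrt(length(profiles)), name = name)
  out$k <- k
  out$n_profiles <- length(profiles)
  class(out) <- c("CompositeProfile", class(out))
  out
}

#' @export
print.CompositeProfile <- function(x, ...) {
  cat(sprintf(
    "CompositeProfile '%s': %d genes from %d profiles (median coverage %d)\n",
    x$name, length(x$z), x$n_profiles, as.integer(stats::median(x$k))))
  invisible(x)
}

#' Up- and down-regulated genes at a Z threshold
#'
#' @param profile A [gene_profile()].
#' @param z_threshold Threshold on |Z| (default 2).
#' @param strict Use strict inequality `|Z| > threshold` (default); set
#'   `FALSE` for `>=`.
#' @return List with `up`, `down` (gene ID vectors, profile order),
#'   `n_up`, `n_down`, `threshold`.
#' @export
threshold_counts <- function(profile, z_threshold = 2, strict = TRUE) {
  stopifnot(inherits(profile, "GeneProfile"))
  cmp <- if (strict) `>` else `>=`
  up <- names(profile$z)[cmp(profile$z, z_threshold)]
  down <- names(profile$z)[cmp(-profile$z, z_threshold)]
  list(up = up, down = down, n_up = length(up), n_down = length(down),
       threshold = z_threshold)
}
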