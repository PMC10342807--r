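# Reversal scoring between two Z profiles. Features significant in both
# profiles (|Z| above a threshold) are cross-classified by direction into a
# 2x2 up/down contingency table; the correlation score
# c = (UU + DD - UD - DU) / N summarises concordance (-1 = perfect
# reversal, +1 = perfect agreement) and a one-sided Fisher exact test on
# the table gives its significance. Works identically on gene-level
# profiles and on pathway-level enrichment Z profiles.

#' Up/down contingency table between two profiles
#'
#' Only features significant in BOTH profiles are counted, classified by
#' the sign pair (first index = direction in `profile_a`).
#'
#' @param profile_a,profile_b [gene_profile()]s (or pathway-level Z
#'   profiles from [enrichment_z_profile()]).
#' @param z_threshold Significance threshold on |Z| (default 2).
#' @param strict Strict inequality `|Z| > threshold` (default).
#' @return A [contingency_table()].
#' @export
contingency <- function(profile_a, profile_b, z_threshold = 2,
                        strict = TRUE) {
  stopifnot(inherits(profile_a, "GeneProfile"),
            inherits(profile_b, "GeneProfile"))
  shared <- intersect(names(profile_a$z), names(profile_b$z))
  if (!length(shared))
    stop("profiles share no features")
  za <- profile_a$z[shared]
  zb <- profile_b$z[shared]
  cmp <- if (strict) `>` else `>=`
  sig <- cmp(abs(za), z_threshold) & cmp(abs(zb), z_threshold)
  contingency_table(UU = sum(sig & za > 0 & zb > 0),
                    UD = sum(sig & za > 0 & zb < 0),
                    DU = sum(sig & za < 0 & zb > 0),
                    DD = sum(sig & za < 0 & zb < 0))
}

#' Contingency correlation score
#'
#' `c = (UU + DD - UD - DU) / (UU + UD + DU + DD)`: +1 when every shared
#' significant feature moves the same way in both profiles, -1 under
#' perfect reversal.
#'
#' @param table A [contingency_table()].
#' @return The correlation score in \[-1, 1\].
#' @export
correlation_score <- function(table) {
  stopifnot(inherits(table, "ContingencyTable"))
  n <- table$UU + table$UD + table$DU + table$DD
  if (n == 0) stop("empty contingency table (N = 0)")
  (table$UU + table$DD - table$UD - table$DU) / n
}

#' One-sided Fisher exact test on an up/down contingency table
#'
#' Exact hypergeometric tail probability conditioned on the table margins.
#' `alternative = "anti"` tests for depletion of concordant pairs (UU
#' below its conditional expectation: drug-reverses-disease direction);
#' `"pro"` tests the opposite tail (enrichment of concordant pairs).
#'
#' @param table A [contingency_table()].
#' @param alternative `"anti"` or `"pro"`.
#' @return The exact one-sided p-value.
#' @export
fisher_one_sided <- function(table, alternative = c("anti", "pro")) {
  stopifnot(inherits(table, "ContingencyTable"))
  alternative <- match.arg(alternative)
  m <- table$UU + table$DU          # features up in profile B
  n <- table$UD + table$DD          # features down in profile B
  k <- table$UU + table$UD          # features up in profile A
  if (alternative == "anti")
    stats::phyper(table$UU, m, n, k)
  else
    stats::phyper(table$UU - 1, m, n, k, lower.tail = FALSE)
}

#' Full concordance report between two profiles
#'
#' Bundles the contingency table, the correlation score and the one-sided
#' Fisher exact p-value. `level` is a label recording whether the inputs
#' are gene-level Z profiles or pathway-level enrichment Z profiles.
#'
#' @inheritParams contingency
#' @param level `"gene"` or `"pathway"` (annotation only; pathway-level
#'   inputs are built with [enrichment_z_profile()]).
#' @param alternative Fisher tail, `"anti"` (default: reversal) or
#'   `"pro"`.
#' @return List of class `ConcordanceResult`: `table`, `c`, `p`,
#'   `alternative`, `level`, `threshold`, `names`.
#' @export
concordance_report <- function(profile_a, profile_b,
                               level = c("gene", "pathway"),
                               z_threshold = 2,
                               alternative = c("anti", "pro"),
                               strict = TRUE) {
  level <- match.arg(level)
  alternative <- match.arg(alternative)
  tab <- contingency(profile_a, profile_b, z_threshold = z_threshold,
                     strict = strict)
  structure(list(table = tab, c = correlation_score(tab),
                 p = fisher_one_sided(tab, alternative),
                 alternative = alternative, level = level,
                 threshold = z_threshold,
                 names = c(profile_a$name, profile_b$name)),
            class = "ConcordanceResult")
}

#' @export
print.ConcordanceResult <- function(x, ...) {
  cat(sprintf("Concordance (%s level, |Z| > %g): %s vs %s\n", x$level,
              x$threshold, x$names[1], x$names[2]))
  print(as.matrix(x$table))
  cat(sprintf("c = %.4f, one-sided Fisher p (%s) = %.3g\n",
              x$c, x$alternative, x$p))
  invisible(x)
}

#' Pearson correlation of two full Z profiles with a Fisher-transform Z
#'
#' Utility comparison over all shared features (no thresholding): plain
#' Pearson r plus the Fisher z-transform standard-normal score
#' `atanh(r) * sqrt(n - 3)`.
#'
#' @param profile_a,profile_b [gene_profile()]s.
#' @return List with `r`, `z`, `n_shared`.
#' @export
pearson_z <- function(profile_a, profile_b) {
  shared <- intersect(names(profile_a$z), names(profile_b$z))
  if (length(shared) < 4) stop("need >= 4 shared features")
  r <- stats::cor(profile_a$z[shared], profile_b$z[shared])
  list(r = r, z = atanh(r) * sqrt(length(shared) - 3),
       n_shared = length(shared))
}
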