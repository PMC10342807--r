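# Signed Kolmogorov-Smirnov-type gene-set enrichment on a ranked Z
# profile. Genes are ranked by Z descending (rank 1 = most up-regulated);
# the observed cumulative fraction of set members along the ranking is
# compared with the uniform expectation r/N. The score S is the sum of the
# maximal deviation above (D+) and below (D-) the null, so a set
# concentrated among up-regulated genes gets S near +1 and one among
# down-regulated genes S near -1. S is calibrated to a Z score against a
# seeded Monte-Carlo null of random same-size gene sets; the null sd
# depends only on (profile size, set size) and is cached.

# ranks (ascending, 1 = top) of the set members on the profile ranking
member_ranks <- function(profile, genes) {
  ord <- order(profile$z, decreasing = TRUE)  # stable: ties by input order
  ranked <- names(profile$z)[ord]
  sort(which(ranked %in% genes))
}

# signed KS statistics from sorted member ranks r (1..N), set size n
ks_from_ranks <- function(r, N) {
  n <- length(r)
  i <- seq_len(n)
  d_plus <- max(0, i / n - r / N)
  d_minus <- min(0, (i - 1) / n - (r - 1) / N)
  list(D_plus = d_plus, D_minus = d_minus, S = d_plus + d_minus)
}

#' Signed KS-type enrichment score of a gene set on a ranked profile
#'
#' Walks the profile ranked by Z descending and records the maximal
#' deviation of the set members' cumulative distribution above (`D_plus`)
#' and below (`D_minus`, signed) the uniform null `r/N`. The score is
#' `S = D_plus + D_minus`; positive S means the set is concentrated among
#' up-regulated genes. Set members absent from the profile are ignored
#' (the effective set size is the intersection size).
#'
#' @param profile A [gene_profile()].
#' @param gene_set Character vector of member genes, or a single set drawn
#'   from a [gene_set_collection()].
#' @param set_name Label for the result row.
#' @return One-row data frame: `set`, `n_set`, `D_plus`, `D_minus`, `S`,
#'   `Z` (NA here; see [calibrate_z()]), `null_sd` (NA), `scoreable`.
#' @export
enrichment_score <- function(profile, gene_set, set_name = "set") {
  stopifnot(inherits(profile, "GeneProfile"))
  gene_set <- as.character(gene_set)
  N <- length(profile$z)
  r <- member_ranks(profile, gene_set)
  if (!length(r))
    return(data.frame(set = set_name, n_set = 0L, D_plus = NA_real_,
                      D_minus = NA_real_, S = NA_real_, Z = NA_real_,
                      null_sd = NA_real_, scoreable = FALSE,
                      stringsAsFactors = FALSE))
  ks <- ks_from_ranks(r, N)
  data.frame(set = set_name, n_set = length(r), D_plus = ks$D_plus,
             D_minus = ks$D_minus, S = ks$S, Z = NA_real_,
             null_sd = NA_real_, scoreable = TRUE, stringsAsFactors = FALSE)
}

# Monte-Carlo null of S for random size-n sets on an N-gene ranking.
# Depends only on (N, n); cached per session.
.null_cache <- new.env(parent = emptyenv())

enrichment_null <- function(N, n, n_null = 1000, seed = 1) {
  key <- paste(N, n, n_null, seed, sep = "_")
  if (!is.null(.null_cache[[key]])) return(.null_cache[[key]])
  s <- withr::with_seed(as.integer(seed), vapply(seq_len(n_null), function(b)
    ks_from_ranks(sort(sample.int(N, n)), N)$S, numeric(1)))
  out <- list(mean = mean(s), sd = stats::sd(s))
  .null_cache[[key]] <- out
  out
}

#' Calibrate an enrichment score to a Z score
#'
#' Estimates the null mean and standard deviation of S over `n_null`
#' seeded random gene sets of the same (intersection) size drawn from the
#' profile's genes, and returns `Z = (S - null_mean) / null_sd`. The null
#' depends only on the profile length and set size and is cached, so
#' scoring many same-size sets costs one null estimation.
#'
#' @inheritParams enrichment_score
#' @param n_null Number of null draws (>= 100, default 1000).
#' @param seed Integer seed for the null draws.
#' @return One-row data frame as [enrichment_score()] with `Z` and
#'   `null_sd` filled in.
#' @export
calibrate_z <- function(profile, gene_set, n_null = 1000, seed = 1,
                        set_name = "set") {
  if (n_null < 100) stop("n_null must be >= 100")
  res <- enrichment_score(profile, gene_set, set_name = set_name)
  if (!res$scoreable) return(res)
  null <- enrichment_null(length(profile$z), res$n_set, n_null, seed)
  if (!is.finite(null$sd) || null$sd == 0)
    stop("degenerate enrichment null (sd = 0) for set size ", res$n_set)
  res$Z <- (res$S - null$mean) / null$sd
  res$null_sd <- null$sd
  res
}

#' Score a whole gene-set collection against a profile
#'
#' One calibrated result per set; sets with no member in the profile are
#' flagged unscoreable. Null distributions are cached per set size.
#'
#' @param profile A [gene_profile()].
#' @param collection A [gene_set_collection()].
#' @param n_null Null draws per distinct set size (default 1000).
#' @param seed Integer seed.
#' @return Data frame of class `EnrichmentProfile` (one row per set) with
#'   attribute `profile_name`.
#' @export
enrich_collection <- function(profile, collection, n_null = 1000, seed = 1) {
  stopifnot(inherits(profile, "GeneProfile"),
            inherits(collection, "GeneSetCollection"))
  rows <- lapply(names(collection$sets), function(nm)
    calibrate_z(profile, collection$sets[[nm]], n_null = n_null,
                seed = seed, set_name = nm))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, profile_name = profile$name,
            class = c("EnrichmentProfile", "data.frame"))
}

#' Turn an enrichment table into a pathway-level Z profile
#'
#' The scoreable sets' calibrated Z scores become a [gene_profile()] keyed
#' by set name, so pathway-level profiles feed the same concordance and
#' embedding machinery as gene-level ones.
#'
#' @param ep An `EnrichmentProfile` from [enrich_collection()].
#' @return A [gene_profile()] over set names.
#' @export
enrichment_z_profile <- function(ep) {
  stopifnot(inherits(ep, "EnrichmentProfile"))
  keep <- ep$scoreable & is.finite(ep$Z)
  if (!any(keep)) stop("no scoreable sets in enrichment profile")
  gene_profile(stats::setNames(ep$Z[keep], ep$set[keep]),
               name = attr(ep, "profile_name"))
}

#' Brownian-bridge approximation to the enrichment null sd
#'
#' Large-N, moderate-n limit: sqrt(n) times the cumulative deviation
#' converges to a Brownian bridge, so `S = max B + min B` scaled by
#' `1/sqrt(n)`. The variance of `max B + min B` is computed numerically
#' from the classical band-crossing series for the bridge. Provided as an
#' analytic cross-check of the Monte-Carlo null, not as the default
#' calibration.
#'
#' @param n Set size.
#' @param grid_step Discretisation step of the (max, -min) grid.
#' @return Approximate null standard deviation of S.
#' @export
bridge_null_sd <- function(n, grid_step = 0.01) {
  # P(max B < a, min B > -b) = sum_j exp(-2 j^2 (a+b)^2)
  #                            - exp(-2 (b + j (a+b))^2),  j over Z
  band_prob <- function(a, b) {
    p <- 0
    for (j in -8:8)
      p <- p + exp(-2 * (j * (a + b))^2) - exp(-2 * (b + j * (a + b))^2)
    p
  }
  g <- seq(grid_step, 4, by = grid_step)
  P <- outer(g, g, Vectorize(band_prob))
  # joint density of (max, -min) by central second differences
  f <- matrix(0, length(g), length(g))
  idx <- 2:(length(g) - 1)
  f[idx, idx] <- (P[idx + 1, idx + 1] - P[idx + 1, idx - 1] -
                    P[idx - 1, idx + 1] + P[idx - 1, idx - 1]) /
    (4 * grid_step^2)
  v <- outer(g, g, "-")          # S_bridge = max - (-min)... max + min = a - b
  ex2 <- sum(v^2 * f) * grid_step^2
  sqrt(ex2 / n)
}
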