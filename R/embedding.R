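# Radial embedding of a compound library around a disease target.
# Contingency correlations c between profiles become distances:
# drug-drug d = f(1 - c), drug-target d = f(1 + c), so anti-correlated
# compounds plot near the centre. Radii are fixed at the target distances;
# only the angles are optimised, by steepest descent on the stress
# Phi = sum_{i>j} (d_ij - |r_i - r_j|)^2 with the Barzilai-Borwein step.

# distance transform of 1 +/- c
dist_transform <- function(x, transform) {
  switch(transform,
         chord = sqrt(pmax(x, 0) / 2),   # chord distance of unit vectors
         half = pmax(x, 0) / 2,
         stop("unknown transform: ", transform))
}

#' Construct a distance model directly from distances
#'
#' Low-level constructor used by [build_distance_model()] and by tests
#' that plant known geometry. `NA` entries in `d` mark unavailable pairs,
#' which are excluded from the stress.
#'
#' @param d Symmetric drug-drug distance matrix (NA allowed off-diagonal).
#' @param r0 Named vector of drug-target distances (the fixed radii).
#' @param correlations Optional list of the source correlations.
#' @param transform Transform label.
#' @return Object of class `DistanceModel`.
#' @export
distance_model <- function(d, r0, correlations = NULL,
                           transform = "chord") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d))))
    stop("`d` must be a symmetric matrix")
  if (length(r0) != nrow(d))
    stop("`r0` length must match the number of drugs")
  if (any(d[!is.na(d)] < 0) || any(r0 < 0, na.rm = TRUE))
    stop("distances must be non-negative")
  if (is.null(rownames(d)))
    rownames(d) <- colnames(d) <- names(r0)
  structure(list(d = d, r0 = stats::setNames(as.numeric(r0), rownames(d)),
                 correlations = correlations, transform = transform),
            class = "DistanceModel")
}

#' Build the drug/target distance model from profiles
#'
#' Computes the contingency correlation c (see [correlation_score()])
#' between every pair of profiles over features significant in both at
#' `z_threshold`, then maps correlations to distances: drug-drug
#' `d = f(1 - c)`, drug-target `d = f(1 + c)`. The default transform
#' `f(x) = sqrt(x / 2)` is the chord distance between unit-normalised
#' vectors (a true metric); `"half"` gives the linear `x / 2` variant.
#' Pairs sharing no significant feature are flagged missing and excluded
#' from the stress; drugs sharing nothing with the target cannot be given
#' a radius and are dropped with a warning.
#'
#' @param target A [gene_profile()] (gene- or pathway-level) at the
#'   centre.
#' @param drugs List of >= 2 [gene_profile()]s.
#' @param z_threshold Significance threshold applied to all pairs.
#' @param transform `"chord"` (default) or `"half"`.
#' @param strict Strict thresholding (default).
#' @return A [distance_model()].
#' @export
build_distance_model <- function(target, drugs, z_threshold = 2,
                                 transform = c("chord", "half"),
                                 strict = TRUE) {
  transform <- match.arg(transform)
  stopifnot(inherits(target, "GeneProfile"), length(drugs) >= 2,
            all(vapply(drugs, inherits, TRUE, "GeneProfile")))
  nm <- vapply(drugs, function(p) p$name, "")
  if (anyDuplicated(nm)) stop("duplicate drug profile names")
  pair_c <- function(a, b) {
    tab <- tryCatch(contingency(a, b, z_threshold, strict),
                    error = function(e) NULL)
    if (is.null(tab)) return(NA_real_)
    n <- tab$UU + tab$UD + tab$DU + tab$DD
    if (n == 0) NA_real_ else correlation_score(tab)
  }
  k <- length(drugs)
  cdrug <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    cdrug[i, i] <- 1
    for (j in seq_len(i - 1L))
      cdrug[i, j] <- cdrug[j, i] <- pair_c(drugs[[i]], drugs[[j]])
  }
  c0 <- vapply(drugs, function(p) pair_c(p, target), numeric(1))
  if (anyNA(c0)) {
    warning("dropping drug(s) sharing no significant feature with the ",
            "target: ", paste(nm[is.na(c0)], collapse = ", "))
    keep <- !is.na(c0)
    if (sum(keep) < 2) stop("fewer than 2 drugs placeable around the target")
    cdrug <- cdrug[keep, keep, drop = FALSE]
    c0 <- c0[keep]
    nm <- nm[keep]
  }
  d <- dist_transform(1 - cdrug, transform)
  diag(d) <- 0
  distance_model(d, stats::setNames(dist_transform(1 + c0, transform), nm),
                 correlations = list(drug_drug = cdrug, drug_target = c0),
                 transform = transform)
}

# pairwise chord lengths of the layout; mask = available pairs (i != j)
layout_chords <- function(r, theta) {
  x <- r * cos(theta)
  y <- r * sin(theta)
  sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2)
}

#' Stress of a layout under a distance model
#'
#' `Phi = sum_{i > j} (d_ij - |r_i - r_j|)^2` over available drug pairs;
#' the target enters only through the fixed radii.
#'
#' @param layout A `Layout` (see [optimize_layout()]) or a list with
#'   `radius` and `theta`.
#' @param model A [distance_model()].
#' @return The stress Phi.
#' @export
stress <- function(layout, model) {
  stopifnot(inherits(model, "DistanceModel"))
  r <- layout$radius
  theta <- layout$theta
  if (length(r) != nrow(model$d)) stop("layout does not match model")
  if (length(r) < 2) return(0)
  L <- layout_chords(r, theta)
  e <- model$d - L
  sum(e[upper.tri(e)]^2, na.rm = TRUE)
}

# gradient of Phi wrt theta
stress_gradient <- function(r, theta, d) {
  L <- layout_chords(r, theta)
  mask <- !is.na(d)
  diag(mask) <- FALSE
  e <- ifelse(mask & L > 0, d - L, 0)
  s <- outer(theta, theta, function(a, b) sin(a - b)) * outer(r, r)
  g <- ifelse(mask & L > 0, -2 * e * s / L, 0)
  rowSums(g)
}

#' Optimise compound angles by steepest descent
#'
#' Radii are fixed at the drug-target distances; angles start at a seeded
#' random assignment and follow steepest descent with the
#' Barzilai-Borwein step
#' `gamma_k = sum(dtheta * dgrad) / sum(dgrad * dgrad)` (first step uses
#' `gamma0`). Because the objective is non-convex, `restarts` seeded
#' starts are run and the lowest-stress layout kept. Iteration stops when
#' `|delta Phi| < tol` or after `max_iter` steps; fifty consecutive
#' stress increases abort with advice to restart with a new seed.
#'
#' @param model A [distance_model()].
#' @param seed Integer seed for the random initial angles.
#' @param max_iter Maximum iterations per start (default 2000).
#' @param tol Convergence tolerance on the stress change (default 1e-10).
#' @param gamma0 First (and fallback) step size.
#' @param restarts Number of random starts (default 5).
#' @return Object of class `Layout`: `drug`, `radius`, `theta` (wrapped to
#'   `[0, 2*pi)`), `x`, `y`, `stress`, `trace` (per-iteration stress of the
#'   winning start), `seed`.
#' @export
optimize_layout <- function(model, seed = 1, max_iter = 2000, tol = 1e-10,
                            gamma0 = 1e-3, restarts = 5) {
  stopifnot(inherits(model, "DistanceModel"))
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (tol <= 0) stop("tol must be positive")
  r <- model$r0
  k <- length(r)
  one_start <- function(start_seed) {
    theta <- withr::with_seed(start_seed,
                              stats::runif(k, 0, 2 * pi))
    phi <- stress(list(radius = r, theta = theta), model)
    trace <- phi
    if (all(r == 0) || k < 2 ||
        all(is.na(model$d[upper.tri(model$d)]))) {
      # angles cannot change the stress; nothing to optimise
      return(list(theta = theta, stress = phi, trace = trace))
    }
    g <- stress_gradient(r, theta, model$d)
    theta_prev <- NULL
    g_prev <- NULL
    n_up <- 0L
    for (it in seq_len(max_iter)) {
      if (is.null(theta_prev)) {
        gamma <- gamma0
      } else {
        dth <- theta - theta_prev
        dg <- g - g_prev
        denom <- sum(dg * dg)
        gamma <- if (is.finite(denom) && denom > 0)
          sum(dth * dg) / denom else gamma0
        if (!is.finite(gamma) || gamma <= 0) gamma <- gamma0
      }
      # safeguard the raw step: halve it until the stress does not grow
      cand <- theta - gamma * g
      phi_new <- stress(list(radius = r, theta = cand), model)
      tries <- 0L
      while (phi_new > phi && tries < 30L) {
        gamma <- gamma / 2
        cand <- theta - gamma * g
        phi_new <- stress(list(radius = r, theta = cand), model)
        tries <- tries + 1L
      }
      if (phi_new > phi) {
        n_up <- n_up + 1L
        if (n_up >= 50L)
          stop("stress increased over 50 consecutive iterations; ",
               "restart with a new seed")
      } else n_up <- 0L
      theta_prev <- theta
      g_prev <- g
      theta <- cand
      trace <- c(trace, phi_new)
      converged <- abs(phi_new - phi) < tol
      phi <- phi_new
      if (converged) break
      g <- stress_gradient(r, theta, model$d)
    }
    list(theta = theta, stress = phi, trace = trace)
  }
  runs <- lapply(seq_len(restarts), function(s) one_start(as.integer(seed) + s - 1L))
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "stress"))]]
  theta <- best$theta %% (2 * pi)
  structure(list(drug = names(r), radius = unname(r), theta = theta,
                 x = unname(r) * cos(theta), y = unname(r) * sin(theta),
                 stress = best$stress, trace = best$trace,
                 seed = as.integer(seed)),
            class = "Layout")
}

#' @export
print.Layout <- function(x, ...) {
  cat(sprintf("Layout: %d compounds around the target, stress = %.4g\n",
              length(x$drug), x$stress))
  invisible(x)
}

#' @export
as.data.frame.Layout <- function(x, ...) {
  data.frame(drug = x$drug, r = x$radius, theta = x$theta, x = x$x,
             y = x$y, stringsAsFactors = FALSE)
}

#' Scatter plot of a layout, target at the centre
#'
#' @param x A `Layout`.
#' @param highlight Optional drug names drawn in violet.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.Layout <- function(x, highlight = NULL, ...) {
  lim <- max(abs(c(x$x, x$y, 0.1)))
  graphics::plot(x$x, x$y, asp = 1, xlim = c(-lim, lim),
                 ylim = c(-lim, lim), pch = 19, col = "grey40",
                 xlab = "", ylab = "", ...)
  graphics::points(0, 0, pch = 19, cex = 1.4, col = "black")
  if (!is.null(highlight)) {
    i <- x$drug %in% highlight
    graphics::points(x$x[i], x$y[i], pch = 19, col = "violet")
  }
  invisible(x)
}
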