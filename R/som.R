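# Self-organising map QC of an expression study. Nodes live in sample
# space: each weight vector summarises a cluster of gene expression
# patterns across the samples. Regressing node weights on a binary
# covariate (treatment, sex) shows which expression variation the covariate
# explains; a permutation null on the maximal node score gives a global
# significance; residualising a covariate out of the study removes its
# variance before a second map is fit.

#' Standardize an expression study gene-wise
#'
#' Scales every gene row to mean 0, sd 1 across samples, the form the map
#' is trained on. Constant genes cannot be scaled and are dropped with a
#' message.
#'
#' @param study An [expression_study()].
#' @return The standardized [expression_study()].
#' @export
standardize <- function(study) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (ncol(study$values) < 2) stop("need at least 2 samples")
  sds <- apply(study$values, 1, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all genes are constant across samples")
  if (any(!keep))
    message(sprintf("standardize: dropped %d constant gene(s)", sum(!keep)))
  vals <- study$values[keep, , drop = FALSE]
  vals <- (vals - rowMeans(vals)) / sds[keep]
  expression_study(vals, study$annotations)
}

#' Configure a self-organising map grid
#'
#' @param rows,cols Lattice dimensions (default 10 x 10).
#' @param delta Initial step size (default 0.01).
#' @param sigma Initial Gaussian neighbourhood width in lattice units
#'   (default 2).
#' @param decay Multiplicative decay of `delta` and `sigma` (default 0.99).
#' @param decay_per `"epoch"` (default): decay applied after each full pass
#'   over the genes; `"presentation"`: after every single gene presentation
#'   (total learning is then bounded and the map cannot fully converge —
#'   kept for comparison).
#' @param kernel `"gaussian"` (default) attenuates by squared lattice
#'   distance to the best-matching node; `"norm_diff"` is the literal
#'   squared-difference-of-squared-norms variant, kept for comparison (it
#'   makes all nodes on a ring around the lattice origin equivalent).
#' @param seed Integer seed for weight initialisation and presentation
#'   order.
#' @return A list of class `SOMGrid` with `weights = NULL` until trained.
#' @export
som_grid <- function(rows = 10, cols = 10, delta = 0.01, sigma = 2,
                     decay = 0.99, decay_per = c("epoch", "presentation"),
                     kernel = c("gaussian", "norm_diff"), seed = 1) {
  if (rows < 1 || cols < 1) stop("lattice dimensions must be positive")
  if (delta <= 0) stop("delta must be positive")
  if (sigma <= 0) stop("sigma must be positive")
  if (decay <= 0 || decay > 1) stop("decay must lie in (0, 1]")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 delta = delta, sigma = sigma, decay = decay,
                 decay_per = match.arg(decay_per),
                 kernel = match.arg(kernel), seed = as.integer(seed),
                 weights = NULL, samples = NULL, epochs = 0L),
            class = "SOMGrid")
}

#' @export
print.SOMGrid <- function(x, ...) {
  cat(sprintf("SOMGrid %dx%d (%s kernel), %s\n", x$rows, x$cols, x$kernel,
              if (is.null(x$weights)) "untrained"
              else sprintf("trained %d epoch(s) on %d samples",
                           x$epochs, length(x$samples))))
  invisible(x)
}

# lattice coordinates, node index running row-major over (i, j), 1-based
som_coords <- function(grid) {
  list(i = rep(seq_len(grid$rows), each = grid$cols),
       j = rep(seq_len(grid$cols), times = grid$rows))
}

#' Train a self-organising map on an expression study
#'
#' Each gene's standardized expression vector is presented in seeded random
#' order; the best-matching node is the Euclidean-nearest weight vector and
#' all weights move toward the presented vector with Gaussian
#' lattice-neighbourhood attenuation. The step size and neighbourhood width
#' decay multiplicatively over training (see [som_grid()]). Weights are
#' initialised i.i.d. N(0, 1).
#'
#' @param study A standardized [expression_study()] (see [standardize()]).
#' @param grid A [som_grid()].
#' @param epochs Number of full passes over the genes (default 20). Zero
#'   epochs returns the random initialisation.
#' @return The trained `SOMGrid` with a `(rows*cols) x n_samples` weight
#'   matrix.
#' @export
train_som <- function(study, grid = som_grid(), epochs = 20) {
  stopifnot(inherits(study, "ExpressionStudy"), inherits(grid, "SOMGrid"))
  if (nrow(study$values) == 0) stop("empty study")
  n_nodes <- grid$rows * grid$cols
  ns <- ncol(study$values)
  co <- som_coords(grid)
  withr::with_seed(grid$seed, {
    W <- matrix(stats::rnorm(n_nodes * ns), nrow = n_nodes)
    if (epochs > 0) {
      ng <- nrow(study$values)
      ord <- unlist(lapply(seq_len(epochs),
                           function(e) sample.int(ng))) - 1L
      t_idx <- seq_along(ord) - 1L
      expo <- if (grid$decay_per == "epoch") (t_idx %/% ng) else t_idx
      delta_t <- grid$delta * grid$decay^expo
      sigma_t <- grid$sigma * grid$decay^expo
      W <- som_train_cpp(W, study$values, ord,
                         as.integer(co$i), as.integer(co$j),
                         delta_t, sigma_t,
                         kernel = if (grid$kernel == "gaussian") 0L else 1L)
    }
  })
  colnames(W) <- colnames(study$values)
  grid$weights <- W
  grid$samples <- colnames(study$values)
  grid$epochs <- as.integer(epochs)
  grid
}

# binary covariate over samples -> 0/1 indicator, with validation
covariate_indicator <- function(annotations, covariate) {
  if (!covariate %in% names(annotations))
    stop("unknown covariate: ", covariate)
  v <- annotations[[covariate]]
  lev <- sort(unique(v))
  if (length(lev) != 2)
    stop("covariate '", covariate, "' is not binary over samples (levels: ",
         paste(lev, collapse = ", "), ")")
  # fixed reference: treatment 'treated' = 1, sex 'F' = 1, else 2nd level
  one <- if ("treated" %in% lev) "treated" else if ("F" %in% lev) "F"
         else lev[2]
  as.numeric(v == one)
}

#' Regress node weights on a binary covariate
#'
#' For every lattice node, fits a simple linear regression of the node's
#' weight vector (over samples) on the 0/1 covariate indicator and records
#' the slope Z score (slope / standard error). Nodes whose weights are
#' constant across samples get Z = 0.
#'
#' @param grid A trained [som_grid()].
#' @param covariate Covariate name in the study annotations, or a numeric
#'   0/1 vector over samples.
#' @param annotations Sample annotation data frame (required when
#'   `covariate` is a name).
#' @return A `rows x cols` Z-score matrix of class `NodeRegressionMap`.
#' @export
regress_weights <- function(grid, covariate, annotations = NULL) {
  stopifnot(inherits(grid, "SOMGrid"))
  if (is.null(grid$weights)) stop("grid is untrained")
  if (is.character(covariate)) {
    if (is.null(annotations))
      stop("annotations required to resolve covariate '", covariate, "'")
    x <- covariate_indicator(annotations, covariate)
    cname <- covariate
  } else {
    x <- as.numeric(covariate)
    cname <- "covariate"
  }
  if (length(x) != ncol(grid$weights))
    stop("covariate length does not match sample count")
  if (stats::sd(x) == 0) stop("covariate is constant across samples")
  z <- node_regression_z(grid$weights, x)
  m <- matrix(z, nrow = grid$rows, ncol = grid$cols, byrow = TRUE)
  structure(m, class = c("NodeRegressionMap", "matrix", "array"),
            covariate = cname)
}

# vectorised per-node slope Z of weights (nodes x samples) on indicator x
node_regression_z <- function(W, x) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  wc <- W - rowMeans(W)
  beta <- as.vector(wc %*% xc) / sxx
  rss <- rowSums(wc^2) - beta^2 * sxx
  rss[rss < 0] <- 0
  df <- n - 2
  se <- sqrt(pmax(rss / df, .Machine$double.xmin) / sxx)
  z <- beta / se
  z[rowSums(wc^2) == 0] <- 0  # constant weight vector: no association
  z
}

#' @export
print.NodeRegressionMap <- function(x, ...) {
  cat(sprintf("NodeRegressionMap (%s): %dx%d, max |Z| = %.2f\n",
              attr(x, "covariate"), nrow(x), ncol(x), max(abs(x))))
  invisible(x)
}

#' Heat map of a node regression map
#'
#' Lattice image of per-node covariate Z scores, blue (negative) to red
#' (positive), centred on zero.
#'
#' @param x A `NodeRegressionMap`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.NodeRegressionMap <- function(x, ...) {
  lim <- max(abs(x))
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
  graphics::image(seq_len(ncol(x)), seq_len(nrow(x)), t(unclass(x)),
                  zlim = c(-lim, lim), col = pal, xlab = "lattice column",
                  ylab = "lattice row",
                  main = paste0("node Z: ", attr(x, "covariate")), ...)
  invisible(x)
}

#' Permutation significance of the maximal node covariate score
#'
#' The observed statistic is the maximal absolute node regression Z over
#' the lattice for the true labels. The null is built by permuting the
#' covariate assignment: in `"retrain"` mode a map is re-fit per
#' permutation with fresh seeded initialisation and presentation order (on
#' a gene subsample when the study is large), capturing training
#' stochasticity; in `"regress"` mode the single trained map is reused and
#' only the labels are permuted (fast, approximate). The p-value uses the
#' add-one convention `(b + 1) / (n_perm + 1)` where `b` counts permuted
#' statistics at or above the observed one.
#'
#' @param study A standardized [expression_study()].
#' @param covariate Covariate name (binary over samples).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for permutations (and per-permutation training
#'   in `"retrain"` mode).
#' @param mode `"retrain"` (default) or `"regress"`.
#' @param grid A [som_grid()] template.
#' @param epochs Training epochs per fit.
#' @param max_genes Gene subsample cap in `"retrain"` mode (default 2000).
#' @return List of class `PermTest`: `p`, `statistic`, `null` (permuted
#'   statistics), `n_perm`, `mode`, `n_exceed`.
#' @export
permutation_significance <- function(study, covariate = "treatment",
                                     n_perm = 1000, seed = 1,
                                     mode = c("retrain", "regress"),
                                     grid = som_grid(), epochs = 20,
                                     max_genes = 2000) {
  stopifnot(inherits(study, "ExpressionStudy"))
  mode <- match.arg(mode)
  if (n_perm < 100) stop("n_perm must be >= 100")
  x <- covariate_indicator(study$annotations, covariate)
  if (min(table(x)) < 2) stop("need at least 2 samples per covariate group")
  seed <- as.integer(seed)
  if (mode == "retrain" && nrow(study$values) > max_genes) {
    keep <- withr::with_seed(seed, sample.int(nrow(study$values), max_genes))
    study <- expression_study(study$values[keep, , drop = FALSE],
                              study$annotations)
  }
  fit_stat <- function(labels, fit_seed) {
    g <- grid
    g$seed <- fit_seed
    trained <- train_som(study, g, epochs = epochs)
    max(abs(node_regression_z(trained$weights, labels)))
  }
  if (mode == "retrain") {
    observed <- fit_stat(x, grid$seed)
    perms <- withr::with_seed(seed, replicate(n_perm, sample(x),
                                              simplify = FALSE))
    null <- vapply(seq_len(n_perm), function(b)
      fit_stat(perms[[b]], seed + b), numeric(1))
  } else {
    trained <- train_som(study, grid, epochs = epochs)
    observed <- max(abs(node_regression_z(trained$weights, x)))
    null <- withr::with_seed(seed, vapply(seq_len(n_perm), function(b)
      max(abs(node_regression_z(trained$weights, sample(x)))), numeric(1)))
  }
  b <- sum(null >= observed)
  structure(list(p = (b + 1) / (n_perm + 1), statistic = observed,
                 null = null, n_perm = n_perm, mode = mode, n_exceed = b,
                 covariate = covariate),
            class = "PermTest")
}

#' @export
print.PermTest <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s, %s mode): max |node Z| = %.2f, %d/%d permutations >= observed, p = %.4g\n",
    x$covariate, x$mode, x$statistic, x$n_exceed, x$n_perm, x$p))
  invisible(x)
}

#' Remove a binary covariate's variance from a study
#'
#' Fits, per gene, a linear model (intercept + 0/1 covariate indicator) of
#' expression across samples and returns the residual matrix, e.g. to take
#' sex variance out before a second map is fit. Residual rows have mean
#' zero; a gene orthogonal to the covariate keeps its (centred) values.
#'
#' @param study An [expression_study()].
#' @param covariate Covariate name (binary over samples).
#' @return The residual [expression_study()] with unchanged annotations.
#' @export
residualize <- function(study, covariate = "sex") {
  stopifnot(inherits(study, "ExpressionStudy"))
  x <- covariate_indicator(study$annotations, covariate)
  if (stats::sd(x) == 0) stop("covariate '", covariate, "' is constant")
  xc <- x - mean(x)
  beta <- (study$values %*% xc) / sum(xc^2)
  res <- study$values - rowMeans(study$values) - beta %*% t(xc)
  expression_study(res, study$annotations)
}
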