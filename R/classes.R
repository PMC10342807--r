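#' Construct an expression study
#'
#' Bundles a gene-by-sample expression matrix with per-sample covariates.
#' This is the object every downstream stage consumes; expression values are
#' assumed to be already normalised (e.g. RMA-style log intensities).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs).
#' @param annotations Data frame with columns `sample_id`, `treatment`
#'   (`"treated"` or `"control"`) and `sex` (`"F"` or `"M"`), one row per
#'   sample of `values`.
#' @return An object of class `ExpressionStudy`: a list with elements
#'   `values` and `annotations` (annotations reordered to match the columns).
#' @export
expression_study <- function(values, annotations) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate gene IDs: ", paste(dup, collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs in expression matrix")
  req <- c("sample_id", "treatment", "sex")
  miss_col <- setdiff(req, names(annotations))
  if (length(miss_col))
    stop("annotation table lacks column(s): ", paste(miss_col, collapse = ", "))
  annotations$sample_id <- as.character(annotations$sample_id)
  missing_samp <- setdiff(colnames(values), annotations$sample_id)
  if (length(missing_samp))
    stop("annotation missing for sample(s): ",
         paste(missing_samp, collapse = ", "))
  extra <- setdiff(annotations$sample_id, colnames(values))
  if (length(extra))
    stop("annotation rows without matching sample(s): ",
         paste(extra, collapse = ", "))
  annotations <- annotations[match(colnames(values), annotations$sample_id), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  bad_tr <- setdiff(unique(annotations$treatment), c("treated", "control"))
  if (length(bad_tr))
    stop("treatment values must be 'treated'/'control'; found: ",
         paste(bad_tr, collapse = ", "))
  bad_sex <- setdiff(unique(annotations$sex), c("F", "M"))
  if (length(bad_sex))
    stop("sex values must be 'F'/'M'; found: ", paste(bad_sex, collapse = ", "))
  structure(list(values = values, annotations = annotations),
            class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  tr <- table(x$annotations$treatment)
  cat(sprintf("ExpressionStudy: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%d %s", tr, names(tr)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ExpressionStudy <- function(x) dim(x$values)

#' Construct a gene profile of signed Z scores
#'
#' A gene profile maps gene identifiers to signed Z scores of differential
#' expression (positive = up-regulated under the contrast of interest). It is
#' the ranked substrate of enrichment, concordance and embedding.
#'
#' @param z Named numeric vector of finite Z scores; names are unique gene IDs.
#' @param name Profile label.
#' @return Object of class `GeneProfile`.
#' @export
gene_profile <- function(z, name = "profile") {
  if (!is.numeric(z) || is.null(names(z)) || any(names(z) == ""))
    stop("`z` must be a numeric vector with non-empty gene names")
  dup <- unique(names(z)[duplicated(names(z))])
  if (length(dup))
    stop("duplicate gene(s) in profile: ", paste(dup, collapse = ", "))
  if (any(!is.finite(z)))
    stop("non-finite Z score(s) in profile")
  structure(list(z = z, name = as.character(name)), class = "GeneProfile")
}

#' @export
print.GeneProfile <- function(x, ...) {
  cat(sprintf("GeneProfile '%s': %d genes, Z range [%.2f, %.2f]\n",
              x$name, length(x$z), min(x$z), max(x$z)))
  invisible(x)
}

#' @export
length.GeneProfile <- function(x) length(x$z)

#' @export
as.data.frame.GeneProfile <- function(x, ...) {
  data.frame(gene = names(x$z), z = unname(x$z), stringsAsFactors = FALSE)
}

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors of member genes. Set names must
#'   be unique and sets non-empty.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return Object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a named list")
  if (anyDuplicated(names(sets)))
    stop("duplicate set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  if (any(lengths(sets) == 0))
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  if (length(descriptions) != length(sets))
    stop("descriptions length must match number of sets")
  structure(list(sets = lapply(sets, as.character),
                 descriptions = as.character(descriptions)),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, sizes %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Construct a 2x2 up/down contingency table
#'
#' Counts of features significant in two profiles, cross-classified by
#' direction: `UU` up in both, `UD` up in the first and down in the second,
#' `DU` the converse, `DD` down in both.
#'
#' @param UU,UD,DU,DD Non-negative integer counts.
#' @return Object of class `ContingencyTable`.
#' @export
contingency_table <- function(UU, UD, DU, DD) {
  counts <- c(UU = UU, UD = UD, DU = DU, DD = DD)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers")
  structure(as.list(counts), class = "ContingencyTable")
}

#' @export
as.matrix.ContingencyTable <- function(x, ...) {
  matrix(c(x$UU, x$UD, x$DU, x$DD), nrow = 2, byrow = TRUE,
         dimnames = list(A = c("U", "D"), B = c("U", "D")))
}

#' @export
print.ContingencyTable <- function(x, ...) {
  print(as.matrix(x))
  invisible(x)
}
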