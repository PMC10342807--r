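# Readers and writers for the plain-text formats the pipeline touches:
# tab-separated expression matrices (plus a GCT 1.2 dialect), two-column
# sample annotations, GMT gene-set collections, two-column gene/Z profile
# tables and probe-to-gene mapping tables. All readers validate strictly and
# fail with the offending line/identifier; writer->reader compositions are
# identities.

#' Read an expression study from tab-separated files
#'
#' The matrix file has a header row of sample IDs and one row per gene, the
#' gene ID in the first column. The annotation file is tab-separated with
#' columns `sample_id`, `treatment` and `sex`.
#'
#' @param matrix_path Path to the expression matrix.
#' @param annotation_path Path to the sample annotation table.
#' @param format `"tsv"` (default) or `"gct"`; the GCT 1.2 dialect skips the
#'   two leading header lines and drops the `Description` column.
#' @return An [expression_study()].
#' @export
read_expression <- function(matrix_path, annotation_path,
                            format = c("tsv", "gct")) {
  format <- match.arg(format)
  for (p in c(matrix_path, annotation_path))
    if (!file.exists(p)) stop("file not found: ", p)
  skip <- if (format == "gct") 2L else 0L
  tab <- utils::read.delim(matrix_path, header = TRUE, skip = skip,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 2) stop("expression matrix needs >= 2 columns in ",
                          matrix_path)
  if (format == "gct" && tolower(names(tab)[2]) == "description")
    tab <- tab[, -2, drop = FALSE]
  genes <- as.character(tab[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene row(s) in ", matrix_path, ": ",
         paste(dup, collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals))
    stop("non-numeric expression values in ", matrix_path)
  rownames(vals) <- genes
  ann <- utils::read.delim(annotation_path, header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
  study <- expression_study(vals, ann)
  message(sprintf("read_expression: %d genes x %d samples from %s",
                  nrow(vals), ncol(vals), matrix_path))
  study
}

#' Write an expression study to tab-separated files
#'
#' @param study An [expression_study()].
#' @param matrix_path,annotation_path Output paths.
#' @param header Optional comment lines (without `#`) prepended to each file.
#' @export
write_expression <- function(study, matrix_path, annotation_path,
                             header = NULL) {
  stopifnot(inherits(study, "ExpressionStudy"))
  out <- data.frame(gene = rownames(study$values), study$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_commented(out, matrix_path, header)
  write_tsv_commented(study$annotations, annotation_path, header)
  invisible(study)
}

#' Read a GMT gene-set collection
#'
#' Each line: set name, description, then one or more member genes, all
#' tab-separated. Member order is preserved.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop("malformed GMT line ", bad[1], " in ", path,
         " (needs >= 3 tab-separated fields)")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  gene_set_collection(sets, vapply(fields, `[[`, "", 2L))
}

#' Write a GMT gene-set collection
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- mapply(function(nm, desc, members)
    paste(c(nm, desc, members), collapse = "\t"),
    names(collection$sets), collection$descriptions, collection$sets)
  writeLines(unname(lines), path)
  invisible(collection)
}

#' Read a gene/Z profile table
#'
#' Two tab-separated columns (gene, Z) with a header row. An optional
#' probe-to-gene mapping can be applied later with [collapse_probes()].
#'
#' @param path Path to the profile table.
#' @param name Profile label; defaults to the file name without extension.
#' @return A [gene_profile()].
#' @export
read_profile <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2) stop("no records in ", path)
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2))
    stop("malformed profile line ", which(nf < 2)[1] + 1L, " in ", path)
  genes <- vapply(fields, `[[`, "", 1L)
  zchr <- vapply(fields, `[[`, "", 2L)
  z <- suppressWarnings(as.numeric(zchr))
  if (anyNA(z))
    stop("non-numeric Z on line ", which(is.na(z))[1] + 1L, " of ", path)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("gene(s) repeated in ", path, ": ", paste(dup, collapse = ", "))
  names(z) <- genes
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_profile(z, name = name)
}

#' Write a gene/Z profile table
#'
#' @param profile A [gene_profile()].
#' @param path Output path.
#' @param digits Decimal places kept (round-trips identically at 6).
#' @param header Optional comment lines (without `#`) prepended.
#' @export
write_profile <- function(profile, path, digits = 6, header = NULL) {
  stopifnot(inherits(profile, "GeneProfile"))
  out <- data.frame(gene = names(profile$z),
                    z = round(unname(profile$z), digits))
  write_tsv_commented(out, path, header)
  invisible(profile)
}

#' Read a two-column probe-to-gene mapping table
#'
#' Tab-separated with a header row: probe ID then gene ID. Used by
#' [collapse_probes()].
#'
#' @param path Path to the mapping table.
#' @return Named character vector mapping probe -> gene.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("mapping table needs 2 columns in ", path)
  if (anyDuplicated(tab[[1]]))
    stop("probe(s) mapped twice in ", path, ": ",
         paste(unique(tab[[1]][duplicated(tab[[1]])]), collapse = ", "))
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

# Shared writer: optional '# '-prefixed comment header, then a TSV table.
write_tsv_commented <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
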