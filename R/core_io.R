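#' Construct an expression matrix object
#'
#' Bundles a genes-by-samples matrix of log2-scale normalized expression with
#' case/control group labels and platform provenance. This is the substrate of
#' every analysis stage in the package.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique (for microarray-style input,
#'   rows are probes until [collapse_probes()] is applied). Values are
#'   log2-scale normalized expression (log2 FPKM for RNA-seq-like data,
#'   normalized log2 intensities for microarray-like data). Missing values are
#'   rejected: inputs are expected to be fully normalized upstream.
#' @param groups Character or factor of length `ncol(values)` with entries
#'   `"case"` or `"control"`, one per sample, in column order.
#' @param platform One of `"rnaseq_fpkm_log2"` or `"microarray_norm"`.
#' @param paired Logical; `TRUE` declares a matched case/control design where
#'   the i-th case sample is paired with the i-th control sample.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `groups`, `platform`, `paired`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expression_matrix(m, c("case", "case", "control", "control"))
#' dim(em)
#' @export
expression_matrix <- function(values, groups,
                              platform = c("rnaseq_fpkm_log2", "microarray_norm"),
                              paired = FALSE) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values))
    stop_validation("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_validation("`values` must have row (gene) and column (sample) names")
  if (anyDuplicated(rownames(values)))
    stop_format("duplicate gene/probe ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop_format("duplicate sample ids in expression matrix")
  if (anyNA(values))
    stop_validation("missing values are not allowed in an expression matrix")
  groups <- as.character(groups)
  if (length(groups) != ncol(values))
    stop_validation("`groups` must provide exactly one label per sample")
  if (!all(groups %in% c("case", "control")))
    stop_validation("group labels must be 'case' or 'control'")
  if (isTRUE(paired) && sum(groups == "case") != sum(groups == "control"))
    stop_validation("paired design requires equal case and control group sizes")
  structure(list(
    values     = values,
    gene_ids   = rownames(values),
    sample_ids = colnames(values),
    groups     = groups,
    platform   = platform,
    paired     = isTRUE(paired)
  ), class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "case"), sum(x$groups == "control")))
  cat(sprintf("  platform: %s, paired: %s\n", x$platform, x$paired))
  invisible(x)
}

#' Subset an expression matrix to a set of genes
#'
#' @param em An `ExpressionMatrix`.
#' @param genes Character vector of gene ids; genes absent from `em` are
#'   dropped silently (use the returned row names to see what survived).
#' @return Numeric submatrix (possibly 0-row), genes in rows.
#' @keywords internal
gene_submatrix <- function(em, genes) {
  em$values[intersect(genes, em$gene_ids), , drop = FALSE]
}

#' Read a tab-separated expression matrix
#'
#' Expects a rectangular TSV with gene ids in the first column and a header
#' row of sample ids; cells are log2-scale expression. Samples not present in
#' `group_map` are rejected rather than silently dropped.
#'
#' @param path Path to the TSV file.
#' @param group_map Named character vector mapping sample id to `"case"` or
#'   `"control"`. Every sample column must be covered.
#' @inheritParams expression_matrix
#' @return An `ExpressionMatrix`.
#' @export
read_expression_matrix <- function(path, group_map,
                                   platform = c("rnaseq_fpkm_log2", "microarray_norm"),
                                   paired = FALSE) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    stop_format(sprintf("ragged TSV: rows have %s fields", paste(unique(nf), collapse = "/")))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    stop_format("duplicate sample ids in header")
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           quote = "", comment.char = "", stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop_format("non-numeric expression values")
  dimnames(vals) <- list(gene_ids, sample_ids)
  missing_lab <- setdiff(sample_ids, names(group_map))
  if (length(missing_lab))
    stop_validation(sprintf("unlabeled samples: %s", paste(missing_lab, collapse = ", ")))
  groups <- unname(group_map[sample_ids])
  if (!all(c("case", "control") %in% groups))
    stop_validation("both case and control groups must be non-empty")
  expression_matrix(vals, groups, platform = platform, paired = paired)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]; the round trip preserves ids and
#' values to full double precision.
#'
#' @param em An `ExpressionMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path) {
  df <- data.frame(gene = em$gene_ids, em$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene set
#'
#' @param name Set name.
#' @param members Character vector of gene ids; duplicates are removed.
#' @return An object of class `GeneSet` with elements `name` and `members`.
#' @export
gene_set <- function(name, members) {
  members <- unique(as.character(members))
  if (!length(members)) stop_validation(sprintf("gene set '%s' is empty", name))
  structure(list(name = as.character(name), members = members), class = "GeneSet")
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then member ids. The description is discarded and
#' duplicate members within a line are de-duplicated.
#'
#' @param path Path to a GMT file.
#' @return A list of `GeneSet` objects in file order (empty list for an empty
#'   file).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop_format(sprintf("GMT line with fewer than 3 fields: '%s'", substr(l, 1, 60)))
    gene_set(f[1], f[-(1:2)])
  })
}

#' Write gene sets in GMT format
#' @param sets List of `GeneSet` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, "na", s$members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' Serializes a stage-keyed result list together with the parameters that
#' produced it, so every reported number is traceable to a stage and a
#' parameter set. Timestamps are deliberately excluded so identical runs give
#' byte-identical files.
#'
#' @param report Named list (typically from [run_pipeline()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# condition helpers: typed errors so callers can distinguish bad formats
# from bad values from missing valleys
stop_format <- function(msg) stop(errorCondition(msg, class = c("warburgph_format_error", "warburgph_error")))
stop_validation <- function(msg) stop(errorCondition(msg, class = c("warburgph_validation_error", "warburgph_error")))
stop_no_valley <- function(msg) stop(errorCondition(msg, class = c("NoValleyError", "warburgph_error")))
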