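#' Construct an expression matrix
#'
#' An expression matrix is a numeric genes-by-samples matrix with unique row
#' (gene) and column (sample) names and a `units` attribute, either `"tpm"`
#' (linear transcripts-per-million) or `"log10"` (log10(TPM + 1)).
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   dimnames set.
#' @param units `"tpm"` or `"log10"`.
#' @return A numeric matrix of class `expr_matrix`.
#' @export
expression_matrix <- function(values, units = c("tpm", "log10")) {
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene (row) and sample (column) names",
         call. = FALSE)
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "), call. = FALSE)
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must all be finite", call. = FALSE)
  if (any(values < 0))
    stop("expression values must be non-negative", call. = FALSE)
  structure(values, units = units, class = c("expr_matrix", class(values)))
}

#' Subset an expression matrix, keeping units and dimensions
#'
#' @param x An `expr_matrix`.
#' @param i,j Gene and sample indices (ids, positions or logicals).
#' @param drop Ignored; subsets never drop to a vector.
#' @return An `expr_matrix`.
#' @export
`[.expr_matrix` <- function(x, i, j, drop = FALSE) {
  v <- unclass(x)
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  expression_matrix(v[i, j, drop = FALSE], units = attr(x, "units"))
}

#' Units of an expression matrix
#' @param m An `expr_matrix`.
#' @return `"tpm"` or `"log10"`.
#' @export
expr_units <- function(m) {
  u <- attr(m, "units")
  if (is.null(u)) stop("matrix has no units attribute; use expression_matrix()",
                       call. = FALSE)
  u
}

.assert_log10 <- function(m, what) {
  if (!identical(expr_units(m), "log10"))
    stop(what, " requires log10-scale expression; call log_transform() first",
         call. = FALSE)
  invisible(m)
}

#' Read a delimited expression table
#'
#' Reads a genes-by-samples expression table in TPM units from delimited
#' text. The first (or named) column carries gene identifiers; every other
#' column is one sample. Duplicate gene ids, non-numeric cells and empty
#' files are hard errors naming the offender.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @param gene_col Name or index of the gene-id column (default first).
#' @return An `expr_matrix` in TPM units.
#' @export
read_expression <- function(path, sep = "\t", gene_col = 1L) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (nrow(raw) == 0L) stop("no genes parsed from ", path, call. = FALSE)
  if (is.character(gene_col)) {
    if (!gene_col %in% names(raw))
      stop("gene-id column '", gene_col, "' not found", call. = FALSE)
    gene_col <- match(gene_col, names(raw))
  }
  ids <- as.character(raw[[gene_col]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene id(s) in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  vals <- raw[, -gene_col, drop = FALSE]
  if (ncol(vals) == 0L) stop("no sample columns in ", path, call. = FALSE)
  for (cn in names(vals)) {
    v <- vals[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop("non-numeric cell(s) in column '", cn, "'",
           if (length(bad)) paste0(", row ", bad[1L]), call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  expression_matrix(m, units = "tpm")
}

#' Write an expression table as TSV
#'
#' Deterministic output: rows and columns in their current order.
#'
#' @param m An `expr_matrix`.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_expression <- function(m, path, sep = "\t") {
  df <- data.frame(gene_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Required columns: `sample_id`, `stage`, `group`. Optional: `sex`,
#' `sibling_group`, `replicate_of` (filled with `NA` when absent).
#'
#' @param path TSV file path.
#' @return A data.frame, one row per sample.
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "stage", "group")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (opt in c("sex", "sibling_group", "replicate_of"))
    if (!opt %in% names(md)) md[[opt]] <- NA_character_
  dup <- unique(md$sample_id[duplicated(md$sample_id)])
  if (length(dup))
    stop("duplicate sample_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  md$stage <- as.character(md$stage)
  md
}

#' Log-transform an expression matrix
#'
#' Replaces every TPM value x by log10(x + 1). Zero TPM maps to 0.
#'
#' @param m An `expr_matrix` in TPM units.
#' @return An `expr_matrix` on the log10 scale.
#' @export
log_transform <- function(m) {
  if (!identical(expr_units(m), "tpm"))
    stop("log_transform() expects a TPM-scale matrix", call. = FALSE)
  if (any(m < 0)) stop("negative TPM value encountered", call. = FALSE)
  out <- log10(unclass(m) + 1)
  expression_matrix(out, units = "log10")
}

#' Remove genes below the detection threshold
#'
#' A gene is dropped only when every sample is below `threshold` on the
#' log10(TPM + 1) scale; one sample at or above the threshold retains it.
#' Gene order is preserved.
#'
#' @param m An `expr_matrix` on the log10 scale.
#' @param threshold Log-scale cutoff, default 0.1; must be >= 0. The
#'   analysis is insensitive to choices in 0 to 1.5.
#' @return The filtered `expr_matrix`.
#' @export
filter_low_expression <- function(m, threshold = 0.1) {
  .assert_log10(m, "filter_low_expression()")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("`threshold` must be a single non-negative number", call. = FALSE)
  keep <- apply(unclass(m) >= threshold, 1L, any)
  expression_matrix(unclass(m)[keep, , drop = FALSE], units = "log10")
}
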