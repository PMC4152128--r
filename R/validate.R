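# Input validation shared across the package.

# Coerce to a genes x samples numeric matrix with unique dimnames,
# inventing gene/sample names only when absent.
as_expression_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("x must be a numeric genes x samples matrix")
  if (nrow(x) < 1L || ncol(x) < 2L)
    stop("x needs at least 1 gene and 2 samples")
  if (anyNA(x))
    stop("x contains missing values; load with read_expression(impute = TRUE) or clean first")
  if (is.null(rownames(x)))
    rownames(x) <- paste0("gene", seq_len(nrow(x)))
  if (is.null(colnames(x)))
    colnames(x) <- paste0("sample", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("gene IDs must be unique")
  if (anyDuplicated(colnames(x))) stop("sample IDs must be unique")
  x
}

# Validate labels against a matrix and return them as a factor in column
# order of x (or in their own order when x is NULL). Requires >= 2 classes,
# every class non-empty, exact sample coverage.
validate_labels <- function(labels, x = NULL) {
  if (is.null(names(labels)) && !is.null(x) &&
      length(labels) == ncol(x)) {
    names(labels) <- colnames(x)
  }
  if (is.null(names(labels)))
    stop("labels must be named by sample ID (or match ncol(x))")
  if (!is.null(x)) {
    x <- as_expression_matrix(x)
    missing_lab <- setdiff(colnames(x), names(labels))
    if (length(missing_lab) > 0L)
      stop("samples without a label: ", paste(missing_lab, collapse = ", "))
    unknown <- setdiff(names(labels), colnames(x))
    if (length(unknown) > 0L)
      stop("labels for unknown samples: ", paste(unknown, collapse = ", "))
    labels <- labels[colnames(x)]
  }
  f <- factor(as.character(labels))
  names(f) <- names(labels)
  if (nlevels(f) < 2L)
    stop("need at least 2 classes, got ", nlevels(f))
  if (any(table(f) == 0L)) stop("every class must be non-empty")
  f
}
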