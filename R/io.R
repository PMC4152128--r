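#' Read an expression matrix from TSV/CSV
#'
#' Reads a genes x samples expression table. The first row is a header of
#' sample identifiers, the first column holds gene identifiers, and every
#' remaining cell must be numeric. The delimiter is chosen from the file
#' extension: \code{.csv} is comma-separated, anything else tab-separated.
#'
#' Row and column order of the file is preserved exactly; nothing is sorted.
#' Missing or non-numeric cells are an error by default because the
#' decomposition assumes complete data; \code{impute = TRUE} instead replaces
#' missing cells (\code{NA}/empty) by the per-gene mean of the observed values.
#'
#' @param path path to a TSV or CSV file.
#' @param impute logical; impute missing cells by per-gene means instead of
#'   failing. Default \code{FALSE}.
#' @return a numeric matrix (genes x samples) with gene identifiers as row
#'   names and sample identifiers as column names.
#' @seealso [read_labels()], [write_selection()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g2\t3\t4"), tf)
#' read_expression(tf)
read_expression <- function(path, impute = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("expression table needs >= 2 sample columns")
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene IDs: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  x <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)), USE.NAMES = FALSE))
  x <- matrix(x, nrow = nrow(raw), ncol = length(sample_ids))
  bad <- which(is.na(x), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    if (impute) {
      for (i in unique(bad[, 1L])) {
        row <- x[i, ]
        if (all(is.na(row)))
          stop("gene ", gene_ids[i], " has no observed values to impute from")
        x[i, is.na(row)] <- mean(row, na.rm = TRUE)
      }
    } else {
      stop(sprintf(
        "non-numeric or missing cell at gene %s, sample %s (use impute = TRUE to fill by gene means)",
        gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
    }
  }
  dimnames(x) <- list(gene_ids, sample_ids)
  x
}

#' Write an expression matrix to TSV/CSV
#'
#' Inverse of [read_expression()]: writes the matrix with a header row of
#' sample IDs and gene IDs in the first column, at 12 significant digits so a
#' read-back reproduces the values.
#'
#' @param x numeric matrix with gene row names and sample column names.
#' @param path output path; extension selects the delimiter as in
#'   [read_expression()].
#' @return invisibly, \code{path}.
#' @export
write_expression <- function(x, path) {
  x <- as_expression_matrix(x)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(gene = rownames(x),
                   signif(x, 12L),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample class labels
#'
#' Reads a two-column tab-separated table of \code{sample_id}, \code{class}.
#' A header row is detected when the second field of the first line is the
#' literal token \code{"class"}. The labels must cover exactly the samples of
#' \code{x}: a sample without a label, or a label for an unknown sample, is an
#' error, as is a single class overall (at least two classes are required).
#'
#' @param path path to the label file.
#' @param x the expression matrix the labels belong to (used for validation);
#'   may be \code{NULL} to skip the coverage check.
#' @return a factor of class labels named by sample ID, ordered like the
#'   columns of \code{x} when given.
#' @export
read_labels <- function(path, x = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("label table needs two columns: sample_id, class")
  if (nrow(raw) > 0L && identical(tolower(raw[1L, 2L]), "class"))
    raw <- raw[-1L, , drop = FALSE]
  labels <- stats::setNames(raw[[2L]], raw[[1L]])
  if (anyDuplicated(names(labels)))
    stop("duplicate sample IDs in label file")
  validate_labels(labels, x)
}

#' Write a gene selection to TSV
#'
#' Writes the ranked selection of a fit as a three-column tab-separated table
#' \code{rank}, \code{gene_id}, \code{score} in selection order. An empty
#' selection writes the header only, with a warning.
#'
#' @param object a \code{cipmd} fit (see [cipmd()]) or a data frame with
#'   columns \code{rank}, \code{gene_id}, \code{score}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_selection <- function(object, path) {
  sel <- if (inherits(object, "cipmd")) object$selection else object
  stopifnot(is.data.frame(sel),
            all(c("rank", "gene_id", "score") %in% names(sel)))
  if (nrow(sel) == 0L) warning("writing an empty selection (header only)")
  out <- data.frame(rank = sel$rank, gene_id = sel$gene_id,
                    score = signif(sel$score, 12L),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene selection written by [write_selection()]
#'
#' @param path path to the selection TSV.
#' @return data frame with columns \code{rank}, \code{gene_id}, \code{score}.
#' @export
read_selection <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("integer", "character", "numeric"),
                    stringsAsFactors = FALSE)
}
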