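#' Class means and grand mean of an expression matrix
#'
#' Computes the per-class mean expression profile m_i (mean over the sample
#' columns of each class) and the grand mean m (unweighted mean over all n
#' sample columns).
#'
#' @param x genes x samples numeric matrix.
#' @param labels per-sample class labels (factor or character, named by
#'   sample ID or in column order).
#' @return list with \code{class_means} (genes x classes matrix, one column
#'   per class level) and \code{grand_mean} (length-p vector).
#' @export
class_statistics <- function(x, labels) {
  x <- as_expression_matrix(x)
  labels <- validate_labels(labels, x)
  cm <- vapply(levels(labels),
               function(cl) rowMeans(x[, labels == cl, drop = FALSE]),
               numeric(nrow(x)))
  cm <- matrix(cm, nrow = nrow(x),
               dimnames = list(rownames(x), levels(labels)))
  list(class_means = cm, grand_mean = rowMeans(x))
}

#' Scatter-matrix factors of a labeled expression matrix
#'
#' Builds the low-rank factors of the between-class scatter
#' S_b = sum_i n_i (m_i - m)(m_i - m)' and within-class scatter
#' S_w = sum_i sum_j (x_ij - m_i)(x_ij - m_i)', without ever forming a
#' p x p matrix: \code{Hb} is p x C with columns sqrt(n_i) (m_i - m) so
#' S_b = Hb Hb', and \code{Hw} is p x n with columns x_ij - m_i so
#' S_w = Hw Hw'. The between- and within-class distances are the traces,
#' computed as squared Frobenius norms of the factors.
#'
#' @inheritParams class_statistics
#' @return an object of class \code{"scatter_factors"}: list with \code{Hb},
#'   \code{Hw}, \code{trace_b}, \code{trace_w}, \code{class_means},
#'   \code{grand_mean}, \code{labels}, \code{n_i}.
#' @seealso [compute_beta()], [st_svd()]
#' @export
scatter_factors <- function(x, labels) {
  x <- as_expression_matrix(x)
  labels <- validate_labels(labels, x)
  st <- class_statistics(x, labels)
  n_i <- table(labels)
  Hb <- sweep(st$class_means - st$grand_mean, 2L,
              sqrt(as.numeric(n_i)), `*`)
  Hw <- x - st$class_means[, as.character(labels), drop = FALSE]
  colnames(Hw) <- colnames(x)
  structure(list(
    Hb = Hb, Hw = Hw,
    trace_b = sum(Hb^2), trace_w = sum(Hw^2),
    class_means = st$class_means, grand_mean = st$grand_mean,
    labels = labels, n_i = as.integer(n_i)
  ), class = "scatter_factors")
}

#' Trade-off parameter beta between the scatter matrices
#'
#' The total scatter matrix weighs within-class closeness against
#' between-class separation through beta. In \code{"adaptive"} mode beta is
#' the ratio of the two distances, tr(S_b) / tr(S_w), so the two terms enter
#' the total scatter on a comparable scale; a numeric \code{mode} fixes beta
#' at that constant.
#'
#' @param factors a \code{"scatter_factors"} object.
#' @param mode \code{"adaptive"} or a single non-negative number.
#' @return beta, a non-negative scalar.
#' @export
compute_beta <- function(factors, mode = "adaptive") {
  stopifnot(inherits(factors, "scatter_factors"))
  if (is.numeric(mode)) {
    if (length(mode) != 1L || is.na(mode) || mode < 0)
      stop("fixed beta must be a single non-negative number")
    return(as.numeric(mode))
  }
  if (!identical(mode, "adaptive"))
    stop("mode must be \"adaptive\" or a non-negative number")
  if (factors$trace_w <= 0)
    stop("within-class scatter has zero trace (identical samples within ",
         "every class); adaptive beta is undefined - use a fixed beta")
  factors$trace_b / factors$trace_w
}
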