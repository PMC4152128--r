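#' @export
print.cipmd <- function(x, ...) {
  cat(if (x$supervised) "Class-information-based penalized matrix decomposition"
      else "Penalized matrix decomposition (unsupervised baseline)", "\n")
  cat(sprintf("  %d genes x %d samples; gamma = %g (c = %.3f), K = %d\n",
              length(x$gene_ids), length(x$sample_ids), x$gamma, x$c, x$K))
  if (x$supervised)
    cat(sprintf("  beta = %.4g (tr S_b = %.4g, tr S_w = %.4g), alpha = %g, rank r = %d\n",
                x$beta, x$trace_b, x$trace_w, x$alpha, x$rank))
  nz <- sum(apply(abs(as.matrix(x$factors$u)), 1L, max) > 0)
  cat(sprintf("  eigensample nonzeros: %d; selected genes: %d (n_select = %d)\n",
              nz, nrow(x$selection), x$n_select))
  if (nrow(x$selection) > 0L) {
    cat("  top genes:",
        paste(utils::head(x$selection$gene_id, 5L), collapse = ", "),
        if (nrow(x$selection) > 5L) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
summary.cipmd <- function(object, ...) {
  s <- list(
    supervised = object$supervised,
    p = length(object$gene_ids), n = length(object$sample_ids),
    gamma = object$gamma, c = object$c, K = object$K,
    alpha = object$alpha, beta = object$beta,
    trace_b = object$trace_b, trace_w = object$trace_w,
    rank = object$rank, sigma = object$sigma,
    d = object$factors$d,
    iterations = object$factors$iterations,
    converged = object$factors$converged,
    n_nonzero = sum(apply(abs(as.matrix(object$factors$u)), 1L, max) > 0),
    n_selected = nrow(object$selection),
    selection = object$selection
  )
  class(s) <- "summary.cipmd"
  s
}

#' @export
print.summary.cipmd <- function(x, ...) {
  cat(if (x$supervised) "CIPMD fit\n" else "PMD baseline fit\n")
  cat(sprintf("  dimensions: %d genes x %d samples\n", x$p, x$n))
  cat(sprintf("  sparsity: gamma = %g, L1 bound c = %.3f\n", x$gamma, x$c))
  if (x$supervised) {
    cat(sprintf("  scatter: tr S_b = %.4g, tr S_w = %.4g, beta = %.4g\n",
                x$trace_b, x$trace_w, x$beta))
    cat(sprintf("  embedding: rank %d, alpha = %g, leading sigma = %s\n",
                x$rank, x$alpha,
                paste(signif(utils::head(x$sigma, 4L), 4L), collapse = ", ")))
  }
  cat(sprintf("  factors: K = %d, d = %s; iterations = %s (converged: %s)\n",
              x$K, paste(signif(x$d, 4L), collapse = ", "),
              paste(x$iterations, collapse = ", "),
              paste(x$converged, collapse = ", ")))
  cat(sprintf("  selection: %d of %d nonzero eigensample entries\n",
              x$n_selected, x$n_nonzero))
  if (x$n_selected > 0L) {
    cat("\n")
    print(utils::head(x$selection, 10L), row.names = FALSE)
    if (x$n_selected > 10L) cat("  ...", x$n_selected - 10L, "more rows\n")
  }
  invisible(x)
}

#' Eigensample weights of a fit
#'
#' Returns the gene scores of the fit: the absolute eigensample weight per
#' gene (maximum over the K factors), named by gene ID. With
#' \code{matrix = TRUE} the full signed p x K eigensample matrix is returned
#' instead.
#'
#' @param object a \code{"cipmd"} fit.
#' @param matrix return the signed factor matrix rather than the score
#'   vector.
#' @param ... unused.
#' @export
coef.cipmd <- function(object, matrix = FALSE, ...) {
  u <- as.matrix(object$factors$u)
  rownames(u) <- object$gene_ids
  if (matrix) return(u)
  stats::setNames(apply(abs(u), 1L, max), object$gene_ids)
}

#' Residuals of the penalized decomposition
#'
#' The residual of the decomposed matrix (the embedded matrix D for a
#' supervised fit, the centered expression matrix for the baseline) after
#' removing the K rank-one factors d_k u_k v_k'.
#'
#' @param object a \code{"cipmd"} fit.
#' @param ... unused.
#' @export
residuals.cipmd <- function(object, ...) {
  target <- if (object$supervised) object$embedded$d else object$embedded
  f <- object$factors
  u <- as.matrix(f$u)
  v <- as.matrix(f$v)
  target - u %*% (f$d * t(v))
}

#' Plot eigensample weights
#'
#' Plots the absolute eigensample weight of every gene against gene index,
#' highlighting the selected genes. The sparsity of the factor is visible as
#' the mass of genes at exactly zero.
#'
#' @param x a \code{"cipmd"} fit.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.cipmd <- function(x, ...) {
  score <- coef(x)
  sel <- x$gene_ids %in% x$selection$gene_id
  graphics::plot(seq_along(score), score, type = "h",
                 col = ifelse(sel, "firebrick", "grey70"),
                 xlab = "gene index", ylab = "|eigensample weight|",
                 main = if (x$supervised) "CIPMD eigensample" else
                   "PMD eigensample", ...)
  graphics::legend("topright", legend = c("selected", "not selected"),
                   col = c("firebrick", "grey70"), lty = 1, bty = "n")
  invisible(x)
}
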