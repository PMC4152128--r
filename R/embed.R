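#' Singular value decomposition of the total scatter matrix
#'
#' The total scatter matrix S_t = S_b - beta S_w (or S_b + beta S_w with
#' \code{st_form = "sum"}) is symmetric with rank at most C + n, so its SVD is
#' computed from the factored form without allocating a p x p array: the
#' combined factor F = [Hb | sqrt(beta) Hw] is reduced by a thin QR, the small
#' (C+n) x (C+n) core R S R' (S a diagonal of signs) is eigendecomposed
#' densely, and the eigenpairs are mapped back through Q. For a symmetric
#' matrix the singular values are the absolute eigenvalues and the left
#' singular vectors the eigenvectors, which keeps the subsequent power
#' transform real even when S_t is indefinite.
#'
#' Singular values below \code{rank_tol * max(sigma)} are dropped. Each
#' retained vector is sign-fixed so its largest-magnitude entry is positive,
#' making the output deterministic.
#'
#' @param factors a \code{"scatter_factors"} object from [scatter_factors()].
#' @param beta non-negative trade-off parameter (see [compute_beta()]).
#' @param st_form \code{"diff"} for S_b - beta S_w (default) or \code{"sum"}
#'   for S_b + beta S_w.
#' @param rank_tol relative cutoff separating rank deficiency from noise.
#' @return list with \code{u} (p x r, orthonormal columns), \code{sigma}
#'   (r singular values, positive, non-increasing), \code{lambda} (the signed
#'   eigenvalues, same order) and \code{r}.
#' @export
st_svd <- function(factors, beta, st_form = c("diff", "sum"),
                   rank_tol = 1e-10) {
  stopifnot(inherits(factors, "scatter_factors"))
  st_form <- match.arg(st_form)
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
    stop("beta must be a single non-negative number")
  Fm <- cbind(factors$Hb, sqrt(beta) * factors$Hw)
  signs <- c(rep(1, ncol(factors$Hb)),
             rep(if (st_form == "diff") -1 else 1, ncol(factors$Hw)))
  qrF <- qr(Fm)
  Q <- qr.Q(qrF)
  R <- qr.R(qrF)
  signs <- signs[qrF$pivot]             # qr() pivots columns of F
  core <- R %*% (signs * t(R))          # R diag(signs) R'
  core <- (core + t(core)) / 2          # enforce symmetry against roundoff
  es <- eigen(core, symmetric = TRUE)
  ord <- order(abs(es$values), decreasing = TRUE)
  lambda <- es$values[ord]
  sigma <- abs(lambda)
  keep <- sigma > rank_tol * max(sigma, 0)
  if (!any(keep))
    stop("total scatter matrix is numerically zero; nothing to embed")
  lambda <- lambda[keep]
  sigma <- sigma[keep]
  u <- Q %*% es$vectors[, ord[keep], drop = FALSE]
  # deterministic sign: largest-magnitude entry of each column positive
  for (j in seq_len(ncol(u))) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  rownames(u) <- rownames(factors$Hb)
  list(u = u, sigma = sigma, lambda = lambda, r = length(sigma))
}

#' Build the class-informed data matrix D = U diag(sigma^alpha)
#'
#' Scales each left singular vector of the total scatter matrix by its
#' singular value raised to the power alpha. Larger alpha amplifies the
#' dominance of the leading class-discriminative directions before the sparse
#' decomposition.
#'
#' @param sv list with components \code{u} and \code{sigma} as returned by
#'   [st_svd()].
#' @param alpha positive power applied to the singular values.
#' @return an object of class \code{"embedded_matrix"}: list with \code{d}
#'   (p x r matrix), \code{u}, \code{sigma}, \code{alpha}, \code{r}.
#' @export
build_embedded <- function(sv, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a single positive number")
  stopifnot(is.matrix(sv$u), length(sv$sigma) == ncol(sv$u))
  d <- sweep(sv$u, 2L, sv$sigma^alpha, `*`)
  structure(list(d = d, u = sv$u, sigma = sv$sigma, alpha = alpha,
                 r = length(sv$sigma)),
            class = "embedded_matrix")
}
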