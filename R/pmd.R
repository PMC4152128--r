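#' Soft-thresholding operator
#'
#' The proximal map of the L1 penalty: sign(x) * max(|x| - delta, 0).
#'
#' @param x numeric vector.
#' @param delta threshold, a single non-negative number.
#' @return vector of the same length as \code{x}.
#' @export
soft_threshold <- function(x, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0)
    stop("delta must be a single non-negative number")
  sign(x) * pmax(abs(x) - delta, 0)
}

#' Maximize a'u over the intersection of the L2 unit ball and an L1 ball
#'
#' Solves max a'u subject to ||u||_2 <= 1 and ||u||_1 <= c. The maximizer is
#' u = S(a, delta) / ||S(a, delta)||_2 with S the soft-thresholding operator:
#' delta = 0 if the plain L2 projection already satisfies the L1 bound,
#' otherwise delta is found by binary search on [0, max|a_i|) so that
#' ||u||_1 = c. The bound is infeasible below 1 for a unit vector, so c < 1
#' is clamped to 1 with a warning.
#'
#' With exactly tied leading |a_i| and c below the L1 norm of the tied-vertex
#' solution, the search converges to the boundary; the result is accepted if
#' ||u||_1 is within 1e-4 of the closest attainable value, else flagged by a
#' warning.
#'
#' @param a numeric vector, not all zero.
#' @param c L1 bound, >= 1.
#' @param maxit maximum binary-search iterations.
#' @return unit vector of the same length as \code{a}.
#' @export
l1_constrained_unit <- function(a, c, maxit = 100L) {
  if (!is.numeric(a) || all(a == 0)) stop("a must be a nonzero numeric vector")
  if (!is.numeric(c) || length(c) != 1L || is.na(c)) stop("c must be a number")
  if (c < 1) {
    warning("L1 bound c < 1 is infeasible for a unit vector; clamped to 1")
    c <- 1
  }
  u <- a / sqrt(sum(a^2))
  if (sum(abs(u)) <= c + 1e-6) return(u)
  lo <- 0
  hi <- max(abs(a))
  width0 <- hi
  for (it in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    su <- soft_threshold(a, mid)
    nrm <- sqrt(sum(su^2))
    l1 <- if (nrm > 0) sum(abs(su)) / nrm else 1
    if (abs(l1 - c) < 1e-12 || (hi - lo) < 1e-15 * width0) break
    if (l1 > c) lo <- mid else hi <- mid
  }
  su <- soft_threshold(a, (lo + hi) / 2)
  nrm <- sqrt(sum(su^2))
  if (nrm == 0) {                      # mid hit max|a|; back off to lo side
    su <- soft_threshold(a, lo)
    nrm <- sqrt(sum(su^2))
  }
  u <- su / nrm
  if (sum(abs(u)) > c + 1e-4)
    warning("binary search could not attain the L1 bound (tied entries); ",
            "||u||_1 = ", format(sum(abs(u))))
  u
}

#' Rank-one penalized matrix decomposition
#'
#' Finds a rank-one factor (u, v, d) of X maximizing u'Xv subject to
#' ||u||_2 = 1, ||u||_1 <= c, ||v||_2 = 1 (no penalty on v). Alternates
#' u <- argmax over the constrained set for fixed v (a soft-thresholded
#' projection, see [l1_constrained_unit()]) and v <- X'u / ||X'u||_2 until
#' the largest componentwise change of either factor drops below \code{tol};
#' then d = u'Xv.
#'
#' @param x numeric matrix, p x r, nonzero.
#' @param c L1 bound on u (>= 1).
#' @param init \code{"svd"} initializes v at the leading right singular
#'   vector (deterministic); \code{"random"} at a random unit vector drawn
#'   from the current RNG stream.
#' @param tol convergence tolerance on the max-norm change of u and v.
#' @param max_iter iteration cap; hitting it sets \code{converged = FALSE}
#'   with a warning.
#' @return list with \code{u}, \code{v}, \code{d}, \code{iterations},
#'   \code{converged}, and \code{objective} (the value u'Xv after each
#'   iteration, non-decreasing).
#' @export
pmd_rank_one <- function(x, c, init = c("svd", "random"),
                         tol = 1e-6, max_iter = 200L) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (all(x == 0)) stop("x must be nonzero")
  init <- match.arg(init)
  v <- if (init == "svd") leading_right_sv(x) else {
    v0 <- stats::rnorm(ncol(x))
    v0 / sqrt(sum(v0^2))
  }
  u <- rep(0, nrow(x))
  objective <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    u_new <- l1_constrained_unit(as.numeric(x %*% v), c)
    b <- as.numeric(crossprod(x, u_new))
    nb <- sqrt(sum(b^2))
    v_new <- if (nb > 0) b / nb else v
    objective <- c(objective, sum(u_new * (x %*% v_new)))
    delta <- max(max(abs(u_new - u)), max(abs(v_new - v)))
    u <- u_new
    v <- v_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("rank-one PMD did not converge in ", max_iter, " iterations")
  d <- sum(u * (x %*% v))
  list(u = u, v = v, d = d, iterations = it, converged = converged,
       objective = objective)
}

# Leading right singular vector of x via the r x r cross-product (r is small
# here: never more than C + n columns).
leading_right_sv <- function(x) {
  cp <- crossprod(x)
  v <- eigen((cp + t(cp)) / 2, symmetric = TRUE)$vectors[, 1L]
  i <- which.max(abs(v))
  if (v[i] < 0) v <- -v
  v
}

#' Rank-K penalized matrix decomposition by deflation
#'
#' Extracts K rank-one factors sequentially: factor k is the rank-one PMD of
#' the residual X - sum_{j<k} d_j u_j v_j'. Stops early with a warning if the
#' residual becomes numerically zero before K factors.
#'
#' @inheritParams pmd_rank_one
#' @param K number of factors.
#' @return an object of class \code{"pmd_factors"}: list with \code{u}
#'   (p x K), \code{v} (r x K), \code{d} (length K), \code{c},
#'   \code{iterations}, \code{converged}, \code{objective} (list of traces).
#' @export
pmd_rank_k <- function(x, c, K = 1L, init = c("svd", "random"),
                       tol = 1e-6, max_iter = 200L) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (!is.numeric(K) || length(K) != 1L || K < 1) stop("K must be >= 1")
  K <- as.integer(K)
  init <- match.arg(init)
  res <- x
  norm0 <- sqrt(sum(x^2))
  us <- vs <- ds <- list()
  its <- integer(0)
  conv <- logical(0)
  objs <- list()
  for (k in seq_len(K)) {
    if (sqrt(sum(res^2)) <= 1e-12 * max(norm0, 1)) {
      warning("residual numerically zero after ", k - 1L,
              " factors; returning fewer than K = ", K)
      break
    }
    f <- pmd_rank_one(res, c, init = init, tol = tol, max_iter = max_iter)
    us[[k]] <- f$u
    vs[[k]] <- f$v
    ds[[k]] <- f$d
    its[k] <- f$iterations
    conv[k] <- f$converged
    objs[[k]] <- f$objective
    res <- res - f$d * tcrossprod(f$u, f$v)
  }
  structure(list(
    u = do.call(cbind, us), v = do.call(cbind, vs),
    d = unlist(ds), c = c,
    iterations = its, converged = conv, objective = objs
  ), class = "pmd_factors")
}
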