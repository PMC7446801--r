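# Logarithmic norms (matrix measures) and metric transformations.
#
# The logarithmic norm mu(A) = lim_{eps -> 0+} (||I + eps*A|| - 1)/eps bounds
# the instantaneous growth rate of ||exp(At)||: trajectories of xdot = A(t) x
# separate no faster than exp(integral of mu(A(t))).  Closed forms exist for
# the induced 1- and 2-norms and those are what the certificates use; the
# finite-difference limit quotient is retained as an independent oracle.

.check_square <- function(a, arg = "a") {
  if (!is.matrix(a) || !is.numeric(a)) {
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(a) != ncol(a)) {
    stop(sprintf("'%s' must be square (got %d x %d)", arg, nrow(a), ncol(a)),
         call. = FALSE)
  }
  if (!all(is.finite(a))) {
    stop(sprintf("'%s' contains non-finite entries", arg), call. = FALSE)
  }
  invisible(a)
}

#' Logarithmic norm induced by the vector 1-norm
#'
#' Computes \eqn{\mu_1(A) = \max_j \left[a_{jj} + \sum_{i \ne j} |a_{ij}|\right]},
#' the matrix measure induced by the 1-norm: the maximum over columns of the
#' diagonal entry plus the absolute off-diagonal column sum.
#'
#' @param a Square numeric matrix.
#' @return Scalar, the 1-norm logarithmic norm of `a`.
#' @seealso [mu2()], [mu_limit_oracle()]
#' @examples
#' mu1(matrix(c(-2, 1, 1, -2), 2, 2)) # -1
#' @export
mu1 <- function(a) {
  .check_square(a)
  col_abs <- colSums(abs(a))
  d <- diag(a)
  max(d + (col_abs - abs(d)))
}

#' Logarithmic norm induced by the vector 2-norm
#'
#' Computes \eqn{\mu_2(A) = \lambda_{\max}\!\big((A^T + A)/2\big)}, the largest
#' eigenvalue of the symmetric part of `a`.  For a symmetric matrix this is the
#' largest eigenvalue of `a` itself.  Negativity of \eqn{\mu_2} of a system's
#' Jacobian along trajectories certifies contraction in the Euclidean metric.
#'
#' @inheritParams mu1
#' @return Scalar, the 2-norm logarithmic norm of `a`.
#' @examples
#' mu2(matrix(c(0, 1, -1, 0), 2, 2)) # 0: antisymmetric
#' @export
mu2 <- function(a) {
  .check_square(a)
  s <- (a + t(a)) / 2
  max(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
}

#' Finite-difference oracle for the logarithmic-norm limit definition
#'
#' Evaluates the defining one-sided limit quotient
#' \eqn{(\|I + \epsilon A\|_i - 1)/\epsilon} at a small fixed \eqn{\epsilon},
#' using the induced 1-norm (maximum absolute column sum) or the induced
#' 2-norm (largest singular value).  Intended as an independent check of the
#' closed forms [mu1()] and [mu2()], not as a production path: the quotient
#' carries an \eqn{O(\epsilon \|A\|^2)} discretization error.
#'
#' @inheritParams mu1
#' @param which_norm Either `1` or `2`, selecting the induced norm.
#' @param epsilon Step of the difference quotient, in `(0, 1e-3]`.
#' @return Scalar approximation of the logarithmic norm.
#' @export
mu_limit_oracle <- function(a, which_norm = 2, epsilon = 1e-7) {
  .check_square(a)
  if (!is.numeric(epsilon) || length(epsilon) != 1 ||
      epsilon <= 0 || epsilon > 1e-3) {
    stop("'epsilon' must be a scalar in (0, 1e-3]", call. = FALSE)
  }
  which_norm <- match.arg(as.character(which_norm), c("1", "2"))
  m <- diag(nrow(a)) + epsilon * a
  nm <- if (which_norm == "1") norm(m, type = "O") else norm(m, type = "2")
  (nm - 1) / epsilon
}

#' Symmetric and antisymmetric parts of a square matrix
#'
#' Every square matrix decomposes uniquely as
#' \eqn{W = \tfrac12(W + W^T) + \tfrac12(W - W^T)}.  The antisymmetric part has
#' zero diagonal and entries \eqn{w_{ij} = -w_{ji}}; the decomposition is the
#' pair of orthogonal projections onto the symmetric and antisymmetric
#' subspaces.
#'
#' @inheritParams mu1
#' @return The symmetric (resp. antisymmetric) part, a square matrix.
#' @export
sym_part <- function(a) {
  .check_square(a)
  (a + t(a)) / 2
}

#' @rdname sym_part
#' @export
antisym_part <- function(a) {
  .check_square(a)
  (a - t(a)) / 2
}

#' Construct a contraction metric from a coordinate transformation
#'
#' An invertible transformation \eqn{y = \theta x} induces the metric
#' \eqn{M = \theta^T \theta}: squared lengths in the new coordinates are
#' \eqn{x^T M x}.  Contraction in any such metric implies convergence of
#' trajectories in all coordinate systems, possibly after transient divergence
#' in the original (identity-metric) coordinates.
#'
#' @param theta Invertible square numeric matrix.
#' @return An object of class `contraction_metric` with components `theta`,
#'   `theta_inv` and `m = t(theta) %*% theta`.
#' @examples
#' identity_metric(3)
#' contraction_metric(diag(c(1, 10)))
#' @export
contraction_metric <- function(theta) {
  .check_square(theta, "theta")
  theta_inv <- tryCatch(solve(theta), error = function(e) {
    stop("'theta' is not invertible: ", conditionMessage(e), call. = FALSE)
  })
  m <- crossprod(theta)
  ev_min <- min(eigen((m + t(m)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values)
  if (ev_min <= 1e-12 * max(1, norm(m, "2"))) {
    stop("metric m = t(theta) %*% theta is numerically singular", call. = FALSE)
  }
  structure(list(theta = theta, theta_inv = theta_inv, m = m),
            class = "contraction_metric")
}

#' @rdname contraction_metric
#' @param n Dimension of the identity metric.
#' @export
identity_metric <- function(n) {
  contraction_metric(diag(n))
}

#' @export
print.contraction_metric <- function(x, ...) {
  cat(sprintf("<contraction_metric> dim %d", nrow(x$theta)))
  if (isTRUE(all.equal(x$theta, diag(nrow(x$theta))))) cat(" (identity)")
  cat("\n")
  invisible(x)
}

#' Logarithmic 2-norm in a transformed metric
#'
#' Computes \eqn{\mu_2(\theta A \theta^{-1})}: the 2-norm matrix measure of
#' `a` after the change of coordinates defining `metric`.  A matrix can have
#' positive \eqn{\mu_2} in the identity metric yet negative \eqn{\mu_2} in a
#' suitable transformed metric; this is the signature of transiently diverging
#' but ultimately contracting dynamics.
#'
#' @inheritParams mu1
#' @param metric A [contraction_metric()] of matching dimension.
#' @return Scalar, \eqn{\mu_2} of the transformed matrix.
#' @examples
#' a <- matrix(c(-1, 0, 10, -1), 2, 2)
#' mu2(a)                                           # +4
#' mu2_in_metric(a, contraction_metric(diag(c(1, 10)))) # -0.5
#' @export
mu2_in_metric <- function(a, metric) {
  .check_square(a)
  if (!inherits(metric, "contraction_metric")) {
    stop("'metric' must be a contraction_metric", call. = FALSE)
  }
  if (nrow(metric$theta) != nrow(a)) {
    stop("metric dimension does not match matrix dimension", call. = FALSE)
  }
  mu2(metric$theta %*% a %*% metric$theta_inv)
}

# Largest eigenvalue of a symmetric operator given only its matvec, via
# Lanczos with full reorthogonalization.  Used for metric-transformed
# Jacobians whose dimension (n + n^2) makes dense eigensolves impractical.
# The start vector is deterministic so results are reproducible without
# touching the global RNG state.
.lanczos_lambda_max <- function(matvec, dim, m = min(dim, 120L), tol = 1e-10) {
  m <- as.integer(max(2L, min(m, dim)))
  q <- sin(seq_len(dim)) + 0.5 / seq_len(dim)
  q <- q / sqrt(sum(q^2))
  qs <- matrix(0, dim, m)
  alpha <- numeric(m)
  beta <- numeric(m)
  qs[, 1] <- q
  lam_prev <- -Inf
  k_used <- m
  for (k in seq_len(m)) {
    v <- matvec(qs[, k])
    alpha[k] <- sum(qs[, k] * v)
    v <- v - alpha[k] * qs[, k]
    if (k > 1) v <- v - beta[k - 1] * qs[, k - 1]
    # full reorthogonalization against all previous vectors
    v <- v - qs[, seq_len(k), drop = FALSE] %*%
      crossprod(qs[, seq_len(k), drop = FALSE], v)
    b <- sqrt(sum(v^2))
    tmat <- diag(alpha[seq_len(k)], k, k)
    if (k > 1) {
      idx <- seq_len(k - 1)
      tmat[cbind(idx, idx + 1)] <- beta[idx]
      tmat[cbind(idx + 1, idx)] <- beta[idx]
    }
    lam <- max(eigen(tmat, symmetric = TRUE, only.values = TRUE)$values)
    if (b < 1e-14 || (k > 10 && abs(lam - lam_prev) < tol * max(1, abs(lam)))) {
      k_used <- k
      break
    }
    lam_prev <- lam
    if (k < m) {
      beta[k] <- b
      qs[, k + 1] <- v / b
    }
    k_used <- k
  }
  lam
}
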