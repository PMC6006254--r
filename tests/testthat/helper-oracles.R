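# Independent oracles used across tests.

# Exact nonnegative least-squares by support enumeration: the optimum of a
# 3-variable NNLS problem is the best feasible unconstrained solution over
# some support set (KKT), so enumerating all supports is an exact oracle.
support_nnls_oracle <- function(A, b) {
  n <- ncol(A)
  best <- list(x = numeric(n), res = sqrt(sum(b^2)))  # x = 0 candidate
  for (k in 1:n) {
    for (S in utils::combn(n, k, simplify = FALSE)) {
      xs <- qr.coef(qr(A[, S, drop = FALSE]), b)
      if (any(is.na(xs)) || any(xs < 0)) next
      x <- numeric(n); x[S] <- xs
      res <- sqrt(sum((A %*% x - b)^2))
      if (res < best$res) best <- list(x = x, res = res)
    }
  }
  best
}

# Brute-force nonnegative grid search at a fixed step. The unconstrained
# solution is checked directly; constrained optima lie on the boundary of the
# nonnegative octant, so faces (2 free vars), edges (1) and the origin are
# scanned on the grid.
grid_nnls_oracle <- function(A, b, step = 0.001, upper = 0.8) {
  xs <- seq(0, upper, by = step)
  G <- crossprod(A)          # Gram matrix
  h <- drop(crossprod(A, b))
  bb <- sum(b^2)
  best <- list(x = numeric(3), res2 = bb)
  x0 <- tryCatch(solve(A, b), error = function(e) NULL)
  if (!is.null(x0) && all(x0 >= 0)) {
    r2 <- sum((A %*% x0 - b)^2)
    if (r2 < best$res2) best <- list(x = as.numeric(x0), res2 = r2)
  }
  for (i in 1:3) {                       # edges
    r2 <- bb - 2 * h[i] * xs + G[i, i] * xs^2
    j <- which.min(r2)
    if (r2[j] < best$res2) {
      x <- numeric(3); x[i] <- xs[j]
      best <- list(x = x, res2 = r2[j])
    }
  }
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {  # faces
    i <- pair[1]; j <- pair[2]
    r2 <- bb + outer(-2 * h[i] * xs + G[i, i] * xs^2,
                     -2 * h[j] * xs + G[j, j] * xs^2, "+") +
      2 * G[i, j] * outer(xs, xs)
    k <- arrayInd(which.min(r2), dim(r2))
    if (r2[k] < best$res2) {
      x <- numeric(3); x[i] <- xs[k[1]]; x[j] <- xs[k[2]]
      best <- list(x = x, res2 = min(r2))
    }
  }
  best$res <- sqrt(max(best$res2, 0))
  best
}

# random 3x3 unmixing-like system; about half have an infeasible
# unconstrained solution
random_unmix_system <- function() {
  A <- matrix(stats::runif(9, 0.2, 1.2), 3, 3)
  x <- stats::runif(3, 0, 0.5)
  flip <- stats::runif(3) < 0.4
  x[flip] <- -stats::runif(sum(flip), 0, 0.2)
  list(A = A, b = as.numeric(A %*% x))
}

quick_params <- function(...) photophysics_params(...)
quick_scheme <- function(...) excitation_scheme(...)
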