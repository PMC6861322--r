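# Dense two-phase primal simplex for small linear programs.
#
# The flux-balance problems solved here involve toy networks with at most a
# dozen or so reactions, so a dense tableau simplex with Bland's anti-cycling
# rule is both adequate and dependency-free. Problems are stated as
#   max / min  c'x   s.t.  A x = b,  lb <= x <= ub
# with finite bounds (callers clamp infinities beforehand).

# Iterate the simplex on a canonical tableau.
# Tb: m x (n+1) tableau [coeffs | rhs], basis: current basic column per row,
# cost: length-n cost vector (minimization). Returns list(Tb, basis, status).
simplex_iterate <- function(Tb, basis, cost, tol = 1e-9, maxit = 20000L) {
  m <- nrow(Tb)
  n <- ncol(Tb) - 1L
  for (it in seq_len(maxit)) {
    # reduced costs r = c - c_B' B^{-1} A (tableau already canonical)
    cb <- cost[basis]
    red <- cost - as.vector(crossprod(Tb[, seq_len(n), drop = FALSE], cb))
    red[basis] <- 0
    enter <- which(red < -tol)
    if (length(enter) == 0L) {
      return(list(Tb = Tb, basis = basis, status = "optimal"))
    }
    j <- enter[1L] # Bland: smallest eligible index
    col <- Tb[, j]
    pos <- which(col > tol)
    if (length(pos) == 0L) {
      return(list(Tb = Tb, basis = basis, status = "unbounded"))
    }
    ratio <- Tb[pos, n + 1L] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    i <- cand[which.min(basis[cand])] # Bland tie-break on basis index
    # pivot on (i, j)
    piv <- Tb[i, j]
    Tb[i, ] <- Tb[i, ] / piv
    other <- setdiff(seq_len(m), i)
    Tb[other, ] <- Tb[other, , drop = FALSE] -
      outer(Tb[other, j], Tb[i, ])
    Tb[other, j] <- 0
    basis[i] <- j
  }
  list(Tb = Tb, basis = basis, status = "maxit")
}

# Solve min c'z s.t. M z = d, z >= 0 by the two-phase method.
solve_standard_form <- function(cvec, M, d, tol = 1e-9) {
  m <- nrow(M)
  n <- ncol(M)
  neg <- d < 0
  if (any(neg)) {
    M[neg, ] <- -M[neg, , drop = FALSE]
    d[neg] <- -d[neg]
  }
  # Phase 1: artificial variables
  Tb <- cbind(M, diag(m), d)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  p1 <- simplex_iterate(Tb, basis, cost1, tol = tol)
  if (p1$status != "optimal") {
    return(list(status = "infeasible", x = NULL, obj = NA_real_))
  }
  if (sum(p1$Tb[, ncol(p1$Tb)][p1$basis > n]) > 1e-7) {
    return(list(status = "infeasible", x = NULL, obj = NA_real_))
  }
  Tb <- p1$Tb
  basis <- p1$basis
  # Drive remaining (zero-valued) artificials out of the basis.
  drop_rows <- integer(0)
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      cand <- which(abs(Tb[i, seq_len(n)]) > tol)
      if (length(cand) == 0L) {
        drop_rows <- c(drop_rows, i) # redundant constraint row
      } else {
        j <- cand[1L]
        piv <- Tb[i, j]
        Tb[i, ] <- Tb[i, ] / piv
        other <- setdiff(seq_len(m), i)
        Tb[other, ] <- Tb[other, , drop = FALSE] - outer(Tb[other, j], Tb[i, ])
        Tb[other, j] <- 0
        basis[i] <- j
      }
    }
  }
  if (length(drop_rows) > 0L) {
    Tb <- Tb[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  # Phase 2 on original columns only
  Tb <- Tb[, c(seq_len(n), ncol(Tb)), drop = FALSE]
  cost2 <- cvec
  p2 <- simplex_iterate(Tb, basis, cost2, tol = tol)
  if (p2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, obj = NA_real_))
  }
  if (p2$status != "optimal") {
    return(list(status = "degenerate", x = NULL, obj = NA_real_))
  }
  x <- numeric(n)
  x[p2$basis] <- p2$Tb[, ncol(p2$Tb)]
  list(status = "optimal", x = x, obj = sum(cvec * x))
}

#' Solve a small bounded linear program
#'
#' Maximizes (or minimizes) `c'x` subject to `A x = b` and box constraints
#' `lb <= x <= ub`, using a dense two-phase simplex. Intended for the toy
#' metabolic networks shipped with the package (tens of variables at most).
#'
#' @param objective Numeric cost vector, length `n`.
#' @param A Equality constraint matrix (`m x n`); may contain redundant rows.
#' @param b Equality right-hand side, length `m`.
#' @param lb,ub Finite lower/upper variable bounds, length `n`.
#' @param maximize Logical; maximize (default) or minimize.
#' @return A list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (solution vector or `NULL`) and `obj` (objective value).
#' @examples
#' # max x1 + x2 with x1 + x2 <= 1 written as equality with a slack
#' lp_solve(c(1, 1, 0), matrix(c(1, 1, 1), 1), 1, c(0, 0, 0), c(2, 2, 2))
#' @export
lp_solve <- function(objective, A, b, lb, ub, maximize = TRUE) {
  n <- length(objective)
  A <- matrix(as.numeric(A), nrow = length(b), ncol = n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("lp_solve requires finite bounds; clamp infinities first")
  }
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = NULL, obj = NA_real_))
  }
  # shift y = x - lb, 0 <= y <= ub - lb; add slack rows y_i + s_i = range_i
  rng <- ub - lb
  b2 <- b - as.vector(A %*% lb)
  m <- length(b)
  M <- cbind(rbind(A, diag(n)), rbind(matrix(0, m, n), diag(n)))
  d <- c(b2, rng)
  cvec <- c(if (maximize) -objective else objective, rep(0, n))
  res <- solve_standard_form(cvec, M, d)
  if (res$status != "optimal") {
    return(list(status = res$status, x = NULL, obj = NA_real_))
  }
  x <- res$x[seq_len(n)] + lb
  list(status = "optimal", x = x, obj = sum(objective * x))
}
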