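# Dense two-phase primal simplex. The DEA programs this package solves are
# tiny (roughly 10 rows by 50 columns), so a tableau method with Bland's
# anti-cycling rule is both adequate and easy to audit.

#' Solve a small linear program
#'
#' Minimizes `c'x` subject to `A1 x <= b1`, `A3 x = b3`, `x >= 0`, by the
#' two-phase primal simplex method with Bland's rule. Intended for the
#' linearized (super-)SBM programs; not a general-purpose large-scale solver.
#'
#' @param cc objective coefficient vector.
#' @param A1,b1 inequality constraints (`A1 x <= b1`), or `NULL`.
#' @param A3,b3 equality constraints (`A3 x = b3`), or `NULL`.
#' @param tol pivot/feasibility tolerance.
#' @param max_iter iteration cap per phase.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxiter"`) and, when optimal, the solution `x` and objective `value`.
#' @keywords internal
#' @noRd
simplex_lp <- function(cc, A1 = NULL, b1 = NULL, A3 = NULL, b3 = NULL,
                       tol = 1e-9, max_iter = 10000L) {
  nv <- length(cc)
  n1 <- if (is.null(A1)) 0L else nrow(A1)
  n3 <- if (is.null(A3)) 0L else nrow(A3)
  m <- n1 + n3
  A <- matrix(0, m, nv + n1)
  b <- numeric(m)
  if (n1 > 0) {
    A[1:n1, 1:nv] <- A1
    A[cbind(1:n1, nv + 1:n1)] <- 1  # slack columns
    b[1:n1] <- b1
  }
  if (n3 > 0) {
    A[n1 + 1:n3, 1:nv] <- A3
    b[n1 + 1:n3] <- b3
  }
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  ntot <- nv + n1

  # initial basis: slack where its +1 coefficient survived the sign flip,
  # artificial variable otherwise
  basis <- integer(m)
  art_rows <- integer(0)
  for (r in seq_len(m)) {
    if (r <= n1 && !neg[r]) basis[r] <- nv + r else art_rows <- c(art_rows, r)
  }
  n_art <- length(art_rows)
  if (n_art > 0) {
    Aart <- matrix(0, m, n_art)
    Aart[cbind(art_rows, seq_len(n_art))] <- 1
    A <- cbind(A, Aart)
    basis[art_rows] <- ntot + seq_len(n_art)
  }

  run_phase <- function(A, b, basis, obj, tol, max_iter) {
    m <- nrow(A)
    for (it in seq_len(max_iter)) {
      cb <- obj[basis]
      red <- obj - as.numeric(crossprod(A, cb))  # valid: tableau kept canonical
      red[basis] <- 0
      cand <- which(red < -tol)
      if (length(cand) == 0)
        return(list(A = A, b = b, basis = basis, status = "optimal"))
      j <- min(cand)                       # Bland: lowest-index entering
      col <- A[, j]
      pos <- which(col > tol)
      if (length(pos) == 0)
        return(list(A = A, b = b, basis = basis, status = "unbounded"))
      ratio <- b[pos] / col[pos]
      rmin <- min(ratio)
      tie <- pos[ratio <= rmin + tol * (1 + rmin)]
      r <- tie[which.min(basis[tie])]      # Bland: lowest basis index leaving
      piv <- A[r, j]
      A[r, ] <- A[r, ] / piv
      b[r] <- b[r] / piv
      other <- setdiff(seq_len(m), r)
      f <- A[other, j]
      A[other, ] <- A[other, , drop = FALSE] - outer(f, A[r, ])
      b[other] <- b[other] - f * b[r]
      b[b < 0 & b > -tol] <- 0
      basis[r] <- j
    }
    list(A = A, b = b, basis = basis, status = "maxiter")
  }

  ncols <- ncol(A)
  if (n_art > 0) {
    obj1 <- c(rep(0, ntot), rep(1, n_art))
    ph1 <- run_phase(A, b, basis, obj1, tol, max_iter)
    if (ph1$status != "optimal") return(list(status = "infeasible"))
    A <- ph1$A; b <- ph1$b; basis <- ph1$basis
    if (sum(b[basis > ntot]) > 1e-7) return(list(status = "infeasible"))
    # pivot residual (degenerate) artificials out of the basis where possible
    for (r in which(basis > ntot)) {
      j <- which(abs(A[r, 1:ntot]) > tol)[1]
      if (!is.na(j)) {
        piv <- A[r, j]
        A[r, ] <- A[r, ] / piv
        b[r] <- b[r] / piv
        other <- setdiff(seq_len(nrow(A)), r)
        f <- A[other, j]
        A[other, ] <- A[other, , drop = FALSE] - outer(f, A[r, ])
        b[other] <- b[other] - f * b[r]
        basis[r] <- j
      }
    }
    keep <- basis <= ntot  # rows still basic in an artificial are redundant
    A <- A[keep, 1:ntot, drop = FALSE]
    b <- b[keep]
    basis <- basis[keep]
  } else {
    A <- A[, 1:ntot, drop = FALSE]
  }

  obj2 <- c(cc, rep(0, n1))
  ph2 <- run_phase(A, b, basis, obj2, tol, max_iter)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  x <- numeric(ntot)
  x[ph2$basis] <- ph2$b
  list(status = "optimal", x = x[1:nv], value = sum(cc * x[1:nv]))
}
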