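# Independent oracles for the DEA tests, by brute force over the
# peer-weight polytope. Both SBM objectives are linear-fractional in
# lambda on suitable regions, so their minima are attained at polytope
# vertices; the oracles enumerate every vertex exactly (all square active
# sets) and evaluate the fractional objective there. No code is shared
# with the LP solver path: no Charnes-Cooper substitution, no pivoting.

# Vertices of {lambda >= 0, sum(lambda) = 1, C lambda <= d}.
# Every vertex solves a square system built from sum(lambda)=1 plus n-1
# active constraints chosen among lambda_i = 0 and rows of C.
polytope_vertices <- function(n, C = NULL, d = NULL, tol = 1e-9) {
  if (n == 1) {
    v <- matrix(1, 1, 1)
    if (!is.null(C) && any(C %*% t(v) > d + tol)) return(NULL)
    return(v)
  }
  rows <- list()
  for (i in seq_len(n)) {
    a <- numeric(n); a[i] <- -1
    rows[[length(rows) + 1]] <- list(a = a, b = 0)      # -lambda_i <= 0
  }
  if (!is.null(C)) {
    for (j in seq_len(nrow(C)))
      rows[[length(rows) + 1]] <- list(a = C[j, ], b = d[j])
  }
  nr <- length(rows)
  if (nr < n - 1) return(NULL)
  combs <- utils::combn(nr, n - 1)
  out <- list()
  for (ci in seq_len(ncol(combs))) {
    act <- combs[, ci]
    A <- rbind(rep(1, n), t(vapply(rows[act], `[[`, numeric(n), "a")))
    b <- c(1, vapply(rows[act], `[[`, numeric(1), "b"))
    v <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(v)) next
    if (any(v < -tol)) next
    if (!is.null(C) && any(C %*% v > d + tol)) next
    out[[length(out) + 1]] <- pmax(v, 0)
  }
  if (length(out) == 0) return(NULL)
  unique(do.call(rbind, out))
}

# VRS SBM score of unit k: minimize the ratio
# (1 - mean((x0 - X'lambda)/x0)) / (1 + mean((Y'lambda - y0)/y0))
# over the polytope {lambda in simplex, X'lambda <= x0, Y'lambda >= y0}.
# Linear-fractional => optimum at a vertex.
oracle_sbm <- function(X, Y, k) {
  x0 <- X[k, ]; y0 <- Y[k, ]
  C <- rbind(t(X), -t(Y))
  d <- c(x0, -y0)
  V <- polytope_vertices(nrow(X), C, d)
  if (is.null(V)) stop("oracle: empty SBM polytope (should be impossible)")
  num <- 1 - rowMeans(sweep(-(V %*% X), 2, x0, "+") %*% diag(1 / x0, length(x0)))
  den <- 1 + rowMeans(sweep(V %*% Y, 2, y0, "-") %*% diag(1 / y0, length(y0)))
  min(num / den)
}

# VRS super-efficiency score of unit k. With the optimal reference point
# xbar = pmax(X'lambda, x0), ybar = pmin(Y'lambda, y0), the objective is
# linear-fractional within each clamp pattern (which inputs/outputs bind
# at the unit's own level); enumerate all patterns, each restricted to its
# polytope, and take the best vertex.
oracle_super <- function(X, Y, k) {
  x0 <- X[k, ]; y0 <- Y[k, ]
  Xo <- X[-k, , drop = FALSE]; Yo <- Y[-k, , drop = FALSE]
  no <- nrow(Xo); m <- length(x0); s <- length(y0)
  best <- Inf
  for (pa in seq_len(2^m) - 1) {
    A <- which(bitwAnd(pa, 2^(seq_len(m) - 1)) > 0)   # Xo'lambda >= x0 here
    for (pb in seq_len(2^s) - 1) {
      B <- which(bitwAnd(pb, 2^(seq_len(s) - 1)) > 0) # Yo'lambda <= y0 here
      C <- NULL; d <- NULL
      for (i in seq_len(m)) {
        if (i %in% A) { C <- rbind(C, -Xo[, i]); d <- c(d, -x0[i]) }
        else          { C <- rbind(C,  Xo[, i]); d <- c(d,  x0[i]) }
      }
      for (r in seq_len(s)) {
        if (r %in% B) { C <- rbind(C,  Yo[, r]); d <- c(d,  y0[r]) }
        else          { C <- rbind(C, -Yo[, r]); d <- c(d, -y0[r]) }
      }
      V <- polytope_vertices(no, C, d)
      if (is.null(V)) next
      xb_over_x0 <- matrix(1, nrow(V), m)
      if (length(A) > 0)
        xb_over_x0[, A] <- sweep((V %*% Xo)[, A, drop = FALSE], 2, x0[A], "/")
      yb_over_y0 <- matrix(1, nrow(V), s)
      if (length(B) > 0)
        yb_over_y0[, B] <- sweep((V %*% Yo)[, B, drop = FALSE], 2, y0[B], "/")
      num <- rowMeans(xb_over_x0)
      den <- rowMeans(yb_over_y0)
      ok <- den > 1e-12
      if (any(ok)) best <- min(best, min(num[ok] / den[ok]))
    }
  }
  best
}

# random positive DEA instance within the oracle-tractable envelope
random_instance <- function(seed, n_max = 5) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  m <- sample(1:2, 1)
  s <- sample(seq_len(3 - m), 1)
  list(X = matrix(stats::runif(n * m, 0.2, 3), n, m),
       Y = matrix(stats::runif(n * s, 0.2, 3), n, s))
}

# small long-format indicator data frame used across the IO tests
toy_panel_data <- function(n_units = 4, years = 2015:2016,
                           inputs = c("centers", "staff", "beds"),
                           outputs = c("visits", "inpatients", "bed_util"),
                           seed = 1) {
  set.seed(seed)
  d <- expand.grid(unit = paste0("U", seq_len(n_units)), year = years,
                   indicator = c(inputs, outputs),
                   stringsAsFactors = FALSE)
  d$value <- round(stats::runif(nrow(d), 1, 100), 3)
  d
}
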