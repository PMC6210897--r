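# Slacks-based measure (SBM) of efficiency and its super-efficiency
# extension. Both are fractional programs; each is linearized exactly by
# the standard positive-scalar substitution (normalize the denominator to
# one) and solved as a small LP.

#' Construct a DEA evaluation cross-section
#'
#' @param X n x m matrix of inputs, strictly positive.
#' @param Y n x s matrix of outputs, strictly positive.
#' @param unit_ids unit identifiers; defaults to rownames of `X` or
#'   `1..n`.
#' @return object of class `dmu_set`.
#' @export
dmu_set <- function(X, Y, unit_ids = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (any(!is.finite(X)) || any(!is.finite(Y)) || any(X <= 0) || any(Y <= 0))
    stop("all inputs and outputs must be finite and strictly positive")
  if (is.null(unit_ids)) unit_ids <- rownames(X)
  if (is.null(unit_ids)) unit_ids <- as.character(seq_len(nrow(X)))
  rownames(X) <- rownames(Y) <- unit_ids
  structure(list(X = X, Y = Y, unit_ids = unit_ids), class = "dmu_set")
}

#' @export
print.dmu_set <- function(x, ...) {
  cat(sprintf("dmu_set: %d units, %d inputs, %d outputs\n",
              nrow(x$X), ncol(x$X), ncol(x$Y)))
  invisible(x)
}

#' Options for the SBM solvers
#'
#' @param returns_to_scale `"vrs"` adds the convexity constraint
#'   `sum(lambda) = 1` to both stages (the default); `"crs"` drops it.
#' @param efficiency_tolerance a stage-1 score of at least
#'   `1 - efficiency_tolerance` counts as efficient and triggers the
#'   super-efficiency re-score.
#' @param lp_tolerance pivot/feasibility tolerance passed to the LP solver.
#' @param infeasible_policy what [score_dmu()] reports when the
#'   super-efficiency program cannot be solved: `"flag"` records status
#'   `"infeasible"` with an `NA` score; `"cap"` records the numeric
#'   `infeasible_cap` instead.
#' @param infeasible_cap score substituted under `infeasible_policy="cap"`.
#' @return list of class `solve_options`.
#' @export
solve_options <- function(returns_to_scale = c("vrs", "crs"),
                          efficiency_tolerance = 1e-6,
                          lp_tolerance = 1e-9,
                          infeasible_policy = c("flag", "cap"),
                          infeasible_cap = 2) {
  returns_to_scale <- match.arg(returns_to_scale)
  infeasible_policy <- match.arg(infeasible_policy)
  if (!(efficiency_tolerance > 0 && efficiency_tolerance <= 1e-3))
    stop("efficiency_tolerance must be in (0, 1e-3]")
  if (!(lp_tolerance > 0 && lp_tolerance <= 1e-3))
    stop("lp_tolerance must be in (0, 1e-3]")
  structure(list(returns_to_scale = returns_to_scale,
                 efficiency_tolerance = efficiency_tolerance,
                 lp_tolerance = lp_tolerance,
                 infeasible_policy = infeasible_policy,
                 infeasible_cap = infeasible_cap),
            class = "solve_options")
}

#' Slacks-based measure of efficiency for one unit
#'
#' Solves the SBM program for unit `k` against the frontier spanned by all
#' units: minimize
#' `(1 - mean(s_in/x0)) / (1 + mean(s_out/y0))` subject to
#' `x0 = X'lambda + s_in`, `y0 = Y'lambda - s_out`, all variables
#' nonnegative, plus `sum(lambda) = 1` under variable returns to scale.
#' The fractional program is linearized exactly by scaling all variables by
#' a positive scalar `t` that normalizes the denominator to one, and solved
#' as an LP; the reported score is the true optimum, in (0, 1], with 1
#' meaning no input excess and no output shortfall.
#'
#' @param dmus a [dmu_set()].
#' @param k index (or unit id) of the unit under evaluation.
#' @param opts a [solve_options()].
#' @return list of class `sbm_result`: `score`, `slacks_in`, `slacks_out`,
#'   `lambda` (peer weights over all units), `status`, `stage = "sbm"`.
#' @export
solve_sbm <- function(dmus, k, opts = solve_options()) {
  stopifnot(inherits(dmus, "dmu_set"))
  k <- resolve_unit(dmus, k)
  X <- dmus$X; Y <- dmus$Y
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  x0 <- X[k, ]; y0 <- Y[k, ]
  # variables: t, Lambda (n), S_in (m), S_out (s), all >= 0
  cc <- c(1, rep(0, n), -1 / (m * x0), rep(0, s))
  Aeq <- rbind(
    c(1, rep(0, n), rep(0, m), 1 / (s * y0)),
    t(vapply(seq_len(m), function(i)
      c(-x0[i], X[, i], as.numeric(seq_len(m) == i), rep(0, s)),
      numeric(1 + n + m + s))),
    t(vapply(seq_len(s), function(r)
      c(-y0[r], Y[, r], rep(0, m), -as.numeric(seq_len(s) == r)),
      numeric(1 + n + m + s))))
  beq <- c(1, rep(0, m + s))
  if (opts$returns_to_scale == "vrs") {
    Aeq <- rbind(Aeq, c(-1, rep(1, n), rep(0, m + s)))
    beq <- c(beq, 0)
  }
  r <- simplex_lp(cc, A3 = Aeq, b3 = beq, tol = opts$lp_tolerance)
  if (r$status != "optimal")
    stop("SBM LP solver failed with status '", r$status, "'")
  tt <- r$x[1]
  structure(list(
    score = min(r$value, 1),  # clip roundoff above 1
    slacks_in = stats::setNames(r$x[(n + 2):(n + m + 1)] / tt, colnames(X)),
    slacks_out = stats::setNames(r$x[(n + m + 2):(n + m + s + 1)] / tt,
                                 colnames(Y)),
    lambda = stats::setNames(r$x[2:(n + 1)] / tt, dmus$unit_ids),
    projection = NULL,
    status = "optimal", stage = "sbm"), class = "sbm_result")
}

#' Super-efficiency SBM score for one efficient unit
#'
#' Re-scores unit `k` against the frontier spanned by all *other* units:
#' minimize `mean(xbar/x0) / mean(ybar/y0)` over reference points
#' `(xbar, ybar)` with `xbar >= X'lambda` (peers only), `ybar <= Y'lambda`,
#' `xbar >= x0`, `0 <= ybar <= y0`, plus the convexity constraint under
#' VRS. The optimum is at least 1 and ranks units that all receive a plain
#' SBM score of 1. The same denominator-normalizing linearization as in
#' [solve_sbm()] is used.
#'
#' @inheritParams solve_sbm
#' @return list of class `sbm_result`: `score` (`delta >= 1`), `lambda`
#'   (peer weights, zero at `k`), `projection` (list `x`, `y`: the optimal
#'   reference point), `status` (`"optimal"` or `"infeasible"`),
#'   `stage = "super"`.
#' @export
solve_super_sbm <- function(dmus, k, opts = solve_options()) {
  stopifnot(inherits(dmus, "dmu_set"))
  k <- resolve_unit(dmus, k)
  X <- dmus$X; Y <- dmus$Y
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  if (n < 2) stop("super-efficiency needs at least 2 units")
  x0 <- X[k, ]; y0 <- Y[k, ]
  Xo <- X[-k, , drop = FALSE]; Yo <- Y[-k, , drop = FALSE]
  no <- n - 1
  nv <- 1 + no + m + s
  # variables: t, Lambda (no), xtilde (m), ytilde (s)
  cc <- c(0, rep(0, no), 1 / (m * x0), rep(0, s))
  Aeq <- rbind(c(0, rep(0, no), rep(0, m), 1 / (s * y0)))
  beq <- 1
  A1 <- rbind(
    t(vapply(seq_len(m), function(i)
      c(0, Xo[, i], -as.numeric(seq_len(m) == i), rep(0, s)), numeric(nv))),
    t(vapply(seq_len(s), function(r)
      c(0, -Yo[, r], rep(0, m), as.numeric(seq_len(s) == r)), numeric(nv))),
    t(vapply(seq_len(m), function(i)
      c(x0[i], rep(0, no), -as.numeric(seq_len(m) == i), rep(0, s)),
      numeric(nv))),
    t(vapply(seq_len(s), function(r)
      c(-y0[r], rep(0, no), rep(0, m), as.numeric(seq_len(s) == r)),
      numeric(nv))))
  b1 <- rep(0, 2 * (m + s))
  if (opts$returns_to_scale == "vrs") {
    Aeq <- rbind(Aeq, c(-1, rep(1, no), rep(0, m + s)))
    beq <- c(beq, 0)
  }
  r <- simplex_lp(cc, A1 = A1, b1 = b1, A3 = Aeq, b3 = beq,
                  tol = opts$lp_tolerance)
  if (r$status != "optimal") {
    return(structure(list(score = NA_real_, slacks_in = NULL,
                          slacks_out = NULL, lambda = NULL, projection = NULL,
                          status = "infeasible", stage = "super"),
                     class = "sbm_result"))
  }
  tt <- r$x[1]
  lam <- numeric(n)
  lam[-k] <- r$x[2:(no + 1)] / tt
  structure(list(
    score = max(r$value, 1),  # clip roundoff below 1
    slacks_in = NULL, slacks_out = NULL,
    lambda = stats::setNames(lam, dmus$unit_ids),
    projection = list(
      x = stats::setNames(r$x[(no + 2):(no + m + 1)] / tt, colnames(X)),
      y = stats::setNames(r$x[(no + m + 2):(no + m + s + 1)] / tt,
                          colnames(Y))),
    status = "optimal", stage = "super"), class = "sbm_result")
}

#' @export
print.sbm_result <- function(x, ...) {
  cat(sprintf("%s-stage SBM result: score %.4f (%s)\n",
              x$stage, x$score, x$status))
  invisible(x)
}

#' Two-stage efficiency score for one unit
#'
#' Runs [solve_sbm()]; if the unit is SBM-efficient (score within
#' `efficiency_tolerance` of 1) it is re-scored by [solve_super_sbm()] so
#' that efficient units can be ranked. Scores above 1 therefore only occur
#' with `stage = "super"`.
#'
#' @inheritParams solve_sbm
#' @return list: `score`, `stage` (`"sbm"` or `"super"`), `status`.
#' @export
score_dmu <- function(dmus, k, opts = solve_options()) {
  first <- solve_sbm(dmus, k, opts)
  if (first$score < 1 - opts$efficiency_tolerance)
    return(list(score = first$score, stage = "sbm", status = "optimal"))
  super <- solve_super_sbm(dmus, k, opts)
  if (super$status == "infeasible") {
    if (opts$infeasible_policy == "cap")
      return(list(score = opts$infeasible_cap, stage = "super",
                  status = "capped"))
    return(list(score = NA_real_, stage = "super", status = "infeasible"))
  }
  list(score = super$score, stage = "super", status = "optimal")
}

#' Score every unit of an indicator panel, year by year
#'
#' Each calendar year is treated as its own evaluation cross-section
#' (contemporaneous frontier): units are compared only against units
#' observed in the same year.
#'
#' @param panel an [indicator_panel()].
#' @param opts a [solve_options()].
#' @return an [efficiency_panel()].
#' @export
evaluate_panel <- function(panel, opts = solve_options()) {
  stopifnot(inherits(panel, "indicator_panel"))
  units <- panel$unit_ids
  years <- panel$years
  if (length(units) < 2) stop("need at least 2 units per year")
  sc <- matrix(NA_real_, length(units), length(years),
               dimnames = list(units, years))
  st <- matrix("infeasible", length(units), length(years),
               dimnames = list(units, years))
  for (y in years) {
    dm <- panel_matrices(panel, y)
    for (k in seq_along(units)) {
      r <- score_dmu(dm, k, opts)
      sc[k, as.character(y)] <- r$score
      st[k, as.character(y)] <- if (r$status == "infeasible")
        "infeasible" else r$stage
    }
  }
  efficiency_panel(sc, st, tol = opts$efficiency_tolerance)
}

#' Efficient units in an efficiency panel
#'
#' @param eff an [efficiency_panel()].
#' @param year one year to query, or `NULL` with `intersection = TRUE` for
#'   the units efficient in *every* year.
#' @param threshold efficiency cut-off (default 1).
#' @param tol scores within `tol` of the threshold count as efficient.
#' @param intersection query the all-years intersection instead of a single
#'   year.
#' @return list with `count` and `units`.
#' @export
count_efficient <- function(eff, year = NULL, threshold = 1, tol = 1e-6,
                            intersection = FALSE) {
  stopifnot(inherits(eff, "efficiency_panel"))
  hit <- !is.na(eff$scores) & eff$scores >= threshold - tol
  if (intersection) {
    u <- eff$unit_ids[rowSums(hit) == length(eff$years)]
  } else {
    if (is.null(year)) stop("give a year or set intersection = TRUE")
    ycol <- as.character(as.integer(year))
    if (!ycol %in% colnames(eff$scores)) stop("year ", year, " not in panel")
    u <- eff$unit_ids[hit[, ycol]]
  }
  list(count = length(u), units = u)
}

resolve_unit <- function(dmus, k) {
  if (is.character(k)) {
    i <- match(k, dmus$unit_ids)
    if (is.na(i)) stop("unknown unit: ", k)
    return(i)
  }
  k <- as.integer(k)
  if (k < 1 || k > nrow(dmus$X)) stop("unit index out of range")
  k
}
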