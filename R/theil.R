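# Generalized-entropy inequality indices and the group-wise Theil
# decomposition with contribution shares.

#' Generalized-entropy inequality index
#'
#' For positive values `e` with weights `p` (summing to 1) and weighted
#' mean `mu = sum(p * e)`:
#' \deqn{GE(\beta) = \frac{1}{\beta(\beta-1)} \sum_i p_i
#'   \left[(e_i/\mu)^\beta - 1\right]}
#' with the analytic limits `beta = 1` (the Theil-T index,
#' `sum(p * (e/mu) * log(e/mu))`) and `beta = 0` (the mean log deviation,
#' `-sum(p * log(e/mu))`). The index is nonnegative, zero exactly when all
#' values are equal, and invariant to a common positive rescaling.
#'
#' @param values strictly positive numeric vector.
#' @param beta sensitivity parameter (default 1, the Theil-T case used by
#'   the group decomposition).
#' @param weights nonnegative weights summing to 1; default uniform
#'   `1/length(values)`.
#' @return nonnegative scalar.
#' @examples
#' ge_index(c(1, 1, 1))                  # 0: perfect equality
#' ge_index(c(1, 2, 4), beta = 1)        # Theil-T
#' ge_index(c(1, 2, 4), beta = 0)        # mean log deviation
#' @export
ge_index <- function(values, beta = 1, weights = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty value vector")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all values must be finite and strictly positive")
  if (is.null(weights)) weights <- rep(1 / length(values), length(values))
  if (length(weights) != length(values))
    stop("weights length must match values")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  mu <- sum(weights * values)
  r <- values / mu
  if (abs(beta - 1) < 1e-12) {
    out <- sum(weights * r * log(r))
  } else if (abs(beta) < 1e-12) {
    out <- -sum(weights * log(r))
  } else {
    out <- sum(weights * (r^beta - 1)) / (beta * (beta - 1))
  }
  max(out, 0)  # clip -0 / roundoff at perfect equality
}

#' Theil decomposition of inequality over a group partition
#'
#' Decomposes the Theil-T index of `values` into a within-group and a
#' between-group component:
#' \deqn{T = T_W + T_B,\qquad
#'   T_W = \sum_p \frac{n_p}{n}\frac{\bar e_p}{\bar e} T_p,\qquad
#'   T_B = \sum_p \frac{n_p}{n}\frac{\bar e_p}{\bar e}
#'         \ln\frac{\bar e_p}{\bar e}}
#' where \eqn{T_p} is the Theil-T index inside group `p`, \eqn{n_p} its
#' size and \eqn{\bar e_p} its mean. The identity `total = within +
#' between` is exact (up to floating point), and each component divided by
#' the total gives its contribution share.
#'
#' @param values strictly positive numeric vector, named with unit ids (or
#'   supply `units`).
#' @param partition a [region_partition()] covering every unit.
#' @param units unit identifiers, defaults to `names(values)`.
#' @return object of class `theil_decomposition`: `total`, `within`,
#'   `between`, `within_terms` (per-group Theil), `group_means`,
#'   `group_sizes`, `grand_mean`, `shares` (per-group within shares plus
#'   `within` and `between`, as fractions of the total), and `degenerate`
#'   (`TRUE` when the total is zero and shares are undefined).
#' @export
theil_decompose <- function(values, partition, units = names(values)) {
  stopifnot(inherits(partition, "region_partition"))
  values <- as.numeric(stats::setNames(values, units))
  if (is.null(units)) stop("values must be named with unit ids")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all values must be finite and strictly positive")
  g <- partition_groups(partition, units)
  groups <- intersect(partition$group_names, unique(g))
  n <- length(values)
  mu <- mean(values)
  within_terms <- vapply(groups, function(p) ge_index(values[g == p]),
                         numeric(1))
  np <- vapply(groups, function(p) sum(g == p), numeric(1))
  mup <- vapply(groups, function(p) mean(values[g == p]), numeric(1))
  w_weights <- (np / n) * (mup / mu)
  within <- sum(w_weights * within_terms)
  between <- sum(w_weights * log(mup / mu))
  total <- ge_index(values)
  degenerate <- total <= 0
  shares <- if (degenerate) {
    stats::setNames(rep(NA_real_, length(groups) + 2),
                    c(groups, "within", "between"))
  } else {
    stats::setNames(c(w_weights * within_terms, within, between) / total,
                    c(groups, "within", "between"))
  }
  structure(list(total = total, within = within, between = between,
                 within_terms = within_terms,
                 group_means = mup, group_sizes = np, grand_mean = mu,
                 shares = shares, degenerate = degenerate),
            class = "theil_decomposition")
}

#' @export
print.theil_decomposition <- function(x, ...) {
  cat(sprintf("Theil decomposition: total %.4f = within %.4f + between %.4f\n",
              x$total, x$within, x$between))
  if (x$degenerate) {
    cat("  degenerate (zero total): shares undefined\n")
  } else {
    cat("  shares:",
        paste(names(x$shares), sprintf("%.1f%%", 100 * x$shares),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Annual Theil series with group decomposition
#'
#' Applies [theil_decompose()] to every yearly cross-section of an
#' efficiency panel. Cells flagged infeasible (NA score) are dropped from
#' that year with a warning; group sizes are recomputed accordingly.
#'
#' @param eff an [efficiency_panel()].
#' @param partition a [region_partition()] covering all units.
#' @return list with `table` (a data frame: year, total index, within and
#'   between shares and per-group within shares, in percent) and
#'   `decompositions` (per-year `theil_decomposition` objects, named by
#'   year).
#' @export
theil_series <- function(eff, partition) {
  stopifnot(inherits(eff, "efficiency_panel"))
  decs <- list()
  rows <- list()
  for (y in as.character(eff$years)) {
    v <- eff$scores[, y]
    if (anyNA(v)) {
      warning("year ", y, ": dropping ", sum(is.na(v)),
              " infeasible cell(s) from the decomposition")
      v <- v[!is.na(v)]
    }
    if (length(v) < 2) stop("year ", y, ": fewer than 2 usable units")
    d <- theil_decompose(v, partition)
    decs[[y]] <- d
    sh <- 100 * d$shares
    rows[[y]] <- data.frame(year = as.integer(y), theil = d$total,
                            t(sh), check.names = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, decompositions = decs)
}
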