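# Synthetic panels with a known production frontier and known efficiency
# structure, so every pipeline stage can be tested against ground truth.

#' Specification for a synthetic indicator panel
#'
#' Units are organized in groups (regions) with a designed mean true
#' efficiency and within-group spread. Inputs are drawn from lognormal
#' distributions (right-skewed and strictly positive, like resource
#' counts); each output is a common Cobb-Douglas frontier of the inputs,
#' \eqn{g(x) = \prod_i x_i^{\alpha_i}}, scaled per output and multiplied by
#' the unit's latent efficiency `u` in (0, 1] and by multiplicative
#' lognormal noise. With `sum(elasticities) == 1` the frontier has constant
#' returns to scale, so fully efficient noise-free units sit exactly on the
#' DEA frontier.
#'
#' @param groups data frame with columns `name`, `n_units` (>= 2),
#'   `mean_eff` in (0, 1] and `spread` (>= 0; lognormal sd of the latent
#'   efficiency around its mean, truncated above at 1).
#' @param years number of years to generate (cross-sections are drawn
#'   independently).
#' @param input_meanlog,input_sdlog per-input lognormal location and scale;
#'   their common length sets the number of inputs.
#' @param elasticities per-input frontier exponents; default equal shares
#'   summing to 1 (constant returns to scale).
#' @param output_scale per-output frontier scale factors; their length sets
#'   the number of outputs.
#' @param noise_sd sd of the multiplicative lognormal output noise.
#' @param seed integer seed; part of the contract — identical seeds give
#'   bit-identical panels.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(groups = data.frame(name = c("east", "central", "west"),
                                               n_units = c(11, 8, 11),
                                               mean_eff = c(0.80, 0.49, 0.72),
                                               spread = c(0.45, 0.25, 0.35)),
                           years = 1,
                           input_meanlog = c(5, 8, 6),
                           input_sdlog = c(0.6, 0.6, 0.6),
                           elasticities = NULL,
                           output_scale = c(50, 5, 0.02),
                           noise_sd = 0,
                           seed = 1) {
  stopifnot(is.data.frame(groups),
            all(c("name", "n_units", "mean_eff", "spread") %in% names(groups)))
  if (any(groups$n_units < 2)) stop("each group needs at least 2 units")
  if (any(groups$mean_eff <= 0 | groups$mean_eff > 1))
    stop("mean efficiencies must lie in (0, 1]")
  if (any(groups$spread < 0)) stop("spreads must be nonnegative")
  m <- length(input_meanlog)
  if (length(input_sdlog) != m) stop("input_meanlog/input_sdlog length mismatch")
  if (is.null(elasticities)) elasticities <- rep(1 / m, m)
  if (length(elasticities) != m) stop("need one elasticity per input")
  if (any(elasticities <= 0)) stop("elasticities must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (years < 1) stop("years must be >= 1")
  structure(list(groups = groups, years = as.integer(years),
                 input_meanlog = input_meanlog, input_sdlog = input_sdlog,
                 elasticities = elasticities, output_scale = output_scale,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic indicator panel with known true efficiencies
#'
#' @param spec a [synthetic_spec()].
#' @return list with `panel` (an [indicator_panel()]), `truth` (data frame
#'   `unit`, `group`, `u`: the latent efficiency, constant across years)
#'   and `partition` (the group structure as a [region_partition()]).
#' @export
generate_dmu_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  g <- spec$groups
  m <- length(spec$input_meanlog)
  s <- length(spec$output_scale)
  in_names <- paste0("input_", seq_len(m))
  out_names <- paste0("output_", seq_len(s))
  units <- unlist(lapply(seq_len(nrow(g)), function(i)
    sprintf("%s_%02d", g$name[i], seq_len(g$n_units[i]))))
  grp <- rep(g$name, g$n_units)
  n <- length(units)
  # latent efficiency: lognormal around the group mean, truncated at 1
  u <- numeric(n)
  for (i in seq_len(nrow(g))) {
    sel <- grp == g$name[i]
    if (g$spread[i] == 0) {
      u[sel] <- g$mean_eff[i]
    } else {
      draw <- g$mean_eff[i] *
        exp(stats::rnorm(sum(sel), 0, g$spread[i]) - g$spread[i]^2 / 2)
      u[sel] <- pmin(1, pmax(0.01, draw))
    }
  }
  rows <- vector("list", spec$years)
  yrs <- seq_len(spec$years)
  for (t in yrs) {
    X <- vapply(seq_len(m), function(i)
      stats::rlnorm(n, spec$input_meanlog[i], spec$input_sdlog[i]),
      numeric(n))
    frontier <- exp(log(X) %*% spec$elasticities)[, 1]
    noise <- if (spec$noise_sd > 0)
      exp(matrix(stats::rnorm(n * s, 0, spec$noise_sd), n, s)) else
      matrix(1, n, s)
    Y <- outer(frontier * u, spec$output_scale) * noise
    rows[[t]] <- data.frame(
      unit = rep(units, m + s), year = t,
      indicator = rep(c(in_names, out_names), each = n),
      value = c(X, Y), stringsAsFactors = FALSE)
  }
  panel <- indicator_panel(do.call(rbind, rows),
                           inputs = in_names, outputs = out_names)
  list(panel = panel,
       truth = data.frame(unit = units, group = grp, u = u,
                          stringsAsFactors = FALSE),
       partition = region_partition(stats::setNames(grp, units),
                                    group_names = g$name))
}

#' Generate a synthetic efficiency panel with a designed group structure
#'
#' Scores are drawn lognormally: group `p` has mean `group_means[p]` and
#' log-scale spread `spreads[p]`, so the population Theil-T index inside
#' group `p` is exactly `spreads[p]^2 / 2`. The implied population
#' between-group contribution share is returned alongside, which makes
#' Monte-Carlo recovery tests possible.
#'
#' @param group_means positive per-group mean scores.
#' @param group_sizes per-group unit counts (>= 2).
#' @param spreads per-group lognormal sd (0 = no within-group variation).
#' @param years number of years (independent draws).
#' @param start_year first calendar year label.
#' @param seed integer seed.
#' @return list with `panel` (an [efficiency_panel()]), `partition` and
#'   `analytic` (population `total`, `within`, `between` and
#'   `between_share`).
#' @export
generate_efficiency_panel <- function(group_means, group_sizes, spreads,
                                      years = 1, start_year = 2008,
                                      seed = 1) {
  if (any(group_means <= 0)) stop("group means must be positive")
  if (any(group_sizes < 2)) stop("each group needs at least 2 units")
  if (any(spreads < 0)) stop("spreads must be nonnegative")
  k <- length(group_means)
  stopifnot(length(group_sizes) == k, length(spreads) == k)
  gname <- if (!is.null(names(group_means))) names(group_means) else
    paste0("g", seq_len(k))
  set.seed(seed)
  units <- unlist(lapply(seq_len(k), function(i)
    sprintf("%s_%02d", gname[i], seq_len(group_sizes[i]))))
  grp <- rep(gname, group_sizes)
  n <- length(units)
  sc <- matrix(NA_real_, n, years,
               dimnames = list(units, start_year + seq_len(years) - 1L))
  for (t in seq_len(years)) {
    v <- numeric(n)
    for (i in seq_len(k)) {
      sel <- grp == gname[i]
      v[sel] <- group_means[i] *
        exp(stats::rnorm(sum(sel), 0, spreads[i]) - spreads[i]^2 / 2)
    }
    sc[, t] <- v
  }
  # population decomposition of the designed lognormal mixture
  sp <- group_sizes / n
  mu <- sum(sp * group_means)
  wp <- sp * (group_means / mu)
  within <- sum(wp * spreads^2 / 2)
  between <- sum(wp * log(group_means / mu))
  list(panel = efficiency_panel(sc),
       partition = region_partition(stats::setNames(grp, units),
                                    group_names = gname),
       analytic = list(total = within + between, within = within,
                       between = between,
                       between_share = between / (within + between)))
}

#' Generate a sequence that a GM(1,1) fit reproduces exactly
#'
#' Builds the sequence from the model's own discretized difference
#' equation `x0(k+1) = b - a * (x1(k) + x1(k+1)) / 2`, i.e. the recursion
#' `x1(k+1) = ((1 - a/2) * x1(k) + b) / (1 + a/2)`. Because the least
#' squares step of [fit_gm11()] regresses on exactly this relation, the
#' residuals of a refit are zero and `(a, b)` are recovered to machine
#' precision. (A sequence sampled from the continuous-time exponential
#' response would not have this fixed-point property.)
#'
#' @param a developing coefficient (`abs(a) < 2`).
#' @param b grey input coefficient.
#' @param x_first first value of the sequence.
#' @param n sequence length (>= 4).
#' @return numeric vector of length `n`.
#' @export
generate_gm_sequence <- function(a, b, x_first, n) {
  n <- as.integer(n)
  if (n < 4) stop("n must be at least 4")
  if (abs(a) >= 2) stop("the discrete recursion requires |a| < 2")
  x1 <- numeric(n)
  x1[1] <- x_first
  for (k in seq_len(n - 1))
    x1[k + 1] <- ((1 - a / 2) * x1[k] + b) / (1 + a / 2)
  c(x_first, diff(x1))
}
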