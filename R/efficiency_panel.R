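# Efficiency panels: unit x year scores plus a per-cell stage flag.

#' Construct an efficiency panel
#'
#' Holds the efficiency score of every unit in every year together with a
#' status flag: `"sbm"` for units scored by the plain slacks-based measure
#' (score in (0, 1]), `"super"` for efficient units re-scored by the
#' super-efficiency program (score >= 1), `"infeasible"` for cells whose
#' super-efficiency program could not be solved (score `NA`).
#'
#' @param scores numeric matrix, units in rows (rownames), years in columns
#'   (colnames coercible to integer years).
#' @param status character matrix of the same shape with entries in
#'   `c("sbm", "super", "infeasible")`. Defaults to `"super"` where
#'   `scores >= 1` and `"sbm"` elsewhere, which is the right labelling for
#'   panels produced by a two-stage scoring protocol.
#' @param tol tolerance used when checking the score/status consistency
#'   invariants.
#' @return object of class `efficiency_panel` with elements `unit_ids`,
#'   `years`, `scores`, `status`.
#' @export
efficiency_panel <- function(scores, status = NULL, tol = 1e-6) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores))) stop("scores must have unit rownames")
  if (is.null(colnames(scores))) stop("scores must have year colnames")
  years <- as.integer(colnames(scores))
  if (anyNA(years)) stop("column names must be calendar years")
  if (is.null(status)) {
    status <- ifelse(scores >= 1, "super", "sbm")
    status[is.na(scores)] <- "infeasible"
  }
  status <- as.matrix(status)
  if (!all(dim(status) == dim(scores)))
    stop("status matrix shape must match scores")
  if (!all(status %in% c("sbm", "super", "infeasible")))
    stop("status entries must be 'sbm', 'super' or 'infeasible'")
  bad_na <- is.na(scores) & status != "infeasible"
  if (any(bad_na)) stop("NA score in a non-infeasible cell")
  ok <- !is.na(scores)
  if (any(scores[ok] <= 0)) stop("scores must be strictly positive")
  if (any(status[ok] == "super" & scores[ok] < 1 - tol))
    stop("status 'super' requires score >= 1 - tol")
  if (any(status[ok] == "sbm" & scores[ok] > 1 + tol))
    stop("status 'sbm' requires score <= 1 + tol")
  dimnames(status) <- dimnames(scores)
  structure(list(unit_ids = rownames(scores), years = years,
                 scores = scores, status = status),
            class = "efficiency_panel")
}

#' @export
print.efficiency_panel <- function(x, ...) {
  cat(sprintf("efficiency panel: %d units x %d years (%d-%d)\n",
              length(x$unit_ids), length(x$years),
              min(x$years), max(x$years)))
  cat(sprintf("  stage counts: %s\n",
              paste(names(table(x$status)), table(x$status),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Read / write efficiency panels (long CSV: unit, year, score, status)
#'
#' @param path CSV file path.
#' @return [read_efficiency_panel()] returns an [efficiency_panel()];
#'   [write_efficiency_panel()] returns `path` invisibly.
#' @export
read_efficiency_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit", "year", "score")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  units <- sort(unique(d$unit))
  years <- sort(unique(as.integer(d$year)))
  sc <- matrix(NA_real_, length(units), length(years),
               dimnames = list(units, years))
  st <- matrix("infeasible", length(units), length(years),
               dimnames = list(units, years))
  sc[cbind(match(d$unit, units), match(d$year, years))] <- d$score
  if ("status" %in% names(d)) {
    st[cbind(match(d$unit, units), match(d$year, years))] <- d$status
  } else {
    st <- ifelse(sc >= 1, "super", "sbm")
    st[is.na(sc)] <- "infeasible"
  }
  efficiency_panel(sc, st)
}

#' @rdname read_efficiency_panel
#' @param eff an [efficiency_panel()].
#' @export
write_efficiency_panel <- function(eff, path) {
  stopifnot(inherits(eff, "efficiency_panel"))
  d <- expand.grid(unit = eff$unit_ids, year = eff$years,
                   stringsAsFactors = FALSE)
  idx <- cbind(match(d$unit, eff$unit_ids), match(d$year, eff$years))
  d$score <- eff$scores[idx]
  d$status <- eff$status[idx]
  d <- d[order(d$unit, d$year), ]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
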