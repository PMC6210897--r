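# Indicator panels: per unit x year input/output indicator values.
# Canonical file layout is long/tidy (unit, year, indicator, value); a wide
# per-year layout is accepted as a convenience on read.

#' Construct an indicator panel
#'
#' An indicator panel holds, for every unit (e.g. province) and calendar
#' year, the values of a set of input indicators and a set of output
#' indicators, all strictly positive. It is the raw material for DEA
#' efficiency scoring: each year forms one evaluation cross-section.
#'
#' @param data data frame in long layout with columns `unit`, `year`,
#'   `indicator`, `value`.
#' @param inputs character vector of indicator names treated as inputs.
#' @param outputs character vector of indicator names treated as outputs.
#' @return object of class `indicator_panel` with elements `data`,
#'   `unit_ids`, `years`, `inputs`, `outputs`.
#' @examples
#' d <- expand.grid(unit = c("A", "B"), year = 2020:2021,
#'                  indicator = c("staff", "visits"),
#'                  stringsAsFactors = FALSE)
#' d$value <- seq_len(nrow(d))
#' indicator_panel(d, inputs = "staff", outputs = "visits")
#' @export
indicator_panel <- function(data, inputs, outputs) {
  stopifnot(is.data.frame(data))
  need <- c("unit", "year", "indicator", "value")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (length(inputs) < 1 || length(outputs) < 1)
    stop("need at least one input and one output indicator")
  data <- data[, need]
  data$unit <- as.character(data$unit)
  data$indicator <- as.character(data$indicator)
  data$year <- as.integer(data$year)
  ind <- c(inputs, outputs)
  if (anyDuplicated(ind))
    stop("an indicator cannot be both input and output")
  extra <- setdiff(unique(data$indicator), ind)
  if (length(extra) > 0)
    stop("indicator(s) not declared as input or output: ",
         paste(extra, collapse = ", "))
  panel <- structure(
    list(data = data,
         unit_ids = sort(unique(data$unit)),
         years = sort(unique(data$year)),
         inputs = inputs,
         outputs = outputs),
    class = "indicator_panel")
  validate_indicator_panel(panel)
  panel
}

validate_indicator_panel <- function(panel) {
  d <- panel$data
  key <- paste(d$unit, d$year, d$indicator, sep = "\r")
  if (anyDuplicated(key)) {
    k <- key[duplicated(key)][1]
    stop("duplicated cell: ", gsub("\r", " / ", k))
  }
  full <- expand.grid(unit = panel$unit_ids, year = panel$years,
                      indicator = c(panel$inputs, panel$outputs),
                      stringsAsFactors = FALSE)
  fkey <- paste(full$unit, full$year, full$indicator, sep = "\r")
  absent <- setdiff(fkey, key)
  if (length(absent) > 0)
    stop("missing cell: ", gsub("\r", " / ", absent[1]))
  bad <- !is.finite(d$value) | d$value <= 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "nonpositive or missing value for unit '%s', year %d, indicator '%s'",
      d$unit[i], d$year[i], d$indicator[i]))
  }
  n <- length(panel$unit_ids)
  ms <- length(panel$inputs) + length(panel$outputs)
  if (n < ms + 1)
    warning(sprintf(
      "only %d units for %d indicators; DEA discrimination will be weak", n, ms))
  invisible(panel)
}

#' @export
print.indicator_panel <- function(x, ...) {
  cat(sprintf(
    "indicator panel: %d units x %d years, %d inputs (%s), %d outputs (%s)\n",
    length(x$unit_ids), length(x$years),
    length(x$inputs), paste(x$inputs, collapse = ", "),
    length(x$outputs), paste(x$outputs, collapse = ", ")))
  invisible(x)
}

#' Extract one year's DEA cross-section from an indicator panel
#'
#' @param panel an `indicator_panel`.
#' @param year calendar year present in the panel.
#' @return a [dmu_set()] with the panel's units as rows.
#' @export
panel_matrices <- function(panel, year) {
  stopifnot(inherits(panel, "indicator_panel"))
  year <- as.integer(year)
  if (!year %in% panel$years) stop("year ", year, " not in panel")
  d <- panel$data[panel$data$year == year, ]
  grab <- function(ind) {
    m <- matrix(NA_real_, length(panel$unit_ids), length(ind),
                dimnames = list(panel$unit_ids, ind))
    for (j in ind)
      m[d$unit[d$indicator == j], j] <- d$value[d$indicator == j]
    m
  }
  dmu_set(grab(panel$inputs), grab(panel$outputs), unit_ids = panel$unit_ids)
}

#' Read an indicator panel from a delimited text file
#'
#' Long layout (the canonical on-disk form) expects columns
#' `unit, year, indicator, value`. Wide layout expects one row per
#' unit-year with a `unit` and a `year` column and one column per
#' indicator.
#'
#' @param path CSV file path.
#' @param inputs,outputs indicator names (column names in wide layout).
#' @param layout `"long"` or `"wide"`.
#' @return an [indicator_panel()].
#' @export
read_indicator_panel <- function(path, inputs, outputs,
                                 layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "wide") {
    need <- c("unit", "year", inputs, outputs)
    miss <- setdiff(need, names(d))
    if (length(miss) > 0)
      stop("missing column(s): ", paste(miss, collapse = ", "))
    long <- do.call(rbind, lapply(c(inputs, outputs), function(j)
      data.frame(unit = d$unit, year = d$year, indicator = j,
                 value = d[[j]], stringsAsFactors = FALSE)))
    d <- long
  }
  indicator_panel(d, inputs = inputs, outputs = outputs)
}

#' Write an indicator panel in the canonical long layout
#'
#' @param panel an [indicator_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_indicator_panel <- function(panel, path) {
  stopifnot(inherits(panel, "indicator_panel"))
  d <- panel$data[order(panel$data$unit, panel$data$year, panel$data$indicator), ]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
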