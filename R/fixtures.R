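# Bundled published reference tables, shipped as plain CSV under extdata.

#' Load a bundled reference table
#'
#' Two fixtures are shipped:
#' \describe{
#'   \item{`table1_efficiency_panel`}{the published super-SBM efficiency
#'     scores of 30 Chinese provincial community-health-service systems for
#'     2008-2016 (30 units x 9 years), returned as an
#'     [efficiency_panel()]. Scores at or above 1 carry status `"super"`.}
#'   \item{`table4_theil_series`}{the published annual Theil index of those
#'     scores, 2008-2016, returned as a named numeric vector (names are
#'     years).}
#' }
#'
#' @param name fixture identifier.
#' @return see Description.
#' @examples
#' eff <- load_fixture("table1_efficiency_panel")
#' eff$scores["Shanghai", "2008"]
#' @export
load_fixture <- function(name) {
  known <- c("table1_efficiency_panel", "table4_theil_series")
  if (!name %in% known)
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "))
  if (name == "table1_efficiency_panel") {
    path <- system.file("extdata", "table1_efficiency.csv",
                        package = "effidiff", mustWork = TRUE)
    d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    sc <- as.matrix(d[, -1])
    rownames(sc) <- d$province
    return(efficiency_panel(sc))
  }
  path <- system.file("extdata", "table4_theil.csv",
                      package = "effidiff", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(d$theil, d$year)
}
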