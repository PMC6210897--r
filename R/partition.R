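# Region partitions: a mapping unit -> group used by the Theil decomposition.

#' Construct a region partition
#'
#' @param membership named character vector: names are unit identifiers,
#'   values are group labels. Every unit belongs to exactly one group.
#' @param group_names optional ordered group labels; defaults to order of
#'   first appearance. Every listed group must be non-empty.
#' @return object of class `region_partition` with elements `group_names`
#'   and `membership`.
#' @export
region_partition <- function(membership, group_names = NULL) {
  if (is.null(names(membership)) || any(names(membership) == ""))
    stop("membership must be a named vector (unit -> group)")
  if (anyDuplicated(names(membership))) {
    dup <- names(membership)[duplicated(names(membership))][1]
    stop("unit assigned more than once: ", dup)
  }
  membership <- vapply(membership, as.character, character(1))
  if (is.null(group_names)) group_names <- unique(unname(membership))
  empty <- setdiff(group_names, membership)
  if (length(empty) > 0)
    stop("empty group(s): ", paste(empty, collapse = ", "))
  stray <- setdiff(unique(membership), group_names)
  if (length(stray) > 0)
    stop("group(s) not listed in group_names: ", paste(stray, collapse = ", "))
  structure(list(group_names = group_names, membership = membership),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  sizes <- table(factor(x$membership, levels = x$group_names))
  cat("region partition:",
      paste(names(sizes), sizes, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Group labels for a set of units
#'
#' @param partition a [region_partition()].
#' @param units unit identifiers; every one must be mapped.
#' @return character vector of group labels, same length as `units`.
#' @export
partition_groups <- function(partition, units) {
  stopifnot(inherits(partition, "region_partition"))
  g <- partition$membership[units]
  if (anyNA(g))
    stop("unit(s) missing from partition: ",
         paste(units[is.na(g)], collapse = ", "))
  unname(g)
}

#' Load a region partition from a file or a builtin name
#'
#' The builtin `"china_three_region"` is the eastern/central/western
#' division of the 30 Chinese provincial areas (Tibet excluded) used by
#' the national health statistical yearbooks: 11 eastern, 8 central and
#' 11 western provinces.
#'
#' @param source either the builtin name `"china_three_region"` or the path
#'   to a CSV file with columns `unit` and `group`.
#' @return a [region_partition()].
#' @export
load_region_partition <- function(source = "china_three_region") {
  if (identical(source, "china_three_region")) return(china_three_region())
  if (!file.exists(source)) stop("no such file or builtin: ", source)
  d <- utils::read.csv(source, stringsAsFactors = FALSE)
  miss <- setdiff(c("unit", "group"), names(d))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  m <- stats::setNames(d$group, d$unit)
  region_partition(m, group_names = unique(d$group))
}

#' @rdname load_region_partition
#' @export
china_three_region <- function() {
  path <- system.file("extdata", "china_three_region.csv",
                      package = "effidiff", mustWork = TRUE)
  load_region_partition(path)
}
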