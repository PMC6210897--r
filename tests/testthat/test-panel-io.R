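# Indicator/efficiency panel IO, region partitions, bundled fixtures.

test_that("indicator panel construction records shape and validates cells", {
  d <- toy_panel_data(n_units = 4, years = 2015:2016)
  p <- suppressWarnings(
    indicator_panel(d, inputs = c("centers", "staff", "beds"),
                    outputs = c("visits", "inpatients", "bed_util")))
  expect_length(p$unit_ids, 4)
  expect_equal(p$years, 2015:2016)
  expect_length(p$inputs, 3)
  expect_length(p$outputs, 3)

  # a zero bed count must be rejected, naming the offending cell
  d2 <- d
  i <- which(d2$unit == "U2" & d2$year == 2016 & d2$indicator == "beds")
  d2$value[i] <- 0
  expect_error(
    indicator_panel(d2, inputs = c("centers", "staff", "beds"),
                    outputs = c("visits", "inpatients", "bed_util")),
    "U2.*2016.*beds")

  # missing cells are caught
  expect_error(
    indicator_panel(d[-1, ], inputs = c("centers", "staff", "beds"),
                    outputs = c("visits", "inpatients", "bed_util")),
    "missing cell")
})

test_that("few units relative to indicator count triggers a warning", {
  d <- toy_panel_data(n_units = 3, years = 2015,
                      inputs = c("a", "b"), outputs = c("c", "d"))
  expect_warning(indicator_panel(d, inputs = c("a", "b"),
                                 outputs = c("c", "d")),
                 "discrimination")
})

test_that("indicator panels round-trip losslessly through long CSV", {
  d <- toy_panel_data()
  p <- suppressWarnings(
    indicator_panel(d, inputs = c("centers", "staff", "beds"),
                    outputs = c("visits", "inpatients", "bed_util")))
  f <- withr::local_tempfile(fileext = ".csv")
  write_indicator_panel(p, f)
  p2 <- suppressWarnings(
    read_indicator_panel(f, inputs = p$inputs, outputs = p$outputs))
  expect_equal(p2$unit_ids, p$unit_ids)
  expect_equal(p2$years, p$years)
  d1 <- p$data[order(p$data$unit, p$data$year, p$data$indicator), ]
  d2 <- p2$data[order(p2$data$unit, p2$data$year, p2$data$indicator), ]
  rownames(d1) <- rownames(d2) <- NULL
  expect_equal(d2, d1)
})

test_that("wide-layout reader agrees with the long-layout reader", {
  d <- toy_panel_data(n_units = 5, years = 2019:2020,
                      inputs = c("a", "b"), outputs = c("c"))
  wide <- reshape(d, idvar = c("unit", "year"), timevar = "indicator",
                  direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  fw <- withr::local_tempfile(fileext = ".csv")
  fl <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(wide, fw, row.names = FALSE)
  utils::write.csv(d, fl, row.names = FALSE)
  pw <- read_indicator_panel(fw, inputs = c("a", "b"), outputs = "c",
                             layout = "wide")
  pl <- read_indicator_panel(fl, inputs = c("a", "b"), outputs = "c")
  expect_equal(panel_matrices(pw, 2019)$X, panel_matrices(pl, 2019)$X)
  expect_equal(panel_matrices(pw, 2020)$Y, panel_matrices(pl, 2020)$Y)
})

test_that("builtin three-region partition matches the published division", {
  part <- china_three_region()
  sizes <- table(factor(part$membership, levels = part$group_names))
  expect_equal(as.integer(sizes[c("eastern", "central", "western")]),
               c(11L, 8L, 11L))
  east <- names(part$membership)[part$membership == "eastern"]
  expect_true(all(c("Beijing", "Hainan", "Shanghai", "Guangdong") %in% east))
  cent <- names(part$membership)[part$membership == "central"]
  expect_length(cent, 8)
  expect_true("Hubei" %in% cent)
  expect_false("Tibet" %in% names(part$membership))
  expect_length(part$membership, 30)
})

test_that("partition files with duplicated or unmapped units are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("unit,group", "Hubei,central", "Hubei,western", "Anhui,central"),
             f)
  expect_error(load_region_partition(f), "more than once")
  part <- china_three_region()
  expect_error(partition_groups(part, c("Hubei", "Atlantis")), "Atlantis")
  expect_error(region_partition(c(A = "g1"), group_names = c("g1", "g2")),
               "empty group")
})

test_that("bundled efficiency panel fixture matches the published table", {
  eff <- load_fixture("table1_efficiency_panel")
  expect_equal(dim(eff$scores), c(30L, 9L))
  expect_equal(eff$years, 2008:2016)
  expect_false(anyNA(eff$scores))          # 270 cells, none missing
  expect_equal(eff$scores["Shanghai", "2008"], 1.889)
  expect_equal(eff$scores["Ningxia", "2016"], 2.147)
  # status labelling is consistent with the two-stage convention
  expect_true(all(eff$status[eff$scores >= 1] == "super"))
  expect_true(all(eff$status[eff$scores < 1] == "sbm"))
})

test_that("fixture per-year means reproduce the published average row", {
  eff <- load_fixture("table1_efficiency_panel")
  printed_avg <- c(0.834, 0.747, 0.660, 0.655, 0.660, 0.656, 0.606, 0.611,
                   0.739)
  expect_equal(round(unname(colMeans(eff$scores)), 3), printed_avg)
})

test_that("bundled Theil series fixture is the published nine-year series", {
  th <- load_fixture("table4_theil_series")
  expect_length(th, 9)
  expect_equal(names(th), as.character(2008:2016))
  expect_equal(unname(th[c("2008", "2012", "2016")]),
               c(0.1779, 0.1818, 0.1468))
  expect_error(load_fixture("table9_nonsense"), "table1_efficiency_panel")
})

test_that("efficiency panels round-trip and enforce score/status invariants", {
  eff <- load_fixture("table1_efficiency_panel")
  f <- withr::local_tempfile(fileext = ".csv")
  write_efficiency_panel(eff, f)
  eff2 <- read_efficiency_panel(f)
  # the reader normalizes unit order; content must survive unchanged
  expect_setequal(eff2$unit_ids, eff$unit_ids)
  expect_equal(eff2$scores[eff$unit_ids, ], eff$scores)
  expect_equal(eff2$status[eff$unit_ids, ], eff$status)

  sc <- matrix(c(0.5, 1.2), 2, 1, dimnames = list(c("a", "b"), "2020"))
  expect_error(efficiency_panel(sc, matrix(c("super", "sbm"), 2, 1)),
               "super")
  expect_error(
    efficiency_panel(matrix(c(-1, 1), 2, 1,
                            dimnames = list(c("a", "b"), "2020"))),
    "positive")
})
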