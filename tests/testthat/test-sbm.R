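# SBM and super-efficiency solvers: closed-form cases, the exact
# vertex-enumeration oracle, and the model's structural invariants.

two_dmu <- dmu_set(matrix(c(1, 2), 2, 1), matrix(c(1, 1), 2, 1),
                   unit_ids = c("A", "B"))

test_that("two-unit closed forms are reproduced exactly", {
  # B uses one extra unit of input for the same output as A:
  # the only efficient peer is A, leaving input slack 1, so rho = 1 - 1/2.
  rB <- solve_sbm(two_dmu, "B")
  expect_equal(rB$score, 0.5, tolerance = 1e-9)
  expect_equal(unname(rB$slacks_in), 1, tolerance = 1e-9)
  expect_equal(unname(rB$slacks_out), 0, tolerance = 1e-9)
  expect_equal(unname(rB$lambda), c(1, 0), tolerance = 1e-9)

  rA <- solve_sbm(two_dmu, "A")
  expect_equal(rA$score, 1, tolerance = 1e-9)

  # super-efficiency of A: the only admissible reference point is B itself,
  # so xbar = 2, ybar = 1 and delta = 2.
  sA <- solve_super_sbm(two_dmu, "A")
  expect_equal(sA$score, 2, tolerance = 1e-9)
  expect_equal(unname(sA$projection$x), 2, tolerance = 1e-9)
  expect_equal(unname(sA$projection$y), 1, tolerance = 1e-9)

  both <- lapply(c("A", "B"), function(u) score_dmu(two_dmu, u))
  expect_equal(both[[1]]$score, 2, tolerance = 1e-9)
  expect_equal(both[[1]]$stage, "super")
  expect_equal(both[[2]]$score, 0.5, tolerance = 1e-9)
  expect_equal(both[[2]]$stage, "sbm")
})

test_that("twin units score 1 in stage one and 1 in the super stage", {
  tw <- dmu_set(matrix(c(1, 1, 3), 3, 1), matrix(c(2, 2, 1), 3, 1))
  expect_equal(solve_sbm(tw, 1)$score, 1, tolerance = 1e-9)
  expect_equal(solve_super_sbm(tw, 1)$score, 1, tolerance = 1e-9)
  # an all-identical set scores (1, super) everywhere
  same <- dmu_set(matrix(1, 3, 2), matrix(2, 3, 2))
  for (k in 1:3) {
    r <- score_dmu(same, k)
    expect_equal(r$score, 1, tolerance = 1e-9)
    expect_equal(r$stage, "super")
  }
})

test_that("a strictly dominated unit is inefficient with stage sbm", {
  dm <- dmu_set(matrix(c(1, 2, 1.5), 3, 1),
                matrix(c(2, 2.5, 1), 3, 1))
  r <- score_dmu(dm, 3)  # more input, less output than unit 1
  expect_lt(r$score, 1)
  expect_equal(r$stage, "sbm")
})

test_that("LP scores match the exact fractional-program oracle", {
  # modest battery here; the full 100-seed battery runs with the
  # acceptance checks
  for (seed in 1:25) {
    inst <- random_instance(seed)
    dm <- dmu_set(inst$X, inst$Y)
    for (k in seq_len(nrow(inst$X))) {
      r <- solve_sbm(dm, k)
      expect_equal(r$score, oracle_sbm(inst$X, inst$Y, k), tolerance = 1e-7)
      if (r$score >= 1 - 1e-6) {
        su <- solve_super_sbm(dm, k)
        expect_equal(su$score, oracle_super(inst$X, inst$Y, k),
                     tolerance = 1e-7)
      }
    }
  }
})

test_that("scores are invariant to rescaling any indicator column", {
  set.seed(101)
  for (rep in 1:5) {
    X <- matrix(runif(8 * 2, 0.5, 4), 8, 2)
    Y <- matrix(runif(8 * 2, 0.5, 4), 8, 2)
    cx <- runif(2, 0.01, 50)
    cy <- runif(2, 0.01, 50)
    dm1 <- dmu_set(X, Y)
    dm2 <- dmu_set(sweep(X, 2, cx, "*"), sweep(Y, 2, cy, "*"))
    for (k in c(1, 4, 8)) {
      expect_equal(solve_sbm(dm2, k)$score, solve_sbm(dm1, k)$score,
                   tolerance = 1e-9)
    }
  }
})

test_that("adding a strictly dominated unit changes no other score", {
  set.seed(7)
  X <- matrix(runif(6 * 2, 1, 3), 6, 2)
  Y <- matrix(runif(6 * 2, 1, 3), 6, 2)
  Xd <- rbind(X, X[1, ] * 2)   # twice the input
  Yd <- rbind(Y, Y[1, ] / 2)   # half the output
  for (rts in c("vrs", "crs")) {
    opts <- solve_options(returns_to_scale = rts)
    dm <- dmu_set(X, Y)
    dmd <- dmu_set(Xd, Yd)
    for (k in 1:6)
      expect_equal(solve_sbm(dmd, k, opts)$score,
                   solve_sbm(dm, k, opts)$score, tolerance = 1e-9)
  }
})

test_that("slack identities hold for inefficient units", {
  set.seed(11)
  X <- matrix(runif(7 * 2, 1, 3), 7, 2)
  Y <- matrix(runif(7, 1, 3), 7, 1)
  dm <- dmu_set(X, Y)
  for (k in 1:7) {
    r <- solve_sbm(dm, k)
    if (r$score < 1 - 1e-9) {
      expect_equal(colSums(r$lambda * X) + r$slacks_in, X[k, ],
                   tolerance = 1e-7, ignore_attr = TRUE)
      expect_equal(colSums(r$lambda * Y) - r$slacks_out, Y[k, ],
                   tolerance = 1e-7, ignore_attr = TRUE)
      expect_equal(sum(r$lambda), 1, tolerance = 1e-7)
    }
  }
})

test_that("two-stage scores below 1 are sbm-stage, above 1 super-stage", {
  set.seed(23)
  X <- matrix(runif(8 * 2, 1, 3), 8, 2)
  Y <- matrix(runif(8 * 1, 1, 3), 8, 1)
  dm <- dmu_set(X, Y)
  for (k in 1:8) {
    r <- score_dmu(dm, k)
    if (r$score < 1 - 1e-6) expect_equal(r$stage, "sbm")
    if (r$score > 1 + 1e-6) expect_equal(r$stage, "super")
  }
})

test_that("panel evaluation scores each year on its own frontier", {
  # year 1 and year 2 identical except unit U1's outputs halved in year 2:
  # U1's score cannot rise, everyone else's cross-section is unchanged
  set.seed(42)
  n <- 10
  X <- matrix(runif(n * 2, 1, 5), n, 2, dimnames = list(paste0("U", 1:n)))
  Y <- matrix(runif(n * 2, 1, 5), n, 2)
  mk_rows <- function(X, Y, year) {
    data.frame(unit = rep(rownames(X), 4), year = year,
               indicator = rep(c("i1", "i2", "o1", "o2"), each = n),
               value = c(X[, 1], X[, 2], Y[, 1], Y[, 2]))
  }
  Y2 <- Y
  Y2[1, ] <- Y2[1, ] * 0.5
  p <- indicator_panel(rbind(mk_rows(X, Y, 2001), mk_rows(X, Y2, 2002)),
                       inputs = c("i1", "i2"), outputs = c("o1", "o2"))
  eff <- evaluate_panel(p)
  expect_equal(dim(eff$scores), c(10L, 2L))
  expect_false(anyNA(eff$scores))
  expect_lte(eff$scores["U1", "2002"], eff$scores["U1", "2001"] + 1e-9)
  # all statuses consistent with the stage invariants
  ok <- !is.na(eff$scores)
  expect_true(all(eff$status[ok] %in% c("sbm", "super")))
  expect_true(all(eff$scores[ok & eff$status == "super"] >= 1 - 1e-6))
  expect_true(all(eff$scores[ok & eff$status == "sbm"] <= 1 + 1e-6))
})

test_that("efficient-unit queries work per year and as intersections", {
  eff <- load_fixture("table1_efficiency_panel")
  expect_equal(count_efficient(eff, 2008)$count, 12)
  expect_true(all(c("Jilin", "Beijing", "Shanghai", "Ningxia") %in%
                    count_efficient(eff, 2008)$units))
  expect_equal(count_efficient(eff, 2016)$count, 10)
  always <- count_efficient(eff, intersection = TRUE)
  expect_equal(always$count, 6)
  expect_setequal(always$units,
                  c("Shanghai", "Jiangsu", "Guangdong", "Hainan",
                    "Chongqing", "Ningxia"))
  expect_error(count_efficient(eff, 2025), "not in panel")
})

test_that("degenerate and invalid DEA inputs are rejected", {
  expect_error(dmu_set(matrix(c(1, -1), 2, 1), matrix(1, 2, 1)), "positive")
  expect_error(solve_super_sbm(dmu_set(matrix(1, 1, 1), matrix(1, 1, 1)), 1),
               "at least 2")
  expect_error(solve_sbm(two_dmu, "Z"), "unknown unit")
  expect_error(solve_options(efficiency_tolerance = 0.5), "tolerance")
})
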