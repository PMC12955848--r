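test_that("next_lambda equalizes the two scalarized objectives", {
  lam <- next_lambda(c(-10, -2), c(-6, 0))
  expect_equal(lam, 1 / 3)
  expect_equal(lam * -10 - (1 - lam) * -2, lam * -6 - (1 - lam) * 0)
  expect_equal(lam * -10 - (1 - lam) * -2, -2)
  expect_error(next_lambda(c(-5, -1), c(-5, -1)), "identical")
  expect_true(is.na(next_lambda(c(-5, -1), c(-5, 0))))   # equal M: degenerate
  expect_true(is.na(next_lambda(c(-6, -1), c(-5, -1))))  # equal S: degenerate
  # random valid pairs: lambda* in (0,1) and both objectives tie there
  set.seed(23)
  for (k in 1:50) {
    a <- c(-10, -3) - runif(2, 0.1, 5)
    b <- a + runif(2, 0.1, 5)
    lam <- next_lambda(a, b)
    expect_gt(lam, 0); expect_lt(lam, 1)
    expect_equal(lam * a[1] - (1 - lam) * a[2],
                 lam * b[1] - (1 - lam) * b[2])
  }
})

test_that("dominance filtering removes dominated and duplicate points", {
  mk <- function(cds, mfe, cai) {
    l <- nchar(cds) / 3
    structure(list(cds = cds, mfe = mfe, cai = cai, S = l * log(cai)),
              class = "design_result")
  }
  pts <- list(mk("AAAUUU", -10, 0.80), mk("AAAUUC", -9, 0.85),
              mk("AAAUUA", -8, 0.70))
  kept <- filter_dominated(pts)
  expect_equal(vapply(kept, `[[`, "", "cds"), c("AAAUUU", "AAAUUC"))
  expect_equal(filter_dominated(pts[1]), pts[1])
  expect_equal(length(filter_dominated(c(pts[1], pts[1]))), 1L)
  # ascending CAI ordering
  expect_true(!is.unsorted(vapply(kept, `[[`, 1.0, "cai")))
})

test_that("percentage normalization is linear with best = 100", {
  mk <- function(mfe, cai) structure(
    list(cds = paste0(mfe, cai), mfe = mfe, cai = cai),
    class = "design_result")
  f <- structure(list(points = list(mk(-20, 0.7), mk(-16.25, 0.8),
                                    mk(-12.5, 0.9))),
                 class = "pareto_front")
  f <- normalize_percentages(f)
  expect_equal(f$mfe_pct, c(100, 50, 0))
  expect_equal(f$cai_pct, c(0, 50, 100))
  f1 <- structure(list(points = list(mk(-5, 0.5))), class = "pareto_front")
  f1 <- normalize_percentages(f1)
  expect_equal(f1$mfe_pct, 100)
  expect_equal(f1$cai_pct, 100)
})

test_that("single-CDS proteins give a one-point front", {
  f <- pareto_front("MW", model = energy_model("nussinov"))
  expect_equal(f$n, 1L)
  expect_equal(length(f$points), 1L)
  expect_gte(f$N, 2L)
  expect_equal(f$mfe_pct, 100)
})

test_that("front points are non-dominated and lambda-optimal vs the oracle", {
  m <- energy_model("nussinov")
  set.seed(29)
  for (k in 1:4) {
    p <- random_protein_bounded(sample(6:9, 1), max_paths = 512)
    f <- pareto_front(p, model = m)
    mfe <- vapply(f$points, `[[`, 1.0, "mfe")
    caiv <- vapply(f$points, `[[`, 1.0, "cai")
    # ascending CAI implies strictly increasing MFE
    expect_true(all(diff(caiv) > 0))
    expect_true(all(diff(mfe) > 0))
    # each point minimizes its own scalarization over ALL CDSs
    tab <- oracle_table(p, model = m)
    for (pt in f$points) {
      lam <- pt$lambda
      expect_equal(lam * pt$mfe - (1 - lam) * pt$S,
                   oracle_min_objective(tab, lam, 1 - lam),
                   tolerance = 1e-9)
    }
    expect_equal(f$n, length(unique(vapply(f$points, `[[`, "", "cds"))))
    expect_lte(f$n, f$N)
  }
})

test_that("pareto runs are bit-reproducible", {
  f1 <- pareto_front("LRSGAF", model = energy_model("nussinov"))
  f2 <- pareto_front("LRSGAF", model = energy_model("nussinov"))
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  expect_identical(f1$N, f2$N)
})

test_that("front TSV serialization round-trips and flags distinct CDSs", {
  f <- pareto_front("LRSGAF", model = energy_model("nussinov"))
  path <- tempfile(fileext = ".tsv")
  write_front_tsv(f, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), f$N)
  expect_equal(sum(tab$distinct_flag), f$n)
  # re-score a written row: mfe and cai reproduce exactly
  i <- which(tab$distinct_flag)[1]
  expect_equal(score_structure(tab$cds[i], tab$structure[i],
                               energy_model("nussinov")), tab$mfe[i])
  expect_equal(cai(tab$cds[i], human_w), tab$cai[i])
})
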