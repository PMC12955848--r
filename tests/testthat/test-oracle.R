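test_that("CDS enumeration matches the genetic code", {
  expect_equal(enumerate_cds("M"), "AUG")
  expect_equal(enumerate_cds("C"), c("UGC", "UGU"))
  expect_equal(enumerate_cds("MF"), c("AUGUUC", "AUGUUU"))
  expect_equal(length(enumerate_cds("MLR")), 36L)
  expect_false(is.unsorted(enumerate_cds("SS")))
  expect_error(enumerate_cds("LLLLLLLLL"), "refusing")
})

test_that("structure enumeration respects the minimum hairpin", {
  expect_equal(enumerate_structures("GAAC"), "....")   # too short to pair
  s <- enumerate_structures("GAAAC")
  expect_setequal(s, c(".....", "(...)"))
  # every enumerated structure decomposes without error
  set.seed(13)
  seq <- random_rna(10)
  for (st in enumerate_structures(seq))
    expect_silent(loop_decompose(seq, st))
})

test_that("exhaustive fold finds the enumerated optimum", {
  m <- energy_model("nussinov")
  expect_equal(exhaustive_fold("GCAAAGC", m)[c("mfe", "structure")],
               list(mfe = -2, structure = "((...))"))
  short <- exhaustive_fold("GAC", m)
  expect_equal(short$mfe, 0)
  expect_equal(short$structure, "...")
  expect_error(exhaustive_fold(random_rna(20), m), "refusing")
})

test_that("brute-force design reduces correctly at the lambda extremes", {
  bf <- brute_force_design("MW", human_w)
  expect_equal(bf$cds, "AUGUGG")
  # derna lambda ~ 0: objective is -S alone -> CAI-optimal codons
  bf0 <- brute_force_design("MSRV", human_w, energy_model("nussinov"),
                            design_objective("derna", 1e-9))
  expect_equal(bf0$cai, 1.0, tolerance = 1e-12)
})
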