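test_that("degenerate designs behave as forced", {
  lat <- build_lattice("MW", human_w)
  for (lam in c(0, 0.5, 1)) {
    r <- design_cds(lat, energy_model("nussinov"),
                    design_objective("derna", lam))
    expect_equal(r$cds, "AUGUGG")
  }
  # single residue: no structure fits within 3 nt under min-loop 3
  r1 <- design_cds(build_lattice("M", human_w), energy_model(),
                   design_objective("derna", 0.9))
  expect_equal(r1$structure, "...")
  expect_equal(r1$mfe, 0)
})

test_that("every design result satisfies its own invariants", {
  set.seed(17)
  for (k in 1:10) {
    p <- random_protein(sample(2:6, 1))
    lat <- build_lattice(p, human_w)
    model <- if (k %% 2) energy_model("nussinov") else energy_model()
    obj <- design_objective(if (k %% 3) "derna" else "linear_design",
                            if (k %% 3) runif(1) else runif(1, 0, 3))
    r <- design_cds(lat, model, obj)
    expect_equal(r$cai, exp(r$S / lat$l))
    expect_equal(r$mfe, score_structure(r$cds, r$structure, model))
    expect_equal(r$objective_value, obj$mu * r$mfe - obj$kappa * r$S)
    expect_equal(translate_cds(r$cds), p)
  }
})

test_that("fixed-sequence folding agrees with exhaustive enumeration", {
  set.seed(19)
  for (k in 1:20) {
    seq <- random_rna(sample(5:12, 1))
    for (model in list(energy_model("nussinov"), energy_model())) {
      dp <- fold_fixed(seq, model)
      ex <- exhaustive_fold(seq, model)
      expect_equal(dp$mfe, ex$mfe, tolerance = 1e-9)
      expect_equal(dp$mfe, score_structure(seq, dp$structure, model))
    }
  }
})

test_that("beam search is dominated by exact search and saturates", {
  lat <- build_lattice("LRSGAF", human_w)
  m <- energy_model("nussinov")
  obj <- design_objective("derna", 0.6)
  exact <- design_cds(lat, m, obj)
  prev <- Inf
  for (b in c(1, 2, 4, 8)) {
    r <- design_cds(lat, m, obj, beam = b)
    expect_gte(r$objective_value, exact$objective_value - 1e-9)
    expect_false(r$exact)
    prev <- r$objective_value
  }
  sat <- design_cds(lat, m, obj, beam = 100000)
  expect_equal(sat$objective_value, exact$objective_value)
  expect_error(design_cds(lat, m, obj, beam = 0), "beam")
})

test_that("increasing derna lambda trades CAI for stability monotonically", {
  lat <- build_lattice("LRSGAFYD", human_w)
  for (m in list(energy_model("nussinov"), energy_model())) {
    prev_mfe <- Inf; prev_S <- Inf
    for (lam in c(0.05, 0.25, 0.5, 0.75, 0.95)) {
      r <- design_cds(lat, m, design_objective("derna", lam))
      expect_lte(r$mfe, prev_mfe + 1e-9)
      expect_lte(r$S, prev_S + 1e-9)
      prev_mfe <- r$mfe; prev_S <- r$S
    }
  }
})

test_that("exact-mode step count grows approximately cubically in L", {
  m <- energy_model("nussinov")
  obj <- design_objective("derna", 1)
  ops <- vapply(c(16L, 32L), function(naa) {
    lat <- build_lattice(strrep("A", naa), human_w)
    design_cds(lat, m, obj)$ops[["split"]]
  }, 1.0)
  ratio <- ops[2] / ops[1]          # doubling L: ~8x for a cubic term
  expect_gt(ratio, 5)
  expect_lt(ratio, 13)
})

test_that("designing through a stop residue uses a stop codon", {
  r <- design_cds(build_lattice("MG*", human_w), energy_model(),
                  design_objective("derna", 0.01))
  expect_equal(substr(r$cds, 7, 9), "UGA")    # most-used human stop
  expect_equal(translate_cds(r$cds), "MG*")
})
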