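test_that("single-path and branched lattices have the right shape", {
  lat <- build_lattice("MW", human_w)
  expect_equal(count_paths(lat), 1)
  expect_equal(codonfold:::lattice_spellings(lat), "AUGUGG")

  lat_s <- build_lattice("S", human_w)
  expect_equal(lat_s$states[[1]]$prefix, c("A", "U"))
  expect_equal(sort(lat_s$states[[2]]$prefix), c("AG", "UC"))
  expect_equal(nrow(lat_s$states[[3]]), 6L)
  expect_equal(count_paths(lat_s), 6)

  expect_equal(count_paths(build_lattice("MSR", human_w)), 36)
  expect_equal(count_paths(build_lattice("L", human_w)), 6)
})

test_that("every lattice path spells a valid CDS and vice versa", {
  set.seed(7)
  for (k in 1:12) {
    p <- random_protein(sample(1:6, 1))
    lat <- build_lattice(p, human_w)
    spelled <- codonfold:::lattice_spellings(lat)
    expect_identical(spelled, enumerate_cds(p))
    expect_equal(length(spelled), count_paths(lat))
    expect_true(all(vapply(spelled, translate_cds, "") == p))
  }
})

test_that("six-codon families never mix sub-family prefixes", {
  # Ser: AG must continue with U/C only, UC with any; no path spells AGA/AGG
  sp <- codonfold:::lattice_spellings(build_lattice("S", human_w))
  expect_setequal(sp, c("AGC", "AGU", "UCA", "UCC", "UCG", "UCU"))
  # Leu: UU continues only with A/G, CU with any
  lp <- codonfold:::lattice_spellings(build_lattice("L", human_w))
  expect_setequal(lp, c("CUA", "CUC", "CUG", "CUU", "UUA", "UUG"))
  # Arg: AG continues only with A/G
  rp <- codonfold:::lattice_spellings(build_lattice("R", human_w))
  expect_setequal(rp, c("AGA", "AGG", "CGA", "CGC", "CGG", "CGU"))
})

test_that("stop residue designs a stop codon, only at the end", {
  lat <- build_lattice("M*", human_w)
  expect_setequal(codonfold:::lattice_spellings(lat),
                  c("AUGUAA", "AUGUAG", "AUGUGA"))
  expect_error(build_lattice("M*W", human_w), "final")
  expect_error(build_lattice("MBX", human_w), "position 2")
})

test_that("lattice dump lists states and transitions", {
  txt <- dump_lattice(build_lattice("MS", human_w))
  expect_true(any(grepl("codon AUG", txt)))
  expect_true(any(grepl("prefix AG", txt)))
})
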