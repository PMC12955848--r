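test_that("loop decomposition identifies the canonical loop types", {
  d <- loop_decompose("GGGAAACCC", "(((...)))")
  types <- sort(vapply(d, `[[`, "", "type"))
  expect_equal(types, c("external", "hairpin", "stack", "stack"))

  d2 <- loop_decompose("AAAAAA", "......")
  expect_equal(length(d2), 1L)
  expect_equal(d2[[1]]$type, "external")
  expect_equal(d2[[1]]$unpaired, 6L)

  # bulge, internal and multiloop
  d3 <- loop_decompose("GGAGAAACCC", "((.(...)))")
  expect_true("bulge" %in% vapply(d3, `[[`, "", "type"))
  d4 <- loop_decompose("GAGAAACACC", "(.(...).).")
  expect_true("internal" %in% vapply(d4, `[[`, "", "type"))
  d5 <- loop_decompose("GGGAAACCGGAAACCAAAC", "(((...))((...))...)")
  ml <- Filter(function(l) l$type == "multiloop", d5)
  expect_equal(length(ml), 1L)
  expect_equal(length(ml[[1]]$branches), 2L)
})

test_that("invalid structures are rejected", {
  expect_error(loop_decompose("GAC", "(.)"), "below the minimum")
  expect_error(loop_decompose("GAAAC", "(...."), "unbalanced")
  expect_error(loop_decompose("GAAAC", "....)"), "unbalanced")
  expect_error(loop_decompose("GAAAC", "..x.."), "invalid structure")
  expect_error(score_structure("AAAAAA", "(....)", energy_model("nussinov")),
               "non-canonical")
})

test_that("nussinov score is exactly minus the number of pairs", {
  m <- energy_model("nussinov")
  expect_equal(score_structure("GGGAAACCC", "(((...)))", m), -3)
  expect_equal(score_structure("AAAAAA", "......", m), 0)
  set.seed(11)
  for (k in 1:25) {
    seq <- random_rna(sample(8:12, 1))
    for (s in utils::head(enumerate_structures(seq), 40)) {
      np <- sum(strsplit(s, "")[[1]] == "(")
      expect_equal(score_structure(seq, s, m), -np)
    }
  }
})

test_that("nearest-neighbor scoring equals the hand-summed table entries", {
  nn <- energy_model("nearest_neighbor")
  # (((...))) on GGGAAACCC: hairpin(3) closed by G-C, two G-C on C-G stacks
  hand <- nn$hairpin[3 + 1] + nn$stack["GC", "CG"] + nn$stack["GC", "CG"]
  expect_equal(score_structure("GGGAAACCC", "(((...)))", nn), hand)
  expect_equal(hand, 5.40 - 3.30 - 3.30)
  # terminal AU penalty applies at each helix end: a lone AU pair is
  # penalized both as hairpin closing and as external-loop branch
  hand_au <- nn$hairpin[4 + 1] + 2 * nn$terminal_au
  expect_equal(score_structure("AAAAAU", "(....)", nn), hand_au)
  # single-nucleotide bulge keeps stacking: ((.(...))) pattern
  val <- score_structure("GGAGAAACCC", "((.(...)))", nn)
  hand_b <- nn$hairpin[3 + 1] +                  # GAAAC hairpin, G-C close
    nn$bulge[1 + 1] + nn$stack["GC", "CG"] +     # 1-bulge with stack term
    nn$stack["GC", "CG"]                         # outer stack
  expect_equal(val, hand_b)
})

test_that("all-dot structures score zero under both models", {
  set.seed(12)
  for (m in list(energy_model("nussinov"), energy_model())) {
    for (k in 1:5) {
      seq <- random_rna(sample(4:20, 1))
      expect_equal(score_structure(seq, strrep(".", nchar(seq)), m), 0)
    }
  }
})

test_that("scoring is a function of the decomposition only", {
  # identical (seq, structure) scored twice, plus invariance of total to
  # traversal order is implied by decomposition uniqueness
  nn <- energy_model()
  seq <- "GGGAAACCGGAAACCAAAC"; st <- "(((...))((...))...)"
  expect_identical(score_structure(seq, st, nn), score_structure(seq, st, nn))
  d <- loop_decompose(seq, st)
  paired_once <- table(unlist(lapply(d, function(l)
    c(l$closing, unlist(l$branches)))))
  # closing pairs appear once as closing and once as branch of the parent
  expect_true(all(paired_once <= 2))
})
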