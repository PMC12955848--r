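test_that("codon usage parsing handles both dialects and T->U", {
  t1 <- load_codon_usage(c("UUU 17.6", "UUC 20.3"), dialect = "kazusa")
  expect_equal(unname(t1["UUU"]), 17.6)
  t2 <- load_codon_usage("TTT\t17.6", dialect = "tsv")
  expect_equal(names(t2), "UUU")
  # kazusa blocks carry parenthesized counts, several codons per line
  t3 <- load_codon_usage(
    "UUU 17.6( 714298)  UUC 20.3( 824692)  UUA  7.7( 311881)  UUG 12.9( 525688)")
  expect_equal(length(t3), 4L)
  expect_equal(unname(t3["UUG"]), 12.9)
})

test_that("malformed usage input is rejected with a line number", {
  expect_error(load_codon_usage("UUX\t5.0", dialect = "tsv"), "line 1")
  expect_error(load_codon_usage(c("UUU\t1.0", "UUU\t2.0"), dialect = "tsv"),
               "duplicate")
  expect_error(load_codon_usage(c("UUU\t1.0", "UUC\tabc"), dialect = "tsv"),
               "line 2")
})

test_that("relative adaptiveness normalizes within families", {
  tab <- structure(c(UUA = 60, UUG = 30), class = "codon_usage")
  w <- relative_adaptiveness(tab)
  expect_equal(unname(w$w["UUA"]), 1.0)
  expect_equal(unname(w$w["UUG"]), 0.5)
  # single-codon family
  w2 <- relative_adaptiveness(structure(c(AUG = 22), class = "codon_usage"))
  expect_equal(unname(w2$w["AUG"]), 1.0)
  # zero-frequency codon gets the floor, not dropped
  w3 <- relative_adaptiveness(structure(c(UUA = 50, UUG = 0),
                                        class = "codon_usage"), floor = 1e-3)
  expect_equal(unname(w3$w["UUG"]), 1e-3)
  expect_error(relative_adaptiveness(structure(c(UUA = 0, UUG = 0),
                                               class = "codon_usage")),
               "all-zero")
})

test_that("relative adaptiveness is invariant to family-wide rescaling", {
  u <- human_codon_usage()
  w1 <- relative_adaptiveness(u)
  w2 <- relative_adaptiveness(structure(u * 7.3, class = "codon_usage"))
  expect_equal(w1$w, w2$w)
})

test_that("CAI is the geometric mean of w and matches its additive form", {
  expect_equal(cai("AUGUGG", human_w), 1.0)     # both single-codon families
  # two codons with w 1.0 and 0.25 -> sqrt(0.25)
  tab <- structure(c(AUG = 10, UUA = 20, UUG = 5), class = "codon_usage")
  w <- relative_adaptiveness(tab)
  expect_equal(cai("AUGUUG", w), 0.5)
  expect_equal(cai("UUG", w), 0.25)
  # additive/multiplicative identity on random CDSs
  set.seed(41)
  for (k in 1:20) {
    p <- random_protein(sample(1:8, 1))
    cds <- sample(enumerate_cds(p), 1)
    l <- nchar(cds) / 3
    expect_equal(cai(cds, human_w),
                 exp(cai_log_sum(cds, human_w) / l))
    expect_gt(cai(cds, human_w), 0)
    expect_lte(cai(cds, human_w), 1)
  }
})

test_that("CAI = 1 exactly when every codon is its family maximum", {
  w <- human_w
  gc <- Biostrings::GENETIC_CODE
  best_of <- function(aa) {
    fam <- codon_family(aa)
    fam[which.max(w$w[fam])]
  }
  p <- "MLRSGA"
  cds <- paste(vapply(strsplit(p, "")[[1]], best_of, ""), collapse = "")
  expect_equal(cai(cds, w), 1.0)
  # swapping in any non-maximal codon drops it below 1
  cds2 <- sub("CUG", "CUA", cds, fixed = TRUE)
  expect_lt(cai(cds2, w), 1.0)
})

test_that("cai rejects bad input", {
  expect_error(cai("AUGU", human_w), "multiple of 3")
  w <- relative_adaptiveness(structure(c(AUG = 1), class = "codon_usage"))
  expect_error(cai("UUU", w), "absent")
})
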