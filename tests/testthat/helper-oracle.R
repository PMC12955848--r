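# Shared fixtures: random proteins/sequences and the per-CDS oracle table.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n, letters = AA20) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# random protein whose synonymous-CDS count stays enumerable
random_protein_bounded <- function(n, max_paths = 1024) {
  repeat {
    p <- random_protein(n)
    if (prod(vapply(strsplit(p, "")[[1]],
                    function(a) length(codon_family(a)), 1L)) <= max_paths)
      return(p)
  }
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

human_w <- relative_adaptiveness(human_codon_usage())

# per-CDS (mfe, S) table: the ground truth all objectives are evaluated on
oracle_table <- function(protein, w = human_w, model, max_codons = 10L) {
  cds <- enumerate_cds(protein, max_codons)
  data.frame(
    cds = cds,
    mfe = vapply(cds, function(x) fold_fixed(x, model)$mfe, 1.0,
                 USE.NAMES = FALSE),
    S = vapply(cds, cai_log_sum, 1.0, w = w, USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

oracle_min_objective <- function(tab, mu, kappa) {
  min(mu * tab$mfe - kappa * tab$S)
}
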