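# Standard genetic code on the RNA alphabet, derived once from
# Biostrings::GENETIC_CODE. Stop is the residue '*' with family
# {UAA, UAG, UGA}.

RNA_BASES <- c("A", "C", "G", "U")

AA_ALPHABET_20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @noRd
genetic_code_rna <- function() {
  if (is.null(.cf_env$gc_rna)) {
    gc <- Biostrings::GENETIC_CODE
    codons <- chartr("T", "U", names(gc))
    map <- setNames(as.character(gc), codons)
    .cf_env$gc_rna <- map[order(names(map))]
  }
  .cf_env$gc_rna
}

#' Synonymous codon family of a residue
#'
#' @param aa single amino-acid letter (one of the 20 standard letters or
#'   `"*"` for stop).
#' @return character vector of RNA codons, lexicographically sorted.
#' @examples
#' codon_family("M")  # AUG
#' codon_family("L")  # six codons
#' @export
codon_family <- function(aa) {
  stopifnot(is.character(aa), length(aa) == 1L, nchar(aa) == 1L)
  gc <- genetic_code_rna()
  fam <- names(gc)[gc == aa]
  if (length(fam) == 0L)
    stop("no codon family for residue '", aa, "'")
  sort(fam)
}

#' Validate and normalize a protein sequence
#'
#' Accepts the 20 standard one-letter residues plus an optional single
#' trailing `*` (stop). Returns the upper-cased sequence.
#'
#' @param protein character scalar.
#' @return the validated sequence (invisibly usable as input elsewhere).
#' @export
validate_protein <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L)
  p <- toupper(protein)
  if (nchar(p) == 0L) stop("protein sequence is empty")
  res <- strsplit(p, "", fixed = TRUE)[[1]]
  allowed <- c(AA_ALPHABET_20, "*")
  bad <- which(!(res %in% allowed))
  if (length(bad) > 0L)
    stop("invalid residue '", res[bad[1]], "' at position ", bad[1])
  star <- which(res == "*")
  if (length(star) > 0L && !(length(star) == 1L && star == length(res)))
    stop("'*' (stop) is only allowed as the final residue")
  p
}

#' Translate an RNA CDS back to protein
#' @param cds RNA string, length divisible by 3.
#' @return protein string (stop as `*`).
#' @export
translate_cds <- function(cds) {
  cods <- split_codons(cds)
  paste(genetic_code_rna()[cods], collapse = "")
}

#' @noRd
split_codons <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- normalize_rna(cds)
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L)
    stop("CDS length ", n, " is not a positive multiple of 3")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' @noRd
normalize_rna <- function(seq) {
  s <- chartr("t", "u", chartr("T", "U", toupper(seq)))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!(ch %in% RNA_BASES))
  if (length(bad) > 0L)
    stop("invalid nucleotide '", ch[bad[1]], "' at position ", bad[1])
  s
}
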