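# Brute-force oracles, usable only at desk scale. Two tiers: exhaustive
# structure enumeration validates fold_fixed on tiny sequences; fold_fixed
# (once validated) then serves as the inner folder for exhaustive CDS
# enumeration, which validates the joint design DP.

#' Enumerate all synonymous CDSs of a protein
#'
#' @param protein protein sequence, at most `max_codons` residues.
#' @param max_codons guard against combinatorial explosion.
#' @return character vector of all RNA CDSs, lexicographically sorted.
#' @export
enumerate_cds <- function(protein, max_codons = 8L) {
  protein <- validate_protein(protein)
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  if (length(res) > max_codons)
    stop("protein longer than ", max_codons,
         " residues; refusing to enumerate")
  fams <- lapply(res, codon_family)
  out <- ""
  for (f in fams) out <- as.vector(outer(out, f, paste0))
  sort(out)
}

#' Enumerate all pseudoknot-free structures of a sequence
#'
#' All structures with canonical pairs and hairpin loops of at least
#' `min_hairpin`, as dot-bracket strings (includes the empty structure).
#'
#' @param seq RNA sequence, at most `max_nt` nucleotides.
#' @param min_hairpin minimum hairpin loop size.
#' @param max_nt length guard.
#' @return character vector of dot-bracket strings.
#' @export
enumerate_structures <- function(seq, min_hairpin = 3L, max_nt = 14L) {
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  if (n > max_nt)
    stop("sequence longer than ", max_nt, " nt; refusing to enumerate")
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {            # structures of region [i, j]
    if (j < i) return("")
    key <- paste0(i, ":", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- paste0(".", rec(i + 1L, j))                 # i unpaired
    if (j - i >= min_hairpin + 1L)
      for (k in (i + min_hairpin + 1L):j)
        if (pair_type(b[i], b[k]) > 0L)
          out <- c(out, as.vector(outer(
            paste0("(", rec(i + 1L, k - 1L), ")"),
            rec(k + 1L, j), paste0)))
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

#' Exhaustive minimum-free-energy fold
#'
#' Scores every structure from [enumerate_structures()] and returns the
#' minimum. Ties are broken toward fewer pairs, then the lexicographically
#' smallest dot-bracket string.
#'
#' @inheritParams enumerate_structures
#' @param model an `energy_model`.
#' @return list with `mfe`, `structure`, and `n_structures` examined.
#' @export
exhaustive_fold <- function(seq, model = energy_model(), max_nt = 14L) {
  seq <- normalize_rna(seq)
  structs <- enumerate_structures(seq, model$min_hairpin, max_nt)
  energies <- vapply(structs, function(s) score_structure(seq, s, model),
                     1.0, USE.NAMES = FALSE)
  npairs <- vapply(structs,
                   function(s) sum(strsplit(s, "")[[1]] == "("),
                   1L, USE.NAMES = FALSE)
  ord <- order(energies, npairs, structs)
  best <- ord[1]
  list(mfe = energies[best], structure = structs[best],
       n_structures = length(structs))
}

#' Brute-force joint CDS design
#'
#' Enumerates every synonymous CDS, folds each one, and returns the CDS
#' minimizing `mu * MFE + kappa * sum(-ln w)`. The independent ground
#' truth for [design_cds()] at small scale.
#'
#' @param protein protein sequence, at most `max_codons` residues.
#' @param w an `adaptiveness_map`.
#' @param model an `energy_model`.
#' @param objective a `design_objective`.
#' @param folder `"dp"` uses [fold_fixed()] as the inner folder (validated
#'   separately against [exhaustive_fold()]); `"exhaustive"` uses full
#'   structure enumeration (proteins of at most 4 codons).
#' @param max_codons guard.
#' @return list with `cds`, `mfe`, `S`, `cai`, `objective_value`, and the
#'   per-CDS table `all` (data.frame: cds, mfe, S, objective).
#' @export
brute_force_design <- function(protein, w, model = energy_model(),
                               objective = design_objective("derna", 0.5),
                               folder = c("dp", "exhaustive"),
                               max_codons = 6L) {
  folder <- match.arg(folder)
  stopifnot(inherits(w, "adaptiveness_map"),
            inherits(objective, "design_objective"))
  protein <- validate_protein(protein)
  l <- nchar(protein)
  if (l > max_codons)
    stop("protein longer than ", max_codons, " residues; use design_cds()")
  if (folder == "exhaustive" && l > 4L)
    stop("exhaustive inner folder limited to 4 codons")
  cdss <- enumerate_cds(protein, max_codons)
  mfe <- vapply(cdss, function(cds) {
    if (folder == "dp") fold_fixed(cds, model)$mfe
    else exhaustive_fold(cds, model, max_nt = 3L * l)$mfe
  }, 1.0, USE.NAMES = FALSE)
  S <- vapply(cdss, cai_log_sum, 1.0, w = w, USE.NAMES = FALSE)
  obj <- objective$mu * mfe - objective$kappa * S
  ord <- order(obj, cdss)                     # tie-break: lex smallest CDS
  k <- ord[1]
  list(cds = cdss[k], mfe = mfe[k], S = S[k], cai = exp(S[k] / l),
       objective_value = obj[k],
       all = data.frame(cds = cdss, mfe = mfe, S = S, objective = obj,
                        stringsAsFactors = FALSE))
}
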