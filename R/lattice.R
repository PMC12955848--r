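# Codon lattice: a compact graph over nucleotide positions 0..3l-1 whose
# root-to-end paths are exactly the synonymous CDSs of a protein. Each
# position holds "variant states" = distinct codon prefixes spelled so far
# within the current codon (length 1, 2 or 3). The prefix-trie transitions
# encode intra-codon dependencies (e.g. for the six-codon families Leu
# UUR/CUN, Arg CGN/AGR, Ser UCN/AGY the first and third nucleotide are
# coupled: an AG prefix for Ser can only continue with U or C). Across a
# codon boundary every third-position state connects to every first-position
# state of the next codon. Third-position states carry the completed codon
# and its ln w weight; the design DP charges that weight exactly once per
# codon.

#' Build the codon lattice for a protein
#'
#' @param protein protein sequence (20 standard letters, optional trailing
#'   `*` designed as a stop codon).
#' @param w an `adaptiveness_map`; each residue's family is the set of its
#'   synonymous codons present in the map.
#' @return a `codon_lattice` object; see Details.
#' @details The object is a list with `protein`, `l` (codons), `L` (= 3l),
#'   `states` (per position, a data.frame with `prefix`, `nuc`, and for
#'   third positions `codon`, `log_w`), and `adj` (per boundary, a logical
#'   matrix of allowed state transitions). States are ordered
#'   lexicographically by prefix, so all downstream tie-breaking is
#'   deterministic.
#' @examples
#' w <- relative_adaptiveness(human_codon_usage())
#' lat <- build_lattice("MS", w)
#' count_paths(lat)  # 6
#' @export
build_lattice <- function(protein, w) {
  stopifnot(inherits(w, "adaptiveness_map"))
  protein <- validate_protein(protein)
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  l <- length(res)
  states <- vector("list", 3L * l)
  adj <- vector("list", 3L * l - 1L)
  fams <- vector("list", l)
  for (i in seq_len(l)) {
    fam_all <- codon_family(res[i])       # errors on unknown residue
    fam <- intersect(fam_all, names(w$w))
    if (length(fam) == 0L)
      stop("residue '", res[i], "' at position ", i,
           " has no codon in the adaptiveness map")
    fams[[i]] <- sort(fam)
  }
  for (i in seq_len(l)) {
    fam <- fams[[i]]
    for (k in 1:3) {
      pref <- sort(unique(substr(fam, 1L, k)))
      st <- data.frame(prefix = pref,
                       nuc = substr(pref, k, k),
                       stringsAsFactors = FALSE)
      if (k == 3L) {
        st$codon <- pref
        st$log_w <- as.numeric(w$log_w[pref])
      } else {
        st$codon <- NA_character_
        st$log_w <- 0
      }
      states[[3L * (i - 1L) + k]] <- st
    }
    # intra-codon transitions: prefix extension
    for (k in 1:2) {
      p <- 3L * (i - 1L) + k
      a <- states[[p]]$prefix
      b <- states[[p + 1L]]$prefix
      adj[[p]] <- outer(a, b, function(x, y) substr(y, 1L, k) == x)
    }
  }
  # codon boundaries: complete bipartite transitions
  for (i in seq_len(l - 1L)) {
    p <- 3L * i
    adj[[p]] <- matrix(TRUE, nrow(states[[p]]), nrow(states[[p + 1L]]))
  }
  structure(list(protein = protein, residues = res, families = fams,
                 l = l, L = 3L * l, states = states, adj = adj),
            class = "codon_lattice")
}

#' Number of distinct CDSs represented by a lattice
#'
#' @param lattice a `codon_lattice`.
#' @return the exact count (product of synonymous family sizes), as a
#'   double to allow very large lattices.
#' @export
count_paths <- function(lattice) {
  stopifnot(inherits(lattice, "codon_lattice"))
  prod(vapply(lattice$families, length, 1L))
}

# Enumerate the CDS spellings of all lattice paths (small proteins only;
# used to validate the lattice against the brute-force codon product).
#' @noRd
lattice_spellings <- function(lattice, max_codons = 8L) {
  stopifnot(inherits(lattice, "codon_lattice"))
  if (lattice$l > max_codons)
    stop("refusing to enumerate paths for more than ", max_codons, " codons")
  walk <- function(p, s) {                 # returns suffix spellings from (p, s)
    nuc <- lattice$states[[p]]$nuc[s]
    if (p == lattice$L) return(nuc)
    nxt <- which(lattice$adj[[p]][s, ])
    unlist(lapply(nxt, function(t) paste0(nuc, walk(p + 1L, t))))
  }
  sort(unlist(lapply(seq_len(nrow(lattice$states[[1]])),
                     function(s) walk(1L, s))))
}

#' @export
print.codon_lattice <- function(x, ...) {
  cat("codon lattice: protein ", x$protein, " (", x$l, " codons, L = ",
      x$L, " nt, ", format(count_paths(x), big.mark = ","),
      " CDS paths)\n", sep = "")
  invisible(x)
}

#' Text dump of a lattice's states and transitions
#'
#' Debug view: one line per state (`position prefix nucleotide [codon ln_w]`)
#' followed by an adjacency listing.
#'
#' @param lattice a `codon_lattice`.
#' @return character vector of lines (invisibly printed if not assigned).
#' @export
dump_lattice <- function(lattice) {
  stopifnot(inherits(lattice, "codon_lattice"))
  out <- character(0)
  for (p in seq_len(lattice$L)) {
    st <- lattice$states[[p]]
    for (s in seq_len(nrow(st))) {
      line <- sprintf("pos %d state %d prefix %-3s nuc %s", p - 1L, s - 1L,
                      st$prefix[s], st$nuc[s])
      if (!is.na(st$codon[s]))
        line <- sprintf("%s codon %s ln_w %.6f", line, st$codon[s], st$log_w[s])
      if (p < lattice$L) {
        nxt <- which(lattice$adj[[p]][s, ]) - 1L
        line <- paste0(line, " -> {", paste(nxt, collapse = ","), "}")
      }
      out <- c(out, line)
    }
  }
  out
}
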