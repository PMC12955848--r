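# Codon-usage tables, relative adaptiveness and CAI.
#
# CAI (Sharp & Li) is the geometric mean of per-codon relative
# adaptiveness w, where w(c) = freq(c) / max frequency in c's synonymous
# family. The additive form S = sum(ln w) over codons satisfies
# CAI = exp(S / l) for l codons; the design DP charges -ln w per codon, so
# S is the quantity the optimizer actually manipulates. Natural logarithms
# are used throughout.

#' Load a codon-usage table
#'
#' Reads per-codon frequencies from either a Kazusa-style "codon frequency"
#' text block (fields like `UUU 17.6( 714298)`, several per line) or a
#' two-column TSV (`codon<TAB>frequency`). DNA codons are transparently
#' converted to RNA (T to U). Units (per-thousand, percent, raw counts) are
#' irrelevant: only within-family ratios are used downstream.
#'
#' @param source path to a file, or a character vector of lines.
#' @param dialect `"auto"` (default), `"kazusa"` or `"tsv"`.
#' @return a `codon_usage` object: named numeric vector of frequencies
#'   keyed by RNA codon.
#' @examples
#' load_codon_usage(c("UUU\t17.6", "UUC\t20.3"), dialect = "tsv")
#' @export
load_codon_usage <- function(source, dialect = c("auto", "kazusa", "tsv")) {
  dialect <- match.arg(dialect)
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else as.character(source)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("codon usage source is empty")
  if (dialect == "auto")
    dialect <- if (any(grepl("\\(", lines))) "kazusa" else "tsv"

  codons <- character(0); freqs <- numeric(0); origin <- integer(0)
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (dialect == "kazusa") {
      # drop parenthesized counts, then read (codon, value) token pairs
      ln2 <- gsub("\\([^)]*\\)", " ", ln)
      toks <- strsplit(trimws(ln2), "\\s+")[[1]]
      if (length(toks) == 0L) next
      if (length(toks) %% 2L != 0L)
        stop("malformed codon usage line ", lineno[k],
             ": expected codon/frequency pairs")
      cs <- toks[seq(1L, length(toks), 2L)]
      fs <- suppressWarnings(as.numeric(toks[seq(2L, length(toks), 2L)]))
    } else {
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(toks) < 2L)
        stop("malformed codon usage line ", lineno[k],
             ": expected 'codon<TAB>frequency'")
      cs <- toks[1L]
      fs <- suppressWarnings(as.numeric(toks[2L]))
    }
    bad <- which(is.na(fs) | fs < 0)
    if (length(bad) > 0L)
      stop("malformed codon usage line ", lineno[k],
           ": bad frequency for '", cs[bad[1]], "'")
    cs <- chartr("T", "U", toupper(cs))
    badc <- which(nchar(cs) != 3L | grepl("[^ACGU]", cs))
    if (length(badc) > 0L)
      stop("malformed codon usage line ", lineno[k],
           ": invalid codon '", cs[badc[1]], "'")
    codons <- c(codons, cs); freqs <- c(freqs, fs)
    origin <- c(origin, rep(lineno[k], length(cs)))
  }
  dup <- which(duplicated(codons))
  if (length(dup) > 0L)
    stop("duplicate codon '", codons[dup[1]], "' at line ", origin[dup[1]])
  structure(setNames(freqs, codons), class = "codon_usage")
}

#' Embedded Homo sapiens codon-usage table
#'
#' The per-thousand human codon-usage frequencies shipped with the package
#' (classic Kazusa Codon Usage Database values).
#'
#' @return a `codon_usage` object covering all 64 codons.
#' @export
human_codon_usage <- function() {
  if (is.null(.cf_env$human_usage)) {
    path <- system.file("extdata", "homo_sapiens_codon_usage.tsv",
                        package = "codonfold", mustWork = TRUE)
    .cf_env$human_usage <- load_codon_usage(path, dialect = "tsv")
  }
  .cf_env$human_usage
}

#' Relative adaptiveness of codons
#'
#' For every synonymous family present in the table, computes
#' `w(c) = max(freq(c), floor * max_freq) / max_freq`, so the family's
#' most-used codon has w = 1 exactly and zero-frequency codons are kept in
#' the search space with a small floored weight rather than dropped (which
#' would silently shrink the structure search space).
#'
#' @param table a `codon_usage` object (or named numeric vector).
#' @param floor small positive constant; default `1e-3`.
#' @return an `adaptiveness_map`: list with `w` (named numeric in (0, 1]),
#'   `log_w` (natural log of `w`) and `floor`.
#' @export
relative_adaptiveness <- function(table, floor = 1e-3) {
  stopifnot(is.numeric(table), !is.null(names(table)),
            is.numeric(floor), length(floor) == 1L, floor > 0)
  gc <- genetic_code_rna()
  unknown <- setdiff(names(table), names(gc))
  if (length(unknown) > 0L)
    stop("unknown codon in usage table: ", unknown[1])
  aa <- gc[names(table)]
  w <- numeric(0)
  for (fam_aa in unique(aa)) {
    idx <- which(aa == fam_aa)
    f <- as.numeric(table[idx])
    mx <- max(f)
    if (mx <= 0)
      stop("all-zero frequencies for the codon family of '", fam_aa, "'")
    wf <- pmax(f, floor * mx) / mx
    w <- c(w, setNames(wf, names(table)[idx]))
  }
  w <- w[order(names(w))]
  structure(list(w = w, log_w = log(w), floor = floor),
            class = "adaptiveness_map")
}

#' Codon adaptation index of a CDS
#'
#' Geometric mean of per-codon relative adaptiveness,
#' `exp(mean(ln w(codon)))`. See [cai_log_sum()] for the additive form
#' `S = sum(ln w)` used by the optimizer (`CAI = exp(S / l)`).
#'
#' @param cds RNA (or DNA) coding sequence, length divisible by 3.
#' @param w an `adaptiveness_map` from [relative_adaptiveness()].
#' @return CAI in (0, 1].
#' @export
cai <- function(cds, w) {
  exp(cai_log_sum(cds, w) / (nchar(normalize_rna(cds)) / 3))
}

#' Sum of log relative adaptiveness over codons
#'
#' @inheritParams cai
#' @return `S = sum over codons of ln w(codon)` (natural log; S <= 0).
#' @export
cai_log_sum <- function(cds, w) {
  stopifnot(inherits(w, "adaptiveness_map"))
  cods <- split_codons(cds)
  miss <- which(!(cods %in% names(w$w)))
  if (length(miss) > 0L)
    stop("codon '", cods[miss[1]], "' (codon position ", miss[1],
         ") absent from the adaptiveness map")
  sum(w$log_w[cods])
}
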