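# FASTA input, result serialization, and the command-line entry point.
# Multi-record protein FASTAs are processed independently; outputs are
# suffixed by record id. There is no randomness anywhere in the package,
# so runs are reproducible without a seed.

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of protein sequences (20 standard residues,
#'   optional single trailing `*`).
#' @return named character vector of validated sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no sequences in ", path)
  seqs <- as.character(aa)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
  out <- character(length(seqs))
  for (i in seq_along(seqs)) {
    out[i] <- tryCatch(validate_protein(seqs[i]), error = function(e)
      stop("record '", ids[i], "': ", conditionMessage(e), call. = FALSE))
  }
  setNames(out, ids)
}

#' @noRd
write_fasta <- function(seqs, path, dna = FALSE) {
  if (dna) seqs <- chartr("U", "T", seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  invisible(path)
}

#' @noRd
cli_parser <- function() {
  if (!requireNamespace("optparse", quietly = TRUE))
    stop("run_cli requires the optparse package")
  optparse::OptionParser(
    usage = "codonfold --protein <fasta> [options]",
    option_list = list(
      optparse::make_option("--protein", type = "character",
        help = "protein FASTA file (required)"),
      optparse::make_option("--mode", type = "character", default = "single",
        help = "single | pareto [default %default]"),
      optparse::make_option("--formulation", type = "character",
        default = "derna",
        help = "derna | linear_design (single mode) [default %default]"),
      optparse::make_option("--lambda", type = "double", default = 0.5,
        help = "trade-off parameter (single mode) [default %default]"),
      optparse::make_option("--beam", type = "integer", default = NA_integer_,
        help = "beam width (omit for exact search)"),
      optparse::make_option("--model", type = "character",
        default = "nearest_neighbor",
        help = "nearest_neighbor | nussinov [default %default]"),
      optparse::make_option("--usage", type = "character", default = "embedded",
        help = "codon usage table path, or 'embedded' [default %default]"),
      optparse::make_option("--out", type = "character", default = "codonfold",
        help = "output prefix [default %default]"),
      optparse::make_option("--dna", action = "store_true", default = FALSE,
        help = "write CDS output as DNA (T instead of U)"),
      optparse::make_option("--quiet", action = "store_true", default = FALSE,
        help = "suppress progress messages")))
}

#' Command-line entry point
#'
#' `single` mode writes, per FASTA record: a CDS FASTA, a Vienna-style
#' `.fold` file (sequence + dot-bracket), and a one-row metrics TSV
#' (mfe, cai, S, objective, lambda). `pareto` mode writes the front TSV
#' (see [write_front_tsv()]) and a FASTA of the distinct front CDSs.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly. Written file paths are
#'   attached as the `"files"` attribute.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  parser <- cli_parser()
  opt <- tryCatch(optparse::parse_args(parser, args = args),
                  error = function(e) e)
  status <- 0L
  files <- character(0)
  out <- tryCatch({
    if (inherits(opt, "error")) stop(conditionMessage(opt))
    if (is.null(opt$protein)) stop("--protein is required")
    if (!opt$mode %in% c("single", "pareto"))
      stop("--mode must be 'single' or 'pareto'")
    if (!opt$model %in% c("nearest_neighbor", "nussinov"))
      stop("--model must be 'nearest_neighbor' or 'nussinov'")
    proteins <- read_protein_fasta(opt$protein)
    model <- energy_model(opt$model)
    usage <- if (identical(opt$usage, "embedded")) human_codon_usage()
             else load_codon_usage(opt$usage)
    w <- relative_adaptiveness(usage)
    beam <- if (is.na(opt$beam)) Inf else opt$beam
    say <- function(...) if (!opt$quiet) message(...)
    for (id in names(proteins)) {
      say("[codonfold] ", opt$mode, " design for record '", id, "' (",
          nchar(proteins[[id]]), " aa, model ", opt$model, ")")
      prefix <- paste0(opt$out, "_", id)
      if (opt$mode == "single") {
        lattice <- build_lattice(proteins[[id]], w)
        obj <- design_objective(opt$formulation, opt$lambda)
        r <- design_cds(lattice, model, obj, beam = beam)
        f1 <- paste0(prefix, "_cds.fasta")
        write_fasta(setNames(r$cds, id), f1, dna = opt$dna)
        f2 <- paste0(prefix, ".fold")
        writeLines(c(paste0(">", id),
                     if (opt$dna) chartr("U", "T", r$cds) else r$cds,
                     r$structure), f2)
        f3 <- paste0(prefix, "_metrics.tsv")
        write.table(data.frame(id = id, mfe = r$mfe, cai = r$cai, S = r$S,
                               objective = r$objective_value,
                               lambda = r$lambda,
                               formulation = r$formulation),
                    f3, sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(files, f1, f2, f3)
        say(sprintf("[codonfold]   MFE %.4f  CAI %.4f  objective %.6f",
                    r$mfe, r$cai, r$objective_value))
      } else {
        front <- pareto_front(proteins[[id]], usage = w, model = model,
                              beam = beam)
        f1 <- paste0(prefix, "_front.tsv")
        write_front_tsv(front, f1)
        fr <- as.data.frame(front)
        f2 <- paste0(prefix, "_cds.fasta")
        write_fasta(setNames(fr$cds,
                             sprintf("%s_pareto_%02d", id, seq_len(nrow(fr)))),
                    f2, dna = opt$dna)
        files <- c(files, f1, f2)
        say(sprintf("[codonfold]   n/N = %d/%d distinct Pareto CDSs",
                    front$n, front$N))
      }
    }
    0L
  }, error = function(e) {
    message("codonfold error: ", conditionMessage(e))
    # remove any partially written outputs of this invocation
    for (f in files) if (file.exists(f)) unlink(f)
    1L
  })
  status <- out
  invisible(structure(status, files = files))
}
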