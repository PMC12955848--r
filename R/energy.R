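# Secondary-structure energy models and the reference structure scorer.
#
# Two models share one loop-decomposition scoring scheme:
#  * "nussinov": every loop closed by a pair contributes exactly -1 unit,
#    so a structure scores -(number of pairs). Useful for exact small-scale
#    validation because the optimum is enumerable.
#  * "nearest_neighbor": a reduced Turner 2004 free-energy model (kcal/mol
#    at 37 C): stacking for all canonical pair-on-pair combinations,
#    hairpin/bulge/internal loop-length penalties (<= 30, logarithmic
#    extrapolation beyond), an affine multiloop term
#    a + b * (branches incl. closing) + c * unpaired, and an optional
#    terminal-AU penalty per helix end. No dangling ends, coaxial stacking,
#    terminal mismatches, special tetraloops, or internal-loop asymmetry:
#    a deliberate reduction of the full model with a bounded parameter
#    surface (see the vignette for the consequences).
#
# Conventions shared with the C++ design DP (must stay in lock-step):
#  * allowed pairs: AU, UA, CG, GC, GU, UG; minimum hairpin loop 3.
#  * stacking term indexed [outer pair (i,j)][reversed inner pair (q,p)].
#  * a length-1 bulge keeps the stacking term and takes no terminal-AU
#    penalty; longer bulges and internal loops take terminal-AU on both
#    closing pairs and no stacking.

PAIR_NAMES <- c("CG", "GC", "GU", "UG", "AU", "UA")

#' @noRd
pair_type <- function(a, b) {
  match(paste0(a, b), PAIR_NAMES, nomatch = 0L)
}

#' Construct an energy model
#'
#' @param name `"nussinov"` (base-pair maximization: -1 per pair) or
#'   `"nearest_neighbor"` (reduced Turner 2004 model, kcal/mol).
#' @param terminal_au apply the terminal-AU/GU helix-end penalty
#'   (nearest-neighbor model only).
#' @param params_file optional path to an alternative parameter table in
#'   the same `term<TAB>context<TAB>value` dialect as the embedded one.
#' @return an `energy_model` object.
#' @export
energy_model <- function(name = c("nearest_neighbor", "nussinov"),
                         terminal_au = TRUE, params_file = NULL) {
  name <- match.arg(name)
  if (name == "nussinov") {
    hp <- rep(-1, 31); hp[1:3] <- Inf          # loop sizes 0..2 impossible
    m <- structure(list(
      name = "nussinov", min_hairpin = 3L, max_loop = 30L,
      stack = matrix(-1, 6, 6, dimnames = list(PAIR_NAMES, PAIR_NAMES)),
      hairpin = hp,
      bulge = c(Inf, rep(-1, 30)),
      internal = c(Inf, Inf, rep(-1, 29)),
      lxc = 0, ml_a = -1, ml_b = 0, ml_c = 0,
      terminal_au = 0, bulge1_stacks = FALSE, unit = "pairs"),
      class = "energy_model")
    return(m)
  }
  if (is.null(params_file))
    params_file <- system.file("extdata", "turner2004_lite.tsv",
                               package = "codonfold", mustWork = TRUE)
  tab <- read.delim(params_file, header = FALSE, comment.char = "#",
                    col.names = c("term", "context", "value"),
                    stringsAsFactors = FALSE)
  tab$value <- suppressWarnings(
    ifelse(tab$value == "Inf", Inf, as.numeric(tab$value)))
  if (anyNA(tab$value)) stop("bad value in energy parameter file")
  get1 <- function(term, context) {
    v <- tab$value[tab$term == term & tab$context == context]
    if (length(v) != 1L) stop("missing parameter ", term, "/", context)
    v
  }
  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_NAMES, PAIR_NAMES))
  for (a in PAIR_NAMES) for (b in PAIR_NAMES)
    stack[a, b] <- get1("stack", paste0(a, "/", b))
  lentab <- function(term) {
    v <- rep(NA_real_, 31)
    sub <- tab[tab$term == term, ]
    v[as.integer(sub$context) + 1L] <- sub$value
    if (anyNA(v)) stop("incomplete ", term, " length table")
    v
  }
  structure(list(
    name = "nearest_neighbor", min_hairpin = 3L, max_loop = 30L,
    stack = stack,
    hairpin = lentab("hairpin"),
    bulge = lentab("bulge"),
    internal = lentab("internal"),
    lxc = get1("misc", "lxc"),
    ml_a = get1("multiloop", "closing_a"),
    ml_b = get1("multiloop", "branch_b"),
    ml_c = get1("multiloop", "unpaired_c"),
    terminal_au = if (isTRUE(terminal_au)) get1("misc", "terminal_au") else 0,
    bulge1_stacks = TRUE, unit = "kcal/mol"),
    class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("energy model:", x$name, "(", x$unit, "), min hairpin",
      x$min_hairpin, "\n")
  invisible(x)
}

#' @noRd
loop_length_term <- function(tab, n, lxc) {
  if (n <= 30L) tab[n + 1L] else tab[31L] + lxc * log(n / 30)
}

#' @noRd
au_penalty <- function(model, ptype) {
  if (ptype >= 3L) model$terminal_au else 0
}

#' Parse a dot-bracket string into a partner vector
#' @noRd
parse_dot_bracket <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  bad <- which(!(ch %in% c("(", ")", ".")))
  if (length(bad) > 0L)
    stop("invalid structure character '", ch[bad[1]], "' at position ", bad[1])
  partner <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' at position ", i)
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    }
  }
  if (length(stack) > 0L)
    stop("unbalanced '(' at position ", stack[length(stack)])
  partner
}

#' Decompose a secondary structure into loops
#'
#' Splits a pseudoknot-free structure into its unique loop decomposition:
#' hairpins, stacks, bulges, internal loops, multiloops and the external
#' loop. Every pair appears exactly once as the closing pair of one loop
#' (pairs in the external loop close the loop beneath them).
#'
#' @param seq RNA sequence (used only for length validation here).
#' @param structure dot-bracket string, same length, single bracket type.
#' @param min_hairpin minimum unpaired length of a hairpin loop.
#' @return list of loops; each a list with `type`, `closing` (i, j pair,
#'   1-based; NULL for the external loop), `branches` (list of inner
#'   pairs), and `unpaired` counts.
#' @export
loop_decompose <- function(seq, structure, min_hairpin = 3L) {
  seq <- normalize_rna(seq)
  if (nchar(seq) != nchar(structure))
    stop("sequence and structure lengths differ (", nchar(seq), " vs ",
         nchar(structure), ")")
  partner <- parse_dot_bracket(structure)
  n <- length(partner)
  # direct children (maximal pairs) of the open region (i, j), exclusive
  children <- function(i, j) {
    out <- list(); k <- i + 1L
    while (k < j) {
      if (partner[k] > k) { out[[length(out) + 1L]] <- c(k, partner[k]); k <- partner[k] + 1L }
      else k <- k + 1L
    }
    out
  }
  loops <- list()
  visit <- function(i, j) {              # loop closed by pair (i, j)
    br <- children(i, j)
    u <- (j - i - 1L) - sum(vapply(br, function(p) p[2] - p[1] + 1L, 1L))
    if (length(br) == 0L) {
      if (u < min_hairpin)
        stop("hairpin loop of length ", u, " closed by (", i, ",", j,
             ") is below the minimum of ", min_hairpin)
      loops[[length(loops) + 1L]] <<- list(type = "hairpin",
                                           closing = c(i, j),
                                           branches = list(), unpaired = u)
    } else if (length(br) == 1L) {
      p <- br[[1]]
      n1 <- p[1] - i - 1L; n2 <- j - p[2] - 1L
      type <- if (n1 == 0L && n2 == 0L) "stack"
              else if (n1 == 0L || n2 == 0L) "bulge" else "internal"
      loops[[length(loops) + 1L]] <<- list(type = type, closing = c(i, j),
                                           branches = br,
                                           unpaired = c(n1, n2))
    } else {
      loops[[length(loops) + 1L]] <<- list(type = "multiloop",
                                           closing = c(i, j),
                                           branches = br, unpaired = u)
    }
    for (p in br) visit(p[1], p[2])
  }
  ext <- children(0L, n + 1L)
  loops[[length(loops) + 1L]] <- list(type = "external", closing = NULL,
                                      branches = ext,
                                      unpaired = n - sum(vapply(ext,
                                        function(p) p[2] - p[1] + 1L, 1L)))
  for (p in ext) visit(p[1], p[2])
  loops
}

#' Score a (sequence, structure) pair under an energy model
#'
#' Sums per-loop terms of the unique loop decomposition. This is the
#' reference scorer: the design DP's reported energies must reproduce it
#' exactly for the structures they return.
#'
#' @inheritParams loop_decompose
#' @param model an `energy_model`.
#' @return total energy (kcal/mol for `nearest_neighbor`, pair units for
#'   `nussinov`).
#' @export
score_structure <- function(seq, structure, model = energy_model()) {
  stopifnot(inherits(model, "energy_model"))
  seq <- normalize_rna(seq)
  loops <- loop_decompose(seq, structure, model$min_hairpin)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  pt <- function(i, j) {
    t <- pair_type(b[i], b[j])
    if (t == 0L)
      stop("non-canonical pair ", b[i], "-", b[j], " at positions (",
           i, ",", j, ")")
    t
  }
  total <- 0
  for (lp in loops) {
    e <- switch(lp$type,
      hairpin = {
        t <- pt(lp$closing[1], lp$closing[2])
        loop_length_term(model$hairpin, lp$unpaired, model$lxc) +
          au_penalty(model, t)
      },
      stack = {
        t_out <- pt(lp$closing[1], lp$closing[2])
        p <- lp$branches[[1]]
        t_in_rev <- pt(p[2], p[1])
        model$stack[t_out, t_in_rev]
      },
      bulge = {
        t_out <- pt(lp$closing[1], lp$closing[2])
        p <- lp$branches[[1]]
        nb <- sum(lp$unpaired)
        v <- loop_length_term(model$bulge, nb, model$lxc)
        if (nb == 1L && model$bulge1_stacks)
          v + model$stack[t_out, pt(p[2], p[1])]
        else
          v + au_penalty(model, t_out) + au_penalty(model, pt(p[1], p[2]))
      },
      internal = {
        t_out <- pt(lp$closing[1], lp$closing[2])
        p <- lp$branches[[1]]
        loop_length_term(model$internal, sum(lp$unpaired), model$lxc) +
          au_penalty(model, t_out) + au_penalty(model, pt(p[1], p[2]))
      },
      multiloop = {
        t_out <- pt(lp$closing[1], lp$closing[2])
        v <- model$ml_a + model$ml_b * (length(lp$branches) + 1L) +
          model$ml_c * lp$unpaired + au_penalty(model, t_out)
        for (p in lp$branches) v <- v + au_penalty(model, pt(p[1], p[2]))
        v
      },
      external = {
        v <- 0
        for (p in lp$branches) v <- v + au_penalty(model, pt(p[1], p[2]))
        v
      })
    total <- total + e
  }
  total
}
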