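# The joint minimization over (CDS, structure): exact mode and beam mode.
#
# Both objective formulations reduce to minimizing
#     mu * E(structure) + kappa * sum(-ln w(codon))
# with (mu, kappa) = (1, lambda)      for the "linear_design" form
#                        MFE - lambda * l * log(CAI), lambda in [0, Inf),
# and (mu, kappa) = (lambda, 1 - lambda) for the "derna" form
#                        lambda * MFE - (1 - lambda) * l * log(CAI),
#                        lambda in [0, 1].
# The equivalence is the additive identity l * log(CAI) = sum(ln w).

BASE_CODE <- c(A = 0L, C = 1L, G = 2L, U = 3L)

#' Construct a design objective
#'
#' @param formulation `"derna"` (`lambda * MFE - (1 - lambda) * l log CAI`,
#'   `lambda` in \[0, 1\]) or `"linear_design"`
#'   (`MFE - lambda * l log CAI`, `lambda >= 0`).
#' @param lambda the trade-off parameter.
#' @return a `design_objective` with derived weights `mu` (on energy) and
#'   `kappa` (on `-ln w` per codon).
#' @export
design_objective <- function(formulation = c("derna", "linear_design"),
                             lambda = 0.5) {
  formulation <- match.arg(formulation)
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda))
  if (formulation == "derna") {
    if (lambda < 0 || lambda > 1)
      stop("derna formulation requires lambda in [0, 1]")
    mu <- lambda; kappa <- 1 - lambda
  } else {
    if (lambda < 0)
      stop("linear_design formulation requires lambda >= 0")
    mu <- 1; kappa <- lambda
  }
  structure(list(formulation = formulation, lambda = lambda,
                 mu = mu, kappa = kappa),
            class = "design_objective")
}

#' @noRd
lattice_arrays <- function(lattice, kappa) {
  L <- lattice$L
  ns <- vapply(lattice$states, nrow, 1L)
  nuc <- integer(6L * L)
  cw <- numeric(6L * L)
  for (p in seq_len(L)) {
    st <- lattice$states[[p]]
    idx <- (p - 1L) * 6L + seq_len(nrow(st))
    nuc[idx] <- BASE_CODE[st$nuc]
    cw[idx] <- kappa * (-st$log_w)
  }
  adjv <- logical(max(L - 1L, 0L) * 36L)
  for (p in seq_len(max(L - 1L, 0L))) {
    a <- lattice$adj[[p]]
    for (s in seq_len(nrow(a)))
      adjv[(p - 1L) * 36L + (s - 1L) * 6L + seq_len(ncol(a))] <- a[s, ]
  }
  list(L = L, ns = ns, nuc = nuc, adjv = adjv, cw = cw)
}

#' @noRd
call_dp <- function(arr, model, mu, beam) {
  if (is.infinite(beam)) beam <- 0L
  beam <- as.integer(beam)
  if (beam < 0L) stop("beam width must be >= 1 (or Inf for exact search)")
  .design_dp(arr$L, arr$ns, arr$nuc, arr$adjv, arr$cw,
             model$stack, model$hairpin, model$bulge, model$internal,
             model$lxc, model$ml_a, model$ml_b, model$ml_c,
             model$terminal_au, model$bulge1_stacks, mu,
             model$min_hairpin, model$max_loop, beam)
}

#' Design a CDS by joint MFE/CAI optimization
#'
#' Runs the Zuker-style dynamic program over the codon lattice. With
#' `beam = Inf` (default) the returned CDS and structure minimize the
#' objective over all (CDS, structure) pairs; with a finite beam width the
#' result is feasible and its objective is an upper bound on the exact
#' optimum (equal once the beam saturates the state space). The per-codon
#' weight `kappa * (-ln w)` is charged exactly once, on the codon-completing
#' third-position lattice edge.
#'
#' @param lattice a `codon_lattice` from [build_lattice()].
#' @param model an `energy_model`.
#' @param objective a `design_objective`.
#' @param beam positive integer beam width, or `Inf` for exact search.
#' @return a `design_result`: list with `cds`, `structure`, `mfe` (energy
#'   of the returned structure under `model`), `S` (= sum ln w), `cai`,
#'   `objective_value`, `lambda`, `formulation`, `exact`, and DP operation
#'   counts in `ops`.
#' @export
design_cds <- function(lattice, model = energy_model(),
                       objective = design_objective("derna", 0.5),
                       beam = Inf) {
  stopifnot(inherits(lattice, "codon_lattice"),
            inherits(model, "energy_model"),
            inherits(objective, "design_objective"))
  if (is.finite(beam) && beam < 1) stop("beam width must be >= 1")
  arr <- lattice_arrays(lattice, objective$kappa)
  res <- call_dp(arr, model, objective$mu, beam)
  st <- res$states + 1L
  cds <- paste(vapply(seq_len(lattice$L),
                      function(p) lattice$states[[p]]$nuc[st[p]], ""),
               collapse = "")
  S <- sum(vapply(seq_len(lattice$l), function(i) {
    p <- 3L * i
    lattice$states[[p]]$log_w[st[p]]
  }, 1.0))
  mfe <- score_structure(cds, res$structure, model)
  obj <- objective$mu * mfe - objective$kappa * S
  if (abs(obj - res$value) > 1e-6)
    stop("internal inconsistency: DP value ", res$value,
         " != rescored objective ", obj)
  structure(list(cds = cds, structure = res$structure, mfe = mfe, S = S,
                 cai = exp(S / lattice$l), objective_value = obj,
                 lambda = objective$lambda,
                 formulation = objective$formulation,
                 exact = is.infinite(beam), protein = lattice$protein,
                 ops = c(twoloop = res$ops_twoloop, split = res$ops_split)),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("designed CDS (", x$formulation, ", lambda = ", format(x$lambda),
      if (!x$exact) ", beam" else "", ")\n", sep = "")
  cat(" ", x$cds, "\n ", x$structure, "\n", sep = "")
  cat(sprintf("  MFE %.4f  CAI %.4f  S %.4f  objective %.6f\n",
              x$mfe, x$cai, x$S, x$objective_value))
  invisible(x)
}

#' Fold a fixed RNA sequence
#'
#' Minimum free energy folding as the degenerate case of the design DP:
#' a single-path lattice (one state per position) with `kappa = 0`.
#'
#' @param seq RNA (or DNA) sequence.
#' @param model an `energy_model`.
#' @return list with `mfe` and `structure` (dot-bracket); the reported
#'   `mfe` equals `score_structure(seq, structure, model)`.
#' @export
fold_fixed <- function(seq, model = energy_model()) {
  stopifnot(inherits(model, "energy_model"))
  seq <- normalize_rna(seq)
  L <- nchar(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  arr <- list(L = L, ns = rep(1L, L),
              nuc = as.integer(rbind(BASE_CODE[bases],
                                     matrix(0L, 5, L))),
              adjv = rep(c(TRUE, rep(FALSE, 35L)), max(L - 1L, 0L)),
              cw = numeric(6L * L))
  res <- call_dp(arr, model, mu = 1, beam = Inf)
  mfe <- score_structure(seq, res$structure, model)
  if (abs(mfe - res$value) > 1e-9)
    stop("internal inconsistency: fold value ", res$value,
         " != rescored ", mfe)
  list(mfe = mfe, structure = res$structure)
}
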