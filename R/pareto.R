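# Weighted-sum enumeration of supported Pareto-optimal CDSs.
#
# Internally uses the derna objective lambda * MFE - (1 - lambda) * S with
# S = sum(ln w). Endpoints are solved at lambda = eps and 1 - eps (pure 0/1
# would ignore one objective entirely and can return dominated
# representatives); then, recursively, the lambda equalizing the two
# endpoint objectives is solved, and the interval is subdivided while the
# new point strictly improves that scalarization. Only supported
# (convex-hull) Pareto points are found, as in weighted-sum methods
# generally. N counts every solver invocation; n counts distinct CDSs on
# the final front.

#' The lambda at which two (MFE, S) points tie
#'
#' For points `a = (Ma, Sa)`, `b = (Mb, Sb)` with `Ma < Mb` and `Sa < Sb`
#' (a is the more stable, lower-CAI point), returns the unique
#' `lambda* = (Sa - Sb) / ((Ma - Mb) + (Sa - Sb))` in (0, 1) where
#' `lambda * M - (1 - lambda) * S` is equal for both.
#'
#' @param a,b numeric length-2 vectors `c(M, S)`.
#' @return `lambda*` in (0, 1), or `NA` for the degenerate cases
#'   `Ma == Mb` / `Sa == Sb` (caller closes the interval).
#' @export
next_lambda <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 2L, length(b) == 2L)
  if (isTRUE(all.equal(a, b, tolerance = 0)) || all(a == b))
    stop("identical points have no separating lambda")
  if (a[1] == b[1] || a[2] == b[2]) return(NA_real_)
  if (!(a[1] < b[1] && a[2] < b[2]))
    stop("expected Ma < Mb and Sa < Sb")
  (a[2] - b[2]) / ((a[1] - b[1]) + (a[2] - b[2]))
}

#' @noRd
scalar_obj <- function(lambda, M, S) lambda * M - (1 - lambda) * S

#' Remove dominated and duplicate design results
#'
#' Keeps only mutually non-dominated points: no retained point has another
#' with MFE at most as low and CAI at least as high (one strictly).
#' Duplicate CDS strings are collapsed; points with identical (MFE, CAI)
#' but different CDSs keep only the lexicographically smallest CDS so the
#' front is strictly ordered. Result is sorted by ascending CAI.
#'
#' @param points list of `design_result` objects.
#' @return filtered, sorted list.
#' @export
filter_dominated <- function(points) {
  if (length(points) == 0L) return(points)
  cds <- vapply(points, `[[`, "", "cds")
  points <- points[!duplicated(cds)]
  mfe <- vapply(points, `[[`, 1.0, "mfe")
  caiv <- vapply(points, `[[`, 1.0, "cai")
  cds <- vapply(points, `[[`, "", "cds")
  keep <- rep(TRUE, length(points))
  for (i in seq_along(points)) {
    for (k in seq_along(points)) {
      if (i == k || !keep[k]) next
      if (mfe[k] <= mfe[i] && caiv[k] >= caiv[i] &&
          (mfe[k] < mfe[i] || caiv[k] > caiv[i])) { keep[i] <- FALSE; break }
    }
  }
  points <- points[keep]
  mfe <- mfe[keep]; caiv <- caiv[keep]; cds <- cds[keep]
  dupobj <- duplicated(paste(signif(mfe, 12), signif(caiv, 12)))
  ord <- order(caiv, mfe, cds)
  points <- points[ord][!dupobj[ord]]
  points
}

#' Annotate a front with MFE and CAI percentages
#'
#' Linearly rescales within the front: `mfe_pct = 100 * (MFEmax - MFE) /
#' (MFEmax - MFEmin)` (100% = most stable) and `cai_pct = 100 *
#' (CAI - CAImin) / (CAImax - CAImin)` (100% = best CAI). A degenerate
#' range (single point) maps to 100 by convention.
#'
#' @param front a `pareto_front` object.
#' @return the front with `mfe_pct` / `cai_pct` filled in.
#' @export
normalize_percentages <- function(front) {
  stopifnot(inherits(front, "pareto_front"))
  mfe <- vapply(front$points, `[[`, 1.0, "mfe")
  caiv <- vapply(front$points, `[[`, 1.0, "cai")
  rng_m <- max(mfe) - min(mfe)
  rng_c <- max(caiv) - min(caiv)
  front$mfe_pct <- if (rng_m > 0) 100 * (max(mfe) - mfe) / rng_m
                   else rep(100, length(mfe))
  front$cai_pct <- if (rng_c > 0) 100 * (caiv - min(caiv)) / rng_c
                   else rep(100, length(caiv))
  front
}

#' Enumerate the supported Pareto front of (MFE, CAI)
#'
#' @param protein protein sequence.
#' @param usage a `codon_usage` table or an `adaptiveness_map`; defaults to
#'   the embedded human table.
#' @param model an `energy_model`.
#' @param beam beam width passed to every solve (default exact).
#' @param eps endpoint perturbation: the extremes are solved at
#'   `lambda = eps` and `1 - eps` so both objectives stay active.
#' @param tol absolute improvement below which an interval is closed.
#' @param max_depth recursion-depth guard (tolerance pathology signal).
#' @param floor floor for [relative_adaptiveness()] when `usage` is a raw
#'   table.
#' @return a `pareto_front`: list with `points` (non-dominated
#'   `design_result`s, ascending CAI), `n` (distinct CDSs), `N` (solver
#'   invocations), `mfe_pct`, `cai_pct`, and `all_results` (every solver
#'   output with its lambda).
#' @export
pareto_front <- function(protein, usage = human_codon_usage(),
                         model = energy_model(), beam = Inf,
                         eps = 1e-6, tol = 1e-9, max_depth = 64L,
                         floor = 1e-3) {
  w <- if (inherits(usage, "adaptiveness_map")) usage
       else relative_adaptiveness(usage, floor = floor)
  lattice <- build_lattice(protein, w)
  all_results <- list()
  solve_at <- function(lambda) {
    r <- design_cds(lattice, model, design_objective("derna", lambda),
                    beam = beam)
    all_results[[length(all_results) + 1L]] <<- r
    r
  }
  hi_cai <- solve_at(eps)        # CAI-lexicographic extreme
  lo_mfe <- solve_at(1 - eps)    # MFE-lexicographic extreme
  pt <- function(r) c(r$mfe, r$S)
  recurse <- function(a, b, depth) {
    # a: lower-MFE/lower-S point; b: higher-MFE/higher-S point
    if (depth > max_depth)
      stop("weighted-sum recursion exceeded depth ", max_depth,
           "; improvement tolerance is pathological for this instance")
    # beam-pruned solves can return unordered endpoint pairs; close then
    if (!(a$mfe < b$mfe && a$S < b$S)) return(invisible(NULL))
    lam <- next_lambda(pt(a), pt(b))
    if (is.na(lam)) return(invisible(NULL))
    r <- solve_at(lam)
    f_new <- scalar_obj(lam, r$mfe, r$S)
    f_end <- scalar_obj(lam, a$mfe, a$S)   # == objective of b at lam
    if (f_new < f_end - tol) {
      recurse(a, r, depth + 1L)
      recurse(r, b, depth + 1L)
    }
    invisible(NULL)
  }
  if (lo_mfe$cds != hi_cai$cds) recurse(lo_mfe, hi_cai, 1L)
  front_points <- filter_dominated(all_results)
  front <- structure(list(protein = lattice$protein, points = front_points,
                          n = length(unique(vapply(front_points, `[[`, "",
                                                   "cds"))),
                          N = length(all_results),
                          all_results = all_results,
                          model = model$name, beam = beam),
                     class = "pareto_front")
  normalize_percentages(front)
}

#' @export
print.pareto_front <- function(x, ...) {
  cat("Pareto front for ", x$protein, " (", x$model, " model): n/N = ",
      x$n, "/", x$N, "\n", sep = "")
  df <- as.data.frame(x)
  print(df[, c("lambda", "mfe", "cai", "mfe_pct", "cai_pct")], digits = 4)
  invisible(x)
}

#' @export
as.data.frame.pareto_front <- function(x, ...) {
  data.frame(
    lambda = vapply(x$points, `[[`, 1.0, "lambda"),
    cds = vapply(x$points, `[[`, "", "cds"),
    structure = vapply(x$points, `[[`, "", "structure"),
    mfe = vapply(x$points, `[[`, 1.0, "mfe"),
    cai = vapply(x$points, `[[`, 1.0, "cai"),
    S = vapply(x$points, `[[`, 1.0, "S"),
    mfe_pct = x$mfe_pct,
    cai_pct = x$cai_pct,
    stringsAsFactors = FALSE)
}

#' Serialize a Pareto run as TSV
#'
#' One row per solver output (N rows), with `distinct_flag` marking rows
#' whose CDS sits on the final deduplicated front.
#'
#' @param front a `pareto_front`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_front_tsv <- function(front, path) {
  stopifnot(inherits(front, "pareto_front"))
  fr <- as.data.frame(front)
  all <- data.frame(
    lambda = vapply(front$all_results, `[[`, 1.0, "lambda"),
    cds = vapply(front$all_results, `[[`, "", "cds"),
    structure = vapply(front$all_results, `[[`, "", "structure"),
    mfe = vapply(front$all_results, `[[`, 1.0, "mfe"),
    cai = vapply(front$all_results, `[[`, 1.0, "cai"),
    S = vapply(front$all_results, `[[`, 1.0, "S"),
    stringsAsFactors = FALSE)
  all$mfe_pct <- fr$mfe_pct[match(all$cds, fr$cds)]
  all$cai_pct <- fr$cai_pct[match(all$cds, fr$cds)]
  all$distinct_flag <- all$cds %in% fr$cds & !duplicated(all$cds)
  write.table(all, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scatter plot of a Pareto front
#'
#' CAI on the x axis, MFE on the y axis, with range-normalized percentage
#' axes on the opposite sides.
#'
#' @param front a `pareto_front`.
#' @return a ggplot object.
#' @export
plot_pareto_front <- function(front) {
  stopifnot(inherits(front, "pareto_front"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_pareto_front requires the ggplot2 package")
  df <- as.data.frame(front)
  mfe_rng <- range(df$mfe); cai_rng <- range(df$cai)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = cai, y = mfe)) +
    ggplot2::geom_step(direction = "hv", colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "CAI", y = sprintf("MFE (%s)",
                    if (front$model == "nussinov") "pairs" else "kcal/mol"),
                  title = sprintf("Pareto-optimal CDSs (n/N = %d/%d)",
                                  front$n, front$N)) +
    ggplot2::theme_minimal()
  if (diff(mfe_rng) > 0)
    p <- p + ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ 100 * (mfe_rng[2] - .) / diff(mfe_rng),
                                   name = "MFE %"))
  if (diff(cai_rng) > 0)
    p <- p + ggplot2::scale_x_continuous(
      sec.axis = ggplot2::sec_axis(~ 100 * (. - cai_rng[1]) / diff(cai_rng),
                                   name = "CAI %"))
  p
}
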