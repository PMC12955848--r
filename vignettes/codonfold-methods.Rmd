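---
title: "codonfold: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{codonfold: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonfold)
```

## The problem

An mRNA's coding sequence (CDS) is underdetermined by the protein it
encodes: each residue may be written with any of its 1–6 synonymous
codons, so a protein of $l$ residues admits up to $6^l$ CDSs. Two
properties of that choice matter for mRNA stability and expression:

* **MFE** — the minimum free energy of the most stable pseudoknot-free
  secondary structure of the CDS; lower (more negative) means a more
  stable, degradation-resistant molecule;
* **CAI** — the codon adaptation index, the geometric mean of per-codon
  relative adaptiveness $w$, where $w(c)$ is a codon's usage frequency
  divided by the maximum frequency in its synonymous family. CAI = 1 means
  every codon is its family's most-used one.

These objectives conflict: the most stable CDS rarely uses the most
adapted codons. `codonfold` minimizes the scalarized objective

$$\mu \cdot \mathrm{MFE} \;+\; \kappa \sum_{\text{codons}} (-\ln w)$$

over **all** (CDS, structure) pairs simultaneously. Because CAI is a
geometric mean, $l \cdot \log \mathrm{CAI} = \sum \ln w$, so the two
published scalarizations are both instances of the same additive form:

* `linear_design`: $\mathrm{MFE} - \lambda\, l \log \mathrm{CAI}$, i.e.
  $(\mu, \kappa) = (1, \lambda)$ with $\lambda \in [0, \infty)$;
* `derna`: $\lambda\, \mathrm{MFE} - (1-\lambda)\, l \log \mathrm{CAI}$,
  i.e. $(\mu, \kappa) = (\lambda, 1-\lambda)$ with $\lambda \in [0, 1]$.

Natural logarithms are used everywhere.

## The codon lattice

All synonymous CDSs are represented as a layered graph with one layer per
nucleotide position ($L = 3l$ layers). A layer's *variant states* are the
distinct codon prefixes spelled so far within the current codon (at most 6
per position, the largest family size). Within a codon, transitions follow
the prefix trie; across a codon boundary every completed codon connects to
every first-position state of the next codon. This prefix encoding
resolves the intra-codon dependencies of the six-codon families: for
serine, an `AG` prefix can only continue with `U` or `C` (AGY), never with
`A` or `G`, and analogously for leucine (UUR/CUN) and arginine (CGN/AGR).
Leucine and arginine are the classically cited dependency cases; serine
has the same two-subfamily split and is handled identically here.

Full codon prefixes are a superset of any minimal "extended nucleotide"
labeling, so no dependency can be lost; the price is at most six states
per layer, which the complexity bounds absorb as a constant. States are
ordered lexicographically by prefix, which makes every later tie-break
deterministic. Third-position states carry the completed codon and its
$\ln w$; the optimizer charges $\kappa(-\ln w)$ exactly once per codon on
that codon-completing state.

## The joint dynamic program

`design_cds()` runs a Zuker-style span DP whose cells are indexed by
*(position, state)* node pairs rather than positions:

* `W` — cheapest all-unpaired state path between two fixed nodes (carries
  the codon charges of unpaired stretches);
* `C` — span closed by a base pair;
* `M1`, `M`, `M2` — multiloop segments with a leading branch, ≥ 1 branch,
  and ≥ 2 branches respectively;
* `F` — external loop, swept left to right.

Allowed pairs are AU, UA, CG, GC, GU, UG; hairpin loops have at least 3
unpaired bases; two-sided loops are searched up to 30 unpaired total (the
standard cutoff). Exact mode is $O(L^3)$ time and $O(L^2)$ memory up to
the constant-bounded state width; the `ops` field of a result exposes
structural step counts so the cubic trend is testable without wall-clock
assertions. The traceback re-derives each decision in a fixed canonical
order, so outputs are bit-reproducible; among co-optimal options it
prefers earlier spans and lexicographically smaller states, which biases
toward lexicographically small CDSs without guaranteeing the global
lexicographic minimum (that would need a second optimization pass and no
consumer of the package depends on it).

Every returned result is re-scored in R: the reported MFE is
`score_structure(cds, structure, model)` recomputed from the loop
decomposition, and construction fails loudly if the DP value and the
re-scored objective disagree by more than $10^{-6}$. The reported MFE is
the energy of the returned structure; at $\mu = 0$ (pure-CAI corner) the
structure is vacuous and the field simply scores it.

### Beam search

With `beam = b`, after each right endpoint's column is completed, only the
$b$ lowest-valued entries of the `C`, `M1` and `M2` matrices are kept
(ties broken by value, then span start and state indices — a deterministic
$O(1)$ rule). `W`, `M` and `F` are never pruned, which keeps every stored
value reproducible by the traceback and guarantees feasibility: the
beam result's objective is always an upper bound on the exact optimum and
equals it once $b$ exceeds the column population.

## Energy models

Two interchangeable models share the loop-decomposition scorer:

* **nussinov** — every loop closed by a pair contributes −1, so the score
  is −(number of pairs). Its optimum is enumerable by brute force, which
  makes it the workhorse of the validation suite.
* **nearest_neighbor** — a reduced Turner 2004 free-energy model
  (kcal/mol, 37 °C) shipped as a plain-text table
  (`inst/extdata/turner2004_lite.tsv`): full 6×6 stacking, hairpin /
  bulge / internal loop-length penalties to 30 with logarithmic
  extrapolation $\Delta G(n) = \Delta G(30) + 1.75\,RT \ln(n/30)$,
  affine multiloops $a + b(\text{branches}+1) + c\,u$ with
  $(a, b, c) = (9.30, -0.90, 0.00)$, and a 0.50 kcal/mol terminal-AU/GU
  penalty applied at every helix end context (hairpin closing, both sides
  of internal loops and long bulges, multiloop closing and branches,
  external branches — so a lone pair is penalized twice, once per end).
  A length-1 bulge keeps its stacking term and takes no AU penalty.

Deliberately **not** modeled: dangling ends, coaxial stacking, terminal
mismatches, 1×1/2×1/2×2 special internal loops, tetraloop bonuses, and
internal-loop asymmetry. This keeps the parameter surface bounded and the
scorer/DP pair exactly mirrorable, at the cost of absolute-energy parity
with full Turner implementations: designs and fronts are qualitatively
right, but published results computed under a full implementation (e.g.
distinct-CDS counts for specific benchmark proteins) should not be
expected to reproduce exactly under this reduced model.

## Codon usage and its defaults

The embedded human table is the classic Kazusa per-thousand snapshot; any
Kazusa-style block or two-column TSV can be substituted, and only
within-family ratios matter. Zero-frequency codons are floored at
`floor * max_freq` (default `1e-3`) rather than dropped, so the structure
search space never silently shrinks; the floor only matters for codons a
usage table reports as absent. Published usage snapshots differ between
database versions, and Pareto-front compositions can shift with the table.

## Pareto enumeration

`pareto_front()` uses the `derna` form internally. The extremes are solved
at $\lambda = \varepsilon$ and $1 - \varepsilon$ with
$\varepsilon = 10^{-6}$: pure 0/1 endpoints ignore one objective entirely
and can return dominated representatives, while the perturbation yields
lexicographic optima at a negligible objective distortion (energies are
$O(10)$, so $\varepsilon \cdot E \sim 10^{-5}$, far above the $10^{-9}$
tie tolerance). For adjacent points $a, b$ (with $M_a < M_b$,
$S_a < S_b$), the recursion solves at the tie point

$$\lambda^* = \frac{S_a - S_b}{(M_a - M_b) + (S_a - S_b)},$$

keeps the new point if it improves the $\lambda^*$-scalarization by more
than $10^{-9}$, and recurses on both sub-intervals (depth capped at 64,
beyond which the tolerance is declared pathological and the run aborts).
`N` counts every solver invocation; `n` counts distinct CDSs on the final
front after a dominance-and-duplicate filter (points with identical
(MFE, CAI) but different CDSs keep the lexicographically smallest so the
front stays strictly ordered — with continuous energies this is a corner
case). Weighted-sum scalarization finds exactly the *supported* (convex
hull) Pareto points; unsupported points are out of scope by construction.

## Validation strategy and problem sizes

The oracle chain is two-tiered so every link is independently checked:

1. `enumerate_structures()` + `score_structure()` exhaustively fold
   sequences up to 14 nt; `fold_fixed()` (the DP with a degenerate
   one-state lattice and $\kappa = 0$) must match it — checked on 100
   random sequences up to 12 nt under both models.
2. With the folder validated, `brute_force_design()` enumerates all CDSs
   of proteins up to 6 residues and folds each; exact-mode `design_cds()`
   must match its optimum — checked on 50 random proteins up to 5
   residues, both formulations, several $\lambda$, both models.
3. Pareto fronts on random proteins up to 10 residues (path count capped
   near $10^3$ for enumerability, nussinov model) are checked
   point-by-point for $\lambda$-optimality against full CDS enumeration,
   mutual non-domination, strict ordering, and bit-reproducibility.

These sizes keep the whole suite under a minute while exercising every
recursion case (hairpins, stacks, bulges, internal loops, multiloops,
external branches, codon-boundary transitions, beam pruning). What
desk-scale validation does *not* show: absolute-energy realism of the
reduced model on long natural mRNAs, and front compositions under full
Turner parity.

## Numerical choices

* Energies are doubles; equality and improvement tests use absolute
  tolerance $10^{-9}$.
* DP-vs-rescore consistency is enforced at $10^{-6}$ (scalarization by
  tiny $\mu$ shrinks energy differences).
* Degenerate inputs: a 1-residue protein folds to all-dots (no pair fits
  within 3 nt under the minimum hairpin loop); proteins whose residues
  have single-codon families yield single-path lattices and one-point
  fronts with percentages fixed at 100 by convention.
* There is no randomness anywhere in the package; reruns are identical.

## Limitations

* Only supported Pareto points are enumerated (weighted-sum property).
* The reduced nearest-neighbor parameterization is not ViennaRNA-parity;
  see the energy section.
* No forbidden-motif, restriction-site or codon-context constraints.
* The brute-force oracles are guards against misuse, not scalable tools.
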