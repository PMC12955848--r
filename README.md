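# codonfold

Design mRNA coding sequences (CDSs) that are simultaneously **stable**
(low secondary-structure minimum free energy, MFE) and **well adapted**
(high codon adaptation index, CAI).

A protein of *l* residues can be encoded by up to 6^*l* synonymous CDSs.
Stability and codon adaptation pull codon choice in opposite directions,
so `codonfold` treats CDS design as the joint minimization

```
  mu * MFE(structure)  +  kappa * sum over codons of (-ln w(codon))
```

over **all** (CDS, structure) pairs at once, where `w` is a codon's
relative adaptiveness (usage frequency over the family maximum). Because
CAI is a geometric mean, `l*log(CAI) = sum(ln w)`, and both published
scalarizations are instances of this additive form:

* `linear_design`: `MFE - lambda * l * log(CAI)`, `lambda >= 0`
* `derna`: `lambda * MFE - (1 - lambda) * l * log(CAI)`, `lambda` in [0, 1]

The search runs on a *codon lattice* — a layered graph whose states are
codon prefixes, so six-codon families (Leu, Arg, Ser) keep their
intra-codon dependencies — via a Zuker-style dynamic program over
(position, state) pairs: exact in O(L³) time / O(L²) memory for a CDS of
L nucleotides, or approximately with beam-search pruning. A recursive
weighted-sum scheme enumerates the supported Pareto front of (MFE, CAI)
trade-offs automatically, with n/N accounting (distinct CDSs / solver
outputs) and range-normalized MFE%/CAI% annotations.

Energy models: `nussinov` (−1 per pair; exactly verifiable by brute
force) and `nearest_neighbor`, a reduced Turner-2004 parameterization
(stacking, loop-length penalties, affine multiloops, terminal-AU; no
dangles/mismatches/special loops) shipped as an editable plain-text
table. The vignette (`vignettes/codonfold-methods.Rmd`) documents the
model, all tunables, and the validation strategy.

## Worked example

```r
library(codonfold)

w   <- relative_adaptiveness(human_codon_usage())
lat <- build_lattice("MSTNPKPQRKTK", w)
design_cds(lat, energy_model("nearest_neighbor"),
           design_objective("derna", 0.5))
#> designed CDS (derna, lambda = 0.5)
#>  AUGUCCACCAAUCCUAAGCCCCAGAGGAAGACAAAG
#>  .((((......((((.........)))).))))...
#>   MFE -4.5000  CAI 0.9530  S -0.5778  objective -1.961099
```

The designed 36-nt CDS back-translates to the input peptide; `MFE` is the
free energy (kcal/mol) of the reported structure, `CAI` its codon
adaptation (0.95: near-optimal codons), `S = sum(ln w)` the additive CAI
form, and `objective` the scalarized value the DP minimized.

```r
pareto_front("MSTNPKPQRKTK", model = energy_model("nearest_neighbor"))
#> Pareto front for MSTNPKPQRKTK (nearest_neighbor model): n/N = 4/7
#>     lambda  mfe    cai mfe_pct cai_pct
#> 1 0.999999 -5.3 0.8781  100.00    0.00
#> 2 0.227380 -4.5 0.9530   84.91   61.43
#> 3 0.113790 -2.9 0.9710   54.72   76.20
#> 4 0.000001  0.0 1.0000    0.00  100.00
```

Seven solver calls (N) found four distinct Pareto-optimal CDSs (n),
from the most stable (−5.3 kcal/mol, CAI 0.88) to the fully
codon-optimal (CAI 1.0, unstructured). `write_front_tsv()` serializes
the run; `plot_pareto_front()` draws CAI-vs-MFE with percentage axes.

Command line (same functionality):

```sh
Rscript inst/cli/codonfold --protein protein.fasta --mode pareto --out run1
Rscript inst/cli/codonfold --protein protein.fasta --mode single \
    --formulation derna --lambda 0.5 --beam 64 --dna --out run2
```

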