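---
title: "Profiling the chitinase insertion domain: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the chitinase insertion domain: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cidtools)
```

## What the package computes

The chitinase insertion domain (CID) is a small α+β module inserted
between the seventh β-strand and seventh α-helix of the (α/β)₈ TIM barrel
of subfamily A family 18 chitinases. Its conserved residues fall into two
functional groups: a few that contact the bound chitin oligosaccharide
(organised into the YxR and [E/D]xx[V/I] motifs) and a larger set that
packs the domain's hydrophobic core. `cidtools` implements the full
analysis chain that supports such conclusions — per-column conservation
and hydropathy profiling of a multiple alignment, consensus motif
scanning, geometric contact detection in holo structures, and
distance-based phylogeny — each stage validated against synthetic inputs
with known ground truth.

## Conservation model

For column $i$ with non-gap residue counts $n_j$ over $n_\mathrm{obs}$
observed residues, $P_j(i) = n_j / n_\mathrm{obs}$ and

$$S(i) = -\sum_j P_j(i)\,\ln P_j(i), \qquad C(i) = 1 - \frac{S(i)}{\ln m}.$$

Assumptions and choices:

* **Gaps are not a residue type.** $P_j$ uses the non-gap denominator;
  gapped columns are handled by a separate rule: any column with more
  than one gap is declared non-conserved ($C = 0$, bin `gap_zeroed`)
  *after* scoring. An all-gap column has no defined entropy and the code
  refuses to compute one.
* **$m = 20$ by default** (the full amino-acid alphabet), so a column
  uniform over all twenty types scores exactly 0. `entropy_m =
  "observed"` switches to the number of types seen in the column; both
  conventions are defensible and the choice is exposed rather than
  hidden.
* **Natural logarithms** throughout; $S$ is reported in nats.
* **Bin boundaries** are `high`: $C \ge 0.45$, `moderate`: $0.35 \le C <
  0.45$, `low`: below. The closed/half-open convention is used because it
  partitions $[0,1]$ with no gaps or overlaps; a prose reading
  ("greater than 0.45") would leave $C = 0.45$ unbinned.
* Ambiguity codes (B, Z, X, J, U, O) are rejected on input by default
  because the entropy model is defined over amino-acid types only;
  `map_ambiguous_to_gap = TRUE` converts them to gaps instead.

## Hydropathy and physicochemical classes

Column hydropathy is the literal sum $\sum_j n_j h_j$ on the
Nozaki–Tanford side-chain transfer free-energy scale (kcal/mol; AAindex
NOZY710101, residues without a measured transfer energy carry 0). The
mean $\sum_j n_j h_j / n_\mathrm{obs}$ is reported alongside and used for
classification so that the class does not depend on alignment depth.

Conserved columns (bins `high`/`moderate`) are classified in a fixed
order:

1. `neutral` if Gly+Ala+Pro make up at least `neutral_majority`
   (default 0.5) of observed residues — these residues are conserved for
   backbone geometry (turns, flexibility), not side-chain chemistry, so
   the identity test precedes any hydropathy test;
2. else `hydrophobic` if the mean hydropathy reaches `hydrophobic_cut`,
   `hydrophilic` if at or below `hydrophilic_cut`.

No published numeric cutoff exists for the hydrophobic/hydrophilic
boundary on this scale, so the default is a single threshold at the
midpoint of the scale's range, $(h_{\min}+h_{\max})/2 = 1.7$ kcal/mol —
chosen once as the scale's natural neutral point and deliberately not
tuned. Because a single threshold classifies borderline residues
(e.g. valine, 1.5) to the hydrophilic side, the synthetic validation
alignments use compositions that are unambiguous under any reasonable
cutoff: pure columns of Ile/Leu/Phe/Trp/Tyr (means ≥ 1.8) versus pure
columns of Asp/Lys/Asn/Arg/Glu (mean 0). Analyses of real alignments
where borderline residues matter should set the cutoffs explicitly; both
are plain configuration values.

## Motif scanning

A motif is an anchored set of column offsets, each with an allowed
residue set and a minimum occupancy. Matching is *column-level consensus*
rather than per-sequence exact match: the biological motif is a conserved
position pattern that tolerates substitutions in individual sequences
(the B. circulans chitinase A1 carries Ser where most sequences carry
Val/Ile in the [E/D]xx[V/I] motif, yet the position is part of the
motif). A hit therefore requires, at every slot column, (a) conservation
bin `high` or `moderate` and (b) at least `min_occupancy` (default 0.5)
of non-gap residues in the allowed set. Intervening "x" columns are
unconstrained. The 0.5 default is the weakest sensible consensus
(a plurality-to-majority rule); it is a package decision, exposed per
motif definition.

## Contact detection

All detectors are geometric, with every cutoff in a single
`contact_criteria()` object:

| interaction | criterion | default |
|---|---|---|
| hydrogen bond | protein N/O/S to ligand N/O distance | ≤ 3.5 Å |
| water-mediated | both legs via a water oxygen | ≤ 3.5 Å each |
| hydrophobic | protein C to ligand C | ≤ 2·1.7 + 0.5 Å |
| salt bridge | Asp/Glu side-chain O to Arg/Lys/His side-chain N | ≤ 4.0 Å |
| π–cation | aromatic ring centroid to guanidinium/ammonium centroid | ≤ 6.0 Å |

These are conventional structural-biology values; published contact
lists derived with other software may not be bit-reproducible under any
single cutoff, which is why `contact_diagnostics()` reports nearest-miss
distances per interaction kind for calibration, and why validation
against published tables should be read as set-inclusion at default
criteria rather than exact equality.

Donor/acceptor typing is element-based without hydrogen placement, since
crystal structures usually lack hydrogens; when explicit hydrogens *are*
present on a candidate partner, at least one X–H⋯Y angle must reach
`hbond_min_angle` (90°). Coordinates are used as deposited (first model,
altloc blank/'A', no symmetry expansion); subsite labels (−n…+n along
the binding cleft) are user input.

## Phylogeny

Distances are p-distances with pairwise gap deletion (only mutually
ungapped columns are compared), optionally corrected with
$d = -\ln(1 - p - p^2/5)$; the correction saturates near $p \approx
0.85$, and saturated pairs are capped at a finite distance (10
substitutions/site) with a warning rather than returned as infinities,
so downstream matrix operations stay defined.

The neighbour-joining implementation follows the classic Saitou–Nei
agglomeration with the $Q$-matrix criterion, implemented in-package
because its numerical details are part of the contract: ties in $Q$
break deterministically in favour of the smallest index pair, and
negative branch-length estimates (a known NJ artefact on non-additive
input) are clamped to zero with a warning and a flag on the returned
tree. On additive matrices the output path lengths reproduce the input
distances to ~1e-12 (floating-point accumulation only). Trees are ape
`phylo` objects, so Newick I/O, plotting and topology comparison use the
standard tooling.

## What the synthetic generators emulate — and what they do not

`gen_alignment()` realises per-column compositions *exactly*
(hypergeometric-style placement, not i.i.d. sampling), so the ground
truth bin and class computed from the specification are guaranteed to be
the measured ones; the seed only permutes which sequence carries which
residue. `synthetic_cid_alignment()` is the package's study twin: 27
sequences × 60 columns with 9/5/5/2/5/6
hydrophobic-high/hydrophobic-moderate/hydrophilic-high/
hydrophilic-moderate/neutral-high/neutral-moderate columns (32 conserved
positions), two gap-zeroed columns, low-conservation filler, and the two
motifs planted among the conserved columns. Moderate columns use
six-type 5,5,5,4,4,4 mixtures over 27 sequences, which give $C \approx
0.40$ under $m = 20$; filler columns spread 27 residues over all twenty
types ($C \approx 0.02$).

`gen_complex()` writes legal PDB files with simplified NAG rings (six
ring heavy atoms plus two hydroxyl oxygens) and protein residues placed
so each planted interaction is realised at its requested distance while
every unintended pair sits outside the cutoffs; decoys go on an 80 Å
shell. `evolve_on_tree()` uses a uniform-rate 20-state model
(substitution probability $(19/20)(1-e^{-20b/19})$ per branch of length
$b$).

None of this emulates real data's hard parts: alignments with
correlated columns, alignment error, or compositional bias; structures
with alternate conformations, missing side chains, or chemically
realistic sugar geometry; evolution with rate heterogeneity, realistic
substitution matrices (BLOSUM/WAG) or indels. Passing the synthetic
suite demonstrates that the *computations* are correct under their
definitions, not that the defaults are optimal for any particular real
dataset.

## Problem sizes and numerical conventions

The validation suite runs at desk scale, chosen to exercise each
property well inside interactive runtimes: 200 random 27-deep columns for
the entropy oracle (agreement to 1e-12), the 27×60 twin for
classification and motif recovery, complexes of ≤ ~100 atoms with up to
50 decoys for contact recovery, and 8-taxon trees with 2000-site
simulated sequences for topology recovery (Robinson–Foulds distance 0).
Report TSVs serialise floats at six significant digits for stable diffs;
the run manifest keeps full precision. Pipeline runs are fully
deterministic given identical inputs and configuration.

## Known limitations

* PDB format only (no mmCIF); first model only; no symmetry mates.
* Motifs are inputs — there is no de novo motif discovery.
* No bootstrap support on trees; branch support is out of scope.
* Domain boundaries within a larger alignment are user-supplied columns;
  the package does not infer them from structure.
* The hydrophobic/hydrophilic boundary on the Nozaki–Tanford scale is a
  configuration choice, not an empirical constant; conclusions sensitive
  to it should be checked across cutoffs.
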