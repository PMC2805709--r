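# cidtools

Conservation, motif, contact and phylogeny analysis for protein domains,
built around the chitinase insertion domain (CID) of subfamily A family 18
chitinases — the small α+β module inserted into the TIM-barrel catalytic
domain that deepens the substrate-binding cleft and helps these enzymes
bind long chitin chains.

The package is for sequence/structure bioinformaticians who have a
protein multiple alignment (and optionally holo crystal structures) and
want to answer, reproducibly: which alignment positions are conserved,
what is their physicochemical character, do known motifs sit on conserved
columns, which residues actually touch the bound oligosaccharide, and how
do the domain sequences cluster phylogenetically?

## The statistics at the core

**Conservation.** For alignment column *i* with amino-acid type fractions
*P<sub>j</sub>(i)* over the non-gap residues, the Shannon entropy is

    S(i) = − Σ_j P_j(i) · ln P_j(i)        (nats)

and the conservation score is

    C(i) = 1 − S(i) / ln(m)

with *m* the number of amino-acid types considered (20 by default).
Columns with C(i) ≥ 0.45 are *highly* conserved, 0.35 ≤ C(i) < 0.45
*moderately*, below 0.35 *less* conserved; columns with more than one gap
are forced to C(i) = 0.

**Hydropathy.** Column hydropathy is Σ<sub>j</sub> n<sub>j</sub>·h<sub>j</sub>
(count of each amino acid times its hydrophobicity) on the Nozaki–Tanford
side-chain transfer-free-energy scale (kcal/mol), reported both as the
literal sum and as a per-residue mean. Conserved columns are classed
neutral (mostly Gly/Ala/Pro), hydrophobic or hydrophilic.

**Motifs.** The YxR (Tyr/any/Arg) and [E/D]xx[V/I] motifs of the CID are
consensus column patterns: a hit requires every slot column to be
conserved and to reach a minimum occupancy (default 0.5) of the allowed
residue types. Hits map to reference-structure numbering (e.g. Y267/R269
in human chitotriosidase).

**Contacts.** Distance-criteria detectors for protein–sugar hydrogen
bonds (≤ 3.5 Å), water-mediated hydrogen bonds, C–C hydrophobic contacts
(vdW sum + 0.5 Å), salt bridges (≤ 4 Å) and aromatic–cation pairs
(centroids ≤ 6 Å), grouped per sugar-binding subsite (−n…+n).

**Phylogeny.** p-distances with pairwise gap deletion, an optional
Kimura-style correction d = −ln(1 − p − p²/5), and the Saitou–Nei
neighbour-joining algorithm (exact on additive matrices), emitting Newick.

A synthetic-data module generates alignments with planted column
compositions, protein–NAG complexes with planted contact geometry, and
sequences evolved on a known tree, so every stage is testable against
exact ground truth without downloads.

## Worked example

```r
library(cidtools)

twin <- synthetic_cid_alignment(seed = 1)   # 27 x 60 study-twin alignment
prof <- profile_alignment(twin$alignment)
glance(prof)
#> # A tibble: 1 × 8
#>   n_columns n_high n_moderate n_low n_gap_zeroed n_hydrophobic n_hydrophilic
#> 1        60     19         13    26            2            14             7

hits <- scan_motifs(twin$alignment, prof)
hits[, c("motif_id", "anchor_column")]
#>   motif_id     anchor_column
#> 1 YxR                     10
#> 2 [E/D]xx[V/I]            30

rmap <- build_residue_map(twin$alignment, twin$alignment$seq_id[1], 267)
hit_to_residues(hits, rmap)[, c("motif_id", "label")]
#>   motif_id     label
#> 1 YxR          Y276
#> 2 YxR          R278
#> 3 [E/D]xx[V/I] E296
#> 4 [E/D]xx[V/I] I299
```

The 32 conserved columns (19 high + 13 moderate) split into 14
hydrophobic, 7 hydrophilic and 11 neutral positions, and the two planted
motifs are recovered at their anchors and mapped to the first sequence's
residue numbering. Structures go through `parse_structure()`,
`select_ligand()` and `find_contacts()`; trees through `aln_nj_tree()`
and `write_newick()`; `run_pipeline()` drives everything end to end and
writes TSV/Newick outputs plus a JSON manifest.

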