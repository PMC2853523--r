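---
title: "Methods: a desk-scale metacaspase census pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale metacaspase census pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbmca)
```

## Scope

`cbmca` reimplements, at desk scale, the computational procedure of a
comparative survey of metacaspases (MCAs) across cyanobacterial genomes:
iterative sequence search seeded with proven family members, domain
annotation of every hit, inspection of the catalytic His/Cys dyad, family
and subfamily classification, a per-strain comparative census, and a
bootstrapped neighbor-joining phylogeny of the catalytic domain. The
published 58-gene census over 33 genomes ships as a plain-text fixture and
is reproduced exactly by `summarize_mca()`; every sequence-level stage is
exercised against synthetic proteomes with planted, fully known
metacaspases rather than real genome downloads.

## Homology search

`local_align()` computes exact Smith–Waterman/Gotoh local alignments
(via Biostrings' pairwise aligner) under `scoring_scheme()`: BLOSUM62 with
affine gap penalties, where a gap of length $L$ costs
$\mathrm{open} + L\cdot\mathrm{ext}$ (defaults 11 and 1). Significance uses
the Karlin–Altschul estimate
$E = K\,m\,n\,e^{-\lambda s}$ with the published gapped BLOSUM62/11/1
parameters $\lambda = 0.267$, $K = 0.041$; $m$ is the query length and $n$
the total residue count of the database actually searched. Because the
aligner is exact rather than heuristic, scores are reproducible and are
checked in the test suite against an independent brute-force recursion.

`iterative_search()` emulates the iterative BLASTp protocol: every protein
not yet accepted is scored against the current query set; proteins at or
below the round's E-value ceiling (1e-10 for rounds one and two, 2e-20
afterwards) are validated — a P20 hit plus an acceptable dyad — and
accepted hits join the query set for the next round. The search stops when
a round adds nothing ("no new proteins"), and the per-round log records
score, E-value and which query found each hit.

## Domain models

The package has no access to conserved-domain services, so each domain type
is represented by a small synthetic profile: a fixed consensus string
compiled to per-position log2-odds columns against background amino-acid
frequencies (`profile_from_consensus()`, consensus mass 0.6 per position).
The two P20 consensus strings (~25% divergent, one per family lineage) were
generated once under explicit constraints — exactly one His context
(`[YF]SGxG`, slot 64) and one Cys context (`QAx[RQ]G`, slot 203) under
*every* tolerated slot substitution, and no transmembrane-like hydropathy
window anywhere, including across tandem-repeat junctions. They are
stand-ins for the COG4249/KOG1546-type caspase models of a real survey, not
curated alignments; consequences: hit scores and thresholds are
package-defined (threshold 30% of the maximal window score for the long P20
model, 50% for the short accessory models), and only the *relative*
behavior (planted domains score far above random background; the test suite
verifies a zero false-positive rate on hundreds of background decoys)
mirrors the original tools.

WD40, Pentapeptide and EZ-HEAT are scanned as repeat units and collapsed
with a copy count (`detect_repeats()`, minimum 3 units); transmembrane
segments use the classic Kyte–Doolittle scan (`detect_tm()`, window 19,
cutoff 1.6) and do not count as accessory domains.

## Dyad and classification rules

`scan_dyad()` finds the first His context and then the first Cys context
downstream of it, confined to the P20 hit span when one is known. The
tolerated substitutions are His→Tyr and Cys→Ser/Asn/Gln/Gly; anything else
is `absent`. `render_sites()` emits the census notation (`""`, `"H-Y"`,
`"C-S"`, …, `"H-Y C-G"`).

`validate_metacaspase()` accepts a protein with a P20 hit and both dyad
sites present (intact or tolerated); strict mode additionally demands an
intact dyad. `assign_family()` assigns family β to any metacaspase with at
least one accessory domain; otherwise subfamily precedence is α-C (catalytic
domain in the C-terminal half), α-TM (transmembrane segment present),
α-other (unannotated C-terminal extension of ≥ 50 residues), α-I (catalytic
domain only). `summarize_mca()` rounds percentages half-up (two decimals per
strain, one decimal for the β share), matching how the published tables are
printed.

## Phylogeny

`progressive_align()` is a ClustalX-style progressive aligner: pairwise
global Gotoh alignments give p-distances, a UPGMA guide tree orders the
merges, and groups are merged by profile–profile global alignment (the DP
inner loop is C++ via Rcpp). The default scheme keeps the survey's gap
penalties (open 10, extend 0.2) but substitutes PAM250 for the Gonnet
series, which is not available in the installed matrix collections; this
affects guide-alignment quality only, not any census number.
`distances()` offers p-distance and its Poisson correction
$-\ln(1-p)$ with pairwise (default) or complete gap deletion.
`nj_tree()` wraps exact neighbor joining with negative branch-length
estimates clamped to zero (deficit moved to the sibling edge), and
`bootstrap_support()` resamples alignment columns, rebuilds the tree per
replicate and reports per-bipartition support percentages.

## Synthetic generator

`generate_proteome()` plants metacaspases into background-sampled decoy
proteomes. Defaults are anchored to the observed census once, up front:
subfamily mix ≈ the published proportions (α-I 2%, α-TM 9%, α-other 34%,
α-C 2%, β 53%), dyad substitution rate 0.3 (≈ 17/58), WD40 cassettes with
7–15 copies, decoy lengths 380–560 aa. Decoys are rejection-sampled so they
never contain a dyad-context pair within catalytic-domain distance, and
planted proteins are re-drawn if flank junctions create an unplanted
transmembrane window — so the ground truth is exact by construction. What
the generator does *not* emulate: real sequence divergence within a family
(plants use the pure lineage consensus, making them maximally detectable),
genome-scale database sizes, and paralog clustering within strains.

## Problem sizes and limitations

Sizes throughout (3 strains × 40 proteins by default, ≤ 12-leaf trees in
the property tests, 200 bootstrap replicates in the pipeline default) are
the package's own desk-scale choices: large enough to exercise every code
path deterministically in seconds, far below a real survey (33 genomes,
~100k proteins, 1000 replicates). The census fixture is authoritative for
the published numbers; the sequence-level stages are validated by
round-trip against planted truth and by independent oracles (brute-force
alignment scores, window-mean hydropathy, additive-matrix recovery), not by
re-deriving the published gene list from public databases.
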