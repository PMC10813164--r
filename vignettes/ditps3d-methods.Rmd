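---
title: "Methods: sequence, structure and product analysis of diterpene synthases"
author: "ditps3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence, structure and product analysis of diterpene synthases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

Plant diterpene synthases (diTPS) convert geranylgeranyl pyrophosphate
(GGPP) or its cyclized intermediates (e.g. copalyl diphosphate, CPP) into
C20 diterpene skeletons. Mechanistically they fall into class I
(ionization-initiated, DDXXD motif in the alpha domain), class II
(protonation-initiated, DXDD motif at the beta-gamma interface), and
bifunctional class I/II enzymes carrying both motifs. `ditps3d` provides a
joint analysis of such a cohort along four axes — sequence, global
structure, the local structure of residues around the bound substrate, and
product chemistry — together with a deterministic synthetic-cohort
generator that plants known signal for every axis, so the whole pipeline
can be exercised and scored end to end without any external data.

## Sequence analysis

Signature motifs are scanned as patterns over the 1-letter alphabet:
DDXXD (`DD..D`), DXDD (`D.DD`), the NSE/DTE triad
(`[ND]D..[ST].[ED]` — the motif is named in the literature without a fixed
per-position spelling, so a permissive triad pattern is used), the literal
trigrams LHS and PNV, PIX with its third position treated as a wildcard
(consistent with how X is used in FEHXW), FEHXW (`FEH.W`) and FERLW. Class
assignment follows the signature logic: DDXXD or NSE/DTE without DXDD is
class I; DXDD without DDXXD is class II; both DDXXD and DXDD is class
I/II.

Domain splitting prefers explicitly curated N/C ranges. Without ranges,
the N/C boundary is anchored on the signatures: the midpoint between the
first position *after* the last class II anchor (DXDD or LHS) and the
start of the first class I anchor (DDXXD or NSE/DTE). The paper trail for
terpene synthases gives no boundary convention between the beta and alpha
domains, so this midpoint rule is a package decision, frozen in the unit
tests.

Pairwise identity uses Needleman–Wunsch global alignment (BLOSUM62, affine
gaps: open 10, extend 0.5, via `Biostrings::pairwiseAlignment`). Identity
is 100 × identical columns / alignment length *including internal gaps but
excluding terminal gap columns*. The exclusion matters because N/C domain
slices differ in length by construction; counting terminal gaps would
deflate every cross-region comparison. The test suite pins this to an
exhaustive affine-gap oracle that enumerates all co-optimal alignments on
short pairs.

Sequence similarity networks threshold the identity matrix (edges keep
pairs at or above the cutoff; isolated nodes are retained). The original
analysis thresholded BLAST E-values; percent identity is the default here
because it needs no external search tool, and an optional Karlin–Altschul
E-value mode (`ka_evalue`, gapped BLOSUM62 constants lambda = 0.267,
K = 0.041) provides comparable semantics when a raw score table is
available.

## Structure analysis

The substrate shell is the "byres within r" selection: a residue belongs
to the shell at radius r iff any of its heavy atoms lies within r
(inclusive) of any ligand atom, and then the whole residue is kept.
Shells are nested by construction across the standard radii 4, 6, 8, 10 Å.

Structural similarity is a TM-score aligner: sequence-order-dependent
correspondences seeded by gapless threading of fragments (lengths 5, L/2,
L), refined by iterating (i) Kabsch superposition on pairs closer than d0,
(ii) semi-global dynamic programming over the TM kernel score matrix
1/(1 + (d_ij/d0)^2) with gap penalty −0.6 and free end gaps, until the
pair set repeats (at most 30 iterations), keeping the best of all seeds.
d0(L) = 1.24·(L−15)^(1/3) − 1.8, floored at 0.5 Å. Both normalizations
(by each structure's length) are reported; matrices use their mean, which
is made exactly symmetric by aligning each pair in a canonical argument
order. The aligner is pinned to an exhaustive monotone-correspondence
oracle on 8-residue toys. Note that TM-scores of 10-residue shells live on
a compressed scale (d0 is clamped at 0.5 Å), so shell-TM values are
useful *comparatively* (within vs between groups), not against the
conventional 0.5 fold-similarity threshold.

## Local 3D motifs

Order-independent site alignment matches shell residues without using
sequence order: each residue is described by its sorted vector of
intra-shell Cα distances; pair scores are the fraction of greedily
matched descriptor entries within 1.5 Å, plus 0.2 for identical residue
letters (the reported score is capped at 1; the assignment objective uses
the uncapped value because in dense shells the descriptor fraction
saturates and letters must still break ties). A maximum-weight bipartite
assignment (igraph, deterministic tie-breaking by lowest index pair) is
refined geometrically: Kabsch on current pairs, dropping pairs deviating
over 3 Å, re-assignment by spatial proximity, up to 10 rounds. The
refinement is multi-start — the full assignment plus rigid-consistent
subsets anchored on different high-weight pairs — and the converged
solution maximizing a distance-kernel-plus-letter objective wins; a
single start can lock into a wrong congruence when a motif contains
repeated letters (the two aspartates of DDXXD-like sites). A final
conservative pass keeps only pairs within 2 Å (between the descriptor
tolerance and the drop cutoff): wide enough for genuinely equivalent
residues under coordinate noise, narrow enough that unrelated pocket
residues rarely coincide.

Motif extraction gates each reference column by coverage c (fraction of
non-reference sites with a match; the reference defines the column and is
not counted) and geometric tightness g = 1 − mean deviation / 3 Å (floored
at 0), keeping columns with c > 0.6 and g > 0.4. These two
operationalized gates carry the published cutoff values for
representative-motif selection; the upstream tool's internal definitions
are not printed anywhere, so both gates are independently configurable.
The motif stores consensus letters, alternatives (letters in at least 20%
of sites), and the reference-site Cα distance template.

Motif search enumerates candidate residue tuples by identity (strict:
every position must carry the consensus or an alternative; relaxed: at
most one position may violate), prunes by pairwise Cα distance
compatibility with the template, and accepts tuples whose Kabsch
superposition onto the template has RMSD ≤ 2 Å. The distance-pruning
tolerance defaults to 2.5 Å rather than the descriptor tolerance: the
template is itself one noisy instance of the motif, so the pruning band
must cover placement noise on both the template and the query side — with
per-structure pairwise-distance deviations bounded by 4σ = 1.2 Å at the
default jitter, a 2.4 Å gap between template and query distances is
possible for a true match, and a tighter band provably prunes true
positives. Search results are exactly reproduced by a brute-force tuple
scan on small queries in the tests. A search may legitimately return
additional geometric matches elsewhere in a query; "finding a planted
site" in all scoring means a returned match maps exactly onto the planted
residues.

## Product chemistry

Products are compared by ECFP (Morgan) fingerprints, radius 2, folded to
2048 bits, with Dice similarity 2|A∩B|/(|A|+|B|). SMILES are parsed by
OpenBabel (through ChemmineR); the fingerprint itself is computed
in-package from the stated construction — initial atom invariant
(element, heavy degree, attached hydrogens, formal charge, ring
membership), then iterative neighborhood hashing over sorted
(bond order, neighbor id) lists — so it is deterministic and independent
of atom input order. Bit (not count) fingerprints at 2048 bits are the
de-facto pairing with Dice; both width and variant are arguments.
Enzyme-pair product similarity is the mean Dice over the full
cross-product of the two product sets. The similarity matrix computes its
diagonal the same way (an enzyme with dissimilar products has
self-similarity below 1); all correlations exclude the diagonal, so this
choice only affects what the matrix itself reports.

Carbon skeletons are computed by deleting heteroatoms and their bonds,
setting all bond orders to 1, dropping stereochemistry, keeping the
largest connected carbon component, and canonicalizing the resulting
graph (BLISS canonical labeling via igraph). Curated skeleton labels take
precedence; `skeletonize` is the fallback for unlabeled products. Note
that deleting a linking heteroatom (e.g. an ester oxygen) disconnects the
molecule, so only the largest fragment's skeleton survives — a direct
consequence of the stated rule.

## Statistics

Composition (AAC) and grouped composition (GAAC) use the five
physicochemical groups (aliphatic GAVLMI, aromatic FYW, positive KRH,
negative DE, uncharged STCPNQ); X residues are skipped and counted.
Residue preferential values are shell frequency / full-sequence
frequency, with letters absent from the full sequence flagged undefined
rather than divided.

Cross-factor correlations use unordered enzyme pairs (diagonal excluded)
with listwise deletion across factors, Pearson's r, and a two-sided p
from the t transform. No multiple-testing correction is applied by
default, mirroring how such factor-pair tables are usually reported; a
flag enables Benjamini–Hochberg. Same-versus-different group comparisons
(by shared substrate or any shared skeleton label — set intersection, so
a multi-skeleton enzyme can be "same" with several groups) use a
two-sided Mann–Whitney U test: exact p by full enumeration of group
assignments for combined n ≤ 20 (valid under ties), tie-corrected normal
approximation above that. The source analysis shows significance stars
without naming a test; Mann–Whitney matches the distribution-free,
box-plot-style presentation.

## The synthetic cohort generator

The generator is first-class, tested code. It plants, per enzyme:

* a Cα-trace backbone (3.8 Å self-avoiding steps with glycine-like atom
  stubs) drawn per family and jittered per enzyme, keeping 12 Å clear of
  the pocket — families therefore separate in global TM;
* a ligand (HETATM block) at the pocket centroid, and the motif residues
  at a fixed irregular template (radii 3.8–5.2 Å; every vertex pair has
  distance profiles separated by ≥ 3.1 Å, because a symmetric template
  would make order-independent site alignment ill-posed) plus N(0, σ²)
  per-axis jitter, resampled so pairwise template distances stay within
  4σ; family-specific pocket residues and per-enzyme decoy residues fill
  the rest of the pocket. Decoys keep 2 Å clearance inside a structure
  and, best-effort, 2.2 Å from other structures' decoys — without the
  cross-structure clearance, independently placed decoys pile into the
  few sterically free gaps and genuinely *are* conserved geometry,
  contradicting the planted truth;
* a sequence embedding the class signatures (DDXXD and/or DXDD at fixed
  windows), with accidental signature occurrences scrubbed, family
  divergence as 4–70 random substitutions from a family ancestor;
* products drawn from per-family scaffold sub-libraries of the same
  carbon skeleton, a shared bridge molecule on every second family
  member, and a 0.39 probability that the last product comes from another
  family's library (product promiscuity, as observed for real
  multi-skeleton diterpene synthases). These three knobs were calibrated
  once by brute force so that the full-sequence-identity versus
  product-Dice Pearson correlation is 0.5 at n = 50, and then frozen;
* one held-out enzyme per family carrying a single substitution at a
  fixed motif position — findable by relaxed motif search (one mismatch)
  and never by strict search.

What the generator does *not* emulate: real protein geometry (no
secondary structure, no side chains beyond stubs), realistic sequence
evolution (i.i.d. substitutions, no indels, no rate variation), docking
noise in ligand poses, or the published skeleton taxonomy. Tests passing
on this cohort therefore demonstrate that the algorithms recover the
specific signal classes they claim to recover at realistic noise levels —
not that the pipeline's scientific conclusions transfer to any particular
real cohort.

## Problem sizes and determinism

The test and acceptance workloads are sized for a desk machine: planted-
motif recovery uses 20 cohorts of 8 training sites plus one held-out
mutant (6-residue motif, σ = 0.3 Å, ~20% decoys); coupling recovery uses
one 50-enzyme, 5-family cohort (1225 pairs); pipeline integration uses an
8-enzyme cohort. All randomness flows from a single integer seed; a fixed
configuration and seed reproduce byte-identical cohorts and pipeline
outputs.

## Known limitations

* The TM aligner implements the standard heuristic, not the full feature
  set of the reference tools (no secondary-structure seeding, no circular
  permutation search); oracle tests cover small cases only.
* ECFP hashing is deterministic and collision-folded at 2048 bits but not
  bit-compatible with any other toolkit's fingerprints; only
  similarities computed within this package are comparable.
* The OpenBabel SMILES path kekulizes aromatic systems; equivalent
  aromatic inputs are handled consistently, but exotic tautomer spellings
  may fingerprint differently.
* Formal charges are read from old-style MOL charge codes when present;
  neutral molecules (the intended domain: terpene hydrocarbons and
  alcohols) are unaffected.
* Mann–Whitney enumeration is exact up to combined n = 20 and switches to
  the tie-corrected normal approximation beyond that.
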