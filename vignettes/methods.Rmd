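---
title: "Assay design and absolute quantification for homologous gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assay design and absolute quantification for homologous gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primequant)
```

## Scope and model

`primequant` builds SYBR Green qRT-PCR assays for multigene families
whose members are nearly identical — the barley hordein storage-protein
families (B, C, D, γ) are the template case, with pairwise identities of
roughly 80–99% and long tandem-repeat blocks inside the coding region.
The package covers the dry half of such a study: repeat trimming,
subfamily classification, hierarchical primer design with in-silico
specificity validation, and the arithmetic that turns threshold cycles
into attomoles, normalized ratios and percentage contributions. Wet-lab
concerns (RNA preparation, cycling conditions, melt curves) and live
database retrieval are out of scope; sequences enter as FASTA plus a
metadata table.

## Repeat detection and core trimming

Storage-protein repeats are short, codon-level motifs. The detector
scans motif lengths 2–12 (configurable down to 1) and reports maximal
runs of at least 3 exact consecutive copies. Shorter motifs take
precedence: a run already explained by a 2-nt motif is not re-reported
as a 4-nt or 6-nt repeat, and when a longer-motif run partially overlaps
an earlier interval it sheds whole copies from the overlapping end
rather than disappearing — junction artifacts between a flank and a
repeat block would otherwise mask the block itself. Imperfect
(degenerate) repeats are deliberately not modelled; at desk scale the
exact detector suffices, and the evolutionary analysis of repeat
expansion needs different tools entirely.

The *core* of a sequence is the longest contiguous window whose repeat
coverage is at most a threshold (default 0.1). Candidate window
boundaries are restricted to repeat-interval boundaries, so runs of
unannotated positions are never split. The 0.1 default, rather than 0,
tolerates the handful of short incidental repeats any real flank
contains while still forcing the main block out; if no window qualifies
the full sequence is returned with an explicit fallback flag. Whether
flanking partial repeat copies belong in the core is a judgment call the
original manual trimming never wrote down; the threshold policy is this
package's explicit, reproducible answer, and the flag keeps the
edge case visible.

## Classification

Pairwise identity is matches over aligned columns, with gap columns in
the denominator and `N` counted as a mismatch — a conservative measure
that cannot be inflated by trimming gaps. Global alignment uses
match +1, mismatch −1, gap opening 2, gap extension 1; multiple
alignments of three or more sequences run through MAFFT's deterministic
progressive mode, and every alignment is checked to degap back to its
exact inputs before use.

Trees are neighbor-joining on p-distance with midpoint rooting. This is
deliberately lighter than a likelihood pipeline: for families at this
identity level the subfamily arrangement is robust — full-length, core
and protein inputs give the same groupings — so the cheap method carries
no practical cost. Subfamily cutting is primarily by a user-supplied
group count per family (mirroring how such families are annotated in
practice: B1/B2/B3, C1/C2, …), implemented as the root-distance cut that
yields exactly k clades; a divergence-threshold mode exists for
automation. No numeric rule separates "major" from "minor" subfamilies;
group sizes are reported and no call is made.

## Primer design

Constraints default to 18–22 nt, 40–60% GC, 50–150 bp amplicons. A
tolerance flag (on by default) relaxes length by ±1 nt and GC by ±5
points, because validated assays for these families routinely include
primers marginally outside the nominal box; strict mode is available.
Candidate windows must be *identical* across all targets — degenerate
bases are never emitted.

Discrimination rests on the 3'-terminal mismatch principle: polymerases
with proofreading extend a primer only when its 3' end is perfectly
paired, so a single terminal mismatch against every non-target makes a
window allele-specific. Pairs are ranked by (a) how many of the two
primers have a 3'-terminal base mismatching every non-target (0–2 —
both-primer discrimination is the strongest design), then (b) total
non-target mismatches within a 3'-protect window (default 1 base), then
(c) amplicon-length centering; ties break deterministically by smallest
forward start, then shortest amplicon. A pair predicted to amplify any
non-target is rejected outright. How many mismatches beyond the terminus
the original manual designs demanded is not recorded anywhere; the
secondary score terms are this package's own choice.

The binding model used for rejection and validation is binary: a primer
binds where it aligns ungapped with at most 2 total mismatches and its
last 3 bases exact (both configurable). There is no melting-temperature
or duplex thermodynamics model — the assays this mirrors run at a
uniform annealing temperature and read presence/absence plus Ct, so the
added machinery would imply precision the method does not use. The
dimer screen is likewise a 3'-anchored complementarity run test
(fail at ≥ 4 bases), an in-silico surrogate for the no-template control.

`design_hierarchy()` attempts one set per node (family, each subfamily,
each member), searching the most discriminating forward and reverse
windows first (a bounded best-first pairing, up to 80 windows per
direction and 25 pairings each) and confirming the top candidates by
full in-silico PCR against every panel member before emitting them.
Nodes with no compliant specific set are reported as unresolved, not
failed: members that differ only inside the trimmed-away repeat block
are genuinely indistinguishable by this assay class, and the report
says so instead of inventing a primer.

## Quantification

The standard curve is ordinary least squares of mean Ct on log10
concentration; the x-axis convention is concentration in ng/µl.
Efficiency is `E = 10^(−1/slope) − 1` (slope −3.3219 ⇔ 100%). The
reliable Ct window defaults to cycles 5–28; readings outside it are
flagged but still converted, so excluded wells remain visible instead of
silently vanishing. Replicate outliers are dropped by a median-deviation
rule (default 0.5 cycles) — the original criterion is unstated, so the
rule here is explicit and conservative: the median-nearest replicates
are always retained, and a two-replicate tie retains both.

Mass converts to moles through the coding-region length with a per-base
molar mass of 660 g/mol/bp (double-stranded, the default) or 330
(single-stranded cDNA); which convention the original conversions used
is unknowable from the published text, so both are supported and the
model in use is part of the output. Normalization is a plain mole ratio
to a reference gene; reference stability is assessed by pairwise
replicate ratios (mean ± SD per sample), not by geNorm-style statistics.
Percentage contributions divide each family-common amount by the total
over families, so they are scale-free; subgroup shares and member
coverage are the corresponding part/whole percentages, with a flag (not
an error) when noise pushes a part above its whole.

The pooled-mixture simulator inverts this pipeline for validation: the
effective template of a primer set is the summed amount over the clones
it amplifies, Ct is simulated through the curve's forward map (optionally
with Gaussian Ct noise), and the amount is recovered through the
quantification path. Per set, the amol↔ng conversion uses the mean
coding length of its amplified clones, so the zero-noise round trip is
exact for any curve with nonzero slope, and subfamily amounts add
exactly to their family total when the subsets partition the family.

## The synthetic family generator

Tests and validation run on generated families with recorded ground
truth. The generator emulates the architecture that makes this problem
hard: a ~900 bp scaffold; a 12-nt proline/glutamine-codon-like motif
repeated 18–28 times (a 216–336 bp central block, placed at 45% of the
scaffold so repeat trimming reproducibly keeps the longer downstream
flank); 10% substitution divergence between subfamilies and 2% within,
which lands pairwise identities in the observed 84–99% band; one
conserved 150 bp segment per flank where divergence is suppressed,
mirroring the conserved terminal domains that make family-common primers
possible in real storage-protein genes; and two reserved member-unique
substitutions per member (one per flank), the discrimination sites that
member-level assays need. Copy numbers vary per member, so members
differ in length the way real repeat-bearing alleles do.

What the generator does *not* emulate: insertions/deletions outside the
repeat block, imperfect repeat copies, pseudogenes, and cultivar-specific
allele absence. Passing tests on synthetic panels therefore demonstrate
the correctness of the algorithms under the stated model of divergence,
not performance on any particular genome; the bundled published tables
are the bridge to real data for the quantification arithmetic.

## Numerical and design notes

- Coordinates are 0-based half-open internally; file outputs carry
  1-based-friendly columns where conventional.
- Design output is deterministic for a fixed panel and constraints;
  every pipeline output file records the package version, a
  configuration hash and the seed.
- The subfamily-recovery and specificity-closure checks in the test
  suite use panels of 2–3 subfamilies × 2–3 members with 500–900 bp
  scaffolds, and the acceptance script uses 10 recovery replicates —
  sizes chosen so the full validation remains a desk-scale computation
  while still exercising every code path.
- The bundled proportion table contains one internal inconsistency
  inherited from its source (the 10-DAP C-member coverage implies 68.06%,
  not the stated 62.06%); the package reports computed values and does
  not special-case it.
- Reciprocal reference-gene ratio products computed from the bundled
  two-decimal stability table deviate from 1 by up to ~0.2 at one
  timepoint. That is an artifact of printing small ratios to two
  decimals (plus the Jensen bias of averaging ratios), and the
  stability functions here compute both orientations from raw
  replicates precisely so that rounding never enters.

## Limitations

No thermodynamic duplex model, no probe (TaqMan/LNA) design, no
melt-curve simulation, no ΔΔCt relative quantification, no multi-plate
batch-effect modelling beyond requiring the standard on each plate.
Approximate repeats are not detected; phylogenies are distance-based
without bootstrap support. These are scope decisions, not accidents: the
assay class this package serves reads binary amplification plus Ct, and
everything the package computes is auditable back to those two signals.
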