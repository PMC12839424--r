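---
title: "Quantifying mutation-induced conformational perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mutation-induced conformational perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varstruct)
```

## The problem

Resequencing a phenotypic variant often ends with a short list of
nonsynonymous changes in a candidate gene — in the motivating use case,
SNPs and a small in-frame insertion in anthocyanin-activating R2R3-MYB
transcription factors. Deciding whether those changes plausibly disturb the
protein requires comparing a wild-type and a mutant structural model
residue by residue. `varstruct` implements that comparison for single-chain
Cα traces. Structure prediction itself is out of scope: predicted or
experimental models are inputs.

The pipeline is: classify CDS variants into protein effects; build the
WT↔mutant residue correspondence; superpose the paired Cα atoms; then
score perturbation globally (RMSD), locally (window RMSD) and per neighbor
(ΔD).

## The statistics and their assumptions

**Global RMSD.** The Kabsch closed form gives the proper rotation and
translation minimizing the sum of squared distances over paired Cα atoms;
RMSD is the root mean square residual. Reflections are excluded by
sign-correcting the smallest singular vector. The fit assumes at least
three non-collinear pairs; collinear input degrades the rotation and is
warned about.

**Outlier rejection.** Interactive aligners refine the fit by cycles that
drop badly fitting pairs and refit. `superpose()` reproduces this:
`cycles = 0` (the default) is the transparent all-pair fit; a preset of
5 cycles with a 2 Å cutoff emulates the documented defaults of the aligner
commonly used for such comparisons, whose reported RMSD is over retained
atoms. Because both conventions are defensible, both `rmsd_all` and
`rmsd_retained` are always reported. One numerical choice matters: a pair
is dropped when its deviation exceeds `max(cutoff, 2 * median deviation)`
rather than the bare cutoff. When a large segment is displaced far (tens of
Å), the initial least-squares fit is dragged off the coherent majority and
*every* pair can exceed a fixed cutoff; the median guard sheds the worst
outliers first and lets later cycles converge onto the coherent core
instead of rejecting everything. Once converged, the rule coincides with
the plain cutoff rule. Dropped pairs are never re-admitted.

**Local RMSD.** For each mutation site, the window spans `flank` residues
on each side (default 5, clipped at the termini) and the RMSD is taken over
the window's *paired* Cα atoms **under the global transform** — there is no
local re-fit. This is deliberate: a locally re-fitted window would show
near-zero RMSD for any rigidly displaced segment, hiding exactly the signal
the statistic is meant to expose. Under the global frame a segment
displaced by δ registers a local RMSD of δ, which is what the
parameter-recovery tests assert, and which is the only reading under which
local RMSD can legitimately exceed the global value by large factors.

**ΔD.** For a site *s* and each neighbor *j* whose Cα lies within
`neighbor_cutoff` (default 8 Å) of the site Cα:

ΔD(s, j) = D_MUT(s′, j′) − D_WT(s, j)

with primes denoting the mutant counterparts through the correspondence
map. ΔD compares internal distances, so it is exactly invariant under any
rigid motion of either model and needs no superposition; it is also
antisymmetric under swapping the two models. Records with
|ΔD| ≥ `flag_threshold` (default 3 Å) are flagged. ΔD is reported signed;
flagging uses the magnitude. Sequence-adjacent neighbors (i±1, i±2) are
*not* excluded: backbone rigidity keeps their ΔD near zero, which acts as a
built-in sanity check.

**Conventions the data left open.** Three points are under-determined by
the source material and fixed here as explicit package conventions:

- *Neighborhood reference.* Neighbors are found in the wild-type structure
  (the pre-mutation reference) for substitution sites. The ΔD records
  themselves are symmetric, so the choice only affects which pairs are
  reported, not their values.
- *Insertion sites.* An inserted residue exists only in the mutant. Its
  site Cα is the inserted mutant residue (neighbors are probed there and
  mapped back to WT indices); the WT-side distance D_WT is measured from
  the residue immediately preceding the insertion point. The convention is
  echoed into `summary.json`.
- *Direction of the position-12 call.* For the MYB fixture, codon
  arithmetic forces GCx (Ala) → TCx (Ser) at codon 12, i.e. wild-type Ala,
  mutant Ser, notation `A12S`; prose accounts of the same variant disagree
  among themselves about the direction. The package reports both residues
  explicitly (`wt_aa`, `mut_aa`) so either reading is recoverable.

## Variant effects

Positions are 1-based CDS coordinates on the coding strand; codon *c*
spans nucleotides 3c−2 … 3c, so the residue index of a position is
⌈pos/3⌉ — which reproduces every printed position pair of the motivating
data (34→12, 340→114, 764→255, 560→187, 667→223). Translation uses the
standard genetic code (table 1), stops at the first stop codon, and each
variant is classified independently against the wild-type frame — matching
how per-variant calls are reported; `translate_haplotype()` gives the joint
mutant protein when the cumulative reading is wanted. In-frame indels are
resolved by re-translating the mutant and taking the longest common
prefix/suffix decomposition against the wild-type protein (equivalent to
re-translating the affected region, and identical to the brute-force
oracle construction); indels with net length not divisible by 3 are
frameshifts and are rejected by the correspondence builder, since a
frameshifted protein is not residue-wise comparable.

One fixture reproduces a genuine inconsistency in its source: an ATG
inserted at the codon-193/194 boundary encodes Met, not the Tyr the prose
reports between residues 194/195. The fixture encodes the printed
nucleotides, and its expected call is asserted only as "in-frame insertion
of one residue after codon 193".

## Correspondence

The default route derives the map exactly from the classified effects:
substitutions pair i↔i, an insertion of k residues after WT residue r puts
mutant r+1…r+k into the inserted set and shifts downstream pairs by +k,
deletions symmetrically. The alignment fallback (`map_by_alignment()`) runs
Needleman–Wunsch with BLOSUM62, gap open 10, gap extension 1 — standard
protein-alignment defaults; any fixed choice suffices because the two
routes are cross-checked against each other on generated cases where the
indel context makes the alignment unambiguous (indel residues chosen to
differ from their flanking residues). Alignment-derived and effect-derived
maps can legitimately differ when an indel sits in a repeat, which is why
the exact route is the default whenever the variants are known.

## The synthetic generator and what passing tests show

`make_helix()` builds an ideal α-helix Cα trace (radius 2.3 Å, rise
1.5 Å/residue, twist 100°/residue), giving the realistic ~3.83 Å
consecutive Cα spacing and non-trivial 8 Å neighborhoods.
`apply_perturbation()` translates a chosen segment by a chosen vector and
optionally adds seeded Gaussian jitter to *all* residues (modeling uniform
model noise; the spec of the plan leaves the jitter target open and this is
the package's choice). Its `expected` oracle is computed by direct
coordinate measurement (base-R `dist` on the pre/post coordinates), sharing
no code with the metric implementations — so oracle-equivalence tests are a
genuine dual route.

What these fixtures emulate is a *rigid, local, known* conformational
change with an analytic answer. What they do not emulate: correlated
backbone deformation, compensating motions, side-chain effects, or the
model uncertainty of predicted structures. Passing the oracle suite
demonstrates that the arithmetic of the pipeline is exact; it does not
certify that any particular predicted-model comparison is biologically
meaningful. For the same reason the structure-specific magnitudes reported
for the motivating proteins (global RMSDs of ~13.7/6.6 Å and the published
per-site values) are *not* reproduction targets here — they depend on
predicted models of unpublished full-length sequences — and are replaced by
the parameter-recovery and oracle-equivalence suites.

Problem sizes used by the test and acceptance suites — helices of 40–80
residues, 100 random 8-point Kabsch instances against a multi-start BFGS
rotation search, a 2 Mb single-chromosome synthetic genome with 2000 SNPs
and 600 InDels in 50 kb windows — were chosen as the smallest sizes at
which every code path (rejection, clipping, cross-boundary neighbors,
correlated tracks) is exercised.

## Variant landscape

SNPs collapse onto the six pyrimidine-context substitution classes
(`C:G>T:A`, `T:A>C:G`, `C:G>A:T`, `C:G>G:C`, `T:A>A:T`, `T:A>G:C`) by
complementing purine-reference records; totals are conserved by
construction and asserted. InDel lengths are signed (`|alt| − |ref|`).
Density tracks count features per non-overlapping tiling window — window
size is a parameter (default 1 Mb, a common choice for chromosome-scale
display; the motivating figures do not state theirs) — and association is
summarized by Spearman's ρ (Pearson on mid-ranks), Pearson's r, and the
least-squares slope/intercept with R² equal to the squared Pearson
correlation of the simple fit. Gene density anchors each gene interval at
its midpoint. The VCF reader is deliberately minimal (CHROM/POS/ID/REF/ALT,
multi-ALT expanded, non-ACGT records skipped with a count): calling and
genotype semantics are upstream concerns.

## Degenerate inputs and numerical notes

- Fewer than 3 pairs, or all pairs rejected: classed errors, never NaN.
- Collinear point sets: conditioning warning from the Kabsch fit.
- Residues without a Cα are skipped on read (warned); altlocs resolve by
  highest occupancy, then first seen. Multi-chain files require an explicit
  chain — there is no silent first-chain default.
- Window/neighbor sets use closed inequalities (`<= cutoff`); windows clip
  at the termini.
- All Å values in TSV outputs print at 3 decimals; JSON outputs embed the
  tool version and a full config echo, making reruns byte-identical.
- Oracle-equivalence tolerances are 1e−6 Å against analytic expectations
  and 1e−9 Å for direct distance recomputation; identity cases are asserted
  to 1e−9 or exactly where floating-point arithmetic is itself identical.

## Known limitations

- Cα-only: side-chain perturbation and all-atom neighbor distances are out
  of scope by design.
- Frameshifted or stop-altered proteins have no residue-wise
  correspondence; such comparisons are refused rather than approximated.
- The alignment fallback inherits the usual ambiguity of gap placement in
  repeats.
- ΔD and local RMSD quantify geometry only; they say nothing about
  stability (ΔΔG) or function.
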