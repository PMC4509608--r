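---
title: "Methods: taxonomy and trait mining for plant-beneficial Pseudomonas genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taxonomy and trait mining for plant-beneficial Pseudomonas genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`pseudomine` re-implements, as a tested pipeline, the comparative-genomics
procedures used to place plant-growth-promoting *Pseudomonas* strains
taxonomically and to mine their genomes for rhizosphere-competence traits:

1. **MLSA taxonomy** — concatenated nucleotide identity (NI) of four
   housekeeping loci (16S rRNA, *gyrB*, *rpoB*, *rpoD*), neighbor-joining
   trees with bootstrap support, and the 97 % species boundary.
2. **ANIb** — average nucleotide identity by fragment-based local
   alignment, with verdicts at the proposed 94 % and 95 % boundaries.
3. **Trait mining** — reciprocal best-hit orthology (E < 10⁻⁵), bait-based
   gene-cluster calling for secretion systems (T1/T2/T3/T5/T6) and
   O-antigen biosynthetic loci, domain-tagged T5SS subfamilies and
   TpsA/TpsB pairing.
4. **Effector screening** — Hrp/Rsp promoter-box scanning combined with
   N-terminal composition rules for type III effector candidates.
5. **TBDP/FPV classification** — TonB-dependent receptor identification,
   N-terminal signaling-extension flagging, and ferric-pyoverdine receptor
   clade assignment by tree placement against six reference receptors.
6. **NRPS architecture** — module parsing (C-A-T-E/TE), substrate
   prediction from ten-residue adenylation-domain signature codes, and
   L/D stereochemistry from epimerization domains.

A synthetic-genome generator with a truth ledger makes every stage testable
end-to-end without downloading any external data.

# Models and procedures

## Alignment statistics

All similarity searches rest on optimal pairwise alignment with affine gap
penalties (a gap of length $L$ costs $g_o + L\,g_e$). Defaults follow
standard search practice — BLOSUM62 with $g_o=-11,\ g_e=-1$ for proteins;
match $+2$, mismatch $-3$, $g_o=-5,\ g_e=-2$ for nucleotides — so that the
E-value thresholds used throughout (orthology at $E<10^{-5}$) behave
familiarly. Raw local scores $S$ are converted to E-values with the
Karlin–Altschul statistic

$$E = K\,m\,n\,e^{-\lambda S},$$

with $(K, \lambda)$ taken from a small shipped constants table per scoring
scheme. These E-values are approximations (the exact constants depend on
the unpublished parameters of the original searches); what the pipeline
relies on is their exact monotonicity in $S$ and linearity in $m$ and $n$,
which hold by construction. The dynamic-programming engine is the one in
Biostrings; its optimality is verified in the test suite against an
independently written plain-R Gotoh oracle on exhaustive small cases.

For genome-scale inputs (ANIb fragments, locus extraction) full DP is
replaced by a seed-and-vote mode: k-mers of the query (k = 13) are looked
up in a hash of the reference on both strands, each hit votes for a
diagonal, and the winning diagonal is scored ungapped (with a banded DP
fallback when the ungapped identity is depressed, which signals indels).
Two safeguards keep chance matches out: a diagonal needs at least two
concordant strided seeds, or at least three *non-overlapping* dense seeds
(overlapping seeds from a single shared word are not independent evidence
— a lone chance 17-mer would otherwise cast five 13-mer votes). On
substitution-only synthetic data the seeded mode reproduces exact-DP
identities within ±0.1 %, which is asserted in the tests.

## MLSA

Each locus is located by bait alignment, extracted in bait orientation,
and profiles are compared locus-by-locus: the four per-locus global
alignments are pooled as $\mathrm{NI} = 100 \times \sum \text{identical
columns} / \sum \text{aligned columns}$. Aligning per locus (rather than
aligning one concatenation) prevents length differences in one locus from
shifting columns in the next. Profiles are ordered canonically before
alignment, making NI exactly symmetric.

**Boundary rule.** The MLSA species boundary is 97 %. This package calls
two strains the same species only when NI *strictly exceeds* 97; an NI at
the boundary is a distinct-species call. The published anchor points sit
well away from the boundary (96 % → distinct; 99–100 % → same), so the
rule only matters exactly at 97.0 — where we take the conservative
position that a claim of conspecificity must exceed the boundary. This
convention also makes the boundary behave deterministically for strain
pairs constructed at a controlled 3 % divergence, whose NI is exactly
97.000 by design.

Neighbor joining is implemented from the $Q$-criterion
$Q(i,j) = (r-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$ with negative
branch lengths clamped to zero and deterministic tie-breaking (earliest
pair in current row order). The implementation is cross-checked against
`ape::nj` and recovers additive matrices exactly (a consistency property
of NJ). Bootstrap supports resample alignment columns with replacement;
support for an internal bipartition is the percentage of replicate trees
containing it. Distances are plain p-distances, matching the
identity-percent framing of MLSA; no model correction is applied.

## ANIb

The query genome is cut into consecutive 1020-bp windows (the established
ANIb fragment length; terminal remainders ≥ 100 bp are kept). Each
fragment's best hit against the reference contributes its percent identity
iff it reaches ≥ 30 % identity over ≥ 70 % of the fragment. The two
directions are averaged into `ani_mean`, the value compared against the
94 % and 95 % species boundaries (both reported, inclusively, so
borderline pairs in the 94–95 band are visible as such). Under the
generator's substitution-only divergence model the expected ANI is exactly
$100(1-d)$, giving closed-form parameter-recovery targets; the acceptance
analysis recovers $d$ within 0.15 percentage points (tolerance 0.5) across
$d \in \{0.01,\dots,0.08\}$ on 200-kb pairs.

## Trait mining

Orthology is the classic reciprocal-best-hit criterion with both
directions at $E \le 10^{-5}$. Cluster calling groups bait-hit genes on
one contig separated by at most five non-hit genes (a configurable
contiguity default chosen to tolerate small insertions while keeping loci
local); a group is a called locus when it meets the system's minimum —
four or more bait-hit genes for T2SS, five or more for T6SS, strictly more
than four *distinct* bait orthologs for an O-antigen locus. Minima for
T1SS/T3SS/T5SS locus calls are not fixed in the field's definitions; the
shipped default of three is deliberately conservative and flagged as an
assumption. Domain tagging (T5a translocator, POTRA, the TpsA
haemagglutinin-activity domain) is alignment-to-exemplar (≥ 25 % identity
over ≥ 60 % of the exemplar) with positional enforcement — e.g. the T5a
translocator domain must sit at the C-terminus; profile HMMs are out of
scope, and the thresholds are validated on synthetic plants.

## Effector screening

A candidate must carry a Hrp/Rsp promoter box *and* pass every N-terminal
composition rule. The box model is block1 `GGAACC`, a 15–17-nt spacer, and
block2 `CCACNNA`, scanned over the 500 bp upstream of the start codon on
the coding strand. The N-terminal rules, computed on the first 50
residues: Ser fraction ≥ 0.10; polar fraction (S,T,N,Q,G,P,C,Y) ≥ 0.40; at
most one acidic residue (D/E) among the first 12 positions (the standard
exclusion reading — secreted effectors avoid early acidic residues; an
override inverts the rule for users who read the criterion oppositely);
and an aliphatic residue (I,L,V,A,P) at position 3 or 4, 1-based with the
initiator Met as position 1.

**Mismatch budget.** The default is an exact consensus match per block.
The choice follows from a chance-hit calculus: with one mismatch allowed
per block, the per-position probability of a block1 · spacer · block2
arrangement is about $2\times10^{-4}$, i.e. an expected ~0.1 chance boxes
per 500-bp promoter, and (after the composition filters, which pass ~20 %
of codon-uniform background proteins) roughly one false candidate per 50
genes — hundreds per genome, incompatible with genome-wide effector counts
in the low tens. At zero mismatches the same calculus gives ~3×10⁻⁴ false
candidates per gene, matching the observed false-discovery rate (< 0.01)
on synthetic genomes. The budget remains fully configurable for users with
a well-calibrated consensus.

## TBDP / FPV classification

TBDPs are proteins whose best bait hit passes $E \le 10^{-5}$ over ≥ 50 %
of the bait. The signaling-extension flag requires ≥ 50 unaligned residues
N-terminal of the receptor-body hit that themselves align to the long-form
exemplar's extension. For FPV assignment, all TBDPs plus the six reference
receptors are placed on an NJ tree built from global-alignment p-distances
(global, not local, so that full-length domain architecture — including
extensions — influences placement); after midpoint rooting, the FPV clade
is the *smallest clade containing all six references*, an operational
rendering of the visual clade call used with reference receptor sets. The
shipped synthetic reference family has ~55–60 % pairwise divergence,
mirroring the looseness of real pyoverdine-receptor families, so that a
receptor at ~55 % identity to one reference falls inside the clade while
unrelated outer-membrane decoys never do.

## NRPS architecture

Domain annotations (C, A, T, E, TE with residue spans) are the primary
input; a motif fallback locates A domains by repeated exemplar alignment.
Modules are cut at each C domain; a leading A-bearing segment is the
initiation module; a trailing TE-only segment is release machinery, not a
module. Modules with zero or multiple A domains raise a structural warning
and are excluded from the peptide. Substrate prediction extracts the ten
pocket-lining signature positions (fixed relative to the reference
A-domain) through a global alignment and looks the code up exactly, else
by nearest Hamming distance with the distance reported. A module's residue
takes the D configuration iff the module carries an E domain; a
configuration flag extends the attribution to dual C/E domains in the
following module, since both conventions appear in the literature. The
chromophore-synthesis NRPS is treated as a separate cluster and excluded
from the peptide. The shipped signature table and domain exemplars are
synthetic, deterministic stand-ins (their codes are internally consistent
but not curated biochemistry); real annotations should bring a curated
table.

# The synthetic-genome generator

The generator is the package's study-condition model, not a realistic
evolutionary simulator. It emulates: multi-contig genomes with
i.i.d. background at a requested GC content; codon-uniform background
genes (ATG + uniform sense codons + stop) on a jittered grid, never
overlapping; planted housekeeping loci at controlled divergence; clustered
bait-homologous genes; effector plants carrying both an exact promoter box
and a compliant N-terminus; TBDP-like proteins with or without the
N-terminal extension; and multi-module NRPS proteins with known domain
strings. A truth ledger records every plant.

Divergence follows "substitute to one of the other three bases with
probability d, each site at most once", so expected identity is exactly
$1-d$ with no back-substitution correction — closed-form targets for
ANIb/MLSA recovery. An exact-count mode (`diverge(..., exact = TRUE)` and
the per-locus controlled mutation used by the taxonomy preset) fixes the
realized substitution count at `round(d·L)`, pinning NI at the boundary
scenarios deterministically. Indels are not simulated (the `indel_rate`
parameter is validated but must be 0): allowing them would break the
closed-form identity expectations that the recovery analyses rest on.

What passing tests on this generator do **not** show: robustness to
rearrangement, horizontal transfer, repeat families, skewed codon usage,
assembly artifacts, or annotation error in real genomes. The detectors'
thresholds transfer to real data only to the extent that real signal
exceeds these synthetic contrasts.

# Numerical choices and degenerate inputs

* Alignment tie-breaks follow the DP engine's deterministic traceback;
  best-hit ties prefer the earlier target in input order, then
  lexicographic id.
* NJ clamps negative branch lengths to zero; ties in $Q$ resolve to the
  earliest pair, making topologies reproducible on degenerate (all-equal)
  matrices.
* An ANIb run in which no fragment passes retention in either direction is
  flagged undefined and carries no verdicts (unrelated genomes, empty
  input).
* Genes whose translation is shorter than 12 residues or contains internal
  stops are reported by the effector screen with NA features and are never
  called.
* All randomness flows from explicit integer seeds; library code saves and
  restores the caller's RNG state. Identical seeds give byte-identical
  genomes, ledgers and reports.

# Problem sizes used in the validation analyses

The shipped analyses run at desk scale, chosen to give tight statistical
bands while staying quick: 1000 random pairs (length ≤ 8) for DP
optimality; 100 random additive 4/5-taxon matrices for NJ recovery; 200-kb
genome pairs, 10 seeds per divergence step, for ANIb recovery (binomial
sd ≈ 0.06 pp per run, so the 0.5-pp tolerance is ~8 sd); 520 background
genes with 20 planted effectors over 20 seeds (400 positive instances) for
the screen's operating characteristics; and the seven-module pyoverdine
layout for NRPS prediction.

# Known limitations

* E-value calibration is approximate by design; thresholds are meaningful
  relatively, and the absolute $10^{-5}$ cut was validated on synthetic
  contrasts only.
* Domain detection is exemplar-alignment, not profile-HMM; remote homologs
  that an HMM would catch can be missed.
* The effector consensus box and composition cut-offs are documented
  assumptions (the source criteria are qualitative); reproducing any
  particular genome's candidate count is a calibration exercise.
* TBDP counts on real proteomes depend on the bait list; the shipped baits
  are synthetic stand-ins and real analyses should substitute curated
  receptor sets.
* The NJ implementation is quadratic per join (cubic overall) — ample for
  MLSA-scale taxa counts, not for thousands of leaves.
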