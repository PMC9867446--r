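---
title: "Sequence-based annotation of CLC anion channel family proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based annotation of CLC anion channel family proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

CLC-family proteins are integral membrane proteins that function either as
anion channels or as electrogenic anion/H+ antiporters (2 anions : 1 H+).
In plants they sit largely on intracellular membranes and move chloride
and nitrate. Remarkably much of their functional identity is legible from
sequence alone:

* Three conserved motifs — **GxGxPE**, **GKxGPxxH**, **PxxGxLF** — line
  the anion pathway. The second residue of GxGxPE is the selectivity
  filter's discriminating position: **proline** marks nitrate preference,
  **serine** chloride preference. Some family members carry a degenerate
  filter region that no longer matches the motif at all.
* Two glutamates decide the transport mechanism. The **gating glutamate**
  (homologous to E148 of the *E. coli* CLC) gates the anion pathway; the
  **proton glutamate** (homologous to E203) is required for H+ transport
  and occurs only in antiporters. Both present: anion/H+ antiporter.
  Exactly one: channel. The package reports the letters found at the two
  anchor-mapped columns, so a lost glutamate shows up as, say, `A` or `T`.
* Cytosolic N- and C-terminal domains carry **YXXΦ** tyrosine and
  **DXXLL** / **[DE]XXXL[LI]** dileucine sorting signals, and the
  C-terminal hydrophilic region carries two regulatory **CBS** domains.

`clcscan` turns those observations into a reproducible pipeline: motif
scanning, anchor mapping by global alignment, a total decision table for
the mechanism call, physicochemical summaries, a hydropathy-based
transmembrane sketch, JTT maximum-likelihood phylogenetics with bootstrap
support and eukaryotic/prokaryotic subgroup assignment, and in-silico
point mutagenesis of coding sequences (the classic experiment being a
single C→T at the first base of the filter's second codon, converting
P→S and thereby a nitrate call into a chloride call).

## Classification model

`annotate_protein()` composes independent sub-calls; every one either
returns a value or an explicit "not determined" with a reason.

**Selectivity.** The first GxGxPE match wins; overlapping matches are all
reported by the scanner, and deduplication is a reporting concern. When no
match exists the filter region is recovered by mapping the reference
filter columns through a global alignment and labelled *degenerate*.
Reports print the field-conventional 5-character filter string for motif
hits (e.g. `GPGIP`) and the full mapped window for degenerate filters
(e.g. `SSKSSQ`) — the two displays intentionally differ in length, as
they do in the literature.

**Glutamates.** Anchor positions live on a reference sequence; a query
position is obtained per anchor via `global_align()` (BLOSUM62, gap open
10, extend 0.5, EMBOSS-style; terminal gaps penalized). "Present" demands
exactly `E` at the mapped column — aspartate is chemically similar but
functionally not equivalent here, so it is reported as absent with the
residue letter retained. Positions are reported in query numbering.

**Mechanism.** The two-glutamate table is total: (E,E) → antiporter,
one E → channel, none → unknown. Channel calls and any call built on a
degenerate/unknown filter carry a low-confidence flag, rendered as a
trailing `?` in the TSV.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| gap open / extend | 10 / 0.5 | score | EMBOSS-style affine costs; identity values agree with common servers to a couple of percentage points, not bit-exactly |
| identity mode | end-gap excluded | — | robust to unaligned terminal extensions (short isoforms) |
| sorting-signal windows | first/last 120 aa | residues | no topology model is consulted; 120 covers the cytosolic termini of family members and is flagged in every report |
| TM window / threshold / min span | 19 / 1.6 / 10 | residues, Kyte–Doolittle units | classic hydropathy calling; explicitly an approximation of dedicated topology predictors |
| CBS identity threshold | 50% over ≥ 40 columns | percent | measured, see below |
| pKa set | Bjellqvist | pH | single documented set rather than an average of web tools; expect ±0.15 against multi-tool means |
| bootstrap replicates | user-set (field habit: 1000) | — | replicate trees are NJ on ML distances, not full ML — a desk-scale simplification |

**The CBS threshold is measured, not guessed.** A commonly suggested 30%
floor turned out to sit *below* the empirical null: best local alignments
of a shuffled 50-residue CBS segment against same-composition background
reach 31–42% identity over ≥ 40 columns (300-shuffle null, max ≈ 42%,
99th percentile ≈ 39%). A copy carrying 20% random substitutions still
scores ≥ 80%. The default is therefore 50% — above the null ceiling, far
below the signal floor — and remains config-exposed.

## Physicochemistry

Mass is the sum of average residue masses plus one water. GRAVY is the
plain Kyte–Doolittle mean. pI solves net-charge(pH) = 0 by bisection on
[0, 14] to |charge| < 1e−4; the charge model is per-group
Henderson–Hasselbalch over D, E, C, Y, H, K, R and both termini with the
Bjellqvist pKa set (including residue-specific N-terminal corrections).
Net charge is strictly decreasing in pH, so the root is unique; the test
suite checks bisection against a 0.001-step grid scan.

## Phylogenetics

The JTT exchangeabilities and stationary frequencies are read at run time
from the installed phangorn copy of the published matrix (verified
against the canonical values) and assembled into a reversible generator
scaled to one expected substitution per unit time. P(t) comes from a
symmetrized eigendecomposition. Pairwise distances maximize the
likelihood of the 20×20 aligned-pair count table; columns with a gap or
unknown residue on either side are dropped pairwise. Trees start from
neighbor joining (taxa sorted first, so ties break by label order),
optionally improve by a deterministic NNI hill-climb under the
Felsenstein-pruning log-likelihood (uniform rates, gaps as missing data),
and carry bootstrap supports computed by resampling columns and
rebuilding NJ/ML-distance trees. Subgroup assignment finds the internal
edges separating the two anchor sets (eukaryotic-branch homologs vs
prokaryotic-branch homologs) and uses the most balanced such split; each
remaining taxon joins the subgroup whose anchors share its side.

Numerical choices worth knowing: branch-length optimization is
coordinate-wise with a bounded 1-D optimizer (tolerance 1e−4, two sweeps
by default); per-node likelihood surfaces are rescaled by their column
maxima to avoid underflow; tiny negative round-off in P(t) is clamped to
zero; NNI acceptance requires an improvement of more than 1e−9 log units,
so plateaus terminate the search.

## What the synthetic generator does and does not emulate

`clc_blueprint()` states a world: 120-residue polar N-terminus, twelve
21-residue hydrophobic helices (L/I/V/F/A/M-weighted, mean hydropathy
≈ 3.6 — the "poly-LIV-like" stretch the transmembrane caller is designed
to see) separated by 12-residue polar linkers hosting the three motifs
and the two glutamate anchors, and a 180-residue polar C-terminus with
two CBS copies; 684 residues in total, inside the 587–811 span of real
family members. Sorting-signal instances are planted in the terminal
windows. A shared `background_seed` makes blueprint variants mutually
alignable (the shipped reference bundle is exactly such a scaffold);
`divergence` randomizes 5% of background positions by default — a close
paralog. After assembly, *unplanned* matches of any modelled motif are
deterministically rewritten, so planted-feature recovery is an exact
count, not a statistical one.

The generator does **not** emulate: indels (so simulated families are
trivially aligned, and alignment-robustness of the phylogeny is untested
here), compositional heterogeneity along loops, signal peptides,
alternative isoform starts, or any expression-level phenomena. A green
recovery test therefore establishes the pipeline's logic, not its
performance on diverged real sequences; the bundled reference is likewise
a synthetic stand-in (files suffixed `_synthetic` / flagged
`"synthetic": true`), with real references drop-in replaceable through
the same FASTA + JSON bundle format.

## Degenerate inputs and edge behaviour

Empty FASTA files, duplicate ids and illegal characters are rejected with
the offending record and position named. Trailing stop codons are trimmed
silently; internal stops are hard errors. A substitution whose stored
reference base disagrees with the CDS is refused (coordinate-drift
guard). Zero-variation alignments bootstrap to star-like replicates;
supports remain defined percentages. `X` residues never satisfy motif
constraints (including `x`), make mass/GRAVY "not determined" for that
record, and contribute no charge to pI.

## Known limitations

* Real-sequence spot checks (`check_table1()`) need the deposited
  records, which must be fetched by the user; the offline test suite
  exercises the identical code paths on the synthetic family instead.
  One curiosity of the published record set is an internal 586 vs 587
  length discrepancy for the short isoform of one member; the package
  records published values as they are and does not reconcile them.
* The transmembrane sketch is a hydropathy heuristic, not a probabilistic
  topology model; its counts are labelled an approximation everywhere.
* Bootstrap replicate trees are NJ-based; supports can differ from
  full-ML bootstraps on hard topologies.
* Rate variation across sites (Γ) is not modelled; the hook exists in the
  model object but uniform rates are the only shipped option.
* Published identity percentages from unspecified aligners are matched to
  within a couple of percentage points, not reproduced bit-for-bit.
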