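---
title: "Methods: comparative molecular evolution of African and Asian rice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative molecular evolution of African and Asian rice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oryzaevol)
```

## The scientific setting

*Oryza glaberrima* (Og, African cultivated rice) and *Oryza sativa* (Asian
rice, with the japonica and indica subspecies, Osj and Osi) diverged on the
order of 10^5^–10^6^ years ago. Gene-enriched shotgun sequencing of Og —
methylation filtration (MF) plus subtractive hybridization (SH) of
repeats — yields a partial genome that can be aligned to the finished Osj
genome, with Osi aligned genome-to-genome and *Sorghum bicolor* serving as
an outgroup for coding sequences. On that three-plus-outgroup scaffold this
package implements five analytical layers:

1. **Read processing** — 3' quality trimming, organelle screening,
   repeat-content filtering, best-hit placement, and a per-site consensus
   with explicit support rules.
2. **Windowed divergence** — substitution counts in fixed windows along the
   reference and transition/transversion (ts/tv) ratios.
3. **Codon evolution** — parsimony assignment of lineage-specific
   substitutions, amino-acid distances under a gamma-Poisson correction,
   synonymous/nonsynonymous distances by the modified Nei–Gojobori method,
   exact three-taxon least-squares branch lengths, per-lineage
   dN/dS (ω) with gene bootstrap, and G-tests of substitution properties.
4. **Splice sites** — detection of lineage-specific substitutions at
   donor/acceptor motifs and a coding-potential test for newly created
   introns.
5. **Microsatellites (SSRs)** — perfect-repeat detection, cross-genome
   clustering, polymorphism classification, and region-stratified
   contingency tests.

A statistical kernel (G-test, chi-square tails, Tajima relative-rate test,
gene bootstrap) underlies all layers, and a synthetic-data generator
provides ground truth for every stage.

## The statistical kernel

The enrichment and polymorphism contrasts all reduce to a 2×2 table with
counts $O_{ij}$ and margin-derived expectations $E_{ij}$, tested with the
log-likelihood-ratio statistic

$$G = 2\sum_{ij} O_{ij}\,\ln(O_{ij}/E_{ij}),$$

with the convention $0\ln(0/E)=0$, referred to a χ² distribution with one
degree of freedom. No correction is applied by default: the uncorrected
G-test reproduces the published domain-enrichment p-values to their printed
precision, which identifies it as the variant actually used; the Williams
adjustment ($G/q$ with
$q = 1 + \frac{(N/r_1+N/r_2-1)(N/c_1+N/c_2-1)}{6N}$) is available as an
option. Tables with a zero margin are rejected rather than continuity-
corrected.

```{r}
gtest_2x2(contingency_2x2(50, 3691, 33, 498))   # NB-ARC enrichment
```

Rate equality between two lineages is tested with Tajima's relative-rate
χ² = $(m_1-m_2)^2/(m_1+m_2)$, where $m_i$ counts sites at which only
lineage $i$ differs from the other lineage and the outgroup:

```{r}
tajima_rrt(286, 315)
```

Standard deviations of ratio statistics (notably ω) are obtained by
bootstrap over **genes** — the natural exchangeable unit of the per-gene
alignment data — with 1000 iterations by default and a fixed seed.

## Modified Nei–Gojobori dN/dS

Synonymous (S) and nonsynonymous (N) *potential sites* are counted per
codon with transition/transversion weighting: each position contributes
weight $R/(R+2)$ for its single transitional neighbour and $1/(R+2)$ for
each of its two transversional neighbours, summed over synonymous changes.
Changes that would create a stop codon are excluded from **both** S and N
(so $S + N = 3L - S_\mathrm{stop}$, with the excluded weight reported):
protein-coding sequence can never realize that mutational opportunity, and
the older convention of leaving it inside N deflates dN — and hence
dN/dS — by the stop share, about 5% at the default weighting, which the
simulation studies resolve cleanly (planted ω recovered with ≈ 0.1% mean
bias under exclusion versus ≈ −5% without). $R$ is the transition/transversion
**rate** ratio: because every site has one transitional and two
transversional neighbours, an observed genome-wide ts/tv **count** ratio of
1.72 corresponds to $R = 2 \times 1.72 = 3.44$, the package default. This
convention matters: simulation with a Kimura mutation process showed that
feeding the count ratio into the weight formula biases recovered ω downward
by roughly 20%, while the rate-ratio convention recovers planted values to
within a few percent. $R = 1$ collapses to the unmodified Nei–Gojobori
counts, which the tests verify against an independent enumeration oracle.

Observed differences between codons are resolved by **pathway averaging**:
for codons differing at $k$ positions, all $k!$ substitution orders are
enumerated, orders passing through a stop codon are discarded, and the
synonymous/nonsynonymous step counts are averaged over the remaining
pathways (if all pathways are blocked the codon pair is skipped and
counted). Proportions $p_S = S_d/\bar S$, $p_N = N_d/\bar N$ (site counts
averaged over the two sequences) receive the Jukes–Cantor correction
$d = -\tfrac34\ln(1-\tfrac43 p)$; saturation ($p \ge 3/4$) yields `NA` with
a flag rather than a silent value.

Per-lineage distances come from the exact three-taxon least-squares
solution $b_x = (d_{xy}+d_{xo}-d_{yo})/2$ applied separately to the dS and
dN matrices of the concatenated gene set; ω per lineage is $b_N/b_S$.
Concatenation (rather than averaging per-gene ratios) was chosen because
the companion count-based G-test operates on total substitution counts;
both modes can be obtained by bootstrapping over genes. Amino-acid branch
lengths use the gamma-Poisson distance
$d = a\,[(1-p)^{-1/a}-1]$ with shape $a = 2.25$, whose $a\to\infty$ limit
is the plain Poisson correction $-\ln(1-p)$.

Codon alignments are accepted when the Og and outgroup rows contain no gaps
or premature stops and the alignment reaches 100 amino acids **or** exceeds
70% coverage of the reference protein; ten codons at each terminus are
excluded from counting to guard against alignment-edge artifacts.

## Amino-acid property tests

Lineage-specific substitutions (assigned by parsimony: the taxon that
differs while the other ingroup taxon equals the outgroup) are classified
as property-preserving or property-changing under four bundled partitions
of the 20 residues — charge, polarity, volume, hydropathy — and each
partition feeds a 2×2 lineage × change G-test. The partitions are
documented package defaults; published alternatives load from a flat
key-value file (`read_property_scheme()`), so the exact historical schemes
can be substituted without code changes.

## Splice sites

Intron positions are taken from the japonica gene models only (the
Og data are partial and its splice variants cannot be called), donor = the
first two intron bases and acceptor = the last two, both read on the
transcript strand. A site enters the analysis only when the motif and
10 bp of flank on each side align without gaps in all three genomes;
lineage assignment then follows the same one-taxon-differs rule, with Og
assignments flagged *unpolarized* because no outgroup genome is aligned. A
stricter flank-clean filter (flanks identical in all three genomes)
controls residual misalignment, mirroring the observation that apparent
indica-specific splice changes were partly alignment artifacts.

For introns between protein-coding exons, coding potential is tested by
translating the intron in the frame that continues the upstream exon:
retention requires intron length ≡ 0 (mod 3) — otherwise the downstream
exon frame cannot reconnect — and no in-frame stop. The mod-3 requirement
is an interpretation (the source analysis only says "translated without
stop codons"), so the raw stop-scan is reported alongside, letting users
adopt either reading. In the lineage summary, the parenthetical GT/AG
counts use the japonica motifs of each intron; for japonica-lineage
changes these are the derived motifs, which is the conservative choice
given that only japonica gene models are trusted.

## Microsatellites

Perfect tandem repeats of primitive 2–4 nt motifs are detected with unit
minima of 9 (di-), 6 (tri-) and 5 (tetra-nucleotide) repeats; motif
primitivity prevents an (AT)ₖ tract from resurfacing as an "ATAT" repeat.
Overlapping candidates are resolved longest-first, then leftmost, then
smallest unit. Canonical motif names merge a motif with its reverse
complement but deliberately not with its rotations (CGC/GCG, CGG/CCG and
GGC/GCC remain distinct classes, as is conventional for rice SSR surveys).

Loci from the three genomes are mapped to alignment columns and clustered
by column overlap; a cluster is kept when each genome contributes a locus
and the 50-bp reference flanks align without gaps — gaps *inside* the
cluster are precisely the length polymorphisms under study and are
allowed. Classification compares the aligned region sequences: identical →
shared; length differing in exactly one genome → lineage-specific length
polymorphism; equal lengths with one deviating sequence → lineage-specific
same-length polymorphism; anything else (including clusters where a genome
contributes several loci) → other. The length-vs-sequence contrast per
lineage is the comparison that uniquely reproduces the published
significance pattern (indica significant at P ≈ 0.006, the other two
lineages not), which is why it is the implemented reading. Regions are
classed protein-coding (inside CDS), non-transcribed (outside all
transcripts) or other; the "other" stratum is excluded from the
region-contrast tests, consistent with published totals that sum below the
global SSR count.

## The synthetic-data generator

`simulate_genomes()` draws an ancestral genome with embedded gene models
(GT..AG introns, a fraction of minus-strand genes, soft-masked repeat
intervals, optionally planted SSR tracts in intergenic and coding
sequence) and evolves it on the fixed topology ((Og, (Osj, Osi)),
outgroup). Mutations are proposed per site under a Kimura scheme with
transition/transversion rate ratio κ; in coding sequence a proposal that
creates a stop is rejected and a nonsynonymous proposal is accepted with
probability ω — a transparent acceptance-probability scheme chosen over a
full Markov codon model because the parameter-recovery tests, not model
realism, establish its adequacy. Defaults mirror the study conditions:
per-branch rates giving an Og–Osj distance near 5×10⁻³ (branch scale
2.5/2.7×10⁻³), κ = 3.44 (ts/tv count ratio 1.72), ω = 0.30 on the Og
branch and 0.25 on the Osj/Osi branches. The outgroup branch rate is set
to 0.10 — closer than a real sorghum comparison, a deliberate compromise
that keeps parsimony assignment clean while exercising the same code
paths; divergence-dependent biases at true sorghum distances are therefore
not probed by these tests. Planted splice-site and SSR events are applied
after branch evolution, with the affected motifs, tracts and their
immediate flanks shielded from random substitutions so that the event
ledger remains exact; insertions and deletions occur only at planted SSR
loci, which keeps the emitted alignment exact by construction (no aligner
is involved, so read-mapping or alignment errors of real pipelines are out
of scope). `simulate_reads()` adds phred-profiled paired shotgun reads
(~2-kb fragments sequenced from both ends), MF/SH library tags, organelle
contaminants and phred-implied sequencing errors.

What passing the simulation-based tests shows: the estimators recover
*their own* generating process without bias detectable at the tested
scale. What it does not show: robustness to real-data features the
generator omits — alignment error, indel evolution outside SSR tracts,
base-composition heterogeneity, CpG effects, and genuine sorghum-scale
outgroup divergence.

## Problem sizes, numerics and reproducibility

The validation suite runs, per fixed seed: 20 panels of 2000 genes × 100
codons for ω recovery (recovery asserted within two bootstrap standard
deviations per run and < 5% mean bias); exhaustive pathway-oracle
comparison over all 61×61 sense-codon pairs; a 10⁴-string regex-oracle
comparison for the SSR detector; and 1000-replicate null calibrations of
the lineage G-tests at α = 0.05 under equal planted ω. These sizes were
chosen as the smallest that make the statistical assertions sharp.

All randomness flows through explicit integer seeds (`withr`-style local
RNG state, so library calls never perturb a caller's stream). Ties are
always broken deterministically and documented: best-hit ties by
(chromosome, start, strand); consensus base ties by phred then MF library
then flagged ambiguous; strict-majority ties at supported sites are
excluded; SSR overlap ties by length, position, unit. Degenerate inputs
have defined behaviour rather than silent defaults: zero-margin tables,
saturated distance corrections, zero transversions, all-pathways-blocked
codon pairs and empty strata all return explicit errors, flags or skip
reasons.

## Pipeline interface

The stages (`simulate`, `qc`, `consensus`, `windows`, `codon`, `splice`,
`ssr`, `enrich`, `report`) are orchestrated by `run_stage()` /
`run_pipeline()` over a run directory with a fixed layout; every stage
writes a JSON manifest with parameter values and md5 checksums of its
outputs, and deterministic stages re-run to identical checksums. The
package is driven from R — the functions and this vignette are the
interface — and the orchestration layer deliberately stays a thin,
file-based state machine rather than a workflow engine.

## Known limitations

* Og splice variants are invisible by design (japonica gene models only).
* The toy seed-and-extend aligner backing the mapping interface is
  adequate for simulated reads, not for real shotgun data; the mapping
  backend is pluggable for that reason.
* The modified Nei–Gojobori R used in the original analysis is not
  recorded; results are reported under the documented default and R is
  exposed.
* Whether published SSR G-tests used the Williams correction is unknown;
  both variants are exposed, uncorrected is the default that reproduces
  the printed values.
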