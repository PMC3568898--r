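# oryzaevol

Comparative molecular evolution of African cultivated rice (*Oryza
glaberrima*, Og) against the japonica (Osj) and indica (Osi) subspecies of
Asian rice (*O. sativa*), with *Sorghum bicolor* as outgroup — for
researchers who have a gene-enriched partial genome of one taxon aligned to
a finished reference and want the full battery of small-scale evolutionary
analyses that setting supports.

The package implements, as tested R functions:

* **G-test engine** — uncorrected (optionally Williams-corrected)
  log-likelihood-ratio tests on 2×2 tables,
  `G = 2 Σ O·ln(O/E)` against χ²(df = 1), for domain-enrichment and
  microsatellite contrasts; Tajima's relative-rate test
  `χ² = (m₁−m₂)²/(m₁+m₂)`; gene-level bootstrap.
* **Read processing** — phred-based 3′ trimming, organelle screening,
  repeat-content filters, deterministic best-hit selection, per-site
  consensus (phred, then methylation-filtration preference), supported-site
  calling, contig N50/coverage statistics.
* **Windowed divergence** — substitution counts in 10-kb windows and
  transition/transversion ratios.
* **Codon evolution** — modified Nei–Gojobori dN/dS with pathway averaging
  and transition/transversion-weighted site counts, Jukes–Cantor and
  gamma-Poisson (shape a = 2.25) corrections, exact three-taxon
  least-squares branch lengths, parsimony lineage assignment, amino-acid
  property-change G-tests.
* **Splice sites** — lineage-specific donor/acceptor substitutions with
  gap-free and flank-clean filters, intron coding-potential testing.
* **SSRs** — perfect-microsatellite detection (unit minima 9/6/5 for
  di/tri/tetra), cross-genome clustering through the alignment,
  shared / length-polymorphic / same-length-polymorphic classification,
  region-stratified G-tests.
* **Synthetic data** — a ground-truth generator that evolves three ingroup
  genomes plus outgroup CDS on ((Og,(Osj,Osi)),outgroup) with κ bias,
  per-branch ω, planted splice/SSR events, and phred-scored shotgun reads.

## Worked example

Is the NB-ARC disease-resistance domain over-represented among the
*O. glaberrima* sequences that fail to map to the japonica genome? 50 of
3741 mapped genes carry the domain versus 33 of 531 unmapped genes:

```r
library(oryzaevol)
gtest_2x2(contingency_2x2(50, 3691, 33, 498))
#> G-test
#>   statistic = 40.475, df = 1, p = 1.992e-10
```

The domain is strongly enriched in the unmapped (Og-specific) fraction.
Equality of amino-acid evolutionary rates on the Og and Osj branches, from
286 and 315 lineage-specific substitutions:

```r
tajima_rrt(286, 315)
#> Tajima relative-rate test
#>   statistic = 1.39933, df = 1, p = 0.2368
```

No rate difference. A miniature end-to-end run on synthetic data:

```r
p   <- simulate_codon_panel(n_genes = 500, n_codons = 150, seed = 3)
fit <- lineage_dnds(p$alignments, mng_params(R = 3.44), n_replicates = 200)
round(fit$omega, 3)
#>    Og   Osj
#> 0.282 0.219
round(fit$omega_sd, 3)
#>    Og   Osj
#> 0.035 0.031
```

The planted dN/dS of 0.30 (Og) and 0.25 (Osj) are recovered within two
bootstrap standard deviations at this 500-gene panel size; the
validation suite (`tests/testthat/test-acceptance.R`) runs 20 seeded
2000-gene panels and bounds the mean bias below 5%.

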