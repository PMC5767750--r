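# coipnet

Scoring and annotation pipeline for affinity-purification
mass-spectrometry (AP-MS) co-immunoprecipitation experiments, written for
studies of meiotic chromosome-axis proteins (ASY1/ASY3-type pulldowns
from anthers and meiocytes) but applicable to any co-IP design with
matched IgG controls.

## What it computes

Given peptide-level evidence tables (dataset, tissue, channel, replicate,
protein, peptide, spectral-ID flag, peak area), the package answers the
questions a co-IP analyst asks:

**Which proteins are genuine interactors?** Peptide areas are aggregated
per protein and replicate, and each dataset is tested independently with
an empirical-Bayes moderated t-test. For protein *g* with pooled residual
variance *s*²_g on *d*_g degrees of freedom, the variance prior
(*d*₀, *s*₀²) is estimated by method of moments on log variances and the
statistic is

> *s*²_post = (*d*₀ *s*₀² + *d*_g *s*²_g) / (*d*₀ + *d*_g),
> *t̃* = Δ / (*s*_post √(1/n₁ + 1/n₂)),  with *d*₀ + *d*_g df,

where Δ is the sample−control difference of mean log₂ areas and the
fold-change is 2^Δ. A protein is *significant* when fold-change ≥ 5 and
p < 0.01 in at least one dataset. Acceptance is two-tier: proteins
identified in any control are excluded outright; sample-specific
proteins with at least two distinct peptides in one dataset are retained
— in the *quantitative* tier when significant somewhere, otherwise in
the less reliable *qualitative* tier.

**What do they correspond to in the reference genome?** Best-BLAST-hit
ortholog assignment (bit score, then E-value, then lexicographic
tie-break; E ≤ 1e-5) with many-to-one collapse of triplicated genes onto
reference loci, plus tissue-overlap accounting at protein and locus
level.

**Do they interact?** A scored edge list over the accepted-locus
universe becomes an undirected graph (combined score ≥ 0.4 by default);
connected components give the main network, the orphans (everything
outside the largest component), and seeded neighborhoods; term
over-representation is tested with the exact hypergeometric distribution
and Benjamini–Hochberg adjustment. Mutant phenotype comparisons use the
Yates-corrected 2×2 chi-square.

**Where are the phosphosites?** Phosphopeptides are mapped to protein
coordinates, merged to distinct sites (an unresolved two-position
localization ambiguity counts as one site unless another peptide
resolves it), and classified against kinase consensus motifs: S/TQ
(ATM/ATR), minimal S/T-P and full S/T-P-X-K/R CDK1 motifs, and an acidic
(+1/+3) CK2 context. S/TQ cluster domains (≥3 motifs spanning ≤100
residues) are detected by a windowed scanner, and sites are carried
across species through global pairwise alignments (BLOSUM62, affine
gaps, needle conventions).

Every input can also be *simulated* with known ground truth
(`simulate_coip()`, `simulate_proteome()`, `simulate_ortholog_hits()`,
`simulate_network()`), which is how the test suite exercises the whole
pipeline offline.

## Worked example

The packaged phosphopeptide table for the Brassica axis proteins BoASY1
and BoASY3 runs through the phospho-only mode:

```r
library(coipnet)
rep <- phospho_report()
rep$summary
#>   protein_id n_peptides n_sites n_stq n_cdk1 n_cdk1_full n_ck2
#> 1     BoASY1         13      18     4      2           0    12
#> 2     BoASY3          6       7     1      4           1     2
```

BoASY1 carries 18 distinct phospho-S/T sites on 13 peptides, four of
them at S/TQ motifs; BoASY3 carries 7 sites on 6 peptides, with four
CDK1-consensus sites (one full, three minimal) and one S/TQ site. The
central S/TQ cluster domain of BoASY1 is recovered from its motif
layout:

```r
scd_from_positions(c(267, 272, 294, 300))
#>   start end n_members member_positions
#> 1   267 300         4  267;272;294;300
```

A full synthetic run with known truth:

```r
b <- demo_bundle(seed = 7)            # writes evidence, FASTA, hits, edges
s <- run_pipeline(b$config, quiet = TRUE)
unlist(s[c("n_accepted", "n_quantitative", "n_qualitative",
           "n_loci", "n_unassigned")])
#>     n_accepted n_quantitative  n_qualitative         n_loci   n_unassigned
#>             75             50             25             62              1
```

All 50 planted complex members land in the quantitative tier and the 25
low-evidence sample-specific proteins in the qualitative tier; none of
the 100 planted background binders survives control exclusion. Stage
TSVs and a `summary.json` are written to the run directory.

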