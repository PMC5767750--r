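---
title: "Methods: co-IP scoring, network and phosphosite annotation in coipnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-IP scoring, network and phosphosite annotation in coipnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coipnet)
```

coipnet analyses affinity-purification mass-spectrometry (AP-MS)
co-immunoprecipitation experiments in which a bait protein — here a
meiotic chromosome-axis protein pulled down from anther and
meiocyte-enriched tissue — is captured together with its associated
complexes, alongside matched non-specific IgG controls. This vignette is
the package's own account of the statistical model, the decision rules,
the simulators, and the numerical choices behind them.

## The quantification model

Peptide peak areas are summed per protein, channel (sample vs control)
and replicate (`aggregate_protein_intensity()`; the rule is configurable
to the mean, because the upstream peak-integration convention differs
between tools and the analysis should not silently depend on it). A cell
is missing when no quantified observation exists — never zero, because a
zero would later be log-transformed. No imputation is performed: a
protein lacking two observed values in either channel of a dataset is
*untestable* there and can only be rescued by the qualitative acceptance
tier. No cross-dataset normalization is applied; each co-IP dataset is a
self-contained sample/control comparison and is tested independently.

On log2 areas, protein $g$ in a dataset with $n_1$ sample and $n_2$
control replicates yields the enrichment
$\Delta_g = \bar x_{g,s} - \bar x_{g,c}$, the pooled residual variance
$s_g^2$ on $d_g = n_1+n_2-2$ df, and the moderated statistic

$$
s^2_{post}=\frac{d_0 s_0^2 + d_g s_g^2}{d_0+d_g},\qquad
\tilde t_g=\frac{\Delta_g}{s_{post}\sqrt{1/n_1+1/n_2}},
$$

referred to a t distribution on $d_0+d_g$ df. The prior $(d_0, s_0^2)$
is fitted by method of moments on $z_g=\log s_g^2$: with
$e_g = z_g-\psi(d_g/2)+\log(d_g/2)$, the between-protein dispersion of
$e_g$ in excess of $\mathrm{trigamma}(d_g/2)$ identifies $d_0$ through
the inverse trigamma (solved by Newton iteration), and the mean
equation then gives $s_0^2$. Two degenerate regimes are handled
explicitly: when the excess dispersion estimate is non-positive the
prior is degenerate ($d_0=\infty$, $s_0^2$ = the df-weighted mean
variance, the maximum-likelihood common variance), and the reference
distribution becomes standard normal; $d_0=0$ gives the shrinkage-free
ordinary pooled t-test, which the tests use as an exact limit check.
The test suite also cross-checks the fit against an independent
empirical-Bayes implementation (limma's `fitFDist`) on simulated
variance draws.

Fold-change is $2^{\Delta_g}$, i.e. computed on the log2-mean
(geometric) scale, consistent with the statistic that accompanies it;
the arithmetic-mean alternative would divorce the two. The ≥ comparison
against the fold-change threshold is guarded by a $10^{-9}$ relative
tolerance so that a ratio of exactly the threshold cannot fail by
floating-point rounding through the log2 round trip.

Significance in a dataset requires fold-change ≥ `fc_min` (default 5)
**and** p < `p_max` (default 0.01). P-values are deliberately *not*
multiplicity-adjusted by default — the decision rule is a per-dataset
screen, not a genome-wide discovery claim — but `bh_adjust()` is
available when an FDR view is wanted.

## Two-tier acceptance

`accept_proteins()` implements the screening logic:

1. identified (spectral ID) in at least one sample-channel observation;
2. identified in **zero** control-channel observations across all
   datasets;
3. at least `min_unique_peptides` (default 2) distinct peptide sequences
   — modifications stripped — within a single dataset.

Accepted proteins that are also significant somewhere form the
quantitative tier; the rest form the qualitative (sample-specific)
tier, which a practitioner treats as less reliable.

Two clauses deserve comment. Control exclusion keys on
*identification*, not on quantified area: peak integration can assign a
control-channel area to a protein that was never spectrally identified
there, and it is precisely those depressed control areas that make the
fold-change ratio of the quantitative tier computable. Treating the two
as one signal would make the quantitative tier and blanket control
exclusion mutually exclusive. Second, the two-peptide threshold is
applied within a single dataset rather than across pooled datasets —
the stricter of the two readings, chosen because evidence reporting is
per dataset; a protein with one peptide in each of two datasets is not
accepted.

## Ortholog collapse and tissue overlap

`assign_best_hits()` consumes BLAST tabular hits (the alignment search
itself is out of scope): per query the hit with the highest bit score
wins, ties broken by lower E-value and then lexicographically smaller
subject, after sorting — so the result is independent of input row
order. Queries whose best hit exceeds E = 1e-5, or with no hits, stay
unassigned. Subject identifiers are normalized to locus form by
stripping transcript suffixes (configurable off).
`collapse_to_loci()` performs the many-to-one collapse that a
lineage-specific whole-genome triplication imposes: several co-IP
proteins may indicate the same reference locus. `tissue_overlap()`
counts both/anther-only/meiocyte-only at the protein level and at the
locus level, where a locus inherits the union of its contributors'
tissue sets.

## Network components

`build_graph()` keeps edges with combined score ≥ 0.4 — the
medium-confidence default of the STRING database, whose exports the
reader tolerates — canonicalizes unordered pairs and retains isolated
universe nodes. *Orphans* are defined as all universe nodes outside the
largest connected component, not merely degree-0 nodes: under this
definition component sizes always partition the submitted universe and
main + orphans = universe, which is the arithmetic a reader expects
from a "main network vs orphans" statement. Components come from igraph;
the test suite recounts them with an independent hand-written union-find
on 100 random graphs. Edges are unweighted for component analysis;
scores are retained for export (SIF/GraphML) only.

## Enrichment and mutant statistics

Term over-representation is the exact upper-tail hypergeometric test
$P(X \ge k)$ against a user-supplied background with BH adjustment
across terms — the generic machinery behind any GO-style enrichment
report; curated term databases themselves are out of scope. Mutant
phenotype contrasts use the Yates-corrected chi-square,
$\sum(|O-E|-0.5)^2/E$ on 1 df, with the correction floored at zero when
$|O-E|<0.5$ so that near-null tables cannot acquire a positive
statistic from the correction itself.

## Phosphosites, motifs and cluster domains

Peptides are located in their protein by unique exact substring match
(`map_peptide_sites()`); zero matches is a mapping error and multiple
matches an ambiguity error, since the site position cannot then be
inferred. Protein coordinates are 1-based inclusive throughout.

Distinct-site counting (`collapse_sites()`) follows one convention: an
unresolved two-position localization ambiguity ("S442 or S443") counts
as **one** site, unless another peptide resolves one of its candidate
positions, in which case the ambiguous observation merges into the
resolved site. Doubly phosphorylated peptides contribute each phospho
group independently; supporting peptides and tissues are unioned. On
the packaged BoASY1/BoASY3 table this convention yields 18 and 7
distinct sites — the inventory the counting rule is asserted against in
the tests.

Motif classification (`classify_site_motifs()`): S/TQ iff Q at +1;
CDK1 minimal iff P at +1; CDK1 full additionally K/R at +3 (full
implies minimal by construction); CK2 iff an acidic residue (D/E) at +1
or +3, where already-assigned phosphosites count as acidic — a declared
operationalization of the informal "multiple acidic residues
surrounding the phosphoserine" description of the CK2 hallmark, liberal
enough to recover the canonical acidic-cluster serines while remaining
a pure function of (sequence, position, prior site set). For ambiguous
sites a label applies when *either* candidate matches. When the context
window runs past the available sequence the affected labels are omitted
and a `context_truncated` flag is raised, never an error; this is what
allows classification from peptide-local context when no full-length
sequence is supplied (the packaged table carries its own protein
coordinates for exactly this mode).

S/TQ cluster domains: any window of ≥ `min_motifs` (3) motifs whose
first-to-last span is ≤ `max_span` (100, inclusive:
last − first + 1 ≤ 100) qualifies; overlapping or chained qualifying
windows merge into one region. Merging can, by chaining, produce a
region whose total span exceeds 100 residues — the alternative
(reporting overlapping sub-regions separately) would double-count
motifs, so merging is preferred and each reported region is guaranteed
to contain at least one qualifying window. The scanner is validated
against a brute-force oracle that enumerates all motif triples and
merges those sharing a motif.

Cross-species correspondence walks the columns of a global alignment
(`global_align()`: BLOSUM62, gap open 10, gap extend 0.5 — the
EMBOSS-needle parameterization, end gaps penalized; a gap of length L
costs open + extend·(L−1)) and maps a source position to its aligned
target position or to a gap. Percent identity and similarity are
computed over the full alignment length, similarity counting columns
with a positive substitution score and identical columns. Alignment is
delegated to Biostrings; the exhaustive-enumeration oracle in the tests
confirms the gap-cost convention on all short pairs.

## What the simulators emulate — and what they do not

`simulate_coip()` defaults encode the study design the pipeline
targets: nine datasets, five anther and four meiocyte, six with
technical triplicates of sample and control; planted true-complex
proteins with mean log2 enrichment 3 (8-fold, comfortably above the
5-fold threshold) and ≥3 peptides; background binders identified in
controls; a low-evidence cohort with exactly two peptides in sample
channels only. Intensities are log-normal: log2 area ~ Normal with SD
derived from a natural-scale CV of 0.2, a typical technical-replicate
CV for label-free peak areas. Missing-at-random (rate 0.1) suppresses
the quantified area of an observation while leaving its spectral
identification intact — modelling the fact that peak integration and
spectral ID are distinct events — so acceptance is deterministic given
the generator's ID contract while quantification sees realistic
missingness. Missing-by-absence arises structurally (the low cohort has
no control observations at all). All generators are pure functions of
(config, seed).

What the simulator does **not** model: spectrum-level noise, shared
(razor) peptides and protein-grouping ambiguity, ratio compression,
batch effects between datasets, or intensity-dependent missingness.
Passing tests therefore demonstrate that the decision rules and
statistics behave as specified under the declared generative model, not
that the thresholds are optimal for any particular instrument.

`simulate_proteome()` draws background sequence from an alphabet
without Q, P, D and E, so no S/TQ, CDK1 or CK2 motif can arise outside
the planted features; plantings are spaced by a 5-residue guard band,
S/TQ-class sites avoid cluster-domain proteins, and at most one loose
S/TQ site is planted per protein so that planted cluster-domain truth
is exactly recoverable. `simulate_ortholog_hits()` plants a
triplicated many-to-one structure with decoy hits and optional
weak-hit-only queries; `simulate_network()` plants one dominant
component (random spanning tree plus extra edges), edge-free orphans
and optional small side components, with all scores above the retention
threshold so construction preserves the planted structure.

## Problem sizes and determinism

The default test run simulates on the order of 10–50 proteins per
cohort and a few hundred nodes/sequences per property loop (200 random
sequences for the cluster-domain oracle, 100 random graphs for the
union-find cross-check, 2000 variance draws for prior recovery) — sizes
at which every oracle is exact and the whole suite runs in about a
minute. The acceptance script works at the study scale where the
quantities are structural (589 query proteins collapsing to 492 loci;
a 492-node universe with a 456-node main component), and at simulator
scale for the stochastic power quantities. All tabular outputs are
sorted by primary key and floats are written at 6 significant digits,
so identical configs reproduce byte-identical files.

## Known limitations

No protein grouping or razor-peptide parsimony; no isoform resolution;
no cross-dataset normalization or match-between-runs; localization
probabilities are consumed, not computed; the CK2 rule is a declared
heuristic, not a calibrated predictor; multiple sequence alignment is
out of scope (pairwise alignment suffices for site correspondence);
curated annotation databases and interaction-score derivation are
consumed as inputs, never recomputed.
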