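---
title: "Profiling oral Streptococcus clades: methods and design notes"
author: "strepclades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling oral Streptococcus clades: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strepclades)
```

## The problem

*Streptococcus* is a core, highly diverse member of the primate oral
microbiome. Its named species fall into a small number of
phylogenetically supported clades — Sanguinis, Mitis, Salivarius,
Anginosus, Bovis, Pyogenic, Mutans and Downei — and clade membership, not
species identity alone, is what structures colonization of oral surfaces
(tooth, mucosa, saliva). Shotgun-metagenomic profiles of dental calculus,
plaque, buccal mucosa and saliva can therefore be summarized at the clade
level, but three obstacles stand in the way:

1. many genomes hit by a taxonomic classifier carry no clade label
   (unnamed or recently described species);
2. read counts are compositional — proportions across taxa are not free to
   vary independently, so naive correlations between taxa are biased
   toward spurious negatives;
3. ancient dental calculus samples may be dominated by environmental taxa
   and must be screened out before any community statistics are computed.

`strepclades` implements the full chain: taxonomic-table ingestion, clade
label propagation from an average-nucleotide-identity (ANI) dendrogram,
layered relative-abundance profiles with per-sample dominance calls,
compositionally-aware correlation and enrichment statistics, a
preservation screen, and a calibrated cohort simulator so that the whole
pipeline is testable end to end without any external download.

## Clade assignment from ANI

Genomes are clustered by average linkage on the distance $1 -
\mathrm{ANI}/100$ and the tree is cut at 95% ANI, the conventional
bacterial species boundary (`cluster_species()`, `threshold_ani`
exposed). A cluster containing a named reference species inherits that
species' clade; a conflict between two named clades in one cluster is a
hard error by default (silent mislabeling would corrupt every downstream
proportion), with an explicit majority-vote downgrade available.

Clusters containing no named species are placed by dendrogram position.
For such a cluster we locate the smallest merge node that contains the
whole cluster and at least one named genome:

* if that node is an internal node, the cluster sits inside the named part
  of the tree and is labeled **Other**;
* if it is the tree root, the cluster is basal to every named clade and is
  labeled **Unknown**.

"Basal" has no formal definition in common usage; root-level attachment of
the lowest common ancestor is our operationalization, and the test suite
checks it against an independent LCA search on the `ape` phylogeny.
Genomes are sorted lexicographically before clustering so results cannot
depend on input order; continuous ANI values make exact merge-height ties
a measure-zero event.

## The three abundance layers

All layers are computed on species-level assignments only; genus-level
reads never resolved to a species enter no numerator and no denominator.
Per sample:

* **clade share of genus** — reads of focal-genus species in each clade,
  over all focal-genus species reads (sums to 1 when the genus was seen);
* **genus share** — focal-genus species reads over all species-level
  reads;
* **clade share of species** — clade reads over all species-level reads
  (sums to the genus share).

The **dominant clade** of a sample is the plurality (argmax) of the first
layer. The dichotomy seen in ancient calculus — most samples dominated by
Sanguinis, a minority by Anginosus — is reported per cohort by
`cohort_summary()`. No abundance cutoff defines "dominance"; plurality is
the operational rule, with exact ties broken by a fixed clade precedence
(Sanguinis, Mitis, Anginosus, Salivarius, Mutans, Bovis, Pyogenic,
Downei, Other, Unknown) so that results are reproducible. Heatmap values
use $\log_{10}(\mathrm{percent} + 1)$, applied to percent-scale values so
that absence maps to exactly 0 and 99% maps to 2.

Species-level relative abundances (e.g. of *S. sinensis*) are expressed
as shares of focal-genus reads. A "share of all species reads" reading is
untenable for the headline plaque numbers: the genus itself averages only
a few percent of plaque reads, so a single species at 11% can only be 11%
*of the genus*.

## Compositional statistics

Counts are transformed by the centered log-ratio (CLR),
$y_i = \ln\!\big((x_i + 1)/g(x + 1)\big)$, with a pseudocount of one read
(exposed as a parameter) and $g$ the geometric mean across features. Two
association measures are computed on CLR columns:

* **CLR-Pearson** — ordinary Pearson correlation with a two-sided
  $t$-distribution p-value, Benjamini–Hochberg adjusted in all-pairs
  mode;
* **proportionality** $\rho = 1 - \mathrm{var}(y_i - y_j) /
  (\mathrm{var}\,y_i + \mathrm{var}\,y_j)$, algebraically equal to
  $2\,\mathrm{cov}(y_i,y_j)/(\mathrm{var}\,y_i + \mathrm{var}\,y_j)$ —
  the tests require both forms to agree to $10^{-12}$.

Both are invariant to per-sample depth rescaling by construction.

For proportionality screens, a data-driven significance cutoff is derived
by permutation: each feature column is shuffled independently across
samples `n_perm` times, and for every candidate cutoff $c$ on a 0.05 grid
the false discovery rate is estimated as the mean number of null pairs at
$|\rho| \ge c$ over the number of observed pairs there. Two numerical
choices matter. First, the estimate is capped at 1. Second, a cutoff only
counts as *attained* if it retains at least one observed pair: without
this, exchangeable (null) data would vacuously "attain" any FDR at
cutoffs beyond the observed maximum, where nothing is discovered at all.
Even with the guard, roughly 5% of fully null datasets attain a cutoff,
because the observed maximum is itself exchangeable with the permutation
null — the tests assert the unattainable rate accordingly.

`clr_pca()` removes species below 0.001% mean relative abundance
(spurious low-abundance classifier hits), CLR-transforms, and decomposes
by centered SVD. Component signs follow a fixed convention — the
largest-magnitude loading of every component is positive — so scores are
reproducible across platforms. `cancor_pairs()` screens metadata
variables against the clade-share block by first canonical correlation
with a permutation p-value; the conventional screening rule (correlation
at least 0.4 and p at most 0.01) flags a variable as significant, and
both thresholds are parameters.

## Two-group enrichment

`wilcoxon_enrichment()` performs the two-sided Mann–Whitney rank-sum test
per feature with the tie-corrected, continuity-corrected normal
approximation supplying the standardized score $Z$ and the rank effect
size $r = |Z|/\sqrt{N}$. For $N \le 12$ without ties the p-value comes
from the exact U distribution instead (the tests check it against full
enumeration of label assignments). A feature is *enriched* only under the
double threshold: BH-adjusted $q < 0.05$ **and** $r \ge 0.4$ — a
significance cutoff alone, at large $n$, would flag differences too small
to matter. Gene tables are first reduced to features present in at least
30% of the samples compared (`prevalence_filter()`), and gene counts are
normalized to reads per kilobase (`rpk_normalize()`).

## Preservation screening

`decay_curve()` ranks a sample's taxa by decreasing abundance and tracks,
at each rank $k$, the percent of the top $k$ taxa that belong to a
reference set of known oral taxa. Well-preserved oral samples stay high;
samples overwhelmed by soil or skin taxa decay immediately. A sample
passes if the curve stays at or above a group-specific threshold from a
burn-in rank onward (defaults: burn-in 10; 50% for ancient samples, 65%
for modern ones — configurable, since appropriate cutoffs are chosen per
dataset in practice). This is deliberately the simple-threshold variant
of cumulative-percent-decay QC: its role in this pipeline is to emulate
the filtering stage, not to reproduce any particular tool's full rule
set.

## The synthetic cohort generator

`generate_cohort()` draws, per sample: a dominance state (ancient
calculus only), a genus share, a clade composition, within-clade species
splits, a background-genus composition, a sequencing depth, and finally a
single multinomial read vector over ~39 focal *Streptococcus* species,
~45 background oral genera, and (for QC-failure samples) 10 soil taxa.
The defaults encode the study conditions the package is tested under:

* **Sample groups and sizes.** Ancient calculus $n=483$; modern calculus
  18; industrial/non-industrial plaque 120/100; buccal mucosa 28 + 28;
  saliva 135/132; chimpanzee, gorilla, baboon and howler calculus and
  swabs; vervet swabs ($n=16$).
* **Genus-share distributions** are logit-normal, moment-matched
  numerically to the group means ± SDs (industrial buccal 39% ± 19%,
  non-industrial buccal 16% ± 8%, plaque 7%/4%, calculus 5%, chimpanzee
  calculus 0.33% ± 0.23%, vervet swabs 59% ± 20%, and so on). The
  logit-normal was chosen because group abundances are bounded
  proportions with right skew at small means; the data motivating the
  targets are summarized only by mean ± SD, so the family is a modeling
  choice.
* **Industrial buccal support floor.** For the industrial buccal group the
  logit-normal is placed on (0.25, 1) rather than (0, 1). The group's
  separation from its non-industrial counterpart is characterized by a
  rank effect size of 0.76 alongside the moments; under any
  two-parameter full-support family matching 39 ± 19 vs 16 ± 8 the
  achievable effect size caps near 0.63, so the distribution shape itself
  carries information: industrial buccal samples do not reach low genus
  shares. The floor is the minimal third parameter that reconciles the
  moments with the rank separation.
* **The dominance mixture.** Ancient samples are a two-component mixture:
  a Sanguinis-dominant majority and an Anginosus-dominant minority with
  suppressed Sanguinis and reduced genus share. The minority weight is
  71/483 (14.7%), realized as an exact stratified count assigned to
  random samples rather than a Binomial draw, because the mixture weight
  is a cohort-level condition, not a sampling distribution to be
  re-estimated. In the minority component *S. constellatus* carries the
  largest Anginosus weight; in the majority component *S. sinensis*
  carries the largest Sanguinis weight.
* **Clade mixtures** are Dirichlet draws around group(/state)-specific
  means with concentration 10 (16 for ancient calculus). The ancient
  state means and concentration were calibrated so that the CLR-Pearson
  correlation between Sanguinis and Anginosus clade counts across the
  cohort is −0.69 ± 0.02 (proportionality −0.65 ± 0.02) and the ancient
  Mitis mean is 13%. Industrial plaque Mitis is centered at 43%,
  non-industrial at 27%.
* **Species splits within clades** are Dirichlet draws (concentration 3)
  around group-specific weights, encoding the species-level exchanges:
  *S. sinensis* averages 11% of genus reads in non-industrial plaque but
  0.43% in industrial plaque, where *S. sanguinis* takes over; *S.
  oralis_S* is higher in industrial plaque.
* **Depths** are log-normal with median $10^5$ species-assigned reads
  (SD 0.5 on the log scale) — desk-scale, large enough that multinomial
  noise is negligible next to between-sample variation.

Everything is reproducible from one integer seed; the pipeline derives
per-stage seeds from the master seed by a stable string hash
(`derive_seed()`).

`generate_ani()` plants the corresponding genome-level structure: genomes
of one species at 96.5–99.9% ANI, species of one clade at 85–94%,
between clades 75–84%, and basal outgroup genomes at 70–74% to everything
named. Basal genomes are drawn slightly closer to one another than to any
named genome so that, with several of them, the outgroup attaches to the
tree as a single subtree at the root; under the strict root-LCA rule,
equally distant basal genomes would otherwise resolve all but the
outermost to "Other", which is not the planted intent.

### What the generator does not emulate

The simulator reproduces group-level compositional structure, not
sequence-level reality: no read-level errors, no ancient-DNA damage or
fragment-length structure, no database mis-assignment between close
relatives, no within-individual (per-tooth) covariance, and background
genera are drawn from one global composition rather than site-specific
ones. Passing tests therefore demonstrate that the *statistics* behave
correctly on data with the assumed structure — they are not evidence
about classifier accuracy or about real cohorts beyond that structure.

## Numerical choices

* Pseudocount 1 read before closure (exposed); CLR rows sum to 0 within
  $10^{-10}$.
* Missing ANI pairs imputed at a configurable floor (default 70%), with a
  warning, because ANI tools omit sub-threshold pairs; asymmetries beyond
  0.5 ANI points are errors, smaller ones are averaged.
* Duplicate lineages in an mpa table are rejected, not summed — a
  duplicate indicates an upstream joining fault.
* Ties: dominance ties by fixed clade precedence; top-species ties
  lexicographic and flagged; decay-curve rank ties lexicographic.
* ANI matrices are written with `%.17g`, so write-then-read is
  bit-identical.
* PCA signs fixed by the largest-magnitude-loading convention.
* Samples with zero species-level reads give all-NA layers and dominance
  "none"; zero-variance features give NA correlations with a flag, never
  errors.

## Problem sizes in the test suite

The suite exercises the full ancient cohort (483 samples) for the
correlation and dominance checks, 20-seed averages for the group-mean
calibrations, 500-replicate null simulations for the error-rate checks,
and enumeration-scale oracles ($N \le 12$) for the exact tests; the whole
suite runs in well under a minute on one core. These sizes were chosen so
every Monte-Carlo assertion has comfortable margin at the package's
default conditions.

## Known limitations

* Clade labels are only as good as the named-species reference; the
  bundled table covers the commonly profiled oral and pathogenic species,
  and unlisted species resolve to Other/Unknown rather than erroring.
* The Other/Unknown rule depends on the dendrogram topology near the
  root; with very few named genomes the distinction is fragile.
* The permutation FDR cutoff is conservative on small feature sets, where
  the grid step (0.05) is coarse relative to the null spread.
* Canonical-correlation screening treats each metadata variable
  marginally; it is a screen, not a joint model.
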