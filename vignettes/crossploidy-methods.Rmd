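---
title: "Comparing transcriptomes across ploidy levels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing transcriptomes across ploidy levels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossploidy)
```

## The problem

A synthetic allohexaploid wheat (genome AABBDD) is created by crossing a
tetraploid parent (AABB) with a diploid parent (DD) and doubling the
chromosomes. Asking "which genes changed expression after
polyploidization?" sounds like a routine RNA-seq contrast, but two
structural features of the design break the routine analysis:

1. **Different transcriptome sizes.** At equal sequencing depth, a D
   gene claims roughly three times the library share in the diploid
   parent that it claims in the hexaploid, because the diploid
   transcribes a third of the gene set. Normalizing whole libraries
   across ploidies therefore manufactures an apparent ~3-fold change for
   every gene, right at a typical fold-change threshold.
2. **Homoeologous cross-mapping.** The A, B and D subgenomes are similar
   enough that a fraction of reads is assigned to the homoeolog on the
   wrong subgenome ("subgenome mismatches"). The hexaploid's libraries
   contain such cross-mapped reads from all three subgenomes; each
   parent's libraries contain them from its own subgenomes only, so
   features that are weakly expressed on their native subgenome can look
   spuriously "induced" in the polyploid.

`crossploidy` implements the analysis design that addresses both
problems — split-by-subgenome normalization within genotype-consistent
groups, and a parental mismatch correction — together with the
surrounding methodology: negative-binomial differential expression,
midparent-value tests for transposable-element (TE) families, expression
based in-silico karyotyping, homoeolog-bias classification of triads on
the expression simplex, and overlap statistics for DEG sets. A seeded
simulator with known ground truth exercises the whole pipeline.

## The generator: what it emulates

`simulate_experiment()` draws negative binomial counts
(variance $\mu + \phi\mu^2$) for a diploid parent, a tetraploid parent
and synthetic hexaploids at a **common library depth**. Each gene has an
expression weight; a sample's per-gene mean is its weight divided by the
sum of weights over the subgenomes that sample transcribes, times the
depth. This renormalization is what creates the compositional
cross-ploidy structure described above; it is deliberate, not an
artifact.

Defaults, chosen once as the study conditions:

* `baseline_mean = 100` expected counts per hexaploid gene — a
  moderately expressed gene at typical bulk RNA-seq depth.
* `dispersion = 0.1` (biological coefficient of variation ~0.32), a
  conservative value for biological replicates; the parental-legacy
  checks use 0.02 (BCV ~0.14), appropriate for genetically identical
  inbred lines grown under controlled conditions.
* `replicates = 3` per role, the usual design scale for this kind of
  experiment.
* Triad bias vectors from a symmetric Dirichlet with concentration 15,
  giving a mostly balanced triad population with realistic spread;
  tests that need a specific bias structure pass `bias_spec` explicitly.
* `mismatch_rate = 0.02` of each gene's reads cross-assigned to its
  triad partners (half each), moved by binomial thinning so reads are
  conserved. No quantitative wheat cross-mapping rate is established, so
  the rate is an explicit free parameter.
* `synthetic_bias_shrink = 0` — synthetics inherit the parental bias
  unchanged (pure parental legacy). Positive values pull the synthetic
  contributions toward balance, emulating a net balancing effect of
  polyploidization.
* Aneuploidy multiplies the weights of one chromosome by 0.5 or 1.5
  before depth renormalization, so a monosomic chromosome also slightly
  inflates every other chromosome — as in real data, where sequencing
  depth is fixed.

`simulate_te_families()` draws per-family library totals around
role-specific expected RPM levels and smears each total multinomially
across A/B/D/unassigned buckets with equal weights, emulating random
placement of multimapping TE reads.

What the generator does **not** emulate: gene-length biases, GC effects,
batch structure, heavy-tailed expression distributions (gene weights are
constant by default so that parameter-recovery tests stay
interpretable; `gene_spread_log2_sd` turns spread on), isoforms, or
mapping at the read level. Passing tests therefore demonstrate that the
pipeline's logic and statistics behave as designed under the assumed
count model — not that any particular biological result would replicate.

## Preprocessing

**Units.** RPM divides by the column total; TPM divides by feature
length in kb and rescales columns to one million. Both require raw
counts as input and keep the original depths in `samples$lib_size`.

**Mismatch correction** (`correct_subgenome_mismatch()`): each parent's
counts on its non-native subgenomes are converted to RPM, scaled by the
subgenome share of the hexaploid transcriptome (1/3 for the diploid,
2/3 for the tetraploid — which converts parental RPM scale to hexaploid
RPM scale), averaged across that parent's replicates, and added to every
library of the other parent after conversion into that library's count
scale. Adding RPM directly to raw counts would be dimensionally
inconsistent, hence the conversion; corrected tables may be fractional
and carry a provenance flag that blocks double application.

A limitation worth stating precisely: because the recipient parent's
library is itself concentrated (a D gene is ~3x the share in the diploid
that it is in the hexaploid), the transferred hexaploid-scale signal is
diluted by the recipient's concentration factor once the comparison is
renormalized per partition. For a feature with essentially **zero**
native expression the corrected parent-vs-synthetic ratio therefore does
not converge to 1 but to roughly the partition's ploidy ratio (~3 on the
D side, ~1.5 on AB) — just at a 3-fold threshold. The correction bounds
an otherwise unbounded artifact rather than removing it entirely, which
is consistent with mismatch-dominated TE families still needing manual
exclusion in practice. The package's efficacy checks therefore plant
cross-mapping-dominated features with ~1% native contribution (where
most of the feature's reads are cross-mapped): there the uncorrected
artifact exceeds the fold-change threshold while the corrected residual
stays well below it, and the corrected pipeline yields at least tenfold
fewer spurious DEGs. Those checks use four replicates per role, which
keeps the fold-change estimator's sampling noise small relative to the
margins being tested.

**TE redistribution** (`redistribute_parent_te_counts()`): in a parent,
all TE reads necessarily originate from its native subgenome(s), so
per-subgenome family buckets are collapsed — everything to D for the
diploid; D and unassigned split equally between A and B for the
tetraploid (the equal split is our convention; the totals, which are all
the downstream MPV test uses, do not depend on it). Synthetic buckets
are left untouched because the midparent-value test sums A+B+D+un per
family anyway.

## Split normalization and differential expression

`build_normalization_groups()` splits each hexaploid transcriptome into
its AB and D parts and forms one normalization group per parent
genotype and partition: the D parts of the synthetics with the diploid
parent's libraries, the AB parts with the tetraploid parent's. Library
sizes are the **partition column totals**, TMM factors are computed
within each group, and features with zero counts in all group members
are then removed (in that order). Only groups sharing a parental
genotype are normalized together.

**TMM** (`tmm_factors()`) follows the published recipe: reference =
library whose 75th expression percentile is closest to the mean, 30%
two-sided trim on the log-ratios, 5% on the average log intensities,
inverse-asymptotic-variance weights, factors rescaled to geometric mean
one. One numerical subtlety: the precision weights depend on absolute
counts, so rescaling a library shifts the weighted factors by ~1%;
exact scale invariance (to 1e-9) holds for the unweighted trimmed mean
(`do_weighting = FALSE`), which is what the invariance tests assert.

**Dispersion** (`estimate_dispersion()`): per-feature method-of-moments
on depth-scaled counts pooled within conditions, shrunk toward the 10%
trimmed common dispersion with a prior weight of 10 degrees of freedom,
floored at 1e-6. This is a deliberately simple, calibration-oriented
estimator: the acceptance surface for the DE stage is type-I error and
power, not equality of coefficients with any particular GLM fitter.
Under the generator's null (2,000 features, 3+3 replicates,
$\phi = 0.1$) the raw p < 0.05 fraction sits near 0.06 and
Benjamini-Hochberg at FDR < 0.01 plus the fold-change filter yields zero
DEGs in ~19 of 20 seeded runs; at planted |log2 FC| = 3 power exceeds
90%.

**Testing** (`de_test()`): per-feature NB likelihood-ratio test of equal
means between parent and synthetic libraries, offsets = log effective
library sizes, fixed plug-in dispersion, $\chi^2_1$ reference. The
likelihood is evaluated through `lgamma`, so fractional corrected counts
are handled exactly; group means are fitted by a vectorized Newton
iteration on the score equation. Significance uses the study thresholds:
BH-adjusted FDR < 0.01 **and** |log2 FC| > 1.585 (fold change > 3);
both stored per record along with the direction.

`de_whole_library()` implements the naive inter-ploidy comparison
(offsets = whole-library depths, no split) purely as a benchmark; on a
null simulation it floods the result with false DEGs around the ploidy
ratio while the split pipeline stays clean — the package's central
methodological claim, verified as a >= 5x count ratio in the tests. TMM
is deliberately not applied across ploidies there: trimmed M-values are
computed on co-expressed genes and would themselves re-derive much of
the split correction, whereas the flawed analyses this benchmark
represents normalize by library size alone.

## The midparent-value TE test

Because TE reads cannot be assigned to subgenomes reliably, families are
tested at the whole-transcriptome level: per family, A+B+D+unassigned
RPM totals of the synthetics are compared with midparent values
MPV = 1/3 RPM(diploid) + 2/3 RPM(tetraploid), one pseudo-library per
pair of parental replicates (`build_mpv_libraries()`). The RPM values
are rounded half-to-even and fed to the same NB machinery with equal
offsets (`te_mpv_de()`). Two caveats are inherited from the design this
reproduces: RPMs are not counts, and the m x n pseudo-libraries are
built from m + n underlying replicates, so their nominal degrees of
freedom overstate the information content. The recovery tests (8x MPV
families flagged, additive families not, in >= 95% of seeded runs) show
the procedure is nevertheless well calibrated at realistic effect sizes.

## In-silico karyotyping

Genes with TPM > 0.01 in at least two samples are sorted by chromosome
and position rank and cut into windows of 200 genes (a trailing partial
window is kept if it holds at least 100). Per window the sample's median
TPM is divided by the median of a replicate-averaged parental reference
(D genes from the diploid, A/B genes from the tetraploid). Raw
hexaploid-vs-parent ratios sit near the ploidy share, not near one, so
the ratios are rescaled by the median raw ratio within the sample's
subgenome partition — restoring the ~1 / ~0.5 / ~1.5 semantics for
euploid, monosomic and trisomic chromosomes. Chromosomes are flagged by
their median rescaled window ratio (monosomy band [0.35, 0.65], trisomy
[1.35, 1.65]).

Numerical note: the rescaling median should be dominated by euploid
windows. With very few windows per partition the aneuploid windows
drag the median and attenuate the recovered ratio by a few percent; the
package's recovery checks therefore simulate seven chromosomes of 600
genes per subgenome (4,200 triads — a desk-scale wheat-like karyotype),
where the effect is negligible. Recovered medians land within ±0.1 of
0.5 for monosomy and ±0.15 of 1.5 for trisomy, in about two seconds per
run on one CPU.

Consistency diagnostics: Pearson correlation of log(RPM + 0.001)
between all sample pairs clustered by UPGMA on 1 - r
(`sample_correlation()`), and a centered PCA of the samples
(`pca_overview()`) with each component's sign fixed by its
largest-magnitude loading.

## Homoeolog bias on the expression simplex

For each triad the replicate-mean RPMs of the A, B and D homoeologs are
expressed as fractions of the triad total; triads below 5 RPM total are
removed (a total of exactly 5 is kept — the filter removes totals
*below* the threshold). Each retained triad is a point on the
2-simplex and is assigned to the nearest of seven centroids by
Euclidean ("eigen") distance: the centre (Balanced), the three vertices
(Dominant A/B/D) and the three edge midpoints (Suppressed A/B/D). Ties
are measure-zero; they are broken deterministically in the fixed
centroid order Balanced, Dominant A/B/D, Suppressed A/B/D.

Bias is compared across samples by Pearson correlation of the
concatenated A/B/D contributions of triads retained in **both** samples
(intersection, not union — triads expressed in only one sample carry no
paired information). Movement between two states uses the same
Euclidean distance between contribution vectors; a movement is reported
when the category changed **and** the distance exceeds 0.3, and the
summary counts unbalanced-to-balanced versus balanced-to-unbalanced
transitions among reported movements.

The in-silico parent — 0.33 x replicate-averaged diploid RPM + 0.67 x
tetraploid RPM per feature — provides the parental reference state for
movement analysis, so that observed bias in the synthetic can be
attributed to parental legacy or to polyploidization.

Two association tests relate bias to DE: a Welch two-sided t-test
comparing log2 fold changes of dominant (contribution > 2/3) versus
suppressed (< 1/6) homoeologs — the exact fractions are used, strictly,
resolving the small print inconsistency between 0.666/0.667 that
floating thresholds invite — and a 2x2 chi-square (without continuity
correction, so that an exactly proportional table scores zero) of
"triad contains a DEG" against "triad is unbalanced".

## Overlap statistics

`overlap_test()` takes two DEG sets and the background of genes
expressed in both analyses: overlap k, expectation n1*n2/N,
representation factor, exact upper-tail hypergeometric probability by
summation of the pmf, and a normal approximation with continuity
correction (accurate to <10% relative error once the expectation is
~10 and the deviation moderate; the exact tail is always reported).
Direction concordance of the shared genes is tested two-sided against a
fair coin (`direction_concordance()`); both tails are relevant because
either systematically concordant or systematically discordant
re-regulation is biologically meaningful, and the sidedness is stated
with the result.

## Pipeline orchestration

`run_pipeline()` runs simulate (or load) -> karyotype and consistency QC
-> mismatch correction and TE redistribution -> split normalization and
DE -> MPV TE test -> triad bias -> DEG overlaps from one YAML
configuration, writing one TSV per result plus a manifest with a config
hash, seed and row counts. QC runs before DE; aneuploidy-flagged
samples are retained with a warning by default (matching the practice of
keeping flagged libraries "with a note of caution") and excluded when
`qc: {exclude_flagged: true}`. Identical configuration and seed give
byte-identical outputs. A thin command-line wrapper is installed under
`inst/scripts/run_pipeline.R`; the exported functions are the primary
interface.

## Known limitations

* The NB machinery targets calibration, not numerical equality with any
  specific GLM implementation; quasi-likelihood and exact-test variants
  are out of scope.
* The mismatch correction bounds, but does not eliminate, artifacts on
  features with (near-)zero native expression — see above.
* TE families are quantified per family only; per-copy TE analysis,
  read-level simulation and GO enrichment are out of scope.
* The karyotype screen detects whole-chromosome dosage; sub-chromosomal
  events only show up on window inspection.
* Whether a user's count table was produced by per-read or fractional
  multi-overlap counting cannot be inferred from the table; the loader
  is agnostic and the convention is the user's to document. Likewise the
  choice of RPM denominator (all mapped reads vs high-confidence genes
  only) follows whatever the input table contains.

## A worked desk-scale example

```{r example, eval = FALSE}
library(crossploidy)

cfg <- list(
  out_dir = "crossploidy_demo", seed = 5,
  simulation = list(n_triads = 2000, n_synthetic_genotypes = 2))
manifest <- run_pipeline(cfg)
manifest
```

The run writes, among others, `de_genes.tsv` (per-gene log2 FC, p, FDR,
significance and direction per genotype and partition),
`karyotype_flags.tsv` (per-sample chromosome flags), `triad_states.tsv`
(contributions and bias categories, including the in-silico parents)
and `deg_overlaps.tsv` (overlap statistics between the two synthetic
genotypes' DEG sets). Under the default no-DE configuration the DEG
counts are zero or near zero — the expected outcome of a null
simulation through a calibrated pipeline.
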