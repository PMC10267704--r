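---
title: "Family-based rare-variant prioritization and case-control replication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based rare-variant prioritization and case-control replication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famrvar)
```

## The problem

Crohn's disease (CD) is a polygenic inflammatory bowel disease (IBD). Genome-wide
association studies explain part of its heritability through common variants;
rare protein-altering variants of larger effect are expected to explain more,
and families with several affected members are the natural place to look for
them: a causal rare variant should be *shared* by the affected relatives. The
study design this package implements sequences affected members of multiplex
CD families, prioritizes the called variants through a cascade of filters
down to a short candidate list, and then tests each candidate in an
independent case-control cohort under a dominant carrier model.

famrvar provides that pipeline as reusable, tested components: readers for the
standard inputs (annotated multi-sample VCF, pedigree, gene panels,
replication genotype tallies, clinical tables), the filter cascade with a
per-stage count report, the 2x2 association machinery, cohort descriptive
statistics, and a fully seeded synthetic cohort generator with known truth so
the whole pipeline can be validated end to end without access to raw
sequencing data.

## The prioritization cascade

Input is one annotated record per (site, alternate allele) plus one call per
sample per record with read support. The cascade applies, in order:

1. **Coding/splice region and call quality.** Keep variants with a coding or
   canonical-splice-site consequence that have at least one carrier call
   passing the quality cut: total depth >= 10 reads, >= 5 variant reads, and
   a variant-read fraction >= 20%. These are the conventional confidence
   thresholds for short-read germline calls; all three are tunable via
   `quality_thresholds()`.
2. **Non-synonymous consequence.** Keep missense, nonsense, frameshift, and
   canonical-splice variants.
3. **Family sharing and protein alteration.** Keep variants that (a) are
   carried, with a high-confidence call, by *every* index patient of at least
   one family, and (b) alter the protein: truncating classes
   (nonsense/frameshift/canonical splice) always; missense only at highly
   conserved positions, phyloP >= 3.0 (`conservation_threshold()`). Sharing
   is evaluated within each family separately — recurrence across families is
   not required. A missing genotype, a low-confidence call, or an absent call
   record counts as non-carrying: absence of evidence is not evidence of
   sharing.
4. **Population rarity.** Remove variants with allele frequency strictly
   above 0.001 in any annotated reference panel (dbSNP, ESP, ExAC,
   1000 Genomes), and variants present in the in-house exome database.
   An *absent* frequency annotation passes: absence from a panel is itself
   evidence of rarity and must not be conflated with frequency zero, which
   is why the annotation model keeps "absent" (`NA`) distinct from numeric
   values throughout.
5. **Candidate-gene category.** Each survivor is categorized against three
   panels — IBD GWAS genes, primary immunodeficiency (PID) genes,
   IBD-implicated pathway genes — with protein-altering variants outside all
   panels categorized `novel`; variants with category `none` are removed.
   Under the definitions above every stage-3 survivor is protein-altering
   and therefore at least `novel`, so this stage only removes variants when
   the protein-altering definition is relaxed by configuration; the stage is
   kept explicit because the category labels are themselves an output and
   because the published analyses this design follows report a substantial
   reduction here, implying additional unstated curation criteria.
6. **External review lists (optional).** A pass list (standing in for manual
   IGV inspection of alignments) and a cap list (standing in for assay panel
   capacity in the replication genotyping) can be supplied as plain variant-id
   lists; both are plain restrictions and are skipped by default, since
   neither is a computation.

Filters only remove variants, so the per-stage counts are monotone
non-increasing, every stage is idempotent, and stages 3 and 4 commute; the
test suite asserts all three properties on simulated cohorts, and re-checks
every final-set variant against the raw predicates rather than the cascade's
own bookkeeping.

## Variant identity

Variants are identified by the compact key `chrom:posREF>ALT`
(e.g. `chr20:1546854GC>GCC`), 1-based, VCF-anchored. Keys round-trip
verbatim through `parse_variant_key()`/`format_variant_key()`; in particular
the package does **not** silently trim redundant shared bases, because
published identifiers are frequently written in padded form and must
re-serialize identically. `normalize_variant_keys()` performs
suffix-then-prefix trimming explicitly when call sets from heterogeneous
sources need to be keyed consistently. Full left-alignment across repeat
tracts would require the reference sequence, which is not among the
pipeline's inputs, and is deliberately out of scope. Multi-allelic sites are
decomposed into one record per alternate allele, preserving total
alternate-allele dosage; phased and unphased genotype separators are treated
identically.

## The replication association model

Replication genotyping yields per-variant genotype tallies for cases and
controls with varying denominators (genotyping missingness); tallies are
used as given and never renormalized. Genotypes are collapsed under the
dominant model: carrier = at least one alternate allele, non-carrier =
homozygous reference, missing excluded. For the 2x2 carrier table
(a = case carriers, b = case non-carriers, c = control carriers,
d = control non-carriers):

* **Test selection.** Pearson's chi-square without continuity correction,
  statistic `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 df, unless any
  expected cell count under independence is below 5, in which case the
  two-sided Fisher exact test (sum of hypergeometric probabilities of all
  tables with the observed margins no more probable than the observed one,
  with the conventional 1e-7 relative tolerance on the comparison) is used.
  The minimum-expected-count rule is the textbook criterion and is the only
  selection rule consistent with the mixed chi-square/Fisher p-values
  reported for this design's reference cohort; both branches are exercised
  and cross-checked against independent oracles (`stats::chisq.test`,
  `stats::fisher.test`, and exhaustive margin enumeration) in the tests.
* **Effect size.** Odds ratio `ad/bc` with the Woolf (log-normal) confidence
  interval `exp(log(OR) ± z sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell
  yields `NA` with a reason code rather than a continuity-corrected
  estimate: corrected estimates for tables this sparse are dominated by the
  correction, and no standard estimator reproduces published values for such
  rows anyway.
* **Carrier composition.** `100 a/(a+c)` (the percentage of carriers who are
  cases) and `100 b/(b+d)` — the pair quoted as the headline enrichment.
* **Significance.** The flag uses the raw p at alpha = 0.05, matching the
  fixed-candidate-list replication design, which by convention does not
  apply multiple-testing correction; Bonferroni- and Benjamini–Hochberg-
  adjusted p-values are emitted alongside for transparency but do not drive
  the flag.
* **Degeneracy.** Monomorphic variants and zero-margin tables degrade to
  `test_used = "not_available"` with a reason code; a batch never aborts on
  a row.

## The synthetic cohort generator

The generator emulates *post-calling* output — the deliverable of the
upstream read-QC/alignment/calling stack — at desk scale, with every random
draw funnelled through one mandatory seed (the ambient RNG state is saved
and restored, and equal seeds give byte-identical output files).

`simulate_families()` produces a cohort of `n_families` x
`members_per_family` affected index patients (default 12 x 2, the scale of
a family-based genome study; every sequenced member is an affected proband,
so all members are index patients). Planted variants are carried
heterozygously by every index patient of their designated family, with read
support drawn from a negative-binomial depth model (mean 30, the typical
depth of modern short-read genomes) and forced to satisfy the quality cut
with margin. Each background variant is assigned one of seven failure
modes — non-coding, low read support, synonymous, weakly conserved missense
(phyloP drawn in [0, 2.5]), carried by a single index patient, common in one
reference panel (frequency drawn log-uniformly in (0.002, 0.05]), or present
in-house — and passes every other predicate, with values drawn safely away
from the thresholds. The expected survivor set is therefore known *by
construction*, recorded in a truth manifest with per-variant failure
reasons, and for planted variants derived by direct predicate evaluation of
the configured annotation values (not by running the cascade). Reference
frequencies for passing variants follow a mixture of a point mass at
"absent" (probability 0.6) and a log-uniform draw capped at half the rarity
cut.

What the generator does *not* emulate: linkage disequilibrium, population
stratification, annotation error, genotyping error, read-level artifacts,
and unaffected relatives. Passing the recovery tests therefore demonstrates
that the cascade implements its predicates exactly — recall and precision
1.0 against the manifest — not that the predicates are robust to noisy
annotations on real data.

`simulate_replication()` draws per-subject carrier status: controls at
frequency `f`, cases at the probability implied by the configured odds ratio
`r` through the odds transform `p = r f / (1 - f + r f)`, making `r` the
estimand of the association module; genotyping missingness removes subjects
independently. Defaults (381/381 subjects, f = 2/381, r = 4.59) mirror the
replication scenario of a rare risk frameshift.

## Numerical and design choices

* Expected-count threshold 5, rarity cut 0.001 (strictly-greater removal),
  phyloP cut 3.0 (inclusive), quality cut 10/5/20% — all exposed as typed
  threshold objects and in the YAML run configuration, with these defaults.
* Missense with *missing* phyloP is excluded from "protein-altering" by
  default (conservative: an unannotated position cannot demonstrate
  conservation), with `missense_missing_phylop = "include"` as the override.
* The Fisher implementation sums `dhyper()` probabilities over the margin
  support; ties are compared with the conventional `1 + 1e-7` relative
  tolerance, the same rule as the enumeration oracle it is tested against
  (agreement to 1e-12 over every table with total <= 30 plus random tables
  up to total 200).
* Chi-square with a zero margin, odds ratios with a zero cell, and
  monomorphic tables all return `NA` with reason codes, never a fallback
  estimate.
* Test problem sizes: the recovery acceptance runs one 12-family x
  5,000-variant cohort plus two 500-variant cohorts; calibration uses
  10,000 null replicates (type-I error of the chi-square branch at
  carrier prevalence 0.10, where expected cell counts are comfortably
  adequate) and 2,000 replicates at true OR 4.59 and control carrier
  frequency 0.005 for Woolf coverage, evaluated among non-degenerate
  tables (about 85% of replicates; with expected control carrier counts
  near 2, the remainder have an empty cell and no Woolf interval).

## Limitations

* The cascade consumes annotations; it never computes them. Consequence
  classes, conservation scores, and panel frequencies are trusted as given.
* Sharing is defined on index patients only; unaffected relatives are not
  modelled, so segregation evidence beyond "all affected probands carry it"
  is out of scope.
* The association module fits the dominant collapsed model only — no
  additive/recessive coding, no covariate adjustment, no exact conditional
  odds-ratio estimation for zero-cell tables.
* Identifier normalization is reference-free (trimming only); call sets
  keyed against different left-alignment conventions should be normalized
  upstream.
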