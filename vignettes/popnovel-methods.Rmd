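---
title: "Methods: SNV quality control, novelty and ancestry projection in popnovel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNV quality control, novelty and ancestry projection in popnovel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

popnovel implements the downstream analysis of a small whole-genome
sequencing cohort: quality control of SNV calls guided by external truth
panels, determination of alleles that are novel relative to large reference
panels, functional characterisation of alleles against transcript models,
simple genome-wide summaries, and inference of sample ancestry by projection
onto a reference-population principal-component model. This vignette
describes the statistical machinery, the tunable parameters, the synthetic
data that the tests run on, and the numerical decisions taken where the
design was genuinely open.

## 1. Allele normalization

All panel comparison is exact matching on atomic, canonical alleles.
`split_multiallelic()` turns each multi-allele VCF record into one record per
alternative allele; a genotype carrying a *different* alternative allele
contributes 0 copies of the focal allele and is flagged (`other_alt`) rather
than treated as missing, because a call to another allele is still a call.
`left_align()` reduces every (ref, alt) pair to its minimal, leftmost
spelling: shared trailing bases are trimmed (prepending the previous
reference base when either allele would become empty), then shared leading
bases are trimmed while both alleles keep at least one base. The operation
is idempotent, and its output is position-minimal — the test suite verifies
this against an oracle that enumerates every equivalent spelling by string
substitution. We trim shared leading bases as well as trailing ones (full
minimal representation); both sides of every comparison pass through the
same normalizer, so the convention cannot cause spurious mismatches.

## 2. Quality control

Sites that cannot be assessed are removed first: QD absent, per-sample DP
zero everywhere, alternative-allele AD zero everywhere, or a non-autosomal
location. Remaining SNV records are classified **true** when any alt allele
has an exact normalized match in any truth panel, else **other**.

A filter rule is a boolean expression over the seven site metrics
(QD, MQ, MQRankSum, ReadPosRankSum, FS, SOR, DP). Each rule is scored by the
fraction of true sites kept, the fraction of other sites kept, and their
ratio — the **discrimination factor** (DF), the factor by which the filter
improves the true:other ratio. For sequential stages the overall ratio
increase is *exactly* the product of stage DFs; the suite asserts this
identity on random cohorts. Two threshold stages are packaged:

* `(MQRankSum > -2.5 & MQRankSum < 1 & QD > 7) | (QD > 0.5 & -0.01 < MQRankSum < 0.01)`
* `(MQ > 50) | (FS == 0 & MQ > 40)`

The written form "X and Y or Z and W" of such compound rules is read as
`(X and Y) or (Z and W)` — two alternative clauses — and user-supplied rules
must be fully parenthesized. A record missing a referenced metric fails the
rule (conservative), except that an absent FS is read as 0, since callers
omit FS where the phred-scaled strand-bias is exactly zero; both behaviours
are switches. `FS == 0` is exact equality on the parsed decimal value.

The final stage is a recalibration score. A K-component multivariate
Gaussian mixture (the *positive* model) is fitted by EM to the standardized
metrics (default DP, SOR, ReadPosRankSum, FS) of truth-matching sites; a
*negative* model of the same form is fitted to the 5% of all sites with the
lowest positive-model density. The score of a site is
$\log f_+(x) - \log f_-(x)$, a log-odds of resembling truth-matching versus
error-stratum sites, and sites below a threshold (default $-0.5$) are
removed. EM defaults: $K = 2$, up to 500 iterations, tolerance $10^{-6}$ on
the mean log-likelihood, diagonal covariance regularization $10^{-6}$,
k-means initialisation under a caller-supplied seed. The likelihood trace is
non-decreasing (asserted), and the fit is cross-checked against an
independent mixture implementation (mclust) in the tests. The negative-model
training fraction is a design choice — the upstream tool's exact selection
is undocumented — and is configurable.

## 3. Novelty

A reference panel is a set of normalized alleles with optional per-entry
pass/fail quality flags and optionally some chromosomes it does not cover.
A query allele is **known** only on an exact (chrom, pos, ref, alt) match to
a *qualifying* entry. By default a match to a quality-failed entry still
counts **novel** (`treat_fail_as = "novel"`): the panel's failed calls are
excluded, reducing the chance that a shared artefact masks a genuine novel
allele. Queries on a panel's missing chromosomes are **not_assessed**.
Site-level tallies separate positions entirely absent from the panel from
positions the panel knows but with a different allele; matching itself is
never position-only.

## 4. Functional characterisation

Each SNV allele is annotated against every overlapping or flanking
transcript and then reduced to a single class by a fixed precedence ladder:
exonic, splicing (first or last two bases of a coding transcript's intron),
ncRNA_exonic, ncRNA_splicing, UTR5, UTR3, intronic, ncRNA_intronic,
upstream, downstream, intergenic. Exonic and splicing share the top tier
conceptually; we rank exonic first within the tier so every allele gets a
unique class (configurable in principle, fixed here). Flank distance
defaults to 1000 bp, the conventional annotator default. For exonic alleles
the codon containing the substitution is translated before and after with
the standard genetic code (strand-aware complementing); effects resolve by
the ladder stop_gain, stop_loss, nonsynonymous, synonymous, unknown, with
`unknown` reserved for incomplete terminal codons. A whole-CDS retranslation
oracle (`effect_by_retranslation()`, built on Biostrings) provides the
independent check. Transcript models come from a 12-column, 1-based
refFlat-like table; only the standard genetic code is supported.

## 5. Spectra and densities

The allele-count spectrum counts, per allele, carried copies across all
sample genotypes (1..2N); any site with a missing genotype is excluded and
tallied, so spectra of disjoint allele subsets add exactly. Block densities
count SNV *sites* per fixed-size block; block $i$ (0-based) covers 1-based
positions $[i b + 1, (i+1) b]$ with $b$ = 10 Mb by default, so a position at
exactly one block size falls in the first block, and the final partial block
is included. Multiallelic sites contribute each allele to spectra but one
site to densities.

## 6. Ancestry projection

Reference-panel sites pass a cascade, in order: minor allele frequency
strictly above 5%; no other catalogued variant (SNV or indel) within 5 bp
— read inclusively, so a distance of exactly 5 bp excludes; an
accessibility mask; and a Hardy–Weinberg exact test at $p \ge 10^{-6}$.
The HWE test is the standard conditional enumeration of heterozygote counts
given allele counts, summing probabilities no larger than the observed
configuration (no mid-p); it is verified against full enumeration for all
tables with total $\le 30$. Query-side rules then shrink the *shared* site
list before any model is fitted, so model and query always see one list:
uncalled sites, sites whose query alt differs from the panel's, hom-ref
sites failing QUAL ≥ 30 / DP ≥ 10 / RGQ ≥ 20 for all samples, variant sites
failing DP ≥ 10 / GQ ≥ 20 for all samples, and sites within 5 bp of another
query variant are dropped. Two extended-LD regions
(chr6:25–35 Mb, chr8:7–14 Mb on real data) are excluded before pruning.

LD pruning removes, within sliding windows of 50 retained sites advancing
by 5, the site with the highest variance inflation factor
($\mathrm{VIF} = 1/(1-R^2)$ from regressing its genotypes on the window's
other retained sites) while any VIF exceeds 2, ties broken toward the lower
genomic position; passes repeat until no window changes, which makes
pruning idempotent and guarantees the bound over the retained sequence. The
reference tool's exact removal order is undocumented, so the contract we
test is the VIF bound itself, not a particular retained set. VIFs are read
off the inverse correlation matrix, with a per-column regression fallback
(perfectly predictable columns get `Inf`) when that matrix is singular.

Genotypes become 0/1/2 alternative-allele counts; the PCA is
`prcomp(center = TRUE, scale. = TRUE)` — columns centred and divided by
their (n−1) standard deviation — and queries are projected with the stored
means, scales and loadings, never refitted. Zero-variance sites are a
hard error by name (the MAF filter should have removed them); missing
reference genotypes, which only the synthetic data produces, are
mean-imputed before fitting. Two components are retained by default.

## 7. What the synthetic data emulates

The generator reproduces the *structure* of the study inputs with known
ground truth: a 3-sample cohort of 10,000 sites whose site metrics come from
class-conditional Gaussians (QD, MQ, FS, SOR, DP truncated at 0), with a
true-site share of 0.42 (a pre-QC true:other ratio near 0.72), 3% indels,
3% multiallelic sites, ~1% of sites with a missing genotype, and ~1–2%
planted prefilter deficiencies; two truth panels whose union is exactly the
true-labelled SNV set; a 1000G-like panel covering exactly 93% of eligible
cohort alleles (a planted 7% novel fraction) plus panel-only and
different-alt entries; a gnomAD-like panel with FILTER flags (5% fail) and
no chrY; a 200 kb toy chromosome with 24 transcripts and planted alleles of
every sequence class; and two Balding–Nichols populations
($F = 0.1$, 100 samples each, 5,000 sites, ancestral frequencies uniform on
[0.05, 0.95]) with five query samples admixed at
$\alpha \in \{0, 0.25, 0.5, 0.75, 1\}$ and planted site-selection and
query-side violations at ~0.1–1% rates.

The planted stop-gain enrichment in the novel stratum is 4-fold over the
all-allele rate, the qualitative effect of interest; the novel-stratum rate
is set to 5% rather than the ~1.5% seen on real exomes because at
desk-scale counts (320 novel exonic alleles) the smaller rate would leave
the recovered ratio statistically meaningless. Metric separation between
the true and error classes is likewise stronger than on real data so that
the packaged rules discriminate visibly at 10⁴ sites. The generator does
not emulate read-level data, realistic LD beyond window-local correlation,
allele-frequency spectra shaped by demography, or sequencing-batch
structure — so green tests demonstrate correctness of the machinery under
the stated models, not calibration on real cohorts.

All generators draw from seed-derived RNG streams and are byte-reproducible;
the pipeline writes a manifest of input/output digests, and a rerun with the
same inputs and seed is byte-identical (asserted).

## 8. Problem sizes and runtime

The shipped tests run the full pipeline at the default desk scale
(10,000-site cohort, ~1,900 planted gene-region alleles, 200 reference
samples × 5,000 sites) and the unit suites at 10²–10³; everything completes
in a few minutes on one CPU. Oracle suites use 500 random indels, 200 HWE
tables, 1,000 precedence multisets and 500 codon substitutions.

## 9. Known limitations

* Per-site (not per-allele) filtering in the QC cascade; INDEL quality
  control is out of scope (SNVs only, as in the underlying study design).
* The mixture score is an analogue of the upstream recalibration tool, not
  a bit-compatible reimplementation; likewise the annotator and pruner
  reproduce documented behaviour, not internals.
* Exact-match novelty cannot see alleles that differ only by representation
  conventions a third-party panel failed to normalize.
* BCF, structural variants and phased-genotype semantics beyond allele
  counting are unsupported.
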