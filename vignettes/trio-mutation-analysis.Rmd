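---
title: "Trio SNP transmission analysis: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio SNP transmission analysis: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`triosnp` analyses variant calls from a parent-offspring trio in which the
two parents come from strongly diverged populations or species — the
motivating case is a horse (mother) x donkey (father) cross producing a
mule — and asks, site by site, how each offspring genotype relates to the
parental genotypes. This vignette is the package's own account of the
method: the classification model and its assumptions, the filtering
cascade, the statistics reported, what the synthetic-data generator does
and does not emulate, and the design decisions taken where the design was
genuinely open.

## The inheritance-state model

At a biallelic or multiallelic SNP with diploid genotypes $G_m$ (mother),
$G_f$ (father) and $G_c$ (offspring), each genotype an unordered pair of
alleles, the site is placed in exactly one of three states:

* **Mendelian** — some choice of one allele from each parent reproduces
  $G_c$: $\exists\, a \in G_m,\ b \in G_f : \{a, b\} = G_c$.
* **Mendelian inheritance error (MIE)** — no such choice exists, but every
  allele of $G_c$ occurs in a single parent's genotype: the offspring
  received *both* alleles from one parent. The origin is that parent.
* **De novo** — $G_c$ contains an allele found in neither parent. This
  test takes precedence over the MIE test, so a site with a novel allele
  is never labelled MIE.

Sites with any missing genotype are *unclassified*, never guessed. A
useful consequence of the definitions (asserted as a property test
against an exhaustive transmission-enumeration oracle): whenever a site
is MIE, the origin parent is uniquely determined — at biallelic sites
provably so, and in practice at multiallelic sites too. The
`UNDETERMINED` origin code exists in the interface for completeness.

The model is deliberately site-wise. Haplotype-block smoothing of
inheritance states (the full state-machine treatment used in human trio
studies) and phasing are out of scope; each site is judged on its own
genotypes and read support.

## Two classifiers and their intersection

Trio studies commonly require non-Mendelian calls to be supported by two
independent routes before believing them. `triosnp` implements both
routes in-package:

1. **Genotype-based** (`classify_by_genotype`): the states above applied
   to the VCF `GT` fields.
2. **Read-based** (`genotype_from_reads`): genotypes are re-called from
   the per-allele read depths (`AD`), then classified the same way. An
   allele is called present when its frequency reaches `min_var_freq`
   (default 0.20) *and* a one-sided binomial test of its read count
   against a per-read base error rate (default 0.01) is significant at
   `p_value` (default 0.05). Sites with fewer than `min_coverage`
   (default 10) reads are uncallable. The two highest-frequency present
   alleles form the genotype; frequency ties break toward the reference
   allele, then lexicographically, so re-calling is deterministic.

A site is reported MIE or de novo only when both classifiers return the
same state (`reconcile_trio`). When the genotype-based call is
non-Mendelian but the read-based call disagrees, the samples whose
read-based genotype differs from their VCF genotype are re-called *once*
under relaxed thresholds (`adj_var_freq` 0.05, `adj_p_value` 0.15); the
re-call either confirms the call ("adjudicated") or the site resolves to
Mendelian/unclassified. The binomial test is a documented, testable
stand-in for the unspecified internal test of the pileup-based trio
callers this mirrors; the error rate is configurable.

Retained non-Mendelian calls must additionally pass read-support rules
(`apply_support_filters`): the offspring reads covering its genotype
alleles must total at least 10; a heterozygous offspring needs at least
5 reads per allele (a homozygote, 10 on its single allele); and each
parent must have site depth of at least `min_coverage`. The ten-read rule
is applied to the offspring only — the published wording does not say
which samples it covered, and the parental-depth knob covers the parents
separately.

## The site-filter cascade

Candidate SNPs pass through three independent filter families, each a
pure predicate; the verdict is the union of tripped filters, so
evaluation order cannot matter (a tested invariant, along with
monotonicity under threshold relaxation):

* **Hard filters** on site annotations, with strict inequalities exactly
  as conventionally printed: QUAL < 30, QD < 2.0, FS > 20.0, MQ < 20.0,
  MQRankSum < -3.0, ReadPosRankSum < -3.0, HaplotypeScore > 13.0. An
  absent annotation never trips its filter: rank-sum statistics are
  undefined at sites lacking both genotype classes, and discarding sites
  for missing metadata would bias the callable set.
* **SNP-cluster filter**: any 3 SNPs spanning at most 10 bp flag all
  members of the window (the behaviour of the cluster filter these
  parameters originate from).
* **Region and depth filters**: overlap with repeat/low-complexity and
  CNV mask tracks; positions within 50 bp of an indel anchor; positions
  within 13 bp of an assembly-gap edge; and a depth window requiring
  total depth in [4, 50] inclusive. The gap rule's published phrasing
  ("within 3 bp and adjacent 10 bp") is ambiguous; the conservative
  reading — a single 3 + 10 = 13 bp exclusion distance — is the default,
  with both distances configurable. The depth window is applied to all
  three samples by default for trio classification (`depth_mode =
  "all"`), because a mis-genotyped parent corrupts the trio call as
  surely as a mis-genotyped offspring; per-genome summary tables use the
  single-sample mode.

Masks are inputs (BED3), not computed: CNV and repeat discovery belong to
their own tools. Indel proximity is measured from a single anchor
coordinate per indel.

## Statistics

Per-genome summaries count heterozygous and homozygous-nonreference
biallelic SNPs, transitions (A↔G, C↔T) and transversions, and report
%SNP, %heterozygosity and Ti/Tv. Ratios and percentages are rounded
half-even to two decimals — R's native `round()` — which reproduces
published per-genome tables of this kind. Division by zero transversions
yields an explicitly absent ratio.

The de novo mutation rate is `n_denovo / callable_sites`, per haploid
reference site per generation, with no factor of two; `callable_sites`
is always an explicit input, never inferred, because the denominator
(reference length vs callable length) is the least-reported quantity in
trio studies and silently guessing it would make rates incomparable.
Fold comparisons against reference counts floor the quotient, matching
the "almost N times" convention of the literature they echo.

## Region annotation

SNPs are classified against GFF3 gene models with the precedence
exonic > UTR5 > UTR3 > intronic > ncRNA exonic > ncRNA intronic >
upstream > downstream > intergenic; when transcripts disagree the
highest-precedence label wins, as in precedence-based annotators.
"Exonic" means coding sequence; fine consequence classes (splice sites,
synonymous/missense) are deliberately collapsed into their parent
region. Upstream/downstream windows default to 1,000 bp (the common
annotator default; the motivating study names only its intergenic rule)
and are strand-aware. Intergenic SNPs are assigned their nearest gene(s)
only within 5,000 bp; farther sites carry no gene. Gene assignment lists
*every* gene whose feature produced the label, so a set of SNPs can map
to more genes than there are SNPs — the behaviour the "embraced by"
gene counts of such studies imply.

Internally all intervals are 1-based closed `IRanges`/`GRanges`, the
Bioconductor convention; BED's 0-based half-open coordinates are
converted exactly once at the format boundary, and `GRanges`
between-range distances are converted to positional base distances
(+1 bp) where proximity rules are defined positionally. Delegating
interval arithmetic to one well-tested container is the package's
defence against off-by-one drift.

## Enrichment

Gene-set over-representation uses the exact hypergeometric upper tail,
$P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$, per pathway, with
Benjamini–Hochberg adjustment across pathways. The universe defaults to
all genes in the supplied annotation (configurable to the pathway map's
own gene set); no significance threshold is hard-coded. Live pathway
database lookups are out of scope — the map is a two-column TSV input —
so published pathway counts, which are database-version-dependent, are
not reproduced.

## The synthetic trio generator

`simulate_trio` emulates the data regime the analysis assumes, with
ground truth:

* **Divergent parental densities.** Defaults place maternal variants at
  0.20% of sites (67% heterozygous) and paternal variants at 0.95% (8%
  heterozygous) — the structure of a cross in which the reference genome
  is of the maternal species, taken from the published per-genome SNP
  table of the motivating trio. The offspring receives one uniformly
  drawn allele from each parent, so its high heterozygosity is emergent,
  not configured.
* **Planted events.** MIE events (default rate 1e-4) force the donor
  parent to a homozygous alternate genotype and the other parent to
  homozygous reference, then copy the donor's pair into the offspring —
  a construction that is always a genuine violation. De novo events
  (default 2e-5) substitute one offspring allele with a base absent from
  both parents. Truth rows record event type and origin.
* **Reads.** Site depth is Poisson (default mean 30); allele depths are
  multinomial over the four bases with a per-read error channel (default
  0.01, uniform over wrong bases). QC annotations are drawn from
  pass-range distributions, with a configured fraction of sites
  (default 2%) given exactly one planted hard-filter violation.
* **Masks and annotation.** Random interval tracks at configured
  densities, three-exon gene models tiled along the chromosomes, and a
  random gene-to-pathway map, all in the exact formats the pipeline
  consumes.

What it does *not* emulate — and therefore what passing tests do not
show about real data: linkage and LD (sites are independent; the
SNP-cluster filter is exercised by explicitly planted cases), alignment
and mapping artefacts, reference bias, indel-realignment effects,
CNV-driven genotype misassignment (masks are random, not correlated with
genotypes), and realistic chromosome structure. The VCF carries the
*true* genotypes in `GT`; consequently classification errors measured
against truth isolate the read-based route's behaviour, and the
depth-degradation property (fidelity falls monotonically from 30x to
15x to 8x, driven by the 10-read coverage floor) is measured as
discrepancy from truth of the final intersected call.

Sites are laid on a regular 100-bp grid per chromosome, so the truth
table, mask tracks and gene models share a coordinate system without a
reference FASTA.

## Problem sizes and numerical choices

The validation suite runs the full pipeline on a 10^6-site simulated
trio at 30x (about 11,500 variant records), recovering planted events
and checking that the 95% binomial CI of the estimated de novo rate
covers the planted 2e-5; unit and property tests use 2e4–1e5 sites.
These sizes were chosen to give each property comfortable statistical
resolution (e.g. ~100 planted MIE and ~20 de novo events at the default
rates) while keeping a full check of the package quick on one CPU.

Determinism is treated as a contract: fixed seeds give byte-identical
simulator output and pipeline summaries (numeric formatting is fixed at
write time), and every tie in genotype re-calling breaks by a stated
rule. Degenerate inputs follow one principle — refuse to guess: missing
genotypes and missing AD yield unclassified calls with a recorded
reason, zero callable sites is a contract error, and zero transversions
make Ti/Tv absent rather than infinite.

## Known limitations

* Site-wise classification cannot separate germline from somatic or
  early-embryonic origin of de novo alleles; no such inference is
  attempted.
* Sex chromosomes are excluded; the autosome set is configuration.
* Multiallelic sites are classified on the full allele set without
  decomposition; allele-specific QC annotations are not modelled.
* Half-missing genotypes (one known allele) are treated as fully
  missing — a conservative reading where conventions differ.
* One arithmetic footnote: in the motivating study's printed region
  distribution, the 5' UTR percentage implied by its own count and total
  (149 / 26,258) is 0.57%, not the printed 0.58%; `distribution_report`
  reports the arithmetically consistent value. Its printed category
  counts also sum to 14 fewer than the stated total, which is why the
  report accepts an explicit percentage denominator.
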