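---
title: "Characterizing dual 6mA/5mC methylomes with sixmac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing dual 6mA/5mC methylomes with sixmac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Some fungal genomes — most prominently several early-diverging lineages —
carry substantial N6-methyladenine (6mA) alongside 5-methylcytosine (5mC),
and the two marks occupy complementary territories: 6mA concentrates in
dense clusters just downstream of transcription start sites of active genes,
while 5mC concentrates in repeats and silenced genes. Species differ
sharply in how they use 6mA. One extreme ("high/symmetric/clustered") has
on the order of 1% of adenines methylated, almost all of them as
*symmetric* ApT pairs — the dinucleotide 5'-AT-3' is its own reverse
complement, so it carries an adenine on each strand and both can be
methylated — organized into methylated adenine clusters (MACs) of roughly
50–500 bp. The other extreme ("low/asymmetric/scattered") has a few tenths
of a percent of adenines methylated, almost entirely on one strand, spread
over the genome with a characteristic A-rich flanking context
(AAA\_CA-like) and intermediate per-site methylation ratios.

`sixmac` implements the full downstream characterization of such dual
methylomes from standard files (FASTA, GFF3, BED, per-site modification
calls, a CX-style bisulfite report, expression tables), plus a seeded
simulator that generates complete synthetic methylomes in either regime so
every stage can be tested against a known truth.

# Site filtering and symmetry

Single-molecule 6mA calls carry a coverage and a modification quality value
(mQv). The default filter keeps sites with coverage ≥ 15 and mQv strictly
greater than 25; a relaxed policy (≥ 5x, mQv > 20) is conventional for
shallow samples and available through the same arguments. Sites without an
mQv (simulated data) pass the quality check by default, so synthetic
fixtures are first-class inputs.

Symmetry is defined only at ApT dinucleotides: for the plus-strand A at
position *i*, the opposing minus-strand A sits at *i + 1*. A pair with both
adenines called after filtering is symmetric; one-sided pairs are
hemimethylated; every methylated adenine not in an ApT is asymmetric by
construction. Whether truly opposed non-ApT adenine pairs should ever count
as symmetric is left restricted — there is no physically opposed adenine
outside ApT, so the restriction is a definition rather than an
approximation. The summary statistic `fraction_symmetric` is the fraction
of *sites* (not pairs) that belong to symmetric pairs.

Flanking contexts are summarized by extracting ± 6 nt around each site
(reverse-complemented for minus-strand sites so the methylated A is always
the center column), column-normalizing the position frequency matrix, and
reporting an IUPAC consensus in which a base enters a column's code when
its frequency is at least 0.25. The 0.25 threshold is a deterministic
replacement for motif discovery by expectation-maximization: it reproduces
degenerate one-letter codes (V, B, W…) on realistic compositions while
staying exactly reproducible.

# MAC detection: the distance scan

The clustering substrate is the track of AT-dinucleotide occurrences,
enumerated left-to-right on the plus strand (AT cannot overlap itself; for
other motifs the same non-overlapping scan rule applies). An occurrence is
methylated when either of its adenines carries a filtered site. A cluster
at relative distance *d* is a maximal chain of methylated occurrences in
which consecutive methylated occurrences are separated by at most *d*
unmethylated occurrences — the distance is counted in motif occurrences,
not base pairs, so AT-free stretches do not break clusters. A single
methylated motif is not a cluster (minimum 2); the stricter ≥ 10 threshold
is applied only when selecting densely methylated genes for term
enrichment.

Each *d* in 1…40 is scored as `recall(d) × purity(d)`, a
density-times-efficiency criterion:

* **recall** — the fraction of methylated motifs genome-wide captured into
  clusters; non-decreasing in *d* (this monotonicity is asserted exactly in
  the tests);
* **purity** — the pooled fraction of motif occurrences inside cluster
  spans that are methylated; this penalizes absorbing unmethylated motifs.

The two move in opposite directions, so the product has a well-defined
optimum; ties break toward the smallest *d* (the more conservative
clustering). The exact formula of the original "density × efficiency"
procedure is not restated in the literature this mirrors, so the scoring
function is a documented choice: the per-`d` table (recall, purity, score,
cluster count) is always retained and exported so alternative definitions
can be audited against it. On the canonical six-occurrence example
(M,U,M,U,U,M) the score is 4/9 at *d* = 1 and 1/2 at *d* ≥ 2, selecting
*d\** = 2.

The 50–500 bp size convention is annotated on each MAC but never enforced:
it is an observed property of MACs, not part of their definition.

# Genomic context

Every base is labeled with exactly one feature class using the precedence
exon > UTR > intron > repeat > promoter > intergenic; promoters are the
600 bp upstream of each TSS, truncated at contig edges; everything left is
intergenic. Gene structure outranks repeats because the two are treated as
disjoint tracks in this style of analysis. Note that in standard GFF3,
exons cover the UTRs, so the UTR classes are only populated by annotations
that provide UTRs disjoint from exons.

Enrichment is observed/expected with a *composition-aware* null: the
expected count of a class is the total site count scaled by the class's
share of eligible bases — adenines on both strands for 6mA,
context-matching cytosines for 5mC. A length-based null would conflate
base composition with methylation preference; composition-aware expectation
is the defensible null for a base-specific modification. Classes with zero
eligible bases are reported as undefined rather than infinite. Observed and
expected totals both sum to the number of sites, an invariant the tests
assert to 1e-9.

Metagene profiles scale each element's body to a common length (1.5 kb for
genes, 3 kb for transposon-style elements), divide it into equal bins (60
body bins by default), and add unscaled flanks (0.5 kb/20 bins for genes,
3 kb/60 bins for elements); minus-strand elements are orientation-flipped
before averaging. The per-bin value is the site count per bp averaged over
elements (the frequency reading) or the read-pooled weighted methylation
level (for bisulfite data); both are supported because published legends do
not always distinguish them, with counts as the default. TSS windows for
site/MAC-gene association are the strand-oriented interval −150/+400 bp,
closed at both ends (the boundary convention is not fixed by the analyses
this mirrors; closed bounds are the documented choice).

# Weighted 5mC

The weighted methylation level pools reads before dividing: total
methylated reads over total reads, per context (CG/CHG/CHH, classified by
the next two bases on the cytosine's own strand) and overall. Under equal
per-site coverage this equals the arithmetic mean of per-site ratios
exactly, and it is invariant to splitting or merging sites with the same
counts — both identities are asserted in the tests. The (≥ 5x, ≥ 10%)
filter defines *methylated sites* for counting and association analyses
only; pooled levels always use all covered cytosines, because filtering
before pooling would inflate levels. Cytosines within 2 bp of a contig end
on their strand have a truncated context and are excluded from context
totals.

# Expression integration

Genes are ranked by abundance (ties broken by gene id, so the
stratification is deterministic and invariant to monotone transforms of
abundance) and cut into rank quartiles, Q1 highest; zero-abundance genes
are flagged silent and sort last. Top-*n* and bottom-*n* sets (default
400) support the association analyses. Between two conditions, MAC gain
and loss are presence-based per TSS window: overlapping-but-shifted MACs
count as stable. Per-site methylation-ratio shifts match sites across
conditions by (contig, position, strand) within the windows of each
differential-expression set and compare the fold-ratio distributions of
up- vs down-regulated sets with a two-tailed Welch test (via
`stats::t.test`; the test suite checks it against the closed-form
Welch–Satterthwaite formulas to 1e-6). Whether the published ratio is
per-site or per-gene is ambiguous; per-site is the default and the
per-gene count ratio is available via `per = "gene"`. Term enrichment is a
one-sided Fisher exact test through the hypergeometric tail, flagged at
p < 0.05 with no multiple-testing correction by default (Benjamini–
Hochberg optional), matching common practice in this literature.

# The simulator and what passing tests mean

`simulate_methylome()` generates, under one seed: an i.i.d. genome at a
target GC (0.40 by default), non-overlapping gene models with 1–5 exons and
interspersed repeats, a log-normal expression table, per-site 6mA calls in
one of the two regimes, and a binomial-read bisulfite report. The defaults
are the study conditions:

* geometry: 1 contig × 500 kb, 200 genes, 50 repeats — small enough for a
  laptop-scale test run, large enough for ~3,300 sites and ~80 clusters in
  the symmetric regime;
* symmetric regime: 1.1% post-filter global level, 92% symmetric sites,
  92% of sites in clusters, cluster spans 50–500 bp starting within 150 bp
  downstream of the TSS, planted preferentially into highly expressed genes
  (selection probabilities 0.7/0.5/0.3/0.1 by expression quartile, with
  further genes drafted if the site budget requires); per-site ratios
  Beta(60, 2), i.e. near 1;
* asymmetric regime: 0.26% global level, 0.3% symmetric, sites placed by a
  position-weight model over the ± 3 flank favoring the AAA\_CA-like
  context (a weight model rather than exact motif placement, so the
  consensus comes out degenerate as in real data); ratios Beta(20, 20);
* coverage negative binomial (mean 30, size 5) and mQv normal (40, 4),
  drawn once per locus and shared by the two strands of an ApT pair —
  local sequencing depth is shared between strands in real data, and this
  is what makes the symmetric fraction invariant under filtering.

Two generator choices deserve emphasis. First, the generator targets the
*post-filter* level: it knows the filter policy and plants
1/P(pass) ≈ 1.14× more sites, so the statistic the pipeline actually
computes lands on the target. Second, planted clusters are *dense runs*
(85% of consecutive methylated motifs adjacent, 15% separated by one
unmethylated motif, and at least 5 methylated motifs per cluster). This is
deliberate: under the 15x filter about 12.6% of loci drop out, and a
dropped locus inside a cluster with internal gap *g* opens a gap of
2*g* + 1 occurrences — always beyond the selected distance when gaps are
wide, which would fragment clusters no matter how good the clustering is.
Dense clusters degrade gracefully (a dropped locus opens a gap of one
motif, bridged at any *d* ≥ 1), so parameter recovery measures the
clustering procedure rather than an artifact of the gap model. For the
same reason the recovery tests compare detected MAC spans against the
*detectable* truth span of each cluster — the planted loci that survive
the filter — and tolerate span-exact failure for a small minority of
clusters (edge loci lost to dropout); both the planted and detectable
spans are recorded in the truth bundle.

What the simulator does **not** emulate: sequencing-error and kinetic
models behind the modification calls, mappability structure, copy-number
variation, TE families with internal structure, correlated coverage along
the genome, or biological replicates. Passing the recovery tests shows the
pipeline's statistics are consistent and its estimators unbiased under the
stated generative model — not that the platform-level calling upstream of
this package is accurate.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout (the Biostrings/
  GenomicRanges convention); BED output converts to 0-based half-open at
  the boundary.
* Fraction-to-count conversion uses round-half-even (R's `round`), which
  is deterministic and unbiased.
* The isoschizomer digest (DpnI cuts methylated GATC, DpnII unmethylated)
  places the cut at the palindromic center of GATC, between A and T — the
  blunt cut DpnI makes — which is also the only offset under which the
  fragment-length multiset is invariant when the genome is
  reverse-complemented; the figure-level contrast depends only on fragment
  sizes, not the offset.
* Scan ties break toward the smallest distance; quartile ties break by
  gene id; filter bounds are inclusive on coverage and ratio, strict on
  mQv — each convention is asserted at its boundary in the tests.
* Empty subsets yield missing values, never zeros: a weighted level with
  zero reads is NA, a Welch test with fewer than two matched sites is NA,
  constant samples (which `t.test` refuses) yield t = 0, p = 1 when the
  means agree.
* Rows of a site table not at an adenine on the stated strand are rejected
  and counted; more than max(10, 1%) rejected rows aborts, since that
  pattern almost always means a 0-based file was declared 1-based.

# Problem sizes and runtime

The shipped tests run the full pipeline on 500 kb single-contig genomes
(about 3,300 6mA sites and 200 k cytosines), and the oracle-equivalence
check covers 200 random tracks of up to 200 occurrences at every distance
in 1…40. These sizes keep the whole suite in a few minutes on one CPU
while leaving every statistic well inside its sampling tolerance; all of
them are configurable upward.

# Known limitations

* Symmetry is ApT-only by definition; organisms with opposed methylation
  in other contexts would need a generalized pairing rule.
* The density-times-efficiency score is one defensible reading of an
  under-specified procedure; the exported per-distance table is the audit
  trail for alternatives.
* Gene models use each gene's first mRNA; alternative isoforms are not
  reconciled.
* The mQv scale is platform-defined; the filter treats it as an opaque
  number and the simulator's normal model is a placeholder calibrated only
  in the sense of exercising the threshold.
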