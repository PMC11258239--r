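# sixmac

Characterization of dual DNA methylomes — N6-methyladenine (6mA) and
5-methylcytosine (5mC) — for fungal-scale genomes.

Several early-diverging fungal lineages use 6mA as a major epigenetic mark
and differ sharply in *how* they use it. At one extreme, about 1% of all
adenines are methylated, almost entirely as **symmetric ApT pairs** (the
dinucleotide 5'-AT-3' is its own reverse complement, so it carries one
adenine per strand and both can be methylated), concentrated in
**methylated adenine clusters (MACs)** of ~50–500 bp just downstream of
the TSS of highly expressed genes, while 5mC is confined to repeats in the
CG context. At the other extreme, only ~0.2–0.3% of adenines are
methylated, almost all on a single strand, scattered genome-wide with an
AAA\_CA-like flanking context and per-site methylation ratios near 0.5.
`sixmac` is a tidyverse-style toolkit for the complete downstream analysis
of such methylomes, for anyone working from per-site modification calls,
bisulfite reports and expression tables.

## What it computes

* **Site classification** — coverage/mQv filtering (default ≥15x, mQv > 25),
  strand-symmetry classification at ApT dinucleotides, ±6 nt context
  position-frequency matrices with IUPAC consensus, the global 6mA level
  (% of adenines on both strands), an in-silico DpnI/DpnII digest, and
  telomeric-repeat search ((TTAGGG)₂ on each strand).
* **MAC detection** — clustering of methylated AT motifs at a relative
  distance *d* (unmethylated motifs allowed between methylated ones),
  scored over *d* = 1…40 as `recall(d) × purity(d)`: recall is the
  fraction of methylated motifs captured into clusters and purity the
  fraction of motif occurrences inside cluster spans that are methylated.
  The optimal distance d\* maximizes the score (ties toward smaller *d*).
* **Genomic context** — a total feature partition (exon/UTR/intron/repeat/
  promoter/intergenic, promoter = 600 bp upstream of the TSS),
  composition-aware observed/expected enrichment (log₂FC), scaled metagene
  profiles, and −150/+400 bp TSS-window site/MAC counts.
* **5mC** — CG/CHG/CHH context assignment, read-pooled weighted
  methylation levels, the ≥5x/≥10% methylated-site filter, per-context
  element metaplots.
* **Expression integration** — expression quartiles and top/bottom-*n*
  sets, per-stratum MAC association, MAC gain/loss between conditions,
  per-site methylation-ratio shifts with two-tailed Welch tests, and
  one-sided Fisher term enrichment.
* **Simulation** — `simulate_methylome()` emits a complete synthetic
  methylome (FASTA, GFF3, repeat BED, site table, CX report, expression
  table) in either regime, with a truth bundle, fully deterministic under
  a seed.

## Worked example

Simulate a high/symmetric/clustered methylome (500 kb, 200 genes) and run
the full characterization:

```r
library(sixmac)

sim <- simulate_methylome("symmetric_clustered", seed = 1)
run <- characterize_methylome(sim$genome, sim$genes, sim$sites,
                              repeats    = sim$repeats,
                              cytosines  = sim$cytosines,
                              expression = sim$expression)
run
#> <methylome_characterization>
#> # A tibble: 1 × 9
#>   n_sites global_level_pct fraction_symmetric fraction_apt consensus     d_star
#>     <int>            <dbl>              <dbl>        <dbl> <chr>          <int>
#> 1    3282             1.09              0.920        0.920 WWWWWWATWWWWW      1
#> # i 3 more variables: n_macs <int>, fraction_in_macs <dbl>,
#> #   weighted_cg_level <dbl>
```

3,282 sites pass the filter; 1.09% of adenines are methylated, 92.0% of
sites sit in symmetric ApT pairs (hence the central `AT` of the consensus,
flanked by W = A/T background), and the distance scan selected d\* = 1:

```r
tidy(run$macs$scan)[1:4, ]
#>   d n_clusters recall purity score
#> 1 1        130  0.995  0.841 0.836
#> 2 2         85  0.998  0.797 0.795
#> 3 3         75  1.000  0.781 0.781
#> 4 4         71  1.000  0.775 0.775
```

At d\* = 1 the 130 MACs capture 99.5% of methylated motifs at 84% purity;
91.5% of all sites fall inside MAC spans (the planted target was 92%).
The 5mC side shows the repeat-concentrated CG methylation the regime
plants:

```r
weighted_methylation(sim$cytosines, regions = sim$repeats)
#>   context n_sites meth_reads total_reads level
#> 1      CG    1528      37180       46354 0.802
#> 2     CHG    1221       3698       36345 0.102
#> 3     CHH    4858      44105      146211 0.302
#> 4     all    7607      84983      228910 0.371
```

Each result type has `tidy()`/`glance()` methods and an `autoplot()`
(distance scan, metagene profile, enrichment, motif summary, Watson-vs-
Crick symmetry scatter). `compare_methylomes()` labels per-gene MAC
gain/loss between two runs and tests ratio shifts in DEG sets.

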