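# overlapfilter

Quality filtering for Illumina paired-end amplicon libraries in which both
mates span the entire insert — e.g. the ~62-nt V6 region of the bacterial
16S rRNA gene sequenced with 2×101-cycle runs — so that every base between
the primer sites is read twice, from opposite strands.

Machine-reported Phred scores are estimates, and when they are
miscalibrated, Q-score-based filters confidently pass erroneous reads;
after clustering, those errors surface as spurious OTUs. The
**complete-overlap filter** implemented here uses no Q-scores at all: a
pair is kept only if the regions between the primer anchors of the two
reads agree at 100% identity with no ambiguous base. For a pair to retain
a random sequencing error, both mates must err at the same position with
complementary changes — probability *e²/3* per position at per-base error
rate *e*. The price is throughput: the retained ~62 nt are ~30.7% of a
2×101-nt pair's bases, and only passed pairs count.

The package provides, as tidy tibble-in/tibble-out functions:

* CASAVA ≥1.8 FASTQ I/O with strict pair synchronization
  (`read_fastq_pairs()`, `write_fastq()`), Phred+33 only;
* the amplicon-design model — inline barcodes, degenerate proximal
  consensus (IUPAC), distal primer, 40-nt/30-nt search windows — with
  degenerate matching and exact-prefix demultiplexing
  (`amplicon_design()`, `find_proximal()`, `find_distal()`,
  `demultiplex()`);
* the complete-overlap filter (`filter_overlap()`) with a full failure
  ledger (`tally_filter()`), and the two classical Q-score filters it is
  benchmarked against (`filter_qscore()`): run-length quality trimming
  with a length-ratio test, and B-tail removal with a first-half Q30
  criterion, both with the published default parameters and the
  either-mate-fails-discard-both pair rule;
* greedy 97%-identity OTU clustering with minimum cluster size 2 and an
  equal-depth subsampling comparison protocol (`cluster_greedy()`,
  `subsample_compare()`, `compare_otus()`);
* a synthetic paired-read simulator with controllable error structure —
  position ramps, N calls, B-tails, Q-score miscalibration, and recurrent
  cycle-specific miscall hotspots — that writes ground truth alongside
  the reads (`simulate_pairs()`, `scenario_miscalibrated()`);
* reporting: three-way Venn partitions of pair fates, per-position mean
  quality by fate region, pass-ratio tables, relative OTU plots, and the
  information-retention arithmetic (`venn_partition()`,
  `quality_by_fate()`, `pass_ratio_table()`, `information_fraction()`),
  each with `autoplot()`/`tidy()`/`glance()` methods;
* a command-line front end (`inst/scripts/overlapfilter.R`) with
  `simulate`, `filter`, `cluster` and `compare` subcommands.

See the methods vignette
(`vignettes/complete-overlap-filtering.Rmd`) for the model, the parameter
semantics and the design decisions.

## Worked example

Simulate a miscalibrated run (1% true substitution rate, reported Q≈38,
three recurrent read-1 miscall hotspots), run all three filters, and
compare OTU yields at equal depth:

```r
library(overlapfilter)

design <- example_design()                      # synthetic 12-barcode design
pool   <- generate_templates(10, seed = 42, design = design)
pairs  <- simulate_pairs(pool, design, 2000, scenario_miscalibrated(), seed = 43)

cmp <- compare_filters(pairs, design)
cmp
#> <filter_comparison> 2000 pairs: overlap 7.4%, bokulich 81.5%, minoche 81.5% passed

venn_partition(cmp)
#> # A tibble: 8 × 4
#>   overlap bokulich minoche     n
#> * <lgl>   <lgl>    <lgl>   <int>
#> 1 TRUE    TRUE     TRUE      147
#> 2 TRUE    TRUE     FALSE       0
#> 3 TRUE    FALSE    TRUE        0
#> 4 TRUE    FALSE    FALSE       1
#> 5 FALSE   TRUE     TRUE     1484
#> 6 FALSE   TRUE     FALSE       0
#> 7 FALSE   FALSE    TRUE        0
#> 8 FALSE   FALSE    FALSE     368
```

Both Q-score filters accept 1,484 pairs that the overlap filter rejects:
their reported scores sit at Q36–40, but at a 1% true error rate most
pairs carry at least one inter-primer discordance. Clustering each
method's output after subsampling to the overlap filter's depth:

```r
glance(compare_otus(cmp, replicates = 5, seed = 44))
#> # A tibble: 3 × 6
#>   method   mean_otus ratio depth replicates threshold
#>   <chr>        <dbl> <dbl> <int>      <int>     <dbl>
#> 1 bokulich      12.4 1       148          5      0.97
#> 2 minoche       11.8 0.952   148          5      0.97
#> 3 overlap       10    0.806   148          5      0.97
```

Ten templates went in; the overlap-filtered reads recover exactly those
ten OTUs, while the Q-score-filtered reads add spurious clusters founded
by recurrent miscalls. The failure ledger accounts for every pair by
sample, reason and read direction:

```r
head(tally_filter(filter_overlap(pairs, design), by = "truth_sample"), 4)
#> # A tibble: 4 × 5
#>   sample reason       direction     n n_with_N
#>   <chr>  <chr>        <chr>     <int>    <int>
#> 1 S01    MISMATCH     <NA>         97       13
#> 2 S01    NO_BARCODE   <NA>          1        0
#> 3 S01    NO_DISTAL_R1 R1            6        2
#> 4 S01    NO_DISTAL_R2 R2            8        0
```

And the throughput arithmetic for a published-scale run (3,683,211 pairs
sequenced, 2,707,801 passing, ~62 nt retained from 2×101 nt):

```r
information_fraction(3683211, 2707801, read_len = 101, trimmed_len = 62)
#> # A tibble: 1 × 2
#>   per_pair_pct dataset_pct
#>          <dbl>       <dbl>
#> 1         30.7        22.6
```

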