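---
title: "Complete-overlap quality filtering: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complete-overlap quality filtering: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overlapfilter)
```

## The problem

Amplicon surveys of microbial communities cluster short marker-gene reads
(here, the ~62-nt V6 hypervariable region of the bacterial 16S rRNA gene)
into operational taxonomic units (OTUs) at a fixed identity threshold.
Random sequencing errors inflate OTU counts: at a 97% threshold on a 62-nt
read, two substitutions are enough to found a spurious cluster. The usual
defence is filtering on machine-reported Phred quality scores, but reported
Q-scores are calibrated estimates, not measurements — when they overstate
basecall accuracy, Q-score filters confidently pass reads that are wrong.

When the sequencing library is designed so that **both mates of a paired-end
run span the entire insert** — e.g. a ~105-nt amplicon sequenced with 2x101
cycles — every inter-primer base is read twice, from opposite strands, by
independent basecalls. Demanding 100% agreement between the two reads is
then a quality filter that owes nothing to Q-scores.

## The filter

For each pair, with a design giving an inline 5' barcode on read 1, a
proximal primer whose degenerate consensus 10-mer anchors the start of the
biological region, and a distal primer whose first 6 nt anchor the end:

1. Reverse-complement read 2.
2. Search for the distal 6-mer within the **last 30 nt** of read 1 and of
   the reverse-complemented read 2; if either read misses, discard the pair
   (`NO_DISTAL_R1` / `NO_DISTAL_R2`).
3. Search for a degenerate match of the proximal 10-mer starting within the
   **first 40 nt** of both; discard on a miss (`NO_PROXIMAL_*`).
4. Extract from each read the region strictly between the two matched
   anchors; this removes barcode plus proximal primer and the distal primer.
5. If the two extractions differ in length, discard
   (`LENGTH_DISAGREEMENT`): the comparison is strictly positional, and an
   indel in either read has no rescue path.
6. Compare position by position. Any differing position, or any position
   where either read reports N, is a discordance; one discordance discards
   the pair (`MISMATCH`). N is never accepted even when both reads agree on
   it — "100% consensus" means consensus between basecalls, and N is the
   absence of one.
7. Demultiplex the read-1 prefix before the proximal anchor against the
   barcode table by exact equality (`NO_BARCODE` on failure); otherwise the
   pair passes, and the retained sequence and qualities are taken from
   read 1 (the bases are identical between mates at this point).

A random sequencing error survives this filter only if both mates err at
the same position with complementary base changes, so that they agree on
the same wrong sense-strand base. At per-base error rate $e$ the
probability per position is $e^2/3$ (`prob_coincident_error()`); at
$e = 10^{-3}$ that is one residual error per ~3 million read-positions.
The filter cannot, by construction, remove errors introduced before
sequencing (PCR substitutions and chimeras are faithfully present in both
strands), and it spends throughput aggressively: a ~62-nt region retained
from a 2x101-nt pair keeps ~30.7% of the pair's bases, less after
multiplying by the pass rate (`information_fraction()`).

## Windows, anchors, tie-breaks

The anchor searches are start-anchored: "within the last 30 nt" means the
match must *start* at position $\ge L - 29$ (1-based), "within the first
40 nt" that it must start at position $\le 40$, even if the 10-mer extends
to position 49. Multiple in-window occurrences resolve to the leftmost,
which maximises the retained region and makes the procedure deterministic.
In the read, N matches no pattern position, degenerate or not. Trim
coordinates anchor on the *matched k-mers*: the retained interval runs from
the end of the proximal 10-mer to the base before the distal 6-mer, so with
a 10-nt consensus (the packaged default) the output is exactly the
inter-primer insert; a longer consensus leaves its tail in the output.
Barcode matching is exact — the protocol reports no error-tolerant barcode
recovery — and barcode lengths may differ, because demultiplexing keys off
the proximal anchor position rather than a fixed offset.

The packaged design (`example_design()`) is **synthetic**: the real
four-primer proximal cocktail is not reproduced in the source text, so the
package ships a degenerate 10-mer with exactly four concrete expansions
(mirroring a four-primer mixture) and twelve 8-nt barcodes, and real data
require the user's own design file.

## The comparison filters

Two Q-score filters are implemented exactly as used for benchmarking, each
applied independently to both mates with the pair discarded if either mate
fails:

* **Run-length trimming ("bokulich")** — truncate at the first run of
  $r = 3$ consecutive bases scoring strictly below $q = 3$; pass if the
  trimmed read keeps $\ge p = 0.75$ of its length and contains at most
  $n = 0$ ambiguous bases. Thresholds are strict inequalities, read
  literally from their definitions; trimming is a single left-to-right
  pass with no re-evaluation.
* **B-tail + first-half Q30 ("minoche")** — strip the maximal suffix of
  bases at quality $\le 2$ (the Illumina B-glyph marks Q2); pass if the
  trimmed read keeps $\ge p = 0.75$ of its length, contains no N, and at
  least two-thirds of the bases in its first half (``floor(length/2)``,
  minimum 1; required count rounded up) score strictly above Q30. Only the
  restated criteria are implemented — the original publication's further
  rules are out of scope, since the benchmark's results reflect exactly
  this restatement.

## Clustering and the comparison protocol

`cluster_greedy()` is abundance-sorted greedy centroid clustering:
dereplicate, order unique sequences by abundance (lexicographic
tie-break, so input order is irrelevant), assign each to the first founded
representative at identity $\ge$ threshold (default 0.97) else found a new
cluster, and drop clusters below `min_size = 2`. Identity is
$1 - d_\mathrm{edit}/\max(|a|,|b|)$ (edit distance via `utils::adist`),
which reduces to the substitution fraction for equal-length reads and
keeps variable-length trimmed reads comparable. This is a deliberate,
documented approximation of the UCLUST-style clustering used in practice,
not a re-implementation of its k-mer heuristics: the quantity the package
reports — *relative* OTU inflation across filters — depends on greedy
threshold clustering generically.

Because the overlap filter keeps the fewest reads, OTU counts are compared
at equal depth: `subsample_compare()` subsamples every method's read list
to the smallest method's depth, 5 times, clusters each subsample and
reports per-method means, normalised so the largest mean is 1.0. Random
streams derive from (seed, method index, replicate index), so adding a
method never perturbs another's subsamples; a method already at minimum
depth is clustered once (subsampling it is the identity).

## The read simulator

`simulate_pairs()` assembles, per pair, `barcode + proximal realization +
template + distal primer + adaptor` and reads 101 nt from each end.
Templates come from `generate_templates()`: one random ancestor, $n-1$
derivatives at a fixed substitution divergence (default 5%, i.e. 4
substitutions on a 62-mer), Fisher log-series abundances. The geometry
requires both mates to span the construct (construct length between
`read_len` and `read_len + barcode length`); the packaged defaults
(8-nt barcode, 10-nt proximal, 60-65-nt templates, 17-nt distal, 8-nt
adaptor) satisfy this as the real library design did.

Two structural guarantees are enforced by rejection sampling rather than
hoped for: templates never contain the distal anchor internally (in real
amplicons the primer sites are conserved *flanks*, not inter-primer
sequence), and each assembled construct is validated so its error-free
reads anchor both primers exactly at their true positions. Zero-error
pairs therefore pass the filter *by construction*, which is what makes the
round-trip acceptance property a test of the filter rather than of the
simulator's luck. For the same reason the substitution injectors redraw
any mutation that would recreate a primer motif and move an anchor.

The error model is:

| knob | default | meaning |
|---|---|---|
| `base_error_rate` | 0.001 | per-base substitution probability, uniform over the 3 alternatives |
| `ramp_slope` | 5e-5 | additive per-cycle increase toward the 3' end (capped at 0.75) |
| `n_rate` | 5e-4 | probability a call becomes N |
| `btail_prob`, `btail_length_range` | 0.05, 5-25 | Q2 suffix on read 2 (quality markdown only; bases untouched) |
| `miscalibration` | off | reported Q drawn from 36-40 (mean ~38) regardless of the error process; otherwise Q is the Phred transform of the modelled error probability, capped at 40 |
| `n_hotspots`, `hotspot_rate` | 0, 0.3 | cycle-specific systematic miscalls (below) |

**Why hotspots exist.** With purely independent uniform errors, a read
carrying two or more substitutions is almost surely unique, so it forms a
singleton cluster and the `min_size = 2` cut removes it: at desk-scale
depths, independent errors cannot inflate OTU counts no matter how many
reads are simulated. Real Illumina runs are not like that — miscalls recur
at specific cycles with preferred substitutions, and reads sharing a
recurrent double miscall form spurious clusters of size $\ge 2$. The
hotspot component models exactly this: `n_hotspots` fixed read-1 cycles
that, with probability `hotspot_rate` per read, replace the base with a
fixed per-hotspot target. The overlap filter rejects these reads (the
mate, sequenced at different cycles, does not reproduce the miscall);
Q-score filters pass them whenever reported scores are high.

`scenario_miscalibrated()` packages the study condition used throughout
the tests and the acceptance script: flat 1% substitution rate, reported
Q approximately 38, N rate 0.001, 5% B-tails, and 3 read-1 hotspots firing in 30% of
reads. All problem sizes were fixed once: 10,000 zero-error pairs for the
round trip, 1,000 single-substitution pairs, and three independent runs of
6,000 pairs for the miscalibrated comparison — sized so that, at the
subsampled depth the overlap filter's yield dictates (~400 reads), pairs of
co-firing hotspots (probability $0.3^2(1-0.3) \approx 0.06$ per pattern per
read) recur often enough to found clusters.

## What the simulations do and do not show

The simulator reproduces the *structure* of the benchmark — fully
overlapping 2x101 pairs, inline barcodes, skewed template abundances,
miscalibrated high Q-scores on error-bearing reads — and the package's
tests reproduce its qualitative findings at desk scale: Q-score filters
pass substantially more pairs than the overlap filter under
miscalibration, and equal-depth clustering of their output yields more
OTUs. It does not emulate PCR errors or chimeras (invisible to all three
filters here), flow-cell spatial effects, context-dependent (as opposed to
cycle-dependent) miscalls, or the exact magnitudes of any published run:
absolute pass rates and OTU ratios on simulated data depend on the chosen
error rates and are not comparable to any real dataset's figures. Passing
tests show the *filters* behave as specified and the *contrast* between
them has the right direction and rough size, not that any particular real
run would show a particular number.

## Numerical and degenerate-input choices

* Quality encoding is fixed at Phred+33 (the post-1.8 CASAVA dialect);
  older +64 files are rejected by their implausible decoded values, never
  auto-detected, to keep behaviour deterministic.
* Pair files must be position-synchronized; the first desynchronized
  record aborts the run with its index. The chastity (`filtered=Y`) flag
  is ignored by default (the protocol states no handling for it), with a
  CLI switch to drop flagged pairs.
* Failed pairs always produce an outcome record; ledger counts partition
  the input exactly (asserted in tests), with primer failures attributed
  to a read direction and N-bearing pairs counted per Table-S2-style
  accounting. `has_N` refers to the full reads, since failed pairs may
  have no defined inter-primer region.
* In the pair verdict, read-1 failures take precedence over read-2, and
  the distal stage over the proximal stage, mirroring the procedure's
  step order.
* Empty reads fail the first-half Q30 criterion; a zero-length first half
  is treated as length 1. Ratios against zero-length originals are
  guarded. Dereplication at threshold 1.0 bypasses edit-distance entirely.
* All randomness flows from explicit integer seeds through one derivation
  function; re-running any simulate/filter/cluster pipeline with the same
  seed is byte-identical (tested via file checksums).

## Known limitations

* The comparison is substitution-oriented: an indel in one mate is
  rejected (`LENGTH_DISAGREEMENT` or `MISMATCH`), never aligned around.
  This is the intended behaviour for a strictly positional filter, but it
  means indel-rich platforms gain less.
* Greedy clustering at these thresholds is order-dependent by design;
  abundance ordering makes it deterministic but, like all greedy centroid
  methods, not globally optimal.
* The Q-score filters implement the benchmark's operational restatement,
  not the full original pipelines.
* Demultiplexing of index reads (i7) is out of scope; the index field is
  parsed from headers and carried through, and only inline read-1 barcodes
  are resolved.
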