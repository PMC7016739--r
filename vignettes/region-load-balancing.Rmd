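---
title: "Two-stage genomic load balancing and the scatter-gather pipeline model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage genomic load balancing and the scatter-gather pipeline model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionpipe)
```

## The model

`regionpipe` treats an RNA-seq variant-calling pipeline as a scatter-gather
computation with three synchronization barriers. Reads are chunked and
aligned in parallel; discovered splice junctions are merged and the genome
index rebuilt once (barrier 1); re-aligned reads are sorted and routed into
genomic regions (barrier 2); each region is called independently; and the
per-region VCFs are merged (barrier 3). The wall clock of the per-region
stage is set by its slowest region, so the quality of the genome partition
is the quality of the pipeline.

The partition is built in two stages with deliberately different
information budgets.

### Static stage

Before any data exist, the only information is the contig inventory of the
reference. With total size $S$ and requested region count $R$, the target
region size is $a_s = S/R$, and a contig of length $L$ is split into

$$k \;=\; \max\!\bigl(1,\ \lfloor L / a_s \rfloor\bigr)$$

equal pieces. Two properties follow. First, every contig keeps at least one
region, so the realised count (RsLB) is at least the number of contigs and
— on references with many small contigs — can exceed the request
substantially. Second, because $k$ floors, a contig marginally larger than
a multiple of $a_s$ is *not* split further, keeping regions at or above the
target size rather than fragmenting.

The underlying assumption is that reads are roughly proportional to
genomic extent. For RNA-seq that assumption is knowingly wrong — coverage
concentrates in expressed genes — which is exactly why a second stage
exists.

### Dynamic stage

After mapping, the observed per-region read counts replace the size proxy.
With $N$ mapped reads in total, the target per-region load is
$a_d = N/\mathrm{RsLB}$ reads, and a region holding $n$ reads splits into
$k = \lfloor n/a_d \rfloor$ sub-regions when $k \ge 2$. Split points are
read-count quantiles, not equal coordinate spans: the $j$-th cut falls
between the $\lceil jn/k \rceil$-th read start and the next, so sub-region
loads differ by at most one read wherever starts are distinct. Equal
coordinate spans would simply reproduce the static stage's blind spot
inside the hot region.

Reads are attributed to regions by their leftmost mapping position only. A
read overlapping a region boundary therefore contributes to exactly one
region. This keeps routing a pure partition (counts conserve exactly) at
the cost of a small, known boundary effect in calling, discussed under
limitations.

### Degenerate inputs and ties

Cut points require distinct read starts. When the quantile falls inside a
run of reads sharing one coordinate, the cut shifts to the nearest
boundary between distinct starts; this never produces a zero-length region
and bounds every sub-region's load by $2a_d$ plus the tie-run size. (The
simpler alternative — dropping the invalid cut — can merge two quantile
blocks and breach that bound with as few as two tied reads.) If all reads
of a region share one coordinate, no cut exists and the region stays
whole: the tiling invariant always wins over balance. A region with zero
reads, or a profile with zero reads in total, never splits.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `num_regions` | config / `static_partition()` | required | Requested region count; the realised RsLB/RdLB are usually higher. Set near the worker count times a small factor. |
| `n_chunks` | config | `workers` | FASTQ chunks; one per worker thread so the mapping stage fills the pool. |
| `workers` | config | 1 | Parallel stage processes at each fan-out. |
| `min_alt`, `min_frac` | `mock_call()` | 3, 0.3 | Mock caller's alt-read count and alt-fraction thresholds. |
| `boundary_margin`, `max_splits` | `gen_truth_set()` | `2*read_length`, 8 | Clearance between default-placed truth sites and any candidate region boundary of a static split into up to `max_splits` pieces. |

The averages $a_s$ and $a_d$ are kept as exact ratios; flooring happens
only at $k$, computed as an exact integer floor of $L \cdot R / S$ (and
$n \cdot \mathrm{RsLB} / N$) with product-based correction. Integer
products stay below $2^{53}$ for any realistic genome, so the split count
at an exact multiple of the target never depends on floating-point
rounding.

## What the synthetic data emulate — and what they do not

The generators exist to exercise the *scaffolding*, not to simulate
sequencing. `gen_reference()` draws uniform A/C/G/T contigs;
`gen_truth_set()` plants SNVs whose ref allele matches the reference by
construction; `gen_reads()` samples read starts uniformly per contig
(count = `round(L * coverage / read_length)`), encodes each read's true
origin in its name, and applies planted alt alleles at the stated allele
fraction. The bundled `mock_align()` simply decodes the origin — there is
no alignment algorithm, no spliced reads, no error model, no quality
realism; the splice-junction tables it emits are synthetic metadata whose
only purpose is to make barrier-1 merging observable and
chunking-invariant. `mock_call()` is a naive pileup over reads *starting*
in its region.

Passing tests therefore demonstrate the orchestration contracts —
conservation, ordering, determinism, barrier correctness, partition
invariance, balance — on data where those contracts can be checked
exactly. They do not demonstrate variant-calling accuracy on real reads,
where alignment ambiguity, spliced alignment, and haplotype-aware
comparison all matter.

Two generator choices are load-bearing. First, default truth sites are
evenly spaced but nudged at least `boundary_margin` bases away from every
boundary any static split into up to `max_splits` pieces could produce
(boundaries sit at multiples of $\lfloor L/k \rfloor$). A region-local
caller sees identical coverage at such sites under any partitioning, which
is what makes the monolithic-oracle comparison *byte*-exact rather than
approximate. Second, the mock caller uses only reads that start in its
region — the cleanest form of the leftmost-position convention — so
partition invariance is a theorem about the fixture rather than a
statistical tendency.

## Numerical and design choices

* **Coordinates** are 0-based half-open internally; 1-based SAM/VCF
  positions convert at the boundary. Contig order is the reference-index
  file order and defines every output's sort order.
* **Sorting** uses radix order (byte-wise, locale-independent), so shard
  and merge outputs are identical across platforms and locales.
* **Intra-contig splitting** uses equal piece sizes with the remainder on
  the last piece; the dynamic stage uses `floor` for $k$, matching the
  static rule.
* **FASTQ chunks** are contiguous blocks of `ceil(total/n_chunks)`
  records (smaller final chunk), so concatenating chunks reproduces the
  input byte-identically and paired mates stay index-aligned.
* **VCF merging** takes the header from the first input, verifies
  `##contig` lines agree, sorts by (reference contig order, position), and
  collapses exact duplicate keys — as can arise at region boundaries — to
  the first occurrence, reporting the collapsed count so conservation
  stays checkable.
* **Concordance** is exact-key matching on (contig, pos, ref, alt) with
  multi-allelic records split per alternate allele; FILTER and genotypes
  are ignored. Haplotype-aware rescue of equivalent representations is a
  research tool of its own and deliberately out of scope, so TP/FP/FN may
  undercount agreement on complex loci relative to a haplotype-aware
  comparator; the sensitivity/precision formulas applied to given counts
  are exact, reported to two decimals.
* **Failure semantics**: a stage command exiting non-zero aborts the run
  at the current barrier; the manifest records per-shard status and every
  intermediate is preserved. Completed task outputs carry `.ok` markers,
  and a rerun with an unchanged config resumes from them, yielding the
  same final VCF as a clean run. These semantics are this package's
  choice; a cluster scheduler would make its own.
* **Process pool**: a single-machine fork-based pool stands in for
  cluster executors. The contract — independent tasks separated by
  barriers — is the portable part; with deterministic stage commands the
  final VCF is byte-identical for any worker count.

## Problem sizes used by the test and acceptance suites

The suites are sized to check the contracts, not to benchmark: random
references up to ten contigs of tens of kb (tiling is verified
base-by-base against a brute-force coverage array), conservation checks at
10^4 reads, and end-to-end runs on a 100 kb genome at 30x coverage
(30,000 reads, 20 planted homozygous SNVs) under a monolithic and two
partitioned configurations. The acceptance script regenerates all inputs
from its `--seed` and recomputes every reported number at run time.

## Known limitations

* Reads crossing a region boundary contribute coverage only to the region
  holding their start; real callers lose a little accuracy near
  boundaries, which is the documented cost of position-based routing. The
  mock caller makes this exact rather than approximate.
* Exact-key concordance understates agreement between call sets that
  represent the same event differently (complex loci, normalisation
  differences).
* The orchestrator targets one machine; it does not schedule across
  nodes, manage memory, or stream — shards are desk-scale and in-memory
  sorting is intentional.
* `RsLB`/`RdLB` values on a real human reference depend on its full
  contig inventory (scaffolds, decoys) and the dataset; the package
  reproduces the mechanism and its invariants, not those absolute counts.
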