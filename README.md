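# regionpipe

Scatter-gather orchestration and two-stage genomic load balancing for
region-parallel RNA-seq variant calling.

## The problem

The GATK-style RNA-seq variant-calling pipeline (two-pass spliced
alignment, duplicate marking, recalibration, per-region variant calling)
parallelises poorly as a monolith: the aligner scales with threads, but the
downstream Picard/GATK stages are essentially serial. The standard remedy
is scatter-gather: chunk the FASTQ input, align chunks in parallel, then
split the genome into regions and run the calling stages once per region.
That only helps if every region carries a similar amount of work — RNA-seq
coverage is concentrated in expressed genes, so naive equal-size regions
leave a few hot regions as stragglers that dominate the wall clock.

`regionpipe` is for pipeline engineers and methods developers who want this
scaffolding — the partitioning, the data movement at the synchronization
barriers, and the bookkeeping — as a testable library with pluggable stage
tools, runnable at desk scale with bundled deterministic mocks and
synthetic data, no downloads required.

## The method

The genome is partitioned in two stages.

**Static load balancing** uses only contig sizes, known before any read is
seen. With total genome size *S* and a requested region count
*numRegions*, the target region size is

    avgSizeStatic = S / numRegions

Regions are first cut along contig boundaries; a contig of length *L* is
then split into `k = max(1, floor(L / avgSizeStatic))` equal pieces
(remainder to the last piece). Small contigs always keep a region of their
own, so the realised count **RsLB** generally exceeds the request.

**Dynamic load balancing** refines the static partition after mapping,
using the observed per-region mapped-read counts. With *N* total mapped
reads, the target per-region load is

    avgSizeDynamic = N / RsLB

A region holding *n* reads is split into `k = floor(n / avgSizeDynamic)`
sub-regions when `k >= 2`, with cut points at read-count quantiles, so
sub-region loads differ by at most one read where read starts are distinct.
The realised count **RdLB** is never below RsLB, and no region's load can
exceed twice the target plus the size of a tie run.

Around the balancer sit the stage-I/O primitives of the execution flow:
FASTQ chunking into nearly equal contiguous blocks (paired files cut at
identical record boundaries), splice-junction table merging between the
two alignment passes (support summed, overhang maximised, order-insensitive
output), SAM routing of each read to the region containing its leftmost
mapping position, and VCF merging (reference-ordered, boundary duplicates
collapsed). An orchestrator runs the whole flow — scatter, three barriers,
gather — driving arbitrary shell-command stage tools with a bounded worker
pool, a resumable manifest, and deterministic outputs. Concordance between
two call sets is evaluated as exact-key TP/FP/FN with

    Sensitivity = TP / (TP + FN),   Precision = TP / (TP + FP)

reported as percentages.

## Worked example

Generate a 100 kb two-contig reference with 20 planted homozygous SNVs,
simulate 30x reads, and run the full pipeline with the bundled mock stage
tools — 4 FASTQ chunks, 7 requested regions, 2 workers:

```r
library(regionpipe)

dir    <- tempfile("demo-")
genome <- gen_reference(c(chr1 = 50000L, chr2 = 50000L), seed = 101, dir = dir)
truth  <- gen_truth_set(genome, n_variants = 20, allele_fraction = 1.0,
                        read_length = 100, coverage = 30, seed = 102)
reads  <- gen_reads(truth, file.path(dir, "reads"))
index  <- gen_mock_index(genome, file.path(dir, "index0"))

config <- validate_config(list(
  reference_index = genome$fai, reference = genome$fasta, index = index,
  inputs = reads$fastq, num_regions = 7, n_chunks = 4, workers = 2,
  workdir = file.path(dir, "run"), stages = mock_stage_commands()))
manifest <- run_pipeline(config)

cat("RsLB:", manifest$plan$rslb, " RdLB:", manifest$plan$rdlb, "\n")
cat("reads in:", manifest$counts$fastq_records,
    " routed:", manifest$counts$routed, "\n")
evaluate_concordance(manifest$final_vcf, reads$truth_vcf)
```

```
RsLB: 6  RdLB: 6 
reads in: 30000  routed: 30000 
AccuracyReport: TP 20, FP 0, FN 0; sensitivity 100.00%, precision 100.00%
```

Seven regions were requested; the balancer realised six (each 50 kb contig
splits into three pieces of the ~14.3 kb target size). Coverage is uniform
here, so the dynamic stage finds nothing to refine and RdLB = RsLB. All
30,000 reads are conserved through chunking and routing, and the merged
final VCF recovers every planted variant with nothing spurious — and is
byte-identical to a single-chunk, single-region run of the same mocks.

A thin command-line front end is installed as `exec/regionpipe`
(subcommands `partition static|dynamic`, `split`, `merge-sj`, `route`,
`merge-vcf`, `evaluate`, `run`).

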