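# Shared fixture builders. Everything is generated in code at test time;
# the slower shared artifacts (a small end-to-end pipeline fixture and one
# completed run) are built once per session and reused read-only.

.fixture_cache <- new.env(parent = emptyenv())

# Minimal SAM record data.frame for routing/profiling tests.
make_records <- function(contig, pos0, qname = NULL, flag = 0L) {
  n <- length(pos0)
  if (is.null(qname)) qname <- sprintf("r%04d", seq_len(n))
  contig <- rep_len(contig, n)
  flag <- rep_len(flag, n)
  pos <- pos0 + 1
  data.frame(
    qname = qname, flag = flag, contig = contig, pos = pos,
    raw = sprintf("%s\t%d\t%s\t%.0f\t60\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
                  qname, flag, contig, pos),
    stringsAsFactors = FALSE
  )
}

# A RegionProfile built from explicit per-contig 0-based positions.
make_profile <- function(ref, num_regions, contigs, pos0) {
  plan <- static_partition(ref, num_regions)
  profile_regions(make_records(contigs, pos0), plan)
}

# Random small reference for property tests (<= 10 contigs, tens of kb).
random_ref <- function(n_contigs = sample(1:10, 1),
                       max_len = 20000L, min_len = 100L) {
  lens <- sample(min_len:max_len, n_contigs, replace = TRUE)
  reference_dict(sprintf("ctg%02d", seq_len(n_contigs)), lens)
}

# Brute-force tiling check: every base of every contig covered exactly once.
expect_tiles_reference <- function(rs, ref) {
  for (i in seq_len(nrow(ref$contigs))) {
    nm <- ref$contigs$name[i]
    L <- ref$contigs$length[i]
    cov <- integer(L)
    sub <- rs[rs$contig == nm, , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      idx <- (sub$start[j] + 1L):sub$end[j]
      cov[idx] <- cov[idx] + 1L
    }
    expect_true(all(cov == 1L),
                label = sprintf("contig %s covered exactly once", nm))
  }
  invisible(rs)
}

# Small FASTQ written from generated qnames/seqs.
write_fastq <- function(path, qnames, seqs = NULL, quals = NULL) {
  n <- length(qnames)
  if (is.null(seqs)) seqs <- rep(strrep("A", 10L), n)
  if (is.null(quals)) quals <- vapply(seqs, function(s)
    strrep("I", nchar(s)), "")
  writeLines(as.vector(rbind(paste0("@", qnames), seqs, "+", quals)), path)
  path
}

# Write a VCF with given variant rows (contig, pos, ref, alt).
write_test_vcf <- function(path, ref, rows) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%.0f>", ref$contigs$name,
                   ref$contigs$length),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(rows)) {
    sprintf("%s\t%.0f\t.\t%s\t%s\t.\t.\t.", rows$contig, rows$pos,
            rows$ref, rows$alt)
  } else character(0)
  writeLines(c(hdr, body), path)
  path
}

# Small end-to-end fixture: 2 x 6 kb contigs, 10x coverage, 60 bp reads,
# 6 planted homozygous SNVs. Built once per session.
tiny_fixture <- function() {
  if (!is.null(.fixture_cache$tiny)) return(.fixture_cache$tiny)
  dir <- file.path(tempdir(), "regionpipe-tiny-fixture")
  g <- gen_reference(c(chrA = 6000L, chrB = 6000L), seed = 7L, dir = dir)
  truth <- gen_truth_set(g, n_variants = 6L, allele_fraction = 1.0,
                         read_length = 60L, coverage = 10, seed = 11L)
  reads <- gen_reads(truth, file.path(dir, "reads"))
  index <- gen_mock_index(g, file.path(dir, "index0"))
  .fixture_cache$tiny <- list(dir = dir, g = g, truth = truth,
                              reads = reads, index = index)
  .fixture_cache$tiny
}

tiny_config <- function(workdir, num_regions = 3L, n_chunks = 2L,
                        workers = 1L) {
  fx <- tiny_fixture()
  list(reference_index = fx$g$fai, reference = fx$g$fasta,
       index = fx$index, inputs = fx$reads$fastq,
       num_regions = num_regions, n_chunks = n_chunks, workers = workers,
       workdir = workdir, stages = mock_stage_commands())
}

contig_length_of <- function(ref, contig) {
  ref$contigs$length[match(contig, ref$contigs$name)]
}

# Mid-size end-to-end fixture: 2 x 50 kb contigs, 30x coverage, 100 bp
# reads, 20 planted homozygous SNVs. Built once per session.
acceptance_fixture <- function() {
  if (!is.null(.fixture_cache$accept)) return(.fixture_cache$accept)
  dir <- file.path(tempdir(), "regionpipe-accept-fixture")
  g <- gen_reference(c(chr1 = 50000L, chr2 = 50000L), seed = 101L,
                     dir = dir)
  truth <- gen_truth_set(g, n_variants = 20L, allele_fraction = 1.0,
                         read_length = 100L, coverage = 30, seed = 102L)
  reads <- gen_reads(truth, file.path(dir, "reads"))
  index <- gen_mock_index(g, file.path(dir, "index0"))
  .fixture_cache$accept <- list(dir = dir, g = g, truth = truth,
                                reads = reads, index = index)
  .fixture_cache$accept
}

acceptance_config <- function(fx, workdir, num_regions, n_chunks, workers) {
  list(reference_index = fx$g$fai, reference = fx$g$fasta,
       index = fx$index, inputs = fx$reads$fastq,
       num_regions = num_regions, n_chunks = n_chunks, workers = workers,
       workdir = workdir, stages = mock_stage_commands())
}

# One completed pipeline run on the tiny fixture, shared read-only.
tiny_run <- function() {
  if (!is.null(.fixture_cache$tiny_run)) return(.fixture_cache$tiny_run)
  wd <- file.path(tempdir(), "regionpipe-tiny-run")
  manifest <- run_pipeline(validate_config(tiny_config(wd)))
  .fixture_cache$tiny_run <- list(workdir = wd, manifest = manifest)
  .fixture_cache$tiny_run
}
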