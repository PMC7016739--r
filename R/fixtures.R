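#' Generate a random reference genome (FASTA + .fai)
#'
#' Writes an uppercase A/C/G/T reference with 60-column sequence lines and a
#' matching FASTA index. Bitwise deterministic for a given seed.
#'
#' @param contig_sizes positive integer vector of contig lengths (bp);
#'   names, if set, become contig names, else `contig01`, `contig02`, ...
#' @param seed integer seed.
#' @param dir output directory (created if missing).
#' @param name basename for the FASTA file (default `genome`).
#' @return List with `fasta`, `fai` (paths) and `ref` (the
#'   [reference_dict()]).
#' @export
gen_reference <- function(contig_sizes, seed, dir, name = "genome") {
  if (length(contig_sizes) == 0L) {
    stop("contig_sizes must not be empty", call. = FALSE)
  }
  if (any(contig_sizes < 1)) stop("contig sizes must be >= 1", call. = FALSE)
  nm <- names(contig_sizes)
  if (is.null(nm)) nm <- sprintf("contig%02d", seq_along(contig_sizes))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, paste0(name, ".fa"))
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  seqs <- lapply(contig_sizes, function(L) {
    sample(c("A", "C", "G", "T"), L, replace = TRUE)
  })
  seqinr::write.fasta(seqs, nm, fasta, nbchar = 60)
  ref <- reference_dict(nm, contig_sizes)
  fai <- paste0(fasta, ".fai")
  write_fai(ref, fai)
  list(fasta = fasta, fai = fai, ref = ref)
}

# Read a FASTA written by gen_reference back as named uppercase strings.
read_fasta_strings <- function(path) {
  s <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  vapply(s, function(x) toupper(as.character(x)[1L]), "")
}

#' Define a truth set of planted SNVs over a generated reference
#'
#' Chooses variant sites and alternate alleles on a reference produced by
#' [gen_reference()]. By default sites are evenly spaced along each contig
#' (allocated proportionally to contig length) and then nudged so that no
#' site lies within `boundary_margin` bases of any region boundary a static
#' partition with up to `max_splits` pieces per contig could produce. A
#' region-local caller sees identical coverage at such sites no matter how
#' the genome is partitioned, which is the precondition for exact truth
#' recovery and partition invariance. Explicit 1-based `positions`
#' (data.frame contig/pos) may be given instead and are used verbatim. The
#' alternate allele is the next base in A>C>G>T>A order, so every planted
#' ref allele matches the reference sequence by construction.
#'
#' @param reference a [gen_reference()] result (or a list with `fasta` and
#'   `ref`).
#' @param n_variants total number of SNVs to plant (ignored when `positions`
#'   is given).
#' @param allele_fraction fraction of overlapping reads carrying the alt
#'   allele (1.0 = homozygous).
#' @param read_length read length the downstream read generator will use.
#' @param coverage target mean coverage depth for the read generator.
#' @param seed integer seed for the read generator.
#' @param positions optional data.frame with `contig` and `pos` (1-based)
#'   columns.
#' @param boundary_margin minimum distance (bp) between a default-placed
#'   site and any candidate region boundary; default `2 * read_length`.
#' @param max_splits largest per-contig piece count whose boundaries
#'   default placement avoids (default 8).
#' @return A `TruthSet`: list with `fasta`, `fai`, `ref`, `variants`
#'   (data.frame contig/pos/ref/alt/fraction), `read_length`, `coverage`,
#'   `seed`.
#' @export
gen_truth_set <- function(reference, n_variants, allele_fraction = 1.0,
                          read_length = 100L, coverage = 30, seed = 1L,
                          positions = NULL, boundary_margin = NULL,
                          max_splits = 8L) {
  ref <- reference$ref
  seqs <- read_fasta_strings(reference$fasta)
  if (is.null(boundary_margin)) boundary_margin <- 2L * read_length
  if (is.null(positions)) {
    lens <- ref$contigs$length
    n_per <- round(n_variants * lens / sum(lens))
    # largest-remainder fixup so counts sum to n_variants
    while (sum(n_per) > n_variants) n_per[which.max(n_per)] <- n_per[which.max(n_per)] - 1L
    while (sum(n_per) < n_variants) n_per[which.min(n_per)] <- n_per[which.min(n_per)] + 1L
    positions <- do.call(rbind, lapply(seq_along(lens), function(i) {
      if (n_per[i] == 0L) return(NULL)
      pos0 <- floor((seq_len(n_per[i]) - 0.5) * lens[i] / n_per[i])
      pos0 <- avoid_region_boundaries(pos0, lens[i], boundary_margin,
                                      max_splits)
      data.frame(contig = ref$contigs$name[i], pos = pos0 + 1,
                 stringsAsFactors = FALSE)
    }))
  }
  if (any(is.na(match(positions$contig, ref$contigs$name)))) {
    stop("variant on contig absent from reference", call. = FALSE)
  }
  lens_at <- ref$contigs$length[match(positions$contig, ref$contigs$name)]
  if (any(positions$pos < 1 | positions$pos > lens_at)) {
    stop("variant position out of contig bounds", call. = FALSE)
  }
  ref_base <- mapply(function(ctg, p) substr(seqs[[ctg]], p, p),
                     positions$contig, positions$pos, USE.NAMES = FALSE)
  nxt <- c(A = "C", C = "G", G = "T", T = "A", N = "A")
  variants <- data.frame(contig = positions$contig, pos = positions$pos,
                         ref = ref_base, alt = unname(nxt[ref_base]),
                         fraction = allele_fraction,
                         stringsAsFactors = FALSE)
  structure(
    list(fasta = reference$fasta, fai = reference$fai, ref = ref,
         variants = variants, read_length = as.integer(read_length),
         coverage = coverage, seed = as.integer(seed)),
    class = "TruthSet"
  )
}

# Nudge 0-based sites away from every boundary a static split of this
# contig into k = 2..max_splits equal pieces would produce (piece size
# floor(L/k), boundaries at its multiples).
avoid_region_boundaries <- function(pos0, L, margin, max_splits) {
  bounds <- unique(unlist(lapply(2:max_splits, function(k) {
    s <- L %/% k
    if (s == 0) return(numeric(0))
    seq_len(k - 1L) * s
  })))
  shifted <- vapply(pos0, function(p) {
    for (pass in 1:10) {
      near <- bounds[abs(bounds - p) < margin]
      if (length(near) == 0L) break
      b <- near[which.min(abs(near - p))]
      p <- if (b + margin <= L - 1) b + margin else b - margin
    }
    p
  }, 1)
  shifted <- pmin(pmax(shifted, 0), L - 1)
  # sites dense enough to collide after nudging are separated minimally;
  # such fixtures trade some boundary clearance for site count
  guard <- 0L
  while (anyDuplicated(shifted) && guard < 1000L) {
    i <- which(duplicated(shifted))
    shifted[i] <- pmin(shifted[i] + 1, L - 1)
    guard <- guard + 1L
  }
  shifted
}

#' Write the planted variants of a truth set as a VCF
#' @param truth a [gen_truth_set()] object.
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(truth, path) {
  stopifnot(inherits(truth, "TruthSet"))
  v <- truth$variants
  rank <- match(v$contig, truth$ref$contigs$name)
  v <- v[order(rank, v$pos, method = "radix"), , drop = FALSE]
  writeLines(c(
    vcf_header_lines(truth$ref),
    sprintf("%s\t%.0f\t.\t%s\t%s\t.\t.\tAF=%g", v$contig, v$pos, v$ref,
            v$alt, v$fraction)
  ), path)
  invisible(path)
}

vcf_header_lines <- function(ref) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%.0f>", ref$contigs$name,
            ref$contigs$length),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

#' Simulate reads from a truth set
#'
#' Samples reads uniformly along each contig (per-contig read count
#' `round(length * coverage / read_length)`). Each read name encodes its
#' origin — `contig:start` for single-end, `contig:start1:start2` for pairs,
#' plus a serial — which is what the bundled [mock_align()] decodes instead
#' of aligning. Reads overlapping a planted variant carry the alt base with
#' the variant's allele fraction (all of them at fraction 1.0; an
#' independent seeded draw per read otherwise). No sequencing-error model.
#' Bitwise deterministic per seed.
#'
#' @param truth a [gen_truth_set()] object.
#' @param out_dir output directory.
#' @param paired generate read pairs (two FASTQ files) instead of single-end
#'   reads.
#' @return List with `fastq` (1 or 2 paths), `truth_vcf` (path) and
#'   `n_reads`.
#' @export
gen_reads <- function(truth, out_dir, paired = FALSE) {
  stopifnot(inherits(truth, "TruthSet"))
  if (truth$coverage <= 0) stop("coverage must be > 0", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  len <- truth$read_length
  seqs <- read_fasta_strings(truth$fasta)
  # alt haplotype per contig: every planted variant applied
  hap <- seqs
  for (k in seq_len(nrow(truth$variants))) {
    v <- truth$variants[k, ]
    substr(hap[[v$contig]], v$pos, v$pos) <- v$alt
  }
  set.seed(truth$seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  frag_gap <- 50L  # inner gap between paired mates
  recs1 <- list(); recs2 <- list()
  serial <- 0L
  for (i in seq_len(nrow(truth$ref$contigs))) {
    ctg <- truth$ref$contigs$name[i]
    L <- truth$ref$contigs$length[i]
    if (L < len) stop("contig ", ctg, " shorter than the read length",
                      call. = FALSE)
    n <- round(L * truth$coverage / len)
    vc <- truth$variants[truth$variants$contig == ctg, , drop = FALSE]
    span <- if (paired) 2L * len + frag_gap else len
    if (paired && L < span) {
      stop("contig ", ctg, " shorter than the paired fragment length",
           call. = FALSE)
    }
    starts0 <- sample.int(L - span + 1L, n, replace = TRUE) - 1L
    draw_seq <- function(s0) {
      # which planted variants does [s0, s0+len) overlap, and does this
      # read carry them?
      ov <- which(vc$pos - 1 >= s0 & vc$pos - 1 < s0 + len)
      if (length(ov) == 0L) return(substr(seqs[[ctg]], s0 + 1L, s0 + len))
      carry <- vc$fraction[ov] >= 1 | stats::runif(length(ov)) < vc$fraction[ov]
      if (all(carry)) return(substr(hap[[ctg]], s0 + 1L, s0 + len))
      s <- substr(seqs[[ctg]], s0 + 1L, s0 + len)
      for (j in ov[carry]) {
        off <- vc$pos[j] - s0
        substr(s, off, off) <- vc$alt[j]
      }
      s
    }
    for (r in seq_len(n)) {
      serial <- serial + 1L
      s1 <- starts0[r]
      if (paired) {
        s2 <- s1 + span - len
        qname <- sprintf("%s:%d:%d:%d", ctg, s1, s2, serial)
        recs1[[length(recs1) + 1L]] <-
          c(paste0("@", qname, "/1"), draw_seq(s1), "+", strrep("I", len))
        recs2[[length(recs2) + 1L]] <-
          c(paste0("@", qname, "/2"), draw_seq(s2), "+", strrep("I", len))
      } else {
        qname <- sprintf("%s:%d:%d", ctg, s1, serial)
        recs1[[length(recs1) + 1L]] <-
          c(paste0("@", qname), draw_seq(s1), "+", strrep("I", len))
      }
    }
  }
  fq1 <- file.path(out_dir, if (paired) "reads_1.fastq" else "reads.fastq")
  writeLines(unlist(recs1, use.names = FALSE), fq1)
  fastq <- fq1
  if (paired) {
    fq2 <- file.path(out_dir, "reads_2.fastq")
    writeLines(unlist(recs2, use.names = FALSE), fq2)
    fastq <- c(fq1, fq2)
  }
  truth_vcf <- file.path(out_dir, "truth.vcf")
  write_truth_vcf(truth, truth_vcf)
  list(fastq = fastq, truth_vcf = truth_vcf, n_reads = serial)
}

#' Expected read count of the generator's sampling scheme
#'
#' `sum over contigs of round(length * coverage / read_length)` — the exact
#' count [gen_reads()] produces.
#'
#' @inheritParams write_truth_vcf
#' @return Integer read (or read-pair) count.
#' @export
expected_read_count <- function(truth) {
  stopifnot(inherits(truth, "TruthSet"))
  sum(round(truth$ref$contigs$length * truth$coverage / truth$read_length))
}

#' Build a mock genome index directory
#'
#' The "index" the mock aligner needs is just the reference FASTA and its
#' .fai, staged in a directory so the index-rebuild stage has something to
#' copy and version.
#'
#' @param reference a [gen_reference()] result.
#' @param dir index directory to create.
#' @return `dir`, invisibly.
#' @export
gen_mock_index <- function(reference, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  file.copy(reference$fasta, file.path(dir, "genome.fa"), overwrite = TRUE)
  file.copy(reference$fai, file.path(dir, "genome.fa.fai"), overwrite = TRUE)
  writeLines("sparse=1", file.path(dir, "index.txt"))
  invisible(dir)
}
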