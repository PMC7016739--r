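#' Mock aligner: place reads at their encoded origin
#'
#' Stands in for a two-pass spliced aligner during testing. Read names carry
#' their true origin (written by [gen_reads()]); the mock emits one primary
#' SAM record per read at that origin (1-based position, full-match CIGAR)
#' plus a small deterministic splice-junction table, so the downstream
#' merge/rebuild machinery is exercised without any alignment algorithmics.
#'
#' The junction table is derived by hashing each read's start into a fixed
#' per-contig junction set (junction id = start mod 5, coordinates a fixed
#' function of contig length), with unique/multi support split by start
#' parity and an overhang of `(start mod 37) + 10`. Per-read contributions
#' are additive, so merging the tables of any chunking of the same reads
#' gives identical totals.
#'
#' @param fastq FASTQ path (mate 1 for paired input).
#' @param index_dir mock index directory (holds `genome.fa.fai` for the SAM
#'   header).
#' @param out_prefix output prefix: writes `<out_prefix>.sam` and
#'   `<out_prefix>.SJ.out.tab`.
#' @param fastq2 optional mate-2 FASTQ path.
#' @return List with `sam`, `sj` (paths) and `n_records`.
#' @export
mock_align <- function(fastq, index_dir, out_prefix, fastq2 = NULL) {
  ref <- load_reference_index(file.path(index_dir, "genome.fa.fai"))
  inputs <- c(fastq, fastq2)
  recs <- list()
  for (m in seq_along(inputs)) {
    lines <- readLines(inputs[m])
    if (length(lines) %% 4L != 0L) {
      stop("ragged FASTQ: ", inputs[m], call. = FALSE)
    }
    name <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
    seq_ <- lines[seq(2L, length(lines), by = 4L)]
    qual <- lines[seq(4L, length(lines), by = 4L)]
    qname <- sub("/[12]$", "", name)
    parts <- strsplit(qname, ":", fixed = TRUE)
    np <- vapply(parts, length, 1L)
    paired <- !is.null(fastq2)
    want <- if (paired) 4L else 3L
    if (any(np != want)) {
      stop("read name without origin encoding: ",
           name[which(np != want)[1L]], call. = FALSE)
    }
    contig <- vapply(parts, `[[`, "", 1L)
    start0 <- as.numeric(vapply(parts, `[[`, "", if (paired && m == 2L) 3L else 2L))
    if (anyNA(start0)) stop("read name without origin encoding", call. = FALSE)
    flag <- if (!paired) 0L else if (m == 1L) 65L else 129L
    recs[[m]] <- data.frame(
      qname = qname, flag = flag, contig = contig, pos = start0 + 1,
      seq = seq_, qual = qual, stringsAsFactors = FALSE
    )
  }
  all <- do.call(rbind, recs)
  bad <- which(is.na(match(all$contig, ref$contigs$name)))
  if (length(bad)) {
    stop("read origin on unknown contig: ", all$contig[bad[1L]],
         call. = FALSE)
  }
  sam_path <- paste0(out_prefix, ".sam")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%.0f", ref$contigs$name,
                      ref$contigs$length))
  body <- sprintf("%s\t%d\t%s\t%.0f\t60\t%dM\t*\t0\t0\t%s\t%s",
                  all$qname, all$flag, all$contig, all$pos,
                  nchar(all$seq), all$seq, all$qual)
  writeLines(c(header, body), sam_path)
  sj_path <- paste0(out_prefix, ".SJ.out.tab")
  write_sj_file(mock_junctions(all, ref), sj_path)
  list(sam = sam_path, sj = sj_path, n_records = nrow(all))
}

# Deterministic per-chunk junction table; contributions are per read, so
# totals are chunking-invariant under merge_splice_junctions().
mock_junctions <- function(recs, ref, n_junctions = 5L) {
  if (nrow(recs) == 0L) return(read_empty_sj())
  start0 <- recs$pos - 1
  j <- start0 %% n_junctions
  lens <- ref$contigs$length[match(recs$contig, ref$contigs$name)]
  offset <- (j + 1) * floor(lens / (n_junctions + 2))
  rows <- data.frame(
    contig = recs$contig,
    intron_start = offset + 1,
    intron_end = offset + 50,
    strand = j %% 3,
    motif = j %% 7,
    annotated = j %% 2,
    n_unique = as.numeric(start0 %% 2 == 0),
    n_multi = as.numeric(start0 %% 2 == 1),
    max_overhang = (start0 %% 37) + 10,
    stringsAsFactors = FALSE
  )
  # aggregate within the chunk exactly as the merge step does across chunks
  aggregate_sj(rows, ref = ref)
}

#' Mock genome-index rebuild
#'
#' Stands in for the sequential index-rebuild step between the two mapping
#' passes. Copies the reference out of the old index directory and records
#' a digest of the merged splice-junction table, so the rebuilt "index"
#' deterministically reflects its splice-junction input.
#'
#' @param sj_path merged SJ.out.tab path.
#' @param index_dir previous index directory.
#' @param out_dir new index directory (created).
#' @return `out_dir`, invisibly.
#' @export
mock_index_rebuild <- function(sj_path, index_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in c("genome.fa", "genome.fa.fai")) {
    if (!file.copy(file.path(index_dir, f), file.path(out_dir, f),
                   overwrite = TRUE)) {
      stop("index directory lacks ", f, ": ", index_dir, call. = FALSE)
    }
  }
  file.copy(sj_path, file.path(out_dir, "sj.merged.tab"), overwrite = TRUE)
  writeLines(c("sparse=1",
               paste0("sj_md5=", unname(tools::md5sum(sj_path)))),
             file.path(out_dir, "index.txt"))
  invisible(out_dir)
}

#' Mock per-region variant caller (naive pileup)
#'
#' Stands in for the per-region duplicate-marking/recalibration/calling
#' stage. Piles up the reads of one region shard against the reference and
#' emits a variant wherever at least `min_alt` reads and at least
#' `min_frac` of the covering reads agree on the same non-reference base.
#'
#' Region-local by construction: only reads *starting* inside the region are
#' in the shard (routing is by leftmost position), only they are piled up,
#' and only positions inside the region are reported. Because coverage at a
#' position is counted from reads starting in the same region, calls at
#' positions at least one read length from the region start are identical to
#' a whole-genome run — the basis of the pipeline's partition-invariance
#' property.
#'
#' @param sam_path region shard SAM (headerless or with header).
#' @param bed_path single-region BED file (contig, start, end).
#' @param ref_fasta reference FASTA path.
#' @param out_path output VCF path.
#' @param min_alt minimum alt-supporting reads (default 3).
#' @param min_frac minimum alt fraction of covering reads (default 0.3).
#' @return List with `out` and `n_variants`, invisibly.
#' @export
mock_call <- function(sam_path, bed_path, ref_fasta, out_path,
                      min_alt = 3L, min_frac = 0.3) {
  bed <- read_region_bed(bed_path)
  if (nrow(bed) != 1L) {
    stop("per-region caller expects a single-region BED", call. = FALSE)
  }
  rctg <- bed$contig[1L]; rstart <- bed$start[1L]; rend <- bed$end[1L]
  seqs <- read_fasta_strings(ref_fasta)
  if (!rctg %in% names(seqs)) {
    stop("region contig absent from reference FASTA: ", rctg, call. = FALSE)
  }
  ref_dict <- reference_dict(names(seqs), nchar(seqs))
  sam <- read_sam_file(sam_path)
  rec <- sam$records[!is_unmapped(sam$records$flag, sam$records$contig), ,
                     drop = FALSE]
  lines_out <- character(0)
  if (nrow(rec) > 0L) {
    f <- strsplit(rec$raw, "\t", fixed = TRUE)
    seq_ <- vapply(f, `[[`, "", 10L)
    start0 <- rec$pos - 1
    if (any(rec$contig != rctg | start0 < rstart | start0 >= rend)) {
      stop("shard contains reads not starting in the region", call. = FALSE)
    }
    refraw <- charToRaw(seqs[[rctg]])
    L <- length(refraw)
    # coverage from read spans; alt evidence from mismatch positions
    cov_d <- numeric(L + 1L)
    mpos <- vector("list", nrow(rec))
    mbase <- vector("list", nrow(rec))
    for (i in seq_len(nrow(rec))) {
      s0 <- start0[i]
      rl <- nchar(seq_[i])
      e0 <- min(s0 + rl, L)
      cov_d[s0 + 1L] <- cov_d[s0 + 1L] + 1
      cov_d[e0 + 1L] <- cov_d[e0 + 1L] - 1
      rd <- charToRaw(seq_[i])[seq_len(e0 - s0)]
      mm <- which(rd != refraw[(s0 + 1L):e0])
      if (length(mm)) {
        mpos[[i]] <- s0 + mm  # 1-based positions
        mbase[[i]] <- rawToChar(rd[mm], multiple = TRUE)
      }
    }
    coverage <- cumsum(cov_d[seq_len(L)])
    pos_all <- unlist(mpos, use.names = FALSE)
    base_all <- unlist(mbase, use.names = FALSE)
    if (length(pos_all)) {
      in_region <- pos_all - 1 >= rstart & pos_all - 1 < rend
      pos_all <- pos_all[in_region]; base_all <- base_all[in_region]
    }
    if (length(pos_all)) {
      key <- paste(pos_all, base_all, sep = "\r")
      tab <- table(key)
      parts <- strsplit(names(tab), "\r", fixed = TRUE)
      cand <- data.frame(
        pos = as.numeric(vapply(parts, `[[`, "", 1L)),
        alt = vapply(parts, `[[`, "", 2L),
        ac = as.integer(tab),
        stringsAsFactors = FALSE
      )
      cand$dp <- coverage[cand$pos]
      keep <- cand$ac >= min_alt & cand$ac >= min_frac * cand$dp &
        cand$alt %in% c("A", "C", "G", "T")
      cand <- cand[keep, , drop = FALSE]
      cand <- cand[order(cand$pos, cand$alt, method = "radix"), ,
                   drop = FALSE]
      if (nrow(cand)) {
        refb <- rawToChar(refraw[cand$pos], multiple = TRUE)
        lines_out <- sprintf("%s\t%.0f\t.\t%s\t%s\t.\t.\tDP=%.0f;AC=%d",
                             rctg, cand$pos, refb, cand$alt, cand$dp,
                             cand$ac)
      }
    }
  }
  writeLines(c(vcf_header_lines(ref_dict), lines_out), out_path)
  invisible(list(out = out_path, n_variants = length(lines_out)))
}

#' Shell command templates for the bundled mock stage tools
#'
#' Returns stage command strings that drive the installed mock CLIs
#' (`inst/mocks/`) through `Rscript`, with the same `{input}`, `{input2}`,
#' `{index}`, `{region_bed}`, `{reference}`, `{output}` placeholders a real
#' STAR/Picard/GATK command line would use. Drop the result into the
#' `stages` field of a pipeline config.
#'
#' @param paired include `{input2}` in the mapping commands (paired-end
#'   input).
#' @return Named list with `map_pass1`, `index_rebuild`, `map_pass2`,
#'   `per_region_call` command templates.
#' @export
mock_stage_commands <- function(paired = FALSE) {
  rscript <- shQuote(file.path(R.home("bin"), "Rscript"))
  mock <- function(script) {
    paste(rscript, shQuote(system.file("mocks", script,
                                       package = "regionpipe",
                                       mustWork = TRUE)))
  }
  mate2 <- if (paired) " --fastq2 {input2}" else ""
  list(
    map_pass1 = paste0(mock("mock_align.R"),
                       " --fastq {input}", mate2,
                       " --index {index} --out {output}"),
    index_rebuild = paste0(mock("mock_index_rebuild.R"),
                           " --sj {input} --index {index} --out {output}"),
    map_pass2 = paste0(mock("mock_align.R"),
                       " --fastq {input}", mate2,
                       " --index {index} --out {output}"),
    per_region_call = paste0(mock("mock_call.R"),
                             " --sam {input} --bed {region_bed}",
                             " --ref {reference} --out {output}")
  )
}

# Minimal --key value argument parser shared by the mock CLIs.
parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  pos <- character(0)
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        out[[substring(a, 3L)]] <- TRUE
        i <- i + 1L
      } else {
        out[[substring(a, 3L)]] <- args[i + 1L]
        i <- i + 2L
      }
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  out[["_positional"]] <- pos
  out
}

#' Command-line entry points of the bundled mock tools
#'
#' Thin wrappers called by the `inst/mocks/*.R` scripts; exported so the
#' scripts stay one-liners.
#'
#' @param args character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)`).
#' @return The wrapped function's value, invisibly.
#' @keywords internal
#' @export
mock_align_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  a <- parse_cli_args(args)
  invisible(mock_align(a$fastq, a$index, a$out, fastq2 = a$fastq2))
}

#' @rdname mock_align_cli
#' @export
mock_index_rebuild_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  a <- parse_cli_args(args)
  invisible(mock_index_rebuild(a$sj, a$index, a$out))
}

#' @rdname mock_align_cli
#' @export
mock_call_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  a <- parse_cli_args(args)
  min_alt <- if (is.null(a[["min-alt"]])) 3L else as.integer(a[["min-alt"]])
  min_frac <- if (is.null(a[["min-frac"]])) 0.3 else as.numeric(a[["min-frac"]])
  invisible(mock_call(a$sam, a$bed, a$ref, a$out, min_alt = min_alt,
                      min_frac = min_frac))
}
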