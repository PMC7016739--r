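#' Read variant keys from a VCF file
#'
#' Extracts the (contig, pos, ref, alt) key of every data line, splitting
#' multi-allelic lines into one key per alternate allele. FILTER and
#' genotype columns are ignored: a variant is identified by its site and
#' alleles only. The verbatim line is kept in `raw` (shared by the split
#' keys of a multi-allelic line).
#'
#' @param path VCF file path (plain text).
#' @return data.frame with columns `contig`, `pos` (1-based), `ref`, `alt`,
#'   `raw`, `line` (source line number).
#' @export
read_vcf_variants <- function(path) {
  lines <- readLines(path)
  keep <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(keep) == 0L) {
    return(data.frame(contig = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      raw = character(), line = integer(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(f, length, 1L) < 5L)
  if (length(bad)) {
    stop(sprintf("unparseable VCF line %d in %s: fewer than 5 fields",
                 keep[bad[1L]], path), call. = FALSE)
  }
  pos <- suppressWarnings(as.numeric(vapply(f, `[[`, "", 2L)))
  if (anyNA(pos)) {
    stop(sprintf("unparseable VCF line %d in %s: non-numeric POS",
                 keep[which(is.na(pos))[1L]], path), call. = FALSE)
  }
  contig <- vapply(f, `[[`, "", 1L)
  ref <- vapply(f, `[[`, "", 4L)
  alts <- strsplit(vapply(f, `[[`, "", 5L), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  i <- rep.int(seq_along(f), n_alt)
  data.frame(contig = contig[i], pos = pos[i], ref = ref[i],
             alt = unlist(alts, use.names = FALSE),
             raw = lines[keep][i], line = keep[i],
             stringsAsFactors = FALSE)
}

# Header lines (## and #CHROM) of a VCF file.
read_vcf_header <- function(path) {
  lines <- readLines(path)
  lines[startsWith(lines, "#")]
}

#' Merge per-region VCF files into one final VCF
#'
#' Takes the header from the first input, verifies that every input's
#' `##contig` lines agree with it, concatenates the data lines, sorts them by
#' (contig order in the reference, position), and collapses exact duplicate
#' keys (contig, pos, ref, alt) — as can arise at region boundaries — to the
#' first occurrence in input order. Duplicates removed are reported so that
#' record conservation stays checkable.
#'
#' @param inputs ordered character vector of per-region VCF paths (>= 1).
#' @param ref the [reference_dict()] fixing contig sort order.
#' @param out output VCF path.
#' @return List with `out`, `n_records` (records written), `n_duplicates`
#'   (exact-key duplicates collapsed), invisibly.
#' @export
merge_vcf <- function(inputs, ref, out) {
  if (length(inputs) == 0L) {
    stop("no input VCFs to merge (nothing to take a header from)",
         call. = FALSE)
  }
  stopifnot(inherits(ref, "ReferenceDict"))
  header <- read_vcf_header(inputs[1L])
  contig_hdr <- header[startsWith(header, "##contig")]
  for (p in inputs[-1L]) {
    h <- read_vcf_header(p)
    ch <- h[startsWith(h, "##contig")]
    if (length(ch) && !identical(ch, contig_hdr)) {
      stop("conflicting ##contig header lines in ", p, call. = FALSE)
    }
  }
  # whole data lines, keyed by (contig, pos, ref, full ALT field)
  raw <- unlist(lapply(inputs, function(p) {
    lines <- readLines(p)
    lines[!startsWith(lines, "#") & nzchar(lines)]
  }), use.names = FALSE)
  n_dup <- 0L
  body <- character(0)
  if (length(raw) > 0L) {
    f <- strsplit(raw, "\t", fixed = TRUE)
    if (any(vapply(f, length, 1L) < 5L)) {
      stop("unparseable VCF data line (fewer than 5 fields)", call. = FALSE)
    }
    contig <- vapply(f, `[[`, "", 1L)
    pos <- as.numeric(vapply(f, `[[`, "", 2L))
    key <- paste(contig, pos, vapply(f, `[[`, "", 4L),
                 vapply(f, `[[`, "", 5L), sep = "\r")
    dup <- duplicated(key)
    n_dup <- sum(dup)
    rank <- match(contig, ref$contigs$name)
    if (anyNA(rank)) {
      stop("VCF record on contig absent from reference: ",
           contig[which(is.na(rank))[1L]], call. = FALSE)
    }
    keep <- which(!dup)
    body <- raw[keep][order(rank[keep], pos[keep], method = "radix")]
  }
  writeLines(c(header, body), out)
  invisible(list(out = out, n_records = length(body), n_duplicates = n_dup))
}
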