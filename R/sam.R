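#' Read a SAM file into minimal routing records
#'
#' Parses only what region routing needs — qname, flag, contig, 1-based
#' leftmost position — and keeps each data line verbatim in `raw` so shard
#' files round-trip byte-identically.
#'
#' @param path SAM file path (plain text; header lines optional).
#' @return List with `header` (character vector of `@` lines) and `records`
#'   (data.frame: `qname`, `flag`, `contig`, `pos`, `raw`).
#' @export
read_sam_file <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0L) {
    return(list(header = hdr,
                records = data.frame(qname = character(), flag = integer(),
                                     contig = character(), pos = numeric(),
                                     raw = character(),
                                     stringsAsFactors = FALSE)))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(f, length, 1L) < 11L)
  if (length(bad)) {
    stop(sprintf("malformed SAM line (fewer than 11 fields): %s...",
                 substr(body[bad[1L]], 1L, 60L)), call. = FALSE)
  }
  list(
    header = hdr,
    records = data.frame(
      qname = vapply(f, `[[`, "", 1L),
      flag = as.integer(vapply(f, `[[`, "", 2L)),
      contig = vapply(f, `[[`, "", 3L),
      pos = as.numeric(vapply(f, `[[`, "", 4L)),
      raw = body,
      stringsAsFactors = FALSE
    )
  )
}

# Unmapped if the 0x4 flag bit is set or the contig is the "*" sentinel.
is_unmapped <- function(flag, contig) {
  bitwAnd(flag, 4L) != 0L | contig == "*"
}

#' Route SAM records into per-region shard files
#'
#' Each mapped record goes to exactly one region file — the region containing
#' its leftmost (0-based) mapping position; a read overlapping a region
#' boundary still belongs only to the region its start falls in. Within each
#' shard, records are sorted by (position, qname). Unmapped records go to a
#' dedicated `unmapped.sam` overflow file in input order. Shards are
#' headerless; the header (if given) is written once to `header.sam`.
#'
#' @param records SAM records data.frame (see [read_sam_file()]) or a SAM
#'   path.
#' @param rs the [region_set()] to route against (must tile the reference).
#' @param out_dir output directory (created if missing).
#' @param header optional character vector of SAM header lines.
#' @return List with `files` (character vector of shard paths, one per
#'   region, in region order), `unmapped` (overflow path), `counts`
#'   (records per shard) and `n_unmapped`.
#' @export
route_sam <- function(records, rs, out_dir, header = NULL) {
  stopifnot(inherits(rs, "RegionSet"))
  if (is.character(records)) {
    sam <- read_sam_file(records)
    if (is.null(header)) header <- sam$header
    records <- sam$records
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mapped <- !is_unmapped(records$flag, records$contig)
  rec <- records[mapped, , drop = FALSE]
  idx <- integer(nrow(rec))
  pos0 <- rec$pos - 1
  for (ctg in unique(rec$contig)) {
    sel <- rec$contig == ctg
    idx[sel] <- region_index_for(rs, ctg, pos0[sel])
  }
  files <- file.path(out_dir, sprintf("region.%04d.sam", rs$index))
  counts <- integer(nrow(rs))
  for (r in seq_len(nrow(rs))) {
    sub <- rec[idx == r, , drop = FALSE]
    ord <- order(sub$pos, sub$qname, method = "radix")
    writeLines(sub$raw[ord], files[r])
    counts[r] <- nrow(sub)
  }
  unmapped_path <- file.path(out_dir, "unmapped.sam")
  writeLines(records$raw[!mapped], unmapped_path)
  if (!is.null(header)) {
    writeLines(header, file.path(out_dir, "header.sam"))
  }
  list(files = files, unmapped = unmapped_path, counts = counts,
       n_unmapped = sum(!mapped))
}
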