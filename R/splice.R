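#' Splice-junction tables (SJ.out.tab)
#'
#' Two-pass RNA-seq alignment discovers splice junctions in pass 1 and needs
#' them merged into a single table before the genome index is rebuilt. The
#' 9-column tab-separated layout is the STAR `SJ.out.tab` convention:
#' contig, intron start and end (1-based, inclusive), strand (0 undefined,
#' 1 +, 2 -), intron motif code (0-6), annotated flag (0/1), number of
#' uniquely mapping reads crossing the junction, number of multi-mapping
#' reads, and the maximal spliced-alignment overhang.
#'
#' @param path SJ.out.tab file path.
#' @return data.frame with columns `contig`, `intron_start`, `intron_end`,
#'   `strand`, `motif`, `annotated`, `n_unique`, `n_multi`, `max_overhang`.
#' @export
read_sj_file <- function(path) {
  cols <- c("contig", "intron_start", "intron_end", "strand", "motif",
            "annotated", "n_unique", "n_multi", "max_overhang")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(read_empty_sj())
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(f, length, 1L) != 9L)
  if (length(bad)) {
    stop(sprintf("malformed SJ line %d in %s: expected 9 columns",
                 bad[1L], path), call. = FALSE)
  }
  df <- data.frame(
    contig = vapply(f, `[[`, "", 1L),
    stringsAsFactors = FALSE
  )
  for (j in 2:9) df[[cols[j]]] <- as.numeric(vapply(f, `[[`, "", j))
  if (anyNA(df[-1L])) stop("non-numeric SJ field in ", path, call. = FALSE)
  df
}

#' Write a splice-junction table
#' @param sj data.frame as from [read_sj_file()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sj_file <- function(sj, path) {
  if (nrow(sj) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  writeLines(sprintf("%s\t%.0f\t%.0f\t%.0f\t%.0f\t%.0f\t%.0f\t%.0f\t%.0f",
                     sj$contig, sj$intron_start, sj$intron_end, sj$strand,
                     sj$motif, sj$annotated, sj$n_unique, sj$n_multi,
                     sj$max_overhang),
             path)
  invisible(path)
}

#' Merge splice-junction tables from parallel alignment chunks
#'
#' Rows are identified by the key (contig, intron_start, intron_end, strand,
#' motif). Duplicate keys across inputs are collapsed to one row: unique and
#' multi-mapping support counts are summed, the annotated flag and maximal
#' overhang are maximised. Output is sorted by (contig order, intron_start,
#' intron_end, strand, motif), which makes the merge associative and
#' insensitive to input order — merging the same files in any order yields
#' byte-identical output.
#'
#' @param inputs character vector of SJ.out.tab paths (may be empty).
#' @param ref optional [reference_dict()] fixing the contig sort order;
#'   without it contigs sort lexicographically (C locale).
#' @param out optional output path; when given the merged table is written
#'   there.
#' @return The merged data.frame, invisibly when `out` is given.
#' @export
merge_splice_junctions <- function(inputs, ref = NULL, out = NULL) {
  tabs <- lapply(inputs, read_sj_file)
  all <- if (length(tabs)) do.call(rbind, tabs) else read_empty_sj()
  merged <- aggregate_sj(all, ref = ref)
  if (!is.null(out)) {
    write_sj_file(merged, out)
    return(invisible(merged))
  }
  merged
}

# Collapse duplicate junction keys and impose the canonical sort order.
aggregate_sj <- function(all, ref = NULL) {
  if (nrow(all) == 0L) return(all)
  key <- paste(all$contig, all$intron_start, all$intron_end, all$strand,
               all$motif, sep = "\r")
  grp <- match(key, unique(key))
  first <- !duplicated(grp)
  merged <- all[first, , drop = FALSE]
  ord_grp <- grp[first]
  merged$n_unique <- as.vector(tapply(all$n_unique, grp, sum))[ord_grp]
  merged$n_multi <- as.vector(tapply(all$n_multi, grp, sum))[ord_grp]
  merged$max_overhang <- as.vector(tapply(all$max_overhang, grp, max))[ord_grp]
  merged$annotated <- as.vector(tapply(all$annotated, grp, max))[ord_grp]
  contig_rank <- if (is.null(ref)) {
    match(merged$contig, sort(unique(merged$contig), method = "radix"))
  } else {
    match(merged$contig, ref$contigs$name)
  }
  if (anyNA(contig_rank)) {
    stop("SJ contig absent from reference", call. = FALSE)
  }
  merged <- merged[order(contig_rank, merged$intron_start,
                         merged$intron_end, merged$strand, merged$motif,
                         method = "radix"), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

read_empty_sj <- function() {
  data.frame(contig = character(0), intron_start = numeric(0),
             intron_end = numeric(0), strand = numeric(0),
             motif = numeric(0), annotated = numeric(0),
             n_unique = numeric(0), n_multi = numeric(0),
             max_overhang = numeric(0), stringsAsFactors = FALSE)
}
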