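#' Split FASTQ input into chunks of nearly equal size
#'
#' Distributes 4-line FASTQ records into contiguous chunks so that parallel
#' aligner instances get nearly equal work: every chunk holds
#' `ceil(total / n_chunks)` records except a possibly smaller final chunk.
#' Paired files are cut at identical record-index boundaries, so chunk i of
#' each mate carries the same fragments in the same order. Concatenating the
#' chunks of one mate reproduces its input byte-identically.
#'
#' When `total < n_chunks * ceil(total/n_chunks)` the tail chunks would be
#' empty; only non-empty chunks are created, so fewer than `n_chunks` files
#' may come back.
#'
#' @param inputs character vector of 1 (single-end) or 2 (paired) FASTQ
#'   paths.
#' @param n_chunks requested number of chunks (>= 1); typically the worker
#'   count, so every thread gets one chunk.
#' @param out_dir output directory (created if missing).
#' @return List with `chunks` — a list of character vectors (length 1 or 2:
#'   the chunk paths for each mate) — and `n_records` (records per input
#'   file).
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c(sapply(1:10, function(i)
#'   c(paste0("@r", i), "ACGT", "+", "IIII"))), fq)
#' sp <- split_fastq(fq, 3, tempfile())
#' length(sp$chunks)  # 3 chunks (of 4, 4 and 2 records)
#' @export
split_fastq <- function(inputs, n_chunks, out_dir) {
  if (!length(inputs) %in% c(1L, 2L)) {
    stop("inputs must be 1 or 2 FASTQ paths", call. = FALSE)
  }
  if (n_chunks < 1 || n_chunks != floor(n_chunks)) {
    stop("n_chunks must be a positive integer", call. = FALSE)
  }
  all_lines <- lapply(inputs, readLines)
  n_rec <- integer(length(inputs))
  for (i in seq_along(inputs)) {
    if (length(all_lines[[i]]) %% 4L != 0L) {
      stop("ragged FASTQ (line count not a multiple of 4): ", inputs[i],
           call. = FALSE)
    }
    n_rec[i] <- length(all_lines[[i]]) %/% 4L
  }
  if (length(inputs) == 2L && n_rec[1L] != n_rec[2L]) {
    stop(sprintf("paired inputs of unequal length (%d vs %d records)",
                 n_rec[1L], n_rec[2L]), call. = FALSE)
  }
  total <- n_rec[1L]
  if (total == 0L) stop("no FASTQ records in ", inputs[1L], call. = FALSE)
  per <- ceiling(total / n_chunks)
  starts <- seq(1L, total, by = per)          # record-index chunk boundaries
  ends <- pmin(starts + per - 1L, total)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chunks <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    paths <- character(length(inputs))
    for (i in seq_along(inputs)) {
      suffix <- if (length(inputs) == 2L) sprintf("_%d", i) else ""
      paths[i] <- file.path(out_dir,
                            sprintf("chunk.%04d%s.fastq", k, suffix))
      lo <- (starts[k] - 1L) * 4L + 1L
      hi <- ends[k] * 4L
      writeLines(all_lines[[i]][lo:hi], paths[i])
    }
    chunks[[k]] <- paths
  }
  list(chunks = chunks, n_records = n_rec)
}
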