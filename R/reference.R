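#' Reference dictionary: ordered contig names and lengths
#'
#' A `ReferenceDict` is the minimal reference-genome metadata the load
#' balancer needs: the ordered list of contigs with their lengths in base
#' pairs. Contig order is the file order of the index and defines the global
#' sort order used for every downstream output (region sets, merged
#' splice-junction tables, merged VCFs), matching the SAM/VCF convention of
#' dictionary-ordered records.
#'
#' @param names character vector of contig names (unique, non-empty).
#' @param lengths integer-valued vector of contig lengths in base pairs
#'   (all >= 1), parallel to `names`.
#'
#' @return An object of class `ReferenceDict`: a list with elements
#'   `contigs` (a data.frame with columns `name`, `length`) and
#'   `total_size` (sum of all contig lengths).
#' @examples
#' ref <- reference_dict(c("chrA", "chrB"), c(1000, 500))
#' total_size(ref)
#' @export
reference_dict <- function(names, lengths) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (length(names) == 0L) {
    stop("reference has no contigs", call. = FALSE)
  }
  if (length(names) != length(lengths)) {
    stop("contig names and lengths differ in length", call. = FALSE)
  }
  if (anyDuplicated(names)) {
    dup <- unique(names[duplicated(names)])
    stop("duplicate contig name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(names)) || any(is.na(names))) {
    stop("contig names must be non-empty", call. = FALSE)
  }
  if (any(is.na(lengths)) || any(lengths < 1) || any(lengths != floor(lengths))) {
    stop("contig lengths must be positive integers", call. = FALSE)
  }
  structure(
    list(
      contigs = data.frame(name = names, length = lengths,
                           stringsAsFactors = FALSE),
      total_size = sum(lengths)
    ),
    class = "ReferenceDict"
  )
}

#' @export
print.ReferenceDict <- function(x, ...) {
  cat(sprintf("ReferenceDict: %d contig(s), %s bp total\n",
              nrow(x$contigs), format(x$total_size, big.mark = ",")))
  utils::head(x$contigs, 10L) |> print(row.names = FALSE)
  if (nrow(x$contigs) > 10L) cat("...\n")
  invisible(x)
}

#' Total reference size in base pairs
#'
#' @param ref a [reference_dict()] object.
#' @return Numeric scalar: sum of all contig lengths.
#' @export
total_size <- function(ref) {
  stopifnot(inherits(ref, "ReferenceDict"))
  ref$total_size
}

#' Length of one contig
#' @param ref a [reference_dict()] object.
#' @param contig contig name.
#' @return Numeric scalar length in bp.
#' @keywords internal
contig_length <- function(ref, contig) {
  i <- match(contig, ref$contigs$name)
  if (is.na(i)) stop("unknown contig: ", contig, call. = FALSE)
  ref$contigs$length[i]
}

#' Load contig names and sizes from a FASTA index or sequence dictionary
#'
#' Reads the two sidecar formats that record contig inventories: a samtools
#' FASTA index (`.fai`; five or more tab-separated columns, name and length
#' first) or a Picard-style sequence dictionary (`.dict`; `@SQ` header lines
#' with `SN:` and `LN:` tags). Contigs are returned in file order.
#'
#' @param path path to the index file.
#' @param format `"auto"` (default; decided from the file extension and
#'   content), `"fai"`, or `"dict"`.
#' @return A [reference_dict()].
#' @examples
#' fai <- tempfile(fileext = ".fai")
#' writeLines(c("chrA\t1000\t6\t60\t61", "chrB\t500\t1030\t60\t61"), fai)
#' load_reference_index(fai)
#' @export
load_reference_index <- function(path, format = c("auto", "fai", "dict")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "dict" || any(startsWith(lines, "@"))) "dict" else "fai"
  }
  lines_kept <- which(nzchar(lines))
  if (length(lines_kept) == 0L) {
    stop("no contigs in ", path, call. = FALSE)
  }
  if (format == "fai") {
    fields <- strsplit(lines[lines_kept], "\t", fixed = TRUE)
    bad <- which(vapply(fields, length, 1L) < 2L)
    if (length(bad)) {
      stop(sprintf("malformed .fai line %d in %s", lines_kept[bad[1L]], path),
           call. = FALSE)
    }
    nm <- vapply(fields, `[[`, "", 1L)
    len <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    if (anyNA(len)) {
      bad <- lines_kept[which(is.na(len))[1L]]
      stop(sprintf("malformed .fai line %d in %s: non-numeric length",
                   bad, path), call. = FALSE)
    }
  } else {
    sq <- which(startsWith(lines, "@SQ"))
    if (length(sq) == 0L) stop("no contigs in ", path, call. = FALSE)
    nm <- character(length(sq))
    len <- numeric(length(sq))
    for (k in seq_along(sq)) {
      tags <- strsplit(lines[sq[k]], "\t", fixed = TRUE)[[1L]]
      sn <- tags[startsWith(tags, "SN:")]
      ln <- tags[startsWith(tags, "LN:")]
      if (length(sn) != 1L || length(ln) != 1L) {
        stop(sprintf("malformed @SQ line %d in %s: need SN: and LN: tags",
                     sq[k], path), call. = FALSE)
      }
      nm[k] <- substring(sn, 4L)
      lnum <- suppressWarnings(as.numeric(substring(ln, 4L)))
      if (is.na(lnum)) {
        stop(sprintf("malformed @SQ line %d in %s: non-numeric LN", sq[k], path),
             call. = FALSE)
      }
      len[k] <- lnum
    }
  }
  reference_dict(nm, len)
}

#' Write a reference dictionary as .fai-style lines
#'
#' Emits one tab-separated line per contig (name, length, offset, linebases,
#' linewidth) assuming a 60-column FASTA layout, so the result round-trips
#' through [load_reference_index()] and matches `samtools faidx` output for
#' FASTA files written by [gen_reference()].
#'
#' @param ref a [reference_dict()].
#' @param path output path.
#' @param linebases sequence-line width assumed for the offset columns.
#' @return `path`, invisibly.
#' @export
write_fai <- function(ref, path, linebases = 60L) {
  stopifnot(inherits(ref, "ReferenceDict"))
  nm <- ref$contigs$name
  len <- ref$contigs$length
  # byte offsets for ">name\n" headers plus newline-terminated 60-char lines
  seq_bytes <- len + ceiling(len / linebases)
  hdr_bytes <- nchar(nm, type = "bytes") + 2
  offset <- cumsum(c(0, utils::head(seq_bytes + hdr_bytes, -1L))) + hdr_bytes
  writeLines(sprintf("%s\t%.0f\t%.0f\t%d\t%d", nm, len, offset,
                     linebases, linebases + 1L), path)
  invisible(path)
}
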