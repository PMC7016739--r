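#' Region sets: contiguous intervals tiling the reference
#'
#' A `RegionSet` is an ordered table of genomic intervals that exactly tiles
#' its reference: for every contig the union of its regions is `[0, length)`
#' with no overlap and no gap. Regions are the unit of per-task work in the
#' per-region variant-calling stage. Coordinates are 0-based half-open
#' everywhere inside the package; 1-based SAM/VCF positions are converted at
#' the boundary.
#'
#' @param regions data.frame with columns `contig` (character), `start`
#'   (0-based inclusive), `end` (exclusive); rows ordered by (contig order in
#'   `ref`, start).
#' @param ref the governing [reference_dict()].
#' @param level `"static"` (from contig sizes alone) or `"dynamic"` (refined
#'   by observed read counts).
#' @param requested the user-requested number of regions, recorded for
#'   provenance (the realised count usually differs).
#'
#' @return An object of class `RegionSet`: the region data.frame with an
#'   `index` column (1-based rank) and attributes `ref`, `level`,
#'   `requested`.
#' @export
region_set <- function(regions, ref, level = c("static", "dynamic"),
                       requested = NA_integer_) {
  level <- match.arg(level)
  stopifnot(inherits(ref, "ReferenceDict"),
            is.data.frame(regions),
            all(c("contig", "start", "end") %in% names(regions)))
  rs <- data.frame(contig = as.character(regions$contig),
                   start = as.numeric(regions$start),
                   end = as.numeric(regions$end),
                   stringsAsFactors = FALSE)
  ord <- order(match(rs$contig, ref$contigs$name), rs$start, method = "radix")
  rs <- rs[ord, , drop = FALSE]
  rs$index <- seq_len(nrow(rs))
  rownames(rs) <- NULL
  out <- structure(rs, class = c("RegionSet", "data.frame"),
                   ref = ref, level = level,
                   requested = as.integer(requested))
  validate_region_set(out)
  out
}

#' Check the tiling invariant of a RegionSet
#'
#' Errors unless every contig of the governing reference is covered by its
#' regions exactly once: starts at 0, ends at the contig length, each region
#' begins where the previous one ends, and no region is empty or spans two
#' contigs.
#'
#' @param rs a [region_set()].
#' @return `rs`, invisibly.
#' @export
validate_region_set <- function(rs) {
  ref <- attr(rs, "ref")
  stopifnot(inherits(rs, "RegionSet"), inherits(ref, "ReferenceDict"))
  if (any(is.na(match(rs$contig, ref$contigs$name)))) {
    stop("region on contig absent from reference", call. = FALSE)
  }
  if (any(rs$start >= rs$end)) stop("empty or inverted region", call. = FALSE)
  for (i in seq_len(nrow(ref$contigs))) {
    nm <- ref$contigs$name[i]
    len <- ref$contigs$length[i]
    sub <- rs[rs$contig == nm, , drop = FALSE]
    if (nrow(sub) == 0L) stop("contig ", nm, " has no regions", call. = FALSE)
    if (sub$start[1L] != 0) stop("contig ", nm, " not covered from 0",
                                 call. = FALSE)
    if (sub$end[nrow(sub)] != len) {
      stop("contig ", nm, " not covered to its length", call. = FALSE)
    }
    if (nrow(sub) > 1L &&
        any(sub$start[-1L] != sub$end[-nrow(sub)])) {
      stop("gap or overlap in regions of contig ", nm, call. = FALSE)
    }
  }
  invisible(rs)
}

#' @export
print.RegionSet <- function(x, ...) {
  cat(sprintf("RegionSet (%s): %d region(s), %d requested\n",
              attr(x, "level"), nrow(x), attr(x, "requested")))
  print.data.frame(utils::head(x, 12L), row.names = FALSE)
  if (nrow(x) > 12L) cat("...\n")
  invisible(x)
}

#' Number of regions in a set
#' @param rs a [region_set()].
#' @return Integer region count (RsLB for a static set, RdLB for a dynamic
#'   one).
#' @export
n_regions <- function(rs) {
  stopifnot(inherits(rs, "RegionSet"))
  nrow(rs)
}

#' Write a RegionSet as BED
#'
#' Standard 4-column BED: contig, 0-based start, exclusive end, region index
#' as the name column.
#'
#' @param rs a [region_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(rs, path) {
  stopifnot(inherits(rs, "RegionSet"))
  writeLines(sprintf("%s\t%.0f\t%.0f\t%d", rs$contig, rs$start, rs$end,
                     rs$index), path)
  invisible(path)
}

#' Read a BED file written by [write_region_bed()]
#' @param path BED path.
#' @return data.frame with contig/start/end/index columns (no reference
#'   attached).
#' @export
read_region_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(contig = character(), start = numeric(),
                      end = numeric(), index = integer()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(f, length, 1L) < 3L)) stop("malformed BED line", call. = FALSE)
  data.frame(
    contig = vapply(f, `[[`, "", 1L),
    start = as.numeric(vapply(f, `[[`, "", 2L)),
    end = as.numeric(vapply(f, `[[`, "", 3L)),
    index = vapply(f, function(x) {
      if (length(x) >= 4L) as.integer(x[[4L]]) else NA_integer_
    }, 1L),
    stringsAsFactors = FALSE
  )
}

# Map 0-based positions on one contig to global region indices of rs.
# Positions must lie in [0, contig length).
region_index_for <- function(rs, contig, pos0) {
  ref <- attr(rs, "ref")
  len <- contig_length(ref, contig)  # errors on unknown contig
  if (length(pos0) == 0L) return(integer(0))
  if (any(pos0 < 0 | pos0 >= len)) {
    stop("position out of bounds on contig ", contig, call. = FALSE)
  }
  sub <- which(rs$contig == contig)
  k <- findInterval(pos0, rs$start[sub])
  rs$index[sub][k]
}
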