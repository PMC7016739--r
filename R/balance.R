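#' Two-stage genomic load balancing
#'
#' The per-region variant-calling stage of a scatter-gather pipeline is only
#' as fast as its slowest region, so regions should carry similar work. The
#' balancer runs in two stages:
#'
#' * **Static** ([static_partition()]): before any reads are seen, the
#'   genome is cut into regions using contig sizes alone. The target region
#'   size is `avgSizeStatic = total genome size / numRegions`; a contig of
#'   length L is split into `k = max(1, floor(L / avgSizeStatic))`
#'   equal-length pieces. Small contigs always keep one region of their own,
#'   so the realised region count (RsLB) is usually larger than the request.
#' * **Dynamic** ([dynamic_partition()]): after mapping, the observed
#'   per-region mapped-read counts refine the static partition. The target
#'   load is `avgSizeDynamic = total mapped reads / RsLB`; a region holding
#'   n reads is split into `k = floor(n / avgSizeDynamic)` sub-regions (when
#'   k >= 2) at read-count quantiles, so RNA-seq coverage hotspots stop
#'   being stragglers. The realised count is RdLB >= RsLB.
#'
#' @name load_balancing
NULL

# Exact floor(num/den) for non-negative integer-valued doubles.
# Division alone can land on the wrong side of an integer when num/den is
# barely above or below it; products below 2^53 are exact, so correct with
# them.
exact_floor_div <- function(num, den) {
  stopifnot(den > 0)
  q <- floor(num / den)
  q <- q - (q * den > num)
  q <- q + ((q + 1) * den <= num)
  q
}

#' Target static region size (bp)
#'
#' The target size of each region under static load balancing: total genome
#' size divided by the requested number of regions. No rounding is applied;
#' flooring happens only when per-contig split counts are derived.
#'
#' @param ref a [reference_dict()].
#' @param num_regions requested number of regions (>= 1).
#' @return Numeric: `total_size(ref) / num_regions`.
#' @examples
#' ref <- reference_dict(c("c1", "c2", "c3"), c(300, 100, 100))
#' avg_size_static(ref, 5)  # 100
#' @export
avg_size_static <- function(ref, num_regions) {
  stopifnot(inherits(ref, "ReferenceDict"))
  if (length(num_regions) != 1L || is.na(num_regions) || num_regions < 1 ||
      num_regions != floor(num_regions)) {
    stop("num_regions must be a positive integer", call. = FALSE)
  }
  total_size(ref) / num_regions
}

#' Static partition of the reference by contig sizes
#'
#' Cuts the genome along contig boundaries first, then splits any contig
#' whose length exceeds a multiple of the target size
#' (`avgSizeStatic = total/num_regions`) into
#' `k = max(1, floor(L / avgSizeStatic))` equal pieces, remainder bases on
#' the last piece. Every contig keeps at least one region, so the realised
#' region count RsLB is `>= max(num_regions adjusted, number of contigs)`
#' and typically exceeds the request.
#'
#' @inheritParams avg_size_static
#' @return A `StaticPlan`: list with `ref`, `num_regions`,
#'   `avg_size_static`, and `region_set` (a static [region_set()]); `rslb`
#'   records the realised region count.
#' @examples
#' ref <- reference_dict(c("c1", "c2", "c3"), c(300, 100, 100))
#' plan <- static_partition(ref, 5)
#' plan$rslb  # 5: c1 split in 3, the others kept whole
#' @export
static_partition <- function(ref, num_regions) {
  avg <- avg_size_static(ref, num_regions)  # validates inputs
  total <- total_size(ref)
  pieces <- lapply(seq_len(nrow(ref$contigs)), function(i) {
    L <- ref$contigs$length[i]
    # k = floor(L/avg) = floor(L*num_regions/total), exactly
    k <- max(1, exact_floor_div(L * num_regions, total))
    size <- L %/% k
    start <- (seq_len(k) - 1) * size
    end <- c(start[-1L], L)  # remainder bases go to the last piece
    data.frame(contig = ref$contigs$name[i], start = start, end = end,
               stringsAsFactors = FALSE)
  })
  rs <- region_set(do.call(rbind, pieces), ref, level = "static",
                   requested = num_regions)
  structure(
    list(ref = ref, num_regions = as.integer(num_regions),
         avg_size_static = avg, region_set = rs, rslb = n_regions(rs)),
    class = "StaticPlan"
  )
}

#' @export
print.StaticPlan <- function(x, ...) {
  cat(sprintf("StaticPlan: %d region(s) realised (RsLB) for %d requested; target %.1f bp\n",
              x$rslb, x$num_regions, x$avg_size_static))
  invisible(x)
}

#' Count mapped reads per static region
#'
#' Routes each mapped record to the region containing its leftmost mapping
#' position (1-based SAM position converted to 0-based on ingest). Unmapped
#' records are counted separately and excluded. The per-region sorted read
#' start positions are retained so [dynamic_partition()] can pick its cut
#' points.
#'
#' @param records SAM records as returned by [read_sam_file()] (data.frame
#'   with `qname`, `flag`, `contig`, `pos` columns), or a path to a SAM
#'   file.
#' @param plan a [static_partition()] plan (any `RegionSet` also works).
#' @return A `RegionProfile`: list with `region_set`, `counts` (one
#'   non-negative integer per region), `positions` (per-region sorted
#'   0-based starts), `total_reads` (sum of counts) and `n_unmapped`.
#' @export
profile_regions <- function(records, plan) {
  rs <- if (inherits(plan, "StaticPlan")) plan$region_set else plan
  stopifnot(inherits(rs, "RegionSet"))
  if (is.character(records)) records <- read_sam_file(records)$records
  mapped <- !is_unmapped(records$flag, records$contig)
  n_unmapped <- sum(!mapped)
  rec <- records[mapped, , drop = FALSE]
  pos0 <- rec$pos - 1
  idx <- integer(nrow(rec))
  for (ctg in unique(rec$contig)) {
    sel <- rec$contig == ctg
    idx[sel] <- region_index_for(rs, ctg, pos0[sel])
  }
  positions <- vector("list", nrow(rs))
  for (r in seq_len(nrow(rs))) positions[[r]] <- sort(pos0[idx == r])
  counts <- lengths(positions)
  structure(
    list(region_set = rs, counts = as.integer(counts), positions = positions,
         total_reads = sum(counts), n_unmapped = n_unmapped),
    class = "RegionProfile"
  )
}

#' @export
print.RegionProfile <- function(x, ...) {
  cat(sprintf("RegionProfile: %d region(s), %d mapped read(s), %d unmapped\n",
              length(x$counts), x$total_reads, x$n_unmapped))
  invisible(x)
}

#' Target dynamic region load (reads)
#'
#' The target number of reads per region under dynamic load balancing: total
#' mapped reads divided by the static region count RsLB.
#'
#' @param profile a [profile_regions()] result.
#' @return Numeric: `total mapped reads / RsLB`.
#' @export
avg_size_dynamic <- function(profile) {
  stopifnot(inherits(profile, "RegionProfile"))
  rslb <- length(profile$counts)
  if (rslb < 1L) stop("empty region set", call. = FALSE)
  profile$total_reads / rslb
}

#' Dynamic refinement of a static partition by observed read counts
#'
#' Splits any static region whose read count n reaches at least twice the
#' target load (`k = floor(n / avgSizeDynamic) >= 2`) into k sub-regions.
#' Cut coordinates sit at read-count quantiles: for j = 1..k-1 the cut falls
#' between the ceil(j*n/k)-th read start and the next, so sub-region read
#' counts differ by at most 1 wherever read positions are distinct. When the
#' quantile falls inside a run of reads sharing one start coordinate, no cut
#' can separate them; the cut shifts to the nearest boundary between
#' distinct starts, which keeps every sub-region's load below
#' `2 * avgSizeDynamic` plus the size of the tie run and never produces a
#' zero-length region. In the extreme — all reads of the region at one
#' coordinate — the region is kept whole. Sub-regions tile their parent
#' exactly, so the dynamic set still tiles the reference and RdLB >= RsLB.
#'
#' @param profile a [profile_regions()] result against the static plan; it
#'   carries the per-region sorted read start positions used for cutting.
#' @return A `DynamicPlan`: list with `profile`, `avg_size_dynamic`,
#'   `region_set` (a dynamic [region_set()]), `counts` (reads per dynamic
#'   region), `parent` (static region index of each dynamic region), and
#'   `rdlb`.
#' @export
dynamic_partition <- function(profile) {
  stopifnot(inherits(profile, "RegionProfile"))
  rs <- profile$region_set
  avg <- avg_size_dynamic(profile)
  total <- profile$total_reads
  rslb <- length(profile$counts)
  out <- vector("list", nrow(rs))
  for (r in seq_len(nrow(rs))) {
    n <- profile$counts[r]
    start <- rs$start[r]; end <- rs$end[r]
    cuts <- numeric(0)
    counts_r <- n
    if (total > 0 && n > 0) {
      # k = floor(n/avg) = floor(n*RsLB/total), exactly; capped at n
      k <- min(exact_floor_div(n * rslb, total), n)
      if (k >= 2) {
        p <- profile$positions[[r]]
        valid <- which(diff(p) > 0)  # a cut can fall between p[d] and p[d+1]
        if (length(valid)) {
          targets <- ceiling(seq_len(k - 1) * n / k)
          # nearest valid boundary to each quantile (ties of tied reads
          # shift the cut minimally instead of dropping it)
          pick <- vapply(targets, function(t) {
            valid[which.min(abs(valid - t))]
          }, 1L)
          cuts <- unique(p[pick] + 1)
        }
        if (length(cuts)) {
          bounds <- c(start, cuts, end)
          counts_r <- vapply(seq_len(length(bounds) - 1L), function(j) {
            sum(p >= bounds[j] & p < bounds[j + 1L])
          }, 1)
        }
      }
    }
    out[[r]] <- data.frame(
      contig = rs$contig[r],
      start = c(start, cuts),
      end = c(cuts, end),
      parent = rs$index[r],
      count = counts_r,
      stringsAsFactors = FALSE
    )
  }
  all <- do.call(rbind, out)
  drs <- region_set(all[c("contig", "start", "end")], attr(rs, "ref"),
                    level = "dynamic", requested = attr(rs, "requested"))
  # region_set re-sorts into canonical order; realign parent/count vectors
  ord <- order(match(all$contig, attr(rs, "ref")$contigs$name), all$start,
               method = "radix")
  structure(
    list(profile = profile, avg_size_dynamic = avg, region_set = drs,
         counts = as.integer(all$count[ord]), parent = all$parent[ord],
         rdlb = n_regions(drs)),
    class = "DynamicPlan"
  )
}

#' @export
print.DynamicPlan <- function(x, ...) {
  cat(sprintf("DynamicPlan: %d region(s) (RdLB) from %d static (RsLB); target %.1f reads/region\n",
              x$rdlb, length(x$profile$counts), x$avg_size_dynamic))
  invisible(x)
}

#' Per-region load summary
#'
#' Deterministic summary of how evenly work is spread across regions,
#' suitable for comparing the maximum region load before and after dynamic
#' balancing: per-region counts and sizes plus min/max/mean and a fixed-bin
#' histogram of the load distribution.
#'
#' @param x a `RegionProfile` or `DynamicPlan`.
#' @param bins number of equal-width histogram bins over `[0, max count]`.
#' @return A `BalanceReport`: list with `regions` (data.frame: index,
#'   contig, start, end, size_bp, reads), `summary` (n, min, max, mean,
#'   total reads) and `histogram` (data.frame: bin_lo, bin_hi, n_regions).
#' @export
balance_report <- function(x, bins = 10L) {
  if (inherits(x, "DynamicPlan")) {
    rs <- x$region_set; counts <- x$counts
  } else if (inherits(x, "RegionProfile")) {
    rs <- x$region_set; counts <- x$counts
  } else {
    stop("balance_report needs a RegionProfile or DynamicPlan", call. = FALSE)
  }
  regions <- data.frame(index = rs$index, contig = rs$contig,
                        start = rs$start, end = rs$end,
                        size_bp = rs$end - rs$start, reads = counts,
                        stringsAsFactors = FALSE)
  if (nrow(regions) == 0L) {
    return(structure(list(regions = regions,
                          summary = list(n = 0L, min = NA, max = NA,
                                         mean = NA, total = 0),
                          histogram = data.frame(bin_lo = numeric(),
                                                 bin_hi = numeric(),
                                                 n_regions = integer())),
                     class = "BalanceReport"))
  }
  hi <- max(counts)
  breaks <- if (hi == 0) c(0, 1) else seq(0, hi, length.out = bins + 1L)
  h <- graphics::hist(counts, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  structure(
    list(regions = regions,
         summary = list(n = nrow(regions), min = min(counts),
                        max = max(counts), mean = mean(counts),
                        total = sum(counts)),
         histogram = data.frame(bin_lo = utils::head(h$breaks, -1L),
                                bin_hi = h$breaks[-1L],
                                n_regions = h$counts)),
    class = "BalanceReport"
  )
}

#' @export
print.BalanceReport <- function(x, ...) {
  s <- x$summary
  cat(sprintf("BalanceReport: %d region(s); reads min %s / mean %s / max %s\n",
              s$n, format(s$min), format(round(s$mean, 1)), format(s$max)))
  invisible(x)
}

#' Write a balance report as TSV
#' @param report a [balance_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_balance_tsv <- function(report, path) {
  stopifnot(inherits(report, "BalanceReport"))
  utils::write.table(report$regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a balance report as JSON
#' @inheritParams write_balance_tsv
#' @return `path`, invisibly.
#' @export
write_balance_json <- function(report, path) {
  stopifnot(inherits(report, "BalanceReport"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
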