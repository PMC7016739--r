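test_that("static target size is the exact total/num_regions ratio", {
  ref <- reference_dict("c", 1000)
  expect_equal(avg_size_static(ref, 10), 100)
  expect_equal(avg_size_static(ref, 1), 1000)
  ref3 <- reference_dict(c("a", "b", "c"), c(300, 100, 100))
  expect_equal(avg_size_static(ref3, 5), 100)
  expect_error(avg_size_static(ref, 0), "positive")
})

test_that("static partition splits contigs by the floor(L/avg) rule", {
  # contig exceeding the target splits; small contigs keep one region each
  ref <- reference_dict(c("a", "b", "c"), c(300, 100, 100))
  plan <- static_partition(ref, 5)
  expect_equal(plan$rslb, 5L)
  expect_equal(plan$region_set$contig, c("a", "a", "a", "b", "c"))
  expect_equal(plan$region_set$end - plan$region_set$start,
               c(100, 100, 100, 100, 100))

  # no contig exceeds the target: one region per contig
  ref_eq <- reference_dict(c("a", "b", "c"), c(100, 100, 100))
  expect_equal(static_partition(ref_eq, 3)$rslb, 3L)

  # single contig in equal pieces
  plan1 <- static_partition(reference_dict("c", 1000), 4)
  expect_equal(plan1$rslb, 4L)
  expect_equal(plan1$region_set$start, c(0, 250, 500, 750))

  # realised count exceeds the request when small contigs dominate
  plan2 <- static_partition(reference_dict(c("a", "b", "c"), c(250, 10, 10)), 2)
  expect_equal(plan2$rslb, 3L)
  expect_gt(plan2$rslb, plan2$num_regions)

  # remainder bases land on the last piece
  plan3 <- static_partition(reference_dict("c", 1001), 4)
  expect_equal(plan3$region_set$end, c(250, 500, 750, 1001))
})

test_that("per-contig split counts match a brute-force oracle on small references", {
  # oracle: largest k with k * avg <= L, i.e. k * total <= L * num_regions,
  # found by stepping through whole multiples (integer products are exact)
  brute_k <- function(L, nr, total) {
    k <- 0
    while ((k + 1) * total <= L * nr) k <- k + 1
    max(1L, k)
  }
  set.seed(42)
  for (case in 1:40) {
    ref <- random_ref(n_contigs = sample(1:5, 1), max_len = 5000L)
    nr <- sample(1:10, 1)
    plan <- static_partition(ref, nr)
    k_obs <- table(factor(plan$region_set$contig,
                          levels = ref$contigs$name))
    k_exp <- vapply(ref$contigs$length, brute_k, 1,
                    nr = nr, total = total_size(ref))
    expect_equal(as.numeric(k_obs), k_exp)
  }
})

test_that("flooring at exact multiples of the target size is exact", {
  # L = 3 * avg exactly: must give 3 pieces, not 2 or 4
  ref <- reference_dict(c("big", "s1", "s2"), c(600, 200, 200))
  plan <- static_partition(ref, 5)  # avg = 200
  expect_equal(sum(plan$region_set$contig == "big"), 3L)
})

test_that("read profiling attributes each mapped read to the region holding its start", {
  ref <- reference_dict("c", 300)
  plan <- static_partition(ref, 3)
  prof <- profile_regions(make_records("c", rep(0, 10)), plan)
  expect_equal(prof$counts, c(10L, 0L, 0L))
  expect_equal(prof$total_reads, 10L)

  # empty stream
  empty <- profile_regions(make_records("c", integer(0)), plan)
  expect_equal(empty$counts, c(0L, 0L, 0L))
  expect_equal(empty$total_reads, 0L)

  # boundary assignment by 0-based leftmost position
  ref2 <- reference_dict("c", 200)
  plan2 <- static_partition(ref2, 2)
  prof2 <- profile_regions(make_records("c", c(0, 99, 100, 199)), plan2)
  expect_equal(prof2$counts, c(2L, 2L))

  # unmapped records counted separately, unknown contigs rejected
  rec <- make_records(c("c", "*"), c(5, 0), flag = c(0L, 4L))
  prof3 <- profile_regions(rec, plan2)
  expect_equal(prof3$total_reads, 1L)
  expect_equal(prof3$n_unmapped, 1L)
  expect_error(profile_regions(make_records("nope", 0), plan2),
               "unknown contig")
})

test_that("dynamic target load is the exact reads/RsLB ratio", {
  ref <- reference_dict("c", 3000)
  prof <- make_profile(ref, 3, "c", c(seq(0, 999, length.out = 400),
                                      seq(1000, 1999, length.out = 100),
                                      seq(2000, 2999, length.out = 100)))
  expect_equal(prof$counts, c(400L, 100L, 100L))
  expect_equal(avg_size_dynamic(prof), 200)

  prof0 <- make_profile(reference_dict("c", 200), 2, "c", integer(0))
  expect_equal(avg_size_dynamic(prof0), 0)

  prof1 <- make_profile(reference_dict("c", 50), 1, "c", rep(3, 7))
  expect_equal(avg_size_dynamic(prof1), 7)
})

test_that("dynamic refinement splits hot regions at read-count quantiles", {
  ref <- reference_dict("c", 3000)
  prof <- make_profile(ref, 3, "c", c(0:399 * 2, # distinct, in [0, 800)
                                      seq(1000, 1999, length.out = 100),
                                      seq(2000, 2999, length.out = 100)))
  expect_equal(prof$counts, c(400L, 100L, 100L))
  dplan <- dynamic_partition(prof)
  expect_equal(dplan$rdlb, 4L)
  # region 1 split into two halves of 200 reads each
  expect_equal(dplan$counts[1:2], c(200L, 200L))
  expect_equal(dplan$parent[1:2], c(1L, 1L))

  # uniform counts: nothing splits
  prof_u <- make_profile(ref, 3, "c",
                         c(0:99 * 10, 1000 + 0:99 * 10, 2000 + 0:99 * 10))
  expect_equal(dynamic_partition(prof_u)$rdlb, 3L)

  # all reads of a hot region at one coordinate: kept whole (no valid cut)
  prof_t <- make_profile(ref, 3, "c", c(rep(5, 400),
                                        seq(1000, 1999, length.out = 100),
                                        seq(2000, 2999, length.out = 100)))
  dplan_t <- dynamic_partition(prof_t)
  expect_equal(dplan_t$rdlb, 3L)
  expect_equal(dplan_t$counts[1L], 400L)
})

test_that("dynamic refinement preserves tiling, nesting and read conservation", {
  set.seed(99)
  for (case in 1:25) {
    ref <- random_ref(n_contigs = sample(1:6, 1), max_len = 30000L)
    nr <- sample(1:12, 1)
    plan <- static_partition(ref, nr)
    # clustered positions: most reads piled on the first contig
    n_reads <- sample(200:1000, 1)
    ctg <- sample(ref$contigs$name, n_reads, replace = TRUE,
                  prob = c(5, rep(1, nrow(ref$contigs) - 1L)))
    pos0 <- vapply(ctg, function(cg) {
      L <- ref$contigs$length[match(cg, ref$contigs$name)]
      sample.int(L, 1L) - 1L
    }, 1)
    prof <- profile_regions(make_records(ctg, pos0), plan)
    dplan <- dynamic_partition(prof)

    # monotone region counts: RdLB >= RsLB >= number of contigs
    expect_gte(plan$rslb, nrow(ref$contigs))
    expect_gte(dplan$rdlb, plan$rslb)

    # both levels tile the reference exactly (brute-force coverage)
    expect_tiles_reference(plan$region_set, ref)
    expect_tiles_reference(dplan$region_set, ref)

    # refinement: every dynamic region nests in its static parent, and
    # merging siblings recovers the static set
    srs <- plan$region_set
    expect_true(all(dplan$region_set$start >= srs$start[dplan$parent] &
                      dplan$region_set$end <= srs$end[dplan$parent]))
    merged <- stats::aggregate(
      cbind(start = dplan$region_set$start, end = dplan$region_set$end),
      by = list(parent = dplan$parent), FUN = min
    )
    merged$end <- stats::aggregate(dplan$region_set$end,
                                   by = list(parent = dplan$parent),
                                   FUN = max)$x
    expect_equal(merged$start, srs$start)
    expect_equal(merged$end, srs$end)

    # conservation: re-profiling against the dynamic set keeps the total
    reprof <- profile_regions(make_records(ctg, pos0), dplan$region_set)
    expect_equal(reprof$total_reads, prof$total_reads)
    expect_equal(reprof$counts, dplan$counts)

    # load bound: count <= 2*avg + ties at the region's cut boundaries
    if (prof$total_reads > 0) {
      avg <- avg_size_dynamic(prof)
      ties <- vapply(seq_len(dplan$rdlb), function(r) {
        p <- reprof$positions[[r]]
        if (length(p) == 0L) return(0L)
        max(table(p))
      }, 1L)
      expect_true(all(dplan$counts <= 2 * avg + ties))
    }
  }
})

test_that("balance reports capture the pre/post refinement load drop", {
  ref <- reference_dict("c", 3000)
  prof <- make_profile(ref, 3, "c", c(0:399 * 2,
                                      seq(1000, 1999, length.out = 100),
                                      seq(2000, 2999, length.out = 100)))
  pre <- balance_report(prof)
  expect_equal(pre$summary$max, 400L)
  expect_equal(pre$summary$total, 600L)

  post <- balance_report(dynamic_partition(prof))
  expect_lte(post$summary$max, 2 * avg_size_dynamic(prof) + 1)
  expect_lt(post$summary$max, pre$summary$max)
  expect_equal(post$summary$total, 600L)
  expect_equal(sum(post$histogram$n_regions), post$summary$n)

  single <- balance_report(make_profile(reference_dict("c", 100), 1,
                                        "c", c(1, 2, 3)))
  expect_equal(single$summary$min, single$summary$max)
  expect_equal(single$summary$max, 3L)

  tsv <- tempfile(fileext = ".tsv")
  json <- tempfile(fileext = ".json")
  write_balance_tsv(post, tsv)
  write_balance_json(post, json)
  expect_equal(nrow(utils::read.delim(tsv)), post$summary$n)
  expect_equal(jsonlite::fromJSON(json)$summary$total, 600L)
})
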