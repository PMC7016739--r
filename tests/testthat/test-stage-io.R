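test_that("FASTQ chunking follows the ceil rule and concatenates back byte-identically", {
  fq <- write_fastq(tempfile(fileext = ".fastq"), sprintf("r%03d", 1:100))
  sp <- split_fastq(fq, 4, tempfile())
  expect_length(sp$chunks, 4L)
  sizes <- vapply(sp$chunks, function(p) length(readLines(p[1])) / 4, 1)
  expect_equal(sizes, rep(25, 4))

  # 10 records into 3 chunks: 4, 4, 2
  fq10 <- write_fastq(tempfile(fileext = ".fastq"), sprintf("r%02d", 1:10))
  sp10 <- split_fastq(fq10, 3, tempfile())
  expect_equal(vapply(sp10$chunks, function(p) length(readLines(p[1])) / 4, 1),
               c(4, 4, 2))

  # concatenation reproduces the input exactly
  cat_lines <- unlist(lapply(sp10$chunks, function(p) readLines(p[1])))
  expect_identical(cat_lines, readLines(fq10))
})

test_that("paired FASTQ chunks share record boundaries so mates stay aligned", {
  qn <- sprintf("frag%03d", 1:11)
  fq1 <- write_fastq(tempfile(), paste0(qn, "/1"))
  fq2 <- write_fastq(tempfile(), paste0(qn, "/2"))
  sp <- split_fastq(c(fq1, fq2), 4, tempfile())
  expect_length(sp$chunks, 4L)
  for (pair in sp$chunks) {
    n1 <- sub("/1$", "", grep("^@", readLines(pair[1]), value = TRUE))
    n2 <- sub("/2$", "", grep("^@", readLines(pair[2]), value = TRUE))
    expect_identical(n1, n2)
  }
})

test_that("ragged or mismatched FASTQ input is rejected", {
  bad <- tempfile()
  writeLines(c("@r1", "ACGT", "+"), bad)  # 3 lines
  expect_error(split_fastq(bad, 2, tempfile()), "ragged")

  fq1 <- write_fastq(tempfile(), c("a/1", "b/1"))
  fq2 <- write_fastq(tempfile(), c("a/2"))
  expect_error(split_fastq(c(fq1, fq2), 2, tempfile()), "unequal")
})

sj_row <- function(contig, s, e, strand = 1, motif = 2, annot = 0,
                   nu = 1, nm = 0, oh = 20) {
  sprintf("%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%d", contig, s, e, strand,
          motif, annot, nu, nm, oh)
}

test_that("splice-junction merge unions disjoint keys and aggregates duplicates", {
  f1 <- tempfile(); f2 <- tempfile()
  writeLines(c(sj_row("c1", 100, 200), sj_row("c1", 300, 400),
               sj_row("c2", 50, 80)), f1)
  writeLines(c(sj_row("c1", 500, 600), sj_row("c2", 10, 30)), f2)
  m <- merge_splice_junctions(c(f1, f2))
  expect_equal(nrow(m), 5L)
  expect_equal(m$intron_start, c(100, 300, 500, 10, 50))

  # duplicate key: support summed, overhang and annotated maximised
  writeLines(sj_row("c1", 100, 200, nu = 5, oh = 20, annot = 0), f1)
  writeLines(sj_row("c1", 100, 200, nu = 7, oh = 31, annot = 1), f2)
  m2 <- merge_splice_junctions(c(f1, f2))
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$n_unique, 12)
  expect_equal(m2$max_overhang, 31)
  expect_equal(m2$annotated, 1)

  # empty input list gives an empty zero-row file
  out <- tempfile()
  merge_splice_junctions(character(0), out = out)
  expect_equal(length(readLines(out)), 0L)

  # wrong column count rejected
  bad <- tempfile()
  writeLines("c1\t1\t2\t3", bad)
  expect_error(merge_splice_junctions(bad), "9 columns")
})

test_that("splice-junction merge output is independent of input order", {
  set.seed(5)
  files <- replicate(5, tempfile())
  for (i in 1:5) {
    rows <- vapply(1:8, function(j) {
      sj_row(sample(c("c1", "c2", "c3"), 1), s = sample(100:120, 1) * 10,
             e = sample(130:150, 1) * 10, nu = sample(1:9, 1),
             oh = sample(10:40, 1))
    }, "")
    writeLines(rows, files[i])
  }
  ref_out <- tempfile()
  merge_splice_junctions(files, out = ref_out)
  ref_bytes <- readBin(ref_out, "raw", file.size(ref_out))
  for (rep in 1:20) {
    out <- tempfile()
    merge_splice_junctions(sample(files), out = out)
    expect_identical(readBin(out, "raw", file.size(out)), ref_bytes)
  }
})

test_that("SAM routing sends each mapped record to the region holding its start", {
  ref <- reference_dict("c", 200)
  rs <- static_partition(ref, 2)$region_set
  rec <- make_records("c", c(199, 0, 100, 99))  # unsorted on purpose
  routed <- route_sam(rec, rs, tempfile())
  expect_equal(routed$counts, c(2L, 2L))
  r1 <- readLines(routed$files[1])
  expect_equal(length(r1), 2L)
  # sorted by (pos, qname) within the shard
  pos <- as.numeric(vapply(strsplit(r1, "\t"), `[[`, "", 4L))
  expect_equal(pos, sort(pos))
})

test_that("unmapped records go to the overflow file and lines survive verbatim", {
  ref <- reference_dict("c", 100)
  rs <- static_partition(ref, 1)$region_set
  rec <- make_records(c("*", "*"), c(0, 0), flag = 4L)
  routed <- route_sam(rec, rs, tempfile())
  expect_equal(routed$counts, 0L)
  expect_equal(routed$n_unmapped, 2L)
  expect_equal(length(readLines(routed$unmapped)), 2L)

  one <- make_records("c", 42)
  routed1 <- route_sam(one, rs, tempfile())
  expect_identical(readLines(routed1$files[1]), one$raw)

  expect_error(route_sam(make_records("nope", 0), rs, tempfile()),
               "unknown contig")
})

test_that("chunking and routing conserve the read multiset", {
  set.seed(21)
  n <- 10000L
  ref <- reference_dict(c("c1", "c2"), c(40000, 20000))
  qn <- sprintf("read%05d", sample(n))
  ctg <- sample(c("c1", "c2"), n, replace = TRUE, prob = c(0.8, 0.2))
  pos0 <- ifelse(ctg == "c1", sample.int(40000, n, replace = TRUE),
                 sample.int(20000, n, replace = TRUE)) - 1
  rec <- make_records(ctg, pos0, qname = qn)

  # routing: count and qname multiset conserved across shards
  rs <- static_partition(ref, 6)$region_set
  routed <- route_sam(rec, rs, tempfile())
  expect_equal(sum(routed$counts), n)
  shard_qn <- unlist(lapply(routed$files, function(f) {
    vapply(strsplit(readLines(f), "\t"), `[[`, "", 1L)
  }))
  expect_equal(sort(shard_qn), sort(qn))

  # chunking: record count and qname multiset conserved across chunks
  fq <- write_fastq(tempfile(), qn)
  sp <- split_fastq(fq, 7, tempfile())
  chunk_qn <- unlist(lapply(sp$chunks, function(p) {
    sub("^@", "", grep("^@", readLines(p[1]), value = TRUE))
  }))
  expect_equal(length(chunk_qn), n)
  expect_equal(sort(chunk_qn), sort(qn))
})

test_that("VCF merge sorts by reference order, dedups boundary keys, keeps the first header", {
  ref <- reference_dict(c("c1", "c2"), c(1000, 1000))
  v1 <- write_test_vcf(tempfile(), ref,
                       data.frame(contig = "c2", pos = c(10, 500),
                                  ref = "A", alt = "T"))
  v2 <- write_test_vcf(tempfile(), ref,
                       data.frame(contig = "c1", pos = c(700, 20, 300),
                                  ref = "C", alt = "G"))
  v3 <- write_test_vcf(tempfile(), ref,
                       data.frame(contig = "c2", pos = 900, ref = "G",
                                  alt = "A"))
  out <- tempfile(fileext = ".vcf")
  res <- merge_vcf(c(v1, v2, v3), ref, out)
  expect_equal(res$n_records, 6L)
  vars <- read_vcf_variants(out)
  expect_equal(vars$contig, c(rep("c1", 3), rep("c2", 3)))
  expect_equal(vars$pos, c(20, 300, 700, 10, 500, 900))

  # duplicate key across adjacent region files collapses to one record
  v4 <- write_test_vcf(tempfile(), ref,
                       data.frame(contig = "c1", pos = 700, ref = "C",
                                  alt = "G"))
  res2 <- merge_vcf(c(v2, v4), ref, tempfile())
  expect_equal(res2$n_duplicates, 1L)
  expect_equal(res2$n_records, 3L)

  # empty input list: nothing to take a header from
  expect_error(merge_vcf(character(0), ref, tempfile()), "header")

  # conflicting contig headers rejected
  ref_other <- reference_dict(c("c1", "c2"), c(1000, 2000))
  v5 <- write_test_vcf(tempfile(), ref_other,
                       data.frame(contig = "c1", pos = 1, ref = "A",
                                  alt = "C"))
  expect_error(merge_vcf(c(v1, v5), ref, tempfile()), "conflicting")
})
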