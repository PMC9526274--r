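test_that("transcript targets extend, sort and stitch CDS regions", {
  # CDS (100,109) and (200,209): l_ext = 0 -> l_T = 20, offsets 0 and 10;
  # the model filter is bypassed by constructing the set from intervals
  ts0 <- targets_from_spec(tibble::tibble(
    chrom = "chrT", start = c(100L, 200L), end = c(109L, 209L),
    element_id = "T1", frame = 0L, strand = "+"))
  expect_equal(ts0$l_T, 20)
  expect_equal(ts0$cum, c(0, 10))

  # same via the model path with l_ext = 10 -> regions (90,119), (190,219)
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chrT\tt\texon\t100\t109\t.\t+\t.\tgene_id \"G\"; transcript_id \"T1\";",
    "chrT\tt\texon\t200\t210\t.\t+\t.\tgene_id \"G\"; transcript_id \"T1\";",
    "chrT\tt\tCDS\t100\t109\t.\t+\t0\tgene_id \"G\"; transcript_id \"T1\";",
    "chrT\tt\tCDS\t200\t210\t.\t+\t0\tgene_id \"G\"; transcript_id \"T1\";"
  ), gtf)
  m <- load_gene_annotation(gtf)
  ts <- build_transcript_targets(m, l_ext = 10)
  expect_equal(ts$regions$start, c(90, 190))
  expect_equal(ts$regions$end, c(119, 220))
  expect_equal(ts$l_T, 30 + 31)
  expect_error(build_transcript_targets(m, l_ext = -1), "l_ext")
})

test_that("transcripts sharing a CDS are redundantly represented", {
  fx <- micro2_fixture()   # P.t1 and P.t2 share both CDS segments
  ts <- build_transcript_targets(fx$model, l_ext = 0)
  p_regions <- ts$regions[ts$regions$element_id %in% c("P.t1", "P.t2"), ]
  expect_equal(nrow(p_regions), 4L)
  # duplicated genomic spans, one per transcript
  expect_equal(sum(p_regions$start == 101), 2L)
  # gene mode deduplicates them
  tg <- build_gene_targets(fx$model, l_ext = 0)
  gp <- tg$regions[tg$regions$element_id == "GP", ]
  expect_equal(nrow(gp), 2L)
  expect_lte(tg$l_T, ts$l_T)
})

test_that("gene targets deduplicate on (start, end, frame) only", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    # T1/T3: CDS (100,129) at frame 0; T2 reaches the shared segment after a
    # 2-base upstream CDS, so its copy of (100,129) sits at frame 1
    "chrT\tt\texon\t100\t129\t.\t+\t.\tgene_id \"G\"; transcript_id \"T1\";",
    "chrT\tt\tCDS\t100\t129\t.\t+\t0\tgene_id \"G\"; transcript_id \"T1\";",
    "chrT\tt\texon\t60\t150\t.\t+\t.\tgene_id \"G\"; transcript_id \"T2\";",
    "chrT\tt\tCDS\t66\t67\t.\t+\t0\tgene_id \"G\"; transcript_id \"T2\";",
    "chrT\tt\tCDS\t100\t129\t.\t+\t1\tgene_id \"G\"; transcript_id \"T2\";",
    "chrT\tt\tCDS\t140\t140\t.\t+\t1\tgene_id \"G\"; transcript_id \"T2\";",
    "chrT\tt\texon\t100\t129\t.\t+\t.\tgene_id \"G\"; transcript_id \"T3\";",
    "chrT\tt\tCDS\t100\t129\t.\t+\t0\tgene_id \"G\"; transcript_id \"T3\";"
  ), gtf)
  m <- load_gene_annotation(gtf)
  tg <- build_gene_targets(m, l_ext = 0)
  # T1/T3 share (100,129,frame 0) -> one region; T2's copy has frame 1
  g100 <- tg$regions[tg$regions$start == 100, ]
  expect_equal(nrow(g100), 2L)
  expect_setequal(g100$frame, c(0L, 1L))
  expect_true(all(tg$regions$element_id == "G"))
})

test_that("region_index matches a linear-scan oracle", {
  ts <- targets_from_spec(tibble::tibble(
    chrom = "chrT", start = c(100L, 200L), end = c(109L, 209L),
    element_id = "T1", frame = 0L, strand = "+"))
  expect_equal(region_index(ts, 1), 1L)
  expect_equal(region_index(ts, 10), 1L)
  expect_equal(region_index(ts, 11), 2L)
  expect_error(region_index(ts, 0), "coordinate")
  expect_error(region_index(ts, 21), "coordinate")

  fx <- micro2_fixture()
  ts2 <- fx$targets
  len <- ts2$regions$end - ts2$regions$start + 1
  linear_scan <- function(nu) {
    for (i in seq_along(len)) {
      if (nu <= sum(len[seq_len(i)])) return(i)
    }
  }
  set.seed(9)
  nus <- sample.int(ts2$l_T, 500, replace = TRUE)
  expect_equal(region_index(ts2, nus),
               vapply(nus, linear_scan, integer(1)))
})

test_that("vector/genomic mappings agree with the brute-force stitched array", {
  # overlapping regions (100,109) and (105,114) of different elements
  ts <- targets_from_spec(tibble::tibble(
    chrom = "chrT", start = c(100L, 105L), end = c(109L, 114L),
    element_id = c("T1", "T2"), frame = 0L, strand = "+"))
  g <- vector_to_genomic(ts, c(1, 5, 13))
  expect_equal(g$pos, c(100L, 104L, 107L))
  expect_equal(genomic_to_vector(ts, "chrT", 107)$nu, c(8L, 13L))
  expect_equal(nrow(genomic_to_vector(ts, "chrT", 99)), 0L)

  # full equivalence on the micro fixture (shared CDS -> overlapping regions)
  fx <- micro2_fixture()
  ts2 <- fx$targets
  stitched <- do.call(rbind, lapply(seq_len(nrow(ts2$regions)), function(i) {
    cbind(i, ts2$regions$start[i]:ts2$regions$end[i])
  }))
  expect_equal(nrow(stitched), ts2$l_T)
  g2 <- vector_to_genomic(ts2, seq_len(ts2$l_T))
  expect_equal(g2$region, stitched[, 1])
  expect_equal(g2$pos, stitched[, 2])
  # round trip: nu is among the coordinates its genomic position maps to
  uq <- !duplicated(paste(g2$chrom, g2$pos))
  m <- genomic_to_vector(ts2, g2$chrom[uq], g2$pos[uq])
  bynu <- split(m$nu, paste(m$chrom, m$pos))
  for (nu in sample.int(ts2$l_T, 200)) {
    expect_true(nu %in% bynu[[paste(g2$chrom[nu], g2$pos[nu])]])
  }
  # cardinality equals interval containment count for every covered position
  cnt <- table(stitched[, 2])
  mcnt <- table(m$pos)
  expect_equal(as.integer(mcnt[names(cnt)]), as.integer(cnt))
})

test_that("conservation: l_T equals the sum of region lengths", {
  fx <- big_fixture()
  ts <- fx$targets
  expect_equal(ts$l_T, sum(ts$regions$end - ts$regions$start + 1))
  expect_equal(utils::tail(ts$ends, 1), ts$l_T)
  expect_true(all(diff(ts$cum) > 0))
})

test_that("BED round trip preserves the coordinate system", {
  fx <- micro2_fixture()
  bed <- tempfile(fileext = ".bed")
  write_targets_bed(fx$targets, bed)
  ts2 <- read_targets_bed(bed, l_ext = fx$targets$l_ext)
  expect_equal(ts2$regions$start, fx$targets$regions$start)
  expect_equal(ts2$regions$end, fx$targets$regions$end)
  expect_equal(ts2$l_T, fx$targets$l_T)
  expect_equal(target_hash(ts2), target_hash(fx$targets))
})
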