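vcf_of <- function(rows) {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", rows), f)
  f
}

test_that("VCF parsing strips anchors and splits multi-allelic rows", {
  vs <- parse_vcf(vcf_of(c(
    "chr1\t100\t.\tA\tG\t.\t.\t.",
    "chr1\t100\t.\tACT\tA\t.\t.\t.",
    "chr1\t100\t.\tA\tACT\t.\t.\t.",
    "chr1\t200\t.\tC\tA,T\t.\t.\t."
  )))
  expect_equal(nrow(vs$snvs), 3L)
  expect_equal(vs$snvs$alt[vs$snvs$pos == 100], "G")
  expect_equal(vs$deletions$d1, 101L)
  expect_equal(vs$deletions$d2, 102L)
  expect_equal(vs$insertions$pos, 100L)
  expect_equal(vs$insertions$seq, "CT")
  expect_setequal(vs$snvs$alt[vs$snvs$pos == 200], c("A", "T"))
})

test_that("symbolic alleles are skipped with a count; bad records error", {
  expect_warning(
    vs <- parse_vcf(vcf_of(c("chr1\t10\t.\tA\t<DEL>\t.\t.\t.",
                             "chr1\t20\t.\tA\tG\t.\t.\t."))),
    "skipped")
  expect_equal(vs$n_skipped, 1L)
  expect_equal(nrow(vs$snvs), 1L)
  expect_error(parse_vcf(vcf_of("chr1\t10\t.\tACT\tG\t.\t.\t.")), "line 3")
  expect_error(parse_vcf(vcf_of("chr1\t10\t.\tA\tCGT\t.\t.\t.")),
               "anchor")
  expect_error(parse_vcf(vcf_of("chr1\t10\t.\tA\tA\t.\t.\t.")), "REF")
})

test_that("loci vectors mark mapped positions per allele", {
  ts <- targets_from_spec(tibble::tibble(
    chrom = "chr1", start = c(100L, 105L), end = c(109L, 114L),
    element_id = c("T1", "T2"), frame = 0L, strand = "+"))

  empty <- variant_set()
  expect_equal(sum(vectorize_loci(empty, ts, "A")$bits), 0)

  # 2-bp deletion inside one region -> 2 consecutive bits
  vs <- variant_set(deletions = tibble::tibble(chrom = "chr1",
                                               d1 = 101L, d2 = 102L))
  lv <- vectorize_loci(vs, ts, "d")
  expect_equal(which(lv$bits == 1), c(2L, 3L))

  # SNV in the overlap maps to both regions
  vs2 <- variant_set(snvs = tibble::tibble(chrom = "chr1", pos = 107L,
                                           ref = "A", alt = "G"))
  expect_equal(which(vectorize_loci(vs2, ts, "G")$bits == 1), c(8L, 13L))
  expect_equal(sum(vectorize_loci(vs2, ts, "A")$bits), 0)

  # off-target variants are counted, not encoded
  vs3 <- variant_set(snvs = tibble::tibble(chrom = "chr1", pos = 99L,
                                           ref = "A", alt = "G"))
  lv3 <- vectorize_loci(vs3, ts, "G")
  expect_equal(sum(lv3$bits), 0)
  expect_equal(lv3$n_off_target, 1L)
})

test_that("SNV popcount equals the sum of mapping cardinalities", {
  fx <- big_fixture()
  vs <- fx$vs
  for (a in c("A", "T")) {
    lv <- vectorize_loci(vs, fx$targets, a)
    snv <- vs$snvs[vs$snvs$alt == a, ]
    m <- genomic_to_vector(fx$targets, snv$chrom, snv$pos)
    expect_equal(sum(lv$bits), length(unique(m$nu)))
  }
  # row order invariance
  vs_rev <- variant_set(snvs = vs$snvs[rev(seq_len(nrow(vs$snvs))), ],
                        deletions = vs$deletions, insertions = vs$insertions)
  expect_equal(vectorize_loci(vs_rev, fx$targets, "A")$bits,
               vectorize_loci(vs, fx$targets, "A")$bits)
})

test_that("genotype matrices encode dosage and existence correctly", {
  ts <- targets_from_spec(tibble::tibble(
    chrom = "chr1", start = 100L, end = 119L,
    element_id = "T1", frame = 0L, strand = "+"))
  gt <- rbind(c("0/1", "1/1", "0/0"),
              c("1|1", "./.", "0/1"))
  colnames(gt) <- c("s1", "s2", "s3")
  sites <- tibble::tibble(chrom = "chr1", pos = c(105L, 110L),
                          ref = c("A", "C"), alt = c("G", "G"))
  f <- tempfile(fileext = ".vcf")
  write_vcf(sites, f, gt = gt)

  Gd <- vectorize_genotypes(f, ts, "G", "dosage")
  expect_equal(Gd$values[6, ], c(1L, 2L, 0L))
  expect_equal(Gd$values[11, ], c(2L, 0L, 1L))
  expect_equal(Gd$missing, c(0L, 1L, 0L))
  Ge <- vectorize_genotypes(f, ts, "G", "existence")
  expect_equal(Ge$values[11, ], c(1L, 0L, 1L))
  expect_error(vectorize_genotypes(vcf_of("x"), ts, "G"), "#CHROM|sample")
})

test_that("deletion genotypes expand spans; non-engulfed ones are excluded", {
  ts <- targets_from_spec(tibble::tibble(
    chrom = "chr1", start = 100L, end = 119L,
    element_id = "T1", frame = 0L, strand = "+"))
  gt <- rbind(c("0/1", "0/0"), c("0/1", "1/1"))
  colnames(gt) <- c("s1", "s2")
  sites <- tibble::tibble(chrom = "chr1", pos = c(104L, 117L),
                          ref = c("ACTG", "ACTGG"), alt = c("A", "A"))
  f <- tempfile(fileext = ".vcf")
  write_vcf(sites, f, gt = gt)
  G <- vectorize_genotypes(f, ts, "d", "existence")
  # first deletion spans 105-107 -> slots 6:8 for s1
  expect_equal(which(G$values[, 1] == 1), 6:8)
  # second deletion (118-121) leaves the region: excluded entirely
  expect_equal(sum(G$values[, 2]), 0)
})

test_that("non-coding element vectors flag any overlapping variant", {
  elements <- tibble::tibble(name = paste0("E", 1:5), chrom = "chr1",
                             start = seq(100, 500, by = 100),
                             end = seq(150, 550, by = 100))
  expect_equal(sum(vectorize_noncoding_elements(variant_set(), elements)$value), 0)
  vs <- variant_set(snvs = tibble::tibble(chrom = "chr1", pos = 320L,
                                          ref = "A", alt = "C"))
  v <- vectorize_noncoding_elements(vs, elements)
  expect_equal(v$value, c(0L, 0L, 1L, 0L, 0L))

  # counts match a brute-force interval check on random variants
  set.seed(11)
  pos <- sample(80:600, 40)
  vs2 <- variant_set(
    snvs = tibble::tibble(chrom = "chr1", pos = pos, ref = "A", alt = "C"),
    deletions = tibble::tibble(chrom = "chr1", d1 = pos, d2 = pos + 9L))
  v2 <- vectorize_noncoding_elements(vs2, elements)
  brute <- vapply(seq_len(nrow(elements)), function(j) {
    any(pos >= elements$start[j] & pos <= elements$end[j]) ||
      any(pos + 9 >= elements$start[j] & pos <= elements$end[j])
  }, logical(1))
  expect_equal(v2$value, as.integer(brute))
})
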