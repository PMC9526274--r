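# micro fixture geometry (see helper-fixtures.R): P.t1 on the plus strand
# with codons ATG GGA AAA TAC ... TAT TAA split 101-130 / 231-260, Q.t1 the
# same protein on the minus strand at 351-410 (translation starts at 410).

ann_at <- function(fx, pos, allele, element = "P.t1") {
  ts <- fx$targets
  m <- genomic_to_vector(ts, "chrT", pos)
  m <- m[ts$regions$element_id[m$region] == element, ]
  annotate_point_mutation(fx$model, fx$store, ts, m$nu[1], allele)
}

test_that("SNV consequences follow codon substitution on the plus strand", {
  fx <- micro_fixture()
  # third-position wobble of GGA (Gly): GGC is still Gly
  expect_equal(ann_at(fx, 106, "C")$terms, "synonymous_variant")
  # first position of AAA (Lys) -> CAA (Gln)
  expect_equal(ann_at(fx, 107, "C")$terms, "missense_variant")
  # TAC -> TAA creates a premature stop
  expect_equal(ann_at(fx, 112, "A")$terms, "stop_gained")
  # any SNV in the start codon loses the start
  expect_equal(ann_at(fx, 102, "C")$terms, "start_lost")
  # stop codon TAA -> TAG keeps a stop; -> TAC loses it
  expect_equal(ann_at(fx, 260, "G")$terms, "stop_retained_variant")
  expect_equal(ann_at(fx, 260, "C")$terms, "stop_lost")
})

test_that("splice windows carry acceptor/donor/region terms", {
  fx <- micro_fixture()
  # 2 intronic bp immediately 5' of exon 2 (plus strand) = acceptor
  a <- ann_at(fx, 229, "A")
  if (identical(a$terms, character(0))) a <- ann_at(fx, 229, "C")
  expect_true("splice_acceptor_variant" %in% a$terms)
  d <- ann_at(fx, 132, "A")
  if (!length(d$terms)) d <- ann_at(fx, 132, "C")
  expect_true("splice_donor_variant" %in% d$terms)
  # exonic within 1-3 bp of the junction
  expect_true("splice_region_variant" %in% ann_at(fx, 129, "C")$terms ||
              "splice_region_variant" %in% ann_at(fx, 129, "A")$terms)

  # exactly 2 donor and 2 acceptor positions per intron on the fixture
  av_d <- build_annotation_vector(fx$model, fx$store, fx$targets, "d")
  u <- unpack_impact(av_d$values)
  g <- vector_to_genomic(fx$targets, seq_len(fx$targets$l_T))
  p1 <- g$element_id == "P.t1"
  donor_bit <- floor(u$bitmap / 2^18) %% 2 == 1     # splice_donor index 18
  acc_bit <- floor(u$bitmap / 2^19) %% 2 == 1       # splice_acceptor index 19
  expect_equal(sum(donor_bit[p1]), 2)
  expect_equal(sum(acc_bit[p1]), 2)
  expect_equal(sort(g$pos[p1][donor_bit[p1]]), c(131L, 132L))
  expect_equal(sort(g$pos[p1][acc_bit[p1]]), c(229L, 230L))
})

test_that("minus-strand consequences mirror the plus strand", {
  fx <- micro_fixture()
  # middle of the start codon (genomic 409 on the minus strand)
  expect_equal(ann_at(fx, 409, "C", "Q.t1")$terms, "start_lost")
  # wobble of codon 2 sits at genomic 405; plus-strand alt G is coding C:
  # GGA -> GGC, synonymous
  expect_equal(ann_at(fx, 405, "G", "Q.t1")$terms, "synonymous_variant")
  # 1-bp deletion in the stop codon (genomic 351-353)
  dd <- ann_at(fx, 353, "d", "Q.t1")
  expect_setequal(dd$terms, c("frameshift_variant", "stop_lost"))
})

test_that("1-bp deletion and insertion signals carry frame and codon flags", {
  fx <- micro_fixture()
  # deleting the first base of the stop codon: frameshift + stop_lost
  d <- ann_at(fx, 258, "d")
  expect_setequal(d$terms, c("frameshift_variant", "stop_lost"))
  # deletion in the start codon
  expect_setequal(ann_at(fx, 103, "d")$terms,
                  c("frameshift_variant", "start_lost"))
  # coding 1-bp insertion is a frameshift signal with the junction frame
  i1 <- ann_at(fx, 104, "i")
  expect_true("frameshift_variant" %in% i1$terms)
  expect_equal(i1$frame, 1L)   # one base of codon 2 lies left of the junction
  i2 <- ann_at(fx, 106, "i")
  expect_equal(i2$frame, 0L)   # between codons 2 and 3
  # deep intronic deletion (inside the extended region, past the splice
  # windows): intron only
  expect_equal(ann_at(fx, 139, "d")$terms, "intron_variant")
})

test_that("annotation vectors equal per-position calls and zero reference alleles", {
  fx <- micro_fixture()
  ts <- fx$targets
  av <- build_annotation_vectors(fx$model, fx$store, ts)
  g <- vector_to_genomic(ts, seq_len(ts$l_T))
  ref <- substring(fx$store$seq[["chrT"]], g$pos, g$pos)
  for (a in c("A", "C", "G", "T")) {
    vals <- av[[a]]$values
    # reference-allele entries are always 0
    nz <- rep(FALSE, ts$l_T); nz[i64_nonzero(vals)] <- TRUE
    expect_true(all(!nz[ref == a]))
  }
  # element-wise agreement with annotate_point_mutation on sampled positions
  set.seed(4)
  for (nu in sample.int(ts$l_T, 40)) {
    for (a in c("G", "d", "i")) {
      one <- annotate_point_mutation(fx$model, fx$store, ts, nu, a)
      packed <- av[[a]]$values[nu]
      if (one$bitmap == 0) {
        expect_equal(length(i64_nonzero(packed)), 0)
      } else {
        u <- unpack_impact(packed)
        expect_equal(u$bitmap, one$bitmap)
        expect_equal(u$frame, one$frame)
        expect_equal(u$neighborhood, one$neighborhood)
      }
    }
  }
  # every non-zero entry unpacks to a bitmap with at least one set bit
  uu <- unpack_impact(av[["d"]]$values[i64_nonzero(av[["d"]]$values)])
  expect_true(all(uu$bitmap > 0))
})
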