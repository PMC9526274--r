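# end-to-end protocol helpers on the micro fixture

micro_pipeline <- function(vs, fx = micro_fixture()) {
  av <- fixture("micro_av", function() {
    f <- micro_fixture()
    build_annotation_vectors(f$model, f$store, f$targets)
  })
  secure_annotate_variants(vs, fx$targets, av, slot = 64)
}

terms_for <- function(records, element = "P.t1") {
  records$terms[records$element_id == element][[1]]
}

test_that("the server refuses mismatched target sets and alleles", {
  fx <- micro_fixture()
  av <- build_annotation_vector(fx$model, fx$store, fx$targets, "A")
  kp <- keygen()
  vs <- variant_set(snvs = tibble::tibble(chrom = "chrT", pos = 107L,
                                          ref = "A", alt = "A"))
  loci <- vectorize_loci(vs, fx$targets, "A")
  ct <- encrypt_loci(loci, kp$public)
  other <- build_transcript_targets(fx$model, l_ext = 5)
  loci2 <- vectorize_loci(vs, other, "A")
  expect_error(secure_annotate(encrypt_loci(loci2, kp$public), av),
               "different target sets")
  av_c <- build_annotation_vector(fx$model, fx$store, fx$targets, "C")
  expect_error(secure_annotate(ct, av_c), "allele mismatch")
})

test_that("the annotated product is the slot-wise plaintext product", {
  fx <- micro_fixture()
  av <- build_annotation_vector(fx$model, fx$store, fx$targets, "G")
  kp <- keygen()
  bits <- integer(fx$targets$l_T); bits[c(3, 17)] <- 1L
  lv <- structure(list(allele = "G", bits = bits, l_T = fx$targets$l_T,
                       target_hash = target_hash(fx$targets),
                       n_variants = 2L, n_off_target = 0L),
                  class = "loci_vector")
  dec <- he_decrypt(secure_annotate(encrypt_loci(lv, kp$public), av),
                    kp$secret)
  expect_equal(i64_nonzero(dec),
               intersect(c(3L, 17L), i64_nonzero(av$values)))
  expect_true(all(dec[17] == av$values[17]))
  # all-zero loci -> all-zero product
  lv0 <- lv; lv0$bits <- integer(fx$targets$l_T)
  dec0 <- he_decrypt(secure_annotate(encrypt_loci(lv0, kp$public), av),
                     kp$secret)
  expect_equal(length(i64_nonzero(dec0)), 0)
})

test_that("SNV translation decodes positions, elements and terms", {
  # wobble SNV + splice acceptor SNV in one batch
  vs <- variant_set(snvs = tibble::tibble(
    chrom = "chrT", pos = c(106L, 229L), ref = c("A", "A"),
    alt = c("C", "C")))
  rec <- micro_pipeline(vs)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$type, c("snv", "snv"))
  expect_equal(terms_for(rec[rec$start == 106, ]), "synonymous_variant")
  expect_true("splice_acceptor_variant" %in%
                terms_for(rec[rec$start == 229, ]))
  # zero vector -> no records
  fx <- micro_fixture()
  expect_equal(nrow(translate_snv(i64_zeros(fx$targets$l_T), fx$targets, "A")),
               0L)
})

test_that("deletion merge recovers frame, codon losses and junction stops", {
  # full interior codon (CCT at 113-115): in-frame, no stop terms
  r1 <- micro_pipeline(variant_set(deletions = tibble::tibble(
    chrom = "chrT", d1 = 113L, d2 = 115L)))
  expect_equal(terms_for(r1), "inframe_deletion")
  # 2-bp CDS deletion: frameshift (codon 6 GAC, junction CTT is no stop)
  r2 <- micro_pipeline(variant_set(deletions = tibble::tibble(
    chrom = "chrT", d1 = 116L, d2 = 117L)))
  expect_equal(terms_for(r2), "frameshift_variant")
  # deletion clipping the stop codon with a junction that re-forms TAA:
  # stop_lost + stop_retained (+ in-frame, 3 bases removed)
  r3 <- micro_pipeline(variant_set(deletions = tibble::tibble(
    chrom = "chrT", d1 = 257L, d2 = 259L)))
  expect_setequal(terms_for(r3),
                  c("inframe_deletion", "stop_lost", "stop_retained_variant"))
  # first base of the stop codon: frameshift + stop_lost
  r4 <- micro_pipeline(variant_set(deletions = tibble::tibble(
    chrom = "chrT", d1 = 258L, d2 = 258L)))
  expect_setequal(terms_for(r4), c("frameshift_variant", "stop_lost"))
  # deletion spanning the acceptor site and exon start: splice_acceptor lost
  r5 <- micro_pipeline(variant_set(deletions = tibble::tibble(
    chrom = "chrT", d1 = 229L, d2 = 232L)))
  expect_true(all(c("splice_acceptor_variant", "frameshift_variant") %in%
                    terms_for(r5)))
  # engulfed flag
  expect_true(r1$engulfed)
})

test_that("insertion translation detects frame and junction stop codons", {
  # 3-bp insertion between codons, no stop created
  r1 <- micro_pipeline(variant_set(insertions = tibble::tibble(
    chrom = "chrT", pos = 115L, seq = "CCC")))
  expect_equal(terms_for(r1), "inframe_insertion")
  # 2-bp CDS insertion: frameshift
  r2 <- micro_pipeline(variant_set(insertions = tibble::tibble(
    chrom = "chrT", pos = 113L, seq = "CT")))
  expect_equal(terms_for(r2), "frameshift_variant")
  # inserting TAA at a codon boundary (frame 0): stop_gained
  r3 <- micro_pipeline(variant_set(insertions = tibble::tibble(
    chrom = "chrT", pos = 115L, seq = "TAA")))
  expect_setequal(terms_for(r3), c("inframe_insertion", "stop_gained"))
})

test_that("translation cross-checks loci against the variant set", {
  fx <- micro_fixture()
  av <- fixture("micro_av", function() {
    f <- micro_fixture()
    build_annotation_vectors(f$model, f$store, f$targets)
  })
  vs <- variant_set(deletions = tibble::tibble(chrom = "chrT",
                                               d1 = 113L, d2 = 115L))
  kp <- keygen()
  dec <- he_decrypt(secure_annotate(
    encrypt_loci(vectorize_loci(vs, fx$targets, "d"), kp$public),
    av[["d"]]), kp$secret)
  # a non-zero slot not claimed by any deletion
  expect_error(translate_deletion(dec, variant_set(), fx$targets),
               "inconsistency")
  # a zero slot inside a claimed span
  wider <- variant_set(deletions = tibble::tibble(chrom = "chrT",
                                                  d1 = 112L, d2 = 116L))
  expect_error(translate_deletion(dec, wider, fx$targets), "inconsistency")
  # insertions: decrypted slot zero where the set claims one
  expect_error(translate_insertion(i64_zeros(fx$targets$l_T),
                                   variant_set(insertions = tibble::tibble(
                                     chrom = "chrT", pos = 115L, seq = "A")),
                                   fx$targets),
               "inconsistency")
})

test_that("secure pipeline equals the direct oracle on the micro fixture", {
  fx <- micro_fixture()
  vs <- variant_set(
    snvs = tibble::tibble(chrom = "chrT", pos = c(102L, 106L, 112L, 405L),
                          ref = "N", alt = c("C", "C", "A", "G")),
    deletions = tibble::tibble(chrom = "chrT",
                               d1 = c(113L, 257L, 353L),
                               d2 = c(115L, 259L, 353L)),
    insertions = tibble::tibble(chrom = "chrT", pos = c(115L, 113L),
                                seq = c("TAA", "CT"))
  )
  sec <- micro_pipeline(vs)
  dir <- annotate_variants_direct(fx$model, fx$store, fx$targets, vs)
  expect_identical(sort(record_key(sec)), sort(record_key(dir)))
})

test_that("length-specific deletion vectors are exact by construction", {
  fx <- micro_fixture()
  kp <- keygen()
  vs <- variant_set(deletions = tibble::tibble(
    chrom = "chrT", d1 = c(113L, 257L, 116L), d2 = c(115L, 259L, 117L)))
  recs <- list()
  for (len in c(2L, 3L)) {
    ann <- build_deletion_length_vector(fx$model, fx$store, fx$targets, len)
    loci <- vectorize_deletion_starts(vs, fx$targets, len)
    dec <- he_decrypt(secure_annotate(encrypt_loci(loci, kp$public), ann),
                      kp$secret)
    recs[[as.character(len)]] <- translate_deletion_length(dec, fx$targets, len)
  }
  got <- dplyr::bind_rows(recs)
  want <- annotate_variants_direct(fx$model, fx$store, fx$targets, vs)
  strip <- function(r) sort(paste(r$chrom, r$start, r$end, r$element_id,
                                  vapply(r$terms, paste, "", collapse = ",")))
  expect_identical(strip(got), strip(want))
})

test_that("external annotation tables can replace the built-in annotator", {
  fx <- micro_fixture()
  one <- annotate_point_mutation(fx$model, fx$store, fx$targets,
                                 genomic_to_vector(fx$targets, "chrT", 107)$nu[1],
                                 "G")
  tsv <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    chrom = "chrT", pos = 107L, allele = "G", element_id = "P.t1",
    terms = paste(one$terms, collapse = ","), frame = one$frame), tsv)
  ann <- read_annotation_tsv(tsv, fx$targets, fx$store, "G")
  builtin <- build_annotation_vector(fx$model, fx$store, fx$targets, "G")
  nu <- genomic_to_vector(fx$targets, "chrT", 107)$nu[1]
  expect_true(all(ann$values[nu] == builtin$values[nu]))
  expect_equal(length(i64_nonzero(ann$values)), 1L)
})

test_that("records collapse to one row per variant with worst severity", {
  fx <- micro2_fixture()
  av <- build_annotation_vectors(fx$model, fx$store, fx$targets)
  vs <- variant_set(snvs = tibble::tibble(chrom = "chrT", pos = 112L,
                                          ref = "C", alt = "A"))
  rec <- secure_annotate_variants(vs, fx$targets, av)
  expect_equal(nrow(rec), 2L)  # P.t1 and P.t2
  col <- collapse_records(rec)
  expect_equal(nrow(col), 1L)
  expect_equal(col$severity, "HIGH")
  expect_equal(col$element_id, "P.t1,P.t2")
})

test_that("reports are written as flat TSV", {
  vs <- variant_set(snvs = tibble::tibble(chrom = "chrT", pos = 106L,
                                          ref = "A", alt = "C"))
  rec <- micro_pipeline(vs)
  f <- tempfile(fileext = ".tsv")
  write_annotation_report(rec, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(back$terms, "synonymous_variant")
})
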