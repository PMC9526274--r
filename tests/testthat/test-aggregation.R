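# small deterministic genotype fixtures built directly on a genotype_matrix
# skeleton: a single 40-bp region split into two regions of 20 for the
# boundary rules

gm_skeleton <- function(values, mode = "existence",
                        region = rep(1L, nrow(values))) {
  structure(list(allele = "d", mode = mode, values = values,
                 n_G = ncol(values), samples = paste0("s", seq_len(ncol(values))),
                 missing = integer(ncol(values)), region = region,
                 target_hash = "fixture"),
            class = "genotype_matrix")
}

test_that("SNV aggregation is the slot-wise sample sum", {
  v <- matrix(0L, 10, 3)
  G <- gm_skeleton(v, mode = "dosage")
  expect_equal(aggregate_snv(G)$counts, rep(0, 10))
  v[4, ] <- c(0L, 2L, 1L)
  G <- gm_skeleton(v, mode = "dosage")
  fv <- aggregate_snv(G)
  expect_equal(fv$counts[4], 3)
  expect_lte(max(fv$counts), 2 * G$n_G)
  # conservation: total count equals total encoded observations
  expect_equal(sum(fv$counts), sum(v))
  # tidy output computes AF on the dosage denominator
  td <- tidy(fv)
  expect_equal(td$af, td$count / (2 * 3))
})

test_that("encrypted aggregation equals the plaintext sum exactly", {
  set.seed(21)
  v <- matrix(rbinom(400 * 25, 2, 0.1), 400, 25)
  G <- gm_skeleton(v, mode = "dosage")
  kp <- keygen()
  enc <- aggregate_encrypted(encrypt_genotypes(G, kp$public, slot = 128))
  expect_equal(as.double(he_decrypt(enc, kp$secret)), rowSums(v))
})

test_that("the exact-span indicator counts engulfed deletions only", {
  # one sample with states (0,1,1,0) around nu = 2, window l_delta = 1
  v <- matrix(c(0L, 1L, 1L, 0L, 0L, 0L), ncol = 1)
  G <- gm_skeleton(v)
  expect_equal(aggregate_deletion_length(G, 1)$counts,
               c(0, 1, 0, 0, 0, 0))
  # left flank set -> no contribution
  v2 <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L), ncol = 1)
  expect_equal(sum(aggregate_deletion_length(gm_skeleton(v2), 1)$counts), 0)
  # the same states do count for the longer window
  expect_equal(aggregate_deletion_length(gm_skeleton(v2), 2)$counts[1], 1)
  # dosage encoding is refused
  expect_error(aggregate_deletion_length(gm_skeleton(v2, mode = "dosage"), 1),
               "encoding")
  # wrapper takes the deleted-base count (= l_delta + 1)
  expect_equal(aggregate_deletion_span(G, 2)$counts,
               aggregate_deletion_length(G, 1)$counts)
})

test_that("region boundaries break spans and zero the flanks", {
  # two stitched regions of 3 slots; a run crossing the boundary is not a
  # deletion span, and a span touching the boundary has a zero flank outside
  v <- matrix(c(0L, 1L, 1L, 1L, 1L, 0L), ncol = 1)
  G <- gm_skeleton(v, region = rep(1:2, each = 3))
  # window of 2 (l_delta = 1): slots 2:3 qualify (right flank slot 4 is in
  # another region, counts as 0); slots 4:5 qualify symmetrically
  expect_equal(aggregate_deletion_length(G, 1)$counts,
               c(0, 1, 0, 1, 0, 0))
  # window of 4 would cross the boundary: nothing counted
  expect_equal(sum(aggregate_deletion_length(G, 3)$counts), 0)
})

test_that("exact-span counts match an exhaustive run-length oracle", {
  set.seed(31)
  n <- 300; k <- 12
  region <- rep(1:3, each = 100)
  v <- matrix(rbinom(n * k, 1, 0.35), n, k)
  G <- gm_skeleton(v, region = region)
  # independent oracle: per sample, exact-length maximal 1-runs within each
  # region, counted at their start slot
  oracle <- function(l_delta) {
    counts <- numeric(n)
    for (s in seq_len(k)) {
      for (r in unique(region)) {
        idx <- which(region == r)
        rl <- rle(v[idx, s])
        ends <- cumsum(rl$lengths)
        starts <- ends - rl$lengths + 1
        hit <- rl$values == 1 & rl$lengths == l_delta + 1
        counts[idx[starts[hit]]] <- counts[idx[starts[hit]]] + 1
      }
    }
    counts
  }
  for (ld in 0:3) {
    expect_equal(aggregate_deletion_length(G, ld)$counts, oracle(ld),
                 info = paste("l_delta =", ld))
  }
  # exact-span property: per sample, the indicator total equals the number
  # of maximal runs of exactly l_delta + 1 ones
  G1 <- gm_skeleton(v[, 1, drop = FALSE], region = region)
  rl_total <- sum(vapply(1:3, function(r) {
    rl <- rle(v[region == r, 1])
    sum(rl$values == 1 & rl$lengths == 3)
  }, numeric(1)))
  expect_equal(sum(aggregate_deletion_length(G1, 2)$counts), rl_total)
})

test_that("the encrypted deletion-span path matches the plaintext op", {
  set.seed(41)
  region <- rep(1:2, each = 50)
  v <- matrix(rbinom(100 * 10, 1, 0.3), 100, 10)
  G <- gm_skeleton(v, region = region)
  kp <- keygen()
  cols <- encrypt_genotypes(G, kp$public, slot = 32)
  for (ld in 0:3) {
    enc <- aggregate_deletion_length_encrypted(cols, ld, region)
    expect_equal(as.double(he_decrypt(enc, kp$secret)),
                 aggregate_deletion_length(G, ld)$counts,
                 info = paste("l_delta =", ld))
  }
  # all-ones column never qualifies (no zero flank anywhere in a region)
  ones <- gm_skeleton(matrix(1L, 100, 1), region = region)
  enc1 <- aggregate_deletion_length_encrypted(
    encrypt_genotypes(ones, kp$public, slot = 32), 1, region)
  expect_equal(sum(as.double(he_decrypt(enc1, kp$secret))), 0)
})

test_that("pooling key-switches every source and sums exactly", {
  set.seed(51)
  vA <- matrix(rbinom(60 * 4, 2, 0.2), 60, 4)
  vB <- matrix(rbinom(60 * 7, 2, 0.2), 60, 7)
  GA <- gm_skeleton(vA, mode = "dosage")
  GB <- gm_skeleton(vB, mode = "dosage")
  kA <- keygen(); kB <- keygen(); kR <- keygen()
  srcA <- encrypt_genotypes(GA, kA$public, slot = 16)
  srcB <- encrypt_genotypes(GB, kB$public, slot = 16)
  sA <- gen_switch_key(kA$secret, kR$secret)
  sB <- gen_switch_key(kB$secret, kR$secret)
  pooled <- pool_and_aggregate(list(srcA, srcB), list(sA, sB))
  expect_equal(as.double(he_decrypt(pooled, kR$secret)),
               rowSums(vA) + rowSums(vB))
  # order invariance
  pooled2 <- pool_and_aggregate(list(srcB, srcA), list(sB, sA))
  expect_equal(as.double(he_decrypt(pooled2, kR$secret)),
               as.double(he_decrypt(pooled, kR$secret)))
  # single source degenerates to one switch + aggregate
  one <- pool_and_aggregate(list(srcA), list(sA))
  expect_equal(as.double(he_decrypt(one, kR$secret)), rowSums(vA))
  # a wrong switch key is refused before any arithmetic
  expect_error(pool_and_aggregate(list(srcA), list(sB)), "key error")
  expect_error(pool_and_aggregate(list(srcA, srcB),
                                  list(sA, gen_switch_key(kB$secret, kA$secret))),
               "key error")
})
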