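make_pair <- function(chrom1, pos1, strand1, len1,
                      chrom2, pos2, strand2, len2) {
  tibble::tibble(chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
                 len1 = len1, chrom2 = chrom2, pos2 = pos2,
                 strand2 = strand2, len2 = len2)
}

test_that("orientation modes follow strand combinations", {
  p <- make_pair("c", c(10L, 10L, 10L, 10L), c("+", "-", "+", "-"),
                 50L, "c", c(500L, 500L, 500L, 500L),
                 c("-", "+", "+", "-"), 50L)
  expect_equal(pair_orientation(p), c("FR", "RF", "FF", "RR"))
})

test_that("classification implements the printed filtering rules", {
  cuts <- list(c1 = c(1000L, 3000L, 10000L), c2 = c(2000L, 5000L))
  lens <- c(c1 = 20000, c2 = 20000)

  # RF with no cut between the reads -> self-ligation product
  p <- make_pair("c1", 3100L, "-", 80L, "c1", 3600L, "+", 80L)
  expect_equal(classify_pairs(p, cuts, lens)$class, "self_ligation")

  # RF with a cut between reads but loci 1200 bp apart -> too close
  p <- make_pair("c1", 2500L, "-", 80L, "c1", 3700L, "+", 80L)
  expect_equal(classify_pairs(p, cuts, lens)$class, "too_close")

  # RF with a cut between and distance >= 1500 -> valid
  p <- make_pair("c1", 2500L, "-", 80L, "c1", 8000L, "+", 80L)
  expect_equal(classify_pairs(p, cuts, lens)$class, "valid_intra")

  # FR with apparent insert 800 > 600 -> valid
  p <- make_pair("c1", 1000L, "+", 80L, "c1", 1700L, "-", 100L)
  expect_equal(classify_pairs(p, cuts, lens)$class, "valid_intra")

  # FR with apparent insert 500 <= 600 -> short insert
  p <- make_pair("c1", 1000L, "+", 80L, "c1", 1400L, "-", 100L)
  expect_equal(classify_pairs(p, cuts, lens)$class, "short_insert")

  # interchromosomal: len 80 + 80, cut distances 100 and 200 -> 460 < 600
  p <- make_pair("c1", 820L, "+", 80L, "c2", 1720L, "+", 80L)
  expect_equal(classify_pairs(p, cuts, lens)$class, "valid_inter")

  # interchromosomal with a far-downstream cut -> short insert
  p <- make_pair("c1", 3100L, "+", 80L, "c2", 1720L, "+", 80L)
  expect_equal(classify_pairs(p, cuts, lens)$class, "short_insert")

  expect_error(classify_pairs(make_pair("cX", 1L, "+", 50L,
                                        "cX", 900L, "-", 50L), cuts, lens),
               "absent from cut index")
})

test_that("duplicate removal canonicalizes side order", {
  a <- make_pair("c1", 100L, "+", 80L, "c1", 900L, "-", 80L)
  b <- a[, c(5:8, 1:4)]  # swapped sides
  names(b) <- names(a)
  expect_equal(nrow(dedup_pairs(dplyr::bind_rows(a, a))), 1L)
  expect_equal(nrow(dedup_pairs(dplyr::bind_rows(a, b))), 1L)
  expect_equal(nrow(dedup_pairs(a[0, ])), 0L)
})

test_that("filter census partitions the deduplicated input", {
  g <- gen_genome(2, c(5e4, 5e4), seed = 3)
  frags <- digest_genome(g, "GATC")
  cuts <- attr(frags, "cuts")
  lens <- c(chr1 = 5e4, chr2 = 5e4)
  rp <- gen_read_pairs(g, cuts, 600,
                       class_mix = c(valid_intra = 0.4, valid_inter = 0.1,
                                     self_ligation = 0.2,
                                     undigested_loop = 0.2,
                                     short_insert = 0.1), seed = 4)
  res <- filter_pairs(rp$pairs, cuts, lens)
  expect_equal(sum(res$census$n) + res$n_duplicates, nrow(rp$pairs))
  expect_true(all(res$contacts$class %in% c("valid_intra", "valid_inter")))

  # pure self-ligation population -> no valid contacts
  rp2 <- gen_read_pairs(g, cuts, 100,
                        class_mix = c(self_ligation = 1), seed = 5)
  expect_equal(nrow(filter_pairs(rp2$pairs, cuts, lens)$contacts), 0L)
})

test_that("classification matches the brute-force oracle on random pairs", {
  g <- gen_genome(2, c(1e5, 6e4), seed = 8)
  frags <- digest_genome(g, "GATC")
  cuts <- attr(frags, "cuts")
  lens <- c(chr1 = 1e5, chr2 = 6e4)
  rp <- gen_read_pairs(g, cuts, 800,
                       class_mix = c(valid_intra = 0.35, valid_inter = 0.15,
                                     self_ligation = 0.2,
                                     undigested_loop = 0.2,
                                     short_insert = 0.1), seed = 9)
  got <- classify_pairs(rp$pairs, cuts, lens)
  expect_equal(got$class, oracle_classify(rp$pairs, cuts, lens))
})

test_that("raising the RF distance threshold never adds valid contacts", {
  g <- gen_genome(1, 1e5, seed = 12)
  cuts <- attr(digest_genome(g, "GATC"), "cuts")
  lens <- c(chr1 = 1e5)
  rp <- gen_read_pairs(g, cuts, 500, seed = 13)
  n_valid <- vapply(c(500, 1500, 3000, 6000), function(th) {
    cl <- classify_pairs(rp$pairs, cuts, lens, min_rf_distance = th)
    sum(cl$class == "valid_intra")
  }, numeric(1))
  expect_true(all(diff(n_valid) <= 0))
})
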