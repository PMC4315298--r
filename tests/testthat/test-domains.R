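test_that("directionality index reproduces hand-computed values", {
  # 70-bin matrix, window 30 bins; focal bin 35 (1-based): upstream
  # cells 0, downstream cells summing to 10
  n <- 70
  v <- matrix(0, n, n)
  b <- 35
  for (o in 1:30) v[b, b + o] <- v[b + o, b] <- 10 / 30
  nm <- contact_matrix(v, "c1", 2000, kind = "normalized")
  di <- directionality_index(nm, window = 60000)
  expect_equal(di$A[b], 0)
  expect_equal(di$B[b], 10)
  expect_equal(di$di[b], 10)   # E = 5; sign(B-A) * (25/5 + 25/5)

  # mirrored matrix: A = 10, B = 0 -> DI = -10
  v2 <- matrix(0, n, n)
  for (o in 1:30) v2[b, b - o] <- v2[b - o, b] <- 10 / 30
  di2 <- directionality_index(contact_matrix(v2, "c1", 2000,
                                             kind = "normalized"))
  expect_equal(di2$di[b], -10)

  # A == B -> 0
  v3 <- v + v2
  di3 <- directionality_index(contact_matrix(v3, "c1", 2000,
                                             kind = "normalized"))
  expect_equal(di3$di[b], 0)
})

test_that("reversing bin order negates the DI track", {
  tr <- synthetic_truth(150, blocks = tibble::tibble(
    start_bin = c(40L, 48L), end_bin = c(47L, 55L),
    direction = c("up", "down")))
  cm <- gen_contact_map(150, truth = tr, di_block_strength = 3, seed = 71)
  nm <- normalize_contacts(cm$matrix, flat_features(cm$matrix))$matrix
  di_fwd <- directionality_index(nm)
  rev_mat <- nm
  n <- nrow(nm$values)
  rev_mat$values <- nm$values[n:1, n:1]
  rev_mat$mask <- rev(nm$mask)
  di_rev <- directionality_index(rev_mat)
  expect_equal(di_rev$di, -rev(di_fwd$di))
})

test_that("the HMM decodes well-separated directionality runs", {
  # constant DI -> everything N
  flat <- tibble::tibble(chrom = "c1", bin = 0:59, di = 0,
                         excluded = FALSE)
  expect_true(all(fit_hmm(flat)$state == "N"))

  set.seed(81)
  di <- tibble::tibble(chrom = "c1", bin = 0:39,
                       di = c(rep(10, 20), rep(-10, 20)) + rnorm(40, 0, 0.5),
                       excluded = FALSE)
  st <- fit_hmm(di, seed = 1)
  expect_equal(st$state[1:20], rep("D", 20))
  expect_equal(st$state[21:40], rep("U", 20))
})

test_that("pattern grammars match their defining examples", {
  ins <- extract_insulators(states_from_string("NNUUDDNN"))
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$subtype, "A")
  expect_equal(c(ins$start_bin, ins$end_bin), c(3L, 4L))

  insB <- extract_insulators(states_from_string("NNUUNDDNN"))
  expect_equal(insB$subtype, "B")
  expect_equal(insB$matched_states, "UND")

  expect_equal(nrow(extract_insulators(states_from_string("NNNNNNNN"))), 0L)

  # boundary at a U -> D junction; the same junction in a longer segment
  # is also a type-A insulator (the two call types overlap by design)
  bd <- extract_boundaries(states_from_string("NUUUUUDDN"))
  expect_equal(nrow(bd), 1L)
  expect_equal(bd$subtype, "U(D/N)")
  expect_equal(c(bd$start_bin, bd$end_bin), c(5L, 6L))
  long <- states_from_string("NNUUUUUDDNN")
  expect_equal(nrow(extract_boundaries(long)), 1L)
  expect_equal(nrow(extract_insulators(long)), 1L)

  # a 7-bin segment cannot host the 8-bin boundary pattern
  expect_equal(nrow(extract_boundaries(states_from_string("NDDDDDN"))), 0L)

  int1 <- extract_interiors(states_from_string("NDDUUUUUN"))
  expect_equal(int1$subtype, "(D/N)U")
  expect_equal(c(int1$start_bin, int1$end_bin), c(2L, 3L))
  int2 <- extract_interiors(states_from_string("DDDDDNUN"))
  expect_equal(int2$subtype, "D(U/N)")
  expect_equal(nrow(extract_interiors(states_from_string(
    strrep("U", 12)))), 0L)
})

test_that("pattern extraction equals the brute-force oracle", {
  set.seed(91)
  for (rep in 1:3) {
    s <- paste(sample(c("U", "D", "N"), 2000, replace = TRUE,
                      prob = c(0.35, 0.35, 0.3)), collapse = "")
    st <- states_from_string(s)
    got <- dplyr::bind_rows(extract_insulators(st),
                            extract_boundaries(st),
                            extract_interiors(st))
    expect_equal(region_key(got), region_key(oracle_patterns(s)))
  }
})

test_that("no pattern spans an excluded gap", {
  s2 <- paste0("NNUUDDNN", "NNUUDDNN")
  st <- states_from_string(s2)
  st$state[8] <- "excluded"   # bin 7 breaks the track into two segments
  got <- extract_insulators(st)
  # the first copy loses its trailing flank to the gap; only the second
  # copy's core keeps two flanking states on both sides
  expect_equal(nrow(got), 1L)
  expect_equal(got$start_bin, 11L)

  # oracle applied per segment agrees
  oracle <- rbind(oracle_patterns(substr(s2, 1, 7), 0L),
                  oracle_patterns(substr(s2, 9, 16), 8L))
  ins_or <- oracle[oracle$type == "insulator", ]
  expect_equal(region_key(got), region_key(ins_or))
})

test_that("unstructured maps give N-majority states with U and D balanced", {
  freqs <- vapply(1:3, function(seed) {
    cm <- gen_contact_map(240, base_count = 40,
                          truth = synthetic_truth(240), seed = seed)
    nm <- normalize_contacts(cm$matrix, flat_features(cm$matrix))$matrix
    st <- fit_hmm(directionality_index(nm), seed = seed)
    tab <- table(factor(st$state, levels = c("U", "D", "N")))
    tab / sum(tab)
  }, numeric(3))
  mean_freq <- rowMeans(freqs)
  expect_lt(abs(mean_freq[["U"]] - mean_freq[["D"]]), 0.05)
  expect_gt(mean_freq[["N"]], max(mean_freq[["U"]], mean_freq[["D"]]))
})
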