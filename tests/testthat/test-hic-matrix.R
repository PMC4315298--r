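test_that("contact binning accumulates symmetric counts", {
  contacts <- tibble::tibble(chrom1 = "c1", pos1 = 1000L,
                             chrom2 = "c1", pos2 = 5000L)
  b <- bin_contacts(contacts, 2000, c(c1 = 10000))
  m <- b$matrices$c1$values
  expect_equal(m[1, 3], 1)
  expect_equal(m[3, 1], 1)
  expect_equal(sum(m), 2)

  # empty input -> zero matrix; permuted input -> identical matrix
  expect_equal(sum(bin_contacts(contacts[0, ], 2000,
                                c(c1 = 10000))$matrices$c1$values), 0)
  many <- tibble::tibble(chrom1 = "c1",
                         pos1 = c(100L, 2500L, 9000L, 100L),
                         chrom2 = "c1",
                         pos2 = c(5000L, 2600L, 200L, 5000L))
  m1 <- bin_contacts(many, 2000, c(c1 = 10000))$matrices$c1$values
  m2 <- bin_contacts(many[c(3, 1, 4, 2), ], 2000,
                     c(c1 = 10000))$matrices$c1$values
  expect_equal(m1, m2)
  expect_error(bin_contacts(tibble::tibble(chrom1 = "c1", pos1 = 99999L,
                                           chrom2 = "c1", pos2 = 1L),
                            2000, c(c1 = 10000)), "beyond chromosome")
})

test_that("exclusion mask applies the two-level thresholds", {
  feats <- tibble::tibble(chrom = "c1", bin = 0:3,
                          eff_len = c(0.5, 0.05, 0.5, 0.5),
                          gc_ends = 0.4, end_count = 5,
                          mappability = c(0.4, 0.9, 0.9, 0.9))
  cen <- tibble::tibble(chrom = "c1", bin = 3L)
  m <- exclusion_mask(feats, cen)
  expect_equal(m$norm_excluded, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(m$analysis_excluded, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("constant covariates and counts give all-zero residuals", {
  n <- 12
  m <- matrix(7, n, n)
  raw <- contact_matrix(m, "c1", 2000, kind = "raw")
  feats <- tibble::tibble(chrom = "c1", bin = seq_len(n) - 1L,
                          eff_len = 0.8, gc_ends = 0.4, end_count = 6,
                          mappability = 1)
  nm <- normalize_contacts(raw, feats)
  off_diag <- nm$matrix$values[upper.tri(nm$matrix$values)]
  expect_equal(max(abs(off_diag)), 0, tolerance = 1e-8)
})

test_that("fit equals a direct likelihood maximization", {
  res <- norm_oracle_compare(seed = 42)
  expect_equal(res$package, res$oracle, tolerance = 1e-6)
  expect_true(all(is.finite(res$fit$coefficients)))
  expect_equal(tidy(res$fit)$term,
               c("(Intercept)", "x_len", "x_gc", "x_end"))
  expect_equal(glance(res$fit)$n_pairs_fit, choose(12, 2))
})

test_that("residuals are centred and invariant to covariate rescaling", {
  tr <- synthetic_truth(120)
  cm <- gen_contact_map(120, base_count = 30, truth = tr, seed = 21)
  feats <- flat_features(cm$matrix)
  feats$end_count <- sample(3:12, 120, replace = TRUE)
  nm1 <- normalize_contacts(cm$matrix, feats)
  off_diag <- upper.tri(nm1$matrix$values)
  expect_lt(abs(mean(nm1$matrix$values[off_diag])), 0.05)

  feats2 <- feats
  feats2$end_count <- feats2$end_count * 10  # global rescale
  nm2 <- normalize_contacts(cm$matrix, feats2)
  expect_equal(nm1$matrix$values, nm2$matrix$values, tolerance = 1e-8)
})

test_that("end-count slope is near zero on unbiased maps", {
  slopes <- vapply(1:5, function(seed) {
    cm <- gen_contact_map(150, base_count = 40,
                          truth = synthetic_truth(150), seed = seed)
    feats <- flat_features(cm$matrix)
    set.seed(seed + 100)
    feats$end_count <- sample(3:12, 150, replace = TRUE)
    normalize_contacts(cm$matrix, feats)$fit$coefficients[["x_end"]]
  }, numeric(1))
  expect_true(all(abs(slopes) < 0.05))
})

test_that("normalization improves agreement with the bias-free expectation", {
  n <- 200
  set.seed(31)
  end_count <- sample(3:12, n, replace = TRUE)
  bias <- end_count / mean(end_count)
  tr <- synthetic_truth(n, bin_bias = bias)
  cm <- gen_contact_map(n, decay_exponent = -1, base_count = 50,
                        truth = tr, seed = 32)
  feats <- flat_features(cm$matrix)
  feats$end_count <- end_count
  nm <- normalize_contacts(cm$matrix, feats)
  d <- abs(row(diag(n)) - col(diag(n)))
  expected <- matrix(0, n, n)
  expected[d > 0] <- 50 * d[d > 0]^-1
  off <- upper.tri(expected) & d > 0
  cor_raw <- cor(cm$matrix$values[off], expected[off])
  cor_norm <- cor(nm$matrix$values[off], expected[off])
  expect_gt(cor_norm, cor_raw)
})

test_that("contact strength sums the ten surrounding bins", {
  n <- 20
  v <- matrix(1, n, n)
  diag(v) <- 0
  mask <- rep(TRUE, n)
  mask[15] <- FALSE
  nm <- contact_matrix(v, "c1", 2000, mask = mask, kind = "normalized")
  cs <- contact_strength(nm, window_bins = 5)
  expect_equal(cs$strength[8], 10)          # interior bin
  expect_equal(cs$strength[1], 5)           # truncated at chromosome start
  expect_false(cs$defined[15])              # masked focal bin
  expect_equal(cs$strength[14], 9)          # masked neighbour skipped
})
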