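test_that("mark coverage is interval-union coverage per bin", {
  lens <- c(c1 = 4000)
  iv <- tibble::tibble(chrom = "c1",
                       start = c(0L, 2000L, 2500L),
                       end = c(2000L, 3000L, 3500L),
                       mark = c("m1", "m2", "m2"))
  cov <- mark_coverage(iv, 2000, lens)
  get <- function(mark, bin) cov$coverage[cov$mark == mark & cov$bin == bin]
  expect_equal(get("m1", 0), 1.0)       # fully covered
  expect_equal(get("m1", 1), 0.0)
  expect_equal(get("m2", 1), 0.75)      # union of [2000,3000) and [2500,3500)

  # overlapping intervals never push coverage above 1
  iv2 <- tibble::tibble(chrom = "c1", start = c(0L, 500L),
                        end = c(1500L, 2000L), mark = "m")
  expect_equal(mark_coverage(iv2, 2000, lens)$coverage[1], 1.0)
  expect_error(mark_coverage(tibble::tibble(chrom = "c1", start = 10L,
                                            end = 10L, mark = "m"),
                             2000, lens), "malformed")
})

test_that("quintile scores follow midrank percentiles with zero pinning", {
  cov <- tibble::tibble(chrom = "c1", bin = 0:9, mark = "m",
                        coverage = (1:10) / 10)
  sc <- quintile_scores(cov)
  expect_equal(sc$m, c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))

  # ties: all equal positive -> everyone at the 50th percentile -> 2
  cov2 <- tibble::tibble(chrom = "c1", bin = 0:4, mark = "m",
                         coverage = 0.3)
  expect_true(all(quintile_scores(cov2)$m == 2L))

  # all-zero rows are unclear
  cov3 <- tidyr::crossing(chrom = "c1", bin = 0:3,
                          mark = c("m1", "m2")) |>
    dplyr::mutate(coverage = ifelse(bin == 2, 0, 0.5))
  sc3 <- quintile_scores(cov3)
  expect_equal(sc3$unclear, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("quintile scoring is invariant to monotone transforms", {
  set.seed(101)
  cov <- tidyr::crossing(chrom = "c1", bin = 0:199,
                         mark = c("m1", "m2", "m3")) |>
    dplyr::mutate(coverage = ifelse(runif(dplyr::n()) < 0.2, 0,
                                    runif(dplyr::n())))
  sc1 <- quintile_scores(cov)
  sc2 <- quintile_scores(dplyr::mutate(cov, coverage = coverage^3))
  sc3 <- quintile_scores(dplyr::mutate(cov,
                                       coverage = log1p(5 * coverage)))
  expect_equal(sc1, sc2)
  expect_equal(sc1, sc3)
})

test_that("k-means recovers planted states and naming is canonical", {
  emis <- matrix(0.02, 6, 16,
                 dimnames = list(NULL, colnames(canonical_state_profiles())))
  for (s in 1:6) emis[s, (2 * s - 1):(2 * s)] <- 0.9
  epi <- gen_epigenome(600, rep(1:6, length.out = 600), emis, seed = 111)
  sc <- quintile_scores(epi$coverage)
  ca <- classify_states(sc, k = 6, seed = 1, restarts = 20)
  keep <- ca$assignment$state != "unclear"
  agree <- chromapack:::adjusted_rand(epi$truth$state_labels[keep],
                                      ca$assignment$state[keep])
  expect_gte(agree, 0.95)
  # the in-package adjusted-Rand agrees with the reference implementation
  expect_equal(agree,
               mclust::adjustedRandIndex(epi$truth$state_labels[keep],
                                         ca$assignment$state[keep]))

  # naming: a centroid dominated by H3K27me3/H3.1/H3.3 must be CS2 and a
  # flat centroid CS4; permuting centroid order permutes names with it
  cen <- canonical_state_profiles()
  rownames(cen) <- paste0("k", 1:6)
  nm <- name_states(cen)
  expect_equal(unname(nm), paste0("CS", 1:6))
  perm <- c(3, 1, 6, 2, 4, 5)
  nm_perm <- name_states(cen[perm, ])
  expect_equal(unname(nm_perm), paste0("CS", 1:6)[perm])

  flatish <- rbind(CSx = rep(1, 16))
  colnames(flatish) <- colnames(cen)
  polycomb <- flatish
  polycomb[1, c("H3K27me3", "H3.1", "H3.3")] <- 4
  both <- rbind(polycomb, flatish)
  nm2 <- name_states(both)
  expect_equal(unname(nm2[1]), "CS2")
  expect_equal(unname(nm2[2]), "CS4")
})

test_that("more k-means restarts never worsen the objective", {
  set.seed(121)
  emis <- matrix(runif(96, 0, 0.8), 6, 16,
                 dimnames = list(NULL, colnames(canonical_state_profiles())))
  epi <- gen_epigenome(300, rep(1:6, length.out = 300), emis, seed = 131)
  sc <- quintile_scores(epi$coverage)
  w1 <- classify_states(sc, seed = 5, restarts = 1)$tot_withinss
  w25 <- classify_states(sc, seed = 5, restarts = 25)$tot_withinss
  expect_lte(w25, w1 + 1e-8)
})

test_that("PCA projection is centred with fixed component signs", {
  set.seed(141)
  base <- matrix(0L, 40, 4)
  base[1:20, 1:2] <- 4L
  base[21:40, 3:4] <- 4L
  sc <- tibble::as_tibble(base, .name_repair = ~paste0("m", 1:4)) |>
    dplyr::mutate(chrom = "c1", bin = dplyr::row_number() - 1L,
                  unclear = FALSE)
  p <- pca_project(sc)
  expect_equal(colMeans(as.matrix(p$projection[, c("PC1", "PC2", "PC3")])),
               c(PC1 = 0, PC2 = 0, PC3 = 0), tolerance = 1e-12)
  # two orthogonal clusters separate on PC1
  expect_gt(min(abs(p$projection$PC1)), 1)
  expect_lt(max(p$projection$PC1[1:20]) * max(p$projection$PC1[21:40]), 0)
  # rank-1 data: PC1 explains all variance
  r1 <- base
  r1[, 3:4] <- base[, 1:2]
  sc1 <- tibble::as_tibble(r1, .name_repair = ~paste0("m", 1:4)) |>
    dplyr::mutate(chrom = "c1", bin = dplyr::row_number() - 1L,
                  unclear = FALSE)
  expect_equal(pca_project(sc1)$var_explained[1], 1, tolerance = 1e-12)
})

test_that("RPKM and expression grouping follow their definitions", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(10, 1000, 2e6), 5)   # doubling the library halves RPKM
  expect_error(rpkm(10, 0, 1e6), "positive")

  expect_true(all(expression_groups(rep(0, 5)) == 1L))
  expect_equal(expression_groups(c(0, 1:8)), c(1L, 2:9))
  set.seed(151)
  x <- c(rep(0, 10), rexp(200))
  g <- expression_groups(x)
  expect_true(all(g[order(x)] == sort(g)))  # monotone in RPKM
  expect_equal(sort(unique(g)), 1:9)
})

test_that("profiles around regions average the track at aligned positions", {
  track <- tibble::tibble(chrom = "c1", bin = 0:9,
                          value = c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9))
  regions <- tibble::tibble(chrom = "c1", start_bin = c(2L, 6L))
  pr <- profile_around(regions, track, flank_bins = 1)
  expect_equal(pr$mean, c(mean(c(1, 5)), mean(c(2, 6)), mean(c(3, 7))))

  # single region: profile equals the track slice
  pr1 <- profile_around(regions[1, ], track, flank_bins = 2)
  expect_equal(pr1$mean, c(0, 1, 2, 3, 4))

  # constant categorical track: frequency 1 for that category
  cat_track <- tibble::tibble(chrom = "c1", bin = 0:9, value = "CS2")
  prc <- profile_around(regions, cat_track, flank_bins = 1)
  expect_true(all(prc$freq == 1))
  expect_true(all(prc$category == "CS2"))

  # positions beyond the chromosome are dropped from the mean
  pr_edge <- profile_around(tibble::tibble(chrom = "c1", start_bin = 0L),
                            track, flank_bins = 2)
  expect_equal(pr_edge$rel_pos, 0:2)
  expect_equal(nrow(profile_around(regions[0, ], track)), 0L)
})
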