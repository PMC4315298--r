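#' Per-bin per-mark enrichment coverage
#'
#' Computes, for each fixed-size bin, the fraction of the bin overlapped
#' by the enriched intervals of each epigenetic mark (interval unions, so
#' overlapping intervals never push coverage above 1).
#'
#' @param intervals Tibble of enriched intervals with columns `chrom`,
#'   `start`, `end` (bp, 0-based half-open) and `mark`.
#' @param bin_size Bin width in bp.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @return Long tibble with `chrom`, `bin` (0-based), `mark`,
#'   `coverage` in `[0, 1]`, including zero rows for every bin/mark.
#' @export
mark_coverage <- function(intervals, bin_size, chrom_lengths) {
  if (any(intervals$start >= intervals$end)) {
    stop_param("malformed interval: start >= end")
  }
  if (any(intervals$end > chrom_lengths[intervals$chrom])) {
    stop_param("interval beyond chromosome length")
  }
  marks <- sort(unique(intervals$mark))
  grid <- purrr::map_dfr(names(chrom_lengths), function(chrom) {
    tibble(chrom = chrom,
           bin = seq_len(ceiling(chrom_lengths[[chrom]] / bin_size)) - 1L)
  }) |>
    tidyr::crossing(mark = marks)

  cov <- purrr::map_dfr(marks, function(mk) {
    purrr::map_dfr(names(chrom_lengths), function(chrom) {
      iv <- intervals |>
        filter(.data$mark == mk, .data$chrom == !!chrom)
      len <- chrom_lengths[[chrom]]
      n_bins <- ceiling(len / bin_size)
      bin_start <- (seq_len(n_bins) - 1L) * bin_size
      bin_end <- pmin(bin_start + bin_size, len)
      if (nrow(iv) == 0) return(NULL)
      rng <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1L,
                                              end = iv$end))
      tibble(chrom = chrom, bin = seq_len(n_bins) - 1L, mark = mk,
             coverage = bin_overlap_fraction(rng, bin_start, bin_end))
    })
  })
  grid |>
    left_join(cov, by = c("chrom", "bin", "mark")) |>
    mutate(coverage = ifelse(is.na(.data$coverage), 0, .data$coverage))
}

#' Quintile enrichment scores per bin and mark
#'
#' Per mark, bins with zero coverage score 0; among bins with positive
#' coverage, the midrank percentile assigns the quintile score 0–4
#' (score `q` for percentiles in `[20q, 20(q+1))`), so the scoring is
#' invariant to any strictly monotone transform of the coverage values.
#' Bins scoring 0 for every mark are flagged `unclear`.
#'
#' @param coverage Long tibble from [mark_coverage()] (columns `chrom`,
#'   `bin`, `mark`, `coverage`).
#' @return Wide tibble: `chrom`, `bin`, one integer score column per
#'   mark, and a logical `unclear` column.
#' @export
quintile_scores <- function(coverage) {
  scored <- coverage |>
    group_by(.data$mark) |>
    mutate(score = quintile_of(.data$coverage)) |>
    ungroup()
  wide <- scored |>
    select("chrom", "bin", "mark", "score") |>
    tidyr::pivot_wider(names_from = "mark", values_from = "score")
  mark_cols <- setdiff(names(wide), c("chrom", "bin"))
  wide$unclear <- rowSums(wide[mark_cols]) == 0
  wide
}

quintile_of <- function(x) {
  s <- integer(length(x))
  pos <- x > 0
  if (any(pos)) {
    p <- midrank_percentile(x[pos])
    s[pos] <- pmin(as.integer(p %/% 20), 4L)
  }
  s
}

#' Classify bins into chromatin states by k-means
#'
#' Runs k-means (Euclidean distance, best of `restarts` random starts)
#' on the 16-dimensional quintile-score vectors of all non-`unclear`
#' bins. Cluster labels are arbitrary until named against canonical
#' profiles with [name_states()].
#'
#' @param scores Score tibble from [quintile_scores()].
#' @param k Number of states (default 6).
#' @param seed Integer seed for the restarts.
#' @param restarts Number of random starts (default 50).
#' @return A list with `assignment` (tibble `chrom`, `bin`, `state` —
#'   `"unclear"` bins keep that label, others get `"1"`..`"k"`),
#'   `centroids` (k x marks matrix) and `tot_withinss`.
#' @export
classify_states <- function(scores, k = 6, seed = 1L, restarts = 50) {
  mark_cols <- setdiff(names(scores), c("chrom", "bin", "unclear"))
  x <- as.matrix(scores[!scores$unclear, mark_cols, drop = FALSE])
  if (nrow(unique(x)) < k) {
    stop_param("fewer than k distinct non-unclear score vectors")
  }
  km <- withr_seed(seed, kmeans(x, centers = k, nstart = restarts,
                                iter.max = 100))
  state <- rep("unclear", nrow(scores))
  state[!scores$unclear] <- as.character(km$cluster)
  list(
    assignment = tibble(chrom = scores$chrom, bin = scores$bin,
                        state = state),
    centroids = km$centers,
    tot_withinss = km$tot.withinss
  )
}

withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Name k-means chromatin states against canonical profiles
#'
#' Matches each centroid to one reference profile by cosine similarity,
#' solved as an optimal one-to-one assignment (total similarity
#' maximized over all bijections), so permuting centroid order never
#' changes the final names. The shipped canonical profiles encode the
#' published state descriptions: CS1/CS5 transcriptionally active
#' euchromatin (CS5 with more H3K36me2, H2Bub and H3.3 but less
#' H3K4me2/3 and H3K9ac), CS2 enriched for H3K27me3, H3.1 and H3.3,
#' CS3/CS6 heterochromatin (CS6 with less H3K9me2/H3K27me1), CS4 with
#' no particular enrichment.
#'
#' @param centroids k x marks centroid matrix from [classify_states()].
#' @param canonical_profiles Reference profile matrix (rows = state
#'   names, columns = marks); defaults to
#'   [canonical_state_profiles()] restricted to shared mark columns.
#' @return Named character vector: canonical name per centroid row.
#' @export
name_states <- function(centroids, canonical_profiles = NULL) {
  canonical_profiles <- canonical_profiles %||% canonical_state_profiles()
  shared <- intersect(colnames(centroids), colnames(canonical_profiles))
  if (length(shared) < 2) {
    stop_param("centroids and canonical profiles share fewer than 2 marks")
  }
  a <- centroids[, shared, drop = FALSE]
  b <- canonical_profiles[, shared, drop = FALSE]
  cosim <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) 0 else sum(u * v) / (nu * nv)
  }
  S <- outer(seq_len(nrow(a)), seq_len(nrow(b)),
             Vectorize(function(i, j) cosim(a[i, ], b[j, ])))
  if (nrow(a) > nrow(b)) stop_param("more centroids than canonical profiles")
  # exact assignment by enumeration (k! with k <= 6 is small)
  perms <- all_permutations(nrow(b), nrow(a))
  tot <- vapply(perms, function(p) sum(S[cbind(seq_len(nrow(a)), p)]),
                numeric(1))
  best <- perms[[which.max(tot)]]
  setNames(rownames(b)[best], rownames(a) %||% seq_len(nrow(a)))
}

all_permutations <- function(n, r) {
  if (r == 1) return(as.list(seq_len(n)))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n, r - 1)
    for (p in rest) if (!i %in% p) out[[length(out) + 1]] <- c(i, p)
  }
  out
}

#' Canonical chromatin-state reference profiles
#'
#' A 6 x 16 matrix of relative enrichment (0–4 scale) over a 16-mark
#' epigenome panel, encoding the qualitative descriptions of the six
#' chromatin states (see [name_states()]). Editable: pass a modified
#' copy to [name_states()] to change the naming scheme.
#'
#' @return Numeric matrix, rows `CS1`..`CS6`, 16 mark columns.
#' @export
canonical_state_profiles <- function() {
  marks <- c("H3K4me2", "H3K4me3", "H3K9ac", "H3K18ac",
             "H3K36me2", "H3K36me3", "H2Bub", "H3.3", "H3.1",
             "H3K27me3", "H3K27me1", "H3K9me2", "H4K16ac",
             "mCG", "mCHG", "mCHH")
  p <- rbind(
    CS1 = c(4, 4, 4, 3, 2, 3, 2, 2, 0, 0, 0, 0, 3, 1, 0, 0),
    CS2 = c(1, 1, 0, 1, 0, 0, 0, 3, 4, 4, 1, 0, 0, 1, 0, 0),
    CS3 = c(0, 0, 0, 0, 0, 0, 0, 0, 3, 1, 4, 4, 0, 4, 4, 4),
    CS4 = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    CS5 = c(2, 2, 2, 2, 4, 3, 4, 4, 0, 0, 0, 0, 2, 1, 0, 0),
    CS6 = c(0, 0, 0, 0, 0, 0, 0, 0, 3, 1, 1, 1, 0, 4, 4, 4)
  )
  colnames(p) <- marks
  p
}

#' Project score vectors on the first three principal components
#'
#' Centered PCA of the per-bin score vectors. The sign of each component
#' is fixed by making the largest-magnitude loading entry positive, so
#' projections are reproducible across platforms.
#'
#' @param scores Score tibble from [quintile_scores()] (non-`unclear`
#'   bins are projected).
#' @param n_comp Number of components (default 3).
#' @return A list with `projection` (tibble `chrom`, `bin`,
#'   `PC1`..`PCn`), `loadings` and `var_explained`.
#' @export
pca_project <- function(scores, n_comp = 3) {
  mark_cols <- setdiff(names(scores), c("chrom", "bin", "unclear"))
  keep <- if ("unclear" %in% names(scores)) !scores$unclear else
    rep(TRUE, nrow(scores))
  x <- as.matrix(scores[keep, mark_cols, drop = FALSE])
  if (nrow(x) < 4) stop_param("need at least 4 bins")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  n_comp <- min(n_comp, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(n_comp), drop = FALSE]
  flip <- vapply(seq_len(n_comp), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  rot <- sweep(rot, 2, flip, `*`)
  proj <- sweep(pc$x[, seq_len(n_comp), drop = FALSE], 2, flip, `*`)
  colnames(proj) <- paste0("PC", seq_len(n_comp))
  list(
    projection = bind_cols(scores[keep, c("chrom", "bin")],
                           as_tibble(proj)),
    loadings = rot,
    var_explained = pc$sdev^2 / sum(pc$sdev^2)
  )
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = 1e9 * count / (total * length)`.
#'
#' @param counts Per-gene read counts.
#' @param lengths Per-gene lengths in bp (all positive).
#' @param total Library size (total mapped reads).
#' @return Numeric vector of RPKM values.
#' @export
rpkm <- function(counts, lengths, total) {
  if (total <= 0) stop_param("`total` must be positive")
  if (any(lengths <= 0)) stop_param("gene lengths must be positive")
  1e9 * counts / (total * lengths)
}

#' Expression-level groups
#'
#' Group 1 collects undetected genes (RPKM 0); the remaining genes are
#' split into `n_groups - 1` equal-occupancy groups (octiles for the
#' default 9 groups) of increasing expression by midrank percentile.
#'
#' @param rpkm_values Per-gene RPKM.
#' @param n_groups Total number of groups (default 9).
#' @return Integer vector of group labels `1..n_groups`.
#' @export
expression_groups <- function(rpkm_values, n_groups = 9) {
  if (n_groups < 2) stop_param("`n_groups` must be at least 2")
  g <- rep(1L, length(rpkm_values))
  pos <- rpkm_values > 0
  if (any(pos)) {
    p <- midrank_percentile(rpkm_values[pos])
    width <- 100 / (n_groups - 1)
    g[pos] <- 2L + pmin(as.integer(p %/% width), n_groups - 2L)
  }
  g
}

#' Average a per-bin track around called regions
#'
#' Aligns regions on their anchor bin (column `anchor_bin` when present,
#' else `start_bin`) and averages the track per relative position over
#' `±flank_bins`. Numeric tracks yield a mean profile; categorical
#' tracks yield per-category frequencies. Positions beyond the track are
#' skipped from the mean.
#'
#' @param regions Region tibble (`chrom`, `start_bin`, optionally
#'   `anchor_bin`).
#' @param track Tibble `chrom`, `bin`, `value` (numeric or
#'   character/factor).
#' @param flank_bins Number of bins on each side of the anchor.
#' @return For numeric tracks a tibble `rel_pos`, `mean`, `n`; for
#'   categorical tracks `rel_pos`, `category`, `freq`, `n`.
#' @export
profile_around <- function(regions, track, flank_bins = 10) {
  if (flank_bins < 0) stop_param("`flank_bins` must be >= 0")
  if (nrow(regions) == 0) return(tibble())
  anchor <- if ("anchor_bin" %in% names(regions)) regions$anchor_bin else
    regions$start_bin
  key <- paste(track$chrom, track$bin)
  rel <- -flank_bins:flank_bins
  rows <- tidyr::crossing(r = seq_len(nrow(regions)), rel_pos = rel) |>
    mutate(chrom = regions$chrom[.data$r],
           bin = anchor[.data$r] + .data$rel_pos,
           value = track$value[match(paste(.data$chrom, .data$bin), key)]) |>
    filter(!is.na(.data$value))
  if (is.numeric(track$value)) {
    rows |>
      group_by(.data$rel_pos) |>
      summarise(mean = mean(.data$value), n = dplyr::n(), .groups = "drop")
  } else {
    rows |>
      count(.data$rel_pos, category = as.character(.data$value)) |>
      group_by(.data$rel_pos) |>
      mutate(freq = .data$n / sum(.data$n), n_total = sum(.data$n)) |>
      ungroup() |>
      select("rel_pos", "category", "freq", n = "n_total")
  }
}
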