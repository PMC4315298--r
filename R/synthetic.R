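#' Ground truth container for synthetic data
#'
#' Collects the planted structure that the generators embed and the
#' downstream callers are expected to recover.
#'
#' @param n_bins Number of analysis bins on the synthetic chromosome.
#' @param strip_bins Integer vector of 0-based bins planted as
#'   high-contact strips.
#' @param blocks Tibble `start_bin`, `end_bin` (0-based inclusive),
#'   `direction` (`"up"`/`"down"`) of directionality-bias blocks;
#'   must be non-overlapping.
#' @param bin_bias Per-bin positive multiplicative bias (default 1).
#' @param insulator_bins 0-based bins at up→down block junctions;
#'   derived automatically from adjacent blocks when `NULL`.
#' @param state_labels Optional latent chromatin state 1–6 per 400-bp bin.
#' @param pair_labels Optional per-pair class labels.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(n_bins, strip_bins = integer(0),
                            blocks = NULL, bin_bias = rep(1, n_bins),
                            insulator_bins = NULL,
                            state_labels = NULL, pair_labels = NULL) {
  blocks <- blocks %||% tibble(start_bin = integer(0), end_bin = integer(0),
                               direction = character(0))
  stopifnot(all(strip_bins >= 0), all(strip_bins < n_bins),
            length(bin_bias) == n_bins, all(bin_bias > 0))
  if (nrow(blocks) > 1) {
    b <- blocks |> arrange(.data$start_bin)
    if (any(b$start_bin[-1] <= b$end_bin[-nrow(b)])) {
      stop_param("bias blocks overlap")
    }
  }
  if (is.null(insulator_bins) && nrow(blocks) > 1) {
    b <- blocks |> arrange(.data$start_bin)
    junction <- which(b$direction[-nrow(b)] == "up" &
                        b$direction[-1] == "down" &
                        b$start_bin[-1] == b$end_bin[-nrow(b)] + 1L)
    insulator_bins <- b$start_bin[junction + 1L]
  }
  structure(
    list(n_bins = as.integer(n_bins),
         strip_bins = as.integer(strip_bins),
         blocks = blocks,
         bin_bias = bin_bias,
         insulator_bins = as.integer(insulator_bins %||% integer(0)),
         state_labels = state_labels,
         pair_labels = pair_labels),
    class = "synthetic_truth"
  )
}

#' Generate a synthetic genome with controllable restriction sites
#'
#' Draws random sequence at the requested GC content, removes spontaneous
#' occurrences of the recognition motif, then injects the motif at a
#' per-bp rate of `site_rate`, so that in-silico digestion yields
#' fragments with a controllable size distribution (expected fragment
#' length approximately `1 / site_rate`).
#'
#' @param n_chrom Number of chromosomes.
#' @param lengths Chromosome lengths in bp (recycled to `n_chrom`;
#'   each at least 10 kb).
#' @param gc GC fraction in (0, 1), or 0 for an AT-only background.
#' @param site Recognition motif to inject (e.g. `"GATC"`).
#' @param site_rate Per-bp injection probability (0 disables injection).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A named [Biostrings::DNAStringSet].
#' @export
gen_genome <- function(n_chrom = 1, lengths = 1e5, gc = 0.36,
                       site = "GATC", site_rate = 1 / 250, seed = 1L) {
  lengths <- rep_len(lengths, n_chrom)
  if (any(lengths < 1e4)) stop_param("chromosome lengths must be >= 10 kb")
  if (gc < 0 || gc >= 1) stop_param("`gc` must be in [0, 1)")
  if (site_rate < 0) stop_param("`site_rate` must be >= 0")
  site <- toupper(site)
  withr_seed(seed, {
    seqs <- vapply(seq_len(n_chrom), function(i) {
      len <- lengths[i]
      p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      s <- sample(names(p), len, replace = TRUE, prob = p)
      s <- break_motif(s, site)
      if (site_rate > 0) {
        cand <- which(runif(len - nchar(site) + 1) < site_rate)
        # enforce non-overlapping injections
        keep <- cand[c(TRUE, diff(cand) >= nchar(site))]
        while (length(keep) < length(cand)) {
          cand <- keep
          keep <- cand[c(TRUE, diff(cand) >= nchar(site))]
        }
        for (pos in keep) {
          s[pos:(pos + nchar(site) - 1)] <- strsplit(site, "")[[1]]
        }
      }
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- paste0("chr", seq_len(n_chrom))
    Biostrings::DNAStringSet(seqs)
  })
}

# mutate the first base of every motif occurrence until none remain
break_motif <- function(s, site) {
  sub <- strsplit(site, "")[[1]]
  k <- length(sub)
  repeat {
    str <- paste(s, collapse = "")
    m <- Biostrings::matchPattern(site, Biostrings::DNAString(str))
    if (length(m) == 0) break
    pos <- BiocGenerics::start(m)
    repl <- setdiff(c("A", "T"), sub[1])[1] %||% "A"
    if (length(setdiff(c("A", "T"), sub[1])) == 0) repl <- "C"
    s[pos] <- repl
  }
  s
}

#' Generate a synthetic contact map with planted structure
#'
#' Expected count for a bin pair `(i, j)` is
#' `base_count * |i - j|^decay_exponent * bias_i * bias_j`, multiplied by
#' `strip_boost` for pairs touching a planted strip bin within 50 kb
#' (offsets 1–25 at 2-kb bins), and by `di_block_strength` for contacts
#' of a "down"-block bin with bins downstream within the 60-kb DI window
#' (mirrored for "up" blocks). Counts are Poisson-distributed and the
#' matrix is symmetric; masked structure is all planted through `truth`.
#'
#' @param n_bins Number of bins (at least 60, to support a 60-kb DI
#'   window at 2-kb bins).
#' @param bin_size Bin width in bp (default 2000).
#' @param decay_exponent Power-law decay exponent (negative).
#' @param base_count Expected count at unit distance.
#' @param truth A [synthetic_truth()] carrying planted strips, blocks
#'   and biases.
#' @param strip_boost Multiplier (> 1) for strip-bin contacts.
#' @param di_block_strength Multiplier (> 1) for directional-block
#'   contacts.
#' @param seed Integer seed.
#' @return A list with `matrix` (raw `contact_matrix`) and `truth`.
#' @export
gen_contact_map <- function(n_bins, bin_size = 2000, decay_exponent = -1,
                            base_count = 50, truth = synthetic_truth(n_bins),
                            strip_boost = 3, di_block_strength = 2,
                            seed = 1L) {
  if (n_bins < 60) stop_param("`n_bins` must be at least 60")
  if (decay_exponent >= 0) stop_param("`decay_exponent` must be negative")
  if (strip_boost <= 1 || di_block_strength <= 1) {
    stop_param("boost multipliers must exceed 1")
  }
  stopifnot(truth$n_bins == n_bins)
  strip_reach <- max(1L, 50000 %/% bin_size)      # strips touch <= 50 kb
  di_reach <- max(1L, 60000 %/% bin_size)         # DI window 60 kb

  lambda <- matrix(0, n_bins, n_bins)
  i <- row(lambda); j <- col(lambda)
  d <- abs(i - j)
  lambda[d > 0] <- base_count * d[d > 0]^decay_exponent
  diag(lambda) <- base_count
  lambda <- lambda * outer(truth$bin_bias, truth$bin_bias)

  if (length(truth$strip_bins) > 0) {
    is_strip <- logical(n_bins)
    is_strip[truth$strip_bins + 1L] <- TRUE
    touch <- (is_strip[i] | is_strip[j]) & d >= 1 & d <= strip_reach
    lambda[touch] <- lambda[touch] * strip_boost
  }

  if (nrow(truth$blocks) > 0) {
    dirf <- matrix(1, n_bins, n_bins)
    for (b in seq_len(nrow(truth$blocks))) {
      bins <- (truth$blocks$start_bin[b]:truth$blocks$end_bin[b]) + 1L
      bins <- bins[bins >= 1 & bins <= n_bins]
      if (truth$blocks$direction[b] == "down") {
        sel <- (i %in% bins) & j > i & (j - i) <= di_reach
        sel <- sel | ((j %in% bins) & i > j & (i - j) <= di_reach)
      } else {
        sel <- (i %in% bins) & j < i & (i - j) <= di_reach
        sel <- sel | ((j %in% bins) & i < j & (j - i) <= di_reach)
      }
      dirf[sel] <- dirf[sel] * di_block_strength
    }
    lambda <- lambda * dirf
  }

  withr_seed(seed, {
    up <- upper.tri(lambda, diag = TRUE)
    counts <- matrix(0, n_bins, n_bins)
    counts[up] <- rpois(sum(up), lambda[up])
    counts <- counts + t(counts) - diag(diag(counts))
  })
  list(matrix = contact_matrix(counts, "chrS", bin_size, kind = "raw"),
       truth = truth)
}

#' Generate a synthetic epigenome with latent chromatin states
#'
#' For each 400-bp bin with latent state `s` and each mark `m`, the
#' enrichment fraction is drawn as a scaled binomial with mean
#' `emission_table[s, m]`, so state-conditional mark profiles match the
#' emission table in expectation.
#'
#' @param n_bins Number of 400-bp bins.
#' @param state_labels Integer vector of latent states 1–6 (recycled).
#' @param emission_table 6 x n_marks matrix of probabilities in `[0, 1]`
#'   (column names become mark names).
#' @param seed Integer seed.
#' @param depth Binomial denominator controlling sampling noise
#'   (default 20).
#' @return A list with `coverage` (long tibble `chrom`, `bin`, `mark`,
#'   `coverage`) and `truth` (a [synthetic_truth()] carrying the state
#'   labels).
#' @export
gen_epigenome <- function(n_bins, state_labels, emission_table,
                          seed = 1L, depth = 20L) {
  if (any(emission_table < 0 | emission_table > 1)) {
    stop_param("emission probabilities must be in [0, 1]")
  }
  state_labels <- rep_len(as.integer(state_labels), n_bins)
  if (any(state_labels < 1 | state_labels > nrow(emission_table))) {
    stop_param("state label outside 1..", nrow(emission_table))
  }
  marks <- colnames(emission_table) %||%
    paste0("mark", seq_len(ncol(emission_table)))
  cov <- withr_seed(seed, {
    purrr::map_dfr(seq_along(marks), function(m) {
      p <- emission_table[state_labels, m]
      tibble(chrom = "chrS", bin = seq_len(n_bins) - 1L, mark = marks[m],
             coverage = rbinom(n_bins, depth, p) / depth)
    })
  })
  truth <- synthetic_truth(n_bins, state_labels = state_labels)
  list(coverage = cov, truth = truth)
}

#' Generate labelled synthetic read pairs
#'
#' Builds read-pair populations whose mapped geometry matches each Hi-C
#' library class by construction: `valid_intra` (FR with apparent insert
#' above 600 bp, or RF with a cut site between the reads and mapped
#' distance at least 1500 bp), `valid_inter` (reads on two chromosomes
#' close upstream of cut sites so the inferred insert stays below
#' 600 bp), `self_ligation` (RF within one restriction fragment),
#' `undigested_loop` (RF spanning a cut site but closer than 1500 bp)
#' and `short_insert` (FR with apparent insert at most 600 bp). True
#' labels are recorded for confusion-matrix evaluation.
#'
#' @param genome Genome the cut index refers to.
#' @param cut_index Named list of sorted cut positions per chromosome.
#' @param n_pairs Number of pairs to generate.
#' @param class_mix Named probabilities over the five classes (must sum
#'   to 1; missing classes default to 0).
#' @param read_len Mapped read length in bp (default 80).
#' @param seed Integer seed.
#' @return A list with `pairs` (pair tibble) and `truth_labels`
#'   (character vector of planted classes, aligned with `pairs` rows).
#' @export
gen_read_pairs <- function(genome, cut_index, n_pairs,
                           class_mix = c(valid_intra = 0.5,
                                         self_ligation = 0.2,
                                         undigested_loop = 0.2,
                                         short_insert = 0.1),
                           read_len = 80L, seed = 1L) {
  genome <- as_dnastringset(genome)
  classes <- c("valid_intra", "valid_inter", "self_ligation",
               "undigested_loop", "short_insert")
  mix <- setNames(numeric(length(classes)), classes)
  mix[names(class_mix)] <- class_mix
  if (abs(sum(mix) - 1) > 1e-8) stop_param("`class_mix` must sum to 1")
  if (n_pairs == 0) {
    return(list(pairs = empty_pairs(), truth_labels = character(0)))
  }
  chroms <- names(genome)
  lens <- setNames(vapply(seq_along(genome), function(i)
    length(genome[[i]]), integer(1)), chroms)
  if (mix[["valid_inter"]] > 0 && length(chroms) < 2) {
    stop_param("valid_inter pairs need at least 2 chromosomes")
  }
  no_cuts <- all(vapply(cut_index, length, integer(1)) == 0)
  if (no_cuts && mix[["valid_intra"]] > 0) {
    stop_param("cannot place valid_intra pairs without cut sites")
  }

  withr_seed(seed, {
    labels <- sample(classes, n_pairs, replace = TRUE, prob = mix)
    rows <- lapply(labels, function(lab) {
      chrom <- sample(chroms, 1)
      cc <- cut_index[[chrom]]
      len <- lens[[chrom]]
      switch(lab,
        valid_intra = sim_valid_intra(chrom, cc, len, read_len),
        valid_inter = sim_valid_inter(chroms, cut_index, lens, read_len),
        self_ligation = sim_self_ligation(chrom, cc, len, read_len),
        undigested_loop = sim_undigested(chrom, cc, len, read_len),
        short_insert = sim_short_insert(chrom, len, read_len)
      )
    })
    list(pairs = bind_rows(rows), truth_labels = labels)
  })
}

empty_pairs <- function() {
  tibble(chrom1 = character(0), pos1 = integer(0), strand1 = character(0),
         len1 = integer(0), chrom2 = character(0), pos2 = integer(0),
         strand2 = character(0), len2 = integer(0))
}

pair_row <- function(chrom1, pos1, strand1, chrom2, pos2, strand2, rl) {
  tibble(chrom1 = chrom1, pos1 = as.integer(pos1), strand1 = strand1,
         len1 = as.integer(rl), chrom2 = chrom2, pos2 = as.integer(pos2),
         strand2 = strand2, len2 = as.integer(rl))
}

sim_valid_intra <- function(chrom, cc, len, rl) {
  if (runif(1) < 0.5 || length(cc) == 0) {
    # FR with apparent insert > 600
    gap <- sample(2000:20000, 1)
    p1 <- sample.int(max(len - gap - 2 * rl, 1), 1) - 1L
    pair_row(chrom, p1, "+", chrom, p1 + gap + rl, "-", rl)
  } else {
    # RF, cut site between reads, distance >= 1500
    gap <- sample(2000:20000, 1)
    for (try in 1:50) {
      p1 <- sample.int(max(len - gap - 2 * rl, 1), 1) - 1L
      p2 <- p1 + gap
      i <- findInterval(p2, cc)
      if (i >= 1 && cc[i] >= p1 + rl) {
        return(pair_row(chrom, p1, "-", chrom, p2, "+", rl))
      }
    }
    pair_row(chrom, 0L, "-", chrom, gap, "+", rl)
  }
}

sim_valid_inter <- function(chroms, cut_index, lens, rl) {
  ch <- sample(chroms, 2)
  place <- function(chrom) {
    cc <- cut_index[[chrom]]
    cc <- cc[cc > rl + 60]
    if (length(cc) == 0) return(NULL)
    cut <- sample(cc, 1)
    d <- sample(0:50, 1)                 # read 3' end d bp before the cut
    pos <- cut - d - rl                  # forward read
    list(pos = max(pos, 0L), strand = "+")
  }
  a <- place(ch[1]); b <- place(ch[2])
  if (is.null(a) || is.null(b)) {
    return(pair_row(ch[1], 0L, "+", ch[2], 0L, "+", rl))
  }
  pair_row(ch[1], a$pos, a$strand, ch[2], b$pos, b$strand, rl)
}

sim_self_ligation <- function(chrom, cc, len, rl) {
  # RF entirely within one fragment: no cut in the gap between reads
  bounds <- c(0, cc, len)
  w <- diff(bounds)
  ok <- which(w >= 2 * rl + 40)
  if (length(ok) == 0) {
    return(pair_row(chrom, 0L, "-", chrom, rl + 10L, "+", rl))
  }
  f <- ok[sample.int(length(ok), 1)]
  fs <- bounds[f]; fw <- w[f]
  gap <- sample.int(fw - 2 * rl, 1)
  p1 <- fs + sample.int(fw - 2 * rl - gap + 1, 1) - 1L
  pair_row(chrom, p1, "-", chrom, p1 + rl + gap, "+", rl)
}

sim_undigested <- function(chrom, cc, len, rl) {
  # RF spanning a cut but distance < 1500
  for (try in 1:100) {
    gap <- sample(300:(1500 - rl - 1), 1)
    p1 <- sample.int(len - gap - 2 * rl, 1) - 1L
    p2 <- p1 + gap
    i <- findInterval(p2, cc)
    if (i >= 1 && cc[i] >= p1 + rl) {
      return(pair_row(chrom, p1, "-", chrom, p2, "+", rl))
    }
  }
  # fall back: drop a synthetic cut assumption; place around first cut
  cut <- if (length(cc) > 0) cc[1] else 1000L
  pair_row(chrom, max(cut - 400L, 0L), "-", chrom, cut + 200L, "+", rl)
}

sim_short_insert <- function(chrom, len, rl) {
  ins <- sample((2 * rl):600, 1)
  p1 <- sample.int(len - ins - 1, 1) - 1L
  pair_row(chrom, p1, "+", chrom, p1 + ins - rl, "-", rl)
}
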