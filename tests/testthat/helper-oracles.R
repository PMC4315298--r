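# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-implementations (per-record loops, per-window
# scans) kept separate from the package's vectorized code paths.

# Brute-force read-pair classifier: rescans the cut list for every pair.
oracle_classify <- function(pairs, cuts, lens,
                            insert_max = 600, min_rf = 1500) {
  out <- character(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    c1 <- pairs$chrom1[k]; p1 <- pairs$pos1[k]
    s1 <- pairs$strand1[k]; l1 <- pairs$len1[k]
    c2 <- pairs$chrom2[k]; p2 <- pairs$pos2[k]
    s2 <- pairs$strand2[k]; l2 <- pairs$len2[k]
    # canonical side order
    if (c1 > c2 || (c1 == c2 && p1 > p2) ||
        (c1 == c2 && p1 == p2 && s1 > s2)) {
      tmp <- list(c1, p1, s1, l1)
      c1 <- c2; p1 <- p2; s1 <- s2; l1 <- l2
      c2 <- tmp[[1]]; p2 <- tmp[[2]]; s2 <- tmp[[3]]; l2 <- tmp[[4]]
    }
    down_dist <- function(chrom, pos, strand, len) {
      cc <- cuts[[chrom]]
      if (strand == "+") {
        cand <- cc[cc >= pos + len]
        if (length(cand) > 0) min(cand) - (pos + len)
        else max(lens[[chrom]] - (pos + len), 0)
      } else {
        cand <- cc[cc <= pos]
        if (length(cand) > 0) pos - max(cand) else pos
      }
    }
    if (c1 != c2) {
      d <- l1 + l2 + down_dist(c1, p1, s1, l1) + down_dist(c2, p2, s2, l2)
      out[k] <- if (d < insert_max) "valid_inter" else "short_insert"
    } else if (s1 == "+" && s2 == "-") {
      out[k] <- if (p2 + l2 - p1 > insert_max) "valid_intra" else
        "short_insert"
    } else if (s1 == "-" && s2 == "+") {
      cc <- cuts[[c1]]
      has_cut <- any(cc >= p1 + l1 & cc <= p2)
      out[k] <- if (!has_cut) "self_ligation"
      else if (p2 - p1 < min_rf) "too_close"
      else "valid_intra"
    } else {
      out[k] <- "valid_intra"
    }
  }
  out
}

# Brute-force pattern matcher over one state string. Returns 0-based
# (start, end) bin spans per subtype, deduplicated. `start_bin` is the
# chromosome bin of the string's first character.
oracle_patterns <- function(s, start_bin = 0L) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  hits <- list()
  add <- function(type, subtype, a, b) {
    hits[[length(hits) + 1]] <<- data.frame(
      start_bin = start_bin + a - 1L, end_bin = start_bin + b - 1L,
      type = type, subtype = subtype)
  }
  for (p in seq_len(n)) {
    # insulators: XXUUDDXX / XXUUNDDXX / XXUUNNDDXX
    if (p >= 3 && p + 5 <= n &&
        all(ch[p:(p + 1)] == "U") && all(ch[(p + 2):(p + 3)] == "D")) {
      add("insulator", "A", p + 1, p + 2)
    }
    if (p >= 3 && p + 6 <= n &&
        all(ch[p:(p + 1)] == "U") && ch[p + 2] == "N" &&
        all(ch[(p + 3):(p + 4)] == "D")) {
      add("insulator", "B", p + 1, p + 3)
    }
    if (p >= 3 && p + 7 <= n &&
        all(ch[p:(p + 1)] == "U") && all(ch[(p + 2):(p + 3)] == "N") &&
        all(ch[(p + 4):(p + 5)] == "D")) {
      add("insulator", "C", p + 1, p + 4)
    }
    # boundaries: UUUUU(D/N)(D/N)X and X(U/N)(U/N)DDDDD
    if (p + 7 <= n && all(ch[p:(p + 4)] == "U") &&
        ch[p + 5] %in% c("D", "N") && ch[p + 6] %in% c("D", "N")) {
      add("boundary", "U(D/N)", p + 4, p + 5)
    }
    if (p + 7 <= n && ch[p + 1] %in% c("U", "N") &&
        ch[p + 2] %in% c("U", "N") && all(ch[(p + 3):(p + 7)] == "D")) {
      add("boundary", "(U/N)D", p + 2, p + 3)
    }
    # interiors: X(D/N)(D/N)UUUUU and DDDDD(U/N)(U/N)X
    if (p + 7 <= n && ch[p + 1] %in% c("D", "N") &&
        ch[p + 2] %in% c("D", "N") && all(ch[(p + 3):(p + 7)] == "U")) {
      add("interior", "(D/N)U", p + 2, p + 3)
    }
    if (p + 7 <= n && all(ch[p:(p + 4)] == "D") &&
        ch[p + 5] %in% c("U", "N") && ch[p + 6] %in% c("U", "N")) {
      add("interior", "D(U/N)", p + 4, p + 5)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start_bin = integer(0), end_bin = integer(0),
                      type = character(0), subtype = character(0)))
  }
  unique(do.call(rbind, hits))
}

# state tibble for a plain string (no exclusions)
states_from_string <- function(s, chrom = "chrT") {
  tibble::tibble(chrom = chrom, bin = seq_len(nchar(s)) - 1L,
                 di = 0, excluded = FALSE,
                 state = strsplit(s, "")[[1]])
}

region_key <- function(df) {
  sort(paste(df$start_bin, df$end_bin, df$type, df$subtype))
}

# Compare the package's Poisson bias fit against an independent
# direct-likelihood optimizer (BFGS with analytic gradient) on a small
# instance: a 12-bin matrix tiling a 4-bin covariate structure.
norm_oracle_compare <- function(seed = 42) {
  set.seed(seed)
  base4 <- list(eff_len = c(0.9, 0.5, 0.7, 0.3),
                gc_ends = c(0.3, 0.45, 0.38, 0.5),
                end_count = c(4, 9, 6, 12),
                mappability = c(1, 0.9, 0.8, 1))
  nn <- 12
  feats <- tibble::tibble(chrom = "c1", bin = seq_len(nn) - 1L,
                          eff_len = rep(base4$eff_len, 3),
                          gc_ends = rep(base4$gc_ends, 3),
                          end_count = rep(base4$end_count, 3),
                          mappability = rep(base4$mappability, 3))
  pr <- t(utils::combn(seq_len(nn), 2))
  X <- cbind(1,
             log(feats$eff_len[pr[, 1]] * feats$eff_len[pr[, 2]]),
             log(feats$gc_ends[pr[, 1]] * feats$gc_ends[pr[, 2]]),
             log(feats$end_count[pr[, 1]] * feats$end_count[pr[, 2]]))
  off <- log(feats$mappability[pr[, 1]] * feats$mappability[pr[, 2]])
  lam <- exp(X %*% c(3, 0.9, 0.4, 0.7) + off)
  u <- stats::rpois(length(lam), lam)
  m <- matrix(0, nn, nn)
  m[pr] <- u
  m[pr[, c(2, 1)]] <- u
  raw <- contact_matrix(m, "c1", 2000, kind = "raw")
  got <- normalize_contacts(raw, feats)

  negll <- function(b) {
    eta <- X %*% b + off
    sum(exp(eta)) - sum(u * eta)
  }
  grad <- function(b) {
    eta <- X %*% b + off
    as.numeric(t(X) %*% (exp(eta) - u))
  }
  oracle <- stats::optim(rep(0, 4), negll, grad, method = "BFGS",
                         control = list(maxit = 2000, reltol = 1e-15))$par
  list(package = unname(got$fit$coefficients), oracle = oracle,
       fit = got$fit)
}

# uniform per-bin covariate table matching a synthetic contact matrix
flat_features <- function(mat) {
  n <- nrow(mat$values)
  tibble::tibble(chrom = mat$chrom, bin = seq_len(n) - 1L,
                 eff_len = 1, gc_ends = 0.5, end_count = 8,
                 mappability = 1)
}
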