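#' Percentile-scored strip index
#'
#' For each focal bin, the contact value at every signed offset
#' `o` in `±{offset_min..offset_max}` (defaults 3–25 bins: 6–50 kb at
#' 2-kb resolution, 46 offsets) is ranked against the *equivalent* values
#' — the same-offset contacts — of the focal bin's nearest unmasked
#' neighbours (`neighbor_count / 2` per side, default 100 per side, a
#' local 400-kb context at 2 kb). Each offset contributes
#' `+score_big` when the midrank percentile is at least `pct_hi2`,
#' `+score_small` at `pct_hi`, `-score_big` at or below `pct_lo2`,
#' `-score_small` at `pct_lo`, else 0; offsets whose cell is masked or
#' out of range contribute 0. The index is the sum over all offsets and
#' is bounded by `±46 * score_big` (±138 with defaults). Because the
#' comparison is always at equal offset, the index is insensitive to the
#' distance decay of contact frequency.
#'
#' Focal bins that are masked, or that have fewer than
#' `neighbor_count / 2` unmasked neighbours in total, are undefined.
#'
#' @param norm A normalized `contact_matrix`.
#' @param offset_min,offset_max Offset range in bins (defaults 3 and 25).
#' @param neighbor_count Total reference neighbours (default 200).
#' @param pct_hi,pct_hi2,pct_lo,pct_lo2 Percentile cutpoints
#'   (defaults 80, 95, 20, 5).
#' @param score_small,score_big Scores awarded at the outer/inner
#'   percentile cutpoints (defaults 1 and 3).
#' @return Tibble with `chrom`, `bin` (0-based), `index`, `defined`.
#' @export
strip_index <- function(norm, offset_min = 3L, offset_max = 25L,
                        neighbor_count = 200L,
                        pct_hi = 80, pct_hi2 = 95,
                        pct_lo = 20, pct_lo2 = 5,
                        score_small = 1L, score_big = 3L) {
  if (norm$kind != "normalized") {
    stop_param("`norm` must be a normalized contact matrix")
  }
  stopifnot(offset_min >= 1, offset_max >= offset_min, neighbor_count >= 2)
  score_small <- as.integer(score_small)
  score_big <- as.integer(score_big)
  half <- neighbor_count %/% 2L
  n <- nrow(norm$values)
  offsets <- c(-(offset_max:offset_min), offset_min:offset_max)
  v <- norm$values
  ok <- norm$mask

  # D[o, i] = contact of bin i at signed offset o (NA when invalid)
  D <- matrix(NA_real_, length(offsets), n)
  for (k in seq_along(offsets)) {
    o <- offsets[k]
    i <- seq_len(n)
    sel <- i + o >= 1 & i + o <= n
    i <- i[sel]
    i <- i[ok[i + o]]
    D[k, i] <- v[cbind(i, i + o)]
  }

  valid_bins <- which(ok)
  pos_in_valid <- match(seq_len(n), valid_bins)

  index <- rep(NA_integer_, n)
  for (i in valid_bins) {
    k <- pos_in_valid[i]
    lo <- max(1L, k - half)
    hi <- min(length(valid_bins), k + half)
    nb <- valid_bins[lo:hi]
    nb <- nb[nb != i]
    # keep the `half` nearest on each side
    left <- nb[nb < i]; right <- nb[nb > i]
    nb <- c(tail(left, half), head(right, half))
    if (length(nb) < half) next  # insufficient neighbour support
    vi <- D[, i]
    ref <- D[, nb, drop = FALSE]
    less <- rowSums(ref < vi, na.rm = TRUE)
    eq <- rowSums(ref == vi, na.rm = TRUE)
    nref <- rowSums(!is.na(ref))
    p <- ifelse(nref > 0, 100 * (less + 0.5 * eq) / nref, NA_real_)
    sc <- dplyr::case_when(
      is.na(vi) | is.na(p) ~ 0L,
      p >= pct_hi2 ~ score_big,
      p >= pct_hi ~ score_small,
      p <= pct_lo2 ~ -score_big,
      p <= pct_lo ~ -score_small,
      TRUE ~ 0L
    )
    index[i] <- sum(sc)
  }
  tibble(chrom = norm$chrom, bin = seq_len(n) - 1L,
         index = index, defined = !is.na(index))
}

#' Call positive and negative strips from an index track
#'
#' Positive strips are maximal runs of consecutive defined bins with
#' index at or above `+cutoff`; negative strips mirror this at or below
#' `-cutoff`. Strips of both polarities are reported; bins in negative
#' strips typically reflect sequence biases and are conventionally
#' excluded from downstream biological interpretation.
#'
#' @param track Index tibble from [strip_index()].
#' @param cutoff Positive index cutoff (default 45).
#' @return Tibble with `chrom`, `start_bin`, `end_bin` (0-based,
#'   inclusive), `polarity` (`"positive"`/`"negative"`), `n_bins`,
#'   `peak_index`.
#' @export
call_strips <- function(track, cutoff = 45) {
  if (cutoff <= 0) stop_param("`cutoff` must be positive")
  track <- track |> arrange(.data$chrom, .data$bin)
  call_one <- function(hit, polarity) {
    sel <- hit & track$defined
    if (!any(sel)) return(NULL)
    # runs of consecutive bins within a chromosome
    brk <- c(TRUE, track$chrom[-1] != track$chrom[-nrow(track)] |
               diff(track$bin) != 1)
    run_id <- cumsum(brk | !sel)
    df <- track[sel, , drop = FALSE]
    df$run <- run_id[sel]
    df |>
      group_by(.data$run) |>
      summarise(chrom = .data$chrom[1],
                start_bin = min(.data$bin), end_bin = max(.data$bin),
                n_bins = dplyr::n(),
                peak_index = .data$index[which.max(abs(.data$index))],
                .groups = "drop") |>
      mutate(polarity = polarity) |>
      select(-"run")
  }
  hit_pos <- !is.na(track$index) & track$index >= cutoff
  hit_neg <- !is.na(track$index) & track$index <= -cutoff
  out <- bind_rows(call_one(hit_pos, "positive"),
                   call_one(hit_neg, "negative"))
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(chrom = character(0), start_bin = integer(0),
                  end_bin = integer(0), n_bins = integer(0),
                  peak_index = integer(0), polarity = character(0)))
  }
  out |>
    select("chrom", "start_bin", "end_bin", "polarity",
           "n_bins", "peak_index") |>
    arrange(.data$chrom, .data$start_bin)
}
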