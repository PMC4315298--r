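#' Orientation mode of mapped read pairs
#'
#' For intrachromosomal pairs ordered so that `pos1 <= pos2`, the pair is
#' `FR` (forward/reverse, "paired-end mode") when the left read maps to the
#' forward strand and the right read to the reverse strand, `RF`
#' (reverse/forward, "mate-pair mode") for the opposite arrangement, and
#' `FF`/`RR` when both reads share a strand.
#'
#' @param pairs Tibble of pair records with columns `strand1`, `strand2`
#'   (values `"+"`/`"-"`), assumed canonically ordered (see
#'   [canonicalize_pairs()]).
#' @return Character vector of modes, one per pair.
#' @export
pair_orientation <- function(pairs) {
  dplyr::case_when(
    pairs$strand1 == "+" & pairs$strand2 == "-" ~ "FR",
    pairs$strand1 == "-" & pairs$strand2 == "+" ~ "RF",
    pairs$strand1 == "+" ~ "FF",
    TRUE ~ "RR"
  )
}

#' Canonically order the two sides of each pair
#'
#' Sides are swapped so that `(chrom1, pos1, strand1)` sorts at or before
#' `(chrom2, pos2, strand2)`. Classification and duplicate removal both
#' assume this ordering.
#'
#' @param pairs Pair tibble (`chrom1, pos1, strand1, len1, chrom2, pos2,
#'   strand2, len2`).
#' @return The same tibble with sides canonically ordered.
#' @export
canonicalize_pairs <- function(pairs) {
  swap <- (pairs$chrom1 > pairs$chrom2) |
    (pairs$chrom1 == pairs$chrom2 & pairs$pos1 > pairs$pos2) |
    (pairs$chrom1 == pairs$chrom2 & pairs$pos1 == pairs$pos2 &
       pairs$strand1 > pairs$strand2)
  swapped <- pairs
  swapped[swap, c("chrom1", "pos1", "strand1", "len1",
                  "chrom2", "pos2", "strand2", "len2")] <-
    pairs[swap, c("chrom2", "pos2", "strand2", "len2",
                  "chrom1", "pos1", "strand1", "len1")]
  swapped
}

#' Classify read pairs into Hi-C contact classes
#'
#' Implements the filtering rules for restriction-based Hi-C libraries:
#'
#' * **Interchromosomal** pairs are `valid_inter` when the sum of the two
#'   mapped read lengths plus each read's distance to the first enzyme cut
#'   site downstream (in the read's 5'→3' orientation, measured from the
#'   3' end of the mapped read) is below the library insert size
#'   (`insert_max`, default 600 bp); otherwise `short_insert`.
#' * **Intrachromosomal FR** pairs are `valid_intra` when the apparent
#'   insert (`pos2 + len2 - pos1`) exceeds `insert_max`, else
#'   `short_insert`.
#' * **Intrachromosomal RF** pairs with no cut site in the gap between the
#'   two reads are `self_ligation`; with a cut site but mapped loci closer
#'   than `min_rf_distance` (default 1500 bp) they are `too_close`
#'   (undigested-loop products); otherwise `valid_intra`.
#' * **FF/RR** pairs cannot arise from self-ligation or an undigested
#'   linear fragment and are kept as `valid_intra`.
#'
#' @param pairs Pair tibble (see [canonicalize_pairs()]; ordering is
#'   applied internally).
#' @param cut_index Named list of sorted cut positions per chromosome
#'   (e.g. `attr(digest_genome(...), "cuts")`), with chromosome lengths as
#'   attribute `"chrom_lengths"` or supplied via `chrom_lengths`.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp),
#'   used when a read maps beyond the last cut site.
#' @param insert_max Library insert size bound in bp (default 600).
#' @param min_rf_distance Minimum mapped-locus distance for RF pairs in bp
#'   (default 1500).
#' @return The input tibble (canonically ordered) with added columns
#'   `mode` and `class`.
#' @export
classify_pairs <- function(pairs, cut_index, chrom_lengths = NULL,
                           insert_max = 600, min_rf_distance = 1500) {
  chrom_lengths <- chrom_lengths %||% attr(cut_index, "chrom_lengths")
  chroms <- unique(c(pairs$chrom1, pairs$chrom2))
  missing <- setdiff(chroms, names(cut_index))
  if (length(missing) > 0) {
    stop_param("chromosome(s) absent from cut index: ",
               paste(missing, collapse = ", "))
  }
  pairs <- canonicalize_pairs(pairs)
  n <- nrow(pairs)
  mode <- pair_orientation(pairs)
  class <- character(n)

  intra <- pairs$chrom1 == pairs$chrom2

  # interchromosomal: insert criterion
  if (any(!intra)) {
    idx <- which(!intra)
    d1 <- downstream_cut_distance(pairs$chrom1[idx], pairs$pos1[idx],
                                  pairs$strand1[idx], pairs$len1[idx],
                                  cut_index, chrom_lengths)
    d2 <- downstream_cut_distance(pairs$chrom2[idx], pairs$pos2[idx],
                                  pairs$strand2[idx], pairs$len2[idx],
                                  cut_index, chrom_lengths)
    tot <- pairs$len1[idx] + pairs$len2[idx] + d1 + d2
    class[idx] <- ifelse(tot < insert_max, "valid_inter", "short_insert")
  }

  # intrachromosomal FR: apparent (outer) insert
  fr <- which(intra & mode == "FR")
  if (length(fr) > 0) {
    ins <- pairs$pos2[fr] + pairs$len2[fr] - pairs$pos1[fr]
    class[fr] <- ifelse(ins > insert_max, "valid_intra", "short_insert")
  }

  # intrachromosomal RF: self-ligation, then distance filter
  rf <- which(intra & mode == "RF")
  if (length(rf) > 0) {
    gap_lo <- pairs$pos1[rf] + pairs$len1[rf]
    gap_hi <- pairs$pos2[rf]
    has_cut <- vapply(seq_along(rf), function(k) {
      cc <- cut_index[[pairs$chrom1[rf[k]]]]
      i <- findInterval(gap_hi[k], cc)       # cuts <= gap_hi
      i >= 1 && cc[i] >= gap_lo[k]
    }, logical(1))
    dist <- pairs$pos2[rf] - pairs$pos1[rf]
    class[rf] <- dplyr::case_when(
      !has_cut ~ "self_ligation",
      dist < min_rf_distance ~ "too_close",
      TRUE ~ "valid_intra"
    )
  }

  # FF / RR: kept (cannot be self-ligation or undigested linear fragments)
  class[intra & mode %in% c("FF", "RR")] <- "valid_intra"

  pairs$mode <- mode
  pairs$class <- class
  pairs
}

# distance from the 3' end of a mapped read to the first cut site
# downstream in the read's orientation; to the chromosome end when no cut
# remains. Positions 0-based; cut positions are between-base coordinates.
downstream_cut_distance <- function(chrom, pos, strand, len,
                                    cut_index, chrom_lengths) {
  vapply(seq_along(chrom), function(k) {
    cc <- cut_index[[chrom[k]]]
    if (strand[k] == "+") {
      e <- pos[k] + len[k]                   # one past the 3' base
      i <- findInterval(e - 1e-9, cc) + 1    # first cut >= e
      if (i <= length(cc)) cc[i] - e
      else {
        cl <- chrom_lengths[[chrom[k]]] %||% NA_real_
        if (is.na(cl)) 0 else max(cl - e, 0)
      }
    } else {
      s <- pos[k]                            # 3' end of a reverse read
      i <- findInterval(s, cc)               # last cut <= s
      if (i >= 1) s - cc[i] else s
    }
  }, numeric(1))
}

#' Remove duplicate read pairs
#'
#' Keeps one representative per identical
#' `(chrom1, pos1, strand1, chrom2, pos2, strand2)` key after canonical
#' side ordering, preserving first-occurrence order.
#'
#' @param pairs Pair tibble.
#' @return Deduplicated tibble (canonically ordered).
#' @export
dedup_pairs <- function(pairs) {
  pairs <- canonicalize_pairs(pairs)
  key <- paste(pairs$chrom1, pairs$pos1, pairs$strand1,
               pairs$chrom2, pairs$pos2, pairs$strand2, sep = "\r")
  pairs[!duplicated(key), , drop = FALSE]
}

#' Filter read pairs to valid Hi-C contacts
#'
#' Applies [dedup_pairs()] then [classify_pairs()] and returns the valid
#' contacts together with a census of all classes.
#'
#' @inheritParams classify_pairs
#' @return A list with elements `contacts` (tibble of
#'   `valid_intra`/`valid_inter` pairs with their classification),
#'   `census` (tibble `class`, `n` over the deduplicated pairs) and
#'   `n_duplicates` (number of records removed as duplicates).
#' @export
filter_pairs <- function(pairs, cut_index, chrom_lengths = NULL,
                         insert_max = 600, min_rf_distance = 1500) {
  n0 <- nrow(pairs)
  dd <- dedup_pairs(pairs)
  cl <- classify_pairs(dd, cut_index, chrom_lengths,
                       insert_max = insert_max,
                       min_rf_distance = min_rf_distance)
  census <- cl |>
    count(.data$class, name = "n") |>
    arrange(desc(.data$n))
  list(
    contacts = cl |> filter(.data$class %in% c("valid_intra", "valid_inter")),
    census = census,
    n_duplicates = n0 - nrow(dd)
  )
}
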