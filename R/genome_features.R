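#' In-silico restriction digestion of a genome
#'
#' Scans each chromosome for occurrences of the enzyme recognition motif on
#' the forward strand and cuts at `occurrence start + cut_offset`. For the
#' palindromic sites of the enzymes relevant at kilobase resolution this is
#' lossless: DpnII ("GATC", cut offset 0) and HindIII ("AAGCTT", cut
#' offset 1) cut both strands at positions recovered by a forward-strand
#' scan. Fragments tile each chromosome without gaps; zero-length fragments
#' (a cut at position 0 or at the chromosome end) are dropped.
#'
#' @param genome A named [Biostrings::DNAStringSet] (or named character
#'   vector of DNA sequences).
#' @param site Recognition motif, e.g. `"GATC"`. Must be A/C/G/T only.
#' @param cut_offset Cut position within the motif (0-based,
#'   `0 <= cut_offset <= nchar(site)`). Defaults to 0 (DpnII-style "^GATC").
#' @return A tibble with columns `chrom`, `start`, `end` (0-based,
#'   half-open) and `length`. The per-chromosome cut positions are attached
#'   as attribute `"cuts"` (a named list of integer vectors), so that
#'   downstream covariate computation can count fragment ends exactly.
#' @examples
#' g <- c(chr1 = "AAAGATCTT")
#' digest_genome(g, "GATC")
#' @export
digest_genome <- function(genome, site, cut_offset = 0L) {
  genome <- as_dnastringset(genome)
  site <- toupper(site)
  if (!grepl("^[ACGT]+$", site)) {
    stop_param("`site` must contain only A/C/G/T characters")
  }
  if (nchar(site) < 2) stop_param("`site` must be at least 2 bp")
  if (cut_offset < 0 || cut_offset > nchar(site)) {
    stop_param("`cut_offset` must lie within the motif")
  }
  cuts <- lapply(seq_along(genome), function(i) {
    m <- Biostrings::matchPattern(site, genome[[i]])
    sort(BiocGenerics::start(m) - 1L + as.integer(cut_offset))
  })
  names(cuts) <- names(genome)
  frags <- purrr::map2_dfr(names(genome), cuts, function(chrom, cc) {
    len <- length(genome[[chrom]])
    bounds <- unique(c(0L, cc, len))
    tibble(
      chrom = chrom,
      start = head(bounds, -1L),
      end = tail(bounds, -1L)
    )
  })
  frags <- frags |>
    filter(.data$end > .data$start) |>
    mutate(length = .data$end - .data$start)
  attr(frags, "cuts") <- cuts
  frags
}

#' Per-bin normalization covariates from a digestion
#'
#' Computes, for fixed-size bins along each chromosome, the covariates that
#' drive coverage bias in restriction-based Hi-C: the number of fragment
#' ends (cut sites) per bin, the GC fraction of the sequence flanking those
#' cut sites, and the effective fragment length (fraction of the bin lying
#' within `eff_flank` bp of a cut site, i.e. the part of the bin that can
#' actually contribute sequenced ligation junctions).
#'
#' @param fragments Fragment tibble from [digest_genome()] (its `"cuts"`
#'   attribute is used when present; otherwise cut positions are recovered
#'   from internal fragment boundaries).
#' @param genome The genome the fragments came from.
#' @param bin_size Bin width in bp.
#' @param end_flank Flank (bp) on each side of a cut site over which
#'   fragment-end GC content is measured. Default 200.
#' @param eff_flank Distance (bp) from a cut site within which sequence is
#'   considered "effective". Default 500.
#' @param mappability Optional per-bin mappability in `[0, 1]`: either a
#'   single value recycled to all bins or a tibble with columns
#'   `chrom`, `bin`, `mappability`. Defaults to 1 everywhere.
#' @return A tibble with columns `chrom`, `bin` (0-based), `start`, `end`,
#'   `eff_len`, `gc_ends`, `end_count`, `mappability`.
#' @export
bin_features <- function(fragments, genome, bin_size,
                         end_flank = 200L, eff_flank = 500L,
                         mappability = 1) {
  if (bin_size <= 0) stop_param("`bin_size` must be positive")
  if (end_flank <= 0 || eff_flank <= 0) {
    stop_param("`end_flank` and `eff_flank` must be positive")
  }
  genome <- as_dnastringset(genome)
  cuts <- attr(fragments, "cuts") %||% cuts_from_fragments(fragments)

  out <- purrr::map_dfr(names(genome), function(chrom) {
    len <- length(genome[[chrom]])
    n_bins <- ceiling(len / bin_size)
    cc <- cuts[[chrom]] %||% integer(0)
    bin_start <- (seq_len(n_bins) - 1L) * bin_size
    bin_end <- pmin(bin_start + bin_size, len)

    end_count <- tabulate(cc %/% bin_size + 1L, nbins = n_bins)

    # coverage of "effective" sequence: union of +/- eff_flank around cuts
    eff_cov <- interval_union_ranges(cc, eff_flank, len)
    eff_len <- bin_overlap_fraction(eff_cov, bin_start, bin_end)

    # GC of fragment-end flanks: per bin, union of +/- end_flank windows
    # around the cut sites inside that bin
    seq_chr <- genome[[chrom]]
    gc_ends <- vapply(seq_len(n_bins), function(b) {
      in_bin <- cc[cc >= bin_start[b] & cc < bin_end[b]]
      if (length(in_bin) == 0) return(0)
      win <- interval_union_ranges(in_bin, end_flank, len)
      if (length(win) == 0) return(0)
      v <- Biostrings::Views(seq_chr, start = BiocGenerics::start(win),
                             end = BiocGenerics::end(win))
      af <- Biostrings::alphabetFrequency(v, baseOnly = TRUE)
      tot <- sum(af[, c("A", "C", "G", "T")])
      if (tot == 0) 0 else sum(af[, c("G", "C")]) / tot
    }, numeric(1))

    tibble(
      chrom = chrom, bin = seq_len(n_bins) - 1L,
      start = bin_start, end = bin_end,
      eff_len = eff_len, gc_ends = gc_ends, end_count = end_count
    )
  })

  if (is.data.frame(mappability)) {
    out <- out |>
      left_join(mappability, by = c("chrom", "bin")) |>
      mutate(mappability = ifelse(is.na(.data$mappability), 1,
                                  .data$mappability))
  } else {
    out$mappability <- rep_len(mappability, nrow(out))
  }
  out
}

#' Centromere mask as bin sets
#'
#' Converts per-chromosome excluded spans (bp) into the set of bin indices
#' overlapping any span. `spans = "tair10"` uses the *A. thaliana*
#' pericentromeric spans (Chr 1 13.7–15.9 Mb, Chr 2 2.45–5.50 Mb,
#' Chr 3 11.3–14.3 Mb, Chr 4 1.80–5.15 Mb, Chr 5 11.0–13.35 Mb).
#'
#' @param spans `"tair10"`, or a tibble with columns `chrom`, `start`,
#'   `end` (bp, 0-based half-open).
#' @param bin_size Bin width in bp.
#' @return A tibble with columns `chrom`, `bin` (0-based) of masked bins.
#' @export
centromere_mask <- function(spans, bin_size) {
  if (bin_size <= 0) stop_param("`bin_size` must be positive")
  if (is.character(spans)) {
    if (!identical(tolower(spans), "tair10")) {
      stop_param("unknown assembly '", spans,
                 "'; pass explicit spans instead")
    }
    spans <- tair10_centromeres()
  }
  if (nrow(spans) == 0) {
    return(tibble(chrom = character(0), bin = integer(0)))
  }
  stopifnot(all(spans$start < spans$end))
  purrr::pmap_dfr(spans, function(chrom, start, end, ...) {
    tibble(chrom = chrom,
           bin = seq.int(floor(start / bin_size),
                         ceiling(end / bin_size) - 1L))
  }) |>
    distinct()
}

#' Pericentromeric spans of the A. thaliana (TAIR10) assembly
#'
#' @return Tibble with `chrom`, `start`, `end` in bp.
#' @export
tair10_centromeres <- function() {
  tibble(
    chrom = paste0("Chr", 1:5),
    start = c(13.7e6, 2.45e6, 11.3e6, 1.80e6, 11.0e6),
    end   = c(15.9e6, 5.50e6, 14.3e6, 5.15e6, 13.35e6)
  )
}

# ---- helpers -------------------------------------------------------------

as_dnastringset <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      stop_param("genome sequences must be named")
    }
    return(Biostrings::DNAStringSet(genome))
  }
  stop_param("`genome` must be a DNAStringSet or named character vector")
}

cuts_from_fragments <- function(fragments) {
  fragments |>
    group_by(.data$chrom) |>
    group_map(.keep = TRUE, function(df, key) {
      b <- sort(unique(c(df$start, df$end)))
      # internal boundaries only: chromosome ends are not cut sites
      list(chrom = df$chrom[1], cuts = b[-c(1, length(b))])
    }) |>
    (\(x) setNames(lapply(x, `[[`, "cuts"),
                   vapply(x, `[[`, character(1), "chrom")))()
}

# union of [c - flank, c + flank) windows clipped to [0, len), as IRanges
interval_union_ranges <- function(cuts, flank, len) {
  if (length(cuts) == 0) return(IRanges::IRanges())
  ir <- IRanges::IRanges(start = pmax(cuts - flank, 0) + 1L,
                         end = pmin(cuts + flank, len))
  IRanges::reduce(ir)
}

# fraction of each [start, end) bin covered by the reduced ranges
bin_overlap_fraction <- function(ranges, bin_start, bin_end) {
  if (length(ranges) == 0) return(rep(0, length(bin_start)))
  bins <- IRanges::IRanges(start = bin_start + 1L, end = bin_end)
  ov <- IRanges::findOverlaps(bins, ranges)
  cov <- rep(0, length(bins))
  if (length(ov) > 0) {
    inter_w <- pmin(BiocGenerics::end(bins)[S4Vectors::queryHits(ov)],
                    BiocGenerics::end(ranges)[S4Vectors::subjectHits(ov)]) -
      pmax(BiocGenerics::start(bins)[S4Vectors::queryHits(ov)],
           BiocGenerics::start(ranges)[S4Vectors::subjectHits(ov)]) + 1L
    agg <- tapply(inter_w, S4Vectors::queryHits(ov), sum)
    cov[as.integer(names(agg))] <- as.numeric(agg)
  }
  cov / (bin_end - bin_start)
}
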