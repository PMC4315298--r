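# Readers and writers for the plain-text interchange formats used by the
# pipeline: FASTA, tab-delimited pairs, coordinate-list contact text,
# BED and bedGraph. All coordinates are 0-based half-open (BED
# convention); contact lists use 0-based bin indices.

#' Write a genome to FASTA
#' @param genome Named DNAStringSet or character vector.
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_dnastringset(genome), path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return A named DNAStringSet.
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write read pairs as tab-delimited text
#'
#' Columns: `chrom1, pos1, strand1, len1, chrom2, pos2, strand2, len2`
#' (0-based positions, strands `+`/`-`).
#' @param pairs Pair tibble.
#' @param path Output file.
#' @export
write_pairs_file <- function(pairs, path) {
  utils::write.table(
    pairs[, c("chrom1", "pos1", "strand1", "len1",
              "chrom2", "pos2", "strand2", "len2")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a tab-delimited pairs file
#' @param path Pairs file written by [write_pairs_file()].
#' @return Pair tibble.
#' @export
read_pairs_file <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              colClasses = c("character", "integer",
                                             "character", "integer",
                                             "character", "integer",
                                             "character", "integer")))
}

#' Write a contact matrix as a 3-column coordinate list
#'
#' Columns `bin1, bin2, value` with 0-based bins, upper triangle only,
#' zero cells omitted.
#' @param mat A `contact_matrix`.
#' @param path Output file.
#' @export
write_contacts <- function(mat, path) {
  tb <- as_tibble(mat, upper_only = TRUE, drop_zero = TRUE)
  utils::write.table(tb[, c("bin1", "bin2", "value")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a coordinate-list contact file into a contact matrix
#' @param path File written by [write_contacts()].
#' @param n_bins Matrix dimension.
#' @param chrom,bin_size,kind Matrix metadata.
#' @return A `contact_matrix`.
#' @export
read_contacts <- function(path, n_bins, chrom = "chr", bin_size = 2000,
                          kind = "raw") {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  m <- matrix(0, n_bins, n_bins)
  m[cbind(df$bin1 + 1L, df$bin2 + 1L)] <- df$value
  m[cbind(df$bin2 + 1L, df$bin1 + 1L)] <- df$value
  contact_matrix(m, chrom, bin_size, kind = kind)
}

#' Write a per-bin track as bedGraph
#' @param track Tibble with `chrom`, `bin` and a value column.
#' @param path Output file.
#' @param value Name of the value column.
#' @param bin_size Bin width in bp.
#' @export
write_bedgraph <- function(track, path, value, bin_size) {
  df <- track[!is.na(track[[value]]), , drop = FALSE]
  out <- data.frame(chrom = df$chrom,
                    start = df$bin * bin_size,
                    end = (df$bin + 1) * bin_size,
                    value = df[[value]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write region calls as BED
#'
#' BED5: chrom, start, end, name (type/subtype or polarity), score.
#' @param regions Region or strip tibble.
#' @param path Output file.
#' @param bin_size Bin width in bp.
#' @export
write_bed_regions <- function(regions, path, bin_size) {
  name <- if ("polarity" %in% names(regions)) {
    regions$polarity
  } else {
    paste0(regions$type, regions$subtype)
  }
  score <- if ("peak_index" %in% names(regions)) {
    abs(regions$peak_index)
  } else {
    0L
  }
  out <- data.frame(chrom = regions$chrom,
                    start = regions$start_bin * bin_size,
                    end = (regions$end_bin + 1) * bin_size,
                    name = name, score = score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#' @param path BED(3+) file; column 4, when present, is kept as `name`.
#' @return Tibble `chrom`, `start`, `end` and optionally `name`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  as_tibble(df[, seq_len(min(ncol(df), 4)), drop = FALSE])
}
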