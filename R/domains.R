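#' Directionality index
#'
#' For each bin, contrasts the summed (normalized) contacts with the
#' upstream versus the downstream bins inside a `window` (default 60 kb,
#' i.e. 30 bins at 2-kb resolution). With `A` the upstream sum, `B` the
#' downstream sum and `E = (A + B) / 2`,
#' `DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)`;
#' `DI = 0` when `A == B` or `E <= 0`. Positive DI marks bins whose
#' interactions are biased towards downstream regions. Masked neighbours
#' are skipped; masked focal bins are excluded (`NA`).
#'
#' @param norm A normalized `contact_matrix`.
#' @param window Window in bp; must be a multiple of the bin size.
#' @return Tibble with `chrom`, `bin` (0-based), `A`, `B`, `di`,
#'   `excluded`.
#' @export
directionality_index <- function(norm, window = 60000) {
  if (norm$kind != "normalized") {
    stop_param("`norm` must be a normalized contact matrix")
  }
  if (window %% norm$bin_size != 0) {
    stop_param("`window` must be a multiple of the bin size")
  }
  w <- window %/% norm$bin_size
  n <- nrow(norm$values)
  A <- numeric(n); B <- numeric(n)
  v <- norm$values
  ok <- norm$mask
  for (o in seq_len(w)) {
    iu <- which(seq_len(n) - o >= 1)
    iu <- iu[ok[iu - o]]
    A[iu] <- A[iu] + v[cbind(iu, iu - o)]
    id <- which(seq_len(n) + o <= n)
    id <- id[ok[id + o]]
    B[id] <- B[id] + v[cbind(id, id + o)]
  }
  E <- (A + B) / 2
  di <- ifelse(A == B | E <= 0, 0,
               sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E))
  di[!ok] <- NA_real_
  tibble(chrom = norm$chrom, bin = seq_len(n) - 1L,
         A = ifelse(ok, A, NA_real_), B = ifelse(ok, B, NA_real_),
         di = di, excluded = !ok)
}

#' Decode per-bin directionality states with a three-state HMM
#'
#' Fits a hidden Markov model with three hidden states and Gaussian
#' emissions to the directionality-index track and decodes the most likely
#' state path. The state with the most negative emission mean is labelled
#' `U` (upstream-biased), the most positive `D` (downstream-biased) and
#' the middle one `N` (no bias); the `N` state's emission mean is pinned
#' at 0 during EM since "no bias" corresponds to DI = 0 by definition.
#' Excluded bins split the chromosome into
#' independent segments; they are returned with state `"excluded"` and no
#' pattern may span them. A degenerate (constant) DI track yields all `N`.
#'
#' @param di DI tibble from [directionality_index()] (one chromosome, or
#'   several: segments never cross chromosomes).
#' @param seed Integer seed (EM initialization is deterministic; the seed
#'   is recorded for provenance).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return `di` with a `state` column (`"U"`, `"D"`, `"N"`,
#'   `"excluded"`) added; HMM parameters attached as attribute `"hmm"`.
#' @export
fit_hmm <- function(di, seed = 1L, max_iter = 500, tol = 1e-6) {
  stopifnot(all(c("chrom", "bin", "di") %in% names(di)))
  di <- di |> arrange(.data$chrom, .data$bin)
  defined <- !is.na(di$di)
  x <- di$di[defined]
  state <- rep("excluded", nrow(di))
  if (length(x) == 0) {
    di$state <- state
    return(di)
  }
  if (sd(x) < 1e-12) {
    state[defined] <- "N"
    di$state <- state
    return(di)
  }
  # split defined bins into segments: contiguous runs of defined bins
  # within one chromosome
  seg_id <- cumsum(!defined |
                     c(TRUE, di$chrom[-1] != di$chrom[-nrow(di)] |
                         diff(di$bin) != 1))
  seg_id <- seg_id[defined]
  segs <- split(x, seg_id)
  segs <- segs[vapply(segs, length, integer(1)) > 0]

  fit <- hmm_fit_gaussian(segs, n_states = 3, max_iter = max_iter,
                          tol = tol, anchor = 0, symmetric = TRUE)
  # label states by emission mean rank: U (most negative), N, D
  lab <- character(3)
  lab[order(fit$par$mu)] <- c("U", "N", "D")
  decoded <- lab[unlist(fit$paths)]
  state[defined] <- decoded
  di$state <- state
  attr(di, "hmm") <- c(fit["par"], fit["loglik"], fit["converged"],
                       list(seed = seed, labels = lab))
  di
}

# ---- pattern grammars ----------------------------------------------------

# Split a state track into per-segment strings; excluded bins break
# segments. Returns tibble: chrom, start_bin, states (string).
state_segments <- function(states) {
  states <- states |> arrange(.data$chrom, .data$bin)
  ok <- states$state %in% c("U", "D", "N")
  seg_id <- cumsum(!ok |
                     c(TRUE, states$chrom[-1] != states$chrom[-nrow(states)] |
                         diff(states$bin) != 1))
  df <- states[ok, , drop = FALSE]
  if (nrow(df) == 0) {
    return(tibble(chrom = character(0), start_bin = integer(0),
                  states = character(0)))
  }
  df$seg <- seg_id[ok]
  df |>
    group_by(.data$seg) |>
    summarise(chrom = .data$chrom[1], start_bin = .data$bin[1],
              states = paste(.data$state, collapse = ""), .groups = "drop") |>
    select(-"seg")
}

# all (overlapping) match starts of a perl regex, 1-based
regex_starts <- function(s, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), s, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

region_tbl <- function(chrom, start_bin, type, subtype, matched) {
  tibble(chrom = chrom, start_bin = as.integer(start_bin),
         end_bin = as.integer(start_bin + nchar(matched) - 1L),
         type = type, subtype = subtype, matched_states = matched)
}

#' Extract insulator-like regions from a decoded state track
#'
#' Insulator-like regions are junctions where an upstream-biased block
#' abuts a downstream-biased block, so that the flanking regions interact
#' away from each other. Three pattern grammars are matched (sliding
#' window, overlaps allowed) within each uninterrupted segment:
#' `XXUUDDXX` (type A, region = the central `UD`), `XXUUNDDXX` (type B,
#' region `UND`) and `XXUUNNDDXX` (type C, region `UNND`), where `X` is
#' any of U/D/N — so the core must lie at least two bins from a segment
#' edge. Identical spans are deduplicated.
#'
#' @param states State tibble from [fit_hmm()].
#' @return Region tibble: `chrom`, `start_bin`, `end_bin` (0-based,
#'   inclusive), `type = "insulator"`, `subtype` (`"A"`/`"B"`/`"C"`),
#'   `matched_states`.
#' @export
extract_insulators <- function(states) {
  segs <- state_segments(states)
  specs <- list(
    list(core = "UUDD", region_off = 1L, region_len = 2L, subtype = "A"),
    list(core = "UUNDD", region_off = 1L, region_len = 3L, subtype = "B"),
    list(core = "UUNNDD", region_off = 1L, region_len = 4L, subtype = "C")
  )
  out <- purrr::pmap_dfr(segs, function(chrom, start_bin, states) {
    len <- nchar(states)
    purrr::map_dfr(specs, function(sp) {
      starts <- regex_starts(states, sp$core)
      # two flanking states required on each side of the core
      starts <- starts[starts >= 3 & starts + nchar(sp$core) + 1 <= len]
      if (length(starts) == 0) return(NULL)
      r0 <- start_bin + starts - 1L + sp$region_off
      region_tbl(chrom, r0, "insulator", sp$subtype,
                 substr(rep(states, length(starts)),
                        starts + sp$region_off,
                        starts + sp$region_off + sp$region_len - 1L) |>
                   vapply(identity, character(1), USE.NAMES = FALSE))
    })
  })
  if (nrow(out) == 0) return(empty_regions())
  distinct(out)
}

#' Extract TAD-boundary-like regions
#'
#' Boundary-like regions mark the end of a run of upstream-biased bins or
#' the start of a run of downstream-biased bins. Two grammars are matched
#' per segment: `UUUUU(D/N)(D/N)X` with region `[last U, next bin]`
#' (subtype `"U(D/N)"`) and `X(U/N)(U/N)DDDDD` with region
#' `[bin before the D run, first D]` (subtype `"(U/N)D"`). Overlapping
#' matches are allowed; identical spans within a subtype are deduplicated.
#'
#' @param states State tibble from [fit_hmm()].
#' @return Region tibble as in [extract_insulators()] with
#'   `type = "boundary"`.
#' @export
extract_boundaries <- function(states) {
  run_edge_regions(states, type = "boundary",
                   spec1 = list(pattern = "U{5}[DN][DN].", off = 4L,
                                subtype = "U(D/N)"),
                   spec2 = list(pattern = ".[UN][UN]D{5}", off = 2L,
                                subtype = "(U/N)D"))
}

#' Extract TAD-interior-like regions
#'
#' Interior-like regions mark the start of a run of upstream-biased bins
#' or the end of a run of downstream-biased bins — the mirror image of
#' [extract_boundaries()]. Grammars: `X(D/N)(D/N)UUUUU` with region
#' `[bin before the U run, first U]` (subtype `"(D/N)U"`) and
#' `DDDDD(U/N)(U/N)X` with region `[last D, next bin]`
#' (subtype `"D(U/N)"`).
#'
#' @param states State tibble from [fit_hmm()].
#' @return Region tibble as in [extract_insulators()] with
#'   `type = "interior"`.
#' @export
extract_interiors <- function(states) {
  run_edge_regions(states, type = "interior",
                   spec1 = list(pattern = "D{5}[UN][UN].", off = 4L,
                                subtype = "D(U/N)"),
                   spec2 = list(pattern = ".[DN][DN]U{5}", off = 2L,
                                subtype = "(D/N)U"))
}

run_edge_regions <- function(states, type, spec1, spec2) {
  segs <- state_segments(states)
  out <- purrr::pmap_dfr(segs, function(chrom, start_bin, states) {
    purrr::map_dfr(list(spec1, spec2), function(sp) {
      starts <- regex_starts(states, sp$pattern)
      if (length(starts) == 0) return(NULL)
      r0 <- start_bin + starts - 1L + sp$off
      region_tbl(chrom, r0, type, sp$subtype,
                 substr(rep(states, length(starts)),
                        starts + sp$off, starts + sp$off + 1L) |>
                   vapply(identity, character(1), USE.NAMES = FALSE))
    })
  })
  if (nrow(out) == 0) return(empty_regions())
  distinct(out)
}

empty_regions <- function() {
  tibble(chrom = character(0), start_bin = integer(0),
         end_bin = integer(0), type = character(0),
         subtype = character(0), matched_states = character(0))
}
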