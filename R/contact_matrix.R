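#' Construct a contact matrix object
#'
#' A `contact_matrix` wraps a symmetric per-chromosome matrix of contact
#' values at a fixed bin size, a per-bin validity mask, and a `kind` flag
#' (`"raw"` counts or `"normalized"` residuals). Bins are 0-based; the
#' matrix cell `(i, j)` holds contacts between bins `i` and `j`.
#'
#' @param values Symmetric numeric matrix.
#' @param chrom Chromosome identifier.
#' @param bin_size Bin width in bp.
#' @param mask Logical vector, `TRUE` where a bin is valid for analysis.
#' @param kind `"raw"` or `"normalized"`.
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(values, chrom, bin_size,
                           mask = rep(TRUE, nrow(values)),
                           kind = c("raw", "normalized")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values), length(mask) == nrow(values))
  if (any(!mask)) {
    values[!mask, ] <- 0
    values[, !mask] <- 0
  }
  structure(
    list(values = values, chrom = chrom, bin_size = as.integer(bin_size),
         mask = as.logical(mask), kind = kind),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins of %d bp (%s), %d masked\n",
              x$chrom, nrow(x$values), x$bin_size, x$kind, sum(!x$mask)))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$values)

#' Tidy a contact matrix into a long tibble
#'
#' @param x A `contact_matrix`.
#' @param upper_only Keep only cells with `bin1 <= bin2`.
#' @param drop_zero Drop zero cells (coordinate-list convention).
#' @param ... Unused.
#' @return Tibble with `chrom`, `bin1`, `bin2` (0-based) and `value`.
#' @importFrom tibble as_tibble
#' @method as_tibble contact_matrix
#' @export
as_tibble.contact_matrix <- function(x, upper_only = TRUE,
                                     drop_zero = TRUE, ...) {
  n <- nrow(x$values)
  idx <- which(if (upper_only) upper.tri(x$values, diag = TRUE)
               else matrix(TRUE, n, n), arr.ind = TRUE)
  out <- tibble(chrom = x$chrom,
                bin1 = idx[, 1] - 1L, bin2 = idx[, 2] - 1L,
                value = x$values[idx])
  if (drop_zero) out <- out[out$value != 0, , drop = FALSE]
  out
}

#' Bin valid contacts into per-chromosome contact matrices
#'
#' @param contacts Tibble of valid pairs (`chrom1, pos1, chrom2, pos2`).
#' @param bin_size Bin width in bp.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @return A list with `matrices` (named list of raw `contact_matrix`
#'   objects, one per chromosome) and `inter` (tibble of interchromosomal
#'   bin-pair counts, reported raw).
#' @export
bin_contacts <- function(contacts, bin_size, chrom_lengths) {
  if (bin_size <= 0) stop_param("`bin_size` must be positive")
  bad <- contacts$pos1 >= chrom_lengths[contacts$chrom1] |
    contacts$pos2 >= chrom_lengths[contacts$chrom2]
  if (any(bad, na.rm = TRUE)) {
    stop_param("contact position beyond chromosome length")
  }
  intra <- contacts$chrom1 == contacts$chrom2
  mats <- lapply(names(chrom_lengths), function(chrom) {
    n <- ceiling(chrom_lengths[[chrom]] / bin_size)
    m <- matrix(0, n, n)
    sel <- which(intra & contacts$chrom1 == chrom)
    if (length(sel) > 0) {
      b1 <- contacts$pos1[sel] %/% bin_size + 1L
      b2 <- contacts$pos2[sel] %/% bin_size + 1L
      for (k in seq_along(sel)) {
        m[b1[k], b2[k]] <- m[b1[k], b2[k]] + 1
        if (b1[k] != b2[k]) m[b2[k], b1[k]] <- m[b2[k], b1[k]] + 1
      }
    }
    contact_matrix(m, chrom, bin_size, kind = "raw")
  })
  names(mats) <- names(chrom_lengths)

  inter_tbl <- if (any(!intra)) {
    tibble(chrom1 = contacts$chrom1[!intra],
           bin1 = contacts$pos1[!intra] %/% bin_size,
           chrom2 = contacts$chrom2[!intra],
           bin2 = contacts$pos2[!intra] %/% bin_size) |>
      count(.data$chrom1, .data$bin1, .data$chrom2, .data$bin2, name = "count")
  } else {
    tibble(chrom1 = character(0), bin1 = integer(0),
           chrom2 = character(0), bin2 = integer(0), count = integer(0))
  }
  list(matrices = mats, inter = inter_tbl)
}

#' Two-level per-bin exclusion mask
#'
#' Bins are excluded from the normalization regression when their
#' mappability falls below `map_min` or their effective fragment length
#' below `efflen_min`. Centromeric bins keep their covariates (they are
#' included in normalization) but are excluded from downstream pattern
#' analysis.
#'
#' @param features Per-bin covariates from [bin_features()].
#' @param centromeres Optional centromeric bins from [centromere_mask()].
#' @param map_min Mappability threshold (default 0.5).
#' @param efflen_min Effective-fragment-length threshold (default 0.1).
#' @return `features` with logical columns `norm_excluded` and
#'   `analysis_excluded` added.
#' @export
exclusion_mask <- function(features, centromeres = NULL,
                           map_min = 0.5, efflen_min = 0.1) {
  stopifnot(map_min >= 0, map_min <= 1, efflen_min >= 0, efflen_min <= 1)
  out <- features |>
    mutate(norm_excluded = .data$mappability < map_min |
             .data$eff_len < efflen_min)
  cen <- if (!is.null(centromeres) && nrow(centromeres) > 0) {
    paste(centromeres$chrom, centromeres$bin) } else character(0)
  out |>
    mutate(analysis_excluded = .data$norm_excluded |
             paste(.data$chrom, .data$bin) %in% cen)
}

#' Poisson-regression bias normalization of a raw contact matrix
#'
#' Fits, per chromosome, the log-linear Poisson model
#' `log lambda_ij = b0 + b_len log(L_i L_j) + b_gc log(G_i G_j) +
#' b_end log(F_i F_j) + log(M_i M_j)` over all unmasked off-diagonal bin
#' pairs, where `L`, `G`, `F` are the effective-fragment-length, end-GC
#' and fragment-end-count covariates and the mappability product `M_i M_j`
#' enters as a fixed offset. The residuals of this regression form the
#' normalized matrix; the default is the Pearson residual
#' `(u - lambda) / sqrt(lambda)` (variance-stabilized), with
#' `residual = "raw"` giving `u - lambda`.
#'
#' Bins flagged `norm_excluded`, and bins with a non-positive covariate
#' (log undefined; auto-masked with a warning), take value 0 in the output
#' and are marked invalid. Centromeric (`analysis_excluded`) bins
#' participate in the fit but are flagged invalid in the output mask.
#'
#' @param raw A raw `contact_matrix` for one chromosome.
#' @param features Covariates for that chromosome, with exclusion flags
#'   from [exclusion_mask()] (computed with defaults when absent).
#' @param residual `"pearson"` (default) or `"raw"`.
#' @param max_iter Maximum IRLS iterations.
#' @return A list with `matrix` (normalized `contact_matrix`) and `fit`
#'   (a `hicnorm_fit` with coefficients and deviance; see [tidy()]).
#' @export
normalize_contacts <- function(raw, features, residual = c("pearson", "raw"),
                               max_iter = 100) {
  residual <- match.arg(residual)
  if (raw$kind != "raw") stop_param("`raw` must be a raw contact matrix")
  feats <- features |> filter(.data$chrom == raw$chrom) |> arrange(.data$bin)
  n <- nrow(raw$values)
  if (nrow(feats) != n) {
    stop_param("features cover ", nrow(feats), " bins but matrix has ", n)
  }
  if (!"norm_excluded" %in% names(feats)) {
    feats <- exclusion_mask(feats)
  }

  zero_cov <- !feats$norm_excluded &
    (feats$eff_len <= 0 | feats$gc_ends <= 0 | feats$end_count <= 0 |
       feats$mappability <= 0)
  if (any(zero_cov)) {
    warning(sum(zero_cov),
            " bin(s) auto-masked: non-positive covariate", call. = FALSE)
  }
  norm_ok <- !feats$norm_excluded & !zero_cov
  if (sum(norm_ok) < 10) stop_param("fewer than 10 unmasked bins")

  idx <- which(norm_ok)
  pr <- t(utils::combn(idx, 2))           # off-diagonal pairs, i < j
  u <- raw$values[pr]
  df <- data.frame(
    u = u,
    x_len = log(feats$eff_len[pr[, 1]] * feats$eff_len[pr[, 2]]),
    x_gc = log(feats$gc_ends[pr[, 1]] * feats$gc_ends[pr[, 2]]),
    x_end = log(feats$end_count[pr[, 1]] * feats$end_count[pr[, 2]]),
    x_map = log(feats$mappability[pr[, 1]] * feats$mappability[pr[, 2]])
  )
  fit <- glm(u ~ x_len + x_gc + x_end + offset(x_map),
             family = poisson(), data = df,
             control = list(maxit = max_iter))
  if (!fit$converged) {
    warning("Poisson regression did not converge; using last iterate",
            call. = FALSE)
  }
  lambda <- fit$fitted.values
  res <- if (residual == "pearson") (u - lambda) / sqrt(lambda) else u - lambda

  vals <- matrix(0, n, n)
  vals[pr] <- res
  vals[pr[, c(2, 1), drop = FALSE]] <- res

  analysis_ok <- norm_ok &
    !(if ("analysis_excluded" %in% names(feats)) feats$analysis_excluded
      else feats$norm_excluded)
  out <- contact_matrix(vals, raw$chrom, raw$bin_size,
                        mask = analysis_ok, kind = "normalized")

  fit_obj <- structure(
    list(coefficients = coef(fit),
         offset_used = TRUE,
         deviance = fit$deviance,
         null_deviance = fit$null.deviance,
         n_pairs_fit = nrow(df),
         converged = fit$converged,
         residual = residual,
         chrom = raw$chrom),
    class = "hicnorm_fit"
  )
  list(matrix = out, fit = fit_obj)
}

#' @export
print.hicnorm_fit <- function(x, ...) {
  cat(sprintf("<hicnorm_fit> %s: %d pairs, deviance %.1f\n",
              x$chrom, x$n_pairs_fit, x$deviance))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Tidy the coefficients of a Hi-C bias fit
#'
#' @param x A `hicnorm_fit` from [normalize_contacts()].
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @method tidy hicnorm_fit
#' @export
tidy.hicnorm_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' One-row fit summary of a Hi-C bias fit
#'
#' @param x A `hicnorm_fit`.
#' @param ... Unused.
#' @return One-row tibble with deviance and fit size.
#' @method glance hicnorm_fit
#' @export
glance.hicnorm_fit <- function(x, ...) {
  tibble(deviance = x$deviance, null_deviance = x$null_deviance,
         n_pairs_fit = x$n_pairs_fit, converged = x$converged)
}

#' Local contact strength
#'
#' The contact strength of a bin is the sum of its (normalized) contacts
#' with the `window_bins` nearest bins on each side — with the default 5
#' at 2-kb resolution, all contacts within 10 kb. Out-of-range or masked
#' neighbours are skipped; masked focal bins are `NA` and flagged.
#'
#' @param norm A normalized `contact_matrix`.
#' @param window_bins Number of neighbours per side (default 5).
#' @return Tibble with `chrom`, `bin` (0-based), `strength`, `defined`.
#' @export
contact_strength <- function(norm, window_bins = 5) {
  if (norm$kind != "normalized") {
    stop_param("`norm` must be a normalized contact matrix")
  }
  if (window_bins < 1) stop_param("`window_bins` must be >= 1")
  n <- nrow(norm$values)
  strength <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!norm$mask[i]) next
    nb <- c(i - seq_len(window_bins), i + seq_len(window_bins))
    nb <- nb[nb >= 1 & nb <= n]
    nb <- nb[norm$mask[nb]]
    strength[i] <- sum(norm$values[i, nb])
  }
  tibble(chrom = norm$chrom, bin = seq_len(n) - 1L,
         strength = strength, defined = !is.na(strength))
}
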