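#' Per-site SNP/InDel-index statistics
#'
#' The SNP-index of a bulk at a parental-informative site is the fraction of
#' the bulk's reads carrying the reference parent's allele (default: the
#' yellow parent P2; the green-parent index is its complement, and the delta
#' statistic is invariant under the choice). `delta_index` is the absolute
#' difference of the two bulk indices. A site is masked in a bulk when its
#' total depth there is below `min_depth`; masked sites carry `NA` indices
#' rather than propagating NaN.
#'
#' @param x A filtered [variant_table()] (from
#'   [filter_parental_informative()], so each site carries its
#'   `yellow_is_ref` annotation).
#' @param min_depth Minimum per-bulk total depth for an unmasked index.
#' @param orientation Which parent's allele the index counts: `"yellow"`
#'   (P2, default) or `"green"` (P1).
#' @return A tibble with columns `chrom`, `pos`, `index_D1`, `index_D2`,
#'   `delta`, `masked`.
#' @export
site_indices <- function(x, min_depth = 10, orientation = c("yellow", "green")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(x, "variant_table"))
  if (!"yellow_is_ref" %in% names(x)) {
    stop("table must first pass filter_parental_informative()", call. = FALSE)
  }
  idx <- function(nref, nalt) {
    tot <- nref + nalt
    ref_frac <- ifelse(tot >= pmax(min_depth, 1), nref / tot, NA_real_)
    yellow <- ifelse(x$yellow_is_ref, ref_frac, 1 - ref_frac)
    if (orientation == "yellow") yellow else 1 - yellow
  }
  index_d1 <- idx(x$D1_ref, x$D1_alt)
  index_d2 <- idx(x$D2_ref, x$D2_alt)
  tibble(
    chrom = x$chrom, pos = x$pos,
    index_D1 = index_d1, index_D2 = index_d2,
    delta = delta_index(index_d1, index_d2),
    masked = is.na(index_d1) | is.na(index_d2)
  )
}

#' @rdname site_indices
#' @param index_D1,index_D2 Bulk SNP-indices in [0, 1]; `NA` marks a masked
#'   site and yields a masked (NA) delta.
#' @export
delta_index <- function(index_D1, index_D2) {
  abs(index_D1 - index_D2)
}

#' Euclidean-distance statistic between the bulks
#'
#' At each site the two bulks' reads are converted to nucleotide frequency
#' vectors over (A, C, G, T) — for indel sites, over the two abstract
#' ref/alt alleles — and the statistic is the Euclidean distance between the
#' D1 and D2 vectors; it is squared (ED^2) to sharpen strong signals. For a
#' biallelic site this equals sqrt(2) * |p_D1 - p_D2| where p is the
#' ref-allele read fraction. Sites with zero depth in either bulk are masked.
#'
#' @param x A [variant_table()] (filtering is not required for the distance
#'   itself, but the scan applies it to the filtered table).
#' @param min_depth Minimum per-bulk total depth for an unmasked value.
#' @return A tibble with columns `chrom`, `pos`, `ed`, `ed2`, `masked`.
#' @export
site_ed <- function(x, min_depth = 1) {
  stopifnot(inherits(x, "variant_table"))
  tot1 <- x$D1_ref + x$D1_alt
  tot2 <- x$D2_ref + x$D2_alt
  ok <- tot1 >= pmax(min_depth, 1) & tot2 >= pmax(min_depth, 1)
  p1 <- ifelse(ok, x$D1_ref / tot1, NA_real_)
  p2 <- ifelse(ok, x$D2_ref / tot2, NA_real_)
  # only the ref and alt components of the 4-nucleotide vectors are nonzero
  ed <- sqrt((p1 - p2)^2 + ((1 - p1) - (1 - p2))^2)
  tibble(chrom = x$chrom, pos = x$pos, ed = ed, ed2 = ed^2, masked = !ok)
}

#' Sliding-window aggregation of a per-site track
#'
#' Windows are anchored at position 1 of each chromosome and advance by
#' `step_bp`; each spans `window_bp` (half-open bp interval `[start, end)`),
#' with the last window truncated at the chromosome end. The window value is
#' the arithmetic mean of its unmasked member sites. Windows with fewer than
#' `min_markers` contributing sites are flagged ineligible and excluded from
#' thresholding.
#'
#' @param sites Tibble with columns `chrom`, `pos`, `value` (and optionally
#'   `masked`); sorted by position within chromosome.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param window_bp Window size in bp (default 3 Mb).
#' @param step_bp Step in bp (default 300 kb).
#' @param min_markers Minimum unmasked sites per eligible window.
#' @return A tibble with `chrom`, `start`, `end`, `mid`, `n_markers`,
#'   `value`, `eligible`.
#' @export
sliding_windows <- function(sites, chrom_lengths, window_bp = 3e6,
                            step_bp = 3e5, min_markers = 10) {
  stopifnot(window_bp > 0, step_bp > 0)
  if (!"masked" %in% names(sites)) sites$masked <- FALSE
  out <- lapply(names(chrom_lengths), function(chr) {
    len <- chrom_lengths[[chr]]
    s <- sites[sites$chrom == chr & !sites$masked & !is.na(sites$value), ]
    starts <- seq(1, len, by = step_bp)
    ends <- pmin(starts + window_bp, len + 1) # half-open [start, end)
    n <- integer(length(starts))
    v <- rep(NA_real_, length(starts))
    if (nrow(s) > 0) {
      pos <- s$pos
      val <- s$value
      csum <- c(0, cumsum(val))
      ord_lo <- findInterval(starts - 0.5, pos) # sites with pos < start
      ord_hi <- findInterval(ends - 0.5, pos) # sites with pos < end
      n <- ord_hi - ord_lo
      v <- ifelse(n > 0, (csum[ord_hi + 1] - csum[ord_lo + 1]) / n, NA_real_)
    }
    tibble(
      chrom = chr, start = starts, end = ends,
      mid = floor((starts + ends) / 2),
      n_markers = as.integer(n), value = v,
      eligible = n >= min_markers
    )
  })
  dplyr::bind_rows(out)
}

#' LOESS smoothing of a genome track
#'
#' Fits a local regression (tricube weights, `degree` 1 by default, one
#' robustness iteration) per chromosome against bp position and returns the
#' fitted values aligned with the input. Chromosomes with fewer than
#' `max(5, degree + 2)` points are passed through unchanged with a warning.
#' `NA` values are ignored in fitting and remain `NA` in the output.
#'
#' @param track Tibble with columns `chrom`, a position column, and `value`.
#' @param span LOESS span (fraction of points per local fit).
#' @param degree Local polynomial degree (0, 1 or 2).
#' @param pos_col Name of the position column (`"mid"` for window tracks,
#'   `"pos"` for site tracks).
#' @return `track` with an added `smoothed` column.
#' @export
loess_smooth <- function(track, span = 0.1, degree = 1, pos_col = "mid") {
  stopifnot(pos_col %in% names(track))
  track$smoothed <- NA_real_
  for (chr in unique(track$chrom)) {
    sel <- which(track$chrom == chr & !is.na(track$value))
    if (length(sel) == 0) next
    if (length(sel) < max(5, degree + 2)) {
      warning(
        "chromosome ", chr, ": too few points for LOESS; passing through",
        call. = FALSE
      )
      track$smoothed[sel] <- track$value[sel]
      next
    }
    d <- data.frame(x = track[[pos_col]][sel], y = track$value[sel])
    fit <- stats::loess(y ~ x,
      data = d, span = span, degree = degree,
      family = "symmetric",
      control = stats::loess.control(iterations = 2, surface = "direct")
    )
    track$smoothed[sel] <- stats::predict(fit, newdata = d)
  }
  track
}

#' Candidate-interval calling from a window track
#'
#' The significance threshold is the genome-wide `quantile` of eligible
#' window values (ties at the threshold are significant). Overlapping or
#' adjacent significant windows are merged into maximal candidate intervals
#' whose bounds are the min start / max end of the merged windows and whose
#' peak value is the maximum member value.
#'
#' @param windows A window tibble (see [sliding_windows()]); the column used
#'   as the window value is `smoothed` if present, else `value`.
#' @param quantile Genome-wide quantile defining the threshold (default 0.99,
#'   the top 1% of window values).
#' @param threshold Optional explicit threshold overriding the quantile.
#' @param per_chromosome Compute the quantile threshold within each
#'   chromosome instead of genome-wide. The genome-wide default matches a
#'   full multi-chromosome genome, where chromosomes without a trait locus
#'   supply the bulk of the null windows; on a reduced genome in which every
#'   simulated chromosome carries a causal locus, the per-chromosome mode
#'   restores that behavior.
#' @return A tibble of intervals (`chrom`, `start`, `end`, `peak_value`,
#'   `n_windows`) with the threshold(s) as attribute `"threshold"`; empty
#'   when no window is significant.
#' @export
call_intervals <- function(windows, quantile = 0.99, threshold = NULL,
                           per_chromosome = FALSE) {
  value <- if ("smoothed" %in% names(windows)) windows$smoothed else windows$value
  elig <- windows$eligible & !is.na(value)
  empty <- tibble(
    chrom = character(), start = numeric(), end = numeric(),
    peak_value = numeric(), n_windows = integer()
  )
  if (sum(elig) == 0) {
    attr(empty, "threshold") <- NA_real_
    return(empty)
  }
  if (sum(elig) < 100) {
    warning("fewer than 100 eligible windows; quantile threshold is unstable",
      call. = FALSE
    )
  }
  if (is.null(threshold)) {
    if (per_chromosome) {
      threshold <- vapply(
        split(value[elig], windows$chrom[elig]),
        stats::quantile, 0, probs = quantile, names = FALSE
      )
    } else {
      threshold <- stats::quantile(value[elig], quantile, names = FALSE)
    }
  }
  thr_of <- if (length(threshold) > 1 || !is.null(names(threshold))) {
    unname(threshold[match(windows$chrom, names(threshold))])
  } else {
    rep(threshold, nrow(windows))
  }
  sig <- elig & !is.na(thr_of) & value >= thr_of
  if (!any(sig)) {
    attr(empty, "threshold") <- threshold
    return(empty)
  }
  w <- windows[sig, ]
  w$value_used <- value[sig]
  w <- w[order(w$chrom, w$start), ]
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(w))) {
    row <- w[i, ]
    if (!is.null(cur) && row$chrom == cur$chrom && row$start <= cur$end) {
      cur$end <- max(cur$end, row$end)
      cur$peak_value <- max(cur$peak_value, row$value_used)
      cur$n_windows <- cur$n_windows + 1L
    } else {
      if (!is.null(cur)) out[[length(out) + 1]] <- cur
      cur <- tibble(
        chrom = row$chrom, start = row$start, end = row$end,
        peak_value = row$value_used, n_windows = 1L
      )
    }
  }
  out[[length(out) + 1]] <- cur
  res <- dplyr::bind_rows(out)
  attr(res, "threshold") <- threshold
  res
}

interval_jaccard <- function(a, b) {
  if (nrow(a) == 0 && nrow(b) == 0) return(NA_real_)
  cover <- function(x, chr) {
    x <- x[x$chrom == chr, ]
    if (nrow(x) == 0) return(matrix(numeric(0), ncol = 2))
    cbind(x$start, x$end)
  }
  inter <- 0
  uni <- 0
  for (chr in union(a$chrom, b$chrom)) {
    ca <- cover(a, chr)
    cb <- cover(b, chr)
    la <- sum(ca[, 2] - ca[, 1])
    lb <- sum(cb[, 2] - cb[, 1])
    ov <- 0
    if (nrow(ca) > 0 && nrow(cb) > 0) {
      for (i in seq_len(nrow(ca))) {
        ov <- ov + sum(pmax(0, pmin(ca[i, 2], cb[, 2]) - pmax(ca[i, 1], cb[, 1])))
      }
    }
    inter <- inter + ov
    uni <- uni + la + lb - ov
  }
  if (uni == 0) NA_real_ else inter / uni
}

#' Run the full BSA genome scan
#'
#' Filters the table to parental-informative sites (unless already filtered),
#' computes per-site SNP-index/delta and ED/ED^2 tracks, aggregates both into
#' sliding windows, smooths the window means with LOESS, and calls candidate
#' intervals for each statistic at the genome-wide quantile threshold. The
#' Jaccard overlap (shared bp fraction) between the two statistics' interval
#' sets is reported as a concordance measure. Deterministic given the table
#' and configuration.
#'
#' @param table A [variant_table()].
#' @param window_bp,step_bp Window geometry in bp (defaults 3 Mb / 300 kb).
#' @param quantile Threshold quantile for [call_intervals()].
#' @param min_depth Per-bulk depth below which a site is masked.
#' @param min_markers Minimum sites per eligible window.
#' @param span,degree LOESS parameters for window-track smoothing.
#' @param smooth Smooth window means before thresholding (default TRUE).
#' @param orientation Reference parent for the SNP-index (see
#'   [site_indices()]).
#' @param per_chromosome Threshold per chromosome instead of genome-wide
#'   (see [call_intervals()]).
#' @param min_parent_depth,max_minor_fraction Passed to
#'   [filter_parental_informative()] when the table is unfiltered.
#' @return An object of class `bsa_scan`: list with `sites` (per-site
#'   indices and ED), `windows_delta`, `windows_ed2`, `intervals` (both
#'   statistics, column `statistic` in `{"delta_index", "ed2"}`),
#'   `thresholds`, and `jaccard`.
#' @export
run_scan <- function(table, window_bp = 3e6, step_bp = 3e5, quantile = 0.99,
                     min_depth = 10, min_markers = 10, span = 0.1, degree = 1,
                     smooth = TRUE, orientation = "yellow",
                     per_chromosome = FALSE,
                     min_parent_depth = 10, max_minor_fraction = 0.05) {
  stopifnot(inherits(table, "variant_table"))
  if (!"yellow_is_ref" %in% names(table)) {
    table <- filter_parental_informative(table, min_parent_depth, max_minor_fraction)
  }
  if (nrow(table) == 0) {
    stop("no parental-informative sites; nothing to scan", call. = FALSE)
  }
  cl <- chrom_lengths(table)
  idx <- site_indices(table, min_depth = min_depth, orientation = orientation)
  ed <- site_ed(table, min_depth = min_depth)
  sites <- dplyr::bind_cols(
    idx,
    ed[, c("ed", "ed2")]
  )
  win_of <- function(value_col, src) {
    s <- tibble(
      chrom = src$chrom, pos = src$pos, value = src[[value_col]],
      masked = is.na(src[[value_col]])
    )
    w <- sliding_windows(s, cl,
      window_bp = window_bp, step_bp = step_bp,
      min_markers = min_markers
    )
    if (smooth) w <- loess_smooth(w, span = span, degree = degree) else w$smoothed <- w$value
    w
  }
  windows_delta <- win_of("delta", sites)
  windows_ed2 <- win_of("ed2", sites)
  iv_delta <- call_intervals(windows_delta,
    quantile = quantile,
    per_chromosome = per_chromosome
  )
  iv_ed2 <- call_intervals(windows_ed2,
    quantile = quantile,
    per_chromosome = per_chromosome
  )
  intervals <- dplyr::bind_rows(
    if (nrow(iv_delta) > 0) dplyr::mutate(iv_delta, statistic = "delta_index"),
    if (nrow(iv_ed2) > 0) dplyr::mutate(iv_ed2, statistic = "ed2")
  )
  if (is.null(intervals) || nrow(intervals) == 0) {
    intervals <- tibble(
      chrom = character(), start = numeric(), end = numeric(),
      peak_value = numeric(), n_windows = integer(), statistic = character()
    )
  }
  structure(
    list(
      sites = sites,
      windows_delta = windows_delta,
      windows_ed2 = windows_ed2,
      intervals = intervals,
      thresholds = list(
        delta_index = attr(iv_delta, "threshold"),
        ed2 = attr(iv_ed2, "threshold")
      ),
      jaccard = interval_jaccard(iv_delta, iv_ed2),
      config = list(
        window_bp = window_bp, step_bp = step_bp, quantile = quantile,
        min_depth = min_depth, min_markers = min_markers, span = span,
        degree = degree, smooth = smooth, orientation = orientation
      )
    ),
    class = "bsa_scan"
  )
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat("<bsa_scan> ", nrow(x$sites), " sites; thresholds: delta ",
    paste(signif(x$thresholds[["delta_index"]], 4), collapse = "/"),
    ", ed2 ", paste(signif(x$thresholds[["ed2"]], 4), collapse = "/"), "\n",
    sep = ""
  )
  print(as.data.frame(x$intervals))
  cat("interval concordance (Jaccard):", round(x$jaccard, 3), "\n")
  invisible(x)
}

#' Write called intervals as BED
#'
#' Standard BED: 0-based half-open coordinates, `name` = statistic, `score` =
#' peak value.
#'
#' @param intervals Interval tibble from [run_scan()] or [call_intervals()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(intervals, path) {
  name <- if ("statistic" %in% names(intervals)) intervals$statistic else rep("interval", nrow(intervals))
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%s",
    intervals$chrom,
    as.integer(intervals$start - 1), # 1-based [start,end) -> 0-based half-open
    as.integer(intervals$end - 1),
    name,
    formatC(intervals$peak_value, format = "g")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0) writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
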