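# Downstream applications: BSA window scans, variety comparison,
# introgression localisation, transgene dilution-series detection.

#' Convert allele dosages to diploid call codes
#'
#' @param dosage matrix or vector of ALT dosages (0/1/2; `NA` becomes NC).
#' @return character codes `AA`/`AB`/`BB`/`NC` with the same shape.
#' @export
dosage_to_calls <- function(dosage) {
  out <- ifelse(is.na(dosage), "NC", DIPLOID_CODES[dosage + 1L])
  if (is.matrix(dosage))
    out <- matrix(out, nrow(dosage), dimnames = dimnames(dosage))
  out
}

#' Majority-consensus call of a bulk
#'
#' Bulked DNA genotyped as one sample is represented by the modal non-NC
#' call of the bulk members per marker; ties or all-NC markers give NC.
#'
#' @param calls call matrix (markers x bulk members).
#' @return named character vector of consensus calls per marker.
#' @export
bulk_consensus <- function(calls) {
  apply(calls, 1L, function(v) {
    v <- v[v != "NC"]
    if (!length(v)) return("NC")
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) return("NC")
    names(tab)[1L]
  })
}

#' Differential-marker window scan
#'
#' Tiles the genome into 0-based half-open windows (default 1 Mb), counts
#' per window the markers whose calls differ between the two call sets
#' (cells that are NC in either set are excluded), and reports the peak
#' window (ties broken by the leftmost window in genome order). This is
#' the bulked-segregant / introgression scan statistic: differential probe
#' counts per 1-Mb window.
#'
#' @param markers data frame with `marker_id`, `chrom`, `pos` (1-based).
#' @param calls_a,calls_b call vectors named by (or aligned to) marker ids.
#' @param genome a [genome_index()] or named chromosome-length vector.
#' @param window_bp window size in bp (default 1e6).
#' @return a `window_scan` object: per-window counts, the differing-marker
#'   table, and the peak window.
#' @export
differential_scan <- function(markers, calls_a, calls_b, genome,
                              window_bp = 1e6) {
  check_columns(markers, c("marker_id", "chrom", "pos"), "differential_scan")
  stopifnot(length(calls_a) == nrow(markers),
            length(calls_b) == nrow(markers))
  lens <- if (inherits(genome, "genome_index")) genome$lengths else genome
  windows <- partition_bins(lens, window_bp)
  diff_i <- which(calls_a != "NC" & calls_b != "NC" & calls_a != calls_b)
  diffs <- markers[diff_i, , drop = FALSE]
  wid <- bin_of(windows$chrom, windows$start + 1, window_bp)
  counts <- integer(nrow(windows))
  if (nrow(diffs)) {
    tab <- table(bin_of(diffs$chrom, diffs$pos, window_bp))
    counts[match(names(tab), wid)] <- as.integer(tab)
  }
  windows$count <- counts
  peak <- windows[which.max(windows$count), , drop = FALSE]  # leftmost tie
  structure(list(windows = windows, diffs = diffs, peak = peak,
                 window_bp = window_bp, n_diff = nrow(diffs)),
            class = "window_scan")
}

#' @export
print.window_scan <- function(x, ...) {
  cat("Window scan:", x$n_diff, "differing marker(s) over",
      nrow(x$windows), "windows of", format(x$window_bp, big.mark = ","),
      "bp\n  peak:", x$peak$bin_id, "with", x$peak$count, "difference(s)\n")
  invisible(x)
}

#' Variety comparison over genome bins
#'
#' Counts markers with different non-NC calls between two varieties, the
#' fraction over markers called in both, and the number of genome bins
#' containing at least one difference.
#'
#' @param markers data frame with `marker_id`, `chrom`, `pos`.
#' @param calls_a,calls_b call vectors aligned to `markers`.
#' @param bin_size bin width in bp (default 100 kb).
#' @return list with `n_polymorphic`, `n_compared`, `fraction`,
#'   `n_bins_hit`.
#' @export
variety_compare <- function(markers, calls_a, calls_b, bin_size = 1e5) {
  check_columns(markers, c("marker_id", "chrom", "pos"), "variety_compare")
  both <- calls_a != "NC" & calls_b != "NC"
  diff_ <- both & calls_a != calls_b
  bins_hit <- unique(bin_of(markers$chrom[diff_], markers$pos[diff_],
                            bin_size))
  list(n_polymorphic = sum(diff_), n_compared = sum(both),
       fraction = if (sum(both)) sum(diff_) / sum(both) else NA_real_,
       n_bins_hit = length(bins_hit))
}

#' Mixture fraction of a d:1 dilution
#'
#' For a negative:positive ratio `d:1` the reported genetic-modification
#' percentage is `100/d` — positive relative to negative, the convention
#' under which 30:1 prints as 3.3%.
#'
#' @param d positive ratio denominators (`d > 0`).
#' @return percentages.
#' @export
gmo_mixture_fraction <- function(d) {
  if (any(d <= 0)) stop("gmo_mixture_fraction: d must be > 0")
  100 / d
}

#' Dilution-series detection verdicts
#'
#' A ratio is called positive iff the one-sided Mann-Whitney test of its
#' replicate signals against the negative controls rejects at `alpha` AND
#' the median test signal exceeds the negative controls' `q` quantile
#' (default 99th percentile). Fewer than 8 negative controls is an error.
#'
#' @param series a `mixture_series` from [simulate_gmo_dilution()] (or any
#'   list with `ratios`, `signals`, `negative`).
#' @param alpha test level (default 0.01).
#' @param q negative-control quantile guard (default 0.99).
#' @return data frame with one row per ratio: `ratio`, `percent`,
#'   `p_value`, `median_signal`, `neg_quantile`, `positive`.
#' @export
gmo_detect <- function(series, alpha = 0.01, q = 0.99) {
  if (length(series$negative) < 8L)
    stop("gmo_detect: at least 8 negative-control replicates required")
  thr <- stats::quantile(series$negative, q, names = FALSE)
  out <- lapply(seq_along(series$ratios), function(i) {
    x <- series$signals[[i]]
    p <- stats::wilcox.test(x, series$negative, alternative = "greater",
                            exact = FALSE)$p.value
    data.frame(ratio = series$ratios[i],
               percent = gmo_mixture_fraction(series$ratios[i]),
               p_value = p, median_signal = stats::median(x),
               neg_quantile = thr,
               positive = p < alpha && stats::median(x) > thr)
  })
  do.call(rbind, out)
}

#' Introgression localisation report
#'
#' Summarises a differential scan relative to a target interval: which scan
#' windows overlap the target, what fraction of all differing markers fall
#' inside the target extended by `flank` bp, and the interval spanned by
#' the `k` differing markers nearest the target midpoint.
#'
#' @param scan a `window_scan` from [differential_scan()].
#' @param target list or one-row data frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param flank bp added on each side for the fraction (default 0).
#' @param k number of nearest differing probes to span (default 4).
#' @return list with `windows_overlapping`, `fraction_inside`,
#'   `nearest_span` (chrom, start, end, n).
#' @export
introgression_report <- function(scan, target, flank = 0, k = 4L) {
  chroms <- unique(scan$windows$chrom)
  if (!target$chrom %in% chroms)
    stop("introgression_report: target chromosome not in scan")
  w <- scan$windows
  ov <- w[w$chrom == target$chrom & w$start < target$end &
            w$end > target$start, , drop = FALSE]
  d <- scan$diffs
  inside <- d$chrom == target$chrom & d$pos - 1 >= target$start - flank &
    d$pos - 1 < target$end + flank
  frac <- if (nrow(d)) sum(inside) / nrow(d) else NA_real_
  span <- NULL
  don <- d[d$chrom == target$chrom, , drop = FALSE]
  if (nrow(don)) {
    mid <- (target$start + target$end) / 2
    near <- don[order(abs(don$pos - 1 - mid))[seq_len(min(k, nrow(don)))], ]
    span <- list(chrom = target$chrom, start = min(near$pos),
                 end = max(near$pos), n = nrow(near))
  }
  list(windows_overlapping = ov, fraction_inside = frac,
       nearest_span = span)
}
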