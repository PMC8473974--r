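# Cluster-file construction from a reference sample panel, automated
# calling of new samples, and replicate-concordance QC.

#' Build a cluster file from reference intensities
#'
#' Fits and classifies a cluster model for every marker of a reference
#' panel. Markers classed `no_signal` (no detectable signal) or
#' `unclassifiable` (poor genotyping ability) are removed; the rest are
#' retained with their fitted cluster positions. The audit satisfies
#' `retained = total - no_signal - poor` by construction and is checked.
#' The build is deterministic: the same intensities give a byte-identical
#' cluster file.
#'
#' The background threshold is the `background_frac` fraction (default 10%)
#' of the panel-wide median of per-marker median R, so it survives
#' arbitrary intensity units.
#'
#' @param intensities data frame of records
#'   (`sample_id`, `marker_id`, `X`, `Y`).
#' @param params a [calling_params()].
#' @return a `cluster_file` object: named list of retained `cluster_model`s,
#'   removal audit, classes of all input markers, and the background
#'   threshold.
#' @export
build_cluster_file <- function(intensities, params = calling_params()) {
  check_columns(intensities, c("sample_id", "marker_id", "X", "Y"),
                "build_cluster_file")
  tr <- theta_r(intensities$X, intensities$Y)
  marker <- factor(intensities$marker_id,
                   levels = unique(intensities$marker_id))
  med_r <- tapply(tr$r, marker, stats::median)
  r_background <- params$background_frac * stats::median(med_r)
  models <- vector("list", nlevels(marker))
  names(models) <- levels(marker)
  idx_by_marker <- split(seq_len(nrow(tr)), marker)
  for (mk in levels(marker)) {
    i <- idx_by_marker[[mk]]
    models[[mk]] <- fit_cluster_model(tr$theta[i], tr$r[i], params,
                                      r_background = r_background,
                                      marker_id = mk)
  }
  classes <- vapply(models, `[[`, "", "class")
  retained <- !classes %in% c("no_signal", "unclassifiable")
  audit <- c(n_input = length(models),
             n_no_signal = sum(classes == "no_signal"),
             n_poor = sum(classes == "unclassifiable"),
             n_retained = sum(retained))
  stopifnot(audit[["n_retained"]] ==
              audit[["n_input"]] - audit[["n_no_signal"]] - audit[["n_poor"]])
  structure(list(models = models[retained], audit = audit,
                 classes = classes, r_background = r_background,
                 params = params),
            class = "cluster_file")
}

#' @export
print.cluster_file <- function(x, ...) {
  cat("Cluster file:", x$audit[["n_retained"]], "retained of",
      x$audit[["n_input"]], "markers (",
      x$audit[["n_no_signal"]], "no-signal,", x$audit[["n_poor"]],
      "poor genotyping )\n")
  invisible(x)
}

#' @export
summary.cluster_file <- function(object, ...) {
  out <- list(audit = object$audit, class_counts = table(object$classes),
              r_background = object$r_background)
  class(out) <- "summary.cluster_file"
  out
}

#' @export
print.summary.cluster_file <- function(x, ...) {
  cat("Cluster file summary\n  background R threshold:",
      format(x$r_background, digits = 4), "\n")
  print(x$audit)
  print(x$class_counts)
  invisible(x)
}

#' Call genotypes for new samples against a cluster file
#'
#' Per marker and sample, assigns the nearest cluster by theta z-distance
#' (no-call beyond `nc_z` standard deviations or below background).
#' Markers present in the intensities but absent from the cluster file get
#' an all-`NC` row with a warning.
#'
#' @param intensities data frame of records
#'   (`sample_id`, `marker_id`, `X`, `Y`).
#' @param cluster_file a `cluster_file` (possibly re-read from disk).
#' @return character call matrix, markers x samples.
#' @export
call_genotypes <- function(intensities, cluster_file) {
  check_columns(intensities, c("sample_id", "marker_id", "X", "Y"),
                "call_genotypes")
  markers <- unique(intensities$marker_id)
  samples <- unique(intensities$sample_id)
  missing <- setdiff(markers, names(cluster_file$models))
  if (length(missing))
    warning("call_genotypes: ", length(missing),
            " marker(s) absent from cluster file; calling NC")
  calls <- matrix("NC", length(markers), length(samples),
                  dimnames = list(markers, samples))
  tr <- theta_r(intensities$X, intensities$Y)
  for (mk in intersect(markers, names(cluster_file$models))) {
    i <- which(intensities$marker_id == mk)
    cc <- predict(cluster_file$models[[mk]],
                  data.frame(theta = tr$theta[i], r = tr$r[i]))
    calls[mk, match(intensities$sample_id[i], samples)] <- cc
  }
  calls
}

#' Alias for [call_genotypes()] in the modelling idiom
#' @param object a `cluster_file`.
#' @param newdata intensity records.
#' @param ... unused.
#' @export
predict.cluster_file <- function(object, newdata, ...) {
  call_genotypes(newdata, object)
}

# ---- cluster file I/O ------------------------------------------------------

#' Write a cluster file to TSV
#'
#' One row per retained marker: `marker_id`, `class`, `k`, `r_background`,
#' `gentrain`, `cluster_sep`, then five `(theta_mean_i, theta_sd_i,
#' r_mean_i, call_i)` column groups (`NA` beyond `k`). Round-trips exactly.
#'
#' @param cluster_file a `cluster_file`.
#' @param path output TSV.
#' @export
write_cluster_file <- function(cluster_file, path) {
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  rows <- lapply(cluster_file$models, function(m) {
    v <- c(marker_id = m$marker_id, class = m$class, k = m$k,
           r_background = fmt(m$r_background), gentrain = fmt(m$gentrain),
           cluster_sep = fmt(m$cluster_sep))
    for (i in 1:5) {
      v[paste0("theta_mean_", i)] <- if (i <= m$k) fmt(m$means[i]) else "NA"
      v[paste0("theta_sd_", i)] <- if (i <= m$k) fmt(m$sds[i]) else "NA"
      v[paste0("r_mean_", i)] <- if (i <= m$k) fmt(m$r_means[i]) else "NA"
      v[paste0("call_", i)] <- if (i <= m$k) m$calls[i] else "NA"
    }
    v
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cluster file from TSV
#'
#' @param path TSV written by [write_cluster_file()].
#' @param params a [calling_params()] supplying calling thresholds
#'   (cluster parameters themselves come from the file).
#' @return a `cluster_file`.
#' @export
read_cluster_file <- function(path, params = calling_params()) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, c("marker_id", "class", "k", "r_background",
                      "gentrain", "cluster_sep", "theta_mean_1"),
                "read_cluster_file")
  models <- vector("list", nrow(df))
  names(models) <- df$marker_id
  for (i in seq_len(nrow(df))) {
    k <- as.integer(df$k[i])
    sel <- seq_len(k)
    models[[i]] <- structure(
      list(marker_id = df$marker_id[i], k = k,
           means = as.numeric(df[i, paste0("theta_mean_", sel)]),
           sds = as.numeric(df[i, paste0("theta_sd_", sel)]),
           props = rep(1 / max(k, 1L), k),
           r_means = as.numeric(df[i, paste0("r_mean_", sel)]),
           calls = as.character(df[i, paste0("call_", sel)]),
           class = df$class[i], gentrain = as.numeric(df$gentrain[i]),
           cluster_sep = as.numeric(df$cluster_sep[i]),
           r_background = as.numeric(df$r_background[i]),
           n = NA_integer_, params = params),
      class = "cluster_model")
  }
  classes <- vapply(models, `[[`, "", "class")
  structure(list(models = models,
                 audit = c(n_input = length(models), n_no_signal = 0L,
                           n_poor = 0L, n_retained = length(models)),
                 classes = classes,
                 r_background = if (nrow(df)) as.numeric(df$r_background[1L]) else 0,
                 params = params),
            class = "cluster_file")
}

# ---- QC --------------------------------------------------------------------

#' F1 trio consistency check
#'
#' For markers where the two parents are opposite homozygotes, the F1 must
#' be heterozygous; other markers are uninformative.
#'
#' @param parent1_calls,parent2_calls,f1_calls named call vectors over the
#'   same markers (diploid codes).
#' @return list with `verdicts` (per-marker data frame), `n_informative`,
#'   and `fraction_ok`.
#' @export
f1_consistency_check <- function(parent1_calls, parent2_calls, f1_calls) {
  stopifnot(length(parent1_calls) == length(parent2_calls),
            length(parent2_calls) == length(f1_calls))
  hom <- c("AA", "BB")
  informative <- parent1_calls %in% hom & parent2_calls %in% hom &
    parent1_calls != parent2_calls
  ok <- informative & f1_calls == "AB"
  verdicts <- data.frame(marker_id = names(f1_calls) %||%
                           seq_along(f1_calls),
                         p1 = parent1_calls, p2 = parent2_calls,
                         f1 = f1_calls, informative = informative,
                         ok = ifelse(informative, ok, NA),
                         stringsAsFactors = FALSE)
  list(verdicts = verdicts, n_informative = sum(informative),
       fraction_ok = if (sum(informative)) sum(ok) / sum(informative)
       else NA_real_)
}

#' Replicate concordance
#'
#' Counts marker-sample cells called (non-NC) in both inputs but with
#' different codes. The reported percentage uses the total marker-cell
#' count as denominator — the cluster-file retained set, the convention
#' under which 166 differing probes of 28,509 is 0.58%.
#'
#' @param calls_a,calls_b call matrices (or vectors) over the same markers.
#' @return list with `n_total`, `n_compared`, `n_discordant`, `percent`.
#' @export
concordance <- function(calls_a, calls_b) {
  a <- as.matrix(calls_a); b <- as.matrix(calls_b)
  if (!identical(dim(a), dim(b)))
    stop("concordance: call sets have different dimensions")
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    if (!length(intersect(rownames(a), rownames(b))))
      stop("concordance: disjoint marker sets")
    common <- intersect(rownames(a), rownames(b))
    a <- a[common, , drop = FALSE]; b <- b[common, , drop = FALSE]
  }
  both <- a != "NC" & b != "NC"
  n_disc <- sum(both & a != b)
  list(n_total = length(a), n_compared = sum(both), n_discordant = n_disc,
       percent = 100 * n_disc / length(a))
}
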