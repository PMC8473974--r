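# Genome binning, pairwise r-squared, greedy LD grouping, and
# density-balanced probe selection with QTL boosting.

#' Partition a genome into fixed-size bins
#'
#' Bins are 0-based half-open `[start, start + bin_size)` tiles per
#' chromosome; the last bin of each chromosome may be short. A 1-based
#' position `p` falls in bin index `floor((p - 1) / bin_size)`.
#'
#' @param genome a [genome_index()] or a named vector of chromosome lengths.
#' @param bin_size bin width in bp (default 100 kb).
#' @return data frame with columns `bin_id`, `chrom`, `index`, `start`,
#'   `end`.
#' @export
partition_bins <- function(genome, bin_size = 1e5) {
  stopifnot(bin_size > 0)
  lens <- if (inherits(genome, "genome_index")) genome$lengths else genome
  out <- lapply(names(lens), function(ch) {
    nb <- ceiling(lens[[ch]] / bin_size)
    idx <- seq_len(nb) - 1L
    data.frame(bin_id = sprintf("%s:%06d", ch, idx), chrom = ch, index = idx,
               start = idx * bin_size,
               end = pmin((idx + 1) * bin_size, lens[[ch]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bin id of 1-based positions
#' @param chrom,pos coordinates (1-based positions).
#' @param bin_size bin width in bp.
#' @return character bin ids matching [partition_bins()].
#' @export
bin_of <- function(chrom, pos, bin_size = 1e5) {
  sprintf("%s:%06d", chrom, floor((pos - 1) / bin_size))
}

#' Linkage-disequilibrium r-squared of two sites
#'
#' Squared Pearson correlation of allele-dosage vectors over
#' pairwise-complete samples: the standard phase-free estimator for
#' unphased genotype data.
#'
#' @param dosage_a,dosage_b numeric dosage vectors (0/1/2, `NA` missing).
#' @return value in \[0, 1\]. Fewer than two complete pairs or zero
#'   variance at either site is an error.
#' @export
r_squared <- function(dosage_a, dosage_b) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(ok) < 2L) stop("r_squared: fewer than 2 complete sample pairs")
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("r_squared: zero variance at a site")
  stats::cor(a, b)^2
}

#' Greedy LD grouping within a bin
#'
#' Iteratively, the unassigned site with the highest MAF (ties broken by
#' smaller position) becomes a group representative, and every unassigned
#' site with `r_squared >= threshold` to it joins the group; this repeats
#' until every site is assigned, so the groups partition the bin.
#' Monomorphic sites (zero dosage variance) form singleton groups.
#'
#' @param dosage dosage matrix (sites x samples) for the bin's sites.
#' @param maf per-site MAF (selection priority).
#' @param pos per-site 1-based positions (tie break).
#' @param site_id per-site ids.
#' @param threshold r-squared threshold (default 0.65).
#' @return data frame with `site_id`, `group_id` (integer within the bin),
#'   `representative` (logical), `rep_id`.
#' @export
greedy_ld_group <- function(dosage, maf, pos, site_id = NULL, threshold = 0.65) {
  m <- nrow(dosage)
  site_id <- site_id %||% as.character(seq_len(m))
  group <- rep(NA_integer_, m)
  rep_of <- rep(NA_character_, m)
  ord <- order(-maf, pos)
  g <- 0L
  for (i in ord) {
    if (!is.na(group[i])) next
    g <- g + 1L
    group[i] <- g
    rep_of[i] <- site_id[i]
    un <- which(is.na(group))
    if (!length(un)) next
    vi <- stats::var(dosage[i, ], na.rm = TRUE)
    if (is.na(vi) || vi == 0) next
    for (j in un) {
      vj <- stats::var(dosage[j, ], na.rm = TRUE)
      if (is.na(vj) || vj == 0) next
      if (r_squared(dosage[i, ], dosage[j, ]) >= threshold) {
        group[j] <- g
        rep_of[j] <- site_id[i]
      }
    }
  }
  data.frame(site_id = site_id, group_id = group,
             representative = rep_of == site_id, rep_id = rep_of,
             stringsAsFactors = FALSE)
}

#' LD-group every bin of a candidate set
#'
#' Bins are the grouping universe: groups never span bin boundaries.
#'
#' @param candidates data frame with `site_id`, `chrom`, `pos`, `maf`.
#' @param dosage dosage matrix aligned to `candidates` rows.
#' @param bin_size bin width in bp.
#' @param threshold r-squared threshold.
#' @return `candidates` with `bin_id`, `ld_group_id` (globally unique) and
#'   `ld_representative` columns appended.
#' @export
ld_group_bins <- function(candidates, dosage, bin_size = 1e5, threshold = 0.65) {
  check_columns(candidates, c("site_id", "chrom", "pos", "maf"), "ld_group_bins")
  candidates$bin_id <- bin_of(candidates$chrom, candidates$pos, bin_size)
  candidates$ld_group_id <- NA_character_
  candidates$ld_representative <- FALSE
  for (b in unique(candidates$bin_id)) {
    idx <- which(candidates$bin_id == b)
    grp <- greedy_ld_group(dosage[idx, , drop = FALSE], candidates$maf[idx],
                           candidates$pos[idx], candidates$site_id[idx],
                           threshold)
    candidates$ld_group_id[idx] <- sprintf("%s:g%03d", b, grp$group_id)
    candidates$ld_representative[idx] <- grp$representative
  }
  candidates
}

#' Deterministic design-score surrogate
#'
#' Stands in for the proprietary assay design score: start at 1.0, subtract
#' 0.2 if the GC fraction of the full probe context lies outside
#' \[0.30, 0.70\], subtract 0.2 per non-overlapping 6-bp homopolymer block
#' (a 12-bp run counts twice), subtract 0.5 if any ambiguity character is
#' present, floor at 0.
#'
#' @param flank5,snp,flank3 probe context parts (forward strand).
#' @return score in \[0, 1\].
#' @export
design_score_surrogate <- function(flank5, snp, flank3) {
  seqs <- toupper(paste0(flank5, snp, flank3))
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1L]]
    score <- 1.0
    gc <- mean(ch %in% c("G", "C"))
    if (gc < 0.30 || gc > 0.70) score <- score - 0.2
    r <- rle(ch)
    score <- score - 0.2 * sum(r$lengths %/% 6L)
    if (any(!ch %in% c("A", "C", "G", "T"))) score <- score - 0.5
    max(0, score)
  }, 0, USE.NAMES = FALSE)
}

#' Density-balanced panel selection with QTL boosting
#'
#' Per bin, up to `max_per_bin` score-eligible sites are chosen in
#' decreasing MAF order (ties by position), taking at most one site per LD
#' group while unrepresented groups remain. Bins overlapping a QTL window
#' (each QTL interval extended by `qtl_window` bp up- and downstream) get
#' their target raised to `qtl_probes`, never exceeding the available
#' eligible candidates. A final global spacing pass removes the lower-MAF
#' member of any pair closer than `min_probe_spacing`. Bins with no
#' eligible candidate are reported uncovered, not an error.
#'
#' @param candidates data frame with `site_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `maf`, `design_score`, `bin_id`, `ld_group_id` (e.g. from
#'   [ld_group_bins()] plus [design_score_surrogate()]).
#' @param bins data frame from [partition_bins()].
#' @param qtl_intervals optional data frame (`chrom`, `start`, `end`,
#'   0-based half-open) of QTL intervals.
#' @param params a [selection_params()].
#' @param genome optional [genome_index()] with sequences, used to fill the
#'   manifest's flank columns.
#' @return a `probe_manifest` with attributes `bin_targets` (per-bin target
#'   counts) and `uncovered_bins`.
#' @export
select_panel <- function(candidates, bins, qtl_intervals = NULL,
                         params = selection_params(), genome = NULL) {
  check_columns(candidates, c("site_id", "chrom", "pos", "maf",
                              "design_score", "bin_id", "ld_group_id"),
                "select_panel")
  elig <- candidates[candidates$design_score >= params$design_score_min, ,
                     drop = FALSE]
  qtl_bins <- character(0)
  if (!is.null(qtl_intervals) && nrow(qtl_intervals)) {
    hit <- logical(nrow(bins))
    for (q in seq_len(nrow(qtl_intervals))) {
      qs <- qtl_intervals$start[q] - params$qtl_window
      qe <- qtl_intervals$end[q] + params$qtl_window
      hit <- hit | (bins$chrom == qtl_intervals$chrom[q] &
                      bins$start < qe & bins$end > qs)
    }
    qtl_bins <- bins$bin_id[hit]
  }
  chosen <- integer(0)
  targets <- stats::setNames(integer(nrow(bins)), bins$bin_id)
  for (b in bins$bin_id) {
    idx <- which(elig$bin_id == b)
    if (!length(idx)) next
    n_groups <- length(unique(elig$ld_group_id[idx]))
    target <- max(params$min_per_bin, min(params$max_per_bin, n_groups))
    if (b %in% qtl_bins) target <- max(target, params$qtl_probes)
    target <- min(target, length(idx))
    targets[b] <- target
    ord <- idx[order(-elig$maf[idx], elig$pos[idx])]
    used_groups <- character(0)
    pick <- integer(0)
    for (i in ord) {       # one per group while unrepresented groups remain
      if (length(pick) >= target) break
      if (!elig$ld_group_id[i] %in% used_groups) {
        pick <- c(pick, i)
        used_groups <- c(used_groups, elig$ld_group_id[i])
      }
    }
    if (length(pick) < target) {
      for (i in setdiff(ord, pick)) {   # groups exhausted: allow reuse
        if (length(pick) >= target) break
        pick <- c(pick, i)
      }
    }
    chosen <- c(chosen, pick)
  }
  sel <- elig[chosen, , drop = FALSE]
  if (nrow(sel)) {
    keep <- enforce_min_spacing(sel$chrom, sel$pos, sel$maf,
                                params$min_probe_spacing)
    sel <- sel[keep, , drop = FALSE]
    sel <- sel[order(match(sel$chrom, unique(bins$chrom)), sel$pos), ,
               drop = FALSE]
  }
  flank5 <- flank3 <- rep(NA_character_, nrow(sel))
  if (!is.null(genome) && nrow(sel)) {
    for (i in seq_len(nrow(sel))) {
      ctx <- probe_context(genome, sel$chrom[i], sel$pos[i], 50L)
      if (!is.null(ctx)) {
        flank5[i] <- substr(ctx, 1, 50)
        flank3[i] <- substr(ctx, 52, 101)
      }
    }
  }
  manifest <- data.frame(
    marker_id = sel$site_id, chrom = sel$chrom, pos = sel$pos,
    ref = sel$ref %||% rep(NA_character_, nrow(sel)),
    alt = sel$alt %||% rep(NA_character_, nrow(sel)),
    flank5 = flank5, flank3 = flank3, design_score = sel$design_score,
    category = ifelse(sel$bin_id %in% qtl_bins, "qtl_boosted", "background"),
    ld_group_id = sel$ld_group_id, bin_id = sel$bin_id,
    stringsAsFactors = FALSE)
  manifest <- as_probe_manifest(manifest)
  covered <- bins$bin_id %in% manifest$bin_id
  has_elig <- bins$bin_id %in% elig$bin_id
  attr(manifest, "bin_targets") <- targets
  attr(manifest, "uncovered_bins") <- bins$bin_id[has_elig & !covered]
  attr(manifest, "params") <- params
  manifest
}

#' Panel selection parameters
#'
#' @param min_per_bin,max_per_bin probes per 100-kb bin (defaults 1 and 5).
#' @param qtl_probes target probes per QTL window (default 3).
#' @param qtl_window bp added up- and downstream of each QTL interval
#'   (default 150 kb).
#' @param design_score_min minimum design score (default 0.6).
#' @param ld_threshold r-squared grouping threshold (default 0.65).
#' @param min_probe_spacing minimum spacing in bp (default 200).
#' @param bin_size bin width in bp (default 100 kb).
#' @return a `selection_params` list.
#' @export
selection_params <- function(min_per_bin = 1L, max_per_bin = 5L,
                             qtl_probes = 3L, qtl_window = 1.5e5,
                             design_score_min = 0.6, ld_threshold = 0.65,
                             min_probe_spacing = 200L, bin_size = 1e5) {
  p <- list(min_per_bin = as.integer(min_per_bin),
            max_per_bin = as.integer(max_per_bin),
            qtl_probes = as.integer(qtl_probes), qtl_window = qtl_window,
            design_score_min = design_score_min, ld_threshold = ld_threshold,
            min_probe_spacing = as.integer(min_probe_spacing),
            bin_size = bin_size)
  stopifnot(p$min_per_bin <= p$max_per_bin, p$qtl_window > 0, p$bin_size > 0)
  class(p) <- "selection_params"
  p
}

#' Independent validity checker for an emitted panel
#'
#' Re-validates, from scratch: design-score threshold, per-bin caps
#' (`max_per_bin`, or `qtl_probes` where boosted), global minimum spacing,
#' and the one-per-group preference (a group may hold two panel probes only
#' if every eligible group of its bin is already represented).
#'
#' @param manifest a `probe_manifest`.
#' @param candidates the candidate table given to [select_panel()]; when
#'   `NULL` the one-per-group check (which needs the full candidate list)
#'   is skipped.
#' @param params the [selection_params()] used.
#' @return list with `ok` (logical) and `checks` (named logical vector).
#' @export
validate_panel <- function(manifest, candidates = NULL,
                           params = selection_params()) {
  checks <- c(score_threshold = all(manifest$design_score >=
                                      params$design_score_min))
  cap <- ifelse(manifest$category == "qtl_boosted",
                max(params$max_per_bin, params$qtl_probes), params$max_per_bin)
  per_bin <- table(manifest$bin_id)
  cap_by_bin <- tapply(cap, manifest$bin_id, max)
  checks["per_bin_cap"] <- all(as.integer(per_bin) <=
                                 cap_by_bin[names(per_bin)])
  ok_sp <- TRUE
  for (ch in unique(manifest$chrom)) {
    p <- sort(manifest$pos[manifest$chrom == ch])
    if (length(p) > 1L && any(diff(p) <= params$min_probe_spacing))
      ok_sp <- FALSE
  }
  checks["spacing"] <- ok_sp
  if (!is.null(candidates)) {
    elig <- candidates[candidates$design_score >= params$design_score_min, ,
                       drop = FALSE]
    ok_grp <- TRUE
    for (b in unique(manifest$bin_id)) {
      sel_groups <- manifest$ld_group_id[manifest$bin_id == b]
      if (anyDuplicated(sel_groups)) {
        all_groups <- unique(elig$ld_group_id[elig$bin_id == b])
        if (!all(all_groups %in% sel_groups)) ok_grp <- FALSE
      }
    }
    checks["one_per_group"] <- ok_grp
  }
  list(ok = all(checks), checks = checks)
}

#' Panel density statistics
#'
#' Gaps are successive position differences between adjacent panel probes
#' within chromosomes only.
#'
#' @param manifest a `probe_manifest`.
#' @param genome a [genome_index()] or named length vector (defines the
#'   chromosome universe; chromosomes without probes contribute no gaps).
#' @param threshold gap size of interest in bp (default 100 kb).
#' @return a `panel_stats` list: `n_probes`, `per_chrom`, `gaps`,
#'   `mean_gap`, `frac_gap_gt` (fraction of gaps > `threshold`),
#'   `threshold`.
#' @export
panel_stats <- function(manifest, genome, threshold = 1e5) {
  lens <- if (inherits(genome, "genome_index")) genome$lengths else genome
  gaps <- numeric(0)
  for (ch in names(lens)) {
    p <- sort(manifest$pos[manifest$chrom == ch])
    if (length(p) > 1L) gaps <- c(gaps, diff(p))
  }
  structure(list(n_probes = nrow(manifest),
                 per_chrom = table(factor(manifest$chrom, levels = names(lens))),
                 gaps = gaps,
                 mean_gap = if (length(gaps)) mean(gaps) else NA_real_,
                 frac_gap_gt = if (length(gaps)) mean(gaps > threshold) else NA_real_,
                 threshold = threshold),
            class = "panel_stats")
}

#' @export
print.panel_stats <- function(x, ...) {
  cat("Panel:", x$n_probes, "probes; mean adjacent gap",
      if (is.na(x$mean_gap)) "NA" else format(round(x$mean_gap), big.mark = ","),
      "bp;", if (is.na(x$frac_gap_gt)) "NA" else
        sprintf("%.1f%%", 100 * x$frac_gap_gt),
      "of gaps >", format(x$threshold, big.mark = ","), "bp\n")
  invisible(x)
}
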