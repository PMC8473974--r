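# The two filter cascades: the re-sequencing SNP screen and the array
# probe-QC screen, both with full audit trails.

#' Filter cascade parameters
#'
#' Threshold strictness follows the published criteria to the letter:
#' call frequency is strictly `>`, probe-screen MAF is strictly `>`, the
#' re-sequencing MAF and the remaining thresholds are `>=`.
#'
#' @param maf_min minimum minor allele frequency (re-sequencing screen
#'   `>=`, probe screen `>`).
#' @param mq_min minimum mapping quality (`>=`; missing MQ fails).
#' @param min_second_allele_carriers minimum number of samples carrying at
#'   least one copy of the minor allele.
#' @param flank_halfwidth flank half-width in bp for cleanliness and
#'   uniqueness checks (the probe context is `2*flank_halfwidth + 1` bp).
#' @param flank_identity_max a probe context with another genomic match at
#'   identity `>=` this fraction is rejected.
#' @param min_probe_spacing probes closer than or equal to this many bp
#'   conflict; the higher-priority one is kept.
#' @param call_freq_min minimum call frequency (strict `>`).
#' @param cluster_sep_min minimum cluster separation score (`>=`).
#' @param design_score_min minimum design score (`>=`).
#' @return a `filter_params` list.
#' @export
filter_params <- function(maf_min = 0.05, mq_min = 30,
                          min_second_allele_carriers = 10L,
                          flank_halfwidth = 50L, flank_identity_max = 0.85,
                          min_probe_spacing = 200L, call_freq_min = 0.8,
                          cluster_sep_min = 0.15, design_score_min = 0.6) {
  p <- list(maf_min = maf_min, mq_min = mq_min,
            min_second_allele_carriers = as.integer(min_second_allele_carriers),
            flank_halfwidth = as.integer(flank_halfwidth),
            flank_identity_max = flank_identity_max,
            min_probe_spacing = as.integer(min_probe_spacing),
            call_freq_min = call_freq_min, cluster_sep_min = cluster_sep_min,
            design_score_min = design_score_min)
  stopifnot(p$maf_min >= 0, p$maf_min <= 0.5, p$mq_min >= 0,
            p$min_second_allele_carriers >= 0, p$flank_halfwidth > 0,
            p$flank_identity_max > 0, p$flank_identity_max <= 1,
            p$min_probe_spacing >= 0, p$call_freq_min >= 0,
            p$call_freq_min <= 1, p$cluster_sep_min >= 0,
            p$design_score_min >= 0, p$design_score_min <= 1)
  class(p) <- "filter_params"
  p
}

#' Minor allele frequency per site
#'
#' MAF is the minimum allele count over the site's alleles (REF and every
#' ALT) divided by the total non-missing allele count, so it lies in
#' \[0, 0.5\] for biallelic sites and is 0 for monomorphic ones.
#'
#' @param vset a [variant_set()].
#' @return numeric vector, one value per site. A site with no non-missing
#'   genotype is an error.
#' @export
minor_allele_frequency <- function(vset) {
  m <- n_sites(vset)
  out <- numeric(m)
  for (i in seq_len(m)) {
    al <- c(vset$a1[i, ], vset$a2[i, ])
    al <- al[!is.na(al)]
    if (!length(al))
      stop("minor_allele_frequency: all genotypes missing at site ", i)
    n_alleles <- 1L + length(strsplit(vset$sites$alt[i], ",", fixed = TRUE)[[1L]])
    counts <- tabulate(al + 1L, nbins = n_alleles)
    out[i] <- min(counts) / length(al)
  }
  out
}

#' Call frequency
#'
#' `Calls / (No_Calls + Calls)`, the array QC statistic.
#'
#' @param n_calls,n_no_calls non-negative counts; both zero is an error.
#' @return fraction in \[0, 1\].
#' @export
call_frequency <- function(n_calls, n_no_calls) {
  if (any(n_calls + n_no_calls <= 0))
    stop("call_frequency: undefined with no observations")
  n_calls / (n_calls + n_no_calls)
}

#' Flank cleanliness: no other SNP within the flanking window
#'
#' A site is clean iff no other variant lies within `halfwidth` bp of it
#' (inclusive: a neighbour at exactly `halfwidth` bp makes it unclean) on
#' the same chromosome. The check is against all supplied sites, i.e. the
#' full candidate list, not just survivors of earlier rules.
#'
#' @param vset a [variant_set()] (all candidate sites).
#' @param halfwidth window half-width in bp (default 50).
#' @return logical vector per site.
#' @export
flank_is_clean <- function(vset, halfwidth = 50L) {
  s <- vset$sites
  out <- logical(nrow(s))
  for (ch in unique(s$chrom)) {
    idx <- which(s$chrom == ch)
    pos <- s$pos[idx]
    o <- order(pos)
    p <- pos[o]
    d_prev <- c(Inf, diff(p))
    d_next <- c(diff(p), Inf)
    clean <- pmin(d_prev, d_next) > halfwidth
    out[idx[o]] <- clean
  }
  out
}

# The 101-bp probe context (flank5 + SNP base + flank3) on the forward
# strand, or NULL when the site is within `halfwidth` of a chromosome end.
probe_context <- function(genome, chrom, pos, halfwidth = 50L) {
  if (pos - halfwidth < 1 || pos + halfwidth > genome$lengths[[chrom]])
    return(NULL)
  genome_subseq(genome, chrom, pos - halfwidth, pos + halfwidth)
}

#' Flank uniqueness: no second genomic match above the identity ceiling
#'
#' The full probe context (`2*halfwidth + 1` bp around the site) is compared
#' against every other location in the genome by ungapped identity
#' (matching bases / probe length); the site is unique iff the best match
#' other than its own locus has identity below `identity_max`. Chromosomes
#' up to 200 kb are scanned exhaustively at every offset; larger ones use an
#' exact 16-mer seed prefilter before verifying candidate offsets, the same
#' seed-and-verify scheme BLAST-type searches use.
#'
#' @param genome a [genome_index()] with sequences.
#' @param chrom,pos site location (1-based).
#' @param halfwidth flank half-width (default 50).
#' @param identity_max rejection ceiling (default 0.85).
#' @return `TRUE`/`FALSE` with attribute `max_identity`; `NA` with attribute
#'   `reason = "flank_truncated"` when the site is too close to a
#'   chromosome end for a full flank.
#' @export
flank_is_unique <- function(genome, chrom, pos, halfwidth = 50L,
                            identity_max = 0.85) {
  res <- flank_unique_batch(genome, chrom, pos, halfwidth, identity_max)
  if (is.na(res$unique[1L]))
    return(structure(NA, reason = res$reason[1L]))
  structure(res$unique[1L], max_identity = res$max_identity[1L])
}

#' Batch flank-uniqueness screen
#'
#' Vectorised form of [flank_is_unique()], used by the filter cascade: all
#' probe contexts are screened in one pass (one seed dictionary, one scan
#' per chromosome), which is the only tractable route for thousands of
#' candidates.
#'
#' @param genome a [genome_index()] with sequences.
#' @param chrom,pos parallel site coordinate vectors (1-based).
#' @param halfwidth flank half-width (default 50).
#' @param identity_max rejection ceiling (default 0.85).
#' @return data frame with `unique` (`NA` for truncated flanks),
#'   `max_identity`, `reason`.
#' @export
flank_unique_batch <- function(genome, chrom, pos, halfwidth = 50L,
                               identity_max = 0.85) {
  n <- length(pos)
  w <- 2L * halfwidth + 1L
  probes <- vapply(seq_len(n), function(i)
    probe_context(genome, chrom[i], pos[i], halfwidth) %||% NA_character_, "")
  ok <- !is.na(probes)
  best <- rep(0, n)
  own_start <- pos - halfwidth
  # candidate offsets per probe per chromosome
  idx_ok <- which(ok)
  if (length(idx_ok)) {
    seed_w <- 16L
    offs <- unique(c(seq(1L, w - seed_w + 1L, by = 8L), w - seed_w + 1L))
    pats <- lapply(idx_ok, function(i) Biostrings::DNAString(probes[i]))
    names(pats) <- as.character(idx_ok)
    # one dictionary over every probe's seeds (constant width)
    seed_seq <- unlist(lapply(idx_ok, function(i)
      substring(probes[i], offs, offs + seed_w - 1L)))
    seed_probe <- rep(idx_ok, each = length(offs))
    seed_off <- rep(offs, times = length(idx_ok))
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed_seq))
    for (ch in genome$chroms) {
      subj <- genome$seq[[ch]]
      L <- length(subj)
      if (L < w) next
      if (L <= 2e5) {
        starts_by_probe <- rep(list(seq_len(L - w + 1L)), length(idx_ok))
        names(starts_by_probe) <- as.character(idx_ok)
      } else {
        si <- Biostrings::startIndex(Biostrings::matchPDict(pd, subj))
        lens <- lengths(si)
        cand_probe <- rep(seed_probe, lens)
        cand_start <- unlist(si) - rep(seed_off, lens) + 1L
        keep <- !is.na(cand_start) & cand_start >= 1L &
          cand_start <= L - w + 1L
        starts_by_probe <- split(cand_start[keep], cand_probe[keep])
      }
      for (key in names(starts_by_probe)) {
        i <- as.integer(key)
        starts <- unique(starts_by_probe[[key]])
        if (chrom[i] == ch) starts <- starts[starts != own_start[i]]
        if (!length(starts)) next
        nedit <- Biostrings::neditStartingAt(pats[[key]], subj,
                                             starting.at = starts,
                                             with.indels = FALSE)
        best[i] <- max(best[i], (w - min(nedit)) / w)
      }
    }
  }
  data.frame(unique = ifelse(ok, best < identity_max, NA),
             max_identity = ifelse(ok, best, NA_real_),
             reason = ifelse(ok, NA_character_, "flank_truncated"),
             stringsAsFactors = FALSE)
}

#' Greedy minimum-spacing enforcement
#'
#' Sites are visited in priority order (higher `priority` first, ties by
#' smaller position); a site is kept iff no already-kept site on the same
#' chromosome lies within `min_bp` (inclusive: distance must exceed
#' `min_bp`).
#'
#' @param chrom,pos site coordinates (1-based positions).
#' @param priority numeric priority (default rule elsewhere: MAF).
#' @param min_bp minimum spacing in bp.
#' @return logical keep vector in input order.
#' @export
enforce_min_spacing <- function(chrom, pos, priority, min_bp) {
  n <- length(pos)
  keep <- logical(n)
  ord <- order(-priority, pos)
  kept_pos <- split(numeric(0), NULL)
  kept <- list()
  for (i in ord) {
    ch <- chrom[i]
    kp <- kept[[ch]]
    if (is.null(kp) || !length(kp) || min(abs(kp - pos[i])) > min_bp) {
      keep[i] <- TRUE
      kept[[ch]] <- c(kp, pos[i])
    }
  }
  keep
}

#' The re-sequencing SNP filter cascade
#'
#' Applies, in order: (1) biallelic SNP; (2) MAF and mapping quality;
#' (3) minor-allele carrier count; (4) clean flanks (no other candidate SNP
#' within the flank window, judged against the full input list);
#' (5) genome-unique flanks (sites with truncated flanks are removed here
#' with reason `flank_truncated`). Returns the survivors and a conserved
#' audit trail.
#'
#' @param vset a [variant_set()] of candidate sites.
#' @param genome a [genome_index()] with sequences.
#' @param params a [filter_params()].
#' @return list with `survivors` (a [variant_set()]), `audit`
#'   (a [filter_audit()]), and `reasons` (per removed site).
#' @export
filter_resequencing_snps <- function(vset, genome, params = filter_params()) {
  m <- n_sites(vset)
  alive <- rep(TRUE, m)
  reasons <- rep(NA_character_, m)
  n_in <- integer(5); n_rm <- integer(5)
  rules <- c("biallelic", "maf_mq", "second_allele_carriers",
             "clean_flanks", "unique_flanks")
  drop_step <- function(step, fail) {
    n_in[step] <<- sum(alive)
    rm_now <- alive & fail
    n_rm[step] <<- sum(rm_now)
    reasons[rm_now] <<- rules[step]
    alive[rm_now] <<- FALSE
  }
  s <- vset$sites
  # (1) biallelic SNP
  biallelic <- !grepl(",", s$alt, fixed = TRUE) &
    nchar(s$ref) == 1L & nchar(s$alt) == 1L
  drop_step(1L, !biallelic)
  # (2) MAF and mapping quality (missing MQ fails, conservatively)
  maf <- if (m) minor_allele_frequency(vset) else numeric(0)
  mq_ok <- !is.na(s$mq) & s$mq >= params$mq_min
  drop_step(2L, !(maf >= params$maf_min & mq_ok))
  # (3) second allele present in >= N samples (carriers of >= 1 minor copy)
  carriers <- integer(m)
  for (i in which(alive)) {
    a1 <- vset$a1[i, ]; a2 <- vset$a2[i, ]
    ok <- !is.na(a1) & !is.na(a2)
    cnt_alt <- sum(a1[ok] > 0) + sum(a2[ok] > 0)
    cnt_ref <- 2L * sum(ok) - cnt_alt
    # minor allele: the one with the smaller count (tie -> ALT)
    minor_is_alt <- cnt_alt <= cnt_ref
    carriers[i] <- if (minor_is_alt)
      sum(ok & (a1 > 0 | a2 > 0)) else sum(ok & (a1 == 0 | a2 == 0))
  }
  drop_step(3L, carriers < params$min_second_allele_carriers)
  # (4) no other candidate SNP within the flank window
  clean <- flank_is_clean(vset, params$flank_halfwidth)
  drop_step(4L, !clean)
  # (5) flank uniqueness on the reference genome (batch scan)
  uniq <- rep(TRUE, m)
  idx5 <- which(alive)
  if (length(idx5)) {
    ub <- flank_unique_batch(genome, s$chrom[idx5], s$pos[idx5],
                             params$flank_halfwidth,
                             params$flank_identity_max)
    uniq[idx5] <- !is.na(ub$unique) & ub$unique
    reasons[idx5[!is.na(ub$reason)]] <- ub$reason[!is.na(ub$reason)]
  }
  n_in[5L] <- sum(alive)
  rm_now <- alive & !uniq
  n_rm[5L] <- sum(rm_now)
  reasons[rm_now & is.na(reasons)] <- rules[5L]
  alive[rm_now] <- FALSE

  list(survivors = subset_sites(vset, alive),
       audit = filter_audit(rules, n_in, n_rm),
       reasons = reasons)
}

#' The array probe-QC screen
#'
#' Applies, in order: (1) call frequency strictly above the threshold;
#' (2) cluster separation at or above the threshold; (3) MAF strictly above
#' the threshold; (4) a unique genomic match; (5) minimum probe spacing
#' (the higher-MAF member of a conflicting pair is kept).
#'
#' @param marker_stats data frame with columns `marker_id`, `chrom`, `pos`,
#'   `call_freq`, `cluster_sep`, `maf`, `unique_match` (logical).
#' @param params a [filter_params()].
#' @return list with `survivors` (subset of `marker_stats`) and `audit`.
#' @export
filter_array_probes <- function(marker_stats, params = filter_params()) {
  check_columns(marker_stats, c("marker_id", "chrom", "pos", "call_freq",
                                "cluster_sep", "maf", "unique_match"),
                "filter_array_probes")
  m <- nrow(marker_stats)
  alive <- rep(TRUE, m)
  n_in <- integer(5); n_rm <- integer(5)
  rules <- c("call_frequency", "cluster_separation", "maf", "unique_match",
             "min_spacing")
  drop_step <- function(step, fail) {
    n_in[step] <<- sum(alive)
    rm_now <- alive & fail
    n_rm[step] <<- sum(rm_now)
    alive[rm_now] <<- FALSE
  }
  drop_step(1L, !(marker_stats$call_freq > params$call_freq_min))
  drop_step(2L, !(marker_stats$cluster_sep >= params$cluster_sep_min))
  drop_step(3L, !(marker_stats$maf > params$maf_min))
  drop_step(4L, !marker_stats$unique_match)
  n_in[5L] <- sum(alive)
  idx <- which(alive)
  keep <- enforce_min_spacing(marker_stats$chrom[idx], marker_stats$pos[idx],
                              marker_stats$maf[idx], params$min_probe_spacing)
  n_rm[5L] <- sum(!keep)
  alive[idx[!keep]] <- FALSE
  list(survivors = marker_stats[alive, , drop = FALSE],
       audit = filter_audit(rules, n_in, n_rm))
}
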