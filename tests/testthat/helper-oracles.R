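# Independent oracles used to cross-check package computations. These are
# deliberately written from first principles (direct sums, exhaustive
# scans, enumeration) and never call the code paths they check.

# Squared Pearson correlation of two dosage vectors via the direct
# covariance formula over pairwise-complete samples.
r2_brute <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  sxy <- sum(a * b) - sum(a) * sum(b) / n
  sxx <- sum(a * a) - sum(a)^2 / n
  syy <- sum(b * b) - sum(b)^2 / n
  (sxy * sxy) / (sxx * syy)
}

# Exhaustive ungapped identity scan of a probe against a genome given as a
# character vector of bases; returns the best identity over all offsets
# excluding `exclude_start`. Equivalent to a Smith-Waterman scan for
# substitution-only duplicates (no indels).
scan_max_identity <- function(genome_chars, probe_chars, exclude_start) {
  w <- length(probe_chars)
  n_off <- length(genome_chars) - w + 1L
  matches <- integer(n_off)
  for (j in seq_len(w))
    matches <- matches + (genome_chars[seq_len(n_off) + j - 1L] == probe_chars[j])
  matches[exclude_start] <- 0L
  max(matches) / w
}

# All partitions of 1..n into labelled star groups: every group has a
# representative and each member satisfies r2(member, rep) >= threshold.
# Returns a list of membership vectors (group id per site).
valid_star_partitions <- function(dosage, threshold) {
  n <- nrow(dosage)
  parts <- list()
  assign_next <- function(z, k) {
    i <- which(z == 0L)[1L]
    if (is.na(i)) { parts[[length(parts) + 1L]] <<- z; return(invisible()) }
    for (g in seq_len(k + 1L)) {
      z2 <- z; z2[i] <- g
      assign_next(z2, max(k, g))
    }
  }
  assign_next(integer(n), 0L)
  ok <- vapply(parts, function(z) {
    all(vapply(unique(z), function(g) {
      members <- which(z == g)
      # some member must work as the representative
      any(vapply(members, function(r) {
        all(vapply(members, function(m) {
          m == r || r_squared(dosage[m, ], dosage[r, ]) >= threshold
        }, TRUE))
      }, TRUE))
    }, TRUE))
  }, TRUE)
  parts[ok]
}

# Expected noise-free marker class from simulation truth: what a perfect
# fit of noise-free intensities would yield for marker i.
truth_expected_class <- function(truth, i) {
  if (truth$no_signal[i]) return("no_signal")
  tot <- truth$dosage[i, ] +
    (if (truth$homoeolog[i]) truth$shadow_dosage[i, ] else 0L)
  u <- sort(unique(tot))
  if (length(u) == 1L) return("monomorphic")
  if (length(u) >= 4L) return("intergenomic_5")
  mu <- if (truth$homoeolog[i]) dosage_theta(u, 4L) else dosage_theta(u, 2L)
  codes <- c("AA", "AB", "BB")[round(mu * 2) + 1L]
  if (anyDuplicated(codes)) "unclassifiable" else "polymorphic_3"
}

# True call codes for a truth marker set: diploid codes for plain markers,
# 5-dosage codes for homoeolog markers.
truth_calls <- function(truth, idx) {
  if (!length(idx)) return(NULL)
  out <- lapply(idx, function(i) {
    if (truth$homoeolog[i]) {
      tot <- truth$dosage[i, ] + truth$shadow_dosage[i, ]
      c("AAAA", "AAAB", "AABB", "ABBB", "BBBB")[tot + 1L]
    } else c("AA", "AB", "BB")[truth$dosage[i, ] + 1L]
  })
  m <- do.call(rbind, out)
  rownames(m) <- truth$marker_id[idx]
  colnames(m) <- colnames(truth$dosage)
  m
}
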