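# File formats and coordinate conventions.
#
# Conventions used throughout the package:
#   * point variants:  1-based inclusive positions (as in VCF);
#   * intervals, bins, windows:  0-based half-open [start, end) (as in BED).
# Every public function documents which convention it uses.

# ---- genome index ----------------------------------------------------------

#' Construct a genome index
#'
#' A genome index maps chromosome names to lengths (bp) in a fixed order and
#' optionally carries the sequences themselves (a [Biostrings::DNAStringSet]).
#'
#' @param lengths named numeric vector of chromosome lengths (bp, > 0).
#' @param seq optional `DNAStringSet` whose names and widths match `lengths`.
#' @return a `genome_index` object.
#' @export
genome_index <- function(lengths, seq = NULL) {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)))
    stop("genome_index: chromosome names must be present and unique")
  if (any(lengths <= 0)) stop("genome_index: lengths must be > 0")
  if (!is.null(seq)) {
    if (!identical(names(seq), names(lengths)) ||
        !all(Biostrings::width(seq) == unname(lengths)))
      stop("genome_index: sequences do not match lengths")
  }
  structure(list(chroms = names(lengths),
                 lengths = stats::setNames(as.numeric(lengths), names(lengths)),
                 seq = seq),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("Genome index:", length(x$chroms), "chromosome(s),",
      format(sum(x$lengths), big.mark = ","), "bp",
      if (is.null(x$seq)) "(lengths only)" else "(with sequence)", "\n")
  invisible(x)
}

#' Read a FASTA reference genome
#'
#' @param path FASTA file.
#' @return a [genome_index()] carrying the sequences.
#' @export
read_fasta <- function(path) {
  seq <- Biostrings::readDNAStringSet(path)
  names(seq) <- sub("\\s.*$", "", names(seq))
  if (anyDuplicated(names(seq)))
    stop("read_fasta: duplicate sequence names in ", path)
  genome_index(stats::setNames(Biostrings::width(seq), names(seq)), seq = seq)
}

#' Write a genome index with sequences to FASTA
#'
#' @param genome a [genome_index()] with sequences.
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  if (is.null(genome$seq)) stop("write_fasta: genome has no sequences")
  Biostrings::writeXStringSet(genome$seq, path, width = 70L)
  invisible(path)
}

#' Extract a reference subsequence (1-based inclusive)
#'
#' @param genome a [genome_index()] with sequences.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @return a character scalar.
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  if (is.null(genome$seq)) stop("genome_subseq: genome has no sequences")
  if (!chrom %in% genome$chroms) stop("genome_subseq: unknown chromosome ", chrom)
  if (start < 1 || end > genome$lengths[[chrom]] || end < start)
    stop(sprintf("genome_subseq: range [%d,%d] outside %s (length %d)",
                 start, end, chrom, genome$lengths[[chrom]]))
  as.character(Biostrings::subseq(genome$seq[[chrom]], start, end))
}

# ---- variant sets ----------------------------------------------------------

#' Construct a set of candidate variant sites
#'
#' Positions are 1-based. Genotypes are stored as two allele-index matrices
#' (`a1`, `a2`; 0 = REF, 1.. = ALT index, `NA` = missing), sites in rows and
#' samples in columns; diploid only.
#'
#' @param sites data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (comma-separated for multi-allelic sites) and optionally `mq`
#'   (phred-like mapping quality).
#' @param a1,a2 integer matrices, `nrow(sites)` x `length(samples)`.
#' @param samples character vector of sample names.
#' @return a `variant_set` object.
#' @export
variant_set <- function(sites, a1, a2, samples) {
  check_columns(sites, c("chrom", "pos", "ref", "alt"), "variant_set")
  sites$pos <- as.numeric(sites$pos)
  sites$mq <- as.numeric(rep(sites$mq %||% NA_real_,
                             length.out = nrow(sites)))
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(nrow(a1) == nrow(sites), nrow(a2) == nrow(sites),
            ncol(a1) == length(samples), ncol(a2) == length(samples))
  rownames(sites) <- NULL
  structure(list(sites = sites, a1 = a1, a2 = a2,
                 samples = as.character(samples)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("Variant set:", nrow(x$sites), "site(s) x", length(x$samples),
      "sample(s) on", length(unique(x$sites$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Number of sites in a variant set
#' @param vset a [variant_set()].
#' @export
n_sites <- function(vset) nrow(vset$sites)

#' Subset a variant set by site index
#' @param vset a [variant_set()].
#' @param i site indices (logical or integer).
#' @export
subset_sites <- function(vset, i) {
  variant_set(vset$sites[i, , drop = FALSE],
              vset$a1[i, , drop = FALSE], vset$a2[i, , drop = FALSE],
              vset$samples)
}

#' ALT-allele dosage matrix of a variant set
#'
#' For biallelic sites this is the usual 0/1/2 dosage; for multi-allelic
#' sites every non-REF allele counts. `NA` where the genotype is missing.
#'
#' @param vset a [variant_set()].
#' @return numeric matrix, sites x samples.
#' @export
alt_dosage <- function(vset) {
  (vset$a1 > 0) + (vset$a2 > 0)
}

# ---- VCF (minimal dialect) -------------------------------------------------

#' Read a minimal VCF v4.x file
#'
#' Supports the essentials this pipeline needs: the `#CHROM` header line,
#' `CHROM/POS/REF/ALT/QUAL/INFO/FORMAT` columns plus diploid `GT` genotype
#' fields, and `MQ=` parsed from INFO when present. Multi-allelic ALT is
#' preserved. `./.` becomes the missing genotype. Any GT of ploidy other
#' than 2 is an error, as is a malformed header (reported with its line
#' number).
#'
#' @param path VCF file.
#' @return a [variant_set()].
#' @export
read_vcf_minimal <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  if (!length(hdr)) {
    bad <- which(!grepl("^##", lines))[1L]
    stop(sprintf("read_vcf_minimal: malformed header, no #CHROM line (line %d: '%s')",
                 if (is.na(bad)) length(lines) else bad,
                 if (is.na(bad)) "" else lines[bad]))
  }
  hdr <- hdr[1L]
  pre <- lines[seq_len(hdr - 1L)]
  if (length(pre) && any(!grepl("^##", pre))) {
    bad <- which(!grepl("^##", pre))[1L]
    stop(sprintf("read_vcf_minimal: malformed header at line %d: '%s'",
                 bad, pre[bad]))
  }
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]]
  need <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(cols) < 8L || !identical(cols[1:8], need))
    stop(sprintf("read_vcf_minimal: malformed header at line %d: '%s'",
                 hdr, lines[hdr]))
  samples <- if (length(cols) > 9L) cols[-(1:9)] else character(0)
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  n <- length(body)
  ns <- length(samples)
  sites <- data.frame(chrom = character(n), pos = numeric(n),
                      ref = character(n), alt = character(n),
                      mq = rep(NA_real_, n), stringsAsFactors = FALSE)
  a1 <- matrix(NA_integer_, n, ns, dimnames = list(NULL, samples))
  a2 <- a1
  for (i in seq_len(n)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L + (ns > 0) * (1L + ns))
      stop("read_vcf_minimal: truncated data line ", hdr + i)
    sites$chrom[i] <- f[1L]
    sites$pos[i] <- as.numeric(f[2L])
    sites$ref[i] <- toupper(f[4L])
    sites$alt[i] <- toupper(f[5L])
    m <- regmatches(f[8L], regexpr("(?<=^|;)MQ=[-0-9.eE]+", f[8L], perl = TRUE))
    if (length(m)) sites$mq[i] <- as.numeric(sub("MQ=", "", m))
    if (ns) {
      fmt <- strsplit(f[9L], ":", fixed = TRUE)[[1L]]
      gi <- match("GT", fmt)
      if (is.na(gi)) stop("read_vcf_minimal: FORMAT without GT at line ", hdr + i)
      for (s in seq_len(ns)) {
        gt <- strsplit(f[9L + s], ":", fixed = TRUE)[[1L]][gi]
        al <- strsplit(gt, "[/|]")[[1L]]
        if (length(al) != 2L)
          stop(sprintf("read_vcf_minimal: GT ploidy %d (expected 2) at line %d",
                       length(al), hdr + i))
        a1[i, s] <- if (al[1L] == ".") NA_integer_ else as.integer(al[1L])
        a2[i, s] <- if (al[2L] == ".") NA_integer_ else as.integer(al[2L])
      }
    }
  }
  variant_set(sites, a1, a2, samples)
}

#' Write a minimal VCF v4.x file
#'
#' Inverse of [read_vcf_minimal()]. Sites must be sorted by (chrom, pos)
#' with chromosomes contiguous.
#'
#' @param vset a [variant_set()].
#' @param path output file.
#' @export
write_vcf_minimal <- function(vset, path) {
  s <- vset$sites
  if (nrow(s)) {
    ord <- order(match(s$chrom, unique(s$chrom)), s$pos)
    if (!identical(ord, seq_len(nrow(s))))
      stop("write_vcf_minimal: sites must be sorted by (chrom, pos)")
    if (anyDuplicated(s$chrom[!duplicated(s$chrom)]))
      stop("write_vcf_minimal: chromosomes must be contiguous")
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  hdr <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(vset$samples)) hdr <- c(hdr, "FORMAT", vset$samples)
  writeLines(paste(hdr, collapse = "\t"), con)
  for (i in seq_len(nrow(s))) {
    info <- if (is.na(s$mq[i])) "." else sprintf("MQ=%s", format(s$mq[i], digits = 15))
    gt <- character(0)
    if (length(vset$samples)) {
      g1 <- ifelse(is.na(vset$a1[i, ]), ".", vset$a1[i, ])
      g2 <- ifelse(is.na(vset$a2[i, ]), ".", vset$a2[i, ])
      gt <- c("GT", paste0(g1, "/", g2))
    }
    writeLines(paste(c(s$chrom[i], format(s$pos[i], scientific = FALSE),
                       ".", s$ref[i], s$alt[i], ".", ".", info, gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

# ---- BED intervals ---------------------------------------------------------

#' Read BED4 intervals
#'
#' BED is 0-based half-open; intervals are kept in that convention
#' internally. Overlapping intervals are preserved, not merged.
#'
#' @param path BED file (3 or 4 columns; the 4th is a label).
#' @return data frame with columns `chrom`, `start`, `end`, `label`.
#' @export
read_bed_intervals <- function(path) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), label = character(0),
                      stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "[ \t]+")
  if (any(lengths(parts) < 3L)) stop("read_bed_intervals: line with < 3 fields")
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    start = as.numeric(vapply(parts, `[`, "", 2L)),
    end = as.numeric(vapply(parts, `[`, "", 3L)),
    label = vapply(parts, function(p) if (length(p) >= 4L) p[4L] else "", ""),
    stringsAsFactors = FALSE)
  if (any(is.na(out$start)) || any(is.na(out$end)))
    stop("read_bed_intervals: non-numeric coordinates")
  if (any(out$end <= out$start))
    stop("read_bed_intervals: interval with end <= start")
  out
}

#' Write BED4 intervals
#' @param intervals data frame as returned by [read_bed_intervals()].
#' @param path output file.
#' @export
write_bed_intervals <- function(intervals, path) {
  check_columns(intervals, c("chrom", "start", "end"), "write_bed_intervals")
  label <- intervals$label %||% rep("", nrow(intervals))
  writeLines(sprintf("%s\t%d\t%d\t%s", intervals$chrom,
                     as.integer(intervals$start), as.integer(intervals$end),
                     label), path)
  invisible(path)
}

# ---- intensity / calls / manifest tables ----------------------------------

#' Read a two-channel intensity table
#'
#' Tab-separated with columns `sample_id`, `marker_id`, `X`, `Y`
#' (non-negative fluorescence units).
#'
#' @param path TSV file.
#' @return data frame of intensity records.
#' @export
read_intensity_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, c("sample_id", "marker_id", "X", "Y"), "read_intensity_tsv")
  if (any(df$X < 0) || any(df$Y < 0))
    stop("read_intensity_tsv: negative intensities")
  df
}

#' Write a two-channel intensity table
#' @param records data frame with `sample_id`, `marker_id`, `X`, `Y`.
#' @param path output TSV.
#' @export
write_intensity_tsv <- function(records, path) {
  check_columns(records, c("sample_id", "marker_id", "X", "Y"),
                "write_intensity_tsv")
  if (any(records$X < 0) || any(records$Y < 0))
    stop("write_intensity_tsv: negative intensities")
  rec <- records[, c("sample_id", "marker_id", "X", "Y")]
  rec$X <- format(rec$X, digits = 17, trim = TRUE, scientific = FALSE)
  rec$Y <- format(rec$Y, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype-call matrix
#'
#' Markers in rows, samples in columns; first column `marker_id`. Allowed
#' codes: `AA AB BB AAAA AAAB AABB ABBB BBBB NC`.
#'
#' @param path TSV file.
#' @return character matrix with marker rownames and sample colnames.
#' @export
read_calls_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, "marker_id", "read_calls_tsv")
  m <- as.matrix(df[, setdiff(names(df), "marker_id"), drop = FALSE])
  rownames(m) <- df$marker_id
  bad <- setdiff(unique(as.vector(m)), ALL_CALL_CODES)
  if (length(bad))
    stop("read_calls_tsv: unknown call code(s): ", paste(bad, collapse = ", "))
  m
}

#' Write a genotype-call matrix
#' @param calls character matrix (markers x samples) of call codes.
#' @param path output TSV.
#' @export
write_calls_tsv <- function(calls, path) {
  bad <- setdiff(unique(as.vector(calls)), ALL_CALL_CODES)
  if (length(bad))
    stop("write_calls_tsv: unknown call code(s): ", paste(bad, collapse = ", "))
  df <- data.frame(marker_id = rownames(calls), calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe manifest CSV
#'
#' Columns: `marker_id, chrom, pos, ref, alt, flank5, flank3, design_score,
#' category, ld_group_id, bin_id`. Marker ids must be unique and records
#' sorted by (chrom, pos).
#'
#' @param path CSV file.
#' @return a `probe_manifest` data frame.
#' @export
read_probe_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_probe_manifest(df)
}

#' Coerce a data frame to a probe manifest
#' @param df data frame with the manifest columns.
#' @return a `probe_manifest` data frame.
#' @export
as_probe_manifest <- function(df) {
  check_columns(df, c("marker_id", "chrom", "pos", "ref", "alt", "flank5",
                      "flank3", "design_score", "category", "ld_group_id",
                      "bin_id"), "probe_manifest")
  if (anyDuplicated(df$marker_id)) stop("probe_manifest: duplicate marker ids")
  ord <- order(match(df$chrom, unique(df$chrom)), df$pos)
  if (!identical(ord, seq_len(nrow(df))))
    stop("probe_manifest: records must be sorted by (chrom, pos)")
  rownames(df) <- NULL
  class(df) <- c("probe_manifest", "data.frame")
  df
}

#' Write a probe manifest CSV
#' @param manifest a `probe_manifest`.
#' @param path output CSV.
#' @export
write_probe_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
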