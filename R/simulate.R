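# Synthetic genomes, populations, crosses, intensities, dilution series.
#
# The generator is the desk-scale test bed standing in for population-scale
# re-sequencing data: founder-haplotype mosaics give block LD structure, a
# Beta MAF spectrum, optional homoeologous "shadow" loci give allotetraploid
# cluster blending, and a two-channel intensity model reproduces the theta/R
# cluster geometry the calling engine must handle.

#' Simulation configuration
#'
#' Defaults describe the package's stated desk-scale world (see the methods
#' vignette for the rationale behind each value). A fixed `seed` makes every
#' generator byte-reproducible; all child generators derive sub-seeds from it
#' via [derive_seed()].
#'
#' @param seed master integer seed.
#' @param n_chromosomes,chrom_length genome shape (lengths in bp).
#' @param n_samples number of diploid samples in the population.
#' @param site_density expected polymorphic sites per bp (default 1/kb,
#'   a desk-scale thinning of re-sequencing SNP density).
#' @param n_founders founder haplotypes per LD block.
#' @param maf_shape1,maf_shape2 Beta shape parameters; per-site ALT allele
#'   frequency is drawn as `rbeta(shape1, shape2) / 2`, giving a spectrum
#'   skewed toward rare alleles with support (0, 0.5].
#' @param block_length_mean mean LD block length in bp (exponential).
#' @param recomb_rate recombination rate per bp per meiosis.
#' @param homoeolog_fraction probability a marker has an interfering
#'   homoeologous locus on the other subgenome.
#' @param no_signal_fraction probability a marker's probe yields no signal
#'   (default 5445/42090, the rate observed on the real array).
#' @param signal_mean expected total intensity R of a full diploid signal;
#'   each allele copy contributes `signal_mean/2` to its channel.
#' @param noise_sd additive Gaussian channel noise (intensity units).
#' @param r_cv coefficient of variation of the shared multiplicative
#'   intensity noise (log-normal, common to both channels, so it perturbs R
#'   but cancels in theta).
#' @param background_mean mean background intensity per channel.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 2L, chrom_length = 5e5,
                       n_samples = 200L, site_density = 1e-3, n_founders = 8L,
                       maf_shape1 = 0.6, maf_shape2 = 1.4,
                       block_length_mean = 5e4, recomb_rate = 1e-8,
                       homoeolog_fraction = 0.3, no_signal_fraction = 5445 / 42090,
                       signal_mean = 2000, noise_sd = 20, r_cv = 0.1,
                       background_mean = 30) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length, n_samples = as.integer(n_samples),
              site_density = site_density, n_founders = as.integer(n_founders),
              maf_shape1 = maf_shape1, maf_shape2 = maf_shape2,
              block_length_mean = block_length_mean, recomb_rate = recomb_rate,
              homoeolog_fraction = homoeolog_fraction,
              no_signal_fraction = no_signal_fraction,
              signal_mean = signal_mean, noise_sd = noise_sd, r_cv = r_cv,
              background_mean = background_mean)
  stopifnot(cfg$n_chromosomes > 0, cfg$chrom_length > 0, cfg$n_samples > 0,
            cfg$site_density > 0, cfg$n_founders >= 2,
            cfg$block_length_mean > 0, cfg$recomb_rate >= 0,
            cfg$homoeolog_fraction >= 0, cfg$homoeolog_fraction <= 1,
            cfg$no_signal_fraction >= 0, cfg$no_signal_fraction <= 1,
            cfg$signal_mean > 0, cfg$noise_sd >= 0, cfg$r_cv >= 0,
            cfg$background_mean >= 0)
  class(cfg) <- "sim_config"
  cfg
}

# Random DNA sequence of length n as a character scalar.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a population with block LD structure
#'
#' Haplotypes are founder mosaics: each chromosome is cut into LD blocks
#' (exponential lengths), each block carries `n_founders` founder haplotypes
#' with per-site ALT frequencies from the configured Beta spectrum, and each
#' of the `2 * n_samples` sample haplotypes copies one founder per block.
#' Sites within a block are therefore in strong LD while sites in different
#' blocks are near-independent.
#'
#' @param config a [sim_config()].
#' @return list with elements `genome` (a [genome_index()] with sequence),
#'   `variants` (a [variant_set()]), `truth` (dosage matrix, homoeolog
#'   status, shadow dosages, no-signal flags) and `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    chroms <- sprintf("chr%02d", seq_len(config$n_chromosomes))
    lens <- stats::setNames(rep(config$chrom_length, config$n_chromosomes), chroms)
    seqs <- Biostrings::DNAStringSet(vapply(lens, random_dna, ""))
    names(seqs) <- chroms
    genome <- genome_index(lens, seq = seqs)

    nh <- 2L * config$n_samples
    samples <- sprintf("S%03d", seq_len(config$n_samples))
    site_list <- list(); hap_list <- list()
    for (ch in chroms) {
      L <- lens[[ch]]
      m <- max(1L, round(L * config$site_density))
      pos <- sort(sample.int(L, m))
      # LD block assignment along the chromosome
      n_blk_draw <- max(8L, ceiling(L / config$block_length_mean * 2))
      brk <- cumsum(stats::rexp(n_blk_draw, 1 / config$block_length_mean))
      while (length(brk) && max(brk) < L)
        brk <- c(brk, max(brk) + cumsum(stats::rexp(n_blk_draw,
                                                    1 / config$block_length_mean)))
      blk <- findInterval(pos, brk) + 1L
      n_blk <- max(blk)
      p_alt <- stats::rbeta(m, config$maf_shape1, config$maf_shape2) / 2
      founder <- matrix(stats::rbinom(config$n_founders * m, 1L,
                                      rep(p_alt, each = config$n_founders)),
                        nrow = config$n_founders)
      choice <- matrix(sample.int(config$n_founders, nh * n_blk, replace = TRUE),
                       nrow = nh)
      hap <- matrix(0L, nh, m)
      for (h in seq_len(nh))
        hap[h, ] <- founder[cbind(choice[h, blk], seq_len(m))]
      ref <- strsplit(genome_subseq(genome, ch, 1, L), "")[[1L]][pos]
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      site_list[[ch]] <- data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
                                    mq = round(pmax(0, pmin(60, stats::rnorm(m, 55, 10)))),
                                    stringsAsFactors = FALSE)
      hap_list[[ch]] <- hap
    }
    sites <- do.call(rbind, site_list)
    rownames(sites) <- NULL
    hap <- do.call(cbind, hap_list)
    a1 <- t(hap[seq(1L, nh, by = 2L), , drop = FALSE])
    a2 <- t(hap[seq(2L, nh, by = 2L), , drop = FALSE])
    colnames(a1) <- colnames(a2) <- samples
    vset <- variant_set(sites, a1, a2, samples)
    m_tot <- nrow(sites)
    homoeolog <- stats::runif(m_tot) < config$homoeolog_fraction
    p_shadow <- stats::rbeta(m_tot, config$maf_shape1, config$maf_shape2) / 2
    shadow <- matrix(stats::rbinom(m_tot * config$n_samples, 2L,
                                   rep(p_shadow, times = config$n_samples)),
                     nrow = m_tot)
    shadow[!homoeolog, ] <- NA_integer_
    colnames(shadow) <- samples
    no_signal <- stats::runif(m_tot) < config$no_signal_fraction
    marker_ids <- paste0(sites$chrom, "_", sites$pos)
    dosage <- a1 + a2
    dimnames(dosage) <- list(marker_ids, samples)
    rownames(shadow) <- marker_ids
    truth <- list(marker_id = marker_ids, dosage = dosage, homoeolog = homoeolog,
                  shadow_dosage = shadow, no_signal = no_signal,
                  p_alt_shadow = p_shadow)
    list(genome = genome, variants = vset, truth = truth, config = config)
  })
}

#' Assemble a truth object for intensity simulation
#'
#' @param dosage ALT-dosage matrix (markers x samples, values 0..2), with
#'   marker rownames and sample colnames.
#' @param homoeolog logical per marker; `FALSE` by default.
#' @param shadow_dosage dosage matrix of the interfering homoeologous locus
#'   (rows where `homoeolog` is `FALSE` are ignored).
#' @param no_signal logical per marker; probes that yield background only.
#' @return a truth list as consumed by [simulate_intensities()].
#' @export
as_truth <- function(dosage, homoeolog = NULL, shadow_dosage = NULL,
                     no_signal = NULL) {
  m <- nrow(dosage)
  list(marker_id = rownames(dosage) %||% sprintf("M%04d", seq_len(m)),
       dosage = dosage,
       homoeolog = homoeolog %||% rep(FALSE, m),
       shadow_dosage = shadow_dosage %||% matrix(NA_integer_, m, ncol(dosage)),
       no_signal = no_signal %||% rep(FALSE, m))
}

#' Simulate two-channel intensities from true dosages
#'
#' For a marker without homoeolog interference, `E[X]` is proportional to the
#' A-allele (REF) dose and `E[Y]` to the B-allele (ALT) dose out of 2; with
#' interference the channel signal is the sum over both subgenome loci, so
#' the total allele dose ranges 0-4 and up to five theta clusters appear.
#' Each channel gets `background_mean` plus additive Gaussian noise
#' (`noise_sd`), the signal part is scaled by a shared log-normal factor
#' (`r_cv`), and both channels are clipped at 0. No-signal markers emit
#' background only.
#'
#' @param truth a truth list ([as_truth()] or `simulate_population()$truth`).
#' @param config a [sim_config()].
#' @param seed optional seed override (defaults to a sub-seed of
#'   `config$seed`).
#' @return data frame of intensity records
#'   (`sample_id`, `marker_id`, `X`, `Y`).
#' @export
simulate_intensities <- function(truth, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% derive_seed(config$seed, 2L)
  with_seed(seed, {
    dos <- truth$dosage
    m <- nrow(dos); n <- ncol(dos)
    sh <- truth$shadow_dosage
    sh[is.na(sh)] <- 0L
    extra <- sh * rep(as.integer(truth$homoeolog), n)
    dose_b <- dos + extra
    ploidy <- matrix(rep(ifelse(truth$homoeolog, 4, 2), n), m, n)
    dose_a <- ploidy - dose_b
    gain <- config$signal_mean / 2
    base_x <- gain * dose_a
    base_y <- gain * dose_b
    base_x[truth$no_signal, ] <- 0
    base_y[truth$no_signal, ] <- 0
    fac <- if (config$r_cv > 0)
      matrix(exp(stats::rnorm(m * n, 0, config$r_cv)), m, n) else 1
    x <- pmax(0, base_x * fac + config$background_mean +
                stats::rnorm(m * n, 0, config$noise_sd))
    y <- pmax(0, base_y * fac + config$background_mean +
                stats::rnorm(m * n, 0, config$noise_sd))
    samples <- colnames(dos) %||% sprintf("S%03d", seq_len(n))
    data.frame(sample_id = rep(samples, each = m),
               marker_id = rep(truth$marker_id, times = n),
               X = as.vector(x), Y = as.vector(y),
               stringsAsFactors = FALSE)
  })
}

# ---- crosses ---------------------------------------------------------------

#' Marker map for cross simulation
#' @param chrom,pos chromosome and 1-based position per marker (sorted).
#' @param marker_id optional ids.
#' @return a data frame with attribute-free (chrom, pos, marker_id) columns.
#' @export
marker_map <- function(chrom, pos, marker_id = NULL) {
  ord <- order(match(chrom, unique(chrom)), pos)
  if (!identical(ord, seq_along(pos))) stop("marker_map: must be sorted")
  data.frame(chrom = chrom, pos = pos,
             marker_id = marker_id %||% paste0(chrom, "_", pos),
             stringsAsFactors = FALSE)
}

#' A diploid individual as two haplotypes over a marker map
#' @param h1,h2 integer 0/1 ALT-allele vectors.
#' @return an `individual` object.
#' @export
individual <- function(h1, h2) {
  stopifnot(length(h1) == length(h2), all(h1 %in% 0:1), all(h2 %in% 0:1))
  structure(list(h1 = as.integer(h1), h2 = as.integer(h2)), class = "individual")
}

#' Fully homozygous (inbred) individual
#' @param alleles integer 0/1 vector.
#' @export
inbred_individual <- function(alleles) individual(alleles, alleles)

# One gamete: recombine the two haplotypes of `ind` along `map`.
gamete <- function(ind, map, rate) {
  out <- integer(length(ind$h1))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos[idx]
    span <- max(pos)
    nx <- stats::rpois(1L, rate * span)
    cp <- if (nx > 0) sort(stats::runif(nx, 0, span)) else numeric(0)
    seg <- findInterval(pos, cp)
    use1 <- (seg + sample.int(2L, 1L)) %% 2L == 0L
    out[idx] <- ifelse(use1, ind$h1[idx], ind$h2[idx])
  }
  out
}

#' Simulate a biparental cross
#'
#' Supported schemes: `"F1"`, `"Fn"` (n generations of selfing from F1, e.g.
#' `"F2"`), and `"BCnF1"` (n backcrosses of the F1 toward the recurrent
#' parent `parents[[1]]`, e.g. `"BC2F1"`). Gametes are formed with Poisson
#' crossovers at `config$recomb_rate` per bp per meiosis; each offspring
#' descends through an independent lineage.
#'
#' @param parents list of two [individual()]s genotyped on `map`.
#' @param scheme scheme string (see above); unknown schemes are an error.
#' @param n_offspring number of offspring.
#' @param map a [marker_map()].
#' @param config a [sim_config()] (supplies `recomb_rate`).
#' @param seed integer seed (defaults to a sub-seed of `config$seed`).
#' @return list with `map`, `offspring` (list of [individual()]s) and
#'   `dosage` (ALT-dosage matrix, markers x offspring).
#' @export
simulate_cross <- function(parents, scheme, n_offspring, map, config,
                           seed = NULL) {
  stopifnot(length(parents) == 2L, inherits(parents[[1]], "individual"),
            inherits(parents[[2]], "individual"))
  seed <- seed %||% derive_seed(config$seed, 3L)
  rate <- config$recomb_rate
  mf <- regmatches(scheme, regexec("^F([0-9]+)$", scheme))[[1L]]
  mb <- regmatches(scheme, regexec("^BC([0-9]+)F1$", scheme))[[1L]]
  if (!length(mf) && !length(mb))
    stop("simulate_cross: unknown scheme '", scheme, "'")
  with_seed(seed, {
    offspring <- vector("list", n_offspring)
    for (i in seq_len(n_offspring)) {
      f1 <- individual(gamete(parents[[1]], map, rate),
                       gamete(parents[[2]], map, rate))
      cur <- f1
      if (length(mf)) {
        n_self <- as.integer(mf[2L]) - 1L
        for (k in seq_len(n_self))
          cur <- individual(gamete(cur, map, rate), gamete(cur, map, rate))
      } else {
        n_bc <- as.integer(mb[2L])
        for (k in seq_len(n_bc))
          cur <- individual(gamete(cur, map, rate),
                            gamete(parents[[1]], map, rate))
      }
      offspring[[i]] <- cur
    }
    dosage <- vapply(offspring, function(o) o$h1 + o$h2,
                     integer(nrow(map)))
    dosage <- matrix(dosage, nrow = nrow(map),
                     dimnames = list(map$marker_id,
                                     sprintf("O%04d", seq_len(n_offspring))))
    list(map = map, offspring = offspring, dosage = dosage)
  })
}

# ---- GMO dilution series ---------------------------------------------------

#' Simulate a transgene dilution series
#'
#' Mixtures of negative (non-transgenic) and positive DNA in ratios `d:1`
#' are assayed on a transgene probe whose signal channel scales with the
#' positive mixture fraction `1/(1+d)` of total DNA, plus background and the
#' configured noise. `d = 0` is pure positive DNA; negative controls have
#' zero positive fraction.
#'
#' @param ratios numeric vector of `d` values (`d >= 0`), e.g.
#'   `c(5, 10, 30, 50, 100)`.
#' @param n_replicates replicates per ratio and for the negative controls.
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to a sub-seed of `config$seed`).
#' @return a `mixture_series` object: per-ratio replicate signals and the
#'   negative-control signal distribution.
#' @export
simulate_gmo_dilution <- function(ratios = c(5, 10, 30, 50, 100),
                                  n_replicates = 24L, config, seed = NULL) {
  if (any(ratios < 0)) stop("simulate_gmo_dilution: negative ratio d")
  stopifnot(inherits(config, "sim_config"), n_replicates >= 1)
  seed <- seed %||% derive_seed(config$seed, 4L)
  one <- function(f, n) {
    fac <- if (config$r_cv > 0) exp(stats::rnorm(n, 0, config$r_cv)) else 1
    pmax(0, f * config$signal_mean * fac + config$background_mean +
           stats::rnorm(n, 0, config$noise_sd))
  }
  with_seed(seed, {
    signals <- lapply(ratios, function(d) one(1 / (1 + d), n_replicates))
    names(signals) <- as.character(ratios)
    structure(list(ratios = ratios, signals = signals,
                   negative = one(0, n_replicates), config = config),
              class = "mixture_series")
  })
}

#' @export
print.mixture_series <- function(x, ...) {
  cat("Transgene dilution series:", length(x$ratios), "ratio(s),",
      length(x$negative), "negative controls\n")
  for (i in seq_along(x$ratios))
    cat(sprintf("  %5s:1  mean signal %.1f\n", x$ratios[i],
                mean(x$signals[[i]])))
  invisible(x)
}
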