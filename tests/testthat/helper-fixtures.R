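# Fixtures built in code at test time (no binary files shipped).

# Random genome_index with sequence.
make_genome <- function(lengths, seed = 1L) {
  set.seed(seed)
  seqs <- Biostrings::DNAStringSet(vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), ""))
  names(seqs) <- names(lengths)
  genome_index(lengths, seq = seqs)
}

# Tiny variant set with explicit genotypes. `geno` is a list of "a/b"
# strings per site ("." for missing), one element per sample.
make_vset <- function(chrom, pos, ref, alt, geno, mq = 60,
                      samples = sprintf("s%02d", seq_along(geno[[1]]))) {
  parse1 <- function(g, which) {
    v <- strsplit(g, "/", fixed = TRUE)[[1L]][which]
    if (v == ".") NA_integer_ else as.integer(v)
  }
  a1 <- do.call(rbind, lapply(geno, function(gs)
    vapply(gs, parse1, 0L, which = 1L, USE.NAMES = FALSE)))
  a2 <- do.call(rbind, lapply(geno, function(gs)
    vapply(gs, parse1, 0L, which = 2L, USE.NAMES = FALSE)))
  dimnames(a1) <- dimnames(a2) <- list(NULL, samples)
  variant_set(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         mq = rep_len(mq, length(pos)),
                         stringsAsFactors = FALSE),
              a1, a2, samples)
}

# The 20-site re-sequencing filter fixture: 15 clean sites plus exactly one
# violator per cascade rule. 60 samples. Clean sites: 12 heterozygous
# carriers (MAF 0.1, carriers 12), MQ 60, spaced 900 bp apart, unique
# flanks on a random 20-kb chromosome.
#   V1 multi-allelic (rule 1), V2 MQ 20 (rule 2), V3 only 9 carriers
#   (rule 3), V4 placed 40 bp from V1 (rule 4, judged against all input
#   sites), V5 with its 101-bp context copied elsewhere (rule 5).
make_filter_fixture <- function(seed = 202L) {
  set.seed(seed)
  n_samp <- 60L
  L <- 20000L
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  slot_pos <- 600L + 900L * (0:18)                  # 19 slots, <= 16800
  v1_pos <- slot_pos[6L]
  v4_pos <- v1_pos + 40L
  pos <- sort(c(slot_pos, v4_pos))
  n <- length(pos)                                   # 20 sites
  roles <- rep("clean", n)
  roles[pos == v1_pos] <- "V1"
  roles[pos == slot_pos[9L]] <- "V2"
  roles[pos == slot_pos[12L]] <- "V3"
  roles[pos == v4_pos] <- "V4"
  v5_pos <- slot_pos[15L]
  roles[pos == v5_pos] <- "V5"
  # plant a copy of V5's probe context (10 bases mutated would also work;
  # exact copy used here) far from every site
  copy_at <- 18500L
  chars[copy_at:(copy_at + 100L)] <- chars[(v5_pos - 50L):(v5_pos + 50L)]
  genome <- genome_index(c(c1 = L),
                         seq = Biostrings::DNAStringSet(c(c1 = paste(chars, collapse = ""))))
  het <- function(k) c(rep("0/1", k), rep("0/0", n_samp - k))
  geno <- lapply(roles, function(r) switch(r,
    V1 = c(rep("0/1", 6L), rep("0/2", 6L), rep("0/0", n_samp - 12L)),
    V3 = het(9L),
    het(12L)))
  ref <- chars[pos]
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  alt[roles == "V1"] <- vapply(which(roles == "V1"), function(i)
    paste(sample(setdiff(c("A", "C", "G", "T"), ref[i]), 2L), collapse = ","), "")
  mq <- ifelse(roles == "V2", 20, 60)
  vset <- make_vset("c1", pos, ref, alt, geno, mq = mq)
  list(vset = vset, genome = genome, roles = roles,
       expected_survivors = which(roles == "clean"))
}

# Small default-world population shared by several tests.
make_small_pop <- function(seed = 31L, ...) {
  simulate_population(sim_config(seed = seed, n_chromosomes = 2L,
                                 chrom_length = 1e5, n_samples = 96L,
                                 site_density = 1e-3, ...))
}
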