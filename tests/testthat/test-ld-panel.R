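test_that("bin partition tiles chromosomes with a short last bin", {
  b <- partition_bins(c(c1 = 250000), 1e5)
  expect_identical(nrow(b), 3L)
  expect_equal(b$end[3L] - b$start[3L], 50000)
  expect_identical(nrow(partition_bins(c(c1 = 200000), 1e5)), 2L)
  # half-open convention: 0-based 99,999 is bin 1; 100,000 is bin 2
  expect_identical(bin_of("c1", 100000), "c1:000000")
  expect_identical(bin_of("c1", 100001), "c1:000001")
  # bins tile without overlap
  b2 <- partition_bins(c(a = 350000, b = 120000), 1e5)
  for (ch in c("a", "b")) {
    x <- b2[b2$chrom == ch, ]
    expect_identical(x$start[-1L], x$end[-nrow(x)])
  }
})

test_that("r_squared matches the brute-force dosage correlation", {
  expect_equal(r_squared(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(r_squared(c(0, 0, 2, 2), c(2, 2, 0, 0)), 1)  # sign squares away
  set.seed(10)
  for (k in 1:50) {
    a <- sample(0:2, 100L, replace = TRUE)
    b <- sample(0:2, 100L, replace = TRUE)
    a[sample(100L, 5L)] <- NA
    expect_equal(r_squared(a, b), r2_brute(a, b), tolerance = 1e-12)
    # symmetry and allele-label swap invariance
    expect_equal(r_squared(a, b), r_squared(b, a), tolerance = 1e-14)
    expect_equal(r_squared(2 - a, b), r_squared(a, b), tolerance = 1e-12)
  }
  expect_error(r_squared(c(1, 1, 1), c(0, 1, 2)), "zero variance")
  expect_error(r_squared(c(1, NA, NA), c(0, 1, 2)), "fewer than 2")
})

test_that("greedy LD grouping partitions a bin as hand-traced", {
  # all pairs above threshold -> one group
  d <- matrix(rep(c(0, 0, 2, 2, 1, 1), 3L), 3, byrow = TRUE)
  g <- greedy_ld_group(d, maf = c(0.5, 0.4, 0.3), pos = 1:3)
  expect_identical(g$group_id, rep(1L, 3L))
  # all pairs below threshold -> singletons
  set.seed(2)
  d2 <- rbind(c(0, 2, 0, 2, 0, 2, 1, 1), c(2, 0, 0, 1, 2, 0, 0, 2),
              c(1, 1, 2, 0, 0, 2, 2, 0))
  stopifnot(r_squared(d2[1, ], d2[2, ]) < 0.65,
            r_squared(d2[1, ], d2[3, ]) < 0.65,
            r_squared(d2[2, ], d2[3, ]) < 0.65)
  g2 <- greedy_ld_group(d2, maf = c(0.5, 0.4, 0.3), pos = 1:3)
  expect_identical(sort(unique(g2$group_id)), 1:3)
  # hand trace: r2(1,2) and r2(2,3) above, r2(1,3) below, MAF 1 > 2 > 3
  d3 <- rbind(c(2, 2, 2, 2, 2, 0, 0, 0, 0, 0),
              c(2, 2, 2, 2, 1, 0, 0, 0, 0, 0),
              c(2, 2, 2, 1, 0, 0, 0, 0, 0, 0))
  expect_gt(r_squared(d3[1, ], d3[2, ]), 0.65)
  expect_gt(r_squared(d3[2, ], d3[3, ]), 0.65)
  expect_lt(r_squared(d3[1, ], d3[3, ]), 0.65)
  g3 <- greedy_ld_group(d3, maf = c(0.5, 0.45, 0.35), pos = 1:3,
                        site_id = c("s1", "s2", "s3"))
  expect_identical(g3$group_id, c(1L, 1L, 2L))        # {s1, s2}, {s3}
  expect_identical(g3$rep_id, c("s1", "s1", "s3"))
  # and the greedy answer is a valid star partition under enumeration
  valid <- valid_star_partitions(d3, 0.65)
  norm <- function(z) match(z, unique(z))
  expect_true(any(vapply(valid, function(z)
    identical(norm(z), norm(g3$group_id)), TRUE)))
})

test_that("grouping on simulated bins is a partition with rep r2 >= 0.65", {
  pop <- make_small_pop(seed = 19L)
  v <- pop$variants
  cand <- data.frame(site_id = pop$truth$marker_id, chrom = v$sites$chrom,
                     pos = v$sites$pos, maf = minor_allele_frequency(v),
                     stringsAsFactors = FALSE)
  dos <- alt_dosage(v)
  cand <- ld_group_bins(cand, dos, bin_size = 2e4, threshold = 0.65)
  expect_false(any(is.na(cand$ld_group_id)))          # partition: all assigned
  for (gid in unique(cand$ld_group_id)) {
    idx <- which(cand$ld_group_id == gid)
    rep_i <- idx[cand$ld_representative[idx]]
    expect_length(rep_i, 1L)                          # exactly one representative
    expect_true(all(cand$bin_id[idx] == cand$bin_id[rep_i]))
    for (i in setdiff(idx, rep_i)) {
      expect_gte(r_squared(dos[i, ], dos[rep_i, ]), 0.65)
    }
  }
})

test_that("design-score surrogate follows the documented arithmetic", {
  balanced <- paste(rep(c("A", "C", "G", "T"), length.out = 101), collapse = "")
  expect_equal(design_score_surrogate(substr(balanced, 1, 50), "A",
                                      substr(balanced, 52, 101)), 1)
  # poly-A: GC out of range and 16 non-overlapping 6-bp blocks -> floor 0
  expect_equal(design_score_surrogate(strrep("A", 50), "A", strrep("A", 50)), 0)
  # one 6-bp run at GC 0.5 -> 0.8
  s <- paste(rep(c("A", "C", "G", "T"), length.out = 95), collapse = "")
  one_run <- paste0("GGGGGG", s)   # 101-mer, single 6-bp run
  expect_equal(design_score_surrogate(substr(one_run, 1, 50),
                                      substr(one_run, 51, 51),
                                      substr(one_run, 52, 101)), 0.8)
  # ambiguity characters cost 0.5
  expect_equal(design_score_surrogate(substr(balanced, 1, 50), "N",
                                      substr(balanced, 52, 101)), 0.5)
})

test_that("panel selection ranks by MAF within score-eligible groups", {
  bins <- partition_bins(c(c1 = 1e5), 1e5)
  cand <- data.frame(site_id = sprintf("s%d", 1:6), chrom = "c1",
                     pos = seq(10000, 60000, by = 10000),
                     ref = "A", alt = "G",
                     maf = seq(0.45, 0.20, by = -0.05), design_score = 0.9,
                     bin_id = "c1:000000",
                     ld_group_id = sprintf("g%d", 1:6),
                     stringsAsFactors = FALSE)
  man <- select_panel(cand, bins)
  expect_identical(sort(man$marker_id), sprintf("s%d", 1:5))  # top-5 MAF
  # all six in one LD group: group exhaustion leaves a single probe
  cand1 <- cand; cand1$ld_group_id <- "g1"
  man1 <- select_panel(cand1, bins)
  expect_identical(man1$marker_id, "s1")
})

test_that("three-bin QTL-boosted selection reproduces the manual trace", {
  bins <- partition_bins(c(c1 = 3e5), 1e5)
  qtl <- data.frame(chrom = "c1", start = 250000, end = 260000,
                    label = "q1", stringsAsFactors = FALSE)
  cand <- rbind(
    # bin 1 (not boosted): 6 candidates in 4 groups, one score-ineligible
    data.frame(site_id = sprintf("A%d", 1:6), pos = seq(10000, 60000, 1e4),
               maf = c(.45, .40, .35, .30, .25, .20),
               design_score = c(.9, .9, .9, .5, .9, .9),
               ld_group_id = c("g1", "g1", "g2", "g3", "g3", "g4")),
    # bin 2 (boosted): 3 candidates in one group -> reuse up to target 3
    data.frame(site_id = sprintf("B%d", 1:3), pos = c(150000, 150500, 151000),
               maf = c(.30, .28, .26), design_score = .9, ld_group_id = "g5"),
    # bin 3 (boosted): 4 candidates in 3 groups -> target 3, one per group
    data.frame(site_id = sprintf("C%d", 1:4), pos = seq(210000, 240000, 1e4),
               maf = c(.50, .45, .40, .35), design_score = .9,
               ld_group_id = c("g6", "g7", "g8", "g6")))
  cand$chrom <- "c1"; cand$ref <- "A"; cand$alt <- "G"
  cand$bin_id <- bin_of(cand$chrom, cand$pos)
  man <- select_panel(cand, bins, qtl)
  expect_identical(man$marker_id,
                   c("A1", "A3", "A5", "A6", "B1", "B2", "B3",
                     "C1", "C2", "C3"))
  expect_identical(unique(man$category[man$bin_id == "c1:000000"]),
                   "background")
  expect_identical(unique(man$category[man$bin_id != "c1:000000"]),
                   "qtl_boosted")
  val <- validate_panel(man, cand)
  expect_true(val$ok)
})

test_that("panel validation catches each violation independently", {
  bins <- partition_bins(c(c1 = 1e5), 1e5)
  man <- data.frame(marker_id = c("s1", "s2"), chrom = "c1",
                    pos = c(1000, 5000), ref = "A", alt = "G",
                    flank5 = NA, flank3 = NA, design_score = c(0.9, 0.9),
                    category = "background",
                    ld_group_id = c("g1", "g2"), bin_id = "c1:000000",
                    stringsAsFactors = FALSE)
  ok <- validate_panel(as_probe_manifest(man))
  expect_true(ok$ok)
  bad_score <- man; bad_score$design_score[1L] <- 0.4
  expect_false(validate_panel(as_probe_manifest(bad_score))$checks[["score_threshold"]])
  bad_sp <- man; bad_sp$pos[2L] <- 1100
  expect_false(validate_panel(as_probe_manifest(bad_sp))$checks[["spacing"]])
})

test_that("panel gap statistics", {
  man <- as_probe_manifest(data.frame(
    marker_id = c("a", "b", "c"), chrom = "c1", pos = c(1, 10001, 20001),
    ref = "A", alt = "G", flank5 = NA, flank3 = NA, design_score = 1,
    category = "background", ld_group_id = c("g1", "g2", "g3"),
    bin_id = "x", stringsAsFactors = FALSE))
  ps <- panel_stats(man, c(c1 = 1e6))
  expect_equal(ps$mean_gap, 10000)
  expect_equal(ps$frac_gap_gt, 0)
  man2 <- man[1:2, ]; man2$pos <- c(1, 150001)
  ps2 <- panel_stats(as_probe_manifest(man2), c(c1 = 1e6))
  expect_equal(ps2$frac_gap_gt, 1)
  # independent recomputation from the manifest of a simulated design
  pop <- make_small_pop(seed = 23L)
  v <- pop$variants
  cand <- data.frame(site_id = pop$truth$marker_id, chrom = v$sites$chrom,
                     pos = v$sites$pos, ref = v$sites$ref, alt = v$sites$alt,
                     maf = minor_allele_frequency(v), stringsAsFactors = FALSE)
  cand <- ld_group_bins(cand, alt_dosage(v), bin_size = 2e4)
  cand$bin_id <- bin_of(cand$chrom, cand$pos, 2e4)
  cand$design_score <- 1
  man3 <- select_panel(cand, partition_bins(pop$genome$lengths, 2e4),
                       params = selection_params(bin_size = 2e4))
  ps3 <- panel_stats(man3, pop$genome)
  gaps <- unlist(lapply(split(man3$pos, man3$chrom), function(p) diff(sort(p))))
  expect_equal(ps3$mean_gap, mean(gaps))
  expect_equal(ps3$frac_gap_gt, mean(gaps > 1e5))
})
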