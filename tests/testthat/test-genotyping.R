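test_that("theta/R transform follows the Infinium convention", {
  expect_equal(theta_r(5, 5)$theta, 0.5)
  expect_equal(theta_r(7, 0)$theta, 0)
  expect_equal(theta_r(0, 7)$theta, 1)
  expect_equal(theta_r(3, 4)$r, 7)
  expect_true(is.na(theta_r(0, 0)$theta))
  expect_error(theta_r(-1, 2), "negative")
  # theta monotone increasing in Y at fixed X
  set.seed(3)
  x <- runif(50, 1, 100)
  y <- sort(runif(50, 0, 100))
  expect_true(all(diff(theta_r(rep(10, 50), y)$theta) >= 0))
  # dosage grid: symmetric points at g/p, intermediates on the arctan grid
  expect_equal(dosage_theta(0:2, 2), c(0, 0.5, 1))
  expect_equal(dosage_theta(0:4, 4),
               c(0, (2 / pi) * atan(1 / 3), 0.5, (2 / pi) * atan(3), 1))
})

test_that("cluster fitting recovers k in the noise-free limit", {
  th3 <- rep(c(0, 0.5, 1), each = 20L)
  m3 <- fit_cluster_model(th3, rep(2000, 60L))
  expect_identical(m3$k, 3L)
  expect_identical(m3$calls, c("AA", "AB", "BB"))
  expect_identical(m3$class, "polymorphic_3")
  th5 <- rep(dosage_theta(0:4, 4), each = 12L)
  m5 <- fit_cluster_model(th5, rep(4000, 60L))
  expect_identical(m5$k, 5L)
  expect_identical(m5$calls, c("AAAA", "AAAB", "AABB", "ABBB", "BBBB"))
  expect_identical(m5$class, "intergenomic_5")
  m1 <- fit_cluster_model(rep(0.5, 20L), rep(2000, 20L))
  expect_identical(m1$k, 1L)
  expect_identical(m1$class, "monomorphic")
  # cluster theta means strictly increasing, call map in theta order
  expect_true(all(diff(m5$means) > 0))
  expect_identical(m5$calls, sort(m5$calls))
  expect_error(fit_cluster_model(rep(0.5, 5L), rep(1, 5L)), "10 samples")
})

test_that("cluster separation follows the envelope formula", {
  m <- list(means = c(0.2, 0.8), sds = c(0.01, 0.01))
  expect_equal(cluster_separation(m), 0.56)
  m2 <- list(means = c(0.45, 0.55), sds = c(0.05, 0.05))
  expect_equal(cluster_separation(m2), 0)          # overlapping envelopes
  expect_equal(cluster_separation(list(means = 0.5, sds = 0.01)), 1)
  # monotone decreasing in sd
  seps <- vapply(c(0.005, 0.01, 0.02, 0.05), function(s)
    cluster_separation(list(means = c(0.2, 0.8), sds = c(s, s))), 0)
  expect_true(all(diff(seps) < 0))
})

test_that("marker classification rules", {
  m1 <- fit_cluster_model(rep(0.3, 30L), rep(2000, 30L))
  expect_identical(classify_marker(m1)$class, "monomorphic")
  th5 <- rep(dosage_theta(0:4, 4), each = 10L)
  expect_identical(classify_marker(fit_cluster_model(th5, rep(4e3, 50L)))$class,
                   "intergenomic_5")
  # colliding call map (clusters at 0 and 0.205 both round to AA) is
  # the "cannot distinguish heterozygote" bucket
  thc <- rep(c(0, dosage_theta(1, 4)), each = 15L) + 1e-9
  mc <- fit_cluster_model(thc, rep(2000, 30L))
  expect_identical(mc$class, "unclassifiable")
  # all samples below background -> no_signal
  mns <- fit_cluster_model(runif(20), rep(5, 20L), r_background = 100)
  expect_identical(mns$class, "no_signal")
})

test_that("calling assigns nearest cluster with a 3-sd no-call guard", {
  th <- rep(c(0, 0.5, 1), each = 10L)
  m <- fit_cluster_model(th, rep(2000, 30L))
  expect_identical(predict(m, data.frame(theta = m$means, r = rep(2000, 3))),
                   c("AA", "AB", "BB"))
  # midway between two well-separated clusters -> NC
  expect_identical(predict(m, data.frame(theta = 0.25, r = 2000)), "NC")
  # below background -> NC
  m2 <- fit_cluster_model(th, rep(2000, 30L), r_background = 50)
  expect_identical(predict(m2, data.frame(theta = 0, r = 10)), "NC")
})

test_that("cluster-file build: conservation, determinism, no-signal input", {
  # every marker no-signal -> empty retained set, audit equals input count
  cfg0 <- sim_config(seed = 14L)
  dos <- matrix(rep(0:2, 48L), 12, 12)
  rownames(dos) <- sprintf("m%02d", 1:12)
  ints0 <- simulate_intensities(as_truth(dos, no_signal = rep(TRUE, 12L)),
                                cfg0)
  cf0 <- build_cluster_file(ints0)
  expect_identical(length(cf0$models), 0L)
  # all 12 removed; background-ratio noise lands in the no-signal or
  # poor-genotyping bucket depending on its accidental theta shape
  expect_identical(unname(cf0$audit["n_no_signal"] + cf0$audit["n_poor"]), 12L)
  expect_gt(unname(cf0$audit["n_no_signal"]), 0L)
  # conservation on a mixed simulated panel
  pop <- make_small_pop(seed = 63L)
  ints <- simulate_intensities(pop$truth, pop$config)
  cf <- build_cluster_file(ints)
  expect_identical(unname(cf$audit["n_retained"]),
                   unname(cf$audit["n_input"] - cf$audit["n_no_signal"] -
                            cf$audit["n_poor"]))
  expect_identical(unname(cf$audit["n_input"]), n_sites(pop$variants))
  # byte-identical cluster file across rebuilds
  f1 <- tempfile(); f2 <- tempfile()
  write_cluster_file(cf, f1)
  write_cluster_file(build_cluster_file(ints), f2)
  expect_identical(readLines(f1), readLines(f2))
  # call-map order invariant: A dosage non-increasing as theta grows
  for (m in cf$models) {
    a_dose <- vapply(m$calls, function(cd)
      sum(strsplit(cd, "")[[1L]] == "A"), 0L)
    expect_true(all(diff(a_dose) <= 0))
    expect_true(all(diff(m$means) > 0))
  }
})

test_that("classification and calls match truth in the default-noise world", {
  pop <- make_small_pop(seed = 99L)
  ints <- simulate_intensities(pop$truth, pop$config)
  cf <- build_cluster_file(ints)
  expected <- vapply(seq_len(n_sites(pop$variants)), function(i)
    truth_expected_class(pop$truth, i), "")
  got <- cf$classes[pop$truth$marker_id]
  expect_gte(mean(got == expected), 0.95)
  # noise-free limit: 100% correct calls
  cfg0 <- sim_config(seed = 99L, noise_sd = 0, r_cv = 0, background_mean = 0)
  ints0 <- simulate_intensities(pop$truth, cfg0)
  cf0 <- build_cluster_file(ints0)
  calls0 <- suppressWarnings(call_genotypes(ints0, cf0))
  poly <- which(expected == "polymorphic_3" & !pop$truth$homoeolog |
                  expected == "intergenomic_5")
  tc <- truth_calls(pop$truth, poly)
  expect_equal(mean(calls0[pop$truth$marker_id[poly], ] == tc), 1)
})

test_that("F1 trio consistency and concordance bookkeeping", {
  p1 <- c(m1 = "AA", m2 = "AA", m3 = "AB", m4 = "BB")
  p2 <- c(m1 = "BB", m2 = "BB", m3 = "AA", m4 = "BB")
  f1 <- c(m1 = "AB", m2 = "AA", m3 = "AB", m4 = "BB")
  chk <- f1_consistency_check(p1, p2, f1)
  expect_identical(chk$n_informative, 2L)        # m1 and m2
  expect_equal(chk$fraction_ok, 0.5)             # m2 violates
  expect_true(chk$verdicts$ok[1L])
  expect_false(chk$verdicts$ok[2L])
  # identical matrices -> zero discordance
  calls <- matrix(c("AA", "AB", "BB", "NC"), 4, 2,
                  dimnames = list(sprintf("m%d", 1:4), c("a", "b")))
  cc <- concordance(calls, calls)
  expect_identical(cc$n_discordant, 0L)
  expect_equal(cc$percent, 0)
  # NC in either set is not compared
  calls2 <- calls; calls2[4L, 1L] <- "AA"
  expect_identical(concordance(calls, calls2)$n_discordant, 0L)
  expect_error(concordance(calls, calls[, 1L]), "dimensions")
})

test_that("simulated trio is Mendel-consistent at default noise", {
  cfg <- sim_config(seed = 120L, n_chromosomes = 1L, chrom_length = 1e5,
                    n_samples = 60L, homoeolog_fraction = 0,
                    no_signal_fraction = 0)
  pop <- simulate_population(cfg)
  ints <- simulate_intensities(pop$truth, cfg)
  cf <- build_cluster_file(ints)
  m <- n_sites(pop$variants)
  trio_dos <- cbind(P1 = rep(0L, m), P2 = rep(2L, m),
                    F1 = rep(1L, m))
  rownames(trio_dos) <- pop$truth$marker_id
  trio_ints <- simulate_intensities(as_truth(trio_dos), cfg,
                                    seed = derive_seed(120L, 9L))
  calls <- call_genotypes(trio_ints, cf)
  retained <- intersect(rownames(calls), names(cf$models))
  chk <- f1_consistency_check(calls[retained, "P1"], calls[retained, "P2"],
                              calls[retained, "F1"])
  expect_gt(chk$n_informative, 20L)
  expect_gte(chk$fraction_ok, 0.99)
})

test_that("cluster-model methods: simulate round trip and plot", {
  th <- rep(c(0, 0.5, 1), each = 20L)
  m <- fit_cluster_model(th, rep(2000, 60L), marker_id = "mk")
  sim <- simulate(m, nsim = 300L, seed = 5L)
  expect_identical(nrow(sim), 300L)
  pr <- predict(m, sim)
  # draws beyond the 3-sd guard become NC; the rest match their cluster
  expect_identical(pr[pr != "NC"], m$calls[sim$cluster][pr != "NC"])
  expect_gt(mean(pr == m$calls[sim$cluster]), 0.98)
  f <- tempfile(fileext = ".pdf")
  grDevices::pdf(f); plot(m); grDevices::dev.off()
  expect_true(file.exists(f))
  expect_output(print(m), "polymorphic_3")
})
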