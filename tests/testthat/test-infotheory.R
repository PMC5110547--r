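test_that("small-sample correction matches the composition-enumeration oracle", {
  for (n in c(1L, 2L, 4L, 9L, 12L)) {
    got <- small_sample_correction(n, "exact")
    want <- enum_correction(n)
    expect_equal(got$e_n, want$e_n, tolerance = 1e-10)
    expect_equal(got$var_H, want$var_H, tolerance = 1e-10)
  }
  # n = 1: plug-in entropy is identically 0, so the bias is the full 2 bits
  expect_equal(small_sample_correction(1L)$e_n, 2)
  expect_equal(small_sample_correction(1L)$var_H, 0)
  expect_error(small_sample_correction(0L))
})

test_that("correction decreases in n, vanishes asymptotically, tracks the 3/(2 ln2 n) rate", {
  e <- vapply(1:30, function(n) small_sample_correction(n, "exact")$e_n, 0)
  expect_true(all(diff(e) < 0))
  for (n in c(20L, 50L, 200L, 1000L)) {
    exact <- small_sample_correction(n, "exact")$e_n
    approx <- small_sample_correction(n, "approximation")$e_n
    expect_lt(abs(exact - approx) / exact, 0.15)
  }
  expect_lt(small_sample_correction(1e6L)$e_n, 1e-5)
  expect_equal(small_sample_correction(1e6L)$method, "approximation")
})

test_that("per-position information handles conserved and uniform columns", {
  e4 <- small_sample_correction(4L)$e_n
  conserved <- information_summary(freq_matrix(c("A", "A", "A", "A")))
  expect_equal(conserved$r, 2 - e4, tolerance = 1e-12)
  uniform <- information_summary(freq_matrix(c("A", "C", "G", "T")))
  expect_equal(uniform$r, -e4, tolerance = 1e-12)  # slightly negative, allowed
  expect_lt(uniform$Rsequence, 0)
})

test_that("Rsequence is the sum of positionwise information", {
  sites <- random_dna(9, 42, seed = 31)
  fm <- freq_matrix(sites)
  info <- information_summary(fm)
  expect_equal(info$Rsequence, sum(info$r), tolerance = 1e-12)
  expect_equal(info$L, 42L)
  expect_equal(info$sigma_Rsequence,
               sqrt(42 * small_sample_correction(9L)$var_H), tolerance = 1e-12)
})

test_that("rfrequency reproduces the canonical genome-scale values", {
  expect_equal(round(rfrequency(4641652, 9), 2), 18.98)
  expect_equal(round(rfrequency(4641652, 60), 2), 16.24)
  expect_equal(rfrequency(1024, 1024), 0)
  expect_error(rfrequency(100, 0))
  expect_error(rfrequency(5, 9))
})

test_that("predicted site counts invert rfrequency and propagate uncertainty", {
  p <- predict_site_count(4641652, 16.1, 0.7)
  expect_equal(round(p$gamma_predicted), 66)
  expect_equal(round(p$sigma_gamma), 32)
  # exact inverse when sigma = 0
  g <- 37
  rs <- rfrequency(4641652, g)
  expect_equal(predict_site_count(4641652, rs)$gamma_predicted, g,
               tolerance = 1e-9)
  p2 <- predict_site_count(1024, 10, 0)
  expect_equal(p2$gamma_predicted, 1.0)
  expect_equal(p2$sigma_gamma, 0)
})

test_that("weight-matrix entries follow 2 + log2 f* - e(n)", {
  sites <- c("AC", "AC", "AC", "AC", "AC", "AC", "AC", "AC", "AG")
  fm <- freq_matrix(sites)
  corr <- small_sample_correction(9L)
  riw <- build_riw(fm, corr)
  # fully conserved column: w = 2 - e(9); unseen bases -> -Inf sentinel
  expect_equal(unname(riw$w["A", 1]), 2 - corr$e_n, tolerance = 1e-12)
  expect_equal(unname(riw$w["C", 1]), -Inf)
  # f = 8/9 column
  expect_equal(unname(riw$w["C", 2]), 2 + log2(8 / 9) - corr$e_n, tolerance = 1e-12)
  # half-frequency column gives w = 1 - e(n)
  half <- build_riw(freq_matrix(c("A", "A", "C", "C")))
  expect_equal(unname(half$w["A", 1]), 1 - small_sample_correction(4L)$e_n,
               tolerance = 1e-12)
  # jeffreys pseudocounts keep every weight finite
  riw_j <- build_riw(fm, corr, pseudocount = "jeffreys")
  expect_true(all(is.finite(riw_j$w)))
})

test_that("mean individual information of the training sites equals Rsequence", {
  for (seed in c(41, 42, 43)) {
    sites <- random_dna(12, 18, seed = seed)
    fm <- freq_matrix(sites)
    corr <- small_sample_correction(fm$n)
    info <- information_summary(fm, corr)
    riw <- build_riw(fm, corr)
    expect_equal(mean(individual_information(riw, sites)), info$Rsequence,
                 tolerance = 1e-9)
  }
})

test_that("identical training sites score L*(2 - e(n)) and N windows are rejected", {
  sites <- rep("ACGTACGT", 5)
  riw <- build_riw(freq_matrix(sites))
  e5 <- small_sample_correction(5L)$e_n
  expect_equal(individual_information(riw, "ACGTACGT"), 8 * (2 - e5),
               tolerance = 1e-12)
  expect_true(is.na(individual_information(riw, "ACGTACGN")))
  expect_error(individual_information(riw, "ACGT"), "length")
  # any non-training base hits the -Inf sentinel
  expect_equal(individual_information(riw, "CCGTACGT"), -Inf)
})

test_that("weight-matrix genome scan matches the naive oracle and recovers plants", {
  train <- random_dna(8, 20, seed = 51)
  fm <- freq_matrix(train)
  corr <- small_sample_correction(fm$n)
  riw <- build_riw(fm, corr, pseudocount = "jeffreys")
  g <- synth_genome(2000, planted = data.frame(sequence = train[1],
                                               position = 501),
                    seed = 52)$genome
  thr <- stats::quantile(individual_information(riw, train), 0.1)
  hits <- scan_riw(g, riw, thr)
  oracle <- naive_scan_riw(g, riw, thr)
  expect_equal(hits$start, oracle$start)
  expect_equal(hits$ri_plus[hits$strands %in% c("+", "+/-")],
               oracle$ri_plus[oracle$on_plus], tolerance = 1e-9)
  # the planted training site is reported with its alignment score
  expect_true(501 %in% hits$start)
  expect_equal(hits$ri[hits$start == 501],
               unname(individual_information(riw, train[1])), tolerance = 1e-9)
})

test_that("a threshold above the achievable maximum yields no sites", {
  train <- random_dna(6, 15, seed = 61)
  riw <- build_riw(freq_matrix(train), pseudocount = "jeffreys")
  max_ri <- sum(apply(riw$w, 2, max))
  g <- synth_genome(3000, seed = 62)$genome
  expect_equal(nrow(scan_riw(g, riw, max_ri)), 0L)
  expect_gt(nrow(scan_riw(g, riw, -Inf)), 0L)
})

test_that("parameter recovery: 50 resampled sites rebuild Rsequence within 2 SE", {
  # sharp generator: consensus-dominated 50-sequence matrix
  founders <- c(rep("GTGAAAACGATTACAC", 40),
                "GTGTAATCGCTTACAC", "CTGAAACCGATTACAC", "GTGCACCGGATTTCAC",
                "TTGAAAGCGGTTACAT", "GTGGAATCGTTTACAC", "ATGTAAGCGTTTACCC",
                "GGGAAACCGTTGCCAC", "GTGAAAGCGGTCGAAC", "GTGTAAGCGATTACAC",
                "GTGAAAACGATTACAG")
  fm0 <- freq_matrix(founders)
  corr0 <- small_sample_correction(fm0$n)
  info0 <- information_summary(fm0, corr0)
  sem0 <- rsequence_se_sites(build_riw(fm0, corr0, pseudocount = "jeffreys"),
                             founders)
  for (seed in c(71L, 72L, 73L)) {
    sites <- sample_sites(fm0, 50, seed = seed)
    fm1 <- freq_matrix(sites)
    corr1 <- small_sample_correction(fm1$n)
    info1 <- information_summary(fm1, corr1)
    sem1 <- rsequence_se_sites(build_riw(fm1, corr1, pseudocount = "jeffreys"),
                               sites)
    expect_lt(abs(info1$Rsequence - info0$Rsequence), 2 * (sem0 + sem1))
  }
})

test_that("logo table carries stack heights and the helical-face cosine", {
  sites <- c("AAC", "AAG", "AAT", "ACA")
  fm <- freq_matrix(sites)
  info <- information_summary(fm)
  lt <- logo_table(fm, info, left_offset = 1L, amplitude = 2)
  expect_equal(lt$coord, c(-1L, 0L, 1L))
  # fully conserved position: single letter of height r
  expect_equal(lt$height_A[1], info$r[1], tolerance = 1e-12)
  expect_equal(lt$height_C[1] + lt$height_G[1] + lt$height_T[1], 0)
  # cosine overlay: amplitude at coordinate 0, ~ -amplitude half a turn away
  expect_equal(lt$sine[2], 2)
  expect_equal(2 * cos(2 * pi * 5.3 / 10.6), -2, tolerance = 1e-12)
  # negative-information stacks are suppressed to zero
  uni <- information_summary(freq_matrix(c("A", "C", "G", "T")))
  lt2 <- logo_table(freq_matrix(c("A", "C", "G", "T")), uni, left_offset = 0L)
  expect_equal(lt2$height_A + lt2$height_C + lt2$height_G + lt2$height_T, 0)
})

test_that("information models survive a JSON round-trip", {
  sites <- random_dna(9, 42, seed = 81)
  fm <- freq_matrix(sites)
  corr <- small_sample_correction(9L)
  path <- withr::local_tempfile(fileext = ".json")
  write_info_model(fm, corr, path)
  back <- read_info_model(path)
  expect_equal(back$freq$counts, fm$counts)
  expect_equal(back$freq$n, 9L)
  expect_equal(back$correction$e_n, corr$e_n, tolerance = 1e-12)
  expect_equal(back$left_offset, 20L)
  riw_a <- build_riw(fm, corr)
  riw_b <- build_riw(back$freq, back$correction)
  expect_equal(riw_a$w, riw_b$w)
})

test_that("aligned_sites extracts one window per operator, symmetrize doubles n", {
  g <- synth_genome(4000, seed = 91)$genome
  ops <- data.frame(start = c(1001L, 2001L, 3001L),
                    end = c(1016L, 2016L, 3016L),
                    strand = c("+", "-", "+"),
                    name = c("a", "b", "c"))
  w <- aligned_sites(g, ops)
  expect_length(w, 3L)
  expect_true(all(nchar(w) == 42L))
  expect_equal(names(w), c("a", "b", "c"))
  ws <- aligned_sites(g, ops, symmetrize = TRUE)
  expect_length(ws, 6L)
  expect_equal(unname(ws[4:6]), unname(revcomp(w)))
})
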