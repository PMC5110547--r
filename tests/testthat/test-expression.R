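toy_annotation <- data.frame(
  gene = c("gA", "gB"), seq_id = "c",
  start = c(1L, 200L), end = c(100L, 300L),
  strand = "+", transcript_id = c("tx1", "tx1"),
  stringsAsFactors = FALSE)

test_that("gene score is the mean natural-log probe score under the gene", {
  probes <- data.frame(seq_id = "c", U = c(10L, 40L, 70L), D = c(30L, 60L, 90L),
                       ln_score = c(1, 2, 3))
  gs <- gene_scores(probes, toy_annotation)
  expect_equal(gs$score[gs$gene == "gA"], 2)
  expect_equal(gs$n_probes[gs$gene == "gA"], 3L)
  # gene with no probes is flagged, not zero-filled
  expect_true(gs$flagged[gs$gene == "gB"])
  expect_true(is.na(gs$score[gs$gene == "gB"]))
  # permuting probe order leaves the mean unchanged
  gs2 <- gene_scores(probes[c(3, 1, 2), ], toy_annotation)
  expect_equal(gs2$score, gs$score)
})

test_that("a probe overlapping two genes contributes to both (>= 1 bp rule)", {
  ann <- data.frame(gene = c("gA", "gB"), seq_id = "c",
                    start = c(1L, 50L), end = c(60L, 120L), strand = "+",
                    transcript_id = c("tx1", "tx2"), stringsAsFactors = FALSE)
  probes <- data.frame(seq_id = "c", U = 55L, D = 65L, ln_score = 4)
  gs <- gene_scores(probes, ann)
  expect_equal(gs$n_probes, c(1L, 1L))
  expect_equal(gs$score, c(4, 4))
  # 1-bp overlap counts; zero overlap does not
  probes2 <- data.frame(seq_id = "c", U = c(60L, 61L), D = c(70L, 70L),
                        ln_score = c(1, 9))
  gs2 <- gene_scores(probes2, ann)
  expect_equal(gs2$n_probes[gs2$gene == "gA"], 1L)
  expect_equal(gs2$score[gs2$gene == "gA"], 1)
})

test_that("regulation calls apply the ratio cutoff with strict default edges", {
  score_tab <- function(vals) data.frame(gene = names(vals),
                                         transcript_id = names(vals),
                                         score = unname(vals),
                                         stringsAsFactors = FALSE)
  wt <- score_tab(c(a = 0, b = 0, c = 0, d = 0))
  mut <- score_tab(c(a = log(3.5), b = log(0.2), c = 0, d = log(3)))
  calls <- regulation_calls(wt, mut, cutoff = 3)
  expect_equal(calls$call[calls$gene == "a"], "up")
  expect_equal(calls$call[calls$gene == "b"], "down")
  expect_equal(calls$call[calls$gene == "c"], "unchanged")
  # a ratio of exactly 3 is unchanged under the strict default ...
  expect_equal(calls$call[calls$gene == "d"], "unchanged")
  # ... and regulated under the inclusive edge policy
  calls_inc <- regulation_calls(wt, mut, cutoff = 3, inclusive = TRUE)
  expect_equal(calls_inc$call[calls_inc$gene == "d"], "up")
})

test_that("ratios are scale invariant and missing conditions are excluded", {
  score_tab <- function(vals) data.frame(gene = names(vals),
                                         transcript_id = names(vals),
                                         score = unname(vals),
                                         stringsAsFactors = FALSE)
  wt <- score_tab(c(a = 1.0, b = 2.0))
  mut <- score_tab(c(a = 1.0 + log(5), b = NA))
  expect_warning(calls <- regulation_calls(wt, mut), "excluded")
  expect_equal(nrow(calls), 1L)
  # doubling both linear scales (adding log 2 to both ln-scores) changes nothing
  wt2 <- score_tab(c(a = 1.0 + log(2)))
  mut2 <- score_tab(c(a = 1.0 + log(5) + log(2)))
  expect_equal(regulation_calls(wt2, mut2)$ratio, calls$ratio, tolerance = 1e-12)
})

test_that("planted regulation is recovered exactly in the seeded simulation", {
  genes <- data.frame(
    gene = sprintf("g%03d", 1:220),
    fold = c(rep(5, 10), rep(1, 210)))
  sim <- synth_expression_pair(genes, probes_per_gene = 20L,
                               noise_sigma = 0.1, seed = 2024L)
  wt <- gene_scores(sim$wt, sim$annotation)
  mut <- gene_scores(sim$mut, sim$annotation)
  calls <- regulation_calls(wt, mut, cutoff = 3)
  merged <- merge(calls, sim$truth, by = "gene")
  expect_equal(merged$call.x, merged$call.y)
  expect_equal(sum(merged$call.x == "up"), 10L)
  expect_equal(sum(merged$call.x == "down"), 0L)
})

test_that("call tallies partition the scored genes", {
  genes <- data.frame(gene = sprintf("g%02d", 1:40),
                      fold = c(rep(6, 4), rep(0.15, 6), rep(1, 30)))
  sim <- synth_expression_pair(genes, seed = 99L)
  calls <- regulation_calls(gene_scores(sim$wt, sim$annotation),
                            gene_scores(sim$mut, sim$annotation))
  tab <- table(factor(calls$call, levels = c("up", "down", "unchanged")))
  expect_equal(sum(tab), nrow(calls))
  expect_equal(unname(tab["up"]) + unname(tab["down"]) +
                 unname(tab["unchanged"]), 40L)
})

test_that("null false-call rate shrinks as probes per gene grow", {
  rates <- vapply(c(5L, 20L, 80L), function(ppg) {
    hits <- 0L
    for (seed in 1:5) {
      genes <- data.frame(gene = sprintf("g%03d", 1:100), fold = 1)
      sim <- synth_expression_pair(genes, probes_per_gene = ppg,
                                   noise_sigma = 1.0, seed = 500L + seed)
      calls <- regulation_calls(gene_scores(sim$wt, sim$annotation),
                                gene_scores(sim$mut, sim$annotation))
      hits <- hits + sum(calls$call != "unchanged")
    }
    hits / (5 * 100)
  }, 0)
  expect_true(all(diff(rates) <= 0))
  expect_lt(rates[3], rates[1])
})

test_that("transcript rollup mirrors the gene/promoter arithmetic", {
  calls <- data.frame(
    gene = sprintf("g%d", 1:8),
    transcript_id = c("t1", "t1", "t2", "t2", "t2", "t3", "t4", "t4"),
    ratio = 1,
    call = c("up", "up", "up", "unchanged", "unchanged", "up", "down", "down"),
    stringsAsFactors = FALSE)
  roll <- rollup_transcripts(calls)
  expect_equal(roll$n_up_transcripts, 3L)   # t1, t2, t3
  expect_equal(roll$n_up_genes, 4L)
  expect_equal(roll$n_down_transcripts, 1L) # t4
  expect_equal(roll$n_down_genes, 2L)
  expect_false(any(roll$transcripts$conflict))
  # mixed transcript is flagged
  calls$call[4] <- "down"
  roll2 <- rollup_transcripts(calls)
  expect_true(roll2$transcripts$conflict[roll2$transcripts$transcript_id == "t2"])
  expect_equal(roll2$transcripts$call[roll2$transcripts$transcript_id == "t2"],
               "conflict")
  # empty input
  roll0 <- rollup_transcripts(calls[0, ])
  expect_equal(roll0$n_up_transcripts, 0L)
  expect_equal(roll0$n_down_genes, 0L)
  # missing transcript ids are an error
  calls$transcript_id[1] <- ""
  expect_error(rollup_transcripts(calls), "transcript_id")
})
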