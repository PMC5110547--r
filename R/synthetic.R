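#' Generate a seeded synthetic genome with planted operator instances
#'
#' The background is i.i.d. over the four bases (uniform by default,
#' matching the 2-bit background assumed by the information model; a GC
#' knob is available). Planted sequences are copied in verbatim at the
#' stated positions — reverse-complemented first for minus-strand
#' plants — and reported in a machine-readable truth table.
#'
#' @param length Genome length in bases.
#' @param planted Optional data frame with `sequence`, `position`
#'   (1-based start on the forward strand) and optionally `strand`
#'   (default `+`). Planted footprints must not overlap.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param base_probs Background probabilities for `A`, `C`, `G`, `T`.
#' @param id Sequence id of the generated genome.
#' @return A list with `genome` (a [genome_sequence()]) and `truth`
#'   (data frame `seq_id`, `start`, `end`, `strand`, `sequence`).
#' @export
synth_genome <- function(length, planted = NULL, seed = 1L,
                         base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                         id = "synthetic") {
  stopifnot(length >= 1L, abs(sum(base_probs) - 1) < 1e-8)
  set.seed(as.integer(seed))
  chars <- sample(BASES, length, replace = TRUE, prob = base_probs)
  truth <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      sequence = character(), stringsAsFactors = FALSE)
  if (!is.null(planted) && nrow(planted) > 0L) {
    strand <- if ("strand" %in% names(planted)) as.character(planted$strand)
              else rep("+", nrow(planted))
    start <- as.integer(planted$position)
    len <- nchar(planted$sequence)
    end <- start + len - 1L
    if (any(start < 1L) || any(end > length))
      stop("planted site extends beyond the genome")
    o <- order(start)
    if (any(start[o][-1L] <= end[o][-length(o)]))
      stop("planted sites overlap")
    for (i in seq_len(nrow(planted))) {
      s <- toupper(planted$sequence[i])
      if (strand[i] == "-") s <- revcomp(s)
      chars[start[i]:end[i]] <- strsplit(s, "", fixed = TRUE)[[1L]]
    }
    truth <- data.frame(seq_id = id, start = start, end = end,
                        strand = strand,
                        sequence = toupper(planted$sequence),
                        stringsAsFactors = FALSE)
  }
  list(genome = genome_sequence(id, paste(chars, collapse = "")),
       truth = truth)
}

#' Sample site sequences from a base-frequency matrix
#'
#' Each position is drawn independently from the matrix's per-position
#' base distribution; used for parameter-recovery tests of the
#' information model.
#'
#' @param freq A [freq_matrix()].
#' @param n Number of sequences to draw.
#' @param seed Integer seed.
#' @return A character vector of `n` DNA strings of length `freq$L`.
#' @export
sample_sites <- function(freq, n, seed = 1L) {
  stopifnot(inherits(freq, "freq_matrix"), n >= 1L)
  set.seed(as.integer(seed))
  vapply(seq_len(n), function(i) {
    paste(vapply(seq_len(freq$L), function(l) {
      sample(BASES, 1L, prob = freq$f[, l])
    }, ""), collapse = "")
  }, "")
}

#' Generate a synthetic tiling probe track with triangular peaks
#'
#' Probes of `probe_length` bases are laid every `spacing` bp (the
#' defaults mirror a 25-mer/8-bp tiling array). Scores are a baseline
#' plus, over each truth region, a triangular enrichment peaking at the
#' region center, all multiplied by log-normal noise. Quality pixel
#' counts are drawn at or above 100 except for a `dropout` fraction of
#' probes, which receive counts below 100 and are removed by the default
#' [filter_probes()] settings.
#'
#' @param genome_length Track extent in bases.
#' @param regions Optional data frame with `start`, `end` and optionally
#'   `apex` (enrichment height at the region center; default 10).
#' @param spacing,probe_length Array geometry (defaults 8 and 25).
#' @param baseline Baseline probe score (default 1).
#' @param noise_sigma Standard deviation of the multiplicative
#'   log-normal noise, ln-units (default 0 = noiseless).
#' @param dropout Fraction of probes given sub-100 pixel counts.
#' @param seed Integer seed.
#' @param seq_id Sequence id carried by the probes.
#' @return A probe data frame (`seq_id`, `U`, `D`, `S`,
#'   `quality_pixels`) sorted by `U`.
#' @export
synth_probe_track <- function(genome_length, regions = NULL, spacing = 8L,
                              probe_length = 25L, baseline = 1,
                              noise_sigma = 0, dropout = 0, seed = 1L,
                              seq_id = "synthetic") {
  stopifnot(genome_length >= probe_length, dropout >= 0, dropout < 1)
  set.seed(as.integer(seed))
  U <- seq.int(1L, genome_length - probe_length + 1L, by = spacing)
  D <- U + probe_length - 1L
  center <- (U + D) / 2
  S <- rep(baseline, length(U))
  if (!is.null(regions) && nrow(regions) > 0L) {
    apex <- if ("apex" %in% names(regions)) regions$apex else rep(10, nrow(regions))
    for (i in seq_len(nrow(regions))) {
      rc <- (regions$start[i] + regions$end[i]) / 2
      half <- (regions$end[i] - regions$start[i]) / 2
      if (half <= 0) next
      h <- apex[i] * pmax(0, 1 - abs(center - rc) / half)
      S <- S + h
    }
  }
  if (noise_sigma > 0)
    S <- S * exp(stats::rnorm(length(S), 0, noise_sigma))
  pixels <- sample(100:1000, length(U), replace = TRUE)
  n_drop <- floor(dropout * length(U))
  if (n_drop > 0L) {
    drop_idx <- sample(length(U), n_drop)
    pixels[drop_idx] <- sample(0:99, n_drop, replace = TRUE)
  }
  data.frame(seq_id = seq_id, U = U, D = D, S = S,
             quality_pixels = pixels, stringsAsFactors = FALSE)
}

#' Generate a paired two-condition expression data set with known truth
#'
#' Genes are laid head-to-tail along a synthetic chromosome, each
#' covered by `probes_per_gene` probes. Wild-type probe ln-scores are
#' `N(0, noise_sigma)`; the mutant condition adds `ln(fold)` to every
#' probe of a gene, so the true linear ratio of gene `g` is
#' `gene_table$fold[g]`. Truth calls apply the same cutoff semantics as
#' [regulation_calls()].
#'
#' @param gene_table Data frame with `gene`, `fold` and optionally
#'   `transcript_id` (defaults to one transcript per gene).
#' @param probes_per_gene Probes under each gene (default 20).
#' @param noise_sigma Probe noise, ln-units (default 0.1).
#' @param spacing Probe spacing in bp (default 8).
#' @param cutoff Ratio cutoff used for the truth call (default 3).
#' @param seed Integer seed.
#' @return A list with `wt` and `mut` probe tables (`seq_id`, `U`, `D`,
#'   `ln_score`), `annotation` (gene annotation data frame) and `truth`
#'   (per-gene `fold` and `call`).
#' @export
synth_expression_pair <- function(gene_table, probes_per_gene = 20L,
                                  noise_sigma = 0.1, spacing = 8L,
                                  cutoff = 3, seed = 1L) {
  stopifnot(all(c("gene", "fold") %in% names(gene_table)),
            all(gene_table$fold > 0), probes_per_gene >= 1L)
  set.seed(as.integer(seed))
  n <- nrow(gene_table)
  tx <- if ("transcript_id" %in% names(gene_table)) gene_table$transcript_id
        else paste0("tx_", gene_table$gene)
  gene_len <- probes_per_gene * spacing
  gap <- 4L * spacing  # keeps neighbouring genes' probes from overlapping
  start <- 1L + (seq_len(n) - 1L) * (gene_len + gap)
  end <- start + gene_len - 1L
  annotation <- data.frame(gene = gene_table$gene, seq_id = "synthetic",
                           start = start, end = end, strand = "+",
                           transcript_id = tx, stringsAsFactors = FALSE)
  U <- unlist(lapply(seq_len(n), function(i) {
    start[i] + (seq_len(probes_per_gene) - 1L) * spacing
  }))
  D <- U + spacing - 1L  # short probes: each falls under exactly one gene
  gene_of_probe <- rep(seq_len(n), each = probes_per_gene)
  base <- stats::rnorm(length(U), 0, noise_sigma)
  wt <- data.frame(seq_id = "synthetic", U = U, D = D,
                   ln_score = base, stringsAsFactors = FALSE)
  mut <- data.frame(seq_id = "synthetic", U = U, D = D,
                    ln_score = stats::rnorm(length(U), 0, noise_sigma) +
                      log(gene_table$fold)[gene_of_probe],
                    stringsAsFactors = FALSE)
  truth_call <- ifelse(gene_table$fold > cutoff, "up",
                       ifelse(gene_table$fold < 1 / cutoff, "down", "unchanged"))
  list(wt = wt, mut = mut, annotation = annotation,
       truth = data.frame(gene = gene_table$gene, transcript_id = tx,
                          fold = gene_table$fold, call = truth_call,
                          stringsAsFactors = FALSE))
}
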