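#' Read a gene/transcript annotation table
#'
#' Tab-separated with columns `gene`, `seq_id`, `start`, `end`, `strand`,
#' `transcript_id`. A transcript groups the genes driven by one promoter
#' (an operon or a single gene).
#'
#' @param path Path to a TSV file.
#' @return A data frame of gene annotations.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "seq_id", "start", "end", "strand", "transcript_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("annotation is missing columns: ", paste(miss, collapse = ", "))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df
}

#' Gene scores from standardized per-probe tiling scores
#'
#' A probe is "under" a gene iff its interval overlaps the gene interval
#' by at least 1 bp, strand-blind (the array tiles both strands). The
#' gene score is the arithmetic mean of the natural-log probe scores of
#' all such probes; a probe overlapping two genes contributes to both.
#' Genes with no probes are flagged (`NA` score), never zero-filled.
#'
#' @param probes Data frame with `seq_id`, `U`, `D`, `ln_score`
#'   (standardized probe score on the natural-log scale).
#' @param annotation Gene annotation as from [read_gene_annotation()].
#' @return A data frame `gene`, `transcript_id`, `score` (mean ln),
#'   `n_probes`, `flagged`.
#' @export
gene_scores <- function(probes, annotation) {
  miss <- setdiff(c("seq_id", "U", "D", "ln_score"), names(probes))
  if (length(miss) > 0L)
    stop("probe table is missing columns: ", paste(miss, collapse = ", "))
  score <- rep(NA_real_, nrow(annotation))
  n_probes <- integer(nrow(annotation))
  for (sid in unique(annotation$seq_id)) {
    gi <- which(annotation$seq_id == sid)
    pi <- which(probes$seq_id == sid)
    if (length(pi) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(annotation$start[gi], annotation$end[gi]),
      IRanges::IRanges(probes$U[pi], probes$D[pi]))
    by_gene <- split(pi[S4Vectors::subjectHits(ov)],
                     factor(S4Vectors::queryHits(ov), levels = seq_along(gi)))
    score[gi] <- vapply(by_gene, function(rows) {
      if (length(rows) == 0L) NA_real_ else mean(probes$ln_score[rows])
    }, 0)
    n_probes[gi] <- lengths(by_gene)
  }
  data.frame(gene = annotation$gene,
             transcript_id = annotation$transcript_id,
             score = score,
             n_probes = n_probes,
             flagged = n_probes == 0L,
             stringsAsFactors = FALSE)
}

#' Classify genes as up-/down-regulated from two-condition gene scores
#'
#' The linear-scale ratio is `exp(score_mut - score_wt)` (scores are
#' means of natural-log probe scores). With the canonical cutoff of 3 a
#' gene is `up` when the ratio strictly exceeds 3 (the regulator acting
#' as a repressor in the deletion comparison), `down` when it falls
#' strictly below 1/3 (activator), else `unchanged`. `inclusive = TRUE`
#' moves the boundary ratio itself into the regulated classes.
#'
#' @param wt,mut Gene-score tables from [gene_scores()] for the
#'   wild-type and mutant condition, on the same annotation.
#' @param cutoff Linear ratio cutoff (default 3).
#' @param inclusive Treat a ratio exactly at the cutoff as regulated
#'   (default `FALSE`, strict inequalities).
#' @return A data frame `gene`, `transcript_id`, `ratio`, `call` with
#'   `call` in `up`/`down`/`unchanged`; genes lacking a score in either
#'   condition are excluded with a warning.
#' @export
regulation_calls <- function(wt, mut, cutoff = 3, inclusive = FALSE) {
  stopifnot(cutoff > 1)
  m <- merge(wt[, c("gene", "transcript_id", "score")],
             mut[, c("gene", "score")],
             by = "gene", suffixes = c("_wt", "_mut"))
  bad <- is.na(m$score_wt) | is.na(m$score_mut)
  if (any(bad)) {
    warning(sum(bad), " gene(s) missing a score in one condition; excluded")
    m <- m[!bad, , drop = FALSE]
  }
  d <- m$score_mut - m$score_wt
  ratio <- exp(d)
  # compare on the ln scale so a ratio exactly at the cutoff is not
  # misclassified by exp() round-off
  up <- if (inclusive) d >= log(cutoff) else d > log(cutoff)
  down <- if (inclusive) d <= -log(cutoff) else d < -log(cutoff)
  data.frame(gene = m$gene,
             transcript_id = m$transcript_id,
             ratio = ratio,
             call = ifelse(up, "up", ifelse(down, "down", "unchanged")),
             stringsAsFactors = FALSE)
}

#' Roll gene-level regulation calls up to transcripts
#'
#' A transcript is up (down) if at least one member gene is up (down);
#' transcripts with both an up and a down gene are flagged as conflicts
#' (and counted in both directions' transcript tallies).
#'
#' @param calls Call table from [regulation_calls()] (each called gene
#'   must carry a `transcript_id`).
#' @return A list with `transcripts` (per-transcript data frame with
#'   `transcript_id`, `call`, `n_genes`, `conflict`), and the tallies
#'   `n_up_transcripts`, `n_down_transcripts`, `n_up_genes`,
#'   `n_down_genes`.
#' @export
rollup_transcripts <- function(calls) {
  if (any(is.na(calls$transcript_id) | !nzchar(calls$transcript_id)))
    stop("every called gene must have a transcript_id")
  if (nrow(calls) == 0L) {
    return(list(transcripts = data.frame(transcript_id = character(),
                                         call = character(),
                                         n_genes = integer(),
                                         conflict = logical()),
                n_up_transcripts = 0L, n_down_transcripts = 0L,
                n_up_genes = 0L, n_down_genes = 0L))
  }
  by_tx <- split(calls$call, calls$transcript_id)
  any_up <- vapply(by_tx, function(x) any(x == "up"), TRUE)
  any_down <- vapply(by_tx, function(x) any(x == "down"), TRUE)
  call <- ifelse(any_up & any_down, "conflict",
                 ifelse(any_up, "up", ifelse(any_down, "down", "unchanged")))
  tx <- data.frame(transcript_id = names(by_tx),
                   call = call,
                   n_genes = lengths(by_tx),
                   conflict = any_up & any_down,
                   stringsAsFactors = FALSE)
  list(transcripts = tx,
       n_up_transcripts = sum(any_up),
       n_down_transcripts = sum(any_down),
       n_up_genes = sum(calls$call == "up"),
       n_down_genes = sum(calls$call == "down"))
}
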