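#' Read a tiling probe track
#'
#' Tab-separated with a header row; required columns `seq_id`, `U`
#' (1-based coordinate of the probe's upstream end), `D` (downstream
#' end), `S` (score, e.g. ChIP/input ratio). An optional
#' `quality_pixels` column carries the per-probe pixel count used by
#' [filter_probes()].
#'
#' @param path Path to a TSV file.
#' @return A data frame of probes.
#' @export
read_probe_track <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("seq_id", "U", "D", "S"), names(df))
  if (length(miss) > 0L)
    stop("probe track is missing columns: ", paste(miss, collapse = ", "))
  df$U <- as.integer(df$U); df$D <- as.integer(df$D)
  if (any(df$U > df$D)) stop("probe track has U > D rows")
  if (any(df$S < 0)) stop("probe scores must be >= 0")
  df
}

#' Drop probes with too few quality pixels
#'
#' Probes with `quality_pixels < min_pixels` (strict) are removed; they
#' correspond to array regions likely missing from the genome. Tracks
#' without a `quality_pixels` column pass through unchanged.
#'
#' @param probes Probe data frame.
#' @param min_pixels Pixel cutoff (default 100).
#' @return The filtered probe data frame.
#' @export
filter_probes <- function(probes, min_pixels = 100L) {
  if (!"quality_pixels" %in% names(probes)) return(probes)
  probes[probes$quality_pixels >= min_pixels, , drop = FALSE]
}

#' Interpolated boundaries of a bound region around its peak probe
#'
#' The upstream boundary interpolates between the peak probe and its
#' upstream neighbour in proportion to their score ratio:
#' `U_P - (U_P - U_prev) * (S_prev / S_P)`. In `"corrected"` mode the
#' downstream boundary mirrors it, `D_P + (D_next - D_P) * (S_next /
#' S_P)`; `"as_printed"` mode keeps the subtraction of the source
#' formula (which places the boundary upstream of the peak) for
#' bit-faithful replication. Coordinates are rounded half-up. A missing
#' flanking probe (`NULL`) behaves as score 0, collapsing the boundary
#' onto the peak probe's own end.
#'
#' @param peak One-row data frame or list with `U`, `D`, `S` of the peak
#'   probe (`S > 0`).
#' @param prev_probe,next_probe Flanking probes of the peak in the track,
#'   or `NULL`.
#' @param mode `"corrected"` (default) or `"as_printed"`.
#' @return Integer vector `c(upstream, downstream)`.
#' @export
region_boundaries <- function(peak, prev_probe = NULL, next_probe = NULL,
                              mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  S_P <- as.numeric(peak$S)
  if (S_P <= 0) stop("peak probe score must be > 0")
  up <- if (is.null(prev_probe)) as.numeric(peak$U) else {
    peak$U - (peak$U - prev_probe$U) * (prev_probe$S / S_P)
  }
  down <- if (is.null(next_probe)) as.numeric(peak$D) else {
    step <- (next_probe$D - peak$D) * (next_probe$S / S_P)
    if (mode == "corrected") peak$D + step else peak$D - step
  }
  round_half_up <- function(x) as.integer(floor(x + 0.5))
  c(upstream = round_half_up(up), downstream = round_half_up(down))
}

#' Call bound regions from a probe track
#'
#' Maximal runs of adjacent probes scoring strictly above `threshold`
#' are merged into regions; within each region the highest-scoring probe
#' is the peak (ties broken toward the most upstream probe). A coverage
#' gap larger than `max_gap` (default twice the median probe spacing)
#' breaks adjacency even between above-threshold probes. Region
#' boundaries are interpolated around the peak probe from its immediate
#' track neighbours via [region_boundaries()].
#'
#' @param probes Probe data frame sorted by `U` within each `seq_id`
#'   (unsorted input is an error).
#' @param threshold Score threshold for a probe to be in a bound region;
#'   no default, it is a property of the enrichment pipeline upstream.
#' @param mode Boundary mode, see [region_boundaries()].
#' @param max_gap Maximum allowed gap (bp, between consecutive probe `U`
#'   coordinates) within one region; `NULL` uses twice the median spacing.
#' @return A data frame with one row per region: `seq_id`, `upstream`,
#'   `downstream`, `peak_position` (center of the peak probe),
#'   `peak_score`, `n_probes`, and a list column `probe_rows` of member
#'   row indices into `probes`.
#' @export
call_regions <- function(probes, threshold, mode = c("corrected", "as_printed"),
                         max_gap = NULL) {
  mode <- match.arg(mode)
  if (missing(threshold)) stop("a region-calling threshold is required")
  empty <- data.frame(seq_id = character(), upstream = integer(),
                      downstream = integer(), peak_position = integer(),
                      peak_score = numeric(), n_probes = integer(),
                      stringsAsFactors = FALSE)
  empty$probe_rows <- list()
  if (nrow(probes) == 0L) return(empty)
  out <- lapply(split(seq_len(nrow(probes)), probes$seq_id), function(idx) {
    p <- probes[idx, , drop = FALSE]
    if (is.unsorted(p$U)) stop("probes must be sorted by U within each seq_id")
    gap_limit <- if (is.null(max_gap)) {
      sp <- diff(p$U)
      if (length(sp) > 0L) 2 * stats::median(sp) else Inf
    } else max_gap
    above <- p$S > threshold
    if (!any(above)) return(empty)
    # run id: increments on below-threshold probes and on large gaps
    breaks <- c(FALSE, diff(p$U) > gap_limit)
    run <- cumsum(!above | breaks)
    groups <- split(which(above), run[above])
    rows <- lapply(groups, function(g) {
      peak_local <- g[which.max(p$S[g])]  # which.max: first max = most upstream
      peak <- p[peak_local, ]
      prev_probe <- if (peak_local > 1L) p[peak_local - 1L, ] else NULL
      next_probe <- if (peak_local < nrow(p)) p[peak_local + 1L, ] else NULL
      b <- region_boundaries(peak, prev_probe, next_probe, mode)
      d <- data.frame(seq_id = peak$seq_id,
                      upstream = b[["upstream"]],
                      downstream = b[["downstream"]],
                      peak_position = as.integer(floor((peak$U + peak$D) / 2)),
                      peak_score = peak$S,
                      n_probes = length(g),
                      stringsAsFactors = FALSE)
      d$probe_rows <- list(idx[g])
      d
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export bound-region sequences as FASTA for motif discovery
#'
#' One record per region spanning `upstream..downstream` (1-based
#' inclusive). Boundaries outside the genome are clipped with a warning.
#' Headers carry `seq_id:start-end|peak=<score>`, suitable as input for
#' an external motif finder.
#'
#' @param regions Region table from [call_regions()].
#' @param genome A [genome_sequence()].
#' @param path Optional FASTA output path.
#' @return A named character vector of region sequences (written to
#'   `path` when given), invisibly when writing.
#' @export
export_region_sequences <- function(regions, genome, path = NULL) {
  stopifnot(inherits(genome, "genome_sequence"))
  if (nrow(regions) == 0L) {
    seqs <- character(0)
  } else {
    lo <- pmax(regions$upstream, 1L)
    hi <- pmin(regions$downstream, genome$length)
    if (any(lo != regions$upstream | hi != regions$downstream))
      warning("some region boundaries were clipped to the genome")
    if (any(lo > hi))
      stop("region with empty span after clipping (upstream > downstream); ",
           "check boundary mode")
    seqs <- substring(genome$residues, lo, hi)
    names(seqs) <- sprintf("%s:%d-%d|peak=%g", regions$seq_id, lo, hi,
                           regions$peak_score)
  }
  if (!is.null(path)) {
    write_fasta(seqs, path)
    return(invisible(seqs))
  }
  seqs
}

#' Write a called-region table to TSV
#'
#' @param regions Region table from [call_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path) {
  cols <- c("seq_id", "upstream", "downstream", "peak_position",
            "peak_score", "n_probes")
  utils::write.table(regions[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
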