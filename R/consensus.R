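#' Define a degenerate consensus motif with fixed critical positions
#'
#' The default is the 16-bp GalR operator consensus
#' `GTGNAANCGNTTNCAC`, a hyphenated dyad with its center between
#' positions 8 and 9. Positions 3, 5, 9 and 15 are critical: a mutation
#' at any of them inactivates the operator, so a candidate must match
#' them exactly. The remaining non-N positions may deviate up to the
#' mismatch budget (default 2). `N` positions are never compared.
#'
#' @param pattern Length-16 string over `A`, `C`, `G`, `T`, `N`.
#' @param fixed 1-based positions that must match exactly; none may be
#'   `N` in the pattern.
#' @param max_mismatches Allowed mismatches over the checkable (non-N,
#'   non-fixed) positions.
#' @return An object of class `consensus_motif` with fields `pattern`,
#'   `fixed_positions`, `checkable_positions`, `max_mismatches`.
#' @export
consensus_motif <- function(pattern = "GTGNAANCGNTTNCAC",
                            fixed = c(3L, 5L, 9L, 15L),
                            max_mismatches = 2L) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c(BASES, "N")))
    stop("pattern may only contain A, C, G, T, N")
  L <- length(chars)
  fixed <- sort(unique(as.integer(fixed)))
  if (any(fixed < 1L | fixed > L)) stop("fixed positions out of range")
  if (any(chars[fixed] == "N")) stop("fixed positions must not be N in the pattern")
  checkable <- setdiff(which(chars != "N"), fixed)
  structure(list(pattern = pattern,
                 length = L,
                 fixed_positions = fixed,
                 checkable_positions = checkable,
                 max_mismatches = as.integer(max_mismatches)),
            class = "consensus_motif")
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat("consensus_motif ", x$pattern,
      "  fixed {", paste(x$fixed_positions, collapse = ","), "}",
      "  <=", x$max_mismatches, " mismatches\n", sep = "")
  invisible(x)
}

# Motif with pattern reverse-complemented and position sets mirrored;
# used to evaluate the minus strand on forward-strand windows. The
# fixed-position set {3,5,9,15} is NOT self-mirroring (it maps to
# {2,8,12,14}), so the two strands genuinely differ.
revcomp_motif <- function(motif) {
  consensus_motif(revcomp(motif$pattern),
                  fixed = motif$length + 1L - motif$fixed_positions,
                  max_mismatches = motif$max_mismatches)
}

#' Match a single window against a consensus motif
#'
#' A window is a hit iff every fixed position matches the pattern exactly
#' and the number of mismatches over the checkable positions does not
#' exceed the motif's budget. Windows containing `N` never match.
#'
#' @param window DNA string of the motif's length.
#' @param motif A [consensus_motif()].
#' @return A list with `hit` (logical) and `mismatches` (mismatch count
#'   over checkable positions; `NA` for windows containing `N`).
#' @export
match_consensus <- function(window, motif = consensus_motif()) {
  stopifnot(is.character(window), length(window) == 1L)
  window <- toupper(window)
  if (nchar(window) != motif$length)
    stop("window must have length ", motif$length, ", got ", nchar(window))
  wcode <- encode_dna(window)
  if (anyNA(wcode)) return(list(hit = FALSE, mismatches = NA_integer_))
  pcode <- encode_dna(motif$pattern)  # N -> NA, never compared
  fixed_ok <- all(wcode[motif$fixed_positions] == pcode[motif$fixed_positions])
  mm <- sum(wcode[motif$checkable_positions] != pcode[motif$checkable_positions])
  list(hit = fixed_ok && mm <= motif$max_mismatches, mismatches = as.integer(mm))
}

# Vectorized single-strand scan over forward windows of `codes`.
# Returns data.frame(start, mismatches) of hits.
scan_one_strand <- function(codes, motif) {
  L <- motif$length
  n_win <- length(codes) - L + 1L
  if (n_win < 1L) return(data.frame(start = integer(), mismatches = integer()))
  pcode <- encode_dna(motif$pattern)
  starts <- seq_len(n_win)
  ok <- rep(TRUE, n_win)
  for (p in motif$fixed_positions) {
    v <- codes[starts + p - 1L]
    ok <- ok & !is.na(v) & v == pcode[p]
  }
  mm <- integer(n_win)
  has_n <- rep(FALSE, n_win)
  for (p in motif$checkable_positions) {
    v <- codes[starts + p - 1L]
    na <- is.na(v)
    has_n <- has_n | na
    mm <- mm + as.integer(!na & v != pcode[p])
  }
  # N anywhere in the window is a non-match (conservative)
  for (p in setdiff(seq_len(L), c(motif$fixed_positions, motif$checkable_positions))) {
    has_n <- has_n | is.na(codes[starts + p - 1L])
  }
  hit <- ok & !has_n & mm <= motif$max_mismatches
  data.frame(start = starts[hit], mismatches = mm[hit])
}

#' Scan a genome for consensus operator hits on both strands
#'
#' Every window of the motif's length on both strands is evaluated.
#' Because the fixed-position set is not preserved under reverse
#' complement, the two strands can disagree even for a palindromic
#' pattern string. Hits whose forward-strand intervals coincide are
#' collapsed to one locus, with `+` preferred as the canonical strand.
#'
#' @param genome A [genome_sequence()].
#' @param motif A [consensus_motif()].
#' @return A data frame with one row per locus: `seq_id`, `start`, `end`,
#'   `strand` (canonical), `strands` (`"+"`, `"-"` or `"+/-"`),
#'   `mismatches` (canonical strand), `sequence` (forward strand) and
#'   `sequence_motif` (motif orientation), sorted by `start`.
#' @export
scan_consensus <- function(genome, motif = consensus_motif()) {
  stopifnot(inherits(genome, "genome_sequence"))
  L <- motif$length
  empty <- data.frame(seq_id = character(), start = integer(), end = integer(),
                      strand = character(), strands = character(),
                      mismatches = integer(), sequence = character(),
                      sequence_motif = character(), stringsAsFactors = FALSE)
  if (genome$length < L) return(empty)
  codes <- encode_dna(genome$residues)
  plus <- scan_one_strand(codes, motif)
  minus <- scan_one_strand(codes, revcomp_motif(motif))
  if (nrow(plus) == 0L && nrow(minus) == 0L) return(empty)
  starts <- sort(unique(c(plus$start, minus$start)))
  on_plus <- starts %in% plus$start
  on_minus <- starts %in% minus$start
  mm_plus <- plus$mismatches[match(starts, plus$start)]
  mm_minus <- minus$mismatches[match(starts, minus$start)]
  strand <- ifelse(on_plus, "+", "-")
  fwd <- substring(genome$residues, starts, starts + L - 1L)
  data.frame(
    seq_id = genome$id,
    start = starts,
    end = starts + L - 1L,
    strand = strand,
    strands = ifelse(on_plus & on_minus, "+/-", strand),
    mismatches = ifelse(on_plus, mm_plus, mm_minus),
    sequence = fwd,
    sequence_motif = ifelse(strand == "+", fwd, revcomp(fwd)),
    stringsAsFactors = FALSE
  )
}

#' Count distinct operator loci in a hit table
#'
#' @param hits A deduplicated hit table from [scan_consensus()].
#' @return The number of distinct loci (`seq_id`, `start`, `end` triples).
#' @export
count_loci <- function(hits) {
  if (nrow(hits) == 0L) return(0L)
  nrow(unique(hits[, c("seq_id", "start", "end")]))
}

#' Write a consensus hit table to TSV
#'
#' @param hits Hit table from [scan_consensus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
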