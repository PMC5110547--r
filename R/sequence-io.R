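BASES <- c("A", "C", "G", "T")
# complement in code space: A<->T, C<->G (codes 1..4 over ACGT)
COMP_CODE <- c(4L, 3L, 2L, 1L)

#' Construct a genome sequence record
#'
#' A `genome_sequence` is a named, validated DNA string with 1-based
#' inclusive public coordinates on the forward strand. All scanning and
#' window-extraction functions in the package take one of these.
#'
#' @param id Sequence identifier (e.g. a chromosome or accession name).
#' @param residues DNA string; lower case and `U` are normalized, only
#'   `A`, `C`, `G`, `T`, `N` are accepted afterwards.
#' @return An object of class `genome_sequence` with fields `id`,
#'   `residues` and `length`.
#' @export
genome_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- chartr("u", "t", toupper(residues))
  residues <- chartr("U", "T", residues)
  bad <- setdiff(unique(strsplit(residues, "", fixed = TRUE)[[1L]]),
                 c(BASES, "N"))
  if (length(bad) > 0L)
    stop("sequence '", id, "' contains non-nucleotide characters: ",
         paste(bad, collapse = ", "))
  if (nchar(residues) == 0L)
    stop("sequence '", id, "' is empty")
  structure(list(id = id, residues = residues, length = nchar(residues)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("genome_sequence ", x$id, ": ", x$length, " bp\n", sep = "")
  invisible(x)
}

#' Read nucleotide sequences from a FASTA file
#'
#' Sequences are uppercased and `U` is mapped to `T`. IUPAC ambiguity
#' codes other than `N` are rejected by default or masked to `N`.
#'
#' @param path Path to a FASTA file.
#' @param ambiguity `"error"` (default) to reject IUPAC codes other than
#'   `N`, or `"mask"` to convert them to `N`.
#' @return A list of [genome_sequence()] objects, in file order.
#' @export
read_fasta <- function(path, ambiguity = c("error", "mask")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no sequences: ", path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    s <- chartr("u", "t", toupper(as.character(set[[i]])))
    s <- chartr("U", "T", s)
    if (ambiguity == "mask") {
      iupac <- "RYSWKMBDHV"
      s <- chartr(iupac, strrep("N", nchar(iupac)), s)
    }
    genome_sequence(ids[i], s)
  })
}

#' Write sequences to a FASTA file
#'
#' @param seqs A list of [genome_sequence()] objects, or a named character
#'   vector of DNA strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    set <- Biostrings::BStringSet(seqs)
    if (length(set) > 0L) {
      nm <- names(seqs)
      if (is.null(nm)) nm <- paste0("seq", seq_along(seqs))
      names(set) <- nm
    }
  } else {
    set <- Biostrings::BStringSet(vapply(seqs, `[[`, "", "residues"))
    names(set) <- vapply(seqs, `[[`, "", "id")
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' `N` maps to `N`; the operation is an involution.
#'
#' @param seq DNA string over `A`, `C`, `G`, `T`, `N` (vectorized).
#' @return The reverse complement string(s).
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  vapply(seq, function(s) {
    u <- utf8ToInt(chartr("ACGTN", "TGCAN", s))
    if (anyNA(match(u, utf8ToInt("ACGTN"))))
      stop("revcomp: sequence contains characters outside {A,C,G,T,N}")
    intToUtf8(rev(u))
  }, "", USE.NAMES = FALSE)
}

# Integer codes 1..4 over ACGT; N and anything else becomes NA.
encode_dna <- function(seq) {
  match(utf8ToInt(seq), utf8ToInt("ACGT"))
}

#' Extract a fixed window around the center of an operator site
#'
#' The window is anchored at position 9 of a 16-bp operator (the base the
#' binding-site logo marks as coordinate 0) and extends `left_offset`
#' bases to its 5' side and `right_offset` bases to its 3' side in the
#' site's own orientation. For minus-strand sites the returned string is
#' the reverse complement of the mirrored forward-strand span, so logo
#' coordinates always read 5' to 3' along the site.
#'
#' @param genome A [genome_sequence()].
#' @param site A list or one-row data frame with `start`, `end`, `strand`
#'   (1-based inclusive forward-strand coordinates).
#' @param left_offset,right_offset Non-negative base counts; the returned
#'   window has length `left_offset + right_offset + 1`.
#' @return A DNA string of length `left_offset + right_offset + 1`.
#' @export
extract_window <- function(genome, site, left_offset = 20L, right_offset = 21L) {
  stopifnot(inherits(genome, "genome_sequence"))
  start <- as.integer(site$start); end <- as.integer(site$end)
  strand <- as.character(site$strand)
  stopifnot(length(start) == 1L, length(end) == 1L, start <= end,
            strand %in% c("+", "-"), left_offset >= 0L, right_offset >= 0L)
  if (end > genome$length) stop("site extends beyond genome end")
  if (strand == "+") {
    center <- start + 8L
    lo <- center - left_offset; hi <- center + right_offset
  } else {
    center <- end - 8L
    lo <- center - right_offset; hi <- center + left_offset
  }
  if (lo < 1L || hi > genome$length)
    stop("window [", lo, ", ", hi, "] exceeds genome bounds (no wraparound)")
  w <- substr(genome$residues, lo, hi)
  if (strand == "-") w <- revcomp(w)
  w
}

#' Read an operator coordinate table
#'
#' Expects a tab-separated file with a header row and columns `seq_id`,
#' `start`, `end`, `strand`, `name`, `sequence` (extra columns are kept).
#'
#' @param path Path to a TSV file.
#' @return A data frame with 1-based inclusive forward-strand intervals.
#' @export
read_operator_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seq_id", "start", "end", "strand", "name", "sequence")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("operator table is missing columns: ", paste(miss, collapse = ", "))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start > df$end)) stop("operator table has start > end rows")
  df
}

#' Read a transcription start point (tsp) table
#'
#' Expects columns `gene`, `tsp`, `strand` in a tab-separated file.
#'
#' @param path Path to a TSV file.
#' @return A data frame of TSS records.
#' @export
read_tss_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene", "tsp", "strand"), names(df))
  if (length(miss) > 0L)
    stop("tss table is missing columns: ", paste(miss, collapse = ", "))
  df$tsp <- as.integer(df$tsp)
  df
}

#' Convert 1-based inclusive intervals to BED (0-based half-open)
#'
#' @param df Data frame with `seq_id`, `start`, `end` and optionally
#'   `name`, `strand` plus a numeric `score` column.
#' @return A data frame in BED column order (`chrom`, `chromStart`,
#'   `chromEnd`, `name`, `score`, `strand`).
#' @export
intervals_to_bed <- function(df) {
  stopifnot(all(c("seq_id", "start", "end") %in% names(df)))
  data.frame(
    chrom = df$seq_id,
    chromStart = as.integer(df$start) - 1L,
    chromEnd = as.integer(df$end),
    name = if ("name" %in% names(df)) df$name else ".",
    score = if ("score" %in% names(df)) df$score else 0,
    strand = if ("strand" %in% names(df)) df$strand else ".",
    stringsAsFactors = FALSE
  )
}

#' Convert BED intervals back to 1-based inclusive coordinates
#'
#' @param bed Data frame with `chrom`, `chromStart`, `chromEnd` (and
#'   optionally `name`, `strand`).
#' @return A data frame with `seq_id`, `start`, `end`, `name`, `strand`.
#' @export
bed_to_intervals <- function(bed) {
  stopifnot(all(c("chrom", "chromStart", "chromEnd") %in% names(bed)))
  data.frame(
    seq_id = bed$chrom,
    start = as.integer(bed$chromStart) + 1L,
    end = as.integer(bed$chromEnd),
    name = if ("name" %in% names(bed)) bed$name else ".",
    strand = if ("strand" %in% names(bed)) bed$strand else "+",
    stringsAsFactors = FALSE
  )
}
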