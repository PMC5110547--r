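#' Packaged GalR data tables
#'
#' Small reference tables shipped with the package, transcribed from the
#' study that mapped the extended GalR regulon:
#'
#' * `galr_known_operators()` — the nine biochemically characterized
#'   operators of the gal regulon (the galE, galP, galR, galS and mglB
#'   promoters) with forward-strand 1-based inclusive coordinates; the
#'   training set of the information model.
#' * `galr_operators_3c()` — operators engaged in long-range (3C)
#'   operator-operator contacts.
#' * `galr_predicted_sites()` — the 60 genomic sites scored above 9.4
#'   bits by the individual-information scan, with their scores and
#'   cognate genes.
#' * `galr_chip_regions()` — GalR-bound regions from ChIP-chip with
#'   peak-probe positions, peak scores and motif-derived inferred sites.
#' * `galr_grs_sites()` — operators classified as Gene Regulatory Sites
#'   (within -200..+400 bp of a tsp). Two rows carry coordinate typos
#'   from the source table (widths other than 16 bp); they are kept as
#'   printed.
#'
#' Coordinates refer to the E. coli K-12 MG1655 chromosome; the genome
#' sequence itself is not packaged and is supplied by the user for any
#' full-scale analysis.
#'
#' @return A data frame (see above).
#' @name galr_tables
NULL

read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "galregulon", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname galr_tables
#' @export
galr_known_operators <- function() read_extdata("known_operators.tsv")

#' @rdname galr_tables
#' @export
galr_operators_3c <- function() read_extdata("operators_3c.tsv")

#' @rdname galr_tables
#' @export
galr_predicted_sites <- function() read_extdata("predicted_sites_info.tsv")

#' @rdname galr_tables
#' @export
galr_chip_regions <- function() read_extdata("chip_bound_regions.tsv")

#' @rdname galr_tables
#' @export
galr_grs_sites <- function() read_extdata("grs_sites.tsv")
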