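#' Extract an aligned set of binding-site windows from a genome
#'
#' Each operator contributes one window of
#' `left_offset + right_offset + 1` bases centered on position 9 of the
#' 16-mer (logo coordinate 0), reverse-complemented for minus-strand
#' sites. With the defaults (20/21) this yields the 42-bp alignment used
#' for the information model. With `symmetrize = TRUE` the reverse
#' complement of every window is appended, doubling `n`; the default
#' keeps each site on its annotated strand.
#'
#' @param genome A [genome_sequence()].
#' @param operators Data frame with `start`, `end`, `strand` and
#'   optionally `name`.
#' @param left_offset,right_offset Window extent around logo coordinate 0.
#' @param symmetrize Append reverse complements of all windows.
#' @return A named character vector of equal-length site windows.
#' @export
aligned_sites <- function(genome, operators, left_offset = 20L,
                          right_offset = 21L, symmetrize = FALSE) {
  stopifnot(nrow(operators) >= 1L)
  w <- vapply(seq_len(nrow(operators)), function(i) {
    extract_window(genome, operators[i, ], left_offset, right_offset)
  }, "")
  names(w) <- if ("name" %in% names(operators)) operators$name
              else paste0("site", seq_along(w))
  if (symmetrize) {
    rc <- revcomp(w)
    names(rc) <- paste0(names(w), "_rc")
    w <- c(w, rc)
  }
  w
}

#' Base-frequency matrix of an aligned site set
#'
#' @param sequences Character vector of aligned DNA strings of equal
#'   length over `A`, `C`, `G`, `T` (no `N`: ambiguous sites must be
#'   resolved or dropped before modelling).
#' @return An object of class `freq_matrix` with fields `counts` (4 x L,
#'   rows `A`,`C`,`G`,`T`), `f` (column-normalized), `n`, `L`.
#' @export
freq_matrix <- function(sequences) {
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  sequences <- toupper(sequences)
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("aligned sequences must all have the same length")
  n <- length(sequences)
  codes <- vapply(sequences, encode_dna, integer(L))  # L x n
  dim(codes) <- c(L, n)
  if (anyNA(codes))
    stop("aligned sequences may only contain A, C, G, T")
  counts <- vapply(seq_len(L), function(l) tabulate(codes[l, ], 4L),
                   integer(4L))
  dimnames(counts) <- list(BASES, NULL)
  structure(list(counts = counts, f = counts / n, n = n, L = L),
            class = "freq_matrix")
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat("freq_matrix: ", x$n, " sites x ", x$L, " positions\n", sep = "")
  invisible(x)
}

#' Small-sample correction for plug-in entropy of base frequencies
#'
#' The plug-in (maximum-likelihood) entropy of `n` draws from the uniform
#' base distribution underestimates 2 bits; the correction
#' `e(n) = 2 - E[Hhat(n)]` is subtracted from every per-position
#' information estimate. The `"exact"` method evaluates the expectation
#' and variance of `Hhat` in closed form over the multinomial null
#' (binomial marginals for the mean, trinomial pairs for the variance),
#' which is algebraically identical to summing over all compositions of
#' `n` into four parts. The `"approximation"` method uses the asymptotic
#' bias `3 / (2 ln(2) n)` and reports `var_H = NA`.
#'
#' @param n Number of aligned sites (>= 1).
#' @param method `"exact"` (default for `n` <= 2000) or `"approximation"`.
#' @return A list with `e_n` (bits/position), `var_H` (bits^2, exact null
#'   variance of the plug-in entropy), `method`, `n`.
#' @export
small_sample_correction <- function(n, method = if (n <= 2000L) "exact" else "approximation") {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  method <- match.arg(method, c("exact", "approximation"))
  if (method == "approximation") {
    return(list(e_n = 3 / (2 * log(2) * n), var_H = NA_real_,
                method = method, n = n))
  }
  k <- 0:n
  h1 <- ifelse(k == 0L, 0, -(k / n) * log2(k / n))
  pb <- stats::dbinom(k, n, 0.25)
  EH <- 4 * sum(pb * h1)
  Eh1sq <- sum(pb * h1^2)
  # pairwise term over the trinomial (n_i, n_j, rest)
  grid_i <- rep.int(0:n, n + 1L)
  grid_j <- rep(0:n, each = n + 1L)
  keep <- grid_i + grid_j <= n
  gi <- grid_i[keep]; gj <- grid_j[keep]
  hi <- ifelse(gi == 0L, 0, -(gi / n) * log2(gi / n))
  hj <- ifelse(gj == 0L, 0, -(gj / n) * log2(gj / n))
  lp <- lgamma(n + 1) - lgamma(gi + 1) - lgamma(gj + 1) -
    lgamma(n - gi - gj + 1) + (gi + gj) * log(0.25) + (n - gi - gj) * log(0.5)
  Eh1h2 <- sum(exp(lp) * hi * hj)
  EH2 <- 4 * Eh1sq + 12 * Eh1h2
  list(e_n = 2 - EH, var_H = max(EH2 - EH^2, 0), method = method, n = n)
}

#' Per-position and total information of an aligned site set
#'
#' The information at position `l` is `r(l) = 2 - Hhat(l) - e(n)` bits,
#' with `Hhat` the plug-in entropy of the observed base frequencies
#' (0 log 0 = 0) and `e(n)` the small-sample correction. `Rsequence` is
#' the sum over positions; its uncertainty is taken as
#' `sqrt(L * var_H)`, the null sampling standard deviation of the summed
#' plug-in entropies.
#'
#' @param freq A [freq_matrix()].
#' @param correction Result of [small_sample_correction()]; defaults to
#'   the exact correction for `freq$n`.
#' @return An object of class `info_summary` with `r` (bits per
#'   position), `Rsequence`, `sigma_Rsequence` (bits/site), `e_n`,
#'   `var_H`, `correction_method`, `L`, `n`.
#' @export
information_summary <- function(freq, correction = small_sample_correction(freq$n)) {
  stopifnot(inherits(freq, "freq_matrix"))
  H <- apply(freq$f, 2L, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  r <- 2 - H - correction$e_n
  sigma <- if (is.na(correction$var_H)) NA_real_ else sqrt(freq$L * correction$var_H)
  structure(list(r = r,
                 Rsequence = sum(r),
                 sigma_Rsequence = sigma,
                 e_n = correction$e_n,
                 var_H = correction$var_H,
                 correction_method = correction$method,
                 L = freq$L, n = freq$n),
            class = "info_summary")
}

#' @export
print.info_summary <- function(x, ...) {
  cat(sprintf("info_summary: Rsequence = %.2f +/- %.2f bits/site (n = %d, L = %d, e_n = %.4f)\n",
              x$Rsequence, x$sigma_Rsequence, x$n, x$L, x$e_n))
  invisible(x)
}

#' Information needed to locate gamma sites among G genomic positions
#'
#' `Rfrequency = log2(G / gamma)` bits/site. `G` counts single-strand
#' positions: with the 4,641,652-bp E. coli chromosome and 9 sites this
#' gives the canonical 18.98 bits/site.
#'
#' @param G Number of genomic positions (>= `gamma`).
#' @param gamma Number of sites (>= 1).
#' @return Bits per site.
#' @export
rfrequency <- function(G, gamma) {
  if (gamma < 1) stop("gamma must be >= 1")
  if (G < gamma) stop("G must be >= gamma")
  log2(G / gamma)
}

#' Predicted number of sites implied by the measured information content
#'
#' Inverts the Rfrequency relation: `gamma = G * 2^(-Rsequence)`. The
#' uncertainty is propagated to first order,
#' `sigma_gamma = gamma * ln(2) * sigma`.
#'
#' @param G Number of genomic positions.
#' @param Rsequence Measured information content, bits/site.
#' @param sigma Uncertainty of `Rsequence`, bits/site.
#' @return A list with `gamma_predicted` and `sigma_gamma` (sites,
#'   unrounded).
#' @export
predict_site_count <- function(G, Rsequence, sigma = 0) {
  stopifnot(G >= 1)
  gamma <- G * 2^(-Rsequence)
  list(gamma_predicted = gamma, sigma_gamma = gamma * log(2) * sigma)
}

#' Individual-information weight matrix from aligned-site frequencies
#'
#' Weights are `w(b, l) = 2 + log2 f*(b, l) - e(n)` bits. With
#' `pseudocount = "none"`, `f*` is the raw frequency and unobserved bases
#' get a `-Inf` sentinel (any window using one is unscorable); with
#' `"jeffreys"`, `f* = (counts + 1/4) / (n + 1)`.
#'
#' @param freq A [freq_matrix()].
#' @param correction Result of [small_sample_correction()].
#' @param pseudocount `"none"` (default) or `"jeffreys"`.
#' @return An object of class `riw_matrix` with `w` (4 x L), `e_n`,
#'   `pseudocount`, `L`, `n`.
#' @export
build_riw <- function(freq, correction = small_sample_correction(freq$n),
                      pseudocount = c("none", "jeffreys")) {
  stopifnot(inherits(freq, "freq_matrix"))
  pseudocount <- match.arg(pseudocount)
  fstar <- switch(pseudocount,
                  none = freq$f,
                  jeffreys = (freq$counts + 0.25) / (freq$n + 1))
  w <- 2 + log2(fstar) - correction$e_n  # log2(0) = -Inf sentinel
  dimnames(w) <- list(BASES, NULL)
  structure(list(w = w, e_n = correction$e_n, pseudocount = pseudocount,
                 L = freq$L, n = freq$n),
            class = "riw_matrix")
}

#' @export
print.riw_matrix <- function(x, ...) {
  cat("riw_matrix: ", x$L, " positions, n = ", x$n,
      ", pseudocount = ", x$pseudocount, "\n", sep = "")
  invisible(x)
}

#' Individual information of windows under a weight matrix
#'
#' `Ri = sum_l w(base_l, l)` bits. Under `pseudocount = "none"` the mean
#' of `Ri` over the training sites equals `Rsequence` exactly. Windows
#' containing `N` are rejected (scored `NA`); a `-Inf` sentinel
#' propagates.
#'
#' @param riw A [build_riw()] matrix.
#' @param windows Character vector of DNA strings of length `riw$L`.
#' @return Numeric vector of `Ri` scores, bits.
#' @export
individual_information <- function(riw, windows) {
  stopifnot(inherits(riw, "riw_matrix"), is.character(windows))
  len <- nchar(windows)
  if (any(len != riw$L))
    stop("windows must have length ", riw$L)
  vapply(windows, function(s) {
    codes <- encode_dna(toupper(s))
    if (anyNA(codes)) return(NA_real_)
    sum(riw$w[cbind(codes, seq_len(riw$L))])
  }, 0, USE.NAMES = FALSE)
}

# score every forward window of `codes` under weight matrix w (4 x L);
# windows touching an N score NA.
score_windows <- function(codes, w) {
  L <- ncol(w)
  n_win <- length(codes) - L + 1L
  if (n_win < 1L) return(numeric(0))
  s <- numeric(n_win)
  bad <- rep(FALSE, n_win)
  starts <- seq_len(n_win)
  for (l in seq_len(L)) {
    v <- codes[starts + l - 1L]
    na <- is.na(v)
    bad <- bad | na
    s <- s + ifelse(na, 0, w[cbind(ifelse(na, 1L, v), l)])
  }
  s[bad] <- NA_real_
  s
}

#' Scan a genome with an individual-information weight matrix
#'
#' Every window of length `riw$L` on both strands is scored; windows with
#' `Ri` strictly above `threshold` are reported. Loci hit on both strands
#' at the same forward interval are collapsed to one record (canonical
#' strand `+`).
#'
#' @param genome A [genome_sequence()].
#' @param riw A [build_riw()] matrix.
#' @param threshold Bits; strict `>` cutoff (the canonical scan uses 9.4
#'   bits, the lowest information content among the proven sites).
#' @return A data frame `seq_id`, `start`, `end`, `strand`, `strands`,
#'   `ri` (canonical strand), `ri_plus`, `ri_minus`, sorted by `start`.
#' @export
scan_riw <- function(genome, riw, threshold) {
  stopifnot(inherits(genome, "genome_sequence"), inherits(riw, "riw_matrix"))
  L <- riw$L
  empty <- data.frame(seq_id = character(), start = integer(), end = integer(),
                      strand = character(), strands = character(),
                      ri = numeric(), ri_plus = numeric(), ri_minus = numeric(),
                      stringsAsFactors = FALSE)
  if (genome$length < L) return(empty)
  codes <- encode_dna(genome$residues)
  s_plus <- score_windows(codes, riw$w)
  w_rc <- riw$w[COMP_CODE, L:1, drop = FALSE]
  rownames(w_rc) <- BASES
  s_minus <- score_windows(codes, w_rc)
  hit_plus <- !is.na(s_plus) & s_plus > threshold
  hit_minus <- !is.na(s_minus) & s_minus > threshold
  starts <- sort(unique(c(which(hit_plus), which(hit_minus))))
  if (length(starts) == 0L) return(empty)
  on_plus <- hit_plus[starts]
  on_minus <- hit_minus[starts]
  strand <- ifelse(on_plus, "+", "-")
  data.frame(
    seq_id = genome$id,
    start = starts,
    end = starts + L - 1L,
    strand = strand,
    strands = ifelse(on_plus & on_minus, "+/-", strand),
    ri = ifelse(on_plus, s_plus[starts], s_minus[starts]),
    ri_plus = s_plus[starts],
    ri_minus = s_minus[starts],
    stringsAsFactors = FALSE
  )
}

#' Across-site standard error of the mean individual information
#'
#' Because the mean individual information of the training sites equals
#' `Rsequence` (pseudocount `"none"`), the standard error of that mean —
#' `sd(Ri) / sqrt(n)` — estimates the sampling uncertainty of
#' `Rsequence` from the site-to-site spread itself, with no null-model
#' assumption. This is the natural "plus/minus" to quote next to
#' `Rsequence` for a small site collection and the scale used by the
#' parameter-recovery checks.
#'
#' @param riw A [build_riw()] matrix.
#' @param sites The aligned training sites the matrix was built from.
#' @return Standard error in bits/site.
#' @export
rsequence_se_sites <- function(riw, sites) {
  ri <- individual_information(riw, sites)
  stats::sd(ri) / sqrt(length(ri))
}

#' Sequence-logo table with helical-face sine overlay
#'
#' One row per alignment position: logo coordinate (0 at the site
#' center), per-base stack heights proportional to `f(b,l) * r(l)`
#' (clipped at zero for positions with negative information), the
#' per-position information, and a cosine overlay with a 10.6-bp helical
#' period peaking at coordinate 0 — the face of the DNA major groove
#' presented to the bound protein.
#'
#' @param freq A [freq_matrix()].
#' @param info Matching [information_summary()].
#' @param left_offset Bases left of logo coordinate 0 (default 20 for the
#'   42-bp window).
#' @param period Helical period in bp (default 10.6).
#' @param amplitude Sine overlay amplitude (default 1).
#' @return A data frame with columns `position`, `coord`, `r`,
#'   `height_A`..`height_T`, `sine`.
#' @export
logo_table <- function(freq, info, left_offset = 20L, period = 10.6,
                       amplitude = 1) {
  stopifnot(inherits(freq, "freq_matrix"), inherits(info, "info_summary"),
            freq$L == info$L)
  coord <- seq_len(freq$L) - 1L - left_offset
  h <- t(freq$f) * pmax(info$r, 0)  # L x 4
  out <- data.frame(position = seq_len(freq$L),
                    coord = coord,
                    r = info$r,
                    height_A = h[, "A"], height_C = h[, "C"],
                    height_G = h[, "G"], height_T = h[, "T"],
                    sine = amplitude * cos(2 * pi * coord / period))
  out
}

#' Serialize an information model (counts, correction, offsets) to JSON
#'
#' @param freq A [freq_matrix()].
#' @param correction Result of [small_sample_correction()].
#' @param path Output path.
#' @param left_offset,right_offset Window offsets the model was built with.
#' @return `path`, invisibly.
#' @export
write_info_model <- function(freq, correction, path,
                             left_offset = 20L, right_offset = 21L) {
  obj <- list(counts = unname(freq$counts), n = freq$n, L = freq$L,
              e_n = correction$e_n, var_H = correction$var_H,
              method = correction$method,
              left_offset = left_offset, right_offset = right_offset)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an information model written by [write_info_model()]
#'
#' @param path Path to the JSON model.
#' @return A list with `freq` (a [freq_matrix()]), `correction`, and the
#'   stored window offsets.
#' @export
read_info_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  counts <- matrix(as.integer(obj$counts), nrow = 4L,
                   dimnames = list(BASES, NULL))
  freq <- structure(list(counts = counts, f = counts / obj$n,
                         n = as.integer(obj$n), L = as.integer(obj$L)),
                    class = "freq_matrix")
  correction <- list(e_n = obj$e_n, var_H = obj$var_H, method = obj$method,
                     n = as.integer(obj$n))
  list(freq = freq, correction = correction,
       left_offset = as.integer(obj$left_offset),
       right_offset = as.integer(obj$right_offset))
}
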