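# Independent oracles used across the suite. These deliberately take the
# slow, direct route (per-window matching, full composition enumeration)
# so they share no code path with the vectorized implementations.

# all-windows, both-strand consensus scan via the single-window matcher
naive_scan_consensus <- function(genome, motif = consensus_motif()) {
  L <- motif$length
  rows <- list()
  if (genome$length >= L) {
    for (s in seq_len(genome$length - L + 1L)) {
      w <- substr(genome$residues, s, s + L - 1L)
      plus <- match_consensus(w, motif)
      minus <- match_consensus(revcomp(w), motif)
      if (isTRUE(plus$hit) || isTRUE(minus$hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = s, end = s + L - 1L,
          on_plus = isTRUE(plus$hit), on_minus = isTRUE(minus$hit),
          mm_plus = plus$mismatches, mm_minus = minus$mismatches)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      on_plus = logical(), on_minus = logical()))
  do.call(rbind, rows)
}

# all-windows, both-strand weight-matrix scan via individual_information
naive_scan_riw <- function(genome, riw, threshold) {
  L <- riw$L
  rows <- list()
  if (genome$length >= L) {
    for (s in seq_len(genome$length - L + 1L)) {
      w <- substr(genome$residues, s, s + L - 1L)
      ri_p <- individual_information(riw, w)
      ri_m <- individual_information(riw, revcomp(w))
      hp <- !is.na(ri_p) && ri_p > threshold
      hm <- !is.na(ri_m) && ri_m > threshold
      if (hp || hm) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = s, on_plus = hp, on_minus = hm,
          ri_plus = ri_p, ri_minus = ri_m)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), on_plus = logical(),
                      on_minus = logical()))
  do.call(rbind, rows)
}

# brute-force entropy-bias oracle: sum over all compositions of n into 4
# parts with multinomial weights under the uniform base distribution
enum_correction <- function(n) {
  comps <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
  comps <- comps[rowSums(comps) <= n, , drop = FALSE]
  comps$d <- n - rowSums(comps)
  H <- apply(comps, 1L, function(k) {
    f <- k / n
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  logp <- apply(comps, 1L, function(k) {
    lgamma(n + 1) - sum(lgamma(k + 1)) + n * log(0.25)
  })
  p <- exp(logp)
  EH <- sum(p * H)
  list(e_n = 2 - EH, var_H = sum(p * H^2) - EH^2)
}

# background genome rejected and re-drawn until the consensus scan finds
# nothing, so planted-site counts are exact by construction
clean_background <- function(length, motif = consensus_motif(), seed = 1L,
                             max_tries = 50L) {
  for (k in seq_len(max_tries)) {
    g <- synth_genome(length, seed = seed + 1000L * (k - 1L))
    if (nrow(scan_consensus(g$genome, motif)) == 0L) return(g$genome)
  }
  stop("could not draw a hit-free background in ", max_tries, " tries")
}

random_dna <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}
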