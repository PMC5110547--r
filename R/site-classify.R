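#' Label operators as gene-regulatory or chromosome-anchoring sites
#'
#' An operator is a Gene Regulatory Site (GRS) when it lies within a
#' promoter-relative window — by default -200 to +400 bp — of at least
#' one transcription start point (tsp); otherwise it is a Chromosome
#' Anchoring Site (CAS), a site proposed to play an architectural role.
#' Offsets are measured strand-aware from the operator's dyad center
#' (the midpoint between positions 8 and 9 of the 16-mer, rounded down):
#' for a plus-strand tsp at `t` the offset is `center - t`; for a
#' minus-strand tsp it is `t - center`, so negative offsets are always
#' promoter-upstream.
#'
#' @param operators Data frame with `start`, `end` and optionally
#'   `seq_id`, `name`.
#' @param tss Data frame of TSS records with `gene`, `tsp`, `strand`
#'   (and optionally `seq_id`, matched against the operators' when both
#'   are present).
#' @param window Length-2 numeric, the closed promoter-relative interval
#'   that qualifies a site as GRS (default `c(-200, 400)`).
#' @return The operator table with added columns `center`, `label`
#'   (`GRS`/`CAS`), `cognate_gene` (gene of the nearest qualifying tsp,
#'   `NA` for CAS) and `offset` (bp to that tsp; for CAS, the offset to
#'   the nearest tsp of any distance, `NA` when there is none).
#' @export
classify_operators <- function(operators, tss, window = c(-200, 400)) {
  stopifnot(all(c("start", "end") %in% names(operators)),
            length(window) == 2L, window[1] <= window[2])
  n <- nrow(operators)
  center <- as.integer(floor((operators$start + operators$end) / 2))
  label <- rep("CAS", n)
  cognate <- rep(NA_character_, n)
  offset <- rep(NA_integer_, n)
  if (nrow(tss) == 0L) {
    warning("empty tss table: all operators labeled CAS")
  } else {
    has_seq <- "seq_id" %in% names(operators) && "seq_id" %in% names(tss)
    for (i in seq_len(n)) {
      t <- if (has_seq) tss[tss$seq_id == operators$seq_id[i], , drop = FALSE] else tss
      if (nrow(t) == 0L) next
      off <- ifelse(t$strand == "+", center[i] - t$tsp, t$tsp - center[i])
      qual <- off >= window[1] & off <= window[2]
      if (any(qual)) {
        j <- which(qual)[which.min(abs(off[qual]))]
        label[i] <- "GRS"
        cognate[i] <- t$gene[j]
        offset[i] <- off[j]
      } else {
        offset[i] <- off[which.min(abs(off))]
      }
    }
  }
  out <- operators
  out$center <- center
  out$label <- label
  out$cognate_gene <- cognate
  out$offset <- offset
  out
}

#' Summarize a GRS/CAS partition
#'
#' @param labeled Output of [classify_operators()], or any data frame
#'   with a `label` column over `GRS`/`CAS`.
#' @return A list with `n_GRS`, `n_CAS`, `pct_GRS`, `pct_CAS`
#'   (percentages rounded to integers) and `empty` (`TRUE` when there
#'   were no operators, in which case percentages are reported as 0).
#' @export
partition_summary <- function(labeled) {
  n_grs <- sum(labeled$label == "GRS")
  n_cas <- sum(labeled$label == "CAS")
  total <- n_grs + n_cas
  if (total == 0L) {
    return(list(n_GRS = 0L, n_CAS = 0L, pct_GRS = 0L, pct_CAS = 0L,
                empty = TRUE))
  }
  list(n_GRS = n_grs, n_CAS = n_cas,
       pct_GRS = as.integer(round(100 * n_grs / total)),
       pct_CAS = as.integer(round(100 * n_cas / total)),
       empty = FALSE)
}
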