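# Local complementarity alignment, the miRanda-style decision axis: a
# Smith-Waterman dynamic program over antiparallel miRNA:target pairing with
# seed-position weighting.

#' Local complementarity alignment score
#'
#' Best local antiparallel alignment of the miRNA against a target window,
#' scored on complementarity: Watson-Crick pair +5, GU wobble +2, mismatch
#' -3, gap open -8, gap extend -2. Contributions at positions opposite
#' miRNA nucleotides 2-8 (the seed) are doubled. The score of the empty
#' alignment is 0, so the result is never negative.
#'
#' @param mirna a [mature_mirna()] or plain sequence.
#' @param utr_window target window, 5'->3', at most 60 nt.
#' @return dimensionless alignment score (>= 0).
#' @export
align_score <- function(mirna, utr_window) {
  m <- if (inherits(mirna, "MatureMirna")) mirna$sequence else as_rna(mirna)
  w <- as_rna(utr_window)
  if (nchar(w) > 60L)
    format_error("align_score: window longer than 60 nt (%d)", nchar(w))
  if (!nchar(w) || !nchar(m)) return(0)
  M <- seq_chars(m)
  # antiparallel: miRNA 5'->3' runs against the window 3'->5'
  W <- rev(seq_chars(w))
  n <- length(M); L <- length(W)
  match_wc <- 5; match_gu <- 2; mismatch <- -3
  gap_open <- -8; gap_extend <- -2
  seed_weight <- ifelse(seq_len(n) >= 2L & seq_len(n) <= 8L, 2, 1)
  NEG <- -1e9
  H <- matrix(0, n + 1L, L + 1L)    # best alignment ending at (i, j)
  Eg <- matrix(NEG, n + 1L, L + 1L) # gap in miRNA (consumes window)
  Fg <- matrix(NEG, n + 1L, L + 1L) # gap in window (consumes miRNA)
  best <- 0
  for (i in 2L:(n + 1L)) {
    mi <- M[i - 1L]; wt <- seed_weight[i - 1L]
    for (j in 2L:(L + 1L)) {
      wj <- W[j - 1L]
      s <- if (is_wc_pair(mi, wj)) match_wc else if (is_gu_pair(mi, wj)) match_gu else mismatch
      s <- s * wt
      Eg[i, j] <- max(H[i, j - 1L] + gap_open, Eg[i, j - 1L] + gap_extend)
      Fg[i, j] <- max(H[i - 1L, j] + gap_open, Fg[i - 1L, j] + gap_extend)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + s, Eg[i, j], Fg[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}
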