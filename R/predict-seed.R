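# Canonical seed-match scanning. The seed is nucleotides 2-8 of the mature
# miRNA (5'->3'); target sites are reverse-complement matches in the 3'UTR,
# graded 8mer > 7mer-m8 > 7mer-A1 > 6mer.

SEED_CLASSES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

seed_class_rank <- function(class) match(class, SEED_CLASSES)

#' Construct a mature miRNA
#'
#' @param mirna_id identifier.
#' @param sequence mature sequence 5' to 3', 18-26 nt; T is accepted and
#'   normalized to U.
#' @return a `MatureMirna` list.
#' @export
mature_mirna <- function(mirna_id, sequence) {
  sequence <- as_rna(sequence)
  if (grepl("[^ACGU]", sequence))
    format_error("miRNA '%s': sequence contains non-ACGU characters", mirna_id)
  if (nchar(sequence) < 18L || nchar(sequence) > 26L)
    format_error("miRNA '%s': mature length must be 18-26 nt, got %d",
                 mirna_id, nchar(sequence))
  structure(list(mirna_id = mirna_id, sequence = sequence),
            class = "MatureMirna")
}

#' Seed sequences of a mature miRNA
#'
#' Returns the 7-nt seed (positions 2-8, 1-based from the 5' end) and the
#' 6-nt seed (positions 2-7).
#'
#' @param mirna a [mature_mirna()] or a plain sequence string (>= 8 nt).
#' @return list with `seed7` and `seed6`.
#' @export
seed_of <- function(mirna) {
  seq <- if (inherits(mirna, "MatureMirna")) mirna$sequence else as_rna(mirna)
  if (nchar(seq) < 8L)
    format_error("seed_of: sequence shorter than 8 nt")
  list(seed7 = substr(seq, 2L, 8L), seed6 = substr(seq, 2L, 7L))
}

# All (possibly overlapping) occurrences of `pattern` in `s`; 1-based
# starts. Zero-width lookahead so overlapping matches are all reported.
find_all_occurrences <- function(pattern, s) {
  if (nchar(pattern) > nchar(s)) return(integer())
  r <- gregexpr(paste0("(?=", pattern, ")"), s, perl = TRUE)[[1L]]
  if (r[1L] == -1L) integer() else as.integer(r)
}

#' Scan a 3'UTR for canonical seed-match sites
#'
#' Scans the UTR 5'->3' for reverse-complement seed matches:
#' 8mer = rc(seed7) followed by A (the A faces miRNA position 1);
#' 7mer-m8 = rc(seed7); 7mer-A1 = rc(seed6) followed by A; 6mer = rc(seed6).
#' Overlapping matches are reported at the highest class only. Intervals are
#' 0-based half-open on the UTR and cover the full matched substring.
#'
#' @param mirna a [mature_mirna()].
#' @param utr UTR sequence (RNA or DNA; case-insensitive).
#' @param mrna_id optional id recorded in the output.
#' @return data.frame with columns `mirna_id`, `mrna_id`, `start`, `end`,
#'   `seed_class`, ordered by `start`.
#' @export
find_seed_sites <- function(mirna, utr, mrna_id = NA_character_) {
  stopifnot(inherits(mirna, "MatureMirna"))
  utr <- as_rna(utr)
  seeds <- seed_of(mirna)
  patterns <- list(
    "8mer"    = paste0(reverse_complement(seeds$seed7), "A"),
    "7mer-m8" = reverse_complement(seeds$seed7),
    "7mer-A1" = paste0(reverse_complement(seeds$seed6), "A"),
    "6mer"    = reverse_complement(seeds$seed6)
  )
  taken_start <- integer(); taken_end <- integer()
  rows <- list()
  for (cls in SEED_CLASSES) {
    pat <- patterns[[cls]]
    k <- nchar(pat)
    for (pos in find_all_occurrences(pat, utr)) {
      s0 <- pos - 1L; e0 <- s0 + k  # 0-based half-open
      overlaps <- length(taken_start) &&
        any(s0 < taken_end & e0 > taken_start)
      if (!overlaps) {
        taken_start <- c(taken_start, s0); taken_end <- c(taken_end, e0)
        rows[[length(rows) + 1L]] <-
          data.frame(mirna_id = mirna$mirna_id, mrna_id = mrna_id,
                     start = s0, end = e0, seed_class = cls,
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(), mrna_id = character(),
               start = integer(), end = integer(), seed_class = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
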