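# Thermodynamic stand-ins: an intermolecular duplex minimum-free-energy
# model over a reduced nearest-neighbor stack table, and a site-accessibility
# score based on a maximum-base-pairing (Nussinov) fold of the local target
# structure. The energy model is deliberately small and fully documented so
# every value can be hand-checked; see the shipped stack table
# (extdata/stack_energies.tsv) and duplex_energy_model().

# cached energy model (stack table lives in extdata so users can audit it)
.mp_env <- new.env(parent = emptyenv())

#' The duplex energy model
#'
#' Stacking energies for two adjacent base pairs are looked up by the
#' miRNA-side dinucleotide (5'->3') when both pairs are Watson-Crick; any
#' stack involving a GU wobble pair uses the flat `gu_stack` value. Bulges
#' and internal loops carry an affine penalty `loop_open + loop_extend *
#' (unpaired nucleotides)`, capped at `max_loop` unpaired nucleotides per
#' strand. Units: kcal/mol.
#'
#' @return list with `stacks` (named numeric, 16 Watson-Crick dinucleotide
#'   stacks), `gu_stack`, `loop_open`, `loop_extend`, `max_loop`.
#' @export
duplex_energy_model <- function() {
  if (is.null(.mp_env$model)) {
    tab <- utils::read.delim(
      system.file("extdata", "stack_energies.tsv", package = "mirpair"),
      stringsAsFactors = FALSE)
    .mp_env$model <- list(
      stacks = setNames(tab$energy_kcal_mol, tab$dinucleotide),
      gu_stack = -0.5, loop_open = 4.0, loop_extend = 1.0, max_loop = 8L)
  }
  .mp_env$model
}

# Energy of stacking pair (m1:t1) on top of pair (m2:t2), m1/m2 consecutive
# miRNA bases 5'->3'. GU wobbles get the flat wobble stack.
stack_energy <- function(m1, m2, t1, t2, model) {
  if (is_gu_pair(m1, t1) || is_gu_pair(m2, t2)) return(model$gu_stack)
  unname(model$stacks[paste0(m1, m2)])
}

#' Minimum free energy of a miRNA:target duplex
#'
#' Best antiparallel intermolecular hybrid between the full miRNA and a
#' target window, without intramolecular structure: consecutive base pairs
#' accrue nearest-neighbor stack energies, bulges/internal loops an affine
#' penalty (see [duplex_energy_model()]). Pairs are Watson-Crick or GU. The
#' result is <= 0 (a lone pair scores 0); if the two sequences admit no pair
#' at all, `NA` is returned as the "no duplex" sentinel.
#'
#' @param mirna a [mature_mirna()] or plain sequence.
#' @param utr_window target window, 5'->3', at most 40 nt.
#' @return energy in kcal/mol (<= 0), or `NA_real_` when no pair exists.
#' @export
duplex_mfe <- function(mirna, utr_window) {
  m <- if (inherits(mirna, "MatureMirna")) mirna$sequence else as_rna(mirna)
  w <- as_rna(utr_window)
  if (nchar(w) > 40L)
    format_error("duplex_mfe: window longer than 40 nt (%d)", nchar(w))
  if (!nchar(m) || !nchar(w)) return(NA_real_)
  model <- duplex_energy_model()
  M <- seq_chars(m); W <- seq_chars(w)
  n <- length(M); L <- length(W)
  # pairs are (i, j): miRNA position i (5'->3') with window position j;
  # antiparallel means successive pairs have increasing i and DECREASING j.
  pairable <- outer(M, W, can_pair)
  if (!any(pairable)) return(NA_real_)
  E <- matrix(Inf, n, L)   # E[i,j]: best energy of a hybrid ending in pair (i,j)
  best <- Inf
  maxg <- model$max_loop
  for (i in seq_len(n)) {
    for (j in seq_len(L)) {
      if (!pairable[i, j]) next
      e <- 0  # hybrid consisting of this single pair
      i0 <- max(1L, i - 1L - maxg)
      j1 <- min(L, j + 1L + maxg)
      for (ip in i0:(i - 1L)) {
        if (ip < 1L) break
        for (jp in (j + 1L):j1) {
          if (jp > L) break
          if (!is.finite(E[ip, jp])) next
          g1 <- i - ip - 1L; g2 <- jp - j - 1L
          link <- if (g1 == 0L && g2 == 0L)
            stack_energy(M[ip], M[i], W[jp], W[j], model)
          else
            model$loop_open + model$loop_extend * (g1 + g2)
          if (E[ip, jp] + link < e) e <- E[ip, jp] + link
        }
      }
      E[i, j] <- e
      if (e < best) best <- e
    }
  }
  min(best, 0)
}

#' Maximum base-pairing fold of an RNA sequence
#'
#' Nussinov-style dynamic program maximizing the number of Watson-Crick/GU
#' pairs with a minimum hairpin loop of 3 unpaired nucleotides. Traceback is
#' deterministic (leaving a position unpaired is preferred on ties, then the
#' 5'-most pairing partner).
#'
#' @param seq RNA sequence.
#' @return data.frame with columns `i`, `j` (1-based paired positions,
#'   i < j); zero rows when nothing pairs.
#' @export
nussinov_fold <- function(seq) {
  s <- seq_chars(as_rna(seq))
  n <- length(s)
  empty <- data.frame(i = integer(), j = integer())
  if (n < 5L) return(empty)
  N <- matrix(0L, n, n)
  for (span in 4L:(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- N[i + 1L, j]            # i unpaired
      for (k in (i + 4L):j) {         # i paired with k (min loop 3)
        if (!can_pair(s[i], s[k])) next
        inner <- if (k - i >= 5L) N[i + 1L, k - 1L] else 0L
        rest <- if (k < j) N[k + 1L, j] else 0L
        cand <- 1L + inner + rest
        if (cand > best) best <- cand
      }
      N[i, j] <- best
    }
  }
  pairs <- empty
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    if (i >= j || j - i < 4L || N[i, j] == 0L) next
    if (N[i, j] == N[i + 1L, j]) { stack[[length(stack) + 1L]] <- c(i + 1L, j); next }
    for (k in (i + 4L):j) {
      if (!can_pair(s[i], s[k])) next
      inner <- if (k - i >= 5L) N[i + 1L, k - 1L] else 0L
      rest <- if (k < j) N[k + 1L, j] else 0L
      if (N[i, j] == 1L + inner + rest) {
        pairs <- rbind(pairs, data.frame(i = i, j = k))
        if (k - i >= 5L) stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
        if (k < j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
        break
      }
    }
  }
  pairs[order(pairs$i), , drop = FALSE]
}

# Window the predictors evaluate around a seed site: the site itself plus
# 16 nt upstream (where miRNA 3'-supplementary pairing binds) and 2 nt
# downstream, clipped to the UTR. 0-based half-open in, sequence out.
site_window <- function(utr, start, end, up = 16L, down = 2L) {
  utr <- as_rna(utr)
  s <- max(0L, start - up); e <- min(nchar(utr), end + down)
  substr(utr, s + 1L, e)
}

#' Site-accessibility score (ddG)
#'
#' PITA-style decision axis: ddG = duplex energy of the site window minus
#' the cost of opening local target structure. The opening cost is modeled
#' as 1.0 kcal/mol per base pair that a maximum-base-pairing fold
#' ([nussinov_fold()]) of the site plus `flank` nt on each side places on
#' the site interval. Lower (more negative) ddG = more favorable.
#'
#' @param utr full UTR sequence.
#' @param site_interval integer c(start, end), 0-based half-open on the UTR.
#' @param mirna a [mature_mirna()] (needed for the duplex term).
#' @param flank flanking context on each side, nt (default 17).
#' @return ddG in kcal/mol (`NA` when the site window admits no duplex).
#' @export
accessibility_ddg <- function(utr, site_interval, mirna, flank = 17L) {
  utr <- as_rna(utr)
  start <- site_interval[1L]; end <- site_interval[2L]
  if (start < 0L || end > nchar(utr) || start >= end)
    format_error("accessibility_ddg: site interval [%d,%d) out of bounds for UTR of length %d",
                 start, end, nchar(utr))
  dup <- duplex_mfe(mirna, site_window(utr, start, end))
  if (is.na(dup)) return(NA_real_)
  ctx_start <- max(0L, start - flank)
  ctx_end <- min(nchar(utr), end + flank)
  ctx <- substr(utr, ctx_start + 1L, ctx_end)
  fold <- nussinov_fold(ctx)
  if (nrow(fold)) {
    # positions of the site within the context, 1-based
    lo <- start - ctx_start + 1L; hi <- end - ctx_start
    removed <- sum(fold$i >= lo & fold$i <= hi | fold$j >= lo & fold$j <= hi)
  } else removed <- 0L
  dup + removed * 1.0
}
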