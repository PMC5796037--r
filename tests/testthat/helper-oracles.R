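# Independent oracles used across the suite. Each is written from the
# definition of the quantity it checks and shares no code with the
# implementation paths it verifies.

# naive all-occurrence substring scan (1-based starts)
naive_occurrences <- function(pattern, s) {
  k <- nchar(pattern)
  n <- nchar(s) - k + 1L
  if (n < 1L) return(integer())
  which(vapply(seq_len(n), function(i) substr(s, i, i + k - 1L) == pattern,
               logical(1)))
}

# naive seed-site scanner: windowed substring comparison per class with the
# same highest-class-wins suppression contract, written independently.
naive_seed_sites <- function(mirna_seq, utr) {
  rc <- function(x) {
    comp <- chartr("ACGU", "UGCA", x)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }
  seed7 <- substr(mirna_seq, 2, 8); seed6 <- substr(mirna_seq, 2, 7)
  pats <- list(`8mer` = paste0(rc(seed7), "A"), `7mer-m8` = rc(seed7),
               `7mer-A1` = paste0(rc(seed6), "A"), `6mer` = rc(seed6))
  found <- data.frame(start = integer(), end = integer(),
                      seed_class = character(), stringsAsFactors = FALSE)
  for (cls in names(pats)) {
    for (p in naive_occurrences(pats[[cls]], utr)) {
      s0 <- p - 1L; e0 <- s0 + nchar(pats[[cls]])
      if (nrow(found) == 0L || all(e0 <= found$start | s0 >= found$end))
        found <- rbind(found, data.frame(start = s0, end = e0,
                                         seed_class = cls,
                                         stringsAsFactors = FALSE))
    }
  }
  found[order(found$start), , drop = FALSE]
}

# exhaustive duplex enumeration under the same documented energy model:
# recursively extend ordered pair sets (increasing miRNA index, decreasing
# window index), scoring stacks/loops from the shipped model.
exhaustive_duplex_mfe <- function(m, w) {
  model <- mirpair::duplex_energy_model()
  M <- strsplit(m, "")[[1]]; W <- strsplit(w, "")[[1]]
  n <- length(M); L <- length(W)
  pairable <- function(a, b)
    paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  stack <- function(m1, m2, t1, t2) {
    gu <- function(a, b) paste0(a, b) %in% c("GU", "UG")
    if (gu(m1, t1) || gu(m2, t2)) model$gu_stack else
      unname(model$stacks[paste0(m1, m2)])
  }
  best <- Inf
  extend <- function(i_prev, j_prev, energy) {
    if (energy < best) best <<- energy
    if (i_prev >= n || j_prev <= 1L) return()
    for (i in (i_prev + 1L):n) {
      for (j in (j_prev - 1L):1L) {
        if (!pairable(M[i], W[j])) next
        g1 <- i - i_prev - 1L; g2 <- j_prev - j - 1L
        if (g1 > model$max_loop || g2 > model$max_loop) next
        link <- if (g1 == 0L && g2 == 0L) stack(M[i_prev], M[i], W[j_prev], W[j])
                else model$loop_open + model$loop_extend * (g1 + g2)
        extend(i, j, energy + link)
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(L))
    if (pairable(M[i], W[j])) extend(i, j, 0)
  if (is.infinite(best)) NA_real_ else min(best, 0)
}

# exhaustive maximum base-pairing count with min hairpin loop 3
exhaustive_max_pairs <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  pairable <- function(a, b)
    paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  rec <- function(lo, hi) {
    if (hi - lo < 4L) return(0L)
    best <- rec(lo + 1L, hi)  # lo unpaired
    for (k in (lo + 4L):hi) {
      if (!pairable(s[lo], s[k])) next
      inner <- if (k - lo >= 5L) rec(lo + 1L, k - 1L) else 0L
      rest <- if (k < hi) rec(k + 1L, hi) else 0L
      best <- max(best, 1L + inner + rest)
    }
    best
  }
  if (n < 5L) 0L else rec(1L, n)
}

# exact hypergeometric upper tail from binomial coefficients (exact in
# double precision for N <= 25)
rational_hypergeom_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# brute-force consensus: enumerate every (feature, direction) combination
# over the DE calls of each dataset
naive_consensus <- function(results, min_datasets) {
  feats <- sort(unique(unlist(lapply(results, function(r) r$records$feature_id))))
  out <- data.frame(feature_id = character(), direction = character(),
                    stringsAsFactors = FALSE)
  for (f in feats) {
    kept <- character()
    for (dir in c("down", "up")) {
      n <- sum(vapply(results, function(r) {
        any(r$records$feature_id == f & r$records$direction == dir)
      }, logical(1)))
      if (n >= min_datasets) kept <- c(kept, dir)
    }
    if (length(kept) == 1L)
      out <- rbind(out, data.frame(feature_id = f, direction = kept,
                                   stringsAsFactors = FALSE))
  }
  out
}

# random RNA string
rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                              collapse = "")

# minimal DatasetDEResult for constructed consensus inputs
fake_de_result <- function(dataset_id, feature_ids, directions) {
  structure(list(
    dataset_id = dataset_id, feature_class = "mirna",
    thresholds = de_thresholds(),
    records = data.frame(feature_id = feature_ids, log2fc = ifelse(directions == "up", 1, ifelse(directions == "down", -1, 0)),
                         t = NA_real_, df = NA_real_,
                         p = ifelse(directions == "none", 0.9, 1e-4),
                         direction = directions, stringsAsFactors = FALSE)),
    class = "DatasetDEResult")
}
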