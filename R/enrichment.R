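# Over-representation analysis against a user-supplied GMT collection:
# hypergeometric tail (optionally the conservative EASE variant) with
# Benjamini-Hochberg adjustment.

#' Upper hypergeometric tail probability
#'
#' P(X >= k) when drawing `n` genes from a background of `N` of which `K`
#' belong to the set. Computed through the hypergeometric distribution in
#' log space for numerical stability at extreme tails.
#'
#' @param k observed hits in the list.
#' @param K set size within the background.
#' @param n list size.
#' @param N background size.
#' @return the tail probability.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (k < 0 || K > N || n > N || k > min(K, n))
    format_error("hypergeom_tail: inconsistent counts (k=%d K=%d n=%d N=%d)",
                 k, K, n, N)
  if (k == 0) return(1)
  # P(X >= k) = P(X > k-1); exp(log) round-trip keeps the log-space path
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, mapped back to the
#' input order.
#'
#' @param pvalues numeric vector of p-values.
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis of a gene list
#'
#' One result per term with at least one hit; the p-value is the
#' hypergeometric tail of the observed overlap given the background, and
#' `use_ease = TRUE` switches to the conservative EASE variant (one hit
#' removed: tail at k-1). Genes absent from the background are dropped with
#' a warning. The default background is the union of all set members.
#'
#' @param gene_list character vector of gene ids.
#' @param gene_sets a `GeneSetCollection` from [read_gmt()].
#' @param background background gene universe (default: union of all sets).
#' @param use_ease use the EASE score (k-1 tail) as the reported `ease_p`.
#' @return data.frame sorted by p-value with columns `term_id`, `term_name`,
#'   `k`, `K`, `n`, `N`, `p_value`, `q_value`, and `ease_p` when requested.
#' @export
enrich <- function(gene_list, gene_sets, background = NULL, use_ease = FALSE) {
  if (is.null(background)) background <- unique(unlist(gene_sets))
  background <- unique(background)
  if (!length(background)) format_error("enrich: empty background")
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, background)
  if (length(outside)) {
    warning(sprintf("enrich: dropping %d gene(s) absent from the background",
                    length(outside)))
    gene_list <- intersect(gene_list, background)
  }
  N <- length(background); n <- length(gene_list)
  term_names <- attr(gene_sets, "term_names")
  rows <- lapply(names(gene_sets), function(term) {
    members <- intersect(gene_sets[[term]], background)
    K <- length(members)
    k <- length(intersect(gene_list, members))
    if (k < 1L) return(NULL)
    data.frame(term_id = term,
               term_name = if (!is.null(term_names)) term_names[[term]] else term,
               k = k, K = K, n = n, N = N,
               p_value = hypergeom_tail(k, K, n, N),
               ease_p = if (use_ease) hypergeom_tail(max(0L, k - 1L), K, n, N)
                        else NA_real_,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(), q_value = numeric(),
                      ease_p = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$term_id),
             c("term_id", "term_name", "k", "K", "n", "N",
               "p_value", "q_value", "ease_p")]
  if (!use_ease) out$ease_p <- NULL
  rownames(out) <- NULL
  out
}
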