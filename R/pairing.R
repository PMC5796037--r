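# Integration of consensus differential expression, inverse Pearson
# correlation on matched samples, and predictor-consensus sites into the
# final miRNA-mRNA pair table.

#' Pearson correlation with a t-transform p-value
#'
#' Standard product-moment correlation; the two-sided p-value comes from
#' t = r * sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom (the same
#' transform `stats::cor.test` uses).
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3L)
    format_error("pearson_r: need equal-length vectors with n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    mp_stop("mirpair_constant_error", "pearson_r: constant vector, correlation undefined")
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t), n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Build the integrated miRNA-mRNA pair table
#'
#' A pair (miRNA m, mRNA g) is emitted iff (a) m and g carry strictly
#' opposite consensus directions, (b) their expression across matched
#' samples is negatively correlated (`r < r_threshold` with `p < alpha`),
#' and (c) in all-three mode at least one consensus-predicted site for m
#' lies in g's UTR. Because miRNAs act as negative regulators, (a) and (b)
#' jointly encode miRNA-mediated repression. Correlation is computed on
#' tumor samples only by default: pooling tumor with normal inflates |r|
#' through the group shift.
#'
#' @param mirna_consensus,mrna_consensus consensus tables from
#'   [consensus_mirna()] / [consensus_mrna()].
#' @param matched_mirna_dataset,matched_mrna_dataset matched-sample
#'   [expression_dataset()] pair with an identical ordered sample list.
#' @param sites predicted-site table (as from [predict_targets()]); ignored
#'   when `require_sites = FALSE`.
#' @param r_threshold correlation cutoff (default 0: any significantly
#'   negative r).
#' @param alpha significance level for the correlation test.
#' @param tumor_only correlate over tumor samples only (default) or all
#'   matched samples.
#' @param require_sites require >= 1 predicted site (all-three mode).
#' @return data.frame of `TargetPair` rows: `mirna_id`, `mirna_direction`,
#'   `mrna_id`, `mrna_direction`, `pearson_r`, `r_pvalue`,
#'   `n_matched_samples`, `n_sites`, `n_predictors`, sorted by
#'   (`mirna_id`, `mrna_id`). Pairs with sites that fail the correlation
#'   filter are in the `sidecar` attribute; pairs skipped for constant
#'   expression in the `skipped` attribute.
#' @export
build_pairs <- function(mirna_consensus, mrna_consensus,
                        matched_mirna_dataset, matched_mrna_dataset,
                        sites, r_threshold = 0.0, alpha = 0.05,
                        tumor_only = TRUE, require_sites = TRUE) {
  if (!identical(matched_mirna_dataset$sample_ids,
                 matched_mrna_dataset$sample_ids))
    format_error("build_pairs: matched datasets must share an identical ordered sample list")
  keep <- if (tumor_only)
    matched_mirna_dataset$group_labels == "tumor" else
    rep(TRUE, length(matched_mirna_dataset$sample_ids))
  if (sum(keep) < 3L)
    format_error("build_pairs: fewer than 3 matched samples for correlation")

  empty <- data.frame(mirna_id = character(), mirna_direction = character(),
                      mrna_id = character(), mrna_direction = character(),
                      pearson_r = numeric(), r_pvalue = numeric(),
                      n_matched_samples = integer(), n_sites = integer(),
                      n_predictors = integer(), stringsAsFactors = FALSE)
  if (!nrow(mirna_consensus) || !nrow(mrna_consensus)) {
    attr(empty, "sidecar") <- empty; attr(empty, "skipped") <- character()
    return(empty)
  }

  site_key <- if (!is.null(sites) && nrow(sites))
    paste(sites$mirna_id, sites$mrna_id, sep = "|") else character()
  rows <- list(); sidecar <- list(); skipped <- character()
  for (i in seq_len(nrow(mirna_consensus))) {
    m <- mirna_consensus$feature_id[i]
    mdir <- mirna_consensus$direction[i]
    if (!m %in% matched_mirna_dataset$feature_ids) next
    mv <- matched_mirna_dataset$values[m, keep]
    for (j in seq_len(nrow(mrna_consensus))) {
      g <- mrna_consensus$feature_id[j]
      gdir <- mrna_consensus$direction[j]
      if (mdir == gdir) next                       # strictly opposite only
      if (!g %in% matched_mrna_dataset$feature_ids) next
      key <- paste(m, g, sep = "|")
      n_sites <- sum(site_key == key)
      if (require_sites && n_sites == 0L) next
      ct <- tryCatch(pearson_r(mv, matched_mrna_dataset$values[g, keep]),
                     mirpair_constant_error = function(e) NULL)
      if (is.null(ct)) { skipped <- c(skipped, key); next }
      n_pred <- if (n_sites > 0L)
        max(sites$n_predictors[site_key == key]) else 0L
      row <- data.frame(mirna_id = m, mirna_direction = mdir,
                        mrna_id = g, mrna_direction = gdir,
                        pearson_r = ct$r, r_pvalue = ct$p,
                        n_matched_samples = ct$n, n_sites = n_sites,
                        n_predictors = n_pred, stringsAsFactors = FALSE)
      if (ct$r < r_threshold && ct$p < alpha)
        rows[[length(rows) + 1L]] <- row
      else if (n_sites > 0L)
        sidecar[[length(sidecar) + 1L]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sidecar") <- if (length(sidecar)) do.call(rbind, sidecar) else empty
  attr(out, "skipped") <- skipped
  out
}

#' Summarize a pair table
#'
#' @param pairs a pair table from [build_pairs()].
#' @return list with `n_pairs`, `n_mirnas`, `n_mrnas`,
#'   `n_up_mirna_down_mrna`, `n_down_mirna_up_mrna`.
#' @export
summarize_pairs <- function(pairs) {
  list(n_pairs = nrow(pairs),
       n_mirnas = length(unique(pairs$mirna_id)),
       n_mrnas = length(unique(pairs$mrna_id)),
       n_up_mirna_down_mrna = sum(pairs$mirna_direction == "up" &
                                    pairs$mrna_direction == "down"),
       n_down_mirna_up_mrna = sum(pairs$mirna_direction == "down" &
                                    pairs$mrna_direction == "up"))
}
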