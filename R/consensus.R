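# Cross-dataset consensus: features kept only when called differentially
# expressed with the same direction in enough independent cohorts.

#' Multi-dataset miRNA consensus
#'
#' A miRNA is retained iff it is called DE with the SAME direction in at
#' least `min_datasets` of the supplied per-dataset results. Features whose
#' conflicting directions both reach the cutoff are dropped (and reported in
#' the `conflicts` attribute). Features that reach exactly
#' `min_datasets - 1` supporting datasets are reported in the `near_miss`
#' attribute for audit of the hard cutoff.
#'
#' @param results list of `DatasetDEResult` objects (from [call_de()]), one
#'   per cohort, with distinct dataset ids.
#' @param min_datasets minimum number of same-direction supporting cohorts.
#' @return data.frame with columns `feature_id`, `direction`,
#'   `supporting_datasets` (comma-joined), `n_support`, sorted by feature id;
#'   attributes `conflicts` and `near_miss`.
#' @export
consensus_mirna <- function(results, min_datasets = 3L) {
  ids <- vapply(results, function(r) r$dataset_id, character(1))
  if (anyDuplicated(ids))
    format_error("duplicate dataset id '%s' in consensus input",
                 ids[duplicated(ids)][1])
  if (length(results) < min_datasets)
    config_error("consensus needs at least min_datasets = %d results, got %d",
                 min_datasets, length(results))
  calls <- do.call(rbind, lapply(results, function(r) {
    de <- r$records[r$records$direction != "none",
                    c("feature_id", "direction"), drop = FALSE]
    if (nrow(de)) de$dataset_id <- r$dataset_id
    de
  }))
  empty <- data.frame(feature_id = character(), direction = character(),
                      supporting_datasets = character(),
                      n_support = integer(), stringsAsFactors = FALSE)
  if (is.null(calls) || !nrow(calls)) {
    attr(empty, "conflicts") <- character()
    attr(empty, "near_miss") <- empty
    return(empty)
  }
  per_feature <- split(calls, calls$feature_id)
  rows <- lapply(per_feature, function(d) {
    counts <- table(d$direction)
    qualifying <- names(counts)[counts >= min_datasets]
    if (length(qualifying) == 1L) {
      sup <- sort(d$dataset_id[d$direction == qualifying])
      return(data.frame(feature_id = d$feature_id[1], direction = qualifying,
                        supporting_datasets = paste(sup, collapse = ","),
                        n_support = length(sup), stringsAsFactors = FALSE))
    }
    NULL
  })
  out <- do.call(rbind, c(list(empty[, 1:4]), rows[!vapply(rows, is.null, logical(1))]))
  out <- out[order(out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  conflicts <- names(per_feature)[vapply(per_feature, function(d) {
    sum(table(d$direction) >= min_datasets) > 1L
  }, logical(1))]
  near <- do.call(rbind, c(list(empty[, 1:4]), lapply(per_feature, function(d) {
    counts <- table(d$direction)
    nm <- names(counts)[counts == min_datasets - 1L]
    if (length(nm) != 1L || any(counts >= min_datasets)) return(NULL)
    sup <- sort(d$dataset_id[d$direction == nm])
    data.frame(feature_id = d$feature_id[1], direction = nm,
               supporting_datasets = paste(sup, collapse = ","),
               n_support = length(sup), stringsAsFactors = FALSE)
  })))
  rownames(near) <- NULL
  if (length(conflicts))
    message("consensus_mirna: dropped ", length(conflicts),
            " feature(s) with conflicting qualifying directions: ",
            paste(conflicts, collapse = ", "))
  attr(out, "conflicts") <- conflicts
  attr(out, "near_miss") <- near
  out
}

#' Two-source mRNA consensus
#'
#' A gene is retained iff DE with the same direction in both the pooled
#' array result and the sequencing result.
#'
#' @param geo_pooled_result `DatasetDEResult` for the pooled array cohorts.
#' @param tcga_result `DatasetDEResult` for the sequencing cohort.
#' @return data.frame as in [consensus_mirna()] with `n_support = 2`.
#' @export
consensus_mrna <- function(geo_pooled_result, tcga_result) {
  consensus_mirna(list(geo_pooled_result, tcga_result), min_datasets = 2L)
}

#' Pool array cohorts into one matrix
#'
#' Column-concatenates datasets on the intersection of their feature sets
#' (an inner join, logged when features are dropped). Sample ids are
#' prefixed with their dataset of origin to keep them unique, and the origin
#' is retained as the `sample_origin` attribute.
#'
#' @param datasets list of [expression_dataset()] objects.
#' @param dataset_id id for the pooled dataset.
#' @return an [expression_dataset()] covering the intersected features.
#' @export
pool_geo_datasets <- function(datasets, dataset_id = "pooled") {
  stopifnot(length(datasets) >= 1L)
  feats <- Reduce(intersect, lapply(datasets, function(d) d$feature_ids))
  if (!length(feats))
    format_error("pool_geo_datasets: empty feature intersection")
  dropped <- sum(vapply(datasets, function(d) length(d$feature_ids), integer(1))) -
    length(feats) * length(datasets)
  if (dropped > 0)
    message("pool_geo_datasets: inner join dropped ", dropped,
            " feature entries outside the common set")
  mats <- lapply(datasets, function(d) d$values[feats, , drop = FALSE])
  sample_ids <- unlist(lapply(datasets, function(d)
    paste(d$dataset_id, d$sample_ids, sep = ".")))
  groups <- unlist(lapply(datasets, function(d) unname(d$group_labels)))
  origin <- unlist(lapply(datasets, function(d)
    rep(d$dataset_id, length(d$sample_ids))))
  values <- do.call(cbind, mats)
  colnames(values) <- sample_ids
  out <- expression_dataset(dataset_id, values, groups,
                            platform = datasets[[1]]$platform,
                            feature_ids = feats, sample_ids = sample_ids)
  out$sample_origin <- setNames(origin, sample_ids)
  out
}
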