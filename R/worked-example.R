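# Bundled worked example: per-cohort log2 fold changes of the nine miRNAs
# reported down-regulated across public gastric-cancer cohorts (three GEO
# series and TCGA STAD). All listed entries were significant in their
# cohorts, so the fixture carries fold changes only and a nominal p-value is
# attached when building DE results.

#' Load the bundled gastric-cancer down-regulated miRNA example
#'
#' Returns the per-cohort log2 fold changes of nine miRNAs reported
#' down-regulated in public gastric-cancer cohorts, as a list of
#' `DatasetDEResult` objects ready for [consensus_mirna()]. Restricting the
#' input to the cohort triple {GSE30070, GSE23739, TCGA_STAD} yields seven
#' consensus miRNAs; the triple {GSE33743, GSE30070, TCGA_STAD} yields two
#' (miR-1-3p and miR-203a-3p).
#'
#' @param datasets cohort ids to include (default: all four).
#' @return list of `DatasetDEResult` objects, one per cohort.
#' @export
gc_mirna_example <- function(datasets = NULL) {
  tab <- utils::read.delim(
    system.file("extdata", "gc_down_mirnas.tsv", package = "mirpair"),
    stringsAsFactors = FALSE)
  if (is.null(datasets)) datasets <- unique(tab$dataset)
  missing <- setdiff(datasets, tab$dataset)
  if (length(missing))
    format_error("gc_mirna_example: unknown dataset(s): %s",
                 paste(missing, collapse = ", "))
  lapply(datasets, function(d) {
    rec <- tab[tab$dataset == d, , drop = FALSE]
    structure(
      list(dataset_id = d, feature_class = "mirna",
           thresholds = de_thresholds(),
           records = data.frame(feature_id = rec$mirna, log2fc = rec$log2fc,
                                t = NA_real_, df = NA_real_, p = 1e-3,
                                direction = ifelse(rec$log2fc < 0, "down", "up"),
                                stringsAsFactors = FALSE)),
      class = "DatasetDEResult")
  })
}
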