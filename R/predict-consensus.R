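# Three-predictor consensus: a candidate seed site is retained only when the
# alignment, duplex-energy and accessibility axes agree (all-three mode), or
# when any of them supports it (union mode).

#' Predictor thresholds
#'
#' Cutoffs for the three target-site predictors. Defaults are calibrated so
#' that canonically 3'-supplemented planted sites pass all three axes while
#' shuffled controls fail; they are configuration, not constants.
#'
#' @param min_align_score minimum local complementarity alignment score.
#' @param max_duplex_mfe maximum (most positive) duplex MFE, kcal/mol.
#' @param max_ddg maximum accessibility ddG, kcal/mol.
#' @param min_seed_class weakest acceptable seed class
#'   (`"8mer" > "7mer-m8" > "7mer-A1" > "6mer"`).
#' @return a `PredictorThresholds` list.
#' @export
predictor_thresholds <- function(min_align_score = 80, max_duplex_mfe = -14,
                                 max_ddg = -5, min_seed_class = "6mer") {
  if (max_duplex_mfe > 0 || max_ddg > 0)
    config_error("energy thresholds must be <= 0 kcal/mol")
  if (!min_seed_class %in% SEED_CLASSES)
    config_error("min_seed_class must be one of %s",
                 paste(SEED_CLASSES, collapse = ", "))
  structure(list(min_align_score = min_align_score,
                 max_duplex_mfe = max_duplex_mfe, max_ddg = max_ddg,
                 min_seed_class = min_seed_class),
            class = "PredictorThresholds")
}

#' Predict target sites of one miRNA on one UTR by predictor consensus
#'
#' Candidate sites come from the seed scanner ([find_seed_sites()], filtered
#' at `min_seed_class`); each is then scored by the three predictors on a
#' window covering the site plus upstream context for 3'-supplementary
#' pairing. In all-three mode a site is reported iff the alignment score,
#' duplex MFE and accessibility ddG all pass their thresholds; in union mode
#' iff at least one passes. The set of passing predictors is recorded per
#' site in `predictors_passed` (comma-joined subset of
#' `seed_align,mfe,accessibility`).
#'
#' @param mirna a [mature_mirna()].
#' @param utr UTR sequence.
#' @param thresholds a [predictor_thresholds()].
#' @param require_all_three all-three consensus (default) or union mode.
#' @param mrna_id optional id recorded in the output.
#' @return data.frame with columns `mirna_id`, `mrna_id`, `start`, `end`,
#'   `seed_class`, `align_score`, `duplex_mfe`, `ddg`, `predictors_passed`,
#'   `n_predictors`.
#' @export
consensus_predict <- function(mirna, utr, thresholds = predictor_thresholds(),
                              require_all_three = TRUE,
                              mrna_id = NA_character_) {
  utr <- as_rna(utr)
  sites <- find_seed_sites(mirna, utr, mrna_id = mrna_id)
  sites <- sites[seed_class_rank(sites$seed_class) <=
                   seed_class_rank(thresholds$min_seed_class), , drop = FALSE]
  empty <- empty_sites_frame()
  if (!nrow(sites)) return(empty)
  rows <- lapply(seq_len(nrow(sites)), function(k) {
    s <- sites[k, ]
    win <- site_window(utr, s$start, s$end)
    aln <- align_score(mirna, win)
    mfe <- duplex_mfe(mirna, win)
    ddg <- accessibility_ddg(utr, c(s$start, s$end), mirna)
    passed <- c(
      if (aln >= thresholds$min_align_score) "seed_align",
      if (!is.na(mfe) && mfe <= thresholds$max_duplex_mfe) "mfe",
      if (!is.na(ddg) && ddg <= thresholds$max_ddg) "accessibility"
    )
    keep <- if (require_all_three) length(passed) == 3L else length(passed) >= 1L
    if (!keep) return(NULL)
    data.frame(mirna_id = s$mirna_id, mrna_id = s$mrna_id,
               start = s$start, end = s$end, seed_class = s$seed_class,
               align_score = aln,
               duplex_mfe = if (is.na(mfe)) NA_real_ else mfe,
               ddg = if (is.na(ddg)) NA_real_ else ddg,
               predictors_passed = paste(passed, collapse = ","),
               n_predictors = length(passed), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predict consensus sites for many miRNAs against many UTRs
#'
#' @param mirnas named character vector of mature sequences (as from
#'   [read_fasta()]) or list of [mature_mirna()] objects.
#' @param utrs named character vector of UTR sequences.
#' @param thresholds a [predictor_thresholds()].
#' @param require_all_three all-three consensus (default) or union mode.
#' @return row-bound data.frame of [consensus_predict()] results.
#' @export
predict_targets <- function(mirnas, utrs, thresholds = predictor_thresholds(),
                            require_all_three = TRUE) {
  if (!is.list(mirnas))
    mirnas <- lapply(names(mirnas), function(id) mature_mirna(id, mirnas[[id]]))
  res <- lapply(mirnas, function(m) {
    per_utr <- lapply(names(utrs), function(g)
      consensus_predict(m, utrs[[g]], thresholds,
                        require_all_three = require_all_three, mrna_id = g))
    do.call(rbind, per_utr)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(empty_sites_frame())
  rownames(out) <- NULL
  out
}

empty_sites_frame <- function() {
  data.frame(mirna_id = character(), mrna_id = character(),
             start = integer(), end = integer(),
             seed_class = character(), align_score = numeric(),
             duplex_mfe = numeric(), ddg = numeric(),
             predictors_passed = character(),
             n_predictors = integer(), stringsAsFactors = FALSE)
}
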