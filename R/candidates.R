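# Candidate-target nomination for one miRNA: predicted targets intersected
# with overexpression down-regulation, filtered by functional annotation;
# plus the delta-delta-Ct relative quantification calculator used for qPCR
# validation.

#' Intersect predicted targets with overexpression down-regulated genes
#'
#' @param predicted_targets_of_mirna gene ids with >= 1 predicted site for
#'   the focus miRNA.
#' @param down_list gene ids down-regulated on overexpression
#'   (from [overexpression_filter()]).
#' @return sorted character vector of common gene ids.
#' @export
intersect_candidates <- function(predicted_targets_of_mirna, down_list) {
  sort(intersect(unique(predicted_targets_of_mirna), unique(down_list)))
}

#' Annotate candidates and keep those hitting required terms
#'
#' Keeps candidates belonging to at least one of the `required_terms`
#' (matched against term ids, or against term names when the collection
#' carries them), recording which terms hit. An optional exclusion list of
#' already-known (miRNA, gene) interactions screens candidates for novelty.
#'
#' @param candidate_ids gene ids from [intersect_candidates()].
#' @param gene_sets a `GeneSetCollection` from [read_gmt()].
#' @param required_terms term ids (or names) that qualify a candidate.
#' @param known_targets optional character vector of gene ids with known
#'   interactions for the focus miRNA; these are dropped.
#' @return data.frame with columns `mrna_id`, `annotation_terms_hit`
#'   (comma-joined term ids).
#' @export
annotate_and_select <- function(candidate_ids, gene_sets, required_terms,
                                known_targets = character()) {
  term_names <- attr(gene_sets, "term_names")
  by_name <- !is.null(term_names) & required_terms %in% term_names
  resolved <- ifelse(by_name,
                     names(term_names)[match(required_terms, term_names)],
                     required_terms)
  missing <- resolved[!resolved %in% names(gene_sets)]
  if (length(missing))
    format_error("annotate_and_select: required term(s) absent from the collection: %s",
                 paste(missing, collapse = ", "))
  candidate_ids <- setdiff(candidate_ids, known_targets)
  rows <- lapply(candidate_ids, function(g) {
    hits <- resolved[vapply(resolved, function(t) g %in% gene_sets[[t]],
                            logical(1))]
    if (!length(hits)) return(NULL)
    data.frame(mrna_id = g, annotation_terms_hit = paste(hits, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(mrna_id = character(), annotation_terms_hit = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative quantification by the delta-delta-Ct method
#'
#' For each condition, delta-Ct = mean(Ct target) - mean(Ct reference);
#' delta-delta-Ct = delta-Ct(case) - delta-Ct(calibrator); the relative
#' expression is RQ = 2^(-delta-delta-Ct).
#'
#' @param ct_target_case,ct_ref_case Ct triplicates (cycles) for the target
#'   and reference gene in the case condition.
#' @param ct_target_calibrator,ct_ref_calibrator same for the calibrator
#'   condition.
#' @return list with `rq`, `ddct`, `dct_case`, `dct_calibrator`, and the
#'   per-triplicate standard deviations `sd` (named list).
#' @export
relative_quantification <- function(ct_target_case, ct_ref_case,
                                    ct_target_calibrator, ct_ref_calibrator) {
  reps <- list(target_case = ct_target_case, ref_case = ct_ref_case,
               target_calibrator = ct_target_calibrator,
               ref_calibrator = ct_ref_calibrator)
  for (nm in names(reps)) {
    v <- reps[[nm]]
    if (!length(v)) format_error("relative_quantification: empty triplicate '%s'", nm)
    if (any(v <= 0)) format_error("relative_quantification: Ct values must be > 0 ('%s')", nm)
  }
  dct_case <- mean(ct_target_case) - mean(ct_ref_case)
  dct_cal <- mean(ct_target_calibrator) - mean(ct_ref_calibrator)
  ddct <- dct_case - dct_cal
  list(rq = 2^(-ddct), ddct = ddct,
       dct_case = dct_case, dct_calibrator = dct_cal,
       sd = lapply(reps, function(v) if (length(v) > 1L) sd(v) else 0))
}
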