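# One-shot orchestration of the full multistep analysis on a synthetic
# cohort: simulate -> per-dataset DE -> consensus -> target prediction ->
# inverse-correlation pairing -> overexpression -> candidate nomination ->
# enrichment, with plain-file handoff between stages and a JSON manifest
# recording the funnel.

#' Pipeline configuration
#'
#' @param sim a [simulation_config()]; its `rng_seed` drives every source of
#'   randomness in the run.
#' @param de a [de_thresholds()].
#' @param predictor a [predictor_thresholds()].
#' @param min_datasets minimum same-direction cohorts for miRNA consensus.
#' @param r_threshold,correlation_alpha,tumor_only correlation settings for
#'   [build_pairs()].
#' @param mode `"all3"` (three-predictor consensus) or `"union"`.
#' @param adjust `"none"` or `"BH"` for per-dataset DE.
#' @param focus_mirna miRNA for the overexpression/candidates stages;
#'   default: the first planted miRNA.
#' @param utr_fasta,mirna_fasta,gmt optional paths to externally supplied
#'   inputs; when `NULL` (default) the corresponding artifact is simulated.
#' @param required_terms annotation terms candidates must hit; default the
#'   simulated `planted_regulon` term.
#' @param use_ease report EASE scores in the enrichment stage.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            de = de_thresholds(),
                            predictor = predictor_thresholds(),
                            min_datasets = 3L, r_threshold = 0.0,
                            correlation_alpha = 0.05, tumor_only = TRUE,
                            mode = c("all3", "union"),
                            adjust = c("none", "BH"),
                            focus_mirna = NULL,
                            utr_fasta = NULL, mirna_fasta = NULL, gmt = NULL,
                            required_terms = "planted_regulon",
                            use_ease = FALSE) {
  mode <- match.arg(mode); adjust <- match.arg(adjust)
  structure(list(sim = sim, de = de, predictor = predictor,
                 min_datasets = as.integer(min_datasets),
                 r_threshold = r_threshold,
                 correlation_alpha = correlation_alpha,
                 tumor_only = tumor_only, mode = mode, adjust = adjust,
                 focus_mirna = focus_mirna, utr_fasta = utr_fasta,
                 mirna_fasta = mirna_fasta, gmt = gmt,
                 required_terms = required_terms, use_ease = use_ease),
            class = "PipelineConfig")
}

# Deterministic JSON writer (sorted names come from construction order;
# binary connection pins LF endings).
write_json_file <- function(x, path, digits = 10) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = digits,
                              null = "null", na = "null", pretty = TRUE), con)
  invisible(path)
}

# Synthetic gene-set collection: the focus regulon (all planted targets)
# plus random decoy terms over the gene universe.
synthetic_gmt <- function(truth, config, n_decoys = 10L, decoy_size = 40L) {
  set.seed(config$rng_seed + 2L)
  genes <- names(truth$mrna_baselines)
  sets <- c(
    list(planted_regulon = unique(truth$planted_pairs$mrna_id)),
    setNames(lapply(seq_len(n_decoys), function(i)
      sort(sample(genes, min(decoy_size, length(genes))))),
      sprintf("decoy_set_%02d", seq_len(n_decoys)))
  )
  sets <- sets[lengths(sets) > 0]
  attr(sets, "term_names") <- setNames(names(sets), names(sets))
  class(sets) <- "GeneSetCollection"
  sets
}

#' Run the full integrated analysis
#'
#' Executes every stage on a synthetic cohort generated under
#' `config$sim$rng_seed`, writing each stage's table to `outdir` and a
#' `manifest.json` recording the configuration hash, seed, stage row counts
#' (the analysis funnel) and the md5 of every output file. Rerunning with
#' the same config and seed reproduces every file byte for byte. Any stage
#' failure aborts with an error naming the stage, and output files are only
#' moved into `outdir` after the whole run succeeds (no partial outputs).
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created; must be empty or absent).
#' @return the manifest, invisibly; files are written under `outdir`.
#' @export
run_all <- function(config, outdir) {
  stopifnot(inherits(config, "PipelineConfig"))
  for (p in c(config$utr_fasta, config$mirna_fasta, config$gmt))
    if (!is.null(p) && !file.exists(p))
      format_error("run_all: input file '%s' does not exist", p)
  if (dir.exists(outdir) && length(dir(outdir)))
    config_error("run_all: output directory '%s' is not empty", outdir)
  staging <- tempfile("mirpair_run_")
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      mp_stop("mirpair_stage_error", "stage '%s' failed: %s",
              name, conditionMessage(e)))
  }
  out <- function(f) file.path(staging, f)

  ## simulate ----------------------------------------------------------------
  sim <- stage("simulate", simulate_cohorts(config$sim))
  truth <- sim$truth
  all_datasets <- c(sim$mirna_datasets, sim$mrna_datasets,
                    list(sim$matched$mirna, sim$matched$mrna))
  for (d in all_datasets)
    write_expression_tsv(d, out(sprintf("expr_%s.tsv", d$dataset_id)))

  utr_res <- stage("simulate_utrs", {
    if (is.null(config$utr_fasta)) simulate_utrs(config$sim, truth)
    else list(utrs = read_fasta(config$utr_fasta),
              planted_sites = truth$planted_sites)
  })
  truth$planted_sites <- utr_res$planted_sites
  utrs <- utr_res$utrs
  mirna_seqs <- if (is.null(config$mirna_fasta)) truth$mirna_sequences
                else read_fasta(config$mirna_fasta)
  write_fasta(utrs, out("utrs.fa"))
  write_fasta(mirna_seqs, out("mirnas.fa"))
  write_json_file(list(
    de_mirnas = as.list(truth$de_mirnas),
    de_mrnas = as.list(truth$de_mrnas),
    planted_pairs = truth$planted_pairs,
    planted_sites = truth$planted_sites), out("truth.json"))

  ## per-dataset differential expression -------------------------------------
  de_mi <- stage("diffexpr", {
    lapply(c(sim$mirna_datasets, list(sim$matched$mirna)), call_de,
           thresholds = config$de, feature_class = "mirna",
           adjust = config$adjust)
  })
  pooled <- stage("pool", pool_geo_datasets(sim$mrna_datasets, "mRNA_array_pooled"))
  de_pooled <- stage("diffexpr", call_de(pooled, config$de, "mrna",
                                         adjust = config$adjust))
  de_matched_mr <- stage("diffexpr", call_de(sim$matched$mrna, config$de, "mrna",
                                             adjust = config$adjust))
  for (r in c(de_mi, list(de_pooled, de_matched_mr)))
    write_table_tsv(r$records, out(sprintf("de_%s.tsv", r$dataset_id)))
  counts$n_de_per_mirna_dataset <- vapply(de_mi, function(r)
    sum(r$records$direction != "none"), integer(1))

  ## consensus ----------------------------------------------------------------
  cons_mi <- stage("consensus_mirna",
                   consensus_mirna(de_mi, min_datasets = config$min_datasets))
  cons_mr <- stage("consensus_mrna", consensus_mrna(de_pooled, de_matched_mr))
  write_table_tsv(cons_mi, out("mirna_consensus.tsv"))
  write_table_tsv(cons_mr, out("mrna_consensus.tsv"))
  write_table_tsv(attr(cons_mi, "near_miss"), out("mirna_consensus_near_miss.tsv"))
  counts$n_consensus_mirnas <- nrow(cons_mi)
  counts$n_consensus_mrnas <- nrow(cons_mr)

  ## target prediction ---------------------------------------------------------
  sites <- stage("predict", {
    q_mirnas <- intersect(cons_mi$feature_id, names(mirna_seqs))
    q_utrs <- utrs[intersect(cons_mr$feature_id, names(utrs))]
    if (length(q_mirnas) && length(q_utrs))
      predict_targets(mirna_seqs[q_mirnas], q_utrs, config$predictor,
                      require_all_three = (config$mode == "all3"))
    else empty_sites_frame()
  })
  write_table_tsv(sites, out("sites.tsv"))
  counts$n_sites <- nrow(sites)

  ## pairing -------------------------------------------------------------------
  pairs <- stage("pair", build_pairs(
    cons_mi, cons_mr, sim$matched$mirna, sim$matched$mrna, sites,
    r_threshold = config$r_threshold, alpha = config$correlation_alpha,
    tumor_only = config$tumor_only,
    require_sites = (config$mode == "all3")))
  write_table_tsv(pairs, out("pairs.tsv"))
  write_table_tsv(attr(pairs, "sidecar"), out("pairs_failed_correlation.tsv"))
  counts <- c(counts, summarize_pairs(pairs))

  ## overexpression + candidates ----------------------------------------------
  focus <- config$focus_mirna
  if (is.null(focus)) focus <- truth$planted_pairs$mirna_id[1]
  cand <- stage("candidates", {
    if (is.null(focus) || is.na(focus)) {
      list(table = data.frame(gene_id = character(), mimic = numeric(),
                              scrambled = numeric()),
           down = character(), candidates = character(),
           selected = data.frame(mrna_id = character(),
                                 annotation_terms_hit = character()))
    } else {
      tab <- simulate_overexpression(truth, focus, config$sim)
      oe <- overexpression_filter(tab, config$de)
      predicted <- unique(sites$mrna_id[sites$mirna_id == focus])
      common <- intersect_candidates(predicted, oe$down)
      gmt <- if (is.null(config$gmt)) synthetic_gmt(truth, config$sim)
             else read_gmt(config$gmt)
      sel <- annotate_and_select(common, gmt, config$required_terms)
      list(table = tab, down = oe$down, candidates = common, selected = sel,
           gmt = gmt)
    }
  })
  write_table_tsv(cand$table, out(sprintf("overexpression_%s.tsv", focus)))
  write_table_tsv(cand$selected, out("candidates.tsv"))
  counts$focus_mirna <- focus
  counts$n_overexpression_down <- length(cand$down)
  counts$n_candidates_common <- length(cand$candidates)
  counts$n_candidates_selected <- nrow(cand$selected)

  ## enrichment ------------------------------------------------------------------
  # over-representation of the integrated pair table's target genes against
  # the measured gene universe
  enr <- stage("enrich", {
    if (!is.null(cand$gmt) && nrow(pairs))
      enrich(unique(pairs$mrna_id), cand$gmt,
             background = names(truth$mrna_baselines),
             use_ease = config$use_ease)
    else data.frame(term_id = character(), term_name = character(),
                    k = integer(), K = integer(), n = integer(), N = integer(),
                    p_value = numeric(), q_value = numeric())
  })
  write_table_tsv(enr, out("enrichment.tsv"))
  counts$n_enriched_terms_q05 <- if (nrow(enr)) sum(enr$q_value < 0.05) else 0L

  ## recovery vs truth + manifest --------------------------------------------
  recov <- evaluate_recovery(pairs, truth)
  cfg_json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = 10)
  cfg_file <- out(".config.json")
  writeLines(cfg_json, cfg_file)
  files <- sort(setdiff(dir(staging), c("manifest.json", ".config.json")))
  manifest <- list(
    tool = "mirpair",
    seed = config$sim$rng_seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    funnel = counts,
    recovery = recov,
    files = setNames(as.list(unname(tools::md5sum(file.path(staging, files)))),
                     files))
  file.remove(cfg_file)
  write_json_file(manifest, out("manifest.json"))

  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  for (f in dir(staging))
    file.copy(file.path(staging, f), file.path(outdir, f), overwrite = FALSE)
  invisible(manifest)
}

# recursively strip S3 classes so jsonlite serializes configs plainly
unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
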