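# Synthetic tumor/normal cohorts with planted regulatory truth. The
# generator emulates the statistical structure the analysis assumes: several
# array-like cohorts plus one matched-sample sequencing-like cohort, a
# minority of features differentially expressed by a fixed log2 shift, and
# planted miRNA->mRNA pairs that are oppositely dysregulated, negatively
# coupled across matched samples, and linked by a seed site embedded in the
# target's 3'UTR.

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: Gaussian log2
#' expression with noise sd 0.5, differential features shifted by 1.5 log2
#' units in tumor (a 3-sigma effect), negative regulatory coupling 0.8, and
#' 50 planted miRNA->mRNA pairs carrying canonical 8mer sites with
#' 3'-supplementary pairing in 600-nt UTRs.
#'
#' @param n_mirna_datasets number of array-like miRNA cohorts (the matched
#'   sequencing-like cohort is generated in addition).
#' @param n_mrna_datasets number of array-like mRNA cohorts.
#' @param samples_per_group samples per group (tumor, normal) per dataset.
#' @param n_mirnas,n_mrnas feature counts.
#' @param frac_de_mirna,frac_de_mrna fraction of features differentially
#'   expressed (split evenly up/down).
#' @param de_shift log2 shift of DE features in tumor (delta).
#' @param noise_sd log2 noise standard deviation (sigma).
#' @param n_planted_pairs number of planted miRNA->mRNA regulatory pairs
#'   (down-regulated miRNA, up-regulated target).
#' @param targets_per_mirna planted targets per planted miRNA.
#' @param coupling negative regulatory coupling beta: on the matched cohort a
#'   planted target's value is baseline + dir*delta*tumor - beta*(centered
#'   miRNA value) + Normal(0, sigma/2).
#' @param utr_length UTR length, nt.
#' @param seed_site_class seed class of planted sites
#'   (`"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"6mer"`).
#' @param bystander_n bystander genes given random fold changes in the
#'   overexpression profile.
#' @param overexpression_margin extra log2 down-shift of direct targets
#'   beyond the 0.5849 filter bound.
#' @param rng_seed integer seed; identical seeds give byte-identical outputs.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(n_mirna_datasets = 4L, n_mrna_datasets = 2L,
                              samples_per_group = 20L,
                              n_mirnas = 200L, n_mrnas = 800L,
                              frac_de_mirna = 0.6, frac_de_mrna = 0.3,
                              de_shift = 1.5, noise_sd = 0.5,
                              n_planted_pairs = 50L, targets_per_mirna = 1L,
                              coupling = 0.8, utr_length = 600L,
                              seed_site_class = "8mer",
                              bystander_n = 30L, overexpression_margin = 0.5,
                              rng_seed = 1L) {
  cfg <- list(n_mirna_datasets = as.integer(n_mirna_datasets),
              n_mrna_datasets = as.integer(n_mrna_datasets),
              samples_per_group = as.integer(samples_per_group),
              n_mirnas = as.integer(n_mirnas), n_mrnas = as.integer(n_mrnas),
              frac_de_mirna = frac_de_mirna, frac_de_mrna = frac_de_mrna,
              de_shift = de_shift, noise_sd = noise_sd,
              n_planted_pairs = as.integer(n_planted_pairs),
              targets_per_mirna = as.integer(targets_per_mirna),
              coupling = coupling, utr_length = as.integer(utr_length),
              seed_site_class = seed_site_class,
              bystander_n = as.integer(bystander_n),
              overexpression_margin = overexpression_margin,
              rng_seed = as.integer(rng_seed))
  counts <- unlist(cfg[c("n_mirna_datasets", "n_mrna_datasets",
                         "samples_per_group", "n_mirnas", "n_mrnas",
                         "n_planted_pairs", "utr_length", "bystander_n")])
  if (any(counts < 0)) config_error("all counts must be >= 0")
  if (cfg$noise_sd <= 0) config_error("noise_sd must be > 0")
  if (!seed_site_class %in% SEED_CLASSES)
    config_error("seed_site_class must be one of %s",
                 paste(SEED_CLASSES, collapse = ", "))
  n_down_mi <- floor(cfg$n_mirnas * cfg$frac_de_mirna / 2)
  n_up_mr <- floor(cfg$n_mrnas * cfg$frac_de_mrna / 2)
  need_mi <- ceiling(cfg$n_planted_pairs / max(1L, cfg$targets_per_mirna))
  if (need_mi > n_down_mi || cfg$n_planted_pairs > n_up_mr)
    config_error(paste0("infeasible planting: need %d down-regulated miRNAs ",
                        "and %d up-regulated mRNAs, have %d and %d"),
                 need_mi, cfg$n_planted_pairs, n_down_mi, n_up_mr)
  structure(cfg, class = "SimulationConfig")
}

# Random RNA sequence of length n (column of a batch for speed).
random_rna <- function(n, count = 1L) {
  chars <- sample(c("A", "C", "G", "U"), n * count, replace = TRUE)
  if (count == 1L) paste(chars, collapse = "") else
    apply(matrix(chars, nrow = n), 2L, paste, collapse = "")
}

# Draw mature miRNA sequences (22 nt) such that (a) DE miRNAs have
# pairwise-distinct 6mer seeds and (b) the site embed of every planted
# miRNA contains no seed match for any other DE miRNA and exactly one for
# its own — so planted sites are attributable to their miRNA alone.
draw_mirna_sequences <- function(ids, de_ids, planted_ids, seed_class) {
  seqs <- setNames(random_rna(22L, length(ids)), ids)
  for (tries in seq_len(300L)) {
    pats <- setNames(vapply(seqs[de_ids], function(s)
      reverse_complement(substr(s, 2L, 7L)), character(1)), de_ids)
    bad <- de_ids[duplicated(pats)]
    for (m in planted_ids) {
      if (m %in% bad) next
      emb <- planted_embed(seqs[[m]], seed_class)
      own <- find_all_occurrences(pats[[m]], emb$embed)
      foreign <- unlist(lapply(setdiff(de_ids, m), function(o)
        find_all_occurrences(pats[[o]], emb$embed)))
      if (length(own) != 1L || own[1L] - 1L != emb$rc6_offset || length(foreign))
        bad <- c(bad, m)
    }
    if (!length(bad)) return(seqs)
    seqs[bad] <- random_rna(22L, length(bad))
  }
  config_error("could not draw miRNAs with distinct, attributable seeds")
}

# One simulated cohort matrix: baseline + DE tumor shift + Gaussian noise.
simulate_dataset <- function(dataset_id, platform, feature_ids, baselines,
                             de_dir, config) {
  n <- length(feature_ids); m <- 2L * config$samples_per_group
  groups <- rep(c("tumor", "normal"), each = config$samples_per_group)
  shift <- de_dir[feature_ids] * config$de_shift  # 0 for non-DE
  values <- baselines[feature_ids] +
    outer(shift, as.numeric(groups == "tumor")) +
    matrix(rnorm(n * m, 0, config$noise_sd), n, m)
  rownames(values) <- feature_ids
  colnames(values) <- sprintf("%s_s%02d", dataset_id, seq_len(m))
  expression_dataset(dataset_id, values, groups, platform)
}

#' Simulate multi-dataset tumor/normal cohorts with planted truth
#'
#' Generates `n_mirna_datasets` array-like miRNA cohorts,
#' `n_mrna_datasets` array-like mRNA cohorts, and one matched-sample
#' sequencing-like cohort pair (miRNA and mRNA matrices over the same
#' samples). Non-DE features are Normal(baseline, sigma) in both groups; DE
#' features are shifted by +/- delta in tumor; on the matched cohort each
#' planted target additionally receives the negative coupling
#' `-beta * centered miRNA value` with reduced noise (sigma/2), encoding
#' miRNA-mediated repression. Fully deterministic under `rng_seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `mirna_datasets`, `mrna_datasets`, `matched` (list with
#'   `mirna`, `mrna`), and `truth` (a `SyntheticTruth`: `de_mirnas`,
#'   `de_mrnas` as id -> direction vectors, `planted_pairs` data.frame,
#'   `mirna_sequences`, `mrna_baselines`).
#' @export
simulate_cohorts <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$rng_seed)
  mirna_ids <- sprintf("miR-sim-%03d", seq_len(config$n_mirnas))
  mrna_ids <- sprintf("GENE%04d", seq_len(config$n_mrnas))

  # DE assignment: an even up/down split among the DE fraction
  n_de_mi <- 2L * floor(config$n_mirnas * config$frac_de_mirna / 2)
  n_de_mr <- 2L * floor(config$n_mrnas * config$frac_de_mrna / 2)
  de_mi_ids <- sort(sample(mirna_ids, n_de_mi))
  de_mr_ids <- sort(sample(mrna_ids, n_de_mr))
  de_mirnas <- setNames(rep(c("down", "up"), each = n_de_mi / 2), de_mi_ids)
  de_mrnas <- setNames(rep(c("up", "down"), each = n_de_mr / 2), de_mr_ids)

  # planted pairs: down miRNAs -> up mRNAs
  need_mi <- ceiling(config$n_planted_pairs / max(1L, config$targets_per_mirna))
  down_mi <- names(de_mirnas)[de_mirnas == "down"]
  up_mr <- names(de_mrnas)[de_mrnas == "up"]
  planted <- if (config$n_planted_pairs > 0)
    data.frame(
      mirna_id = rep(down_mi[seq_len(need_mi)],
                     each = max(1L, config$targets_per_mirna))[seq_len(config$n_planted_pairs)],
      mrna_id = up_mr[seq_len(config$n_planted_pairs)],
      beta = config$coupling, stringsAsFactors = FALSE)
  else
    data.frame(mirna_id = character(), mrna_id = character(),
               beta = numeric(), stringsAsFactors = FALSE)

  mirna_sequences <- draw_mirna_sequences(
    mirna_ids, de_ids = de_mi_ids,
    planted_ids = unique(planted$mirna_id),
    seed_class = config$seed_site_class)

  dir_num_mi <- setNames(rep(0, config$n_mirnas), mirna_ids)
  dir_num_mi[names(de_mirnas)] <- ifelse(de_mirnas == "up", 1, -1)
  dir_num_mr <- setNames(rep(0, config$n_mrnas), mrna_ids)
  dir_num_mr[names(de_mrnas)] <- ifelse(de_mrnas == "up", 1, -1)

  base_mi <- setNames(runif(config$n_mirnas, 6, 12), mirna_ids)
  base_mr <- setNames(runif(config$n_mrnas, 6, 12), mrna_ids)

  mirna_datasets <- lapply(seq_len(config$n_mirna_datasets), function(k)
    simulate_dataset(sprintf("miRNA_array_%d", k), "array",
                     mirna_ids, base_mi, dir_num_mi, config))
  mrna_datasets <- lapply(seq_len(config$n_mrna_datasets), function(k)
    simulate_dataset(sprintf("mRNA_array_%d", k), "array",
                     mrna_ids, base_mr, dir_num_mr, config))

  matched_mi <- simulate_dataset("matched_seq_miRNA", "rnaseq",
                                 mirna_ids, base_mi, dir_num_mi, config)
  matched_mr <- simulate_dataset("matched_seq_mRNA", "rnaseq",
                                 mrna_ids, base_mr, dir_num_mr, config)
  matched_mr$sample_ids <- colnames(matched_mr$values) <- matched_mi$sample_ids
  names(matched_mr$group_labels) <- matched_mi$sample_ids
  # overwrite planted targets with the coupled model
  if (nrow(planted)) {
    tumor_ind <- as.numeric(matched_mr$group_labels == "tumor")
    m_samples <- ncol(matched_mr$values)
    for (k in seq_len(nrow(planted))) {
      g <- planted$mrna_id[k]; m <- planted$mirna_id[k]
      m_centered <- matched_mi$values[m, ] - mean(matched_mi$values[m, ])
      matched_mr$values[g, ] <- base_mr[g] +
        dir_num_mr[g] * config$de_shift * tumor_ind -
        planted$beta[k] * m_centered +
        rnorm(m_samples, 0, config$noise_sd / 2)
    }
  }

  truth <- structure(
    list(de_mirnas = de_mirnas, de_mrnas = de_mrnas,
         planted_pairs = planted,
         planted_sites = NULL,  # filled by simulate_utrs()
         mirna_sequences = mirna_sequences,
         mrna_baselines = base_mr),
    class = "SyntheticTruth")

  list(mirna_datasets = mirna_datasets, mrna_datasets = mrna_datasets,
       matched = list(mirna = matched_mi, mrna = matched_mr),
       truth = truth)
}

# The UTR substring embedded for a planted site: extended antiparallel
# complementarity to miRNA positions 2-19 (seed + central + 3'-supplementary
# pairing, as in canonically 3'-supplemented sites), terminated according to
# the seed class. Returns list(embed, site_offset, site_len): the seed-site
# interval within the embed that find_seed_sites() will report.
planted_embed <- function(mirna_seq, seed_class) {
  sup <- reverse_complement(substr(mirna_seq, 9L, 19L))   # positions 19..9
  s <- seed_of(mirna_seq)
  rc7 <- reverse_complement(s$seed7)
  rc6 <- reverse_complement(s$seed6)
  m8 <- substr(mirna_seq, 8L, 8L)
  not_comp_m8 <- setdiff(c("A", "C", "G", "U"),
                         chartr("ACGU", "UGCA", m8))[1L]
  # site_offset: 0-based start of the reported seed-site interval within the
  # embed; rc6_offset: 0-based start of the rc(seed6) core (one base further
  # in for classes that pair miRNA position 8).
  switch(seed_class,
    "8mer" = {
      core <- paste0(rc7, "A")
      list(embed = paste0(sup, core), site_offset = nchar(sup), site_len = 8L,
           rc6_offset = nchar(sup) + 1L)
    },
    "7mer-m8" = {
      core <- rc7  # followed by a fixed non-A so the class is not upgraded
      list(embed = paste0(sup, core, "C"), site_offset = nchar(sup),
           site_len = 7L, rc6_offset = nchar(sup) + 1L)
    },
    "7mer-A1" = {
      core <- paste0(rc6, "A")  # m8 left unpaired via a non-complementary spacer
      list(embed = paste0(sup, not_comp_m8, core),
           site_offset = nchar(sup) + 1L, site_len = 7L,
           rc6_offset = nchar(sup) + 1L)
    },
    "6mer" = {
      list(embed = paste0(sup, not_comp_m8, rc6, "C"),
           site_offset = nchar(sup) + 1L, site_len = 6L,
           rc6_offset = nchar(sup) + 1L)
    })
}

# Positions (1-based) where any of the forbidden 6mers occurs in `s`.
forbidden_hits <- function(s, combined_pattern) {
  r <- gregexpr(combined_pattern, s, perl = TRUE)[[1L]]
  if (r[1L] == -1L) integer() else as.integer(r)
}

# Resample the 6-nt windows at offending positions until the sequence is
# free of forbidden 6mers; bounded.
scrub_sequence <- function(s, combined_pattern, max_iter = 100L) {
  for (it in seq_len(max_iter)) {
    hits <- forbidden_hits(s, combined_pattern)
    if (!length(hits)) return(s)
    for (pos in hits)
      substr(s, pos, pos + 5L) <- random_rna(6L)
  }
  NULL
}

#' Simulate 3'UTR sequences with planted seed sites
#'
#' Every planted pair's target UTR contains one embedded site of the
#' configured seed class (with 3'-supplementary complementarity) at a
#' recorded interval; all other sequence — including every non-planted UTR —
#' is sampled free of 6mer-or-better seed matches for any DE miRNA, so that
#' site-level false positives are attributable to the predictor, not the
#' generator. Deterministic under the config seed.
#'
#' @param config a [simulation_config()].
#' @param truth the `SyntheticTruth` from [simulate_cohorts()].
#' @return list with `utrs` (named character vector, mRNA id -> UTR) and
#'   `planted_sites` (data.frame `mirna_id`, `mrna_id`, `start`, `end`,
#'   `seed_class`; 0-based half-open intervals).
#' @export
simulate_utrs <- function(config, truth) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  set.seed(config$rng_seed + 1L)
  mrna_ids <- names(truth$mrna_baselines)
  de_mi <- names(truth$de_mirnas)
  patterns <- unique(vapply(truth$mirna_sequences[de_mi], function(s)
    reverse_complement(seed_of(s)$seed6), character(1)))
  combined <- paste0("(?=(?:", paste(patterns, collapse = "|"), "))")
  L <- config$utr_length

  clean_background <- function() {
    for (try in seq_len(50L)) {
      s <- scrub_sequence(random_rna(L), combined)
      if (!is.null(s)) return(s)
    }
    config_error(paste0("simulate_utrs: could not sample a seed-free UTR ",
                        "background; try shorter UTRs or fewer DE miRNAs"))
  }

  utrs <- setNames(character(length(mrna_ids)), mrna_ids)
  planted_by_gene <- split(truth$planted_pairs, truth$planted_pairs$mrna_id)
  sites <- list()
  for (g in mrna_ids) {
    if (is.null(planted_by_gene[[g]])) { utrs[[g]] <- clean_background(); next }
    pair <- planted_by_gene[[g]][1L, ]  # one planted site per target
    emb <- planted_embed(truth$mirna_sequences[[pair$mirna_id]],
                         config$seed_site_class)
    own6 <- reverse_complement(seed_of(truth$mirna_sequences[[pair$mirna_id]])$seed6)
    ok <- FALSE
    for (try in seq_len(50L)) {
      bg <- clean_background()
      ins <- sample.int(L - nchar(emb$embed) - 1L, 1L)  # 1-based insert position
      utr <- paste0(substr(bg, 1L, ins - 1L), emb$embed,
                    substr(bg, ins + nchar(emb$embed), L))
      # verify: only the planted site's own 6mer occurs, exactly once
      hits <- forbidden_hits(utr, combined)
      site_start0 <- ins - 1L + emb$site_offset        # 0-based
      rc6_start0 <- ins - 1L + emb$rc6_offset
      own_hits <- forbidden_hits(utr,
                                 paste0("(?=", own6, ")"))
      if (length(hits) == length(own_hits) &&
          length(own_hits) == 1L &&
          own_hits[1L] - 1L == rc6_start0) {
        utrs[[g]] <- utr
        sites[[length(sites) + 1L]] <- data.frame(
          mirna_id = pair$mirna_id, mrna_id = g,
          start = site_start0, end = site_start0 + emb$site_len,
          seed_class = config$seed_site_class, stringsAsFactors = FALSE)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      config_error("simulate_utrs: could not place a clean planted site in '%s'", g)
  }
  planted_sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(mirna_id = character(), mrna_id = character(),
               start = integer(), end = integer(), seed_class = character(),
               stringsAsFactors = FALSE)
  list(utrs = utrs, planted_sites = planted_sites)
}

#' Simulate an overexpression RNA-seq profile for one miRNA
#'
#' Two-column log2 expression table (mimic, scrambled control). Direct
#' targets (the planted pairs of `mirna_id`) are shifted down by at least
#' `0.5849 + overexpression_margin` log2 units; `bystander_n` random
#' non-target genes receive uniform fold changes in [-2, 2]; the remainder
#' get small Gaussian jitter. Deterministic under the config seed.
#'
#' @param truth `SyntheticTruth` from [simulate_cohorts()].
#' @param mirna_id the overexpressed miRNA (must appear in the truth).
#' @param config the [simulation_config()].
#' @return data.frame with columns `gene_id`, `mimic`, `scrambled`.
#' @export
simulate_overexpression <- function(truth, mirna_id, config) {
  if (!mirna_id %in% names(truth$mirna_sequences))
    config_error("simulate_overexpression: unknown miRNA '%s'", mirna_id)
  idx <- match(mirna_id, names(truth$mirna_sequences))
  set.seed(config$rng_seed + 10000L + idx)
  genes <- names(truth$mrna_baselines)
  targets <- truth$planted_pairs$mrna_id[truth$planted_pairs$mirna_id == mirna_id]
  scrambled <- unname(truth$mrna_baselines)
  lfc <- rnorm(length(genes), 0, 0.05)
  nontargets <- setdiff(genes, targets)
  bystanders <- sample(nontargets, min(config$bystander_n, length(nontargets)))
  lfc[match(bystanders, genes)] <- runif(length(bystanders), -2, 2)
  lfc[match(targets, genes)] <-
    -(0.5849 + config$overexpression_margin) - runif(length(targets), 0, 0.5)
  data.frame(gene_id = genes, mimic = scrambled + lfc, scrambled = scrambled,
             stringsAsFactors = FALSE)
}

#' Score reported pairs against the planted truth
#'
#' Precision = |reported and planted| / |reported|, defined as 1 when
#' nothing is reported; recall analogous over the planted set; F1 their
#' harmonic mean (0 when both are 0).
#'
#' @param reported_pairs data.frame with `mirna_id`, `mrna_id` columns (or a
#'   character vector of `"mirna|mrna"` keys).
#' @param truth `SyntheticTruth` (its `planted_pairs` are the positives).
#' @return list with `precision`, `recall`, `f1`, `n_reported`, `n_planted`,
#'   `n_true_positive`.
#' @export
evaluate_recovery <- function(reported_pairs, truth) {
  rep_keys <- if (is.character(reported_pairs)) reported_pairs else
    paste(reported_pairs$mirna_id, reported_pairs$mrna_id, sep = "|")
  rep_keys <- unique(rep_keys)
  truth_keys <- unique(paste(truth$planted_pairs$mirna_id,
                             truth$planted_pairs$mrna_id, sep = "|"))
  tp <- length(intersect(rep_keys, truth_keys))
  precision <- if (!length(rep_keys)) 1 else tp / length(rep_keys)
  recall <- if (!length(truth_keys)) 1 else tp / length(truth_keys)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_reported = length(rep_keys), n_planted = length(truth_keys),
       n_true_positive = tp)
}
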