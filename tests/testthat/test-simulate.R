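test_that("identical seeds give byte-identical simulated artifacts", {
  cfg <- tiny_sim_config(rng_seed = 99L)
  run <- function() {
    sim <- simulate_cohorts(cfg)
    utr <- simulate_utrs(cfg, sim$truth)
    oe <- simulate_overexpression(sim$truth, sim$truth$planted_pairs$mirna_id[1],
                                  cfg)
    d <- withr::local_tempdir()
    write_expression_tsv(sim$mirna_datasets[[1]], file.path(d, "m.tsv"))
    write_fasta(utr$utrs, file.path(d, "u.fa"))
    list(tsv = readLines(file.path(d, "m.tsv")),
         fa = readLines(file.path(d, "u.fa")), oe = oe)
  }
  a <- run(); b <- run()
  expect_identical(a$tsv, b$tsv)
  expect_identical(a$fa, b$fa)
  expect_identical(a$oe, b$oe)
})

test_that("the null configuration yields empty truth and alpha-level calling", {
  cfg <- simulation_config(n_mirna_datasets = 1L, n_mrna_datasets = 1L,
                           samples_per_group = 10L, n_mirnas = 4000L,
                           n_mrnas = 10L, frac_de_mirna = 0,
                           frac_de_mrna = 0, n_planted_pairs = 0L,
                           rng_seed = 321L)
  sim <- simulate_cohorts(cfg)
  expect_length(sim$truth$de_mirnas, 0L)
  expect_equal(nrow(sim$truth$planted_pairs), 0L)
  de <- call_de(sim$mirna_datasets[[1]], de_thresholds(), "mirna")
  rate <- mean(de$records$direction != "none")
  expect_gt(rate, 0.035); expect_lt(rate, 0.065)
})

test_that("strong planted pairs are oppositely dysregulated and anticorrelated", {
  cfg <- simulation_config(n_mirna_datasets = 1L, n_mrna_datasets = 1L,
                           samples_per_group = 10L, n_mirnas = 60L,
                           n_mrnas = 80L, frac_de_mirna = 0.5,
                           frac_de_mrna = 0.5, de_shift = 3, noise_sd = 0.1,
                           n_planted_pairs = 10L, rng_seed = 7L)
  sim <- simulate_cohorts(cfg)
  truth <- sim$truth
  expect_equal(nrow(truth$planted_pairs), 10L)
  tumor <- sim$matched$mirna$group_labels == "tumor"
  for (k in seq_len(10L)) {
    m <- truth$planted_pairs$mirna_id[k]; g <- truth$planted_pairs$mrna_id[k]
    expect_identical(unname(truth$de_mirnas[m]), "down")
    expect_identical(unname(truth$de_mrnas[g]), "up")
    # opposite direction also holds empirically in each cohort
    expect_lt(log2_fold_change(sim$matched$mirna$values[m, tumor],
                               sim$matched$mirna$values[m, !tumor]), 0)
    expect_gt(log2_fold_change(sim$matched$mrna$values[g, tumor],
                               sim$matched$mrna$values[g, !tumor]), 0)
    # negative coupling across matched samples
    expect_lt(cor(sim$matched$mirna$values[m, ],
                  sim$matched$mrna$values[g, ]), 0)
  }
})

test_that("planted UTRs carry exactly the recorded site; backgrounds are clean", {
  fx <- tiny_sim()
  truth <- fx$sim$truth
  de_patterns <- vapply(truth$mirna_sequences[names(truth$de_mirnas)],
                        function(s) reverse_complement(seed_of(s)$seed6),
                        character(1))
  planted_genes <- truth$planted_sites$mrna_id
  for (g in names(fx$utrs)) {
    utr <- fx$utrs[[g]]
    hits <- unlist(lapply(de_patterns, naive_occurrences, s = utr))
    if (!g %in% planted_genes) {
      expect_length(hits, 0L)
    } else {
      ps <- truth$planted_sites[truth$planted_sites$mrna_id == g, ]
      m <- mature_mirna(ps$mirna_id, truth$mirna_sequences[[ps$mirna_id]])
      found <- find_seed_sites(m, utr)
      expect_equal(nrow(found), 1L)
      expect_equal(found$start, ps$start)
      expect_equal(found$end, ps$end)
      expect_identical(found$seed_class, ps$seed_class)
    }
  }
})

test_that("overexpression profiles push planted targets past the filter", {
  cfg <- simulation_config(n_mirna_datasets = 1L, n_mrna_datasets = 1L,
                           samples_per_group = 5L, n_mirnas = 40L,
                           n_mrnas = 60L, frac_de_mirna = 0.5,
                           frac_de_mrna = 0.5, n_planted_pairs = 5L,
                           targets_per_mirna = 5L,
                           overexpression_margin = 0.5, rng_seed = 60L)
  sim <- simulate_cohorts(cfg)
  truth <- sim$truth
  focus <- truth$planted_pairs$mirna_id[1]
  expect_equal(sum(truth$planted_pairs$mirna_id == focus), 5L)
  tab <- simulate_overexpression(truth, focus, cfg)
  down <- overexpression_filter(tab, de_thresholds())$down
  expect_true(all(truth$planted_pairs$mrna_id %in% down))
  # a miRNA with no planted targets has an empty intersection downstream
  lonely <- setdiff(names(truth$de_mirnas)[truth$de_mirnas == "down"],
                    truth$planted_pairs$mirna_id)[1]
  tab2 <- simulate_overexpression(truth, lonely, cfg)
  down2 <- overexpression_filter(tab2, de_thresholds())$down
  expect_length(intersect(down2, character(0)), 0L)
  expect_identical(tab, simulate_overexpression(truth, focus, cfg))
  expect_error(simulate_overexpression(truth, "nope", cfg), "unknown miRNA")
})

test_that("recovery scoring follows the stated conventions", {
  truth <- structure(list(planted_pairs = data.frame(
    mirna_id = sprintf("m%d", 1:10), mrna_id = sprintf("g%d", 1:10))),
    class = "SyntheticTruth")
  all_keys <- paste(sprintf("m%d", 1:10), sprintf("g%d", 1:10), sep = "|")
  perfect <- evaluate_recovery(all_keys, truth)
  expect_equal(perfect[c("precision", "recall", "f1")],
               list(precision = 1, recall = 1, f1 = 1))
  none <- evaluate_recovery(character(), truth)
  expect_equal(none$precision, 1); expect_equal(none$recall, 0)
  spurious <- evaluate_recovery(c(all_keys, "mX|gX"), truth)
  expect_equal(spurious$precision, 10 / 11, tolerance = 1e-12)
  expect_equal(spurious$recall, 1)
})

test_that("infeasible planting is rejected at configuration time", {
  expect_error(simulation_config(n_mirnas = 10L, frac_de_mirna = 0.2,
                                 n_planted_pairs = 5L),
               "infeasible planting")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
})
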