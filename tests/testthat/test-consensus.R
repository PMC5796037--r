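test_that("the bundled gastric-cancer example reproduces the cohort-triple counts", {
  large <- consensus_mirna(
    gc_mirna_example(c("GSE30070", "GSE23739", "TCGA_STAD")), min_datasets = 3)
  expect_equal(nrow(large), 7L)
  expect_setequal(large$feature_id,
                  c("miR-204-5p", "miR-145-5p", "miR-375", "miR-642a-5p",
                    "miR-26a-5p", "miR-30a-5p", "miR-342-3p"))
  small <- consensus_mirna(
    gc_mirna_example(c("GSE33743", "GSE30070", "TCGA_STAD")), min_datasets = 3)
  expect_equal(nrow(small), 2L)
  expect_setequal(small$feature_id, c("miR-1-3p", "miR-203a-3p"))
  expect_true(all(large$direction == "down"))
})

test_that("direction consistency is required and conflicts are dropped", {
  res <- list(
    fake_de_result("d1", c("x", "y"), c("up", "up")),
    fake_de_result("d2", c("x", "y"), c("up", "down")),
    fake_de_result("d3", c("x", "y"), c("down", "down")),
    fake_de_result("d4", c("x", "y"), c("down", "down")))
  out <- consensus_mirna(res, min_datasets = 2)
  # x: up in 2, down in 2 -> two qualifying directions -> excluded
  expect_false("x" %in% out$feature_id)
  expect_identical(out$direction[out$feature_id == "y"], "down")
  expect_error(consensus_mirna(res[c(1, 1, 2)], min_datasets = 2),
               "duplicate dataset id")
})

test_that("consensus is permutation-invariant and anti-monotone in min_datasets", {
  set.seed(44)
  mk <- function(id) fake_de_result(id, sprintf("f%02d", 1:20),
                                    sample(c("up", "down", "none"), 20, TRUE))
  res <- lapply(sprintf("d%d", 1:5), mk)
  base <- consensus_mirna(res, min_datasets = 3)
  perm <- consensus_mirna(res[c(3, 5, 1, 4, 2)], min_datasets = 3)
  expect_identical(base, perm, ignore_attr = TRUE)
  stricter <- consensus_mirna(res, min_datasets = 4)
  expect_true(all(stricter$feature_id %in% base$feature_id))
})

test_that("consensus equals brute-force enumeration on random small instances", {
  set.seed(73)
  for (rep in 1:20) {
    nd <- sample(3:5, 1); nf <- sample(5:20, 1)
    res <- lapply(sprintf("d%d", seq_len(nd)), function(id)
      fake_de_result(id, sprintf("f%02d", seq_len(nf)),
                     sample(c("up", "down", "none"), nf, TRUE)))
    m <- sample(2:nd, 1)
    mine <- consensus_mirna(res, min_datasets = m)
    ref <- naive_consensus(res, min_datasets = m)
    expect_identical(mine[, c("feature_id", "direction")], ref,
                     ignore_attr = TRUE)
  }
})

test_that("two-source mRNA consensus keeps same-direction features only", {
  geo <- fake_de_result("geo", c("a", "b", "c"), c("up", "up", "down"))
  tcga <- fake_de_result("tcga", c("a", "b", "c"), c("up", "down", "none"))
  out <- consensus_mrna(geo, tcga)
  expect_identical(out$feature_id, "a")
  expect_identical(out$direction, "up")
})

test_that("pooling concatenates samples on the common feature set", {
  set.seed(21)
  mk <- function(id, feats) {
    vals <- matrix(rnorm(length(feats) * 8, 8), length(feats), 8,
                   dimnames = list(feats, sprintf("%s_s%d", id, 1:8)))
    expression_dataset(id, vals, rep(c("tumor", "normal"), each = 4))
  }
  d1 <- mk("c1", c("a", "b", "c")); d2 <- mk("c2", c("b", "c", "d"))
  pooled <- suppressMessages(pool_geo_datasets(list(d1, d2)))
  expect_setequal(pooled$feature_ids, c("b", "c"))
  expect_equal(length(pooled$sample_ids), 16L)
  expect_error(pool_geo_datasets(list(mk("x", c("a")), mk("y", c("b")))),
               "empty feature intersection")
  # pooling a cohort with a relabelled copy of itself doubles samples and
  # preserves DE directions
  d1b <- mk("c1", c("a", "b", "c")); d1b$dataset_id <- "c1copy"
  d1b$values <- d1$values
  double <- pool_geo_datasets(list(d1, d1b))
  expect_equal(ncol(double$values), 16L)
  de1 <- call_de(d1, de_thresholds(), "mirna")$records
  de2 <- call_de(double, de_thresholds(), "mirna")$records
  expect_equal(de2$log2fc, de1$log2fc, tolerance = 1e-12)
  called <- de1$direction != "none"
  expect_identical(de2$direction[called], de1$direction[called])
})

test_that("pooled cohorts recover planted features with more power than one cohort", {
  cfg <- simulation_config(n_mirna_datasets = 1L, n_mrna_datasets = 3L,
                           samples_per_group = 5L, n_mirnas = 20L,
                           n_mrnas = 300L, frac_de_mirna = 0.4,
                           frac_de_mrna = 0.3, de_shift = 0.9,
                           noise_sd = 0.7, n_planted_pairs = 0L,
                           rng_seed = 17L)
  sim <- simulate_cohorts(cfg)
  truth_de <- names(sim$truth$de_mrnas)
  single <- call_de(sim$mrna_datasets[[1]], de_thresholds(lfc_mrna = 0.5), "mrna")
  pooled <- call_de(pool_geo_datasets(sim$mrna_datasets),
                    de_thresholds(lfc_mrna = 0.5), "mrna")
  hit <- function(r) sum(r$records$feature_id %in% truth_de &
                           r$records$direction != "none")
  expect_gt(hit(pooled), hit(single))
})
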