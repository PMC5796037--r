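test_that("pearson_r matches the definition and stats::cor.test", {
  expect_equal(pearson_r(1:5, -(1:5))$r, -1)
  expect_equal(pearson_r(1:5, 1:5 * 2)$r, 1)
  ex <- pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(ex$r, 0.6, tolerance = 1e-12)
  set.seed(202)
  for (i in 1:30) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    mine <- pearson_r(x, y)
    # definition oracle: covariance over the sd product
    r_def <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(mine$r, r_def, tolerance = 1e-12)
    ref <- cor.test(x, y)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

make_matched <- function(values_mi, values_mr, groups) {
  samples <- sprintf("s%02d", seq_along(groups))
  colnames(values_mi) <- samples; colnames(values_mr) <- samples
  list(mi = expression_dataset("mi", values_mi, groups, "rnaseq"),
       mr = expression_dataset("mr", values_mr, groups, "rnaseq"))
}

test_that("pairs require opposite directions, negative correlation and a site", {
  set.seed(77)
  groups <- rep("tumor", 12)
  m_vals <- matrix(rnorm(12, 8), 1, dimnames = list("m1", NULL))
  g_anti <- 10 - 0.9 * m_vals[1, ] + rnorm(12, 0, 0.1)
  g_pos <- 4 + 0.9 * m_vals[1, ] + rnorm(12, 0, 0.1)
  mr_vals <- rbind(gA = g_anti, gB = g_pos)
  ds <- make_matched(m_vals, mr_vals, groups)
  cons_mi <- data.frame(feature_id = "m1", direction = "down",
                        stringsAsFactors = FALSE)
  cons_mr <- data.frame(feature_id = c("gA", "gB"),
                        direction = c("up", "down"), stringsAsFactors = FALSE)
  sites <- data.frame(mirna_id = c("m1", "m1"), mrna_id = c("gA", "gB"),
                      n_predictors = c(3L, 3L), stringsAsFactors = FALSE)
  pairs <- build_pairs(cons_mi, cons_mr, ds$mi, ds$mr, sites)
  # gA: opposite direction, anticorrelated, has a site -> emitted
  expect_identical(pairs$mrna_id, "gA")
  expect_lt(pairs$pearson_r, 0)
  # gB fails the direction rule even though a site exists
  expect_false("gB" %in% pairs$mrna_id)
  # without a site gA is not emitted in all-three mode but is without sites
  no_sites <- build_pairs(cons_mi, cons_mr, ds$mi, ds$mr,
                          sites[0, ], require_sites = TRUE)
  expect_equal(nrow(no_sites), 0L)
  relaxed <- build_pairs(cons_mi, cons_mr, ds$mi, ds$mr,
                         sites[0, ], require_sites = FALSE)
  expect_identical(relaxed$mrna_id, "gA")
  # empty consensus lists give an empty pair table
  expect_equal(nrow(build_pairs(cons_mi[0, ], cons_mr, ds$mi, ds$mr, sites)), 0L)
  # positively-correlated opposite-direction pair is not emitted but audited
  cons_mr2 <- data.frame(feature_id = "gB", direction = "up",
                         stringsAsFactors = FALSE)
  audited <- build_pairs(cons_mi, cons_mr2, ds$mi, ds$mr, sites)
  expect_equal(nrow(audited), 0L)
  expect_identical(attr(audited, "sidecar")$mrna_id, "gB")
})

test_that("matched datasets must share the ordered sample list", {
  groups <- rep("tumor", 6)
  a <- matrix(rnorm(6), 1, dimnames = list("m1", NULL))
  b <- matrix(rnorm(6), 1, dimnames = list("g1", NULL))
  ds <- make_matched(a, b, groups)
  ds$mr$sample_ids <- rev(ds$mr$sample_ids)
  expect_error(build_pairs(data.frame(feature_id = "m1", direction = "down"),
                           data.frame(feature_id = "g1", direction = "up"),
                           ds$mi, ds$mr, NULL),
               "identical ordered sample list")
})

test_that("tightening the correlation threshold never enlarges the pair set", {
  fx <- tiny_sim()
  sim <- fx$sim
  de_mi <- lapply(c(sim$mirna_datasets, list(sim$matched$mirna)), call_de,
                  thresholds = de_thresholds(), feature_class = "mirna")
  cons_mi <- consensus_mirna(de_mi, min_datasets = 2)
  cons_mr <- consensus_mrna(
    call_de(sim$mrna_datasets[[1]], de_thresholds(), "mrna"),
    call_de(sim$matched$mrna, de_thresholds(), "mrna"))
  sites <- predict_targets(sim$truth$mirna_sequences[cons_mi$feature_id],
                           fx$utrs[intersect(cons_mr$feature_id, names(fx$utrs))])
  loose <- build_pairs(cons_mi, cons_mr, sim$matched$mirna, sim$matched$mrna,
                       sites, r_threshold = 0)
  tight <- build_pairs(cons_mi, cons_mr, sim$matched$mirna, sim$matched$mrna,
                       sites, r_threshold = -0.5)
  key <- function(p) paste(p$mirna_id, p$mrna_id)
  expect_true(all(key(tight) %in% key(loose)))
  # referential integrity
  expect_true(all(loose$mirna_id %in% cons_mi$feature_id))
  expect_true(all(loose$mrna_id %in% cons_mr$feature_id))
  # summary conservation
  s <- summarize_pairs(loose)
  expect_equal(s$n_pairs, s$n_up_mirna_down_mrna + s$n_down_mirna_up_mrna)
})

test_that("summaries of an empty pair table are all zero", {
  empty <- data.frame(mirna_id = character(), mrna_id = character(),
                      mirna_direction = character(),
                      mrna_direction = character())
  s <- summarize_pairs(empty)
  expect_equal(unlist(s), c(n_pairs = 0, n_mirnas = 0, n_mrnas = 0,
                            n_up_mirna_down_mrna = 0,
                            n_down_mirna_up_mrna = 0))
})
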