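# Per-dataset differential expression: two-sample t-test on log2 expression
# plus class-specific fold-change thresholds, and the two-column
# overexpression fold-change filter.

#' Differential-expression thresholds
#'
#' @param alpha significance level for the per-feature t-test (raw p-values;
#'   no multiple-testing correction by default, see [call_de()]).
#' @param lfc_mrna absolute log2 fold-change cutoff for mRNA calling
#'   (strict inequality).
#' @param lfc_mirna cutoff for miRNA calling; the default 0 means calling is
#'   significance-driven (any nonzero fold change with p < alpha).
#' @param lfc_overexpression inclusive log2 fold-change bound for the
#'   two-column overexpression filter; 0.5849 = log2(1.5).
#' @return a `DEThresholds` list.
#' @export
de_thresholds <- function(alpha = 0.05, lfc_mrna = 1.0, lfc_mirna = 0.0,
                          lfc_overexpression = 0.5849) {
  if (!(alpha > 0 && alpha < 1)) config_error("alpha must be in (0,1)")
  if (lfc_mrna < 0 || lfc_mirna < 0 || lfc_overexpression < 0)
    config_error("log2 fold-change thresholds must be >= 0")
  structure(list(alpha = alpha, lfc_mrna = lfc_mrna, lfc_mirna = lfc_mirna,
                 lfc_overexpression = lfc_overexpression),
            class = "DEThresholds")
}

#' Log2 fold change between groups
#'
#' Inputs are already in log2 space, so the fold change is the difference of
#' group means: mean(tumor) - mean(normal).
#'
#' @param tumor_values,normal_values numeric vectors of log2 expression.
#' @return the log2 fold change (scalar).
#' @export
log2_fold_change <- function(tumor_values, normal_values) {
  if (!length(tumor_values) || !length(normal_values))
    format_error("log2_fold_change: empty group")
  mean(tumor_values) - mean(normal_values)
}

#' Two-sample Student t-test
#'
#' Pooled-variance ("Student") two-sample t by default; Welch's unequal
#' variance test when `equal_variance = FALSE`. The two-sided p-value comes
#' from the t distribution. Degenerate inputs are resolved by a documented
#' convention: zero variance with equal means gives t = 0, p = 1; zero
#' variance with unequal means gives the p -> 0 limit, flagged via the
#' `degenerate` field.
#'
#' @param a,b numeric vectors, at least 2 observations each.
#' @param equal_variance pooled-variance test if `TRUE` (default).
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
student_t_test <- function(a, b, equal_variance = TRUE) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    format_error("student_t_test: need at least 2 observations per group")
  ma <- mean(a); mb <- mean(b)
  va <- sum((a - ma)^2) / (na - 1); vb <- sum((b - mb)^2) / (nb - 1)
  if (equal_variance) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (se == 0) {
    if (ma == mb) return(list(t = 0, df = df, p = 1, degenerate = TRUE))
    return(list(t = sign(ma - mb) * Inf, df = df, p = 0, degenerate = TRUE))
  }
  t <- (ma - mb) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df), degenerate = FALSE)
}

# Vectorized pooled/Welch t across the rows of two matrices (features x
# samples). Used by call_de so that 10k-feature matrices are tested in one
# pass; agreement with student_t_test() is property-tested.
row_t_test <- function(A, B, equal_variance = TRUE) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  if (equal_variance) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  p <- 2 * pt(-abs(t), df)
  zero <- se == 0
  if (any(zero)) {
    eq <- zero & (ma == mb)
    t[eq] <- 0; p[eq] <- 1; df[eq] <- if (equal_variance) na + nb - 2 else NA_real_
    ne <- zero & (ma != mb)
    t[ne] <- sign(ma - mb)[ne] * Inf; p[ne] <- 0
  }
  list(t = t, df = df, p = p, lfc = ma - mb, degenerate = zero)
}

#' Call differential expression on one dataset
#'
#' For every feature a two-sample t-test (tumor vs normal) and the log2 fold
#' change are computed; a direction (`up`/`down`) is assigned iff
#' p < alpha AND |log2FC| strictly exceeds the class threshold
#' (`lfc_mrna` for mRNA, `lfc_mirna` for miRNA). Raw p-values are used by
#' default; `adjust = "BH"` switches the significance filter to
#' Benjamini-Hochberg adjusted values.
#'
#' @param dataset an [expression_dataset()] with >= 2 samples per group.
#' @param thresholds a [de_thresholds()] object.
#' @param feature_class `"mrna"` or `"mirna"`; selects the fold-change cutoff.
#' @param equal_variance pooled-variance t (default) or Welch.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return a `DatasetDEResult`: list with `dataset_id`, `feature_class`,
#'   `thresholds` and `records`, a data.frame with columns `feature_id`,
#'   `log2fc`, `t`, `df`, `p`, `direction`.
#' @export
call_de <- function(dataset, thresholds = de_thresholds(),
                    feature_class = c("mrna", "mirna"),
                    equal_variance = TRUE, adjust = c("none", "BH")) {
  feature_class <- match.arg(feature_class)
  adjust <- match.arg(adjust)
  stopifnot(inherits(dataset, "ExpressionDataset"))
  tum <- dataset$group_labels == "tumor"
  if (sum(tum) < 2L || sum(!tum) < 2L)
    format_error("dataset '%s': need >= 2 samples per group for DE",
                 dataset$dataset_id)
  res <- row_t_test(dataset$values[, tum, drop = FALSE],
                    dataset$values[, !tum, drop = FALSE],
                    equal_variance = equal_variance)
  p_filter <- if (adjust == "BH") p.adjust(res$p, method = "BH") else res$p
  lfc_cut <- if (feature_class == "mrna") thresholds$lfc_mrna else thresholds$lfc_mirna
  direction <- rep("none", length(res$p))
  sig <- p_filter < thresholds$alpha & abs(res$lfc) > lfc_cut
  direction[sig & res$lfc > 0] <- "up"
  direction[sig & res$lfc < 0] <- "down"
  structure(
    list(dataset_id = dataset$dataset_id, feature_class = feature_class,
         thresholds = thresholds,
         records = data.frame(feature_id = dataset$feature_ids,
                              log2fc = res$lfc, t = res$t, df = res$df,
                              p = res$p, direction = direction,
                              stringsAsFactors = FALSE)),
    class = "DatasetDEResult"
  )
}

#' @export
print.DatasetDEResult <- function(x, ...) {
  cat(sprintf("DE result '%s' (%s): %d features, %d up, %d down\n",
              x$dataset_id, x$feature_class, nrow(x$records),
              sum(x$records$direction == "up"),
              sum(x$records$direction == "down")))
  invisible(x)
}

#' Two-column overexpression fold-change filter
#'
#' For an overexpression experiment without replicates (one mimic column, one
#' scrambled-control column of log2 expression), genes are partitioned by
#' log2FC = mimic - scrambled with inclusive bounds:
#' down = {log2FC <= -lfc_overexpression}, up = {log2FC >= +lfc_overexpression}.
#'
#' @param two_condition_table data.frame with columns `gene_id`, `mimic`,
#'   `scrambled` (log2 expression).
#' @param thresholds a [de_thresholds()]; only `lfc_overexpression` is used.
#' @return list with `up`, `down` (gene id vectors) and `log2fc` (named
#'   vector over all genes).
#' @export
overexpression_filter <- function(two_condition_table,
                                  thresholds = de_thresholds()) {
  need <- c("gene_id", "mimic", "scrambled")
  missing <- setdiff(need, names(two_condition_table))
  if (length(missing))
    format_error("overexpression table: missing column '%s'", missing[1])
  lfc <- setNames(two_condition_table$mimic - two_condition_table$scrambled,
                  two_condition_table$gene_id)
  cut <- thresholds$lfc_overexpression
  list(up = names(lfc)[lfc >= cut],
       down = names(lfc)[lfc <= -cut],
       log2fc = lfc)
}
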