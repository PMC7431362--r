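# Benchmarking of scoring functions against true model quality (TM-score or
# GDT_TS-like labels in [0, 1]). All statistics are computed within targets
# and pooled, so only relative scores matter and chain-length effects cancel.

#' Model-quality category scheme
#'
#' Partitions the `[0, 1]` quality scale into near-native `[0.8, 1.0]`,
#' good `[0.6, 0.8)`, medium `[0.4, 0.6)`, and poor `[0, 0.4)`, with a
#' minimum quality difference for a pair of models to count as rankable.
#'
#' @param thresholds Decreasing category boundaries.
#' @param min_diff Minimum quality difference between two compared models.
#' @return A list of class `quality_scheme`.
#' @export
quality_scheme <- function(thresholds = c(0.8, 0.6, 0.4), min_diff = 0.1) {
  stopifnot(length(thresholds) == 3, all(diff(thresholds) < 0),
            min_diff >= 0)
  structure(list(thresholds = thresholds,
                 names = c("near-native", "good", "medium", "poor"),
                 min_diff = min_diff),
            class = "quality_scheme")
}

#' Assign quality categories
#'
#' @param q Numeric vector of true qualities in `[0, 1]`.
#' @param scheme A [quality_scheme()].
#' @return Character vector of category names.
#' @export
categorize <- function(q, scheme = quality_scheme()) {
  if (any(q < 0 | q > 1, na.rm = TRUE)) stop("quality must lie in [0, 1]")
  th <- scheme$thresholds
  out <- rep(scheme$names[4], length(q))
  out[q >= th[3]] <- scheme$names[3]
  out[q >= th[2]] <- scheme$names[2]
  out[q >= th[1]] <- scheme$names[1]
  out
}

check_benchmark_df <- function(df) {
  need <- c("target", "model", "score", "quality")
  if (!all(need %in% names(df)))
    stop("benchmark data needs columns: ", paste(need, collapse = ", "))
  df
}

target_pairs <- function(n) {
  # all unordered index pairs (i < j) of n models
  i <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
  j <- sequence(rev(seq_len(n - 1L))) + i
  cbind(i, j)
}

#' Pairwise ranking accuracy
#'
#' Within each target, every unordered pair of models whose true qualities
#' differ by at least `scheme$min_diff` is classified as correctly ranked
#' when the lower (better) score belongs to the higher-quality model; tied
#' scores count as incorrect. Accuracy is the pooled percentage of correct
#' pairs over all targets. 50 percent corresponds to random ranking.
#'
#' @param df data.frame with columns `target`, `model`, `score`, `quality`.
#' @param scheme A [quality_scheme()].
#' @param category Restrict to pairs of this quality category (`NULL`: all
#'   qualifying pairs).
#' @param pair_category How a pair is assigned a category: by its
#'   `"higher"`-quality member (default), its `"lower"` one, or only when
#'   `"both"` members fall in the category.
#' @return List with `accuracy` (percent, `NA` if no qualifying pair),
#'   `n_pairs`, and `per_target` (data.frame target/correct/total).
#' @export
pairwise_accuracy <- function(df, scheme = quality_scheme(), category = NULL,
                              pair_category = c("higher", "lower", "both")) {
  df <- check_benchmark_df(df)
  pair_category <- match.arg(pair_category)
  per_target <- lapply(split(df, df$target), function(g) {
    n <- nrow(g)
    if (n < 2) return(c(correct = 0, total = 0))
    ij <- target_pairs(n)
    q1 <- g$quality[ij[, 1]]; q2 <- g$quality[ij[, 2]]
    keep <- abs(q1 - q2) >= scheme$min_diff
    if (!is.null(category)) {
      cat1 <- categorize(q1, scheme); cat2 <- categorize(q2, scheme)
      hi <- ifelse(q1 >= q2, cat1, cat2)
      lo <- ifelse(q1 >= q2, cat2, cat1)
      keep <- keep & switch(pair_category,
                            higher = hi == category,
                            lower = lo == category,
                            both = cat1 == category & cat2 == category)
    }
    if (!any(keep)) return(c(correct = 0, total = 0))
    s1 <- g$score[ij[keep, 1]]; s2 <- g$score[ij[keep, 2]]
    qd <- (q1 - q2)[keep]
    better_score <- ifelse(qd > 0, s1, s2)
    worse_score <- ifelse(qd > 0, s2, s1)
    c(correct = sum(better_score < worse_score), total = sum(keep))
  })
  pt <- do.call(rbind, per_target)
  pt <- data.frame(target = rownames(pt), correct = pt[, "correct"],
                   total = pt[, "total"], row.names = NULL,
                   stringsAsFactors = FALSE)
  n_pairs <- sum(pt$total)
  list(accuracy = if (n_pairs > 0) 100 * sum(pt$correct) / n_pairs else NA_real_,
       n_pairs = n_pairs,
       per_target = pt)
}

#' Average predicted rank of a quality category
#'
#' Within each target, models are ranked ascending by score (rank 1 = best
#' predicted, ties share averaged ranks); the ranks of models whose true
#' quality falls in the category are averaged per target, then averaged over
#' the targets containing that category.
#'
#' @inheritParams pairwise_accuracy
#' @param category Quality category name.
#' @return Mean predicted rank (`NA` if the category is empty everywhere).
#' @export
average_predicted_rank <- function(df, category, scheme = quality_scheme()) {
  df <- check_benchmark_df(df)
  per_target <- vapply(split(df, df$target), function(g) {
    r <- rank(g$score, ties.method = "average")
    in_cat <- categorize(g$quality, scheme) == category
    if (!any(in_cat)) return(NA_real_)
    mean(r[in_cat])
  }, numeric(1))
  if (all(is.na(per_target))) return(NA_real_)
  mean(per_target, na.rm = TRUE)
}

#' Mean per-target Pearson correlation between score and quality
#'
#' Good scoring functions correlate negatively with quality (lower score =
#' better model). Targets with fewer than 3 models or zero score variance
#' are skipped with a warning.
#'
#' @inheritParams pairwise_accuracy
#' @return List with `mean_r` (unweighted mean over targets) and
#'   `per_target` (named vector of correlations).
#' @export
mean_pearson <- function(df) {
  df <- check_benchmark_df(df)
  per_target <- vapply(split(df, df$target), function(g) {
    if (nrow(g) < 3 || stats::sd(g$score) == 0 || stats::sd(g$quality) == 0) {
      warning("target '", g$target[1],
              "' skipped: too few models or zero variance")
      return(NA_real_)
    }
    stats::cor(g$score, g$quality)
  }, numeric(1))
  list(mean_r = mean(per_target, na.rm = TRUE), per_target = per_target)
}

#' Compare two methods by Wilcoxon signed-rank test
#'
#' Two-sided Wilcoxon signed-rank test on paired per-target accuracy
#' percentages. Zero-difference pairs are dropped; if all pairs are zero the
#' p-value is 1 and the difference is not significant.
#'
#' @param acc_a,acc_b Equal-length numeric vectors of per-target accuracies
#'   for the two methods, over the same targets.
#' @param alpha Significance level.
#' @return List with `p_value`, `significant`, and `direction` (`"A"` if A
#'   has the higher accuracies, `"B"` otherwise, `"none"` if identical).
#' @export
compare_methods <- function(acc_a, acc_b, alpha = 0.05) {
  stopifnot(length(acc_a) == length(acc_b))
  d <- acc_a - acc_b
  d <- d[!is.na(d) & d != 0]
  if (length(d) == 0)
    return(list(p_value = 1, significant = FALSE, direction = "none"))
  p <- suppressWarnings(stats::wilcox.test(d, mu = 0)$p.value)
  list(p_value = p,
       significant = p < alpha,
       direction = if (sum(d > 0) >= sum(d < 0)) "A" else "B")
}

#' Full category-stratified benchmark report
#'
#' Convenience wrapper computing, for one scored method, the pairwise
#' ranking accuracy and average predicted rank per quality category plus
#' the mean per-target Pearson correlation.
#'
#' @inheritParams pairwise_accuracy
#' @return List with `by_category` (data.frame category/accuracy/n_pairs/
#'   avg_rank) and `mean_r`.
#' @export
benchmark_report <- function(df, scheme = quality_scheme()) {
  df <- check_benchmark_df(df)
  rows <- lapply(scheme$names, function(cat) {
    acc <- pairwise_accuracy(df, scheme, category = cat)
    data.frame(category = cat,
               accuracy = acc$accuracy,
               n_pairs = acc$n_pairs,
               avg_rank = average_predicted_rank(df, cat, scheme),
               stringsAsFactors = FALSE)
  })
  r <- suppressWarnings(mean_pearson(df))
  list(by_category = do.call(rbind, rows), mean_r = r$mean_r)
}
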