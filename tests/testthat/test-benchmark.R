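test_that("quality categories follow the interval conventions", {
  expect_equal(categorize(0.95), "near-native")
  expect_equal(categorize(0.8), "near-native")
  expect_equal(categorize(0.7), "good")
  expect_equal(categorize(0.6), "good")
  expect_equal(categorize(0.4), "medium")
  expect_equal(categorize(0.0), "poor")
  expect_equal(categorize(1.0), "near-native")
  expect_error(categorize(1.2), "\\[0, 1\\]")
})

test_that("pairwise accuracy classifies simple constructed cases", {
  df <- data.frame(target = "t1", model = c("a", "b"),
                   score = c(-50, -10), quality = c(0.9, 0.5))
  expect_equal(pairwise_accuracy(df, category = "near-native")$accuracy, 100)
  df$score <- rev(df$score)
  expect_equal(pairwise_accuracy(df, category = "near-native")$accuracy, 0)
  # quality difference below 0.1 excludes the pair entirely
  df2 <- data.frame(target = "t1", model = c("a", "b"),
                    score = c(-50, -10), quality = c(0.55, 0.50))
  res <- pairwise_accuracy(df2)
  expect_equal(res$n_pairs, 0)
  expect_true(is.na(res$accuracy))
  # tied scores count as incorrect
  df3 <- data.frame(target = "t1", model = c("a", "b"),
                    score = c(-10, -10), quality = c(0.9, 0.5))
  expect_equal(pairwise_accuracy(df3)$accuracy, 0)
})

test_that("a random scorer sits at 50% and a perfect scorer at 100%", {
  set.seed(31)
  df <- do.call(rbind, lapply(1:120, function(t) {
    data.frame(target = sprintf("t%03d", t), model = paste0("m", 1:50),
               score = runif(50), quality = runif(50))
  }))
  res <- pairwise_accuracy(df)
  expect_gt(res$n_pairs, 1e5)
  expect_equal(res$accuracy, 50, tolerance = 0.02)  # 50 +/- 1 percent
  # the ideal scorer (negated quality) is perfect in every category
  df$score <- -df$quality
  for (cat in c("near-native", "good", "medium", "poor")) {
    a <- pairwise_accuracy(df, category = cat)
    if (a$n_pairs > 0) expect_equal(a$accuracy, 100)
  }
  expect_equal(mean_pearson(df)$mean_r, -1)
})

test_that("a scorer and its negation split the pair set to 100%", {
  set.seed(32)
  df <- do.call(rbind, lapply(1:20, function(t) {
    data.frame(target = paste0("t", t), model = paste0("m", 1:20),
               score = runif(20), quality = runif(20))
  }))
  a1 <- pairwise_accuracy(df)
  df$score <- -df$score
  a2 <- pairwise_accuracy(df)
  expect_equal(a1$accuracy + a2$accuracy, 100)
  expect_equal(a1$n_pairs, a2$n_pairs)
})

test_that("accuracy is invariant under strictly monotone score transforms", {
  set.seed(33)
  df <- data.frame(target = rep(paste0("t", 1:10), each = 15),
                   model = paste0("m", 1:150),
                   score = rnorm(150), quality = runif(150))
  a0 <- pairwise_accuracy(df)$accuracy
  df2 <- df; df2$score <- exp(df$score)
  df3 <- df; df3$score <- 2 * df$score - 7
  expect_equal(pairwise_accuracy(df2)$accuracy, a0)
  expect_equal(pairwise_accuracy(df3)$accuracy, a0)
})

test_that("average predicted rank honors tie and pooling conventions", {
  df <- data.frame(target = "t1", model = c("a", "b", "c"),
                   score = c(-30, -20, -10), quality = c(0.9, 0.5, 0.3))
  expect_equal(average_predicted_rank(df, "near-native"), 1.0)
  # tied scores share an averaged rank
  df2 <- data.frame(target = "t1", model = c("a", "b", "c"),
                    score = c(-30, -30, -10), quality = c(0.9, 0.85, 0.3))
  expect_equal(average_predicted_rank(df2, "near-native"), 1.5)
  # pooled over categories, the mean rank per target is (n + 1)/2
  set.seed(34)
  df3 <- data.frame(target = rep("t1", 11), model = paste0("m", 1:11),
                    score = rnorm(11), quality = runif(11))
  ranks <- vapply(c("near-native", "good", "medium", "poor"), function(cat) {
    r <- average_predicted_rank(df3, cat)
    n <- sum(categorize(df3$quality) == cat)
    if (is.na(r)) 0 else r * n
  }, numeric(1))
  expect_equal(sum(ranks) / 11, (11 + 1) / 2)
  # an anti-correlated scorer ranks poor models best
  df4 <- data.frame(target = "t1", model = paste0("m", 1:10),
                    score = seq(-5, 4), quality = seq(0.05, 0.95, by = 0.1))
  expect_lt(average_predicted_rank(df4, "poor"),
            average_predicted_rank(df4, "near-native"))
  expect_true(is.na(average_predicted_rank(
    data.frame(target = "t1", model = "a", score = 1, quality = 0.9),
    "poor")))
})

test_that("mean Pearson correlation averages per-target coefficients", {
  df <- rbind(
    data.frame(target = "t1", model = paste0("a", 1:5),
               score = -(1:5) * 0.1, quality = (1:5) * 0.1),
    data.frame(target = "t2", model = paste0("b", 1:5),
               score = -(1:5) * 0.2, quality = (1:5) * 0.15))
  expect_equal(mean_pearson(df)$mean_r, -1)
  # arithmetic over two targets with known correlations
  set.seed(35)
  mk <- function(tg, r) {
    x <- rnorm(500)
    y <- r * x + sqrt(1 - r^2) * rnorm(500)
    data.frame(target = tg, model = paste0(tg, 1:500), score = x,
               quality = (y - min(y)) / (max(y) - min(y)))
  }
  df2 <- rbind(mk("t1", -0.5), mk("t2", -0.9))
  got <- mean_pearson(df2)
  expect_equal(got$mean_r, mean(got$per_target))
  expect_lt(got$mean_r, -0.5)
  # random scores: mean r near zero
  set.seed(36)
  df3 <- data.frame(target = rep(paste0("t", 1:100), each = 50),
                    model = paste0("m", 1:5000),
                    score = rnorm(5000), quality = runif(5000))
  expect_equal(mean_pearson(df3)$mean_r, 0, tolerance = 0.03)
  # zero-variance targets are skipped with a warning
  df4 <- rbind(df[df$target == "t1", ],
               data.frame(target = "t3", model = paste0("c", 1:4),
                          score = 1, quality = (1:4) / 5))
  expect_warning(r4 <- mean_pearson(df4), "skipped")
  expect_equal(r4$mean_r, -1)
})

test_that("the Wilcoxon comparison behaves at the edges and under real differences", {
  a <- c(70, 72, 68, 75, 71)
  expect_false(compare_methods(a, a)$significant)
  expect_equal(compare_methods(a, a)$p_value, 1)
  set.seed(37)
  b <- runif(50, 60, 80)
  res <- compare_methods(b + 5, b)
  expect_true(res$significant)
  expect_equal(res$direction, "A")
  res2 <- compare_methods(b, b + 5)
  expect_equal(res2$direction, "B")
})

test_that("the Wilcoxon test holds its type-I error on paired noise", {
  set.seed(38)
  rejections <- vapply(1:1000, function(i) {
    base <- runif(30, 50, 90)
    noise <- rnorm(30, 0, 3)
    compare_methods(base + noise, base, alpha = 0.05)$significant
  }, logical(1))
  expect_equal(100 * mean(rejections), 5, tolerance = 0.4)  # 5 +/- 2 points
})
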