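make_blobs <- function(n_per = 30, sep = 10, seed = 8L) {
  set.seed(seed)
  centers <- list(c(0, 0), c(sep, 0), c(0, sep), c(sep, sep))
  do.call(rbind, lapply(1:4, function(k)
    data.frame(diameter_cm = rnorm(n_per, centers[[k]][1], 0.3),
               volume_cc = rnorm(n_per, centers[[k]][2], 0.3),
               score = factor(k + 1, levels = 2:5))))
}

test_that("separable classes are classified perfectly by all three models", {
  tab <- make_blobs()
  for (kind in c("lda", "svm-linear", "svm-gaussian")) {
    rep <- cross_validate(tab, classifier_spec(kind), folds = 5, seed = 2L)
    expect_equal(unname(rep$accuracy["mean"]), 100)
    expect_equal(unname(rep$accuracy["sd"]), 0)
    expect_equal(rep$auc, 1.0)
  }
})

test_that("LDA with equal symmetric Gaussians splits at the midpoint", {
  set.seed(10)
  n <- 400
  train <- data.frame(x = c(rnorm(n, -2), rnorm(n, 2)),
                      y = c(rnorm(n, 0), rnorm(n, 0)),
                      label = rep(c("a", "b"), each = n))
  # probe points straddling the x = 0 midpoint hyperplane
  test <- data.frame(x = c(-0.4, -0.1, 0.1, 0.4), y = 0)
  pred <- train_classify(train, test, classifier_spec("lda"))$predicted
  expect_equal(as.character(pred), c("a", "a", "b", "b"))
  # decision boundary location: posterior crosses 0.5 within |x| < 0.15
  sc <- train_classify(train,
                       data.frame(x = seq(-0.15, 0.15, 0.01), y = 0),
                       classifier_spec("lda"))$scores
  expect_true(any(sc[, "a"] > 0.5) && any(sc[, "b"] > 0.5))
})

test_that("single-class training input is an error", {
  tab <- data.frame(diameter_cm = rnorm(10), volume_cc = rnorm(10),
                    score = factor(rep(2, 10)))
  expect_error(train_classify(tab, tab, classifier_spec("lda")),
               "2 classes")
})

test_that("stratified folds preserve class proportions within one sample", {
  tab <- make_blobs(n_per = 13)   # awkward count on purpose
  y <- tab$score
  folds <- 5L
  set.seed(3)
  # reproduce the fold construction contract through cross_validate:
  # every class must appear floor(n_c/k) or ceiling(n_c/k) times per fold
  rep <- cross_validate(tab, classifier_spec("lda"), folds = folds,
                        seed = 3L)
  expect_equal(sum(rep$confusion), nrow(tab))
  expect_equal(unname(rowSums(rep$confusion)), unname(table(y)[]),
               ignore_attr = TRUE)

  small <- tab[c(1:3, 14:26, 27:39, 40:52), ]
  expect_error(cross_validate(small, classifier_spec("lda"), folds = 5),
               "fewer members")
})

test_that("permuted labels give chance-level AUC", {
  set.seed(21)
  n <- 400
  tab <- data.frame(diameter_cm = rnorm(n), volume_cc = rnorm(n),
                    score = factor(sample(c("lo", "hi"), n, TRUE)))
  rep <- cross_validate(tab, classifier_spec("lda"), folds = 5, seed = 4L)
  expect_lt(abs(rep$auc - 0.5), 0.05)
})

test_that("cross-validation is invariant to row shuffling", {
  tab <- make_blobs(n_per = 12)
  set.seed(99)
  shuf <- tab[sample(nrow(tab)), ]
  r1 <- cross_validate(tab, classifier_spec("lda"), folds = 4, seed = 5L)
  r2 <- cross_validate(shuf, classifier_spec("lda"), folds = 4, seed = 5L)
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(r1$auc, r2$auc)
})

test_that("ROC/AUC equals brute-force pair counting", {
  # perfect and anti-perfect rankings
  expect_equal(roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_curve(c(4, 3, 2, 1), c(0, 0, 1, 1))$auc, 0.0)
  # 6-point toy set with a tie, against direct concordance counting
  s <- c(0.1, 0.4, 0.4, 0.6, 0.7, 0.2)
  y <- c(0, 0, 1, 1, 0, 1)
  pairs <- expand.grid(p = which(y == 1), n = which(y == 0))
  brute <- mean(ifelse(s[pairs$p] > s[pairs$n], 1,
                       ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
  expect_equal(roc_curve(s, y)$auc, brute)
  expect_error(roc_curve(1:3, c(1, 1, 1)), "both classes")
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic (property)", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(8:40, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # forces ties
    u <- sum(rank(s)[y == 1]) - sum(y) * (sum(y) + 1) / 2
    expect_equal(roc_curve(s, y)$auc, u / (sum(y) * sum(1 - y)))
  }
})

test_that("confusion-matrix trace equals the overall correct rate", {
  tab <- make_blobs(n_per = 10, sep = 2, seed = 12L)  # overlapping
  rep <- cross_validate(tab, classifier_spec("lda"), folds = 5, seed = 6L)
  overall <- 100 * sum(diag(rep$confusion)) / sum(rep$confusion)
  pooled <- 100 * sum(diag(rep$confusion)) / nrow(tab)
  expect_equal(overall, pooled)
  expect_true(all(rep$per_class_rate >= 0 & rep$per_class_rate <= 100))
})

test_that("agreement computes r, confusion and detection rates", {
  expect_equal(agreement(c(2, 3, 4, 5), c(2, 3, 4, 5))$r, 1.0)
  expect_equal(agreement(c(5, 4, 3, 2), c(2, 3, 4, 5))$r, -1.0)
  # hand-evaluated product-moment formula
  a <- c(2, 3, 4, 5, 5); b <- c(2, 3, 4, 5, 4)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  ag <- agreement(a, b)
  expect_equal(ag$r, r_hand)
  expect_equal(unname(ag$detection_rate[["4"]]), 50)   # 1 of 2 correct
  expect_error(agreement(c(2, 2, 2), c(2, 3, 4)), "zero variance")
  expect_error(agreement(1:2, 1:2), "length")
})

test_that("binarization maps 2-3 to low and 4-5 to high", {
  tab <- make_blobs(n_per = 3)
  b <- binarize_scores(tab)
  expect_equal(as.character(b$score),
               rep(c("low", "low", "high", "high"), each = 3))
})
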