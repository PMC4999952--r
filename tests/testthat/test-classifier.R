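make_clusters <- function(n_per_class, d = 2, sep = 6, seed = 3) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * d), n_per_class, d),
               matrix(rnorm(n_per_class * d, mean = sep), n_per_class, d))
  })
  list(x = x, y = rep(c(-1, 1), each = n_per_class))
}

test_that("stratified split honors per-class counts and determinism", {
  labels <- rep(c(1, -1), each = 52)
  sp <- split_stratified(labels, 2 / 3, seed = 1)
  expect_length(sp$train, 70)
  expect_length(sp$test, 34)
  expect_equal(sum(labels[sp$train] == 1), 35)
  expect_equal(sum(labels[sp$test] == 1), 17)
  expect_identical(sp, split_stratified(labels, 2 / 3, seed = 1))
  expect_false(identical(sp$train, split_stratified(labels, 2 / 3, 2)$train))
  expect_setequal(c(sp$train, sp$test), seq_along(labels))

  expect_error(split_stratified(labels, 1, seed = 1), "empty")
  expect_error(split_stratified(rep(1, 10), 0.5, seed = 1), "both classes")
  expect_error(split_stratified(c(1, 1, -1, rep(1, 5)), 0.5, seed = 1),
               "at least 3")
})

test_that("training validates inputs", {
  cl <- make_clusters(10)
  expect_error(train_mlp(cl$x, cl$y, 0), "n_hidden")
  bad <- cl$x; bad[1, 1] <- NA
  expect_error(train_mlp(bad, cl$y, 3), "non-finite")
  expect_error(train_mlp(cl$x, rep(1, 20), 3), "both classes")
  expect_error(train_mlp(cl$x, rep(2, 20), 3), "labels")
})

test_that("well-separated clusters are learned perfectly", {
  cl <- make_clusters(100)
  m <- train_mlp(cl$x, cl$y, 5, mlp_config(lr = 0.05, max_epochs = 2000,
                                           seed = 1))
  expect_equal(mean(classify(predict(m, cl$x)) == cl$y), 1)
})

test_that("one example per class yields separating score signs", {
  x <- matrix(c(0, 1), 2, 1)
  m <- train_mlp(x, c(-1, 1), 2, mlp_config(lr = 0.1, max_epochs = 5000,
                                            seed = 2))
  s <- predict(m, x)
  expect_lt(s[1], 0)
  expect_gt(s[2], 0)
})

test_that("prediction is deterministic, shift invariant, and checks dims", {
  cl <- make_clusters(40)
  m <- train_mlp(cl$x, cl$y, 4, mlp_config(max_epochs = 300, seed = 5))
  expect_identical(predict(m, cl$x), predict(m, cl$x))
  # shifting train+test identically is absorbed by the normalization stats
  m2 <- train_mlp(cl$x + 100, cl$y, 4, mlp_config(max_epochs = 300, seed = 5))
  expect_equal(predict(m2, cl$x + 100), predict(m, cl$x), tolerance = 1e-8)
  expect_error(predict(m, cl$x[, 1, drop = FALSE]), "dimension mismatch")

  # all-zero weights score 0 -> classified as control
  m$w1[] <- 0; m$b1[] <- 0; m$w2[] <- 0; m$b2 <- 0
  expect_equal(predict(m, cl$x), rep(0, nrow(cl$x)))
  expect_true(all(classify(predict(m, cl$x)) == -1))

  # single-input single-hidden-unit model with positive weights is monotone
  mono <- m
  mono$w1 <- matrix(1); mono$b1 <- 0; mono$w2 <- matrix(1); mono$b2 <- 0
  mono$norm_stats <- list(mean = 0, sd = 1)
  s <- predict(mono, matrix(seq(-2, 2, 0.5)))
  expect_true(all(diff(s) > 0))
})

test_that("training is reproducible and loss nonincreasing at small lr", {
  cl <- make_clusters(50)
  cfg <- mlp_config(lr = 0.005, max_epochs = 400, seed = 11)
  m1 <- train_mlp(cl$x, cl$y, 5, cfg, trace = TRUE)
  m2 <- train_mlp(cl$x, cl$y, 5, cfg)
  expect_identical(m1$w1, m2$w1)
  expect_identical(m1$b2, m2$b2)
  expect_true(all(diff(m1$mse_history) <= 1e-12))
})

test_that("XOR reaches the 1e-5 MSE stopping rule for some seed", {
  x <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  y <- c(-1, 1, 1, -1)
  conv <- vapply(1:10, function(s) {
    train_mlp(x, y, 5, mlp_config(lr = 0.1, momentum = 0.9,
                                  max_epochs = 20000,
                                  seed = s))$train_meta$converged
  }, NA)
  expect_gte(sum(conv), 1)
})

test_that("evaluate reproduces printed worked examples", {
  r <- eval_from_counts(tp = 15, fn = 2, tn = 14, fp = 3)
  expect_equal(round(100 * r$sensitivity, 1), 88.2)
  expect_equal(round(100 * r$specificity, 1), 82.4)
  expect_equal(round(100 * r$accuracy, 1), 85.3)
  expect_equal(round(100 * r$ppv, 1), 83.3)
  expect_equal(round(100 * r$npv, 1), 87.5)
})

test_that("evaluate handles perfect, chance and one-class inputs", {
  s <- c(1, 2, 3, -1, -2, -3)
  y <- c(1, 1, 1, -1, -1, -1)
  r <- evaluate(s, y)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  r <- evaluate(rep(0.5, 6), y)
  expect_equal(r$auc, 0.5)
  expect_warning(r1 <- evaluate(c(1, 2), c(1, 1)), "one-class")
  expect_true(is.na(r1$auc))
  expect_error(evaluate(1:3, 1:2), "length")
})

test_that("ROC curve is monotone from (0,0) to (1,1)", {
  withr::with_seed(23, {
    s <- rnorm(60)
    y <- sample(c(-1, 1), 60, replace = TRUE, prob = c(0.5, 0.5))
  })
  r <- evaluate(s, y)
  expect_equal(r$roc$fpr[1], 0)
  expect_equal(r$roc$tpr[1], 0)
  expect_equal(tail(r$roc$fpr, 1), 1)
  expect_equal(tail(r$roc$tpr, 1), 1)
  expect_true(all(diff(r$roc$fpr) >= 0))
  expect_true(all(diff(r$roc$tpr) >= 0))
})

test_that("trapezoidal AUC equals pairwise AUC, ties included", {
  expect_equal(auc_brute(c(3, 2, 1, 0), c(1, 1, -1, -1)), 1)
  expect_equal(auc_brute(c(1, 1), c(1, -1)), 0.5)
  withr::with_seed(29, {
    for (i in 1:40) {
      n <- sample(6:50, 1)
      s <- round(rnorm(n), sample(0:2, 1))  # induce ties
      y <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
      ab <- auc_brute(s, y)
      expect_equal(evaluate(s, y)$auc, ab, tolerance = 1e-12)
      expect_equal(ab, auc_pairwise_oracle(s, y), tolerance = 1e-12)
      # label-swap symmetry
      expect_equal(auc_brute(-s, -y), ab, tolerance = 1e-12)
    }
  })
})

test_that("confusion identities hold on random reports", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(10:80, 1)
      s <- rnorm(n)
      y <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
      r <- evaluate(s, y)
      expect_equal(r$tp + r$fn, sum(y == 1))
      expect_equal(r$tn + r$fp, sum(y == -1))
      expect_equal(r$accuracy, (r$tp + r$tn) / n)
      expect_equal(r$sensitivity * (r$tp + r$fn), r$tp)
    }
  })
})

test_that("model JSON serialization round-trips exactly", {
  cl <- make_clusters(20)
  colnames(cl$x) <- c("f1", "f2")
  m <- train_mlp(cl$x, cl$y, 3, mlp_config(max_epochs = 150, seed = 9))
  path <- withr::local_tempfile(fileext = ".json")
  write_mlp_json(m, path)
  back <- read_mlp_json(path)
  expect_equal(back$w1, m$w1, tolerance = 0)
  expect_equal(back$w2, m$w2, tolerance = 0)
  expect_equal(back$b1, m$b1, tolerance = 0)
  expect_equal(back$norm_stats$mean, unname(m$norm_stats$mean), tolerance = 0)
  expect_identical(predict(back, cl$x), unname(predict(m, cl$x)))
})

test_that("hidden-size selection returns a width with best validation accuracy", {
  cl <- make_clusters(60, sep = 4)
  sel <- select_hidden(cl$x, cl$y, widths = c(1, 3, 5),
                       cfg = mlp_config(max_epochs = 300, seed = 2))
  expect_true(sel$best %in% c(1, 3, 5))
  expect_length(sel$accuracy, 3)
  expect_true(all(sel$accuracy >= 0.5))
})
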