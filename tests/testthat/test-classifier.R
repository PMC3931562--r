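# small labelled corpus for split tests: n sequences per class per bin
toy_truth <- function(n = 6) {
  bins <- length_bins()
  do.call(rbind, lapply(TAXON_GROUPS, function(cl) {
    do.call(rbind, lapply(seq_len(nrow(bins)), function(i) {
      lo <- bins$lower[i]
      hi <- min(bins$upper[i] - 1, 900)
      data.frame(id = sprintf("%s_b%d_%02d", cl, i, seq_len(n)), class = cl,
                 length = round(seq(lo, hi, length.out = n)),
                 stringsAsFactors = FALSE)
    }))
  }))
}

test_that("train/test splits are disjoint, balanced and seed-reproducible", {
  truth <- toy_truth(n = 6)
  for (seed in 1:20) {
    sp <- build_training_sets(truth, sizes = c(2, 2, 2), seed = seed)
    expect_length(intersect(sp$train$id, sp$test$id), 0)
    expect_length(intersect(sp$train$id, sp$customdb$id), 0)
    expect_length(intersect(sp$test$id, sp$customdb$id), 0)
    # per bin and class, exactly `size` in train and test
    expect_true(all(table(sp$train$class, sp$train$bin) == 2))
    expect_true(all(table(sp$test$class, sp$test$bin) == 2))
    # leftovers all route to the custom pool
    expect_setequal(c(sp$train$id, sp$test$id, sp$customdb$id), truth$id)
  }
  s1 <- build_training_sets(truth, sizes = c(2, 2, 2), seed = 7)
  s2 <- build_training_sets(truth, sizes = c(2, 2, 2), seed = 7)
  s3 <- build_training_sets(truth, sizes = c(2, 2, 2), seed = 8)
  expect_identical(s1, s2)
  expect_false(identical(sort(s1$train$id), sort(s3$train$id)))
  expect_equal(nrow(s3$train), nrow(s1$train))
})

test_that("an unfillable split errors naming the deficient class and bin", {
  truth <- toy_truth(n = 1)  # one sequence per class/bin: test set unfillable
  expect_error(build_training_sets(truth, sizes = c(1, 1, 1), seed = 1),
               "insufficient sequences.*cnidarian.*150-300")
})

test_that("training learns a separable toy problem and is reproducible", {
  set.seed(42)
  n <- 40
  x <- rbind(matrix(rnorm(2 * n, mean = 0), ncol = 2),
             matrix(rnorm(2 * n, mean = 4), ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("cnidarian", "dinoflagellate"), each = n)

  model <- train_classifier(x, y, seed = 1)
  pred <- classify_contigs(model, x)
  expect_equal(pred$predicted, y)  # 100% training accuracy when separable

  probe <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("f1", "f2")))
  p1 <- classify_contigs(train_classifier(x, y, seed = 1), probe)
  p2 <- classify_contigs(train_classifier(x, y, seed = 1), probe)
  expect_identical(p1, p2)

  expect_error(train_classifier(x, rep("cnidarian", 2 * n)), ">= 2 classes")
  expect_error(train_classifier(x, rep(c("whale", "yeast"), each = n)),
               "labels")
  expect_error(classify_contigs(model, x[, 1, drop = FALSE]),
               "dimensionality mismatch")
})

test_that("feature scaling is fit on training data only and frozen", {
  set.seed(3)
  train <- matrix(rnorm(60, mean = 2, sd = 1), ncol = 2,
                  dimnames = list(NULL, c("f1", "f2")))
  test <- matrix(rnorm(60, mean = 10, sd = 5), ncol = 2,
                 dimnames = list(NULL, c("f1", "f2")))
  y <- rep(c("cnidarian", "fungal"), 15)
  model <- train_classifier(train, y, seed = 1)
  expect_equal(unname(model$scaler$center), unname(colMeans(train)))
  expect_equal(unname(model$scaler$scale), unname(apply(train, 2, sd)))
  # a scaler refit on train+test is detectably different
  leaky <- symbiosort:::fit_scaler(rbind(train, test))
  expect_gt(max(abs(leaky$center - model$scaler$center)), 1)
  # classifying must not mutate the stored scaler
  classify_contigs(model, test)
  expect_equal(unname(model$scaler$center), unname(colMeans(train)))
})

test_that("batch classification equals row-by-row re-prediction", {
  set.seed(8)
  x <- matrix(rnorm(200), ncol = 4,
              dimnames = list(sprintf("c%02d", 1:50), paste0("f", 1:4)))
  y <- rep(c("cnidarian", "dinoflagellate", "fungal", "bacterial"),
           length.out = 50)
  x[y == "dinoflagellate", 1] <- x[y == "dinoflagellate", 1] + 3
  x[y == "fungal", 2] <- x[y == "fungal", 2] + 3
  x[y == "bacterial", 3] <- x[y == "bacterial", 3] + 3
  model <- train_classifier(x, y, seed = 1)
  batch <- classify_contigs(model, x)
  single <- vapply(seq_len(nrow(x)), function(i)
    classify_contigs(model, x[i, , drop = FALSE])$predicted, character(1))
  expect_equal(batch$predicted, single)
  # a duplicated contig gets an identical label
  expect_equal(classify_contigs(model, x[c(1, 1), ])$predicted[1],
               classify_contigs(model, x[c(1, 1), ])$predicted[2])
})

test_that("per-bin evaluation pools correctly and keeps unbinned contigs", {
  lens <- c(200, 200, 350, 350, 600, 600)
  truth <- rep("cnidarian", 6)
  ev <- evaluate_by_bin(truth, truth, lens)
  expect_equal(ev$accuracy[ev$bin != "unbinned"], rep(1, 4))

  # half wrong in one bin of 10
  lens <- rep(200, 10)
  pred <- rep(c("cnidarian", "fungal"), 5)
  ev <- evaluate_by_bin(pred, rep("cnidarian", 10), lens)
  expect_equal(ev$accuracy[ev$bin == "150-300"], 0.5)
  expect_equal(ev$error_rate[ev$bin == "overall"], 0.5)

  # short contigs land in an explicit unbinned row, not dropped
  ev <- evaluate_by_bin(c("cnidarian", "fungal"), c("cnidarian", "cnidarian"),
                        c(100, 250))
  expect_equal(ev$n[ev$bin == "unbinned"], 1)
  expect_equal(sum(ev$n[ev$bin != "overall"]), 2)
})

test_that("a random-label baseline sits at chance for four balanced classes", {
  set.seed(77)
  n <- 4000
  truth <- rep(TAXON_GROUPS, each = n / 4)
  pred <- sample(TAXON_GROUPS, n, replace = TRUE)
  acc <- mean(pred == truth)
  # binomial oracle: p = 1/4, 99.9% interval
  ci <- qbinom(c(5e-4, 1 - 5e-4), n, 0.25) / n
  expect_gte(acc, ci[1])
  expect_lte(acc, ci[2])
})
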