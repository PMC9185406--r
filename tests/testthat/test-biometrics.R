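test_that("8-bit quantization maps each template onto the full range", {
  q <- quantize_templates(matrix(seq(0, 1, length.out = 10), nrow = 1))
  expect_equal(min(q), 0L)
  expect_equal(max(q), 255L)

  expect_true(all(quantize_templates(matrix(2, 1, 8)) == 128L))

  # round-trip error bounded by range/255 per sample
  set.seed(2)
  m <- matrix(rnorm(200), 10, 20)
  q <- quantize_templates(m)
  for (i in 1:10) {
    rng <- max(m[i, ]) - min(m[i, ])
    back <- min(m[i, ]) + q[i, ] / 255 * rng
    expect_lte(max(abs(back - m[i, ])), rng / 255)
  }
})

test_that("train-fitted standardization normalizes the training set", {
  set.seed(4)
  x <- matrix(rnorm(600, 5, 3), 30, 20)
  st <- fit_standardization(x)
  xs <- apply_standardization(x, st)
  expect_lt(max(abs(colMeans(xs))), 1e-10)
  expect_equal(unname(apply(xs, 2, sd)), rep(1, 20), tolerance = 1e-10)
})

test_that("static splits take the first and last templates; random splits are seeded", {
  sets <- list(A = matrix(1:90, 90, 1), B = matrix(101:190, 90, 1))
  sp <- split_templates(sets, protocol_spec("static", n_test = 30))
  expect_equal(sp$train$x[sp$train$y == "A", 1], 1:30)
  expect_equal(sp$test$x[sp$test$y == "A", 1], 61:90)

  sp15 <- split_templates(sets, protocol_spec("static", n_test = 15))
  expect_equal(sp15$test$x[sp15$test$y == "A", 1], 76:90)

  r1 <- split_templates(sets, protocol_spec("random"), rep = 2, seed = 9)
  r2 <- split_templates(sets, protocol_spec("random"), rep = 2, seed = 9)
  expect_identical(r1, r2)
  r3 <- split_templates(sets, protocol_spec("random"), rep = 3, seed = 9)
  expect_false(identical(r1$train$x, r3$train$x))
  # disjoint train/test covering all templates
  expect_equal(sort(c(r1$train$x[r1$train$y == "A", 1],
                      r1$test$x[r1$test$y == "A", 1])), 1:90)

  expect_error(split_templates(list(A = matrix(1, 40, 1)),
                               protocol_spec("static", n_test = 30)), "A has 40")
})

test_that("classifiers separate well-separated synthetic classes", {
  set.seed(11)
  n <- 40; L <- 30
  xa <- matrix(rnorm(n * L, 0, 0.1), n, L); xa[, 1:10] <- xa[, 1:10] + 2
  xb <- matrix(rnorm(n * L, 0, 0.1), n, L); xb[, 21:30] <- xb[, 21:30] + 2
  x <- rbind(xa, xb); y <- rep(c("a", "b"), each = n)
  for (kind in c("SVM", "GaussianNB", "KNN3")) {
    m <- train_classifier(kind, x, y)
    expect_equal(mean(predict(m, x) == y), 1, info = kind)
  }
  expect_error(train_classifier("SVM", xa, rep("a", n)), "2 classes")
})

test_that("deterministic 3-NN agrees with the reference implementation", {
  set.seed(21)
  train <- matrix(rnorm(200), 50, 4)
  y <- factor(rep(c("a", "b"), 25))
  test <- matrix(rnorm(80), 20, 4)
  ours <- seatecg:::knn3_predict(train, y, test)
  theirs <- as.character(class::knn(train, test, y, k = 3))
  expect_equal(unname(ours), theirs)
})

test_that("a degenerate always-one-class predictor scores chance metrics", {
  truth <- factor(rep(c("A", "B"), each = 10))
  pred <- factor(rep("A", 20), levels = c("A", "B"))
  m <- classification_metrics(truth, pred)
  expect_equal(m[["accuracy"]], 50)
  expect_equal(m[["recall"]], 50)
})

test_that("identical twin profiles are indistinguishable (chance accuracy)", {
  prof <- subject_profile("S01", 70, 2)
  twin <- prof; twin$subject_id <- "S02"
  degr <- degradation_spec(saturation_episodes = list(c(50, 10)))
  sets <- harvest_templates(list(prof, twin), degr,
                            duration = 120, fs = 250, seed = 77)
  res <- evaluate_identification(sets, "KNN3",
                                 protocol_spec("random", n_repetitions = 5),
                                 population_sizes = 2, seed = 3)
  expect_lt(mean(res$accuracy), 75)
  expect_gt(mean(res$accuracy), 25)
})

test_that("the binary-weight CNN learns a separable problem deterministically", {
  set.seed(31)
  n <- 30; L <- 64
  t <- seq(0, 1, length.out = L)
  xa <- t(replicate(n, sin(2 * pi * 3 * t) + rnorm(L, 0, 0.2)))
  xb <- t(replicate(n, sin(2 * pi * 7 * t) + rnorm(L, 0, 0.2)))
  x <- rbind(xa, xb); y <- rep(c("a", "b"), each = n)
  m1 <- train_classifier("BCNN", x, y, seed = 5, epochs = 15)
  acc <- mean(predict(m1, x) == y)
  expect_gte(acc, 0.95)
  m2 <- train_classifier("BCNN", x, y, seed = 5, epochs = 15)
  expect_identical(predict(m1, x), predict(m2, x))
  # binarized layers hold latent weights in [-1, 1]
  expect_lte(max(abs(m1$fit$W2)), 1)
  expect_lte(max(abs(m1$fit$Wd)), 1)
})

test_that("the evaluation sweep is ordered, bounded and seed-reproducible", {
  sets <- default_sets4()
  prot <- protocol_spec("random", n_repetitions = 2)
  r1 <- evaluate_identification(sets, c("SVM", "KNN3"), prot,
                                population_sizes = c(2, 4), seed = 8)
  r2 <- evaluate_identification(sets, c("SVM", "KNN3"), prot,
                                population_sizes = c(2, 4), seed = 8)
  expect_identical(r1, r2)
  expect_true(all(r1$accuracy >= 0 & r1$accuracy <= 100))
  expect_true(all(r1$recall >= 0 & r1$recall <= 100))
  sm <- summarize_identification(r1)
  expect_true(all(sm$accuracy_mean >= pmin(sm$accuracy_mean) &
                    sm$accuracy_mean <= 100))
  expect_error(evaluate_identification(sets, "KNN3", prot,
                                       population_sizes = 9, seed = 1),
               "exceeds")
})
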