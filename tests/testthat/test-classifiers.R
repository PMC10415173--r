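# two linearly separated point clouds in D = 4 (A-corner vs T-corner)
make_clouds <- function(n_per = 20, seed = 0) {
  set.seed(seed)
  a <- cbind(runif(n_per, 0.7, 0.9), runif(n_per, 0, 0.1),
             runif(n_per, 0, 0.1), runif(n_per, 0, 0.1))
  b <- cbind(runif(n_per, 0, 0.1), runif(n_per, 0, 0.1),
             runif(n_per, 0, 0.1), runif(n_per, 0.7, 0.9))
  x <- rbind(a, b)
  colnames(x) <- c("A", "C", "G", "T")
  list(x = x, y = rep(c("cornerA", "cornerT"), each = n_per))
}

test_that("a single-class training set yields a constant predictor", {
  x <- matrix(runif(40), 10, 4)
  m <- train_classifier(x, rep("Bacteria", 10), family = "bagged_trees")
  expect_equal(predict(m, matrix(runif(8), 2, 4)),
               c("Bacteria", "Bacteria"))
  expect_error(train_classifier(x, rep("Bacteria", 10), family = "svm_linear"),
               class = "kbalance_class_error")
})

test_that("every family separates two distant point clouds perfectly", {
  d <- make_clouds(seed = 1)
  for (fam in c("bagged_trees", "subspace_knn", "subspace_discriminant",
                "svm_linear", "svm_gaussian", "svm_polynomial", "mlp")) {
    m <- train_classifier(d$x, d$y, family = fam, hidden_size = 32, seed = 0)
    expect_equal(predict(m, d$x), d$y, info = fam)
  }
})

test_that("training is deterministic given the seed", {
  d <- make_clouds(n_per = 25, seed = 2)
  set.seed(77)
  probe <- matrix(runif(40 * 4), 40, 4, dimnames = list(NULL, colnames(d$x)))
  for (fam in c("bagged_trees", "subspace_knn", "mlp")) {
    m1 <- train_classifier(d$x, d$y, family = fam, hidden_size = 16, seed = 9)
    m2 <- train_classifier(d$x, d$y, family = fam, hidden_size = 16, seed = 9)
    expect_identical(predict(m1, probe), predict(m2, probe), info = fam)
  }
})

test_that("predictions never leave the training label set", {
  set.seed(4)
  x <- matrix(runif(200), 50, 4)
  y <- sample(c("p", "q", "r"), 50, replace = TRUE)
  probe <- matrix(runif(80), 20, 4)
  for (fam in c("bagged_trees", "subspace_knn", "subspace_discriminant")) {
    m <- train_classifier(x, y, family = fam, n_learners = 10, seed = 1)
    expect_true(all(predict(m, probe) %in% c("p", "q", "r")), info = fam)
  }
})

test_that("bagging with one learner and no bootstrap is a single tree", {
  set.seed(10)
  x <- matrix(runif(400), 100, 4)
  y <- ifelse(x[, 1] + 0.3 * runif(100) > 0.6, "hi", "lo")
  m <- train_classifier(x, y, family = "bagged_trees", n_learners = 1,
                        bootstrap = FALSE, seed = 3)
  df <- as.data.frame(x)
  names(df) <- paste0("f", 1:4)
  df$.y <- factor(y)
  ref <- rpart::rpart(.y ~ ., data = df, method = "class")
  expect_equal(predict(m, x),
               as.character(predict(ref, df, type = "class")))
})

test_that("subspace members use exactly subspace_dim features and vary", {
  set.seed(11)
  x <- matrix(runif(50 * 16), 50, 16)
  y <- rep(c("a", "b"), 25)
  m1 <- train_classifier(x, y, family = "subspace_knn", n_learners = 8,
                         subspace_dim = 5, seed = 1)
  feats1 <- lapply(m1$fitted$members, `[[`, "features")
  expect_true(all(lengths(feats1) == 5))
  expect_gt(length(unique(feats1)), 1)  # members differ within a model
  m2 <- train_classifier(x, y, family = "subspace_knn", n_learners = 8,
                         subspace_dim = 5, seed = 2)
  feats2 <- lapply(m2$fitted$members, `[[`, "features")
  expect_false(identical(feats1, feats2))  # and across seeds
})

test_that("prediction refuses mismatched feature spaces", {
  d <- make_clouds(seed = 3)
  m <- train_classifier(d$x, d$y, family = "subspace_knn", seed = 0)
  expect_error(predict(m, matrix(runif(32), 2, 16)),
               "D = 4", class = "kbalance_fingerprint_error")
  wrong_names <- d$x
  colnames(wrong_names) <- c("T", "G", "C", "A")
  expect_error(predict(m, wrong_names), class = "kbalance_fingerprint_error")
  expect_equal(predict(m, d$x[0, , drop = FALSE]), character(0))
})

test_that("NaN features and tiny inputs are rejected", {
  x <- matrix(runif(40), 10, 4)
  x[3, 2] <- NaN
  expect_error(train_classifier(x, rep(c("a", "b"), 5), family = "subspace_knn"),
               class = "kbalance_range_error")
  expect_error(train_classifier(x[1, , drop = FALSE], "a",
                                family = "bagged_trees"),
               class = "kbalance_type_error")
})

test_that("models survive a save/load round trip and refuse bad files", {
  d <- make_clouds(seed = 5)
  m <- train_classifier(d$x, d$y, family = "subspace_knn", seed = 0)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  set.seed(20)
  probe <- matrix(runif(20), 5, 4, dimnames = list(NULL, colnames(d$x)))
  expect_identical(predict(m, probe), predict(m2, probe))

  junk <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a model", junk)
  expect_error(load_model(junk), class = "kbalance_parse_error")

  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "kbalance_model", version = 99L, model = m), other)
  expect_error(load_model(other), class = "kbalance_version_error")

  # a model fit on k=1 features refuses k=2 feature matrices
  k2 <- matrix(runif(32), 2, 16, dimnames = list(NULL, kmer_words(2)))
  expect_error(predict(m2, k2), class = "kbalance_fingerprint_error")
})

test_that("ensemble vote ties break towards the first class label", {
  votes <- matrix(c("b", "a", "a", "b"), nrow = 2)
  expect_equal(kbalance:::vote_labels(votes, c("a", "b")), c("a", "a"))
})
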