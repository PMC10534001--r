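# Synthetic two-pattern image set: class A carries its energy in the top
# half, class B in the bottom half, with mild noise - linearly separable.
make_pattern_set <- function(n_per_class = 20, seed = 5) {
  set.seed(seed)
  mk <- function(top) {
    a <- array(0.1, c(28, 28, 3))
    rows <- if (top) 1:14 else 15:28
    a[rows, , ] <- 0.9
    as.vector(a) + stats::rnorm(28 * 28 * 3, 0, 0.05)
  }
  x <- rbind(t(replicate(n_per_class, mk(TRUE))),
             t(replicate(n_per_class, mk(FALSE))))
  list(x = x, y = rep(c("A", "B"), each = n_per_class))
}

test_that("built model is seeded, normalised and two-headed", {
  cfg <- train_config(seed = 3)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$layers, m2$layers)
  expect_equal(ncol(m1$layers$fc$W), 2)

  set.seed(1)
  x <- matrix(stats::runif(5 * 2352), 5)
  p <- predict(m1, x)
  expect_equal(dim(p), c(5, 2))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p >= 0))

  expect_error(build_model(train_config(backbone = "resnet50")),
               "unknown backbone")
  expect_error(train_config(learning_rate = 0), "positive")
  expect_error(train_config(epochs = 0), "at least 1")
})

test_that("training separates trivially distinct patterns and is deterministic", {
  d <- make_pattern_set()
  cfg <- train_config(epochs = 20, seed = 7)
  model <- build_model(cfg)

  # zero epochs: parameters untouched
  m0 <- train_model(model, d$x, d$y, cfg, epochs = 0)
  expect_identical(m0$layers, model$layers)

  fit <- train_model(model, d$x, d$y, cfg)
  expect_equal(fit$loss_trace$accuracy[20], 1)
  # loss trend is downward overall
  expect_lt(mean(tail(fit$loss_trace$loss, 5)),
            mean(head(fit$loss_trace$loss, 5)))
  p <- predict(fit, d$x)
  expect_equal(colnames(p)[max.col(p)], d$y)

  fit2 <- train_model(build_model(cfg), d$x, d$y, cfg)
  expect_identical(fit2$loss_trace$loss, fit$loss_trace$loss)

  expect_error(train_model(model, d$x[1:20, ], rep("A", 20), cfg),
               "at least one image per class")
})

test_that("regularised LDA separates well-separated Gaussian clouds", {
  set.seed(13)
  p <- 5
  mu <- rep(6 / sqrt(p), p)          # 6 sigma separation overall
  xtr <- rbind(matrix(stats::rnorm(40 * p), 40),
               matrix(stats::rnorm(40 * p), 40) + rep(mu, each = 40))
  ytr <- rep(c("Control", "SSc"), each = 40)
  xte <- rbind(matrix(stats::rnorm(50 * p), 50),
               matrix(stats::rnorm(50 * p), 50) + rep(mu, each = 50))
  yte <- rep(c("Control", "SSc"), each = 50)

  fit <- fit_lda(xtr, ytr)
  pred <- predict(fit, xte)
  expect_gte(mean(pred$class == yte), 0.95)
  expect_equal(rowSums(pred$posterior), rep(1, 100), tolerance = 1e-9)

  expect_error(fit_lda(xtr[c(1, 41), ], ytr[c(1, 41)]), "at least 2")
})

test_that("regularised LDA agrees with MASS::lda when well-conditioned", {
  skip_if_not_installed("MASS")
  set.seed(14)
  x <- rbind(matrix(stats::rnorm(60 * 3), 60),
             matrix(stats::rnorm(60 * 3), 60) + 2)
  y <- rep(c("a", "b"), each = 60)
  ours <- predict(fit_lda(x, y, ridge = 1e-10), x)$class
  ref <- as.character(stats::predict(MASS::lda(x, grouping = y), x)$class)
  expect_gte(mean(ours == ref), 0.99)
})

test_that("KNN votes over the nine nearest neighbours deterministically", {
  x9 <- matrix(rep(c(1, 2), each = 9), 9)
  fit <- fit_knn(x9, rep("SSc", 9), k = 9)
  expect_equal(unname(predict(fit, matrix(c(50, -3), 1))), "SSc")

  set.seed(15)
  xtr <- matrix(stats::rnorm(40 * 4), 40)
  ytr <- rep(c("SSc", "Control"), 20)
  fit1 <- fit_knn(xtr, ytr, k = 1)
  expect_equal(unname(predict(fit1, xtr)), ytr)

  expect_error(fit_knn(xtr, ytr, k = 41), "larger than the training set")
})

test_that("KNN matches the standard reference implementation", {
  skip_if_not_installed("class")
  set.seed(16)
  xtr <- matrix(stats::rnorm(60 * 6), 60)
  ytr <- rep(c("SSc", "Control"), each = 30)
  xte <- matrix(stats::rnorm(25 * 6), 25)
  ours <- predict(fit_knn(xtr, ytr, k = 9), xte)
  z <- list(centre = colMeans(xtr), scale = apply(xtr, 2, sd))
  std <- function(m) sweep(sweep(m, 2, z$centre), 2, z$scale, "/")
  ref <- as.character(class::knn(std(xtr), std(xte), ytr, k = 9))
  expect_equal(unname(ours), ref)
})

test_that("permuted labels collapse cross-validated accuracy to chance", {
  set.seed(17)
  n <- 30
  x <- rbind(matrix(stats::rnorm(10 * 6), 10) + 4,
             matrix(stats::rnorm(20 * 6), 20))
  feats <- data.frame(participant_id = sprintf("P%02d", 1:n),
                      class_label = rep(c("SSc", "Control"), c(10, 20)))
  feats <- cbind(feats, as.data.frame(x))
  plan <- make_folds(feats, k = 5, seed = 1)

  real <- run_cv_features(feats, plan, "lda")
  expect_gte(mean(real$truth == real$predicted), 0.95)

  set.seed(18)
  feats_perm <- feats
  feats_perm$class_label <- sample(feats$class_label)
  plan_perm <- make_folds(feats_perm, k = 5, seed = 1)
  perm <- run_cv_features(feats_perm, plan_perm, "lda")
  expect_lte(mean(perm$truth == perm$predicted), 0.85)
})
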