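test_that("feature extraction is deterministic with a documented layout", {
  segs <- list(
    fixture_segment(list(temperature = rep(20, 60), pir = rep(1, 60)),
                    room = "kitchen", node_id = 1L),
    fixture_segment(list(temperature = rep(20, 60), pir = rep(1, 60)),
                    room = "kitchen", node_id = 1L)
  )
  ft <- extract_features(segment_summaries(segs))
  expect_equal(ft$temperature_sd, c(0, 0)) # constant channel
  expect_equal(as.list(ft[1, ]), as.list(ft[2, ])) # identical segments
  expect_equal(ft$room_kitchen, c(1, 1))
  expect_equal(ft$room_bedroom, c(0, 0))
  expect_false(anyNA(as.matrix(ft)))
})

test_that("synthetic cooking and sleeping segments separate linearly", {
  mk <- function(room, temp_slope, n = 120) {
    fixture_segment(list(
      temperature = 21 + seq(0, temp_slope, length.out = n),
      pir = rep(1, n)), room = room,
      node_id = if (room == "kitchen") 1L else 3L)
  }
  cook <- lapply(1:5, function(i) mk("kitchen", 3))
  sleep <- lapply(1:5, function(i) mk("bedroom", 0))
  ft <- extract_features(segment_summaries(c(cook, sleep)))
  # room indicator alone separates the classes
  expect_true(all(ft$room_kitchen[1:5] == 1) &&
                all(ft$room_kitchen[6:10] == 0))
  expect_true(min(ft$temperature_slope[1:5]) >
                max(ft$temperature_slope[6:10]))
})

test_that("Gaussian naive Bayes puts the boundary at the midpoint and
           normalizes posteriors", {
  set.seed(41)
  x <- matrix(c(rnorm(200, 0), rnorm(200, 4)), ncol = 1)
  y <- rep(c("a", "b"), each = 200)
  m <- nb_train(x, y)
  # equal variances, equal priors: boundary at the midpoint of the means
  mid <- mean(m$means[, 1])
  expect_equal(nb_predict(m, matrix(mid - 0.5)), "a")
  expect_equal(nb_predict(m, matrix(mid + 0.5)), "b")
  post <- nb_predict(m, matrix(seq(-2, 6, length.out = 30)),
                     type = "posterior")
  expect_equal(unname(rowSums(post)), rep(1, 30))
  expect_error(nb_train(x, rep("a", 400)), "classes")
})

test_that("naive Bayes agrees with an independent reference
           implementation", {
  set.seed(42)
  n <- 300
  x <- rbind(matrix(rnorm(2 * n, 0), ncol = 2),
             matrix(rnorm(2 * n, 1.5), ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- factor(rep(c("a", "b"), each = n))
  xt <- rbind(matrix(rnorm(2 * 200, 0), ncol = 2),
              matrix(rnorm(2 * 200, 1.5), ncol = 2))
  colnames(xt) <- c("f1", "f2")
  yt <- factor(rep(c("a", "b"), each = 200))

  ours <- nb_predict(nb_train(x, y), xt)
  ref <- as.character(predict(e1071::naiveBayes(as.data.frame(x), y),
                              as.data.frame(xt)))
  acc_ours <- mean(ours == yt)
  acc_ref <- mean(ref == yt)
  expect_lt(abs(acc_ours - acc_ref), 0.02)
  # and the two classifiers disagree on almost no instance
  expect_gt(mean(ours == ref), 0.98)
})

test_that("naive Bayes is invariant to consistent affine feature
           rescaling", {
  set.seed(43)
  x <- matrix(rnorm(200), ncol = 2)
  y <- rep(c("a", "b"), 50)
  xt <- matrix(rnorm(60), ncol = 2)
  a <- c(3, 0.2); b <- c(-5, 100)
  scale_m <- function(m) sweep(sweep(m, 2, a, `*`), 2, b, `+`)
  p1 <- nb_predict(nb_train(x, y), xt)
  p2 <- nb_predict(nb_train(scale_m(x), y), scale_m(xt))
  expect_identical(p1, p2)
})

test_that("random forest honours the contract: single tree, separable
           accuracy, tie break, determinism", {
  set.seed(44)
  x <- data.frame(f1 = c(rnorm(50, 0), rnorm(50, 5)),
                  f2 = c(rnorm(50, 0), rnorm(50, 5)))
  y <- rep(c("a", "b"), each = 50)

  # n_trees = 1 with all features: predictions are that single tree's votes
  m1 <- rf_train(x, y, n_trees = 1, seed = 3, mtry = 2)
  pred <- predict(m1$forest, newdata = x, predict.all = TRUE)
  expect_identical(rf_predict(m1, x),
                   as.character(pred$individual[, 1]))

  # perfectly separable data: 100% training accuracy
  m <- rf_train(x, y, n_trees = 25, seed = 3)
  expect_equal(mean(rf_predict(m, x) == y), 1)

  # 3 vs 3 vote: smallest class index wins
  votes <- matrix(c("b", "a", "b", "a", "b", "a"), nrow = 1)
  expect_identical(adlsense:::majority_vote(votes, c("a", "b")), "a")
  votes2 <- matrix(rep(c("c", "b"), 3), nrow = 1)
  expect_identical(adlsense:::majority_vote(votes2, c("a", "b", "c")), "b")

  # determinism under seed
  ma <- rf_train(x, y, n_trees = 10, seed = 7)
  mb <- rf_train(x, y, n_trees = 10, seed = 7)
  expect_identical(rf_predict(ma, x), rf_predict(mb, x))
})

test_that("out-of-bag error weakly improves with more trees", {
  set.seed(45)
  x <- data.frame(f1 = c(rnorm(60, 0), rnorm(60, 1.2)),
                  f2 = c(rnorm(60, 0), rnorm(60, 1.2)))
  y <- rep(c("a", "b"), each = 60)
  oob <- function(nt) {
    mean(vapply(1:10, function(s) {
      rf_oob_error(rf_train(x, y, n_trees = nt, seed = s))
    }, numeric(1)))
  }
  expect_lte(oob(60), oob(5) + 1e-9)
})
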