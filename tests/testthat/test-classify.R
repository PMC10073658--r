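test_that("a separable toy set is fit to training accuracy 1", {
  toy <- toy_features()
  m <- svm_train(toy$x, toy$y, C = 1)
  expect_equal(mean(predict_raw(m, toy$x) == toy$y), 1)
})

test_that("degenerate training input is rejected", {
  toy <- toy_features()
  expect_error(svm_train(toy$x, rep(1, nrow(toy$x))), "single-class")
  expect_error(svm_train(toy$x, toy$y[-1]), "aligned")
  expect_error(predict_raw(svm_train(toy$x, toy$y), toy$x[, -1]),
               "dimension")
})

test_that("duplicating every training point leaves predictions unchanged", {
  toy <- toy_features(seed = 9)
  m1 <- svm_train(toy$x, toy$y, C = 0.5, max_epochs = 5000, tol = 1e-8)
  m2 <- svm_train(rbind(toy$x, toy$x), c(toy$y, toy$y), C = 0.5,
                  max_epochs = 5000, tol = 1e-8)
  # probe on training-distribution-like points (off the decision boundary)
  probe <- toy_features(n_pos = 40, n_neg = 40, seed = 10)
  expect_equal(predict_raw(m1, probe$x), predict_raw(m2, probe$x))
  expect_equal(predict_raw(m1, probe$x), probe$y)
})

test_that("raw prediction is the sign of the linear decision function", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      d <- sample(3:12, 1)
      m <- structure(list(weights = rnorm(d), bias = rnorm(1),
                          C = 1, voting = voting_params()),
                     class = "climb_model")
      x <- matrix(rnorm(30 * d), 30)
      expect_equal(predict_raw(m, x),
                   as.integer(x %*% m$weights + m$bias > 0))
    }
  })
  # a frame exactly on the boundary is non-climbing
  m <- structure(list(weights = c(1, -1), bias = 0, C = 1,
                      voting = voting_params()), class = "climb_model")
  expect_equal(predict_raw(m, matrix(c(2, 2), 1)), 0L)
})

test_that("the decision function agrees with a reference SVM solver", {
  skip_if_not_installed("e1071")
  toy <- toy_features(n_pos = 30, n_neg = 30, dim = 8, seed = 5)
  probe <- matrix(abs(rnorm(200 * 8, 0, 0.5)), 200)
  for (C in c(0.1, 1, 10)) {
    ours <- svm_train(toy$x, toy$y, C = C, max_epochs = 2000, tol = 1e-8)
    ref <- e1071::svm(toy$x, factor(toy$y), kernel = "linear", cost = C,
                      scale = FALSE)
    ref_pred <- as.integer(as.character(predict(ref, probe)))
    agree <- mean(predict_raw(ours, probe) == ref_pred)
    expect_gte(agree, 0.97)
  }
})

test_that("temporal voting removes islands and heals gaps", {
  v <- voting_params(half_width = 1, vote_fraction = 0.5)
  expect_equal(temporal_vote(c(0, 0, 1, 0, 0), v), rep(0L, 5))
  expect_equal(temporal_vote(c(1, 1, 0, 1, 1), v), rep(1L, 5))
  expect_equal(temporal_vote(c(0, 1, 1, 0, 0, 1), voting_params(0)),
               c(0L, 1L, 1L, 0L, 0L, 1L))
  expect_error(temporal_vote(integer(0), v), "empty")
})

test_that("temporal voting equals a brute-force window scan", {
  withr::with_seed(31, {
    for (rep in 1:60) {
      n <- sample(1:60, 1)
      raw <- as.integer(runif(n) < runif(1))
      k <- sample(0:8, 1)
      theta <- sample(c(0.3, 0.5, 0.7), 1)
      expect_equal(temporal_vote(raw, voting_params(k, theta)),
                   oracle_vote(raw, k, theta))
    }
  })
})

test_that("voting is monotone in the raw labels", {
  withr::with_seed(32, {
    for (rep in 1:30) {
      raw <- as.integer(runif(40) < 0.4)
      v <- voting_params(sample(1:5, 1))
      base <- temporal_vote(raw, v)
      zero <- which(raw == 0)
      if (!length(zero)) next
      raw2 <- raw
      raw2[sample(zero, 1)] <- 1L
      expect_true(all(temporal_vote(raw2, v) >= base))
    }
  })
})

test_that("cross-validation selects by fold-mean score with simplicity ties", {
  segs <- toy_segments(n_seg = 4)
  single <- data.frame(C = 1, k = 3, theta = 0.5)
  cv1 <- leave_one_segment_out(segs, single)
  expect_equal(cv1$selected$C, 1)
  expect_equal(cv1$selected$k, 3)

  # separable segments: every candidate scores ~1, ties must resolve to the
  # smallest C then smallest k
  grid <- expand.grid(C = c(0.1, 1), k = c(0L, 2L), theta = 0.5)
  cv2 <- leave_one_segment_out(segs, grid)
  best <- max(aggregate(score ~ C + k, cv2$fold_table, mean)$score)
  agg <- aggregate(score ~ C + k, cv2$fold_table, mean)
  tied <- agg[agg$score == best, ]
  expect_equal(cv2$selected$C, min(tied$C))
})

test_that("the fold table records one fit per candidate per fold", {
  segs <- toy_segments(n_seg = 15, n_frames = 30)
  grid <- data.frame(C = c(0.1, 1, 10), k = 0L, theta = 0.5)
  cv <- leave_one_segment_out(segs, grid)
  expect_equal(nrow(cv$fold_table), 45)
  expect_equal(length(unique(cv$fold_table$fold)), 15)
})

test_that("cross-validation is deterministic", {
  segs <- toy_segments(n_seg = 3)
  cv1 <- leave_one_segment_out(segs)
  cv2 <- leave_one_segment_out(segs)
  expect_identical(cv1$selected, cv2$selected)
  expect_identical(cv1$model$weights, cv2$model$weights)
  expect_identical(cv1$fold_table, cv2$fold_table)
})

test_that("a dominating candidate is always selected", {
  # candidate with k=0 sees raw labels; a huge k washes predictions toward
  # the majority class, scoring strictly worse on every fold
  segs <- toy_segments(n_seg = 3, n_frames = 80, seed = 12)
  grid <- data.frame(C = 1, k = c(0L, 200L), theta = 0.5)
  cv <- leave_one_segment_out(segs, grid)
  s0 <- cv$fold_table$score[cv$fold_table$k == 0]
  s1 <- cv$fold_table$score[cv$fold_table$k == 200]
  expect_true(all(s0 > s1))
  expect_equal(cv$selected$k, 0L)
})
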