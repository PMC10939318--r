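test_that("identical stride lists match perfectly", {
  s <- stride_list(c(0, 100, 200), c(100, 200, 300))
  m <- match_stride_lists(s, s, 0.03, 100)
  expect_equal(nrow(m$pairs), 3)
  expect_length(m$false_positives, 0)
  expect_length(m$false_negatives, 0)
  sc <- precision_recall_f1(m)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  expect_equal(sc$f1, 1)
})

test_that("a stride shifted beyond the tolerance becomes one FP and one FN", {
  det <- stride_list(10, 110)
  ref <- stride_list(0, 100)
  m <- match_stride_lists(det, ref, 0.03, 100)  # tolerance 3 samples
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$false_positives, 0L)
  expect_equal(m$false_negatives, 0L)
  # within tolerance it matches
  m2 <- match_stride_lists(det, ref, 0.1, 100)
  expect_equal(nrow(m2$pairs), 1)
  expect_error(match_stride_lists(det, ref, -1, 100), "non-negative")
})

test_that("matching equals the exhaustive optimal assignment on jittered lists", {
  set.seed(111)
  for (rep in 1:20) {
    n_ref <- sample(3:8, 1)
    starts <- cumsum(sample(80:120, n_ref, replace = TRUE))
    ref <- stride_list(starts, starts + 70)
    # jittered copies with occasional drops/spurious extras
    keep <- runif(n_ref) > 0.2
    js <- starts[keep] + sample(-4:4, sum(keep), replace = TRUE)
    if (runif(1) > 0.5) js <- c(js, max(starts) + 500)
    js <- sort(js)
    det <- stride_list(js, js + 70 + sample(-3:3, length(js), replace = TRUE))
    tol <- 0.05; rate <- 100
    m <- match_stride_lists(det, ref, tol, rate)
    oracle <- oracle_match(det, ref, floor(tol * rate + 0.5))
    expect_equal(nrow(m$pairs), oracle$card)
    if (oracle$card > 0) {
      got <- m$pairs[order(m$pairs$detected_id), ]
      want <- oracle$pairs[order(oracle$pairs[, 1]), , drop = FALSE]
      expect_equal(got$detected_id, det$stride_id[want[, 1]])
      expect_equal(got$reference_id, ref$stride_id[want[, 2]])
    }
    # counting identities hold always
    expect_equal(nrow(m$pairs) + length(m$false_negatives), nrow(ref))
    expect_equal(nrow(m$pairs) + length(m$false_positives), nrow(det))
    # swapping the roles swaps FP and FN, TP unchanged
    ms <- match_stride_lists(ref, det, tol, rate)
    expect_equal(nrow(ms$pairs), nrow(m$pairs))
    expect_equal(length(ms$false_positives), length(m$false_negatives))
    expect_equal(length(ms$false_negatives), length(m$false_positives))
  }
})

test_that("precision/recall/F1 formulas and undefined flags", {
  sc <- precision_recall_f1(list(tp = 8, fp = 2, fn = 2))
  expect_equal(sc$precision, 0.8)
  expect_equal(sc$recall, 0.8)
  expect_equal(sc$f1, 0.8)
  perfect <- precision_recall_f1(list(tp = 5, fp = 0, fn = 0))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$f1, 1)
  # empty denominators are NA flags, not zeros
  edge <- precision_recall_f1(list(tp = 0, fp = 0, fn = 5))
  expect_true(is.na(edge$precision))
  expect_equal(edge$recall, 0)
  # harmonic-mean identity recomputed independently
  set.seed(17)
  for (i in 1:10) {
    tp <- sample(0:20, 1); fp <- sample(0:10, 1); fn <- sample(0:10, 1)
    sc <- precision_recall_f1(list(tp = tp, fp = fp, fn = fn))
    if (!is.na(sc$precision) && !is.na(sc$recall) &&
        (sc$precision + sc$recall) > 0) {
      expect_equal(sc$f1,
                   2 * sc$precision * sc$recall / (sc$precision + sc$recall),
                   tolerance = 1e-12)
    }
  }
})

test_that("parameter errors aggregate per test and per fold", {
  ref <- tidyr::expand_grid(fold = 1:2, test_id = 1:2, stride_id = 0:4)
  ref$value <- 1
  pred <- ref
  # pred = ref: all errors zero at every level
  pe0 <- parameter_errors(pred, ref, "value", test = "test_id",
                          fold = "fold")
  expect_true(all(pe0$per_stride$abs_error == 0))
  expect_true(all(pe0$per_test$mae == 0))
  expect_true(all(pe0$per_fold$mae == 0))

  # per-test values {0.1, 0.3} in one fold -> per-fold MAE 0.2
  pred2 <- ref
  pred2$value[pred2$fold == 1 & pred2$test_id == 1] <- 1.1
  pred2$value[pred2$fold == 1 & pred2$test_id == 2] <- 1.3
  pe <- parameter_errors(pred2, ref, "value", test = "test_id",
                         fold = "fold")
  f1 <- pe$per_fold[pe$per_fold$fold == 1, ]
  expect_equal(f1$mae, 0.2)
})

test_that("per-test and per-fold medians can legitimately differ", {
  # one fold, three tests of very different sizes: the stride-weighted
  # per-test median differs from the per-fold (test-weighted) summary
  ref <- dplyr::bind_rows(
    tidyr::expand_grid(fold = 1, test_id = 1, stride_id = 0:19),
    tidyr::expand_grid(fold = 1, test_id = 2, stride_id = 0:1),
    tidyr::expand_grid(fold = 1, test_id = 3, stride_id = 0:1)
  )
  ref$value <- 1
  pred <- ref
  pred$value[pred$test_id == 1] <- 1.05
  pred$value[pred$test_id == 2] <- 1.5
  pred$value[pred$test_id == 3] <- 1.6
  pe <- parameter_errors(pred, ref, "value", test = "test_id",
                         fold = "fold")
  median_per_test <- stats::median(pe$per_test$mae)       # 0.5
  median_per_stride <- stats::median(pe$per_stride$abs_error)  # 0.05
  expect_false(isTRUE(all.equal(median_per_test, median_per_stride)))
})

test_that("grouped cross-validation partitions groups and is reproducible", {
  data <- tidyr::expand_grid(participant = letters[1:10], item = 1:2)
  data$score_true <- seq_len(nrow(data))
  scorer <- function(item, params) list(s = item$score_true)
  cv1 <- grouped_cross_validation(data, "participant", k = 5, scorer,
                                  seed = 7)
  cv2 <- grouped_cross_validation(data, "participant", k = 5, scorer,
                                  seed = 7)
  expect_identical(cv1$folds, cv2$folds)
  # each group in exactly one fold
  expect_equal(sort(cv1$folds$group), letters[1:10])
  expect_equal(unname(table(cv1$folds$fold)), rep(2L, 5),
               ignore_attr = TRUE)
  # every item scored exactly once, untouched by training
  expect_equal(sort(cv1$results$s), sort(data$score_true))
  expect_error(grouped_cross_validation(data, "participant", 11, scorer),
               "exceeds")
})

test_that("a pipeline without tunable parameters scores as without CV", {
  data <- tibble::tibble(participant = letters[1:6], x = rnorm(6))
  scorer <- function(item, params) list(s = item$x * 2)
  cv <- grouped_cross_validation(data, "participant", k = 3, scorer,
                                 seed = 1)
  expect_equal(sort(cv$results$s), sort(data$x * 2))
  # fit() receives only training groups
  seen <- list()
  fit <- function(train) {
    seen[[length(seen) + 1]] <<- train$participant
    NULL
  }
  cv2 <- grouped_cross_validation(data, "participant", k = 3, scorer,
                                  fit = fit, seed = 1)
  test_groups <- split(cv2$folds$group, cv2$folds$fold)
  for (f in 1:3) {
    expect_length(intersect(seen[[f]], test_groups[[f]]), 0)
  }
})
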