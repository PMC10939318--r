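# a short asymmetric template used throughout; scaling 1 keeps hand
# arithmetic easy
toy_template <- function(rate = 100) {
  # leading nonzero sample so a following copy's onset terminates the
  # trailing cost plateau of the preceding match
  stride_template(c(1, 3, 5, 3, 1, 0, 0, 0), sampling_rate = rate,
                  scaling = 1)
}

test_that("an exact copy of the template matches with cost zero", {
  tpl <- toy_template()
  sig <- tpl$samples
  out <- subsequence_dtw(sig, tpl, max_cost = 1e-9,
                         min_match_duration = 0.01, max_match_duration = 1)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 0L)
  expect_equal(out$end, length(sig))
  expect_equal(out$cost, 0)
})

test_that("two separated template copies are both found at known offsets", {
  tpl <- toy_template()
  sig <- c(tpl$samples, rep(0, 50), tpl$samples)
  out <- subsequence_dtw(sig, tpl, max_cost = 0.5,
                         min_match_duration = 0.01, max_match_duration = 10)
  oracle <- oracle_subsequence_dtw(sig, tpl$samples, 0.5, 0.01, 10, 100)
  expect_equal(out$start, as.integer(oracle$start))
  expect_equal(out$end, as.integer(oracle$end))
  expect_equal(out$cost, oracle$cost)
  expect_equal(nrow(out), 2)
  # the first match starts at the true offset; its end extends across the
  # zero run up to the onset of the second copy (plateau right edge)
  expect_equal(out$start[1], 0L)
  expect_equal(out$end[1], length(tpl$samples) + 50L)
  expect_equal(out$start[2], length(tpl$samples) + 50L)
  expect_equal(out$end[2], length(sig))
})

test_that("max_cost zero yields no matches on a non-matching signal", {
  tpl <- toy_template()
  sig <- tpl$samples + 0.5
  out <- subsequence_dtw(sig, tpl, max_cost = 0,
                         min_match_duration = 0.01, max_match_duration = 1)
  expect_equal(nrow(out), 0)
})

test_that("plain DTW equals the brute-force DP oracle on seeded random signals", {
  set.seed(101)
  for (rep in 1:20) {
    M <- sample(5:50, 1)
    N <- sample(60:500, 1)
    tpl_s <- rnorm(M)
    sig <- rnorm(N)
    # embed one or two noisy template copies so real matches exist
    for (k in seq_len(sample(1:2, 1))) {
      at <- sample(1:(N - M), 1)
      sig[at:(at + M - 1)] <- tpl_s + rnorm(M, sd = 0.05)
    }
    tpl <- stride_template(tpl_s, 100, scaling = 1)
    max_cost <- runif(1, 0.5, 4)
    out <- subsequence_dtw(sig, tpl, max_cost = max_cost,
                           min_match_duration = 0.01,
                           max_match_duration = 10)
    oracle <- oracle_subsequence_dtw(sig, tpl_s, max_cost, 0.01, 10, 100)
    expect_identical(out$start, as.integer(oracle$start))
    expect_identical(out$end, as.integer(oracle$end))
    expect_equal(out$cost, oracle$cost, tolerance = 1e-12)
  }
})

test_that("constrained DTW equals its brute-force state-space oracle", {
  set.seed(202)
  for (rep in 1:8) {
    M <- sample(5:15, 1)
    N <- sample(40:150, 1)
    tpl_s <- rnorm(M)
    sig <- rnorm(N)
    at <- sample(1:(N - M), 1)
    sig[at:(at + M - 1)] <- tpl_s + rnorm(M, sd = 0.05)
    tpl <- stride_template(tpl_s, 100, scaling = 1)
    R <- sample(2:4, 1)
    max_cost <- runif(1, 0.5, 3)
    out <- subsequence_dtw(sig, tpl, max_cost = max_cost,
                           min_match_duration = 0.01,
                           max_match_duration = 10, max_local_run = R)
    oracle <- oracle_subsequence_dtw_constrained(
      sig, tpl_s, R, max_cost, 0.01, 10, 100)
    expect_identical(out$start, as.integer(oracle$start))
    expect_identical(out$end, as.integer(oracle$end))
    expect_equal(out$cost, oracle$cost, tolerance = 1e-12)
  }
})

test_that("the local warping constraint only removes over-warped paths", {
  # a run of > R identical samples in the signal must be absorbed by
  # horizontal steps; with a tight constraint the cost rises
  tpl <- stride_template(c(0, 5, 0), 100, scaling = 1)
  sig <- c(0, 5, 5, 5, 5, 5, 0)
  free <- subsequence_dtw(sig, tpl, max_cost = 100,
                          min_match_duration = 0.01, max_match_duration = 1)
  tight <- subsequence_dtw(sig, tpl, max_cost = 100,
                           min_match_duration = 0.01,
                           max_match_duration = 1, max_local_run = 1)
  expect_true(min(tight$cost) >= min(free$cost))
})

test_that("infinite max_local_run reproduces the plain algorithm bitwise", {
  set.seed(303)
  tpl <- stride_template(rnorm(12), 100, scaling = 1)
  sig <- rnorm(200)
  a <- subsequence_dtw(sig, tpl, max_cost = 5, min_match_duration = 0.01,
                       max_match_duration = 10, max_local_run = Inf)
  b <- subsequence_dtw(sig, tpl, max_cost = 5, min_match_duration = 0.01,
                       max_match_duration = 10)
  expect_identical(a, b)
})

test_that("raising max_cost never removes matches (overlap resolution off)", {
  set.seed(404)
  tpl <- stride_template(rnorm(10), 100, scaling = 1)
  sig <- rnorm(300)
  lo <- subsequence_dtw(sig, tpl, max_cost = 1, min_match_duration = 0.01,
                        max_match_duration = 10, resolve_overlaps = FALSE)
  hi <- subsequence_dtw(sig, tpl, max_cost = 3, min_match_duration = 0.01,
                        max_match_duration = 10, resolve_overlaps = FALSE)
  lo_keys <- paste(lo$start, lo$end)
  hi_keys <- paste(hi$start, hi$end)
  expect_true(all(lo_keys %in% hi_keys))
})

test_that("segmentation output always satisfies interval-list invariants", {
  set.seed(55)
  tpl <- stride_template(rnorm(10), 100, scaling = 1)
  for (rep in 1:5) {
    sig <- rnorm(250)
    out <- subsequence_dtw(sig, tpl, max_cost = 5,
                           min_match_duration = 0.01,
                           max_match_duration = 10)
    expect_silent(validate_interval_list(out))
  }
  expect_error(subsequence_dtw(numeric(), tpl), "empty")
})

test_that("snap_to_min moves borders to window minima and reverts crossings", {
  sig <- rep(1, 100)
  sig[13] <- -5          # minimum near border 10 (0-based index 12)
  strides <- stride_list(c(10, 40), c(40, 80))
  # zero window: unchanged
  expect_identical(snap_to_min(strides, sig, 0, 100), strides)
  out <- snap_to_min(strides, sig, snap_window = 0.1, rate = 100)
  expect_equal(out$start[1], 12L)
  # violating moves revert: on a short stride both borders would snap to
  # the same shared minimum, collapsing the stride to zero length
  sig2 <- rep(1, 100)
  sig2[44] <- -9         # 0-based sample 43, within both border windows
  out2 <- snap_to_min(stride_list(40, 44), sig2,
                      snap_window = 0.1, rate = 100)
  expect_equal(out2$start, 40L)
  expect_equal(out2$end, 44L)
})

test_that("the packaged template regenerates from the simulator", {
  tpl <- default_stride_template()
  regen <- synthetic_stride_template()
  expect_equal(tpl$samples, regen$samples, tolerance = 1e-12)
  expect_equal(tpl$sampling_rate, regen$sampling_rate)
  expect_equal(tpl$scaling, regen$scaling)
})
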