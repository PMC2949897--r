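test_that("scale_to_height maps each value kind onto the 0-100 display scale", {
  sc <- assoc_table("1", c(10, 20, 30), c("a", "b", "c"),
                    c(50, 150, 0), "score")
  expect_equal(scale_to_height(sc, 100)$height, c(50, 100, 0))
  pv <- assoc_table("1", c(10, 20, 30), c("a", "b", "c"),
                    c(1e-8, 1e-4, 1), "pvalue")
  expect_equal(scale_to_height(pv, 8)$height, c(100, 50, 0))
  rk <- assoc_table("1", 10 * (1:200), sprintf("r%03d", 1:200),
                    1:200, "rank")
  h <- scale_to_height(rk)$height
  expect_equal(h[1], 100)            # rank 1 saturates
  expect_equal(h[200], 100 / 200)    # worst rank near zero
  expect_error(scale_to_height(sc, 0), "max_expected")
})

test_that("log filter matches its closed form and fixes the saturated value", {
  expect_equal(log_filter(score_track(100), 37)$height, 100)
  expect_equal(log_filter(score_track(0), 1)$height, 50)     # 100 * 2^-1
  expect_equal(log_filter(score_track(50), 2)$height, 50)    # 100 * 2^-1
  expect_error(log_filter(score_track(10), 0), "positive")
  expect_error(log_filter(score_track(10), -3), "positive")
})

test_that("log filter is strictly increasing and never reaches zero", {
  set.seed(21)
  for (rep in 1:20) {
    f <- runif(1, 0.1, 60)
    r <- sort(runif(100, 0, 100))
    out <- log_filter(score_track(r), f)$height
    expect_true(all(diff(out) > 0))
    expect_true(all(out > 0 & out <= 100))
    expect_equal(out, 100 * 2^(f * (r / 100 - 1)))
  }
})

test_that("best-of-window smoothing reproduces the hand-computed examples", {
  expect_equal(sliding_window_best(score_track(c(3, 1, 4, 1, 5)), 1, 0)$height,
               c(3, 1, 4, 1, 5))  # m = 1 is the identity
  expect_equal(sliding_window_best(score_track(c(0, 0, 90, 0, 0)), 3, 0)$height,
               c(30, 30, 30, 0, 0))
  expect_equal(sliding_window_best(score_track(c(10, 50, 20, 5)), 3, 1)$height,
               c(35, 35, 12.5, 5))
  expect_error(sliding_window_best(score_track(1:3), 3, 3), "d must")
  expect_error(sliding_window_best(score_track(1:3), 0, 0), "m must")
})

test_that("windows never cross chromosome boundaries", {
  heights <- c(80, 0, 0, 60, 0, 0)
  tab <- assoc_table(rep(c("1", "2"), each = 3), rep(c(10, 20, 30), 2),
                     sprintf("s%d", 1:6), heights, "score")
  trk <- scale_to_height(tab, 100)
  out <- sliding_window_best(trk, 3, 0)$height
  # chromosome 2's peak must not bleed into chromosome 1's last windows
  expect_equal(out, c(80 / 3, 0, 0, 20, 0, 0))
})

test_that("best-of-window smoothing matches the brute-force oracle", {
  set.seed(33)
  for (rep in 1:60) {
    n <- sample(1:80, 1)
    m <- sample(1:10, 1)
    d <- sample(0:(m - 1), 1)
    h <- runif(n, 0, 100)
    out <- sliding_window_best(score_track(h), m, d)$height
    expect_equal(out, window_oracle(h, m, d))
    expect_true(all(out <= max(h) + 1e-12))
  }
})

test_that("cutoff crops relative to the maximum and restretches to 100", {
  expect_equal(cutoff_stretch(score_track(c(40, 80)), 0)$height, c(50, 100))
  expect_equal(cutoff_stretch(score_track(c(100, 50, 20, 10)), 20)$height,
               c(100, 37.5, 0, 0))
  zeros <- score_track(c(0, 0, 0))
  expect_equal(cutoff_stretch(zeros, 30)$height, c(0, 0, 0))
  expect_error(cutoff_stretch(zeros, 100), "p_cut")
  expect_error(cutoff_stretch(zeros, -1), "p_cut")
})

test_that("cutoff is order-preserving and can work per chromosome", {
  set.seed(5)
  h <- runif(50, 0, 90)
  out <- cutoff_stretch(score_track(h), 35)$height
  expect_true(all(diff(out[order(h)]) >= 0))  # order-preserving
  expect_true(all(out >= 0 & out <= 100))
  expect_equal(max(out), 100)
  tab <- assoc_table(rep(c("1", "2"), each = 2), rep(c(10, 20), 2),
                     sprintf("s%d", 1:4), c(80, 40, 40, 20), "score")
  trk <- scale_to_height(tab, 100)
  per <- cutoff_stretch(trk, 0, per_chromosome = TRUE)$height
  expect_equal(per, c(100, 50, 100, 50))
  whole <- cutoff_stretch(trk, 0)$height
  expect_equal(whole, c(100, 50, 50, 25))
})

test_that("filter chains compose left to right and preserve identity columns", {
  trk <- score_track(c(10, 80, 30, 0, 55))
  expect_equal(apply_filter_chain(trk, list()), trk)
  expect_equal(apply_filter_chain(trk, list(step_log(7))), log_filter(trk, 7))
  chained <- apply_filter_chain(trk, list(step_log(50), step_window(3, 1),
                                          step_cutoff(20)))
  manual <- cutoff_stretch(sliding_window_best(log_filter(trk, 50), 3, 1), 20)
  expect_equal(chained, manual)
  expect_equal(chained[c("chrom", "pos", "snp_id")],
               trk[c("chrom", "pos", "snp_id")])
  expect_true(all(chained$height >= 0 & chained$height <= 100))
  expect_error(apply_filter_chain(trk, list(list(filter = "median"))),
               "unknown filter")
})
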