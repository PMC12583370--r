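test_that("background estimation follows the control median / percentile rule", {
  expect_equal(estimate_background(matrix(7, 10, 10)), 7)
  expect_equal(estimate_background(matrix(50, 5, 5),
                                   negative_control = matrix(0, 5, 5)), 0)
  # 10% of pixels at 100, the rest at 10: 5th percentile is the background
  ch <- matrix(10, 20, 50)
  ch[1:2, ] <- 100
  expect_equal(estimate_background(ch), 10)
  # control median beats the channel percentile when supplied
  expect_equal(estimate_background(ch, negative_control = matrix(3, 4, 4)), 3)
})

test_that("threshold_mask separates signal from control-bounded background", {
  set.seed(1)
  ctrl <- matrix(runif(64 * 64, 0, 10), 64)
  ch <- matrix(runif(64 * 64, 0, 9), 64)   # stays below the control threshold
  ch[20:30, 20:30] <- 100
  mk <- threshold_mask(ch, negative_control = ctrl)
  truth <- matrix(FALSE, 64, 64); truth[20:30, 20:30] <- TRUE
  expect_equal(unname(mk == truth), matrix(TRUE, 64, 64))
  expect_identical(attr(mk, "method"), "negative_control")

  expect_false(any(threshold_mask(matrix(0, 8, 8), method = "otsu")))
  expect_error(threshold_mask(ch, method = "negative_control"),
               "negative-control")
})

test_that("otsu threshold agrees with an exhaustive between-class sweep", {
  set.seed(7)
  x <- matrix(c(rnorm(3000, 10, 2), rnorm(1000, 100, 2)), 40)
  mk <- threshold_mask(x, method = "otsu")
  thr <- attr(mk, "threshold")
  expect_gt(thr, 20); expect_lt(thr, 95)
  # oracle: maximize between-class variance over candidate thresholds
  cand <- seq(min(x), max(x), length.out = 512)
  bcv <- vapply(cand, function(t) {
    w1 <- mean(x <= t); w2 <- 1 - w1
    if (w1 == 0 || w2 == 0) return(0)
    w1 * w2 * (mean(x[x > t]) - mean(x[x <= t]))^2
  }, 0)
  thr_oracle <- cand[which.max(bcv)]
  # both must split between the modes; mask area within 1% of truth
  expect_lt(abs(mean(x > thr) - mean(x > thr_oracle)), 0.001)
  expect_lt(abs(sum(mk) - 1000) / 1000, 0.01)
})

test_that("threshold monotonicity: higher thresholds never grow the mask", {
  set.seed(3)
  ch <- matrix(runif(400, 0, 100), 20)
  for (t in c(10, 30, 60)) {
    m_lo <- ch > t
    m_hi <- ch > (t + 15)
    expect_true(all(m_lo | !m_hi))
  }
})

test_that("clean_mask removes exactly the sub-threshold components", {
  m <- matrix(FALSE, 30, 30)
  m[2:4, 2] <- TRUE                 # 3 px
  m[10:19, 10:14] <- TRUE           # 50 px
  expect_identical(unname(clean_mask(m, 1)), m)
  cl <- clean_mask(m, 5)
  expect_equal(sum(cl), 50)
  # oracle comparison on random speckle
  set.seed(11)
  sp <- matrix(runif(40 * 40) < 0.2, 40)
  cl5 <- clean_mask(sp, 5)
  lab <- label8_bruteforce(sp)
  keep <- which(tabulate(lab[lab > 0]) >= 5)
  expect_identical(unname(cl5), matrix(lab %in% keep, 40))
  # idempotence
  expect_identical(clean_mask(cl5, 5), cl5)
})

test_that("skeletonize thins to 1 px, preserves components, is idempotent", {
  expect_false(any(skeletonize(matrix(FALSE, 10, 10))))
  # 3 x 20 bar: single-pixel path of about 20 px
  bar <- matrix(FALSE, 20, 40)
  bar[9:11, 10:29] <- TRUE
  sk <- skeletonize(bar)
  expect_equal(max(label8_bruteforce(sk)), 1)
  expect_gte(sum(sk), 16); expect_lte(sum(sk), 21)
  deg <- table(mitonet:::nbr_count8(mitonet:::as_binary_int(sk))[sk])
  expect_true(all(names(deg) %in% c("1", "2")))
  # idempotence + component preservation on random blobs
  set.seed(5)
  for (i in 1:5) {
    blob <- matrix(runif(60 * 60) < 0.35, 60)
    blob <- clean_mask(blob, 4)
    sk <- skeletonize(blob)
    expect_identical(skeletonize(sk), sk)
    expect_equal(max(label8_bruteforce(sk)), max(label8_bruteforce(blob)))
  }
})
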