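test_that("partial gradients follow the border convention", {
  # hand-enumerated 2x2 example: rows (0,1) / (0,1)
  f <- matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE)
  g <- partial_gradients(f)
  expect_equal(g$d1, matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE))
  expect_equal(g$d2, matrix(0, 2, 2))
  expect_equal(g$d3, matrix(c(0, 0, 0, 1), 2, 2, byrow = TRUE))
  expect_equal(g$d4, matrix(c(0, 0, -1, 0), 2, 2, byrow = TRUE))
  # constant image: all four fields vanish
  gc <- partial_gradients(matrix(3.7, 5, 5))
  for (d in gc) expect_equal(d, matrix(0, 5, 5))
  # vertical step: d2 nonzero only on the step row
  step <- rbind(matrix(0, 3, 6), matrix(1, 3, 6))
  gs <- partial_gradients(step)
  expect_true(all(gs$d2[4, ] == 1))
  expect_true(all(gs$d2[-4, ] == 0))
  expect_error(partial_gradients(matrix(1, 1, 1)), ">= 2")
  # shift invariance
  set.seed(2)
  r <- matrix(rnorm(36), 6, 6)
  expect_equal(partial_gradients(r), partial_gradients(r + 11.3))
})

test_that("TD and WTD measures match direct summation", {
  expect_equal(td_measure(matrix(5, 4, 4)), 0)
  chk <- make_test_phantom("checker", 8)
  expect_equal(td_measure(chk), 2 * 8 * 7)
  set.seed(4)
  r <- matrix(rnorm(49), 7, 7)
  expect_equal(td_measure(r), wtd_measure(r, alpha = 0))
  f <- matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(wtd_measure(f, alpha = 1), 4)
  expect_equal(wtd_measure(matrix(2, 3, 3), alpha = 5), 0)
  expect_error(wtd_measure(r, alpha = -1), ">= 0")
})

test_that("soft threshold has its closed form", {
  expect_equal(soft_threshold(5, 2), 3)
  expect_equal(soft_threshold(-5, 2), -3)
  expect_equal(soft_threshold(1, 2), 0)
  expect_equal(soft_threshold(c(-5, 1, 5), 2), c(-3, 0, 3))
  expect_error(soft_threshold(1, -1), ">= 0")
})

test_that("the filtering step has its algebraic special cases", {
  set.seed(6)
  f <- matrix(rnorm(64, sd = 0.3), 8, 8)
  # constant image unchanged for any w, alpha
  cst <- matrix(1.05, 6, 6)
  expect_equal(stf_filter_step(cst, w = 0.5, alpha = 1), cst)
  # w = 0 is the identity
  expect_equal(stf_filter_step(f, w = 0, alpha = 1), f, tolerance = 1e-14)
  # w -> Inf tends to the alpha-weighted 8-neighborhood mean
  alpha <- 0.7
  big <- stf_filter_step(f, w = 1e9, alpha = alpha)
  expect_equal(big, naive_stf_filter(f, w = 1e9, alpha = alpha),
               tolerance = 1e-12)
  # independent loop oracle at generic w, for alpha = 0 (TD 4-neighbor
  # filtering) and alpha = 1
  for (a in c(0, 1))
    expect_equal(stf_filter_step(f, w = 0.1, alpha = a),
                 naive_stf_filter(f, 0.1, a), tolerance = 1e-12)
  expect_error(stf_filter_step(f, w = -1), ">= 0")
  expect_error(stf_filter_step(matrix(1, 2, 2), w = 0.1), ">= 3")
})

test_that("filtering preserves constants, bounds the range, lowers the WTD", {
  set.seed(9)
  # noisy piecewise-constant image
  base <- rbind(cbind(matrix(0, 8, 8), matrix(1, 8, 8)),
                cbind(matrix(1, 8, 8), matrix(0.5, 8, 8)))
  noisy <- base + matrix(rnorm(256, sd = 0.05), 16, 16)
  w <- 0.03
  cur <- noisy
  wtds <- wtd_measure(cur, 1)
  for (k in 1:10) {
    cur <- stf_filter_step(cur, w, alpha = 1)
    wtds <- c(wtds, wtd_measure(cur, 1))
    expect_true(all(cur >= min(noisy) - w & cur <= max(noisy) + w))
  }
  expect_true(all(diff(wtds) < 0))
  # image_grid in, image_grid out
  img <- image_grid(noisy, 0.1)
  out <- stf_filter_step(img, w)
  expect_s3_class(out, "image_grid")
  expect_equal(out$values, stf_filter_step(noisy, w))
})

test_that("the threshold schedule decays geometrically", {
  expect_equal(threshold_schedule(0.02, 0.995, 0:2),
               0.02 * 0.995^(0:2))
  expect_error(threshold_schedule(0.02, 1.5), "decay")
})
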