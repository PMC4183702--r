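# minimal hand-built system "matrix" exercising the SART formula directly
fake_system <- function(row_ptr, col_ind, val, N, views, bins) {
  M <- views * bins
  vcs <- matrix(0, N, views)
  rs <- numeric(M)
  for (i in seq_len(M)) {
    k <- row_ptr[i] + seq_len(row_ptr[i + 1] - row_ptr[i])
    rs[i] <- sum(val[k])
    v <- (i - 1) %/% bins + 1
    for (kk in k) vcs[col_ind[kk] + 1, v] <- vcs[col_ind[kk] + 1, v] + val[kk]
  }
  structure(list(row_ptr = as.integer(row_ptr), col_ind = as.integer(col_ind),
                 val = val, row_sums = rs, col_sums = rowSums(vcs),
                 view_col_sums = vcs, M = M, N = N,
                 geom = list(views = views, bins = bins), n = sqrt(N),
                 pixel_size = 1),
            class = "system_matrix")
}

test_that("one SART sweep solves the single-ray closed form", {
  # 1 ray, weight 1 on pixel 1, lambda = 1, f0 = 0 -> f = p
  A <- fake_system(c(0, 1), 0, 1.0, N = 4, views = 1, bins = 1)
  out <- sart_sweep(A, p = 3.5, f = rep(0, 4), lambda = 1)
  expect_equal(out$image, c(3.5, 0, 0, 0))
  expect_equal(out$residual, 3.5)
})

test_that("a sweep matches the loop-based naive oracle on a tiny system", {
  st <- tiny_setup(n = 4, views = 2, bins = 4, pixel_size = 0.5,
                   aperture = 0.6, sad = 15)
  D <- as_dense_matrix(st$A)
  set.seed(8)
  p <- runif(st$A$M)
  f0 <- runif(st$A$N)
  mine <- sart_sweep(st$A, p, f0, lambda = 0.9)$image
  ref <- naive_sart_sweep(D, p, f0, 0.9, views = 2, bins = 4)
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("SART decreases the residual on consistent data", {
  disc <- make_test_phantom("uniform-disc", 16, 0.5)
  geom <- fan_beam_geometry(views = 6, bins = 17, bin_aperture = 0.55,
                            source_to_axis = 25)
  A <- system_matrix(geom, disc)
  p <- forward_project(A, disc)
  f <- image_grid(matrix(0, 16, 16), 0.5)
  res <- numeric(50)
  for (k in 1:50) {
    f <- sart_sweep(A, p, f, lambda = 1)$image
    res[k] <- sqrt(sum((forward_project(A, f)$values - p$values)^2))
  }
  expect_true(all(diff(res) <= 1e-12))
  expect_lt(res[50], res[1] / 10)
})

test_that("SART input validation works", {
  A <- fake_system(c(0, 1), 0, 1.0, N = 4, views = 1, bins = 1)
  expect_warning(sart_sweep(A, 1, rep(0, 4), lambda = 2.5), "relax")
  expect_error(sart_sweep(A, NaN, rep(0, 4)), "NA/NaN")
  expect_error(sart_sweep(A, c(1, 2), rep(0, 4)), "!= M")
  expect_error(sart_sweep(A, 1, rep(0, 3)), "!= N")
})

test_that("the momentum recurrence matches its closed form and growth", {
  fs <- fista_step(1, 1, 1)
  expect_equal(fs$t_next, (1 + sqrt(5)) / 2)
  # equal iterates: extrapolation is a no-op
  x <- matrix(rnorm(9), 3, 3)
  expect_equal(fista_step(2.3, x, x)$image, x)
  # t_k grows like (k+1)/2
  t <- 1
  for (k in 1:1000) t <- (1 + sqrt(1 + 4 * t^2)) / 2
  expect_lt(abs(t / (1001 / 2) - 1), 0.01)
  expect_error(fista_step(0.5, x, x), ">= 1")
})

test_that("reconstruct respects the iteration budget and zero start", {
  st <- tiny_setup(n = 8, views = 4, bins = 9, pixel_size = 0.5,
                   aperture = 0.5, sad = 20)
  disc <- make_test_phantom("uniform-disc", 8, 0.5)
  p <- forward_project(st$A, disc)
  r0 <- reconstruct(st$A, p, recon_config("sart", max_iterations = 0))
  expect_equal(r0$image$values, matrix(0, 8, 8))
  expect_equal(nrow(r0$trace), 0)
  r5 <- reconstruct(st$A, p, recon_config("sart", max_iterations = 5),
                    truth = disc)
  expect_equal(nrow(r5$trace), 5)
  expect_true(all(is.finite(r5$image$values)))
  expect_error(reconstruct(st$A, p, recon_config(max_iterations = 5),
                           checkpoints = c(9)), "checkpoints")
})

test_that("the TD algorithm is exactly the WTD algorithm at alpha zero", {
  st <- tiny_setup(n = 16, views = 8, bins = 17, pixel_size = 0.5,
                   aperture = 0.55, sad = 25)
  disc <- make_test_phantom("uniform-disc", 16, 0.5)
  p <- forward_project(st$A, disc)
  rtd <- reconstruct(st$A, p, recon_config("tdm-stf", max_iterations = 40))
  rwtd0 <- reconstruct(st$A, p, recon_config("wtdm-stf", alpha = 0,
                                             max_iterations = 40))
  expect_identical(rtd$image$values, rwtd0$image$values)
  # noise-free reconstruction is bit-reproducible
  again <- reconstruct(st$A, p, recon_config("tdm-stf", max_iterations = 40))
  expect_identical(rtd$image$values, again$image$values)
})

test_that("checkpoints snapshot the filtered iterate at the right times", {
  st <- tiny_setup(n = 8, views = 4, bins = 9, pixel_size = 0.5,
                   aperture = 0.5, sad = 20)
  disc <- make_test_phantom("uniform-disc", 8, 0.5)
  p <- forward_project(st$A, disc)
  cfg <- recon_config("wtdm-stf", max_iterations = 12)
  r <- reconstruct(st$A, p, cfg, checkpoints = c(6, 12))
  expect_named(r$checkpoints, c("6", "12"))
  expect_identical(r$checkpoints[["12"]]$values, r$image$values)
  r6 <- reconstruct(st$A, p, recon_config("wtdm-stf", max_iterations = 6))
  expect_identical(r$checkpoints[["6"]]$values, r6$image$values)
})

test_that("config validation enforces the documented bounds", {
  expect_error(recon_config(lambda = 2.5), "\\(0, 2\\)")
  expect_error(recon_config(lambda = 0), "\\(0, 2\\)")
  expect_error(recon_config(max_iterations = -1), ">= 0")
  expect_error(recon_config(alpha = -0.5), ">= 0")
  cfg <- recon_config("tdm-stf", alpha = 5)
  expect_equal(cfg$alpha, 0)  # TD algorithm forces alpha = 0
})
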