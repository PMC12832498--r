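# Forward degradation models: blur paths, noise sampling, priors, outliers.

test_that("degrade preserves constants and identities", {
  x <- matrix(0.5, 16, 16)
  spec <- degradation_spec(box_kernel(1), noise_spec())
  expect_equal(degrade(x, spec), x)

  set.seed(42)
  x2 <- matrix(runif(256), 16, 16)
  spec_id <- degradation_spec(delta_kernel(1), noise_spec())
  expect_identical(degrade(x2, spec_id), x2)
})

test_that("blur path equals explicit dense-matrix multiply", {
  ramp <- matrix(rep(seq(0, 1, length.out = 16), each = 16), 16, 16)
  k <- box_kernel(1)
  H <- oracle_blur_matrix(16, 16, k, "reflect")
  expect_lt(max(abs(as.vector(convolve_image(ramp, k, "reflect")) -
                    H %*% as.vector(ramp))), 1e-12)

  # all boundary rules, asymmetric kernel, random image
  set.seed(7)
  kw <- matrix(runif(9), 3, 3); kw <- kw / sum(kw)
  x <- rand_image(12, 10, 3)
  for (b in c("reflect", "wrap", "constant")) {
    Hb <- oracle_blur_matrix(12, 10, kw, b)
    expect_lt(max(abs(as.vector(convolve_image(x, kw, b)) -
                      Hb %*% as.vector(x))), 1e-12)
  }
})

test_that("degrade is linear in x without noise or nonlinearity", {
  spec <- degradation_spec(gaussian_kernel(1), noise_spec())
  x1 <- rand_image(16, 16, 1) / 2
  x2 <- rand_image(16, 16, 2) / 2
  a <- 0.3; b <- 0.6
  lhs <- spec_fwd <- convolve_image(a * x1 + b * x2, spec$blur, spec$boundary)
  rhs <- a * convolve_image(x1, spec$blur, spec$boundary) +
    b * convolve_image(x2, spec$blur, spec$boundary)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("degrade rejects oversized kernels and non-finite input", {
  x <- matrix(0.5, 8, 8)
  spec <- degradation_spec(box_kernel(4), noise_spec())
  expect_error(degrade(x, spec), "radius")
  xbad <- x; xbad[1] <- NA
  expect_error(degrade(xbad, degradation_spec(box_kernel(1), noise_spec())),
               "non-finite")
})

test_that("kernel fields reduce to uniform blur and preserve constants", {
  set.seed(11)
  g <- gaussian_kernel(0.8, radius = 1L)
  fld <- kernel_field_uniform(12, 12, g)
  x <- rand_image(12, 12, 5)
  expect_lt(max(abs(apply_kernel_field(x, fld, "reflect") -
                    convolve_image(x, g, "reflect"))), 1e-12)

  expect_equal(apply_kernel_field(matrix(0.25, 12, 12), fld, "reflect"),
               matrix(0.25, 12, 12))

  dfld <- kernel_field_uniform(12, 12, delta_kernel(1))
  expect_equal(apply_kernel_field(x, dfld, "reflect"), x)
})

test_that("spatially varying kernel field matches its dense matrix", {
  sig <- matrix(seq(0.3, 1.5, length.out = 10), 10, 10, byrow = TRUE)
  fld <- kernel_field_gaussian(sig, radius = 1L)
  x <- rand_image(10, 10, 9)
  H <- oracle_field_matrix(fld, "reflect")
  expect_lt(max(abs(as.vector(apply_kernel_field(x, fld, "reflect")) -
                    H %*% as.vector(x))), 1e-12)
  expect_error(apply_kernel_field(rand_image(8, 8, 1), fld), "8x8")
})

test_that("flux is conserved by normalized kernels under reflect boundary", {
  x <- rand_image(32, 32, 4)
  for (k in list(box_kernel(2), gaussian_kernel(1.5))) {
    y <- convolve_image(x, k, "reflect")
    expect_lt(abs(mean(y) - mean(x)), 1e-6)
  }
})

test_that("sample_noise matches its calibration bounds and is seed-stable", {
  expect_identical(sample_noise(c(16, 16), noise_spec(), 1), matrix(0, 16, 16))

  # Gaussian component: chi-square 99.9% interval for the sample sd at n = 65536
  eps <- sample_noise(c(256, 256), noise_spec(gaussian_sigma = 0.1), 7)
  expect_gt(sd(eps), 0.09); expect_lt(sd(eps), 0.11)

  # impulse component: binomial 99.9% interval for the hit count
  eps2 <- sample_noise(c(128, 128), noise_spec(outlier_rate = 0.01), 3)
  cnt <- sum(eps2 != 0)
  bounds <- qbinom(c(0.0005, 0.9995), 16384, 0.01)
  expect_gte(cnt, bounds[1]); expect_lte(cnt, bounds[2])
  expect_true(all(abs(eps2[eps2 != 0]) == 0.5))

  expect_identical(sample_noise(c(64, 64), noise_spec(0.05, 0.01), 11),
                   sample_noise(c(64, 64), noise_spec(0.05, 0.01), 11))
  expect_error(noise_spec(gaussian_sigma = -1), "sigma")
})

test_that("mixed observation blends blur output with the noise image", {
  x <- rand_image(16, 16, 8)
  eta <- matrix(0.25, 16, 16)
  mk <- function(alpha) {
    degradation_spec(delta_kernel(1), noise_spec(),
                     mix_attention = list(alpha = alpha, eta = eta))
  }
  expect_equal(mixed_observation(x, mk(matrix(1, 16, 16))), x)
  expect_equal(mixed_observation(x, mk(matrix(0, 16, 16))), matrix(0.25, 16, 16))
  half <- mixed_observation(x, mk(matrix(0.5, 16, 16)))
  expect_equal(half, x / 2 + 0.125)
  spec_nomix <- degradation_spec(delta_kernel(1), noise_spec())
  expect_error(mixed_observation(x, spec_nomix), "mix_attention")
})

test_that("sensor transform is monotone and applied after blur", {
  x <- rand_image(16, 16, 12)
  spec <- degradation_spec(delta_kernel(1), noise_spec(),
                           sensor = sensor_transform(0.7, 0.02, 0.98))
  y <- degrade(x, spec)
  expect_equal(y, pmin(pmax(x^0.7, 0.02), 0.98))
  v <- seq(0, 1, length.out = 101)
  tv <- pmin(pmax(v^0.7, 0.02), 0.98)
  expect_true(all(diff(tv) >= 0))
})

test_that("prior penalties match hand counts and the dense Laplacian oracle", {
  expect_equal(prior_penalties(matrix(0.4, 8, 8)),
               list(grad_l1 = 0, tikhonov = 0))

  x22 <- matrix(c(0, 0, 1, 1), 2, 2)   # [[0,1],[0,1]] row-wise
  expect_equal(prior_penalties(x22)$grad_l1, 2)

  x <- rand_image(8, 8, 21)
  L <- oracle_laplacian_matrix(8, 8)
  expect_lt(abs(prior_penalties(x)$tikhonov -
                sum((L %*% as.vector(x))^2)), 1e-10)
})

test_that("outlier estimation is the soft threshold with exact zeroing", {
  y <- matrix(0, 8, 8); hx <- matrix(0, 8, 8)
  y[3, 3] <- 0.5
  o <- estimate_outliers(y, hx, 0.4)
  expect_equal(o$values[3, 3], 0.3)
  y[3, 3] <- 0.1
  expect_equal(estimate_outliers(y, hx, 0.4)$values[3, 3], 0)
  expect_error(estimate_outliers(y, hx, 0), "lambda")
})

test_that("planted impulses are recovered with high recall and few false positives", {
  hx <- make_phantom(128, 128, seed = 5)$image * 0.5 + 0.25
  imp <- sample_noise(c(128, 128), noise_spec(outlier_rate = 0.01,
                                              outlier_amplitude = 0.5), 0)
  y <- hx + imp
  o <- estimate_outliers(y, hx, 0.2)
  support <- imp != 0
  recall <- sum(o$values != 0 & support) / sum(support)
  fpr <- sum(o$values != 0 & !support) / sum(!support)
  expect_gte(recall, 0.95)
  expect_lte(fpr, 0.01)
})
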