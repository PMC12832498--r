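# Progressive structure-guided optimizer: confidence, graph, gradient,
# schedules, loop behavior.

test_that("confidence map matches its closed form", {
  y <- matrix(0.5, 8, 8); hx <- y
  expect_equal(confidence_map(y, hx, 0.1), matrix(1, 8, 8))

  hx2 <- y; hx2[2, 2] <- y[2, 2] - 0.1
  C <- confidence_map(y, hx2, 0.1)
  expect_equal(C[2, 2], exp(-1))
  expect_true(all(C > 0 & C <= 1))
  expect_error(confidence_map(y, hx, 0), "sigma_conf")
})

test_that("mean confidence under Gaussian residuals matches the analytic value", {
  # E exp(-r^2/s^2) with r ~ N(0, s^2) equals 1/sqrt(3)
  set.seed(123)
  n <- 1e5
  s <- 0.05
  r <- matrix(rnorm(n, sd = s), 250, 400)
  C <- confidence_map(r, matrix(0, 250, 400), s)
  expect_lt(abs(mean(C) - 1 / sqrt(3)), 0.01)
})

test_that("partition and weights honor thresholds and reweighting", {
  C <- matrix(seq(0, 1, length.out = 64), 8, 8)
  pw0 <- partition_and_weights(C, tau = 0, gamma = 0.5)
  expect_true(all(pw0$reliable))
  expect_true(all(pw0$omega == 1))

  pw1 <- partition_and_weights(C, tau = 1 + 1e-9, gamma = 0.3)
  expect_true(all(pw1$omega[C < 1] == 0.3))

  sig <- matrix(0.5, 8, 8)
  pw2 <- partition_and_weights(C, 0.5, 0.3, sigma_map = sig, delta = 0)
  expect_equal(pw2$omega, partition_and_weights(C, 0.5, 0.3)$omega)
  pw3 <- partition_and_weights(C, 0.5, 0.3, sigma_map = sig * 0, delta = 2)
  expect_equal(pw3$omega, partition_and_weights(C, 0.5, 0.3)$omega)

  pw4 <- partition_and_weights(C, 0.5, 0.3, sigma_map = sig, delta = 2,
                               uncertainty_mode = "literal")
  expect_equal(pw4$omega, partition_and_weights(C, 0.5, 0.3)$omega * 2)
  pw5 <- partition_and_weights(C, 0.5, 0.3, sigma_map = sig, delta = 2,
                               uncertainty_mode = "inverse")
  expect_equal(pw5$omega, partition_and_weights(C, 0.5, 0.3)$omega / 2)
  expect_error(partition_and_weights(C, 0.5, 0), "gamma")

  # reliable fraction is non-increasing in tau for fixed C
  fracs <- vapply(seq(0, 1, by = 0.05), function(tau) {
    mean(partition_and_weights(C, tau, 0.5)$reliable)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("weighted fidelity equals the naive loop sum", {
  y <- matrix(0, 8, 8); hx <- y
  expect_equal(weighted_fidelity(y, hx, matrix(1, 8, 8)), 0)

  hx2 <- y; hx2[4, 4] <- -0.2
  om <- matrix(1, 8, 8); om[4, 4] <- 0.5
  expect_equal(weighted_fidelity(y, hx2, om), 0.02)

  yr <- rand_image(8, 8, 2); hr <- rand_image(8, 8, 3); or_ <- rand_image(8, 8, 4)
  naive <- 0
  for (q in seq_along(yr)) naive <- naive + or_[q] * (yr[q] - hr[q])^2
  expect_lt(abs(weighted_fidelity(yr, hr, or_) - naive), 1e-12)
})

test_that("graph construction matches the exhaustive oracle on small images", {
  set.seed(5)
  f <- array(rnorm(16 * 16 * 4), dim = c(16, 16, 4))
  g <- build_graph(f, eps = 100, beta = 2, k = 255L)
  orc <- oracle_exhaustive_graph(matrix(f, 256, 4), eps = 100, beta = 2, k = 255L)
  got <- g$edges[order(g$edges$i, g$edges$j), ]
  expect_equal(nrow(got), nrow(orc))
  expect_equal(got$i, orc$i)
  expect_equal(got$j, orc$j)
  expect_equal(got$w, orc$w, tolerance = 1e-9)
})

test_that("graph edge cases: identical features, empty graphs, bad k", {
  f0 <- array(0.3, dim = c(8, 8, 3))
  g0 <- build_graph(f0, eps = 1, beta = 1, k = 4L)
  expect_true(all(abs(g0$edges$w - 1) < 1e-12))   # exp(0) affinities
  deg <- tabulate(c(g0$edges$i, g0$edges$j), nbins = 64)
  expect_lte(max(deg), 4L)

  set.seed(9)
  f1 <- array(rnorm(64 * 2, sd = 10), dim = c(8, 8, 2))
  g1 <- build_graph(f1, eps = 1e-8, beta = 1, k = 4L)
  expect_equal(nrow(g1$edges), 0L)

  expect_error(build_graph(f0, 1, 1, k = 64L), "smaller")
})

test_that("graph penalty equals the dense Laplacian quadratic form", {
  x <- rand_image(8, 8, 31)
  g <- structure(list(n = 64L, h = 8L, w = 8L,
                      edges = data.frame(i = 1L, j = 10L, w = 0.5, d2 = 0.1),
                      eps = 1, beta = 1, k = 4L), class = "pixel_graph")
  xv <- as.vector(x); xv[1] <- 0.2; xv[10] <- 0.6
  expect_equal(graph_penalty(matrix(xv, 8, 8), g), 0.5 * 0.4^2, tolerance = 1e-12)
  expect_equal(graph_penalty(matrix(0.7, 8, 8), g), 0)

  set.seed(6)
  f <- array(rnorm(12 * 12 * 3), dim = c(12, 12, 3))
  gr <- build_graph(f, eps = 5, beta = 1.5, k = 8L)
  x2 <- rand_image(12, 12, 8)
  Ld <- oracle_dense_laplacian(gr$edges, 144L)
  expect_lt(abs(graph_penalty(x2, gr) -
                as.numeric(t(as.vector(x2)) %*% Ld %*% as.vector(x2))), 1e-10)
  # and the sparse Laplacian agrees with the dense one
  expect_lt(max(abs(as.matrix(graph_laplacian(gr)) - Ld)), 1e-12)
})

test_that("objective gradient matches closed forms and finite differences", {
  y <- rand_image(8, 8, 41)
  x <- rand_image(8, 8, 42)
  idop <- list(H = identity, Ht = function(g, x = NULL) g)
  emptyg <- NULL

  # stationary point: x = y, no regularizer
  og0 <- objective_and_gradient(y, y, idop, emptyg, matrix(1, 8, 8), 0)
  expect_equal(og0$J, 0)
  expect_equal(og0$grad, matrix(0, 8, 8))

  # lambda = 0, identity H: grad = 2 (x - y)
  og1 <- objective_and_gradient(x, y, idop, emptyg, matrix(1, 8, 8), 0)
  expect_equal(og1$grad, 2 * (x - y), tolerance = 1e-12)

  # full problem: 3x3 blur, nonempty graph, mixed weights, FD oracle
  k <- gaussian_kernel(0.8, radius = 1L)
  fwd <- structura:::blur_operator(k, "reflect")
  set.seed(7)
  f <- array(rnorm(8 * 8 * 3), dim = c(8, 8, 3))
  gr <- build_graph(f, eps = 5, beta = 2, k = 6L)
  om <- matrix(runif(64, 0.2, 1), 8, 8)
  lam <- 0.3
  og <- objective_and_gradient(x, y, fwd, gr, om, lam)
  fdg <- oracle_fd_gradient(function(z) {
    r <- y - convolve_image(z, k, "reflect")
    sum(om * r^2) + lam * oracle_graph_penalty(z, gr$edges)
  }, x)
  rel <- max(abs(og$grad - fdg)) / max(abs(fdg))
  expect_lt(rel, 1e-5)
  expect_error(objective_and_gradient(x, y, fwd, gr, om, -1), "lambda")
})

test_that("gradient of the nonlinear sensor forward model is exact", {
  y <- rand_image(8, 8, 51) * 0.8 + 0.1
  x <- rand_image(8, 8, 52) * 0.8 + 0.1
  spec <- degradation_spec(gaussian_kernel(0.8, radius = 1L), noise_spec(),
                           sensor = sensor_transform(0.7, 0.02, 0.98))
  fwd <- structura:::spec_operator(spec)
  om <- matrix(1, 8, 8)
  og <- objective_and_gradient(x, y, fwd, NULL, om, 0)
  fdg <- oracle_fd_gradient(function(z) sum((y - fwd$H(z))^2), x)
  expect_lt(max(abs(og$grad - fdg)) / max(abs(fdg)), 1e-5)
})

test_that("schedules match their closed forms exactly", {
  s <- psgo_schedules(eta0 = 0.1, rho = 1, tau0 = 0.8, kappa = 0.9, K = 5L,
                      eps0 = 2, beta0 = 4)
  v0 <- schedules_eval(0, s)
  expect_equal(v0$eta, 0.1)
  expect_equal(v0$tau, 0.8)
  expect_equal(schedules_eval(3, s)$eta, 0.025)
  expect_equal(schedules_eval(5, s)$tau, 0.72)

  ts <- c(0:10, 99, 1234, 10000)
  for (t in ts) {
    v <- schedules_eval(t, s)
    expect_identical(v$eta, 0.1 / (1 + t))
    expect_identical(v$tau, 0.8 * 0.9^floor(t / 5))
    expect_identical(v$gamma, min(1, 0.01 + t * 0.02))
    expect_identical(v$zeta, 0.05 / (1 + t))
    expect_identical(v$eps, 2 * 0.95^floor(t / 5))
    expect_identical(v$xi, 1e-4 / (1 + t))
  }
  expect_error(schedules_eval(-1, s), "t must")
  expect_error(psgo_schedules(T = 0L), "T must")
})

test_that("sharpening residual of a constant image is zero", {
  expect_true(all(abs(structura:::sharpen_residual(matrix(0.4, 16, 16))) < 1e-12))
})

test_that("restructure tightens the graph and respects its schedule", {
  sc <- make_scenario("uniform_blur_gauss")
  sim <- simulate_scenario(sc)
  sched <- psgo_schedules(T = 12L, K = 5L)
  res <- run_psgo(sim$y, sc$spec, sched, seed = 0)

  # re-create the state at t = 10 by construction: every edge of a freshly
  # restructured graph satisfies the current (tightened) eps
  params <- encoder_params(init_seed = structura:::derive_seed(0L, 7L))
  f <- encode_features(res$x_hat, params)
  cal <- structura:::calibrate_graph_scales(f, sched$k)
  s2 <- sched; s2$eps0 <- cal$eps0; s2$beta0 <- cal$beta0
  sv <- schedules_eval(10, s2)
  g <- build_graph(f, sv$eps, sv$beta, s2$k)
  expect_true(all(sqrt(g$edges$d2) <= sv$eps + 1e-12))
  expect_true(all(abs(g$edges$w - exp(-g$edges$d2 / sv$beta)) < 1e-9))

  # off-schedule restructure is a contract error unless lenient
  st <- structura:::new_psgo_state(sim$y)
  st$t <- 3L
  prob <- list(y = sim$y, forward = structura:::spec_operator(sc$spec),
               params = params)
  expect_error(restructure(st, prob, s2), "multiple of K")
  expect_identical(restructure(st, prob, s2, lenient = TRUE), st)
})

test_that("optimizer terminates immediately on an already-optimal problem", {
  x <- make_phantom(32, 32, seed = 4)$image
  spec <- degradation_spec(delta_kernel(1), noise_spec())
  res <- run_psgo(x, spec, psgo_schedules(lambda = 0, T = 30L), seed = 1)
  expect_lte(nrow(res$trace), 3L)
  expect_identical(res$x_hat, x)
  expect_equal(res$converged_at, nrow(res$trace))
})

test_that("the optimizer is bitwise deterministic per seed", {
  sc <- make_scenario("uniform_blur_gauss")
  sim <- simulate_scenario(sc)
  cfg <- psgo_schedules(T = 8L)
  r1 <- run_psgo(sim$y, sc$spec, cfg, seed = 3)
  r2 <- run_psgo(sim$y, sc$spec, cfg, seed = 3)
  expect_identical(r1$x_hat, r2$x_hat)
  expect_identical(r1$trace, r2$trace)
})
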