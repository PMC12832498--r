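#' Noise specification
#'
#' Composite noise model: additive Gaussian noise with scalar or per-pixel
#' standard deviation plus sparse impulse ("salt-and-pepper type") outliers of
#' fixed amplitude and random sign placed at Bernoulli-sampled pixels.
#'
#' @param gaussian_sigma scalar or matrix of per-pixel standard deviations
#'   (intensity units), all `>= 0`.
#' @param outlier_rate probability in \[0, 1\] that a pixel carries an impulse.
#' @param outlier_amplitude absolute impulse magnitude (intensity units).
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(gaussian_sigma = 0, outlier_rate = 0,
                       outlier_amplitude = 0.5) {
  if (any(gaussian_sigma < 0) || any(!is.finite(gaussian_sigma))) {
    stop("gaussian_sigma must be finite and >= 0", call. = FALSE)
  }
  if (outlier_rate < 0 || outlier_rate > 1) {
    stop("outlier_rate must lie in [0, 1]", call. = FALSE)
  }
  if (outlier_amplitude < 0) stop("outlier_amplitude must be >= 0", call. = FALSE)
  structure(list(gaussian_sigma = gaussian_sigma,
                 outlier_rate = outlier_rate,
                 outlier_amplitude = outlier_amplitude),
            class = "noise_spec")
}

#' Sensor nonlinearity
#'
#' Pointwise transform `v -> clip(v^gamma, clip_low, clip_high)` modeling
#' gamma correction plus saturation clipping; monotone nondecreasing on
#' \[0, 1\] by construction.
#'
#' @param gamma positive exponent.
#' @param clip_low,clip_high clipping bounds with `clip_low < clip_high`.
#' @return an object of class `sensor_transform`.
#' @export
sensor_transform <- function(gamma = 1, clip_low = 0, clip_high = 1) {
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (clip_low >= clip_high) stop("clip_low must be < clip_high", call. = FALSE)
  structure(list(gamma = gamma, clip_low = clip_low, clip_high = clip_high),
            class = "sensor_transform")
}

apply_sensor <- function(x, sensor) {
  if (is.null(sensor)) return(x)
  pmin(pmax(pmax(x, 0)^sensor$gamma, sensor$clip_low), sensor$clip_high)
}

#' Full forward degradation specification
#'
#' Bundles the blur operator (uniform kernel or per-pixel kernel field), the
#' noise law, an optional sensor nonlinearity applied after blur and before
#' noise, the boundary rule, and an optional attention-mixed observation
#' component `y = alpha * H(x) + (1 - alpha) * eta` describing regions
#' dominated by a noise image `eta`.
#'
#' @param blur a [blur_kernel()] or [kernel_field()].
#' @param noise a [noise_spec()].
#' @param sensor optional [sensor_transform()].
#' @param boundary one of `"reflect"`, `"wrap"`, `"constant"`.
#' @param mix_attention optional `list(alpha = <matrix in [0,1]>, eta = <Image>)`.
#' @return an object of class `degradation_spec`.
#' @export
degradation_spec <- function(blur, noise = noise_spec(), sensor = NULL,
                             boundary = c("reflect", "wrap", "constant"),
                             mix_attention = NULL) {
  boundary <- match.arg(boundary)
  if (!inherits(blur, "blur_kernel") && !inherits(blur, "kernel_field")) {
    stop("blur must be a blur_kernel or kernel_field", call. = FALSE)
  }
  stopifnot(inherits(noise, "noise_spec"))
  if (!is.null(sensor)) stopifnot(inherits(sensor, "sensor_transform"))
  if (!is.null(mix_attention)) {
    if (!is.list(mix_attention) || is.null(mix_attention$alpha) ||
        is.null(mix_attention$eta)) {
      stop("mix_attention must be list(alpha = , eta = )", call. = FALSE)
    }
    a <- mix_attention$alpha
    if (min(a) < 0 || max(a) > 1) {
      stop("mix_attention$alpha values must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(blur = blur, noise = noise, sensor = sensor,
                 boundary = boundary, mix_attention = mix_attention),
            class = "degradation_spec")
}

spec_radius <- function(spec) {
  if (inherits(spec$blur, "kernel_field")) spec$blur$radius
  else kernel_radius(spec$blur)
}

# H(x) for a spec: blur only (no sensor, no noise, no mixing).
spec_forward <- function(x, spec) {
  if (inherits(spec$blur, "kernel_field")) {
    apply_kernel_field(x, spec$blur, spec$boundary)
  } else {
    convolve_image(x, spec$blur, spec$boundary)
  }
}

#' Sample composite noise
#'
#' Draws `eps = eps_G + eps_S`: Gaussian noise with per-pixel standard
#' deviation and sparse impulses of `+/- outlier_amplitude` at
#' `Bernoulli(outlier_rate)` pixels. Bitwise reproducible per seed.
#'
#' @param dim integer vector `c(h, w)`.
#' @param spec a [noise_spec()].
#' @param seed integer seed.
#' @return an `h x w` noise matrix.
#' @export
sample_noise <- function(dim, spec, seed = 0L) {
  stopifnot(inherits(spec, "noise_spec"), length(dim) == 2L, all(dim >= 1))
  h <- dim[1L]; w <- dim[2L]
  n <- h * w
  with_seed(seed, {
    eps <- matrix(stats::rnorm(n), h, w) * spec$gaussian_sigma
    if (spec$outlier_rate > 0 && spec$outlier_amplitude > 0) {
      hit <- matrix(stats::runif(n) < spec$outlier_rate, h, w)
      sgn <- matrix(sign(stats::runif(n) - 0.5), h, w)
      sgn[sgn == 0] <- 1
      eps <- eps + hit * sgn * spec$outlier_amplitude
    }
    eps
  })
}

#' Degrade an image through the full forward model
#'
#' Computes `y = G(H(x)) + eps` clipped to \[0, 1\]: blur (uniform or
#' spatially variant), optional sensor nonlinearity `G`, then additive
#' composite noise. When the spec carries an attention mix, the noiseless blur
#' output is first blended as `alpha * H(x) + (1 - alpha) * eta`.
#'
#' @param x image matrix (values in \[0, 1\], at least 8x8).
#' @param spec a [degradation_spec()].
#' @param seed integer seed controlling the noise draw.
#' @return degraded image, same shape as `x`.
#' @export
degrade <- function(x, spec, seed = 0L) {
  assert_image(x)
  stopifnot(inherits(spec, "degradation_spec"))
  r <- spec_radius(spec)
  if (r >= min(dim(x)) / 2) {
    stop(sprintf("kernel radius %d too large for a %dx%d image",
                 r, nrow(x), ncol(x)), call. = FALSE)
  }
  hx <- spec_forward(x, spec)
  if (!is.null(spec$mix_attention)) {
    hx <- spec$mix_attention$alpha * hx +
      (1 - spec$mix_attention$alpha) * spec$mix_attention$eta
  }
  gx <- apply_sensor(hx, spec$sensor)
  eps <- sample_noise(dim(x), spec$noise, seed)
  if (all(eps == 0)) {
    # exact identity path: no clipping artifacts when there is no noise and
    # the blur/sensor already map into [0, 1]
    return(clip01(gx))
  }
  clip01(gx + eps)
}

#' Attention-mixed observation
#'
#' `y = alpha * H(x) + (1 - alpha) * eta` elementwise: pixels with attention
#' near one follow the blurred latent, pixels near zero are dominated by the
#' noise image `eta`.
#'
#' @param x image matrix.
#' @param spec a [degradation_spec()] whose `mix_attention` slot is set.
#' @return mixed observation, same shape as `x`.
#' @export
mixed_observation <- function(x, spec) {
  assert_image(x)
  stopifnot(inherits(spec, "degradation_spec"))
  if (is.null(spec$mix_attention)) {
    stop("spec has no mix_attention component", call. = FALSE)
  }
  a <- spec$mix_attention$alpha
  a * spec_forward(x, spec) + (1 - a) * spec$mix_attention$eta
}

#' Classical smoothness priors
#'
#' `grad_l1` is the anisotropic total-variation style penalty
#' `sum |D_h x| + sum |D_v x|` with forward differences (last row/column
#' difference zero). `tikhonov` is `||L x||^2` with `L` the 5-point Laplacian
#' under reflect boundary.
#'
#' @param x image matrix.
#' @return `list(grad_l1 = , tikhonov = )`, both nonnegative.
#' @export
prior_penalties <- function(x) {
  if (!is.matrix(x) || any(!is.finite(x))) {
    stop("x must be a finite numeric matrix", call. = FALSE)
  }
  dh <- cbind(x[, -1L, drop = FALSE] - x[, -ncol(x), drop = FALSE], 0)
  dv <- rbind(x[-1L, , drop = FALSE] - x[-nrow(x), , drop = FALSE], 0)
  lx <- laplacian_5pt(x)
  list(grad_l1 = sum(abs(dh)) + sum(abs(dv)), tikhonov = sum(lx^2))
}

# 5-point Laplacian with reflect (Neumann-like) boundary: out-of-range
# neighbors reflect onto the edge pixel itself.
laplacian_5pt <- function(x) {
  h <- nrow(x); w <- ncol(x)
  xp <- pad_image(x, 1L, "reflect")
  4 * x - xp[1:h, (1:w) + 1L] - xp[(1:h) + 2L, (1:w) + 1L] -
    xp[(1:h) + 1L, 1:w] - xp[(1:h) + 1L, (1:w) + 2L]
}

#' Estimate sparse outliers by soft thresholding
#'
#' Closed-form minimizer of `||y - hx - o||^2 + lambda * ||o||_1`: the
#' elementwise soft threshold of the residual at `lambda / 2`. Residual
#' magnitudes at or below the threshold map to exactly zero, so the recovered
#' field is sparse when impulses are sparse.
#'
#' @param y observed image.
#' @param hx forward-model prediction, same shape.
#' @param lambda positive sparsity penalty.
#' @return `list(values = <matrix o>, nonzero_fraction = , lambda = )`.
#' @export
estimate_outliers <- function(y, hx, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop("lambda must be a positive scalar", call. = FALSE)
  }
  if (!all(dim(y) == dim(hx))) stop("y and hx must have the same shape", call. = FALSE)
  r <- y - hx
  thr <- lambda / 2
  o <- sign(r) * pmax(abs(r) - thr, 0)
  structure(list(values = o, nonzero_fraction = mean(o != 0), lambda = lambda),
            class = "outlier_field")
}
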