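#' Encoder and dynamic-filter parameters
#'
#' Parameter bundle for the content-adaptive filtering stack: a two-layer
#' convolutional feature encoder (1 -> hidden -> d channels, 3x3 filters, ReLU
#' between layers), a per-pixel kernel generator mapping each d-dimensional
#' feature to `(2r+1)^2` raw scores (softmax-normalized downstream), an
#' optional semantic-prior bias, and an affine-then-sigmoid attention gate.
#' All weights are He-initialized deterministically from `init_seed`.
#'
#' @param d feature dimension per pixel (default 16).
#' @param radius dynamic-filter radius `r` (default 1, i.e. 3x3 kernels).
#' @param hidden hidden channels in the encoder's first layer.
#' @param prior_length length of the optional semantic-prior vector (0 = none).
#' @param init_seed integer seed for the weight draw.
#' @param zero_bias if `TRUE`, all bias terms start at zero.
#' @return an object of class `encoder_params`.
#' @export
encoder_params <- function(d = 16L, radius = 1L, hidden = 8L,
                           prior_length = 0L, init_seed = 1L,
                           zero_bias = TRUE) {
  if (d <= 0) stop("feature dimension d must be positive", call. = FALSE)
  stopifnot(radius >= 1L, hidden >= 1L, prior_length >= 0L)
  m <- (2L * radius + 1L)^2
  with_seed(derive_seed(init_seed, 101L), {
    he <- function(n, fan_in) stats::rnorm(n, sd = sqrt(2 / fan_in))
    p <- list(
      d = as.integer(d), radius = as.integer(radius),
      hidden = as.integer(hidden), prior_length = as.integer(prior_length),
      init_seed = as.integer(init_seed),
      W1 = array(he(9L * hidden, 9L), dim = c(3L, 3L, hidden)),
      b1 = if (zero_bias) numeric(hidden) else he(hidden, hidden),
      W2 = array(he(9L * hidden * d, 9L * hidden), dim = c(3L, 3L, hidden, d)),
      b2 = if (zero_bias) numeric(d) else he(d, d),
      Wk = matrix(he(m * d, d), m, d),
      bk = if (zero_bias) numeric(m) else he(m, m),
      Bp = if (prior_length > 0L) matrix(he(m * prior_length, prior_length),
                                         m, prior_length) else NULL,
      gate_w = he(d + 1L, d + 1L),
      gate_b = 0
    )
    structure(p, class = "encoder_params")
  })
}

#' Encode per-pixel features
#'
#' Two 3x3 convolution layers with a ReLU in between, reflect boundary,
#' producing a `d`-channel feature map. Deterministic given `(x, params)` and
#' shift-equivariant away from the border.
#'
#' @param x image matrix.
#' @param params an [encoder_params()].
#' @return numeric array `h x w x d` of class `feature_map`.
#' @export
encode_features <- function(x, params) {
  stopifnot(inherits(params, "encoder_params"))
  if (!is.matrix(x) || any(!is.finite(x))) {
    stop("x must be a finite numeric matrix", call. = FALSE)
  }
  h <- nrow(x); w <- ncol(x)
  hid <- array(0, dim = c(h, w, params$hidden))
  for (c1 in seq_len(params$hidden)) {
    hid[, , c1] <- pmax(convolve_image(x, params$W1[, , c1], "reflect") +
                          params$b1[c1], 0)
  }
  f <- array(0, dim = c(h, w, params$d))
  for (c2 in seq_len(params$d)) {
    acc <- matrix(params$b2[c2], h, w)
    for (c1 in seq_len(params$hidden)) {
      acc <- acc + convolve_image(hid[, , c1], params$W2[, , c1, c2], "reflect")
    }
    f[, , c2] <- acc
  }
  structure(f, class = "feature_map")
}

#' Generate per-pixel dynamic filter weights
#'
#' Maps each pixel's feature vector through the kernel generator (an affine
#' map to `(2r+1)^2` raw scores, plus an optional semantic-prior bias), then
#' normalizes per pixel with a softmax. Outputs are strictly positive and sum
#' to one at every pixel, so the downstream filter is a convex combination.
#'
#' @param features a `feature_map` from [encode_features()].
#' @param params the matching [encoder_params()].
#' @param prior optional numeric vector of length `params$prior_length`,
#'   added as a shared bias to the raw scores before the softmax.
#' @return a [kernel_field()]-compatible object of class
#'   `c("dynamic_weights", "kernel_field")`.
#' @export
generate_dynamic_weights <- function(features, params, prior = NULL) {
  stopifnot(inherits(params, "encoder_params"))
  dm <- dim(features)
  if (length(dm) != 3L || dm[3L] != params$d) {
    stop("features must be an h x w x d array matching params$d", call. = FALSE)
  }
  h <- dm[1L]; w <- dm[2L]
  m <- (2L * params$radius + 1L)^2
  fmat <- matrix(features, nrow = h * w, ncol = params$d)
  scores <- fmat %*% t(params$Wk)                       # (h*w) x m
  scores <- sweep(scores, 2L, params$bk, "+")
  if (!is.null(prior)) {
    if (is.null(params$Bp) || length(prior) != params$prior_length) {
      stop("prior length does not match params$prior_length", call. = FALSE)
    }
    scores <- sweep(scores, 2L, as.vector(params$Bp %*% prior), "+")
  }
  if (any(!is.finite(scores))) {
    bad <- which(rowSums(!is.finite(scores)) > 0)[1L]
    stop(sprintf("non-finite kernel scores at pixel %d", bad), call. = FALSE)
  }
  # per-pixel softmax, max-shifted for stability
  scores <- scores - apply(scores, 1L, max)
  e <- exp(scores)
  wts <- e / rowSums(e)
  fld <- kernel_field(array(wts, dim = c(h, w, m)), params$radius,
                      normalize = FALSE)
  class(fld) <- c("dynamic_weights", class(fld))
  fld
}

#' Apply per-pixel dynamic filter weights
#'
#' Content-adaptive filtering `out(i) = sum_{j in O(i)} w_{i,j} x(j)`. Because
#' each pixel's weights lie on the simplex, the output is pixelwise bracketed
#' by `min(x)` and `max(x)` and constants are preserved.
#'
#' @param x image matrix.
#' @param weights output of [generate_dynamic_weights()].
#' @param boundary boundary rule.
#' @return filtered image, same shape as `x`.
#' @export
apply_dynamic_filter <- function(x, weights, boundary = "reflect") {
  apply_kernel_field(x, weights, boundary)
}

#' Structure map
#'
#' Sobel gradient magnitude normalized to \[0, 1\] by its own maximum,
#' highlighting prominent edges, textures and ridges; identically zero on flat
#' images.
#'
#' @param x image matrix.
#' @return matrix of structure scores in \[0, 1\].
#' @export
extract_structure <- function(x) {
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # column gradient
  sy <- t(sx)
  gx <- convolve_image(x, sx, "reflect")
  gy <- convolve_image(x, sy, "reflect")
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  # below ~1e-12 the "gradients" are pure float cancellation noise on a flat
  # image; report a zero map instead of normalizing noise up to 1
  if (mx > 1e-12) mag / mx else mag * 0
}

#' Attention-gated modulation
#'
#' Computes a per-pixel gate `alpha(i) = sigmoid(g(f_i, s(i)))` with `g` an
#' affine map on the feature vector concatenated with the structure score, and
#' blends `x_tilde = alpha * filtered + (1 - alpha) * x`. The output is
#' pixelwise bracketed by its two inputs.
#'
#' @param x original image.
#' @param filtered dynamically filtered image.
#' @param features the `feature_map` for `x`.
#' @param s structure map from [extract_structure()].
#' @param params the [encoder_params()] carrying the gate.
#' @return `list(x_tilde = , alpha = )`.
#' @export
attention_modulate <- function(x, filtered, features, s, params) {
  stopifnot(all(dim(x) == dim(filtered)), all(dim(x) == dim(s)))
  h <- nrow(x); w <- ncol(x)
  fmat <- matrix(features, nrow = h * w, ncol = params$d)
  z <- as.vector(fmat %*% params$gate_w[seq_len(params$d)]) +
    as.vector(s) * params$gate_w[params$d + 1L] + params$gate_b
  alpha <- matrix(1 / (1 + exp(-z)), h, w)
  list(x_tilde = alpha * filtered + (1 - alpha) * x, alpha = alpha)
}

# Local median over a (2r+1)^2 window, reflect boundary.
local_median <- function(x, r) {
  h <- nrow(x); w <- ncol(x)
  xp <- pad_image(x, r, "reflect")
  m <- (2L * r + 1L)^2
  st <- matrix(0, h * w, m)
  o <- 0L
  for (dx in -r:r) {
    for (dy in -r:r) {
      o <- o + 1L
      st[, o] <- as.vector(xp[(1L:h) + r + dy, (1L:w) + r + dx])
    }
  }
  # row-wise median of an n x m matrix; m is odd so this is a single order stat
  k <- (m + 1L) %/% 2L
  med <- apply(st, 1L, function(v) sort.int(v, partial = k)[k])
  matrix(med, h, w)
}

#' Local noise level and noise-adaptive feature normalization
#'
#' The per-pixel noise level is estimated robustly as `1.4826 *` the local
#' median absolute deviation (7x7 windows) of the high-pass residual
#' `x - median3x3(x)`. Features are then standardized per pixel,
#' `f_tilde = (f - mu) / sqrt(var + 1e-6)`, where the conditioning mean and
#' variance are Gaussian-window statistics whose bandwidth grows with the
#' local noise estimate (sigma-binned: wider averaging where noise is higher).
#'
#' @param features a `feature_map`.
#' @param x the image the features were computed from.
#' @return `list(f_tilde = <feature_map>, sigma_map = <matrix >= 0>)`.
#' @export
noise_adaptive_normalize <- function(features, x) {
  dm <- dim(features)
  stopifnot(length(dm) == 3L, dm[1L] == nrow(x), dm[2L] == ncol(x))
  res <- x - local_median(x, 1L)
  med7 <- local_median(res, 3L)
  sigma_map <- 1.4826 * local_median(abs(res - med7), 3L)

  # sigma-binned conditioning windows: Gaussian bandwidth grows with noise
  bw <- c(1.5, 3, 6)
  bin <- 1L + (sigma_map >= 0.02) + (sigma_map >= 0.08)
  eps <- 1e-6
  f_tilde <- array(0, dim = dm)
  smoothers <- lapply(bw, gaussian_kernel)
  for (ch in seq_len(dm[3L])) {
    f <- features[, , ch]
    out <- matrix(0, dm[1L], dm[2L])
    for (b in seq_along(bw)) {
      sel <- bin == b
      if (!any(sel)) next
      mu <- convolve_image(f, smoothers[[b]], "reflect")
      # one fixed-point refinement so the standardized output has (to second
      # order) zero Gaussian-window local mean
      mu <- mu + convolve_image(f - mu, smoothers[[b]], "reflect")
      d <- f - mu
      v <- convolve_image(d^2, smoothers[[b]], "reflect")
      z <- d / sqrt(v + eps)
      out[sel] <- z[sel]
    }
    f_tilde[, , ch] <- out
  }
  structure(list(f_tilde = structure(f_tilde, class = "feature_map"),
                 sigma_map = sigma_map), class = "normalized_features")
}

#' One pass of the dynamic structure-aware filtering pipeline
#'
#' Convenience composition: encode features, generate per-pixel kernels,
#' filter, extract structure, and blend through the attention gate. This is
#' the per-scale processor used by the multiscale refiner and the feature
#' source for the optimizer's pixel graph.
#'
#' @param x image matrix.
#' @param params an [encoder_params()].
#' @param prior optional semantic-prior vector.
#' @return `list(x_tilde, alpha, features, weights, structure)`.
#' @export
structure_aware_filter <- function(x, params, prior = NULL) {
  f <- encode_features(x, params)
  wts <- generate_dynamic_weights(f, params, prior)
  filt <- apply_dynamic_filter(x, wts)
  s <- extract_structure(x)
  mod <- attention_modulate(x, filt, f, s, params)
  list(x_tilde = mod$x_tilde, alpha = mod$alpha, features = f,
       weights = wts, structure = s)
}
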