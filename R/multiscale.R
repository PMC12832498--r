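#' Downsample by a factor of two (area mean)
#'
#' 2x2 block average; odd dimensions are first extended by replicating the
#' last row/column, giving ceil(n/2) output size. Exact inverse of bilinear
#' upsampling on constant images.
#'
#' @param x image matrix.
#' @return matrix of roughly half the size.
#' @export
downsample2 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  if (h %% 2L == 1L) x <- rbind(x, x[h, , drop = FALSE])
  if (w %% 2L == 1L) x <- cbind(x, x[, w, drop = FALSE])
  h2 <- nrow(x) %/% 2L; w2 <- ncol(x) %/% 2L
  (x[2L * (1:h2) - 1L, 2L * (1:w2) - 1L, drop = FALSE] +
     x[2L * (1:h2),    2L * (1:w2) - 1L, drop = FALSE] +
     x[2L * (1:h2) - 1L, 2L * (1:w2), drop = FALSE] +
     x[2L * (1:h2),    2L * (1:w2), drop = FALSE]) / 4
}

#' Bilinear upsampling to a target shape
#'
#' Pixel-center-aligned bilinear interpolation (edge-clamped), the upsampler
#' paired with [downsample2()]: down-then-up round trips are exact on
#' constants and accurate on smooth ramps.
#'
#' @param x image matrix.
#' @param out_h,out_w target dimensions.
#' @return `out_h x out_w` matrix.
#' @export
upsample_bilinear <- function(x, out_h, out_w) {
  h <- nrow(x); w <- ncol(x)
  interp_axis <- function(n_out, n_in) {
    u <- ((seq_len(n_out) - 0.5) * n_in / n_out) + 0.5
    u <- pmin(pmax(u, 1), n_in)
    lo <- pmin(floor(u), n_in - if (n_in > 1L) 1L else 0L)
    list(lo = as.integer(lo),
         hi = as.integer(pmin(lo + 1L, n_in)),
         t = u - lo)
  }
  ri <- interp_axis(out_h, h)
  ci <- interp_axis(out_w, w)
  a <- x[ri$lo, ci$lo, drop = FALSE]; b <- x[ri$hi, ci$lo, drop = FALSE]
  c_ <- x[ri$lo, ci$hi, drop = FALSE]; d <- x[ri$hi, ci$hi, drop = FALSE]
  tr <- matrix(ri$t, out_h, out_w)
  tc <- matrix(ci$t, out_h, out_w, byrow = TRUE)
  (a * (1 - tr) + b * tr) * (1 - tc) + (c_ * (1 - tr) + d * tr) * tc
}

#' Build an observation pyramid
#'
#' Produces `S` levels by repeated 2x area-mean downsampling, ordered coarse to
#' fine (level `S` is the input). When a degradation spec with a Gaussian blur
#' is supplied, per-scale operator specs are derived by halving the blur width
#' per coarsening step; other blur types are reused unchanged across scales.
#'
#' @param y image matrix (finest level).
#' @param S number of scales (`>= 1`).
#' @param spec optional [degradation_spec()] for the finest level.
#' @return object of class `scale_pyramid`: `list(levels = <coarse..fine>,
#'   specs = <per-level or NULL>, S = )`.
#' @export
build_pyramid <- function(y, S, spec = NULL) {
  stopifnot(S >= 1)
  lv <- vector("list", S)
  lv[[S]] <- y
  for (s in rev(seq_len(S - 1L))) {
    lv[[s]] <- downsample2(lv[[s + 1L]])
  }
  if (min(dim(lv[[1L]])) < 8L) {
    stop(sprintf("S = %d gives a coarsest level below 8 pixels for a %dx%d image",
                 S, nrow(y), ncol(y)), call. = FALSE)
  }
  specs <- NULL
  if (!is.null(spec)) {
    specs <- vector("list", S)
    specs[[S]] <- spec
    for (s in rev(seq_len(S - 1L))) {
      specs[[s]] <- rescale_spec(specs[[s + 1L]])
    }
  }
  structure(list(levels = lv, specs = specs, S = as.integer(S)),
            class = "scale_pyramid")
}

# Derive a one-level-coarser degradation spec: Gaussian kernels have their
# width halved; other kernels and kernel fields are reused as-is.
rescale_spec <- function(spec) {
  blur <- spec$blur
  if (inherits(blur, "blur_kernel") && !is.null(attr(blur, "sigma"))) {
    blur <- gaussian_kernel(attr(blur, "sigma") / 2)
  }
  degradation_spec(blur, spec$noise, spec$sensor, spec$boundary,
                   spec$mix_attention)
}

#' Refine one scale and lift to the next
#'
#' `x_{s+1} = U(F_s(x_s))`: apply the per-scale processor (by default the
#' dynamic filtering pipeline, or the identity) and upsample the result to
#' doubled resolution.
#'
#' @param x_s image at scale `s`.
#' @param processor function image -> image (e.g. built from
#'   [structure_aware_filter()]); `NULL` means identity.
#' @return image at doubled resolution.
#' @export
refine_scale <- function(x_s, processor = NULL) {
  z <- if (is.null(processor)) x_s else processor(x_s)
  stopifnot(is.matrix(z), all(dim(z) == dim(x_s)))
  upsample_bilinear(z, 2L * nrow(x_s), 2L * ncol(x_s))
}

#' Per-scale data residual
#'
#' `r_s = y_s - H_s(x_tilde_s)`: zero exactly when the refined estimate
#' explains the observation at that scale.
#'
#' @param y_s observation at scale `s`.
#' @param x_tilde_s refined estimate at scale `s`.
#' @param H_s forward operator: a function image -> image, a
#'   [degradation_spec()] (its blur path is used), or `NULL` for identity.
#' @return residual image.
#' @export
scale_residual <- function(y_s, x_tilde_s, H_s = NULL) {
  stopifnot(all(dim(y_s) == dim(x_tilde_s)))
  hx <- if (is.null(H_s)) x_tilde_s
        else if (is.function(H_s)) H_s(x_tilde_s)
        else spec_forward(x_tilde_s, H_s)
  y_s - hx
}

#' Scale alignment loss
#'
#' `sum_s || D(x_{s+1}) - x_s ||^2` over adjacent levels, with `D` the same
#' area-mean downsampler used to build pyramids. Zero exactly on
#' self-consistent pyramids; defined as 0 for a single level.
#'
#' @param pyramid a `scale_pyramid` (or plain list of images coarse to fine).
#' @return nonnegative scalar.
#' @export
alignment_loss <- function(pyramid) {
  lv <- if (inherits(pyramid, "scale_pyramid")) pyramid$levels else pyramid
  S <- length(lv)
  if (S < 2L) return(0)
  loss <- 0
  for (s in seq_len(S - 1L)) {
    d <- downsample2(lv[[s + 1L]]) - lv[[s]]
    loss <- loss + sum(d^2)
  }
  loss
}

#' Per-scale fusion weights (channel-attention realization)
#'
#' Pools each level (after upsampling to the finest grid) with average and max
#' pooling, passes the pooled pair through one shared affine map, and
#' softmax-normalizes across scales. Equal statistics give exactly uniform
#' weights.
#'
#' @param pyramid a `scale_pyramid` or list of images coarse to fine.
#' @param w_avg,w_max,bias shared affine map coefficients.
#' @return numeric vector on the simplex, one weight per scale.
#' @export
fusion_weights <- function(pyramid, w_avg = 1, w_max = 1, bias = 0) {
  lv <- if (inherits(pyramid, "scale_pyramid")) pyramid$levels else pyramid
  S <- length(lv)
  fin <- dim(lv[[S]])
  z <- vapply(lv, function(im) {
    up <- if (all(dim(im) == fin)) im else upsample_bilinear(im, fin[1L], fin[2L])
    w_avg * mean(up) + w_max * max(up) + bias
  }, numeric(1L))
  e <- exp(z - max(z))
  e / sum(e)
}

#' Fuse pyramid levels into one image
#'
#' Upsamples every level to the finest grid and combines them convexly with
#' the given (or channel-attention derived) weights. A single scale returns
#' the level unchanged.
#'
#' @param pyramid a `scale_pyramid` or list of images coarse to fine.
#' @param weights optional per-scale weights on the simplex; computed with
#'   [fusion_weights()] when omitted.
#' @return fused image at the finest resolution.
#' @export
fuse_scales <- function(pyramid, weights = NULL) {
  lv <- if (inherits(pyramid, "scale_pyramid")) pyramid$levels else pyramid
  S <- length(lv)
  if (is.null(weights)) weights <- fusion_weights(lv)
  if (length(weights) != S || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop("fusion weights must be nonnegative and sum to 1", call. = FALSE)
  }
  if (S == 1L) return(lv[[1L]])
  fin <- dim(lv[[S]])
  out <- matrix(0, fin[1L], fin[2L])
  for (s in seq_len(S)) {
    up <- if (all(dim(lv[[s]]) == fin)) lv[[s]]
          else upsample_bilinear(lv[[s]], fin[1L], fin[2L])
    out <- out + weights[s] * up
  }
  out
}

#' Uncertainty map and correction
#'
#' The predictive uncertainty at each pixel is the standard deviation of the
#' trailing `m` iterates; it shrinks to zero as the iteration converges. The
#' corrected image is `x_hat = x + beta * Sigma` where `beta` is fit by 1-D
#' least squares so that the correction moves along the direction that best
#' explains the current data residual (requires `y` and `forward`), capped at
#' `|beta| <= 1`. Without a residual to fit against, `beta = 0` and the image
#' is returned unchanged.
#'
#' @param x current image.
#' @param history list of past iterates (matrices), oldest first; at least 2.
#' @param m number of trailing iterates used (default 5).
#' @param beta optional fixed value overriding the least-squares fit.
#' @param y,forward optional observation and forward operator (function) used
#'   to fit `beta`.
#' @return `list(x_hat = , sigma = <UncertaintyMap>, beta = )`.
#' @export
uncertainty_correct <- function(x, history, m = 5L, beta = NULL,
                                y = NULL, forward = NULL) {
  if (!is.list(history) || length(history) < 2L) {
    stop("history must contain at least 2 iterates", call. = FALSE)
  }
  tail_h <- history[seq.int(max(1L, length(history) - m + 1L), length(history))]
  st <- vapply(tail_h, as.vector, numeric(length(x)))
  mu <- rowMeans(st)
  sigma <- matrix(sqrt(rowSums((st - mu)^2) / (ncol(st) - 1L)),
                  nrow(x), ncol(x))
  if (is.null(beta)) {
    beta <- 0
    if (!is.null(y) && !is.null(forward) && any(sigma > 0)) {
      hd <- forward(sigma)
      r <- y - forward(x)
      den <- sum(hd^2)
      if (den > 1e-12) beta <- max(-1, min(1, sum(r * hd) / den))
    }
  }
  list(x_hat = x + beta * sigma, sigma = sigma, beta = beta)
}
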