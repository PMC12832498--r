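# Windowed convolution engine with explicit boundary handling and exact
# adjoints. Everything downstream (degradation forward models, dynamic
# filtering, optimizer gradients) routes through these functions, so the
# adjoint here must match the forward map exactly including the boundary
# fold -- gradient correctness is checked against finite differences.

# Source index for each padded position 1..(n + 2r). 0 means "outside"
# (constant-zero padding). reflect = symmetric reflection including the edge
# pixel (position 0 maps to 1, -1 to 2, n+1 to n, ...).
boundary_index <- function(n, r, boundary = c("reflect", "wrap", "constant")) {
  boundary <- match.arg(boundary)
  idx <- seq_len(n + 2L * r) - r
  switch(boundary,
    reflect = {
      idx <- ifelse(idx < 1L, 1L - idx, idx)
      ifelse(idx > n, 2L * n + 1L - idx, idx)
    },
    wrap = ((idx - 1L) %% n) + 1L,
    constant = ifelse(idx < 1L | idx > n, 0L, idx)
  )
}

# Pad a matrix by r on every side under the given boundary rule.
pad_image <- function(x, r, boundary = "reflect") {
  if (r == 0L) return(x)
  rm_ <- boundary_index(nrow(x), r, boundary)
  cm_ <- boundary_index(ncol(x), r, boundary)
  xp <- x[pmax(rm_, 1L), pmax(cm_, 1L), drop = FALSE]
  if (any(rm_ == 0L)) xp[rm_ == 0L, ] <- 0
  if (any(cm_ == 0L)) xp[, cm_ == 0L] <- 0
  xp
}

# Adjoint of pad_image: fold padded-border contributions back onto their
# source pixels (reflect/wrap) or drop them (constant).
unpad_adjoint <- function(tmp, h, w, r, boundary = "reflect") {
  if (r == 0L) return(tmp)
  rm_ <- boundary_index(h, r, boundary)
  cm_ <- boundary_index(w, r, boundary)
  kr <- rm_ > 0L
  a <- rowsum(tmp[kr, , drop = FALSE], rm_[kr])         # groups 1..h, sorted
  kc <- cm_ > 0L
  t(rowsum(t(a[, kc, drop = FALSE]), cm_[kc]))
}

#' Convolve an image with a uniform kernel
#'
#' Computes `out(i) = sum_{j in O(i)} k_j x(j)` over the (2r+1)^2 window
#' centered at each pixel, with the chosen boundary rule. Weight `k[a, b]`
#' multiplies the neighbor at row offset `a - r - 1`, column offset
#' `b - r - 1` (correlation orientation; symmetric kernels are unaffected).
#'
#' @param x numeric matrix.
#' @param kernel a [blur_kernel()] (or any square odd-sided matrix).
#' @param boundary one of `"reflect"`, `"wrap"`, `"constant"`.
#' @return matrix of the same shape as `x`.
#' @export
convolve_image <- function(x, kernel, boundary = "reflect") {
  r <- (nrow(kernel) - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  if (r >= min(h, w) / 2) {
    stop(sprintf("kernel radius %d too large for a %dx%d image", r, h, w),
         call. = FALSE)
  }
  xp <- pad_image(x, r, boundary)
  out <- matrix(0, h, w)
  for (dx in -r:r) {
    for (dy in -r:r) {
      kv <- kernel[dy + r + 1L, dx + r + 1L]
      if (kv != 0) {
        out <- out + kv * xp[(1L:h) + r + dy, (1L:w) + r + dx, drop = FALSE]
      }
    }
  }
  out
}

# Adjoint of convolve_image: for gradients of 1/2 ||y - Hx||^2 style terms.
convolve_adjoint <- function(g, kernel, boundary = "reflect") {
  r <- (nrow(kernel) - 1L) %/% 2L
  h <- nrow(g); w <- ncol(g)
  tmp <- matrix(0, h + 2L * r, w + 2L * r)
  for (dx in -r:r) {
    for (dy in -r:r) {
      kv <- kernel[dy + r + 1L, dx + r + 1L]
      if (kv != 0) {
        ii <- (1L:h) + r + dy; jj <- (1L:w) + r + dx
        tmp[ii, jj] <- tmp[ii, jj] + kv * g
      }
    }
  }
  unpad_adjoint(tmp, h, w, r, boundary)
}

#' Apply a per-pixel kernel field
#'
#' Spatially variant blur: `out(i) = sum_{j in O(i)} k_{i,j} x(j)` where every
#' pixel `i` carries its own normalized kernel. Constant images map to
#' themselves (per-pixel kernels sum to one).
#'
#' @param x numeric matrix.
#' @param field a [kernel_field()].
#' @param boundary boundary rule, as in [convolve_image()].
#' @return matrix of the same shape as `x`.
#' @export
apply_kernel_field <- function(x, field, boundary = "reflect") {
  stopifnot(inherits(field, "kernel_field"))
  h <- nrow(x); w <- ncol(x)
  if (field$height != h || field$width != w) {
    stop(sprintf("kernel field is %dx%d but image is %dx%d",
                 field$height, field$width, h, w), call. = FALSE)
  }
  r <- field$radius
  if (r >= min(h, w) / 2) {
    stop(sprintf("kernel radius %d too large for a %dx%d image", r, h, w),
         call. = FALSE)
  }
  xp <- pad_image(x, r, boundary)
  out <- matrix(0, h, w)
  o <- 0L
  for (dx in -r:r) {
    for (dy in -r:r) {
      o <- o + 1L
      out <- out + field$weights[, , o] *
        xp[(1L:h) + r + dy, (1L:w) + r + dx, drop = FALSE]
    }
  }
  out
}

# Adjoint of apply_kernel_field.
kernel_field_adjoint <- function(g, field, boundary = "reflect") {
  h <- nrow(g); w <- ncol(g)
  r <- field$radius
  tmp <- matrix(0, h + 2L * r, w + 2L * r)
  o <- 0L
  for (dx in -r:r) {
    for (dy in -r:r) {
      o <- o + 1L
      ii <- (1L:h) + r + dy; jj <- (1L:w) + r + dx
      tmp[ii, jj] <- tmp[ii, jj] + field$weights[, , o] * g
    }
  }
  unpad_adjoint(tmp, h, w, r, boundary)
}

# Forward blur operator and its adjoint for a degradation spec's blur slot.
# Ht takes (g, x); linear operators ignore x.
blur_operator <- function(blur, boundary = "reflect") {
  if (inherits(blur, "kernel_field")) {
    list(
      H  = function(x) apply_kernel_field(x, blur, boundary),
      Ht = function(g, x = NULL) kernel_field_adjoint(g, blur, boundary)
    )
  } else {
    list(
      H  = function(x) convolve_image(x, blur, boundary),
      Ht = function(g, x = NULL) convolve_adjoint(g, blur, boundary)
    )
  }
}

# Full forward operator of a degradation spec -- blur, then the optional
# attention mix, then the optional sensor nonlinearity -- together with the
# adjoint of its Jacobian at a given point (exact chain rule; the clipped
# region of the sensor transform has zero derivative, and the power-law slope
# is evaluated with a small floor to keep gamma < 1 finite at zero).
spec_operator <- function(spec) {
  blur <- blur_operator(spec$blur, spec$boundary)
  mix <- spec$mix_attention
  sensor <- spec$sensor
  pre_sensor <- function(x) {
    u <- blur$H(x)
    if (!is.null(mix)) u <- mix$alpha * u + (1 - mix$alpha) * mix$eta
    u
  }
  H <- function(x) apply_sensor(pre_sensor(x), sensor)
  Ht <- function(g, x = NULL) {
    if (!is.null(sensor)) {
      stopifnot(!is.null(x))
      u <- pmax(pre_sensor(x), 1e-6)
      v <- u^sensor$gamma
      active <- (v > sensor$clip_low) & (v < sensor$clip_high)
      g <- g * active * sensor$gamma * u^(sensor$gamma - 1)
    }
    if (!is.null(mix)) g <- mix$alpha * g
    blur$Ht(g)
  }
  list(H = H, Ht = Ht)
}
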