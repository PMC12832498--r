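#' Blur kernels and per-pixel kernel fields
#'
#' A `blur_kernel` is a square (2r+1) x (2r+1) matrix of nonnegative weights
#' summing to one (flux preservation): applying it to a constant image returns
#' the same constant. A `kernel_field` carries one such kernel per pixel,
#' modeling spatially variant blur (a distinct point-spread function at every
#' location); per-pixel kernels are normalized to sum to one as well, so
#' constant images are preserved by the spatially variant path too.
#'
#' @param weights square numeric matrix with odd side length.
#' @param normalize if `TRUE`, rescale weights to sum to one.
#' @return an object of class `blur_kernel` (a matrix with a `radius`
#'   attribute).
#' @examples
#' k <- gaussian_kernel(1)        # 7x7, sigma = 1
#' b <- box_kernel(1)             # 3x3 box
#' d <- delta_kernel(2)           # 5x5 identity kernel
#' @export
blur_kernel <- function(weights, normalize = FALSE) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights) ||
      nrow(weights) %% 2L != 1L) {
    stop("kernel weights must be a square matrix with odd side length",
         call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("kernel weights must be finite and nonnegative", call. = FALSE)
  }
  s <- sum(weights)
  if (normalize) {
    if (s <= 0) stop("cannot normalize an all-zero kernel", call. = FALSE)
    weights <- weights / s
  } else if (abs(s - 1) > 1e-9) {
    stop(sprintf("kernel weights must sum to 1 (got %.12g); use normalize = TRUE", s),
         call. = FALSE)
  }
  structure(weights, radius = (nrow(weights) - 1L) %/% 2L,
            class = c("blur_kernel", "matrix"))
}

#' @rdname blur_kernel
#' @param sigma standard deviation of the Gaussian, in pixels.
#' @param radius kernel radius; defaults to `ceiling(3 * sigma)` (at least 1).
#' @export
gaussian_kernel <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  stopifnot(sigma >= 0, radius >= 1)
  u <- -radius:radius
  g <- if (sigma == 0) as.numeric(u == 0) else exp(-u^2 / (2 * sigma^2))
  k <- outer(g, g)
  blur_kernel(k / sum(k))
}

#' @rdname blur_kernel
#' @export
box_kernel <- function(radius = 1L) {
  n <- 2L * radius + 1L
  blur_kernel(matrix(1 / n^2, n, n))
}

#' @rdname blur_kernel
#' @export
delta_kernel <- function(radius = 1L) {
  n <- 2L * radius + 1L
  k <- matrix(0, n, n)
  k[radius + 1L, radius + 1L] <- 1
  blur_kernel(k)
}

kernel_radius <- function(kernel) attr(kernel, "radius")

#' Construct a per-pixel kernel field
#'
#' @param weights numeric array of dimension `c(h, w, (2r+1)^2)`: slice `o`
#'   holds, for every pixel, the weight of window offset `o`. Offsets are
#'   enumerated column-major over `(dy, dx)` with `dy, dx` in `-r..r`, i.e.
#'   slice index `o = (dx + r) * (2r + 1) + (dy + r) + 1`.
#' @param radius kernel radius `r`.
#' @param normalize if `TRUE` (default), normalize each pixel's kernel to sum
#'   to one.
#' @return an object of class `kernel_field`.
#' @export
kernel_field <- function(weights, radius, normalize = TRUE) {
  if (!is.array(weights) || length(dim(weights)) != 3L) {
    stop("kernel field weights must be an h x w x (2r+1)^2 array", call. = FALSE)
  }
  m <- (2L * radius + 1L)^2
  if (dim(weights)[3L] != m) {
    stop(sprintf("kernel field third dimension must be %d for radius %d", m, radius),
         call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("kernel field weights must be finite and nonnegative", call. = FALSE)
  }
  sums <- rowSums(matrix(weights, ncol = m))
  if (normalize) {
    if (any(sums <= 0)) stop("some per-pixel kernels are all-zero", call. = FALSE)
    weights <- array(as.vector(weights) / rep(sums, m), dim = dim(weights))
  } else if (any(abs(sums - 1) > 1e-9)) {
    stop("each per-pixel kernel must sum to 1; use normalize = TRUE", call. = FALSE)
  }
  structure(list(weights = weights, radius = as.integer(radius),
                 height = dim(weights)[1L], width = dim(weights)[2L]),
            class = "kernel_field")
}

#' Spatially varying Gaussian kernel field
#'
#' Builds a kernel field where the Gaussian width varies per pixel, e.g. a
#' point-spread function that broadens across the field of view.
#'
#' @param sigma_map matrix of per-pixel Gaussian standard deviations (pixels).
#' @param radius shared kernel radius.
#' @return a `kernel_field`.
#' @export
kernel_field_gaussian <- function(sigma_map, radius = 2L) {
  stopifnot(is.matrix(sigma_map), all(sigma_map >= 0))
  h <- nrow(sigma_map); w <- ncol(sigma_map)
  n <- 2L * radius + 1L
  u <- -radius:radius
  # profile per pixel: exp(-u^2 / (2 sigma^2)); sigma = 0 degenerates to delta
  wts <- array(0, dim = c(h, w, n * n))
  s2 <- 2 * pmax(sigma_map, 1e-12)^2
  o <- 0L
  for (dx in u) {
    for (dy in u) {
      o <- o + 1L
      wts[, , o] <- exp(-(dy^2 + dx^2) / s2)
    }
  }
  zero <- sigma_map == 0
  if (any(zero)) {
    ctr <- (radius) * n + radius + 1L
    for (o in seq_len(n * n)) wts[, , o][zero] <- as.numeric(o == ctr)
  }
  kernel_field(wts, radius, normalize = TRUE)
}

# A kernel field whose every pixel carries the same uniform kernel.
kernel_field_uniform <- function(h, w, kernel) {
  r <- kernel_radius(kernel)
  m <- (2L * r + 1L)^2
  wts <- array(rep(as.vector(kernel), each = h * w), dim = c(h, w, m))
  kernel_field(wts, r, normalize = FALSE)
}

#' Read a kernel from a plain-text matrix file
#'
#' Whitespace-separated rows of numbers; the matrix must be square with odd
#' side length. Weights are normalized to sum to one.
#'
#' @param path file path.
#' @return a `blur_kernel`.
#' @export
read_kernel <- function(path) {
  if (!file.exists(path)) stop(sprintf("kernel file not found: %s", path), call. = FALSE)
  rows <- readLines(path, warn = FALSE)
  rows <- rows[nzchar(trimws(rows))]
  vals <- lapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]))
  nc <- unique(lengths(vals))
  if (length(nc) != 1L) stop(sprintf("ragged kernel matrix in %s", path), call. = FALSE)
  k <- do.call(rbind, vals)
  blur_kernel(k, normalize = TRUE)
}
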