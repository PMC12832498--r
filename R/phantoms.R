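#' Generate a tissue-like synthetic phantom
#'
#' Piecewise-smooth test image with known ground truth: hard-edged elliptical
#' blobs of distinct intensities on a uniform background (step edges),
#' band-limited texture inside the first blob (textured region), and thin
#' bright sinusoidal ridge curves. Intensities are rescaled to \[0, 1\].
#' Bitwise reproducible per seed.
#'
#' The generator emulates the qualitative structure vocabulary of tissue
#' images -- edges, textures, ridges -- not the physics of any particular
#' modality.
#'
#' @param height,width image dimensions (`>= 32`).
#' @param params `list(n_blobs = , texture_amplitude = , ridge_count = )`.
#' @param seed integer seed.
#' @return object of class `phantom`: `list(image, region_labels, params,
#'   seed)`.
#' @export
make_phantom <- function(height = 64L, width = 64L,
                         params = list(n_blobs = 5L, texture_amplitude = 0.15,
                                       ridge_count = 2L),
                         seed = 0L) {
  if (height < 32L || width < 32L) {
    stop("phantom dimensions must be at least 32", call. = FALSE)
  }
  defaults <- list(n_blobs = 5L, texture_amplitude = 0.15, ridge_count = 2L)
  params <- utils::modifyList(defaults, params)
  with_seed(derive_seed(seed, 211L), {
    img <- matrix(0.2, height, width)
    labels <- matrix(0L, height, width)
    rows <- matrix(seq_len(height), height, width)
    cols <- matrix(seq_len(width), height, width, byrow = TRUE)
    if (params$n_blobs > 0L) {
      for (b in seq_len(params$n_blobs)) {
        cy <- stats::runif(1, 0.2, 0.8) * height
        cx <- stats::runif(1, 0.2, 0.8) * width
        ry <- stats::runif(1, 0.10, 0.28) * height
        rx <- stats::runif(1, 0.10, 0.28) * width
        ang <- stats::runif(1, 0, pi)
        val <- stats::runif(1, 0.35, 0.95)
        dy <- rows - cy; dx <- cols - cx
        u <- cos(ang) * dx + sin(ang) * dy
        v <- -sin(ang) * dx + cos(ang) * dy
        inside <- (u / rx)^2 + (v / ry)^2 <= 1
        img[inside] <- val
        labels[inside] <- b
      }
    }
    if (params$texture_amplitude > 0) {
      noise <- matrix(stats::rnorm(height * width), height, width)
      tex <- convolve_image(noise, gaussian_kernel(1), "reflect") -
        convolve_image(noise, gaussian_kernel(4), "reflect")
      sdt <- stats::sd(tex)
      if (sdt > 0) tex <- tex / sdt
      region <- if (params$n_blobs > 0L) labels == 1L else labels == 0L
      img[region] <- img[region] + params$texture_amplitude * tex[region]
    }
    if (params$ridge_count > 0L) {
      for (rdg in seq_len(params$ridge_count)) {
        base <- stats::runif(1, 0.2, 0.8) * width
        amp <- stats::runif(1, 0.05, 0.15) * width
        freq <- stats::runif(1, 1, 3)
        phase <- stats::runif(1, 0, 2 * pi)
        centers <- base + amp * sin(2 * pi * freq * seq_len(height) / height + phase)
        dist <- sweep(cols, 1L, centers, "-")
        img <- img + 0.6 * exp(-dist^2 / (2 * 1.5^2))
      }
    }
    rng <- range(img)
    if (rng[2] > rng[1]) {
      img <- (img - rng[1]) / (rng[2] - rng[1])
    } else {
      img <- clip01(img)
    }
    structure(list(image = img, region_labels = labels, params = params,
                   seed = as.integer(seed)),
              class = "phantom")
  })
}

#' Named degradation scenarios
#'
#' Frozen (phantom spec, degradation spec, seed) tuples exercising the four
#' forward-model regimes:
#' \describe{
#'   \item{uniform_blur_gauss}{64x64 phantom (seed 0), 5x5 Gaussian blur with
#'     sigma = 1, Gaussian noise sigma = 0.02.}
#'   \item{variant_blur_impulse}{64x64 phantom (seed 1), spatially varying
#'     Gaussian blur with sigma ramping 0.5 to 2 across the image, Gaussian
#'     noise sigma = 0.01 plus 1\% impulses of amplitude 0.5.}
#'   \item{nonlinear_clip}{64x64 phantom (seed 2), 5x5 Gaussian blur sigma = 1,
#'     sensor gamma = 0.7 with clipping to \[0.02, 0.98\], noise sigma = 0.02.}
#'   \item{mixed_attention}{64x64 phantom (seed 3), 5x5 Gaussian blur
#'     sigma = 1, attention-mixed observation with a smooth attention map in
#'     \[0.7, 1\] and a structured dominant-noise image, noise sigma = 0.01.}
#' }
#'
#' @param name one of the registry names above.
#' @return object of class `scenario`: `list(name, phantom, spec, seed)`.
#' @export
make_scenario <- function(name) {
  known <- scenario_names()
  if (!name %in% known) {
    stop(sprintf("unknown scenario '%s'; known: %s", name,
                 paste(known, collapse = ", ")), call. = FALSE)
  }
  sc <- switch(name,
    uniform_blur_gauss = {
      k <- gaussian_kernel(1, radius = 2L)
      attr(k, "sigma") <- 1
      list(phantom = make_phantom(64L, 64L, seed = 0L),
           spec = degradation_spec(k, noise_spec(gaussian_sigma = 0.02)),
           seed = 0L)
    },
    variant_blur_impulse = {
      sig <- matrix(seq(0.5, 2, length.out = 64L), 64L, 64L, byrow = TRUE)
      fld <- kernel_field_gaussian(sig, radius = 2L)
      list(phantom = make_phantom(64L, 64L, seed = 1L),
           spec = degradation_spec(fld, noise_spec(gaussian_sigma = 0.01,
                                                   outlier_rate = 0.01,
                                                   outlier_amplitude = 0.5)),
           seed = 1L)
    },
    nonlinear_clip = {
      k <- gaussian_kernel(1, radius = 2L)
      attr(k, "sigma") <- 1
      list(phantom = make_phantom(64L, 64L, seed = 2L),
           spec = degradation_spec(k, noise_spec(gaussian_sigma = 0.02),
                                   sensor = sensor_transform(gamma = 0.7,
                                                             clip_low = 0.02,
                                                             clip_high = 0.98)),
           seed = 2L)
    },
    mixed_attention = {
      k <- gaussian_kernel(1, radius = 2L)
      attr(k, "sigma") <- 1
      mix <- with_seed(derive_seed(3L, 977L), {
        a_raw <- convolve_image(matrix(stats::rnorm(64L * 64L), 64L, 64L),
                                gaussian_kernel(4), "reflect")
        a <- 0.7 + 0.3 * (a_raw - min(a_raw)) / (max(a_raw) - min(a_raw))
        e_raw <- convolve_image(matrix(stats::rnorm(64L * 64L), 64L, 64L),
                                gaussian_kernel(2), "reflect")
        eta <- (e_raw - min(e_raw)) / (max(e_raw) - min(e_raw))
        list(alpha = a, eta = eta)
      })
      list(phantom = make_phantom(64L, 64L, seed = 3L),
           spec = degradation_spec(k, noise_spec(gaussian_sigma = 0.01),
                                   mix_attention = mix),
           seed = 3L)
    }
  )
  structure(list(name = name, phantom = sc$phantom, spec = sc$spec,
                 seed = sc$seed), class = "scenario")
}

#' @rdname make_scenario
#' @export
scenario_names <- function() {
  c("uniform_blur_gauss", "variant_blur_impulse", "nonlinear_clip",
    "mixed_attention")
}

#' Simulate a scenario's observation
#'
#' @param scenario a [make_scenario()] result.
#' @return `list(x_true = , y = )`.
#' @export
simulate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  x_true <- scenario$phantom$image
  list(x_true = x_true, y = degrade(x_true, scenario$spec, scenario$seed))
}

#' Reconstruction quality metrics
#'
#' Mean squared error, PSNR in decibels with peak 1 (`Inf` when the images are
#' identical), and the Pearson correlation of the two Sobel structure maps
#' (0 if either image is flat).
#'
#' @param x image under evaluation.
#' @param ref reference image, same shape.
#' @return `list(mse = , psnr_db = , structure_corr = )`.
#' @export
image_metrics <- function(x, ref) {
  if (!all(dim(x) == dim(ref))) {
    stop("x and ref must have the same shape", call. = FALSE)
  }
  mse <- mean((x - ref)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(1 / mse)
  sx <- extract_structure(x)
  sr <- extract_structure(ref)
  sc <- if (stats::sd(sx) == 0 || stats::sd(sr) == 0) 0
        else stats::cor(as.vector(sx), as.vector(sr))
  list(mse = mse, psnr_db = psnr, structure_corr = sc)
}
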