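#' Read a grayscale image
#'
#' PNG or TIFF; values are mapped linearly to \[0, 1\] (the format readers
#' already deliver that scale). RGB(A) inputs are reduced to grayscale by
#' Rec. 709 luminance. Alpha channels are dropped.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return numeric matrix in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '%s' for %s", ext, path), call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] >= 3L) {
      img <- 0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] + 0.0722 * img[, , 3L]
    } else {
      img <- img[, , 1L]
    }
  }
  clip01(img)
}

#' Write a grayscale image
#'
#' TIFF output is quantized to 16 bits (round trips within 1/65535 per pixel);
#' PNG output is 8-bit (the `png` writer's depth), which round trips within
#' 1/255.
#'
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @param x image matrix in \[0, 1\].
#' @return `path`, invisibly.
#' @export
write_image <- function(path, x) {
  stopifnot(is.matrix(x))
  x <- clip01(x)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 16L,
                           compression = "none"),
    stop(sprintf("unsupported image format '%s' for %s", ext, path), call. = FALSE)
  )
  invisible(path)
}

# ---------------------------------------------------------------------------
# TOML-style configuration (minimal subset: [section] headers, key = value,
# values are numbers, booleans or double-quoted strings, # comments).

config_schema <- function() {
  num <- "numeric"; int <- "integer"; chr <- "character"; lgl <- "logical"
  c(
    "scenario" = chr, "seed" = int, "boundary" = chr,
    "blur.type" = chr, "blur.sigma" = num, "blur.radius" = int,
    "blur.path" = chr, "blur.sigma_min" = num, "blur.sigma_max" = num,
    "noise.sigma" = num, "noise.outlier_rate" = num,
    "noise.outlier_amplitude" = num,
    "sensor.gamma" = num, "sensor.clip_low" = num, "sensor.clip_high" = num,
    "encoder.d" = int, "encoder.radius" = int, "encoder.hidden" = int,
    "encoder.init_seed" = int,
    "psgo.eta0" = num, "psgo.rho" = num, "psgo.tau0" = num,
    "psgo.kappa" = num, "psgo.K" = int, "psgo.gamma0" = num,
    "psgo.dgamma" = num, "psgo.zeta0" = num, "psgo.eps0" = num,
    "psgo.eps_decay" = num, "psgo.beta0" = num, "psgo.beta_decay" = num,
    "psgo.xi0" = num, "psgo.lambda" = num, "psgo.delta" = num,
    "psgo.k" = int, "psgo.T" = int, "psgo.sigma_conf" = num,
    "psgo.uncertainty_mode" = chr, "psgo.momentum" = lgl
  )
}

#' Read a TOML-style run configuration
#'
#' Supports `[section]` headers and `key = value` lines (numbers, booleans,
#' double-quoted strings; `#` comments). Keys are flattened to `section.key`
#' and validated against the documented schema; unknown keys are errors.
#'
#' @param path config file path.
#' @return named list of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  cfg <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- trimws(substr(ln, 2L, nchar(ln) - 1L))
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L) {
      stop(sprintf("cannot parse config line: '%s'", ln), call. = FALSE)
    }
    key <- if (nzchar(section)) paste0(section, ".", m[2L]) else m[2L]
    cfg[[key]] <- parse_toml_value(trimws(m[3L]), key)
  }
  validate_config(cfg)
}

parse_toml_value <- function(v, key) {
  if (grepl('^".*"$', v)) return(substr(v, 2L, nchar(v) - 1L))
  if (v %in% c("true", "false")) return(v == "true")
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  stop(sprintf("cannot parse value '%s' for key '%s'", v, key), call. = FALSE)
}

validate_config <- function(cfg) {
  schema <- config_schema()
  for (key in names(cfg)) {
    if (!key %in% names(schema)) {
      stop(sprintf("unknown config key: '%s'", key), call. = FALSE)
    }
    want <- schema[[key]]
    val <- cfg[[key]]
    ok <- switch(want,
                 numeric = is.numeric(val),
                 integer = is.numeric(val) && val == round(val),
                 character = is.character(val),
                 logical = is.logical(val))
    if (!ok) {
      stop(sprintf("config key '%s' must be %s", key, want), call. = FALSE)
    }
    if (want == "integer") cfg[[key]] <- as.integer(val)
  }
  cfg
}

#' Serialize a configuration back to TOML-style text
#'
#' Inverse of [read_config()]: `read_config` of the written file reproduces
#' the same configuration (round-trip idempotence).
#'
#' @param cfg named list as returned by [read_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  keys <- names(cfg)
  sections <- ifelse(grepl("\\.", keys), sub("\\..*$", "", keys), "")
  out <- character(0)
  for (sec in unique(sections)) {
    if (nzchar(sec)) out <- c(out, sprintf("[%s]", sec))
    for (i in which(sections == sec)) {
      leaf <- sub("^[^.]*\\.", "", keys[i])
      val <- cfg[[i]]
      vs <- if (is.character(val)) sprintf('"%s"', val)
            else if (is.logical(val)) tolower(as.character(val))
            else format(val, digits = 17)
      out <- c(out, sprintf("%s = %s", leaf, vs))
    }
  }
  writeLines(out, path)
  invisible(path)
}

# Build a degradation_spec from flattened config keys (used by the CLI).
config_to_spec <- function(cfg) {
  boundary <- cfg[["boundary"]] %||% "reflect"
  type <- cfg[["blur.type"]] %||% "gaussian"
  radius <- cfg[["blur.radius"]] %||% 2L
  blur <- switch(type,
    gaussian = {
      k <- gaussian_kernel(cfg[["blur.sigma"]] %||% 1, radius = radius)
      attr(k, "sigma") <- cfg[["blur.sigma"]] %||% 1
      k
    },
    box = box_kernel(radius),
    delta = delta_kernel(radius),
    file = read_kernel(cfg[["blur.path"]]),
    stop(sprintf("unknown blur.type '%s'", type), call. = FALSE)
  )
  noise <- noise_spec(
    gaussian_sigma = cfg[["noise.sigma"]] %||% 0,
    outlier_rate = cfg[["noise.outlier_rate"]] %||% 0,
    outlier_amplitude = cfg[["noise.outlier_amplitude"]] %||% 0.5
  )
  sensor <- NULL
  if (!is.null(cfg[["sensor.gamma"]])) {
    sensor <- sensor_transform(cfg[["sensor.gamma"]],
                               cfg[["sensor.clip_low"]] %||% 0,
                               cfg[["sensor.clip_high"]] %||% 1)
  }
  degradation_spec(blur, noise, sensor, boundary)
}

config_to_schedules <- function(cfg) {
  g <- function(key, default) cfg[[paste0("psgo.", key)]] %||% default
  psgo_schedules(
    eta0 = g("eta0", 0.4), rho = g("rho", 0.05), tau0 = g("tau0", 0.8),
    kappa = g("kappa", 0.9), K = g("K", 5L), gamma0 = g("gamma0", 0.01),
    dgamma = g("dgamma", 0.02), zeta0 = g("zeta0", 0.05),
    eps0 = g("eps0", NA_real_), eps_decay = g("eps_decay", 0.95),
    beta0 = g("beta0", NA_real_), beta_decay = g("beta_decay", 0.95),
    xi0 = g("xi0", 1e-4), lambda = g("lambda", 0.2),
    delta = g("delta", 0.5), k = g("k", 16L), T = g("T", 60L),
    sigma_conf = g("sigma_conf", NA_real_),
    uncertainty_mode = g("uncertainty_mode", "literal"),
    momentum = g("momentum", FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
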