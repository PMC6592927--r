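# Seeded synthetic immunofluorescence-like image generator.
#
# One parametric renderer serves all four classes; a class only selects its
# default parameter set. The morphology is deliberately stylised: elliptical
# ring outlines stand in for stained vessel walls, short bright line segments
# for reticulin fibers, a smooth mottle field for Wharton's-jelly background,
# and fine-grained speckle for the unstructured negative background. The
# descriptor consumes texture statistics, not biological detail, so these cues
# are what the classes must differ in.

#' Per-class texture parameters
#'
#' Default rendering parameters for one diagnostic class. Intensities are
#' dimensionless in `[0, 1]`; `fiber_density` is fibers per 1000 px^2;
#' `mottle_amp`/`mottle_scale` control the amplitude (intensity) and
#' correlation length (pixels of Gaussian smoothing) of the background field.
#'
#' Defaults per class: I (positive) bright rings + dense fibers over a
#' mid-level coarse mottle; II (negative) dim fine-grained speckle, no
#' structures; III (IgA deficient) near-dark, almost flat; IV (equivocal)
#' class-I morphology at strongly reduced brightness and contrast.
#'
#' @param cls One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param ... Named overrides of individual fields.
#' @return A list of class `class_texture_params`.
#' @export
class_texture_params <- function(cls = c("I", "II", "III", "IV"), ...) {
  cls <- match.arg(cls)
  p <- switch(cls,
    I   = list(ring_count = 4, ring_brightness = 0.55, fiber_density = 8,
               fiber_brightness = 0.50, background_level = 0.35,
               noise_sd = 0.05, mottle_amp = 0.10, mottle_scale = 2.0),
    II  = list(ring_count = 0, ring_brightness = 0, fiber_density = 0,
               fiber_brightness = 0, background_level = 0.12,
               noise_sd = 0.05, mottle_amp = 0.08, mottle_scale = 0.8),
    III = list(ring_count = 0, ring_brightness = 0, fiber_density = 0,
               fiber_brightness = 0, background_level = 0.03,
               noise_sd = 0.015, mottle_amp = 0.005, mottle_scale = 0.8),
    IV  = list(ring_count = 4, ring_brightness = 0.18, fiber_density = 5,
               fiber_brightness = 0.15, background_level = 0.18,
               noise_sd = 0.05, mottle_amp = 0.05, mottle_scale = 2.0)
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(p)))
  p[names(over)] <- over
  validate_texture_params(p)
  structure(p, class = "class_texture_params")
}

validate_texture_params <- function(p) {
  ints <- c("ring_brightness", "fiber_brightness", "background_level")
  for (f in ints) {
    if (p[[f]] < 0 || p[[f]] > 1) {
      stop_emaclass(f, " must be in [0, 1]",
                    class = "emaclass_validation_error")
    }
  }
  if (p$noise_sd < 0 || p$mottle_amp < 0 || p$fiber_density < 0 ||
      p$ring_count < 0) {
    stop_emaclass("texture parameters must be non-negative",
                  class = "emaclass_validation_error")
  }
  invisible(p)
}

# blend class parameters toward the across-class mean: separability 1 keeps
# the class-specific set, 0 collapses all classes onto one shared set
blend_params <- function(cls, separability) {
  stopifnot(separability >= 0, separability <= 1)
  own <- unclass(class_texture_params(cls))
  all4 <- lapply(EMA_CLASSES, function(k) unclass(class_texture_params(k)))
  shared <- lapply(names(own), function(f) mean(vapply(all4, `[[`, 0, f)))
  names(shared) <- names(own)
  out <- lapply(names(own), function(f) {
    shared[[f]] + separability * (own[[f]] - shared[[f]])
  })
  names(out) <- names(own)
  out$ring_count <- round(out$ring_count)
  structure(out, class = "class_texture_params")
}

#' Render one synthetic immunofluorescence-like image
#'
#' Fully seed-determined class-conditional rendering: background level plus a
#' smoothed mottle field, `ring_count` elliptical ring outlines (vessel
#' walls), short oriented bright segments (reticulin fibers) at
#' `fiber_density` per 1000 px^2, additive Gaussian pixel noise, all clipped
#' to `[0, 1]`.
#'
#' @param cls Class label `"I"`..`"IV"` (selects default `p`).
#' @param p A [class_texture_params()]; defaults to the class's own set.
#' @param size Image side in pixels (square, > 24).
#' @param seed Integer seed; `NULL` draws from the current RNG stream.
#' @return Numeric `size` x `size` matrix in `[0, 1]`.
#' @export
generate_image <- function(cls, p = class_texture_params(cls), size = 64,
                           seed = NULL) {
  size <- as.integer(size)
  if (size <= 24) {
    stop_emaclass("image size must exceed 24 pixels (descriptor minimum), got ",
                  size, class = "emaclass_size_error")
  }
  validate_texture_params(p)
  with_seed(seed, render_image(p, size))
}

render_image <- function(p, size) {
  img <- matrix(p$background_level, size, size)
  # background mottle: smoothed white noise, rescaled to sd = mottle_amp
  if (p$mottle_amp > 0) {
    field <- matrix(stats::rnorm(size * size), size, size)
    field <- gaussian_blur(field, max(p$mottle_scale, 1e-6))
    field <- field / max(stats::sd(field), 1e-12) * p$mottle_amp
    img <- img + field
  }
  # vessel-wall ring outlines: smooth Gaussian profile around an ellipse
  xs <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  ys <- matrix(rep(seq_len(size), times = size), size, size)  # row index
  for (i in seq_len(p$ring_count)) {
    cx <- stats::runif(1, 0.15 * size, 0.85 * size)
    cy <- stats::runif(1, 0.15 * size, 0.85 * size)
    a <- stats::runif(1, size / 10, size / 5)
    b <- stats::runif(1, size / 10, size / 5)
    phi <- stats::runif(1, 0, pi)
    dx <- xs - cx; dy <- ys - cy
    u <- dx * cos(phi) + dy * sin(phi)
    v <- -dx * sin(phi) + dy * cos(phi)
    q <- sqrt((u / a)^2 + (v / b)^2)
    ring <- exp(-((q - 1) * min(a, b) / 1.2)^2)
    img <- img + p$ring_brightness * ring
  }
  # reticulin fibers: short line segments splatted as Gaussian dots
  n_fib <- round(p$fiber_density * size^2 / 1000)
  if (n_fib > 0 && p$fiber_brightness > 0) {
    layer <- matrix(0, size, size)
    for (i in seq_len(n_fib)) {
      len <- stats::runif(1, 4, 10)
      ang <- stats::runif(1, 0, pi)
      x0 <- stats::runif(1, 2, size - 2)
      y0 <- stats::runif(1, 2, size - 2)
      tpts <- seq(0, len, by = 0.5)
      px <- pmin(pmax(round(x0 + tpts * cos(ang)), 1), size)
      py <- pmin(pmax(round(y0 + tpts * sin(ang)), 1), size)
      layer[cbind(py, px)] <- 1
    }
    layer <- gaussian_blur(layer, 0.6)
    layer <- layer / max(max(layer), 1e-12)
    img <- img + p$fiber_brightness * layer
  }
  if (p$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(size * size, sd = p$noise_sd), size, size)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Class mix observed in routine screening
#'
#' The strongly imbalanced four-class prevalence profile typical of a
#' screening laboratory: 10.55\% positive, 87.02\% negative, 0.50\% IgA
#' deficient, 1.93\% equivocal.
#'
#' @return Named numeric vector of proportions summing to 1.
#' @export
clinical_proportions <- function() {
  c(I = 0.1055, II = 0.8702, III = 0.0050, IV = 0.0193)
}

#' Specification of a synthetic dataset
#'
#' Either `n_per_class` (length-4 counts) or `n_total` plus `proportions`
#' (apportioned by the largest-remainder method so the total is exact).
#'
#' @param n_per_class Integer vector of per-class counts (order I..IV).
#' @param n_total Total image count, used with `proportions`.
#' @param proportions Length-4 class shares (summing to 1).
#' @param image_size Side of the square images (> 24).
#' @param separability In `[0, 1]`: 1 = full class-specific contrast, 0 = all
#'   classes share one parameter set (chance-level problem).
#' @param seed Integer seed controlling rendering and shuffling.
#' @return A list of class `dataset_spec` (with resolved `counts`).
#' @export
dataset_spec <- function(n_per_class = NULL, n_total = NULL,
                         proportions = NULL, image_size = 64,
                         separability = 1, seed = 0) {
  if (is.null(n_per_class)) {
    if (is.null(n_total) || is.null(proportions)) {
      stop_emaclass("give either n_per_class or n_total + proportions",
                    class = "emaclass_validation_error")
    }
    stopifnot(length(proportions) == 4, abs(sum(proportions) - 1) < 1e-6)
    counts <- apportion(n_total, proportions)
  } else {
    stopifnot(length(n_per_class) == 4, all(n_per_class >= 0))
    counts <- as.integer(n_per_class)
  }
  if (sum(counts) < 4) {
    stop_emaclass("total dataset size must be at least 4",
                  class = "emaclass_validation_error")
  }
  stopifnot(image_size > 24, separability >= 0, separability <= 1)
  names(counts) <- EMA_CLASSES
  structure(list(counts = counts, image_size = as.integer(image_size),
                 separability = separability, seed = as.integer(seed)),
            class = "dataset_spec")
}

# largest-remainder apportionment: exact total, round-half-up start
apportion <- function(total, shares) {
  raw <- total * shares / sum(shares)
  base <- floor(raw + 0.5)
  diff <- total - sum(base)
  if (diff != 0) {
    # distribute the discrepancy by largest (or smallest) remainder,
    # ties resolved in class order
    frac <- raw - floor(raw)
    ord <- order(if (diff > 0) -frac else frac, seq_along(frac))
    for (i in seq_len(abs(diff))) {
      j <- ord[(i - 1) %% length(ord) + 1]
      base[j] <- base[j] + sign(diff)
    }
  }
  as.integer(base)
}

#' Generate a seeded synthetic dataset
#'
#' Renders the requested number of images per class at the requested
#' separability, shuffles their order (seeded), and returns them together
#' with a manifest recording everything needed to regenerate the set.
#'
#' @param spec A [dataset_spec()].
#' @return A list with `images` (list of matrices), `labels` (factor I..IV),
#'   and `manifest` (list: counts, parameters per class, seed, size,
#'   separability, warnings).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  params <- lapply(EMA_CLASSES, blend_params, separability = spec$separability)
  names(params) <- EMA_CLASSES
  warnings <- character(0)
  if (any(spec$counts == 0)) {
    warnings <- c(warnings, paste0(
      "class(es) with zero samples: ",
      paste(EMA_CLASSES[spec$counts == 0], collapse = ", "),
      "; stratified splitting downstream will fail"))
  }
  with_seed(spec$seed, {
    labels <- rep(EMA_CLASSES, times = spec$counts)
    images <- lapply(labels, function(cls) {
      generate_image(cls, params[[cls]], size = spec$image_size, seed = NULL)
    })
    ord <- sample(length(images))
    list(
      images = images[ord],
      labels = factor(labels[ord], levels = EMA_CLASSES),
      manifest = list(
        counts = spec$counts,
        image_size = spec$image_size,
        separability = spec$separability,
        seed = spec$seed,
        params = lapply(params, unclass),
        warnings = warnings
      )
    )
  })
}

#' Write a generated dataset to disk
#'
#' Writes one PNG per image plus the `path,label` manifest CSV consumed by
#' [extract_feature_table()], and a JSON sidecar with the generation record.
#'
#' @param ds Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(ds$images)
  fname <- sprintf("img%04d_%s.png", seq_len(n), ds$labels)
  for (i in seq_len(n)) {
    png::writePNG(ds$images[[i]], file.path(dir, fname[i]))
  }
  man <- data.frame(path = fname, label = as.character(ds$labels))
  csv <- file.path(dir, "manifest.csv")
  utils::write.csv(man, csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(ds$manifest, file.path(dir, "generation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv)
}
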