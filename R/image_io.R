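#' Read a microscopy image as a green-channel intensity matrix
#'
#' Loads a JPEG, PNG or TIFF image and reduces it to the single intensity
#' plane the descriptor consumes. EmA slides are acquired with red and blue
#' channels suppressed, so for colour sources only the green plane carries
#' signal and is selected; single-channel sources pass through unchanged.
#' Integer intensities are rescaled to `[0, 1]` by the dtype maximum (the
#' underlying readers already do this for 8- and 16-bit data).
#'
#' @param path Path to a `.jpg`/`.jpeg`, `.png`, `.tif`/`.tiff` file.
#' @return A numeric matrix with values in `[0, 1]` (rows = image rows).
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' rgb <- array(0, c(8, 8, 3)); rgb[, , 2] <- 0.5
#' png::writePNG(rgb, f)
#' img <- load_image(f)   # constant 0.5 green plane
#' range(img)
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    stop_emaclass("cannot read image: file not found: ", path,
                  class = "emaclass_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  reader <- switch(ext,
    jpg = , jpeg = jpeg::readJPEG,
    png = png::readPNG,
    tif = , tiff = function(p) tiff::readTIFF(p, as.is = FALSE),
    stop_emaclass("unsupported image format '.", ext, "' for ", path,
                  class = "emaclass_format_error")
  )
  arr <- tryCatch(reader(path), error = function(e) {
    stop_emaclass("failed to decode image ", path, ": ", conditionMessage(e),
                  class = "emaclass_io_error")
  })
  px <- green_plane(arr, path)
  validate_gray_image(px)
  px
}

# channel selection: 1 channel passes through, 3/4 channels take green ([,,2])
green_plane <- function(arr, path = "<array>") {
  if (is.matrix(arr)) return(arr * 1)
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    if (nch == 1) return(arr[, , 1])
    if (nch %in% c(3, 4)) return(arr[, , 2])
    stop_emaclass("unsupported channel count (", nch, ") in ", path,
                  class = "emaclass_format_error")
  }
  stop_emaclass("unsupported image layout in ", path,
                class = "emaclass_format_error")
}

validate_gray_image <- function(px) {
  if (!is.matrix(px) || !is.numeric(px) || nrow(px) < 1 || ncol(px) < 1) {
    stop_emaclass("image must be a non-empty numeric matrix",
                  class = "emaclass_validation_error")
  }
  if (any(!is.finite(px))) {
    stop_emaclass("image contains non-finite pixels",
                  class = "emaclass_validation_error")
  }
  if (min(px) < 0 || max(px) > 1) {
    stop_emaclass("image intensities must lie in [0, 1]",
                  class = "emaclass_validation_error")
  }
  invisible(px)
}

#' Preprocessing configuration
#'
#' Edge enhancement settings applied before feature extraction. Enhancement is
#' unsharp masking: `out = clip(img + amount * (img - gaussian_blur(img,
#' blur_sigma)), 0, 1)`. With `amount = 0` (or `enhance = FALSE`) the
#' operation is the identity.
#'
#' @param enhance Apply enhancement at all?
#' @param blur_sigma Gaussian blur standard deviation in pixels (> 0).
#' @param amount Strength of the high-frequency boost (>= 0); 1 doubles edge
#'   contrast relative to the blurred baseline.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(enhance = TRUE, blur_sigma = 1.0, amount = 1.0) {
  stopifnot(is.numeric(blur_sigma), length(blur_sigma) == 1, blur_sigma > 0,
            is.numeric(amount), length(amount) == 1, amount >= 0)
  structure(list(enhance = isTRUE(enhance), blur_sigma = blur_sigma,
                 amount = amount),
            class = "preprocess_config")
}

#' Gaussian blur with symmetric boundary padding
#'
#' Separable Gaussian convolution. Boundaries use symmetric (mirror) padding
#' so that constant images are exact fixed points and the operator commutes
#' with 90-degree rotation of square images.
#'
#' @param img Numeric matrix.
#' @param sigma Standard deviation in pixels (> 0).
#' @return Blurred matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma > 0)
  rad <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  k <- k / sum(k)
  img <- convolve_axis(img, k, rad, margin = 1)
  convolve_axis(img, k, rad, margin = 2)
}

# 1D convolution along rows (margin = 1) or columns (margin = 2) with
# symmetric padding; k has length 2*rad + 1
convolve_axis <- function(m, k, rad, margin) {
  n <- if (margin == 1) nrow(m) else ncol(m)
  pad_idx <- c(pmin(rad:1, n), seq_len(n), pmax(n - seq_len(rad) + 1L, 1L))
  if (margin == 1) {
    mp <- m[pad_idx, , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[(j - 1) + seq_len(nrow(m)), , drop = FALSE]
    }
  } else {
    mp <- m[, pad_idx, drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[, (j - 1) + seq_len(ncol(m)), drop = FALSE]
    }
  }
  out
}

#' Unsharp-mask edge enhancement
#'
#' Boosts local contrast before texture extraction:
#' `clip(img + amount * (img - gaussian_blur(img, blur_sigma)), 0, 1)`.
#' The blur kernel is symmetric and mirror-padded, so the operation commutes
#' with 90-degree rotation and leaves constant images unchanged.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param cfg A [preprocess_config()].
#' @return Enhanced matrix, same dimensions, clipped to `[0, 1]`.
#' @export
enhance_edges <- function(img, cfg = preprocess_config()) {
  validate_gray_image(img)
  if (!cfg$enhance || cfg$amount == 0) return(img)
  blur <- gaussian_blur(img, cfg$blur_sigma)
  out <- img + cfg$amount * (img - blur)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Rotate an image 90 degrees counter-clockwise
#'
#' @param m Matrix.
#' @param k Number of 90-degree turns (default 1).
#' @return Rotated matrix.
#' @export
rot90_image <- function(m, k = 1) {
  k <- as.integer(k) %% 4L
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

#' Read an image manifest
#'
#' A manifest is a CSV with columns `path` and `label` (label in I--IV).
#' Relative image paths are resolved against the manifest's directory.
#'
#' @param manifest_csv Path to the CSV.
#' @return A data.frame with columns `path` (absolute) and `label` (factor).
#' @export
read_manifest <- function(manifest_csv) {
  if (!file.exists(manifest_csv)) {
    stop_emaclass("manifest not found: ", manifest_csv,
                  class = "emaclass_io_error")
  }
  df <- utils::read.csv(manifest_csv, stringsAsFactors = FALSE)
  miss <- setdiff(c("path", "label"), names(df))
  if (length(miss) > 0) {
    stop_emaclass("manifest is missing column(s): ", paste(miss, collapse = ", "),
                  class = "emaclass_validation_error")
  }
  if (nrow(df) == 0) {
    stop_emaclass("manifest is empty: ", manifest_csv,
                  class = "emaclass_validation_error")
  }
  base <- dirname(normalizePath(manifest_csv))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                file.path(base, df$path))
  data.frame(path = abs, label = check_labels(df$label),
             stringsAsFactors = FALSE)
}
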