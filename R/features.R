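# Multi-scale rotation-invariant co-occurrence LBP descriptor.
#
# Conventions used throughout:
#   * LBP codes are 4-bit: bit order (East, North, West, South) at offsets
#     (0,+r), (-r,0), (0,-r), (+r,0) in (row, col) terms; a bit is set when
#     neighbour - centre >= 0 (ties count as 1 so flat regions give code 15).
#   * Co-occurrence directions theta in {0, 45, 90, 135} degrees are the
#     standard GLCM set, (drow, dcol) in {(0,d), (-d,d), (-d,0), (-d,-d)}.
#   * Raw histogram cells are indexed 0-based as theta_idx*256 + A*16 + B.

DIR_OFFSETS <- function(d) list(c(0L, d), c(-d, d), c(-d, 0L), c(-d, -d))

#' Local binary pattern map (4-neighbour cross)
#'
#' Computes the 4-bit LBP code of every pixel at least `r` pixels from the
#' border. A bit is 1 when the neighbour intensity is greater than or equal
#' to the centre (so constant regions give code 15), in bit order East (1),
#' North (2), West (4), South (8).
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param r Neighbour radius in pixels (positive integer).
#' @return An object of class `lbp_map`: list with `codes` (integer matrix,
#'   `NA` in the border of width `r`), `scale_r`, and `margin` (= `r`).
#' @export
lbp_map <- function(img, r) {
  validate_gray_image(img)
  r <- as.integer(r)
  stopifnot(r >= 1)
  h <- nrow(img); w <- ncol(img)
  if (h <= 2 * r || w <= 2 * r) {
    stop_emaclass("image (", h, "x", w, ") too small for LBP radius r = ", r,
                  class = "emaclass_size_error")
  }
  rows <- (r + 1):(h - r)
  cols <- (r + 1):(w - r)
  C <- img[rows, cols, drop = FALSE]
  E <- img[rows, cols + r, drop = FALSE]
  N <- img[rows - r, cols, drop = FALSE]
  W <- img[rows, cols - r, drop = FALSE]
  S <- img[rows + r, cols, drop = FALSE]
  code <- (E >= C) + 2L * (N >= C) + 4L * (W >= C) + 8L * (S >= C)
  codes <- matrix(NA_integer_, h, w)
  codes[rows, cols] <- as.integer(code)
  structure(list(codes = codes, scale_r = r, margin = r), class = "lbp_map")
}

#' Rotate a 4-bit LBP code by 90 degrees
#'
#' Cyclic left shift of the bit pattern (East -> North -> West -> South ->
#' East): the code a patch would produce after rotating the image 90 degrees
#' counter-clockwise. Vectorised.
#'
#' @param code Integer vector with values in `[0, 15]`.
#' @return Integer vector of rotated codes.
#' @export
rot90_code <- function(code) {
  code <- as.integer(code)
  if (any(is.na(code)) || any(code < 0L | code > 15L)) {
    stop_emaclass("LBP codes must be integers in [0, 15]",
                  class = "emaclass_validation_error")
  }
  bitwOr(bitwAnd(bitwShiftL(code, 1L), 15L), bitwShiftR(code, 3L))
}

#' Co-occurrence histogram of adjacent LBP codes
#'
#' Counts ordered pairs of LBP codes at displacement `d` along the four
#' canonical directions (0, 45, 90, 135 degrees). Each ordered pair oriented
#' along a canonical direction is counted once for every endpoint that lies
#' in the valid centre region (equivalently: every valid centre contributes
#' its 8 displacements +-a_theta, the pair being recorded as (theta, code at
#' the tail, code at the head)). The total count is therefore exactly
#' `8 * |valid region|`, and the histogram pooled over rotation orbits is
#' exactly invariant under 90-degree image rotation.
#'
#' @param m An [lbp_map()].
#' @param d Co-occurrence displacement in pixels.
#' @param margin Border width (in pixels) excluded from the centre region on
#'   all four sides; must be at least `m$margin + d`. Defaults to the minimum.
#'   Feature extraction passes a shared margin so all scales scan the same
#'   centres.
#' @return Object of class `coalbp_histogram`: list with `counts` (numeric
#'   vector of length 1024, cell order theta-major then code A then code B),
#'   `scale_r`, `interval_d`, `margin`, `n_centers`.
#' @export
coalbp_histogram <- function(m, d, margin = m$margin + d) {
  stopifnot(inherits(m, "lbp_map"))
  d <- as.integer(d); margin <- as.integer(margin)
  stopifnot(d >= 1)
  if (margin < m$margin + d) {
    stop_emaclass("margin (", margin, ") must be >= lbp margin + d = ",
                  m$margin + d, class = "emaclass_size_error")
  }
  h <- nrow(m$codes); w <- ncol(m$codes)
  if (h <= 2 * margin || w <= 2 * margin) {
    stop_emaclass("empty valid region: image ", h, "x", w, " with margin ",
                  margin, class = "emaclass_size_error")
  }
  rows <- (margin + 1):(h - margin)
  cols <- (margin + 1):(w - margin)
  counts <- numeric(1024)
  offs <- DIR_OFFSETS(d)
  Cc <- m$codes[rows, cols, drop = FALSE]
  for (t in seq_len(4)) {
    dr <- offs[[t]][1]; dc <- offs[[t]][2]
    # forward displacement: centre is the tail of the pair
    B <- m$codes[rows + dr, cols + dc, drop = FALSE]
    counts <- counts + tabulate((t - 1L) * 256L + Cc * 16L + B + 1L,
                                nbins = 1024L)
    # backward displacement: centre is the head; tail code comes from c - a
    A <- m$codes[rows - dr, cols - dc, drop = FALSE]
    counts <- counts + tabulate((t - 1L) * 256L + A * 16L + Cc + 1L,
                                nbins = 1024L)
  }
  structure(list(counts = counts, scale_r = m$scale_r, interval_d = d,
                 margin = margin,
                 n_centers = length(rows) * length(cols)),
            class = "coalbp_histogram")
}

# cache for the orbit table (it is a pure function of nothing)
.ric_cache <- new.env(parent = emptyenv())

#' Rotation-orbit label table for co-occurrence cells
#'
#' Builds the equivalence of the 1024 raw cells (theta, codeA, codeB) under
#' the order-4 rotation action `g`: rotating the image by 90 degrees rotates
#' both codes and advances theta by 90 degrees; when theta wraps past 180 the
#' pair direction reverses, so the codes swap. Each cell is labelled with the
#' minimum raw index (0-based, theta-major) of its orbit. There are exactly
#' 272 orbits, which the Burnside count (1024 + 0 + 64 + 0) / 4 confirms.
#'
#' @return Object of class `ric_label_table`: list with `label_of` (integer
#'   vector of length 1024, canonical raw index per cell), `bin_of` (integer
#'   1..272 compressed bin per cell), `labels` (sorted canonical indices) and
#'   `n_labels`.
#' @export
ric_label_table <- function() {
  if (!is.null(.ric_cache$table)) return(.ric_cache$table)
  idx <- 0:1023
  theta <- idx %/% 256L
  A <- (idx %% 256L) %/% 16L
  B <- idx %% 16L
  # one application of g to every cell, vectorised
  g_apply <- function(theta, A, B) {
    wrap <- theta >= 2L            # 90 -> 180, 135 -> 225: direction reverses
    nt <- (theta + 2L) %% 4L
    nA <- ifelse(wrap, rot90_code(B), rot90_code(A))
    nB <- ifelse(wrap, rot90_code(A), rot90_code(B))
    list(theta = nt, A = as.integer(nA), B = as.integer(nB))
  }
  lab <- idx
  cur <- list(theta = theta, A = A, B = B)
  for (k in 1:3) {
    cur <- g_apply(cur$theta, cur$A, cur$B)
    lab <- pmin(lab, cur$theta * 256L + cur$A * 16L + cur$B)
  }
  labels <- sort(unique(lab))
  tab <- structure(list(label_of = lab,
                        bin_of = match(lab, labels),
                        labels = labels,
                        n_labels = length(labels)),
                   class = "ric_label_table")
  .ric_cache$table <- tab
  tab
}

#' Pool a raw co-occurrence histogram over rotation orbits
#'
#' @param h A [coalbp_histogram()] (or any numeric vector of length 1024).
#' @param table A [ric_label_table()].
#' @return Numeric vector of length 272 (orbit bins in increasing canonical
#'   index order); total count is conserved.
#' @export
ric_histogram <- function(h, table = ric_label_table()) {
  counts <- if (inherits(h, "coalbp_histogram")) h$counts else h
  if (length(counts) != 1024) {
    stop_emaclass("raw histogram must have 1024 cells",
                  class = "emaclass_validation_error")
  }
  as.numeric(rowsum(counts, group = table$bin_of, reorder = TRUE))
}

#' Descriptor scales
#'
#' The three (radius, displacement) pairs of the multi-scale descriptor and
#' the shared margin implied by the largest.
#' @return A list with elements `r`, `d` (length-3 integer vectors) and
#'   `margin` (12).
#' @export
descriptor_scales <- function() {
  list(r = c(1L, 2L, 4L), d = c(2L, 4L, 8L), margin = 12L)
}

#' Extract the multi-scale rotation-invariant texture feature vector
#'
#' Runs the full descriptor: unsharp edge enhancement, then for each scale
#' `(r, d)` in `{(1,2), (2,4), (4,8)}` an LBP map, co-occurrence histogram and
#' rotation-orbit pooling, each 272-bin block L1-normalised to a probability
#' distribution, concatenated in scale order (816 values). All scales share
#' one centre region (margin 12 on every side) so the feature vector is
#' exactly invariant under 90/180/270-degree rotation of square images.
#'
#' @param img Numeric matrix in `[0, 1]`, both dimensions > 24.
#' @param cfg A [preprocess_config()].
#' @return Named numeric vector `f0` ... `f815`.
#' @export
extract_features <- function(img, cfg = preprocess_config()) {
  validate_gray_image(img)
  sc <- descriptor_scales()
  min_dim <- 2 * sc$margin + 1
  if (nrow(img) < min_dim || ncol(img) < min_dim) {
    stop_emaclass("image (", nrow(img), "x", ncol(img), ") too small for the ",
                  "descriptor: both dimensions must be > ", 2 * sc$margin,
                  class = "emaclass_size_error")
  }
  img <- enhance_edges(img, cfg)
  tab <- ric_label_table()
  blocks <- lapply(seq_along(sc$r), function(i) {
    m <- lbp_map(img, sc$r[i])
    h <- coalbp_histogram(m, sc$d[i], margin = sc$margin)
    v <- ric_histogram(h, tab)
    s <- sum(v)
    if (s > 0) v / s else v
  })
  out <- unlist(blocks, use.names = FALSE)
  names(out) <- paste0("f", seq_along(out) - 1)
  out
}

#' Length of the descriptor feature vector
#' @return Integer, `3 * 272 = 816`.
#' @export
feature_length <- function() {
  3L * ric_label_table()$n_labels
}
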