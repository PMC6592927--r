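# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals: plain double
# loops and direct convolution only.

# LBP code of every interior pixel, one pixel at a time
brute_lbp <- function(img, r) {
  h <- nrow(img); w <- ncol(img)
  codes <- matrix(NA_integer_, h, w)
  for (i in (r + 1):(h - r)) {
    for (j in (r + 1):(w - r)) {
      c0 <- img[i, j]
      bits <- c(img[i, j + r] >= c0,   # E
                img[i - r, j] >= c0,   # N
                img[i, j - r] >= c0,   # W
                img[i + r, j] >= c0)   # S
      codes[i, j] <- sum(bits * c(1L, 2L, 4L, 8L))
    }
  }
  codes
}

# co-occurrence histogram: every valid centre contributes its 8 displacements
# +-a_theta, each recorded as the ordered pair along +a_theta
brute_coalbp <- function(img, r, d, margin = r + d) {
  codes <- brute_lbp(img, r)
  offs <- list(c(0, d), c(-d, d), c(-d, 0), c(-d, -d))
  counts <- numeric(1024)
  h <- nrow(img); w <- ncol(img)
  for (i in (margin + 1):(h - margin)) {
    for (j in (margin + 1):(w - margin)) {
      for (t in 1:4) {
        dr <- offs[[t]][1]; dc <- offs[[t]][2]
        # centre as tail of the oriented pair
        cell <- (t - 1) * 256 + codes[i, j] * 16 + codes[i + dr, j + dc]
        counts[cell + 1] <- counts[cell + 1] + 1
        # centre as head of the oriented pair
        cell <- (t - 1) * 256 + codes[i - dr, j - dc] * 16 + codes[i, j]
        counts[cell + 1] <- counts[cell + 1] + 1
      }
    }
  }
  counts
}

# orbit enumeration by breadth-first closure over the rotation action,
# written against the cell triple directly (no index arithmetic shared with
# the package)
brute_orbit_of <- function(theta, A, B) {
  shift_code <- function(x) ((x * 2) %% 16) + (x >= 8)
  seen <- character(0)
  frontier <- list(c(theta, A, B))
  orbit <- list()
  while (length(frontier) > 0) {
    cell <- frontier[[1]]; frontier <- frontier[-1]
    key <- paste(cell, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    orbit[[length(orbit) + 1]] <- cell
    th <- cell[1] + 90
    nxt <- if (th < 180) c(th, shift_code(cell[2]), shift_code(cell[3]))
           else c(th - 180, shift_code(cell[3]), shift_code(cell[2]))
    frontier[[length(frontier) + 1]] <- nxt
  }
  orbit
}

brute_orbit_count <- function() {
  assigned <- matrix(FALSE, nrow = 4 * 16, ncol = 16)
  n <- 0
  for (theta in c(0, 45, 90, 135)) {
    for (A in 0:15) {
      for (B in 0:15) {
        ti <- match(theta, c(0, 45, 90, 135)) - 1
        if (assigned[ti * 16 + A + 1, B + 1]) next
        n <- n + 1
        for (cell in brute_orbit_of(theta, A, B)) {
          ci <- match(cell[1], c(0, 45, 90, 135)) - 1
          assigned[ci * 16 + cell[2] + 1, cell[3] + 1] <- TRUE
        }
      }
    }
  }
  n
}

# direct (non-separable) Gaussian convolution with symmetric padding
brute_gaussian_blur <- function(img, sigma) {
  rad <- max(1, ceiling(4 * sigma))
  ax <- seq(-rad, rad)
  k2 <- outer(exp(-ax^2 / (2 * sigma^2)), exp(-ax^2 / (2 * sigma^2)))
  k2 <- k2 / sum(k2)
  h <- nrow(img); w <- ncol(img)
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (a in seq_along(ax)) {
        for (b in seq_along(ax)) {
          acc <- acc + k2[a, b] *
            img[reflect(i + ax[a], h), reflect(j + ax[b], w)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# bilinear rotation by an arbitrary angle about the image centre; the caller
# is responsible for staying away from the undefined corners
rotate_bilinear <- function(img, angle_deg) {
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- angle_deg * pi / 180
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      dy <- i - cy; dx <- j - cx
      sy <- cy + dy * cos(th) - dx * sin(th)
      sx <- cx + dy * sin(th) + dx * cos(th)
      i0 <- floor(sy); j0 <- floor(sx)
      if (i0 < 1 || j0 < 1 || i0 + 1 > h || j0 + 1 > w) next
      fy <- sy - i0; fx <- sx - j0
      out[i, j] <- img[i0, j0] * (1 - fy) * (1 - fx) +
        img[i0 + 1, j0] * fy * (1 - fx) +
        img[i0, j0 + 1] * (1 - fy) * fx +
        img[i0 + 1, j0 + 1] * fy * fx
    }
  }
  out
}

# centre crop to side s
center_crop <- function(img, s) {
  r0 <- floor((nrow(img) - s) / 2)
  c0 <- floor((ncol(img) - s) / 2)
  img[r0 + seq_len(s), c0 + seq_len(s)]
}

# gaussian feature clouds for classifier tests: k classes at given centre
# separation (in units of the unit within-class sd)
make_clouds <- function(n_per_class, separation, n_classes = 2, dim = 5,
                        seed = 0) {
  withr::with_seed(seed, {
    centers <- matrix(0, n_classes, dim)
    for (k in seq_len(n_classes)) centers[k, 1] <- (k - 1) * separation
    x <- do.call(rbind, lapply(seq_len(n_classes), function(k) {
      matrix(rnorm(n_per_class * dim), n_per_class, dim) +
        matrix(centers[k, ], n_per_class, dim, byrow = TRUE)
    }))
    labeled_dataset(x, rep(EMA_CLASSES[seq_len(n_classes)],
                           each = n_per_class))
  })
}

random_image <- function(h, w, seed) {
  withr::with_seed(seed, matrix(runif(h * w), h, w))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
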