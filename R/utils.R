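# Shared helpers: intensity clipping, RNG scoping, kernels, resizing,
# thresholds, mask geometry.

clip_intensity <- function(img, lo = 0, hi = 255) {
  img[img < lo] <- lo
  img[img > hi] <- hi
  img
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{expr} with the global RNG seeded to \code{seed} and restores
#' the caller's RNG state afterwards, so seeded package operations never
#' perturb user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Counter-based derived seed so per-colony streams are independent of the
# order colonies are visited.  Arithmetic kept in doubles below 2^53;
# result < 2^31 - 1.
derive_seed <- function(seed, counter) {
  m <- 2147483587
  s <- as.double(seed) %% m
  as.integer((s * 48271 + as.double(counter) * 1009 + 1) %% m)
}

# Odd-sized unit-sum Gaussian kernel.
gaussian_kernel <- function(size, sigma) {
  stopifnot(size >= 1, size %% 2 == 1, sigma > 0)
  h <- (size - 1) / 2
  g <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Reflect-padded 2-D convolution (kernel must have odd dimensions).
convolve_reflect <- function(img, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  hr <- (kr - 1) / 2; hc <- (kc - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rev(seq_len(min(hr, nr))), seq_len(nr),
          nr + 1 - seq_len(min(hr, nr)))
  ci <- c(rev(seq_len(min(hc, nc))), seq_len(nc),
          nc + 1 - seq_len(min(hc, nc)))
  pad <- img[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      w <- kernel[i, j]
      if (w == 0) next
      out <- out + w * pad[(i - 1) + seq_len(nr), (j - 1) + seq_len(nc),
                           drop = FALSE]
    }
  }
  out
}

# Otsu threshold on a [0,255] image (256 bins); returns the threshold value;
# foreground is conventionally the above-threshold (bright) side.
otsu_threshold <- function(img) {
  b <- pmin(pmax(round(as.vector(img)), 0), 255)
  h <- tabulate(b + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  which.max(sigma_b) - 1L
}

# Convert an RGB array (h x w x 3, any of [0,1] or [0,255] scale) or a
# matrix to a grayscale matrix on [0,255] using Rec.601 luminance weights.
as_gray <- function(img) {
  if (is.matrix(img)) {
    g <- img
  } else if (length(dim(img)) == 3) {
    d3 <- dim(img)[3]
    if (d3 >= 3) {
      g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      g <- img[, , 1]
    }
    # single-row/column slices drop dims; restore the matrix shape
    if (is.null(dim(g))) g <- matrix(g, dim(img)[1], dim(img)[2])
  } else {
    stop("unsupported image array with ", length(dim(img)), " dimensions")
  }
  if (max(g) <= 1 + 1e-9) g <- g * 255
  clip_intensity(g)
}

# Bilinear resize; for downscaling a Gaussian pre-blur (sigma ~ 1/(2*factor))
# provides anti-aliasing.
resize_gray <- function(img, factor) {
  stopifnot(factor > 0)
  if (abs(factor - 1) < 1e-12) return(img)
  nr <- nrow(img); nc <- ncol(img)
  nr2 <- max(1L, as.integer(round(nr * factor)))
  nc2 <- max(1L, as.integer(round(nc * factor)))
  if (factor < 1) {
    sigma <- 0.5 / factor
    size <- 2L * as.integer(ceiling(2 * sigma)) + 1L
    img <- convolve_reflect(img, gaussian_kernel(size, sigma))
  }
  # map output pixel centers to input coordinates (align pixel centers)
  rs <- (seq_len(nr2) - 0.5) * nr / nr2 + 0.5
  cs <- (seq_len(nc2) - 0.5) * nc / nc2 + 0.5
  r0 <- pmin(pmax(floor(rs), 1), nr); r1 <- pmin(r0 + 1, nr)
  c0 <- pmin(pmax(floor(cs), 1), nc); c1 <- pmin(c0 + 1, nc)
  wr <- pmin(pmax(rs - r0, 0), 1); wc <- pmin(pmax(cs - c0, 0), 1)
  a <- img[r0, c0, drop = FALSE]; b <- img[r0, c1, drop = FALSE]
  d <- img[r1, c0, drop = FALSE]; e <- img[r1, c1, drop = FALSE]
  W <- outer(1 - wr, 1 - wc); X <- outer(1 - wr, wc)
  Y <- outer(wr, 1 - wc); Z <- outer(wr, wc)
  a * W + b * X + d * Y + e * Z
}

# Intensity-unweighted area centroid of a mask, in 0-based (x, y).
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no centroid")
  c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
}

# Boundary pixels of a mask: object pixels with at least one background
# 4-neighbour (out-of-image counts as background).  Returns x, y columns
# (0-based).
boundary_points <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  inner <- pad[2:(nr + 1), 2:(nc + 1)]
  up    <- pad[1:nr, 2:(nc + 1)]
  down  <- pad[3:(nr + 2), 2:(nc + 1)]
  left  <- pad[2:(nr + 1), 1:nc]
  right <- pad[2:(nr + 1), 3:(nc + 2)]
  b <- inner & !(up & down & left & right)
  idx <- which(b, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

# Euclidean distance transform (distance to nearest TRUE pixel).
distance_transform <- function(mask) {
  sqrt(cpp_sq_edt(mask))
}

# Look up the mask value at continuous 0-based coordinates (nearest pixel).
mask_contains <- function(mask, x, y) {
  r <- round(y) + 1
  c <- round(x) + 1
  ok <- r >= 1 & r <= nrow(mask) & c >= 1 & c <= ncol(mask)
  out <- logical(length(x))
  out[ok] <- mask[cbind(r[ok], c[ok])]
  out
}

# Dice coefficient between two masks.
dice_coefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
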