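# Background removal and contrast conditioning ahead of segmentation:
# rolling-ball top-hat, CLAHE, then border enhancement (above-threshold
# amplification followed by Gaussian blur).

# Ball-shaped (non-flat) structuring element of radius r and height h:
# offsets within radius r, height profile h * sqrt(1 - rho^2 / r^2).
ball_structuring_element <- function(radius, height) {
  stopifnot(radius > 0, height >= 0)
  r <- ceiling(radius)
  d <- -r:r
  dx <- rep(d, times = length(d))
  dy <- rep(d, each = length(d))
  rho2 <- dx^2 + dy^2
  keep <- rho2 <= radius^2
  list(dx = as.integer(dx[keep]), dy = as.integer(dy[keep]),
       h = height * sqrt(pmax(0, 1 - rho2[keep] / radius^2)))
}

#' Rolling-ball top-hat background removal
#'
#' Subtracts the grayscale opening of the image by a ball-shaped
#' structuring element (radius `ball_radius_px`, height `ball_height`),
#' removing slowly varying background while preserving structures smaller
#' than the ball.  The result is non-negative and clipped to `[0, 255]`.
#'
#' @param img grayscale matrix on `[0, 255]`.
#' @param ball_radius_px ball radius in pixels (> 0, smaller than the
#'   image's minimum dimension).
#' @param ball_height ball height in intensity units.
#' @return grayscale matrix on `[0, 255]`.
#' @export
remove_background <- function(img, ball_radius_px = 25, ball_height = 40) {
  stopifnot(is.matrix(img), ball_radius_px > 0)
  if (ball_radius_px > min(dim(img)))
    stop("ball_radius_px (", ball_radius_px,
         ") exceeds the image's minimum dimension (", min(dim(img)), ")")
  se <- ball_structuring_element(ball_radius_px, ball_height)
  opened <- cpp_gray_dilate(cpp_gray_erode(img, se$dx, se$dy, se$h),
                            se$dx, se$dy, se$h)
  clip_intensity(img - opened)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with clipping.  `clip` is a multiple of
#' the mean histogram bin count (OpenCV convention); `Inf` disables
#' clipping, in which case a single-tile configuration degenerates to plain
#' global histogram equalization.  Tile mappings are blended by bilinear
#' interpolation between tile centers.
#'
#' @param img grayscale matrix on `[0, 255]`.
#' @param clip clip limit (> 0 or `Inf`).
#' @param tiles integer vector `(rows, cols)` of the tile grid, each >= 1.
#' @return grayscale matrix on `[0, 255]`.
#' @export
clahe <- function(img, clip = 2.5, tiles = c(8, 8)) {
  stopifnot(is.matrix(img), length(tiles) == 2, all(tiles >= 1))
  cpp_clahe(img, as.integer(tiles[1]), as.integer(tiles[2]), clip)
}

#' Border enhancement: amplify above-threshold pixels, then blur
#'
#' Computes `G * (I + gain * I * H(I - t))` where `H` is the Heaviside step
#' and `G` a unit-sum Gaussian kernel of odd size `border_gauss_size_px`
#' and standard deviation `border_gauss_sigma`, with reflect padding.
#' Pixels strictly above the threshold `t` are amplified by `(1 + gain)`
#' before the blur; the result is clipped to `[0, 255]`.
#'
#' @param img grayscale matrix on `[0, 255]`.
#' @param border_gauss_size_px odd kernel size >= 3.
#' @param border_gauss_sigma Gaussian standard deviation (> 0).
#' @param border_threshold threshold `t` in intensity units.
#' @param border_gain non-negative amplification gain.
#' @return grayscale matrix on `[0, 255]`.
#' @export
enhance_borders <- function(img, border_gauss_size_px = 7,
                            border_gauss_sigma = 2,
                            border_threshold = 128, border_gain = 0.5) {
  stopifnot(is.matrix(img), border_gauss_size_px >= 3,
            border_gauss_size_px %% 2 == 1, border_gauss_sigma > 0,
            border_gain >= 0)
  amp <- img + border_gain * img * (img > border_threshold)
  k <- gaussian_kernel(border_gauss_size_px, border_gauss_sigma)
  clip_intensity(convolve_reflect(amp, k))
}

#' Full preprocessing stage
#'
#' Composition `remove_background` -> `clahe` -> `enhance_borders`, mapping
#' `[0, 255]` into `[0, 255]`.
#'
#' @param img grayscale matrix.
#' @param params named list with the fields of the `preprocess` config
#'   section (see [default_config()]).
#' @return preprocessed grayscale matrix.
#' @export
preprocess_image <- function(img, params = default_config()$preprocess) {
  img <- remove_background(img, params$ball_radius_px, params$ball_height)
  img <- clahe(img, params$clahe_clip, unlist(params$clahe_tiles))
  enhance_borders(img, params$border_gauss_size_px, params$border_gauss_sigma,
                  params$border_threshold, params$border_gain)
}
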