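# Colony segmentation: two-phase region-competition level set (a simplified
# single-contour, two-dimensional interaction model), binary cleanup, and
# watershed splitting into labeled colony objects.
#
# Level-set convention: phi < 0 inside segmented objects, phi > 0 outside,
# zero level = contour.  The regularized Heaviside/Dirac pair is the arctan
# family: H_eps(z) = 1/2 (1 + 2/pi atan(z/eps)), delta_eps(z) =
# eps / (pi (eps^2 + z^2)).

heaviside_eps <- function(z, eps) 0.5 * (1 + (2 / pi) * atan(z / eps))
dirac_eps <- function(z, eps) eps / (pi * (eps^2 + z^2))

#' Level-set evolution parameters
#'
#' @param lambda_in,lambda_out positive fidelity weights of the inside and
#'   outside intensity-variance terms.
#' @param mu_length non-negative contour-length weight (intensity^2 units;
#'   on the `[0, 255]` scale values of a few hundred are a mild smoothing).
#' @param epsilon width of the regularized Heaviside/Dirac pair.
#' @param dt explicit gradient-descent step.
#' @param n_iter number of descent iterations.
#' @param init_mode `"otsu_mask"` (signed distance to the Otsu foreground)
#'   or `"checkerboard"` (sin-product of period 16 px).
#' @return a named list of class `levelset_params`.
#' @export
levelset_params <- function(lambda_in = 1, lambda_out = 1, mu_length = 650,
                            epsilon = 1, dt = 5e-4, n_iter = 200,
                            init_mode = c("otsu_mask", "checkerboard")) {
  init_mode <- match.arg(init_mode)
  stopifnot(lambda_in > 0, lambda_out > 0, mu_length >= 0, epsilon > 0,
            dt > 0, n_iter >= 0)
  structure(list(lambda_in = lambda_in, lambda_out = lambda_out,
                 mu_length = mu_length, epsilon = epsilon, dt = dt,
                 n_iter = as.integer(n_iter), init_mode = init_mode),
            class = "levelset_params")
}

#' Initialize a level-set field
#'
#' `"checkerboard"` gives `phi = sin(pi x / 8) sin(pi y / 8)` (period 16 px,
#' both signs present); `"otsu_mask"` gives the signed Euclidean distance to
#' the Otsu-threshold foreground mask (negative inside, so the zero level
#' starts on the thresholded object rims).
#'
#' @param shape integer `(rows, cols)`.
#' @param init_mode `"checkerboard"` or `"otsu_mask"`.
#' @param preprocessed grayscale matrix (required for `"otsu_mask"`).
#' @return numeric matrix `phi`.
#' @export
initialize_level_set <- function(shape, init_mode = "otsu_mask",
                                 preprocessed = NULL) {
  nr <- shape[1]; nc <- shape[2]
  if (init_mode == "checkerboard") {
    x <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
    y <- matrix(rep(0:(nr - 1), times = nc), nr, nc)
    return(sin(pi * x / 8) * sin(pi * y / 8))
  }
  stopifnot(init_mode == "otsu_mask", is.matrix(preprocessed),
            all(dim(preprocessed) == shape))
  thr <- otsu_threshold(preprocessed)
  mask <- preprocessed > thr
  if (!any(mask) || all(mask))
    stop("Otsu initialization produced a degenerate (empty or full) mask")
  signed_distance(mask)
}

# Signed Euclidean distance to the mask boundary: negative inside.
signed_distance <- function(mask) {
  d_in <- distance_transform(!mask)   # distance to nearest background px
  d_out <- distance_transform(mask)   # distance to nearest object px
  out <- d_out
  out[mask] <- -d_in[mask]
  out
}

#' Regularized region means
#'
#' `c1` is the image mean weighted by `H_eps(-phi)` (inside), `c2` the mean
#' weighted by `H_eps(phi)` (outside).
#'
#' @param img grayscale matrix.
#' @param phi level-set field of the same shape.
#' @param epsilon regularization width.
#' @return numeric vector `c(c1, c2)`.
#' @export
region_means <- function(img, phi, epsilon = 1) {
  stopifnot(all(dim(img) == dim(phi)))
  w_in <- heaviside_eps(-phi, epsilon)
  w_out <- heaviside_eps(phi, epsilon)
  s_in <- sum(w_in); s_out <- sum(w_out)
  if (s_in <= 1e-12) stop("inside region has zero total weight")
  if (s_out <= 1e-12) stop("outside region has zero total weight")
  c(c1 = sum(img * w_in) / s_in, c2 = sum(img * w_out) / s_out)
}

#' Evolve the segmentation level set
#'
#' Runs `n_iter` explicit gradient-descent steps of the two-phase energy
#' \deqn{E = \lambda_{in} \int |I - c_1|^2 H(-\phi) +
#'       \lambda_{out} \int |I - c_2|^2 H(\phi) +
#'       \mu \int |\nabla H(\phi)|}
#' with update `phi <- phi + dt * delta_eps(phi) * (lambda_in (I-c1)^2 -
#' lambda_out (I-c2)^2 + mu * curvature(phi))`, recomputing the region
#' means each iteration.  Curvature is `div(grad phi / |grad phi|)` with the
#' gradient magnitude floored at 1e-8; `phi` is clipped to `[-50, 50]` each
#' step instead of being reinitialized.
#'
#' @param img grayscale matrix.
#' @param phi0 initial level-set field.
#' @param params a [levelset_params()].
#' @return the evolved `phi`.
#' @export
evolve_level_set <- function(img, phi0, params = levelset_params()) {
  stopifnot(inherits(params, "levelset_params"),
            all(dim(img) == dim(phi0)))
  cpp_evolve_level_set(img, phi0, params$lambda_in, params$lambda_out,
                       params$mu_length, params$epsilon, params$dt,
                       params$n_iter)
}

#' Discrete level-set energy
#'
#' Evaluates the discretized two-phase energy at the current `phi` (with
#' region means recomputed from `phi`); used to monitor descent.
#'
#' @inheritParams evolve_level_set
#' @return a scalar energy value.
#' @export
level_set_energy <- function(img, phi, params = levelset_params()) {
  cc <- region_means(img, phi, params$epsilon)
  H <- heaviside_eps(phi, params$epsilon)
  data_term <- params$lambda_in * sum((img - cc[1])^2 * (1 - H)) +
    params$lambda_out * sum((img - cc[2])^2 * H)
  nr <- nrow(phi); nc <- ncol(phi)
  cp <- pmin(seq_len(nc) + 1, nc); cm <- pmax(seq_len(nc) - 1, 1)
  rp <- pmin(seq_len(nr) + 1, nr); rm <- pmax(seq_len(nr) - 1, 1)
  denc <- matrix(cp - cm, nr, nc, byrow = TRUE)
  denr <- matrix(rp - rm, nr, nc)
  px <- (phi[, cp] - phi[, cm]) / pmax(denc, 1)
  py <- (phi[rp, ] - phi[rm, ]) / pmax(denr, 1)
  length_term <- params$mu_length *
    sum(dirac_eps(phi, params$epsilon) * sqrt(px^2 + py^2))
  data_term + length_term
}

#' Binarize a level-set field
#'
#' @param phi level-set field.
#' @return logical mask, `TRUE` exactly where `phi < 0`.
#' @export
binarize <- function(phi) phi < 0

#' Morphological cleanup of the segmentation mask
#'
#' Dilation by a flat disk of radius `disk_radius_px`, hole filling (a hole
#' is background not 4-connected to the image border), then removal of
#' connected components with area below `min_area_px`.
#'
#' @param mask logical matrix.
#' @param disk_radius_px dilation radius (>= 0; 0 skips the dilation).
#' @param min_area_px minimal surviving component area in pixels.
#' @return cleaned logical mask.
#' @export
enhance_binary <- function(mask, disk_radius_px = 2, min_area_px = 500) {
  stopifnot(is.matrix(mask), disk_radius_px >= 0)
  m <- mask
  if (disk_radius_px > 0) {
    se <- ball_structuring_element(disk_radius_px, 0)
    m <- cpp_gray_dilate(m * 1.0, se$dx, se$dy, se$h) > 0.5
  }
  m <- cpp_fill_holes(m)
  lab <- cpp_label(m, 8L)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    small <- which(areas < min_area_px)
    if (length(small)) m[lab %in% small] <- FALSE
  }
  m
}

# Construct a colony object from one labeled component.
make_colony <- function(mask, label) {
  idx <- which(mask, arr.ind = TRUE)
  xs <- idx[, 2] - 1; ys <- idx[, 1] - 1
  cx <- mean(xs); cy <- mean(ys)
  mu20 <- mean((xs - cx)^2); mu02 <- mean((ys - cy)^2)
  mu11 <- mean((xs - cx) * (ys - cy))
  # ellipse-equivalent major axis from second-order central moments
  common <- sqrt(pmax(0, (mu20 - mu02)^2 + 4 * mu11^2))
  l1 <- (mu20 + mu02 + common) / 2
  structure(list(
    label = as.integer(label),
    mask = mask,
    area_px = nrow(idx),
    centroid = c(x = cx, y = cy),
    boundary = boundary_points(mask),
    major_axis_px = 4 * sqrt(l1),
    bbox = c(x_min = min(xs), y_min = min(ys),
             x_max = max(xs), y_max = max(ys))
  ), class = "colony")
}

#' @export
print.colony <- function(x, ...) {
  cat(sprintf(
    "<colony %d> area %d px, centroid (%.1f, %.1f), major axis %.1f px\n",
    x$label, x$area_px, x$centroid["x"], x$centroid["y"], x$major_axis_px))
  invisible(x)
}

#' Split a cleaned mask into individual colonies
#'
#' Marker-controlled watershed on the negated Euclidean distance transform
#' of the mask.  Markers are the regional maxima of the distance transform
#' after h-maxima suppression of depth `h_merge` (shallow maxima closer
#' than `h_merge` in distance value are merged, preventing
#' over-segmentation of single colonies with rough distance landscapes).
#'
#' @param mask logical matrix (typically from [enhance_binary()]).
#' @param h_merge h-maxima suppression depth in pixels (default 4).
#' @return a list of `colony` objects (empty for an empty mask); their
#'   masks partition the input mask.
#' @export
split_colonies <- function(mask, h_merge = 4) {
  if (!any(mask)) return(list())
  edt <- distance_transform(!mask)
  edt[!mask] <- 0
  recon <- cpp_reconstruct_dilate(pmax(edt - h_merge, 0), edt)
  maxima <- cpp_regional_maxima(recon, mask)
  markers <- cpp_label(maxima, 8L)
  lab <- cpp_watershed(edt, markers, mask)
  labs <- sort(unique(lab[lab > 0]))
  lapply(seq_along(labs), function(i) {
    make_colony(lab == labs[i], i)
  })
}

#' Segment colonies in a preprocessed image
#'
#' Convenience composition: level-set initialization, evolution,
#' binarization, binary cleanup, watershed splitting.
#'
#' @param img preprocessed grayscale matrix.
#' @param ls_params a [levelset_params()].
#' @param disk_radius_px,min_area_px,h_merge cleanup/splitting parameters,
#'   see [enhance_binary()] and [split_colonies()].
#' @return a list of `colony` objects.
#' @export
segment_colonies <- function(img, ls_params = levelset_params(),
                             disk_radius_px = 2, min_area_px = 500,
                             h_merge = 4) {
  phi0 <- initialize_level_set(dim(img), ls_params$init_mode, img)
  phi <- evolve_level_set(img, phi0, ls_params)
  mask <- enhance_binary(binarize(phi), disk_radius_px, min_area_px)
  split_colonies(mask, h_merge)
}
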