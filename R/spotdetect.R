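# Marked-cell detection: Perona-Malik diffusion prefiltering followed by an
# Orientation Matching transform over a bank of annulus templates.
#
# Orientation Matching correlates the image's *normalized* gradient field
# with an artificial annulus gradient whose every point carries a radial
# unit vector scaled by 1/rho (rho = distance from the annulus center), so
# circular rims with radius inside the template band produce strong peaks
# at their centers regardless of contrast.

#' Detection parameters
#'
#' @param diffusion_iters,diffusion_kappa,diffusion_dt Perona-Malik
#'   prefilter settings; `diffusion_dt` must be <= 0.25 for stability of
#'   the explicit scheme.
#' @param r1,r2 inner/outer radius (pixels) of the annulus band, 0 < r1 < r2.
#' @param radius_step step `s` of the sub-annulus bank; responses are
#'   maximized over sub-annuli `[r, r + s]` for `r = r1, r1 + s, ...`.
#' @param polarity `"dark"` for spots darker than their surroundings
#'   (chromogenic staining), `"bright"` for fluorescence-like spots.
#' @param score_threshold minimal orientation-matching score of a
#'   detection.
#' @param min_separation_px non-maximum-suppression radius; defaults to
#'   `r1` (two true cells cannot overlap more than their minimal radius).
#' @param gradient_floor gradient magnitudes below this are treated as
#'   zero before normalization (the normalized gradient is undefined at
#'   zero gradient).
#' @return a named list of class `detect_params`.
#' @export
detect_params <- function(diffusion_iters = 10, diffusion_kappa = 50,
                          diffusion_dt = 0.2, r1 = 6, r2 = 9,
                          radius_step = 1,
                          polarity = c("dark", "bright"),
                          score_threshold = 4, min_separation_px = NULL,
                          gradient_floor = 1.0) {
  polarity <- match.arg(polarity)
  stopifnot(diffusion_iters >= 0, diffusion_kappa > 0,
            diffusion_dt > 0, diffusion_dt <= 0.25,
            r1 > 0, r2 > r1, radius_step > 0, gradient_floor >= 0)
  if (is.null(min_separation_px)) min_separation_px <- r1
  structure(list(diffusion_iters = as.integer(diffusion_iters),
                 diffusion_kappa = diffusion_kappa,
                 diffusion_dt = diffusion_dt,
                 r1 = r1, r2 = r2, radius_step = radius_step,
                 polarity = polarity, score_threshold = score_threshold,
                 min_separation_px = min_separation_px,
                 gradient_floor = gradient_floor),
            class = "detect_params")
}

#' Perona-Malik anisotropic diffusion
#'
#' Edge-preserving smoothing with exponential conductance
#' `g(|grad I|) = exp(-(|grad I| / kappa)^2)`, explicit 4-neighbour flux
#' scheme with zero-flux (Neumann) boundaries.  The pairwise-antisymmetric
#' fluxes conserve the global mean exactly; constant images are fixed
#' points.
#'
#' @param img grayscale matrix.
#' @param iters number of diffusion steps.
#' @param kappa conductance scale (intensity units): gradients well below
#'   `kappa` diffuse freely, gradients well above are preserved.
#' @param dt time step (<= 0.25).
#' @return diffused grayscale matrix.
#' @export
nonlinear_diffusion <- function(img, iters = 10, kappa = 50, dt = 0.2) {
  stopifnot(is.matrix(img), iters >= 0, kappa > 0, dt > 0, dt <= 0.25)
  if (iters == 0) return(img)
  cpp_perona_malik(img, as.integer(iters), kappa, dt)
}

#' Image gradient
#'
#' Central differences in the interior, one-sided differences at the
#' borders.  `gx` is the derivative along columns (x), `gy` along rows (y).
#'
#' @param img grayscale matrix.
#' @return list with matrices `gx`, `gy`.
#' @export
image_gradient <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  cp <- pmin(seq_len(nc) + 1, nc); cm <- pmax(seq_len(nc) - 1, 1)
  rp <- pmin(seq_len(nr) + 1, nr); rm <- pmax(seq_len(nr) - 1, 1)
  gx <- (img[, cp, drop = FALSE] - img[, cm, drop = FALSE]) /
    matrix(pmax(cp - cm, 1), nr, nc, byrow = TRUE)
  gy <- (img[rp, , drop = FALSE] - img[rm, , drop = FALSE]) /
    matrix(pmax(rp - rm, 1), nr, nc)
  list(gx = gx, gy = gy)
}

#' Build an annulus gradient template
#'
#' Enumerates all integer offsets `(dx, dy)` with `r1 <= sqrt(dx^2 + dy^2)
#' <= r2`; each offset carries the outward radial weight
#' `(dx, dy) / rho^2`, i.e. a unit radial direction scaled by `1 / rho`.
#' By radial antisymmetry the weight vectors sum to zero.
#'
#' @param r1,r2 band radii, 0 < r1 < r2.
#' @return list with integer vectors `dx`, `dy` and numeric weights
#'   `wx`, `wy`, plus `r1`, `r2`.
#' @export
build_annulus_template <- function(r1, r2) {
  stopifnot(r1 > 0, r2 > r1)
  r <- ceiling(r2)
  d <- -r:r
  dx <- rep(d, times = length(d))
  dy <- rep(d, each = length(d))
  rho <- sqrt(dx^2 + dy^2)
  keep <- rho >= r1 & rho <= r2
  if (!any(keep))
    stop("annulus band [", r1, ", ", r2, "] contains no integer grid points")
  dx <- dx[keep]; dy <- dy[keep]; rho <- rho[keep]
  list(dx = as.integer(dx), dy = as.integer(dy),
       wx = dx / rho^2, wy = dy / rho^2, r1 = r1, r2 = r2)
}

# Sub-annulus bands [r, r + s] covering [r1, r2].
annulus_bands <- function(r1, r2, s) {
  starts <- seq(r1, r2, by = s)
  starts <- starts[starts + s <= r2 + 1e-9]
  if (length(starts) == 0) return(cbind(lo = r1, hi = r2))
  cbind(lo = starts, hi = starts + s)
}

#' Orientation Matching transform
#'
#' Normalizes the image gradient (magnitudes below `gradient_floor` give
#' the zero vector), then for each sub-annulus `[r, r + s]` of the radius
#' band computes the per-pixel correlation with the annulus template; the
#' score map is the per-pixel maximum over sub-annuli and `best_radius`
#' the midpoint of the winning band.  The sign is chosen so that spots of
#' the configured polarity score positively (a dark disc has an outward
#' rim gradient, a bright disc an inward one; the two polarities give
#' exactly opposite scores).
#'
#' @param img grayscale matrix (typically already diffused).
#' @param params a [detect_params()].
#' @return list of class `score_map` with matrices `score` and
#'   `best_radius`, and the band matrix `bands`.
#' @export
orientation_matching <- function(img, params = detect_params()) {
  stopifnot(inherits(params, "detect_params"))
  g <- image_gradient(img)
  mag <- sqrt(g$gx^2 + g$gy^2)
  keep <- mag >= max(params$gradient_floor, 1e-300)
  nx <- matrix(0, nrow(img), ncol(img)); ny <- nx
  nx[keep] <- g$gx[keep] / mag[keep]
  ny[keep] <- g$gy[keep] / mag[keep]
  sgn <- if (params$polarity == "dark") 1 else -1
  bands <- annulus_bands(params$r1, params$r2, params$radius_step)
  score <- matrix(-Inf, nrow(img), ncol(img))
  best <- matrix(NA_real_, nrow(img), ncol(img))
  for (b in seq_len(nrow(bands))) {
    tpl <- build_annulus_template(bands[b, 1], bands[b, 2])
    resp <- sgn * cpp_om_response(nx, ny, tpl$dx, tpl$dy, tpl$wx, tpl$wy)
    upd <- resp > score
    score[upd] <- resp[upd]
    best[upd] <- mean(bands[b, ])
  }
  structure(list(score = score, best_radius = best, bands = bands),
            class = "score_map")
}

#' Extract spot detections from a score map
#'
#' Local maxima of the score map at or above `score_threshold` undergo
#' greedy non-maximum suppression within `min_separation_px` (higher score
#' wins; ties broken by smaller row, then smaller column).  Survivors
#' outside every colony mask are discarded; the rest are assigned the
#' label of the colony containing their center.
#'
#' @param om a `score_map` from [orientation_matching()].
#' @param colonies list of `colony` objects (may be empty, in which case
#'   no detection survives the containment filter unless
#'   `keep_unassigned = TRUE`).
#' @param params a [detect_params()].
#' @param keep_unassigned keep detections outside all colonies with
#'   `colony_id = NA` (used by phantom-level tests).
#' @return data frame with columns `colony_id`, `x`, `y`, `radius_px`,
#'   `score` (0-based pixel coordinates).
#' @export
detect_spots <- function(om, colonies, params = detect_params(),
                         keep_unassigned = FALSE) {
  peaks <- cpp_local_maxima(om$score, params$score_threshold)
  idx <- which(peaks, arr.ind = TRUE)
  empty <- data.frame(colony_id = integer(), x = numeric(), y = numeric(),
                      radius_px = numeric(), score = numeric())
  if (nrow(idx) == 0) return(empty)
  cand <- data.frame(x = idx[, 2] - 1, y = idx[, 1] - 1,
                     score = om$score[idx],
                     radius_px = om$best_radius[idx])
  cand <- cand[order(-cand$score, cand$y, cand$x), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d2 <- (cand$x[j] - cand$x[i])^2 + (cand$y[j] - cand$y[i])^2
      keep[j[d2 < params$min_separation_px^2]] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  lab <- rep(NA_integer_, nrow(cand))
  for (col in colonies) {
    inside <- mask_contains(col$mask, cand$x, cand$y)
    lab[inside & is.na(lab)] <- col$label
  }
  out <- data.frame(colony_id = lab, x = cand$x, y = cand$y,
                    radius_px = cand$radius_px, score = cand$score)
  if (!keep_unassigned) out <- out[!is.na(out$colony_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect marked cells in a grayscale image
#'
#' Convenience composition: Perona-Malik diffusion, Orientation Matching,
#' peak extraction and colony assignment.
#'
#' @param img grayscale matrix.
#' @param colonies list of `colony` objects.
#' @param params a [detect_params()].
#' @param keep_unassigned see [detect_spots()].
#' @return detections data frame, see [detect_spots()].
#' @export
detect_cells <- function(img, colonies, params = detect_params(),
                         keep_unassigned = FALSE) {
  sm <- nonlinear_diffusion(img, params$diffusion_iters,
                            params$diffusion_kappa, params$diffusion_dt)
  om <- orientation_matching(sm, params)
  detect_spots(om, colonies, params, keep_unassigned)
}
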