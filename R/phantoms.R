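# Synthetic colony phantoms: images, point patterns and ground truth with
# controllable spatial structure, so every downstream stage of the pipeline
# is testable without microscope data.
#
# Colonies are rendered as rotated ellipses (real colonies are quasi-circular
# but not perfect circles) with a soft ~1.5 px rim; marked cells are filled
# discs of configurable polarity with the same soft edge, so gradient-based
# detection sees realistic rims rather than trivially hard steps.

#' Specification of a synthetic colony phantom
#'
#' Collects every knob of the phantom generator and validates the
#' containment invariants: spot radii must fit strictly inside the smallest
#' admissible colony and colonies may neither overlap nor touch the image
#' border.
#'
#' @param image_height_px,image_width_px image size in pixels.
#' @param n_colonies number of colonies to place.
#' @param colony_radius_range_px range (min, max) of the colony semi-major
#'   axis in pixels.
#' @param colony_eccentricity_max maximal ellipse eccentricity in `[0, 1)`.
#' @param n_spots_per_colony marked cells rendered per colony.
#' @param spot_radius_range_px range of spot radii (pixels); must lie
#'   strictly below the lower colony radius bound.
#' @param spot_polarity `"dark"` (chromogenic staining on a brighter colony)
#'   or `"bright"` (fluorescence-like).
#' @param placement spatial law of spot centers: `"uniform"`,
#'   `"inner_clustered"` or `"edge_biased"`.
#' @param placement_concentration positive rate of the truncated-exponential
#'   placement weight `exp(-concentration * delta)` (inner) or
#'   `exp(-concentration * (1 - delta))` (edge).
#' @param background_level,colony_level intensities in `[0, 255]`.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param illumination_gradient peak-to-peak amplitude of a linear
#'   illumination tilt across the image diagonal (intensity units).
#' @param seed integer seed; the generator is bitwise deterministic in it.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_height_px = 480L,
                         image_width_px = 640L,
                         n_colonies = 3L,
                         colony_radius_range_px = c(50, 85),
                         colony_eccentricity_max = 0.6,
                         n_spots_per_colony = 10L,
                         spot_radius_range_px = c(6, 9),
                         spot_polarity = c("dark", "bright"),
                         placement = c("uniform", "inner_clustered",
                                       "edge_biased"),
                         placement_concentration = 3,
                         background_level = 40,
                         colony_level = 160,
                         noise_sd = 3,
                         illumination_gradient = 0,
                         seed = 1L) {
  spot_polarity <- match.arg(spot_polarity)
  placement <- match.arg(placement)
  stopifnot(image_height_px >= 16, image_width_px >= 16,
            n_colonies >= 1,
            length(colony_radius_range_px) == 2,
            colony_radius_range_px[1] > 0,
            diff(colony_radius_range_px) >= 0,
            colony_eccentricity_max >= 0, colony_eccentricity_max < 1,
            n_spots_per_colony >= 0,
            length(spot_radius_range_px) == 2,
            spot_radius_range_px[1] > 0,
            diff(spot_radius_range_px) >= 0,
            placement_concentration > 0,
            background_level >= 0, background_level <= 255,
            colony_level >= 0, colony_level <= 255,
            noise_sd >= 0, illumination_gradient >= 0)
  if (spot_radius_range_px[2] >= colony_radius_range_px[1])
    stop("spot_radius_range_px must lie strictly inside the lower colony ",
         "radius bound (spots must fit inside colonies)")
  structure(list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    n_colonies = as.integer(n_colonies),
    colony_radius_range_px = as.numeric(colony_radius_range_px),
    colony_eccentricity_max = colony_eccentricity_max,
    n_spots_per_colony = as.integer(n_spots_per_colony),
    spot_radius_range_px = as.numeric(spot_radius_range_px),
    spot_polarity = spot_polarity,
    placement = placement,
    placement_concentration = placement_concentration,
    background_level = background_level,
    colony_level = colony_level,
    noise_sd = noise_sd,
    illumination_gradient = illumination_gradient,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Sample the normalized radial coordinate u in [0, u_max] for a spot center.
# Area element makes the uniform-in-ellipse density proportional to u; the
# clustered/edge modes multiply the truncated-exponential weight.
sample_radial <- function(n, placement, concentration, u_max) {
  grid <- seq(0, u_max, length.out = 2048)
  w <- switch(placement,
              uniform = rep(1, length(grid)),
              inner_clustered = exp(-concentration * grid),
              edge_biased = exp(-concentration * (1 - grid)))
  dens <- grid * w
  cdf <- cumsum(dens)
  if (cdf[length(cdf)] <= 0) return(rep(0, n))
  cdf <- cdf / cdf[length(cdf)]
  u <- runif(n)
  grid[findInterval(u, cdf) + 1]
}

#' Generate a synthetic colony image with ground truth
#'
#' Renders `n_colonies` non-overlapping soft-edged ellipses on a flat
#' background, places marked-cell discs inside each one under the configured
#' spatial law, then adds the illumination tilt and Gaussian noise last and
#' clips to `[0, 255]`.  Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @return a list with `image` (numeric matrix on `[0, 255]`) and `truth`,
#'   itself a list of two data frames: `colonies` (`colony_id`, `center_x`,
#'   `center_y`, `semi_major_px`, `semi_minor_px`, `rotation_rad`) and
#'   `spots` (`colony_id`, `x`, `y`, `radius_px`, `delta`), coordinates
#'   0-based with x = column.
#' @export
make_colony_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    h <- spec$image_height_px; w <- spec$image_width_px
    img <- matrix(spec$background_level, h, w)
    placed <- list()
    for (k in seq_len(spec$n_colonies)) {
      ok <- FALSE
      for (attempt in seq_len(1000L)) {
        a <- runif(1, spec$colony_radius_range_px[1],
                   spec$colony_radius_range_px[2])
        ecc <- runif(1, 0, spec$colony_eccentricity_max)
        b <- a * sqrt(1 - ecc^2)
        th <- runif(1, 0, pi)
        if (2 * (a + 3) >= w - 1 || 2 * (a + 3) >= h - 1)
          next  # colony cannot fit clear of the border at this size
        cx <- runif(1, a + 3, w - 1 - a - 3)
        cy <- runif(1, a + 3, h - 1 - a - 3)
        clash <- FALSE
        for (p in placed) {
          if (sqrt((cx - p$cx)^2 + (cy - p$cy)^2) < a + p$a + 6) {
            clash <- TRUE; break
          }
        }
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok)
        stop("colony placement failed after 1000 attempts: ",
             "colonies cannot fit without overlap inside the image ",
             "(reduce n_colonies or colony_radius_range_px)")
      placed[[k]] <- list(cx = cx, cy = cy, a = a, b = b, th = th)
    }
    spot_rows <- list()
    spot_level <- if (spec$spot_polarity == "dark")
      max(0, spec$colony_level - 110) else min(255, spec$colony_level + 80)
    for (k in seq_along(placed)) {
      p <- placed[[k]]
      # render the colony ellipse with a soft rim
      x0 <- max(0, floor(p$cx - p$a - 3)); x1 <- min(w - 1, ceiling(p$cx + p$a + 3))
      y0 <- max(0, floor(p$cy - p$a - 3)); y1 <- min(h - 1, ceiling(p$cy + p$a + 3))
      xs <- x0:x1; ys <- y0:y1
      dx <- outer(rep(1, length(ys)), xs - p$cx)
      dy <- outer(ys - p$cy, rep(1, length(xs)))
      xr <- dx * cos(p$th) + dy * sin(p$th)
      yr <- -dx * sin(p$th) + dy * cos(p$th)
      u <- sqrt((xr / p$a)^2 + (yr / p$b)^2)
      sdist <- (1 - u) * p$b              # approximate inward signed distance
      alpha <- pmin(pmax((sdist + 0.75) / 1.5, 0), 1)
      sub <- img[ys + 1, xs + 1, drop = FALSE]
      img[ys + 1, xs + 1] <- sub + alpha * (spec$colony_level - sub)
      # spots: sequential rejection keeps cells from overlapping (up to a
      # 200-attempt budget per spot; dense patterns fall back to accepting
      # the last draw, which only matters far above realistic densities)
      n_s <- spec$n_spots_per_colony
      if (n_s > 0) {
        rad <- runif(n_s, spec$spot_radius_range_px[1],
                     spec$spot_radius_range_px[2])
        u_max <- pmax(0, 1 - (rad + 5) / p$b)
        us <- numeric(n_s); psi <- numeric(n_s)
        sx <- numeric(n_s); sy <- numeric(n_s)
        for (i in seq_len(n_s)) {
          for (att in seq_len(200L)) {
            u_i <- sample_radial(1, spec$placement,
                                 spec$placement_concentration, u_max[i])
            psi_i <- runif(1, 0, 2 * pi)
            ex <- p$a * u_i * cos(psi_i); ey <- p$b * u_i * sin(psi_i)
            x_i <- p$cx + ex * cos(p$th) - ey * sin(p$th)
            y_i <- p$cy + ex * sin(p$th) + ey * cos(p$th)
            if (i == 1) break
            j <- seq_len(i - 1)
            sep <- sqrt((sx[j] - x_i)^2 + (sy[j] - y_i)^2)
            if (all(sep >= rad[j] + rad[i] + 6)) break
          }
          us[i] <- u_i; psi[i] <- psi_i; sx[i] <- x_i; sy[i] <- y_i
        }
        for (i in seq_len(n_s)) {
          sx0 <- max(0, floor(sx[i] - rad[i] - 2))
          sx1 <- min(w - 1, ceiling(sx[i] + rad[i] + 2))
          sy0 <- max(0, floor(sy[i] - rad[i] - 2))
          sy1 <- min(h - 1, ceiling(sy[i] + rad[i] + 2))
          xs2 <- sx0:sx1; ys2 <- sy0:sy1
          rho <- sqrt(outer(rep(1, length(ys2)), (xs2 - sx[i])^2) +
                      outer((ys2 - sy[i])^2, rep(1, length(xs2))))
          al <- pmin(pmax((rad[i] + 0.75 - rho) / 1.5, 0), 1)
          sub <- img[ys2 + 1, xs2 + 1, drop = FALSE]
          img[ys2 + 1, xs2 + 1] <- sub + al * (spot_level - sub)
        }
        spot_rows[[k]] <- data.frame(colony_id = k, x = sx, y = sy,
                                     radius_px = rad, delta = us)
      }
    }
    if (spec$illumination_gradient > 0) {
      xn <- (col(img) - 1) / (w - 1)
      yn <- (row(img) - 1) / (h - 1)
      img <- img + spec$illumination_gradient * ((xn + yn) / 2 - 0.5)
    }
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
    img <- clip_intensity(img)
    colonies <- do.call(rbind, lapply(seq_along(placed), function(k) {
      p <- placed[[k]]
      data.frame(colony_id = k, center_x = p$cx, center_y = p$cy,
                 semi_major_px = p$a, semi_minor_px = p$b,
                 rotation_rad = p$th)
    }))
    spots <- if (length(spot_rows)) do.call(rbind, spot_rows) else
      data.frame(colony_id = integer(), x = numeric(), y = numeric(),
                 radius_px = numeric(), delta = numeric())
    list(image = img, truth = list(colonies = colonies, spots = spots))
  })
}

#' Sample a spatial point pattern on a colony mask
#'
#' Draws `n_points` pixel-center points on `colony_mask`.  `"uniform"`
#' samples mask pixels uniformly; `"inner_clustered"` weights pixels by
#' `exp(-concentration * delta)` and `"edge_biased"` by
#' `exp(-concentration * (1 - delta))`, where `delta` is the normalized
#' centroid distance of the pixel (0 at the centroid, 1 at the edge).
#'
#' @param colony_mask logical matrix, non-empty.
#' @param n_points number of points (>= 1).
#' @param placement `"uniform"`, `"inner_clustered"` or `"edge_biased"`.
#' @param concentration positive weight rate.
#' @param seed integer seed.
#' @param dmap optional precomputed per-pixel normalized-distance map of
#'   the mask (from the internal \code{delta_map}); recomputed when
#'   \code{NULL}.  Passing it avoids repeated geometry work in repeated
#'   simulation runs on the same mask.
#' @return an `n_points` x 2 matrix with columns `x`, `y` (0-based pixel
#'   coordinates).
#' @export
make_point_phantom <- function(colony_mask, n_points,
                               placement = c("uniform", "inner_clustered",
                                             "edge_biased"),
                               concentration = 3, seed = 1L, dmap = NULL) {
  placement <- match.arg(placement)
  if (n_points < 1) stop("n_points must be >= 1")
  idx <- which(colony_mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("colony_mask is empty")
  if (placement == "uniform" || nrow(idx) == 1) {
    wgt <- rep(1, nrow(idx))
  } else {
    if (is.null(dmap)) dmap <- delta_map(colony_mask)
    dl <- dmap[idx]
    wgt <- if (placement == "inner_clustered") exp(-concentration * dl)
           else exp(-concentration * (1 - dl))
  }
  pick <- with_seed(seed,
    sample.int(nrow(idx), n_points, replace = TRUE, prob = wgt))
  cbind(x = idx[pick, 2] - 1, y = idx[pick, 1] - 1)
}

#' Convert phantom ground truth into colony objects
#'
#' Rasterizes each ground-truth ellipse into a mask and builds the same
#' `colony` objects the segmentation stage produces, so detection and
#' location statistics can be exercised against exact colony geometry
#' without running the segmenter.
#'
#' @param truth the `truth` element of [make_colony_phantom()] output.
#' @param dim integer `(rows, cols)` of the phantom image.
#' @return a list of `colony` objects labeled like the ground truth.
#' @export
truth_to_colonies <- function(truth, dim) {
  xs <- matrix(rep(0:(dim[2] - 1), each = dim[1]), dim[1], dim[2])
  ys <- matrix(rep(0:(dim[1] - 1), times = dim[2]), dim[1], dim[2])
  lapply(seq_len(nrow(truth$colonies)), function(k) {
    tc <- truth$colonies[k, ]
    dx <- xs - tc$center_x; dy <- ys - tc$center_y
    xr <- dx * cos(tc$rotation_rad) + dy * sin(tc$rotation_rad)
    yr <- -dx * sin(tc$rotation_rad) + dy * cos(tc$rotation_rad)
    mask <- (xr / tc$semi_major_px)^2 + (yr / tc$semi_minor_px)^2 <= 1
    col <- make_colony(mask, tc$colony_id)
    col
  })
}
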