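# Shared fixture builders (all geometry 0-based, x = column, y = row).

disc_mask <- function(nr, nc, cx, cy, R) {
  m <- matrix(FALSE, nr, nc)
  sqrt((col(m) - 1 - cx)^2 + (row(m) - 1 - cy)^2) <= R
}

ellipse_mask <- function(nr, nc, cx, cy, a, b, theta = 0) {
  m <- matrix(FALSE, nr, nc)
  dx <- col(m) - 1 - cx; dy <- row(m) - 1 - cy
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

# Soft-edged disc rendered onto an existing image (same ramp the phantom
# generator uses).
render_soft_disc <- function(img, cx, cy, r, level, edge = 1.5) {
  rho <- sqrt((col(img) - 1 - cx)^2 + (row(img) - 1 - cy)^2)
  alpha <- pmin(pmax((r + edge / 2 - rho) / edge, 0), 1)
  img + alpha * (level - img)
}

# The standard detection phantom of the acceptance suite: 3 colonies,
# 4 in-band spots each, optionally noise-free.
detection_phantom_spec <- function(seed, noise_sd = 0) {
  phantom_spec(seed = seed, noise_sd = noise_sd, n_spots_per_colony = 4,
               image_height_px = 360, image_width_px = 480,
               colony_radius_range_px = c(45, 70))
}

# A colony object for a plain disc mask.
disc_colony <- function(R = 40, pad = 6, label = 1L) {
  n <- as.integer(2 * (R + pad) + 1)
  colonyspot:::make_colony(disc_mask(n, n, R + pad, R + pad, R), label)
}
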