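# Diffusion prefilter, gradient, annulus templates, Orientation Matching,
# peak extraction.

test_that("diffusion fixes constants and conserves the global mean", {
  img <- matrix(42.5, 30, 30)
  expect_equal(nonlinear_diffusion(img, 25, 10, 0.2), img)
  set.seed(11)
  r <- matrix(runif(50 * 40, 0, 255), 50, 40)
  out <- nonlinear_diffusion(r, 40, 20, 0.25)
  expect_lt(abs(mean(out) - mean(r)) / mean(r), 1e-9)
  expect_error(nonlinear_diffusion(r, 10, 10, 0.3), "dt")
})

test_that("diffusion denoises while preserving a strong step edge", {
  set.seed(12)
  img <- matrix(50, 40, 60); img[, 31:60] <- 150   # step amplitude 100
  img <- img + matrix(rnorm(40 * 60, 0, 5), 40, 60)
  out <- nonlinear_diffusion(img, 20, 10, 0.2)
  v0 <- var(as.vector(img[, 5:25])); v1 <- var(as.vector(out[, 5:25]))
  expect_gte(1 - v1 / v0, 0.8)
  amp0 <- mean(img[, 35:55]) - mean(img[, 5:25])
  amp1 <- mean(out[, 35:55]) - mean(out[, 5:25])
  expect_lte(abs(amp0 - amp1) / amp0, 0.1)
})

test_that("image gradient is exact on linear and quadratic fields", {
  x <- matrix(0:6, 7, 7, byrow = TRUE)   # varies along columns
  y <- matrix(0:6, 7, 7)                 # varies along rows
  g <- image_gradient(3 * x + 4 * y)
  expect_equal(g$gx[2:6, 2:6], matrix(3, 5, 5))
  expect_equal(g$gy[2:6, 2:6], matrix(4, 5, 5))
  g0 <- image_gradient(matrix(7, 5, 5))
  expect_equal(g0$gx, matrix(0, 5, 5))
  expect_equal(g0$gy, matrix(0, 5, 5))
  gq <- image_gradient(x^2)          # central differences exact for x^2
  expect_equal(gq$gx[, 2:6], 2 * x[, 2:6])
})

test_that("annulus template enumerates the lattice band with radial weights", {
  t8 <- build_annulus_template(1, 1.5)
  expect_length(t8$dx, 8)                 # the 8-neighbourhood ring
  expect_setequal(paste(t8$dx, t8$dy),
                  paste(c(-1, 0, 1, -1, 1, -1, 0, 1),
                        c(-1, -1, -1, 0, 0, 1, 1, 1)))
  wmag <- sqrt(t8$wx^2 + t8$wy^2)
  expect_true(all(wmag >= 1 / 1.5 - 1e-12 & wmag <= 1 + 1e-12))

  tpl <- build_annulus_template(6, 9)
  # oracle: exhaustive lattice scan over a generous window
  cnt <- 0
  for (dx in -12:12) for (dy in -12:12) {
    rho <- sqrt(dx^2 + dy^2)
    if (rho >= 6 && rho <= 9) cnt <- cnt + 1
  }
  expect_length(tpl$dx, cnt)
  # weights are radial with magnitude 1/rho; vector sum is zero
  rho <- sqrt(tpl$dx^2 + tpl$dy^2)
  expect_equal(tpl$wx * rho^2, as.numeric(tpl$dx), tolerance = 1e-12)
  expect_equal(sum(tpl$wx), 0, tolerance = 1e-12)
  expect_equal(sum(tpl$wy), 0, tolerance = 1e-12)
  expect_error(build_annulus_template(0.2, 0.4), "no integer grid points")
})

test_that("orientation matching: constant image scores zero everywhere", {
  om <- orientation_matching(matrix(5, 40, 40),
                             detect_params(diffusion_iters = 0))
  expect_equal(max(abs(om$score)), 0)
})

test_that("orientation matching peaks at a dark disc center and matches the naive oracle", {
  img <- matrix(200, 48, 48)
  img[disc_mask(48, 48, 22, 25, 7)] <- 60
  dp <- detect_params(r1 = 6, r2 = 9, radius_step = 1, polarity = "dark",
                      diffusion_iters = 0)
  om <- orientation_matching(img, dp)
  am <- which(om$score == max(om$score), arr.ind = TRUE)
  expect_lte(sqrt((am[1, 2] - 1 - 22)^2 + (am[1, 1] - 1 - 25)^2), 1)
  # naive per-pixel template-sum oracle over every pixel and band
  g <- image_gradient(img)
  mag <- sqrt(g$gx^2 + g$gy^2)
  nx <- ifelse(mag >= 1e-3, g$gx / mag, 0)
  ny <- ifelse(mag >= 1e-3, g$gy / mag, 0)
  bands <- rbind(c(6, 7), c(7, 8), c(8, 9))
  oracle <- matrix(-Inf, 48, 48)
  for (b in 1:3) {
    tpl <- build_annulus_template(bands[b, 1], bands[b, 2])
    for (i in 1:48) for (j in 1:48) {
      ii <- i + tpl$dy; jj <- j + tpl$dx
      ok <- ii >= 1 & ii <= 48 & jj >= 1 & jj <= 48
      s <- sum(nx[cbind(ii[ok], jj[ok])] * tpl$wx[ok] +
               ny[cbind(ii[ok], jj[ok])] * tpl$wy[ok])
      oracle[i, j] <- max(oracle[i, j], s)
    }
  }
  expect_equal(om$score, oracle, tolerance = 1e-10)
})

test_that("bright polarity negates the dark-polarity score (single band)", {
  # negation commutes with the per-band response, so the sign symmetry is
  # exact for a single-band configuration (with a multi-band maximum the
  # winning band may differ between polarities)
  img <- matrix(200, 40, 40)
  img[disc_mask(40, 40, 20, 20, 7)] <- 60
  omd <- orientation_matching(img, detect_params(polarity = "dark",
                                                 radius_step = 3,
                                                 diffusion_iters = 0))
  omb <- orientation_matching(img, detect_params(polarity = "bright",
                                                 radius_step = 3,
                                                 diffusion_iters = 0))
  expect_equal(omb$score, -omd$score, tolerance = 1e-12)
  expect_gt(omd$score[21, 21], 0)   # dark spot, dark polarity: positive peak
})

test_that("score argmax is translation-equivariant in the interior", {
  base <- matrix(170, 70, 70)
  img1 <- render_soft_disc(base, 30, 33, 7, 50)
  img2 <- render_soft_disc(base, 36, 28, 7, 50)   # shifted by (+6, -5)
  dp <- detect_params(diffusion_iters = 0)
  a1 <- which(orientation_matching(img1, dp)$score ==
              max(orientation_matching(img1, dp)$score), arr.ind = TRUE)[1, ]
  a2 <- which(orientation_matching(img2, dp)$score ==
              max(orientation_matching(img2, dp)$score), arr.ind = TRUE)[1, ]
  expect_equal(unname(a2 - a1), c(-5, 6))
})

test_that("radius selectivity: out-of-band discs score lower at center", {
  dp <- detect_params(r1 = 6, r2 = 9, diffusion_iters = 0)
  score_at <- function(r) {
    img <- render_soft_disc(matrix(170, 80, 80), 40, 40, r, 50)
    orientation_matching(img, dp)$score[41, 41]
  }
  expect_gt(score_at(7), score_at(3))     # r1 - 3
  expect_gt(score_at(7), score_at(12))    # r2 + 3
})

test_that("peak extraction: thresholds, suppression and tie-breaking", {
  sc <- matrix(0, 30, 30)
  sc[10, 12] <- 5
  om <- structure(list(score = sc,
                       best_radius = matrix(7, 30, 30)),
                  class = "score_map")
  cc <- disc_colony(R = 12, label = 4L)   # 37x37 mask, too small; make big
  big <- colonyspot:::make_colony(matrix(TRUE, 30, 30), 4L)
  det <- detect_spots(om, list(big), detect_params(score_threshold = 4,
                                                   diffusion_iters = 0))
  expect_equal(nrow(det), 1)
  expect_equal(c(det$x, det$y, det$colony_id), c(11, 9, 4))
  # two peaks 3 px apart, min_separation 5 -> keep the higher
  sc2 <- matrix(0, 30, 30); sc2[10, 12] <- 5; sc2[10, 15] <- 6
  om2 <- structure(list(score = sc2, best_radius = matrix(7, 30, 30)),
                   class = "score_map")
  det2 <- detect_spots(om2, list(big),
                       detect_params(score_threshold = 4,
                                     min_separation_px = 5,
                                     diffusion_iters = 0))
  expect_equal(nrow(det2), 1)
  expect_equal(det2$x, 14)
  # detections outside every colony are discarded
  small <- colonyspot:::make_colony(disc_mask(30, 30, 25, 25, 3), 1L)
  det3 <- detect_spots(om2, list(small),
                       detect_params(score_threshold = 4,
                                     diffusion_iters = 0))
  expect_equal(nrow(det3), 0)
})

test_that("phantom with 12 spots: all recovered within 2 px, none outside", {
  spec <- detection_phantom_spec(seed = 31, noise_sd = 3)
  ph <- make_colony_phantom(spec)
  cols <- truth_to_colonies(ph$truth, dim(ph$image))
  det <- detect_cells(ph$image, cols, detect_params(polarity = "dark"))
  expect_equal(nrow(det), 12)
  for (i in seq_len(nrow(ph$truth$spots))) {
    d <- sqrt((det$x - ph$truth$spots$x[i])^2 +
              (det$y - ph$truth$spots$y[i])^2)
    expect_lte(min(d), 2)
  }
  expect_true(all(!is.na(det$colony_id)))
  expect_true(all(det$radius_px >= 6 & det$radius_px <= 9))
})
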