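# Level-set segmentation, binary enhancement, watershed splitting.

test_that("otsu_mask initialization puts the zero level on the object rim", {
  img <- matrix(40, 48, 48)
  img[disc_mask(48, 48, 24, 22, 12)] <- 200
  phi <- initialize_level_set(dim(img), "otsu_mask", img)
  expect_true(all(phi[disc_mask(48, 48, 24, 22, 10)] < 0))
  expect_true(all(phi[!disc_mask(48, 48, 24, 22, 14)] > 0))
  # zero level within 1 px of the rim
  rim <- abs(sqrt((col(img) - 1 - 24)^2 + (row(img) - 1 - 22)^2) - 12) < 0.5
  expect_true(all(abs(phi[rim]) <= 1.5))
})

test_that("checkerboard initialization has both signs", {
  phi <- initialize_level_set(c(40, 40), "checkerboard")
  expect_gt(sum(phi > 0), 100)
  expect_gt(sum(phi < 0), 100)
})

test_that("otsu_mask phi is a signed distance (|grad| ~ 1, exact EDT oracle)", {
  img <- matrix(0, 32, 32)
  mask <- disc_mask(32, 32, 16, 16, 9)
  img[mask] <- 255
  phi <- initialize_level_set(dim(img), "otsu_mask", img)
  # oracle: exhaustive min distance to the opposite region
  obj <- which(mask, arr.ind = TRUE); bg <- which(!mask, arr.ind = TRUE)
  for (p in list(c(5, 5), c(16, 16), c(16, 26), c(30, 16))) {
    if (mask[p[1], p[2]]) {
      d <- -min(sqrt((bg[, 1] - p[1])^2 + (bg[, 2] - p[2])^2))
    } else {
      d <- min(sqrt((obj[, 1] - p[1])^2 + (obj[, 2] - p[2])^2))
    }
    expect_equal(phi[p[1], p[2]], d, tolerance = 1e-9)
  }
  g <- image_gradient(phi)
  mag <- sqrt(g$gx^2 + g$gy^2)
  interior <- abs(phi) > 2 & abs(phi) < 7
  expect_lt(max(abs(mag[interior] - 1)), 0.35)
  expect_lt(abs(mean(mag[interior]) - 1), 0.1)
})

test_that("region means match an explicit weighted-sum oracle", {
  img <- matrix(100, 6, 6)
  expect_equal(unname(region_means(img, matrix(rnorm(36), 6, 6), 1)),
               c(100, 100))
  set.seed(7)
  img <- matrix(runif(64, 0, 255), 8, 8)
  phi <- matrix(rnorm(64, 0, 3), 8, 8)
  cc <- region_means(img, phi, 1)
  H <- function(z) 0.5 * (1 + (2 / pi) * atan(z))
  expect_equal(unname(cc[1]), sum(img * H(-phi)) / sum(H(-phi)),
               tolerance = 1e-12)
  expect_equal(unname(cc[2]), sum(img * H(phi)) / sum(H(phi)),
               tolerance = 1e-12)
  expect_error(region_means(img, matrix(1e9, 8, 8), 1e-6), "zero total weight")
})

test_that("piecewise-constant image with aligned phi recovers region means", {
  img <- matrix(40, 20, 20); img[, 11:20] <- 200
  phi <- matrix(10, 20, 20); phi[, 11:20] <- -10
  cc <- region_means(img, phi, 0.01)
  expect_equal(unname(cc), c(200, 40), tolerance = 1e-3)
})

test_that("level-set evolution segments a two-level disc (Dice >= 0.98)", {
  img <- matrix(40, 128, 128)
  truth <- disc_mask(128, 128, 64, 60, 35)
  img[truth] <- 200
  phi0 <- initialize_level_set(dim(img), "otsu_mask", img)
  phi <- evolve_level_set(img, phi0, levelset_params(n_iter = 200))
  m <- binarize(phi)
  expect_gte(2 * sum(m & truth) / (sum(m) + sum(truth)), 0.98)
})

test_that("discrete energy is non-increasing within a 1% band", {
  img <- matrix(40, 96, 96)
  img[disc_mask(96, 96, 48, 48, 26)] <- 200
  p <- levelset_params(n_iter = 10)
  phi <- initialize_level_set(dim(img), "otsu_mask", img)
  e <- level_set_energy(img, phi, p)
  for (i in 1:20) {
    phi <- evolve_level_set(img, phi, p)
    e2 <- level_set_energy(img, phi, p)
    expect_lte(e2, e * 1.01)
    e <- e2
  }
})

test_that("on a constant image a small contour monotonically shrinks", {
  img <- matrix(100, 64, 64)
  rho <- sqrt((col(img) - 33)^2 + (row(img) - 33)^2)
  phi <- sign(rho - 10) * pmax(abs(rho - 10), 0.5)
  areas <- sum(phi < 0)
  p <- levelset_params(mu_length = 650, n_iter = 25)
  for (i in 1:8) {
    phi <- evolve_level_set(img, phi, p)
    areas <- c(areas, sum(phi < 0))
  }
  expect_true(all(diff(areas) <= 0))
  expect_lt(areas[length(areas)], areas[1])
})

test_that("binarize follows the sign convention and symmetry", {
  expect_equal(sum(binarize(matrix(1, 5, 5))), 0)
  phi <- colonyspot:::signed_distance(disc_mask(30, 30, 15, 15, 7))
  expect_equal(binarize(phi), disc_mask(30, 30, 15, 15, 7))
  nonzero <- phi != 0
  expect_equal(binarize(-phi)[nonzero], !binarize(phi)[nonzero])
})

test_that("enhance_binary dilates, fills holes and filters small areas", {
  m <- matrix(FALSE, 21, 21); m[11, 11] <- TRUE
  d <- enhance_binary(m, 3, 0)
  expect_equal(d, disc_mask(21, 21, 10, 10, 3))
  ring <- disc_mask(41, 41, 20, 20, 15) & !disc_mask(41, 41, 20, 20, 8)
  filled <- enhance_binary(ring, 0, 0)
  expect_equal(filled, disc_mask(41, 41, 20, 20, 15))
  two <- matrix(FALSE, 60, 60)
  two[2:31, 2:18] <- TRUE          # 510 px
  two[45:50, 45:49] <- TRUE        # 30 px
  out <- enhance_binary(two, 0, 100)
  expect_equal(sum(out), 510)
  expect_false(any(out[45:50, 45:49]))
})

test_that("watershed splitting: single blob, dumbbell, partition contract", {
  one <- ellipse_mask(60, 80, 40, 30, 25, 18, 0.3)
  cols <- split_colonies(one)
  expect_length(cols, 1)
  expect_equal(cols[[1]]$mask, one)

  dumb <- disc_mask(80, 100, 36, 41, 20) | disc_mask(80, 100, 66, 41, 20)
  cols2 <- split_colonies(dumb)
  expect_length(cols2, 2)
  single <- sum(disc_mask(80, 100, 36, 41, 20))
  for (cc in cols2)
    expect_lt(abs(cc$area_px - single) / single, 0.15)
  # partition: union = input, intersections empty
  u <- cols2[[1]]$mask | cols2[[2]]$mask
  expect_equal(u, dumb)
  expect_false(any(cols2[[1]]$mask & cols2[[2]]$mask))

  expect_length(split_colonies(matrix(FALSE, 10, 10)), 0)
})

test_that("colony geometry: centroid, boundary, major axis, bbox", {
  R <- 31
  cc <- disc_colony(R = R, label = 3L)
  expect_lt(sqrt(sum((cc$centroid - c(R + 6, R + 6))^2)), 1.5)
  expect_lt(abs(cc$major_axis_px - 2 * R) / (2 * R), 0.05)
  # boundary pixels all have a background 4-neighbour
  b <- cc$boundary
  for (i in head(seq_len(nrow(b)), 25)) {
    r <- b[i, "y"] + 1; c <- b[i, "x"] + 1
    nb <- c(cc$mask[r - 1, c], cc$mask[r + 1, c],
            cc$mask[r, c - 1], cc$mask[r, c + 1])
    expect_true(any(!nb))
  }
  expect_true(cc$centroid["x"] >= cc$bbox["x_min"] &&
              cc$centroid["x"] <= cc$bbox["x_max"])
  # rendered ellipse centroid matches generating center within 1.5 px
  ph <- make_colony_phantom(phantom_spec(seed = 9, n_colonies = 1,
                                         n_spots_per_colony = 0,
                                         noise_sd = 0,
                                         image_height_px = 200,
                                         image_width_px = 200,
                                         colony_radius_range_px = c(40, 55)))
  sc <- segment_colonies(ph$image)
  expect_length(sc, 1)
  tc <- ph$truth$colonies
  expect_lt(sqrt((sc[[1]]$centroid["x"] - tc$center_x)^2 +
                 (sc[[1]]$centroid["y"] - tc$center_y)^2), 1.5)
})
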