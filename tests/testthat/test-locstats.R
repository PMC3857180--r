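# Normalized distances, mutual distances, the Monte-Carlo null, KS testing
# and the location classification.

test_that("centroid distances match the hypot oracle", {
  C <- c(10, 20)
  expect_equal(distance_to_centroid(C, C), 0)
  expect_equal(distance_to_centroid(C + c(3, 4), C), 5)
  set.seed(13)
  P <- matrix(runif(40, -50, 50), ncol = 2)
  expect_equal(distance_to_centroid(P, C),
               sqrt((P[, 1] - 10)^2 + (P[, 2] - 20)^2), tolerance = 1e-12)
})

test_that("edge intersection on a disc returns D ~ R in every direction", {
  cc <- disc_colony(R = 40)
  C <- cc$centroid
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  P <- cbind(C[1] + 15 * cos(th), C[2] + 15 * sin(th))
  ei <- edge_intersection(C, P, cc$boundary)
  expect_true(all(abs(ei$D - 40) <= 1))
  # b is always a member of E
  for (i in seq_len(nrow(P)))
    expect_true(any(cc$boundary[, 1] == ei$b[i, 1] &
                    cc$boundary[, 2] == ei$b[i, 2]))
  expect_error(edge_intersection(C, C, cc$boundary), "centroid")
})

test_that("edge intersection on a square hits the diagonal corner distance", {
  a <- 20   # half side
  mask <- matrix(FALSE, 51, 51)
  mask[6:46, 6:46] <- TRUE   # square of side 2a+1 centred at (25, 25)
  cc <- colonyspot:::make_colony(mask, 1L)
  C <- cc$centroid
  ei <- edge_intersection(C, C + c(7, 7), cc$boundary)   # on the diagonal
  expect_lt(abs(ei$D - a * sqrt(2)), 1.5)
  # along an axis the edge is at distance a
  ei2 <- edge_intersection(C, C + c(7, 0), cc$boundary)
  expect_lt(abs(ei2$D - a), 1.5)
})

test_that("normalize_distance clamps and validates", {
  expect_equal(normalize_distance(0, 10), 0)
  expect_equal(normalize_distance(2, 4), 0.5)
  expect_equal(normalize_distance(4.05, 4), 1)   # overshoot clamp
  expect_error(normalize_distance(1, 0), "degenerate")
})

test_that("truncation removes the edge-extremity interval", {
  expect_equal(truncate_extremes(c(0.1, 0.5, 0.9), 0.95), c(0.1, 0.5, 0.9))
  expect_equal(truncate_extremes(c(0.2, 0.96, 0.99), 0.95), 0.2)
  set.seed(14)
  x <- runif(1000)
  expect_length(truncate_extremes(x, 0.9), sum(x < 0.9))
  expect_error(truncate_extremes(x, 1.2), "lower_cut")
})

test_that("mutual distances enumerate all pairs and match brute force", {
  m <- mutual_distances(rbind(c(0, 0), c(3, 4)), 10)
  expect_equal(nrow(m), 1)
  expect_equal(m$mhat, 0.5)
  set.seed(15)
  P <- matrix(runif(10, 0, 50), ncol = 2)   # 5 cells -> 10 pairs
  M <- 30
  out <- mutual_distances(P, M)
  expect_equal(nrow(out), 10)
  for (k in seq_len(nrow(out))) {
    i <- out$i[k]; j <- out$j[k]
    expect_lt(i, j)
    d <- sqrt(sum((P[i, ] - P[j, ])^2))
    expect_equal(out$m_px[k], d, tolerance = 1e-12)
    expect_equal(out$mhat[k], d / M, tolerance = 1e-12)
  }
  expect_equal(nrow(mutual_distances(matrix(c(1, 2), ncol = 2), 5)), 0)
})

test_that("null sampling retains exactly multiplier x n_real inside points", {
  cc <- disc_colony(R = 30)
  np <- generate_null_points(cc, 37, 10, seed = 5)
  expect_equal(nrow(np), 370)
  expect_true(all(colonyspot:::mask_contains(cc$mask, np[, 1], np[, 2])))
  expect_identical(np, generate_null_points(cc, 37, 10, seed = 5))
  expect_false(identical(np, generate_null_points(cc, 37, 10, seed = 6)))
})

test_that("null sampling on a single-pixel colony degenerates cleanly", {
  m <- matrix(FALSE, 7, 7); m[3, 5] <- TRUE
  cc <- colonyspot:::make_colony(m, 1L)
  np <- generate_null_points(cc, 2, 10, seed = 1)
  expect_equal(nrow(np), 20)
  expect_true(all(round(np[, 1]) == 4 & round(np[, 2]) == 2))
})

test_that("null sampling is uniform over the colony (chi-square quadrants)", {
  cc <- disc_colony(R = 36)
  C <- cc$centroid
  mask <- cc$mask
  q_of <- function(x, y) 1 + (x > C[1]) + 2 * (y > C[2])
  idx <- which(mask, arr.ind = TRUE)
  npx <- tabulate(q_of(idx[, 2] - 1, idx[, 1] - 1), 4)
  pass <- 0
  for (s in 1:30) {
    np <- generate_null_points(cc, 400, 10, seed = s)
    q <- tabulate(q_of(np[, 1], np[, 2]), 4)
    if (stats::chisq.test(q, p = npx / sum(npx))$p.value > 0.01)
      pass <- pass + 1
  }
  expect_gte(pass, 26)
})

test_that("KS statistic and p-value behave at the extremes", {
  x <- c(0.1, 0.4, 0.7)
  r <- ks_two_sample(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r2 <- ks_two_sample(c(1, 2, 3), c(11, 12, 13))
  expect_equal(r2$statistic, 1)
  expect_error(ks_two_sample(numeric(0), x), "non-empty")
})

test_that("KS D matches the brute-force ECDF oracle and stats::ks.test", {
  set.seed(16)
  for (trial in 1:20) {
    a <- runif(sample(2:30, 1)); b <- rnorm(sample(2:30, 1), 0.3, 0.4)
    r <- ks_two_sample(a, b)
    pooled <- c(a, b)
    D_or <- max(vapply(pooled, function(t)
      abs(mean(a <= t) - mean(b <= t)), numeric(1)))
    expect_equal(r$statistic, D_or, tolerance = 1e-12)
    expect_equal(r$statistic,
                 unname(suppressWarnings(stats::ks.test(a, b)$statistic)),
                 tolerance = 1e-12)
  }
  # the asymptotic p-value is a sane approximation at moderate n
  set.seed(17)
  a <- runif(80); b <- runif(120)
  r <- ks_two_sample(a, b)
  p_ref <- suppressWarnings(stats::ks.test(a, b)$p.value)
  expect_lt(abs(r$p_value - p_ref), 0.1)
})

test_that("moving-average smoothing shrinks its window at the edges", {
  expect_equal(smooth_distribution(rep(2, 7), 3), rep(2, 7))
  expect_equal(smooth_distribution(c(0, 3, 0), 3), c(1.5, 1, 1.5))
  set.seed(18)
  h <- runif(12)
  s <- smooth_distribution(h, 3)
  for (i in 2:11) expect_equal(s[i], mean(h[(i - 1):(i + 1)]))
  expect_error(smooth_distribution(h, 4), "window")
})

test_that("copied samples classify as NON_PREFERENTIAL / NON_CLUSTERED", {
  set.seed(19)
  d <- runif(60, 0, 0.9); m <- runif(60, 0, 1)
  rep <- classify_location(d, d, m, m, alpha = 0.001)
  expect_equal(rep$label_location, "NON_PREFERENTIAL")
  expect_equal(rep$label_radial, "NONE")
  expect_equal(rep$label_cluster, "NON_CLUSTERED")
  expect_equal(rep$centroid_ks$statistic, 0)
})

test_that("label_radial is NONE exactly when NON_PREFERENTIAL", {
  set.seed(20)
  for (trial in 1:12) {
    n <- 120
    shift <- sample(c(0, 0.25), 1)
    d <- pmin(runif(n, 0, 0.9) * (1 - shift), 0.94)
    nd <- runif(10 * n, 0, 0.9)
    rep <- classify_location(d, nd, runif(n), runif(n), alpha = 0.001)
    expect_equal(rep$label_radial != "NONE",
                 rep$label_location == "PREFERENTIAL")
  }
})

test_that("over-dispersed mutual distances stay NON_CLUSTERED with a note", {
  set.seed(21)
  d <- runif(100, 0, 0.9)
  real_m <- runif(200, 0.5, 1)    # significantly larger than null
  null_m <- runif(2000, 0, 1)
  rep <- classify_location(d, d, real_m, null_m, alpha = 0.001)
  expect_equal(rep$label_cluster, "NON_CLUSTERED")
  expect_true(any(grepl("over-dispersion", rep$notes)))
})

test_that("small real samples carry a KS-reliability warning note", {
  rep <- classify_location(runif(10, 0, 0.9), runif(100, 0, 0.9),
                           runif(5), runif(50))
  expect_true(any(grepl("reliable", rep$notes)))
})

test_that("location records short-circuit cells at the centroid", {
  cc <- disc_colony(R = 25)
  rec <- location_records(cc, rbind(cc$centroid,
                                    cc$centroid + c(12.5, 0)))
  expect_equal(rec$delta[1], 0)
  expect_lt(abs(rec$delta[2] - 0.5), 0.03)
})

test_that("analyze_locations pools colonies and is colony-order invariant", {
  cols <- list(disc_colony(R = 30, label = 1L), disc_colony(R = 24, label = 2L))
  det <- rbind(
    data.frame(colony_id = 1L,
               x = make_point_phantom(cols[[1]]$mask, 40, "uniform",
                                      seed = 7)[, 1],
               y = make_point_phantom(cols[[1]]$mask, 40, "uniform",
                                      seed = 7)[, 2]),
    data.frame(colony_id = 2L,
               x = make_point_phantom(cols[[2]]$mask, 30, "uniform",
                                      seed = 8)[, 1],
               y = make_point_phantom(cols[[2]]$mask, 30, "uniform",
                                      seed = 8)[, 2]))
  r1 <- analyze_locations(cols, det, seed = 3)
  r2 <- analyze_locations(rev(cols), det, seed = 3)
  expect_equal(r1$centroid_ks$statistic, r2$centroid_ks$statistic)
  expect_equal(r1$label_location, r2$label_location)
  # truncation removes at most a few observations from 70 real / 700 null
  expect_lte(r1$n_real, 70)
  expect_gte(r1$n_real, 60)
  expect_lte(r1$n_null, 700)
  expect_s3_class(r1, "location_report")
})
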