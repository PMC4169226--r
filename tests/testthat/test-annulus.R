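test_that("scrambled hexagons are restored to canonical angular order", {
  hexp <- make_hexagon(R = 20, saddle = 2)
  set.seed(41)
  for (rep in 1:5) {
    scr <- hexp[sample(6), ]
    ord <- order_annulus_points(scr)
    # angle-sort oracle: sort by atan2 in the xy plane, start at 4ch septal
    ang <- atan2(scr[, 2], scr[, 1])
    oracle <- scr[order(ang), ]
    s <- which(rownames(oracle) == "four_chamber/septal")
    oracle <- oracle[((seq_len(6) + s - 2L) %% 6L) + 1L, ]
    # same cyclic ring, possibly reversed handedness relative to the oracle
    expect_equal(rownames(ord)[1], "four_chamber/septal")
    expect_setequal(rownames(ord), rownames(oracle))
    fwd <- identical(rownames(ord), rownames(oracle))
    rev_ <- identical(rownames(ord),
                      rownames(oracle)[c(1L, 6:2)])
    expect_true(fwd || rev_)
  }
  # idempotence
  once <- order_annulus_points(hexp)
  expect_equal(unclass(order_annulus_points(once)), unclass(once),
               ignore_attr = TRUE)
})

test_that("degenerate point sets are rejected", {
  hexp <- make_hexagon()
  dup <- hexp; dup[2, ] <- dup[1, ]
  expect_error(order_annulus_points(dup), "coincident")
  line <- cbind(1:6, 2 * (1:6), 3 * (1:6))
  rownames(line) <- rownames(hexp)
  expect_error(order_annulus_points(line), "collinear")
})

test_that("the closed spline reproduces a circle and its inputs", {
  hexp <- make_hexagon(R = 20)
  # 241 samples over the closed equal-chord hexagon: every input parameter
  # value coincides with a sample, so pass-through is directly observable
  cv <- interpolate_annulus(order_annulus_points(hexp), 241)
  r <- sqrt(rowSums(cv[, 1:2]^2))
  expect_lt(max(abs(r - 20)) / 20, 0.02)          # radial error < 2%
  expect_lt(max(abs(cv[, 3])), 1e-9)              # planarity preserved
  # passes through every input point
  for (i in 1:6) {
    d <- sqrt(rowSums(sweep(cv, 2, hexp[i, ])^2))
    expect_lt(min(d), 1e-6)
  }
  # closure: last sample repeats the first
  expect_equal(cv[1, ], cv[nrow(cv), ], tolerance = 1e-9)
  # saddle ring: nonplanar but still closed
  sad <- interpolate_annulus(order_annulus_points(make_hexagon(saddle = 2)))
  expect_gt(diff(range(sad[, 3])), 1)
  expect_equal(sad[1, ], sad[nrow(sad), ], tolerance = 1e-9)
})

test_that("area and centroid match analytic and triangulation oracles", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  circ <- cbind(25 * cos(th), 25 * sin(th), 0 * th)
  g <- annulus_area_centroid(circ)
  expect_lt(abs(g$area_mm2 - pi * 625) / (pi * 625), 0.005)
  expect_equal(g$centroid, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(abs(g$plane_normal[3]), 1, tolerance = 1e-9)
  # unit square: shoelace oracle gives exactly 1
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(annulus_area_centroid(sq)$area_mm2, 1, tolerance = 1e-12)
  # saddle ring: independent projected-shoelace oracle (plane fit by
  # prcomp, polygon area by the 2D shoelace formula)
  sadd <- cbind(20 * cos(th), 20 * sin(th), 2 * cos(2 * th))
  ga <- annulus_area_centroid(sadd)
  pc <- stats::prcomp(sadd, center = TRUE)
  xy <- pc$x[, 1:2]
  nn <- nrow(xy)
  shoelace <- abs(sum(xy[, 1] * xy[c(2:nn, 1), 2] -
                        xy[c(2:nn, 1), 1] * xy[, 2])) / 2
  expect_equal(ga$area_mm2, shoelace, tolerance = 1e-9)
  # the slant (unprojected-fan) surface area exceeds the projected area by
  # O((saddle/R)^2): verify the documented quadratic scaling
  slant_gap <- function(h, R) {
    sd_ <- cbind(R * cos(th), R * sin(th), h * cos(2 * th))
    a <- annulus_area_centroid(sd_)
    ctr <- colMeans(sd_)
    nxt <- rbind(sd_[-1, ], sd_[1, ])
    tri <- 0.5 * sqrt(rowSums(pracma::cross(sweep(sd_, 2, ctr),
                                            sweep(nxt, 2, ctr))^2))
    (sum(tri) - a$area_mm2) / sum(tri)
  }
  g1 <- slant_gap(1, 20); g2 <- slant_gap(2, 20)
  expect_lt(g1, 0.01)
  expect_equal(g2 / g1, 4, tolerance = 0.15)
  expect_error(annulus_area_centroid(rbind(c(0, 0, 0), c(1, 1, 1),
                                           c(2, 2, 2))), "degenerate")
})

test_that("doubling the spline sampling changes areas by <0.1%", {
  hexp <- make_hexagon(R = 18, saddle = 2)
  a1 <- annulus_frame(hexp, n_samples = 120)$area_mm2
  a2 <- annulus_frame(hexp, n_samples = 240)$area_mm2
  expect_lt(abs(a2 - a1) / a1, 0.001)
})

test_that("a rigid ring step sweeps exactly area times distance", {
  f0 <- ring_frame(20, 0, 0)
  f1 <- ring_frame(20, -7.5, 1)   # descend 7.5 mm toward the apex (-z)
  f2 <- ring_frame(20, -7.5, 2)
  curve <- sweep_volume(list(f0, f1, f2), rr_interval_ms = 900,
                        long_axis = c(0, 0, -1))
  expect_equal(curve$increments_mm3[1], f0$area_mm2 * 7.5,
               tolerance = 1e-9)
  expect_equal(curve$increments_mm3[2], 0)
  expect_equal(curve$cumulative_mm3[1], 0)
  expect_equal(curve$essv_mm3, f0$area_mm2 * 7.5, tolerance = 1e-9)
})

test_that("a stationary annulus raises the no-excursion error", {
  frames <- lapply(0:3, function(p) ring_frame(15, 0, p))
  expect_error(sweep_volume(frames, 900, long_axis = c(0, 0, -1)),
               "no systolic excursion")
})

test_that("cone-frustum cumulative volume matches the closed form", {
  P <- 101
  R1 <- 22; R2 <- 14; d <- 12
  frames <- lapply(seq_len(P), function(i) {
    f <- (i - 1) / (P - 1)
    ring_frame(R1 + (R2 - R1) * f, -d * f, i - 1, n_pts = 24,
               n_samples = 240)
  })
  curve <- sweep_volume(frames, 900, long_axis = c(0, 0, -1))
  vol <- curve$cumulative_mm3[P]
  truth <- pi * d * (R1^2 + R1 * R2 + R2^2) / 3
  expect_lt(abs(vol - truth) / truth, 0.001)
})

test_that("sweep volume is equivariant under rigid scene rotation", {
  mk_frames <- function(rot = diag(3)) {
    lapply(0:9, function(p) {
      z <- -10 * sin(pi * p / 9)^2
      th <- (0:5) * pi / 3
      pts <- cbind(16 * cos(th), 16 * sin(th), z + 1.5 * cos(2 * th))
      pts <- pts %*% t(rot)
      rownames(pts) <- paste0("p", 1:6)
      annulus_frame(pts, phase = p)
    })
  }
  a <- 0.7; b <- 0.4
  rot <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3) %*%
    matrix(c(1, 0, 0, 0, cos(b), sin(b), 0, -sin(b), cos(b)), 3, 3)
  c1 <- sweep_volume(mk_frames(), 800, long_axis = c(0, 0, -1))
  c2 <- sweep_volume(mk_frames(rot), 800,
                     long_axis = as.numeric(rot %*% c(0, 0, -1)))
  expect_equal(c1$cumulative_mm3, c2$cumulative_mm3, tolerance = 1e-9)
  expect_equal(c1$essv_mm3, c2$essv_mm3, tolerance = 1e-9)
})

test_that("reversing the motion negates every increment", {
  zs <- c(0, -3, -7, -10, -8, -4, -1)
  f_fwd <- lapply(seq_along(zs), function(i) ring_frame(17, zs[i], i - 1))
  f_rev <- rev(f_fwd)
  inc_f <- sweep_volume(f_fwd, 800, long_axis = c(0, 0, -1))$increments_mm3
  inc_r <- sweep_volume(f_rev, 800, long_axis = c(0, 0, -1))$increments_mm3
  expect_equal(inc_f, -rev(inc_r), tolerance = 1e-9)
})

test_that("pure translation with constant area gives A x displacement", {
  zs <- -c(0, 1, 3, 6, 8, 9, 7, 4, 2, 1)
  frames <- lapply(seq_along(zs), function(i) ring_frame(15, zs[i], i - 1))
  curve <- sweep_volume(frames, 800, long_axis = c(0, 0, -1))
  A <- frames[[1]]$area_mm2
  expect_equal(curve$cumulative_mm3, A * (-zs), tolerance = 1e-9)
  # closure residual returns the curve exactly to its starting level
  expect_equal(curve$cumulative_mm3[10] + curve$closure_mm3, 0,
               tolerance = 1e-9)
})

test_that("the long axis is estimated apex-directed from end-diastole", {
  zs <- -c(0, 2, 5, 8, 6, 3, 1)
  frames <- lapply(seq_along(zs), function(i)
    ring_frame(15, zs[i], i - 1, saddle = 1.5))
  ax <- estimate_long_axis(frames)
  expect_equal(abs(ax[3]), 1, tolerance = 1e-6)
  expect_lt(ax[3], 0)  # descent is toward -z here
  curve <- sweep_volume(frames, 800)
  expect_gt(curve$essv_mm3, 0)
})
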