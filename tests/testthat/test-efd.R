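make_ellipse <- function(a, b, n = 400) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  list(xy = cbind(a * cos(th), b * sin(th)), t = th)
}

test_that("an ellipse parameterized by its own angle is exactly one harmonic", {
  e <- make_ellipse(2, 1)
  ef <- compute_efd(e$xy, 6, t = e$t)
  expect_equal(unname(ef$coeffs[1, ]), c(2, 0, 0, 1), tolerance = 1e-4)
  expect_lt(max(abs(ef$coeffs[-1, ])), 1e-9)
  expect_equal(ef$A0, 0, tolerance = 1e-9)
  nm <- normalize_efd(ef)
  expect_equal(unname(nm$free["d1"]), 0.5, tolerance = 1e-6)
  expect_lt(max(abs(nm$free[-1])), 1e-9)
})

test_that("a circle decomposes to equal first-harmonic semi-axes", {
  e <- make_ellipse(3, 3)
  ef <- compute_efd(e$xy, 4)  # arc length == angle parameter for a circle
  expect_equal(unname(ef$coeffs[1, "a"]), 3, tolerance = 1e-3)
  expect_equal(unname(ef$coeffs[1, "d"]), 3, tolerance = 1e-3)
  expect_lt(max(abs(ef$coeffs[-1, ])), 1e-6)
})

test_that("normalization removes translation, rotation, scale and start point", {
  set.seed(61)
  poly <- unclass(sample_outline(seed_classes()$CULTIVATED))
  base <- normalize_efd(compute_efd(poly, 10))
  expect_equal(unname(base$coeffs[1, 1:3]), c(1, 0, 0))
  expect_gte(base$coeffs[2, 1], 0)  # a2 >= 0 branch convention

  rot <- matrix(c(cos(0.59), -sin(0.59), sin(0.59), cos(0.59)), 2, 2)
  variants <- list(
    translated = sweep(poly, 2, c(-4.2, 7.7), `+`),
    rotscaled = 2.7 * poly %*% t(rot) + 3,
    restarted = poly[c(101:nrow(poly), 1:100), ])
  for (v in variants) {
    nm <- normalize_efd(compute_efd(v, 10))
    expect_equal(nm$free, base$free, tolerance = 1e-9)
  }
  expect_equal(normalize_efd(compute_efd(2.7 * poly %*% t(rot), 10))$E,
               2.7 * base$E, tolerance = 1e-6)
})

test_that("mirror-image outlines keep distinct coefficients", {
  set.seed(67)
  poly <- unclass(sample_outline(seed_classes()$CULTIVATED))
  mirrored <- cbind(poly[, 1], -poly[, 2])[rev(seq_len(nrow(poly))), ]
  a <- normalize_efd(compute_efd(poly, 10))$free
  b <- normalize_efd(compute_efd(mirrored, 10))$free
  expect_gt(max(abs(a - b)), 0.001)  # reflection is deliberately not removed
})

test_that("the free coefficient vector has 4N - 3 named entries", {
  expect_length(efd_names(20), 77)
  expect_equal(efd_names(2), c("d1", "a2", "b2", "c2", "d2"))
  set.seed(71)
  nm <- normalize_efd(compute_efd(unclass(sample_outline(seed_classes()$WILD)), 20))
  expect_length(nm$free, 77)
  expect_named(nm$free, efd_names(20))
})

test_that("harmonic counts beyond the sampling limit are refused", {
  e <- make_ellipse(2, 1, n = 12)
  expect_error(compute_efd(e$xy, 7), "harmonics")
  expect_silent(compute_efd(e$xy, 6))
  expect_error(compute_efd(e$xy[1:2, ], 1), "3 points")
})

test_that("reconstruction inverts the decomposition", {
  e <- make_ellipse(2, 1, 200)
  rec <- reconstruct_efd(compute_efd(e$xy, 1, t = e$t), 64)
  expect_lt(max(abs(sqrt((rec[, 1] / 2)^2 + rec[, 2]^2) - 1)), 1e-4)
  # regular octagon on a circle
  oct <- reconstruct_efd(compute_efd(make_ellipse(5, 5, 240)$xy, 1), 8)
  r <- sqrt(rowSums(oct^2))
  expect_equal(r, rep(r[1], 8), tolerance = 1e-9)
  steps <- sqrt(rowSums((oct - oct[c(2:8, 1), ])^2))
  expect_equal(steps, rep(steps[1], 8), tolerance = 1e-9)
  expect_error(reconstruct_efd(compute_efd(e$xy, 2), 4), "n_points")
})

test_that("a 20-harmonic round trip stays within a pixel of the contour", {
  set.seed(73)
  sc <- render_scene(list(sample_outline(seed_classes()$WILD)), dpi = 400)
  ct <- trace_boundary(label_particles(binarize(sc$image))[[1]])
  ef <- compute_efd(ct, 20)
  rec <- reconstruct_efd(ef, 512)
  pts <- cbind(ct$points[, 1], -ct$points[, 2])
  # directed Hausdorff distances, both ways
  d1 <- max(apply(rec, 1, function(q) min(sqrt(colSums((t(pts) - q)^2)))))
  d2 <- max(apply(pts, 1, function(q) min(sqrt(colSums((t(rec) - q)^2)))))
  expect_lt(max(d1, d2), 1)
  # mean deviation well below half a pixel
  expect_lt(mean(apply(pts, 1, function(q) min(sqrt(colSums((t(rec) - q)^2))))), 0.5)
})

test_that("raster extraction at 400 dpi is invariant to pose within 0.02", {
  set.seed(79)
  o <- sample_outline(seed_classes()$CULTIVATED)
  sc <- render_scene(list(o), dpi = 400)
  m <- binarize(sc$image)
  free_of <- function(mask) {
    normalize_efd(compute_efd(trace_boundary(as_seed_mask(mask)), 20))$free
  }
  base <- free_of(m)
  expect_lt(max(abs(free_of(rotate_mask_90(m)) - base)), 0.02)
  # start-point shift: quarter-turn twice = half turn
  expect_lt(max(abs(free_of(rotate_mask_90(rotate_mask_90(m))) - base)), 0.02)
})

test_that("normalized coefficients agree across 200 and 400 dpi renders", {
  set.seed(83)
  o <- sample_outline(seed_classes()$WILD)
  free_at <- function(dpi) {
    sc <- render_scene(list(o), dpi = dpi)
    normalize_efd(compute_efd(
      trace_boundary(label_particles(binarize(sc$image), dpi = dpi)[[1]]), 20))$free
  }
  expect_lt(max(abs(free_at(400) - free_at(200))), 0.03)
})

test_that("degenerate first harmonics are refused", {
  # a contour that is pure second harmonic has no first-harmonic ellipse
  cf <- matrix(0, 2, 4); cf[2, ] <- c(1, 0, 0, 1)
  poly <- reconstruct_efd(cf, 64)
  expect_error(normalize_efd(compute_efd(poly, 3)), "degenerate")
})
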