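test_that("a rasterized disk has near-ideal shape descriptors", {
  f <- measure_seed(as_seed_mask(disk_mask(50)))
  # chain-length perimeters overestimate smooth boundaries by ~5.5%
  # (staircase effect), so Circ sits near 0.9 rather than 1 for a disk
  expect_gt(f$Circ, 0.85); expect_lt(f$Circ, 1 + 1e-9)
  expect_gte(f$Sphericity, 0.97)
  expect_gte(f$Solidity, 0.98)
  expect_equal(f$Roundness, 1, tolerance = 0.03)
  expect_equal(f$AspRatio, 1, tolerance = 0.02)
  expect_equal(f$Feret, 100, tolerance = 1)
})

test_that("an axis-aligned rectangle reproduces exact closed-form values", {
  f <- measure_seed(as_seed_mask(rect_mask(10, 20)))
  expect_identical(f$Pixels, 200L)
  expect_equal(unname(f$Feret), sqrt(9^2 + 19^2))
  expect_equal(f$Area, 9 * 19)
  expect_equal(f$Perim, 2 * (9 + 19))
  expect_equal(f$CArea, 9 * 19)
  expect_equal(f$MBCRadius, sqrt(9^2 + 19^2) / 2)
  expect_equal(f$Solidity, 1)
  expect_equal(f$Concavity, 0)
  expect_equal(f$Shape, f$Perim^2 / f$Area)
  # breadth: projection of the corners perpendicular to the diagonal
  u <- c(19, 9) / sqrt(9^2 + 19^2)
  corners <- rbind(c(0, 0), c(19, 0), c(19, 9), c(0, 9))
  proj <- corners %*% c(-u[2], u[1])
  expect_equal(f$Breadth, max(proj) - min(proj))
})

test_that("base quantities match the exhaustive brute-force oracle", {
  set.seed(41)
  for (i in 1:8) {
    sd <- random_blob_mask()
    ct <- trace_boundary(sd)
    f <- measure_seed(sd, ct)
    o <- morpho_oracle(sd, ct)
    expect_equal(f$Pixels, o$Pixels)
    expect_equal(f$Area, o$Area, tolerance = 1e-9)
    expect_equal(f$Feret, o$Feret, tolerance = 1e-9)
    expect_equal(f$Breadth, o$Breadth, tolerance = 1e-9)
    expect_equal(f$MinR, o$MinR, tolerance = 1e-9)
    expect_equal(f$MaxR, o$MaxR, tolerance = 1e-9)
    expect_equal(f$CHull, o$CHull, tolerance = 1e-9)
    expect_equal(f$CArea, o$CArea, tolerance = 1e-9)
    expect_equal(f$MBCRadius, o$MBCRadius, tolerance = 1e-9)
  }
})

test_that("derived ratios follow their defining formulas", {
  set.seed(43)
  sd <- random_blob_mask()
  f <- measure_seed(sd)
  expect_equal(f$AspRatio, f$Feret / f$Breadth)
  expect_equal(f$Circ, 4 * pi * f$Area / f$Perim^2)
  expect_equal(f$Roundness, 4 * f$Area / (pi * f$Feret^2))
  expect_equal(f$ArEquivD, sqrt(4 * f$Area / pi))
  expect_equal(f$PerEquivD, f$Perim / pi)
  expect_equal(f$EquivEllAr, pi * f$Feret * f$Breadth / 4)
  expect_equal(f$Compactness, f$ArEquivD / f$Feret)
  expect_equal(f$Solidity, f$Area / f$CArea)
  expect_equal(f$Concavity, f$CArea - f$Area)
  expect_equal(f$Convexity, f$CHull / f$Perim)
  expect_equal(f$RFactor, f$CHull / (f$Feret * pi))
  expect_equal(f$ModRatio, 2 * f$MinR / f$Feret)
  expect_equal(f$Sphericity, f$MinR / f$MaxR)
  expect_equal(f$ArBBox, f$Feret * f$Breadth)
  expect_equal(f$Rectang, f$Area / f$ArBBox)
  # range invariants
  expect_lte(f$Area, f$CArea)
  expect_gte(f$Concavity, 0)
  expect_lte(f$MinR, f$MaxR)
  expect_lte(f$MBCRadius, f$MaxR + 1e-9)
  expect_gte(f$MBCRadius, f$Feret / 2 - 1e-9)
  expect_lte(f$MBCRadius, f$MaxR * 2 / sqrt(3) + 1e-9)
  # legacy strict mode for the perimeter-equivalent diameter
  fs <- measure_seed(sd, strict_per_equiv_d = TRUE)
  expect_equal(fs$PerEquivD, f$Area / pi)
})

test_that("dimensionless descriptors are invariant to quarter-turn rotation", {
  set.seed(47)
  m <- random_blob_mask()$mask
  f1 <- measure_seed(as_seed_mask(m))
  f2 <- measure_seed(as_seed_mask(rotate_mask_90(m)))
  dimless <- c("AspRatio", "Circ", "Roundness", "Compactness", "Solidity",
               "Convexity", "Shape", "RFactor", "ModRatio", "Sphericity",
               "Rectang")
  for (v in dimless) expect_equal(f1[[v]], f2[[v]], tolerance = 1e-9)
  for (v in c("Perim", "Area", "Feret", "Breadth", "CHull", "CArea",
              "MBCRadius", "MinR", "MaxR"))
    expect_equal(f1[[v]], f2[[v]], tolerance = 1e-12)
})

test_that("convex shapes have zero concavity up to discretization", {
  # staircase notches add O(perimeter) spurious concavity, so the relative
  # bound needs a disk large enough that boundary effects are subdominant
  f <- measure_seed(as_seed_mask(disk_mask(80)))
  expect_lte(f$Concavity, 0.01 * f$Area)
  expect_lte(f$Convexity, 1 + 1e-9)
})

test_that("the minimal enclosing circle matches the cubic oracle on point clouds", {
  set.seed(53)
  for (i in 1:10) {
    pts <- matrix(stats::rnorm(2 * 25), ncol = 2)
    got <- min_enclosing_circle(pts)$radius
    expect_equal(got, mbc_oracle(pts), tolerance = 1e-9)
  }
})

test_that("unit conversion scales lengths and areas correctly", {
  sd <- as_seed_mask(rect_mask(10, 20))
  f <- measure_seed(sd)
  expect_identical(to_physical(f, 1), f)
  s <- 25.4 / 400
  expect_equal(s, 0.0635)
  g <- to_physical(f, s)
  expect_equal(g$Area, f$Area * s^2)
  expect_equal(g$Feret, f$Feret * s)
  expect_equal(g$AspRatio, f$AspRatio)
  expect_identical(g$Pixels, f$Pixels)
  expect_error(to_physical(f, 0), "positive")
})

test_that("doubling the raster resolution barely moves dimensionless descriptors", {
  set.seed(59)
  o <- sample_outline(seed_classes()$CULTIVATED)
  get <- function(dpi) {
    sc <- render_scene(list(o), dpi = dpi)
    measure_seed(label_particles(binarize(sc$image), dpi = dpi)[[1]])
  }
  f1 <- get(200); f2 <- get(400)
  for (v in c("AspRatio", "Roundness", "Solidity", "Sphericity", "Rectang",
              "Circ", "Compactness"))
    expect_lt(abs(f2[[v]] - f1[[v]]) / abs(f1[[v]]), 0.02)
})
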