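test_that("construction removes duplicate vertices and rejects degenerate input", {
  # explicit closing vertex and consecutive duplicates are dropped
  p <- IsletPolygon(rbind(c(0, 0), c(0, 0), c(3, 0), c(0, 3), c(0, 0)))
  expect_equal(nrow(vertices(p)), 3)
  expect_error(IsletPolygon(rbind(c(0, 0), c(1, 1))), "degenerate")
  expect_error(IsletPolygon(rbind(c(0, 0), c(1, 1), c(0, 0), c(1, 1))),
               "degenerate")
  expect_error(IsletPolygon(rbind(c(0, 0), c(1, NA), c(2, 0))), "finite")
})

test_that("centroid is the vertex mean, invariant under cyclic relabelling", {
  sq <- IsletPolygon(rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1)))
  expect_equal(polygonCentroid(sq), c(0, 0))
  tri <- IsletPolygon(rbind(c(0, 0), c(3, 0), c(0, 3)))
  expect_equal(polygonCentroid(tri), c(1, 1))

  set.seed(42)
  v <- vertices(randomConvexPolygon(10))
  for (k in seq_len(nrow(v) - 1)) {
    rot <- IsletPolygon(v[c((k + 1):nrow(v), 1:k), ])
    expect_identical(polygonCentroid(rot), polygonCentroid(IsletPolygon(v)))
  }
})

test_that("area-weighted centroid matches the shoelace formula", {
  # off-centre right triangle: area centroid at the vertex mean
  tri <- IsletPolygon(rbind(c(2, 1), c(5, 1), c(2, 7)))
  expect_equal(polygonCentroid(tri, "area"), c(3, 3))
  # asymmetric quad where vertex mean and area centroid differ
  q <- IsletPolygon(rbind(c(0, 0), c(4, 0), c(4, 1), c(0, 2)))
  expect_false(isTRUE(all.equal(polygonCentroid(q, "area"),
                                polygonCentroid(q, "vertex"))))
})

test_that("convex polygons are valid from any start vertex, both orientations", {
  set.seed(7)
  for (rep in 1:10) {
    poly <- randomConvexPolygon(10)
    v <- vertices(poly)
    n <- nrow(v)
    for (k in seq_len(n)) {
      idx <- c(k:n, seq_len(k - 1))
      for (vv in list(v[idx, ], v[rev(idx), ])) {
        out <- validatePolygon(IsletPolygon(vv))
        expect_false(wasInvalid(out))
        expect_identical(vertices(out), vv)  # valid polygons are untouched
      }
    }
  }
})

test_that("scrambled polygons are flagged invalid, warned about, angle-sorted", {
  # vertices at angles 0, 180, 90, 270 degrees about the origin
  bad <- IsletPolygon(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
  expect_warning(out <- validatePolygon(bad), "invalid polygon")
  expect_true(wasInvalid(out))
  expect_equal(vertices(out),
               rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)))
})

test_that("equal vertex angles are tie-broken by ascending radius", {
  # two vertices along +x (angle 0) entered radius-descending, plus a
  # scrambled remainder to force the sort
  v <- rbind(c(2, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  expect_warning(out <- validatePolygon(IsletPolygon(v)))
  ctr <- polygonCentroid(IsletPolygon(v))
  pol <- toPolar(vertices(out), ctr)
  ang <- pol[, "theta"]
  expect_true(all(diff(ang) >= 0))
  same <- which(abs(diff(ang)) < 1e-12)
  for (i in same) expect_lte(pol[i, "r"], pol[i + 1, "r"])
})

test_that("a concave star polygon with monotone angles is still valid", {
  # eight-pointed star: concave, but angle-sorted, so the projection is
  # unambiguous and no repair happens (in either traversal direction)
  phi <- 2 * pi * (0:7) / 8
  rad <- rep(c(2, 1), 4)
  v <- cbind(rad * cos(phi), rad * sin(phi))
  expect_false(wasInvalid(validatePolygon(IsletPolygon(v))))
  expect_false(wasInvalid(validatePolygon(IsletPolygon(v[8:1, ]))))
})
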