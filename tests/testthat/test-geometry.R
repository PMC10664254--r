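test_that("centroid is the component-wise mean and rejects empty input", {
  expect_equal(centroid(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  expect_equal(centroid(matrix(c(1, 2, 3), 1)), c(1, 2, 3))
  expect_error(centroid(matrix(numeric(0), 0, 3)), "empty")
})

test_that("cartesian-to-spherical uses polar theta from +z and azimuth in [0,360)", {
  expect_equal(unname(cart_to_spherical(c(0, 0, 1))[1, ]), c(1, 0, 0))
  expect_equal(unname(cart_to_spherical(c(0, -1, 0))[1, ]), c(1, 270, 90))
  # hand trigonometry: r = sqrt(3), phi = 45, theta = acos(1/sqrt(3))
  s <- cart_to_spherical(c(1, 1, 1))[1, ]
  expect_equal(unname(s), c(sqrt(3), 45, acos(1 / sqrt(3)) * 180 / pi),
               tolerance = 1e-12)
  expect_equal(unname(cart_to_spherical(c(0, 0, 0))[1, ]), c(0, 0, 0))
})

test_that("quantization rounds to tenths with ties away from zero, wraps phi, clamps theta", {
  expect_equal(unname(quantize_spherical(cbind(1.7321, 45, 54.7356))[1, ]),
               c(17L, 450L, 547L))
  expect_equal(unname(quantize_spherical(cbind(0.04, 0.04, 0.04))[1, ]),
               c(0L, 0L, 0L))
  # 0.05 rounds up (away from zero), 359.96 wraps to 0, 179.96 hits the clamp
  expect_equal(unname(quantize_spherical(cbind(0.05, 359.96, 179.96))[1, ]),
               c(1L, 0L, 1800L))
})

test_that("quantized spherical triples invert to Cartesian within the decimal step", {
  expect_equal(unname(spherical_to_cart(cbind(10L, 0L, 0L))[1, ]), c(0, 0, 1))
  expect_equal(unname(spherical_to_cart(cbind(10L, 900L, 900L))[1, ]),
               c(0, 1, 0), tolerance = 1e-12)
  q <- quantize_spherical(cart_to_spherical(c(1, 1, 1)))
  expect_lt(max(abs(spherical_to_cart(q) - c(1, 1, 1))), 0.06)
})

test_that("quantization is a projection (idempotent through the inverse map)", {
  set.seed(41)
  pts <- matrix(runif(300, -80, 80), ncol = 3)
  q1 <- quantize_spherical(cart_to_spherical(pts))
  q2 <- quantize_spherical(cart_to_spherical(spherical_to_cart(q1)))
  expect_identical(q1, q2)
})

test_that("reconstruction error respects the quantization ball bound", {
  set.seed(42)
  for (r_max in c(5, 60, 199)) {
    pts <- generate_cloud(400, r_max = r_max, mode = "uniform_ball",
                          seed = r_max)
    back <- spherical_to_cart(quantize_spherical(cart_to_spherical(pts)))
    expect_lte(max(abs(back - pts)), 0.2)
    expect_lte(max(sqrt(rowSums((back - pts)^2))), 0.2 * sqrt(3))
  }
})

test_that("rmsd is the unaligned root-mean-square deviation", {
  a <- rbind(c(0, 0, 0), c(1, 0, 0))
  b <- rbind(c(0, 0, 0), c(1, 0.1, 0))
  expect_equal(rmsd(a, a), 0)
  expect_equal(rmsd(a, b), sqrt(0.005))
  expect_equal(rmsd(a, b), rmsd(b, a))
  expect_error(rmsd(a, b[1, , drop = FALSE]), "different lengths")
})
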