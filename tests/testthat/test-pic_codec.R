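test_that("epsilon validation enforces the bit-alignment constraints", {
  cfg <- codec_config(2.5)
  expect_equal(cfg$m, 2L)
  expect_equal(cfg$H, 7200L)
  expect_equal(cfg$ptr_width, 13L)
  expect_equal(codec_config(1.25)$m, 1L)  # boundary value is legal
  expect_error(codec_config(2), "illegal epsilon")     # 0.8*2 = 1.6
  expect_error(codec_config(1), "illegal epsilon")     # below 1.25
})

test_that("positional encoding maps (r, phi) to (10r, 0.8*eps*phi_decideg)", {
  expect_equal(unname(map_position(c(15L, 1200L, 0L), 2.5)[1, ]),
               c(15L, 2400L))
  expect_equal(unname(map_position(c(0L, 0L, 0L), 5)[1, ]), c(0L, 0L))
  expect_equal(unname(map_position(c(123L, 3599L, 10L), 2.5)[1, ]),
               c(123L, 7198L))
})

test_that("records pack to the worked bit strings and unpack exactly", {
  # 900 = 1110000100 in binary, padded to 11 bits behind the "10" prefix
  expect_equal(paste(pack_record(900), collapse = ""), "1001110000100")
  expect_equal(paste(pack_record(0), collapse = ""), "1000000000000")
  # pointered record at eps = 2.5: "11", 13-bit pointer 5, 11-bit 1800
  expect_equal(paste(pack_record(1800, p = 5, config = 2.5), collapse = ""),
               paste0("11", "0000000000101", "11100001000"))
  expect_length(pack_record(1800, p = 5, config = 2.5), 26)

  r <- unpack_record(pack_record(900))
  expect_equal(r, list(theta_code = 900L, p = NULL, length = 13L))
  expect_error(pack_record(1801), "out of")
  expect_error(pack_record(900, p = 0), "out of range")
  expect_error(unpack_record(c(0L, 1L, rep(0L, 11))), "start with a 1")
  expect_error(unpack_record(c(1L, 0L, 1L)), "truncated")
})

test_that("pack/unpack round trips across record space and epsilons", {
  set.seed(11)
  for (eps in c(1.25, 2.5, 5, 10)) {
    cfg <- codec_config(eps)
    for (i in 1:50) {
      theta <- sample(0:1800, 1)
      p <- if (i %% 2) NULL else sample.int(cfg$H - 1L, 1)
      bits <- pack_record(theta, p, cfg)
      expect_length(bits, if (is.null(p)) 13L else 13L + cfg$ptr_width)
      back <- unpack_record(c(bits, sample(0:1, 7, TRUE)), cfg)
      expect_equal(back$theta_code, theta)
      expect_equal(back$p, p)
    }
  }
})

test_that("slot finding takes the target first, then scans with the pointer rule", {
  cfg <- codec_config(2.5)
  empty <- rep(FALSE, cfg$H)
  expect_equal(find_slot(empty, 800, cfg), list(b_star = 800L, p = NULL))

  # first record occupies bits 800..812; the displaced second record lands
  # at 813 with pointer back to b' = 801, p = 12
  occ <- empty
  occ[800:812 + 1L] <- TRUE
  expect_equal(find_slot(occ, 800, cfg), list(b_star = 813L, p = 12L))

  expect_null(find_slot(rep(TRUE, cfg$H), 800, cfg))
})

test_that("a single atom encodes to one image holding exactly 13 bits", {
  a <- pic_encode(matrix(c(3, 4, 5), 1), 2.5, keep_log = TRUE)
  expect_length(a$images, 1L)
  expect_equal(sum(a$log$length), 13L)
  # fill accounting agrees: 13 written bits over H bits in one column
  expect_equal(a$fill, 13 / 7200)
  expect_equal(a$r_star_decit, 0L)  # a lone point is its own centroid
})

test_that("record count and total written bits are conserved", {
  pts <- generate_cloud(800, 25, "duplicate_heavy", seed = 5)
  a <- pic_encode(pts, 1.25, keep_log = TRUE)
  expect_equal(nrow(a$log), 800L)
  expect_equal(sum(a$log$length),
               sum(a$fill * a$config$H * (a$r_star_decit + 1)))
  expect_true(all(a$log$length %in%
                    c(13L, 13L + a$config$ptr_width)))
})

test_that("decode(encode(cloud)) returns the quantized triples in input order", {
  pts <- generate_cloud(5000, 50, "uniform_ball", seed = 1)
  a <- pic_encode(pts, 2.5)
  expect_identical(unname(pic_decode(a, quantized = TRUE)),
                   quantized_of(pts))
})

test_that("cropping removes exactly the all-black margins and is invertible", {
  r <- matrix(0L, 20, 30)
  r[6, 8] <- 200L
  cr <- crop_raster(r)
  expect_equal(dim(cr$raster), c(1L, 1L))
  expect_equal(c(cr$top, cr$left), c(5L, 7L))
  expect_identical(uncrop_raster(cr$raster, cr$top, cr$left, 20, 30), r)

  full <- matrix(0L, 4, 5)
  full[1, 1] <- 1L; full[4, 5] <- 1L
  cr2 <- crop_raster(full)
  expect_identical(cr2$raster, full)
  expect_equal(c(cr2$top, cr2$left), c(0L, 0L))

  expect_error(crop_raster(matrix(0L, 3, 3)), "all-black")

  set.seed(12)
  for (i in 1:10) {
    sp <- matrix(0L, 45, 60)
    sp[sample(length(sp), 40)] <- sample(1:255, 40, TRUE)
    cr <- crop_raster(sp)
    expect_identical(uncrop_raster(cr$raster, cr$top, cr$left, 45, 60), sp)
  }
})

test_that("the PNG layer is pixel-exact", {
  set.seed(13)
  r <- matrix(sample(0:255, 40 * 25, TRUE), 40, 25)
  expect_identical(read_png(render_png(r)), r)
  z <- matrix(0L, 10, 10)
  expect_identical(read_png(render_png(z)), z)
  # the raster of a real encode survives PNG + crop untouched
  pts <- generate_cloud(2000, 30, "chain_walk", seed = 9)
  a <- pic_encode(pts, 2.5)
  expect_identical(unname(pic_decode(a, quantized = TRUE)),
                   quantized_of(pts))
})

test_that("the scanning decoder recovers the encoder write log exactly", {
  for (mode in c("uniform_ball", "duplicate_heavy")) {
    pts <- generate_cloud(1000, 15, mode, seed = 3)
    cfg <- codec_config(1.25)
    a <- pic_encode(pts, cfg, keep_log = TRUE)
    decoded <- decode_scan_log(a)
    log <- a$log[order(a$log$image, a$log$column, a$log$bit), ]
    expect_equal(decoded$image, log$image)
    expect_equal(decoded$column, log$column)
    expect_equal(decoded$bit, log$bit)
    expect_equal(decoded$pointer, log$pointer)
    # no record crosses the bottom edge, pointers stay in range
    expect_true(all(log$bit + log$length - 1 < cfg$H))
    ptr <- log$pointer[!is.na(log$pointer)]
    expect_true(all(ptr >= 1 & ptr < cfg$H))
  }
})

test_that("duplicate-heavy clouds overflow into extra full-size images and still round trip", {
  pts <- generate_cloud(20000, 15, "duplicate_heavy", seed = 2)
  a <- pic_encode(pts, 1.25)
  expect_gt(length(a$images), 1L)
  expect_identical(unname(pic_decode(a, quantized = TRUE)),
                   quantized_of(pts))
  expect_equal(sort(a$permutation), 0:(nrow(pts) - 1L))
})

test_that("mean image fill is non-decreasing in atom count for nested clouds", {
  full <- generate_cloud(20000, 40, "uniform_ball", seed = 4)
  fills <- sapply(c(2000, 5000, 10000, 20000), function(n)
    mean(pic_encode(full[1:n, ], 2.5)$fill))
  expect_true(all(diff(fills) >= 0))
})

test_that("decoding rejects degenerate or inconsistent archives", {
  a <- pic_encode(generate_cloud(10, 10, seed = 1), 2.5)
  broken <- a
  broken$images <- list()
  expect_error(pic_decode(broken), "no images")
  swapped <- a
  swapped$permutation <- rep(0L, a$n)
  expect_error(pic_decode(swapped), "bijection")
  short <- a
  short$permutation <- a$permutation[-1]
  expect_error(pic_decode(short), "permutation lists")
})
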