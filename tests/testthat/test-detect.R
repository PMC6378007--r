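test_that("two well-separated spots are each recovered within 0.3 um", {
  opt <- test_optics(seed = 12)
  pos <- rbind(c(-2, 0.3, -0.2), c(2, 0.1, 0.4))   # 4 um apart
  m <- two_spot_model(seed = 13, positions = pos)
  st <- render_stack(m, opt)
  det <- detect_spots(st, "green", mask = segment_nucleus(st)$mask)
  expect_equal(nrow(det), 2)
  err <- vapply(seq_len(2), function(i)
    min(sqrt((det$x - pos[i, 1])^2 + (det$y - pos[i, 2])^2 +
             (det$z - pos[i, 3])^2)), numeric(1))
  expect_true(all(err <= 0.3))
  expect_true(all(diff(det$quality) <= 0))  # sorted by quality
})

test_that("spots below the resolution limit fuse into one detection", {
  opt <- test_optics(seed = 14)
  pos <- rbind(c(0, 0, 0), c(0.2, 0, 0))
  m <- two_spot_model(seed = 15, positions = pos)
  st <- render_stack(m, opt)
  det <- detect_spots(st, "green", mask = segment_nucleus(st)$mask)
  expect_equal(nrow(det), 1)
})

test_that("spot-free channels yield no detections in at least 95% of trials", {
  opt0 <- test_optics()
  zero <- 0
  for (i in 1:100) {
    opt <- opt0; opt$seed <- 5000 + i
    m <- generate_nucleus_model(seed = 300 + i)
    st <- render_stack(m, opt)
    det <- detect_spots(st, "green", mask = segment_nucleus(st)$mask)
    zero <- zero + (nrow(det) == 0)
  }
  expect_gte(zero, 95)
})

test_that("non-positive blob scales are a parameter error", {
  st <- image_stack(list(green = array(1, c(8, 8, 8))), 0.25, 0.25, 0.2)
  expect_error(detect_spots(st, "green", blob_sigma_lateral = 0), "positive")
})

test_that("allele selection keeps the best spots and flags the rest", {
  sp <- tibble::tibble(channel = "green", x = 1:3, y = 0, z = 0,
                       intensity = c(50, 40, 8), quality = c(80, 60, 7.5))
  kept <- select_gene_spots(sp, 2)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$quality, c(80, 60))
  expect_equal(attr(kept, "qc_flag"), "extra_spots")
  expect_equal(attr(select_gene_spots(sp[1:2, ], 2), "qc_flag"), "ok")
  one <- select_gene_spots(sp[1, ], 2)
  expect_equal(nrow(one), 1)
  expect_equal(attr(one, "qc_flag"), "missing_spots")
})

test_that("detected positions follow a rigid motion of the ground truth", {
  opt <- test_optics(seed = 16)
  pos <- rbind(c(-1.6, 0.4, 0.1), c(1.9, -0.7, -0.6))
  m <- two_spot_model(seed = 17, positions = pos)
  st <- render_stack(m, opt)
  d1 <- detect_spots(st, "green", mask = segment_nucleus(st)$mask)

  th <- pi / 7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- c(0.8, -0.5, 0.3)
  m2 <- transform_nucleus_model(m, R, tr)
  st2 <- render_stack(m2, opt)
  d2 <- detect_spots(st2, "green", mask = segment_nucleus(st2)$mask)
  expect_equal(nrow(d2), 2)

  p1 <- sweep(as.matrix(d1[, c("x", "y", "z")]) %*% t(R), 2, tr, "+")
  p2 <- as.matrix(d2[, c("x", "y", "z")])
  err <- vapply(1:2, function(i)
    min(sqrt(rowSums(sweep(p2, 2, p1[i, ])^2))), numeric(1))
  expect_true(all(err <= 0.3))
})

test_that("reported distances scale with the axial calibration", {
  # same voxel data, doubled dz: z separations must double
  g <- function(n, c0, s) dnorm(seq_len(n) - c0, 0, s)
  blob <- function(cx, cy, cz) {
    outer(outer(g(48, cx, 1), g(48, cy, 1)), g(48, cz, 2))
  }
  arr <- 1e4 * (blob(14, 24, 18) + blob(34, 24, 38))
  d_of <- function(dz) {
    st <- image_stack(list(green = arr), 0.25, 0.25, dz)
    det <- detect_spots(st, "green")
    expect_equal(nrow(det), 2)
    abs(diff(det$z))
  }
  expect_equal(d_of(0.4), 2 * d_of(0.2), tolerance = 1e-6)
})
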