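test_that("models are a pure function of their seed", {
  shape <- nucleus_shape_params()
  a <- generate_nucleus_model(shape, seed = 42)
  b <- generate_nucleus_model(shape, seed = 42)
  expect_equal(a, b)
  c <- generate_nucleus_model(shape, seed = 43)
  expect_false(identical(a$semi_axes, c$semi_axes))
})

test_that("generation under a seed does not disturb the ambient RNG", {
  set.seed(99); before <- .Random.seed
  invisible(generate_nucleus_model(seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("an undeformed sphere has the analytic mask and volume", {
  m <- generate_nucleus_model(sphere_shape(4), seed = 1)
  pts <- matrix(runif(3000 * 3, -5, 5), ncol = 3)
  r <- sqrt(rowSums(sweep(pts, 2, m$center)^2))
  expect_identical(inside_nucleus(m, pts), r <= 4)

  # voxelised volume agrees with (4/3) pi r^3 = 268.08 um^3 within 2%
  opt <- test_optics()
  origin <- m$center - c(opt$nx * opt$dx, opt$ny * opt$dy, opt$nz * opt$dz) / 2
  vox <- sum(truth_mask(m, opt, origin)) * opt$dx * opt$dy * opt$dz
  expect_lt(abs(vox / (4 / 3 * pi * 4^3) - 1), 0.02)
})

test_that("nucleolus spheres lie entirely inside the undeformed ellipsoid", {
  shape <- nucleus_shape_params(semi_axes = c(5.0, 4.2, 3.5),
                                semi_axis_jitter = 0,
                                deformation_amplitude = 0.1,
                                n_nucleoli = 2,
                                nucleolus_radius_range = c(0.8, 0.8))
  # oracle: dense sampling of each nucleolus surface must satisfy the
  # ellipsoid inequality
  dirs <- matrix(rnorm(3 * 800), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (seed in 1:20) {
    m <- generate_nucleus_model(shape, seed = seed)
    for (i in seq_len(nrow(m$nucleoli))) {
      nc <- m$nucleoli[i, ]
      surf <- sweep(dirs * nc$radius, 2, c(nc$x, nc$y, nc$z), "+")
      body <- surf %*% m$rotation
      e <- sweep(body, 2, m$semi_axes, "/")
      expect_true(all(rowSums(e^2) <= 1 + 1e-12))
    }
  }
})

test_that("impossible parameters are rejected", {
  expect_error(nucleus_shape_params(deformation_amplitude = 0.5), "0, 0.3")
  expect_error(
    generate_nucleus_model(nucleus_shape_params(
      semi_axes = c(5, 4.2, 3.5), semi_axis_jitter = 0,
      nucleolus_radius_range = c(3.6, 3.6)), seed = 1),
    "nucleolus radius")
})

test_that("deformed masks stay within the stated amplitude bounds", {
  shape <- nucleus_shape_params(semi_axis_jitter = 0, deformation_amplitude = 0.3)
  m <- generate_nucleus_model(shape, seed = 5)
  pts <- sample_points_in_nucleus(m, 2000)
  body <- sweep(pts, 2, m$center) %*% m$rotation
  e <- sweep(body, 2, m$semi_axes, "/")
  expect_true(all(sqrt(rowSums(e^2)) <= 1.3 + 1e-9))
})

test_that("rigid transforms move every model component consistently", {
  m <- generate_nucleus_model(seed = 3)
  m <- place_signals(m, placement_spec(seed = 4))
  th <- pi / 5
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- c(1.5, -2, 0.75)
  m2 <- transform_nucleus_model(m, R, tr)
  p <- as.matrix(m$true_spots[, c("x", "y", "z")])
  p2 <- as.matrix(m2$true_spots[, c("x", "y", "z")])
  expect_equal(p2, sweep(p %*% t(R), 2, tr, "+"), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(inside_nucleus(m2, p2)))
})
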