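test_that("each gene contributes exactly its copies, all inside the mask", {
  m <- generate_nucleus_model(seed = 10)
  m <- place_signals(m, placement_spec(seed = 11))
  sp <- m$true_spots
  expect_equal(nrow(sp), 4)
  expect_equal(unname(table(sp$gene)[c("POU5F1", "CDYL")]), c(2L, 2L),
               ignore_attr = TRUE)
  expect_setequal(sp$allele_index, c(1, 2))
  expect_true(all(inside_nucleus(m, sp)))
  expect_true(all(sp$brightness > 0))
})

test_that("forced colocalization always yields a pair within the radius", {
  spec <- placement_spec(coloc_probability = c("POU5F1:CDYL" = 1),
                         coloc_radius = 2)
  for (seed in 1:25) {
    m <- place_signals(generate_nucleus_model(seed = seed), spec)
    sp <- m$true_spots
    d <- pairwise_distances(sp[sp$gene == "POU5F1", ], sp[sp$gene == "CDYL", ])
    expect_lte(min(d), 2)
    expect_true(all(inside_nucleus(m, sp)))
  }
})

test_that("unforced placement is uniform over the mask", {
  # in a sphere of radius R, uniformity means (r/R)^3 ~ U(0,1) and octant
  # occupancy is flat
  m <- generate_nucleus_model(sphere_shape(4), seed = 1)
  spec <- placement_spec()
  pts <- withr::with_seed(2024, {
    do.call(rbind, lapply(1:2500, function(i) {
      sp <- place_signals(m, spec)$true_spots
      as.matrix(sp[, c("x", "y", "z")])
    }))
  })
  rel <- sweep(pts, 2, m$center)
  u <- (sqrt(rowSums(rel^2)) / 4)^3
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)

  oct <- table(paste0(rel[, 1] > 0, rel[, 2] > 0, rel[, 3] > 0))
  chi <- stats::chisq.test(as.vector(oct))
  expect_length(oct, 8)
  expect_gt(chi$p.value, 0.01)
})

test_that("nucleolus exclusion is honoured when requested", {
  shape <- nucleus_shape_params(n_nucleoli = 3,
                                nucleolus_radius_range = c(0.9, 1.0))
  spec <- placement_spec(exclude_nucleoli = TRUE)
  for (seed in 1:10) {
    m <- place_signals(generate_nucleus_model(shape, seed = seed), spec)
    expect_true(all(inside_nucleus(m, m$true_spots, exclude_nucleoli = TRUE)))
  }
})

test_that("malformed placement specs are rejected", {
  expect_error(placement_spec(coloc_probability = c("POU5F1:CDYL" = 1.2)),
               "\\[0, 1\\]")
  expect_error(placement_spec(coloc_probability = c("POU5F1:NOPE" = 0.5)),
               "gene panel")
})
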