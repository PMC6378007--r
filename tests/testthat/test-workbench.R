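test_that("stacks round-trip through TIFF with calibration intact", {
  m <- place_signals(generate_nucleus_model(seed = 2),
                     placement_spec(seed = 3))
  st <- render_stack(m, test_optics(nx = 48, ny = 48, nz = 40, seed = 4))
  tf <- file.path(withr::local_tempdir(), "stack.tif")
  write_stack(st, tf)
  rt <- read_stack(tf)
  for (ch in c("dapi", "green", "red")) {
    scale <- max(st$channels[[ch]], 1)
    expect_lt(max(abs(rt$channels[[ch]] - st$channels[[ch]])) / scale, 1e-6)
  }
  expect_equal(c(rt$dx, rt$dy, rt$dz), c(st$dx, st$dy, st$dz))
  expect_equal(rt$origin, st$origin)
})

test_that("a stack without metadata demands explicit calibration", {
  m <- generate_nucleus_model(sphere_shape(3), seed = 5)
  st <- render_stack(m, test_optics(nx = 32, ny = 32, nz = 24, seed = 6))
  tf <- file.path(withr::local_tempdir(), "bare.tif")
  write_stack(st, tf)
  file.remove(paste0(tf, ".json"))
  expect_error(read_stack(tf), "--dx --dy --dz")
  rt <- read_stack(tf, dx = 0.25, dy = 0.25, dz = 0.2)
  expect_equal(rt$dz, 0.2)
})

test_that("configs are validated before any computation", {
  cfg <- default_run_config()
  cfg$optics <- NULL
  expect_error(run_pipeline(cfg), "missing section")
  cfg2 <- default_run_config()
  cfg2$conditions[[1]]$coloc <- list("POU5F1:RUNX1" = 0.2)
  expect_error(run_pipeline(cfg2), "not a configured pair")
  cfg3 <- default_run_config()
  cfg3$conditions[[1]]$coloc[["POU5F1:CDYL"]] <- 1.4
  expect_error(run_pipeline(cfg3), "\\[0, 1\\]")
})

test_that("the demo pipeline runs, is deterministic, and writes its tables", {
  cfg <- default_run_config(n_nuclei = 6, seed = 21)
  cfg$null_model$n_draws <- 4000
  run <- run_pipeline(cfg)
  expect_s3_class(run, "fishfactory_run")
  expect_setequal(unique(run$summary$condition),
                  c("pluripotent", "differentiated"))
  expect_true(all(run$summary$percent >= 0 & run$summary$percent <= 100))
  expect_equal(sum(run$histograms$count),
               sum(run$records$n_pairs[run$records$valid]))
  expect_equal(run$provenance$seed, 21)

  run2 <- run_pipeline(cfg)
  expect_identical(run$summary, run2$summary)
  expect_identical(run$spots, run2$spots)
  expect_identical(run$null$fraction_below_threshold,
                   run2$null$fraction_below_threshold)

  out <- withr::local_tempdir()
  paths <- write_tables(run, out)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[["summary"]])
  expect_equal(back$percent, run$summary$percent)
})

test_that("YAML configs drive the pipeline", {
  cfg <- default_run_config(n_nuclei = 2, seed = 9)
  cfg$null_model$n_draws <- 1000
  yf <- file.path(withr::local_tempdir(), "cfg.yaml")
  yaml::write_yaml(cfg, yf)
  run <- run_pipeline(yf)
  expect_equal(run$provenance$seed, 9)
})

test_that("slides hold the requested number of non-overlapping nuclei", {
  sl <- populate_slide(5, seed = 31, slide_um = c(80, 80))
  expect_equal(nrow(sl$manifest), 5)
  cen <- as.matrix(sl$manifest[, c("center_x", "center_y")])
  r_bound <- 5 * 1.05 * 1.1
  d <- as.matrix(stats::dist(cen))
  expect_true(all(d[upper.tri(d)] > 2 * r_bound))
  # bounding spheres disjoint implies masks disjoint; spot-check the truth
  expect_true(all(table(sl$truth$nucleus_id) == 4))

  sl2 <- populate_slide(5, seed = 31, slide_um = c(80, 80))
  expect_identical(sl$manifest, sl2$manifest)

  expect_error(populate_slide(200, seed = 1, slide_um = c(40, 40),
                              max_tries = 20),
               "placement error")
})

test_that("a slide can carry a full per-condition sample of 500 nuclei", {
  sl <- populate_slide(500, seed = 7, slide_um = c(900, 900))
  expect_equal(nrow(sl$manifest), 500)
  expect_equal(length(sl$models), 500)
  expect_equal(nrow(sl$truth), 2000)
})

test_that("emulation presets carry the published percentages", {
  pre <- emulation_presets()
  expect_equal(pre$percent[pre$condition == "pluripotent" &
                             pre$gene_pair == "POU5F1:CDYL"], 38.5)
  expect_true(all(pre$percent > 0 & pre$percent < 100))
})
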