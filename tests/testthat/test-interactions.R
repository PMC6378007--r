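test_that("pairwise distances are plain 3-D Euclidean distances", {
  expect_equal(pairwise_distances(matrix(c(0, 0, 0), 1),
                                  matrix(c(3, 4, 0), 1)), 5)
  # voxel-centre calibration: z indices 10 and 20 at dz = 0.2 are 2 um apart
  z1 <- (10 - 0.5) * 0.2; z2 <- (20 - 0.5) * 0.2
  expect_equal(pairwise_distances(matrix(c(1, 1, z1), 1),
                                  matrix(c(1, 1, z2), 1)), 2)
  # 2 x 2 spots give exactly 4 cross distances; allele pairing gives 1
  a <- matrix(rnorm(6), 2); b <- matrix(rnorm(6), 2)
  expect_length(pairwise_distances(a, b), 4)
  expect_length(pairwise_distances(a), 1)
  expect_length(pairwise_distances(matrix(rnorm(9), 3)), 3)
})

test_that("distances are invariant under rigid motion of all spots", {
  a <- matrix(rnorm(12), 4); b <- matrix(rnorm(6), 2)
  th <- 0.7
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  tr <- c(3, -1, 2)
  expect_equal(pairwise_distances(a, b),
               pairwise_distances(sweep(a %*% t(R), 2, tr, "+"),
                                  sweep(b %*% t(R), 2, tr, "+")))
})

make_records <- function(mins, condition = "c", valid = TRUE) {
  tibble::tibble(
    nucleus_id = sprintf("n%04d", seq_along(mins)), condition = condition,
    gene_pair = "A:B", gene_a = "A", gene_b = "B", n_a = 2L, n_b = 2L,
    distances = lapply(mins, function(m) c(m, m + 3, m + 4, m + 6)),
    n_pairs = 4L, min_distance_um = mins, valid = valid)
}

test_that("the 2 um interaction criterion is boundary-inclusive", {
  rec <- call_interactions(make_records(c(2.0, 2.0001, 1.2, 5)))
  expect_equal(rec$interacting, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("the all-pairs variant counts each pair separately", {
  rec <- tibble::tibble(distances = list(c(1.5, 1.9, 3.0, 6.0)),
                        min_distance_um = 1.5, n_pairs = 4L)
  rec <- call_interactions(rec)
  expect_equal(rec$n_pairs_interacting, 2L)
})

test_that("percent interacting is non-decreasing in the threshold", {
  set.seed(31)
  rec0 <- make_records(runif(200, 0, 12))
  pc <- vapply(seq(0.5, 10, by = 0.5), function(thr) {
    r <- call_interactions(rec0, interaction_params(threshold_um = thr))
    mean(r$interacting) * 100
  }, numeric(1))
  expect_true(all(diff(pc) >= 0))
})

test_that("records built from spot tables track validity and distances", {
  spots <- tibble::tibble(
    nucleus_id = rep(c("n1", "n2"), c(4, 3)),
    condition = "pluripotent",
    gene = c("POU5F1", "POU5F1", "CDYL", "CDYL", "POU5F1", "POU5F1", "CDYL"),
    x = c(0, 1, 0, 5, 0, 2, 0), y = c(0, 0, 0, 0, 0, 0, 1.5), z = 0)
  rec <- interaction_records(spots, c("POU5F1:CDYL", "POU5F1:POU5F1"))
  expect_equal(nrow(rec), 4)
  r1 <- rec[rec$nucleus_id == "n1" & rec$gene_pair == "POU5F1:CDYL", ]
  expect_equal(r1$n_pairs, 4L)
  expect_equal(r1$min_distance_um, 0)
  expect_true(r1$valid && r1$interacting)
  # n2 lacks one CDYL allele: QC-counted, not valid
  r2 <- rec[rec$nucleus_id == "n2" & rec$gene_pair == "POU5F1:CDYL", ]
  expect_false(r2$valid)
  expect_equal(r2$n_pairs, 2L)
  # allele pairing has a single inter-allele distance
  expect_equal(rec$n_pairs[rec$gene_pair == "POU5F1:POU5F1"], c(1L, 1L))
})

test_that("summaries report the binomial standard error for one replicate", {
  rec <- call_interactions(make_records(c(rep(1, 100), rep(5, 400))))
  sm <- summarize_condition(rec)
  expect_equal(sm$percent, 20)
  expect_equal(sm$sem, 100 * sqrt(0.2 * 0.8 / 500))
  expect_equal(sm$n_nuclei, 500L)

  all_in <- summarize_condition(call_interactions(make_records(rep(0.5, 40))))
  expect_equal(all_in$percent, 100)
  expect_equal(all_in$sem, 0)
})

test_that("summaries use the SEM across replicates when present", {
  rec <- call_interactions(dplyr::bind_rows(
    dplyr::mutate(make_records(c(rep(1, 9), rep(5, 41))), rep = "r1"),
    dplyr::mutate(make_records(c(rep(1, 11), rep(5, 39))), rep = "r2")))
  sm <- summarize_condition(rec, replicate_col = "rep")
  expect_equal(sm$percent, 20)  # mean of 18% and 22%
  expect_equal(sm$sem, 2)       # SEM of two values = half their difference
  expect_equal(sm$n_replicates, 2L)
})

test_that("summaries refuse a condition with no valid nuclei", {
  rec <- call_interactions(make_records(c(1, 2), valid = FALSE))
  expect_error(summarize_condition(rec), "no valid nuclei")
})

test_that("condition comparisons follow the t-test and star convention", {
  ra <- call_interactions(make_records(c(rep(1, 100), rep(5, 400)), "a"))
  rb <- call_interactions(make_records(c(rep(1, 200), rep(5, 300)), "b"))
  cmp <- compare_conditions(ra, rb)
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$stars, "***")
  expect_equal(c(cmp$percent_a, cmp$percent_b), c(20, 40))

  same <- compare_conditions(ra, ra)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$stars, "")

  # a moderate difference lands in the single-star band of the caption rule
  rc <- call_interactions(make_records(c(rep(1, 10), rep(5, 40)), "c"))
  rd <- call_interactions(make_records(c(rep(1, 21), rep(5, 29)), "d"))
  cmp2 <- compare_conditions(rc, rd)
  oracle <- stats::t.test(rep(c(1, 0), c(10, 40)), rep(c(1, 0), c(21, 29)))
  expect_equal(cmp2$p_value, oracle$p.value)
  expect_true(cmp2$p_value > 0.01 && cmp2$p_value < 0.05)
  expect_equal(cmp2$stars, "*")

  expect_error(compare_conditions(ra[1, ], rb), "at least 2")
})

test_that("distance histograms use 14 intervals with an open tail", {
  h <- bin_distances(c(0.5, 5.2, 13.9, 20.0))
  expect_equal(length(h$counts), 14)
  expect_equal(h$counts[c(1, 6, 14)], c(1L, 1L, 2L))
  expect_equal(sum(h$counts), 4)
  expect_equal(h$n_total, 4)

  empty <- bin_distances(numeric(0))
  expect_equal(sum(empty$counts), 0)
  expect_equal(empty$n_total, 0)

  expect_error(bin_distances(c(1, -0.1)), "negative")
  expect_error(bin_distances(20, interaction_params(last_bin_open = FALSE)),
               "support")
})

test_that("histogram counts conserve n for arbitrary inputs", {
  set.seed(77)
  for (i in 1:20) {
    d <- runif(sample(1:400, 1), 0, 30)
    h <- bin_distances(d)
    expect_equal(sum(h$counts), length(d))
    expect_true(all(diff(h$edges) > 0))
  }
})

test_that("volume comparisons report means, ratio and test", {
  same <- compare_volumes(rep(300, 10), rep(300, 12))
  expect_equal(same$ratio, 1)
  expect_equal(same$p_value, 1)
  set.seed(5)
  va <- rnorm(40, 320, 15); vb <- rnorm(40, 256, 12)
  cmp <- compare_volumes(va, vb)
  expect_equal(cmp$ratio, mean(vb) / mean(va))
  expect_lt(cmp$p_value, 0.001)
  expect_error(compare_volumes(300, c(250, 260)), "at least 2")
})
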