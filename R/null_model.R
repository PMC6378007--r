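#' Exact CDF of the distance between two uniform points in a ball
#'
#' The classical closed form for the distance `s` between two independent
#' uniformly distributed points in a ball of radius `R`:
#' `F(s) = (s/R)^3 - (9/16)(s/R)^4 + (1/32)(s/R)^6`, `0 <= s <= 2R`.
#' Serves as the analytic oracle for the Monte-Carlo null model.
#'
#' @param s_um Distance(s), um.
#' @param R_um Ball radius, um.
#' @param clamp If `TRUE`, values outside `[0, 2R]` are clamped instead of
#'   raising a domain error.
#' @return CDF value(s) in `[0, 1]`.
#' @export
sphere_distance_cdf <- function(s_um, R_um, clamp = FALSE) {
  stopifnot(R_um > 0)
  if (!clamp && (any(s_um < 0) || any(s_um > 2 * R_um)))
    abort("domain error: s must lie in [0, 2R]")
  t <- pmin(pmax(s_um / R_um, 0), 2)
  t^3 - (9 / 16) * t^4 + (1 / 32) * t^6
}

#' Geometries for the random-placement null model
#'
#' @param radius_um Sphere radius, um. The package-level calibration
#'   `radius_um = 4.23` makes the 2 um interaction fraction of the sphere
#'   null equal 7.79%; it is an equivalent-sphere calibration, not a
#'   measured nuclear radius.
#' @return A geometry list consumed by [null_model_config()].
#' @export
sphere_geometry <- function(radius_um = 4.23) {
  stopifnot(radius_um > 0)
  structure(list(type = "sphere", radius = radius_um), class = "null_geometry")
}

#' @rdname sphere_geometry
#' @param a,b,c Ellipsoid semi-axes, um.
#' @export
ellipsoid_geometry <- function(a, b, c) {
  stopifnot(a > 0, b > 0, c > 0)
  structure(list(type = "ellipsoid", semi_axes = c(a, b, c)),
            class = "null_geometry")
}

#' @rdname sphere_geometry
#' @param model A `nucleus_model` whose deformed voxel mask defines the
#'   admissible region (rejection sampling).
#' @export
mask_geometry <- function(model) {
  stopifnot(inherits(model, "nucleus_model"))
  structure(list(type = "mask", model = model), class = "null_geometry")
}

#' Configuration of the random-placement null model
#'
#' @param geometry A [sphere_geometry()], [ellipsoid_geometry()] or
#'   [mask_geometry()].
#' @param threshold_um Interaction distance criterion, um.
#' @param n_draws Number of signal-pair draws.
#' @param seed Integer seed or `NULL`.
#' @param params [interaction_params()] used for the distance histogram.
#' @return A list of class `null_model_config`.
#' @export
null_model_config <- function(geometry = sphere_geometry(),
                              threshold_um = 2.0, n_draws = 1e5,
                              seed = NULL,
                              params = interaction_params(threshold_um = threshold_um)) {
  stopifnot(inherits(geometry, "null_geometry"), threshold_um > 0, n_draws >= 1)
  structure(list(geometry = geometry, threshold_um = threshold_um,
                 n_draws = as.integer(n_draws), seed = seed, params = params),
            class = "null_model_config")
}

# n uniform points in a geometry, as an n x 3 matrix (um).
sample_geometry_points <- function(geometry, n) {
  switch(geometry$type,
    sphere = runif_ball(n) * geometry$radius,
    ellipsoid = runif_ball(n) * matrix(geometry$semi_axes, n, 3, byrow = TRUE),
    mask = sample_points_in_nucleus(geometry$model, n),
    abort("unknown null-model geometry"))
}

#' Monte-Carlo random-placement null model
#'
#' Draws independent uniformly placed signals in the configured nucleus
#' geometry and reports the fraction of signal pairs within the interaction
#' threshold, its binomial Monte-Carlo standard error, and the distance
#' histogram. With `copies = c(1, 1)` (the default) each draw is a single
#' signal pair; with e.g. `copies = c(2, 2)` each draw emulates a diploid
#' nucleus and the fraction refers to the per-nucleus minimum over all
#' cross pairs - the background rate relevant to per-nucleus interaction
#' percentages.
#'
#' @param config A [null_model_config()].
#' @param copies Integer pair: signals per draw in each channel.
#' @return An object of class `null_result`: `fraction_below_threshold`,
#'   `mc_standard_error`, `histogram` (over all cross distances),
#'   `min_distances`, `threshold_um`, `n_draws`, `copies`.
#' @export
simulate_null <- function(config = null_model_config(), copies = c(1, 1)) {
  stopifnot(inherits(config, "null_model_config"),
            length(copies) == 2, all(copies >= 1))
  n <- config$n_draws
  ca <- as.integer(copies[1]); cb <- as.integer(copies[2])
  with_seed_(config$seed, {
    A <- sample_geometry_points(config$geometry, n * ca)
    B <- sample_geometry_points(config$geometry, n * cb)
    mind <- rep(Inf, n)
    all_d <- vector("list", ca * cb)
    k <- 1L
    for (i in seq_len(ca)) {
      ai <- A[seq.int(i, by = ca, length.out = n), , drop = FALSE]
      for (j in seq_len(cb)) {
        bj <- B[seq.int(j, by = cb, length.out = n), , drop = FALSE]
        d <- sqrt(rowSums((ai - bj)^2))
        mind <- pmin(mind, d)
        all_d[[k]] <- d
        k <- k + 1L
      }
    }
    frac <- mean(mind <= config$threshold_um)
    structure(list(
      fraction_below_threshold = frac,
      mc_standard_error = sqrt(frac * (1 - frac) / n),
      histogram = bin_distances(unlist(all_d), config$params),
      min_distances = mind,
      threshold_um = config$threshold_um,
      n_draws = n, copies = c(ca, cb),
      geometry = config$geometry$type, seed = config$seed),
      class = "null_result")
  })
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf("<null_result> %s geometry, %d draws (%d x %d signals)\n",
              x$geometry, x$n_draws, x$copies[1], x$copies[2]))
  cat(sprintf("  fraction within %.2f um: %.4f (MC SE %.4f)\n",
              x$threshold_um, x$fraction_below_threshold, x$mc_standard_error))
  invisible(x)
}

#' @describeIn simulate_null One-row summary tibble of a null result.
#' @param x A `null_result`.
#' @param ... Unused.
#' @export
glance.null_result <- function(x, ...) {
  tibble(geometry = x$geometry, n_draws = x$n_draws,
         copies_a = x$copies[1], copies_b = x$copies[2],
         threshold_um = x$threshold_um,
         fraction_below_threshold = x$fraction_below_threshold,
         percent_below_threshold = 100 * x$fraction_below_threshold,
         mc_standard_error = x$mc_standard_error)
}

#' @describeIn simulate_null Distance histogram of a null result as a
#'   tibble.
#' @export
tidy.null_result <- function(x, ...) tidy(x$histogram)

#' Compare an observed distance distribution with the random null
#'
#' Chi-squared goodness-of-fit of observed interval counts against the
#' expected proportions of a Monte-Carlo null result on identical interval
#' edges, plus the excess of observed mass beyond 10 um (the far-tail
#' signature of random placement). Adjacent intervals are pooled from the
#' right until every expected count reaches `min_expected`, the usual
#' validity rule for the chi-squared approximation.
#'
#' @param observed A `distance_histogram` from [bin_distances()].
#' @param null A `null_result` from [simulate_null()].
#' @param min_expected Minimum pooled expected count per cell.
#' @param tail_um Tail cutoff for the far-distance excess, um.
#' @return An object of class `null_comparison` with the per-bin table,
#'   the chi-squared statistic, degrees of freedom, p-value and tail
#'   excess; see [tidy.null_comparison()] and [glance.null_comparison()].
#' @export
compare_to_null <- function(observed, null, min_expected = 5, tail_um = 10) {
  stopifnot(inherits(observed, "distance_histogram"),
            inherits(null, "null_result"))
  nh <- null$histogram
  if (length(observed$edges) != length(nh$edges) ||
      any(observed$edges != nh$edges))
    abort("bin mismatch: observed and null histograms use different edges")
  if (observed$n_total == 0)
    abort("empty observed histogram")

  p_exp <- nh$counts / nh$n_total
  expected <- p_exp * observed$n_total
  tab <- tibble(bin_lo = observed$edges[-length(observed$edges)],
                bin_hi = observed$edges[-1],
                observed = observed$counts, expected = expected)

  # pool sparse high-distance cells so the chi-squared approximation holds
  obs_p <- observed$counts
  exp_p <- expected
  while (length(exp_p) > 1 && min(exp_p) < min_expected) {
    i <- which.min(exp_p)
    j <- if (i == length(exp_p)) i - 1 else i + 1
    exp_p[j] <- exp_p[j] + exp_p[i]; exp_p <- exp_p[-i]
    obs_p[j] <- obs_p[j] + obs_p[i]; obs_p <- obs_p[-i]
  }
  keep <- exp_p > 0
  obs_p <- obs_p[keep]; exp_p <- exp_p[keep]
  stat <- sum((obs_p - exp_p)^2 / exp_p)
  df <- length(exp_p) - 1
  p <- pchisq(stat, df, lower.tail = FALSE)

  tail_obs <- sum(observed$counts[observed$edges[-length(observed$edges)] >= tail_um]) /
    observed$n_total
  tail_exp <- sum(nh$counts[nh$edges[-length(nh$edges)] >= tail_um]) / nh$n_total

  structure(list(table = tab, statistic = stat, df = df, p_value = p,
                 tail_um = tail_um, tail_observed = tail_obs,
                 tail_expected = tail_exp,
                 tail_excess = tail_obs - tail_exp,
                 n_observed = observed$n_total),
            class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf("<null_comparison> X-squared = %.3f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("  mass beyond %g um: observed %.3f vs null %.3f (excess %+.3f)\n",
              x$tail_um, x$tail_observed, x$tail_expected, x$tail_excess))
  invisible(x)
}

#' Tidy and summarise null-model comparisons
#'
#' @param x A `null_comparison` from [compare_to_null()].
#' @param ... Unused.
#' @return `tidy()` gives the per-interval observed/expected table;
#'   `glance()` the test statistic, p-value and far-tail excess.
#' @export
tidy.null_comparison <- function(x, ...) x$table

#' @rdname tidy.null_comparison
#' @export
glance.null_comparison <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         tail_um = x$tail_um, tail_observed = x$tail_observed,
         tail_expected = x$tail_expected, tail_excess = x$tail_excess,
         n_observed = x$n_observed)
}

#' Background interaction rate of the synthetic-nucleus ensemble
#'
#' Monte-Carlo estimate of the probability that, with all signals placed
#' uniformly at random (no injected colocalization), the closest cross
#' pair in a nucleus falls within the interaction threshold. Unlike the
#' fixed-geometry null this averages over the generator's shape ensemble
#' (semi-axis jitter, surface deformation), so it is the exact geometric
#' background against which injected colocalization probabilities are
#' recovered: the expected per-nucleus interaction rate for injection
#' probability p is `p + (1 - p) * background`.
#'
#' @param shape A [nucleus_shape_params()].
#' @param copies Signals per channel in each draw (default diploid 2 x 2).
#' @param threshold_um Interaction criterion, um.
#' @param n_models Number of nucleus shapes drawn.
#' @param draws_per_model Placement draws per shape.
#' @param seed Integer seed or `NULL`.
#' @return List: `rate`, `mc_standard_error`, `n_draws`.
#' @export
background_interaction_rate <- function(shape = nucleus_shape_params(),
                                        copies = c(2, 2), threshold_um = 2.0,
                                        n_models = 400, draws_per_model = 8,
                                        seed = NULL) {
  with_seed_(seed, {
    hits <- 0L; n <- 0L
    for (i in seq_len(n_models)) {
      m <- generate_nucleus_model(shape, id = sprintf("bg-%d", i))
      for (j in seq_len(draws_per_model)) {
        a <- sample_points_in_nucleus(m, copies[1])
        b <- sample_points_in_nucleus(m, copies[2])
        hits <- hits + (min(pairwise_distances(a, b)) <= threshold_um)
        n <- n + 1L
      }
    }
    rate <- hits / n
    list(rate = rate, mc_standard_error = sqrt(rate * (1 - rate) / n),
         n_draws = n)
  })
}
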