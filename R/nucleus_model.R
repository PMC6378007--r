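#' Shape parameters for simulated nuclei
#'
#' Bundles the geometric parameters of the in-silico nucleus generator: a
#' moderately deformed ellipsoid containing spherical nucleoli and a
#' chromatin-like procedural texture. Defaults give a nucleus of volume
#' about 308 um^3 (equivalent-sphere radius about 4.2 um), a realistic size
#' for a cultured human interphase nucleus.
#'
#' @param semi_axes Ellipsoid semi-axes in um (length 3, all > 0).
#' @param semi_axis_jitter Multiplicative half-range of per-nucleus uniform
#'   jitter on each semi-axis (0 disables size variation).
#' @param deformation_amplitude Relative amplitude of the smooth radial
#'   surface perturbation, in `[0, 0.3]`. 0 gives an exact ellipsoid.
#' @param orientation Either `"random"` (uniform Euler angles) or a numeric
#'   vector of three rotation angles in radians.
#' @param n_nucleoli Number of spherical nucleoli (texture gaps).
#' @param nucleolus_radius_range Min/max nucleolus radius in um.
#' @param texture_scale Correlation length of the chromatin texture, um.
#' @param texture_contrast Relative contrast of the texture (fraction of the
#'   mean DAPI intensity).
#' @return A list of class `nucleus_shape_params`.
#' @export
nucleus_shape_params <- function(semi_axes = c(5.0, 4.2, 3.5),
                                 semi_axis_jitter = 0.05,
                                 deformation_amplitude = 0.1,
                                 orientation = "random",
                                 n_nucleoli = 2,
                                 nucleolus_radius_range = c(0.6, 1.0),
                                 texture_scale = 0.8,
                                 texture_contrast = 0.4) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0))
  if (deformation_amplitude < 0 || deformation_amplitude > 0.3)
    abort("`deformation_amplitude` must lie in [0, 0.3].")
  stopifnot(semi_axis_jitter >= 0, semi_axis_jitter < 1,
            n_nucleoli >= 0, length(nucleolus_radius_range) == 2,
            nucleolus_radius_range[1] <= nucleolus_radius_range[2],
            texture_scale > 0, texture_contrast >= 0)
  structure(list(semi_axes = as.numeric(semi_axes),
                 semi_axis_jitter = semi_axis_jitter,
                 deformation_amplitude = deformation_amplitude,
                 orientation = orientation,
                 n_nucleoli = as.integer(n_nucleoli),
                 nucleolus_radius_range = as.numeric(nucleolus_radius_range),
                 texture_scale = texture_scale,
                 texture_contrast = texture_contrast),
            class = "nucleus_shape_params")
}

# Number of random surface directions used to normalise the deformation
# field so its sup-norm equals the requested amplitude.
N_DEFORM_NORM_DIRS <- 4096L

#' Generate the geometric ground truth of one simulated nucleus
#'
#' Draws a deformed-ellipsoid nucleus: jittered semi-axes, a random rigid
#' orientation, a smooth low-order radial deformation of the surface, and
#' nucleoli rejection-sampled so every nucleolus sphere lies entirely inside
#' the undeformed ellipsoid. The result is a pure function of `seed` and
#' `shape` (with `seed = NULL` the ambient RNG stream is consumed, so batch
#' generators can seed once).
#'
#' The deformation multiplies the ellipsoidal radius by
#' `1 + A * g(u) / max|g|`, where `g` is a fixed sum of six low-frequency
#' cosine harmonics of the surface direction `u`. The perturbed shape stays
#' star-convex about the centre, so point-in-nucleus tests remain exact and
#' cheap.
#'
#' @param shape A [nucleus_shape_params()] object.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @param id Identifier stored on the model.
#' @param center Nucleus centre in lab/slide coordinates (um).
#' @return A list of class `nucleus_model` with fields `id`, `center`,
#'   `semi_axes`, `orientation`, `rotation` (3x3 matrix, lab = R %*% body),
#'   `deformation_amplitude`, `deform` (harmonic coefficients),
#'   `nucleoli` (tibble: x, y, z offsets from centre and radius, um),
#'   `texture_params`, and an initially empty `true_spots` tibble.
#' @seealso [place_signals()], [render_stack()]
#' @export
generate_nucleus_model <- function(shape = nucleus_shape_params(),
                                   seed = NULL,
                                   id = "nucleus-1",
                                   center = c(0, 0, 0)) {
  if (!inherits(shape, "nucleus_shape_params")) shape <- do.call(nucleus_shape_params, shape)
  with_seed_(seed, {
    jit <- shape$semi_axis_jitter
    semi <- shape$semi_axes * runif(3, 1 - jit, 1 + jit)
    angles <- if (identical(shape$orientation, "random")) {
      runif(3, 0, 2 * pi)
    } else as.numeric(shape$orientation)
    amp <- shape$deformation_amplitude

    # low-order random harmonics on the unit sphere of surface directions
    freqs <- matrix(rnorm(18), ncol = 3)
    freqs <- freqs / sqrt(rowSums(freqs^2)) * runif(6, 1.5, 3.5)
    phases <- runif(6, 0, 2 * pi)
    coefs <- rnorm(6)
    dirs <- matrix(rnorm(3 * N_DEFORM_NORM_DIRS), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    gvals <- cos(dirs %*% t(freqs) + matrix(phases, nrow(dirs), 6, byrow = TRUE)) %*% coefs
    norm <- max(abs(gvals), 1e-12)
    deform <- list(freqs = freqs, phases = phases, coefs = coefs, norm = norm)

    rot <- rotation_matrix(angles)

    # nucleoli: uniform in the ellipsoid shrunk by the nucleolus radius,
    # which guarantees the containment invariant for moderate radii
    nuc <- tibble(x = numeric(0), y = numeric(0), z = numeric(0), radius = numeric(0))
    if (shape$n_nucleoli > 0) {
      radii <- runif(shape$n_nucleoli, shape$nucleolus_radius_range[1],
                     shape$nucleolus_radius_range[2])
      if (any(min(semi) - radii <= 0))
        abort("nucleolus radius range too large to fit inside the ellipsoid")
      offs <- matrix(0, shape$n_nucleoli, 3)
      for (i in seq_len(shape$n_nucleoli)) {
        shrunk <- semi - radii[i]
        p <- runif_ball(1) * matrix(shrunk, 1, 3)
        offs[i, ] <- p %*% t(rot)
      }
      nuc <- tibble(x = offs[, 1], y = offs[, 2], z = offs[, 3], radius = radii)
    }

    texture_seed <- sample.int(.Machine$integer.max - 1L, 1L)

    structure(list(id = id,
                   center = as.numeric(center),
                   semi_axes = semi,
                   orientation = angles,
                   rotation = rot,
                   deformation_amplitude = amp,
                   deformation_seed = seed,
                   deform = deform,
                   nucleoli = nuc,
                   texture_params = list(scale = shape$texture_scale,
                                         contrast = shape$texture_contrast,
                                         seed = texture_seed),
                   true_spots = empty_spots_tibble()),
              class = "nucleus_model")
  })
}

empty_spots_tibble <- function() {
  tibble(gene = character(0), allele_index = integer(0), channel = character(0),
         x = numeric(0), y = numeric(0), z = numeric(0), brightness = numeric(0))
}

# Deformation factor f(u) >= 1 - A for unit direction rows u (in the
# normalised ellipsoid frame).
radial_factor <- function(model, u) {
  a <- model$deformation_amplitude
  if (a == 0) return(rep(1, nrow(u)))
  d <- model$deform
  g <- cos(u %*% t(d$freqs) + matrix(d$phases, nrow(u), 6, byrow = TRUE)) %*% d$coefs
  1 + a * as.numeric(g) / d$norm
}

#' Point-in-nucleus predicate
#'
#' Tests which lab-frame points lie inside the (deformed) nucleus mask of a
#' model; optionally treats nucleolus interiors as outside.
#'
#' @param model A `nucleus_model`.
#' @param pts An n x 3 matrix (or data frame with x, y, z) of lab
#'   coordinates in um.
#' @param exclude_nucleoli If `TRUE`, points inside a nucleolus sphere are
#'   reported as outside.
#' @return Logical vector of length n.
#' @export
inside_nucleus <- function(model, pts, exclude_nucleoli = FALSE) {
  pts <- as_point_matrix(pts)
  rel <- sweep(pts, 2, model$center)
  body <- rel %*% model$rotation            # t(R) %*% x, rowwise
  e <- sweep(body, 2, model$semi_axes, "/")
  n <- sqrt(rowSums(e^2))
  inside <- rep(TRUE, length(n))
  pos <- n > 0
  if (model$deformation_amplitude > 0 && any(pos)) {
    u <- e[pos, , drop = FALSE] / n[pos]
    inside[pos] <- n[pos] <= radial_factor(model, u)
  } else {
    inside[pos] <- n[pos] <= 1
  }
  if (exclude_nucleoli && nrow(model$nucleoli) > 0) {
    for (i in seq_len(nrow(model$nucleoli))) {
      nc <- model$nucleoli[i, ]
      d2 <- (rel[, 1] - nc$x)^2 + (rel[, 2] - nc$y)^2 + (rel[, 3] - nc$z)^2
      inside <- inside & d2 > nc$radius^2
    }
  }
  inside
}

#' Uniform random points inside a nucleus mask
#'
#' Rejection-samples points uniformly over the deformed nucleus volume
#' (optionally excluding nucleoli), using the bounding ellipsoid scaled by
#' `1 + deformation_amplitude` as the proposal.
#'
#' @inheritParams inside_nucleus
#' @param n Number of points.
#' @param max_batches Safety cap on rejection rounds.
#' @return An n x 3 matrix of lab coordinates (um).
#' @export
sample_points_in_nucleus <- function(model, n, exclude_nucleoli = FALSE,
                                     max_batches = 200) {
  bound <- model$semi_axes * (1 + model$deformation_amplitude)
  out <- matrix(NA_real_, 0, 3)
  batch <- max(2L * n, 16L)
  for (i in seq_len(max_batches)) {
    p <- runif_ball(batch) * matrix(bound, batch, 3, byrow = TRUE)
    lab <- p %*% t(model$rotation) + matrix(model$center, batch, 3, byrow = TRUE)
    keep <- inside_nucleus(model, lab, exclude_nucleoli = exclude_nucleoli)
    out <- rbind(out, lab[keep, , drop = FALSE])
    if (nrow(out) >= n) return(out[seq_len(n), , drop = FALSE])
  }
  abort("placement error: nucleus mask has (near-)zero admissible volume")
}

#' Analytic volume of the undeformed ellipsoid of a model
#' @param model A `nucleus_model`.
#' @return Volume in um^3.
#' @export
ellipsoid_volume <- function(model) {
  semi <- if (inherits(model, "nucleus_model")) model$semi_axes else as.numeric(model)
  4 / 3 * pi * prod(semi)
}

#' Apply a rigid motion to a nucleus model
#'
#' Rotates the whole model (shape, nucleoli, true spots) about the origin by
#' `rotation` and then translates by `translation`. Used to verify that the
#' measurement pipeline is equivariant under isometries.
#'
#' @param model A `nucleus_model`.
#' @param rotation A 3x3 rotation matrix (default identity).
#' @param translation Length-3 translation in um.
#' @return The transformed `nucleus_model`.
#' @export
transform_nucleus_model <- function(model, rotation = diag(3),
                                    translation = c(0, 0, 0)) {
  stopifnot(all(dim(rotation) == c(3, 3)))
  m <- model
  m$center <- as.numeric(rotation %*% model$center + translation)
  m$rotation <- rotation %*% model$rotation
  m$orientation <- NA_real_  # angles no longer tracked; matrix is canonical
  if (nrow(m$nucleoli) > 0) {
    off <- as.matrix(m$nucleoli[, c("x", "y", "z")]) %*% t(rotation)
    m$nucleoli$x <- off[, 1]; m$nucleoli$y <- off[, 2]; m$nucleoli$z <- off[, 3]
  }
  if (nrow(m$true_spots) > 0) {
    p <- as.matrix(m$true_spots[, c("x", "y", "z")]) %*% t(rotation)
    p <- sweep(p, 2, translation, "+")
    m$true_spots$x <- p[, 1]; m$true_spots$y <- p[, 2]; m$true_spots$z <- p[, 3]
  }
  m
}

#' @export
print.nucleus_model <- function(x, ...) {
  cat("<nucleus_model> ", x$id, "\n", sep = "")
  cat(sprintf("  semi-axes (um): %.2f %.2f %.2f   deformation: %.2f\n",
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3],
              x$deformation_amplitude))
  cat(sprintf("  nucleoli: %d   true spots: %d\n",
              nrow(x$nucleoli), nrow(x$true_spots)))
  invisible(x)
}
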