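#' Populate a virtual microscope slide with simulated nuclei
#'
#' Repeats the single-nucleus generator to fill a slide: nucleus centres
#' are drawn uniformly over the slide area and accepted only if their
#' bounding spheres (max semi-axis times `1 + deformation`, plus a
#' clearance margin) do not overlap any previously placed nucleus, so all
#' masks are pairwise disjoint in slide coordinates. Each accepted nucleus
#' gets signals placed per `spec`; rendering per-nucleus stacks is optional
#' because ground-truth-only slides (no voxel data) are often all a study
#' needs.
#'
#' @param n_cells Number of nuclei to place (>= 1).
#' @param shape A [nucleus_shape_params()].
#' @param spec A [placement_spec()].
#' @param optics An [optics_config()]; defines the per-nucleus stack
#'   geometry when `render = TRUE` and the slide z extent.
#' @param seed Integer seed; the whole slide is a pure function of it.
#' @param slide_um Lateral slide dimensions, um.
#' @param margin_um Minimum clearance between nucleus bounding spheres, um.
#' @param render If `TRUE`, each nucleus is rendered into its own stack.
#' @param max_tries Placement attempts per nucleus before giving up.
#' @return List with `models` (list of `nucleus_model`), `stacks` (list of
#'   [image_stack()] or `NULL`), `manifest` (tibble: nucleus_id, centre,
#'   per-nucleus seed, stack origin, spot count) and `truth` (tibble of all
#'   true spots with nucleus ids).
#' @export
populate_slide <- function(n_cells, shape = nucleus_shape_params(),
                           spec = placement_spec(), optics = optics_config(),
                           seed = 1, slide_um = c(250, 250),
                           margin_um = 1, render = FALSE,
                           max_tries = 500) {
  stopifnot(n_cells >= 1, length(slide_um) == 2, all(slide_um > 0))
  r_bound <- max(shape$semi_axes) * (1 + shape$semi_axis_jitter) *
    (1 + shape$deformation_amplitude)
  if (2 * r_bound > min(slide_um))
    abort("slide smaller than one nucleus")
  z_mid <- optics$nz * optics$dz / 2

  with_seed_(seed, {
    centers <- matrix(NA_real_, n_cells, 3)
    placed <- 0L
    tries <- 0L
    while (placed < n_cells) {
      tries <- tries + 1L
      if (tries > max_tries * n_cells)
        abort("placement error: could not fit all nuclei on the slide without overlap")
      cand <- c(runif(1, r_bound, slide_um[1] - r_bound),
                runif(1, r_bound, slide_um[2] - r_bound), z_mid)
      ok <- placed == 0L ||
        all(sqrt((centers[seq_len(placed), 1] - cand[1])^2 +
                 (centers[seq_len(placed), 2] - cand[2])^2) >
            2 * r_bound + margin_um)
      if (ok) { placed <- placed + 1L; centers[placed, ] <- cand }
    }

    cell_seeds <- sample.int(.Machine$integer.max - 1L, n_cells)
    models <- vector("list", n_cells)
    stacks <- vector("list", n_cells)
    rows <- vector("list", n_cells)
    truth <- vector("list", n_cells)
    fov <- c(optics$nx * optics$dx, optics$ny * optics$dy, optics$nz * optics$dz)
    for (i in seq_len(n_cells)) {
      id <- sprintf("cell-%04d", i)
      m <- generate_nucleus_model(shape, seed = cell_seeds[i], id = id,
                                  center = centers[i, ])
      m <- place_signals(m, spec)
      models[[i]] <- m
      origin <- centers[i, ] - fov / 2
      origin[3] <- 0
      if (render) stacks[[i]] <- render_stack(m, optics, origin = origin)
      rows[[i]] <- tibble(nucleus_id = id,
                          center_x = centers[i, 1], center_y = centers[i, 2],
                          center_z = centers[i, 3], seed = cell_seeds[i],
                          origin_x = origin[1], origin_y = origin[2],
                          origin_z = origin[3],
                          n_spots = nrow(m$true_spots))
      truth[[i]] <- dplyr::mutate(m$true_spots, nucleus_id = id, .before = 1)
    }
    list(models = models, stacks = stacks,
         manifest = dplyr::bind_rows(rows),
         truth = dplyr::bind_rows(truth))
  })
}

#' Simulate and measure one experimental condition end-to-end
#'
#' The workhorse behind recovery experiments: for each nucleus it
#' generates a model, places signals (with the condition's injected
#' colocalization probabilities), renders the confocal-like stack, and
#' measures it back (segmentation, spot detection, allele selection).
#' Stacks are discarded after measurement so memory stays flat at any
#' sample size.
#'
#' @param n_nuclei Nuclei to simulate.
#' @param shape,spec,optics Generator settings; see
#'   [nucleus_shape_params()], [placement_spec()], [optics_config()].
#' @param condition Condition label for all outputs.
#' @param seed Integer seed (the whole run is deterministic given it).
#' @param keep_truth Attach the true spot table.
#' @param ... Passed to [measure_stack()] (detector/segmentation tuning).
#' @return List of tibbles: `spots` (detected), `nuclei` (measurements and
#'   QC), and `truth` if requested.
#' @export
run_condition <- function(n_nuclei, shape = nucleus_shape_params(),
                          spec = placement_spec(),
                          optics = optics_config(nx = 64, ny = 64, nz = 64),
                          condition = "simulated_random", seed = 1,
                          keep_truth = TRUE, ...) {
  stopifnot(n_nuclei >= 1)
  with_seed_(seed, {
    spots <- vector("list", n_nuclei)
    nuclei <- vector("list", n_nuclei)
    truth <- vector("list", n_nuclei)
    for (i in seq_len(n_nuclei)) {
      id <- sprintf("%s-%04d", condition, i)
      m <- generate_nucleus_model(shape, id = id)
      m <- place_signals(m, spec)
      st <- render_stack(m, optics)
      res <- measure_stack(st, genes = spec$genes, nucleus_id = id,
                           condition = condition, ...)
      spots[[i]] <- res$spots
      nuclei[[i]] <- res$nucleus
      if (keep_truth)
        truth[[i]] <- dplyr::mutate(m$true_spots, nucleus_id = id,
                                    condition = condition, .before = 1)
    }
    out <- list(spots = dplyr::bind_rows(spots),
                nuclei = dplyr::bind_rows(nuclei))
    if (keep_truth) out$truth <- dplyr::bind_rows(truth)
    out
  })
}
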