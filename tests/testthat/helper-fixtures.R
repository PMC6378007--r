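# Shared fixtures: all synthetic data is generated in code at test time.

# Per-nucleus crop geometry used throughout the suite: 16 x 16 x 12.8 um at
# the acquisition's 0.2 um axial step, comfortably containing the default
# nucleus in any orientation.
test_optics <- function(...) {
  args <- utils::modifyList(
    list(nx = 64, ny = 64, nz = 64, dx = 0.25, dy = 0.25, dz = 0.2),
    list(...))
  do.call(optics_config, args)
}

# An exact sphere of radius 4 um, no nucleoli, no size jitter: the shape
# with a closed-form volume (268.08 um^3) and distance distribution.
sphere_shape <- function(radius = 4) {
  nucleus_shape_params(semi_axes = rep(radius, 3), semi_axis_jitter = 0,
                       deformation_amplitude = 0, n_nucleoli = 0)
}

# Deterministic two-spot model: spots set explicitly rather than placed.
two_spot_model <- function(seed = 1, positions, brightness = 1200,
                           shape = nucleus_shape_params()) {
  m <- generate_nucleus_model(shape, seed = seed)
  m$true_spots <- tibble::tibble(
    gene = "POU5F1", allele_index = seq_len(nrow(positions)),
    channel = "green",
    x = positions[, 1], y = positions[, 2], z = positions[, 3],
    brightness = brightness)
  m
}

# Ground-truth voxel mask of a model on the grid render_stack() uses.
truth_mask <- function(model, optics, origin) {
  fishfactory:::voxelize_nucleus(model, optics, origin) > 0
}
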