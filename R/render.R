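#' Confocal acquisition geometry and noise settings
#'
#' Defaults mirror the acquisition used for the real data this package
#' emulates: 1024 x 1024 px slices, 60 slices at a 0.2 um axial step. The
#' lateral pixel size is not dictated by that geometry and defaults to
#' 0.25 um/px. The point-spread function is approximated as a separable
#' anisotropic Gaussian - the standard desk-scale surrogate for a confocal
#' PSF.
#'
#' @param nx,ny Pixels per slice.
#' @param nz Number of z slices.
#' @param dx,dy Lateral sampling, um/px.
#' @param dz Axial step, um.
#' @param psf_sigma_lateral,psf_sigma_axial Gaussian PSF sigmas, um.
#' @param noise_model One of `"none"`, `"poisson"`, `"poisson+gaussian"`.
#' @param gaussian_sd Read-noise SD (intensity units) for the
#'   `"poisson+gaussian"` model.
#' @param dapi_level Mean DAPI intensity inside the nucleus, photons.
#' @param background Uniform background level added to the probe channels,
#'   photons.
#' @param seed Integer seed for the noise draw, or `NULL` (ambient RNG).
#' @return A list of class `optics_config`.
#' @export
optics_config <- function(nx = 1024, ny = 1024, nz = 60,
                          dx = 0.25, dy = 0.25, dz = 0.2,
                          psf_sigma_lateral = 0.2, psf_sigma_axial = 0.5,
                          noise_model = c("poisson", "none", "poisson+gaussian"),
                          gaussian_sd = 1,
                          dapi_level = 60, background = 2,
                          seed = NULL) {
  noise_model <- match.arg(noise_model)
  stopifnot(nx >= 1, ny >= 1, nz >= 1, dx > 0, dy > 0, dz > 0,
            psf_sigma_lateral >= 0, psf_sigma_axial >= 0,
            gaussian_sd >= 0, dapi_level >= 0, background >= 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
                 dx = dx, dy = dy, dz = dz,
                 psf_sigma_lateral = psf_sigma_lateral,
                 psf_sigma_axial = psf_sigma_axial,
                 noise_model = noise_model, gaussian_sd = gaussian_sd,
                 dapi_level = dapi_level, background = background,
                 seed = seed),
            class = "optics_config")
}

#' Construct a calibrated multi-channel image stack object
#'
#' @param channels Named list of 3-D numeric arrays (dims nx, ny, nz), names
#'   drawn from `dapi`, `green`, `red`.
#' @param dx,dy,dz Voxel spacing, um.
#' @param origin Physical coordinate (um) of the stack corner; voxel
#'   `[i,j,k]` is centred at `origin + ((i,j,k) - 0.5) * (dx,dy,dz)`.
#' @param provenance Free-form provenance list (seeds, source path, ...).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, dx, dy, dz, origin = c(0, 0, 0),
                        provenance = list()) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), dx > 0, dy > 0, dz > 0)
  d <- dim(channels[[1]])
  for (ch in channels) stopifnot(identical(dim(ch), d), all(ch >= 0))
  structure(list(channels = channels, dx = dx, dy = dy, dz = dz,
                 origin = as.numeric(origin), provenance = provenance),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %d x %d x %d, channels: %s\n", d[1], d[2], d[3],
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  calibration (um): dx=%.3g dy=%.3g dz=%.3g\n", x$dx, x$dy, x$dz))
  invisible(x)
}

stack_dim <- function(stack) dim(stack$channels[[1]])

# voxel-centre coordinate vectors of a stack
voxel_axes <- function(stack) {
  d <- stack_dim(stack)
  list(x = stack$origin[1] + (seq_len(d[1]) - 0.5) * stack$dx,
       y = stack$origin[2] + (seq_len(d[2]) - 0.5) * stack$dy,
       z = stack$origin[3] + (seq_len(d[3]) - 0.5) * stack$dz)
}

# Indices of the voxel-centre axis `ax` lying within `half` of `centre`
# (never empty: clamped to at least one voxel).
crop_range <- function(ax, centre, half) {
  i <- which(ax >= centre - half & ax <= centre + half)
  if (length(i) == 0) i <- which.min(abs(ax - centre))
  seq.int(min(i), max(i))
}

# Voxel classification of a model on the grid of an optics configuration:
# 0 outside, 1 lumen, 2 nucleolus. Exposed for ground-truth mask queries
# (e.g. Dice scores against segmentation).
voxelize_nucleus <- function(model, optics, origin) {
  d <- model$deform %||% list(freqs = matrix(0, 1, 3), phases = 0, coefs = 0,
                              norm = 1)
  nucm <- if (nrow(model$nucleoli) > 0) as.matrix(model$nucleoli[, c("x", "y", "z", "radius")])
          else matrix(0, 0, 4)
  .nucleus_mask_codes(c(optics$nx, optics$ny, optics$nz), origin,
                      c(optics$dx, optics$dy, optics$dz), model$center,
                      model$rotation, model$semi_axes,
                      model$deformation_amplitude,
                      d$freqs, d$phases, d$coefs, d$norm, nucm)
}

# Band-limited procedural texture: iid standard-normal values on a coarse
# grid with spacing `scale`, trilinearly interpolated at the voxel centres.
# Approximately unit variance, correlation length ~ scale.
texture_on_voxels <- function(optics, origin, tp, pad = 2) {
  fov <- c(optics$nx * optics$dx, optics$ny * optics$dy, optics$nz * optics$dz)
  lo <- origin - pad * tp$scale
  hi <- origin + fov + pad * tp$scale
  ng <- pmax(2L, ceiling((hi - lo) / tp$scale) + 1L)
  vals <- with_seed_(tp$seed, array(rnorm(prod(ng)), dim = ng))
  .texture_on_grid(c(optics$nx, optics$ny, optics$nz), origin,
                   c(optics$dx, optics$dy, optics$dz), vals, lo, tp$scale)
}

#' Render a nucleus model into a confocal-like z-stack
#'
#' Produces the DAPI channel as the nucleus mask filled with a
#' multiplicative band-limited chromatin texture (zeroed inside nucleoli)
#' and blurred by the Gaussian PSF; FISH probe channels render each true
#' spot as an anisotropic Gaussian intensity kernel whose voxel sum equals
#' the spot brightness (up to kernel truncation at the field edge). Photon
#' noise is applied according to the optics noise model. Deterministic given
#' the model and optics seeds.
#'
#' @param model A `nucleus_model` with placed spots.
#' @param optics An [optics_config()].
#' @param origin Stack corner in lab coordinates (um); the default centres
#'   the nucleus in the field of view.
#' @param channels Which channels to render.
#' @return An [image_stack()] whose provenance records the model id, seeds,
#'   and any spots clipped by the field of view (clipping also raises a
#'   warning).
#' @export
render_stack <- function(model, optics = optics_config(),
                         origin = NULL,
                         channels = c("dapi", "green", "red")) {
  stopifnot(inherits(model, "nucleus_model"), inherits(optics, "optics_config"))
  nx <- optics$nx; ny <- optics$ny; nz <- optics$nz
  fov <- c(nx * optics$dx, ny * optics$dy, nz * optics$dz)
  if (is.null(origin)) origin <- model$center - fov / 2

  xs <- origin[1] + (seq_len(nx) - 0.5) * optics$dx
  ys <- origin[2] + (seq_len(ny) - 0.5) * optics$dy
  zs <- origin[3] + (seq_len(nz) - 0.5) * optics$dz

  out <- list()
  clipped <- character(0)

  if ("dapi" %in% channels) {
    # the nucleus occupies a small crop of the field of view; compute the
    # texture-filled mask and its PSF blur there only, then paste
    r_bound <- max(model$semi_axes) * (1 + model$deformation_amplitude)
    pad <- 4 * max(optics$psf_sigma_lateral, optics$psf_sigma_axial) + 0.5
    ix <- crop_range(xs, model$center[1], r_bound + pad)
    iy <- crop_range(ys, model$center[2], r_bound + pad)
    iz <- crop_range(zs, model$center[3], r_bound + pad)
    cdim <- c(length(ix), length(iy), length(iz))
    corig <- c(origin[1] + (ix[1] - 1) * optics$dx,
               origin[2] + (iy[1] - 1) * optics$dy,
               origin[3] + (iz[1] - 1) * optics$dz)
    copt <- optics
    copt$nx <- cdim[1]; copt$ny <- cdim[2]; copt$nz <- cdim[3]
    codes <- voxelize_nucleus(model, copt, corig)
    tp <- model$texture_params
    tex <- texture_on_voxels(copt, corig, tp)
    crop <- optics$dapi_level * pmax(0, 1 + tp$contrast * tex)
    crop[codes != 1L] <- 0          # outside, or a nucleolus gap in the texture
    dim(crop) <- cdim
    if (optics$psf_sigma_lateral > 0 || optics$psf_sigma_axial > 0) {
      kl <- gauss_kernel(max(optics$psf_sigma_lateral, 1e-6) / optics$dx)
      km <- gauss_kernel(max(optics$psf_sigma_lateral, 1e-6) / optics$dy)
      ka <- gauss_kernel(max(optics$psf_sigma_axial, 1e-6) / optics$dz)
      crop <- .conv3d_sep(crop, kl, km, ka)
    }
    dapi <- array(0, c(nx, ny, nz))
    dapi[ix, iy, iz] <- crop
    out$dapi <- dapi
  }

  for (ch in intersect(c("green", "red"), channels)) {
    img <- array(optics$background, dim = c(nx, ny, nz))
    sp <- model$true_spots[model$true_spots$channel == ch, , drop = FALSE]
    for (i in seq_len(nrow(sp))) {
      res <- add_spot(img, c(sp$x[i], sp$y[i], sp$z[i]), sp$brightness[i],
                      xs, ys, zs, optics)
      img <- res$img
      if (res$clipped) clipped <- c(clipped, paste0(sp$gene[i], "/", ch, "#", sp$allele_index[i]))
    }
    out[[ch]] <- img
  }

  if (length(clipped))
    warn(paste("spot(s) clipped by the field of view:",
               paste(clipped, collapse = ", ")))

  out <- with_seed_(optics$seed, lapply(out, apply_noise, optics = optics))

  image_stack(out, optics$dx, optics$dy, optics$dz, origin = origin,
              provenance = list(model_id = model$id,
                                optics_seed = optics$seed,
                                texture_seed = model$texture_params$seed,
                                clipped_spots = clipped))
}

# Accumulate one Gaussian spot into `img` within a +/- 4 sigma window.
# The separable product of normalised 1-D Gaussians times the voxel pitch
# makes the voxel sum equal the brightness when the window is uncut.
add_spot <- function(img, pos, brightness, xs, ys, zs, optics) {
  sx <- max(optics$psf_sigma_lateral, 1e-3)
  sz <- max(optics$psf_sigma_axial, 1e-3)
  wx <- which(abs(xs - pos[1]) <= 4 * sx + optics$dx)
  wy <- which(abs(ys - pos[2]) <= 4 * sx + optics$dy)
  wz <- which(abs(zs - pos[3]) <= 4 * sz + optics$dz)
  clipped <- length(wx) == 0 || length(wy) == 0 || length(wz) == 0 ||
    pos[1] < xs[1] - 0.5 * optics$dx || pos[1] > xs[length(xs)] + 0.5 * optics$dx ||
    pos[2] < ys[1] - 0.5 * optics$dy || pos[2] > ys[length(ys)] + 0.5 * optics$dy ||
    pos[3] < zs[1] - 0.5 * optics$dz || pos[3] > zs[length(zs)] + 0.5 * optics$dz
  if (length(wx) && length(wy) && length(wz)) {
    gx <- dnorm(xs[wx], pos[1], sx) * optics$dx
    gy <- dnorm(ys[wy], pos[2], sx) * optics$dy
    gz <- dnorm(zs[wz], pos[3], sz) * optics$dz
    ker <- outer(outer(gx, gy), gz) * brightness
    img[wx, wy, wz] <- img[wx, wy, wz] + ker
  }
  list(img = img, clipped = clipped)
}

apply_noise <- function(img, optics) {
  d <- dim(img)
  v <- switch(optics$noise_model,
    none = img,
    poisson = rpois(length(img), pmax(img, 0)),
    `poisson+gaussian` = rpois(length(img), pmax(img, 0)) +
      rnorm(length(img), 0, optics$gaussian_sd))
  v <- pmax(as.numeric(v), 0)
  dim(v) <- d
  v
}
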