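#' Segment nuclei in a calibrated z-stack
#'
#' Gaussian-smooths the DAPI channel, applies a global Otsu threshold,
#' fills enclosed holes (nucleoli are dark and must count towards nuclear
#' volume), and labels 6-connected components. Components touching the
#' stack border are flagged: their volume is truncated by the field of view
#' and they are excluded from volume statistics downstream.
#'
#' @param stack An [image_stack()] with a `dapi` channel.
#' @param smooth_sigma_um Isotropic smoothing sigma before thresholding, um.
#' @param min_volume_um3 Components smaller than this are discarded as
#'   debris.
#' @param dapi_channel Channel name holding the nuclear counterstain.
#' @return A list with `labels` (integer array, 0 = background), and
#'   `nuclei`, a tibble with one row per retained component: `label`,
#'   `volume_um3`, `border_touch`, and centroid `x`, `y`, `z` (um).
#' @export
segment_nuclei <- function(stack, smooth_sigma_um = 0.4, min_volume_um3 = 20,
                           dapi_channel = "dapi") {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$channels[[dapi_channel]]
  if (is.null(v)) abort("segmentation error: no DAPI channel in the stack")
  if (max(v) <= min(v))
    abort("segmentation error: DAPI channel is empty or flat")

  kx <- gauss_kernel(smooth_sigma_um / stack$dx)
  ky <- gauss_kernel(smooth_sigma_um / stack$dy)
  kz <- gauss_kernel(smooth_sigma_um / stack$dz)
  sm <- .conv3d_sep(v, kx, ky, kz)

  thr <- otsu_threshold(sm)
  mask <- sm > thr
  dim(mask) <- dim(v)
  mask <- fill_holes3(mask)

  lab <- .label3d(mask)
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) == 0)
    abort("segmentation error: no foreground voxels after thresholding")

  voxvol <- stack$dx * stack$dy * stack$dz
  keep <- which(sizes * voxvol >= min_volume_um3)
  if (length(keep) == 0)
    abort("segmentation error: no component above the minimum volume")

  d <- dim(v)
  border <- border_labels(lab)
  ax <- voxel_axes(stack)
  rows <- lapply(keep, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    tibble(label = l,
           volume_um3 = nrow(idx) * voxvol,
           border_touch = l %in% border,
           x = mean(ax$x[idx[, 1]]),
           y = mean(ax$y[idx[, 2]]),
           z = mean(ax$z[idx[, 3]]))
  })
  relabel <- array(0L, d)
  for (l in keep) relabel[lab == l] <- l
  list(labels = relabel, nuclei = dplyr::bind_rows(rows))
}

#' Segment the single largest nucleus in a stack
#'
#' Convenience wrapper around [segment_nuclei()] for per-nucleus crops:
#' returns the largest component as a logical mask plus its measurements.
#'
#' @inheritParams segment_nuclei
#' @return List with `mask` (logical array), `volume_um3`, `border_touch`,
#'   and the centroid.
#' @export
segment_nucleus <- function(stack, smooth_sigma_um = 0.4, min_volume_um3 = 20,
                            dapi_channel = "dapi") {
  seg <- segment_nuclei(stack, smooth_sigma_um, min_volume_um3, dapi_channel)
  top <- seg$nuclei[which.max(seg$nuclei$volume_um3), ]
  mask <- seg$labels == top$label
  list(mask = mask, volume_um3 = top$volume_um3,
       border_touch = top$border_touch,
       centroid = c(top$x, top$y, top$z))
}

# Global Otsu threshold on a numeric array (EBImage's otsu works per 2-D
# frame, so the volume is flattened to a single frame first).
otsu_threshold <- function(v, levels = 1024) {
  mn <- min(v); mx <- max(v)
  if (mx <= mn) abort("cannot threshold a flat image")
  img <- EBImage::Image(matrix((as.numeric(v) - mn) / (mx - mn), ncol = 1L))
  thr <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  mn + thr * (mx - mn)
}

# Fill cavities: any background component not connected to the stack border
# becomes foreground.
fill_holes3 <- function(mask) {
  lab <- .label3d(!mask)
  border <- border_labels(lab)
  hole <- lab > 0 & !(lab %in% border)
  out <- mask | hole
  dim(out) <- dim(mask)
  out
}

border_labels <- function(lab) {
  d <- dim(lab)
  unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
           lab[, , 1], lab[, , d[3]])) |> setdiff(0L)
}
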