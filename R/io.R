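#' Write a multi-channel stack as a multi-page TIFF with a JSON sidecar
#'
#' Slices are written as 32-bit float RGB pages (red = red probe, green =
#' green probe, blue = DAPI), intensities divided by a common scale so the
#' pixel range fits `[0, 1]`. Baseline TIFF tags cannot carry the axial
#' step or channel semantics, so calibration, channel roles, intensity
#' scale and origin go to `<path>.json` next to the image.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return Invisibly, a list with the TIFF and sidecar paths.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- stack_dim(stack)
  scale <- max(1, vapply(stack$channels, max, numeric(1)))
  get_ch <- function(nm) {
    if (!is.null(stack$channels[[nm]])) stack$channels[[nm]] / scale
    else array(0, d)
  }
  r <- get_ch("red"); g <- get_ch("green"); b <- get_ch("dapi")
  pages <- lapply(seq_len(d[3]), function(k) {
    pg <- array(0, c(d[1], d[2], 3))
    pg[, , 1] <- r[, , k]; pg[, , 2] <- g[, , k]; pg[, , 3] <- b[, , k]
    pg
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(dx = stack$dx, dy = stack$dy, dz = stack$dz,
         origin = stack$origin, scale = scale,
         channel_roles = list(red = "probe_red", green = "probe_green",
                              blue = "dapi"),
         channels_present = names(stack$channels),
         provenance = stack$provenance),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(list(tiff = path, sidecar = sidecar))
}

#' Read a calibrated stack written by [write_stack()] (or a plain RGB TIFF)
#'
#' Calibration is taken from the JSON sidecar when present; otherwise
#' `dx`, `dy` and `dz` must be supplied explicitly (the CLI flags `--dx
#' --dy --dz`), and an error naming them is raised if they are not.
#'
#' @param path TIFF path.
#' @param dx,dy,dz Calibration overrides, um; required when no sidecar
#'   exists.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, dx = NULL, dy = NULL, dz = NULL) {
  if (!file.exists(path)) abort(paste0("unreadable file: ", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
          else NULL
  dx <- dx %||% meta$dx; dy <- dy %||% meta$dy; dz <- dz %||% meta$dz
  if (is.null(dx) || is.null(dy) || is.null(dz))
    abort(paste("missing calibration: no sidecar metadata found;",
                "supply `dx`, `dy`, `dz` (CLI flags --dx --dy --dz)"))
  scale <- meta$scale %||% 1
  origin <- meta$origin %||% c(0, 0, 0)
  nz <- length(pages)
  d1 <- dim(pages[[1]])
  if (length(d1) != 3 || d1[3] < 3)
    abort("expected RGB pages (red probe, green probe, DAPI)")
  mk <- function(plane) {
    a <- array(0, c(d1[1], d1[2], nz))
    for (k in seq_len(nz)) a[, , k] <- pages[[k]][, , plane]
    a * scale
  }
  image_stack(list(dapi = mk(3), green = mk(2), red = mk(1)),
              dx = dx, dy = dy, dz = dz, origin = origin,
              provenance = list(source = path))
}

#' Write the tables of a pipeline result bundle to CSV
#'
#' Emits the spots, nuclei, interaction-record, summary, comparison,
#' histogram and null-comparison tables plus a `provenance.json` capturing
#' package version, configuration hash and seeds, so every number in every
#' table is traceable to a config and seed.
#'
#' @param bundle A result bundle from [run_pipeline()].
#' @param root Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_tables <- function(bundle, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  put <- function(df, name) {
    p <- file.path(root, paste0(name, ".csv"))
    write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  put(bundle$spots, "spots")
  put(bundle$nuclei, "nuclei")
  put(dplyr::select(bundle$records, -"distances"), "records")
  put(bundle$summary, "summary")
  if (!is.null(bundle$comparisons) && nrow(bundle$comparisons))
    put(bundle$comparisons, "comparisons")
  if (!is.null(bundle$volume_comparisons) && nrow(bundle$volume_comparisons))
    put(bundle$volume_comparisons, "volume_comparisons")
  put(bundle$histograms, "histograms")
  put(glance(bundle$null), "null_summary")
  if (!is.null(bundle$null_comparisons) && nrow(bundle$null_comparisons))
    put(bundle$null_comparisons, "null_comparisons")
  pj <- file.path(root, "provenance.json")
  jsonlite::write_json(bundle$provenance, pj, auto_unbox = TRUE, digits = NA)
  paths[["provenance"]] <- pj
  invisible(unlist(paths))
}
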