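#' Specification of FISH signal placement within a nucleus
#'
#' Describes which gene probes are present, how many hybridisation spots
#' (alleles) each contributes per nucleus, and - optionally - a controlled
#' colocalization probability per gene pair. Random placement is uniform
#' over the nucleus mask; the correlated option exists so that known
#' interaction rates can be injected and later recovered through the
#' measurement pipeline. Correlated placement is a testing device, not a
#' biophysical model.
#'
#' @param genes A data frame with columns `gene`, `channel`
#'   (`"green"`/`"red"`), `copies` (spots per nucleus, normally 2). Default:
#'   POU5F1 (green) and CDYL (red), two alleles each.
#' @param coloc_probability Named numeric vector/list, names `"A:B"`, values
#'   in `[0, 1]`: with that probability one allele of B is re-placed
#'   uniformly within `coloc_radius` of a random A allele (still inside the
#'   mask).
#' @param coloc_radius Colocalization radius in um (default 2, the
#'   long-range-interaction criterion).
#' @param exclude_nucleoli If `TRUE`, spots avoid nucleolus interiors. The
#'   default `FALSE` places spots uniformly over the whole nucleus.
#' @param brightness Mean spot brightness in photons.
#' @param brightness_cv Coefficient of variation of per-spot brightness
#'   (log-normal); 0 for constant brightness.
#' @param seed Integer seed or `NULL` (ambient RNG).
#' @return A list of class `placement_spec`.
#' @export
placement_spec <- function(genes = default_gene_panel(),
                           coloc_probability = NULL,
                           coloc_radius = 2.0,
                           exclude_nucleoli = FALSE,
                           brightness = 1200,
                           brightness_cv = 0.15,
                           seed = NULL) {
  genes <- as_tibble(genes)
  stopifnot(all(c("gene", "channel", "copies") %in% names(genes)),
            all(genes$channel %in% c("green", "red")),
            all(genes$copies >= 1), coloc_radius > 0,
            brightness > 0, brightness_cv >= 0)
  cp <- unlist(coloc_probability)
  if (length(cp)) {
    if (any(cp < 0 | cp > 1)) abort("coloc probabilities must lie in [0, 1]")
    for (nm in names(cp)) {
      gg <- strsplit(nm, ":", fixed = TRUE)[[1]]
      if (length(gg) != 2 || !all(gg %in% genes$gene))
        abort(paste0("coloc_probability name '", nm, "' does not match the gene panel"))
    }
  }
  structure(list(genes = genes, coloc_probability = cp,
                 coloc_radius = coloc_radius,
                 exclude_nucleoli = exclude_nucleoli,
                 brightness = brightness, brightness_cv = brightness_cv,
                 seed = seed),
            class = "placement_spec")
}

#' Default two-gene FISH panel
#' @param gene_a,gene_b Gene labels for the green and red probes.
#' @param copies Alleles per gene.
#' @return Tibble with columns gene, channel, copies.
#' @export
default_gene_panel <- function(gene_a = "POU5F1", gene_b = "CDYL", copies = 2) {
  tibble(gene = c(gene_a, gene_b), channel = c("green", "red"),
         copies = as.integer(copies))
}

#' Place FISH signals inside a nucleus model
#'
#' Fills `model$true_spots`: each gene contributes exactly its
#' copies-per-nucleus spots, placed uniformly over the nucleus mask (minus
#' nucleoli if requested). For every gene pair with a configured
#' colocalization probability p, with probability p one allele of the second
#' gene is re-placed uniformly within the colocalization radius of a
#' randomly chosen allele of the first gene, still inside the mask.
#'
#' @param model A `nucleus_model`.
#' @param spec A [placement_spec()].
#' @return The model with `true_spots` filled (tibble: gene, allele_index,
#'   channel, x, y, z in um, brightness).
#' @export
place_signals <- function(model, spec = placement_spec()) {
  stopifnot(inherits(model, "nucleus_model"), inherits(spec, "placement_spec"))
  with_seed_(spec$seed, {
    rows <- list()
    for (i in seq_len(nrow(spec$genes))) {
      g <- spec$genes[i, ]
      pos <- sample_points_in_nucleus(model, g$copies,
                                      exclude_nucleoli = spec$exclude_nucleoli)
      br <- spot_brightness(spec, g$copies)
      rows[[i]] <- tibble(gene = g$gene, allele_index = seq_len(g$copies),
                          channel = g$channel,
                          x = pos[, 1], y = pos[, 2], z = pos[, 3],
                          brightness = br)
    }
    spots <- dplyr::bind_rows(rows)

    for (nm in names(spec$coloc_probability)) {
      p <- spec$coloc_probability[[nm]]
      if (p <= 0) next
      if (runif(1) > p) next
      gg <- strsplit(nm, ":", fixed = TRUE)[[1]]
      ia <- which(spots$gene == gg[1])
      ib <- which(spots$gene == gg[2])
      if (identical(gg[1], gg[2])) { # allele pairing: move one allele near the other
        ia <- ia[1]; ib <- ib[length(ib)]
      } else {
        ia <- ia[sample.int(length(ia), 1)]
        ib <- ib[sample.int(length(ib), 1)]
      }
      anchor <- c(spots$x[ia], spots$y[ia], spots$z[ia])
      q <- place_near(model, anchor, spec$coloc_radius, spec$exclude_nucleoli)
      spots$x[ib] <- q[1]; spots$y[ib] <- q[2]; spots$z[ib] <- q[3]
    }

    model$true_spots <- spots
    model
  })
}

spot_brightness <- function(spec, n) {
  if (spec$brightness_cv == 0) return(rep(spec$brightness, n))
  sdl <- sqrt(log(1 + spec$brightness_cv^2))
  spec$brightness * exp(rnorm(n, -sdl^2 / 2, sdl))
}

# Uniform point in ball(anchor, radius) intersected with the nucleus mask.
# The anchor is inside the mask, so the intersection has positive volume and
# rejection sampling terminates quickly.
place_near <- function(model, anchor, radius, exclude_nucleoli, max_tries = 5000) {
  for (i in seq_len(max_tries)) {
    cand <- anchor + runif_ball(1)[1, ] * radius
    if (inside_nucleus(model, matrix(cand, 1, 3),
                       exclude_nucleoli = exclude_nucleoli))
      return(cand)
  }
  abort("placement error: could not place a colocalized signal inside the mask")
}
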