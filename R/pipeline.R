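#' Default end-to-end demonstration configuration
#'
#' A small, fully specified run configuration: one gene pair, two
#' conditions with different injected colocalization probabilities, the
#' second with a 20% smaller nuclear volume (per-axis scale 0.928). Every
#' field can be overridden via YAML ([read_run_config()]) or by editing
#' the returned list.
#'
#' @param n_nuclei Nuclei per condition.
#' @param seed Master seed; all stages derive their seeds from it.
#' @return A run-configuration list.
#' @export
default_run_config <- function(n_nuclei = 30, seed = 1) {
  list(
    experiment = "demo",
    seed = seed,
    optics = list(nx = 64, ny = 64, nz = 64, dx = 0.25, dy = 0.25, dz = 0.2),
    shape = list(semi_axes = c(5.0, 4.2, 3.5), deformation_amplitude = 0.1),
    genes = list(list(gene = "POU5F1", channel = "green", copies = 2),
                 list(gene = "CDYL", channel = "red", copies = 2)),
    pairs = "POU5F1:CDYL",
    conditions = list(
      list(name = "pluripotent", n_nuclei = n_nuclei,
           coloc = list("POU5F1:CDYL" = 0.385)),
      list(name = "differentiated", n_nuclei = n_nuclei,
           coloc = list("POU5F1:CDYL" = 0.30), volume_scale = 0.928)),
    interaction = list(threshold_um = 2.0, metric = "per_nucleus_min",
                       histogram_bins = 14, bin_width_um = 1.0),
    null_model = list(radius_um = 4.23, n_draws = 20000)
  )
}

#' Published interaction percentages usable as emulation presets
#'
#' The per-condition long-range-interaction percentages reported for the
#' real microscopy data (whose raw images are not publicly deposited).
#' They are offered as presets for the synthetic generator's injected
#' colocalization probabilities when a run should *emulate* the published
#' effect sizes; note the observed percentage of a simulated condition is
#' the injected probability plus the geometric background rate, so these
#' are emulation targets, not expected outputs.
#'
#' @return Tibble: condition, gene_pair, percent.
#' @export
emulation_presets <- function() {
  tibble(
    condition = rep(c("pluripotent", "differentiated"), c(5, 3)),
    gene_pair = c("POU5F1:CDYL", "POU5F1:TLE2", "POU5F1:RARG",
                  "POU5F1:MSX1", "POU5F1:RUNX1",
                  "POU5F1:CDYL", "POU5F1:TLE2", "POU5F1:RUNX1"),
    percent = c(38.5, 24.23, 14.4, 16, 8.22, 30, 13, 18))
}

#' Read a run configuration from YAML
#' @param path YAML file path.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config not found: ", path))
  yaml::read_yaml(path)
}

#' Validate a run configuration
#'
#' Checks structural completeness before any computation: required
#' sections, resolvable gene pairs, probabilities in range.
#'
#' @param config A run-configuration list.
#' @return The config, invisibly, or an error describing the first
#'   problem.
#' @export
validate_run_config <- function(config) {
  req <- c("seed", "optics", "shape", "genes", "pairs", "conditions",
           "interaction", "null_model")
  missing <- setdiff(req, names(config))
  if (length(missing))
    abort(paste("validation error: config is missing section(s):",
                paste(missing, collapse = ", ")))
  genes <- vapply(config$genes, function(g) g$gene, character(1))
  for (p in config$pairs) {
    gg <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(gg) != 2 || !all(gg %in% genes))
      abort(paste0("validation error: pair '", p, "' does not resolve to the gene panel"))
  }
  for (cond in config$conditions) {
    if (is.null(cond$name) || is.null(cond$n_nuclei))
      abort("validation error: every condition needs `name` and `n_nuclei`")
    for (nm in names(cond$coloc)) {
      pr <- cond$coloc[[nm]]
      if (pr < 0 || pr > 1)
        abort("validation error: coloc probabilities must lie in [0, 1]")
      if (!nm %in% config$pairs)
        abort(paste0("validation error: coloc preset '", nm, "' is not a configured pair"))
    }
  }
  invisible(config)
}

#' Run the full simulate-measure-summarise pipeline
#'
#' For every condition and gene pair, simulates the configured number of
#' nuclei, renders and measures them (segmentation, sub-voxel spot
#' detection), builds interaction records, and aggregates: condition
#' summaries with error bars, between-condition t-tests, nuclear-volume
#' comparisons, 14-interval distance histograms, the random-placement
#' null, and observed-vs-null goodness-of-fit. Deterministic given
#' `config$seed`.
#'
#' @param config Run-configuration list (see [default_run_config()]), or a
#'   YAML path.
#' @return A list of class `fishfactory_run` with tibbles `spots`,
#'   `nuclei`, `records`, `summary`, `comparisons`, `volume_comparisons`,
#'   `histograms`, `null_comparisons`, the `null` result, and
#'   `provenance`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)

  optics <- do.call(optics_config, config$optics)
  params <- do.call(interaction_params, config$interaction)
  genes_tbl <- dplyr::bind_rows(lapply(config$genes, as_tibble))

  spots <- list(); nuclei <- list(); records <- list()
  seed_step <- 0L
  for (cond in config$conditions) {
    shape_args <- config$shape
    if (!is.null(cond$volume_scale))
      shape_args$semi_axes <- shape_args$semi_axes * cond$volume_scale
    shape <- do.call(nucleus_shape_params, shape_args)
    for (pair in config$pairs) {
      gg <- unique(strsplit(pair, ":", fixed = TRUE)[[1]])
      panel <- genes_tbl[genes_tbl$gene %in% gg, , drop = FALSE]
      pr <- cond$coloc[[pair]] %||% 0
      spec <- placement_spec(genes = panel,
                             coloc_probability = if (pr > 0) setNames(pr, pair) else NULL)
      seed_step <- seed_step + 1L
      res <- run_condition(cond$n_nuclei, shape = shape, spec = spec,
                           optics = optics, condition = cond$name,
                           seed = config$seed + 1000L * seed_step,
                           keep_truth = FALSE)
      key <- paste(cond$name, pair, sep = "|")
      spots[[key]] <- res$spots
      nuclei[[key]] <- dplyr::mutate(res$nuclei, gene_pair = pair)
      if (nrow(res$spots))
        records[[key]] <- interaction_records(res$spots, pair, params,
                                              expected_copies = max(panel$copies))
    }
  }
  spots <- dplyr::bind_rows(spots)
  nuclei <- dplyr::bind_rows(nuclei)
  records <- dplyr::bind_rows(records)

  summary <- summarize_condition(records, params)

  cond_names <- vapply(config$conditions, function(x) x$name, character(1))
  comparisons <- list(); volcmp <- list()
  if (length(cond_names) >= 2) {
    cmb <- utils::combn(cond_names, 2, simplify = FALSE)
    for (pair in config$pairs) for (cc in cmb) {
      ra <- records[records$condition == cc[1] & records$gene_pair == pair, ]
      rb <- records[records$condition == cc[2] & records$gene_pair == pair, ]
      if (sum(ra$valid) >= 2 && sum(rb$valid) >= 2)
        comparisons[[paste(pair, cc[1], cc[2])]] <-
          dplyr::mutate(compare_conditions(ra, rb),
                        gene_pair = pair, condition_a = cc[1],
                        condition_b = cc[2], .before = 1)
    }
    for (cc in cmb) {
      va <- nuclei[nuclei$condition == cc[1] & !nuclei$border_touch, ]
      vb <- nuclei[nuclei$condition == cc[2] & !nuclei$border_touch, ]
      if (nrow(va) >= 2 && nrow(vb) >= 2)
        volcmp[[paste(cc, collapse = " ")]] <-
          dplyr::mutate(compare_volumes(va, vb),
                        condition_a = cc[1], condition_b = cc[2], .before = 1)
    }
  }

  null_cfg <- null_model_config(
    geometry = sphere_geometry(config$null_model$radius_um %||% 4.23),
    threshold_um = params$threshold_um,
    n_draws = config$null_model$n_draws %||% 1e5,
    seed = config$seed + 777L, params = params)
  null <- simulate_null(null_cfg)

  histograms <- list(); nullcmp <- list()
  grp <- dplyr::group_split(dplyr::group_by(records, .data$condition, .data$gene_pair))
  for (g in grp) {
    d <- unlist(g$distances[g$valid])
    h <- bin_distances(d, params)
    key <- paste(g$condition[1], g$gene_pair[1])
    histograms[[key]] <- dplyr::mutate(tidy(h), condition = g$condition[1],
                                       gene_pair = g$gene_pair[1], .before = 1)
    if (h$n_total > 0)
      nullcmp[[key]] <- dplyr::mutate(glance(compare_to_null(h, null)),
                                      condition = g$condition[1],
                                      gene_pair = g$gene_pair[1], .before = 1)
  }

  provenance <- list(
    package = "fishfactory",
    version = as.character(utils::packageVersion("fishfactory")),
    config_hash = rlang::hash(config),
    seed = config$seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    experiment = config$experiment %||% "unnamed")

  structure(list(config = config, spots = spots, nuclei = nuclei,
                 records = records, summary = summary,
                 comparisons = dplyr::bind_rows(comparisons),
                 volume_comparisons = dplyr::bind_rows(volcmp),
                 histograms = dplyr::bind_rows(histograms),
                 null = null,
                 null_comparisons = dplyr::bind_rows(nullcmp),
                 provenance = provenance),
            class = "fishfactory_run")
}

#' @export
print.fishfactory_run <- function(x, ...) {
  cat("<fishfactory_run> ", x$provenance$experiment,
      " (seed ", x$provenance$seed, ")\n", sep = "")
  cat("  nuclei measured:", nrow(x$nuclei), "\n")
  print(x$summary)
  invisible(x)
}
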