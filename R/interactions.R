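#' Parameters for the long-range-interaction statistics
#'
#' @param threshold_um Distance criterion for calling a long-range
#'   interaction; the default 2 um is inclusive (a pair at exactly 2 um
#'   interacts).
#' @param metric `"per_nucleus_min"` (a nucleus interacts when its closest
#'   cross-pair is within the threshold; the headline percentage) or
#'   `"all_pairs"` (every spot pair is counted separately).
#' @param histogram_bins Number of distance intervals (default 14).
#' @param bin_width_um Interval width, um (default 1).
#' @param last_bin_open If `TRUE` (default) the final interval is open
#'   (`[13, Inf)` with the defaults) so the long tail beyond 10 um is kept.
#' @return A list of class `interaction_params`.
#' @export
interaction_params <- function(threshold_um = 2.0,
                               metric = c("per_nucleus_min", "all_pairs"),
                               histogram_bins = 14, bin_width_um = 1.0,
                               last_bin_open = TRUE) {
  metric <- match.arg(metric)
  stopifnot(threshold_um > 0, histogram_bins >= 1, bin_width_um > 0)
  structure(list(threshold_um = threshold_um, metric = metric,
                 histogram_bins = as.integer(histogram_bins),
                 bin_width_um = bin_width_um, last_bin_open = last_bin_open),
            class = "interaction_params")
}

#' All pairwise 3-D distances between two spot sets
#'
#' For two different genes this is every cross pair (m x n distances); for
#' allele pairing (`b` missing or identical to `a`) it is the distances
#' between distinct spots of the one set, self-pairs excluded.
#'
#' @param a,b Spot coordinates: n x 3 matrices or data frames with columns
#'   x, y, z, in um.
#' @return Numeric vector of Euclidean distances (um).
#' @export
pairwise_distances <- function(a, b = NULL) {
  a <- as_point_matrix(a)
  if (is.null(b)) {
    if (nrow(a) < 2) return(numeric(0))
    return(as.numeric(stats::dist(a)))
  }
  b <- as_point_matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(numeric(0))
  out <- numeric(nrow(a) * nrow(b))
  k <- 1L
  for (i in seq_len(nrow(a))) {
    d <- sqrt((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2)
    out[k:(k + nrow(b) - 1)] <- d
    k <- k + nrow(b)
  }
  out
}

#' Build per-nucleus, per-gene-pair interaction records
#'
#' Computes, for every nucleus and every requested gene pair, all cross
#' distances, the minimum distance, and the interaction call. A record is
#' `valid` only when both genes show their full expected spot complement
#' in that nucleus; invalid records are kept for QC counting but excluded
#' from percentage denominators.
#'
#' @param spots Spots tibble with columns `nucleus_id`, `gene`, `x`, `y`,
#'   `z` (um) and optionally `condition`.
#' @param pairs Character vector of gene pairs, `"A:B"`; `"A:A"` requests
#'   allele pairing within gene A.
#' @param params An [interaction_params()].
#' @param expected_copies Expected spots per gene (default 2).
#' @return Tibble with one row per nucleus x pair: `nucleus_id`,
#'   `condition`, `gene_pair`, `gene_a`, `gene_b`, `n_a`, `n_b`,
#'   `distances` (list column), `n_pairs`, `min_distance_um`,
#'   `n_pairs_interacting`, `interacting`, `valid`.
#' @export
interaction_records <- function(spots, pairs,
                                params = interaction_params(),
                                expected_copies = 2) {
  stopifnot(is.data.frame(spots), length(pairs) >= 1)
  if (!"condition" %in% names(spots)) spots$condition <- "unspecified"
  split_pairs <- strsplit(pairs, ":", fixed = TRUE)
  if (any(lengths(split_pairs) != 2))
    abort("pairs must be given as 'GENEA:GENEB'")

  nuclei <- dplyr::distinct(spots, .data$nucleus_id, .data$condition)
  rows <- vector("list", nrow(nuclei) * length(pairs))
  k <- 1L
  for (i in seq_len(nrow(nuclei))) {
    sub <- spots[spots$nucleus_id == nuclei$nucleus_id[i], , drop = FALSE]
    for (j in seq_along(pairs)) {
      ga <- split_pairs[[j]][1]; gb <- split_pairs[[j]][2]
      sa <- sub[sub$gene == ga, , drop = FALSE]
      d <- if (ga == gb) {
        pairwise_distances(sa)
      } else {
        sb <- sub[sub$gene == gb, , drop = FALSE]
        pairwise_distances(sa, sb)
      }
      n_a <- nrow(sa)
      n_b <- if (ga == gb) n_a else sum(sub$gene == gb)
      valid <- if (ga == gb) n_a == expected_copies
               else n_a == expected_copies && n_b == expected_copies
      rows[[k]] <- tibble(
        nucleus_id = nuclei$nucleus_id[i], condition = nuclei$condition[i],
        gene_pair = pairs[j], gene_a = ga, gene_b = gb,
        n_a = n_a, n_b = n_b,
        distances = list(d), n_pairs = length(d),
        min_distance_um = if (length(d)) min(d) else NA_real_,
        valid = valid)
      k <- k + 1L
    }
  }
  call_interactions(dplyr::bind_rows(rows), params)
}

#' Apply the long-range-interaction criterion to records
#'
#' Sets `interacting` (closest pair within the threshold, inclusive) and
#' `n_pairs_interacting` (for the all-pairs variant) on a record table.
#'
#' @param records Tibble from [interaction_records()].
#' @param params An [interaction_params()].
#' @return The records with the call columns (re)computed.
#' @export
call_interactions <- function(records, params = interaction_params()) {
  thr <- params$threshold_um
  records$n_pairs_interacting <-
    vapply(records$distances, function(d) sum(d <= thr), integer(1))
  records$interacting <- !is.na(records$min_distance_um) &
    records$min_distance_um <= thr
  records
}

#' Bin distances into the standard interval histogram
#'
#' Distances are separated into `histogram_bins` left-closed right-open
#' intervals of width `bin_width_um`; with the defaults that is 14 one-um
#' intervals whose last interval is open (`[13, Inf)`), so the far tail is
#' conserved.
#'
#' @param distances_um Non-negative distances, um.
#' @param params An [interaction_params()].
#' @return An object of class `distance_histogram`: list with `edges`
#'   (length bins + 1, last edge possibly `Inf`), `counts`, `n_total`.
#' @export
bin_distances <- function(distances_um, params = interaction_params()) {
  distances_um <- as.numeric(distances_um)
  if (any(is.na(distances_um))) abort("data error: NA distance")
  if (any(distances_um < 0)) abort("data error: negative distance")
  nb <- params$histogram_bins
  edges <- seq(0, by = params$bin_width_um, length.out = nb + 1)
  if (params$last_bin_open) edges[nb + 1] <- Inf
  if (length(distances_um) && any(distances_um >= edges[nb + 1]))
    abort("data error: distance beyond the histogram support (use an open last bin)")
  idx <- findInterval(distances_um, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = nb)
  structure(list(edges = edges, counts = counts,
                 n_total = length(distances_um)),
            class = "distance_histogram")
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf("<distance_histogram> %d intervals, n = %d\n",
              length(x$counts), x$n_total))
  print(tidy(x), ...)
  invisible(x)
}

#' @describeIn bin_distances Tidy a histogram into a tibble (bin_lo,
#'   bin_hi, count, proportion).
#' @param x A `distance_histogram`.
#' @param ... Unused.
#' @export
tidy.distance_histogram <- function(x, ...) {
  nb <- length(x$counts)
  tibble(bin_lo = x$edges[seq_len(nb)], bin_hi = x$edges[-1],
         count = x$counts,
         proportion = if (x$n_total > 0) x$counts / x$n_total else rep(NA_real_, nb))
}
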