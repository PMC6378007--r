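#' Aggregate interaction records into condition-level percentages
#'
#' Computes, per condition and gene pair, the percentage of interacting
#' nuclei (or of interacting spot pairs under the all-pairs metric) with
#' its error bar. When a replicate column with at least two levels is
#' present the error is the SEM of the replicate percentages (the error-bar
#' convention of two-replicate bar charts); otherwise the binomial standard
#' error `100 * sqrt(p(1-p)/n)` is used. Only nuclei with a full spot
#' complement enter the denominator; excluded nuclei are reported in
#' `n_excluded`.
#'
#' @param records Record tibble from [interaction_records()].
#' @param params An [interaction_params()]; `params$metric` selects the
#'   percentage definition.
#' @param replicate_col Optional name of a replicate id column in
#'   `records`.
#' @return Tibble with columns `condition`, `gene_pair`, `metric`,
#'   `percent`, `sem`, `n_nuclei`, `n_excluded`, `n_replicates`.
#' @export
summarize_condition <- function(records, params = interaction_params(),
                                replicate_col = NULL) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  groups <- dplyr::group_split(dplyr::group_by(records, .data$condition, .data$gene_pair))
  out <- lapply(groups, function(g) {
    valid <- g[g$valid, , drop = FALSE]
    if (nrow(valid) == 0)
      abort(paste0("aggregation error: no valid nuclei for ",
                   g$condition[1], " / ", g$gene_pair[1]))
    pct_of <- function(v) {
      if (params$metric == "per_nucleus_min") 100 * mean(v$interacting)
      else 100 * sum(v$n_pairs_interacting) / sum(v$n_pairs)
    }
    pct <- pct_of(valid)
    reps <- if (!is.null(replicate_col)) unique(valid[[replicate_col]]) else NULL
    if (length(reps) >= 2) {
      rp <- vapply(reps, function(r) pct_of(valid[valid[[replicate_col]] == r, ]),
                   numeric(1))
      pct <- mean(rp)
      sem <- sd(rp) / sqrt(length(rp))
      n_rep <- length(reps)
    } else {
      n <- if (params$metric == "per_nucleus_min") nrow(valid) else sum(valid$n_pairs)
      sem <- 100 * sqrt(pct / 100 * (1 - pct / 100) / n)
      n_rep <- 1L
    }
    tibble(condition = g$condition[1], gene_pair = g$gene_pair[1],
           metric = params$metric, percent = pct, sem = sem,
           n_nuclei = nrow(valid), n_excluded = nrow(g) - nrow(valid),
           n_replicates = n_rep)
  })
  dplyr::bind_rows(out)
}

star_level <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   .default = "")
}

#' Compare interaction rates between two conditions
#'
#' Student's t-test on the per-nucleus interaction indicators of the two
#' groups (Welch by default; set `var_equal = TRUE` for the classic pooled
#' test). Stars follow the usual convention: `***` p < 0.001, `**`
#' p < 0.01, `*` p < 0.05.
#'
#' @param records_a,records_b Record tibbles (single condition and gene
#'   pair each) from [interaction_records()].
#' @param var_equal Use the pooled-variance Student's t-test.
#' @return One-row tibble: `percent_a`, `percent_b`, `n_a`, `n_b`,
#'   `statistic`, `df`, `p_value`, `stars`.
#' @export
compare_conditions <- function(records_a, records_b, var_equal = FALSE) {
  ia <- indicator_vector(records_a)
  ib <- indicator_vector(records_b)
  if (length(ia) < 2 || length(ib) < 2)
    abort("comparison error: each group needs at least 2 valid nuclei")
  tt <- degenerate_safe_t_test(ia, ib, var_equal)
  tibble(percent_a = 100 * mean(ia), percent_b = 100 * mean(ib),
         n_a = length(ia), n_b = length(ib),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, stars = star_level(tt$p.value))
}

# t.test() refuses zero-variance data; return the limiting statistic
# instead (t = 0, p = 1 for identical constant groups; |t| = Inf, p = 0
# for distinct constant groups).
degenerate_safe_t_test <- function(a, b, var_equal) {
  df0 <- length(a) + length(b) - 2
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = c(t = 0), parameter = c(df = df0), p.value = 1))
    return(list(statistic = c(t = sign(mean(a) - mean(b)) * Inf),
                parameter = c(df = df0), p.value = 0))
  }
  t.test(a, b, var.equal = var_equal)
}

indicator_vector <- function(records) {
  v <- records[records$valid, , drop = FALSE]
  as.numeric(v$interacting)
}

#' Compare nuclear volumes between two conditions
#'
#' Per-condition mean and SEM, the volume ratio B/A, and a Student's
#' t-test (Welch by default). Nuclei flagged as touching the stack border
#' should be excluded upstream since their volume is truncated.
#'
#' @param volumes_a,volumes_b Numeric vectors of nuclear volumes (um^3), or
#'   data frames with a `volume_um3` column.
#' @param var_equal Use the pooled-variance test.
#' @return One-row tibble: `mean_a`, `sem_a`, `mean_b`, `sem_b`, `ratio`
#'   (B/A), `statistic`, `df`, `p_value`, `stars`.
#' @export
compare_volumes <- function(volumes_a, volumes_b, var_equal = FALSE) {
  va <- volume_vector(volumes_a)
  vb <- volume_vector(volumes_b)
  if (length(va) < 2 || length(vb) < 2)
    abort("comparison error: each group needs at least 2 nuclei")
  tt <- degenerate_safe_t_test(va, vb, var_equal)
  tibble(mean_a = mean(va), sem_a = sd(va) / sqrt(length(va)),
         mean_b = mean(vb), sem_b = sd(vb) / sqrt(length(vb)),
         ratio = mean(vb) / mean(va),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, stars = star_level(tt$p.value))
}

volume_vector <- function(v) {
  if (is.data.frame(v)) v <- v$volume_um3
  v <- as.numeric(v)
  stopifnot(all(v > 0))
  v
}
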