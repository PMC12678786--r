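#' Per-sample coverage decay rate for one gene
#'
#' Summarizes degradation-style positional coverage bias as the ordinary
#' least-squares slope of `log10(depth + 1)` against normalized transcript
#' position over exonic bases, ordered 5' to 3' (genomic order for `+`
#' strand genes, reversed for `-` strand), sign-flipped so that coverage
#' decaying along the 5'->3' transcript axis gives a larger (positive)
#' decay; higher decay means more severe degradation. Flat coverage
#' gives 0. Genes with fewer than `min_covered` exonic
#' positions of nonzero depth return `NA`: a slope fit on a near-empty vector
#' is noise, and such entries are excluded from pooling.
#'
#' @param matrix A [coverage_matrix()].
#' @param sample Sample id (or column index).
#' @param model Optional [gene_model()]; defaults to the matrix's own model.
#'   Only the strand is used.
#' @param min_covered Minimum exonic positions with nonzero depth for a
#'   finite value (default 50).
#' @return A single number, or `NA_real_` when coverage is too sparse.
#' @export
decay_rate <- function(matrix, sample, model = NULL, min_covered = 50L) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  if (is.null(model)) model <- matrix$model
  strand <- if (is.null(model)) "+" else model$strand
  if (is.character(sample) && !sample %in% matrix$sample_ids)
    stop("unknown sample: ", sample)
  y <- matrix$depth[matrix$exon_mask, sample]
  if (sum(y > 0) < min_covered) return(NA_real_)
  if (strand == "-") y <- rev(y)
  n <- length(y)
  x <- if (n > 1L) seq(0, 1, length.out = n) else 0.5
  ly <- log10(y + 1)
  # OLS slope, closed form
  slope <- sum((x - mean(x)) * (ly - mean(ly))) / sum((x - mean(x))^2)
  -slope
}

#' Decay-rate table for a cohort
#'
#' @param store A [cohort_store()] whose genes carry models (for strand).
#' @param min_covered Passed to [decay_rate()].
#' @return Object of class `decay_table`: samples x genes matrix `decay`
#'   (`NA` = too sparse), plus `n_pooled`, the count of finite entries.
#' @export
decay_table <- function(store, min_covered = 50L) {
  genes <- store_genes(store)
  ids <- store_samples(store)
  if (length(genes) == 0L || length(ids) == 0L) stop("empty cohort store")
  decay <- matrix(NA_real_, nrow = length(ids), ncol = length(genes),
                  dimnames = list(ids, genes))
  for (g in genes) {
    cm <- store_read(store, g)
    for (s in ids) decay[s, g] <- decay_rate(cm, s, min_covered = min_covered)
  }
  structure(list(sample_ids = ids, gene_ids = genes, decay = decay,
                 n_pooled = sum(is.finite(decay))),
            class = "decay_table")
}

#' @export
print.decay_table <- function(x, ...) {
  cat(sprintf("decay_table: %d sample(s) x %d gene(s), %d finite value(s)\n",
              length(x$sample_ids), length(x$gene_ids), x$n_pooled))
  invisible(x)
}

#' Pooled decay threshold (global degraded/non-degraded cut)
#'
#' Pools every finite decay value across all samples and genes, sorts them in
#' descending order, and returns the value at rank `ceil(top_frac * N)`
#' (1-based) — the 95th-percentile cut at the default `top_frac = 0.05`.
#' Being an order statistic, it is invariant to any permutation of the pool.
#'
#' @param table A [decay_table()] (or a bare numeric vector of pooled values).
#' @param top_frac Fraction of the pool called degraded, in (0, 1).
#' @export
pooled_decay_threshold <- function(table, top_frac = 0.05) {
  stopifnot(top_frac > 0, top_frac < 1)
  pool <- if (inherits(table, "decay_table")) table$decay else as.numeric(table)
  pool <- pool[is.finite(pool)]
  if (length(pool) == 0L) stop("no finite decay values to pool")
  sorted <- sort(pool, decreasing = TRUE)
  sorted[ceiling(top_frac * length(sorted))]
}

#' Flag genome-widely degraded samples
#'
#' A (sample, gene) entry is degraded when its decay exceeds the pooled
#' threshold (strictly); a sample is excluded when its fraction of degraded
#' genes, over the genes with a finite decay value, exceeds
#' `max_degraded_gene_frac` (strictly, per "more than 10%").
#'
#' @param table A [decay_table()].
#' @param threshold Global decay cut, typically [pooled_decay_threshold()];
#'   computed from `table` at `top_frac` when omitted.
#' @param max_degraded_gene_frac Exclusion cut on the per-sample degraded
#'   fraction (default 0.10).
#' @param top_frac Used only when `threshold` is omitted.
#' @return Object of class `sample_filter`: `threshold`,
#'   `degraded_gene_frac` (named per sample), `retained`, `excluded`,
#'   `params`.
#' @export
flag_degraded <- function(table, threshold = NULL,
                          max_degraded_gene_frac = 0.10, top_frac = 0.05) {
  stopifnot(inherits(table, "decay_table"))
  if (is.null(threshold)) threshold <- pooled_decay_threshold(table, top_frac)
  if (!is.finite(threshold)) stop("threshold must be finite")
  frac <- stats::setNames(numeric(length(table$sample_ids)), table$sample_ids)
  for (s in table$sample_ids) {
    d <- table$decay[s, ]
    ok <- is.finite(d)
    if (!any(ok)) {
      warning("sample ", s, " has no finite decay values; retained with fraction 0")
      frac[s] <- 0
    } else {
      frac[s] <- sum(d[ok] > threshold) / sum(ok)
    }
  }
  excluded <- names(frac)[frac > max_degraded_gene_frac]
  structure(list(threshold = threshold, degraded_gene_frac = frac,
                 retained = setdiff(table$sample_ids, excluded),
                 excluded = excluded,
                 params = list(top_frac = top_frac,
                               max_degraded_gene_frac = max_degraded_gene_frac)),
            class = "sample_filter")
}

#' @export
print.sample_filter <- function(x, ...) {
  cat(sprintf(
    "sample_filter: threshold %.4g; %d retained, %d excluded (max degraded-gene fraction %.2f)\n",
    x$threshold, length(x$retained), length(x$excluded),
    x$params$max_degraded_gene_frac))
  invisible(x)
}
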