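#' Parameters for on/off state calling
#'
#' A sample is *on* for a gene iff its LSS is strictly greater than
#' `lss_threshold`; a boundary value equal to the threshold is *off*. The
#' default 0.6 separates the modes of bimodal LSS distributions of
#' known-silenced genes (XIST in males, Y-chromosome genes in females).
#'
#' @param lss_threshold Cut in (0, 1); default 0.6.
#' @export
on_off_params <- function(lss_threshold = 0.6) {
  stopifnot(lss_threshold > 0, lss_threshold < 1)
  structure(list(lss_threshold = lss_threshold,
                 boundary_rule = "strictly greater => on"),
            class = "on_off_params")
}

#' Binarize an LSS matrix into on/off states
#'
#' @param lss An [lss_matrix()] (or numeric matrix in `[0, 1]` with
#'   dimnames).
#' @param params An [on_off_params()].
#' @return Object of class `on_off_matrix`: integer matrix (1 = on, 0 = off)
#'   of the same shape, with `params` attached.
#' @export
call_on_off <- function(lss, params = on_off_params()) {
  m <- unclass(as.matrix(lss))
  if (anyNA(m) || any(m < 0) || any(m > 1))
    stop("LSS values must lie in [0, 1]")
  state <- matrix(as.integer(m > params$lss_threshold), nrow = nrow(m),
                  dimnames = dimnames(m))
  structure(state, params = params,
            class = c("on_off_matrix", "matrix", "array"))
}

#' @export
print.on_off_matrix <- function(x, ...) {
  cat(sprintf("on_off_matrix: %d gene(s) x %d sample(s), %.1f%% on (threshold %.2f)\n",
              nrow(x), ncol(x), 100 * mean(x),
              attr(x, "params")$lss_threshold))
  invisible(x)
}

#' Define the offonome gene set of a cohort
#'
#' The offonome is the set of genes that are *off* in at least
#' `min_off_frac` of the cohort's samples (inclusive boundary), regardless of
#' expression level; recurrent off states are unlikely to arise from a few
#' outlying samples. Off fractions are recorded for every gene, members and
#' non-members alike.
#'
#' @param states An [call_on_off()] matrix.
#' @param min_off_frac Minimum off fraction for membership, in (0, 1];
#'   default 0.20.
#' @param cohort_name Label carried into the result.
#' @return Object of class `offonome_set`: `gene_ids` (members),
#'   `off_fraction` (all genes), `min_off_frac`, `n_samples`, `cohort_name`.
#' @export
define_offonome <- function(states, min_off_frac = 0.20,
                            cohort_name = "cohort") {
  stopifnot(min_off_frac > 0, min_off_frac <= 1)
  m <- unclass(as.matrix(states))
  if (ncol(m) == 0L) stop("state matrix has zero samples")
  if (!all(m %in% c(0L, 1L))) stop("states must be 0/1")
  off_frac <- rowMeans(m == 0L)
  members <- rownames(m)[off_frac >= min_off_frac]
  structure(list(cohort_name = cohort_name, gene_ids = members,
                 off_fraction = off_frac, min_off_frac = min_off_frac,
                 n_samples = ncol(m)),
            class = "offonome_set")
}

#' @export
print.offonome_set <- function(x, ...) {
  cat(sprintf(
    "offonome_set '%s': %d gene(s) off in >= %.0f%% of %d samples (of %d assessed)\n",
    x$cohort_name, length(x$gene_ids), 100 * x$min_off_frac, x$n_samples,
    length(x$off_fraction)))
  invisible(x)
}

#' Exclusive Venn partition of 2 or 3 gene sets
#'
#' Counts every exclusive membership region. Regions are named by the sorted
#' member set names joined with `&` (e.g. `"LUAD&LUSC"`), so the partition is
#' invariant to the order the sets are supplied in; region counts always sum
#' to the union size, and pairwise unions obey inclusion-exclusion.
#'
#' @param sets Named list of 2 or 3 character vectors (or
#'   [define_offonome()] results, whose member `gene_ids` are used).
#' @return Object of class `venn_partition`: `regions` (named counts),
#'   `union_size`, `set_sizes`.
#' @export
venn_partition <- function(sets) {
  sets <- lapply(sets, function(s)
    if (inherits(s, "offonome_set")) s$gene_ids else as.character(s))
  if (length(sets) < 2L || length(sets) > 3L)
    stop("venn_partition needs 2 or 3 named sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  member <- matrix(member, ncol = length(sets),
                   dimnames = list(NULL, names(sets)))
  patterns <- region_names(names(sets))
  regions <- stats::setNames(integer(length(patterns)), patterns)
  if (length(all_genes)) {
    key <- apply(member, 1L, function(r)
      paste(sort(names(sets)[r]), collapse = "&"))
    tab <- table(key)
    regions[names(tab)] <- as.integer(tab)
  }
  structure(list(regions = regions, union_size = length(all_genes),
                 set_sizes = vapply(sets, length, 0L)),
            class = "venn_partition")
}

region_names <- function(set_names) {
  s <- sort(set_names)
  combs <- unlist(lapply(seq_along(s), function(k)
    utils::combn(s, k, paste, collapse = "&")))
  combs
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("venn_partition of %d sets, union %d gene(s)\n",
              length(x$set_sizes), x$union_size))
  for (r in names(x$regions))
    cat(sprintf("  %-24s %6d\n", r, x$regions[[r]]))
  invisible(x)
}

#' Count-based low-expression filter rule
#'
#' The conventional counts-per-million filter used by differential-expression
#' pipelines, kept here as a comparator for the shape-based offonome (it is
#' not a recommended filter). Defaults follow the widely used convention:
#' `min_count = 10`, `min_total_count = 15`, `min_prop = 0.7`,
#' `large_n = 10`.
#'
#' @param min_count Per-sample count a gene must reach (as CPM-equivalent).
#' @param min_total_count Minimum total count across samples.
#' @param min_prop,large_n Group-size adjustment: with the smallest group of
#'   size `n > large_n`, the required number of passing samples is
#'   `large_n + (n - large_n) * min_prop`.
#' @export
count_filter_rule <- function(min_count = 10, min_total_count = 15,
                              min_prop = 0.7, large_n = 10) {
  stopifnot(min_count >= 0, min_total_count >= 0, min_prop >= 0,
            min_prop <= 1, large_n >= 0)
  structure(list(min_count = min_count, min_total_count = min_total_count,
                 min_prop = min_prop, large_n = large_n),
            class = "count_filter_rule")
}

#' Apply the count-based low-expression filter
#'
#' Keeps genes whose counts-per-million reach a cutoff — `min_count`
#' rescaled by the median library size — in at least `k` samples, where `k`
#' is the smallest group size (adjusted by `min_prop` beyond `large_n`), and
#' whose total count reaches `min_total_count`. Small numeric tolerances
#' match the conventional implementation so boundary genes are treated
#' identically.
#'
#' @param counts Non-negative gene x sample count matrix.
#' @param rule A [count_filter_rule()].
#' @param group Optional factor of sample groups; the smallest group drives
#'   `k`. Default: all samples one group.
#' @return Character vector of retained gene ids (rownames), or retained row
#'   indices when `counts` has no rownames.
#' @export
count_filter <- function(counts, rule = count_filter_rule(), group = NULL) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  lib_size <- colSums(counts)
  if (any(lib_size == 0)) stop("library with zero total counts")
  n <- if (is.null(group)) ncol(counts) else min(table(group))
  if (n > rule$large_n) n <- rule$large_n + (n - rule$large_n) * rule$min_prop
  median_lib <- stats::median(lib_size)
  cpm_cutoff <- rule$min_count / median_lib * 1e6
  cpm <- t(t(counts) / lib_size) * 1e6
  tol <- 1e-14
  keep <- rowSums(cpm >= cpm_cutoff) >= (n - tol) &
    rowSums(counts) >= (rule$min_total_count - tol)
  if (!is.null(rownames(counts))) rownames(counts)[keep] else which(keep)
}

#' Fraction of one gene set contained in another
#'
#' `|a intersect b| / |a|` — e.g. the fraction of offonome genes that a
#' count-based filter would also remove.
#'
#' @param a Non-empty character vector (reference set).
#' @param b Character vector.
#' @export
overlap_fraction <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (length(a) == 0L) stop("reference set is empty")
  length(intersect(a, b)) / length(a)
}
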