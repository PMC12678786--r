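#' Parameters for Level of Shape Similarity computation
#'
#' @param k Pseudo-offset inside the log transform, `log10(depth + k)`;
#'   with the default `k = 1` a zero depth maps to exactly 0 and coverage
#'   vectors stay non-negative, keeping the cosine in `[0, 1]`.
#' @param min_expressed_frac Minimum fraction of samples that must show
#'   expression (total raw depth > 0) for a mean profile to be defined;
#'   genes below it get LSS 0 everywhere so unexpressed or noise-dominated
#'   genes are never called *on*. Default 0.05.
#' @param max_iter Maximum mean-profile refinement iterations (default 20).
#' @param tol L2 convergence tolerance on the mean-profile change
#'   (default 1e-6).
#' @param trim_quantile Fraction of the least-similar expressed samples
#'   excluded when the mean profile is re-estimated each round (default
#'   0.05); robustifies the consensus shape against outliers.
#' @param domain `"full_locus"` (default; introns included) or
#'   `"exons_only"`.
#' @return Object of class `lss_params`.
#' @export
lss_params <- function(k = 1, min_expressed_frac = 0.05, max_iter = 20L,
                       tol = 1e-6, trim_quantile = 0.05,
                       domain = c("full_locus", "exons_only")) {
  domain <- match.arg(domain)
  stopifnot(k > 0, min_expressed_frac >= 0, min_expressed_frac < 1,
            trim_quantile > 0, trim_quantile < 0.5, tol > 0, max_iter >= 1L)
  structure(list(k = k, min_expressed_frac = min_expressed_frac,
                 max_iter = as.integer(max_iter), tol = tol,
                 trim_quantile = trim_quantile, domain = domain),
            class = "lss_params")
}

#' Log-adjust read depths
#'
#' `log10(depth + k)`, elementwise. With `k = 1`, 0 -> 0, 9 -> 1, 99 -> 2.
#'
#' @param depth Non-negative numeric vector or matrix.
#' @param k Positive pseudo-offset.
#' @export
log_adjust <- function(depth, k = 1) {
  if (k <= 0) stop("k must be positive")
  if (anyNA(depth) || any(depth < 0)) stop("depths must be non-negative")
  log10(depth + k)
}

#' Cosine similarity between two non-negative shape vectors
#'
#' `<u,v> / (||u|| ||v||)`: 1 iff the vectors are positive scalar multiples
#' (identical shape), 0 for orthogonal shapes. A zero-norm vector has no
#' defined shape and returns 0, matching the convention that zero-read
#' samples get LSS 0.
#'
#' @param u,v Equal-length non-negative numeric vectors.
#' @export
shape_cosine <- function(u, v) {
  if (length(u) != length(v))
    stop("vectors differ in length (", length(u), " vs ", length(v), ")")
  if (anyNA(u) || anyNA(v) || any(u < 0) || any(v < 0))
    stop("shape vectors must be non-negative")
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) return(0)
  min(1, sum(u * v) / (nu * nv))
}

# cosine of every column of M against vector v; zero-norm columns -> 0
col_cosines <- function(M, v) {
  nv <- sqrt(sum(v * v))
  if (nv == 0) return(numeric(ncol(M)))
  nm <- sqrt(colSums(M * M))
  out <- numeric(ncol(M))
  ok <- nm > 0
  out[ok] <- pmin(1, colSums(M[, ok, drop = FALSE] * v) / (nm[ok] * nv))
  out
}

#' Iteratively refined cohort mean coverage profile
#'
#' Estimates the consensus shape of a gene. A sample "shows expression" when
#' its total raw depth is positive; if fewer than `min_expressed_frac` of
#' samples do, the profile is undefined and all LSS values for the gene are 0.
#' Otherwise, starting from all expressed samples, the mean of the logged
#' columns is computed, every expressed sample is scored by cosine against
#' it, and the lowest `trim_quantile` fraction is set aside before the mean
#' is re-estimated; rounds repeat until the mean vector moves less than `tol`
#' in L2 norm or `max_iter` is reached. Ties at the trim boundary break by
#' sample id so the procedure is deterministic.
#'
#' @param logged Non-negative numeric matrix (positions x samples) of
#'   log-adjusted depths.
#' @param raw_totals Total raw depth per sample (defines "expressed"); when
#'   omitted, a positive logged column sum stands in.
#' @param params An [lss_params()].
#' @return Object of class `mean_profile` with fields `vector` (NULL when
#'   undefined), `expressed_fraction`, `defined`, `n_iterations`, `converged`.
#' @export
mean_profile <- function(logged, params = lss_params(), raw_totals = NULL) {
  logged <- as.matrix(logged)
  if (nrow(logged) == 0L || ncol(logged) == 0L) stop("empty coverage matrix")
  if (anyNA(logged) || any(logged < 0))
    stop("logged depths must be non-negative")
  if (is.null(raw_totals)) raw_totals <- colSums(logged)
  expressed <- which(raw_totals > 0)
  frac <- length(expressed) / ncol(logged)
  undefined <- structure(list(vector = NULL, expressed_fraction = frac,
                              defined = FALSE, n_iterations = 0L,
                              converged = TRUE),
                         class = "mean_profile")
  if (frac < params$min_expressed_frac || length(expressed) == 0L)
    return(undefined)

  ids <- colnames(logged)
  if (is.null(ids)) ids <- sprintf("s%06d", seq_len(ncol(logged)))
  sub <- logged[, expressed, drop = FALSE]
  sub_ids <- ids[expressed]
  n_drop <- floor(params$trim_quantile * length(expressed))

  keep <- seq_len(ncol(sub))
  m <- rowMeans(sub[, keep, drop = FALSE])
  iter <- 0L; converged <- FALSE
  while (iter < params$max_iter) {
    iter <- iter + 1L
    cs <- col_cosines(sub, m)
    if (n_drop > 0L) {
      # lowest-cosine samples out; ties at the boundary break by sample id
      ord <- order(cs, sub_ids)
      keep <- sort(ord[(n_drop + 1L):length(ord)])
    }
    m_new <- rowMeans(sub[, keep, drop = FALSE])
    delta <- sqrt(sum((m_new - m)^2))
    m <- m_new
    if (delta < params$tol) { converged <- TRUE; break }
  }
  structure(list(vector = m, expressed_fraction = frac, defined = TRUE,
                 n_iterations = iter, converged = converged),
            class = "mean_profile")
}

#' @export
print.mean_profile <- function(x, ...) {
  if (x$defined)
    cat(sprintf(
      "mean_profile: defined, %d positions, expressed fraction %.3f, %d iteration(s), %s\n",
      length(x$vector), x$expressed_fraction, x$n_iterations,
      if (x$converged) "converged" else "max_iter reached"))
  else
    cat(sprintf("mean_profile: undefined (expressed fraction %.3f)\n",
                x$expressed_fraction))
  invisible(x)
}

#' Level of Shape Similarity for every sample of one gene
#'
#' LSS of a sample is the cosine between its log-adjusted coverage vector and
#' the gene's refined mean profile. Genes with zero reads in every sample, or
#' whose mean profile is undefined (too few expressed samples), get exactly 0
#' for all samples; zero-depth samples get 0 through the zero-norm rule.
#'
#' @param matrix A [coverage_matrix()] (or plain depth matrix).
#' @param params An [lss_params()].
#' @param diagnostics Also return the mean-profile diagnostics.
#' @return Named numeric vector of LSS values in `[0, 1]`, one per sample;
#'   with `diagnostics = TRUE`, a list `(lss, profile)`.
#' @export
compute_lss <- function(matrix, params = lss_params(), diagnostics = FALSE) {
  if (inherits(matrix, "coverage_matrix")) {
    depth <- matrix$depth
    if (params$domain == "exons_only")
      depth <- depth[matrix$exon_mask, , drop = FALSE]
  } else {
    depth <- as.matrix(matrix)
  }
  if (anyNA(depth) || any(depth < 0)) stop("depths must be non-negative")
  ids <- colnames(depth)
  if (is.null(ids)) ids <- sprintf("s%06d", seq_len(ncol(depth)))
  out <- stats::setNames(numeric(ncol(depth)), ids)

  raw_totals <- colSums(depth)
  if (all(raw_totals == 0)) {
    prof <- structure(list(vector = NULL, expressed_fraction = 0,
                           defined = FALSE, n_iterations = 0L,
                           converged = TRUE), class = "mean_profile")
    return(if (diagnostics) list(lss = out, profile = prof) else out)
  }
  logged <- log_adjust(depth, params$k)
  colnames(logged) <- ids
  prof <- mean_profile(logged, params, raw_totals = raw_totals)
  if (prof$defined) out[] <- col_cosines(logged, prof$vector)
  if (diagnostics) list(lss = out, profile = prof) else out
}

#' Genes x samples LSS matrix
#'
#' @param values Numeric matrix in `[0, 1]`, genes in rows, samples in
#'   columns, both dimensions named.
#' @param diagnostics Optional per-gene diagnostics list.
#' @return Object of class `lss_matrix` (a numeric matrix with extra class
#'   and attribute).
#' @export
lss_matrix <- function(values, diagnostics = NULL) {
  values <- as.matrix(values)
  if (anyNA(values) || any(values < 0) || any(values > 1))
    stop("LSS values must lie in [0, 1]")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("gene and sample names required")
  structure(values, diagnostics = diagnostics,
            class = c("lss_matrix", "matrix", "array"))
}

#' @export
print.lss_matrix <- function(x, ...) {
  cat(sprintf("lss_matrix: %d gene(s) x %d sample(s), values in [%.3f, %.3f]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Compute the LSS matrix for a whole cohort store
#'
#' @param store A [cohort_store()].
#' @param params An [lss_params()].
#' @return An [lss_matrix()] with per-gene diagnostics (expressed fraction,
#'   iterations, convergence) in `attr(, "diagnostics")`.
#' @export
compute_lss_cohort <- function(store, params = lss_params()) {
  genes <- store_genes(store)
  if (length(genes) == 0L) stop("cohort store is empty")
  ids <- store_samples(store)
  vals <- matrix(0, nrow = length(genes), ncol = length(ids),
                 dimnames = list(genes, ids))
  diags <- vector("list", length(genes)); names(diags) <- genes
  for (g in genes) {
    cm <- store_read(store, g)
    if (!identical(cm$sample_ids, ids))
      stop("gene ", g, ": sample set differs from the cohort manifest")
    res <- compute_lss(cm, params, diagnostics = TRUE)
    vals[g, ] <- res$lss
    p <- res$profile
    diags[[g]] <- list(expressed_fraction = p$expressed_fraction,
                       defined = p$defined, n_iterations = p$n_iterations,
                       converged = p$converged)
  }
  lss_matrix(vals, diagnostics = diags)
}

#' Write an LSS matrix as TSV (plus JSON diagnostics sidecar)
#'
#' @param lss An [lss_matrix()].
#' @param path Output TSV; values printed with 6 decimals. When diagnostics
#'   are attached, `<path>.diag.json` is written alongside.
#' @export
write_lss_tsv <- function(lss, path) {
  df <- data.frame(gene_id = rownames(lss),
                   format(round(unclass(lss), 6), nsmall = 6, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  diags <- attr(lss, "diagnostics")
  if (!is.null(diags))
    jsonlite::write_json(diags, paste0(path, ".diag.json"), auto_unbox = TRUE,
                         pretty = TRUE)
  invisible(path)
}

#' Read an LSS matrix written by [write_lss_tsv()]
#' @param path TSV path.
#' @export
read_lss_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  lss_matrix(m)
}
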