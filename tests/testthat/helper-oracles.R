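# Independent brute-force oracles. These deliberately avoid the package's
# code paths: the pileup oracle walks CIGAR strings base by base, the cosine
# oracle is direct arithmetic, and the Ward oracle re-derives every merge by
# exhaustive evaluation of the variance-increase criterion.

# naive O(reads x length) pileup over the locus [start0, end0) of `chrom`
# from raw SAM text lines; M/=/X add depth, D/N consume reference silently
oracle_pileup <- function(sam_lines, chrom, start0, end0) {
  depth <- integer(end0 - start0)
  for (line in sam_lines) {
    if (startsWith(line, "@")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (f[3] != chrom) next
    pos <- as.integer(f[4]) - 1L  # SAM is 1-based
    cigar <- f[6]
    ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    ref <- pos
    for (op in ops) {
      n <- as.integer(sub("[MIDNSHP=X]$", "", op))
      type <- substr(op, nchar(op), nchar(op))
      if (type %in% c("M", "=", "X")) {
        for (p in ref:(ref + n - 1L)) {
          if (p >= start0 && p < end0) {
            i <- p - start0 + 1L
            depth[i] <- depth[i] + 1L
          }
        }
        ref <- ref + n
      } else if (type %in% c("D", "N")) {
        ref <- ref + n
      } # I/S/H/P consume no reference
    }
  }
  depth
}

oracle_cosine <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

# plain-mean LSS with no iteration/trim: cosine of each logged column against
# the arithmetic mean of the logged columns of expressed samples
oracle_lss_plain <- function(depth, k = 1, min_expressed_frac = 0.05) {
  out <- numeric(ncol(depth))
  expressed <- colSums(depth) > 0
  if (mean(expressed) < min_expressed_frac || !any(expressed)) return(out)
  logged <- log10(depth + k)
  m <- rowMeans(logged[, expressed, drop = FALSE])
  for (j in seq_len(ncol(depth))) out[j] <- oracle_cosine(logged[, j], m)
  out
}

# exhaustive Ward agglomeration on a points-in-rows matrix: at each step,
# evaluate the within-cluster sum-of-squares increase of every candidate
# merge and take the minimum (ties -> lexicographically lowest index pair).
# Heights follow the sqrt(2 * delta-ESS) convention so singleton merges sit
# at their Euclidean distance.
oracle_ward <- function(pts) {
  clusters <- lapply(seq_len(nrow(pts)), identity)
  merges <- list()
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- NULL; best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      a <- clusters[[i]]; b <- clusters[[j]]
      ca <- colMeans(pts[a, , drop = FALSE])
      cb <- colMeans(pts[b, , drop = FALSE])
      d_ess <- length(a) * length(b) / (length(a) + length(b)) *
        sum((ca - cb)^2)
      if (d_ess < best_d - 1e-12) { best_d <- d_ess; best <- c(i, j) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- merged
    heights <- c(heights, sqrt(2 * best_d))
    clusters <- c(clusters[-best], list(merged))
  }
  list(merges = merges, heights = heights)
}

# member sets created by each merge of an hclust tree, in merge order
hclust_merge_sets <- function(hc) {
  n <- nrow(hc$merge) + 1L
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    members <- integer()
    for (v in hc$merge[i, ]) {
      members <- c(members, if (v < 0) -v else sets[[v]])
    }
    sets[[i]] <- sort(members)
  }
  sets
}

# deterministic id pools for constructing gene sets of prescribed sizes
make_ids <- function(n, prefix = "g") sprintf("%s%05d", prefix, seq_len(n))

# a small coverage_matrix fixture over a single-exon locus
toy_coverage <- function(depth, gene_id = "toy", strand = "+") {
  depth <- as.matrix(depth)
  L <- nrow(depth)
  model <- gene_model(gene_id, "chrT", strand, 0L, L, cbind(0L, L))
  ids <- colnames(depth)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(ncol(depth)))
  coverage_matrix(gene_id, depth, sample_ids = ids, model = model)
}
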