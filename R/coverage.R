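#' Per-gene base-resolution coverage matrix
#'
#' The central "pileup data object": integer read depth at every position of
#' the full gene locus (exons and introns), one column per sample.
#'
#' @param gene_id Gene identifier.
#' @param depth Integer matrix, `locus_length` rows x samples columns, all
#'   entries non-negative.
#' @param sample_ids Unique sample identifiers, one per column.
#' @param exon_mask Logical vector flagging exonic rows.
#' @param model Optional owning [gene_model()]; when given, `depth` row count
#'   must equal its `locus_length` and `exon_mask` defaults from it.
#' @return Object of class `coverage_matrix`.
#' @export
coverage_matrix <- function(gene_id, depth, sample_ids, exon_mask = NULL,
                            model = NULL) {
  depth <- as.matrix(depth)
  storage.mode(depth) <- "integer"
  if (anyNA(depth) || any(depth < 0L)) stop("depths must be non-negative")
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != ncol(depth))
    stop("sample_ids length != number of columns")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (!is.null(model)) {
    stopifnot(inherits(model, "gene_model"))
    if (nrow(depth) != model$locus_length)
      stop("depth has ", nrow(depth), " rows but locus_length is ",
           model$locus_length)
    if (is.null(exon_mask)) exon_mask <- exon_mask(model)
  }
  if (is.null(exon_mask)) exon_mask <- rep(TRUE, nrow(depth))
  exon_mask <- as.logical(exon_mask)
  if (length(exon_mask) != nrow(depth))
    stop("exon_mask length != number of rows")
  dimnames(depth) <- list(NULL, sample_ids)
  structure(list(gene_id = as.character(gene_id), depth = depth,
                 sample_ids = sample_ids, exon_mask = exon_mask,
                 model = model),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf(
    "coverage_matrix %s: %d positions (%d exonic) x %d samples, total depth %.0f\n",
    x$gene_id, nrow(x$depth), sum(x$exon_mask), ncol(x$depth), sum(x$depth)))
  invisible(x)
}

#' Restrict a coverage matrix to exonic positions
#'
#' @param matrix A [coverage_matrix()].
#' @return A `coverage_matrix` keeping only exonic rows (its `model` is
#'   dropped since the row axis no longer spans the locus).
#' @export
exons_only <- function(matrix) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  coverage_matrix(matrix$gene_id,
                  matrix$depth[matrix$exon_mask, , drop = FALSE],
                  matrix$sample_ids,
                  exon_mask = rep(TRUE, sum(matrix$exon_mask)))
}

#' Extract base-resolution coverage for one gene from BAM files
#'
#' Builds the positions x samples depth matrix over the full locus of `model`
#' by counting, at every position, the aligned bases of retained reads.
#' Spliced alignments (`N` CIGAR operations) and deletions contribute no
#' depth to the skipped/deleted positions. Counting is strand-agnostic.
#'
#' @param alignment_files Character vector of indexed BAM paths, one per
#'   sample; names (or basenames) become sample ids.
#' @param model A [gene_model()].
#' @param min_mapq Minimum mapping quality (default 0).
#' @param count_mode `"primary_only"` (default) drops secondary and
#'   supplementary alignments; `"all_reads"` keeps them.
#' @param drop_duplicates Drop reads flagged as PCR/optical duplicates
#'   (default `FALSE`).
#' @return A [coverage_matrix()].
#' @export
extract_gene_coverage <- function(alignment_files, model, min_mapq = 0L,
                                  count_mode = c("primary_only", "all_reads"),
                                  drop_duplicates = FALSE) {
  stopifnot(inherits(model, "gene_model"))
  count_mode <- match.arg(count_mode)
  ids <- names(alignment_files)
  if (is.null(ids)) ids <- basename(alignment_files)
  ids <- ifelse(nzchar(ids), ids, basename(alignment_files))

  region <- GenomicRanges::GRanges(model$chrom,
                                   IRanges::IRanges(model$start + 1L, model$end))
  depth <- matrix(0L, nrow = model$locus_length, ncol = length(alignment_files))
  for (j in seq_along(alignment_files)) {
    bam <- alignment_files[[j]]
    if (!file.exists(bam)) stop("BAM not found: ", bam)
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam)))
      stop("BAM index (.bai) missing for ", bam)
    hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
    if (!model$chrom %in% names(hdr))
      stop("contig ", model$chrom, " absent from BAM header of ", bam)
    flags <- Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isSecondaryAlignment = if (count_mode == "primary_only") FALSE else NA,
      isSupplementaryAlignment = if (count_mode == "primary_only") FALSE else NA,
      isDuplicate = if (drop_duplicates) FALSE else NA)
    param <- Rsamtools::ScanBamParam(which = region, flag = flags,
                                     mapqFilter = min_mapq)
    aln <- GenomicAlignments::readGAlignments(bam, param = param)
    if (length(aln)) {
      # count aligned bases only: deletions (D), like splices (N), contribute
      # no depth to the reference positions they span
      grl <- GenomicAlignments::grglist(aln, drop.D.ranges = TRUE)
      cov <- GenomicRanges::coverage(grl)[[model$chrom]]
      # coverage() runs from position 1; take the locus window (1-based)
      win <- S4Vectors::window(cov, start = model$start + 1L, end = model$end)
      depth[, j] <- as.integer(win)
    }
  }
  coverage_matrix(model$gene_id, depth, ids, model = model)
}

#' Write one gene's coverage matrix as TSV
#'
#' Columns: `position` (0-based locus-relative), `exon` (0/1), then one
#' integer depth column per sample.
#'
#' @param matrix A [coverage_matrix()].
#' @param path Output file.
#' @export
write_coverage_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  df <- data.frame(position = seq_len(nrow(matrix$depth)) - 1L,
                   exon = as.integer(matrix$exon_mask),
                   matrix$depth, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
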