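#' Gene model: locus and exon structure of one gene
#'
#' A `gene_model` fixes the coordinate axis of every coverage vector for a
#' gene: the full locus (exons and introns) from `start` to `end`, stored
#' 0-based half-open regardless of the annotation dialect it was parsed from.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param start,end Locus bounds, 0-based half-open.
#' @param exons Two-column matrix of exon `(start, end)` intervals in genomic
#'   0-based half-open coordinates; overlapping or book-ended intervals are
#'   merged, and all must lie within `[start, end)`.
#'
#' @return An object of class `gene_model` with fields `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `exons`, `locus_length`.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end, exons) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  strand <- as.character(strand)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-', got '", strand, "'")
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || end <= start)
    stop("gene ", gene_id, ": locus must satisfy end > start")
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("gene ", gene_id, ": at least one exon required")
  exons <- merge_intervals(exons)
  if (any(exons[, 1L] < start) || any(exons[, 2L] > end))
    stop("gene ", gene_id, ": exons outside locus bounds")
  structure(list(gene_id = gene_id, chrom = as.character(chrom),
                 strand = strand, start = start, end = end, exons = exons,
                 locus_length = end - start),
            class = "gene_model")
}

# union of half-open intervals, sorted by start
merge_intervals <- function(ivl) {
  ivl <- ivl[order(ivl[, 1L], ivl[, 2L]), , drop = FALSE]
  if (any(ivl[, 2L] <= ivl[, 1L])) stop("degenerate interval (end <= start)")
  out <- ivl[1L, , drop = FALSE]
  if (nrow(ivl) > 1L) for (i in 2L:nrow(ivl)) {
    last <- nrow(out)
    if (ivl[i, 1L] <= out[last, 2L]) {
      out[last, 2L] <- max(out[last, 2L], ivl[i, 2L])
    } else {
      out <- rbind(out, ivl[i, , drop = FALSE])
    }
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s  %s:%d-%d(%s)  %d bp, %d exon(s)\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand,
              x$locus_length, nrow(x$exons)))
  invisible(x)
}

#' Logical exon mask along the locus
#'
#' @param model A [gene_model()].
#' @return Logical vector of length `locus_length`; `TRUE` at exonic positions.
#' @export
exon_mask <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  m <- logical(model$locus_length)
  for (i in seq_len(nrow(model$exons))) {
    a <- model$exons[i, 1L] - model$start + 1L
    b <- model$exons[i, 2L] - model$start
    m[a:b] <- TRUE
  }
  m
}

#' Load gene models from a GTF or BED12 annotation
#'
#' GTF is parsed as 1-based inclusive (Ensembl dialect; exon features grouped
#' by `gene_id`), BED12 as 0-based half-open with block structure; both are
#' mapped to the internal 0-based half-open convention. Overlapping exon
#' records of a gene are merged. Models are returned in deterministic
#' `(chrom, start, gene_id)` order.
#'
#' @param path Annotation file.
#' @param format `"GTF"` or `"BED12"`; defaults from the file extension.
#' @param gene_ids Optional character vector restricting (and requiring) the
#'   genes to load; an absent id is an error.
#' @return Named list of [gene_model()] objects.
#' @export
load_gene_models <- function(path, format = NULL, gene_ids = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gtf = "GTF", gff = "GTF", bed = "BED12",
                     stop("cannot infer annotation format from extension '",
                          ext, "'"))
  }
  format <- toupper(format)
  if (!format %in% c("GTF", "BED12"))
    stop("unknown annotation format: ", format)
  if (!is.null(gene_ids) && length(gene_ids) == 0L)
    stop("gene_ids filter must be non-empty when given")

  models <- switch(format,
    GTF = parse_gtf_models(path),
    BED12 = parse_bed12_models(path))

  if (!is.null(gene_ids)) {
    missing <- setdiff(gene_ids, names(models))
    if (length(missing))
      stop("gene(s) absent from annotation: ", paste(missing, collapse = ", "))
    models <- models[names(models) %in% gene_ids]
  }
  ord <- order(vapply(models, `[[`, "", "chrom"),
               vapply(models, `[[`, 0L, "start"),
               names(models))
  models[ord]
}

parse_gtf_models <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("GTF parse error in ", path, ": ",
                                          conditionMessage(e)))
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L) stop("no exon records in ", path)
  ids <- as.character(S4Vectors::mcols(gr)$gene_id)
  if (anyNA(ids)) stop("GTF exon record without gene_id in ", path)
  out <- list()
  for (g in unique(ids)) {
    sub <- gr[ids == g]
    chrom <- as.character(GenomicRanges::seqnames(sub))
    std <- as.character(BiocGenerics::strand(sub))
    if (length(unique(chrom)) != 1L)
      stop("gene ", g, " spans multiple chromosomes")
    std <- if (all(std == "-")) "-" else "+"
    # GTF is 1-based inclusive; GRanges start()/end() keep that dialect
    ex <- cbind(BiocGenerics::start(sub) - 1L, BiocGenerics::end(sub))
    ex <- merge_intervals(ex)
    out[[g]] <- gene_model(g, chrom[1L], std,
                           start = min(ex[, 1L]), end = max(ex[, 2L]),
                           exons = ex)
  }
  out
}

parse_bed12_models <- function(path) {
  bed <- tryCatch(rtracklayer::import(path, format = "bed"),
                  error = function(e) stop("BED parse error in ", path, ": ",
                                           conditionMessage(e)))
  if (length(bed) == 0L) stop("no records in ", path)
  out <- list()
  blocks <- S4Vectors::mcols(bed)$blocks
  for (i in seq_along(bed)) {
    g <- as.character(S4Vectors::mcols(bed)$name[i])
    if (is.na(g) || !nzchar(g)) stop("BED12 record ", i, " lacks a name")
    chrom <- as.character(GenomicRanges::seqnames(bed[i]))
    std <- as.character(BiocGenerics::strand(bed[i]))
    if (!std %in% c("+", "-")) std <- "+"
    lstart <- BiocGenerics::start(bed[i]) - 1L  # back to BED 0-based
    lend <- BiocGenerics::end(bed[i])
    if (!is.null(blocks) && length(blocks[[i]]) > 0L) {
      bl <- blocks[[i]]  # block IRanges are relative 1-based within the record
      ex <- cbind(lstart + BiocGenerics::start(bl) - 1L,
                  lstart + BiocGenerics::end(bl))
    } else {
      ex <- cbind(lstart, lend)
    }
    out[[g]] <- gene_model(g, chrom, std, lstart, lend, ex)
  }
  out
}
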