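#' Plain-text cohort store of per-gene coverage matrices
#'
#' A cohort store is a directory holding one TSV depth matrix per gene (via
#' [write_coverage_tsv()]), a JSON gene-model table, and a JSON manifest
#' recording the cohort name, the shared sample order, and provenance. All
#' integers are stored exactly, so a write-then-read roundtrip is
#' bit-identical.
#'
#' @param path Directory to create or open.
#' @param cohort_name Cohort label recorded in the manifest (required when
#'   creating).
#' @param provenance Optional named list stored verbatim in the manifest.
#' @return Object of class `cohort_store`.
#' @export
cohort_store <- function(path, cohort_name = NULL, provenance = list()) {
  manifest_path <- file.path(path, "manifest.json")
  if (file.exists(manifest_path)) {
    manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    manifest$genes <- as.character(manifest$genes)
  } else {
    if (is.null(cohort_name))
      stop("cohort_name required to create a new store at ", path)
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(cohort_name = cohort_name, sample_ids = character(),
                     genes = character(), provenance = provenance,
                     tool = paste0("offonome ",
                                   as.character(utils::packageVersion("offonome"))))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  structure(list(path = path, manifest = manifest), class = "cohort_store")
}

#' @export
print.cohort_store <- function(x, ...) {
  cat(sprintf("cohort_store '%s' at %s: %d gene(s), %d sample(s)\n",
              x$manifest$cohort_name, x$path, length(x$manifest$genes),
              length(x$manifest$sample_ids)))
  invisible(x)
}

#' List gene ids held in a store
#' @param store A [cohort_store()].
#' @export
store_genes <- function(store) {
  stopifnot(inherits(store, "cohort_store"))
  as.character(store$manifest$genes)
}

#' Sample ids shared by every gene in a store
#' @param store A [cohort_store()].
#' @export
store_samples <- function(store) {
  stopifnot(inherits(store, "cohort_store"))
  as.character(store$manifest$sample_ids)
}

save_manifest <- function(store) {
  jsonlite::write_json(store$manifest, file.path(store$path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  store
}

#' Write a coverage matrix into a store
#'
#' The first matrix written fixes the cohort's sample order; later writes
#' with a different sample set or order are a consistency error.
#'
#' @param store A [cohort_store()].
#' @param matrix A [coverage_matrix()].
#' @return The updated store, invisibly.
#' @export
store_write <- function(store, matrix) {
  stopifnot(inherits(store, "cohort_store"), inherits(matrix, "coverage_matrix"))
  if (length(store$manifest$sample_ids) == 0L) {
    store$manifest$sample_ids <- matrix$sample_ids
  } else if (!identical(as.character(store$manifest$sample_ids),
                        matrix$sample_ids)) {
    stop("sample ids/order of gene ", matrix$gene_id,
         " differ from the store manifest")
  }
  write_coverage_tsv(matrix, file.path(store$path,
                                       paste0(matrix$gene_id, ".cov.tsv")))
  if (!is.null(matrix$model)) {
    m <- matrix$model
    jsonlite::write_json(
      list(gene_id = m$gene_id, chrom = m$chrom, strand = m$strand,
           start = m$start, end = m$end,
           exons = list(start = m$exons[, 1L], end = m$exons[, 2L])),
      file.path(store$path, paste0(matrix$gene_id, ".model.json")),
      auto_unbox = TRUE)
  }
  store$manifest$genes <- union(store$manifest$genes, matrix$gene_id)
  invisible(save_manifest(store))
}

#' Read a gene's coverage matrix back from a store
#'
#' @param store A [cohort_store()].
#' @param gene_id Gene to read.
#' @return A [coverage_matrix()] (with its [gene_model()] when one was stored).
#' @export
store_read <- function(store, gene_id) {
  stopifnot(inherits(store, "cohort_store"))
  if (!gene_id %in% store$manifest$genes)
    stop("gene ", gene_id, " not in store manifest")
  df <- utils::read.table(file.path(store$path, paste0(gene_id, ".cov.tsv")),
                          header = TRUE, sep = "\t", check.names = FALSE)
  model_path <- file.path(store$path, paste0(gene_id, ".model.json"))
  model <- NULL
  if (file.exists(model_path)) {
    mj <- jsonlite::read_json(model_path, simplifyVector = TRUE)
    model <- gene_model(mj$gene_id, mj$chrom, mj$strand, mj$start, mj$end,
                        cbind(mj$exons$start, mj$exons$end))
  }
  ids <- as.character(store$manifest$sample_ids)
  coverage_matrix(gene_id, as.matrix(df[, ids, drop = FALSE]), ids,
                  exon_mask = df$exon == 1L, model = model)
}

#' Write-then-read roundtrip of one matrix
#'
#' @param store A [cohort_store()].
#' @param matrix A [coverage_matrix()].
#' @return The matrix as re-read from disk.
#' @export
store_roundtrip <- function(store, matrix) {
  store_write(store, matrix)
  # manifest changed on disk; reopen to pick it up
  store_read(cohort_store(store$path), matrix$gene_id)
}
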