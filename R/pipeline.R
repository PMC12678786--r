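#' Validate a pipeline configuration
#'
#' A config is a named list (or YAML file) with blocks:
#' \describe{
#'   \item{cohort}{Path to a [cohort_store()] directory (required unless a
#'     `simulate` block is present, which generates one).}
#'   \item{out_dir}{Output directory (required).}
#'   \item{lss}{Optional overrides for [lss_params()] fields.}
#'   \item{on_off}{Optional `lss_threshold`.}
#'   \item{offonome}{Optional `min_off_frac`, `cohort_name`.}
#'   \item{degradation}{Optional `enabled` (default TRUE), `top_frac`,
#'     `max_degraded_gene_frac`, `min_covered`.}
#'   \item{cluster}{Optional `k` (default 2), `input` ("states" or "lss").}
#'   \item{simulate}{Optional [sim_params()] fields incl. `seed`.}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @return The validated config list (with defaults filled in).
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path")
  bad <- character()
  if (is.null(config$out_dir)) bad <- c(bad, "out_dir (missing)")
  if (is.null(config$cohort) && is.null(config$simulate))
    bad <- c(bad, "cohort (missing; no simulate block either)")
  check_range <- function(block, key, lo, hi, lo_open = TRUE, hi_open = TRUE) {
    v <- config[[block]][[key]]
    if (!is.null(v)) {
      ok <- is.numeric(v) &&
        (if (lo_open) v > lo else v >= lo) &&
        (if (hi_open) v < hi else v <= hi)
      if (!ok) bad <<- c(bad, sprintf("%s.%s (out of range)", block, key))
    }
  }
  check_range("lss", "k", 0, Inf)
  check_range("lss", "min_expressed_frac", 0, 1, lo_open = FALSE)
  check_range("lss", "trim_quantile", 0, 0.5)
  check_range("on_off", "lss_threshold", 0, 1)
  check_range("offonome", "min_off_frac", 0, 1, hi_open = FALSE)
  check_range("degradation", "top_frac", 0, 1)
  check_range("degradation", "max_degraded_gene_frac", 0, 1, lo_open = FALSE)
  if (length(bad))
    stop("invalid pipeline config: ", paste(bad, collapse = "; "))
  config$cluster <- utils::modifyList(list(k = 2L, input = "states"),
                                      config$cluster %||% list())
  config$degradation <- utils::modifyList(
    list(enabled = TRUE, top_frac = 0.05, max_degraded_gene_frac = 0.10,
         min_covered = 50L),
    config$degradation %||% list())
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the whole on/off pipeline from a config
#'
#' Stage order follows the method: (optional simulation) -> degradation
#' filtering -> LSS -> on/off calling -> offonome definition -> Ward
#' clustering. Each stage writes its artifact under `out_dir` (`lss.tsv`,
#' `states.tsv`, `offonome.json`, `filter.json`, `clusters.json`) and a
#' completed stage is skipped on rerun when its output is newer than the
#' cohort store manifest. A `manifest.json` records every artifact with a
#' parameter echo and the package version.
#'
#' @param config Config list or YAML path, see [pipeline_config()].
#' @return Invisibly, the artifact manifest (named list of paths).
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)

  if (!is.null(cfg$simulate) && is.null(cfg$cohort)) {
    cfg$cohort <- out("cohort")
    if (!file.exists(file.path(cfg$cohort, "manifest.json"))) {
      sp <- do.call(sim_params, cfg$simulate)
      sim_to_store(simulate_cohort(sp), cfg$cohort)
    }
  }
  store <- cohort_store(cfg$cohort)
  ref_time <- file.mtime(file.path(cfg$cohort, "manifest.json"))
  fresh <- function(f) file.exists(f) && file.mtime(f) >= ref_time
  skipped <- character()

  # degradation filter
  filter_path <- out("filter.json")
  retained <- store_samples(store)
  if (isTRUE(cfg$degradation$enabled)) {
    if (fresh(filter_path)) {
      skipped <- c(skipped, "degradation")
      retained <- unlist(jsonlite::read_json(filter_path,
                                             simplifyVector = TRUE)$retained)
    } else {
      dt <- decay_table(store, min_covered = cfg$degradation$min_covered)
      flt <- if (dt$n_pooled > 0)
        flag_degraded(dt, top_frac = cfg$degradation$top_frac,
                      max_degraded_gene_frac =
                        cfg$degradation$max_degraded_gene_frac)
      else list(threshold = NA_real_,
                degraded_gene_frac = stats::setNames(
                  numeric(length(retained)), retained),
                retained = retained, excluded = character(),
                params = cfg$degradation)
      jsonlite::write_json(
        list(threshold = flt$threshold,
             degraded_gene_frac = as.list(flt$degraded_gene_frac),
             retained = flt$retained, excluded = flt$excluded,
             params = flt$params),
        filter_path, auto_unbox = TRUE, pretty = TRUE)
      retained <- flt$retained
    }
  }

  # LSS on retained samples
  lss_path <- out("lss.tsv")
  if (fresh(lss_path)) {
    skipped <- c(skipped, "lss")
    lss <- read_lss_tsv(lss_path)
  } else {
    lp <- do.call(lss_params, cfg$lss %||% list())
    lss_all <- compute_lss_cohort(store, lp)
    lss <- lss_matrix(unclass(lss_all)[, retained, drop = FALSE],
                      diagnostics = attr(lss_all, "diagnostics"))
    write_lss_tsv(lss, lss_path)
  }

  # on/off states
  states_path <- out("states.tsv")
  if (fresh(states_path)) {
    skipped <- c(skipped, "call")
    states_df <- utils::read.table(states_path, header = TRUE, sep = "\t",
                                   check.names = FALSE)
    states <- as.matrix(states_df[, -1L, drop = FALSE])
    rownames(states) <- states_df$gene_id
  } else {
    op <- do.call(on_off_params, cfg$on_off %||% list())
    states <- call_on_off(lss, op)
    utils::write.table(
      data.frame(gene_id = rownames(states), unclass(states),
                 check.names = FALSE),
      states_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # offonome set
  off_path <- out("offonome.json")
  if (fresh(off_path)) {
    skipped <- c(skipped, "define")
  } else {
    oc <- cfg$offonome %||% list()
    oset <- define_offonome(states, min_off_frac = oc$min_off_frac %||% 0.20,
                            cohort_name = oc$cohort_name %||%
                              store$manifest$cohort_name)
    jsonlite::write_json(
      list(cohort_name = oset$cohort_name, gene_ids = oset$gene_ids,
           off_fraction = as.list(oset$off_fraction),
           min_off_frac = oset$min_off_frac, n_samples = oset$n_samples),
      off_path, auto_unbox = TRUE, pretty = TRUE)
  }

  # Ward clustering of samples
  clusters_path <- out("clusters.json")
  if (fresh(clusters_path)) {
    skipped <- c(skipped, "cluster")
  } else if (ncol(states) >= 2L) {
    cm <- if (identical(cfg$cluster$input, "lss")) unclass(lss) else states
    wc <- ward_cluster(cm, axis = "samples")
    cl <- cut_clusters(wc, min(cfg$cluster$k, ncol(cm)))
    jsonlite::write_json(
      list(k = min(cfg$cluster$k, ncol(cm)), input = cfg$cluster$input,
           assignment = as.list(cl), leaf_order = wc$labels[wc$leaf_order],
           merge = wc$hclust$merge, height = wc$hclust$height),
      clusters_path, auto_unbox = TRUE, pretty = TRUE)
  }

  manifest <- list(
    artifacts = list(filter = filter_path, lss = lss_path,
                     states = states_path, offonome = off_path,
                     clusters = clusters_path),
    skipped = skipped,
    config = cfg,
    tool = paste0("offonome ",
                  as.character(utils::packageVersion("offonome"))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
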