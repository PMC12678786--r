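#' Parameters for the synthetic coverage-cohort generator
#'
#' The generator realizes the contrast the shape-similarity method relies
#' on: *on* samples share a smooth, exon-structured coverage template and
#' differ only in depth scale and counting noise, while *off* samples carry
#' a handful of stray reads at random positions — blocky, inconsistent
#' pileups rather than i.i.d. per-base noise. Optionally a subset of samples
#' is degraded: their template is attenuated exponentially toward the 5'
#' end before counts are drawn.
#'
#' @param n_genes,n_samples Cohort dimensions.
#' @param exon_spec List with `n_exons`, `exon_len` (length-2 range, bp) and
#'   `intron_len` (range, bp).
#' @param on_prob Probability a sample is *on* for a gene; scalar or
#'   per-gene vector. Default 0.5.
#' @param depth_mean Mean exonic read depth of *on* samples (default 50).
#' @param depth_dispersion Negative-binomial dispersion of per-base counts
#'   (default 0.3; 0 gives Poisson).
#' @param template_roughness Amplitude of the smooth positional modulation
#'   shared by all *on* samples (default 0.5; 0 gives per-exon flat blocks).
#' @param background_reads Mean number of stray reads placed in an *off*
#'   sample's locus (Poisson; default 3).
#' @param degraded_sample_frac Fraction of samples simulated as degraded
#'   (default 0).
#' @param decay_strength Exponential 5'->3' attenuation delta for degraded
#'   samples: the template is multiplied by `exp(-delta * x)` with `x` the
#'   normalized transcript position from the 3' end toward 5' (default 3,
#'   i.e. 5'-end coverage reduced to ~5%).
#' @param read_length Length of simulated reads, bp (default 50).
#' @param seed Mandatory integer seed; every artifact is reproducible
#'   from it.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(n_genes = 20L, n_samples = 40L,
                       exon_spec = list(n_exons = 3L, exon_len = c(100L, 300L),
                                        intron_len = c(50L, 200L)),
                       on_prob = 0.5, depth_mean = 50,
                       depth_dispersion = 0.3, template_roughness = 0.5,
                       background_reads = 3, degraded_sample_frac = 0,
                       decay_strength = 3, read_length = 50L, seed) {
  if (missing(seed) || !is.finite(seed))
    stop("seed is mandatory for reproducibility")
  stopifnot(n_genes >= 1L, n_samples >= 1L,
            all(on_prob >= 0), all(on_prob <= 1),
            length(on_prob) %in% c(1L, n_genes),
            depth_mean > 0, depth_dispersion >= 0, template_roughness >= 0,
            background_reads >= 0, degraded_sample_frac >= 0,
            degraded_sample_frac <= 1, decay_strength >= 0, read_length >= 1L)
  check_exon_spec(exon_spec)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples), exon_spec = exon_spec,
                 on_prob = if (length(on_prob) == 1L)
                   rep(on_prob, n_genes) else on_prob,
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 template_roughness = template_roughness,
                 background_reads = background_reads,
                 degraded_sample_frac = degraded_sample_frac,
                 decay_strength = decay_strength,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "sim_params")
}

check_exon_spec <- function(spec) {
  need <- c("n_exons", "exon_len", "intron_len")
  if (!all(need %in% names(spec)))
    stop("exon_spec needs fields: ", paste(need, collapse = ", "))
  if (spec$n_exons < 1L) stop("exon_spec: n_exons must be >= 1")
  for (f in c("exon_len", "intron_len")) {
    r <- spec[[f]]
    if (length(r) != 2L || any(r < 1L) || r[2L] < r[1L])
      stop("exon_spec: ", f, " must be a valid (lo, hi) range of positive lengths")
  }
  invisible(spec)
}

# run expr with a private RNG stream seeded from `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

rint <- function(range) {
  if (range[1L] == range[2L]) as.integer(range[1L])
  else sample(range[1L]:range[2L], 1L)
}

#' Sample a random exon/intron gene structure
#'
#' @param spec Exon spec as in [sim_params()].
#' @param seed Integer seed; the same seed always yields the same model.
#' @param gene_id,chrom,origin Identity and genomic placement of the model
#'   (`origin` = 0-based locus start).
#' @param strand `"+"`, `"-"`, or `"random"`.
#' @return A [gene_model()].
#' @export
make_gene_model <- function(spec, seed, gene_id = "gene1", chrom = "chrS",
                            origin = 0L, strand = "random") {
  check_exon_spec(spec)
  with_seed(seed, {
    std <- if (strand == "random") sample(c("+", "-"), 1L) else strand
    exons <- matrix(0L, nrow = spec$n_exons, ncol = 2L)
    pos <- as.integer(origin)
    for (i in seq_len(spec$n_exons)) {
      if (i > 1L) pos <- pos + rint(spec$intron_len)
      len <- rint(spec$exon_len)
      exons[i, ] <- c(pos, pos + len)
      pos <- pos + len
    }
    gene_model(gene_id, chrom, std, origin, pos, exons)
  })
}

#' Simulate a base-resolution coverage cohort with known truth
#'
#' For each gene a shared smooth positive template is drawn over exonic
#' bases (per-exon level times a smooth positional modulation). Each *on*
#' sample draws per-base negative-binomial counts with mean equal to its
#' own scale factor times the template (introns stay at zero); each *off*
#' sample receives `Poisson(background_reads)` whole reads of `read_length`
#' at uniform positions across the locus. Degraded samples have the
#' template attenuated by `exp(-delta x)` along the 5'->3' transcript axis
#' before counts are drawn. All randomness flows from `params$seed`.
#'
#' @param params A [sim_params()].
#' @return Object of class `simulated_cohort`: `models` (named list),
#'   `matrices` (named list of [coverage_matrix()]), `truth` (character
#'   genes x samples matrix, `"on"`/`"off"`), `degraded` (named logical per
#'   sample), `params`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    gene_ids <- sprintf("g%03d", seq_len(params$n_genes))
    sample_ids <- sprintf("s%03d", seq_len(params$n_samples))
    degraded <- stats::setNames(logical(params$n_samples), sample_ids)
    n_deg <- round(params$degraded_sample_frac * params$n_samples)
    if (n_deg > 0L)
      degraded[sample(params$n_samples, n_deg)] <- TRUE
    # per-sample depth scale shared across genes (library-size analogue);
    # lognormal with mean exactly 1 so on-sample depth is centred on depth_mean
    scale_s <- exp(stats::rnorm(params$n_samples, -0.02, 0.2))

    truth <- matrix("off", params$n_genes, params$n_samples,
                    dimnames = list(gene_ids, sample_ids))
    models <- vector("list", params$n_genes); names(models) <- gene_ids
    matrices <- vector("list", params$n_genes); names(matrices) <- gene_ids
    origin <- 0L
    for (gi in seq_len(params$n_genes)) {
      g <- gene_ids[gi]
      model <- make_gene_model(params$exon_spec,
                               seed = sample.int(2147483646L, 1L),
                               gene_id = g, chrom = "chrS", origin = origin)
      origin <- model$end + 1000L
      models[[g]] <- model
      L <- model$locus_length
      emask <- exon_mask(model)
      tmpl <- gene_template(model, emask, params)
      on <- stats::runif(params$n_samples) < params$on_prob[gi]
      truth[g, on] <- "on"
      depth <- matrix(0L, nrow = L, ncol = params$n_samples)
      # 5'->3' normalized position along the locus, for degradation
      x53 <- seq(0, 1, length.out = L)
      if (model$strand == "-") x53 <- rev(x53)
      for (s in seq_len(params$n_samples)) {
        if (on[s]) {
          mu <- scale_s[s] * tmpl
          if (degraded[s] && params$decay_strength > 0)
            mu <- mu * exp(-params$decay_strength * x53)
          d <- numeric(L)
          idx <- which(mu > 0)
          d[idx] <- if (params$depth_dispersion > 1e-8)
            stats::rnbinom(length(idx), mu = mu[idx],
                           size = 1 / params$depth_dispersion)
          else stats::rpois(length(idx), mu[idx])
          depth[, s] <- as.integer(d)
        } else if (params$background_reads > 0) {
          n_reads <- stats::rpois(1L, params$background_reads)
          if (n_reads > 0L) {
            starts <- sample.int(L, n_reads, replace = TRUE)
            for (st in starts) {
              en <- min(L, st + params$read_length - 1L)
              depth[st:en, s] <- depth[st:en, s] + 1L
            }
          }
        }
      }
      matrices[[g]] <- coverage_matrix(g, depth, sample_ids, model = model)
    }
    structure(list(models = models, matrices = matrices, truth = truth,
                   degraded = degraded, params = params),
              class = "simulated_cohort")
  })
}

# shared positive template over exonic positions: per-exon level x smooth
# positional modulation; scaled to mean exonic depth = depth_mean
gene_template <- function(model, emask, params) {
  L <- model$locus_length
  tmpl <- numeric(L)
  n_ex <- nrow(model$exons)
  levels <- exp(stats::rnorm(n_ex, 0, 0.5))
  xe <- seq(0, 1, length.out = sum(emask))
  r <- params$template_roughness
  freq <- sample(2:6, 2L)
  phase <- stats::runif(2L, 0, 2 * pi)
  mod <- exp(r * (sin(2 * pi * freq[1L] * xe + phase[1L]) +
                  0.5 * sin(2 * pi * freq[2L] * xe + phase[2L])))
  exon_id <- integer(L)
  for (i in seq_len(n_ex)) {
    a <- model$exons[i, 1L] - model$start + 1L
    b <- model$exons[i, 2L] - model$start
    exon_id[a:b] <- i
  }
  tmpl[emask] <- levels[exon_id[emask]] * mod
  tmpl * (params$depth_mean / mean(tmpl[emask]))
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(
    "simulated_cohort: %d gene(s) x %d sample(s), %.0f%% on pairs, %d degraded sample(s), seed %d\n",
    nrow(x$truth), ncol(x$truth), 100 * mean(x$truth == "on"),
    sum(x$degraded), x$params$seed))
  invisible(x)
}

#' Persist a simulated cohort into a cohort store
#'
#' @param cohort A [simulate_cohort()] result.
#' @param path Store directory.
#' @param cohort_name Label; defaults to `"simulated"`.
#' @return The [cohort_store()].
#' @export
sim_to_store <- function(cohort, path, cohort_name = "simulated") {
  stopifnot(inherits(cohort, "simulated_cohort"))
  store <- cohort_store(path, cohort_name,
                        provenance = list(generator = "simulate_cohort",
                                          seed = cohort$params$seed))
  for (g in names(cohort$matrices))
    store <- store_write(store, cohort$matrices[[g]])
  cohort_store(path)
}

#' Export a simulated cohort as per-sample SAM (optionally BAM) files
#'
#' Reads are tiled to reproduce each stored depth matrix exactly: every
#' level set of the depth profile is decomposed into maximal runs, each run
#' chopped into `read_length` pieces, one `M`-only read per piece. Piling
#' the exported reads back up therefore returns the stored matrix
#' bit-identically, which makes this the end-to-end fixture generator for
#' coverage extraction.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param out_dir Output directory.
#' @param as_bam Also coordinate-sort, convert and index with Rsamtools;
#'   returned paths are then the BAMs.
#' @return Named character vector of file paths, one per sample.
#' @export
export_sam <- function(cohort, out_dir, as_bam = FALSE) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  models <- cohort$models
  chrom_len <- max(vapply(models, `[[`, 0L, "end")) + 1000L
  sq <- sprintf("@SQ\tSN:%s\tLN:%d", models[[1L]]$chrom, chrom_len)
  sample_ids <- colnames(cohort$truth)
  out <- stats::setNames(character(length(sample_ids)), sample_ids)
  for (si in seq_along(sample_ids)) {
    s <- sample_ids[si]
    lines <- c("@HD\tVN:1.6\tSO:coordinate", sq)
    recs <- list()
    for (g in names(models)) {
      d <- cohort$matrices[[g]]$depth[, s]
      runs <- depth_to_reads(d, cohort$params$read_length)
      if (nrow(runs)) {
        pos <- models[[g]]$start + runs[, 1L]  # 0-based offset -> 1-based SAM
        len <- runs[, 2L]
        recs[[g]] <- data.frame(pos = pos, len = len)
      }
    }
    if (length(recs)) {
      recs <- do.call(rbind, recs)
      recs <- recs[order(recs$pos), , drop = FALSE]
      lines <- c(lines, sprintf(
        "r%s_%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
        s, seq_len(nrow(recs)), models[[1L]]$chrom, recs$pos, recs$len,
        vapply(recs$len, function(l) strrep("A", l), "")))
    }
    sam <- file.path(out_dir, paste0(s, ".sam"))
    writeLines(lines, sam)
    if (as_bam) {
      bam <- Rsamtools::asBam(sam, file.path(out_dir, s), overwrite = TRUE,
                              indexDestination = TRUE)
      out[s] <- bam
    } else out[s] <- sam
  }
  out
}

# decompose a depth vector into (1-based start offset, length) read pieces
# whose pileup equals the vector exactly
depth_to_reads <- function(d, read_length) {
  out <- matrix(integer(), ncol = 2L)
  if (!any(d > 0)) return(out)
  pieces <- list()
  for (lev in seq_len(max(d))) {
    above <- d >= lev
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      a <- starts[j]; b <- ends[j]
      while (a <= b) {
        l <- min(read_length, b - a + 1L)
        pieces[[length(pieces) + 1L]] <- c(a, l)
        a <- a + l
      }
    }
  }
  do.call(rbind, pieces)
}
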