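test_that("log adjustment has the documented fixed points and rejects bad input", {
  expect_identical(log_adjust(0, 1), 0)
  expect_identical(log_adjust(9, 1), 1)
  expect_identical(log_adjust(99, 1), 2)
  expect_equal(log_adjust(matrix(c(0, 9, 99, 999), 2)),
               matrix(c(0, 1, 2, 3), 2))
  expect_error(log_adjust(-1), "non-negative")
  expect_error(log_adjust(5, k = 0), "positive")
})

test_that("shape cosine matches its defining arithmetic", {
  u <- c(3, 1, 4, 1, 5)
  expect_equal(shape_cosine(u, u), 1)
  expect_equal(shape_cosine(c(1, 0), c(0, 1)), 0)
  expect_equal(shape_cosine(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(shape_cosine(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(shape_cosine(u, rep(0, 5)), 0)  # zero-norm convention
  expect_error(shape_cosine(1:3, 1:4), "length")
  expect_error(shape_cosine(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("cosine is scale-invariant and agrees with the direct oracle on random vectors", {
  withr::local_seed(7)
  for (i in 1:25) {
    u <- runif(12); v <- runif(12); c <- runif(1, 0.01, 100)
    expect_equal(shape_cosine(u, v), oracle_cosine(u, v), tolerance = 1e-12)
    expect_equal(shape_cosine(c * u, v), shape_cosine(u, v),
                 tolerance = 1e-12)
  }
})

test_that("mean profile of identical columns is that column, converged immediately", {
  col <- log10(c(5, 20, 50, 20, 5) + 1)
  logged <- matrix(col, nrow = 5, ncol = 10)
  p <- mean_profile(logged, lss_params())
  expect_true(p$defined)
  expect_true(p$converged)
  expect_equal(p$vector, col)
  expect_equal(p$expressed_fraction, 1)
})

test_that("too few expressed samples leave the profile undefined", {
  depth <- matrix(0, nrow = 8, ncol = 100)
  depth[, 1:3] <- 5
  p <- mean_profile(log_adjust(depth), lss_params(min_expressed_frac = 0.05),
                    raw_totals = colSums(depth))
  expect_false(p$defined)
  expect_equal(p$expressed_fraction, 0.03)
  expect_null(p$vector)
  # and compute_lss then yields exact zeros
  expect_equal(unname(compute_lss(depth)), rep(0, 100))
})

test_that("trimmed re-estimation converges to the plain mean of the non-outlier columns", {
  withr::local_seed(13)
  template <- c(2, 30, 80, 30, 2, 60, 90, 60, 5, 2)
  good <- sapply(1:19, function(i) template * runif(10, 0.9, 1.1))
  outlier <- rev(template) * 5
  logged <- log10(cbind(good, outlier) + 1)
  colnames(logged) <- sprintf("s%02d", 1:20)
  p <- mean_profile(logged, lss_params(trim_quantile = 0.05))
  expect_true(p$converged)
  # floor(0.05 * 20) = 1 sample trimmed: the outlier
  expect_equal(p$vector, rowMeans(logged[, 1:19]), tolerance = 1e-9)
})

test_that("LSS of a zero gene is exactly 0 and of identical columns exactly 1", {
  zero <- toy_coverage(matrix(0L, 30, 6))
  expect_identical(unname(compute_lss(zero)), rep(0, 6))

  same <- toy_coverage(matrix(rep(c(3L, 9L, 27L, 9L, 3L), 4), 5, 4))
  expect_equal(unname(compute_lss(same)), rep(1, 4), tolerance = 1e-12)
})

test_that("a sparse random column scores below template-following columns", {
  withr::local_seed(3)
  template <- as.integer(round(50 * exp(-((1:40) - 20)^2 / 80)))
  noise <- integer(40); noise[sample(40, 5)] <- 1L
  depth <- cbind(c1 = template, c2 = template, c3 = noise)
  lss <- compute_lss(toy_coverage(depth))
  expect_equal(lss[["c1"]], lss[["c2"]])
  expect_gt(lss[["c1"]], lss[["c3"]])
  # with 3 expressed samples floor(0.05*3) = 0 are trimmed, so the refined
  # mean is the plain mean and the no-iteration oracle applies exactly
  expect_equal(unname(lss), oracle_lss_plain(depth), tolerance = 1e-12)
})

test_that("with trimming disabled LSS equals the brute-force plain-mean cosine", {
  withr::local_seed(19)
  params <- lss_params(trim_quantile = 0.01, max_iter = 1L)
  for (i in 1:20) {
    depth <- matrix(rpois(40, 3), nrow = 5, ncol = 8)
    depth[, sample(8, 2)] <- 0L
    expect_equal(unname(compute_lss(depth, params)),
                 oracle_lss_plain(depth), tolerance = 1e-12)
  }
})

test_that("LSS stays in [0,1] and is deterministic for arbitrary non-negative input", {
  withr::local_seed(23)
  for (i in 1:15) {
    depth <- matrix(rnbinom(60, mu = runif(1, 0.1, 80), size = 0.5),
                    nrow = 10, ncol = 6)
    a <- compute_lss(depth)
    b <- compute_lss(depth)
    expect_true(all(a >= 0 & a <= 1))
    expect_identical(a, b)
  }
})

test_that("cohort-level LSS reproduces single-gene calls and records diagnostics", {
  withr::local_seed(29)
  store <- cohort_store(tempfile(), "lss-test")
  mats <- list()
  for (i in 1:10) {
    g <- sprintf("g%02d", i)
    depth <- matrix(rpois(120, sample(c(0.2, 6, 40), 1)), nrow = 15, ncol = 8)
    mats[[g]] <- toy_coverage(depth, gene_id = g)
    store <- store_write(store, mats[[g]])
  }
  lss <- compute_lss_cohort(store)
  expect_equal(dim(lss), c(10L, 8L))
  for (g in rownames(lss))
    expect_equal(unname(unclass(lss)[g, ]), unname(compute_lss(mats[[g]])))
  d <- attr(lss, "diagnostics")
  expect_named(d, rownames(lss))
  expect_true(all(vapply(d, function(x) is.logical(x$converged), NA)))

  # all-zero store yields an all-zero matrix
  z <- cohort_store(tempfile(), "zeros")
  z <- store_write(z, toy_coverage(matrix(0L, 10, 4), gene_id = "z1"))
  expect_true(all(unclass(compute_lss_cohort(z)) == 0))
})

test_that("exons_only domain restricts the shape comparison to exonic bases", {
  model <- gene_model("e", "chrT", "+", 0L, 30L, cbind(c(0L, 20L), c(10L, 30L)))
  depth <- matrix(0L, 30, 3)
  depth[c(1:10, 21:30), ] <- 8L       # identical exonic coverage
  depth[11:20, 3] <- 40L              # intronic blob in sample 3 only
  cm <- coverage_matrix("e", depth, c("a", "b", "c"), model = model)
  full <- compute_lss(cm, lss_params(domain = "full_locus"))
  exonic <- compute_lss(cm, lss_params(domain = "exons_only"))
  expect_lt(full[["c"]], 1 - 1e-6)
  expect_equal(unname(exonic), rep(1, 3), tolerance = 1e-12)
})

test_that("LSS TSV roundtrip preserves values to the printed precision", {
  m <- lss_matrix(matrix(c(0, 0.123456789, 0.6, 1), 2,
                         dimnames = list(c("g1", "g2"), c("s1", "s2"))))
  path <- tempfile(fileext = ".tsv")
  write_lss_tsv(m, path)
  back <- read_lss_tsv(path)
  expect_equal(unclass(back), round(unclass(m), 6), tolerance = 1e-12,
               ignore_attr = TRUE)
})
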