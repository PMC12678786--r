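lss_fix <- function(values, genes = sprintf("g%d", seq_len(nrow(values))),
                    samples = sprintf("s%d", seq_len(ncol(values)))) {
  lss_matrix(matrix(values, nrow = length(genes),
                    dimnames = list(genes, samples)))
}

test_that("on/off boundary is strictly greater than the threshold", {
  lss <- lss_fix(matrix(c(0.61, 0.60, 0.59, 0, 1, 0.6000001), nrow = 1))
  st <- call_on_off(lss)
  expect_equal(unname(st[1, ]), c(1L, 0L, 0L, 0L, 1L, 1L))
  expect_error(call_on_off(matrix(1.5, 1, 1, dimnames = list("g", "s"))),
               "\\[0, 1\\]")
})

test_that("raising the threshold never switches a state off->on", {
  withr::local_seed(5)
  lss <- lss_fix(matrix(runif(200), nrow = 20))
  thresholds <- c(0.3, 0.5, 0.6, 0.8)
  prev <- call_on_off(lss, on_off_params(thresholds[1]))
  for (th in thresholds[-1]) {
    cur <- call_on_off(lss, on_off_params(th))
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("offonome membership uses the inclusive at-least boundary", {
  states <- matrix(1L, nrow = 3, ncol = 10,
                   dimnames = list(c("boundary", "below", "never"),
                                   sprintf("s%d", 1:10)))
  states["boundary", 1:2] <- 0L   # off in exactly 20%
  states["below", 1] <- 0L        # off in 10%
  states["never", ] <- 0L         # off everywhere
  oset <- define_offonome(structure(states,
                                    class = c("on_off_matrix", "matrix", "array")),
                          min_off_frac = 0.20)
  expect_setequal(oset$gene_ids, c("boundary", "never"))
  expect_equal(unname(oset$off_fraction), c(0.2, 0.1, 1))

  # degenerate matrices: all-on -> empty set; all-off -> every gene
  all_on <- call_on_off(lss_fix(matrix(0.9, 4, 6)))
  expect_length(define_offonome(all_on)$gene_ids, 0L)
  all_off <- call_on_off(lss_fix(matrix(0.1, 4, 6)))
  expect_length(define_offonome(all_off)$gene_ids, 4L)
  # lowering min_off_frac never removes genes
  a <- define_offonome(all_off, min_off_frac = 0.5)$gene_ids
  b <- define_offonome(all_off, min_off_frac = 0.2)$gene_ids
  expect_true(all(a %in% b))
})

test_that("two-set Venn partition reproduces the published lung-union arithmetic", {
  ids <- make_ids(5742)
  common <- ids[1:4984]
  luad <- c(common, ids[4985:5434])   # 5,434 genes, 450 specific
  lusc <- c(common, ids[5435:5742])   # 5,292 genes, 308 specific
  vp <- venn_partition(list(LUAD = luad, LUSC = lusc))
  expect_equal(vp$union_size, 5742L)
  expect_equal(vp$regions[["LUAD"]], 450L)
  expect_equal(vp$regions[["LUSC"]], 308L)
  expect_equal(vp$regions[["LUAD&LUSC"]], 4984L)
  expect_equal(sum(vp$regions), vp$union_size)
  # inclusion-exclusion on the input sizes
  expect_equal(length(luad) + length(lusc) - 4984L, vp$union_size)
})

test_that("three-set partition counts are exclusive, order-invariant, and sum to the union", {
  # region sizes: (HNSC&LUAD&LUSC, HNSC&LUSC, LUAD&LUSC, HNSC&LUAD,
  #                HNSC, LUAD, LUSC)
  sizes <- c(4813L, 288L, 171L, 164L, 586L, 286L, 20L)
  ids <- make_ids(sum(sizes))
  pool <- split(ids, rep(seq_along(sizes), sizes))
  hnsc <- c(pool[[1]], pool[[2]], pool[[4]], pool[[5]])
  luad <- c(pool[[1]], pool[[3]], pool[[4]], pool[[6]])
  lusc <- c(pool[[1]], pool[[2]], pool[[3]], pool[[7]])
  vp <- venn_partition(list(HNSC = hnsc, LUAD = luad, LUSC = lusc))
  expect_equal(vp$union_size, 6328L)
  expect_equal(vp$regions[["HNSC&LUAD&LUSC"]], 4813L)
  expect_equal(vp$regions[["HNSC&LUSC"]], 288L)
  expect_equal(vp$regions[["LUAD&LUSC"]], 171L)
  expect_equal(vp$regions[["HNSC&LUAD"]], 164L)
  expect_equal(vp$regions[["HNSC"]], 586L)
  expect_equal(vp$regions[["LUAD"]], 286L)
  expect_equal(vp$regions[["LUSC"]], 20L)
  expect_equal(sum(vp$regions), vp$union_size)
  # permutation invariance of set naming
  vp2 <- venn_partition(list(LUSC = lusc, HNSC = hnsc, LUAD = luad))
  expect_equal(vp2$regions[sort(names(vp2$regions))],
               vp$regions[sort(names(vp$regions))])

  expect_equal(venn_partition(list(A = "g1", B = "g2"))$union_size, 2L)
  expect_error(venn_partition(list(A = "g1")), "2 or 3")
})

test_that("count filter keeps and drops the trivially decidable genes", {
  counts <- rbind(zero = c(0, 0, 0, 0),
                  strong = c(50, 60, 40, 55),
                  weak = c(1, 0, 2, 1))
  colnames(counts) <- sprintf("s%d", 1:4)
  # equal library sizes would be degenerate; pad with background genes
  withr::local_seed(8)
  bg <- matrix(rpois(400, 20), nrow = 100,
               dimnames = list(sprintf("bg%03d", 1:100), colnames(counts)))
  kept <- count_filter(rbind(counts, bg))
  expect_false("zero" %in% kept)
  expect_true("strong" %in% kept)
  expect_false("weak" %in% kept)
})

test_that("count filter matches a hand-executed evaluation of the rule", {
  # 6 genes x 5 samples; library sizes 1000 each so CPM = count * 1000
  counts <- rbind(
    gA = c(12, 15, 11, 20, 13),   # passes everywhere
    gB = c(12, 15, 11, 20, 0),    # fails CPM in one sample
    gC = c(10, 10, 10, 10, 10),   # exactly at the CPM cutoff
    gD = c(9, 9, 9, 9, 9),        # just below cutoff
    gE = c(4, 4, 4, 2, 1),        # passes nothing
    gF = c(953, 947, 955, 939, 967))
  colnames(counts) <- sprintf("s%d", 1:5)
  lib <- colSums(counts)  # all 1000 by construction
  expect_true(all(lib == 1000))
  # hand evaluation: median lib 1000 -> CPM cutoff 10/1000*1e6 = 1e4 CPM,
  # i.e. count >= 10 in all 5 samples (min group 5 <= large_n); total >= 15
  kept <- count_filter(counts)
  expect_setequal(kept, c("gA", "gC", "gF"))
})

test_that("count filter agrees with the reference implementation on random cohorts", {
  skip_if_not_installed("edgeR")
  withr::local_seed(17)
  for (i in 1:5) {
    n <- sample(4:30, 1)
    counts <- matrix(rnbinom(80 * n, mu = 12, size = 0.4), nrow = 80,
                     dimnames = list(sprintf("g%02d", 1:80),
                                     sprintf("s%02d", 1:n)))
    counts <- counts[, colSums(counts) > 0, drop = FALSE]
    mine <- count_filter(counts)
    ref <- rownames(counts)[edgeR::filterByExpr(counts)]
    expect_setequal(mine, ref)
  }
})

test_that("overlap fraction is the contained share of the reference set", {
  expect_equal(overlap_fraction(letters[1:5], letters), 1)
  expect_equal(overlap_fraction(letters[1:5], LETTERS), 0)
  a <- make_ids(50); b <- c(a[1:33], make_ids(100, "x"))
  expect_equal(overlap_fraction(a, b), 0.66)
  expect_error(overlap_fraction(character(), letters), "empty")
})
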