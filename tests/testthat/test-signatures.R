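test_that("signature selection keeps the top fraction of overexpressed genes", {
  set.seed(1)
  de <- data.frame(gene = sprintf("G%03d", 1:600),
                   log2fc = c(runif(490, 0.01, 3), runif(110, -3, -0.01)))
  sig <- build_weighted_signature(de, q_sel = 0.2)
  expect_length(sig$genes, 98)
  expect_true(all(sig$weights > 0))
  expect_equal(sig$genes, de$gene[order(-de$log2fc)][1:98])

  expect_length(build_weighted_signature(de, q_sel = 1)$genes, 490)

  de10 <- data.frame(gene = letters[1:10], log2fc = (10:1) / 5)
  expect_equal(build_weighted_signature(de10, 0.3)$genes, c("a", "b", "c"))

  expect_error(build_weighted_signature(
    data.frame(gene = "a", log2fc = -1)), "over-expressed")
})

test_that("weighted score is the averaged weight-expression product", {
  sig <- structure(list(genes = c("g1", "g2"), weights = c(g1 = 2, g2 = 1)),
                   class = "weighted_signature")
  expr <- matrix(c(3, 4), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(unname(score_weighted_signature(expr, sig)), 5.0)
  expect_equal(unname(score_weighted_signature(expr * 0, sig)), 0)
  expect_equal(score_weighted_signature(expr * 2, sig),
               score_weighted_signature(expr, sig) * 2)

  # missing genes are dropped with adjusted denominator
  expr2 <- rbind(expr, g3 = 9)
  sig3 <- structure(list(genes = c("g1", "g2", "gX"),
                         weights = c(g1 = 2, g2 = 1, gX = 5)),
                    class = "weighted_signature")
  expect_warning(s <- score_weighted_signature(expr2, sig3), "absent")
  expect_equal(unname(s), 5.0)
  rownames(expr2) <- c("a", "b", "c")
  expect_error(score_weighted_signature(expr2, sig), "no signature gene")
})

test_that("median stratification applies the documented tie rule", {
  s <- stratify_by_signature(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(as.character(s), c("low", "low", "high", "high"))
  # odd n: the sample at the median goes low
  s2 <- stratify_by_signature(c(1, 2, 3))
  expect_equal(as.character(s2), c("low", "low", "high"))
  expect_error(stratify_by_signature(rep(2, 5)), "degenerate")
})

test_that("module scores are centered by bin-matched controls", {
  const <- matrix(5, nrow = 200, ncol = 30,
                  dimnames = list(sprintf("g%03d", 1:200), NULL))
  ms <- module_score(const, sprintf("g%03d", 1:10), seed = 1)
  expect_equal(max(abs(ms)), 0)

  # planted 4x upregulation in half the spots separates the groups
  set.seed(9)
  n_spots <- 1000
  expr <- matrix(rlnorm(300 * n_spots, 2, 0.4), nrow = 300,
                 dimnames = list(sprintf("g%03d", 1:300), NULL))
  hot <- seq_len(n_spots) <= n_spots / 2
  expr[1:20, hot] <- expr[1:20, hot] * 4
  ms2 <- module_score(expr, sprintf("g%03d", 1:20), seed = 2)
  expect_lt(wilcox.test(ms2[hot], ms2[!hot])$p.value, 1e-6)
  expect_gt(mean(ms2[hot]), mean(ms2[!hot]))
  expect_identical(ms2, module_score(expr, sprintf("g%03d", 1:20), seed = 2))
  expect_error(module_score(expr, "nope"), "present")
})

test_that("spot categories use exact per-sample quantile counts", {
  set.seed(3)
  m <- setNames(rnorm(10), sprintf("s%02d", 1:10))
  e <- setNames(rnorm(10), sprintf("s%02d", 1:10))
  cat1 <- categorize_spots(m, e, "A", q = 0.2)
  # exactly floor(0.2 * 10) = 2 spots in each high/low flag per score
  hi_m <- names(sort(m, decreasing = TRUE))[1:2]
  hi_e <- names(sort(e, decreasing = TRUE))[1:2]
  both <- intersect(hi_m, hi_e)
  expect_equal(sum(cat1$category == "mCAFhigh_endohigh"), length(both))
  expect_equal(sum(table(cat1$category)), 10)

  # a spot in both top sets lands in the double-high category
  m2 <- setNames(c(5, 4, 0, -1, -2, 0, 0, 0, 0, -5), sprintf("s%02d", 1:10))
  e2 <- setNames(c(5, -4, 0, 1, -2, 0, 0, 0, 0, -5), sprintf("s%02d", 1:10))
  cat2 <- categorize_spots(m2, e2, "A", q = 0.2)
  expect_equal(as.character(cat2$category[cat2$spot_id == "s01"]),
               "mCAFhigh_endohigh")
  expect_error(categorize_spots(m[1:4], e[1:4], "A", q = 0.2), "too few")
})

test_that("rank-sum DE is null on duplicated groups and antisymmetric", {
  set.seed(5)
  half <- matrix(rlnorm(50 * 20), nrow = 50,
                 dimnames = list(sprintf("g%02d", 1:50), NULL))
  expr <- cbind(half, half)
  grp <- rep(c(TRUE, FALSE), each = 20)
  de <- rank_sum_de(expr, grp)
  expect_equal(max(abs(de$avg_log2FC)), 0)
  expect_equal(min(de$p), 1)

  # planted 4x gene recovers avg_log2FC ~ 2
  set.seed(6)
  e2 <- matrix(rlnorm(20 * 1000, 2, 0.1), nrow = 20,
               dimnames = list(sprintf("g%02d", 1:20), NULL))
  gA <- seq_len(1000) <= 500
  e2[1, gA] <- e2[1, gA] * 4
  de2 <- rank_sum_de(e2, gA)
  expect_equal(unname(de2$avg_log2FC[de2$gene == "g01"]), 2, tolerance = 0.05)
  de2r <- rank_sum_de(e2, !gA)
  expect_equal(de2$avg_log2FC, -de2r$avg_log2FC[match(de2$gene, de2r$gene)])
  expect_true(all(de2$p_adj >= de2$p))
  expect_error(rank_sum_de(e2, rep(TRUE, 1000)), "non-empty")
})

test_that("GMT parsing handles fixtures, duplicates and malformed lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdescr\tg1\tg2\tg3\tg2",
               "setB\tdescr\tg9\tg10"), path)
  gs <- read_gmt(path)
  expect_length(gs, 2)
  expect_equal(gs$setA, c("g1", "g2", "g3"))
  expect_length(gs$setB, 2)

  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(), empty)
  expect_length(read_gmt(empty), 0)

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdescr\tg1", "oops"), bad)
  expect_error(read_gmt(bad), "line 2")
})

test_that("enrichment scores match fgsea and respect the coverage filter", {
  set.seed(8)
  ranked <- sprintf("G%03d", 1:200)
  sets <- list(top = ranked[1:15],
               rand = sample(ranked, 15),
               thin = c(ranked[1:7], sprintf("ZZ%02d", 1:11)))  # 39% coverage
  expect_error(preranked_enrichment(ranked, sets["thin"]), "coverage")
  en <- preranked_enrichment(ranked, sets, n_perm = 500, seed = 2)
  expect_false("thin" %in% en$set)
  expect_gt(en$es[en$set == "top"], 0.8)
  expect_true(all(en$es >= -1 & en$es <= 1))
  expect_true(all(en$q >= en$p))

  skip_if_not_installed("fgsea")
  # independent cross-check of the running-sum statistic (unweighted)
  stats_vec <- setNames(seq(10, 0.01, length.out = 200), ranked)
  ref <- suppressWarnings(
    fgsea::fgseaSimple(sets[c("top", "rand")], stats_vec, nperm = 10,
                       gseaParam = 0, scoreType = "std"))
  expect_equal(en$es[match(c("top", "rand"), en$set)],
               ref$ES[match(c("top", "rand"), ref$pathway)],
               tolerance = 1e-8)
})

test_that("enrichment p-values are calibrated under the permutation null", {
  set.seed(10)
  ranked <- sprintf("G%03d", 1:150)
  ps <- vapply(1:60, function(i) {
    sets <- list(s = sample(ranked, 12))
    preranked_enrichment(sample(ranked), sets, n_perm = 200,
                         seed = 100 + i)$p
  }, 0)
  expect_gte(mean(ps <= 0.05), 0.0)
  expect_lte(mean(ps <= 0.05), 0.17)
  expect_gt(mean(ps <= 0.5), 0.3)
})

test_that("score correlation handles exact and degenerate cases", {
  x <- rnorm(50)
  expect_equal(score_correlation(x, x)$r, 1)
  expect_equal(score_correlation(x, -x)$r, -1)
  expect_error(score_correlation(x, rep(1, 50)), "variance")
  set.seed(2)
  z <- MASS::mvrnorm(2000, c(0, 0), matrix(c(1, 0.5, 0.5, 1), 2))
  r <- score_correlation(z[, 1], z[, 2])$r
  expect_gt(r, 0.42)
  expect_lt(r, 0.58)
})
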