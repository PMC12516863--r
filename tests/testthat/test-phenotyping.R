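test_that("arcsinh transform matches closed form and is scale-consistent", {
  expect_equal(asinh_transform(0), 0)
  expect_equal(asinh_transform(1, 1), log(1 + sqrt(2)), tolerance = 1e-6)
  expect_equal(asinh_transform(1, 1), 0.881374, tolerance = 1e-6)
  x <- sort(runif(50, 0, 100))
  expect_true(all(diff(asinh_transform(x, 5)) > 0))
  expect_error(asinh_transform(-1), "non-negative")
  expect_error(asinh_transform(1, 0), "positive")
  # rescaling raw counts and the cofactor together leaves values unchanged
  expect_equal(asinh_transform(x * 7, 5 * 7), asinh_transform(x, 5))
})

test_that("GMM tumor gate separates a planted two-component mixture", {
  set.seed(42)
  ck <- c(rnorm(500, 0.5, 0.1), rnorm(500, 3, 0.3))
  planted <- rep(c(FALSE, TRUE), each = 500)
  g <- gate_tumor(ck, seed = 1)
  expect_gte(mean(g$is_tumor == planted), 0.99)
  expect_gt(g$threshold, g$means["low"])
  expect_lt(g$threshold, g$means["high"])
  expect_error(gate_tumor(rep(1, 200)), "separable")
  expect_error(gate_tumor(rnorm(50)), "at least 100")
})

test_that("SOM + consensus recovers well-separated archetypes", {
  set.seed(7)
  centers <- rbind(c(0, 0, 8), c(8, 0, 0), c(0, 8, 0))
  truth <- rep(1:3, each = 400)
  mat <- centers[truth, ] + matrix(rnorm(1200 * 3, sd = 1), ncol = 3)
  rownames(mat) <- sprintf("c%04d", seq_len(1200))
  colnames(mat) <- c("m1", "m2", "m3")

  som <- som_cluster(mat, grid = c(8, 8), seed = 3)
  som2 <- som_cluster(mat, grid = c(8, 8), seed = 3)
  expect_identical(som$node, som2$node)

  used <- sort(unique(som$node))
  cm <- consensus_metacluster(som$codes[used, ], k = 3, seed = 5)
  pred <- cm$metacluster[match(som$node, used)]
  expect_gte(mclust::adjustedRandIndex(pred, truth), 0.95)

  expect_error(som_cluster(mat[1:10, ], grid = c(8, 8)), "fewer cells")
})

test_that("consensus with one full-sample rep equals a plain hierarchical cut", {
  set.seed(1)
  codes <- matrix(rnorm(40), nrow = 10)
  cm <- consensus_metacluster(codes, k = 3, reps = 1, subsample = 1, seed = 2)
  direct <- cutree(hclust(dist(codes), "average"), k = 3)
  # same partition up to label permutation
  expect_equal(mclust::adjustedRandIndex(cm$metacluster, direct), 1)
  expect_true(all(cm$consensus >= 0 & cm$consensus <= 1))
  expect_true(all(diag(cm$consensus) == 1))
  expect_error(consensus_metacluster(codes, k = 11), "exceeds")

  # two planted node groups: consensus is block-structured
  codes2 <- rbind(matrix(rnorm(20, 0, 0.1), 10),
                  matrix(rnorm(20, 5, 0.1), 10))
  cm2 <- consensus_metacluster(codes2, k = 2, reps = 50, seed = 3)
  off <- cm2$consensus[1:10, 11:20]
  expect_lt(mean(off), 0.2)
})

# builds a minimal transformed cell table directly from a profile matrix
cells_from_profiles <- function(profiles, n_each = 60, sd = 0.05, seed = 1) {
  withr::with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(nrow(profiles)), function(i) {
      m <- matrix(rnorm(n_each * ncol(profiles), rep(profiles[i, ], each = n_each), sd),
                  nrow = n_each)
      colnames(m) <- colnames(profiles)
      m
    }))
    df <- tibble::tibble(cell_id = sprintf("c%04d", seq_len(nrow(rows))))
    for (j in colnames(rows)) df[[paste0(j, "_t")]] <- rows[, j]
    df$planted <- rep(rownames(profiles), each = n_each)
    df
  })
}

test_that("level-1 rules label endothelia, immune and CAF meta-clusters", {
  prof <- rbind(endothelia = c(CD31 = 4.6, CD45 = 0.5, CD138 = 0.5),
                immune     = c(CD31 = 0.5, CD45 = 4.6, CD138 = 0.5),
                plasma     = c(CD31 = 0.5, CD45 = 4.6, CD138 = 4.6),
                CAF        = c(CD31 = 0.5, CD45 = 0.5, CD138 = 0.5))
  cells <- cells_from_profiles(prof)
  res <- classify_level1(cells, seed = 2)
  expect_equal(unname(res$label[cells$planted == "endothelia"][1]), "endothelia")
  expect_true(all(res$label[cells$planted %in% c("immune", "plasma")] == "immune"))
  expect_true(all(res$label[cells$planted == "CAF"] == "CAF"))
  empty <- classify_level1(cells[0, ], seed = 2)
  expect_length(empty$label, 0)
})

test_that("immune rules resolve plasma, CD8, CD4 grades and CD4 subsets", {
  prof <- rbind(
    plasma  = c(CD45 = 4.6, CD4 = 0.5, CD8a = 0.5, CD138 = 4.6, CD74 = 0.5, Ki67 = 0.5),
    cd8     = c(CD45 = 4.6, CD4 = 0.5, CD8a = 4.6, CD138 = 0.5, CD74 = 0.5, Ki67 = 0.5),
    cd4     = c(CD45 = 4.6, CD4 = 4.6, CD8a = 0.5, CD138 = 0.5, CD74 = 0.5, Ki67 = 0.5),
    cd4prol = c(CD45 = 4.6, CD4 = 4.6, CD8a = 0.5, CD138 = 0.5, CD74 = 0.5, Ki67 = 4.6),
    cd4cd74 = c(CD45 = 4.6, CD4 = 4.6, CD8a = 0.5, CD138 = 0.5, CD74 = 4.6, Ki67 = 0.5),
    othercd4 = c(CD45 = 4.6, CD4 = 2.3, CD8a = 0.5, CD138 = 0.5, CD74 = 0.5, Ki67 = 0.5),
    otherimm = c(CD45 = 4.6, CD4 = 0.5, CD8a = 0.5, CD138 = 0.5, CD74 = 0.5, Ki67 = 0.5))
  cells <- cells_from_profiles(prof, n_each = 50)
  res <- classify_immune(cells, seed = 4)
  got <- tapply(res$label[cells$cell_id], cells$planted, function(x) names(which.max(table(x))))
  expect_equal(unname(got["plasma"]), "plasma cell")
  expect_equal(unname(got["cd8"]), "CD8 T")
  expect_equal(unname(got["cd4"]), "CD4 T")
  expect_equal(unname(got["cd4prol"]), "proliferating CD4 T")
  expect_equal(unname(got["cd4cd74"]), "CD4+CD74+ T")
  expect_equal(unname(got["othercd4"]), "other CD4+")
  expect_equal(unname(got["otherimm"]), "other immune")
})

test_that("CAF rules cover all subsets and relabel all-negative cells tumor", {
  prof <- rbind(
    mcaf    = c(Vimentin = 4.6, aSMA = 4.6, Collagen1 = 4.6, Ki67 = 0.5, CD74 = 0.5),
    colcaf  = c(Vimentin = 4.6, aSMA = 0.5, Collagen1 = 4.6, Ki67 = 0.5, CD74 = 0.5),
    smacaf  = c(Vimentin = 4.6, aSMA = 4.6, Collagen1 = 0.5, Ki67 = 0.5, CD74 = 0.5),
    dcaf    = c(Vimentin = 4.6, aSMA = 0.5, Collagen1 = 0.5, Ki67 = 4.6, CD74 = 0.5),
    apcaf   = c(Vimentin = 4.6, aSMA = 0.5, Collagen1 = 0.5, Ki67 = 0.5, CD74 = 4.6),
    vimonly = c(Vimentin = 4.6, aSMA = 0.5, Collagen1 = 0.5, Ki67 = 0.5, CD74 = 0.5),
    allneg  = c(Vimentin = 0.5, aSMA = 0.5, Collagen1 = 0.5, Ki67 = 0.5, CD74 = 0.5))
  cells <- cells_from_profiles(prof, n_each = 50)
  res <- classify_caf(cells, seed = 4)
  got <- tapply(res$label[cells$cell_id], cells$planted, function(x) names(which.max(table(x))))
  expect_equal(unname(got["mcaf"]), "mCAF")
  expect_equal(unname(got["colcaf"]), "Collagen CAF")
  expect_equal(unname(got["smacaf"]), "SMA CAF")
  expect_equal(unname(got["dcaf"]), "dCAF")
  expect_equal(unname(got["apcaf"]), "apCAF")
  expect_equal(unname(got["vimonly"]), "other CAF (Vimentin+)")
  expect_equal(unname(got["allneg"]), "tumor")
})

test_that("full hierarchy recovers planted labels and partitions every cell", {
  roi <- generate_roi(sim_config(cells_per_roi = 3000, seed = 8), "ACC",
                      seed = 18)
  ph <- run_phenotyping(roi$cells, seed = 2)
  truth <- roi$truth$true_type[ph$cell_id]
  expect_gte(macro_recall(truth, ph$label_final), 0.9)

  # exactly one final label per cell, consistent with level 1
  expect_false(anyNA(ph$label_final))
  ct <- sgc_cell_types()
  expect_true(all(ph$label_level1 ==
                    ct$level1[match(ph$label_final, ct$label)]))
  expect_equal(sum(table(ph$label_final)), nrow(ph))

  # row-order invariance after cell_id realignment
  perm <- withr::with_seed(3, sample(nrow(roi$cells)))
  ph2 <- run_phenotyping(roi$cells[perm, ], seed = 2)
  ph2 <- ph2[match(ph$cell_id, ph2$cell_id), ]
  expect_equal(ph$label_final, ph2$label_final)
})
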