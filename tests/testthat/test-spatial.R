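test_that("kNN graph matches brute force, caps degree, and breaks ties by id", {
  cells <- tibble::tibble(cell_id = c("a", "b", "c"), roi_id = "r",
                          x_um = c(0, 1, 3), y_um = 0)
  g <- build_knn_graph(cells, k = 1)
  expect_equal(g$cell_id[g$idx[, 1]], c("b", "a", "b"))

  # k >= n caps out-degree at n - 1
  g2 <- build_knn_graph(cells, k = 10)
  expect_equal(ncol(g2$idx), 2)

  # equidistant neighbors resolve to the lower cell_id
  tie <- tibble::tibble(cell_id = c("a", "b", "q"), roi_id = "r",
                        x_um = c(-1, 1, 0), y_um = 0)
  gt <- build_knn_graph(tie, k = 1)
  expect_equal(gt$cell_id[gt$idx[gt$cell_id == "q", 1]], "a")

  # random instances against the brute-force oracle
  for (s in 1:3) {
    cells <- rand_roi_coords(150 + 50 * s, seed = s)
    g <- build_knn_graph(cells, k = 20)
    expect_equal(unname(g$idx), unname(oracle_knn(cells, 20)))
  }
  expect_error(build_knn_graph(cells, k = 0), "positive")
  expect_error(build_knn_graph(cells[1, ], k = 1), "at least 2")
})

test_that("neighbor fractions reproduce hand counts and sum to one", {
  # one query cell at the origin surrounded by 12 tumor, 5 mCAF, 3 CD8 cells
  th <- seq(0, 2 * pi, length.out = 21)[1:20]
  cells <- tibble::tibble(
    cell_id = c("a_query", sprintf("b%02d", 1:20)), roi_id = "r",
    x_um = c(0, 10 * cos(th) + (1:20) * 0.01), y_um = c(0, 10 * sin(th)))
  lab <- setNames(c("CD4 T", rep("tumor", 12), rep("mCAF", 5), rep("CD8 T", 3)),
                  cells$cell_id)
  g <- build_knn_graph(cells, k = 20)
  prof <- neighbor_fractions(g, lab)
  expect_equal(unname(prof["a_query", c("tumor", "mCAF", "CD8 T")]),
               c(0.60, 0.25, 0.15))
  expect_equal(unname(rowSums(prof)), rep(1, nrow(prof)))
  lab2 <- lab; lab2[3] <- NA
  expect_error(neighbor_fractions(g, lab2), "unlabeled")
})

test_that("cellular neighborhoods recover two planted niches", {
  set.seed(5)
  n <- 600
  cells <- tibble::tibble(
    cell_id = sprintf("c%04d", 1:n), roi_id = "r",
    x_um = c(runif(n / 2, 0, 220), runif(n / 2, 280, 500)),
    y_um = runif(n, 0, 500))
  niche <- rep(1:2, each = n / 2)
  lab <- setNames(ifelse(niche == 1, "tumor", "CD8 T"), cells$cell_id)
  g <- build_knn_graph(cells, k = 20)
  prof <- neighbor_fractions(g, lab)
  cn <- assign_neighborhoods(prof, 2, seed = 3)
  expect_gte(mclust::adjustedRandIndex(cn$cn, niche), 0.95)

  cn2 <- assign_neighborhoods(prof, 2, seed = 3)
  expect_identical(cn$cn, cn2$cn)

  # degenerate uniform niche collapses to one neighborhood
  uni <- matrix(0.5, nrow = 10, ncol = 2,
                dimnames = list(sprintf("u%d", 1:10), c("tumor", "CD8 T")))
  expect_true(all(assign_neighborhoods(uni, 1, seed = 1)$cn == 1))
  expect_error(assign_neighborhoods(prof[1:3, ], 9), "fewer cells")
})

test_that("patch detection honors min_size and matches flood fill", {
  # chain of 10 adjacent tumor cells -> one patch; 9 cells -> none
  mk_chain <- function(n, label) {
    cells <- tibble::tibble(cell_id = sprintf("c%02d", 1:(n + 5)), roi_id = "r",
                            x_um = c(seq(0, (n - 1) * 10, by = 10),
                                     400 + (1:5) * 3),
                            y_um = 0)
    lab <- setNames(c(rep(label, n), rep("mCAF", 5)), cells$cell_id)
    list(g = build_knn_graph(cells, k = 3), lab = lab)
  }
  ch10 <- mk_chain(10, "tumor")
  p10 <- detect_patches(ch10$g, ch10$lab, min_size = 10)
  expect_length(p10$members, 1)
  expect_length(p10$members[[1]], 10)

  ch9 <- mk_chain(9, "tumor")
  expect_length(detect_patches(ch9$g, ch9$lab, min_size = 10)$members, 0)

  # no tumor cells -> empty patch set
  none <- mk_chain(10, "CD8 T")
  expect_length(detect_patches(none$g, none$lab, min_size = 10)$members, 0)

  # two disjoint 15-cell components, checked against the flood-fill oracle
  cells <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:30), roi_id = "r",
    x_um = c(seq(0, 140, 10), seq(350, 490, 10)), y_um = 0)
  lab <- setNames(rep("tumor", 30), cells$cell_id)
  g <- build_knn_graph(cells, k = 4)
  ps <- detect_patches(g, lab, min_size = 10)
  expect_length(ps$members, 2)
  oracle <- oracle_flood_fill(g, lab)
  expect_equal(mclust::adjustedRandIndex(ps$patch, oracle), 1)
})

test_that("border distances are Euclidean, signed, and flag infiltration", {
  # square patch of tumor cells with one TME cell inside and one outside
  gx <- expand.grid(x = seq(0, 40, 10), y = seq(0, 40, 10))
  cells <- tibble::tibble(
    cell_id = c(sprintf("t%02d", seq_len(nrow(gx))), "inside", "outside",
                "coincident"),
    roi_id = "r",
    x_um = c(gx$x, 15, 43, 0), y_um = c(gx$y, 15, 44, 0))
  lab <- setNames(c(rep("tumor", nrow(gx)), "mCAF", "mCAF", "mCAF"),
                  cells$cell_id)
  g <- build_knn_graph(cells, k = 6)
  ps <- detect_patches(g, lab, min_size = 10)
  expect_length(ps$members, 1)
  d <- distance_to_border(g, ps)
  d <- d[match(cells$cell_id, d$cell_id), ]

  expect_equal(d$dist_border_um[d$cell_id == "coincident"], 0)
  # outside cell at (43, 44): nearest patch member is (40, 40) -> 5 um
  expect_equal(d$dist_border_um[d$cell_id == "outside"], 5)
  expect_lt(d$dist_border_um[d$cell_id == "inside"], 0)
  expect_true(d$infiltrating[d$cell_id == "inside"])
  expect_false(d$infiltrating[d$cell_id == "outside"])

  # empty patch set: distances undefined, no flags
  lab0 <- setNames(rep("mCAF", nrow(cells)), cells$cell_id)
  ps0 <- detect_patches(g, lab0)
  d0 <- distance_to_border(g, ps0)
  expect_true(all(is.na(d0$dist_border_um)))
  expect_false(any(d0$infiltrating))
})

test_that("interaction test: single-label ROI gives p = 1 and stat = k", {
  cells <- rand_roi_coords(60, seed = 2)
  g <- build_knn_graph(cells, k = 20)
  lab <- setNames(rep("tumor", 60), cells$cell_id)
  it <- test_interactions(g, lab, n_perm = 200, seed = 1)
  expect_equal(nrow(it), 1)
  expect_equal(it$ct, 20)
  expect_equal(it$p_gt, 1)
  expect_equal(it$p_lt, 1)
  expect_error(test_interactions(g, lab, n_perm = 0), "positive")
})

test_that("interaction test flags avoidance of segregated blocks", {
  set.seed(11)
  cells <- tibble::tibble(
    cell_id = sprintf("c%03d", 1:300), roi_id = "r",
    x_um = c(runif(150, 0, 200), runif(150, 300, 500)), y_um = runif(300, 0, 500))
  lab <- setNames(rep(c("A", "B"), each = 150), cells$cell_id)
  g <- build_knn_graph(cells, k = 20)
  it <- test_interactions(g, lab, n_perm = 1000, alpha = 0.01, seed = 4)
  ab <- it[it$from_label == "A" & it$to_label == "B", ]
  expect_lte(ab$p_lt, 0.01)
  expect_equal(ab$sig, -1L)
  # p-values bounded away from zero by the add-one estimator
  expect_true(all(it$p_gt >= 1 / 1001 & it$p_gt <= 1))
  expect_true(all(it$p_lt >= 1 / 1001 & it$p_lt <= 1))
})

test_that("interaction summaries tally signed ROI counts per directed pair", {
  expect_equal(nrow(summarize_interactions(NULL)), 0)
  fab <- tibble::tibble(
    roi = c("r1", "r2", "r3", "r1"),
    from_label = c("A", "A", "A", "B"),
    to_label = c("B", "B", "B", "A"),
    ct = 1, p_gt = 1, p_lt = 1,
    sig = c(1L, 1L, -1L, 0L))
  s <- summarize_interactions(fab)
  ab <- s[s$from_label == "A" & s$to_label == "B", ]
  expect_equal(c(ab$n_pos, ab$n_neg, ab$net), c(2, 1, 1))
  ba <- s[s$from_label == "B" & s$to_label == "A", ]
  expect_equal(c(ba$n_pos, ba$n_neg, ba$net), c(0, 0, 0))
})
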