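# Spatial analysis: per-ROI kNN graphs, neighbor-fraction profiles, cellular
# neighborhoods, tumor patches, border distances and permutation-tested
# cell-cell interactions.

#' Build the k-nearest-neighbor graph of one ROI
#'
#' Exact Euclidean kNN over cell centroids (directed: each cell points to its
#' k nearest cells). Distance ties are broken by ascending `cell_id`.
#' Out-degree is `min(k, n - 1)`; no self-edges.
#'
#' @param cells cell table of a single ROI with columns `cell_id`, `x_um`,
#'   `y_um`.
#' @param k neighbor count (default 20).
#' @return a `knn_graph`: list with `cell_id` (sorted ascending), `x`, `y`,
#'   `k`, `roi_id` and `idx`, an n x min(k, n-1) matrix of neighbor row
#'   indices ordered nearest-first.
#' @export
#' @examples
#' cells <- tibble::tibble(cell_id = c("a", "b", "c"),
#'                         x_um = c(0, 1, 3), y_um = 0)
#' g <- build_knn_graph(cells, k = 1)
#' g$cell_id[g$idx[, 1]]
build_knn_graph <- function(cells, k = 20) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (nrow(cells) < 2) stop("need at least 2 cells in the ROI", call. = FALSE)
  if (length(unique(cells$roi_id %||% "roi")) > 1) {
    stop("build_knn_graph expects cells of a single ROI", call. = FALSE)
  }
  ord <- order(cells$cell_id)
  cells <- cells[ord, ]
  idx <- .knn_brute(cells$x_um, cells$y_um, as.integer(k))
  structure(list(
    roi_id = (cells$roi_id %||% "roi")[1],
    cell_id = cells$cell_id,
    x = cells$x_um, y = cells$y_um,
    k = as.integer(k), idx = idx
  ), class = "knn_graph")
}

#' @export
print.knn_graph <- function(x, ...) {
  cat(sprintf("kNN graph '%s': %d cells, k = %d (out-degree %d)\n",
              x$roi_id, length(x$cell_id), x$k, ncol(x$idx)))
  invisible(x)
}

.graph_labels <- function(graph, labels) {
  if (!is.null(names(labels))) {
    miss <- setdiff(graph$cell_id, names(labels))
    if (length(miss) > 0) {
      stop("unlabeled cell(s): ", paste(head(miss, 3), collapse = ", "),
           call. = FALSE)
    }
    labels <- labels[graph$cell_id]
  } else if (length(labels) != length(graph$cell_id)) {
    stop("labels must be named by cell_id or aligned to graph$cell_id",
         call. = FALSE)
  }
  if (anyNA(labels)) stop("unlabeled cell(s): NA labels present", call. = FALSE)
  as.character(labels)
}

#' Neighbor-fraction profile of every cell
#'
#' For each cell, the fraction of each cell-type among its k nearest
#' neighbors. Types absent from the vocabulary get 0; rows sum to 1.
#'
#' @param graph a [build_knn_graph()] result.
#' @param labels final labels, named by `cell_id` or aligned to
#'   `graph$cell_id`.
#' @param levels label vocabulary spanning the profile columns
#'   (default [sgc_labels()], plus any observed label not listed there).
#' @return numeric matrix (cells x labels), rownames = `cell_id`.
#' @export
neighbor_fractions <- function(graph, labels, levels = NULL) {
  lab <- .graph_labels(graph, labels)
  levels <- levels %||% union(sgc_labels(), sort(unique(lab)))
  if (!all(lab %in% levels)) {
    stop("labels outside the supplied vocabulary: ",
         paste(setdiff(lab, levels), collapse = ", "), call. = FALSE)
  }
  li <- match(lab, levels)
  n <- length(lab); kk <- ncol(graph$idx); L <- length(levels)
  nl <- matrix(li[graph$idx], nrow = n)
  counts <- matrix(0L, nrow = n, ncol = L)
  for (j in seq_len(kk)) {
    counts[cbind(seq_len(n), nl[, j])] <- counts[cbind(seq_len(n), nl[, j])] + 1L
  }
  prof <- counts / kk
  dimnames(prof) <- list(graph$cell_id, levels)
  prof
}

#' Cluster cells into cellular neighborhoods
#'
#' k-means in neighbor-fraction space (10 restarts, seeded). The default of
#' nine neighborhoods follows the published analysis; 6 and 12 are the
#' documented alternatives.
#'
#' @param profiles neighbor-fraction matrix from [neighbor_fractions()]
#'   (pooled across ROIs for a cohort-level model).
#' @param n_neighborhoods number of neighborhoods (default 9).
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @return a `cn_model`: list with `cn` (integer CN id per cell, named),
#'   `centers` (CN x label fraction centroids) and `n_neighborhoods`.
#' @export
assign_neighborhoods <- function(profiles, n_neighborhoods = 9, seed = 1L,
                                 nstart = 10) {
  n_neighborhoods <- assert_count(n_neighborhoods, "n_neighborhoods")
  if (nrow(profiles) < n_neighborhoods) {
    stop("fewer cells than requested neighborhoods", call. = FALSE)
  }
  uniq <- nrow(unique(round(profiles, 12)))
  if (n_neighborhoods == 1 || uniq == 1) {
    cn <- setNames(rep(1L, nrow(profiles)), rownames(profiles))
    centers <- matrix(colMeans(profiles), nrow = 1,
                      dimnames = list(NULL, colnames(profiles)))
    return(structure(list(cn = cn, centers = centers,
                          n_neighborhoods = n_neighborhoods),
                     class = "cn_model"))
  }
  km <- with_seed(seed,
    kmeans(profiles, centers = min(n_neighborhoods, uniq), nstart = nstart,
           iter.max = 100))
  structure(list(
    cn = setNames(as.integer(km$cluster), rownames(profiles)),
    centers = km$centers, n_neighborhoods = n_neighborhoods
  ), class = "cn_model")
}

#' Detect tumor patches
#'
#' Connected components of the symmetrized kNN graph restricted to tumor
#' cells; components with at least `min_size` members become patches.
#'
#' @param graph a [build_knn_graph()] result.
#' @param labels final labels (named by cell_id or aligned).
#' @param min_size minimal patch size (default 10).
#' @param tumor_label label identifying tumor cells.
#' @return a `tumor_patches` object: list with `patch` (integer patch id per
#'   cell, NA outside patches, named by cell_id), `members` (list patch id ->
#'   cell ids) and `min_size`.
#' @export
detect_patches <- function(graph, labels, min_size = 10,
                           tumor_label = "tumor") {
  lab <- .graph_labels(graph, labels)
  tum <- which(lab == tumor_label)
  patch <- setNames(rep(NA_integer_, length(lab)), graph$cell_id)
  members <- list()
  if (length(tum) > 0) {
    # symmetrized adjacency restricted to tumor cells
    n <- length(lab); kk <- ncol(graph$idx)
    from <- rep(seq_len(n), kk)
    to <- as.vector(graph$idx)
    keep <- lab[from] == tumor_label & lab[to] == tumor_label
    sub_from <- match(from[keep], tum)
    sub_to <- match(to[keep], tum)
    g <- igraph::graph_from_edgelist(cbind(sub_from, sub_to), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(tum) - igraph::vcount(g)))
    comp <- igraph::components(g)
    big <- which(comp$csize >= min_size)
    pid <- 0L
    for (b in big) {
      pid <- pid + 1L
      cell_rows <- tum[comp$membership == b]
      patch[cell_rows] <- pid
      members[[pid]] <- graph$cell_id[cell_rows]
    }
  }
  structure(list(patch = patch, members = members, min_size = min_size,
                 roi_id = graph$roi_id),
            class = "tumor_patches")
}

#' @export
print.tumor_patches <- function(x, ...) {
  cat(sprintf("tumor patches '%s': %d patch(es), min size %d\n",
              x$roi_id, length(x$members), x$min_size))
  invisible(x)
}

# closed boundary loops of all patch convex hulls, in mgcv::in.out format
.patch_hulls <- function(graph, patchset) {
  loops <- list()
  for (m in patchset$members) {
    rows <- match(m, graph$cell_id)
    if (length(rows) < 3) next
    xy <- cbind(graph$x[rows], graph$y[rows])
    h <- grDevices::chull(xy)
    loops[[length(loops) + 1]] <- xy[c(h, h[1]), , drop = FALSE]
  }
  if (length(loops) == 0) return(NULL)
  do.call(rbind, lapply(seq_along(loops), function(i) {
    if (i == 1) loops[[i]] else rbind(c(NA, NA), loops[[i]])
  }))
}

#' Signed distance of every cell to the nearest tumor patch
#'
#' Euclidean centroid-to-centroid distance to the nearest patch-member cell.
#' The sign is negative for cells inside a patch region (patch members, or
#' cells falling within the convex hull of a patch); such non-tumor cells are
#' flagged `infiltrating`.
#'
#' @param graph a [build_knn_graph()] result (provides the coordinates).
#' @param patchset a [detect_patches()] result.
#' @return tibble: `cell_id`, `dist_border_um` (NA when no patches exist),
#'   `inside_patch`, `infiltrating` (inside and not a patch member).
#' @export
distance_to_border <- function(graph, patchset) {
  ids <- graph$cell_id
  if (length(patchset$members) == 0) {
    return(tibble::tibble(cell_id = ids, dist_border_um = NA_real_,
                          inside_patch = FALSE, infiltrating = FALSE))
  }
  member_ids <- unlist(patchset$members, use.names = FALSE)
  rows <- match(member_ids, ids)
  d <- .nearest_cross(graph$x, graph$y, graph$x[rows], graph$y[rows])
  inside <- ids %in% member_ids
  bnd <- .patch_hulls(graph, patchset)
  if (!is.null(bnd)) {
    pts <- cbind(graph$x, graph$y)
    in_hull <- mgcv::in.out(bnd, pts)
    inside <- inside | in_hull
  }
  tibble::tibble(
    cell_id = ids,
    dist_border_um = ifelse(inside, -d, d),
    inside_patch = inside,
    infiltrating = inside & !(ids %in% member_ids)
  )
}

#' Permutation test of pairwise cell-type interactions in one ROI
#'
#' For each ordered type pair (A, B) the statistic is the mean number of
#' B-neighbors over A-cells in the directed kNN graph. The null is built by
#' permuting all labels over the fixed cell positions. One-sided p-values use
#' the add-one estimator `p = (1 + #permutations at least as extreme)/(P+1)`,
#' so p is never 0 and never below `1/(P+1)`.
#'
#' @param graph a [build_knn_graph()] result.
#' @param labels final labels.
#' @param n_perm number of permutations P (default 1000).
#' @param alpha per-ROI significance level (default 0.01).
#' @param seed integer seed.
#' @return tibble with one row per ordered pair of observed types: `roi`,
#'   `from_label`, `to_label`, `ct` (observed mean neighbor count), `p_gt`
#'   (interaction), `p_lt` (avoidance) and `sig` in \{-1, 0, +1\}.
#' @export
test_interactions <- function(graph, labels, n_perm = 1000, alpha = 0.01,
                              seed = 1L) {
  if (n_perm <= 0) stop("n_perm must be positive", call. = FALSE)
  lab <- .graph_labels(graph, labels)
  types <- sort(unique(lab))
  tn <- length(types)
  li <- match(lab, types)
  n <- length(lab); kk <- ncol(graph$idx)
  from <- rep(seq_len(n), kk)
  to <- as.vector(graph$idx)
  n_a <- tabulate(li, tn)

  edge_counts <- function(z) {
    tabulate((z[from] - 1L) * tn + z[to], tn * tn)
  }
  obs <- edge_counts(li)
  ge <- integer(tn * tn)
  le <- integer(tn * tn)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      cnt <- edge_counts(sample(li))
      ge <- ge + (cnt >= obs)
      le <- le + (cnt <= obs)
    }
  })
  p_gt <- (1 + ge) / (n_perm + 1)
  p_lt <- (1 + le) / (n_perm + 1)
  pair_from <- rep(seq_len(tn), each = tn)
  pair_to <- rep(seq_len(tn), times = tn)
  ct <- obs / n_a[pair_from]
  sig <- ifelse(p_gt <= alpha, 1L, ifelse(p_lt <= alpha, -1L, 0L))
  tibble::tibble(
    roi = graph$roi_id,
    from_label = types[pair_from],
    to_label = types[pair_to],
    ct = ct, p_gt = p_gt, p_lt = p_lt, sig = sig
  )
}

#' Summarize interaction tests across ROIs
#'
#' Tallies, for every ordered type pair, in how many ROIs the pair was
#' significantly interacting (`sig = +1`) or avoiding (`sig = -1`).
#' (A, B) and (B, A) are counted independently (the statistic is directed).
#'
#' @param tables [test_interactions()] results bound over ROIs.
#' @return tibble: `from_label`, `to_label`, `n_pos`, `n_neg`, `net`.
#' @export
summarize_interactions <- function(tables) {
  if (is.null(tables) || nrow(tables) == 0) {
    return(tibble::tibble(from_label = character(), to_label = character(),
                          n_pos = integer(), n_neg = integer(),
                          net = integer()))
  }
  dplyr::summarise(
    dplyr::group_by(tables, .data$from_label, .data$to_label),
    n_pos = sum(.data$sig == 1L),
    n_neg = sum(.data$sig == -1L),
    net = .data$n_pos - .data$n_neg,
    .groups = "drop"
  )
}
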