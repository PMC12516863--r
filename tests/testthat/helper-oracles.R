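# Independent oracles and fixture builders used across tests.

# uniform random coordinate table for one ROI
rand_roi_coords <- function(n, seed, field = 500, roi = "r") {
  withr::with_seed(seed, tibble::tibble(
    cell_id = sprintf("%s_c%04d", roi, seq_len(n)), roi_id = roi,
    x_um = runif(n, 0, field), y_um = runif(n, 0, field)
  ))
}

# brute-force kNN with the documented tie rule (distance, then ascending id)
oracle_knn <- function(cells, k) {
  cells <- cells[order(cells$cell_id), ]
  n <- nrow(cells)
  d <- as.matrix(dist(cbind(cells$x_um, cells$y_um)))
  diag(d) <- Inf
  kk <- min(k, n - 1)
  t(vapply(seq_len(n), function(i) {
    order(d[i, ], seq_len(n))[seq_len(kk)]
  }, integer(kk)))
}

# flood-fill connected components of tumor cells over the symmetrized kNN
# graph; returns membership vector (NA for non-tumor), components of any size
oracle_flood_fill <- function(graph, labels, tumor_label = "tumor") {
  lab <- labels[graph$cell_id]
  n <- length(lab)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in graph$idx[i, ]) {
      if (lab[i] == tumor_label && lab[j] == tumor_label) {
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in which(lab == tumor_label)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(comp[w])) { comp[w] <- cid; queue <- c(queue, w) }
      }
    }
  }
  stats::setNames(comp, graph$cell_id)
}

# composition over the full vocabulary from a short named vector
full_composition <- function(short) {
  lab <- sgc_labels()
  v <- stats::setNames(rep(0, length(lab)), lab)
  v[names(short)] <- short
  v / sum(v)
}

# an 8-type study composition exercising every branch of the hierarchy
eight_type_composition <- function() {
  full_composition(c(
    tumor = 0.40, endothelia = 0.06, `plasma cell` = 0.07, `CD8 T` = 0.08,
    `CD4 T` = 0.08, `other immune` = 0.07, mCAF = 0.12, `Collagen CAF` = 0.12
  ))
}

# per-type recall of predicted labels against planted truth
macro_recall <- function(truth, pred) {
  labs <- sort(unique(truth))
  mean(vapply(labs, function(l) mean(pred[truth == l] == l), 0))
}
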