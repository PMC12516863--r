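# Hierarchical marker-based phenotyping: Gaussian-mixture tumor gate,
# SOM + consensus meta-clustering of TME cells, and explicit marker rules
# for immune and CAF subsets.

#' Phenotyping stage parameters
#'
#' @param cofactor arcsinh cofactor for the raw counts.
#' @param som_grid SOM grid dimensions (shrunk automatically when a stage has
#'   few cells, keeping at least ~10 cells per node).
#' @param k_level1,k_immune,k_immune_cd4,k_caf meta-cluster counts per stage.
#' @param consensus_reps,consensus_subsample consensus-clustering resampling
#'   parameters.
#' @param gate_posterior posterior cut of the tumor gate (ties go non-tumor).
#' @param min_range minimal across-cluster range (arcsinh units) for a marker
#'   to be called by the midrange rule. Clustering can spread a unimodal
#'   positive population by up to ~2 cell-level standard deviations, so the
#'   guard sits at half the assumed 4-SD archetype separation; below it the
#'   absolute fallback thresholds apply.
#' @param abs_pos,abs_lowpos absolute fallback thresholds (arcsinh units) for
#'   positive and weakly-positive calls.
#' @return validated list of class `phenotype_config`.
#' @export
phenotype_config <- function(cofactor = 1, som_grid = c(10, 10),
                             k_level1 = 6, k_immune = 6, k_immune_cd4 = 4,
                             k_caf = 8, consensus_reps = 100,
                             consensus_subsample = 0.8,
                             gate_posterior = 0.5, min_range = 2,
                             abs_pos = 2, abs_lowpos = 1.2) {
  cfg <- list(cofactor = cofactor, som_grid = som_grid, k_level1 = k_level1,
              k_immune = k_immune, k_immune_cd4 = k_immune_cd4, k_caf = k_caf,
              consensus_reps = consensus_reps,
              consensus_subsample = consensus_subsample,
              gate_posterior = gate_posterior, min_range = min_range,
              abs_pos = abs_pos, abs_lowpos = abs_lowpos)
  stopifnot(cofactor > 0, length(som_grid) == 2, all(som_grid >= 2),
            consensus_reps >= 1, consensus_subsample > 0,
            consensus_subsample <= 1)
  structure(cfg, class = "phenotype_config")
}

#' Two-component Gaussian-mixture gate on cytokeratin expression
#'
#' Fits a 1-D two-component Gaussian mixture by EM on the transformed
#' cytokeratin values; cells whose posterior for the high-mean component
#' exceeds `posterior_cut` are called tumor. The reported threshold is the
#' density crossing point between the two component means.
#'
#' @param ck transformed cytokeratin values (>= 100 cells, non-degenerate).
#' @param seed integer seed.
#' @param posterior_cut posterior cut (default 0.5; ties called non-tumor).
#' @return a `gate_result`: list with `threshold`, `means`, `sds`, `weights`,
#'   `posterior_high` and logical `is_tumor`.
#' @export
#' @examples
#' set.seed(1)
#' ck <- c(rnorm(300, 0.5, 0.1), rnorm(300, 3, 0.3))
#' g <- gate_tumor(ck)
#' mean(g$is_tumor)
gate_tumor <- function(ck, seed = 1L, posterior_cut = 0.5) {
  if (length(ck) < 100) stop("tumor gate needs at least 100 cells", call. = FALSE)
  if (sd(ck) == 0) stop("no separable components: constant input", call. = FALSE)
  mclustBIC <- mclust::mclustBIC # Mclust resolves this symbol in the caller
  fit <- with_seed(seed, suppressWarnings(
    mclust::Mclust(ck, G = 2, modelNames = "V", verbose = FALSE)))
  if (is.null(fit)) {
    fit <- with_seed(seed, suppressWarnings(
      mclust::Mclust(ck, G = 2, modelNames = "E", verbose = FALSE)))
  }
  if (is.null(fit)) stop("no separable components", call. = FALSE)
  mu <- fit$parameters$mean
  sig <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sig) == 1) sig <- rep(sig, 2)
  w <- fit$parameters$pro
  hi <- which.max(mu); lo <- which.min(mu)
  post_hi <- fit$z[, hi]
  g <- function(x) {
    w[hi] * stats::dnorm(x, mu[hi], sig[hi]) -
      w[lo] * stats::dnorm(x, mu[lo], sig[lo])
  }
  thr <- if (g(mu[lo]) * g(mu[hi]) < 0) {
    stats::uniroot(g, lower = mu[lo], upper = mu[hi])$root
  } else {
    mean(mu)
  }
  structure(list(
    threshold = thr,
    means = c(low = unname(mu[lo]), high = unname(mu[hi])),
    sds = c(low = unname(sig[lo]), high = unname(sig[hi])),
    weights = c(low = unname(w[lo]), high = unname(w[hi])),
    posterior_high = post_hi,
    is_tumor = post_hi > posterior_cut
  ), class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf(paste0("GMM tumor gate: threshold %.3f between component means ",
                     "%.3f / %.3f; %d of %d cells called tumor\n"),
              x$threshold, x$means["low"], x$means["high"],
              sum(x$is_tumor), length(x$is_tumor)))
  invisible(x)
}

# shrink the grid so nodes <= cells / 10 (never below 2 x 2)
.som_grid_for <- function(n, grid) {
  while (prod(grid) * 10 > n && all(grid > 2)) {
    grid <- pmax(grid - 1, 2)
  }
  grid
}

#' Self-organizing-map clustering of cells
#'
#' Trains a batch SOM on selected transformed markers and assigns every cell
#' to its best-matching node.
#'
#' @param mat numeric matrix (cells x markers); rownames = cell ids.
#' @param grid SOM grid dimensions, e.g. `c(10, 10)`.
#' @param seed integer seed (initialization and batch schedule are seeded).
#' @return a `cluster_model`: list with `codes` (node x marker codebook),
#'   `node` (node id per cell, named), `grid`.
#' @export
som_cluster <- function(mat, grid = c(10, 10), seed = 1L) {
  n <- nrow(mat)
  nodes <- prod(grid)
  if (n < nodes) stop("fewer cells than SOM nodes", call. = FALSE)
  with_seed(seed, {
    sg <- class::somgrid(grid[1], grid[2], "rectangular")
    radii <- rep(seq(max(grid) / 2, 0.5, length.out = 8), each = 3)
    init <- mat[sample(n, nodes), , drop = FALSE]
    som <- class::batchSOM(mat, sg, radii = radii, init = init)
    codes <- som$codes
    # nearest-code assignment
    d <- outer(rowSums(mat^2), rep(1, nodes)) +
      outer(rep(1, n), rowSums(codes^2)) - 2 * mat %*% t(codes)
    node <- max.col(-d, ties.method = "first")
    structure(list(
      codes = codes, node = setNames(node, rownames(mat)), grid = grid,
      markers = colnames(mat)
    ), class = "cluster_model")
  })
}

#' Consensus meta-clustering of SOM nodes
#'
#' Builds a consensus matrix over the node codebook by repeated subsampled
#' average-linkage hierarchical clusterings, then cuts the consensus
#' dendrogram at `k`. With `reps = 1, subsample = 1` this reduces exactly to
#' a single hierarchical cut.
#'
#' @param model a [som_cluster()] result (or a plain codebook matrix).
#' @param k number of meta-clusters (must not exceed the node count).
#' @param reps,subsample resampling scheme (defaults 100 reps, 80%).
#' @param seed integer seed.
#' @return list with `metacluster` (id per node), `consensus` (node x node
#'   matrix in \[0,1\], diagonal 1) and `k`.
#' @export
consensus_metacluster <- function(model, k, reps = 100, subsample = 0.8,
                                  seed = 1L) {
  codes <- if (inherits(model, "cluster_model")) model$codes else model
  nn <- nrow(codes)
  if (k > nn) stop("k exceeds the number of nodes", call. = FALSE)
  co <- matrix(0, nn, nn)
  tog <- matrix(0, nn, nn)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      take <- sort(sample(nn, max(2, floor(subsample * nn))))
      hc <- hclust(dist(codes[take, , drop = FALSE]), method = "average")
      cl <- cutree(hc, k = min(k, length(take)))
      same <- outer(cl, cl, "==") * 1
      co[take, take] <- co[take, take] + same
      tog[take, take] <- tog[take, take] + 1
    }
  })
  cons <- ifelse(tog > 0, co / pmax(tog, 1), 0)
  diag(cons) <- 1
  hc <- hclust(as.dist(1 - cons), method = "average")
  meta <- cutree(hc, k = k)
  list(metacluster = meta, consensus = cons, k = k)
}

# --- marker positivity rules ------------------------------------------------

# Cluster-level positivity: a meta-cluster is positive for a marker when its
# mean transformed value exceeds the across-cluster midrange, provided the
# across-cluster range is informative (>= min_range); otherwise an absolute
# threshold is the fallback. Returns a logical matrix clusters x markers.
.positivity <- function(means, min_range, abs_pos) {
  lo <- apply(means, 2, min)
  hi <- apply(means, 2, max)
  rng <- hi - lo
  pos <- matrix(FALSE, nrow(means), ncol(means), dimnames = dimnames(means))
  for (j in seq_len(ncol(means))) {
    pos[, j] <- if (rng[j] >= min_range) {
      means[, j] > (lo[j] + hi[j]) / 2
    } else {
      means[, j] > abs_pos
    }
  }
  pos
}

# graded CD4 call: "high" / "low" (weak positive) / "neg"
.cd4_level <- function(means_cd4, min_range, abs_pos, abs_lowpos) {
  lo <- min(means_cd4); hi <- max(means_cd4); rng <- hi - lo
  if (rng >= min_range) {
    ifelse(means_cd4 > lo + 0.5 * rng, "high",
           ifelse(means_cd4 > lo + 0.2 * rng, "low", "neg"))
  } else {
    ifelse(means_cd4 > abs_pos, "high",
           ifelse(means_cd4 > abs_lowpos, "low", "neg"))
  }
}

# SOM + consensus on a marker subset; returns per-cell metacluster id and
# the metacluster x marker mean matrix
.stage_cluster <- function(cells, markers, k, cfg, seed) {
  mat <- as.matrix(cells[, paste0(markers, "_t")])
  colnames(mat) <- markers
  rownames(mat) <- cells$cell_id
  n <- nrow(mat)
  if (n < 4 || n < k) {
    # too few cells to cluster: every cell is its own "cluster"
    meta <- seq_len(n)
    means <- mat
    return(list(meta = setNames(meta, cells$cell_id), means = means))
  }
  if (n <= 500) {
    # small stages: consensus-cluster the cells directly; a SOM at this size
    # has too few nodes to keep rare subtypes from blending into one code
    cm <- consensus_metacluster(mat, k = min(k, n),
                                reps = cfg$consensus_reps,
                                subsample = cfg$consensus_subsample,
                                seed = child_seed(seed, 1))
    meta <- cm$metacluster
    means <- do.call(rbind, lapply(sort(unique(meta)), function(g) {
      colMeans(mat[meta == g, , drop = FALSE])
    }))
    rownames(means) <- sort(unique(meta))
    return(list(meta = setNames(meta, cells$cell_id), means = means))
  }
  grid <- .som_grid_for(n, cfg$som_grid)
  som <- som_cluster(mat, grid = grid, seed = seed)
  # meta-cluster only nodes that own cells; empty nodes keep stale codebook
  # vectors that would otherwise consume meta-cluster slots
  used <- sort(unique(som$node))
  cm <- consensus_metacluster(som$codes[used, , drop = FALSE],
                              k = min(k, length(used)),
                              reps = cfg$consensus_reps,
                              subsample = cfg$consensus_subsample,
                              seed = child_seed(seed, 1))
  meta <- cm$metacluster[match(som$node, used)]
  means <- do.call(rbind, lapply(sort(unique(meta)), function(g) {
    colMeans(mat[meta == g, , drop = FALSE])
  }))
  rownames(means) <- sort(unique(meta))
  list(meta = setNames(meta, cells$cell_id), means = means)
}

#' Level-1 classification of TME cells
#'
#' Clusters non-tumor cells on CD31/CD45/CD138 and labels each meta-cluster:
#' endothelia (CD31 positive), immune (CD45 or CD138 positive), CAF
#' (explicit negative selection: none of CD31/CD45/CD138).
#'
#' @param cells TME cell table with transformed marker columns.
#' @param cfg a [phenotype_config()].
#' @param seed integer seed.
#' @return list with `label` (level-1 label per cell, named by cell id) and
#'   `audit` (meta-cluster mean profiles and assigned labels).
#' @export
classify_level1 <- function(cells, cfg = phenotype_config(), seed = 1L) {
  if (nrow(cells) == 0) {
    return(list(label = setNames(character(), character()), audit = NULL))
  }
  st <- .stage_cluster(cells, c("CD31", "CD45", "CD138"), cfg$k_level1, cfg, seed)
  pos <- .positivity(st$means, cfg$min_range, cfg$abs_pos)
  cl_label <- ifelse(pos[, "CD31"], "endothelia",
                     ifelse(pos[, "CD45"] | pos[, "CD138"], "immune", "CAF"))
  label <- cl_label[as.character(st$meta)]
  list(label = setNames(label, names(st$meta)),
       audit = list(stage = "level1", means = st$means, labels = cl_label))
}

#' Immune subset classification
#'
#' Clusters immune cells on CD45/CD4/CD8a/CD138: plasma cell (CD138+),
#' CD8 T (CD8a+), then a graded CD4 call (CD4-high -> CD4 T lineage,
#' weakly CD4+ -> other CD4+, otherwise other immune). CD4 T cells are
#' re-clustered on CD45/CD4/CD74/Ki67 into proliferating CD4 T (Ki67+),
#' CD4+CD74+ T (CD74+) and CD4 T.
#'
#' @inheritParams classify_level1
#' @return list with `label` (final immune label per cell) and `audit`.
#' @export
classify_immune <- function(cells, cfg = phenotype_config(), seed = 1L) {
  if (nrow(cells) == 0) {
    return(list(label = setNames(character(), character()), audit = NULL))
  }
  st <- .stage_cluster(cells, c("CD45", "CD4", "CD8a", "CD138"),
                       cfg$k_immune, cfg, seed)
  pos <- .positivity(st$means, cfg$min_range, cfg$abs_pos)
  cd4 <- .cd4_level(st$means[, "CD4"], cfg$min_range, cfg$abs_pos, cfg$abs_lowpos)
  cl_label <- ifelse(pos[, "CD138"], "plasma cell",
              ifelse(pos[, "CD8a"], "CD8 T",
              ifelse(cd4 == "high", "CD4 T",
              ifelse(cd4 == "low", "other CD4+", "other immune"))))
  label <- setNames(cl_label[as.character(st$meta)], names(st$meta))
  audit <- list(list(stage = "immune", means = st$means, labels = cl_label))

  cd4_cells <- cells[label[cells$cell_id] == "CD4 T", , drop = FALSE]
  if (nrow(cd4_cells) > 0) {
    st2 <- .stage_cluster(cd4_cells, c("CD45", "CD4", "CD74", "Ki67"),
                          cfg$k_immune_cd4, cfg, child_seed(seed, 2))
    pos2 <- .positivity(st2$means, cfg$min_range, cfg$abs_pos)
    cl2 <- ifelse(pos2[, "Ki67"], "proliferating CD4 T",
           ifelse(pos2[, "CD74"], "CD4+CD74+ T", "CD4 T"))
    label[names(st2$meta)] <- cl2[as.character(st2$meta)]
    audit <- c(audit, list(list(stage = "immune_cd4", means = st2$means,
                                labels = cl2)))
  }
  list(label = label, audit = audit)
}

.caf_rules <- function(pos) {
  ifelse(pos[, "aSMA"] & pos[, "Collagen1"], "mCAF",
  ifelse(pos[, "Collagen1"], "Collagen CAF",
  ifelse(pos[, "aSMA"], "SMA CAF",
  ifelse(pos[, "Ki67"] & pos[, "Vimentin"], "dCAF",
  ifelse(pos[, "CD74"] & pos[, "Vimentin"], "apCAF",
  ifelse(pos[, "Vimentin"], "other CAF (Vimentin+)", "residual"))))))
}

#' CAF subset classification with residual reassignment
#'
#' Clusters CAF cells on Vimentin/aSMA/Collagen1/Ki67/CD74 and applies the
#' marker rules: mCAF (SMA+Collagen1+), Collagen CAF (SMA-Collagen1+),
#' SMA CAF (SMA+Collagen1-), dCAF (Ki67+Vimentin+), apCAF (CD74+Vimentin+),
#' other CAF (Vimentin only). Cells matching no rule are re-clustered once;
#' cells still negative for every marker are relabeled tumor (they sit in
#' tumor patches and likely express cytokeratin below detection).
#'
#' @inheritParams classify_level1
#' @return list with `label` (final label per cell; may contain "tumor") and
#'   `audit`.
#' @export
classify_caf <- function(cells, cfg = phenotype_config(), seed = 1L) {
  if (nrow(cells) == 0) {
    return(list(label = setNames(character(), character()), audit = NULL))
  }
  mk <- c("Vimentin", "aSMA", "Collagen1", "Ki67", "CD74")
  st <- .stage_cluster(cells, mk, cfg$k_caf, cfg, seed)
  pos <- .positivity(st$means, cfg$min_range, cfg$abs_pos)
  cl_label <- .caf_rules(pos)
  label <- setNames(cl_label[as.character(st$meta)], names(st$meta))
  audit <- list(list(stage = "caf", means = st$means, labels = cl_label))

  res <- cells[label[cells$cell_id] == "residual", , drop = FALSE]
  if (nrow(res) > 0) {
    st2 <- .stage_cluster(res, mk, max(2, min(4, nrow(res))), cfg,
                          child_seed(seed, 3))
    pos2 <- .positivity(st2$means, cfg$min_range, cfg$abs_pos)
    cl2 <- .caf_rules(pos2)
    cl2[cl2 == "residual"] <- "tumor"
    label[names(st2$meta)] <- cl2[as.character(st2$meta)]
    audit <- c(audit, list(list(stage = "caf_residual", means = st2$means,
                                labels = cl2)))
  }
  list(label = label, audit = audit)
}

#' Run the full phenotyping hierarchy
#'
#' Transforms raw counts (if needed), gates tumor cells on cytokeratin with a
#' Gaussian mixture, classifies TME cells into endothelia/immune/CAF, then
#' resolves immune and CAF subsets; CAF residuals negative for every marker
#' are relabeled tumor. An audit log of every cluster-to-label assignment is
#' attached as attribute `"audit"`.
#'
#' @param cells cell table with raw marker columns (and `cell_id`).
#' @param cfg a [phenotype_config()].
#' @param seed integer seed.
#' @return `cells` with added `label_level1` and `label_final` columns, in
#'   the original row order.
#' @export
run_phenotyping <- function(cells, cfg = phenotype_config(), seed = 1L) {
  panel <- sgc_panel()$marker
  missing <- setdiff(panel, names(cells))
  if (length(missing) > 0) {
    stop("missing panel marker column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  orig_ids <- cells$cell_id
  if (anyDuplicated(orig_ids)) stop("cell_id must be unique", call. = FALSE)
  if (!all(paste0(panel, "_t") %in% names(cells))) {
    cells <- transform_markers(cells, panel, cfg$cofactor)
  }
  cells <- cells[order(cells$cell_id), ]
  audit <- list()

  gate <- gate_tumor(cells$CKAE13_t, seed = child_seed(seed, 10),
                     posterior_cut = cfg$gate_posterior)
  audit$gate <- gate[c("threshold", "means", "weights")]
  label1 <- setNames(ifelse(gate$is_tumor, "tumor", NA_character_),
                     cells$cell_id)

  tme <- cells[!gate$is_tumor, , drop = FALSE]
  lv1 <- classify_level1(tme, cfg, seed = child_seed(seed, 11))
  label1[names(lv1$label)] <- lv1$label
  audit$level1 <- lv1$audit

  final <- label1
  imm <- tme[lv1$label[tme$cell_id] == "immune", , drop = FALSE]
  im <- classify_immune(imm, cfg, seed = child_seed(seed, 12))
  final[names(im$label)] <- im$label
  audit$immune <- im$audit

  caf <- tme[lv1$label[tme$cell_id] == "CAF", , drop = FALSE]
  cf <- classify_caf(caf, cfg, seed = child_seed(seed, 13))
  final[names(cf$label)] <- cf$label
  audit$caf <- cf$audit

  # residuals relabeled tumor must be consistent at level 1 as well
  label1[names(final)[final == "tumor"]] <- "tumor"

  cells$label_level1 <- unname(label1[cells$cell_id])
  cells$label_final <- unname(final[cells$cell_id])
  cells <- cells[match(orig_ids, cells$cell_id), ]
  attr(cells, "audit") <- audit
  cells
}
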