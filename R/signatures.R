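# Weighted gene-signature construction and scoring, module scores with
# expression-bin-matched controls, quantile spot categorization, rank-sum
# differential expression and pre-ranked gene-set enrichment.

#' Build a log2FC-weighted signature from a differential-expression table
#'
#' Keeps over-expressed genes (log2FC > 0), ranks them by log2FC descending
#' and retains the top fraction `q_sel` (ceiling rule). A matrix-CAF
#' differential-expression program with 490 over-expressed genes yields a
#' 98-gene signature at the default 20% cutoff.
#'
#' @param de_table data frame with columns `gene` and `log2fc` (a column
#'   named `log2FC` or `avg_log2FC` is also accepted).
#' @param q_sel fraction of over-expressed genes to retain (default 0.2).
#' @return a `weighted_signature`: list with `genes` and `weights`
#'   (log2FC, all > 0).
#' @export
#' @examples
#' de <- data.frame(gene = paste0("g", 1:10), log2fc = seq(2, -1, length = 10))
#' build_weighted_signature(de, q_sel = 0.3)
build_weighted_signature <- function(de_table, q_sel = 0.2) {
  fc_col <- intersect(c("log2fc", "log2FC", "avg_log2FC"), names(de_table))[1]
  if (is.na(fc_col) || !"gene" %in% names(de_table)) {
    stop("de_table needs columns 'gene' and 'log2fc'", call. = FALSE)
  }
  if (q_sel <= 0 || q_sel > 1) stop("q_sel must lie in (0, 1]", call. = FALSE)
  de <- de_table[de_table[[fc_col]] > 0, , drop = FALSE]
  if (nrow(de) == 0) stop("no over-expressed genes (log2FC > 0)", call. = FALSE)
  if (anyDuplicated(de$gene)) stop("duplicate gene names", call. = FALSE)
  de <- de[order(-de[[fc_col]]), , drop = FALSE]
  n_keep <- ceiling(q_sel * nrow(de))
  de <- de[seq_len(n_keep), , drop = FALSE]
  structure(list(genes = as.character(de$gene),
                 weights = setNames(de[[fc_col]], de$gene)),
            class = "weighted_signature")
}

#' @export
print.weighted_signature <- function(x, ...) {
  cat(sprintf("weighted signature: %d genes, log2FC weights in [%.2f, %.2f]\n",
              length(x$genes), min(x$weights), max(x$weights)))
  invisible(x)
}

#' Score samples with a weighted signature
#'
#' Per sample: each signature gene's expression is multiplied by its log2FC
#' weight, and the products are summed and averaged over the signature genes
#' present in the matrix. Signature genes missing from the matrix are
#' dropped with a warning and the averaging denominator adjusted.
#'
#' @param expr expression matrix (genes x samples), TPM scale.
#' @param signature a [build_weighted_signature()] result.
#' @param log_transform score on `log2(TPM + 1)` instead of raw TPM.
#' @return named numeric vector of per-sample scores.
#' @export
#' @examples
#' expr <- matrix(c(3, 4), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' sig <- structure(list(genes = c("g1", "g2"),
#'                       weights = c(g1 = 2, g2 = 1)),
#'                  class = "weighted_signature")
#' score_weighted_signature(expr, sig)  # (3*2 + 4*1)/2 = 5
score_weighted_signature <- function(expr, signature, log_transform = FALSE) {
  present <- intersect(signature$genes, rownames(expr))
  if (length(present) == 0) {
    stop("no signature gene present in the expression matrix", call. = FALSE)
  }
  if (length(present) < length(signature$genes)) {
    warning(sprintf("%d of %d signature genes absent from the matrix; dropped",
                    length(signature$genes) - length(present),
                    length(signature$genes)), call. = FALSE)
  }
  e <- expr[present, , drop = FALSE]
  if (log_transform) e <- log2(e + 1)
  colSums(e * signature$weights[present]) / length(present)
}

#' Median stratification of signature scores
#'
#' Scores strictly above the median are "high", the rest "low" (samples at
#' the median go low).
#'
#' @param scores named numeric vector (>= 2 samples).
#' @return factor with levels `low`, `high`, named like `scores`.
#' @export
stratify_by_signature <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 samples", call. = FALSE)
  if (length(unique(scores)) == 1) {
    stop("degenerate stratification: all scores equal", call. = FALSE)
  }
  med <- median(scores)
  factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
}

#' Module score with expression-bin-matched control genes
#'
#' Per spot: mean expression of the gene set minus the mean expression of
#' control genes. For every set gene, `n_ctrl` controls are drawn (seeded)
#' from the same average-expression bin (`n_bins` bins over all genes).
#' Log2FC weights are deliberately not used.
#'
#' @param expr expression matrix (genes x spots).
#' @param genes gene set (at least one gene must be present).
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl controls per set gene (default 100; capped at bin size).
#' @param seed integer seed for the control draw.
#' @return named numeric vector of per-spot scores.
#' @export
module_score <- function(expr, genes, n_bins = 24, n_ctrl = 100, seed = 1L) {
  stopifnot(n_bins >= 1, n_ctrl >= 1)
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0) {
    stop("no gene of the set is present in the matrix", call. = FALSE)
  }
  avg <- rowMeans(expr)
  # rank-based binning copes with heavily tied/skewed averages
  bins <- cut(rank(avg, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  names(bins) <- rownames(expr)
  ctrl <- with_seed(seed, {
    unique(unlist(lapply(present, function(g) {
      pool <- names(bins)[bins == bins[g]]
      sample(pool, min(n_ctrl, length(pool)))
    })))
  })
  colMeans(expr[present, , drop = FALSE]) -
    colMeans(expr[ctrl, , drop = FALSE])
}

#' Categorize spots by paired quantile cuts of two module scores
#'
#' Per sample, the spots with the `q`-fraction highest (lowest) mCAF and
#' endothelia scores are flagged high (low); exactly `floor(q * n)` spots per
#' flag, ties broken by spot id. The four intersections plus "other"
#' partition all spots; samples are then pooled.
#'
#' @param mcaf,endo named per-spot module scores.
#' @param sample_id sample of each spot (recycled if length 1).
#' @param q quantile fraction (default 0.2; 0.1 and 0.3 are the documented
#'   alternatives).
#' @return tibble: `spot_id`, `sample_id`, `category` (factor with levels
#'   `mCAFhigh_endohigh`, `mCAFhigh_endolow`, `mCAFlow_endohigh`,
#'   `mCAFlow_endolow`, `other`).
#' @export
categorize_spots <- function(mcaf, endo, sample_id, q = 0.2) {
  stopifnot(length(mcaf) == length(endo))
  ids <- names(mcaf) %||% as.character(seq_along(mcaf))
  if (length(sample_id) == 1) sample_id <- rep(sample_id, length(mcaf))
  out <- lapply(split(seq_along(mcaf), sample_id), function(ix) {
    n <- length(ix)
    m <- floor(q * n)
    if (m < 1) stop("q * n < 1: too few spots per sample", call. = FALSE)
    pick <- function(score, decreasing) {
      ord <- order(score[ix], ids[ix], decreasing = c(decreasing, FALSE),
                   method = "radix")
      ix[ord][seq_len(m)]
    }
    m_hi <- pick(mcaf, TRUE); m_lo <- pick(mcaf, FALSE)
    e_hi <- pick(endo, TRUE); e_lo <- pick(endo, FALSE)
    cat <- rep("other", n)
    names(cat) <- as.character(ix)
    cat[as.character(intersect(m_hi, e_hi))] <- "mCAFhigh_endohigh"
    cat[as.character(intersect(m_hi, e_lo))] <- "mCAFhigh_endolow"
    cat[as.character(intersect(m_lo, e_hi))] <- "mCAFlow_endohigh"
    cat[as.character(intersect(m_lo, e_lo))] <- "mCAFlow_endolow"
    tibble::tibble(spot_id = ids[ix], sample_id = sample_id[ix],
                   category = unname(cat))
  })
  res <- dplyr::bind_rows(out)
  res$category <- factor(res$category,
                         levels = c("mCAFhigh_endohigh", "mCAFhigh_endolow",
                                    "mCAFlow_endohigh", "mCAFlow_endolow",
                                    "other"))
  res[match(ids, res$spot_id), ]
}

#' Rank-sum differential expression between two spot groups
#'
#' Per gene: two-sided Wilcoxon rank-sum p-value and a pseudocount-stabilized
#' average log2 fold change `log2((mean_A + eps) / (mean_B + eps))`, with
#' Benjamini-Hochberg adjustment across genes.
#'
#' @param expr expression matrix (genes x spots).
#' @param group logical or two-level factor over spots; `TRUE` (or the first
#'   level) is group A.
#' @param eps pseudocount for the fold change (default 1e-9).
#' @return tibble: `gene`, `avg_log2FC`, `p`, `p_adj`, ordered by
#'   decreasing `avg_log2FC`.
#' @export
rank_sum_de <- function(expr, group, eps = 1e-9) {
  if (is.factor(group) || is.character(group)) {
    group <- group == (levels(factor(group))[1])
  }
  a <- which(group); b <- which(!group)
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  # vectorized rank-sum: rank each gene's row once
  ranks <- t(apply(expr, 1, rank))
  w <- rowSums(ranks[, a, drop = FALSE]) - na * (na + 1) / 2
  mu <- na * nb / 2
  # normal approximation with tie correction per gene
  tie_term <- apply(expr, 1, function(v) {
    tt <- table(v); sum(tt^3 - tt)
  })
  n <- na + nb
  sig2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- (w - mu) / sqrt(pmax(sig2, .Machine$double.eps))
  p <- ifelse(sig2 <= 0, 1, 2 * pnorm(-abs(z)))
  ma <- rowMeans(expr[, a, drop = FALSE])
  mb <- rowMeans(expr[, b, drop = FALSE])
  lfc <- log2((ma + eps) / (mb + eps))
  out <- tibble::tibble(gene = rownames(expr), avg_log2FC = unname(lfc),
                        p = unname(p), p_adj = p.adjust(unname(p), "BH"))
  out[order(-out$avg_log2FC), ]
}

#' Read gene sets from a GMT file
#'
#' Tab-separated lines: set name, description, then member genes. Duplicate
#' genes within a set are stored once.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(setNames(list(), character()))
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop(sprintf("malformed GMT line %d: expected name, description, genes",
                   i), call. = FALSE)
    }
    sets[[parts[1]]] <- unique(parts[-(1:2)])
  }
  sets
}

# running-sum enrichment score (Kolmogorov-Smirnov style, unweighted):
# ranked = gene names, decreasing by the ranking statistic
.running_es <- function(ranked, set) {
  hit <- ranked %in% set
  nh <- sum(hit)
  n <- length(ranked)
  if (nh == 0 || nh == n) return(0)
  step <- ifelse(hit, 1 / nh, -1 / (n - nh))
  rs <- cumsum(step)
  rs[which.max(abs(rs))]
}

#' Pre-ranked gene-set enrichment
#'
#' Kolmogorov-Smirnov-style running-sum enrichment score on a ranked gene
#' list, permutation p-values by gene-label permutation, and BH q-values
#' across sets. Sets covering less than `min_coverage` of their genes in the
#' ranked list are excluded before testing.
#'
#' @param ranked_genes character vector of genes ordered by decreasing
#'   ranking statistic (e.g. `avg_log2FC`).
#' @param gene_sets named list of gene sets (see [read_gmt()]).
#' @param n_perm permutations (default 1000).
#' @param min_coverage minimal fraction of set genes present (default 0.4).
#' @param seed integer seed.
#' @return tibble: `set`, `size` (genes present), `coverage`, `es`,
#'   `p`, `q`.
#' @export
preranked_enrichment <- function(ranked_genes, gene_sets, n_perm = 1000,
                                 min_coverage = 0.4, seed = 1L) {
  cov <- vapply(gene_sets, function(s) mean(s %in% ranked_genes), 0)
  keep <- cov >= min_coverage & vapply(gene_sets, function(s) {
    k <- sum(s %in% ranked_genes); k >= 1 && k < length(ranked_genes)
  }, TRUE)
  if (!any(keep)) {
    stop("no gene set passes the coverage filter", call. = FALSE)
  }
  gene_sets <- gene_sets[keep]
  cov <- cov[keep]
  n <- length(ranked_genes)
  res <- with_seed(seed, {
    lapply(names(gene_sets), function(nm) {
      members <- intersect(gene_sets[[nm]], ranked_genes)
      es <- .running_es(ranked_genes, members)
      null <- vapply(seq_len(n_perm), function(i) {
        .running_es(ranked_genes, sample(ranked_genes, length(members)))
      }, 0)
      p <- (1 + sum(abs(null) >= abs(es))) / (n_perm + 1)
      tibble::tibble(set = nm, size = length(members), coverage = cov[[nm]],
                     es = es, p = p)
    })
  })
  out <- dplyr::bind_rows(res)
  out$q <- p.adjust(out$p, "BH")
  out[order(-abs(out$es)), ]
}

#' Pearson correlation of two per-spot score vectors
#'
#' @param x,y equal-length numeric vectors (n >= 3, non-constant).
#' @return list with `r` and `p` (two-sided).
#' @export
score_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance in a score vector", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
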