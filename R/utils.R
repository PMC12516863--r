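#' @importFrom stats rnorm runif rlnorm rexp rgamma rbinom median quantile
#'   sd var cor cor.test wilcox.test kruskal.test p.adjust setNames aggregate
#'   hclust cutree dist kmeans as.dist pnorm pchisq complete.cases
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded internals do not
#' perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(old <- globalenv()$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed and index tuple
#'
#' Stable integer hashing so that one global seed fans out to per-unit seeds
#' (e.g. per patient x ROI) that are reproducible and order-independent.
#'
#' @param seed parent integer seed.
#' @param ... non-negative integer indices identifying the child stream.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, 3, 7)
child_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(idx) >= 1, all(idx >= 0))
  m <- 2147483629 # prime < 2^31
  h <- as.numeric(seed) %% m
  for (i in idx) {
    # 64-bit-safe modular mix using doubles (products stay < 2^53)
    h <- (h * 48271 + (as.numeric(i) + 1) * 16807) %% m
    h <- (h * 69621 + 12345) %% m
  }
  as.integer(h %% (2^31 - 3) + 1)
}

assert_prob_vector <- function(p, what = "probability vector", tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < -tol)) {
    stop(sprintf("invalid %s: entries must be finite and non-negative", what),
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("invalid %s: entries sum to %.12f, not 1", what, sum(p)),
         call. = FALSE)
  }
  invisible(p)
}

assert_count <- function(x, what) {
  if (length(x) != 1 || !is.finite(x) || x <= 0 || x != round(x)) {
    stop(sprintf("%s must be a single positive integer", what), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Dirichlet draw via gamma representation (no external dependency needed).
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}
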