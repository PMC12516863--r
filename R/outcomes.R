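# Patient-level aggregation, group comparisons, eigengene correlations and
# survival analysis with dichotomized TME variables.

#' Per-patient median cell-type (or neighborhood) frequencies
#'
#' Computes per-ROI fractions over `by` (final label or CN id), then the
#' per-patient median of each fraction across that patient's ROIs.
#'
#' @param cells labeled cell table with `patient_id`, `roi_id` and the
#'   column named by `by`.
#' @param by column holding the per-cell category (default `label_final`).
#' @param levels category vocabulary (default: observed values, plus the
#'   full label vocabulary when `by = "label_final"`).
#' @param primaries_only if not NULL, a character vector of ROI ids to keep
#'   (e.g. primary cores only).
#' @return tibble: one row per patient, one column per category (medians of
#'   per-ROI fractions, in \[0,1\]).
#' @export
per_patient_frequencies <- function(cells, by = "label_final", levels = NULL,
                                    primaries_only = NULL) {
  if (!by %in% names(cells)) stop("no column '", by, "'", call. = FALSE)
  if (!is.null(primaries_only)) {
    cells <- cells[cells$roi_id %in% primaries_only, , drop = FALSE]
  }
  if (anyNA(cells[[by]])) stop("unlabeled cells present", call. = FALSE)
  levels <- levels %||% if (by == "label_final") {
    union(sgc_labels(), sort(unique(as.character(cells[[by]]))))
  } else {
    sort(unique(cells[[by]]))
  }
  tab <- table(cells$roi_id, factor(cells[[by]], levels = levels))
  frac <- tab / rowSums(tab)
  stopifnot(all(abs(rowSums(frac) - 1) < 1e-9))
  roi2pt <- cells$patient_id[match(rownames(frac), cells$roi_id)]
  med <- apply(frac, 2, function(col) tapply(col, roi2pt, median))
  if (is.null(dim(med))) med <- matrix(med, nrow = 1,
                                       dimnames = list(unique(roi2pt), levels))
  tibble::as_tibble(med, rownames = "patient_id")
}

#' Nonparametric group comparison of cell frequencies
#'
#' Mann-Whitney U for two groups, Kruskal-Wallis for more, per cell-type
#' column, with Benjamini-Hochberg adjustment across the tested columns
#' (one BH family per comparison table).
#'
#' @param freqs [per_patient_frequencies()] result (or any tibble with
#'   `patient_id` plus numeric columns).
#' @param grouping named vector (by patient_id) or vector aligned to rows.
#' @return tibble: `variable`, `test`, `statistic`, `p`, `p_adj`; columns
#'   where any group has fewer than 2 observations are skipped with a
#'   warning.
#' @export
compare_groups <- function(freqs, grouping) {
  g <- if (!is.null(names(grouping))) grouping[freqs$patient_id] else grouping
  g <- factor(g)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  vars <- setdiff(names(freqs), "patient_id")
  rows <- lapply(vars, function(v) {
    x <- freqs[[v]]
    sizes <- table(g[!is.na(x)])
    if (any(sizes < 2) || length(sizes) < nlevels(g)) {
      warning("skipping '", v, "': a group has < 2 observations",
              call. = FALSE)
      return(NULL)
    }
    if (nlevels(g) == 2) {
      ht <- suppressWarnings(wilcox.test(x ~ g))
      tibble::tibble(variable = v, test = "mann-whitney",
                     statistic = unname(ht$statistic), p = ht$p.value)
    } else {
      ht <- kruskal.test(x ~ g)
      tibble::tibble(variable = v, test = "kruskal-wallis",
                     statistic = unname(ht$statistic), p = ht$p.value)
    }
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) out$p_adj <- p.adjust(out$p, "BH")
  out
}

#' Spearman correlation of cell frequencies with ECM module eigengenes
#'
#' @param freqs [per_patient_frequencies()] result.
#' @param eigengenes tibble/data.frame with `patient_id` (or sample id
#'   matching `freqs$patient_id`) and one numeric column per ECM module.
#' @return tibble: `cell_type`, `module`, `rho`, `p`, `p_adj` (BH across the
#'   whole matrix).
#' @export
spearman_vs_eigengenes <- function(freqs, eigengenes) {
  common <- intersect(freqs$patient_id, eigengenes$patient_id)
  if (length(common) < 3) {
    stop("fewer than 3 overlapping samples", call. = FALSE)
  }
  f <- freqs[match(common, freqs$patient_id), , drop = FALSE]
  e <- eigengenes[match(common, eigengenes$patient_id), , drop = FALSE]
  cts <- setdiff(names(f), "patient_id")
  mods <- setdiff(names(e), "patient_id")
  rows <- list()
  for (ct in cts) {
    for (m in mods) {
      st <- suppressWarnings(
        cor.test(f[[ct]], e[[m]], method = "spearman"))
      rows[[length(rows) + 1]] <- tibble::tibble(
        cell_type = ct, module = m,
        rho = unname(st$estimate), p = st$p.value)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_adj <- p.adjust(out$p, "BH")
  out
}

#' Median dichotomization of a TME variable
#'
#' Values strictly above the median go "high", the rest "low". When the
#' median equals zero the split is positive vs negative (zero) instead.
#'
#' @param values numeric vector (>= 2, non-constant), optionally named.
#' @return factor with levels `low`, `high` (or `negative`, `positive` when
#'   the median is zero).
#' @export
#' @examples
#' dichotomize_median(c(0, 0, 0, 0.2, 0.5))
dichotomize_median <- function(values) {
  if (length(values) < 2) stop("need at least 2 patients", call. = FALSE)
  if (length(unique(values)) == 1) {
    stop("constant values cannot be dichotomized", call. = FALSE)
  }
  med <- median(values)
  if (med == 0) {
    out <- factor(ifelse(values > 0, "positive", "negative"),
                  levels = c("negative", "positive"))
  } else {
    out <- factor(ifelse(values > med, "high", "low"),
                  levels = c("low", "high"))
  }
  names(out) <- names(values)
  out
}

#' Kaplan-Meier estimate with survival rates at requested times
#'
#' Product-limit estimator; the five-year rate is conventionally read at 60
#' months.
#'
#' @param times follow-up times (>= 0).
#' @param events event indicators (1 = event, 0 = censored).
#' @param eval_times times at which to report survival (default 60).
#' @return list with `fit` (a `survfit`), `curve` (tibble time/surv) and
#'   `rates` (named survival probabilities at `eval_times`).
#' @export
km_estimate <- function(times, events, eval_times = 60) {
  stopifnot(all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  sf <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  rates <- setNames(sf(eval_times), paste0("t", eval_times))
  list(fit = fit,
       curve = tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                              n_event = fit$n.event, surv = fit$surv),
       rates = rates)
}

#' Log-rank test between two groups
#'
#' Two-sided via the chi-square statistic; one-sided from the signed normal
#' deviate, testing the alternative that the *second* group level has the
#' higher hazard (worse outcome).
#'
#' @param times,events follow-up data.
#' @param group two-level factor.
#' @param sided `"two"` or `"one"`.
#' @return list with `chisq`, `p` and (one-sided) `direction_worse`, the
#'   level with the higher observed/expected event ratio.
#' @export
logrank_test <- function(times, events, group, sided = c("two", "one")) {
  sided <- match.arg(sided)
  group <- factor(group)
  if (nlevels(group) != 2) stop("need exactly 2 groups", call. = FALSE)
  if (sum(events) == 0) stop("no events observed", call. = FALSE)
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ group)
  chisq <- sd_$chisq
  p2 <- pchisq(chisq, df = 1, lower.tail = FALSE)
  # signed deviate: positive when the second level has excess events
  z <- (sd_$obs[2] - sd_$exp[2]) / sqrt(sd_$var[2, 2])
  worse <- levels(group)[if (z >= 0) 2 else 1]
  if (sided == "two") {
    list(chisq = chisq, p = p2, z = z, direction_worse = worse)
  } else {
    list(chisq = chisq, p = pnorm(z, lower.tail = FALSE), z = z,
         direction_worse = worse)
  }
}

#' Cox proportional-hazards fit with complete-separation detection
#'
#' Univariate (one model per covariate) or multivariate partial-likelihood
#' fit. A covariate is flagged `complete_separation` when a binary level
#' contains all or none of the events, or when the fit drifts to an
#' unbounded coefficient (monotone likelihood); such covariates are
#' reported with the flag raised so callers can exclude them.
#'
#' @param data data frame of covariates.
#' @param covariates covariate column names.
#' @param times,events follow-up data (aligned with `data` rows).
#' @param mode `"univariate"` or `"multivariate"`.
#' @param ties tie handling passed to [survival::coxph()] (default
#'   `"efron"`).
#' @return tibble: `covariate`, `term`, `hr`, `ci_lower`, `ci_upper`, `p`,
#'   `complete_separation`.
#' @export
cox_fit <- function(data, covariates, times, events,
                    mode = c("univariate", "multivariate"),
                    ties = "efron") {
  mode <- match.arg(mode)
  if (sum(events) == 0) stop("no events observed", call. = FALSE)
  sep_flag <- function(v) {
    # a binary/categorical level holding all (equivalently: another holding
    # none) of the events gives a monotone partial likelihood
    if (is.numeric(v) && length(unique(v)) > 2) return(FALSE)
    any(vapply(split(events, v), function(e) sum(e) == 0, TRUE))
  }
  fit_one <- function(cov_set) {
    df <- data[, cov_set, drop = FALSE]
    df$.time <- times
    df$.event <- events
    fml <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~",
      paste(sprintf("`%s`", cov_set), collapse = " + ")))
    fit <- suppressWarnings(survival::coxph(fml, data = df, ties = ties))
    sm <- summary(fit)
    coefs <- sm$coefficients
    ci <- sm$conf.int
    terms <- rownames(coefs)
    cov_of_term <- vapply(terms, function(tr) {
      hits <- cov_set[startsWith(tr, sprintf("`%s`", cov_set)) |
                        startsWith(tr, cov_set)]
      hits[which.max(nchar(hits))]
    }, "")
    tibble::tibble(
      covariate = unname(cov_of_term), term = terms,
      hr = unname(coefs[, "exp(coef)"]),
      ci_lower = unname(ci[, "lower .95"]),
      ci_upper = unname(ci[, "upper .95"]),
      p = unname(coefs[, "Pr(>|z|)"]),
      complete_separation =
        vapply(cov_of_term, function(cv) sep_flag(data[[cv]]), TRUE) |
        abs(coefs[, "coef"]) > 15 | !is.finite(coefs[, "se(coef)"])
    )
  }
  out <- if (mode == "univariate") {
    dplyr::bind_rows(lapply(covariates, fit_one))
  } else {
    fit_one(covariates)
  }
  out
}
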