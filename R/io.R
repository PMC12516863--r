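# File formats, configuration and the pipeline driver.

#' Read a segmented single-cell table
#'
#' CSV with one row per cell: `cell_id`, `patient_id`, `roi_id`, `x_um`,
#' `y_um` and one column per raw marker. Raw counts must be non-negative.
#'
#' @param path CSV path.
#' @param markers marker columns expected (default: the 13-marker panel).
#' @return tibble cell table.
#' @export
read_cell_table <- function(path, markers = sgc_panel()$marker) {
  cells <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("cell_id", "patient_id", "roi_id", "x_um", "y_um", markers)
  for (col in required) {
    if (!col %in% names(cells)) {
      stop("missing column ", col, call. = FALSE)
    }
  }
  for (m in markers) {
    if (any(cells[[m]] < 0, na.rm = TRUE)) {
      stop("negative raw counts in column ", m, call. = FALSE)
    }
  }
  cells$cell_id <- as.character(cells$cell_id)
  cells
}

#' Write a cell table as CSV
#'
#' @param cells cell table.
#' @param path destination path.
#' @export
write_cell_table <- function(cells, path) {
  readr::write_csv(cells, path)
  invisible(path)
}

#' Published cohort bookkeeping counts
#'
#' Small tables of printed cohort summary counts bundled with the package:
#' retained-core cell counts per level-1 compartment, analyzed cores by
#' role, and pooled spatial-transcriptomics spot category sizes. Used for
#' bookkeeping identities (compartments sum to the post-exclusion cell
#' count; primaries + metastases sum to the analyzed cores; category counts
#' sum to the total spots).
#'
#' @return list of tibbles `compartment_cells`, `cores`,
#'   `st_spot_categories`.
#' @export
published_counts <- function() {
  dir <- system.file("extdata", "published_counts", package = "sgctme")
  list(
    compartment_cells = readr::read_csv(
      file.path(dir, "compartment_cells.csv"), show_col_types = FALSE),
    cores = readr::read_csv(
      file.path(dir, "cores.csv"), show_col_types = FALSE),
    st_spot_categories = readr::read_csv(
      file.path(dir, "st_spot_categories.csv"), show_col_types = FALSE)
  )
}

#' Build and validate a pipeline configuration
#'
#' One document holding every stage parameter; unknown keys are rejected.
#'
#' @param simulate [sim_config()] arguments (list) for the synthetic stage,
#'   or NULL to start from an existing cell table.
#' @param cell_table path to a cell-table CSV (ignored when `simulate` is
#'   given).
#' @param phenotype [phenotype_config()] arguments (list).
#' @param k spatial graph neighbor count.
#' @param n_neighborhoods cellular-neighborhood count.
#' @param min_patch_size minimal tumor patch size.
#' @param n_perm,alpha interaction-test permutations and per-ROI level.
#' @param q_sel signature selection fraction.
#' @param q_spot spot-category quantile fraction.
#' @param n_bins,n_ctrl module-score parameters.
#' @param survival_times evaluation times (months) for survival rates.
#' @param seed global seed.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = list(), cell_table = NULL,
                            phenotype = list(), k = 20, n_neighborhoods = 9,
                            min_patch_size = 10, n_perm = 1000, alpha = 0.01,
                            q_sel = 0.2, q_spot = 0.2, n_bins = 24,
                            n_ctrl = 100, survival_times = 60, seed = 1L) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (n_neighborhoods <= 0) stop("n_neighborhoods must be positive",
                                 call. = FALSE)
  if (min_patch_size <= 0) stop("min_patch_size must be positive",
                                call. = FALSE)
  if (n_perm <= 0) stop("n_perm must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  sim <- if (is.null(simulate)) NULL else {
    do.call(sim_config, modifyList(simulate, list(seed = seed)))
  }
  ph <- do.call(phenotype_config, phenotype)
  structure(list(
    simulate = sim, cell_table = cell_table, phenotype = ph, k = k,
    n_neighborhoods = n_neighborhoods, min_patch_size = min_patch_size,
    n_perm = n_perm, alpha = alpha, q_sel = q_sel, q_spot = q_spot,
    n_bins = n_bins, n_ctrl = n_ctrl, survival_times = survival_times,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The document is a flat mapping of [pipeline_config()] arguments; unknown
#' keys are rejected before any stage runs.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in the published order: simulate (or load) a cell
#' table, phenotype every cell, build per-ROI spatial graphs (cellular
#' neighborhoods, tumor patches, border distances, interaction tests), and
#' aggregate to patient-level frequencies with survival stratification by
#' the mCAF fraction. A machine-readable manifest (seed, parameters, output
#' hashes) accompanies the outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir if given, results are written as CSV/JSON under this
#'   directory.
#' @return list with `cells`, `clinical`, `cn_model`, `interactions`,
#'   `interaction_summary`, `frequencies`, `survival`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage <- function(...) message("[sgctme] ", sprintf(...))

  # --- simulate / load -------------------------------------------------
  clinical <- NULL
  if (!is.null(config$simulate)) {
    log_stage("simulate: %d patients x %d ROIs x %d cells",
              config$simulate$n_patients, config$simulate$rois_per_patient,
              config$simulate$cells_per_roi)
    cohort <- generate_cohort(config$simulate)
    cells <- cohort$cells
    clinical <- cohort$clinical
  } else {
    if (is.null(config$cell_table)) {
      stop("pipeline needs either a simulate block or a cell_table path",
           call. = FALSE)
    }
    log_stage("load: %s", config$cell_table)
    cells <- read_cell_table(config$cell_table)
  }

  # --- phenotype --------------------------------------------------------
  log_stage("phenotype: %d cells", nrow(cells))
  cells <- run_phenotyping(cells, config$phenotype,
                           seed = child_seed(config$seed, 100))

  # --- spatial ----------------------------------------------------------
  rois <- split(seq_len(nrow(cells)), cells$roi_id)
  log_stage("spatial: %d ROIs, k = %d", length(rois), config$k)
  profiles <- list()
  inter <- list()
  spatial_cols <- list()
  for (rid in names(rois)) {
    roi_cells <- cells[rois[[rid]], ]
    if (nrow(roi_cells) < 2) next
    g <- build_knn_graph(roi_cells, k = config$k)
    lab <- setNames(roi_cells$label_final, roi_cells$cell_id)
    profiles[[rid]] <- neighbor_fractions(g, lab)
    patches <- detect_patches(g, lab, min_size = config$min_patch_size)
    dists <- distance_to_border(g, patches)
    dists$patch_id <- unname(patches$patch[dists$cell_id])
    spatial_cols[[rid]] <- dists
    inter[[rid]] <- test_interactions(
      g, lab, n_perm = config$n_perm, alpha = config$alpha,
      seed = child_seed(config$seed, 200, match(rid, names(rois))))
  }
  prof_all <- do.call(rbind, profiles)
  cn <- assign_neighborhoods(prof_all, config$n_neighborhoods,
                             seed = child_seed(config$seed, 300))
  sp <- dplyr::bind_rows(spatial_cols)
  cells <- dplyr::left_join(cells, sp, by = "cell_id")
  cells$cn <- unname(cn$cn[cells$cell_id])
  interactions <- dplyr::bind_rows(inter)
  inter_sum <- summarize_interactions(interactions)

  # --- outcomes ---------------------------------------------------------
  log_stage("outcomes: per-patient frequencies and survival")
  freqs <- per_patient_frequencies(cells)
  survival_res <- NULL
  if (!is.null(clinical)) {
    mcaf <- setNames(freqs$mCAF, freqs$patient_id)[clinical$patient_id]
    grp <- dichotomize_median(mcaf)
    lr <- logrank_test(clinical$time_rfp, clinical$event_recurrence, grp,
                       sided = "one")
    km_by <- lapply(split(seq_along(grp), grp), function(ix) {
      km_estimate(clinical$time_rfp[ix], clinical$event_recurrence[ix],
                  eval_times = config$survival_times)$rates
    })
    cox <- cox_fit(data.frame(mcaf_group = grp), "mcaf_group",
                   clinical$time_rfp, clinical$event_recurrence)
    survival_res <- list(group = grp, logrank = lr, km_rates = km_by,
                         cox = cox)
  }

  manifest <- list(
    package = "sgctme",
    version = as.character(utils::packageVersion("sgctme")),
    seed = config$seed,
    parameters = list(k = config$k, n_neighborhoods = config$n_neighborhoods,
                      min_patch_size = config$min_patch_size,
                      n_perm = config$n_perm, alpha = config$alpha),
    n_cells = nrow(cells), n_rois = length(rois)
  )

  result <- list(cells = cells, clinical = clinical, cn_model = cn,
                 interactions = interactions, interaction_summary = inter_sum,
                 frequencies = freqs, survival = survival_res,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(cells, file.path(out_dir, "cells.csv"))
    if (!is.null(clinical)) {
      readr::write_csv(clinical, file.path(out_dir, "clinical.csv"))
    }
    readr::write_csv(interactions, file.path(out_dir, "interactions.csv"))
    readr::write_csv(inter_sum, file.path(out_dir, "interaction_summary.csv"))
    readr::write_csv(freqs, file.path(out_dir, "frequencies.csv"))
    files <- list.files(out_dir, full.names = TRUE, pattern = "\\.csv$")
    manifest$output_md5 <- as.list(tools::md5sum(files))
    result$manifest <- manifest
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}
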