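# Synthetic cohort generator: spatial cell maps with planted niches,
# clinical outcomes tied to the true mCAF fraction, bulk expression and
# spatial-transcriptomics spots with tunable mCAF-endothelia co-localization.

#' Default entity-specific cell-type compositions
#'
#' Probability vectors over the final label vocabulary for the four tumor
#' entities. The tumor compartment dominates (~55-65%), the acinic cell
#' carcinoma (ACC) composition carries a visibly larger immune compartment,
#' and endothelia are rare everywhere, mirroring the compartment sizes seen
#' in salivary gland carcinoma tissue.
#'
#' @return named list of named probability vectors, one per entity.
#' @export
default_compositions <- function() {
  lab <- sgc_labels()
  mk <- function(v) {
    names(v) <- lab
    assert_prob_vector(v, "composition")
    v
  }
  list(
    SDC = mk(c(0.640, 0.010,
               0.020, 0.015, 0.020, 0.005, 0.005, 0.020, 0.020,
               0.080, 0.060, 0.030, 0.010, 0.015, 0.050)),
    ACC = mk(c(0.540, 0.010,
               0.030, 0.035, 0.045, 0.010, 0.010, 0.040, 0.040,
               0.050, 0.060, 0.020, 0.010, 0.040, 0.060)),
    MEC = mk(c(0.620, 0.010,
               0.020, 0.020, 0.025, 0.005, 0.005, 0.025, 0.020,
               0.060, 0.070, 0.030, 0.010, 0.020, 0.060)),
    Sec = mk(c(0.630, 0.010,
               0.020, 0.015, 0.020, 0.005, 0.005, 0.025, 0.020,
               0.050, 0.070, 0.030, 0.010, 0.020, 0.070))
  )
}

#' Default per-cell-type marker archetypes
#'
#' Log-normal location/scale parameters of the raw counts for every
#' (cell type, marker) pair. Defining markers sit at a high location
#' (count ~60), negatives at a low baseline (count ~0.5); on the arcsinh
#' scale (cofactor 1) this separates type means by well over 4 standard
#' deviations, which is what marker-rule phenotyping assumes. The weakly
#' CD4-expressing myeloid-like class ("other CD4+") is planted at an
#' intermediate CD4 level (count ~5).
#'
#' @return list with matrices `meanlog` and `sdlog` (type x marker).
#' @export
default_marker_model <- function() {
  labels <- sgc_labels()
  markers <- sgc_panel()$marker
  lo <- log(0.5)
  hi <- log(60)
  mid <- log(5)
  meanlog <- matrix(lo, nrow = length(labels), ncol = length(markers),
                    dimnames = list(labels, markers))
  sdlog <- matrix(0.35, nrow = length(labels), ncol = length(markers),
                  dimnames = list(labels, markers))
  meanlog[, "DNA"] <- hi
  pos <- list(
    "tumor"                 = c("CKAE13"),
    "endothelia"            = c("CD31", "CD34"),
    "plasma cell"           = c("CD45", "CD138"),
    "CD8 T"                 = c("CD45", "CD8a"),
    "CD4 T"                 = c("CD45", "CD4"),
    "proliferating CD4 T"   = c("CD45", "CD4", "Ki67"),
    "CD4+CD74+ T"           = c("CD45", "CD4", "CD74"),
    "other immune"          = c("CD45"),
    "mCAF"                  = c("aSMA", "Collagen1", "Vimentin"),
    "Collagen CAF"          = c("Collagen1", "Vimentin"),
    "SMA CAF"               = c("aSMA", "Vimentin"),
    "dCAF"                  = c("Ki67", "Vimentin"),
    "apCAF"                 = c("CD74", "Vimentin"),
    "other CAF (Vimentin+)" = c("Vimentin")
  )
  for (ty in names(pos)) meanlog[ty, pos[[ty]]] <- hi
  meanlog["other CD4+", "CD45"] <- hi
  meanlog["other CD4+", "CD4"] <- mid
  list(meanlog = meanlog, sdlog = sdlog)
}

#' Build and validate a simulation configuration
#'
#' Defaults describe the emulated cohort: 54 patients across four entities
#' (SDC/ACC/MEC/Sec at the observed case mix), a handful of 500 x 500 um
#' ROIs per patient at roughly two thousand cells each, tumor cells
#' concentrated in patches, mCAFs attracted to vessel lines, lymphocyte
#' aggregates, and recurrence hazards elevated in mCAF-rich patients.
#'
#' @param n_patients,rois_per_patient,cells_per_roi cohort dimensions.
#' @param entity_mix probability vector over entities SDC/ACC/MEC/Sec.
#' @param composition named list: per entity, probability vector over
#'   [sgc_labels()].
#' @param marker_model list of `meanlog`/`sdlog` matrices (type x marker);
#'   see [default_marker_model()].
#' @param niche_params list: `n_tumor_patches`, `patch_radius_um`,
#'   `n_vessels`, `vessel_buffer_um`, `mcaf_vessel_affinity` in \[0,1\],
#'   `n_lymph_aggregates`, `lymph_radius_um`, `lymph_density` in \[0,1\]
#'   (fraction of lymphocytes placed inside aggregates).
#' @param hazard_log_hr_mcaf planted log hazard ratio for recurrence
#'   endpoints; interpretation set by `hazard_model`.
#' @param hazard_model `"group"` (log HR between mCAF-high and -low patient
#'   groups, dichotomized at the median true fraction) or `"fraction"`
#'   (log HR per unit true mCAF fraction).
#' @param baseline_hazard baseline event rate per month.
#' @param censor_rate target fraction of patients censored before the event
#'   (0 = administrative censoring only, 1 = everything censored at time 0).
#' @param horizon_months administrative follow-up horizon.
#' @param st_colocalization latent correlation in \[-1,1\] between the true
#'   mCAF and endothelia abundance fields of spatial-transcriptomics spots.
#' @param composition_concentration Dirichlet concentration for per-patient
#'   composition variability around the entity composition.
#' @param seed global integer seed; fans out to child seeds via [child_seed()].
#' @return a validated `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 4, rois_per_patient = 1, cells_per_roi = 200)
sim_config <- function(n_patients = 54,
                       rois_per_patient = 4,
                       cells_per_roi = 2000,
                       entity_mix = c(SDC = 23, ACC = 13, MEC = 12, Sec = 6) / 54,
                       composition = default_compositions(),
                       marker_model = default_marker_model(),
                       niche_params = list(),
                       hazard_log_hr_mcaf = log(6),
                       hazard_model = c("group", "fraction"),
                       baseline_hazard = 0.006,
                       censor_rate = 0.25,
                       horizon_months = 120,
                       st_colocalization = 0.5,
                       composition_concentration = 150,
                       seed = 1L) {
  hazard_model <- match.arg(hazard_model)
  n_patients <- assert_count(n_patients, "n_patients")
  rois_per_patient <- assert_count(rois_per_patient, "rois_per_patient")
  cells_per_roi <- assert_count(cells_per_roi, "cells_per_roi")
  assert_prob_vector(entity_mix, "entity_mix")
  if (!all(sort(names(entity_mix)) == sort(c("SDC", "ACC", "MEC", "Sec")))) {
    stop("entity_mix must be named over SDC, ACC, MEC, Sec", call. = FALSE)
  }
  lab <- sgc_labels()
  for (e in names(composition)) {
    cmp <- composition[[e]]
    if (!identical(sort(names(cmp)), sort(lab))) {
      stop("composition for entity ", e,
           " must be named over the full label vocabulary", call. = FALSE)
    }
    assert_prob_vector(cmp, paste0("composition[", e, "]"))
  }
  missing_ent <- setdiff(names(entity_mix), names(composition))
  if (length(missing_ent) > 0) {
    stop("no composition for entit(ies): ", paste(missing_ent, collapse = ", "),
         call. = FALSE)
  }
  np_def <- list(n_tumor_patches = 3, patch_radius_um = 80,
                 n_vessels = 2, vessel_buffer_um = 20,
                 mcaf_vessel_affinity = 0.8,
                 n_lymph_aggregates = 2, lymph_radius_um = 50,
                 lymph_density = 0.6)
  unknown <- setdiff(names(niche_params), names(np_def))
  if (length(unknown) > 0) {
    stop("unknown niche_params: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  np <- modifyList(np_def, niche_params)
  if (np$mcaf_vessel_affinity < 0 || np$mcaf_vessel_affinity > 1) {
    stop("mcaf_vessel_affinity must lie in [0, 1]", call. = FALSE)
  }
  if (np$lymph_density < 0 || np$lymph_density > 1) {
    stop("lymph_density must lie in [0, 1]", call. = FALSE)
  }
  if (censor_rate < 0 || censor_rate > 1) {
    stop("censor_rate must lie in [0, 1]", call. = FALSE)
  }
  if (st_colocalization < -1 || st_colocalization > 1) {
    stop("st_colocalization must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(
    n_patients = n_patients, rois_per_patient = rois_per_patient,
    cells_per_roi = cells_per_roi, entity_mix = entity_mix,
    composition = composition, marker_model = marker_model,
    niche_params = np, hazard_log_hr_mcaf = hazard_log_hr_mcaf,
    hazard_model = hazard_model, baseline_hazard = baseline_hazard,
    censor_rate = censor_rate, horizon_months = horizon_months,
    st_colocalization = st_colocalization,
    composition_concentration = composition_concentration,
    field_um = 500, seed = as.integer(seed)
  ), class = "sim_config")
}

# distance from points to a segment p1-p2
.seg_dist <- function(x, y, p1, p2) {
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  len2 <- vx^2 + vy^2
  t <- ((x - p1[1]) * vx + (y - p1[2]) * vy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((x - (p1[1] + t * vx))^2 + (y - (p1[2] + t * vy))^2)
}

# random chord of the square [0, f]^2: random interior point plus angle,
# extended to the borders
.random_chord <- function(f) {
  cx <- runif(1, 0.2 * f, 0.8 * f)
  cy <- runif(1, 0.2 * f, 0.8 * f)
  th <- runif(1, 0, pi)
  d <- c(cos(th), sin(th))
  ts <- c()
  for (s in c(-1, 1)) {
    t <- f * 2
    # clip to square
    for (axis in 1:2) {
      o <- c(cx, cy)[axis]
      dd <- d[axis] * s
      if (abs(dd) > 1e-12) {
        t <- min(t, max((0 - o) / dd, (f - o) / dd))
      }
    }
    ts <- c(ts, t * s)
  }
  list(p1 = c(cx + ts[1] * d[1], cy + ts[1] * d[2]),
       p2 = c(cx + ts[2] * d[1], cy + ts[2] * d[2]))
}

#' Generate one synthetic ROI with planted spatial niches
#'
#' Places `cells_per_roi` cells in a 500 x 500 um field: tumor cells
#' concentrated in circular patches, endothelia strung along vessel line
#' segments, mCAFs attracted to the 20 um vessel buffer with probability
#' `mcaf_vessel_affinity`, lymphocytes partially pooled in aggregates, and
#' everything else uniform. Raw marker counts are drawn from the per-type
#' log-normal archetypes. Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param entity entity name (must have a composition in `config`).
#' @param seed integer seed for this ROI.
#' @param composition optional composition overriding the entity default
#'   (used for patient-specific compositions).
#' @param roi_id,patient_id identifiers stamped into the table.
#' @return list with `cells` (tibble: cell_id, patient_id, roi_id, x_um,
#'   y_um, raw marker columns) and `truth` (true per-cell type, niche map).
#' @export
#' @examples
#' roi <- generate_roi(sim_config(cells_per_roi = 200), "SDC", seed = 7)
#' table(roi$truth$true_type)
generate_roi <- function(config, entity, seed,
                         composition = NULL,
                         roi_id = "roi1", patient_id = "pt1") {
  stopifnot(inherits(config, "sim_config"))
  if (config$cells_per_roi < 50) {
    stop("cells_per_roi must be at least 50", call. = FALSE)
  }
  cmp <- composition %||% config$composition[[entity]]
  if (is.null(cmp)) stop("no composition for entity ", entity, call. = FALSE)
  assert_prob_vector(cmp, "composition")
  lab <- sgc_labels()
  cmp <- cmp[lab]
  np <- config$niche_params
  f <- config$field_um
  mm <- config$marker_model
  markers <- colnames(mm$meanlog)
  with_seed(seed, {
    n <- config$cells_per_roi
    type <- sample(lab, n, replace = TRUE, prob = cmp)

    patches <- cbind(runif(np$n_tumor_patches, 0.15 * f, 0.85 * f),
                     runif(np$n_tumor_patches, 0.15 * f, 0.85 * f))
    vessels <- lapply(seq_len(np$n_vessels), function(i) .random_chord(f))
    aggs <- cbind(runif(np$n_lymph_aggregates, 0.15 * f, 0.85 * f),
                  runif(np$n_lymph_aggregates, 0.15 * f, 0.85 * f))

    x <- runif(n, 0, f)
    y <- runif(n, 0, f)

    place_gauss <- function(idx, centers, radius) {
      if (length(idx) == 0 || nrow(centers) == 0) return()
      ci <- sample(nrow(centers), length(idx), replace = TRUE)
      px <- rnorm(length(idx), centers[ci, 1], radius / 2)
      py <- rnorm(length(idx), centers[ci, 2], radius / 2)
      x[idx] <<- pmin(pmax(px, 0), f)
      y[idx] <<- pmin(pmax(py, 0), f)
    }

    # tumor cells: 90% into patches
    ti <- which(type == "tumor")
    in_patch <- ti[runif(length(ti)) < 0.9]
    place_gauss(in_patch, patches, np$patch_radius_um)

    # lymphocytes into aggregates with probability lymph_density
    lymph <- which(type %in% c("plasma cell", "CD8 T", "CD4 T",
                               "proliferating CD4 T", "CD4+CD74+ T"))
    in_agg <- lymph[runif(length(lymph)) < np$lymph_density]
    place_gauss(in_agg, aggs, np$lymph_radius_um)

    place_on_vessel <- function(idx, max_perp) {
      # rejection-sample so the placed point stays inside the field AND
      # within max_perp of its vessel (clamping could break the buffer
      # guarantee near corners)
      for (i in idx) {
        v <- vessels[[sample(length(vessels), 1)]]
        for (try in 1:100) {
          t <- runif(1)
          px <- v$p1[1] + t * (v$p2[1] - v$p1[1])
          py <- v$p1[2] + t * (v$p2[2] - v$p1[2])
          ang <- runif(1, 0, 2 * pi)
          r <- runif(1, 0, max_perp)
          qx <- px + r * cos(ang); qy <- py + r * sin(ang)
          if (qx >= 0 && qx <= f && qy >= 0 && qy <= f) {
            x[i] <<- qx; y[i] <<- qy
            break
          }
        }
      }
    }

    if (np$n_vessels > 0) {
      place_on_vessel(which(type == "endothelia"), 5)
      mi <- which(type == "mCAF")
      near <- mi[runif(length(mi)) < np$mcaf_vessel_affinity]
      place_on_vessel(near, np$vessel_buffer_um)
    }

    raw <- matrix(0, nrow = n, ncol = length(markers),
                  dimnames = list(NULL, markers))
    for (ty in unique(type)) {
      idx <- which(type == ty)
      for (m in markers) {
        raw[idx, m] <- rlnorm(length(idx), mm$meanlog[ty, m], mm$sdlog[ty, m])
      }
    }

    cells <- tibble::tibble(
      cell_id = sprintf("%s_c%05d", roi_id, seq_len(n)),
      patient_id = patient_id, roi_id = roi_id,
      x_um = x, y_um = y
    )
    for (m in markers) cells[[m]] <- raw[, m]
    truth <- list(
      true_type = setNames(type, cells$cell_id),
      patches = patches, vessels = vessels, aggregates = aggs,
      composition = cmp, seed = seed
    )
    list(cells = cells, truth = truth)
  })
}

#' Generate a full synthetic cohort
#'
#' Samples entities and per-patient compositions, generates all ROIs (unless
#' `include_cells = FALSE`, for survival-focused studies), and draws clinical
#' covariates and outcomes. Recurrence and distant-recurrence hazards are
#' elevated for mCAF-rich patients according to `hazard_model`; overall
#' survival is independent of the mCAF fraction. Censoring is administrative
#' at `horizon_months` plus an independent exponential censoring process
#' calibrated to `censor_rate`.
#'
#' @param config a [sim_config()].
#' @param include_cells generate cell tables for every ROI (may be slow for
#'   large cohorts; the clinical table and ground truth never require it).
#' @return list with `cells` (tibble or NULL), `clinical` (tibble with one
#'   row per patient: entity, age, sex, AR percent, HER2 score, T/N stage,
#'   times and event flags for OS/RFS/RFP/DCR) and `truth` (per-patient true
#'   mCAF fraction, planted group, planted log HR, per-ROI niche maps).
#' @export
generate_cohort <- function(config, include_cells = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  lab <- sgc_labels()
  with_seed(child_seed(config$seed, 0), {
    n <- config$n_patients
    entity <- sample(names(config$entity_mix), n, replace = TRUE,
                     prob = config$entity_mix)
    pcomp <- matrix(0, nrow = n, ncol = length(lab),
                    dimnames = list(NULL, lab))
    for (i in seq_len(n)) {
      base <- config$composition[[entity[i]]][lab]
      pcomp[i, ] <- rdirichlet1(base * config$composition_concentration)
    }
    mcaf_frac <- pcomp[, "mCAF"]

    # clinical covariates, sampled near the observed cohort marginals
    age <- round(rnorm(n, mean = c(SDC = 66, ACC = 54, MEC = 49,
                                   Sec = 49)[entity], sd = 16))
    sex <- sample(c("F", "M"), n, replace = TRUE)
    ar_percent <- ifelse(entity == "SDC", round(runif(n, 0, 100)), NA_real_)
    her2_score <- ifelse(entity == "SDC",
                         sample(0:3, n, replace = TRUE,
                                prob = c(0.23, 0.18, 0.23, 0.36)), NA_integer_)
    t_stage <- sample(c("T1/2", "T3/4"), n, replace = TRUE, prob = c(0.58, 0.42))
    n_stage <- sample(c("N0", "N+"), n, replace = TRUE, prob = c(0.58, 0.42))

    grp_high <- mcaf_frac > median(mcaf_frac)
    lp <- switch(config$hazard_model,
                 group = config$hazard_log_hr_mcaf * as.numeric(grp_high),
                 fraction = config$hazard_log_hr_mcaf * mcaf_frac)
    lam0 <- config$baseline_hazard
    t_rec <- rexp(n, rate = lam0 * exp(lp))
    t_dist <- rexp(n, rate = 0.8 * lam0 * exp(lp))
    t_death <- rexp(n, rate = 0.7 * lam0)

    cr <- config$censor_rate
    if (cr >= 1) {
      cens <- rep(0, n)
    } else if (cr <= 0) {
      cens <- rep(config$horizon_months, n)
    } else {
      cens <- pmin(rexp(n, rate = lam0 * cr / (1 - cr)), config$horizon_months)
    }
    obs <- function(t) list(time = pmin(t, cens), event = as.integer(t <= cens))
    os <- obs(t_death)
    rfp <- obs(t_rec)
    dcr <- obs(t_dist)
    rfs <- obs(pmin(t_rec, t_death))

    clinical <- tibble::tibble(
      patient_id = sprintf("pt%03d", seq_len(n)),
      entity = entity, age = age, sex = sex,
      ar_percent = ar_percent, her2_score = her2_score,
      t_stage = t_stage, n_stage = n_stage,
      time_os = os$time, event_death = os$event,
      time_rfs = rfs$time, event_rfs = rfs$event,
      time_rfp = rfp$time, event_recurrence = rfp$event,
      time_dcr = dcr$time, event_distant = dcr$event
    )
    truth <- list(
      mcaf_fraction = setNames(mcaf_frac, clinical$patient_id),
      mcaf_group_high = setNames(grp_high, clinical$patient_id),
      composition = pcomp,
      hazard_log_hr = config$hazard_log_hr_mcaf,
      hazard_model = config$hazard_model,
      rois = list()
    )
    cells <- NULL
    if (include_cells) {
      pieces <- vector("list", n * config$rois_per_patient)
      kk <- 0
      for (i in seq_len(n)) {
        for (r in seq_len(config$rois_per_patient)) {
          kk <- kk + 1
          rid <- sprintf("pt%03d_roi%02d", i, r)
          roi <- generate_roi(config, entity[i],
                              seed = child_seed(config$seed, i, r),
                              composition = setNames(pcomp[i, ], lab),
                              roi_id = rid,
                              patient_id = clinical$patient_id[i])
          pieces[[kk]] <- roi$cells
          truth$rois[[rid]] <- roi$truth
        }
      }
      cells <- dplyr::bind_rows(pieces)
    }
    list(cells = cells, clinical = clinical, truth = truth)
  })
}

#' Generate a synthetic bulk expression matrix with a planted signature shift
#'
#' TPM-like matrix (genes x samples): log-normal baseline expression, the
#' signature genes multiplied by `effect` in the "high" half of the samples,
#' then every column renormalized to a constant total of 1e6.
#'
#' @param signature a [build_weighted_signature()] result (or anything with
#'   a `$genes` field).
#' @param n_samples number of samples (half labelled "high").
#' @param effect fold-change applied to signature genes in high samples
#'   (must be > 0; 1 = null).
#' @param n_background number of non-signature background genes.
#' @param seed integer seed.
#' @return list with `expr` (genes x samples matrix), `group`
#'   (factor high/low) and `genes`.
#' @export
generate_bulk <- function(signature, n_samples = 60, effect = 4,
                          n_background = 1000, seed = 1L) {
  genes_sig <- signature$genes
  if (length(genes_sig) == 0) stop("signature is empty", call. = FALSE)
  if (!is.finite(effect) || effect <= 0) {
    stop("effect must be a positive fold-change", call. = FALSE)
  }
  with_seed(seed, {
    bg <- sprintf("BG%04d", seq_len(n_background))
    genes <- c(genes_sig, bg)
    base <- rlnorm(length(genes), meanlog = 3, sdlog = 1)
    expr <- matrix(rlnorm(length(genes) * n_samples,
                          meanlog = log(base), sdlog = 0.3),
                   nrow = length(genes),
                   dimnames = list(genes, sprintf("s%03d", seq_len(n_samples))))
    group <- factor(rep(c("high", "low"), length.out = n_samples),
                    levels = c("high", "low"))
    expr[genes_sig, group == "high"] <- expr[genes_sig, group == "high"] * effect
    expr <- sweep(expr, 2, colSums(expr), "/") * 1e6
    list(expr = expr, group = group, genes = genes)
  })
}

#' Generate synthetic spatial-transcriptomics spots
#'
#' Each spot carries a true cell-type composition; its expression is the
#' composition-weighted mix of cell-type expression profiles with
#' log-normal noise. The latent mCAF and endothelia abundances are drawn
#' from a bivariate normal with correlation `st_colocalization`, so the
#' planted co-localization level is directly tunable.
#'
#' @param config a [sim_config()] (uses `st_colocalization`).
#' @param n_spots spots per sample.
#' @param n_samples number of samples to pool.
#' @param mcaf_genes,endo_genes,n_background gene content of the profiles;
#'   defaults use 40 mCAF program genes, the 5 canonical endothelial markers
#'   and 500 background genes.
#' @param seed integer seed.
#' @return list with `expr` (genes x spots), `spots` (tibble: spot_id,
#'   sample_id, x, y, true mCAF/endothelia abundance).
#' @export
generate_st <- function(config, n_spots = 1500, n_samples = 3,
                        mcaf_genes = sprintf("MCAFG%02d", 1:40),
                        endo_genes = c("PECAM1", "VWF", "CDH5", "KDR", "MCAM"),
                        n_background = 500, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  rho <- config$st_colocalization
  with_seed(seed, {
    genes <- c(mcaf_genes, endo_genes, sprintf("BG%04d", seq_len(n_background)))
    ng <- length(genes)
    # cell-type profiles: mCAF program, endothelial program, tumor background
    prof <- matrix(1, nrow = ng, ncol = 3,
                   dimnames = list(genes, c("mcaf", "endo", "tumor")))
    prof[, "tumor"] <- rlnorm(ng, meanlog = 1, sdlog = 0.5)
    prof[, "mcaf"] <- prof[, "tumor"]
    prof[, "endo"] <- prof[, "tumor"]
    prof[mcaf_genes, "mcaf"] <- prof[mcaf_genes, "tumor"] * 8
    prof[endo_genes, "endo"] <- prof[endo_genes, "tumor"] * 8

    pieces <- list()
    abund <- list()
    for (s in seq_len(n_samples)) {
      z1 <- rnorm(n_spots)
      z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * rnorm(n_spots)
      m_ab <- stats::plogis(z1) * 0.5          # mCAF fraction in [0, 0.5]
      e_ab <- stats::plogis(z2) * 0.3          # endothelia fraction in [0, 0.3]
      t_ab <- pmax(1 - m_ab - e_ab, 0)
      comp <- cbind(mcaf = m_ab, endo = e_ab, tumor = t_ab)
      mu <- prof %*% t(comp)                   # genes x spots expected mix
      noise <- matrix(rlnorm(ng * n_spots, meanlog = 0, sdlog = 0.3),
                      nrow = ng)
      pieces[[s]] <- mu * noise
      abund[[s]] <- tibble::tibble(
        spot_id = sprintf("s%d_spot%05d", s, seq_len(n_spots)),
        sample_id = sprintf("sample%d", s),
        x = runif(n_spots, 0, 6500), y = runif(n_spots, 0, 6500),
        mcaf_abundance = m_ab, endo_abundance = e_ab
      )
    }
    expr <- do.call(cbind, pieces)
    spots <- dplyr::bind_rows(abund)
    colnames(expr) <- spots$spot_id
    rownames(expr) <- genes
    list(expr = expr, spots = spots)
  })
}
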