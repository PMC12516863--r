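# sgctme

Spatial single-cell analysis of the salivary gland carcinoma (SGC) tumor
microenvironment (TME).

Salivary gland carcinomas are rare, heterogeneous, and — in the case of
salivary duct carcinoma (SDC) — highly aggressive. Imaging mass cytometry
(IMC) reads a panel of metal-tagged antibodies off tissue sections at
single-cell resolution, which makes it possible to ask not just *which*
cells populate the TME (fibroblast subtypes, immune subsets, vessels) but
*where they sit relative to each other*, and whether that spatial
organization carries prognostic information. This package implements that
analysis chain for users working from segmented single-cell tables
(CellProfiler-style CSV exports) and matched clinical data:

1. **Phenotyping** — `asinh(raw/cofactor)` transformation; a two-component
   Gaussian-mixture gate on cytokeratin separates tumor from TME cells;
   TME cells pass through SOM clustering with consensus meta-clustering and
   explicit marker rules into endothelia, immune subsets (plasma cells,
   CD8⁺ T, CD4⁺ T and its proliferating/CD74⁺/weak-CD4 variants) and CAF
   subtypes (mCAF = SMA⁺Collagen1⁺, Collagen CAF, SMA CAF, dCAF, apCAF,
   Vimentin-only).
2. **Spatial analysis** — per-ROI directed k-nearest-neighbor graphs
   (k = 20, ties by cell id); cellular neighborhoods as k-means clusters of
   neighbor-fraction vectors (default 9); tumor patches as connected
   components of ≥ 10 tumor cells with signed border distances and
   infiltration flags; permutation-null interaction/avoidance tests per
   ordered type pair, with the statistic
   `ct(A,B) = mean over A-cells of #B among its k neighbors` and
   `p = (1 + #{null ≥ obs}) / (P + 1)`.
3. **Signatures** — log2FC-weighted gene signatures (top 20% of
   over-expressed genes; score = mean over genes of expression × log2FC)
   for bulk RNA-seq; bin-matched-control module scores, quantile spot
   categories, rank-sum differential expression and pre-ranked
   Kolmogorov–Smirnov gene-set enrichment for spatial transcriptomics.
4. **Outcomes** — per-patient median cell-type/neighborhood frequencies;
   Mann–Whitney/Kruskal–Wallis comparisons with Benjamini–Hochberg
   adjustment; Spearman correlation against ECM module eigengenes; median
   dichotomization (positive-vs-negative when the median is zero);
   Kaplan–Meier, one- and two-sided log-rank, and Cox
   proportional-hazards fits with complete-separation flagging.
5. **Synthetic cohorts** — a seeded generator planting every recoverable
   target: entity-specific compositions, tumor patches, vessel-attracted
   mCAFs, lymphocyte aggregates, survival hazards tied to the true mCAF
   fraction, signature-shifted bulk matrices, and ST spots with a tunable
   mCAF–endothelia co-localization.

## Worked example

A small synthetic cohort end to end (simulate → phenotype → spatial →
outcomes):

```r
library(sgctme)

cfg <- pipeline_config(
  simulate = list(n_patients = 6, rois_per_patient = 2, cells_per_roi = 1000),
  n_perm = 500, n_neighborhoods = 4, seed = 42)
res <- run_pipeline(cfg)

dplyr::select(res$frequencies, patient_id, tumor, mCAF, `CD8 T`)
#> # A tibble: 6 × 4
#>   patient_id tumor   mCAF `CD8 T`
#> 1 pt001      0.593 0.118   0.0115
#> 2 pt002      0.628 0.112   0.017
#> 3 pt003      0.604 0.072   0.0255
#> 4 pt004      0.697 0.047   0.004
#> 5 pt005      0.492 0.0565  0.0375
#> 6 pt006      0.726 0.057   0.0165
```

Per-patient rows are medians across that patient's ROIs of per-ROI label
fractions. Interaction summaries count, per directed type pair, the ROIs
with significant co-localization (`n_pos`) or avoidance (`n_neg`):

```r
res$interaction_summary[res$interaction_summary$n_pos > 1, ]
#>   from_label to_label     n_pos n_neg   net
#> 1 CD4 T      CD4 T           10     0    10
#> 2 CD4 T      CD4+CD74+ T      6     0     6
#> 3 CD4 T      CD8 T            8     0     8
#> ...
```

(lymphocytes aggregate, so T-cell subsets co-localize across most ROIs).
Survival stratification by the median mCAF fraction:

```r
res$survival$logrank$p        # one-sided log-rank, mCAF-high worse RFP
#> 0.183
res$survival$cox[, c("term", "hr", "ci_lower", "ci_upper", "p")]
#>   term           hr       ci_lower ci_upper  p
#> 1 mcaf_grouphigh 2.73     0.283    26.4      0.385
```

At six patients the planted hazard (group HR 6) is not detectable — the
hazard ratio points the right way but the confidence interval is wide. The
acceptance script below demonstrates ≥ 90% one-sided log-rank power and
near-nominal Cox CI coverage at 200 patients over 100 replicates.

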