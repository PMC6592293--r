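# The two diagnostic procedures: the step-wise clinical algorithm and the
# molecular decision rule, plus the dysplasia grade flag derived from the
# mutation profile.

#' Configuration of the diagnostic rules
#'
#' Tunable parameters shared by the clinical and molecular classifiers.
#'
#' @param cea_threshold_ng_ml Cyst-fluid CEA cut-off in ng/ml, inclusive
#'   (default 192; 124 is the ROC-optimal alternative on the full cohort).
#' @param kras_maf_threshold_pct KRAS mutant allele frequency gate in percent,
#'   inclusive (default 1.8, the ROC-derived threshold separating incidental
#'   low-level KRAS clones from mucinous neoplasia).
#' @param size_threshold_mm Cyst size (mm) that, together with a mucinous EUS
#'   impression, fires the size step (default 30, the conventional
#'   "worrisome feature" size; the source algorithm's exact cut-off is not
#'   published, so this is a documented extrapolation).
#' @param mucinous_gene_panel Genes whose confirmed somatic mutation labels a
#'   cyst mucinous (default BRAF, KRAS, GNAS, PIK3CA, CDKN2A, PTEN, SMAD4,
#'   TP53).
#' @param nonmucinous_marker_genes Genes flagging a specific non-mucinous
#'   etiology (default VHL, the serous cystadenoma marker).
#' @param use_maf_gate When `TRUE`, KRAS variants count toward the molecular
#'   rule only if their MAF is at least `kras_maf_threshold_pct` (missing MAF
#'   still counts). Default `FALSE`.
#' @param step_order Evaluation order of the clinical steps; a permutation of
#'   `c("cytology", "cea", "viscosity", "mural_nodule", "eus_size")`.
#' @return An object of class `algorithm_config`.
#' @export
algorithm_config <- function(cea_threshold_ng_ml = 192,
                             kras_maf_threshold_pct = 1.8,
                             size_threshold_mm = 30,
                             mucinous_gene_panel = c("BRAF", "KRAS", "GNAS",
                                                     "PIK3CA", "CDKN2A", "PTEN",
                                                     "SMAD4", "TP53"),
                             nonmucinous_marker_genes = "VHL",
                             use_maf_gate = FALSE,
                             step_order = c("cytology", "cea", "viscosity",
                                            "mural_nodule", "eus_size")) {
  if (cea_threshold_ng_ml <= 0 || kras_maf_threshold_pct <= 0 ||
      size_threshold_mm <= 0) {
    abort("thresholds must be strictly positive")
  }
  mucinous_gene_panel <- normalize_gene(mucinous_gene_panel)
  nonmucinous_marker_genes <- normalize_gene(nonmucinous_marker_genes)
  if (length(intersect(mucinous_gene_panel, nonmucinous_marker_genes)) > 0) {
    abort("mucinous and non-mucinous gene panels must be disjoint")
  }
  steps <- c("cytology", "cea", "viscosity", "mural_nodule", "eus_size")
  if (!setequal(step_order, steps)) {
    abort(sprintf("step_order must be a permutation of: %s",
                  paste(steps, collapse = ", ")))
  }
  structure(
    list(cea_threshold_ng_ml = cea_threshold_ng_ml,
         kras_maf_threshold_pct = kras_maf_threshold_pct,
         size_threshold_mm = size_threshold_mm,
         mucinous_gene_panel = mucinous_gene_panel,
         nonmucinous_marker_genes = nonmucinous_marker_genes,
         use_maf_gate = use_maf_gate,
         step_order = step_order),
    class = "algorithm_config"
  )
}

.new_diagnosis <- function(case_id, label, grade_flag, rationale) {
  tibble::tibble(
    case_id = case_id, label = label, grade_flag = grade_flag,
    rationale = list(rationale)
  )
}

.rationale_row <- function(rule, fired, evidence) {
  tibble::tibble(rule = rule, fired = fired, evidence = evidence)
}

# One clinical step: returns NULL when the feature is missing (step skipped),
# else a rationale row whose `fired` decides the label.
.clinical_step <- function(step, case, cfg) {
  switch(step,
    cytology = {
      if (case$cytology == "MISSING") return(NULL)
      fired <- case$cytology %in% c("ATY_SUS", "POS")
      .rationale_row("cytology", fired,
                     sprintf("cytology %s", case$cytology))
    },
    cea = {
      if (is.na(case$cea_ng_ml)) return(NULL)
      fired <- case$cea_ng_ml >= cfg$cea_threshold_ng_ml
      .rationale_row("cea", fired,
                     sprintf("CEA %.1f ng/ml vs threshold %.0f",
                             case$cea_ng_ml, cfg$cea_threshold_ng_ml))
    },
    viscosity = {
      if (case$viscosity == "unknown") return(NULL)
      .rationale_row("viscosity", case$viscosity == "viscous",
                     sprintf("fluid %s", case$viscosity))
    },
    mural_nodule = {
      if (case$mural_nodule == "unknown") return(NULL)
      .rationale_row("mural_nodule", case$mural_nodule == "yes",
                     sprintf("mural nodule %s", case$mural_nodule))
    },
    eus_size = {
      if (case$eus_impression == "unknown" || is.na(case$cyst_size_mm)) return(NULL)
      fired <- case$eus_impression == "mucinous" &&
        case$cyst_size_mm >= cfg$size_threshold_mm
      .rationale_row("eus_size", fired,
                     sprintf("EUS %s, size %.0f mm vs threshold %.0f",
                             case$eus_impression, case$cyst_size_mm,
                             cfg$size_threshold_mm))
    }
  )
}

#' Step-wise clinical classification
#'
#' Applies the clinical algorithm to each case: the configured steps are
#' evaluated in order (default: cytology, CEA, viscosity, mural nodule, then
#' EUS impression with size) and the first step that fires labels the cyst
#' mucinous (`mPCN`); if no step fires the label is non-mucinous (`nmPCL`).
#' Steps whose feature is missing are skipped rather than imputed. The
#' rationale trail records every step actually evaluated, in order.
#'
#' @param cases A case tibble (one or more rows).
#' @param cfg An [algorithm_config()].
#' @return A diagnosis tibble: `case_id`, `label`, `grade_flag`
#'   (`"not_applicable"` for the clinical route), `rationale` list-column.
#' @export
classify_clinical <- function(cases, cfg = algorithm_config()) {
  stopifnot(inherits(cfg, "algorithm_config"))
  out <- lapply(seq_len(nrow(cases)), function(i) {
    case <- cases[i, ]
    available <- c(case$cytology != "MISSING", !is.na(case$cea_ng_ml),
                   case$viscosity != "unknown", case$mural_nodule != "unknown",
                   case$eus_impression != "unknown", !is.na(case$cyst_size_mm))
    if (!any(available)) {
      abort(sprintf("case %s: all clinical features missing, unclassifiable",
                    case$case_id))
    }
    trail <- list()
    label <- "nmPCL"
    for (step in cfg$step_order) {
      row <- .clinical_step(step, case, cfg)
      if (is.null(row)) next
      trail[[length(trail) + 1]] <- row
      if (row$fired) {
        label <- "mPCN"
        break
      }
    }
    if (length(trail) == 0) {
      abort(sprintf("case %s: no clinical step evaluable", case$case_id))
    }
    .new_diagnosis(case$case_id, label, "not_applicable",
                   dplyr::bind_rows(trail))
  })
  dplyr::bind_rows(out)
}

# Variants counted by the molecular rule for one case, after germline removal
# and the optional KRAS MAF gate.
.counted_variants <- function(v, cfg) {
  v <- v[v$somatic_status != "germline_snp", , drop = FALSE]
  if (cfg$use_maf_gate && nrow(v) > 0) {
    gated <- v$gene == "KRAS" & !is.na(v$maf_percent) &
      v$maf_percent < cfg$kras_maf_threshold_pct
    v <- v[!gated, , drop = FALSE]
  }
  v
}

#' Molecular classification
#'
#' Labels a cyst mucinous (`mPCN`) when at least one retained somatic variant
#' falls in the mucinous gene panel, and non-mucinous (`nmPCL`) otherwise.
#' With `use_maf_gate` enabled, KRAS variants only count when their MAF is at
#' least the configured threshold (variants with unreported MAF still count),
#' which filters incidental low-level KRAS clones such as PanIN. A profile
#' whose only mutations are in the non-mucinous marker genes (VHL) is
#' annotated as suggestive of serous cystadenoma. The dysplasia grade flag
#' (see [grade_flag()]) is attached to every mucinous diagnosis.
#'
#' Run raw NGS output through [filter_variants()] first; this function
#' assumes calls are already retained, apart from always ignoring germline
#' polymorphisms.
#'
#' @param cases A case tibble.
#' @param variants A variant tibble covering the cases.
#' @param cfg An [algorithm_config()].
#' @return A diagnosis tibble (`case_id`, `label`, `grade_flag`, `rationale`).
#' @export
classify_molecular <- function(cases, variants, cfg = algorithm_config()) {
  stopifnot(inherits(cfg, "algorithm_config"))
  validate_cohort(cases, variants, require_ngs_maf = FALSE)
  out <- lapply(seq_len(nrow(cases)), function(i) {
    case <- cases[i, ]
    tested <- strsplit(case$genes_tested, ";", fixed = TRUE)[[1]]
    if (length(tested) == 0) {
      abort(sprintf("case %s: genes_tested is empty", case$case_id))
    }
    v <- variants[variants$case_id == case$case_id, , drop = FALSE]
    counted <- .counted_variants(v, cfg)
    panel_hits <- counted$gene[counted$gene %in% cfg$mucinous_gene_panel]
    label <- if (length(panel_hits) > 0) "mPCN" else "nmPCL"
    trail <- list(.rationale_row(
      "panel_mutation", length(panel_hits) > 0,
      if (length(panel_hits) > 0) {
        sprintf("panel gene(s) mutated: %s", paste(unique(panel_hits), collapse = ", "))
      } else "no retained mutation in the mucinous gene panel"
    ))
    if (cfg$use_maf_gate) {
      n_gated <- sum(v$gene == "KRAS" & !is.na(v$maf_percent) &
                       v$maf_percent < cfg$kras_maf_threshold_pct)
      trail[[length(trail) + 1]] <- .rationale_row(
        "kras_maf_gate", n_gated > 0,
        sprintf("%d KRAS call(s) below %.1f%% MAF excluded", n_gated,
                cfg$kras_maf_threshold_pct))
    }
    nonmuc <- counted$gene[counted$gene %in% cfg$nonmucinous_marker_genes]
    vhl_only <- length(nonmuc) > 0 && length(panel_hits) == 0 &&
      all(counted$gene %in% cfg$nonmucinous_marker_genes)
    if (vhl_only) {
      trail[[length(trail) + 1]] <- .rationale_row(
        "nonmucinous_marker", TRUE,
        sprintf("SCA-suggestive: only %s mutated",
                paste(unique(nonmuc), collapse = ", ")))
    }
    gf <- if (label == "mPCN") .grade_flag_one(counted) else "not_applicable"
    .new_diagnosis(case$case_id, label, gf, dplyr::bind_rows(trail))
  })
  dplyr::bind_rows(out)
}

.grade_flag_one <- function(v) {
  if (nrow(v) == 0) return("low_grade_consistent")
  outside <- any(!v$gene %in% c("KRAS", "GNAS"))
  n_changes <- function(gene) {
    pc <- v$protein_change[v$gene == gene]
    if (length(pc) == 0) return(0L)
    pc[is.na(pc)] <- paste0(".unnamed", seq_len(sum(is.na(pc))))
    length(unique(pc))
  }
  if (outside || n_changes("KRAS") >= 2 || n_changes("GNAS") >= 2) {
    "elevated_grade_suspicion"
  } else {
    "low_grade_consistent"
  }
}

#' Dysplasia grade flag from the mutation profile
#'
#' Mucinous neoplasms with low-grade dysplasia carry only single KRAS and/or
#' GNAS mutations; mutations in additional genes, or multiple distinct
#' protein changes within KRAS or within GNAS, track with intermediate/high
#' grade and progression. For mucinous diagnoses this flags
#' `elevated_grade_suspicion` accordingly, else `low_grade_consistent`;
#' non-mucinous diagnoses return `not_applicable`.
#'
#' @param diagnoses A diagnosis tibble from [classify_molecular()] (the flag
#'   is already attached there; this accessor recomputes it from variants).
#' @param variants The variant tibble used for classification.
#' @return Character vector of flags, one per diagnosis row.
#' @export
grade_flag <- function(diagnoses, variants) {
  vapply(seq_len(nrow(diagnoses)), function(i) {
    if (diagnoses$label[i] != "mPCN") return("not_applicable")
    v <- variants[variants$case_id == diagnoses$case_id[i] &
                    variants$somatic_status != "germline_snp", , drop = FALSE]
    .grade_flag_one(v)
  }, character(1))
}

#' Run both classifiers over a cohort
#'
#' Convenience wrapper: clinical and/or molecular classification for every
#' case, returned as one tidy table.
#'
#' @param cases,variants Cohort tibbles.
#' @param cfg An [algorithm_config()].
#' @param mode `"both"` (default), `"clinical"` or `"molecular"`.
#' @return A diagnosis tibble with an extra `classifier` column.
#' @export
classify_cases <- function(cases, variants = NULL, cfg = algorithm_config(),
                           mode = c("both", "clinical", "molecular")) {
  mode <- match.arg(mode)
  out <- list()
  if (mode %in% c("both", "clinical")) {
    d <- classify_clinical(cases, cfg)
    d$classifier <- "clinical"
    out[[length(out) + 1]] <- d
  }
  if (mode %in% c("both", "molecular")) {
    if (is.null(variants)) abort("molecular classification needs variants")
    d <- classify_molecular(cases, variants, cfg)
    d$classifier <- "molecular"
    out[[length(out) + 1]] <- d
  }
  dplyr::bind_rows(out)
}
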