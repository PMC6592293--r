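# Packaged surgical cohort: 46 resected pancreatic cystic lesions with
# preoperative cyst-fluid molecular results, cytology, and the labels assigned
# by the clinical algorithm and the molecular rule. Used as the reference
# dataset throughout the package.

.table1_md5 <- c(
  table1_cases.tsv    = "9d57fe2987b43a270ac6028de5b512de",
  table1_variants.tsv = "b4bc2db80a94b5580875ba7f8e71a147"
)

#' Load the packaged 46-case surgical cohort
#'
#' Returns the surgical reference cohort: 46 resected pancreatic cystic
#' lesions (19 IPMN, 9 MCN, 8 PDAC, 2 SCA, 3 PNET, 5 pseudocysts) with the
#' histologic diagnosis and dysplasia grade, preoperative cyst-fluid cytology
#' category, every reported somatic mutation (gene plus protein change where
#' reported), and the mucinous/non-mucinous labels assigned by the clinical
#' algorithm and by the molecular rule. Per-call mutant allele frequencies
#' were not reported for this cohort and are stored as missing, as are the
#' per-case clinical measurements (CEA, size, viscosity).
#'
#' A checksum of the packaged files is verified on load, so silent edits of
#' the installed data are detected rather than propagated.
#'
#' @return A list with elements `cases` (46-row case tibble) and `variants`
#'   (one row per somatic call; multi-allelic cases contribute one row per
#'   protein change).
#' @export
load_table1 <- function() {
  paths <- c(
    cases = system.file("extdata", "table1_cases.tsv", package = "pancyst"),
    variants = system.file("extdata", "table1_variants.tsv", package = "pancyst")
  )
  if (any(paths == "")) abort("packaged surgical cohort files not found")
  sums <- tools::md5sum(paths)
  expected <- .table1_md5[basename(paths)]
  if (any(sums != expected)) {
    abort(sprintf("packaged cohort file(s) modified (checksum mismatch): %s",
                  paste(basename(paths)[sums != expected], collapse = ", ")))
  }
  cases <- read_case_table(paths[["cases"]], dialect = "tsv")
  variants <- read_variant_table(paths[["variants"]], dialect = "tsv")
  # Historical table: per-call MAF not reported, so NGS calls carry no MAF.
  validate_cohort(cases, variants, require_ngs_maf = FALSE)
  list(cases = cases, variants = variants)
}

#' Surgical ground truth: mucinous vs non-mucinous
#'
#' A resected lesion counts as mucinous when the surgical pathology diagnosis
#' is IPMN, MCN or PDAC; SCA, PNET and pseudocysts are non-mucinous.
#'
#' @param pathology_dx Character vector of pathology diagnoses (one of
#'   [PATHOLOGY_LEVELS]), or a case tibble with a `pathology_dx` column.
#' @return Character vector, `"mucinous"` or `"non_mucinous"`.
#' @export
surgical_truth <- function(pathology_dx) {
  if (is.data.frame(pathology_dx)) pathology_dx <- pathology_dx$pathology_dx
  bad <- !pathology_dx %in% PATHOLOGY_LEVELS
  if (any(bad)) {
    abort(sprintf("unknown pathology_dx: %s",
                  paste(unique(pathology_dx[bad]), collapse = ", ")))
  }
  if (any(pathology_dx == "UNKNOWN")) {
    abort("surgical truth undefined for UNKNOWN pathology")
  }
  ifelse(pathology_dx %in% c("IPMN", "MCN", "PDAC"), "mucinous", "non_mucinous")
}

#' Summary constants for the full 318-specimen cohort
#'
#' Aggregate counts for the full EUS-FNA cohort from which the surgical cases
#' were drawn. Per-case data for the full cohort were never published; these
#' constants parameterize the synthetic generator and give context for the
#' accuracy figures.
#'
#' @return A list: `n_total` (318 specimens), `n_with_cytology` (309),
#'   `cytology_counts` (specimens per cytology tier), `mucinous_by_cytology`
#'   (algorithm-mucinous specimens per tier), `n_kras_tested` (303 specimens
#'   with KRAS testing), `n_dual_tested` (182 with both KRAS and GNAS).
#' @export
cohort_summary <- function() {
  out <- list(
    n_total = 318L,
    n_with_cytology = 309L,
    cytology_counts = c(ND = 89L, NEG = 156L, ATY_SUS = 53L, POS = 11L),
    mucinous_by_cytology = c(ND = 45L, NEG = 38L, ATY_SUS = 53L, POS = 11L),
    n_kras_tested = 303L,
    n_dual_tested = 182L
  )
  stopifnot(sum(out$cytology_counts) == out$n_with_cytology,
            all(out$mucinous_by_cytology <= out$cytology_counts))
  out
}
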