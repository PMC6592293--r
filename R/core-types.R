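# Domain vocabulary: controlled level sets shared by every pipeline stage.

#' Controlled vocabularies for cyst-fluid case tables
#'
#' Level sets for the categorical fields of a case table. Cytology uses the
#' four-tier reporting scheme applied to pancreatic cyst fluid (non-diagnostic,
#' negative for malignancy, atypical/suspicious, positive for malignancy) plus
#' an explicit `MISSING` state for specimens never submitted for cytology.
#'
#' @format Character vectors of allowed values.
#' @name vocab
NULL

#' @rdname vocab
#' @export
PATHOLOGY_LEVELS <- c("IPMN", "MCN", "PDAC", "SCA", "PNET", "PSEUDOCYST", "UNKNOWN")

#' @rdname vocab
#' @export
GRADE_LEVELS <- c("LG", "MG", "HG", "NA")

#' @rdname vocab
#' @export
CYTOLOGY_LEVELS <- c("ND", "NEG", "ATY_SUS", "POS", "MISSING")

#' @rdname vocab
#' @export
TRISTATE_LEVELS <- c("yes", "no", "unknown")

#' @rdname vocab
#' @export
VISCOSITY_LEVELS <- c("viscous", "non_viscous", "unknown")

#' @rdname vocab
#' @export
EUS_LEVELS <- c("mucinous", "non_mucinous", "unknown")

#' @rdname vocab
#' @export
LABEL_LEVELS <- c("mPCN", "nmPCL")

#' @rdname vocab
#' @export
ASSAY_LEVELS <- c("PNA_CLAMP", "NGS")

#' @rdname vocab
#' @export
SOMATIC_STATUS_LEVELS <- c("cosmic_confirmed", "germline_snp", "unreviewed")

# Synonym maps: abbreviations used in clinical tables -> canonical levels.
# Keys are matched after trimming and upper-casing.
.cytology_synonyms <- c(
  "ND" = "ND", "NON-DIAGNOSTIC" = "ND", "NONDIAGNOSTIC" = "ND",
  "NEG" = "NEG", "NEGATIVE" = "NEG",
  "A/S" = "ATY_SUS", "ATY/SUS" = "ATY_SUS", "ATY_SUS" = "ATY_SUS",
  "ATYPICAL/SUSPICIOUS" = "ATY_SUS", "ATYPICAL" = "ATY_SUS", "SUSPICIOUS" = "ATY_SUS",
  "POS" = "POS", "POSITIVE" = "POS",
  "MISSING" = "MISSING"
)

.pathology_synonyms <- c(
  "IPMN" = "IPMN", "MCN" = "MCN",
  "PDAC" = "PDAC", "PDA" = "PDAC",
  "SCA" = "SCA", "PNET" = "PNET",
  "PSEUDOCYST" = "PSEUDOCYST", "PSEUDOCYST/CP" = "PSEUDOCYST",
  "UNKNOWN" = "UNKNOWN"
)

.grade_synonyms <- c(
  "LG" = "LG", "LOW" = "LG", "LOW-GRADE" = "LG",
  "MG" = "MG", "IG" = "MG", "INTERMEDIATE" = "MG", "INTERMEDIATE-GRADE" = "MG",
  "HG" = "HG", "HIGH" = "HG", "HIGH-GRADE" = "HG",
  "NA" = "NA"
)

.tristate_synonyms <- c(
  "YES" = "yes", "Y" = "yes", "TRUE" = "yes",
  "NO" = "no", "N" = "no", "FALSE" = "no",
  "UNKNOWN" = "unknown", "UNK" = "unknown"
)

.viscosity_synonyms <- c(
  "VISCOUS" = "viscous", "V" = "viscous",
  "NON_VISCOUS" = "non_viscous", "NON-VISCOUS" = "non_viscous", "NV" = "non_viscous",
  "UNKNOWN" = "unknown"
)

.eus_synonyms <- c(
  "MUCINOUS" = "mucinous", "M" = "mucinous",
  "NON_MUCINOUS" = "non_mucinous", "NON-MUCINOUS" = "non_mucinous", "NM" = "non_mucinous",
  "UNKNOWN" = "unknown"
)

.label_synonyms <- c("MPCN" = "mPCN", "NMPCL" = "nmPCL", "NMPCN" = "nmPCL")

# Gene symbols are upper-cased; PIC3CA is a recurring typographical variant.
.gene_synonyms <- c("PIC3CA" = "PIK3CA")

#' Normalize gene symbols
#'
#' Upper-cases symbols and repairs known typographical variants
#' (e.g. `PIC3CA` -> `PIK3CA`).
#'
#' @param genes Character vector of gene symbols.
#' @return Character vector of normalized symbols.
#' @export
normalize_gene <- function(genes) {
  out <- toupper(trimws(genes))
  hit <- out %in% names(.gene_synonyms)
  out[hit] <- .gene_synonyms[out[hit]]
  out
}

# Map raw strings onto a canonical level set via a synonym table.
# `missing_to` supplies the value used for NA/empty cells; NULL means
# missing cells are an error. Returns the canonical vector; unknown values
# raise an error naming the offending rows.
.parse_enum <- function(x, synonyms, field, missing_to = NULL) {
  raw <- trimws(as.character(x))
  key <- toupper(raw)
  out <- unname(synonyms[key])
  is_missing <- is.na(x) | raw == ""
  if (!is.null(missing_to)) {
    out[is_missing] <- missing_to
  }
  bad <- which(is.na(out) & !is_missing)
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid %s value%s %s in row%s %s",
      field, if (length(bad) > 1) "s" else "",
      paste(sQuote(unique(raw[bad])), collapse = ", "),
      if (length(bad) > 1) "s" else "",
      paste(bad, collapse = ", ")
    ))
  }
  if (is.null(missing_to) && any(is.na(out))) {
    bad <- which(is.na(out))
    abort(sprintf("missing %s in row%s %s", field,
                  if (length(bad) > 1) "s" else "", paste(bad, collapse = ", ")))
  }
  out
}

.parse_numeric <- function(x, field) {
  raw <- trimws(as.character(x))
  raw[raw == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(out) & !is.na(raw))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric %s in row%s %s", field,
                  if (length(bad) > 1) "s" else "", paste(bad, collapse = ", ")))
  }
  if (any(out < 0, na.rm = TRUE)) {
    abort(sprintf("negative %s not allowed", field))
  }
  out
}

.case_columns <- c(
  "case_id", "pathology_dx", "dysplasia_grade", "cytology", "cea_ng_ml",
  "amylase_u_l", "cyst_size_mm", "mural_nodule", "viscosity",
  "eus_impression", "genes_tested", "algorithm_label", "molecular_label"
)

#' Read a case table
#'
#' Reads a delimited table of cyst-fluid specimens, one row per case, mapping
#' clinical shorthand (e.g. cytology `"A/S"`, pathology `"PDA"`) onto the
#' package's controlled vocabularies. Missing cells become explicit missing
#' states (`MISSING`/`unknown`/`NA`); they are never imputed, so downstream
#' classifier steps can skip them. Columns outside the modeled set are
#' preserved untouched.
#'
#' @param path Path to a CSV or TSV file. Must contain at least `case_id`.
#' @param dialect `"auto"` (by file extension; default), `"csv"` or `"tsv"`.
#' @return A tibble with one row per case and the columns `case_id`,
#'   `pathology_dx`, `dysplasia_grade`, `cytology`, `cea_ng_ml`,
#'   `amylase_u_l`, `cyst_size_mm`, `mural_nodule`, `viscosity`,
#'   `eus_impression`, `genes_tested` (semicolon-separated symbols),
#'   `algorithm_label`, `molecular_label`, plus any extra input columns.
#' @export
read_case_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  reader <- if (dialect == "csv") readr::read_csv else readr::read_tsv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  if (!"case_id" %in% names(raw)) abort("case table must contain a case_id column")
  as_case_table(raw)
}

#' Coerce a data frame to a canonical case table
#'
#' The workhorse behind [read_case_table()]: validates and canonicalizes an
#' in-memory data frame. Absent modeled columns are filled with their missing
#' state.
#'
#' @param df A data frame with at least `case_id`.
#' @return A canonical case tibble (see [read_case_table()]).
#' @export
as_case_table <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"case_id" %in% names(df)) abort("case table must contain a case_id column")
  n <- nrow(df)
  get <- function(col) if (col %in% names(df)) df[[col]] else rep(NA_character_, n)

  out <- tibble::tibble(
    case_id = as.character(df$case_id),
    pathology_dx = .parse_enum(get("pathology_dx"), .pathology_synonyms,
                               "pathology_dx", missing_to = "UNKNOWN"),
    dysplasia_grade = .parse_enum(get("dysplasia_grade"), .grade_synonyms,
                                  "dysplasia_grade", missing_to = "NA"),
    cytology = .parse_enum(get("cytology"), .cytology_synonyms,
                           "cytology", missing_to = "MISSING"),
    cea_ng_ml = .parse_numeric(get("cea_ng_ml"), "cea_ng_ml"),
    amylase_u_l = .parse_numeric(get("amylase_u_l"), "amylase_u_l"),
    cyst_size_mm = .parse_numeric(get("cyst_size_mm"), "cyst_size_mm"),
    mural_nodule = .parse_enum(get("mural_nodule"), .tristate_synonyms,
                               "mural_nodule", missing_to = "unknown"),
    viscosity = .parse_enum(get("viscosity"), .viscosity_synonyms,
                            "viscosity", missing_to = "unknown"),
    eus_impression = .parse_enum(get("eus_impression"), .eus_synonyms,
                                 "eus_impression", missing_to = "unknown"),
    genes_tested = vapply(get("genes_tested"), function(g) {
      if (is.na(g) || trimws(g) == "") return("")
      paste(normalize_gene(strsplit(g, ";", fixed = TRUE)[[1]]), collapse = ";")
    }, character(1), USE.NAMES = FALSE),
    algorithm_label = .parse_enum(get("algorithm_label"), .label_synonyms,
                                  "algorithm_label", missing_to = NA_character_),
    molecular_label = .parse_enum(get("molecular_label"), .label_synonyms,
                                  "molecular_label", missing_to = NA_character_)
  )
  if (any(is.na(out$case_id) | out$case_id == "")) abort("empty case_id")
  dup <- out$case_id[duplicated(out$case_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate case_id: %s", paste(unique(dup), collapse = ", ")))
  }
  extra <- setdiff(names(df), .case_columns)
  out <- dplyr::bind_cols(out, df[extra])
  out
}

#' Read a variant table
#'
#' Reads a TSV/CSV of somatic variant calls, one row per call, with columns
#' `case_id`, `gene`, `protein_change`, `maf_percent`, `read_depth`, `assay`,
#' `somatic_status`. Gene symbols are normalized; `maf_percent` is validated
#' to lie in (0, 100] where present.
#'
#' @inheritParams read_case_table
#' @return A tibble of variant calls.
#' @export
read_variant_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  reader <- if (dialect == "csv") readr::read_csv else readr::read_tsv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  as_variant_table(raw)
}

#' Coerce a data frame to a canonical variant table
#'
#' @param df A data frame with at least `case_id` and `gene`.
#' @return A canonical variant tibble (see [read_variant_table()]).
#' @export
as_variant_table <- function(df) {
  df <- tibble::as_tibble(df)
  for (col in c("case_id", "gene")) {
    if (!col %in% names(df)) abort(sprintf("variant table must contain %s", col))
  }
  n <- nrow(df)
  get <- function(col) if (col %in% names(df)) df[[col]] else rep(NA_character_, n)
  pc <- trimws(as.character(get("protein_change")))
  pc[!is.na(pc) & pc == ""] <- NA_character_
  out <- tibble::tibble(
    case_id = as.character(df$case_id),
    gene = normalize_gene(df$gene),
    protein_change = pc,
    maf_percent = .parse_numeric(get("maf_percent"), "maf_percent"),
    read_depth = {
      d <- .parse_numeric(get("read_depth"), "read_depth")
      if (any(d %% 1 != 0, na.rm = TRUE)) abort("read_depth must be integer")
      as.integer(d)
    },
    assay = .parse_enum(get("assay"), setNames(ASSAY_LEVELS, ASSAY_LEVELS),
                        "assay", missing_to = "NGS"),
    somatic_status = .parse_enum(
      get("somatic_status"),
      setNames(SOMATIC_STATUS_LEVELS, toupper(SOMATIC_STATUS_LEVELS)),
      "somatic_status", missing_to = "unreviewed")
  )
  bad_maf <- which(!is.na(out$maf_percent) &
                     (out$maf_percent <= 0 | out$maf_percent > 100))
  if (length(bad_maf) > 0) {
    abort(sprintf("maf_percent outside (0, 100] in row%s %s",
                  if (length(bad_maf) > 1) "s" else "",
                  paste(bad_maf, collapse = ", ")))
  }
  out
}

#' Validate a cohort (cases plus variants)
#'
#' Checks the structural invariants that the classifiers rely on: every
#' variant's case exists and its gene was tested in that case, MAFs lie in
#' (0, 100], dysplasia grade is only recorded for IPMN/MCN, and (optionally)
#' every NGS call carries an MAF.
#'
#' @param cases A case tibble.
#' @param variants A variant tibble, or `NULL` to skip variant checks.
#' @param require_ngs_maf Require `maf_percent` on NGS calls (default `TRUE`).
#'   Historical tables that do not report per-call MAF are loaded with `FALSE`.
#' @return Invisibly, `TRUE`. Errors describe the first violated invariant.
#' @export
validate_cohort <- function(cases, variants = NULL, require_ngs_maf = TRUE) {
  stopifnot(is.data.frame(cases))
  bad_grade <- cases$dysplasia_grade != "NA" &
    !cases$pathology_dx %in% c("IPMN", "MCN")
  if (any(bad_grade)) {
    abort(sprintf("dysplasia grade recorded for non-IPMN/MCN case(s): %s",
                  paste(cases$case_id[bad_grade], collapse = ", ")))
  }
  if (!is.null(variants) && nrow(variants) > 0) {
    orphan <- setdiff(variants$case_id, cases$case_id)
    if (length(orphan) > 0) {
      abort(sprintf("variants reference unknown case_id: %s",
                    paste(orphan, collapse = ", ")))
    }
    tested <- strsplit(setNames(cases$genes_tested, cases$case_id), ";", fixed = TRUE)
    untested <- mapply(function(cid, g) !(g %in% tested[[cid]]),
                       variants$case_id, variants$gene)
    if (any(untested)) {
      abort(sprintf("variant in untested gene for case(s): %s",
                    paste(unique(variants$case_id[untested]), collapse = ", ")))
    }
    if (require_ngs_maf) {
      miss <- variants$assay == "NGS" & is.na(variants$maf_percent)
      if (any(miss)) {
        abort(sprintf("NGS call(s) missing maf_percent for case(s): %s",
                      paste(unique(variants$case_id[miss]), collapse = ", ")))
      }
    }
  }
  invisible(TRUE)
}

#' Write a case/variant cohort to disk
#'
#' Serializes the canonical tibbles back to TSV so that
#' `read_case_table(write_cohort(x))` round-trips every modeled field.
#'
#' @param cases,variants Canonical tibbles.
#' @param cases_path,variants_path Output paths (TSV).
#' @return Invisibly, a list of the two paths.
#' @export
write_cohort <- function(cases, cases_path, variants = NULL, variants_path = NULL) {
  readr::write_tsv(cases, cases_path, progress = FALSE)
  if (!is.null(variants)) {
    if (is.null(variants_path)) abort("variants_path required when variants given")
    readr::write_tsv(variants, variants_path, progress = FALSE)
  }
  invisible(list(cases = cases_path, variants = variants_path))
}
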