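# JSON report: the machine-readable output of a classification run.

.report_schema_version <- "1.0"

#' Write a diagnosis report
#'
#' Serializes a diagnosis table (as returned by [classify_clinical()] or
#' [classify_molecular()]) to a versioned JSON document with, per case, the
#' mucinous/non-mucinous label, the dysplasia grade flag, and the full
#' rule-by-rule rationale trail in evaluation order.
#'
#' @param diagnoses A diagnosis tibble: columns `case_id`, `label`,
#'   `grade_flag` and a `rationale` list-column of per-rule records.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(diagnoses, path) {
  entries <- lapply(seq_len(nrow(diagnoses)), function(i) {
    r <- diagnoses$rationale[[i]]
    list(
      case_id = diagnoses$case_id[i],
      label = diagnoses$label[i],
      grade_flag = diagnoses$grade_flag[i],
      rationale = lapply(seq_len(nrow(r)), function(j) {
        list(rule = r$rule[j], fired = r$fired[j], evidence = r$evidence[j])
      })
    )
  })
  doc <- list(
    schema_version = .report_schema_version,
    n_cases = nrow(diagnoses),
    cases = entries
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a diagnosis report
#'
#' Inverse of [write_report()]: reconstructs the diagnosis tibble, including
#' the rationale trail, from a JSON report.
#'
#' @param path Path to a JSON report written by [write_report()].
#' @return A diagnosis tibble.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$schema_version)) abort("not a diagnosis report (no schema_version)")
  cases <- doc$cases %||% list()
  tibble::tibble(
    case_id = vapply(cases, function(x) x$case_id, character(1)),
    label = vapply(cases, function(x) x$label, character(1)),
    grade_flag = vapply(cases, function(x) x$grade_flag, character(1)),
    rationale = lapply(cases, function(x) {
      tibble::tibble(
        rule = vapply(x$rationale, function(r) r$rule, character(1)),
        fired = vapply(x$rationale, function(r) isTRUE(r$fired), logical(1)),
        evidence = vapply(x$rationale, function(r) r$evidence, character(1))
      )
    })
  )
}
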