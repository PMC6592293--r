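# PNA-clamp real-time PCR interpretation.
#
# A peptide nucleic acid (PNA) oligomer suppresses amplification of the
# wild-type allele, so the cycle-threshold shift between the clamped and
# unclamped reactions (delta-Ct = Ct_with - Ct_without) grows as the mutant
# fraction shrinks. Each run carries 100/10/1/0% mutant controls; the 1%
# control anchors the mutant/wild-type call and the 100/10/1% points form a
# calibration curve for quantifying mutant allele fraction.

#' @rdname vocab
#' @export
CLAMP_TARGETS <- c("KRAS_12_13", "KRAS_61", "GNAS_201", "BRAF_598_602")

.clamp_detection_limit <- 0.01  # percent mutant; assay floor

#' Construct a clamp assay calibration
#'
#' Bundles the control delta-Ct values for one PNA-clamp target. Controls must
#' be strictly ordered: the 100% mutant control has the smallest delta-Ct and
#' the 0% (wild-type) control the largest, since clamping shifts Ct more the
#' less mutant template is present.
#'
#' @param target One of `r paste(CLAMP_TARGETS, collapse = ", ")`.
#' @param controls Named numeric of control delta-Ct values (cycles); names
#'   must be `"100"`, `"10"`, `"1"`, `"0"` (% mutant).
#' @return An object of class `clamp_assay`.
#' @export
clamp_assay <- function(target, controls) {
  target <- match.arg(target, CLAMP_TARGETS)
  needed <- c("100", "10", "1", "0")
  if (!all(needed %in% names(controls))) {
    abort(sprintf("controls must include levels %s", paste(needed, collapse = ", ")))
  }
  controls <- as.numeric(controls[needed])
  names(controls) <- needed
  if (any(!is.finite(controls))) abort("control delta-Ct values must be finite")
  if (any(diff(controls) <= 0)) {
    abort("control delta-Ct must strictly increase as % mutant decreases")
  }
  structure(list(target = target, controls = controls), class = "clamp_assay")
}

#' @export
print.clamp_assay <- function(x, ...) {
  cat(sprintf("<clamp_assay> target %s; control dCt (100/10/1/0%%): %s\n",
              x$target, paste(format(x$controls), collapse = " / ")))
  invisible(x)
}

#' Delta-Ct of a clamped/unclamped reaction pair
#'
#' @param ct_with_clamp,ct_without_clamp Cycle thresholds (cycles); both must
#'   be finite. Vectorized.
#' @return `ct_with_clamp - ct_without_clamp`, in cycles (may be negative).
#' @export
delta_ct <- function(ct_with_clamp, ct_without_clamp) {
  if (any(!is.finite(ct_with_clamp)) || any(!is.finite(ct_without_clamp))) {
    abort("Ct values must be finite")
  }
  ct_with_clamp - ct_without_clamp
}

#' Mutant/wild-type call against the 1% control
#'
#' A specimen is reported wild-type when its delta-Ct is at least `margin`
#' cycles above the 1% mutant control, and mutant otherwise (the boundary
#' itself is wild-type). A mutant call is provisional until the variant's
#' somatic status is reviewed (Sanger confirmation in the wet-lab workflow):
#' see the `confirmed` flag on [quantify_plate()] output.
#'
#' @param sample_dct Specimen delta-Ct (cycles). Vectorized.
#' @param assay A [clamp_assay()].
#' @param margin Cycles above the 1% control that define wild-type (default 2).
#' @return `"mutant"` or `"wild_type"` per specimen.
#' @export
call_clamp <- function(sample_dct, assay, margin = 2) {
  stopifnot(inherits(assay, "clamp_assay"))
  if (any(!is.finite(sample_dct))) abort("sample delta-Ct must be finite")
  ifelse(sample_dct >= assay$controls[["1"]] + margin, "wild_type", "mutant")
}

#' Quantify mutant allele fraction from delta-Ct
#'
#' Interpolates log10(percent mutant) piecewise-linearly in delta-Ct through
#' the 100/10/1% calibration points (qPCR Ct is log-linear in template
#' abundance). Values below the 100% control delta-Ct are clamped to 100%;
#' values at or beyond the 0% control are floored at the assay detection
#' limit of 0.01%. Between the 1% and 0% controls the last calibration
#' segment is extrapolated, subject to the same floor.
#'
#' @inheritParams call_clamp
#' @return Percent mutant in \[0.01, 100\]. Vectorized over `sample_dct`.
#' @export
quantify_maf <- function(sample_dct, assay) {
  stopifnot(inherits(assay, "clamp_assay"))
  if (any(!is.finite(sample_dct))) abort("sample delta-Ct must be finite")
  ctrl <- assay$controls
  knots_x <- c(ctrl[["100"]], ctrl[["10"]], ctrl[["1"]])
  knots_y <- c(2, 1, 0)  # log10(percent)
  slope_last <- (knots_y[3] - knots_y[2]) / (knots_x[3] - knots_x[2])
  log10p <- vapply(sample_dct, function(d) {
    if (d <= knots_x[1]) return(2)
    if (d >= ctrl[["0"]]) return(log10(.clamp_detection_limit))
    if (d <= knots_x[3]) {
      return(stats::approx(knots_x, knots_y, xout = d)$y)
    }
    knots_y[3] + slope_last * (d - knots_x[3])
  }, numeric(1))
  pmin(100, pmax(.clamp_detection_limit, 10^log10p))
}

#' Read a clamp plate export
#'
#' Reads a TSV plate export with columns `well`, `target`, `ct_with_clamp`,
#' `ct_without_clamp`, `role` (`sample`/`control`) and `control_percent`
#' (blank for samples).
#'
#' @param path Path to the plate TSV.
#' @return A tibble, one row per well.
#' @export
read_plate <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("well", "target", "ct_with_clamp", "ct_without_clamp", "role")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("plate export missing column(s): %s", paste(missing, collapse = ", ")))
  }
  tibble::tibble(
    well = raw$well,
    target = raw$target,
    ct_with_clamp = .parse_numeric(raw$ct_with_clamp, "ct_with_clamp"),
    ct_without_clamp = .parse_numeric(raw$ct_without_clamp, "ct_without_clamp"),
    role = .parse_enum(raw$role, c("SAMPLE" = "sample", "CONTROL" = "control"), "role"),
    control_percent = .parse_numeric(
      if ("control_percent" %in% names(raw)) raw$control_percent else NA, "control_percent")
  )
}

#' Interpret a whole clamp plate
#'
#' For each target on the plate, builds the calibration from the control
#' wells, then computes delta-Ct, the mutant/wild-type call, and (for mutant
#' calls) the quantified mutant fraction for every sample well.
#'
#' @param plate A tibble from [read_plate()].
#' @param margin Wild-type margin in cycles (see [call_clamp()]).
#' @return A tibble with one row per sample well: `well`, `target`,
#'   `delta_ct`, `call`, `maf_percent` (`NA` for wild-type calls).
#' @export
quantify_plate <- function(plate, margin = 2) {
  out <- lapply(split(plate, plate$target), function(p) {
    ctl <- p[p$role == "control", ]
    if (nrow(ctl) < 4) {
      abort(sprintf("target %s: need 100/10/1/0%% control wells", p$target[1]))
    }
    dct <- delta_ct(ctl$ct_with_clamp, ctl$ct_without_clamp)
    assay <- clamp_assay(p$target[1],
                         setNames(dct, as.character(ctl$control_percent)))
    smp <- p[p$role == "sample", ]
    sdct <- delta_ct(smp$ct_with_clamp, smp$ct_without_clamp)
    call <- call_clamp(sdct, assay, margin = margin)
    tibble::tibble(
      well = smp$well, target = smp$target, delta_ct = sdct, call = call,
      maf_percent = ifelse(call == "mutant", quantify_maf(sdct, assay), NA_real_)
    )
  })
  dplyr::bind_rows(out)
}
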