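# NGS variant retention rules and dual-pipeline concordance.

#' Packaged hotspot annotation micro-table
#'
#' A small, offline lookup of (gene, protein change) pairs for the panel's
#' recurrent hotspots: somatic hotspots recorded in catalogues of somatic
#' mutations plus a few well-known germline polymorphisms that masquerade as
#' calls. Stands in for live database queries so that annotation is
#' reproducible and injectable.
#'
#' @return A tibble with columns `gene`, `protein_change`, `somatic_status`.
#' @export
hotspot_annotation <- function() {
  path <- system.file("extdata", "hotspot_annotation.tsv", package = "pancyst")
  readr::read_tsv(path, col_types = "ccc", progress = FALSE)
}

#' Annotate somatic status via an injectable lookup
#'
#' Fills in `somatic_status` for unreviewed calls by matching
#' (gene, protein change) against an annotation table; calls with no match
#' stay `unreviewed` (and are therefore dropped by [filter_variants()]).
#' Already-reviewed calls are never overwritten.
#'
#' @param variants A variant tibble.
#' @param annotation An annotation tibble (default [hotspot_annotation()]).
#' @return The variant tibble with updated `somatic_status`.
#' @export
annotate_variants <- function(variants, annotation = hotspot_annotation()) {
  key <- paste(variants$gene, variants$protein_change, sep = "|")
  akey <- paste(normalize_gene(annotation$gene), annotation$protein_change, sep = "|")
  hit <- match(key, akey)
  unrev <- variants$somatic_status == "unreviewed" & !is.na(hit)
  variants$somatic_status[unrev] <- annotation$somatic_status[hit[unrev]]
  variants
}

#' Variant retention policy
#'
#' The rules applied to raw NGS output before any call reaches a classifier:
#' minimum read support (inclusive), minimum mutant allele frequency
#' (strict), and somatic-status confirmation. The assay's analytic limit of
#' sensitivity (0.2% MAF) is below the calling threshold and is carried as
#' metadata only.
#'
#' @param min_reads Minimum supporting reads, inclusive (default 10).
#' @param min_maf_percent MAF must strictly exceed this, in percent (default 1).
#' @param require_both_pipelines Whether classification should only use calls
#'   concordant between two caller pipelines (default `TRUE`; see
#'   [concordant_calls()]).
#' @param annotation Injectable annotation table used to resolve unreviewed
#'   calls (default [hotspot_annotation()]).
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(min_reads = 10, min_maf_percent = 1,
                          require_both_pipelines = TRUE,
                          annotation = hotspot_annotation()) {
  if (min_reads < 1) abort("min_reads must be >= 1")
  if (min_maf_percent < 0) abort("min_maf_percent must be >= 0")
  structure(
    list(min_reads = min_reads, min_maf_percent = min_maf_percent,
         require_both_pipelines = require_both_pipelines,
         annotation = annotation, limit_of_sensitivity_pct = 0.2),
    class = "filter_policy"
  )
}

#' Apply the variant retention rules
#'
#' NGS calls are kept when read depth is at least `min_reads`, MAF strictly
#' exceeds `min_maf_percent`, and the call is confirmed somatic; known
#' germline polymorphisms are always dropped, whatever the assay. PNA-clamp
#' calls pass through untouched (their calling rule lives in the clamp
#' module). Order is preserved and filtering is idempotent.
#'
#' @param calls A variant tibble.
#' @param policy A [filter_policy()].
#' @return The retained subset of `calls`, in input order.
#' @export
filter_variants <- function(calls, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  if (nrow(calls) == 0) return(calls)
  calls <- annotate_variants(calls, policy$annotation)
  is_ngs <- calls$assay == "NGS"
  incomplete <- is_ngs & (is.na(calls$read_depth) | is.na(calls$maf_percent))
  if (any(incomplete)) {
    i <- which(incomplete)[1]
    abort(sprintf("NGS call missing read_depth/maf_percent: case %s %s %s",
                  calls$case_id[i], calls$gene[i],
                  calls$protein_change[i] %||% "?"))
  }
  keep_ngs <- !is_ngs | (calls$read_depth >= policy$min_reads &
                           calls$maf_percent > policy$min_maf_percent &
                           calls$somatic_status == "cosmic_confirmed")
  keep <- keep_ngs & calls$somatic_status != "germline_snp"
  calls[keep, , drop = FALSE]
}

#' Dual-pipeline concordance
#'
#' Partitions two callers' outputs by the match key (gene, protein change).
#' Concordant calls are reported once with the mean of the two pipelines'
#' MAFs; the remainder are returned per side. The partition is exhaustive and
#' disjoint.
#'
#' @param pipeline_a,pipeline_b Variant tibbles from the two callers.
#' @return A list with elements `concordant`, `discordant_a`, `discordant_b`.
#' @export
concordant_calls <- function(pipeline_a, pipeline_b) {
  key <- function(v) paste(v$gene, v$protein_change, sep = "|")
  ka <- key(pipeline_a)
  kb <- key(pipeline_b)
  shared_a <- ka %in% kb
  shared_b <- kb %in% ka
  conc <- pipeline_a[shared_a, , drop = FALSE]
  if (nrow(conc) > 0) {
    mb <- match(ka[shared_a], kb)
    conc$maf_percent <- rowMeans(
      cbind(conc$maf_percent, pipeline_b$maf_percent[mb]), na.rm = TRUE)
    conc$maf_percent[is.nan(conc$maf_percent)] <- NA_real_
  }
  list(
    concordant = conc,
    discordant_a = pipeline_a[!shared_a, , drop = FALSE],
    discordant_b = pipeline_b[!shared_b, , drop = FALSE]
  )
}
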