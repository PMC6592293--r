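# Optional minimal VCF ingestion. The pipeline starts at annotated variant
# calls, so only the annotation fields are read: gene and protein change from
# the INFO column (either explicit GENE/HGVSP keys or the first record of a
# snpEff-style ANN field), allele fraction from AF (scaled to percent) and
# depth from DP.

#' Read variant calls from a minimal annotated VCF
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @param case_id Case identifier to stamp on every call.
#' @param somatic_status Status assigned to the calls (default `"unreviewed"`;
#'   run [annotate_variants()] afterwards).
#' @return A canonical variant tibble (see [read_variant_table()]).
#' @export
read_vcf_variants <- function(path, case_id, somatic_status = "unreviewed") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_vcf_variants requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  n <- nrow(v@fix)
  if (n == 0) {
    return(as_variant_table(tibble::tibble(case_id = character(0),
                                           gene = character(0))))
  }
  info_val <- function(key) vcfR::extract.info(v, element = key)
  gene <- info_val("GENE")
  hgvsp <- info_val("HGVSP")
  ann <- info_val("ANN")
  use_ann <- is.na(gene) & !is.na(ann)
  if (any(use_ann)) {
    fields <- strsplit(ann[use_ann], "\\|")
    gene[use_ann] <- vapply(fields, function(f) f[4] %||% NA_character_, character(1))
    hgvsp[use_ann] <- vapply(fields, function(f) {
      p <- if (length(f) >= 11) f[11] else NA_character_
      if (is.null(p) || identical(p, "")) NA_character_ else p
    }, character(1))
  }
  if (any(is.na(gene))) abort("VCF record without gene annotation (GENE or ANN)")
  af <- suppressWarnings(as.numeric(info_val("AF")))
  dp <- suppressWarnings(as.numeric(info_val("DP")))
  as_variant_table(tibble::tibble(
    case_id = rep(as.character(case_id), n),
    gene = gene,
    protein_change = sub("^.*:", "", hgvsp),
    maf_percent = af * 100,
    read_depth = dp,
    assay = "NGS",
    somatic_status = somatic_status
  ))
}
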