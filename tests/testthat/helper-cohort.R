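# Builders for minimal canonical cases/variants used across the suite.

make_case <- function(case_id = "c1", pathology_dx = "UNKNOWN",
                      dysplasia_grade = "NA", cytology = "MISSING",
                      cea_ng_ml = NA_real_, amylase_u_l = NA_real_,
                      cyst_size_mm = NA_real_, mural_nodule = "unknown",
                      viscosity = "unknown", eus_impression = "unknown",
                      genes_tested = "KRAS;GNAS;BRAF;PIK3CA;CDKN2A;PTEN;SMAD4;TP53;VHL;APC;ATM",
                      algorithm_label = NA_character_,
                      molecular_label = NA_character_) {
  tibble::tibble(
    case_id = case_id, pathology_dx = pathology_dx,
    dysplasia_grade = dysplasia_grade, cytology = cytology,
    cea_ng_ml = as.numeric(cea_ng_ml), amylase_u_l = as.numeric(amylase_u_l),
    cyst_size_mm = as.numeric(cyst_size_mm), mural_nodule = mural_nodule,
    viscosity = viscosity, eus_impression = eus_impression,
    genes_tested = genes_tested, algorithm_label = algorithm_label,
    molecular_label = molecular_label
  )
}

make_variant <- function(case_id = "c1", gene = "KRAS",
                         protein_change = "p.G12D", maf_percent = 30,
                         read_depth = 1000L, assay = "NGS",
                         somatic_status = "cosmic_confirmed") {
  tibble::tibble(
    case_id = case_id, gene = gene, protein_change = protein_change,
    maf_percent = as.numeric(maf_percent), read_depth = as.integer(read_depth),
    assay = assay, somatic_status = somatic_status
  )
}

no_variants <- function() make_variant()[0, ]

random_variants <- function(n, seed) {
  withr::with_seed(seed, {
    make_variant(
      case_id = "c1",
      gene = sample(c("KRAS", "GNAS", "TP53", "VHL", "ATM"), n, replace = TRUE),
      protein_change = paste0("p.X", seq_len(n)),
      maf_percent = round(runif(n, 0.1, 60), 2),
      read_depth = sample(c(5L, 9L, 10L, 11L, 200L, 1500L), n, replace = TRUE),
      assay = sample(c("NGS", "PNA_CLAMP"), n, replace = TRUE),
      somatic_status = sample(c("cosmic_confirmed", "germline_snp", "unreviewed"),
                              n, replace = TRUE, prob = c(0.7, 0.15, 0.15))
    )
  })
}
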