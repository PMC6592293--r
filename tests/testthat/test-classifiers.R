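cfg <- algorithm_config()

test_that("clinical steps fire in order and the first hit decides", {
  # cytology alone
  d <- classify_clinical(make_case(cytology = "POS"), cfg)
  expect_equal(d$label, "mPCN")
  expect_equal(d$rationale[[1]]$rule, "cytology")
  # CEA threshold is inclusive at 192 ng/ml
  d <- classify_clinical(make_case(cytology = "NEG", cea_ng_ml = 192), cfg)
  expect_equal(d$label, "mPCN")
  expect_equal(d$rationale[[1]]$rule, c("cytology", "cea"))
  d <- classify_clinical(make_case(cytology = "NEG", cea_ng_ml = 191.9), cfg)
  expect_equal(d$label, "nmPCL")
  # all features at non-mucinous values: every step evaluated, none fires
  full <- make_case(cytology = "NEG", cea_ng_ml = 10, cyst_size_mm = 15,
                    mural_nodule = "no", viscosity = "non_viscous",
                    eus_impression = "non_mucinous")
  d <- classify_clinical(full, cfg)
  expect_equal(d$label, "nmPCL")
  expect_equal(d$rationale[[1]]$rule,
               c("cytology", "cea", "viscosity", "mural_nodule", "eus_size"))
  expect_false(any(d$rationale[[1]]$fired))
})

test_that("missing clinical features are skipped, never imputed", {
  d <- classify_clinical(make_case(viscosity = "viscous"), cfg)
  expect_equal(d$label, "mPCN")
  expect_equal(d$rationale[[1]]$rule, "viscosity")  # only evaluable step
  # EUS step needs both impression and size
  d <- classify_clinical(make_case(eus_impression = "mucinous",
                                   cyst_size_mm = 45), cfg)
  expect_equal(d$label, "mPCN")
  d <- classify_clinical(make_case(cytology = "NEG",
                                   eus_impression = "mucinous"), cfg)
  expect_equal(d$label, "nmPCL")  # size missing -> step skipped
  expect_error(classify_clinical(make_case(), cfg), "unclassifiable")
})

test_that("the step order is configurable and logged", {
  cfg2 <- algorithm_config(step_order = c("cea", "cytology", "viscosity",
                                          "mural_nodule", "eus_size"))
  d <- classify_clinical(make_case(cytology = "POS", cea_ng_ml = 500), cfg2)
  expect_equal(d$rationale[[1]]$rule, "cea")
  expect_error(algorithm_config(step_order = c("cea", "cytology")),
               "permutation")
})

test_that("molecular rule follows the panel and annotates VHL-only profiles", {
  case <- make_case("m1")
  expect_equal(classify_molecular(case, make_variant("m1"))$label, "mPCN")
  d <- classify_molecular(case, make_variant("m1", gene = "VHL",
                                             protein_change = "p.R167W"))
  expect_equal(d$label, "nmPCL")
  expect_true(any(grepl("SCA-suggestive", d$rationale[[1]]$evidence)))
  expect_equal(classify_molecular(case, no_variants())$label, "nmPCL")
  # ATM is outside the mucinous panel
  d <- classify_molecular(case, make_variant("m1", gene = "ATM",
                                             protein_change = "p.R337C"))
  expect_equal(d$label, "nmPCL")
  expect_false(any(grepl("SCA", d$rationale[[1]]$evidence)))
  expect_error(classify_molecular(make_case("m1", genes_tested = ""),
                                  no_variants()),
               "genes_tested is empty")
  expect_error(
    classify_molecular(make_case("m1", genes_tested = "KRAS"),
                       make_variant("m1", gene = "GNAS")),
    "untested gene")
})

test_that("the KRAS MAF gate is inclusive at the threshold and one-directional", {
  gated <- algorithm_config(use_maf_gate = TRUE)
  case <- make_case("g1")
  lab <- function(maf, cfg) {
    classify_molecular(case, make_variant("g1", maf_percent = maf), cfg)$label
  }
  expect_equal(lab(1.5, gated), "nmPCL")
  expect_equal(lab(1.8, gated), "mPCN")   # "at least 1.8%" counts
  expect_equal(lab(NA, gated), "mPCN")    # unreported MAF still counts
  expect_equal(lab(1.5, cfg), "mPCN")     # gate off by default
  # non-KRAS genes are not gated
  d <- classify_molecular(case, make_variant("g1", gene = "GNAS",
                                             protein_change = "p.R201C",
                                             maf_percent = 1.2), gated)
  expect_equal(d$label, "mPCN")
  # enabling the gate can only move labels mPCN -> nmPCL
  for (seed in 1:5) {
    v <- random_variants(30, seed + 100)
    v$case_id <- "g1"
    open <- classify_molecular(case, v, cfg)$label
    shut <- classify_molecular(case, v, gated)$label
    expect_false(open == "nmPCL" && shut == "mPCN")
  }
})

test_that("enlarging the mucinous panel never flips a case to non-mucinous", {
  small <- algorithm_config(mucinous_gene_panel = c("KRAS", "GNAS"))
  big <- algorithm_config(mucinous_gene_panel = c("KRAS", "GNAS", "BRAF",
                                                  "PIK3CA", "CDKN2A", "PTEN",
                                                  "SMAD4", "TP53", "ATM"))
  t1 <- load_table1()
  d_small <- classify_molecular(t1$cases, t1$variants, small)
  d_big <- classify_molecular(t1$cases, t1$variants, big)
  expect_false(any(d_small$label == "mPCN" & d_big$label == "nmPCL"))
  # on the reference cohort: sensitivity non-decreasing, specificity non-increasing
  truth <- ifelse(surgical_truth(t1$cases) == "mucinous", "mPCN", "nmPCL")
  m_small <- confusion_metrics(confusion(d_small$label, truth, "mPCN"))
  m_big <- confusion_metrics(confusion(d_big$label, truth, "mPCN"))
  sens <- function(m) m$proportion[m$metric == "sensitivity"]
  spec <- function(m) m$proportion[m$metric == "specificity"]
  expect_gte(sens(m_big), sens(m_small))
  expect_lte(spec(m_big), spec(m_small))
})

test_that("grade flag tracks additional genes and double mutations", {
  case <- make_case("k1")
  flag <- function(v) classify_molecular(case, v, cfg)$grade_flag
  # single KRAS + single GNAS: consistent with low grade
  v <- dplyr::bind_rows(
    make_variant("k1", gene = "KRAS", protein_change = "p.G12V"),
    make_variant("k1", gene = "GNAS", protein_change = "p.R201C"))
  expect_equal(flag(v), "low_grade_consistent")
  # a gene beyond KRAS/GNAS raises suspicion
  v2 <- dplyr::bind_rows(v, make_variant("k1", gene = "TP53",
                                         protein_change = "p.R175H"))
  expect_equal(flag(v2), "elevated_grade_suspicion")
  # two distinct protein changes in KRAS raise suspicion
  v3 <- dplyr::bind_rows(
    make_variant("k1", gene = "KRAS", protein_change = "p.G12A"),
    make_variant("k1", gene = "KRAS", protein_change = "p.G12T"))
  expect_equal(flag(v3), "elevated_grade_suspicion")
  # non-mucinous diagnoses carry no grade flag
  d <- classify_molecular(case, no_variants(), cfg)
  expect_equal(d$grade_flag, "not_applicable")
  # the standalone accessor agrees with the attached flag
  d2 <- classify_molecular(case, v2, cfg)
  expect_equal(grade_flag(d2, v2), d2$grade_flag)
})

test_that("classification is deterministic including the rationale trail", {
  t1 <- load_table1()
  a <- classify_molecular(t1$cases, t1$variants, cfg)
  b <- classify_molecular(t1$cases, t1$variants, cfg)
  expect_identical(a, b)
  cc <- make_case(cytology = "NEG", cea_ng_ml = 300)
  expect_identical(classify_clinical(cc, cfg), classify_clinical(cc, cfg))
})

test_that("the combined wrapper stacks both classifiers", {
  t1 <- load_table1()
  both <- classify_cases(t1$cases[1:3, ],
                         t1$variants[t1$variants$case_id %in% 1:3, ],
                         cfg, mode = "both")
  expect_equal(sort(unique(both$classifier)), c("clinical", "molecular"))
  expect_equal(nrow(both), 6)
})
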