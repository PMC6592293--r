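test_that("cohort generation is reproducible and respects n = 0", {
  cfg <- sim_config(n_cases = 120, seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  e <- generate_cohort(sim_config(n_cases = 0, seed = 1))
  expect_equal(nrow(e$cases), 0)
  expect_equal(nrow(e$variants), 0)
  # a different seed gives a different cohort
  c2 <- generate_cohort(sim_config(n_cases = 120, seed = 10))
  expect_false(identical(a$cases, c2$cases))
})

test_that("generated cohorts are valid and fully populated", {
  ch <- generate_cohort(sim_config(n_cases = 300, seed = 4))
  expect_true(validate_cohort(ch$cases, ch$variants))
  expect_true(all(!is.na(ch$cases$cea_ng_ml)))
  expect_true(all(ch$cases$cyst_size_mm >= 5 & ch$cases$cyst_size_mm <= 114))
  expect_true(all(ch$variants$maf_percent > 0 & ch$variants$maf_percent <= 100))
  expect_true(all(ch$variants$read_depth >= 500 & ch$variants$read_depth <= 2500))
  # GNAS is only sometimes part of the tested panel
  gnas <- grepl("GNAS", ch$cases$genes_tested)
  expect_true(any(gnas) && !all(gnas))
  expect_true(all(surgical_truth(ch$cases) %in% c("mucinous", "non_mucinous")))
})

test_that("empirical marginals approach the configured conditionals", {
  cfg <- sim_config(n_cases = 10000, seed = 12)
  ch <- generate_cohort(cfg)
  truth <- surgical_truth(ch$cases)
  for (cl in c("mucinous", "non_mucinous")) {
    sel <- truth == cl & ch$cases$cytology != "MISSING"
    emp <- prop.table(table(factor(ch$cases$cytology[sel],
                                   levels = c("ND", "NEG", "ATY_SUS", "POS"))))
    expect_true(all(abs(emp - cfg$cytology_conditionals[[cl]]) < 0.02))
  }
  emp_type <- prop.table(table(ch$cases$pathology_dx))
  expect_true(all(abs(emp_type[names(cfg$type_prevalence)] -
                        cfg$type_prevalence) < 0.02))
})

test_that("invalid probability maps are rejected", {
  expect_error(sim_config(type_prevalence = c(IPMN = 0.7, MCN = 0.7)),
               "sum to 1")
  expect_error(
    sim_config(mutation_model = list(LG = list(gene_probs = c(KRAS = 1.3)))),
    "outside")
})

test_that("recovered sensitivity tracks the configured detection probability", {
  # KRAS-or-GNAS detection set to the headline full-cohort rate
  for (p in c(0.933, 0.6)) {
    mm <- list(
      LG = list(gene_probs = c(KRAS = p)),
      MG = list(gene_probs = c(KRAS = p)),
      HG = list(gene_probs = c(KRAS = p)),
      PDAC = list(gene_probs = c(KRAS = p)),
      SCA = list(gene_probs = c(VHL = 1.0)),
      PNET = list(gene_probs = c()),
      PSEUDOCYST = list(gene_probs = c())
    )
    cfg <- sim_config(n_cases = 1000, seed = 20, mutation_model = mm)
    got <- recover_operating_characteristics(cfg, n_reps = 1)
    sens <- got$mean[got$classifier == "molecular" & got$metric == "sensitivity"]
    n_muc <- round(1000 * sum(cfg$type_prevalence[c("IPMN", "MCN", "PDAC")]))
    expect_lt(abs(sens - p), 3 * sqrt(p * (1 - p) / n_muc))
  }
})

test_that("degenerate mutation and CEA models reach their limits", {
  # no mutations anywhere: molecular sensitivity 0
  mm0 <- list(LG = list(gene_probs = c()), MG = list(gene_probs = c()),
              HG = list(gene_probs = c()), PDAC = list(gene_probs = c()),
              SCA = list(gene_probs = c()), PNET = list(gene_probs = c()),
              PSEUDOCYST = list(gene_probs = c()))
  got <- recover_operating_characteristics(
    sim_config(n_cases = 400, seed = 21, mutation_model = mm0), n_reps = 1)
  expect_equal(got$mean[got$classifier == "molecular" &
                          got$metric == "sensitivity"], 0)
  # fully separated CEA and silenced other non-mucinous triggers:
  # clinical specificity reaches 100%
  cfg <- sim_config(
    n_cases = 400, seed = 22,
    cea_model = list(mucinous = c(meanlog = log(5000), sdlog = 0.1),
                     non_mucinous = c(meanlog = log(10), sdlog = 0.1)),
    viscosity_conditionals = list(
      mucinous = c(viscous = 1, non_viscous = 0),
      non_mucinous = c(viscous = 0, non_viscous = 1)),
    mural_nodule_prob = c(mucinous = 0, non_mucinous = 0),
    eus_conditionals = list(
      mucinous = c(mucinous = 1, non_mucinous = 0, unknown = 0),
      non_mucinous = c(mucinous = 0, non_mucinous = 1, unknown = 0)))
  got <- recover_operating_characteristics(cfg, n_reps = 1)
  expect_equal(got$mean[got$classifier == "clinical" &
                          got$metric == "specificity"], 1)
})

test_that("wider MAF dispersion degrades ROC separation on average", {
  mean_auc <- function(sdlog) {
    aucs <- vapply(1:5, function(s) {
      cfg <- sim_config(
        n_cases = 1200, seed = 700 + s,
        maf_model = list(mucinous = c(meanlog = log(25), sdlog = sdlog),
                         incidental = c(meanlog = log(5), sdlog = sdlog)))
      ch <- generate_cohort(cfg)
      kras <- ch$variants[ch$variants$gene == "KRAS", ]
      score <- vapply(ch$cases$case_id, function(id) {
        m <- kras$maf_percent[kras$case_id == id]
        if (length(m) == 0) 0 else max(m)
      }, numeric(1))
      labels <- surgical_truth(ch$cases) == "mucinous"
      roc_threshold(score, labels)$auc
    }, numeric(1))
    mean(aucs)
  }
  aucs <- vapply(c(0.4, 1.0, 1.8), mean_auc, numeric(1))
  expect_true(all(diff(aucs) < 0))
})

test_that("ROC threshold recovery lands near the density-intersection boundary", {
  # equal dispersions and balanced classes: boundary is the geometric mean
  b <- lognormal_boundary(log(25), 0.9, log(5), 0.9)
  expect_equal(b, sqrt(25 * 5), tolerance = 1e-9)
  withr::with_seed(55, {
    for (i in 1:3) {
      pos <- rlnorm(2000, log(25), 0.9)
      neg <- rlnorm(2000, log(5), 0.9)
      r <- roc_threshold(c(pos, neg), rep(c(TRUE, FALSE), each = 2000))
      expect_gt(r$optimal_threshold / b, 0.6)
      expect_lt(r$optimal_threshold / b, 1.6)
    }
  })
  # unbalanced priors shift the boundary toward the rarer class
  b_rare_pos <- lognormal_boundary(log(25), 0.9, log(5), 0.9, prior1 = 0.2)
  expect_gt(b_rare_pos, b)
})
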