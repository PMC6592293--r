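# Synthetic cyst-fluid cohorts with the statistical structure of the study
# population: cyst-type prevalence and grade mix as in the surgical series,
# per-type/grade mutation spectra, log-normal MAF and CEA, cytology and
# viscosity conditionals from the full-cohort summary, and partial GNAS
# testing. Every simulated case carries its ground truth, so classifier
# operating characteristics can be recovered and compared with configured
# rates.

.hotspot_changes <- list(
  KRAS = c("p.G12D", "p.G12V", "p.G12R", "p.G12A", "p.G12C", "p.G12S", "p.Q61H"),
  GNAS = c("p.R201C", "p.R201H"),
  BRAF = "p.V600E", TP53 = c("p.R175H", "p.R248Q", "p.R273H"),
  SMAD4 = c("p.R361H", "p.R361C"), CDKN2A = c("p.H83Y", "p.D108N"),
  PIK3CA = c("p.E545K", "p.H1047R"), PTEN = "p.R130G",
  VHL = c("p.R167W", "p.S65L"), APC = "p.R1450X", ATM = "p.R337C",
  RB1 = "p.R455X", ARID1A = "p.R1989X"
)

.sim_panel <- c("KRAS", "GNAS", "BRAF", "PIK3CA", "CDKN2A", "PTEN", "SMAD4",
                "TP53", "VHL", "APC", "ATM", "RB1", "ARID1A")

# Triangular deviates on [a, b] with mode c (inverse-CDF sampling); used for
# size and amylase, whose published summaries are medians with ranges only.
.rtriangular <- function(n, a, b, c) {
  u <- runif(n)
  fc <- (c - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

# Mode giving a target median m for a triangular on [a, b] (requires m below
# the midpoint, true for all published medians used here).
.tri_mode_for_median <- function(a, b, m) a + 2 * (m - a)^2 / (b - a)

#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults reproduce the study
#' population: cyst-type prevalence and dysplasia grade mix from the surgical
#' series; per-type/grade mutation probabilities (low-grade mucinous lesions
#' mutate only KRAS/GNAS; intermediate grade adds a further gene a third of
#' the time, high grade/PDAC 90% of the time; SCA always carries VHL;
#' pseudocysts harbor incidental KRAS in 20%); log-normal MAF with median 25%
#' for mucinous lesions and 5% for incidental clones; log-normal CEA with
#' class medians 2126.7 and 188.9 ng/ml; cytology and viscosity category
#' probabilities conditional on class from the full-cohort summary; and GNAS
#' tested in 182/303 of specimens.
#'
#' @param n_cases Number of cases to simulate.
#' @param seed Integer seed; the generator is fully reproducible given the
#'   seed.
#' @param type_prevalence Named probabilities over pathology types.
#' @param grade_mix Named list (`IPMN`, `MCN`) of LG/MG/HG probabilities.
#' @param mutation_model Named list keyed by `"TYPE"` or `"TYPE.GRADE"`; each
#'   entry has `gene_probs` (per-gene mutation probability), optional
#'   `additional_prob`/`additional_genes` (chance of one further gene), and
#'   optional `double_prob` (chance a mutated KRAS/GNAS carries two distinct
#'   protein changes).
#' @param maf_model Per-class log-normal parameters for MAF percent
#'   (`mucinous`, `incidental`), each `c(meanlog, sdlog)`.
#' @param cea_model,size_model,amylase_model Per-class distribution
#'   parameters (log-normal for CEA; triangular min/max/median for size and
#'   amylase).
#' @param cytology_conditionals Per-class probabilities over cytology tiers.
#' @param cytology_missing_prob Chance a specimen was never sent to cytology.
#' @param viscosity_conditionals Per-class viscous/non-viscous probabilities.
#' @param mural_nodule_prob,eus_conditionals Per-class probabilities for the
#'   remaining clinical features.
#' @param gnas_tested_prob Chance GNAS is part of the tested panel.
#' @param depth_range Read-depth range for simulated NGS calls.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(
    n_cases = 318,
    seed = 1,
    type_prevalence = c(IPMN = 19, MCN = 9, PDAC = 8, SCA = 2, PNET = 3,
                        PSEUDOCYST = 5) / 46,
    grade_mix = list(IPMN = c(LG = 12, MG = 5, HG = 2) / 19,
                     MCN = c(LG = 5, MG = 4, HG = 0) / 9),
    mutation_model = list(
      LG = list(gene_probs = c(KRAS = 0.82, GNAS = 0.41)),
      MG = list(gene_probs = c(KRAS = 0.82, GNAS = 0.41),
                additional_prob = 0.33,
                additional_genes = c("TP53", "CDKN2A", "APC"),
                double_prob = 0.10),
      HG = list(gene_probs = c(KRAS = 0.82, GNAS = 0.41),
                additional_prob = 0.90,
                additional_genes = c("TP53", "SMAD4", "CDKN2A", "BRAF",
                                     "ARID1A", "RB1", "PTEN", "PIK3CA"),
                double_prob = 0.10),
      PDAC = list(gene_probs = c(KRAS = 0.82, GNAS = 0.41),
                  additional_prob = 0.90,
                  additional_genes = c("TP53", "SMAD4", "CDKN2A", "PTEN",
                                       "RB1", "PIK3CA"),
                  double_prob = 0.10),
      SCA = list(gene_probs = c(VHL = 1.0)),
      PNET = list(gene_probs = c()),
      PSEUDOCYST = list(gene_probs = c(KRAS = 0.2))
    ),
    maf_model = list(mucinous = c(meanlog = log(25), sdlog = 0.9),
                     incidental = c(meanlog = log(5), sdlog = 0.9)),
    cea_model = list(mucinous = c(meanlog = log(2126.7), sdlog = 1.5),
                     non_mucinous = c(meanlog = log(188.9), sdlog = 1.5)),
    size_model = list(min = 5, max = 114,
                      median = c(mucinous = 30.2, non_mucinous = 36.6)),
    amylase_model = list(min = 2.4, max = 24990,
                         median = c(mucinous = 5061.8, non_mucinous = 7764.6)),
    cytology_conditionals = list(
      mucinous = c(ND = 45, NEG = 38, ATY_SUS = 53, POS = 11) / 147,
      non_mucinous = c(ND = 44, NEG = 118, ATY_SUS = 0, POS = 0) / 162),
    cytology_missing_prob = 9 / 318,
    viscosity_conditionals = list(
      mucinous = c(viscous = 91, non_viscous = 35) / 126,
      non_mucinous = c(viscous = 36, non_viscous = 113) / 149),
    mural_nodule_prob = c(mucinous = 0.15, non_mucinous = 0.03),
    eus_conditionals = list(
      mucinous = c(mucinous = 0.70, non_mucinous = 0.10, unknown = 0.20),
      non_mucinous = c(mucinous = 0.15, non_mucinous = 0.65, unknown = 0.20)),
    gnas_tested_prob = 182 / 303,
    depth_range = c(500, 2500)) {
  check_probs <- function(p, what) {
    if (any(p < 0) || any(p > 1)) abort(sprintf("%s outside [0, 1]", what))
  }
  check_simplex <- function(p, what) {
    check_probs(p, what)
    if (abs(sum(p) - 1) > 1e-9) abort(sprintf("%s must sum to 1", what))
  }
  check_simplex(type_prevalence, "type_prevalence")
  for (t in names(grade_mix)) check_simplex(grade_mix[[t]], paste("grade_mix", t))
  for (k in names(mutation_model)) {
    check_probs(mutation_model[[k]]$gene_probs %||% numeric(0),
                paste("mutation_model", k))
  }
  for (k in names(cytology_conditionals)) {
    check_simplex(cytology_conditionals[[k]], paste("cytology", k))
  }
  structure(
    list(n_cases = n_cases, seed = seed, type_prevalence = type_prevalence,
         grade_mix = grade_mix, mutation_model = mutation_model,
         maf_model = maf_model, cea_model = cea_model, size_model = size_model,
         amylase_model = amylase_model,
         cytology_conditionals = cytology_conditionals,
         cytology_missing_prob = cytology_missing_prob,
         viscosity_conditionals = viscosity_conditionals,
         mural_nodule_prob = mural_nodule_prob,
         eus_conditionals = eus_conditionals,
         gnas_tested_prob = gnas_tested_prob, depth_range = depth_range),
    class = "sim_config"
  )
}

.sample_levels <- function(n, probs) {
  if (n == 0) return(character(0))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic cohort
#'
#' Draws `config$n_cases` fully populated cases (clinical features, cytology,
#' tested genes, variant calls with MAF and read depth, and the pathology
#' ground truth) from a [sim_config()]. Reproducible: the same config yields
#' the same cohort.
#'
#' @param config A [sim_config()].
#' @return A list with canonical `cases` and `variants` tibbles; mucinous
#'   ground truth is recoverable via [surgical_truth()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cases
  empty_cases <- tibble::tibble(
    case_id = character(0), pathology_dx = character(0),
    dysplasia_grade = character(0), cytology = character(0),
    cea_ng_ml = numeric(0), amylase_u_l = numeric(0),
    cyst_size_mm = numeric(0), mural_nodule = character(0),
    viscosity = character(0), eus_impression = character(0),
    genes_tested = character(0), algorithm_label = character(0),
    molecular_label = character(0))
  empty_variants <- tibble::tibble(
    case_id = character(0), gene = character(0), protein_change = character(0),
    maf_percent = numeric(0), read_depth = integer(0), assay = character(0),
    somatic_status = character(0))
  if (n == 0) return(list(cases = empty_cases, variants = empty_variants))

  withr::with_seed(config$seed, {
    type <- .sample_levels(n, config$type_prevalence)
    grade <- rep("NA", n)
    for (t in names(config$grade_mix)) {
      idx <- which(type == t)
      grade[idx] <- .sample_levels(length(idx), config$grade_mix[[t]])
    }
    truth <- ifelse(type %in% c("IPMN", "MCN", "PDAC"), "mucinous", "non_mucinous")

    gnas_tested <- runif(n) < config$gnas_tested_prob
    genes_tested <- vapply(gnas_tested, function(g) {
      panel <- if (g) .sim_panel else setdiff(.sim_panel, "GNAS")
      paste(panel, collapse = ";")
    }, character(1))

    # clinical features, conditional on class
    pick <- function(cond) {
      out <- character(n)
      for (cl in c("mucinous", "non_mucinous")) {
        idx <- which(truth == cl)
        out[idx] <- .sample_levels(length(idx), cond[[cl]])
      }
      out
    }
    cytology <- pick(config$cytology_conditionals)
    cytology[runif(n) < config$cytology_missing_prob] <- "MISSING"
    viscosity <- pick(config$viscosity_conditionals)
    eus <- pick(config$eus_conditionals)
    mural <- ifelse(runif(n) < config$mural_nodule_prob[truth], "yes", "no")
    cea <- numeric(n)
    size <- numeric(n)
    amylase <- numeric(n)
    for (cl in c("mucinous", "non_mucinous")) {
      idx <- which(truth == cl)
      cm <- config$cea_model[[cl]]
      cea[idx] <- rlnorm(length(idx), cm[["meanlog"]], cm[["sdlog"]])
      sm <- config$size_model
      size[idx] <- .rtriangular(length(idx), sm$min, sm$max,
                                .tri_mode_for_median(sm$min, sm$max, sm$median[[cl]]))
      am <- config$amylase_model
      amylase[idx] <- .rtriangular(length(idx), am$min, am$max,
                                   .tri_mode_for_median(am$min, am$max, am$median[[cl]]))
    }

    # mutations, per (type, grade) model entry
    model_key <- ifelse(type %in% c("IPMN", "MCN"), grade, type)
    var_rows <- list()
    draw_maf <- function(k, class) {
      mm <- config$maf_model[[class]]
      pmin(100, rlnorm(k, mm[["meanlog"]], mm[["sdlog"]]))
    }
    for (i in seq_len(n)) {
      entry <- config$mutation_model[[model_key[i]]]
      if (is.null(entry)) next
      tested <- strsplit(genes_tested[i], ";", fixed = TRUE)[[1]]
      maf_class <- if (truth[i] == "mucinous") "mucinous" else "incidental"
      genes <- character(0)
      gp <- entry$gene_probs
      for (g in names(gp)) {
        if (g %in% tested && runif(1) < gp[[g]]) genes <- c(genes, g)
      }
      if (!is.null(entry$additional_prob) && runif(1) < entry$additional_prob) {
        extra <- intersect(entry$additional_genes, tested)
        extra <- setdiff(extra, genes)
        if (length(extra) > 0) genes <- c(genes, sample(extra, 1))
      }
      for (g in genes) {
        pool <- .hotspot_changes[[g]] %||% "p.?"
        k <- 1L
        if (g %in% c("KRAS", "GNAS") && !is.null(entry$double_prob) &&
            length(pool) >= 2 && runif(1) < entry$double_prob) {
          k <- 2L
        }
        pc <- sample(pool, k)
        var_rows[[length(var_rows) + 1]] <- tibble::tibble(
          case_id = as.character(i), gene = g, protein_change = pc,
          maf_percent = draw_maf(k, maf_class),
          read_depth = as.integer(round(runif(k, config$depth_range[1],
                                              config$depth_range[2]))),
          assay = "NGS", somatic_status = "cosmic_confirmed")
      }
    }
    variants <- if (length(var_rows) > 0) dplyr::bind_rows(var_rows) else empty_variants

    cases <- tibble::tibble(
      case_id = as.character(seq_len(n)), pathology_dx = type,
      dysplasia_grade = grade, cytology = cytology, cea_ng_ml = cea,
      amylase_u_l = amylase, cyst_size_mm = size, mural_nodule = mural,
      viscosity = viscosity, eus_impression = eus, genes_tested = genes_tested,
      algorithm_label = NA_character_, molecular_label = NA_character_)
    list(cases = cases, variants = variants)
  })
}

#' Recover classifier operating characteristics by simulation
#'
#' Generates `n_reps` cohorts from `config` (seeds derived from
#' `config$seed`), classifies each with the molecular rule and the clinical
#' algorithm, scores both against the simulated pathology ground truth, and
#' summarizes sensitivity and specificity across replicates.
#'
#' @param config A [sim_config()].
#' @param n_reps Number of replicate cohorts (>= 1).
#' @param cfg An [algorithm_config()] for the classifiers.
#' @return A tibble: `classifier`, `metric`, `mean`, `sd`, `n_reps`.
#' @export
recover_operating_characteristics <- function(config, n_reps = 5,
                                              cfg = algorithm_config()) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  rows <- list()
  for (r in seq_len(n_reps)) {
    rc <- config
    rc$seed <- config$seed + r - 1
    cohort <- generate_cohort(rc)
    truth <- surgical_truth(cohort$cases)
    for (classifier in c("molecular", "clinical")) {
      diag <- if (classifier == "molecular") {
        classify_molecular(cohort$cases, cohort$variants, cfg)
      } else {
        classify_clinical(cohort$cases, cfg)
      }
      ct <- confusion(diag$label, ifelse(truth == "mucinous", "mPCN", "nmPCL"),
                      positive = "mPCN")
      m <- confusion_metrics(ct)
      rows[[length(rows) + 1]] <- tibble::tibble(
        rep = r, classifier = classifier,
        metric = m$metric, value = m$proportion)
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::filter(.data$metric %in% c("sensitivity", "specificity")) |>
    dplyr::group_by(.data$classifier, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n_reps = dplyr::n(), .groups = "drop")
}

#' Density-intersection boundary of two log-normal score models
#'
#' Closed-form decision boundary between two log-normal densities with class
#' priors: the score(s) where the weighted densities are equal. Used to
#' benchmark ROC threshold recovery on synthetic MAF distributions.
#'
#' @param meanlog1,sdlog1 Parameters of the positive-class log-normal.
#' @param meanlog2,sdlog2 Parameters of the negative-class log-normal.
#' @param prior1 Prior probability of the positive class (default 0.5).
#' @return The boundary score(s) on the original scale, increasing.
#' @export
lognormal_boundary <- function(meanlog1, sdlog1, meanlog2, sdlog2,
                               prior1 = 0.5) {
  # equate log densities in t = log(x); the -log(x) Jacobian cancels
  a <- 1 / (2 * sdlog2^2) - 1 / (2 * sdlog1^2)
  b <- meanlog1 / sdlog1^2 - meanlog2 / sdlog2^2
  c <- meanlog2^2 / (2 * sdlog2^2) - meanlog1^2 / (2 * sdlog1^2) +
    log(prior1 / (1 - prior1)) + log(sdlog2 / sdlog1)
  if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) abort("densities are identical; no boundary")
    return(exp(-c / b))
  }
  disc <- b^2 - 4 * a * c
  if (disc < 0) abort("densities do not intersect")
  t <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  exp(t)
}
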