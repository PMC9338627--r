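#' Synthetic cohort configuration
#'
#' Builds a validated configuration for [generate_cohort()].  The defaults
#' encode the published marginals of the institutional cohort the generator
#' emulates: 2,593 patients, 51.4% female, 88.7% white, 3.5% Hispanic,
#' mean age 62 at first genetic test and 58 at initial diagnosis, ten named
#' primary cancer types plus 10% unknown primary, 46% structured-diagnosis
#' (warehouse) coverage, 19.5% dictionary-covered variant nomenclature, and
#' report receipt dates spanning January 2016 to June 2020.  Joint structure
#' the source never printed (mutation prevalences, treatment affinities,
#' Weibull survival) is an explicit modelling choice documented in the
#' methods vignette.
#'
#' @param n_patients Cohort size.
#' @param cancer_type_weights Named probability vector over the ten named
#'   cancer types plus `"unknown primary"`; must sum to 1.
#' @param frac_unknown_primary Probability of the unknown-primary category;
#'   must agree with `cancer_type_weights["unknown primary"]`.
#' @param frac_female,frac_white,frac_hispanic Demographic probabilities.
#' @param mean_age_first_test,mean_age_initial_dx Mean ages in years; their
#'   difference sets the mean diagnosis-to-test gap.
#' @param structured_dx_coverage Probability a patient has warehouse
#'   diagnosis codes (in addition to the report-sourced diagnosis).
#' @param gene_prevalence List: cancer type -> named vector of per-gene
#'   mutation probabilities.
#' @param treatment_affinity Nested list: gene -> cancer type -> named
#'   vector of per-drug prescription probabilities within the post-test
#'   year (the planted targeted-therapy signal).
#' @param background_drug_rates List: cancer type -> named vector of
#'   per-drug prescription probabilities applied to every patient of that
#'   type regardless of genotype (chemotherapy/immunotherapy backbone).
#' @param variant_mappable_frac Probability a generated variant string uses
#'   dictionary-covered nomenclature.
#' @param survival_model List with `shape` (Weibull shape), `scale_by_stage`
#'   (named days, stages I-IV) and `hazard_multiplier` (named per-gene
#'   multipliers, > 1 = worse prognosis; default TP53 = 2).
#' @param censoring_rate Probability of random loss to follow-up (on top of
#'   the administrative cutoff at `study_end`).
#' @param report_date_window Character or Date length-2: calendar range of
#'   report receipt dates.
#' @param study_end Administrative censoring date.
#' @return A validated object of class `cohort_config`.
#' @export
cohort_config <- function(
    n_patients = 2593,
    cancer_type_weights = default_cancer_type_weights(),
    frac_unknown_primary = 0.10,
    frac_female = 0.514,
    frac_white = 0.887,
    frac_hispanic = 0.035,
    mean_age_first_test = 62,
    mean_age_initial_dx = 58,
    structured_dx_coverage = 0.46,
    gene_prevalence = default_gene_prevalence(),
    treatment_affinity = default_treatment_affinity(),
    background_drug_rates = default_background_drug_rates(),
    variant_mappable_frac = 0.195,
    survival_model = default_survival_model(),
    censoring_rate = 0.25,
    report_date_window = c("2016-01-01", "2020-06-30"),
    study_end = "2021-06-30") {
  cfg <- structure(list(
    n_patients = n_patients,
    cancer_type_weights = cancer_type_weights,
    frac_unknown_primary = frac_unknown_primary,
    frac_female = frac_female,
    frac_white = frac_white,
    frac_hispanic = frac_hispanic,
    mean_age_first_test = mean_age_first_test,
    mean_age_initial_dx = mean_age_initial_dx,
    structured_dx_coverage = structured_dx_coverage,
    gene_prevalence = gene_prevalence,
    treatment_affinity = treatment_affinity,
    background_drug_rates = background_drug_rates,
    variant_mappable_frac = variant_mappable_frac,
    survival_model = survival_model,
    censoring_rate = censoring_rate,
    report_date_window = as.Date(report_date_window),
    study_end = as.Date(study_end)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @param config An object to validate.
#' @export
validate_cohort_config <- function(config) {
  chk_prob <- function(field) {
    v <- config[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      abort_config(field, "must be a single probability in [0,1]")
  }
  if (!is.numeric(config$n_patients) || length(config$n_patients) != 1 ||
      is.na(config$n_patients) || config$n_patients < 0 ||
      config$n_patients != round(config$n_patients))
    abort_config("n_patients", "must be a non-negative integer")
  for (f in c("frac_unknown_primary", "frac_female", "frac_white",
              "frac_hispanic", "structured_dx_coverage",
              "variant_mappable_frac", "censoring_rate"))
    chk_prob(f)
  w <- config$cancer_type_weights
  if (is.null(names(w)) || any(!nzchar(names(w))))
    abort_config("cancer_type_weights", "must be a named probability vector")
  if (any(w < 0) || any(w > 1))
    abort_config("cancer_type_weights", "entries must lie in [0,1]")
  if (abs(sum(w) - 1) > 1e-9)
    abort_config("cancer_type_weights",
                 sprintf("must sum to 1 (got %.12f)", sum(w)))
  if (!"unknown primary" %in% names(w))
    abort_config("cancer_type_weights", "must include 'unknown primary'")
  if (abs(w[["unknown primary"]] - config$frac_unknown_primary) > 1e-9)
    abort_config("frac_unknown_primary",
                 "must equal cancer_type_weights['unknown primary']")
  for (ct in names(config$gene_prevalence)) {
    p <- config$gene_prevalence[[ct]]
    if (any(p < 0) || any(p > 1))
      abort_config("gene_prevalence",
                   sprintf("probabilities for '%s' must lie in [0,1]", ct))
  }
  for (g in names(config$treatment_affinity)) {
    for (ct in names(config$treatment_affinity[[g]])) {
      p <- config$treatment_affinity[[g]][[ct]]
      if (any(p < 0) || any(p > 1))
        abort_config("treatment_affinity",
                     sprintf("probabilities for (%s, %s) must lie in [0,1]",
                             g, ct))
    }
  }
  for (ct in names(config$background_drug_rates)) {
    p <- config$background_drug_rates[[ct]]
    if (any(p < 0) || any(p > 1))
      abort_config("background_drug_rates",
                   sprintf("probabilities for '%s' must lie in [0,1]", ct))
  }
  sm <- config$survival_model
  if (!is.numeric(sm$shape) || sm$shape <= 0)
    abort_config("survival_model", "shape must be positive")
  if (is.null(sm$scale_by_stage) || any(sm$scale_by_stage <= 0) ||
      !all(c("I", "II", "III", "IV") %in% names(sm$scale_by_stage)))
    abort_config("survival_model",
                 "scale_by_stage must be positive and name stages I-IV")
  if (length(sm$hazard_multiplier) && any(sm$hazard_multiplier <= 0))
    abort_config("survival_model", "hazard multipliers must be > 0")
  if (length(config$report_date_window) != 2 ||
      anyNA(config$report_date_window) ||
      config$report_date_window[1] > config$report_date_window[2])
    abort_config("report_date_window", "must be an ordered date pair")
  invisible(config)
}

#' @rdname cohort_config
#' @export
default_cancer_type_weights <- function() {
  c("lung" = 0.20, "colorectal" = 0.12, "breast" = 0.12, "melanoma" = 0.08,
    "pancreatic" = 0.08, "prostate" = 0.07, "ovarian" = 0.07,
    "glioma" = 0.06, "cholangiocarcinoma" = 0.05, "lymphoma" = 0.05,
    "unknown primary" = 0.10)
}

# canonical disease name recorded for each cancer type
cancer_type_disease <- c(
  "lung" = "lung adenocarcinoma",
  "colorectal" = "colorectal cancer",
  "breast" = "breast cancer",
  "melanoma" = "melanoma",
  "pancreatic" = "pancreatic cancer",
  "prostate" = "prostate cancer",
  "ovarian" = "ovarian cancer",
  "glioma" = "glioma",
  "cholangiocarcinoma" = "cholangiocarcinoma",
  "lymphoma" = "lymphoma",
  "unknown primary" = "cancer of unknown primary")

#' @rdname cohort_config
#' @export
default_gene_prevalence <- function() {
  list(
    "lung" = c(TP53 = 0.50, EGFR = 0.17, KRAS = 0.30, ALK = 0.05,
               MET = 0.05, STK11 = 0.15, CDKN2A = 0.10),
    "colorectal" = c(TP53 = 0.60, APC = 0.70, KRAS = 0.40, PIK3CA = 0.20,
                     BRAF = 0.10, SMAD4 = 0.10, EGFR = 0.05),
    "breast" = c(TP53 = 0.35, PIK3CA = 0.35, ERBB2 = 0.15, BRCA1 = 0.05,
                 BRCA2 = 0.05, CHEK2 = 0.05),
    "melanoma" = c(BRAF = 0.50, NRAS = 0.25, TP53 = 0.15, CDKN2A = 0.30,
                   KIT = 0.05, EGFR = 0.03),
    "pancreatic" = c(KRAS = 0.90, TP53 = 0.60, CDKN2A = 0.40, SMAD4 = 0.30,
                     BRCA2 = 0.05),
    "prostate" = c(TP53 = 0.40, PTEN = 0.30, AR = 0.15, BRCA2 = 0.10,
                   RB1 = 0.10),
    "ovarian" = c(TP53 = 0.80, BRCA1 = 0.15, BRCA2 = 0.10, PIK3CA = 0.10),
    "glioma" = c(IDH1 = 0.40, TP53 = 0.40, EGFR = 0.10, PTEN = 0.25,
                 CDKN2A = 0.30),
    "cholangiocarcinoma" = c(TP53 = 0.30, KRAS = 0.20, IDH1 = 0.20,
                             FGFR2 = 0.15),
    "lymphoma" = c(TP53 = 0.20, MYC = 0.15, DNMT3A = 0.10),
    "unknown primary" = c(TP53 = 0.45, KRAS = 0.20, EGFR = 0.05,
                          CDKN2A = 0.20, PIK3CA = 0.10))
}

#' @rdname cohort_config
#' @export
default_treatment_affinity <- function() {
  list(
    EGFR = list("lung" = c(osimertinib = 0.60, erlotinib = 0.15,
                           gefitinib = 0.08, afatinib = 0.06)),
    ALK = list("lung" = c(alectinib = 0.45, crizotinib = 0.25,
                          lorlatinib = 0.10, brigatinib = 0.05)),
    MET = list("lung" = c(crizotinib = 0.30)),
    BRAF = list("melanoma" = c(dabrafenib = 0.40, trametinib = 0.35,
                               vemurafenib = 0.20)),
    ERBB2 = list("breast" = c(trastuzumab = 0.60)),
    BRCA1 = list("ovarian" = c(olaparib = 0.35)),
    BRCA2 = list("ovarian" = c(olaparib = 0.35)),
    FGFR2 = list("cholangiocarcinoma" = c(pemigatinib = 0.40)),
    KIT = list("melanoma" = c(imatinib = 0.30)))
}

#' @rdname cohort_config
#' @export
default_background_drug_rates <- function() {
  list(
    "lung" = c(carboplatin = 0.30, pemetrexed = 0.25, pembrolizumab = 0.30,
               docetaxel = 0.10),
    "colorectal" = c(oxaliplatin = 0.40, fluorouracil = 0.45,
                     irinotecan = 0.20, bevacizumab = 0.25,
                     cetuximab = 0.10),
    "breast" = c(paclitaxel = 0.35, doxorubicin = 0.20,
                 cyclophosphamide = 0.20, capecitabine = 0.10),
    "melanoma" = c(pembrolizumab = 0.50, nivolumab = 0.30,
                   ipilimumab = 0.20),
    "pancreatic" = c(gemcitabine = 0.50, fluorouracil = 0.30,
                     oxaliplatin = 0.25, irinotecan = 0.20),
    "prostate" = c(docetaxel = 0.30),
    "ovarian" = c(carboplatin = 0.60, paclitaxel = 0.50),
    "glioma" = c(temozolomide = 0.60),
    "cholangiocarcinoma" = c(gemcitabine = 0.50, cisplatin = 0.40),
    "lymphoma" = c(rituximab = 0.50, cyclophosphamide = 0.45,
                   doxorubicin = 0.40, etoposide = 0.15),
    "unknown primary" = c(carboplatin = 0.40, paclitaxel = 0.35))
}

#' @rdname cohort_config
#' @export
default_survival_model <- function() {
  list(shape = 1.1,
       scale_by_stage = c(I = 2600, II = 2000, III = 1300, IV = 650),
       hazard_multiplier = c(TP53 = 2.0))
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> n_patients =", x$n_patients, "\n")
  cat("  cancer types:", length(x$cancer_type_weights),
      sprintf("(unknown primary %.1f%%)", 100 * x$frac_unknown_primary), "\n")
  cat(sprintf("  female %.1f%% | white %.1f%% | hispanic %.1f%%\n",
              100 * x$frac_female, 100 * x$frac_white, 100 * x$frac_hispanic))
  cat(sprintf("  structured dx coverage %.0f%% | variant mappable %.1f%%\n",
              100 * x$structured_dx_coverage,
              100 * x$variant_mappable_frac))
  invisible(x)
}

# read a cohort_config from a JSON file (CLI `simulate --config`)
read_cohort_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(cohort_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  # jsonlite may return mappings as lists of length-1 numerics
  fix_num <- function(x) if (is.list(x)) vapply(x, as.numeric, 1) else x
  for (f in c("cancer_type_weights")) {
    if (!is.null(raw[[f]])) raw[[f]] <- fix_num(raw[[f]])
  }
  for (f in c("gene_prevalence", "background_drug_rates")) {
    if (!is.null(raw[[f]])) raw[[f]] <- lapply(raw[[f]], fix_num)
  }
  if (!is.null(raw$treatment_affinity)) {
    raw$treatment_affinity <- lapply(raw$treatment_affinity,
                                     function(g) lapply(g, fix_num))
  }
  if (!is.null(raw$survival_model)) {
    sm <- raw$survival_model
    sm$shape <- as.numeric(sm$shape)
    sm$scale_by_stage <- fix_num(sm$scale_by_stage)
    sm$hazard_multiplier <- fix_num(sm$hazard_multiplier)
    raw$survival_model <- sm
  }
  do.call(cohort_config, raw)
}
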