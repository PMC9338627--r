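# Synthetic cohort generation.
#
# The generator is a stated world, not a fitting device: its defaults are
# the published marginals of the cohort it emulates (size, demographics,
# unknown-primary share, structured-diagnosis coverage, variant
# mappability), plus explicit modelling choices for everything the source
# never printed (categorical cancer types, Bernoulli mutations, Weibull
# survival with a TP53 hazard penalty, planted gene-drug treatment
# affinities).  See the methods vignette for the rationale behind each
# choice.

FIRST_NAMES <- c("James", "Mary", "Robert", "Patricia", "John", "Jennifer",
  "Michael", "Linda", "David", "Elizabeth", "William", "Barbara", "Richard",
  "Susan", "Joseph", "Jessica", "Thomas", "Sarah", "Charles", "Karen",
  "Maria", "Nancy", "Daniel", "Lisa", "Matthew", "Betty", "Anthony",
  "Margaret", "Mark", "Sandra", "Donald", "Ashley", "Steven", "Kimberly",
  "Paul", "Emily", "Andrew", "Donna", "Joshua", "Michelle")

LAST_NAMES <- c("Smith", "Johnson", "Williams", "Brown", "Jones", "Garcia",
  "Miller", "Davis", "Rodriguez", "Martinez", "Hernandez", "Lopez",
  "Gonzalez", "Wilson", "Anderson", "Thomas", "Taylor", "Moore", "Jackson",
  "Martin", "Lee", "Perez", "Thompson", "White", "Harris", "Sanchez",
  "Clark", "Ramirez", "Lewis", "Robinson", "Walker", "Young", "Allen",
  "King", "Wright", "Scott", "Torres", "Nguyen", "Hill", "Flores",
  "Green", "Adams", "Nelson", "Baker", "Hall", "Rivera", "Campbell",
  "Mitchell", "Carter", "Roberts")

NOTE_TEMPLATES <- c("Patient started %s on %s.",
                    "Plan: initiate %s next cycle.",
                    "Continues %s; tolerating treatment well.",
                    "Discussed risks and benefits of %s therapy.")

DECOY_SENTENCES <- c("Follow-up imaging reviewed; no new findings.",
                     "Patient reports fatigue improving.",
                     "Genetic counseling discussed with family.",
                     "No new medication changes today.")

cohort_table_columns <- list(
  patients = c(patient_id = "character", clinic_number = "character",
               first_name = "character", last_name = "character",
               dob = "Date", sex = "character", race = "character",
               ethnicity = "character", cancer_type = "character",
               diagnosis_date = "Date", stage = "character",
               has_structured_dx = "logical", death_date = "Date",
               last_contact_date = "Date"),
  reports = c(report_id = "character", clinic_number = "character",
              first_name = "character", last_name = "character",
              dob = "Date", receipt_date = "Date", panel = "character"),
  findings = c(report_id = "character", gene = "character",
               variant = "character"),
  diagnoses = c(patient_id = "character", source = "character",
                diagnosis_text = "character", date = "Date",
                stage = "character", is_primary = "logical"),
  medications = c(patient_id = "character", drug_name = "character",
                  date = "Date", source = "character"),
  notes = c(patient_id = "character", date = "Date", text = "character"))

empty_cohort <- function() {
  structure(lapply(cohort_table_columns, empty_df),
            class = "synthetic_cohort")
}

#' Generate a synthetic precision-oncology cohort
#'
#' Draws a reproducible cohort of patients with genetic test reports
#' (findings in a two-dialect variant nomenclature), report- and
#' warehouse-sourced diagnosis records, warehouse medication records, and
#' templated clinical-note sentences carrying drug mentions.  Output is
#' byte-identical for identical `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_cohort`: a list of data.frames
#'   `patients`, `reports`, `findings`, `diagnoses`, `medications`,
#'   `notes`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 50), seed = 1)
#' nrow(coh$patients)
#' @export
generate_cohort <- function(config = cohort_config(), seed) {
  validate_cohort_config(config)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("a single integer seed is required", call. = FALSE)
  n <- as.integer(config$n_patients)
  if (n == 0L) return(empty_cohort())
  set.seed(as.integer(seed))
  dict <- default_dictionary()
  variant_forms <- dict_variant_forms(dict)

  ## ---- patients ------------------------------------------------------
  patient_id <- sprintf("P%05d", seq_len(n))
  clinic_number <- sprintf("MC%07d", sample.int(9999999L, n))
  first_name <- sample(FIRST_NAMES, n, replace = TRUE)
  last_name <- sample(LAST_NAMES, n, replace = TRUE)
  sex <- ifelse(stats::runif(n) < config$frac_female, "female", "male")
  race <- ifelse(stats::runif(n) < config$frac_white, "white",
                 sample(c("black", "asian", "other"), n, replace = TRUE))
  ethnicity <- ifelse(stats::runif(n) < config$frac_hispanic,
                      "hispanic", "not hispanic")
  types <- names(config$cancer_type_weights)
  cancer_type <- sample(types, n, replace = TRUE,
                        prob = config$cancer_type_weights)
  stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                  prob = c(0.15, 0.20, 0.25, 0.40))

  window <- config$report_date_window
  receipt_date <- window[1] +
    floor(stats::runif(n) * (as.numeric(window[2] - window[1]) + 1))
  age_test <- pmin(pmax(stats::rnorm(n, config$mean_age_first_test, 11), 19), 95)
  mean_gap <- max(config$mean_age_first_test - config$mean_age_initial_dx,
                  0.25)
  # raw diagnosis-to-test gap; final gap also conditioned on survival below
  gap_raw <- pmax(stats::rexp(n, rate = 1 / mean_gap), 0.05)
  dob <- receipt_date - round(age_test * 365.25)
  has_structured_dx <- stats::runif(n) < config$structured_dx_coverage

  ## ---- findings ------------------------------------------------------
  frows <- list()
  for (ct in types) {
    idx <- which(cancer_type == ct)
    if (!length(idx)) next
    prev <- config$gene_prevalence[[ct]]
    for (g in names(prev)) {
      hit <- idx[stats::runif(length(idx)) < prev[[g]]]
      if (length(hit)) {
        frows[[length(frows) + 1]] <-
          data.frame(pidx = hit, gene = g, stringsAsFactors = FALSE)
      }
    }
  }
  findings <- if (length(frows)) do.call(rbind, frows) else
    data.frame(pidx = integer(0), gene = character(0))
  findings <- findings[order(findings$pidx, findings$gene), , drop = FALSE]

  nf <- nrow(findings)
  variant <- character(nf)
  if (nf) {
    mappable <- stats::runif(nf) < config$variant_mappable_frac
    partners <- c("EML4", "CD74", "KIF5B", "TPM3", "FGFR3")
    for (k in seq_len(nf)) {
      g <- findings$gene[k]
      forms <- variant_forms[[g]]
      if (mappable[k] && length(forms)) {
        variant[k] <- forms[sample.int(length(forms), 1)]
      } else {
        variant[k] <- switch(sample.int(5, 1),
          paste(g, "deletion exon", sample.int(20, 1)),
          paste(g, "amplification"),
          paste0(g, "-", sample(partners, 1), " fusion"),
          paste(g, "rearrangement"),
          paste0(g, " splice site ", sample(1000:4999, 1), "-1G>A"))
      }
    }
  }
  findings$variant <- variant

  ## ---- reports -------------------------------------------------------
  report_id <- sprintf("R%05d", seq_len(n))
  has_clinic <- stats::runif(n) < 0.92
  reports <- data.frame(
    report_id = report_id,
    clinic_number = ifelse(has_clinic, clinic_number, ""),
    first_name = first_name, last_name = last_name, dob = dob,
    receipt_date = receipt_date,
    panel = sample(c("solid tumor panel", "heme panel"), n,
                   replace = TRUE, prob = c(0.9, 0.1)),
    stringsAsFactors = FALSE)
  findings_tab <- data.frame(
    report_id = report_id[findings$pidx],
    gene = findings$gene, variant = findings$variant,
    stringsAsFactors = FALSE)

  ## ---- survival ------------------------------------------------------
  sm <- config$survival_model
  mult <- rep(1, n)
  if (nf && length(sm$hazard_multiplier)) {
    for (g in names(sm$hazard_multiplier)) {
      carrier <- unique(findings$pidx[findings$gene == g])
      mult[carrier] <- mult[carrier] * sm$hazard_multiplier[[g]]
    }
  }
  scale <- unname(sm$scale_by_stage[stage]) * mult^(-1 / sm$shape)
  # survival from diagnosis is pure Weibull (so the per-gene hazard
  # multiplier separates groups undiluted); the test is placed between
  # diagnosis and death, so everyone is alive when tested
  t_days <- stats::rweibull(n, shape = sm$shape, scale = scale)
  gap_days <- round(pmin(gap_raw * 365.25, 0.9 * t_days,
                         (age_test - 18) * 365.25))
  diagnosis_date <- receipt_date - gap_days
  admin_days <- as.numeric(config$study_end - diagnosis_date)
  lost <- stats::runif(n) < config$censoring_rate
  loss_days <- ifelse(lost,
                      gap_days + stats::runif(n) * pmax(admin_days - gap_days, 1),
                      Inf)
  cens_days <- pmin(admin_days, loss_days)
  event <- t_days <= cens_days
  death_date <- as.Date(ifelse(event, diagnosis_date + round(t_days), NA),
                        origin = "1970-01-01")
  last_contact_date <- diagnosis_date + round(pmin(t_days, cens_days))

  patients <- data.frame(
    patient_id = patient_id, clinic_number = clinic_number,
    first_name = first_name, last_name = last_name, dob = dob,
    sex = sex, race = race, ethnicity = ethnicity,
    cancer_type = cancer_type, diagnosis_date = diagnosis_date,
    stage = stage, has_structured_dx = has_structured_dx,
    death_date = death_date, last_contact_date = last_contact_date,
    stringsAsFactors = FALSE)

  ## ---- diagnoses -----------------------------------------------------
  dz_report <- data.frame(
    patient_id = patient_id, source = "report",
    diagnosis_text = unname(cancer_type_disease[cancer_type]),
    date = diagnosis_date, stage = stage, is_primary = TRUE,
    stringsAsFactors = FALSE)
  wh <- which(has_structured_dx)
  discordant <- stats::runif(length(wh)) < 0.05
  wh_text <- unname(cancer_type_disease[cancer_type[wh]])
  if (any(discordant)) {
    alt <- vapply(cancer_type[wh[discordant]], function(ct) {
      sample(setdiff(unname(cancer_type_disease), cancer_type_disease[[ct]]), 1)
    }, character(1))
    wh_text[discordant] <- alt
  }
  dz_wh <- data.frame(
    patient_id = patient_id[wh], source = "warehouse",
    diagnosis_text = wh_text, date = diagnosis_date[wh],
    stage = stage[wh], is_primary = TRUE, stringsAsFactors = FALSE)
  extra <- wh[stats::runif(length(wh)) < 0.5]
  dz_nc <- if (length(extra)) data.frame(
    patient_id = patient_id[extra], source = "warehouse",
    diagnosis_text = sample(c("hypertension", "type 2 diabetes mellitus",
                              "atrial fibrillation", "hyperlipidemia"),
                            length(extra), replace = TRUE),
    date = diagnosis_date[extra] +
      floor(stats::runif(length(extra)) * pmax(gap_days[extra], 1)),
    stage = "", is_primary = FALSE, stringsAsFactors = FALSE) else NULL
  diagnoses <- rbind(dz_report, dz_wh, dz_nc)
  diagnoses <- diagnoses[order(diagnoses$patient_id, diagnoses$source,
                               diagnoses$diagnosis_text), , drop = FALSE]
  rownames(diagnoses) <- NULL

  ## ---- medication events --------------------------------------------
  ev <- list()
  add_events <- function(idx, drug, dates) {
    if (length(idx)) {
      ev[[length(ev) + 1]] <<- data.frame(
        pidx = idx, drug = drug, date = dates, stringsAsFactors = FALSE)
    }
  }
  # planted gene-conditional targeted therapy, post-test
  for (g in names(config$treatment_affinity)) {
    for (ct in names(config$treatment_affinity[[g]])) {
      carriers <- intersect(unique(findings$pidx[findings$gene == g]),
                            which(cancer_type == ct))
      if (!length(carriers)) next
      aff <- config$treatment_affinity[[g]][[ct]]
      for (d in names(aff)) {
        hit <- carriers[stats::runif(length(carriers)) < aff[[d]]]
        add_events(hit, d,
                   receipt_date[hit] + sample(15:300, length(hit), TRUE))
      }
    }
  }
  # genotype-agnostic backbone, post-test, plus occasional pre-test course
  for (ct in names(config$background_drug_rates)) {
    idx <- which(cancer_type == ct)
    if (!length(idx)) next
    bg <- config$background_drug_rates[[ct]]
    for (d in names(bg)) {
      hit <- idx[stats::runif(length(idx)) < bg[[d]]]
      add_events(hit, d, receipt_date[hit] + sample(1:330, length(hit), TRUE))
      pre <- idx[stats::runif(length(idx)) < 0.25 * bg[[d]] &
                   gap_days[idx] > 30]
      if (length(pre)) {
        add_events(pre, d, diagnosis_date[pre] +
                     10 + floor(stats::runif(length(pre)) *
                                  (gap_days[pre] - 20)))
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(pidx = integer(0), drug = character(0),
               date = as.Date(character(0)))
  events <- events[order(events$pidx, events$drug, events$date), , drop = FALSE]
  events <- events[!duplicated(events), , drop = FALSE]

  ## ---- route events to warehouse rows and note sentences -------------
  ne <- nrow(events)
  meds <- empty_df(cohort_table_columns$medications)
  note_rows <- empty_df(cohort_table_columns$notes)
  if (ne) {
    route <- stats::runif(ne)
    to_wh <- route < 0.75            # warehouse (possibly also notes)
    to_note <- route >= 0.45         # notes (possibly also warehouse)
    brand <- vapply(events$drug, function(d) dict_brand_of(dict, d),
                    character(1))
    wh_name <- ifelse(stats::runif(ne) < 0.15 & nzchar(brand),
                      brand, events$drug)
    note_name <- ifelse(stats::runif(ne) < 0.40 & nzchar(brand),
                        brand, events$drug)
    meds <- data.frame(
      patient_id = patient_id[events$pidx[to_wh]],
      drug_name = wh_name[to_wh],
      date = events$date[to_wh],
      source = "warehouse", stringsAsFactors = FALSE)
    tmpl <- sample(NOTE_TEMPLATES, ne, replace = TRUE)
    txt <- character(ne)
    two <- grepl("%s.*%s", tmpl)
    if (any(two)) {
      txt[two] <- sprintf(tmpl[two], note_name[two],
                          as_iso_date(events$date[two]))
    }
    if (any(!two)) txt[!two] <- sprintf(tmpl[!two], note_name[!two])
    note_rows <- data.frame(
      patient_id = patient_id[events$pidx[to_note]],
      date = events$date[to_note],
      text = txt[to_note], stringsAsFactors = FALSE)
  }
  decoy <- which(stats::runif(n) < 0.4)
  if (length(decoy)) {
    note_rows <- rbind(note_rows, data.frame(
      patient_id = patient_id[decoy],
      date = receipt_date[decoy] + sample(0:200, length(decoy), TRUE),
      text = sample(DECOY_SENTENCES, length(decoy), replace = TRUE),
      stringsAsFactors = FALSE))
  }
  note_rows <- note_rows[order(note_rows$patient_id, note_rows$date,
                               note_rows$text), , drop = FALSE]
  rownames(note_rows) <- NULL
  meds <- meds[order(meds$patient_id, meds$drug_name, meds$date), , drop = FALSE]
  rownames(meds) <- NULL

  structure(list(patients = patients, reports = reports,
                 findings = findings_tab, diagnoses = diagnoses,
                 medications = meds, notes = note_rows),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  for (nm in names(cohort_table_columns)) {
    cat(sprintf("  %-12s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Persist / load a cohort as delimited tables
#'
#' A cohort is stored as six tab-delimited files (`patients.tsv`,
#' `reports.tsv`, `findings.tsv`, `diagnoses.tsv`, `medications.tsv`,
#' `notes.tsv`) with ISO-8601 dates; empty strings denote missing values.
#' `read_cohort(write_cohort(x, d))` restores `x` field-for-field.
#'
#' @param cohort A `synthetic_cohort`.
#' @param directory Directory to write to / read from (created if needed).
#' @return `write_cohort` returns the directory invisibly; `read_cohort`
#'   returns a `synthetic_cohort`.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort_table_columns)) {
    tab <- cohort[[nm]]
    out <- tab
    for (cl in names(out)) {
      if (inherits(out[[cl]], "Date")) {
        out[[cl]] <- ifelse(is.na(out[[cl]]), "", as_iso_date(out[[cl]]))
      }
    }
    utils::write.table(out, file.path(directory, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
  }
  invisible(directory)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  out <- list()
  for (nm in names(cohort_table_columns)) {
    path <- file.path(directory, paste0(nm, ".tsv"))
    if (!file.exists(path)) {
      stop("cohort file missing: ", path, call. = FALSE)
    }
    cols <- cohort_table_columns[[nm]]
    tab <- utils::read.delim(path, colClasses = "character",
                             check.names = FALSE, quote = "")
    missing <- setdiff(names(cols), names(tab))
    if (length(missing)) {
      stop(sprintf("parse error in %s: missing required column(s) %s",
                   path, paste(missing, collapse = ", ")), call. = FALSE)
    }
    tab <- tab[names(cols)]
    for (cl in names(cols)) {
      if (cols[[cl]] == "Date") {
        raw <- tab[[cl]]
        parsed <- as.Date(raw, format = "%Y-%m-%d")
        bad <- which(nzchar(raw) & is.na(parsed))
        if (length(bad)) {
          stop(sprintf("parse error in %s line %d: bad date '%s' in column %s",
                       path, bad[1] + 1L, raw[bad[1]], cl), call. = FALSE)
        }
        tab[[cl]] <- parsed
      } else if (cols[[cl]] == "logical") {
        parsed <- as.logical(tab[[cl]])
        bad <- which(nzchar(tab[[cl]]) & is.na(parsed))
        if (length(bad)) {
          stop(sprintf("parse error in %s line %d: bad logical '%s' in column %s",
                       path, bad[1] + 1L, tab[[cl]][bad[1]], cl),
               call. = FALSE)
        }
        tab[[cl]] <- parsed
      }
    }
    rownames(tab) <- NULL
    out[[nm]] <- tab
  }
  structure(out, class = "synthetic_cohort")
}
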