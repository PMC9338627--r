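# Record linkage, disease resolution, per-patient bundles, and derivation
# of the schema's object-property relations under the temporal validity
# rules (diagnoses up to one year before the genetic test; prescriptions up
# to one year after; disease-drug pairs counted once per patient).

#' Link genetic reports to patients
#'
#' A report links to a patient when the clinic number matches; absent a
#' clinic number, when case-folded first + last name AND date of birth both
#' match exactly.  The clinic number dominates: when present it is the only
#' key consulted.  Unmatched reports are returned separately, never
#' silently dropped.
#'
#' @param reports Data.frame of reports (`report_id`, `clinic_number`,
#'   `first_name`, `last_name`, `dob`, `receipt_date`, ...).
#' @param ehr_patients Data.frame of patients (`patient_id`,
#'   `clinic_number`, `first_name`, `last_name`, `dob`, ...).
#' @return A list with `linked` (reports plus a `patient_id` column) and
#'   `unlinked` (the residual report rows).
#' @export
link_records <- function(reports, ehr_patients) {
  if (nrow(reports) == 0) {
    return(list(linked = cbind(reports, patient_id = character(0)),
                unlinked = reports))
  }
  pc <- as.character(ehr_patients$clinic_number)
  dup <- pc[nzchar(pc)][duplicated(pc[nzchar(pc)])]
  rep_clinic <- as.character(reports$clinic_number)
  amb <- intersect(rep_clinic[nzchar(rep_clinic)], dup)
  if (length(amb)) {
    cands <- ehr_patients$patient_id[pc %in% amb[1]]
    stop(sprintf("ambiguous linkage: clinic number '%s' matches patients %s",
                 amb[1], paste(cands, collapse = ", ")), call. = FALSE)
  }
  name_key <- function(first, last, dob) {
    paste(fold_term(first), fold_term(last), as_iso_date(dob), sep = "|")
  }
  pkey <- name_key(ehr_patients$first_name, ehr_patients$last_name,
                   ehr_patients$dob)
  use_name <- !nzchar(rep_clinic)
  if (any(use_name)) {
    rkey <- name_key(reports$first_name, reports$last_name,
                     reports$dob)[use_name]
    dup_key <- pkey[duplicated(pkey)]
    amb2 <- intersect(rkey, dup_key)
    if (length(amb2)) {
      cands <- ehr_patients$patient_id[pkey %in% amb2[1]]
      stop(sprintf("ambiguous linkage: name+dob key matches patients %s",
                   paste(cands, collapse = ", ")), call. = FALSE)
    }
  }
  idx <- integer(nrow(reports))
  idx[!use_name] <- match(rep_clinic[!use_name], pc)
  idx[use_name] <- match(name_key(reports$first_name, reports$last_name,
                                  reports$dob)[use_name], pkey)
  linked <- reports[!is.na(idx), , drop = FALSE]
  linked$patient_id <- ehr_patients$patient_id[idx[!is.na(idx)]]
  list(linked = linked, unlinked = reports[is.na(idx), , drop = FALSE])
}

#' Resolve disease records across sources
#'
#' Normalizes diagnosis texts, discards non-cancer diagnoses (dictionary
#' `is_cancer` flag), merges concordant report/warehouse entries (taking
#' diagnosis date and stage from the warehouse when available), keeps the
#' genetic report as gold standard on primary-cancer discordance (the
#' discordant warehouse entry is retained but marked `superseded`), and
#' retains warehouse-only cancers.
#'
#' @param report_dx,warehouse_dx Data.frames of diagnosis records with
#'   columns `diagnosis_text`, `date`, `stage`, `is_primary` and optionally
#'   `patient_id` (defaults to a single implicit patient).
#' @inheritParams map_term
#' @return A data.frame with columns `patient_id`, `disease` (preferred
#'   term), `cui`, `date`, `stage`, `sources`, `superseded`.
#' @export
resolve_diseases <- function(report_dx, warehouse_dx,
                             dict = default_dictionary()) {
  prep <- function(df, src) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    df <- as.data.frame(df)
    if (is.null(df$patient_id)) df$patient_id <- "p1"
    if (is.null(df$is_primary)) df$is_primary <- TRUE
    if (is.null(df$stage)) df$stage <- ""
    data.frame(patient_id = as.character(df$patient_id),
               diagnosis_text = as.character(df$diagnosis_text),
               date = as.Date(df$date), stage = as.character(df$stage),
               is_primary = as.logical(df$is_primary), src = src,
               stringsAsFactors = FALSE)
  }
  all_dx <- rbind(prep(report_dx, "report"), prep(warehouse_dx, "warehouse"))
  out_cols <- c(patient_id = "character", disease = "character",
                cui = "character", date = "Date", stage = "character",
                sources = "character", superseded = "logical")
  if (is.null(all_dx) || nrow(all_dx) == 0) return(empty_df(out_cols))

  m <- map_term(all_dx$diagnosis_text, "disease", dict)
  dz <- dict_class(dict, "disease")
  cancer_of <- !duplicated(fold_term(dz$preferred))
  cancer_map <- stats::setNames(dz$is_cancer[cancer_of] == "TRUE",
                                fold_term(dz$preferred[cancer_of]))
  keep <- m$status == "mapped" &
    cancer_map[fold_term(m$preferred_term)] %in% TRUE
  all_dx <- all_dx[keep, , drop = FALSE]
  if (!nrow(all_dx)) return(empty_df(out_cols))
  all_dx$disease <- m$preferred_term[keep]
  all_dx$cui <- m$cui[keep]

  key <- paste(all_dx$patient_id, fold_term(all_dx$disease), sep = "\r")
  grp <- split(seq_len(nrow(all_dx)), key)
  rows <- lapply(grp, function(i) {
    sub <- all_dx[i, , drop = FALSE]
    wh <- sub[sub$src == "warehouse", , drop = FALSE]
    rp <- sub[sub$src == "report", , drop = FALSE]
    use <- if (nrow(wh) && !is.na(wh$date[1])) wh[1, ] else sub[1, ]
    stage <- if (nrow(wh) && nzchar(wh$stage[1])) wh$stage[1] else
      if (nrow(rp)) rp$stage[1] else wh$stage[1]
    data.frame(patient_id = sub$patient_id[1], disease = sub$disease[1],
               cui = sub$cui[1], date = use$date, stage = stage,
               sources = paste(sort(unique(sub$src)), collapse = "+"),
               is_primary = any(sub$is_primary),
               from_report = nrow(rp) > 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  # report is gold standard on primary-cancer discordance
  res$superseded <- FALSE
  for (pid in unique(res$patient_id)) {
    i <- which(res$patient_id == pid)
    rep_primary <- res$disease[i][res$from_report[i] & res$is_primary[i]]
    if (!length(rep_primary)) next
    disc <- i[!res$from_report[i] & res$is_primary[i] &
                !res$disease[i] %in% rep_primary]
    res$superseded[disc] <- TRUE
  }
  res[order(res$patient_id, res$disease),
      c("patient_id", "disease", "cui", "date", "stage", "sources",
        "superseded")]
}

#' Assemble normalized per-patient bundles
#'
#' Pipeline driver: links reports to patients, derives the index test date
#' (earliest report receipt per patient), normalizes genes, variants,
#' diseases and drugs through the dictionary, resolves disease discordance,
#' and merges warehouse medications with drug mentions extracted from note
#' sentences.
#'
#' @param cohort A `synthetic_cohort` (or user-supplied object with the
#'   same tables).
#' @inheritParams map_term
#' @return An object of class `patient_bundles`: data.frames `patients`
#'   (demographics + `index_test_date`), `findings`, `diseases`, `drugs`,
#'   plus the `unlinked` report rows.
#' @export
build_bundles <- function(cohort, dict = default_dictionary()) {
  lk <- link_records(cohort$reports, cohort$patients)
  if (nrow(lk$unlinked)) {
    warning(nrow(lk$unlinked), " report(s) could not be linked to a patient",
            call. = FALSE)
  }
  linked <- lk$linked

  # index test date: earliest receipt per patient
  idx_date <- tapply(linked$receipt_date, linked$patient_id,
                     function(d) min(d), simplify = TRUE)
  patients <- cohort$patients
  patients$index_test_date <-
    as.Date(unname(idx_date[patients$patient_id]), origin = "1970-01-01")

  # findings joined through reports, normalized
  f <- cohort$findings
  f$patient_id <- linked$patient_id[match(f$report_id, linked$report_id)]
  f <- f[!is.na(f$patient_id), , drop = FALSE]
  if (nrow(f)) {
    gm <- map_term(f$gene, "gene", dict)
    vm <- normalize_variant(f$variant, f$gene, dict)
    gene_name <- ifelse(gm$status == "mapped", gm$preferred_term, f$gene)
    variant_name <- ifelse(vm$status == "mapped", vm$preferred_term,
                    ifelse(vm$status == "hgvs_normalized",
                           paste(gene_name, vm$preferred_term), f$variant))
    findings <- data.frame(
      patient_id = f$patient_id, gene = gene_name, gene_cui = gm$cui,
      variant = variant_name, variant_raw = f$variant,
      variant_cui = vm$cui, variant_status = vm$status,
      stringsAsFactors = FALSE)
    findings <- findings[!duplicated(findings[c("patient_id", "gene",
                                                "variant")]), , drop = FALSE]
    findings <- findings[order(findings$patient_id, findings$gene,
                               findings$variant), , drop = FALSE]
    rownames(findings) <- NULL
  } else {
    findings <- empty_df(c(patient_id = "character", gene = "character",
                           gene_cui = "character", variant = "character",
                           variant_raw = "character",
                           variant_cui = "character",
                           variant_status = "character"))
  }

  dx <- cohort$diagnoses
  diseases <- resolve_diseases(dx[dx$source == "report", , drop = FALSE],
                               dx[dx$source == "warehouse", , drop = FALSE],
                               dict)

  meds <- cohort$medications
  drug_rows <- list()
  if (nrow(meds)) {
    dm <- normalize_drug(meds$drug_name, dict)
    drug_rows$warehouse <- data.frame(
      patient_id = meds$patient_id,
      drug = ifelse(dm$status == "mapped", dm$preferred_term,
                    meds$drug_name),
      drug_cui = dm$cui, date = as.Date(meds$date), source = meds$source,
      stringsAsFactors = FALSE)
  }
  notes_meds <- extract_drug_mentions(cohort$notes, dict)
  if (nrow(notes_meds)) {
    nm <- normalize_drug(notes_meds$drug_name, dict)
    drug_rows$notes <- data.frame(
      patient_id = notes_meds$patient_id, drug = notes_meds$drug_name,
      drug_cui = nm$cui, date = notes_meds$date, source = "notes",
      stringsAsFactors = FALSE)
  }
  drugs <- if (length(drug_rows)) do.call(rbind, drug_rows) else
    empty_df(c(patient_id = "character", drug = "character",
               drug_cui = "character", date = "Date", source = "character"))
  drugs <- drugs[!duplicated(drugs[c("patient_id", "drug", "date",
                                     "source")]), , drop = FALSE]
  drugs <- drugs[order(drugs$patient_id, drugs$drug, drugs$date), , drop = FALSE]
  rownames(drugs) <- NULL

  structure(list(patients = patients, findings = findings,
                 diseases = diseases, drugs = drugs,
                 unlinked = lk$unlinked),
            class = "patient_bundles")
}

#' @export
print.patient_bundles <- function(x, ...) {
  cat("<patient_bundles> ", nrow(x$patients), " patients, ",
      nrow(x$findings), " findings, ", nrow(x$diseases), " diseases, ",
      nrow(x$drugs), " drug records\n", sep = "")
  invisible(x)
}

#' Extract the bundle of a single patient
#'
#' @param bundles A `patient_bundles` object.
#' @param patient_id Patient identifier.
#' @return A `patient_bundles` object restricted to one patient.
#' @export
bundle <- function(bundles, patient_id) {
  out <- lapply(bundles[c("patients", "findings", "diseases", "drugs")],
                function(tab) {
                  tab[tab$patient_id %in% patient_id, , drop = FALSE]
                })
  out$unlinked <- bundles$unlinked[0, , drop = FALSE]
  structure(out, class = "patient_bundles")
}

relation_cols <- c(patient_id = "character", predicate = "character",
                   subject_class = "character", subject = "character",
                   object_class = "character", object = "character",
                   date1 = "Date", date2 = "Date")

#' Derive schema relations under the temporal validity rules
#'
#' Emits, per patient: `HasMutGene`/`HasVariant` per finding and
#' `AssociatedWithVariant` (gene to variant); `HasDisease` and
#' `AssociatedWithGene` (disease to gene) for diagnoses dated within
#' `[test - window, test]`; `TreatedBy` (patient to drug) for prescriptions
#' dated within `(test, test + window]`; `MayTargetedBy` (gene to drug) for
#' the same window, restricted to targeted therapies whose dictionary
#' annotation lists a gene the patient carries; `MayTreatedBy` (disease to
#' drug) for prescriptions on or after the diagnosis date (no upper bound,
#' all drug categories), counted once per patient.  All relations are
#' deduplicated per patient.  Records with missing dates are skipped with a
#' warning, never an error.
#'
#' @param bundles A `patient_bundles` object (one patient or many).
#' @param window_days Temporal validity window in days (default 365, i.e.
#'   "one year").
#' @inheritParams map_term
#' @return A data.frame of relations with columns `patient_id`,
#'   `predicate`, `subject_class`, `subject`, `object_class`, `object`,
#'   `date1`, `date2`.
#' @export
derive_relations <- function(bundles, window_days = 365,
                             dict = default_dictionary()) {
  stopifnot(inherits(bundles, "patient_bundles"))
  pts <- bundles$patients
  test_of <- stats::setNames(pts$index_test_date, pts$patient_id)
  rel <- list()
  add <- function(df) if (!is.null(df) && nrow(df)) rel[[length(rel) + 1]] <<- df

  f <- bundles$findings
  if (nrow(f)) {
    t_f <- as.Date(unname(test_of[f$patient_id]), origin = "1970-01-01")
    add(data.frame(patient_id = f$patient_id, predicate = "HasMutGene",
                   subject_class = "Patient", subject = f$patient_id,
                   object_class = "Gene", object = f$gene,
                   date1 = t_f, date2 = as.Date(NA),
                   stringsAsFactors = FALSE))
    add(data.frame(patient_id = f$patient_id, predicate = "HasVariant",
                   subject_class = "Patient", subject = f$patient_id,
                   object_class = "Variant", object = f$variant,
                   date1 = t_f, date2 = as.Date(NA),
                   stringsAsFactors = FALSE))
    add(data.frame(patient_id = f$patient_id,
                   predicate = "AssociatedWithVariant",
                   subject_class = "Gene", subject = f$gene,
                   object_class = "Variant", object = f$variant,
                   date1 = t_f, date2 = as.Date(NA),
                   stringsAsFactors = FALSE))
  }

  dz <- bundles$diseases
  dz <- dz[!dz$superseded, , drop = FALSE]
  if (nrow(dz)) {
    miss <- is.na(dz$date)
    if (any(miss)) {
      warning(sum(miss), " diagnosis record(s) skipped: missing date",
              call. = FALSE)
      dz <- dz[!miss, , drop = FALSE]
    }
  }
  if (nrow(dz)) {
    t_d <- as.Date(unname(test_of[dz$patient_id]), origin = "1970-01-01")
    in_win <- !is.na(t_d) & dz$date >= t_d - window_days & dz$date <= t_d
    dwin <- dz[in_win, , drop = FALSE]
    if (nrow(dwin)) {
      t_w <- t_d[in_win]
      add(data.frame(patient_id = dwin$patient_id, predicate = "HasDisease",
                     subject_class = "Patient", subject = dwin$patient_id,
                     object_class = "Disease", object = dwin$disease,
                     date1 = dwin$date, date2 = t_w,
                     stringsAsFactors = FALSE))
      # disease -> each mutated gene of the same patient
      ag <- merge(dwin[c("patient_id", "disease", "date")],
                  f[c("patient_id", "gene")], by = "patient_id")
      if (nrow(ag)) {
        add(data.frame(patient_id = ag$patient_id,
                       predicate = "AssociatedWithGene",
                       subject_class = "Disease", subject = ag$disease,
                       object_class = "Gene", object = ag$gene,
                       date1 = ag$date,
                       date2 = as.Date(unname(test_of[ag$patient_id]),
                                       origin = "1970-01-01"),
                       stringsAsFactors = FALSE))
      }
    }
  }

  dr <- bundles$drugs
  if (nrow(dr)) {
    miss <- is.na(dr$date)
    if (any(miss)) {
      warning(sum(miss), " medication record(s) skipped: missing date",
              call. = FALSE)
      dr <- dr[!miss, , drop = FALSE]
    }
  }
  if (nrow(dr)) {
    t_r <- as.Date(unname(test_of[dr$patient_id]), origin = "1970-01-01")
    post <- !is.na(t_r) & dr$date > t_r & dr$date <= t_r + window_days
    dpost <- dr[post, , drop = FALSE]
    if (nrow(dpost)) {
      add(data.frame(patient_id = dpost$patient_id, predicate = "TreatedBy",
                     subject_class = "Patient", subject = dpost$patient_id,
                     object_class = "Drug", object = dpost$drug,
                     date1 = t_r[post], date2 = dpost$date,
                     stringsAsFactors = FALSE))
      # gene <- drug: targeted therapies annotated for a gene the patient
      # carries, same post-test window
      chem <- dict_chemicals(dict)
      cat_of <- stats::setNames(chem$drug_category, fold_term(chem$surface))
      tg_of <- stats::setNames(chem$target_genes, fold_term(chem$surface))
      dk <- fold_term(dpost$drug)
      targeted <- cat_of[dk] %in% "targeted therapy" & nzchar(tg_of[dk])
      if (any(targeted)) {
        tsub <- dpost[targeted, , drop = FALSE]
        tg <- strsplit(unname(tg_of[fold_term(tsub$drug)]), "|", fixed = TRUE)
        mt <- data.frame(
          patient_id = rep(tsub$patient_id, lengths(tg)),
          drug = rep(tsub$drug, lengths(tg)),
          date = rep(tsub$date, lengths(tg)),
          gene = unlist(tg), stringsAsFactors = FALSE)
        carried <- paste(f$patient_id, f$gene, sep = "\r")
        mt <- mt[paste(mt$patient_id, mt$gene, sep = "\r") %in% carried, ,
                 drop = FALSE]
        if (nrow(mt)) {
          add(data.frame(patient_id = mt$patient_id,
                         predicate = "MayTargetedBy",
                         subject_class = "Gene", subject = mt$gene,
                         object_class = "Drug", object = mt$drug,
                         date1 = as.Date(unname(test_of[mt$patient_id]),
                                         origin = "1970-01-01"),
                         date2 = mt$date, stringsAsFactors = FALSE))
        }
      }
    }
    # disease -> drug: prescription on/after diagnosis, any category
    if (nrow(dz)) {
      dd <- merge(dz[c("patient_id", "disease", "date")],
                  dr[c("patient_id", "drug", "date")],
                  by = "patient_id", suffixes = c("_dx", "_rx"))
      dd <- dd[dd$date_rx >= dd$date_dx, , drop = FALSE]
      if (nrow(dd)) {
        dd <- dd[order(dd$patient_id, dd$disease, dd$drug, dd$date_rx), ,
                 drop = FALSE]
        dd <- dd[!duplicated(dd[c("patient_id", "disease", "drug")]), ,
                 drop = FALSE]
        add(data.frame(patient_id = dd$patient_id,
                       predicate = "MayTreatedBy",
                       subject_class = "Disease", subject = dd$disease,
                       object_class = "Drug", object = dd$drug,
                       date1 = dd$date_dx, date2 = dd$date_rx,
                       stringsAsFactors = FALSE))
      }
    }
  }

  if (!length(rel)) return(empty_df(relation_cols))
  out <- do.call(rbind, rel)
  out <- out[!duplicated(out[c("patient_id", "predicate", "subject",
                               "object")]), , drop = FALSE]
  out <- out[order(out$patient_id, out$predicate, out$subject, out$object), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
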