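#' Map raw terms to dictionary concepts
#'
#' Deterministic, exact dictionary lookup (after case-folding, trimming of
#' surrounding punctuation and whitespace collapsing).  This deliberately
#' replaces fuzzy candidate scoring: a term either hits a dictionary surface
#' form (or a preferred term) with score 1, or it is `unmapped` with score
#' 0.  Substring matches never count, which avoids the abbreviation and
#' substring-ambiguity errors that plague fuzzy mappers on clinical text.
#'
#' `map_term` is vectorized over `raw_term` and idempotent: mapping a
#' mapping's `preferred_term` returns the same concept.
#'
#' @param raw_term Character vector of raw surface forms (non-empty).
#' @param entity_class One of `"gene"`, `"variant"`, `"disease"`, `"drug"`.
#' @param dict A [concept dictionary][read_concept_dictionary].
#' @return A data.frame with one row per input term and columns
#'   `raw_term`, `entity_class`, `status` (`mapped`/`unmapped`), `cui`,
#'   `preferred_term`, `score`.
#' @examples
#' map_term("EGFR", "gene", default_dictionary())
#' @export
map_term <- function(raw_term, entity_class, dict = default_dictionary()) {
  if (!entity_class %in% c("gene", "variant", "disease", "drug")) {
    stop("unknown entity_class: ", entity_class, call. = FALSE)
  }
  if (any(!nzchar(trimws(raw_term)))) {
    stop("raw_term must be non-empty", call. = FALSE)
  }
  sub <- dict_class(dict, entity_class)
  keys <- fold_term(raw_term)
  i <- match(keys, sub$key)
  # fall back to preferred-term match so mapping is idempotent even when a
  # preferred term is not itself listed as a surface form
  miss <- is.na(i)
  if (any(miss)) {
    i[miss] <- match(keys[miss], fold_term(sub$preferred))
  }
  hit <- !is.na(i)
  out <- data.frame(
    raw_term = as.character(raw_term),
    entity_class = entity_class,
    status = ifelse(hit, "mapped", "unmapped"),
    cui = ifelse(hit, sub$cui[i], NA_character_),
    preferred_term = ifelse(hit, sub$preferred[i], NA_character_),
    score = as.numeric(hit),
    stringsAsFactors = FALSE
  )
  # a dictionary row may legitimately lack a CUI; such a hit is not "mapped"
  no_cui <- hit & (is.na(out$cui) | out$cui == "")
  out$status[no_cui] <- "unmapped"
  out$cui[no_cui] <- NA_character_
  out$score[no_cui] <- 0
  out$preferred_term[no_cui] <- NA_character_
  out
}

#' Normalize a drug name to its chemical name
#'
#' Brand names resolve through the dictionary's `brand_of` link to the
#' chemical entry; chemical names map to themselves.  The returned
#' `preferred_term` is always a chemical name.  Unrecognized strings come
#' back `unmapped` (never an error).
#'
#' @param raw Character vector of drug names (brand or chemical).
#' @inheritParams map_term
#' @return A mapping data.frame as in [map_term()].
#' @export
normalize_drug <- function(raw, dict = default_dictionary()) {
  # brand rows carry preferred = chemical name, so one lookup suffices
  map_term(raw, "drug", dict)
}

#' Normalize a variant name
#'
#' Resolution order per variant: (1) exact dictionary hit on the raw string,
#' (2) exact dictionary hit on `"<gene> <raw>"` (report findings usually
#' store the variant without the gene symbol), (3) if the raw string is a
#' single-letter protein substitution (e.g. `L858R`), rewrite it to the
#' three-letter HGVS protein form (`p.Leu858Arg`) with status
#' `hgvs_normalized` and no CUI, (4) otherwise `unmapped` with the raw
#' string retained verbatim.  Deletions, fusions, frameshifts and other
#' free-form nomenclature therefore stay unmapped, mirroring the low
#' real-world mappability of non-SNV variant descriptions.
#'
#' @param raw Character vector of variant strings.
#' @param gene Character vector (recycled) of gene symbols giving context.
#' @inheritParams map_term
#' @return A mapping data.frame as in [map_term()], with status possibly
#'   `hgvs_normalized`.
#' @export
normalize_variant <- function(raw, gene = "", dict = default_dictionary()) {
  gene <- rep_len(as.character(gene), length(raw))
  out <- map_term(raw, "variant", dict)
  # (2) retry with gene context
  retry <- out$status == "unmapped" & nzchar(gene) &
    !startsWith(fold_term(raw), fold_term(gene))
  if (any(retry)) {
    ctx <- map_term(paste(gene[retry], raw[retry]), "variant", dict)
    ok <- ctx$status == "mapped"
    idx <- which(retry)[ok]
    out$status[idx] <- "mapped"
    out$cui[idx] <- ctx$cui[ok]
    out$preferred_term[idx] <- ctx$preferred_term[ok]
    out$score[idx] <- 1
  }
  # (3) HGVS protein-substitution fallback
  left <- which(out$status == "unmapped")
  if (length(left)) {
    r <- trimws(raw[left])
    m1 <- regexec("^([A-Z])([0-9]+)([A-Z*])$", r)
    hit1 <- vapply(regmatches(r, m1), length, 1L) == 4L
    parts <- regmatches(r, m1)
    hgvs <- vapply(seq_along(r), function(j) {
      if (!hit1[j]) return(NA_character_)
      p <- parts[[j]]
      a1 <- AA3[p[2]]; a2 <- AA3[p[4]]
      if (is.na(a1) || is.na(a2)) return(NA_character_)
      paste0("p.", a1, p[3], a2)
    }, character(1))
    # already three-letter HGVS protein form: identity
    already <- grepl("^p\\.[A-Z][a-z]{2}[0-9]+([A-Z][a-z]{2}|Ter)$", r)
    hgvs[already] <- r[already]
    ok <- !is.na(hgvs)
    idx <- left[ok]
    out$status[idx] <- "hgvs_normalized"
    out$preferred_term[idx] <- hgvs[ok]
    out$score[idx] <- 1
  }
  out
}

#' Extract drug mentions from note sentences
#'
#' Whole-word, case-insensitive dictionary matching over free-text
#' sentences; both brand and chemical surface forms are looked up, and
#' every match is reported under the chemical name.  Duplicate mentions of
#' the same drug within one sentence collapse to a single record.  No
#' substring matching: a drug name embedded in a longer word is not a
#' mention.
#'
#' @param sentences A data.frame with columns `patient_id`, `date`, `text`
#'   (one clinical-note sentence per row).
#' @inheritParams map_term
#' @return A data.frame of medication records with columns `patient_id`,
#'   `drug_name` (chemical), `date`, `source` (always `"notes"`).
#' @export
extract_drug_mentions <- function(sentences, dict = default_dictionary()) {
  empty <- empty_df(c(patient_id = "character", drug_name = "character",
                      date = "Date", source = "character"))
  if (is.null(sentences) || nrow(sentences) == 0) return(empty)
  drugs <- dict_class(dict, "drug")
  if (!nrow(drugs)) stop("dictionary contains no drug entries", call. = FALSE)
  hits <- list()
  txt <- as.character(sentences$text)
  for (i in seq_len(nrow(drugs))) {
    pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                              drugs$surface[i]), "\\b")
    j <- grep(pat, txt, ignore.case = TRUE, perl = TRUE)
    if (length(j)) {
      hits[[length(hits) + 1]] <- data.frame(
        row = j, drug_name = drugs$preferred[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty)
  h <- do.call(rbind, hits)
  h <- h[!duplicated(h[c("row", "drug_name")]), , drop = FALSE]
  out <- data.frame(
    patient_id = as.character(sentences$patient_id)[h$row],
    drug_name = h$drug_name,
    date = as.Date(sentences$date)[h$row],
    source = "notes",
    stringsAsFactors = FALSE
  )
  out[order(h$row, out$drug_name), , drop = FALSE]
}

#' Mapping-coverage statistics
#'
#' Summarizes a set of concept mappings the way terminology-coverage tables
#' are reported: total occurrences, identifiable occurrences, unique
#' concepts (case-folded raw terms) and unique identifiable concepts, per
#' entity class.  An occurrence is identifiable when its status is `mapped`,
#' or `hgvs_normalized` with a CUI; an HGVS rewrite without a CUI is *not*
#' identifiable (it has no concept identifier to link on).
#'
#' Percentages are derived, never stored: use
#' `100 * identifiable_occurrences / total_occurrences`.
#'
#' @param mappings A mapping data.frame as returned by [map_term()] and
#'   friends (rows from several classes may be mixed).
#' @return A data.frame with one row per entity class, columns
#'   `entity_class`, `total_occurrences`, `identifiable_occurrences`,
#'   `unique_concepts`, `unique_identifiable`.
#' @export
coverage_stats <- function(mappings) {
  cols <- c(entity_class = "character", total_occurrences = "integer",
            identifiable_occurrences = "integer", unique_concepts = "integer",
            unique_identifiable = "integer")
  if (is.null(mappings) || nrow(mappings) == 0) return(empty_df(cols))
  identifiable <- mappings$status == "mapped" |
    (mappings$status == "hgvs_normalized" &
       !is.na(mappings$cui) & nzchar(mappings$cui))
  key <- fold_term(mappings$raw_term)
  out <- lapply(split(seq_len(nrow(mappings)), mappings$entity_class),
    function(i) {
      data.frame(
        entity_class = mappings$entity_class[i[1]],
        total_occurrences = length(i),
        identifiable_occurrences = sum(identifiable[i]),
        unique_concepts = length(unique(key[i])),
        unique_identifiable = length(unique(key[i][identifiable[i]])),
        stringsAsFactors = FALSE)
    })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Normalize every record of a cohort
#'
#' Bulk driver used by the pipeline and the command-line interface: maps all
#' gene, variant (with gene context), disease and drug occurrences of a
#' cohort, including drug mentions extracted from note sentences.
#'
#' @param cohort A [synthetic_cohort][generate_cohort] (or any object with
#'   the same tables).
#' @inheritParams map_term
#' @return A mapping data.frame (all classes stacked) suitable for
#'   [coverage_stats()].
#' @export
normalize_cohort <- function(cohort, dict = default_dictionary()) {
  maps <- list()
  if (nrow(cohort$findings)) {
    maps$gene <- map_term(cohort$findings$gene, "gene", dict)
    maps$variant <- normalize_variant(cohort$findings$variant,
                                      cohort$findings$gene, dict)
  }
  if (nrow(cohort$diagnoses)) {
    maps$disease <- map_term(cohort$diagnoses$diagnosis_text, "disease", dict)
  }
  drug_terms <- character(0)
  if (nrow(cohort$medications)) {
    drug_terms <- cohort$medications$drug_name
  }
  notes_meds <- extract_drug_mentions(cohort$notes, dict)
  drug_terms <- c(drug_terms, notes_meds$drug_name)
  if (length(drug_terms)) {
    maps$drug <- normalize_drug(drug_terms, dict)
  }
  out <- do.call(rbind, maps)
  rownames(out) <- NULL
  out
}
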