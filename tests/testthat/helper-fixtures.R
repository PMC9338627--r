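# Shared fixtures, built in code.  Heavier objects are memoised so several
# test files can reuse them without regeneration.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

small_cohort <- function() {
  memo("small_cohort", generate_cohort(cohort_config(n_patients = 120),
                                       seed = 7))
}

small_bundles <- function() {
  memo("small_bundles", suppressWarnings(build_bundles(small_cohort())))
}

small_relations <- function() {
  memo("small_relations", derive_relations(small_bundles()))
}

small_graph <- function() {
  memo("small_graph",
       build_graph(entity_tables(small_bundles()), small_relations()))
}

# Two-patient worked example: patient 1 with lung adenocarcinoma (diagnosed
# 100 days before the test), EGFR/TP53/CHEK2 findings, osimertinib 30 days
# after the test; patient 2 with melanoma (200 days before), five mutated
# genes, pembrolizumab 30 days after.
two_patient_cohort <- function() {
  patients <- data.frame(
    patient_id = c("P1", "P2"),
    clinic_number = c("MC0000001", "MC0000002"),
    first_name = c("Ada", "Grace"), last_name = c("Lovelace", "Hopper"),
    dob = as.Date(c("1955-03-01", "1948-11-20")),
    sex = c("female", "female"), race = c("white", "white"),
    ethnicity = c("not hispanic", "not hispanic"),
    cancer_type = c("lung", "melanoma"),
    diagnosis_date = as.Date(c("2019-02-21", "2018-11-13")),
    stage = c("III", "IV"),
    has_structured_dx = c(FALSE, FALSE),
    death_date = as.Date(c(NA, NA)),
    last_contact_date = as.Date(c("2020-06-01", "2020-06-01")),
    stringsAsFactors = FALSE)
  reports <- data.frame(
    report_id = c("R1", "R2"),
    clinic_number = c("MC0000001", "MC0000002"),
    first_name = patients$first_name, last_name = patients$last_name,
    dob = patients$dob,
    receipt_date = as.Date(c("2019-06-01", "2019-06-01")),
    panel = "solid tumor panel", stringsAsFactors = FALSE)
  findings <- data.frame(
    report_id = c("R1", "R1", "R1", "R2", "R2", "R2", "R2", "R2"),
    gene = c("EGFR", "TP53", "CHEK2",
             "EGFR", "TP53", "DNMT3A", "CDKN2A/B", "RAF1"),
    variant = c("EGFR L858R", "TP53 R175H", "CHEK2 I157T",
                "EGFR T790M", "TP53 R273H", "DNMT3A R882H",
                "CDKN2A/B loss", "RAF1 S257L"),
    stringsAsFactors = FALSE)
  diagnoses <- data.frame(
    patient_id = c("P1", "P2"),
    source = "report",
    diagnosis_text = c("lung adenocarcinoma", "melanoma"),
    date = patients$diagnosis_date,
    stage = patients$stage, is_primary = TRUE, stringsAsFactors = FALSE)
  medications <- data.frame(
    patient_id = c("P1", "P2"),
    drug_name = c("osimertinib", "pembrolizumab"),
    date = as.Date(c("2019-07-01", "2019-07-01")),
    source = "warehouse", stringsAsFactors = FALSE)
  notes <- data.frame(patient_id = character(0),
                      date = as.Date(character(0)),
                      text = character(0), stringsAsFactors = FALSE)
  structure(list(patients = patients, reports = reports,
                 findings = findings, diagnoses = diagnoses,
                 medications = medications, notes = notes),
            class = "synthetic_cohort")
}

two_patient_bundles <- function() {
  memo("two_patient_bundles", build_bundles(two_patient_cohort()))
}

# Minimal dictionary with NO variant entries, for exercising the HGVS
# fallback path in isolation.
novariant_dict <- function() {
  memo("novariant_dict", {
    src <- system.file("extdata", "concept_dictionary.tsv",
                       package = "oncordf")
    tab <- read.delim(src, colClasses = "character")
    tab <- tab[tab$entity_class != "variant", , drop = FALSE]
    path <- tempfile(fileext = ".tsv")
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    read_concept_dictionary(path)
  })
}

# Independent brute-force support: plain double loop, no set helpers.
brute_support <- function(X, trans) {
  hit <- 0L
  for (t in trans) {
    ok <- TRUE
    for (x in X) if (!x %in% t) { ok <- FALSE; break }
    if (ok) hit <- hit + 1L
  }
  hit / length(trans)
}
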