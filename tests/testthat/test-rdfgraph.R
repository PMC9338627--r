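# RDF materialization, serialization round trips, class triple counts and
# the SPARQL SELECT subset.

egfr_entity_graph <- function() {
  ent <- list(Gene = data.frame(
    Gene_Name = "EGFR", UMLS_CUI = "C1414313", OMIM_ID = "131550",
    CIViC_Gene_ID = "1956", OncoKB_Gene_ID = "2",
    PharmGKB_Gene_ID = "PA7360", stringsAsFactors = FALSE))
  build_graph(ent)
}

test_that("an entity yields one typing triple plus one per populated property", {
  g <- egfr_entity_graph()
  expect_identical(nrow(g$triples), 7L)   # 1 typing + 6 data properties
  lit <- g$triples[g$triples$o_type == "literal", ]
  expect_setequal(lit$o, c("EGFR", "C1414313", "131550", "1956", "2",
                           "PA7360"))
  # unpopulated properties are skipped
  ent2 <- list(Gene = data.frame(
    Gene_Name = "MYGENE", UMLS_CUI = "", OMIM_ID = "", CIViC_Gene_ID = "",
    OncoKB_Gene_ID = "", PharmGKB_Gene_ID = "", stringsAsFactors = FALSE))
  expect_identical(nrow(build_graph(ent2)$triples), 2L)
})

test_that("a one-patient one-gene graph matches the hand enumeration", {
  ent <- list(
    Patient = data.frame(Patient_ID = "P1", Date_of_Birth = "1950-01-01",
                         Race = "white", Ethnicity = "not hispanic",
                         Sex = "female", Death = "",
                         stringsAsFactors = FALSE),
    Gene = data.frame(Gene_Name = "EGFR", UMLS_CUI = "C1414313",
                      OMIM_ID = "", CIViC_Gene_ID = "",
                      OncoKB_Gene_ID = "", PharmGKB_Gene_ID = "",
                      stringsAsFactors = FALSE))
  rel <- data.frame(patient_id = "P1", predicate = "HasMutGene",
                    subject_class = "Patient", subject = "P1",
                    object_class = "Gene", object = "EGFR",
                    stringsAsFactors = FALSE)
  g <- build_graph(ent, rel)
  ns <- g$namespace
  # hand enumeration: patient typing + 5 populated props (Death empty),
  # gene typing + 2 props, 1 object property = 10 triples
  expect_identical(nrow(g$triples), 10L)
  expect_true(paste0(ns, "Patient/P1") %in% g$triples$s)
  obj <- g$triples[g$triples$p == paste0(ns, "HasMutGene"), ]
  expect_identical(obj$s, paste0(ns, "Patient/P1"))
  expect_identical(obj$o, paste0(ns, "Gene/C1414313-EGFR"))
  # dates carry the xsd:date datatype
  dob <- g$triples[g$triples$p == paste0(ns, "Date_of_Birth"), ]
  expect_match(dob$dtype, "XMLSchema#date")
})

test_that("unknown relation endpoints raise a referential-integrity error", {
  ent <- list(Gene = data.frame(Gene_Name = "EGFR", UMLS_CUI = "C1414313",
                                OMIM_ID = "", CIViC_Gene_ID = "",
                                OncoKB_Gene_ID = "", PharmGKB_Gene_ID = "",
                                stringsAsFactors = FALSE))
  rel <- data.frame(patient_id = "P9", predicate = "HasMutGene",
                    subject_class = "Patient", subject = "P9",
                    object_class = "Gene", object = "EGFR",
                    stringsAsFactors = FALSE)
  expect_error(build_graph(ent, rel), "referential integrity.*P9")
})

test_that("serialization round-trips in both formats, unicode included", {
  g <- small_graph()
  for (fmt in c("turtle", "ntriples")) {
    path <- withr::local_tempfile(
      fileext = if (fmt == "turtle") ".ttl" else ".nt")
    write_graph(g, path, format = fmt)
    g2 <- read_graph(path)
    expect_identical(g2$triples, g$triples)
    expect_identical(g2$namespace, g$namespace)
  }
  # empty graph round trip
  ge <- build_graph(list())
  path <- withr::local_tempfile(fileext = ".ttl")
  write_graph(ge, path)
  expect_identical(nrow(read_graph(path)$triples), 0L)
  # unicode and escaped characters in literals
  ent <- list(Disease = data.frame(
    Disease_Name = "Erdheim–Chester \"disease\" ü",
    UMLS_CUI = "C0001", OMIM_ID = "", CIViC_DOID = "",
    OncoKB_Disease_ID = "", PharmGKB_Disease_ID = "",
    Stage_At_Diagnosis = "", stringsAsFactors = FALSE))
  gu <- build_graph(ent)
  for (fmt in c("turtle", "ntriples")) {
    path <- withr::local_tempfile(fileext = ".rdf")
    write_graph(gu, path, format = fmt)
    expect_identical(read_graph(path, format = fmt)$triples, gu$triples)
  }
})

test_that("malformed RDF input raises a parse error with location", {
  path <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c("@prefix onco: <http://example.org/x/> .",
               "<http://a> <http://b> ."), path)
  expect_error(read_graph(path), "line 2")
})

test_that("count_by_class matches a brute-force recount", {
  g <- small_graph()
  cc <- count_by_class(g)
  expect_identical(cc$total, nrow(g$triples))
  # independent recount from the typing triples
  t <- g$triples
  typ <- t[t$p == "http://www.w3.org/1999/02/22-rdf-syntax-ns#type", ]
  for (cls in names(cc$by_class)) {
    subj <- typ$s[typ$o == paste0(g$namespace, cls)]
    expect_identical(cc$by_class[[cls]], sum(t$s %in% subj))
  }
  expect_lte(sum(cc$by_class), cc$total)
  empty <- count_by_class(build_graph(list()))
  expect_identical(sum(empty$by_class), 0L)
  expect_identical(empty$total, 0L)
})

test_that("triple-count ledger: entities + populated properties + relations", {
  b <- small_bundles()
  ent <- entity_tables(b)
  rel <- small_relations()
  g <- build_graph(ent, rel)
  schema <- schema_def()
  expected <- 0L
  for (cls in names(ent)) {
    tab <- ent[[cls]]
    props <- schema$data_properties[[cls]]
    populated <- sum(vapply(props, function(p) {
      sum(!is.na(tab[[p]]) & nzchar(tab[[p]]))
    }, numeric(1)))
    expected <- expected + nrow(tab) + populated
  }
  uniq_rel <- unique(rel[c("predicate", "subject_class", "subject",
                           "object_class", "object")])
  expect_identical(nrow(g$triples), as.integer(expected + nrow(uniq_rel)))
})

test_that("the gene-centric retrieval query returns the printed identifiers", {
  g <- egfr_entity_graph()
  q <- 'SELECT distinct ?Gene ?property ?hasValue
        WHERE {?Gene a onco:Gene. FILTER regex(str(?Gene), "EGFR")
               ?Gene ?property ?hasValue}'
  res <- run_query(g, q)
  expect_identical(ncol(res), 3L)
  vals <- c("EGFR", "C1414313", "131550", "1956", "2", "PA7360")
  expect_true(all(vals %in% res$hasValue))
  expect_true(all(grepl("EGFR", res$Gene)))
  # a graph without EGFR yields no rows
  ent <- list(Gene = data.frame(Gene_Name = "TP53", UMLS_CUI = "C1",
                                OMIM_ID = "", CIViC_Gene_ID = "",
                                OncoKB_Gene_ID = "", PharmGKB_Gene_ID = "",
                                stringsAsFactors = FALSE))
  expect_identical(nrow(run_query(build_graph(ent), q)), 0L)
})

test_that("queries on an empty graph return zero rows; bad queries error", {
  ge <- build_graph(list())
  expect_identical(nrow(run_query(ge, canned_query("gene_properties"))), 0L)
  expect_error(run_query(ge, "SELEKT ?x WHERE {?x ?y ?z}"),
               "query-syntax")
  expect_error(run_query(ge, "SELECT ?x WHERE {?x ?y}"), "three terms")
  expect_error(run_query(ge,
    'SELECT ?x WHERE {?x ?y ?z FILTER langMatches(lang(?z), "en")}'),
    "FILTER")
})

test_that("canned queries agree with direct relational computation", {
  rel <- derive_relations(two_patient_bundles())
  g <- build_graph(entity_tables(two_patient_bundles()), rel)

  drugs <- run_query(g, canned_query("gene_drugs", gene = "EGFR"))
  expect_identical(drugs$Drug_Name,
                   sort(unique(rel$object[rel$predicate == "MayTargetedBy" &
                                            rel$subject == "EGFR"])))
  expect_identical(drugs$Drug_Name, "osimertinib")  # via patient 1

  dz <- run_query(g, canned_query("gene_diseases", gene = "EGFR"))
  expect_setequal(dz$Disease_Name,
                  unique(rel$subject[rel$predicate == "AssociatedWithGene" &
                                       rel$object == "EGFR"]))

  pats <- run_query(g, canned_query("gene_patients", gene = "TP53"))
  expect_setequal(pats$Patient_ID,
                  unique(rel$subject[rel$predicate == "HasMutGene" &
                                       rel$object == "TP53"]))

  # and on a generated cohort, for every canned query
  relg <- small_relations()
  gg <- small_graph()
  for (gene in c("EGFR", "TP53", "KRAS")) {
    got <- sort(run_query(gg, canned_query("gene_patients", gene))$Patient_ID)
    want <- sort(unique(relg$subject[relg$predicate == "HasMutGene" &
                                       relg$object == gene]))
    expect_identical(got, want)
  }
})

test_that("graph construction is deterministic (IRI stability)", {
  b <- two_patient_bundles()
  g1 <- build_graph(entity_tables(b), derive_relations(b))
  g2 <- build_graph(entity_tables(b), derive_relations(b))
  expect_identical(g1, g2)
})
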