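# Native RDF triple store under the genetic-testing-ontology-derived
# schema: five classes, fixed data properties, nine object properties with
# one (domain, range) pair each.  No server: the graph lives in a
# data.frame, serializes to Turtle / N-Triples, and answers a SPARQL 1.1
# SELECT subset in-process.

RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
XSD_DATE <- "http://www.w3.org/2001/XMLSchema#date"
DEFAULT_NS <- "http://example.org/oncordf/"

#' Schema definition
#'
#' Classes, per-class data properties and object properties (with domain
#' and range) of the knowledge-graph schema.  Property names are
#' bit-exact contract: downstream SPARQL queries address them literally.
#'
#' @return A list with `classes`, `data_properties` (named list of
#'   character vectors) and `object_properties` (data.frame `predicate`,
#'   `domain`, `range`).
#' @export
schema_def <- function() {
  list(
    classes = c("Patient", "Gene", "Variant", "Disease", "Drug"),
    data_properties = list(
      Patient = c("Patient_ID", "Date_of_Birth", "Race", "Ethnicity",
                  "Sex", "Death"),
      Gene = c("Gene_Name", "UMLS_CUI", "OMIM_ID", "CIViC_Gene_ID",
               "OncoKB_Gene_ID", "PharmGKB_Gene_ID"),
      Variant = c("Var_Name", "UMLS_CUI", "ClinVar_ID", "dbSNP_ID",
                  "CIViC_Var_ID", "OncoKB_Var_ID"),
      Disease = c("Disease_Name", "UMLS_CUI", "OMIM_ID", "CIViC_DOID",
                  "OncoKB_Disease_ID", "PharmGKB_Disease_ID",
                  "Stage_At_Diagnosis"),
      Drug = c("Drug_Name", "Brand_Name", "Drug_Category", "UMLS_CUI",
               "NUI", "CIViC_Drug_ID", "OncoKB_Drug_ID",
               "PharmGKB_Drug_ID")),
    object_properties = data.frame(
      predicate = c("HasMutGene", "HasVariant", "HasDisease", "TreatedBy",
                    "AssociatedWithGene", "AssociatedWithVariant",
                    "MayTreatedBy", "MayTargetedBy",
                    "HasContraindicationWith"),
      domain = c("Patient", "Patient", "Patient", "Patient",
                 "Disease", "Gene", "Disease", "Gene", "Drug"),
      range = c("Gene", "Variant", "Disease", "Drug",
                "Gene", "Variant", "Drug", "Drug", "Disease"),
      stringsAsFactors = FALSE)
  )
}

# IRI local identifier: CUI-anchored but human-greppable (gene-centric
# retrieval filters on regex over the stringified IRI, so the symbol must
# appear in it); patients use their Patient_ID verbatim.
iri_local <- function(name, cui = NA_character_) {
  safe <- gsub("^-+|-+$", "", gsub("[^A-Za-z0-9]+", "-", name))
  ifelse(!is.na(cui) & nzchar(cui), paste0(cui, "-", safe), safe)
}

entity_iri <- function(ns, class, local) paste0(ns, class, "/", local)

#' Entity tables for the knowledge graph
#'
#' Builds the per-class entity tables (one row per distinct entity, columns
#' exactly the schema's data properties) from normalized bundles and the
#' dictionary's external identifiers.  `Stage_At_Diagnosis` is left
#' unpopulated: disease entities are shared across patients, so a
#' per-patient stage has no single value (see the methods vignette).
#'
#' @param bundles A `patient_bundles` object.
#' @inheritParams map_term
#' @return Named list of data.frames (`Patient`, `Gene`, `Variant`,
#'   `Disease`, `Drug`).
#' @export
entity_tables <- function(bundles, dict = default_dictionary()) {
  p <- bundles$patients
  patient <- data.frame(
    Patient_ID = p$patient_id,
    Date_of_Birth = as_iso_date(p$dob),
    Race = p$race, Ethnicity = p$ethnicity, Sex = p$sex,
    Death = ifelse(is.na(p$death_date), "", as_iso_date(p$death_date)),
    stringsAsFactors = FALSE)

  dtab <- dict$table
  pick <- function(name, class, col) {
    i <- match(fold_term(name), ifelse(dtab$entity_class == class,
                                       fold_term(dtab$preferred), NA))
    ifelse(is.na(i), "", dtab[[col]][i])
  }
  f <- bundles$findings
  genes <- sort(unique(f$gene))
  gene <- data.frame(
    Gene_Name = genes,
    UMLS_CUI = pick(genes, "gene", "cui"),
    OMIM_ID = pick(genes, "gene", "omim_id"),
    CIViC_Gene_ID = pick(genes, "gene", "civic_id"),
    OncoKB_Gene_ID = pick(genes, "gene", "oncokb_id"),
    PharmGKB_Gene_ID = pick(genes, "gene", "pharmgkb_id"),
    stringsAsFactors = FALSE)

  vf <- f[!duplicated(f$variant), , drop = FALSE]
  variant <- data.frame(
    Var_Name = vf$variant,
    UMLS_CUI = ifelse(is.na(vf$variant_cui), "", vf$variant_cui),
    ClinVar_ID = pick(vf$variant, "variant", "clinvar_id"),
    dbSNP_ID = pick(vf$variant, "variant", "dbsnp_id"),
    CIViC_Var_ID = pick(vf$variant, "variant", "civic_id"),
    OncoKB_Var_ID = pick(vf$variant, "variant", "oncokb_id"),
    stringsAsFactors = FALSE)
  variant <- variant[order(variant$Var_Name), , drop = FALSE]

  dz <- bundles$diseases[!bundles$diseases$superseded, , drop = FALSE]
  dzn <- sort(unique(dz$disease))
  disease <- data.frame(
    Disease_Name = dzn,
    UMLS_CUI = pick(dzn, "disease", "cui"),
    OMIM_ID = pick(dzn, "disease", "omim_id"),
    CIViC_DOID = pick(dzn, "disease", "doid"),
    OncoKB_Disease_ID = pick(dzn, "disease", "oncokb_id"),
    PharmGKB_Disease_ID = pick(dzn, "disease", "pharmgkb_id"),
    Stage_At_Diagnosis = "",
    stringsAsFactors = FALSE)

  drn <- sort(unique(bundles$drugs$drug))
  brand <- vapply(drn, function(d) dict_brand_of(dict, d), character(1))
  drug <- data.frame(
    Drug_Name = drn,
    Brand_Name = unname(brand),
    Drug_Category = pick(drn, "drug", "drug_category"),
    UMLS_CUI = pick(drn, "drug", "cui"),
    NUI = pick(drn, "drug", "nui"),
    CIViC_Drug_ID = pick(drn, "drug", "civic_id"),
    OncoKB_Drug_ID = pick(drn, "drug", "oncokb_id"),
    PharmGKB_Drug_ID = pick(drn, "drug", "pharmgkb_id"),
    stringsAsFactors = FALSE)

  lapply(list(Patient = patient, Gene = gene, Variant = variant,
              Disease = disease, Drug = drug),
         function(t) { rownames(t) <- NULL; t })
}

entity_name_col <- c(Patient = "Patient_ID", Gene = "Gene_Name",
                     Variant = "Var_Name", Disease = "Disease_Name",
                     Drug = "Drug_Name")

#' Materialize the RDF knowledge graph
#'
#' Per entity: one class-typing triple plus one triple per populated data
#' property.  Per relation: exactly one object-property triple (relations
#' are deduplicated on subject/predicate/object across patients, since a
#' triple set cannot hold copies).  IRIs are deterministic:
#' `namespace + Class + "/" + local`, where local is the entity's CUI
#' joined with a sanitized name (patients: `Patient_ID`).
#'
#' @param entities Named list of per-class entity tables
#'   ([entity_tables()]).
#' @param relations Relation data.frame ([derive_relations()]).
#' @param schema A [schema_def()].
#' @param namespace Base IRI.
#' @return An object of class `rdf_graph`.
#' @export
build_graph <- function(entities, relations = NULL, schema = schema_def(),
                        namespace = DEFAULT_NS) {
  trip <- list()
  iri_of <- list()  # class -> named map entity name -> IRI
  for (cls in schema$classes) {
    tab <- entities[[cls]]
    if (is.null(tab) || nrow(tab) == 0) {
      iri_of[[cls]] <- character(0)
      next
    }
    props <- schema$data_properties[[cls]]
    name <- tab[[entity_name_col[[cls]]]]
    cui <- if (cls == "Patient") NA_character_ else tab[["UMLS_CUI"]]
    local <- if (cls == "Patient") name else iri_local(name, cui)
    iri <- entity_iri(namespace, cls, local)
    iri_of[[cls]] <- stats::setNames(iri, fold_term(name))
    trip[[length(trip) + 1]] <- data.frame(
      s = iri, p = RDF_TYPE, o = paste0(namespace, cls),
      o_type = "iri", dtype = NA_character_, stringsAsFactors = FALSE)
    for (pr in props) {
      v <- as.character(tab[[pr]])
      keep <- !is.na(v) & nzchar(v)
      if (!any(keep)) next
      trip[[length(trip) + 1]] <- data.frame(
        s = iri[keep], p = paste0(namespace, pr), o = v[keep],
        o_type = "literal",
        dtype = if (pr %in% c("Date_of_Birth", "Death"))
          XSD_DATE else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(relations) && nrow(relations)) {
    op <- schema$object_properties
    bad_pred <- setdiff(unique(relations$predicate), op$predicate)
    if (length(bad_pred)) {
      stop("unknown object property: ", paste(bad_pred, collapse = ", "),
           call. = FALSE)
    }
    s_iri <- mapply(function(cls, nm) {
      iri_of[[cls]][fold_term(nm)] %||% NA_character_
    }, relations$subject_class, relations$subject)
    o_iri <- mapply(function(cls, nm) {
      iri_of[[cls]][fold_term(nm)] %||% NA_character_
    }, relations$object_class, relations$object)
    miss <- which(is.na(s_iri) | is.na(o_iri))
    if (length(miss)) {
      i <- miss[1]
      endpoint <- if (is.na(s_iri[i])) relations$subject[i] else
        relations$object[i]
      stop(sprintf("referential integrity: relation endpoint '%s' (%s) absent from entity tables",
                   endpoint, relations$predicate[i]), call. = FALSE)
    }
    trip[[length(trip) + 1]] <- data.frame(
      s = unname(s_iri), p = paste0(namespace, relations$predicate),
      o = unname(o_iri), o_type = "iri", dtype = NA_character_,
      stringsAsFactors = FALSE)
  }
  triples <- if (length(trip)) do.call(rbind, trip) else
    empty_df(c(s = "character", p = "character", o = "character",
               o_type = "character", dtype = "character"))
  triples <- triples[!duplicated(triples[c("s", "p", "o", "o_type")]), ,
                     drop = FALSE]
  triples <- triples[order(triples$s, triples$p, triples$o), , drop = FALSE]
  rownames(triples) <- NULL
  structure(list(triples = triples, namespace = namespace),
            class = "rdf_graph")
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat("<rdf_graph> ", nrow(x$triples), " triples, namespace <",
      x$namespace, ">\n", sep = "")
  invisible(x)
}

#' Triple counts by class
#'
#' A triple counts toward class C when its subject is typed C (object-
#' property triples count toward the subject's class only).  `total` is the
#' size of the triple set.
#'
#' @param graph An `rdf_graph`.
#' @return A list with `by_class` (named integer vector) and `total`.
#' @export
count_by_class <- function(graph) {
  t <- graph$triples
  typing <- t[t$p == RDF_TYPE, , drop = FALSE]
  cls <- sub(paste0("^", graph$namespace), "", typing$o)
  class_of <- stats::setNames(cls, typing$s)
  subj_cls <- class_of[t$s]
  by_class <- table(factor(subj_cls, levels = schema_def()$classes))
  list(by_class = stats::setNames(as.integer(by_class), names(by_class)),
       total = nrow(t))
}

## ---- serialization ---------------------------------------------------

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

#' Serialize / parse an RDF graph
#'
#' Standard flat-file serializations: N-Triples (`format = "ntriples"`,
#' full IRIs, UTF-8) and a line-oriented Turtle subset (`format =
#' "turtle"`, `@prefix` declarations, `a` for the typing predicate,
#' prefixed predicate names).  `read_graph(write_graph(g))` restores the
#' triple set exactly, in either format.
#'
#' @param graph An `rdf_graph`.
#' @param path Output / input file path.
#' @param format `"turtle"` or `"ntriples"`; for `read_graph` the default
#'   infers from the file extension (`.ttl` / `.nt`).
#' @return `write_graph` returns `path` invisibly; `read_graph` an
#'   `rdf_graph`.
#' @export
write_graph <- function(graph, path, format = c("turtle", "ntriples")) {
  format <- match.arg(format)
  t <- graph$triples
  ns <- graph$namespace
  con <- file(path, open = "wb")
  on.exit(close(con))
  emit <- function(lines) writeLines(lines, con, useBytes = TRUE)
  obj_nt <- function(o, o_type, dtype) {
    ifelse(o_type == "iri", paste0("<", o, ">"),
           paste0("\"", escape_literal(o), "\"",
                  ifelse(is.na(dtype), "", paste0("^^<", dtype, ">"))))
  }
  if (format == "ntriples") {
    if (nrow(t)) {
      emit(enc2utf8(paste0("<", t$s, "> <", t$p, "> ",
                           obj_nt(t$o, t$o_type, t$dtype), " .")))
    } else emit(character(0))
  } else {
    emit(c(paste0("@prefix onco: <", ns, "> ."),
           "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
           "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
           ""))
    if (nrow(t)) {
      pred <- ifelse(t$p == RDF_TYPE, "a",
              ifelse(startsWith(t$p, ns),
                     paste0("onco:", substring(t$p, nchar(ns) + 1)),
                     paste0("<", t$p, ">")))
      obj <- ifelse(t$o_type == "iri", paste0("<", t$o, ">"),
             paste0("\"", escape_literal(t$o), "\"",
                    ifelse(is.na(t$dtype), "",
                    ifelse(t$dtype == XSD_DATE, "^^xsd:date",
                           paste0("^^<", t$dtype, ">")))))
      emit(enc2utf8(paste0("<", t$s, "> ", pred, " ", obj, " .")))
    }
  }
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.nt$", path)) "ntriples" else "turtle"
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  prefixes <- c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
                xsd = "http://www.w3.org/2001/XMLSchema#")
  ns <- DEFAULT_NS
  rows <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (grepl("^@prefix", line)) {
      m <- regmatches(line,
        regexec("^@prefix[[:space:]]+([A-Za-z][A-Za-z0-9_-]*):[[:space:]]*<([^>]*)>", line))[[1]]
      if (length(m) != 3) {
        stop(sprintf("RDF parse error at %s line %d: bad @prefix", path, i),
             call. = FALSE)
      }
      prefixes[m[2]] <- m[3]
      if (m[2] == "onco") ns <- m[3]
      next
    }
    toks <- tokenize_terms(line, path, i)
    if (length(toks) < 4 || toks[[length(toks)]]$kind != "dot") {
      stop(sprintf("RDF parse error at %s line %d: expected 's p o .'",
                   path, i), call. = FALSE)
    }
    toks <- toks[-length(toks)]
    if (length(toks) != 3) {
      stop(sprintf("RDF parse error at %s line %d: expected 3 terms, got %d",
                   path, i, length(toks)), call. = FALSE)
    }
    resolve <- function(tk) {
      if (tk$kind == "iri") return(list(v = tk$value, type = "iri"))
      if (tk$kind == "a") return(list(v = RDF_TYPE, type = "iri"))
      if (tk$kind == "pname") {
        base <- prefixes[tk$prefix]
        if (is.na(base)) {
          stop(sprintf("RDF parse error at %s line %d: unknown prefix '%s'",
                       path, i, tk$prefix), call. = FALSE)
        }
        return(list(v = paste0(base, tk$local), type = "iri"))
      }
      if (tk$kind == "literal") {
        dt <- tk$dtype
        if (!is.na(dt)) {
          if (startsWith(dt, "<")) {
            dt <- substr(dt, 2, nchar(dt) - 1)
          } else {
            pr <- sub(":.*$", "", dt)
            if (is.na(prefixes[pr])) {
              stop(sprintf("RDF parse error at %s line %d: unknown prefix '%s'",
                           path, i, pr), call. = FALSE)
            }
            dt <- paste0(prefixes[pr], sub("^[^:]*:", "", dt))
          }
        }
        return(list(v = tk$value, type = "literal", dtype = dt))
      }
      stop(sprintf("RDF parse error at %s line %d: unexpected token",
                   path, i), call. = FALSE)
    }
    s <- resolve(toks[[1]]); p <- resolve(toks[[2]]); o <- resolve(toks[[3]])
    if (s$type != "iri" || p$type != "iri") {
      stop(sprintf("RDF parse error at %s line %d: subject/predicate must be IRIs",
                   path, i), call. = FALSE)
    }
    rows[[length(rows) + 1]] <- data.frame(
      s = s$v, p = p$v, o = o$v, o_type = o$type,
      dtype = if (o$type == "literal") (o$dtype %||% NA_character_) else
        NA_character_,
      stringsAsFactors = FALSE)
  }
  triples <- if (length(rows)) do.call(rbind, rows) else
    empty_df(c(s = "character", p = "character", o = "character",
               o_type = "character", dtype = "character"))
  triples <- triples[!duplicated(triples[c("s", "p", "o", "o_type")]), ,
                     drop = FALSE]
  triples <- triples[order(triples$s, triples$p, triples$o), , drop = FALSE]
  rownames(triples) <- NULL
  structure(list(triples = triples, namespace = ns), class = "rdf_graph")
}

# Tokenizer shared by the serializer's parser and the SPARQL engine.
# Recognizes <iri>, prefixed names, "literals"(^^type)?, ?variables, 'a',
# '.', '{', '}'.
tokenize_terms <- function(text, path = "<query>", lineno = NA) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  err <- function(msg) {
    stop(sprintf("parse error at %s line %s, char %d: %s", path,
                 as.character(lineno), i, msg), call. = FALSE)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    rest <- substring(text, i)
    if (ch == "<") {
      m <- regmatches(rest, regexec("^<([^>]*)>", rest))[[1]]
      if (!length(m)) err("unterminated IRI")
      toks[[length(toks) + 1]] <- list(kind = "iri", value = m[2])
      i <- i + nchar(m[1])
    } else if (ch == "\"") {
      m <- regmatches(rest,
        regexec("^\"((?:[^\"\\\\]|\\\\.)*)\"(\\^\\^(<[^>]*>|[A-Za-z][A-Za-z0-9_-]*:[A-Za-z0-9_]+))?",
                rest, perl = TRUE))[[1]]
      if (!length(m)) err("unterminated literal")
      # dtype kept verbatim ("<iri>" or "prefix:local"); resolved later
      dt <- if (nzchar(m[3])) sub("^\\^\\^", "", m[3]) else NA_character_
      toks[[length(toks) + 1]] <- list(kind = "literal",
                                       value = unescape_literal(m[2]),
                                       dtype = dt)
      i <- i + nchar(m[1])
    } else if (ch == "?") {
      m <- regmatches(rest, regexec("^\\?([A-Za-z_][A-Za-z0-9_]*)", rest))[[1]]
      if (!length(m)) err("bad variable name")
      toks[[length(toks) + 1]] <- list(kind = "var", value = m[2])
      i <- i + nchar(m[1])
    } else if (ch == ".") {
      toks[[length(toks) + 1]] <- list(kind = "dot")
      i <- i + 1L
    } else if (ch == "{" || ch == "}") {
      toks[[length(toks) + 1]] <- list(kind = ch)
      i <- i + 1L
    } else {
      # local names may contain interior dots but a trailing dot is the
      # statement terminator
      m <- regmatches(rest,
        regexec("^([A-Za-z][A-Za-z0-9_-]*):([A-Za-z0-9_](?:[A-Za-z0-9_.-]*[A-Za-z0-9_-])?)",
                rest, perl = TRUE))[[1]]
      if (length(m)) {
        toks[[length(toks) + 1]] <- list(kind = "pname", prefix = m[2],
                                         local = m[3])
        i <- i + nchar(m[1])
      } else if (grepl("^a([[:space:]]|$|[.<?])", rest)) {
        toks[[length(toks) + 1]] <- list(kind = "a")
        i <- i + 1L
      } else {
        err(paste0("unexpected character '", ch, "'"))
      }
    }
  }
  toks
}
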