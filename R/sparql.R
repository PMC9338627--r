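# In-process SPARQL 1.1 SELECT subset: basic graph patterns (variables in
# any position, including the predicate), DISTINCT, FILTER regex over
# stringified terms, PREFIX declarations, and 'a' for rdf:type.  The
# prefix bound to the graph's own namespace is predeclared as `onco:`.

#' Run a SPARQL SELECT query
#'
#' Supported grammar:
#' \preformatted{
#'   (PREFIX name: <iri>)*
#'   SELECT [DISTINCT] (?var... | *)
#'   WHERE { pattern ('.' pattern)* FILTER regex(str(?var), "re" [, "i"]) ... }
#' }
#' Each pattern is three terms; a term is `?var`, `a`, `prefix:local`,
#' `<iri>` or a quoted literal.  `FILTER regex` applies to the string form
#' of a bound term (the IRI text, or the literal value).  Patterns are
#' joined on shared variables; results are projected onto the `SELECT`
#' variables, deduplicated under `DISTINCT`.
#'
#' @param graph An `rdf_graph`.
#' @param sparql Query string.
#' @return A data.frame with one column per selected variable; bound IRIs
#'   and literal values as strings.
#' @examples
#' \dontrun{
#' run_query(g, 'SELECT distinct ?Gene ?property ?hasValue
#'   WHERE {?Gene a onco:Gene. FILTER regex(str(?Gene), "EGFR")
#'          ?Gene ?property ?hasValue}')
#' }
#' @export
run_query <- function(graph, sparql) {
  stopifnot(inherits(graph, "rdf_graph"))
  q <- parse_sparql(sparql, graph$namespace)
  t <- graph$triples
  bindings <- NULL  # data.frame of variable bindings; NULL = unit
  for (pat in q$patterns) {
    cand <- t
    # constant positions restrict candidates
    sel <- rep(TRUE, nrow(cand))
    for (pos in c("s", "p", "o")) {
      term <- pat[[pos]]
      if (term$kind == "const_iri") {
        sel <- sel & cand[[pos]] == term$value &
          (pos != "o" | cand$o_type == "iri")
      } else if (term$kind == "const_lit") {
        sel <- sel & cand[[pos]] == term$value &
          (pos != "o" | cand$o_type == "literal")
      }
    }
    cand <- cand[sel, , drop = FALSE]
    vnames <- character(0)
    vcols <- list()
    for (pos in c("s", "p", "o")) {
      term <- pat[[pos]]
      if (term$kind == "var") {
        vnames <- c(vnames, term$value)
        vcols[[length(vcols) + 1]] <- cand[[pos]]
      }
    }
    if (!length(vcols)) {
      # pattern with no variables: acts as an existence check
      if (!nrow(cand)) {
        bindings <- data.frame()[0, , drop = FALSE]
        break
      }
      next
    }
    # a variable repeated within one pattern must bind consistently
    keep <- rep(TRUE, nrow(cand))
    for (nm in unique(vnames[duplicated(vnames)])) {
      idx <- which(vnames == nm)
      for (j in idx[-1]) keep <- keep & vcols[[idx[1]]] == vcols[[j]]
    }
    first <- !duplicated(vnames)
    step <- as.data.frame(stats::setNames(
      lapply(which(first), function(j) vcols[[j]][keep]), vnames[first]),
      stringsAsFactors = FALSE, check.names = FALSE)
    step <- unique(step)
    if (is.null(bindings)) {
      bindings <- step
    } else {
      common <- intersect(names(bindings), names(step))
      if (length(common)) {
        bindings <- merge(bindings, step, by = common)
      } else {
        bindings <- merge(bindings, step, by = NULL)
      }
    }
    if (!nrow(bindings)) break
  }
  if (is.null(bindings)) {
    bindings <- data.frame(row.names = 1)[, 0, drop = FALSE]
  }
  for (f in q$filters) {
    if (!f$var %in% names(bindings)) {
      stop("query-syntax error: FILTER references unbound variable ?",
           f$var, call. = FALSE)
    }
    keep <- grepl(f$regex, bindings[[f$var]],
                  ignore.case = isTRUE(f$ignore_case))
    bindings <- bindings[keep, , drop = FALSE]
  }
  vars <- q$select
  if (identical(vars, "*")) vars <- names(bindings)
  missing <- setdiff(vars, names(bindings))
  for (v in missing) bindings[[v]] <- rep(NA_character_, nrow(bindings))
  out <- bindings[, vars, drop = FALSE]
  if (q$distinct) out <- unique(out)
  rownames(out) <- NULL
  out
}

parse_sparql <- function(sparql, namespace) {
  if (!is.character(sparql) || length(sparql) != 1 || !nzchar(trimws(sparql))) {
    stop("query-syntax error: query must be a non-empty string",
         call. = FALSE)
  }
  txt <- gsub("[\r\n]+", " ", sparql)
  prefixes <- c(onco = namespace,
                rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
                xsd = "http://www.w3.org/2001/XMLSchema#")
  # PREFIX declarations
  repeat {
    m <- regmatches(txt, regexec(
      "^[[:space:]]*PREFIX[[:space:]]+([A-Za-z][A-Za-z0-9_-]*):[[:space:]]*<([^>]*)>[[:space:]]*",
      txt, ignore.case = TRUE))[[1]]
    if (!length(m)) break
    prefixes[m[2]] <- m[3]
    txt <- substring(txt, nchar(m[1]) + 1)
  }
  m <- regmatches(txt, regexec(
    "^[[:space:]]*SELECT[[:space:]]+(DISTINCT[[:space:]]+)?(.*?)[[:space:]]*WHERE[[:space:]]*\\{(.*)\\}[[:space:]]*$",
    txt, ignore.case = TRUE))[[1]]
  if (!length(m)) {
    stop("query-syntax error: expected 'SELECT ... WHERE { ... }'",
         call. = FALSE)
  }
  distinct <- nzchar(m[2])
  sel_txt <- trimws(m[3])
  body <- m[4]
  if (sel_txt == "*") {
    select <- "*"
  } else {
    sv <- regmatches(sel_txt, gregexpr("\\?[A-Za-z_][A-Za-z0-9_]*", sel_txt))[[1]]
    if (!length(sv) || nchar(gsub("[[:space:]]|\\?[A-Za-z_][A-Za-z0-9_]*",
                                  "", sel_txt)) > 0) {
      stop("query-syntax error: bad SELECT clause '", sel_txt, "'",
           call. = FALSE)
    }
    select <- sub("^\\?", "", sv)
  }
  # extract FILTER regex(...) clauses, then tokenize the remaining patterns
  filters <- list()
  repeat {
    fm <- regmatches(body, regexec(
      "FILTER[[:space:]]*regex[[:space:]]*\\([[:space:]]*str[[:space:]]*\\([[:space:]]*\\?([A-Za-z_][A-Za-z0-9_]*)[[:space:]]*\\)[[:space:]]*,[[:space:]]*\"([^\"]*)\"[[:space:]]*(,[[:space:]]*\"([^\"]*)\")?[[:space:]]*\\)[[:space:]]*\\.?",
      body, ignore.case = TRUE))[[1]]
    if (!length(fm)) break
    filters[[length(filters) + 1]] <- list(
      var = fm[2], regex = fm[3],
      ignore_case = grepl("i", fm[5], fixed = TRUE))
    body <- sub(fm[1], "", body, fixed = TRUE)
  }
  if (grepl("FILTER", body, ignore.case = TRUE)) {
    stop("query-syntax error: only 'FILTER regex(str(?var), \"re\")' is supported",
         call. = FALSE)
  }
  toks <- tokenize_terms(body, "<query>", NA)
  toks <- Filter(function(tk) tk$kind != "dot", toks)
  if (length(toks) %% 3 != 0) {
    stop("query-syntax error: graph patterns must have three terms each",
         call. = FALSE)
  }
  to_term <- function(tk) {
    switch(tk$kind,
      var = list(kind = "var", value = tk$value),
      a = list(kind = "const_iri", value = RDF_TYPE),
      iri = list(kind = "const_iri", value = tk$value),
      pname = {
        base <- prefixes[tk$prefix]
        if (is.na(base)) {
          stop("query-syntax error: unknown prefix '", tk$prefix, "'",
               call. = FALSE)
        }
        list(kind = "const_iri", value = paste0(base, tk$local))
      },
      literal = list(kind = "const_lit", value = tk$value),
      stop("query-syntax error: unexpected token in pattern", call. = FALSE))
  }
  patterns <- lapply(seq_len(length(toks) / 3), function(k) {
    list(s = to_term(toks[[3 * k - 2]]),
         p = to_term(toks[[3 * k - 1]]),
         o = to_term(toks[[3 * k]]))
  })
  list(select = select, distinct = distinct, patterns = patterns,
       filters = filters)
}

#' Canned gene-centric queries
#'
#' Ready-made SPARQL strings for the bundled retrieval patterns:
#' `"gene_properties"` (all data-property values of genes whose IRI matches
#' the symbol — the gene-centric retrieval table), `"gene_diseases"`
#' (diseases associated with the gene), `"gene_drugs"` (drugs the gene may
#' be targeted by) and `"gene_patients"` (patients carrying a mutation in
#' the gene).
#'
#' @param name Query name (see above).
#' @param gene Gene symbol interpolated into the query.
#' @return A SPARQL string for [run_query()].
#' @export
canned_query <- function(name = c("gene_properties", "gene_diseases",
                                  "gene_drugs", "gene_patients"),
                         gene = "EGFR") {
  name <- match.arg(name)
  switch(name,
    gene_properties = sprintf(
      'SELECT distinct ?Gene ?property ?hasValue
       WHERE {?Gene a onco:Gene. FILTER regex(str(?Gene), "%s")
              ?Gene ?property ?hasValue}', gene),
    gene_diseases = sprintf(
      'SELECT distinct ?Disease_Name
       WHERE {?g onco:Gene_Name "%s" . ?d onco:AssociatedWithGene ?g .
              ?d onco:Disease_Name ?Disease_Name}', gene),
    gene_drugs = sprintf(
      'SELECT distinct ?Drug_Name
       WHERE {?g onco:Gene_Name "%s" . ?g onco:MayTargetedBy ?r .
              ?r onco:Drug_Name ?Drug_Name}', gene),
    gene_patients = sprintf(
      'SELECT distinct ?Patient_ID
       WHERE {?g onco:Gene_Name "%s" . ?p onco:HasMutGene ?g .
              ?p onco:Patient_ID ?Patient_ID}', gene))
}
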