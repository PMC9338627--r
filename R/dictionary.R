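#' Read a concept dictionary
#'
#' The dictionary is the package's stand-in for a terminology service: a
#' delimited table mapping surface forms of genes, variants, diseases and
#' drugs to preferred terms, UMLS-style concept identifiers (CUIs) and
#' external knowledgebase identifiers.  Lookups are exact after case-folding
#' and trimming of surrounding punctuation; no fuzzy matching is attempted.
#'
#' Required columns: `entity_class` (one of `gene`, `variant`, `disease`,
#' `drug`), `surface`, `preferred`, `cui`, `omim_id`, `civic_id`,
#' `oncokb_id`, `pharmgkb_id`, `clinvar_id`, `dbsnp_id`, `nui`, `doid`,
#' `drug_category`, `brand_of`, `target_genes` (pipe-separated gene symbols
#' a drug is annotated as targeting), `is_cancer` (`TRUE`/`FALSE` for
#' disease rows).  Empty strings denote missing values.
#'
#' @param path Path to a tab-delimited dictionary file.
#' @return An object of class `concept_dictionary`: the dictionary table
#'   plus a precomputed case-folded lookup key.
#' @export
read_concept_dictionary <- function(path) {
  if (!file.exists(path)) {
    stop("dictionary file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  required <- c("entity_class", "surface", "preferred", "cui", "omim_id",
                "civic_id", "oncokb_id", "pharmgkb_id", "clinvar_id",
                "dbsnp_id", "nui", "doid", "drug_category", "brand_of",
                "target_genes", "is_cancer")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("dictionary file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(!tab$entity_class %in% c("gene", "variant", "disease", "drug"))
  if (length(bad)) {
    stop(sprintf("dictionary parse error at %s line %d: unknown entity_class '%s'",
                 path, bad[1] + 1L, tab$entity_class[bad[1]]), call. = FALSE)
  }
  tab$key <- fold_term(tab$surface)
  dup <- duplicated(paste(tab$entity_class, tab$key))
  if (any(dup)) {
    stop(sprintf("dictionary parse error at %s line %d: duplicate surface '%s'",
                 path, which(dup)[1] + 1L, tab$surface[which(dup)[1]]),
         call. = FALSE)
  }
  # every brand must resolve to an existing chemical entry
  drugs <- tab[tab$entity_class == "drug", ]
  br <- drugs$brand_of[drugs$brand_of != ""]
  orphan <- setdiff(fold_term(br), drugs$key)
  if (length(orphan)) {
    stop("dictionary brand_of target(s) missing chemical entry: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  structure(list(table = tab, path = path), class = "concept_dictionary")
}

#' Bundled concept dictionary
#'
#' Loads the curated dictionary fixture shipped with the package (~34 genes,
#' ~42 drugs with brand names and HemOnc-style categories, ~20 diseases,
#' hotspot variants for the simulated gene universe).  Only the EGFR gene
#' identifiers are real published values; all other identifiers are
#' synthetic placeholders in realistic formats.
#'
#' @return A `concept_dictionary`.
#' @export
default_dictionary <- function() {
  if (is.null(.oncordf_env$dict)) {
    path <- system.file("extdata", "concept_dictionary.tsv",
                        package = "oncordf", mustWork = TRUE)
    .oncordf_env$dict <- read_concept_dictionary(path)
  }
  .oncordf_env$dict
}

.oncordf_env <- new.env(parent = emptyenv())

#' @export
print.concept_dictionary <- function(x, ...) {
  cls <- table(x$table$entity_class)
  cat("<concept_dictionary> ", nrow(x$table), " entries (",
      paste(sprintf("%s: %d", names(cls), as.integer(cls)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# internal: rows of one entity class
dict_class <- function(dict, entity_class) {
  dict$table[dict$table$entity_class == entity_class, , drop = FALSE]
}

# internal: chemical-name rows only (brand rows excluded)
dict_chemicals <- function(dict) {
  d <- dict_class(dict, "drug")
  d[d$brand_of == "", , drop = FALSE]
}

# internal: brand name for a chemical, "" if none
dict_brand_of <- function(dict, chemical) {
  d <- dict_class(dict, "drug")
  hit <- d$surface[d$brand_of == chemical]
  if (length(hit)) hit[1] else ""
}

# internal: dictionary-covered variant surfaces grouped by gene symbol
# (the gene symbol is the first token of the surface form)
dict_variant_forms <- function(dict) {
  v <- dict_class(dict, "variant")
  if (!nrow(v)) return(list())
  gene <- sub(" .*$", "", v$surface)
  split(v$surface, gene)
}
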