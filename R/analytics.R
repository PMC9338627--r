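# Use-case analytics: association-rule mining of gene-drug co-occurrence
# (support/confidence over per-patient transactions) and Kaplan-Meier
# survival stratified by mutation status and stage.

#' Build the per-patient transaction set
#'
#' Each patient is one transaction; the item set is the patient's mutated
#' genes plus every drug prescribed in `(test, test + window]`.  Drugs are
#' deliberately NOT restricted to targeted therapies here — co-prescription
#' of chemotherapy and immunotherapy is exactly what the confidence ranking
#' is meant to expose.  Patients with empty item sets still count toward
#' the transaction total.
#'
#' @param bundles A `patient_bundles` object.
#' @param window_days Post-test window in days (default 365).
#' @return An object of class `transaction_set`: `transactions` (named list
#'   patient_id -> character item set) and `n` (total transactions).
#' @export
build_transactions <- function(bundles, window_days = 365) {
  stopifnot(inherits(bundles, "patient_bundles"))
  pts <- bundles$patients
  items <- stats::setNames(
    rep(list(character(0)), nrow(pts)), pts$patient_id)
  f <- bundles$findings
  if (nrow(f)) {
    gsets <- split(f$gene, f$patient_id)
    items[names(gsets)] <- lapply(gsets, unique)
  }
  dr <- bundles$drugs
  if (nrow(dr)) {
    t_r <- pts$index_test_date[match(dr$patient_id, pts$patient_id)]
    post <- !is.na(t_r) & !is.na(dr$date) & dr$date > t_r &
      dr$date <= t_r + window_days
    dsets <- split(dr$drug[post], dr$patient_id[post])
    for (pid in names(dsets)) {
      items[[pid]] <- unique(c(items[[pid]], dsets[[pid]]))
    }
  }
  structure(list(transactions = items, n = length(items)),
            class = "transaction_set")
}

#' @export
print.transaction_set <- function(x, ...) {
  sizes <- lengths(x$transactions)
  cat("<transaction_set> ", x$n, " transactions, ",
      length(unique(unlist(x$transactions))), " distinct items, mean size ",
      round(mean(sizes), 2), "\n", sep = "")
  invisible(x)
}

#' Association-rule support and confidence
#'
#' `support(X)` is the proportion of transactions containing every item of
#' `X`; `confidence(X, Y) = support(X union Y) / support(X)`.  Requesting
#' the confidence of a rule whose antecedent never occurs is an error (the
#' rule is undefined, not zero).
#'
#' @param X,Y Character vectors of items (genes and/or drugs).
#' @param T A `transaction_set`.
#' @return A proportion in `[0, 1]`.
#' @export
support <- function(X, T) {
  stopifnot(inherits(T, "transaction_set"))
  if (T$n == 0) {
    stop("support is undefined on an empty transaction set", call. = FALSE)
  }
  X <- unique(as.character(X))
  hits <- vapply(T$transactions, function(t) all(X %in% t), logical(1))
  sum(hits) / T$n
}

#' @rdname support
#' @export
confidence <- function(X, Y, T) {
  sX <- support(X, T)
  if (sX == 0) {
    stop("undefined rule: support of the antecedent is 0", call. = FALSE)
  }
  support(union(X, Y), T) / sX
}

#' Rank drugs by confidence given a gene
#'
#' Computes `confidence({gene}, {drug})` for every drug item in the
#' transaction set, sorts descending with lexicographic tie-breaking (for
#' run-to-run determinism), and returns the top `k`.
#'
#' @param gene Gene symbol (must have positive support).
#' @param T A `transaction_set`.
#' @param k Number of drugs to return (default 10).
#' @param drug_items Optional character vector restricting the candidate
#'   items; by default every item that is not a gene item is treated as a
#'   drug.
#' @return A data.frame `drug`, `support`, `confidence`, sorted.
#' @export
rank_drugs_for_gene <- function(gene, T, k = 10, drug_items = NULL) {
  stopifnot(inherits(T, "transaction_set"))
  if (T$n == 0 || support(gene, T) == 0) {
    stop("undefined rule: gene '", gene, "' has no support", call. = FALSE)
  }
  if (is.null(drug_items)) {
    # items whose surface is a known dictionary drug; fall back to
    # "everything that is not the query gene" for foreign item vocabularies
    all_items <- unique(unlist(T$transactions))
    chem <- dict_chemicals(default_dictionary())
    drug_items <- intersect(all_items, chem$preferred)
    if (!length(drug_items)) drug_items <- setdiff(all_items, gene)
  }
  if (!length(drug_items)) {
    return(data.frame(drug = character(0), support = numeric(0),
                      confidence = numeric(0)))
  }
  has_gene <- vapply(T$transactions, function(t) gene %in% t, logical(1))
  n_gene <- sum(has_gene)
  conf <- vapply(drug_items, function(d) {
    sum(vapply(T$transactions[has_gene], function(t) d %in% t,
               logical(1))) / n_gene
  }, numeric(1))
  supp <- vapply(drug_items, function(d) {
    sum(vapply(T$transactions, function(t) d %in% t, logical(1))) / T$n
  }, numeric(1))
  ord <- order(-conf, drug_items)
  out <- data.frame(drug = drug_items[ord], support = supp[ord],
                    confidence = conf[ord], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  utils::head(out, k)
}

#' Kaplan-Meier product-limit estimator
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`, with
#' censored observations leaving the risk set after their time (a censored
#' time equal to an event time is still at risk for that event, the usual
#' convention).
#'
#' @param records Data.frame with columns `time` (days, >= 0) and `event`
#'   (1 = death observed, 0 = censored).
#' @return An object of class `km_curve`: a data.frame `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` over the distinct observed times, plus
#'   a `median` attribute (smallest time with `S <= 0.5`, `NA` if never
#'   reached).
#' @export
km_curve <- function(records) {
  time <- as.numeric(records$time)
  event <- as.integer(records$event)
  if (any(is.na(time)) || any(time < 0)) {
    stop("survival times must be non-negative and non-missing",
         call. = FALSE)
  }
  ut <- sort(unique(time))
  n <- length(time)
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1L), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0L), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  tab <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, surv = surv)
  med <- if (any(surv <= 0.5)) ut[which(surv <= 0.5)[1]] else NA_real_
  structure(tab, class = c("km_curve", "data.frame"), median = med, n = n)
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> n = ", attr(x, "n"), ", ", sum(x$n_event),
      " events, median = ", attr(x, "median"), "\n", sep = "")
  NextMethod()
}

#' Survival median of a curve
#' @param curve A `km_curve`.
#' @return Smallest time with `S(t) <= 0.5`, or `NA`.
#' @export
km_median <- function(curve) attr(curve, "median")

#' Mutation- and stage-stratified survival
#'
#' For patients carrying the given disease: the index date is the diagnosis
#' date; time is death (event) or last contact (censored) minus index;
#' groups are gene-mutant vs wild-type crossed with stage.  Patients
#' without a usable diagnosis date are dropped.
#'
#' @param bundles A `patient_bundles` object.
#' @param gene Gene symbol defining mutant status.
#' @param disease Disease name (normalized through the dictionary).
#' @inheritParams map_term
#' @return A list with `curves` (named list of `km_curve`, names like
#'   `"mutant|III"`) and `medians` (data.frame `status`, `stage`, `n`,
#'   `events`, `median`), or an empty result (zero curves) when no patient
#'   carries the disease.
#' @export
stratified_survival <- function(bundles, gene, disease,
                                dict = default_dictionary()) {
  stopifnot(inherits(bundles, "patient_bundles"))
  dm <- map_term(disease, "disease", dict)
  target <- if (dm$status == "mapped") dm$preferred_term else disease
  dz <- bundles$diseases
  dz <- dz[!dz$superseded & fold_term(dz$disease) == fold_term(target), ,
           drop = FALSE]
  if (!nrow(dz)) {
    return(list(curves = list(),
                medians = data.frame(status = character(0),
                                     stage = character(0), n = integer(0),
                                     events = integer(0),
                                     median = numeric(0))))
  }
  pts <- bundles$patients
  i <- match(dz$patient_id, pts$patient_id)
  index <- dz$date
  end <- as.Date(ifelse(is.na(pts$death_date[i]),
                        pts$last_contact_date[i], pts$death_date[i]),
                 origin = "1970-01-01")
  ok <- !is.na(index) & !is.na(end) & end >= index
  dz <- dz[ok, , drop = FALSE]; i <- i[ok]
  time <- as.numeric(end[ok] - index[ok])
  event <- as.integer(!is.na(pts$death_date[i]))
  mut <- dz$patient_id %in%
    bundles$findings$patient_id[bundles$findings$gene == gene]
  status <- ifelse(mut, "mutant", "wild-type")
  stage <- ifelse(nzchar(dz$stage), dz$stage, "unknown")
  grp <- paste(status, stage, sep = "|")
  curves <- lapply(split(data.frame(time = time, event = event), grp),
                   km_curve)
  med <- data.frame(
    status = sub("\\|.*$", "", names(curves)),
    stage = sub("^.*\\|", "", names(curves)),
    n = vapply(curves, function(c) attr(c, "n"), numeric(1)),
    events = vapply(curves, function(c) sum(c$n_event), numeric(1)),
    median = vapply(curves, km_median, numeric(1)),
    stringsAsFactors = FALSE)
  med <- med[order(med$stage, med$status), , drop = FALSE]
  rownames(med) <- NULL
  list(curves = curves, medians = med)
}

#' Tripartite co-occurrence summary
#'
#' Collapses the relation table to a weighted edge list over gene-disease,
#' disease-drug and gene-drug pairs.  An edge's weight is the number of
#' distinct patients contributing the pair; a node's degree is its number
#' of distinct partners.  Gene-gene edges are not emitted.
#'
#' @param relations A relation data.frame ([derive_relations()]).
#' @return A list with `edges` (`from_class`, `from`, `to_class`, `to`,
#'   `weight`) and `nodes` (`class`, `name`, `degree`).
#' @export
cooccurrence_summary <- function(relations) {
  pred_map <- c(AssociatedWithGene = "disease-gene",
                MayTreatedBy = "disease-drug",
                MayTargetedBy = "gene-drug")
  rel <- relations[relations$predicate %in% names(pred_map), , drop = FALSE]
  if (!nrow(rel)) {
    return(list(edges = empty_df(c(from_class = "character",
                                   from = "character",
                                   to_class = "character", to = "character",
                                   weight = "integer")),
                nodes = empty_df(c(class = "character", name = "character",
                                   degree = "integer"))))
  }
  key <- paste(rel$subject_class, rel$subject, rel$object_class, rel$object,
               sep = "\r")
  # weight = distinct patients per pair (upstream dedup guarantees one
  # relation per patient per pair, but recount defensively)
  w <- tapply(rel$patient_id, key, function(p) length(unique(p)))
  parts <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
  edges <- data.frame(from_class = parts[, 1], from = parts[, 2],
                      to_class = parts[, 3], to = parts[, 4],
                      weight = as.integer(w), stringsAsFactors = FALSE)
  edges <- edges[order(edges$from_class, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  ends <- rbind(
    data.frame(class = edges$from_class, name = edges$from,
               partner = paste(edges$to_class, edges$to),
               stringsAsFactors = FALSE),
    data.frame(class = edges$to_class, name = edges$to,
               partner = paste(edges$from_class, edges$from),
               stringsAsFactors = FALSE))
  nk <- paste(ends$class, ends$name, sep = "\r")
  deg <- tapply(ends$partner, nk, function(p) length(unique(p)))
  nparts <- do.call(rbind, strsplit(names(deg), "\r", fixed = TRUE))
  nodes <- data.frame(class = nparts[, 1], name = nparts[, 2],
                      degree = as.integer(deg), stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$class, nodes$name), , drop = FALSE]
  rownames(nodes) <- NULL
  list(edges = edges, nodes = nodes)
}
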