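# Small shared helpers.  Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
abort_config <- function(field, msg) {
  stop(sprintf("invalid cohort configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

# Case-fold + trim surrounding whitespace/punctuation + collapse internal
# whitespace.  This is the canonical key under which all dictionary lookups
# happen, so "Tarceva." and "  tarceva" resolve identically.
fold_term <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", x)
  gsub("[[:space:]]+", " ", x)
}

# Lowercase slug for IRI local names: alphanumerics kept, runs of anything
# else become a single hyphen.
slugify <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[^a-z0-9]+", "-", x)
  gsub("^-+|-+$", "", x)
}

as_iso_date <- function(x) format(as.Date(x), "%Y-%m-%d")

# Stable empty data.frame constructor: cols is a named character vector of
# column classes ("character", "numeric", "integer", "logical", "Date").
empty_df <- function(cols) {
  out <- lapply(cols, function(cl) switch(cl,
    character = character(0),
    numeric   = numeric(0),
    integer   = integer(0),
    logical   = logical(0),
    Date      = as.Date(character(0)),
    stop("unknown column class: ", cl)))
  as.data.frame(out, stringsAsFactors = FALSE)
}

# One-letter -> three-letter amino-acid codes (HGVS protein notation).
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
         Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
         L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
         S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
         `*` = "Ter")

# Draw n seeds < 2^31 deterministically from one master seed; used wherever
# a multi-seed average is needed so a single --seed drives everything.
derive_seeds <- function(seed, n) {
  (as.integer(seed) %% 1000000L) * 1000L + seq_len(n)
}
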