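#' Entity references
#'
#' Entities (chemicals, genes, phenotypes, diseases) are identified by a
#' namespace (a controlled-vocabulary label such as \code{"MESH"},
#' \code{"GO"} or \code{"GENE"}) and an accession.  The pair
#' \code{(namespace, accession)} is the identity key; display names are
#' carried only for reporting.  Internally entities travel as compact key
#' strings \code{"NAMESPACE:accession"}.
#'
#' Normalization policy: namespaces are upper-cased and trimmed; gene
#' accessions (symbols) are matched case-insensitively and stored
#' upper-case; accessions in other namespaces are trimmed but keep their
#' case.  Normalization is idempotent.
#'
#' @param namespace character vector of vocabulary labels.
#' @param accession character vector of accessions; must be non-empty
#'   after trimming.
#' @param display_name optional character vector of human-readable names.
#' @return `entity_ref()` returns a data.frame with columns `namespace`,
#'   `accession`, `display_name` and `key`.  `entity_key()` returns the
#'   key strings only.
#' @examples
#' entity_ref("mesh", "D012640", "Seizures")$key
#' entity_key("GENE", c("Chrna4", "chrna4"))  # same key twice
#' @export
entity_ref <- function(namespace, accession, display_name = NA_character_) {
  ns <- normalize_namespace(namespace)
  acc <- normalize_accession(ns, accession)
  bad <- !nzchar(acc) | is.na(acc)
  if (any(bad)) {
    stop("empty accession in entity reference (namespace ",
         paste(unique(ns[bad]), collapse = ", "), ")", call. = FALSE)
  }
  data.frame(namespace = ns, accession = acc,
             display_name = as.character(display_name),
             key = paste0(ns, ":", acc),
             stringsAsFactors = FALSE)
}

#' @rdname entity_ref
#' @export
entity_key <- function(namespace, accession) {
  ns <- normalize_namespace(namespace)
  paste0(ns, ":", normalize_accession(ns, accession))
}

normalize_namespace <- function(x) toupper(trimws(as.character(x)))

normalize_accession <- function(ns, acc) {
  acc <- trimws(as.character(acc))
  ns <- rep_len(ns, length(acc))
  ifelse(ns == "GENE", toupper(acc), acc)
}

## Split "NS:acc" keys back into parts.  Accessions may themselves contain
## ':' (e.g. "MESH:C1:2" would be pathological but must not corrupt), so
## split on the first ':' only.
split_key <- function(key) {
  pos <- regexpr(":", key, fixed = TRUE)
  data.frame(namespace = ifelse(pos > 0, substr(key, 1L, pos - 1L), ""),
             accession = ifelse(pos > 0, substring(key, pos + 1L), key),
             stringsAsFactors = FALSE)
}

## Accession part of a key (used for gene-symbol matching).
key_accession <- function(key) split_key(key)$accession

## Case-insensitive gene-symbol set membership.
symbol_in <- function(keys, symbols) {
  toupper(key_accession(keys)) %in% toupper(trimws(symbols))
}
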