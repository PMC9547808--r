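#' Entity types understood by the network model
#'
#' The five biomedical entity types a layer may contain. The `(entity_type,
#' identifier)` pair is the unique entity key used to match shared nodes
#' across layers.
#'
#' @return Character vector of valid entity types.
#' @export
entity_types <- function() {
  c("gene", "disease", "pathway", "phenotype", "chemical")
}

#' Construct a tibble of entity references
#'
#' An entity reference is a typed, namespaced identifier — the unit of
#' ranking. Identifiers are trimmed and case-normalized: gene symbols are
#' upper-cased (so `app` and `APP` are the same gene), all other types are
#' kept verbatim.
#'
#' @param entity_type Character vector of types (see [entity_types()]).
#' @param identifier Character vector of identifiers, non-empty after
#'   trimming.
#' @return A tibble with columns `entity_type` and `identifier`.
#' @examples
#' entity("gene", c("APP", "chchd6"))
#' @export
entity <- function(entity_type, identifier) {
  entity_type <- as.character(entity_type)
  identifier <- as.character(identifier)
  bad_type <- !entity_type %in% entity_types()
  if (any(bad_type)) {
    abort(sprintf(
      "Unknown entity_type(s): %s (valid: %s)",
      paste(unique(entity_type[bad_type]), collapse = ", "),
      paste(entity_types(), collapse = ", ")
    ))
  }
  identifier <- normalize_identifier(entity_type, identifier)
  if (any(!nzchar(identifier))) {
    abort("Entity identifiers must be non-empty after trimming")
  }
  tibble::tibble(entity_type = entity_type, identifier = identifier)
}

#' Parse `"type:identifier"` strings into entity references
#'
#' Convenience for seed specification, e.g. `"gene:CHCHD6"`.
#'
#' @param x Character vector like `"gene:APP"`; everything after the first
#'   colon is the identifier.
#' @return A tibble as from [entity()].
#' @export
parse_entity <- function(x) {
  m <- regexpr(":", x, fixed = TRUE)
  if (any(m < 0)) {
    abort(sprintf(
      "Entity string(s) not in 'type:identifier' form: %s",
      paste(x[m < 0], collapse = ", ")
    ))
  }
  entity(substr(x, 1, m - 1), substring(x, m + 1))
}

# Case normalization: gene symbols upper-cased, other namespaces verbatim.
normalize_identifier <- function(entity_type, identifier) {
  identifier <- trimws(identifier)
  is_gene <- entity_type == "gene"
  identifier[is_gene] <- toupper(identifier[is_gene])
  identifier
}

# The unique entity key; also the within-layer sort key for node indexing.
entity_key <- function(entity_type, identifier) {
  paste(entity_type, identifier, sep = ":")
}

# Coerce seeds given as strings or a data frame into an entity tibble.
as_entity_tbl <- function(x) {
  if (is.character(x)) {
    return(parse_entity(x))
  }
  if (is.data.frame(x)) {
    if (!all(c("entity_type", "identifier") %in% names(x))) {
      abort("Entity data frames need columns entity_type and identifier")
    }
    return(entity(x$entity_type, x$identifier))
  }
  abort("Entities must be 'type:id' strings or a data frame")
}
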