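#' Split a full IRI into namespace and local name
#'
#' The namespace is everything up to and including the last `#`; when no `#`
#' is present, the last `/` is used instead. Splitting is exact and
#' reversible: `paste0(namespace, local_name)` recovers the input.
#'
#' @param full_iri Character vector of absolute IRIs.
#' @return A tibble with columns `iri`, `namespace`, `local_name`.
#' @export
#' @examples
#' split_iri("http://www.estados-mexico.org/estados#Puebla")
split_iri <- function(full_iri) {
  stopifnot(is.character(full_iri))
  pos_hash <- stringr::str_locate_all(full_iri, "#")
  cut <- purrr::map2_int(full_iri, pos_hash, function(iri, m) {
    if (nrow(m) > 0) return(as.integer(m[nrow(m), "start"]))
    sl <- stringr::str_locate_all(iri, "/")[[1]]
    if (nrow(sl) > 0) return(as.integer(sl[nrow(sl), "start"]))
    NA_integer_
  })
  if (anyNA(cut)) {
    bad <- full_iri[is.na(cut)]
    stop("malformed IRI (no '#' or '/'): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    iri = full_iri,
    namespace = substr(full_iri, 1L, cut),
    local_name = substr(full_iri, cut + 1L, nchar(full_iri))
  )
}

#' Compose a full IRI from a namespace and a local name
#'
#' @param namespace Absolute IRI namespace ending in `#` or `/`.
#' @param local_name Non-empty token without whitespace.
#' @return Character vector of full IRIs.
#' @export
iri <- function(namespace, local_name) {
  ok_ns <- grepl("[#/]$", namespace)
  if (!all(ok_ns)) {
    stop("namespace must end in '#' or '/': ", paste(namespace[!ok_ns], collapse = ", "),
         call. = FALSE)
  }
  if (any(local_name == "" | grepl("\\s", local_name))) {
    stop("local_name must be a non-empty token without whitespace", call. = FALSE)
  }
  paste0(namespace, local_name)
}

# Strip accents/diacritics via NFD decomposition, drop combining marks, lower-case.
# Used for gazetteer matching and name matching across modules.
fold_term <- function(x) {
  x <- stringi::stri_trans_nfd(x)
  x <- stringi::stri_replace_all_regex(x, "\\p{Mn}", "")
  stringr::str_to_lower(stringi::stri_trans_nfc(x))
}

# Underscore slug used for geographic / drug individuals: "Insulina Glargina"
# -> "Insulina_Glargina".
slug_underscore <- function(x) {
  x <- stringi::stri_trans_nfd(x)
  x <- stringi::stri_replace_all_regex(x, "\\p{Mn}", "")
  x <- stringi::stri_trans_nfc(x)
  x <- stringr::str_to_title(x)
  gsub("[^A-Za-z0-9]+", "_", trimws(x))
}

# CamelCase slug used for clinical-entity individuals:
# "diabetes mellitus tipo 2" -> "DiabetesMellitusTipo2".
slug_camel <- function(x) {
  gsub("_", "", slug_underscore(x))
}

utils::globalVariables(".")
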