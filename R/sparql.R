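# A small SPARQL evaluator: basic graph patterns, SELECT / SELECT DISTINCT,
# and FILTER over literals. That subset is sufficient for the competency
# registries; it is documented as a subset, not a SPARQL implementation.

sparql_split_statements <- function(body) {
  out <- character(); buf <- character()
  chars <- strsplit(body, "")[[1]]
  in_iri <- FALSE; in_str <- FALSE; depth <- 0L
  for (ch in chars) {
    if (ch == "<" && !in_str) in_iri <- TRUE
    if (ch == ">" && !in_str) in_iri <- FALSE
    if (ch == '"') in_str <- !in_str
    if (ch == "(" && !in_str && !in_iri) depth <- depth + 1L
    if (ch == ")" && !in_str && !in_iri) depth <- depth - 1L
    if (ch == "." && !in_iri && !in_str && depth == 0L) {
      out <- c(out, paste(buf, collapse = "")); buf <- character()
    } else {
      buf <- c(buf, ch)
    }
  }
  tail <- trimws(paste(buf, collapse = ""))
  if (nzchar(tail)) out <- c(out, tail)
  trimws(out)[nzchar(trimws(out))]
}

sparql_term <- function(tok, prefixes) {
  tok <- trimws(tok)
  if (tok == "a") return(list(kind = "iri", value = RDF_TYPE))
  if (startsWith(tok, "?")) return(list(kind = "var", value = substring(tok, 2)))
  if (grepl("^<.*>$", tok)) return(list(kind = "iri", value = gsub("^<|>$", "", tok)))
  if (grepl("^\"", tok)) {
    return(list(kind = "lit", value = gsub("^\"|\"(\\^\\^.*)?$", "",
                                           sub("\\^\\^\\S+$", "", tok))))
  }
  if (grepl("^-?[0-9.]+$", tok)) return(list(kind = "lit", value = tok))
  m <- regmatches(tok, regexec("^([A-Za-z0-9_]*):([A-Za-z0-9_.]+)$", tok))[[1]]
  if (length(m) == 0) stop_onto("cannot parse SPARQL term: ", tok)
  ns <- prefixes[[m[2]]]
  if (is.null(ns)) stop_onto("unknown prefix in query: '", m[2], ":'")
  list(kind = "iri", value = paste0(ns, m[3]))
}

match_pattern <- function(triples, stmt, prefixes, bindings) {
  toks <- regmatches(stmt, gregexpr("<[^>]+>|\"[^\"]*\"(\\^\\^\\S+)?|\\S+", stmt))[[1]]
  if (length(toks) != 3) stop_onto("cannot parse triple pattern: ", stmt)
  s <- sparql_term(toks[1], prefixes)
  p <- sparql_term(toks[2], prefixes)
  o <- sparql_term(toks[3], prefixes)
  df <- triples
  if (p$kind != "var") df <- df[df$predicate == p$value, ]
  if (s$kind != "var") df <- df[df$subject == s$value, ]
  if (o$kind != "var") {
    df <- if (o$kind == "iri") {
      df[df$object_kind == "iri" & df$object == o$value, ]
    } else {
      df[df$object_kind == "literal" & df$object == o$value, ]
    }
  }
  cols <- list()
  if (s$kind == "var") cols[[s$value]] <- df$subject
  if (p$kind == "var") cols[[p$value]] <- df$predicate
  if (o$kind == "var") cols[[o$value]] <- df$object
  rows <- dplyr::distinct(tibble::as_tibble(cols))
  if (ncol(rows) == 0) {
    return(if (nrow(df) > 0) bindings else NULL)
  }
  join_bindings(bindings, rows)
}

apply_filter <- function(bindings, expr, prefixes) {
  if (is.null(bindings) || nrow(bindings) == 0) return(bindings)
  m <- regmatches(expr, regexec(
    "^\\s*(\\?[A-Za-z0-9_]+)\\s*(<=|>=|!=|=|<|>)\\s*(.+?)\\s*$", expr))[[1]]
  if (length(m) == 0) stop_onto("unsupported FILTER expression: ", expr)
  var <- substring(m[2], 2)
  op <- m[3]
  if (!var %in% names(bindings)) stop_onto("FILTER on unbound variable ?", var)
  rhs <- sparql_term(m[4], prefixes)
  lhs_chr <- bindings[[var]]
  if (grepl("^-?[0-9.]+$", rhs$value)) {
    a <- suppressWarnings(as.numeric(lhs_chr)); b <- as.numeric(rhs$value)
    keep <- switch(op, "=" = a == b, "!=" = a != b, "<" = a < b,
                   ">" = a > b, "<=" = a <= b, ">=" = a >= b)
  } else {
    keep <- switch(op, "=" = lhs_chr == rhs$value, "!=" = lhs_chr != rhs$value,
                   stop_onto("string FILTER supports = and != only"))
  }
  keep[is.na(keep)] <- FALSE
  bindings[keep, , drop = FALSE]
}

#' Run a SPARQL query (basic-graph-pattern subset) against the network
#'
#' Supports `PREFIX` declarations, `SELECT` / `SELECT DISTINCT`, conjunctive
#' triple patterns (`a` for `rdf:type`), and simple `FILTER` comparisons on
#' literals. Queries see the full triple view of the network with `sameAs`
#' pairs expanded, so either member of an equivalence answers for both.
#'
#' @param net An `onto_network`.
#' @param query SPARQL query string.
#' @param triples Optional pre-computed triple view (for repeated querying).
#' @return Tibble with one column per selected variable.
#' @export
sparql_query <- function(net, query, triples = NULL) {
  pfx_m <- stringr::str_match_all(query,
    stringr::regex("PREFIX\\s+([A-Za-z0-9_]*)\\s*:\\s*<\\s*([^>\\s]+)\\s*>",
                   ignore_case = TRUE))[[1]]
  prefixes <- default_prefixes(net)
  for (i in seq_len(nrow(pfx_m))) prefixes[[pfx_m[i, 2]]] <- pfx_m[i, 3]
  sel_m <- stringr::str_match(query,
    stringr::regex("SELECT\\s+(DISTINCT\\s+)?(.*?)\\s*WHERE",
                   ignore_case = TRUE, dotall = TRUE))
  if (is.na(sel_m[1, 1])) stop_onto("query has no SELECT ... WHERE clause")
  distinct <- !is.na(sel_m[1, 2])
  vars <- gsub("^\\?", "", stringr::str_extract_all(sel_m[1, 3], "\\?[A-Za-z0-9_]+")[[1]])
  if (length(vars) == 0) stop_onto("no selected variables in query")
  body_m <- stringr::str_match(query, stringr::regex("\\{(.*)\\}", dotall = TRUE))
  if (is.na(body_m[1, 1])) stop_onto("query has no { } group pattern")
  stmts <- sparql_split_statements(body_m[1, 2])
  if (is.null(triples)) {
    triples <- expand_same_as(network_triples(net), net$same_as)
  }
  bindings <- NULL
  first <- TRUE
  for (stmt in stmts) {
    if (grepl("^FILTER", stmt, ignore.case = TRUE)) {
      expr <- stringr::str_match(stmt, stringr::regex("FILTER\\s*\\((.*)\\)\\s*$",
                                                      dotall = TRUE))[1, 2]
      bindings <- apply_filter(bindings, expr, prefixes)
    } else {
      bindings <- match_pattern(triples, stmt, prefixes, bindings)
      first <- FALSE
    }
    if (!is.null(bindings) && nrow(bindings) == 0) break
  }
  if (is.null(bindings)) bindings <- tibble::tibble()
  missing_vars <- setdiff(vars, names(bindings))
  for (v in missing_vars) bindings[[v]] <- character(0)
  out <- bindings[, vars, drop = FALSE]
  if (distinct) out <- dplyr::distinct(out)
  tibble::as_tibble(out)
}
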