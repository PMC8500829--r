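# On-disk formats. Turtle (a documented line-oriented subset: one triple per
# statement, prefixed names or <IRI>s, typed literals) is the canonical
# serialization: one file per module plus a network file importing all,
# written in a deterministic order (subjects sorted, then predicates, IRIs
# before literals) so two writes of the same network are byte-identical.

OWL_IMPORTS <- "http://www.w3.org/2002/07/owl#imports"

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

ttl_unescape <- function(x) {
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

network_prefix_map <- function(net) {
  p <- c(BASE_PREFIXES, red = net$network_iri,
         stats::setNames(net$modules$namespace, net$modules$key))
  p[order(names(p), method = "radix")]
}

ttl_term <- function(value, kind, datatype, prefixes) {
  if (kind == "literal") {
    if (is.na(datatype) || datatype == "string") {
      return(paste0("\"", ttl_escape(value), "\""))
    }
    return(paste0("\"", ttl_escape(value), "\"^^xsd:", datatype))
  }
  ns_hit <- which(startsWith(value, prefixes))
  if (length(ns_hit) > 0) {
    # longest matching namespace wins
    best <- ns_hit[which.max(nchar(prefixes[ns_hit]))]
    local <- substring(value, nchar(prefixes[best]) + 1)
    if (grepl("^[A-Za-z0-9_.-]+$", local) && nzchar(local)) {
      return(paste0(names(prefixes)[best], ":", local))
    }
  }
  paste0("<", value, ">")
}

format_ttl <- function(triples, prefixes) {
  header <- paste0("@prefix ", names(prefixes), ": <", prefixes, "> .")
  if (nrow(triples) == 0) return(c(header, ""))
  ord <- order(triples$subject, triples$predicate, triples$object_kind,
               triples$object, method = "radix")
  triples <- triples[ord, ]
  lines <- vapply(seq_len(nrow(triples)), function(i) {
    paste(ttl_term(triples$subject[i], "iri", NA, prefixes),
          ttl_term(triples$predicate[i], "iri", NA, prefixes),
          ttl_term(triples$object[i], triples$object_kind[i], triples$datatype[i],
                   prefixes),
          ".")
  }, character(1))
  c(header, "", lines)
}

#' Write the network to a directory of Turtle files
#'
#' One `<module key>.ttl` per module (triples about that module's namespace)
#' plus `network.ttl` holding the network-namespace triples and `owl:imports`
#' of every module. Output ordering is deterministic.
#'
#' @param net An `onto_network`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_network <- function(net, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prefixes <- network_prefix_map(net)
  triples <- network_triples(net)
  mod_subject <- function(ns) sub("[#/]$", "", ns)
  paths <- character()
  assigned <- rep(FALSE, nrow(triples))
  for (i in seq_len(nrow(net$modules))) {
    ns <- net$modules$namespace[i]
    sel <- startsWith(triples$subject, ns) | triples$subject == mod_subject(ns)
    sel <- sel & !assigned
    assigned <- assigned | sel
    path <- file.path(dir, paste0(net$modules$key[i], ".ttl"))
    writeLines(format_ttl(triples[sel, ], prefixes), path, useBytes = TRUE)
    paths <- c(paths, path)
  }
  rest <- triples[!assigned, ]
  net_subj <- mod_subject(net$network_iri)
  imports <- tibble::tibble(subject = net_subj, predicate = OWL_IMPORTS,
                            object = mod_subject(net$modules$namespace),
                            object_kind = "iri", datatype = NA_character_)
  path <- file.path(dir, "network.ttl")
  writeLines(format_ttl(dplyr::bind_rows(rest, imports), prefixes), path,
             useBytes = TRUE)
  invisible(c(paths, path))
}

parse_ttl_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  prefixes <- character()
  n <- length(lines)
  subject <- predicate <- object <- object_kind <- datatype <- character(n)
  k <- 0L
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (startsWith(line, "@prefix")) {
      m <- regmatches(line, regexec("^@prefix\\s+([A-Za-z0-9_]*):\\s*<([^>]*)>\\s*\\.$",
                                    line))[[1]]
      if (length(m) == 0) stop_onto(basename(path), ":", ln, ": malformed @prefix line")
      prefixes[m[2]] <- m[3]
      next
    }
    toks <- regmatches(line,
      gregexpr('<[^>]*>|"(\\\\.|[^"\\\\])*"(\\^\\^[A-Za-z0-9_:]+)?|\\S+', line,
               perl = TRUE))[[1]]
    if (length(toks) != 4 || toks[4] != ".") {
      stop_onto(basename(path), ":", ln, ": malformed triple statement")
    }
    term <- function(tok) {
      if (startsWith(tok, "<")) {
        return(c(substr(tok, 2, nchar(tok) - 1L), "iri", NA_character_))
      }
      if (startsWith(tok, "\"")) {
        dt_m <- regmatches(tok, regexec("\\^\\^xsd:([A-Za-z]+)$", tok))[[1]]
        dt <- if (length(dt_m) > 0) dt_m[2] else "string"
        val <- sub("\\^\\^[A-Za-z0-9_:]+$", "", tok)
        return(c(ttl_unescape(substr(val, 2, nchar(val) - 1L)), "literal", dt))
      }
      if (tok == "a") return(c(RDF_TYPE, "iri", NA_character_))
      m <- regmatches(tok, regexec("^([A-Za-z0-9_]*):([A-Za-z0-9_.-]+)$", tok))[[1]]
      if (length(m) == 0 || !m[2] %in% names(prefixes)) {
        stop_onto(basename(path), ":", ln, ": undeclared prefix or bad term '", tok, "'")
      }
      c(paste0(prefixes[[m[2]]], m[3]), "iri", NA_character_)
    }
    s <- term(toks[1]); p <- term(toks[2]); o <- term(toks[3])
    if (s[2] != "iri" || p[2] != "iri") {
      stop_onto(basename(path), ":", ln, ": subject/predicate must be IRIs")
    }
    k <- k + 1L
    subject[k] <- s[1]; predicate[k] <- p[1]
    object[k] <- o[1]; object_kind[k] <- o[2]; datatype[k] <- o[3]
  }
  idx <- seq_len(k)
  list(prefixes = prefixes,
       triples = tibble::tibble(subject = subject[idx], predicate = predicate[idx],
                                object = object[idx], object_kind = object_kind[idx],
                                datatype = datatype[idx]))
}

#' Read a network from Turtle files
#'
#' Reconstructs an `onto_network` from files produced by [write_network()]
#' (or hand-written in the same subset). `owl:imports` statements are
#' treated as file-organisation metadata. The round trip is lossless: the
#' triple set of the parsed network equals the serialized one.
#'
#' @param paths Turtle file paths, or a directory containing `.ttl` files.
#' @return An `onto_network`.
#' @export
read_network <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.ttl$", full.names = TRUE)
  }
  parsed <- lapply(paths, parse_ttl_file)
  prefixes <- do.call(c, lapply(parsed, function(x) x$prefixes))
  prefixes <- prefixes[!duplicated(names(prefixes))]
  triples <- dplyr::distinct(dplyr::bind_rows(lapply(parsed, function(x) x$triples)))
  triples <- triples[triples$predicate != OWL_IMPORTS, ]

  of_pred <- function(p) triples[triples$predicate == p, ]
  types <- of_pred(RDF_TYPE)
  onto_subjects <- types$subject[types$object == OWL_ONTOLOGY]
  labels <- of_pred(RDFS_LABEL)
  label_of <- function(s) {
    v <- labels$object[labels$subject == s]
    if (length(v) > 0) v[[1]] else NA_character_
  }
  ns_of_subject <- function(s) paste0(s, "#")
  is_network <- vapply(onto_subjects, function(s) {
    identical(label_of(s), "Ontology Network")
  }, logical(1))
  if (sum(is_network) != 1) stop_onto("expected exactly one network ontology declaration")
  network_iri <- ns_of_subject(onto_subjects[is_network])
  net <- new_network(network_iri)
  mods <- onto_subjects[!is_network]
  key_of_ns <- function(ns) {
    hit <- names(prefixes)[prefixes == ns]
    if (length(hit) > 0) hit[[1]] else NA_character_
  }
  mods <- mods[order(mods, method = "radix")]
  for (s in mods) {
    ns <- ns_of_subject(s)
    key <- key_of_ns(ns)
    if (is.na(key)) stop_onto("module namespace has no prefix declaration: ", ns)
    net <- add_module(net, key, label_of(s), ns)
  }
  red <- function(x) iri(network_iri, x)

  class_iris <- types$subject[types$object == OWL_CLASS]
  parents <- of_pred(RDFS_SUBCLASS)
  prim_flags <- of_pred(red("esPrimitiva"))
  todo <- class_iris
  while (length(todo) > 0) {
    progressed <- FALSE
    for (cl in todo) {
      par <- parents$object[parents$subject == cl]
      par <- if (length(par) > 0) par[[1]] else NA_character_
      if (!is.na(par) && !par %in% net$classes$iri) next
      net <- add_class(net, cl, parent = par,
                       primitive = !cl %in% prim_flags$subject)
      todo <- setdiff(todo, cl)
      progressed <- TRUE
    }
    if (!progressed) stop_onto("class hierarchy is cyclic or has missing parents")
  }

  domains <- of_pred(RDFS_DOMAIN); ranges <- of_pred(RDFS_RANGE)
  stage_t <- of_pred(red("etapa"))
  one <- function(df, s) { v <- df$object[df$subject == s]; if (length(v)) v[[1]] else NA }
  for (p in types$subject[types$object == OWL_OBJPROP]) {
    st <- stage_t$object[stage_t$subject == p]
    net <- add_object_property(net, p, one(domains, p), one(ranges, p),
                               stage = if (length(st)) st[[1]] else NA_character_)
  }
  for (p in types$subject[types$object == OWL_DATAPROP]) {
    rng <- sub(XSD_NS, "", one(ranges, p), fixed = TRUE)
    net <- add_data_property(net, p, one(domains, p), rng)
  }

  ind_rows <- types[types$object %in% net$classes$iri, ]
  if (nrow(ind_rows) > 0) {
    mods <- vapply(split_iri(ind_rows$subject)$namespace,
                   function(x) module_of_ns(net, x), character(1))
    if (anyNA(mods)) stop_onto("individual namespace matches no module")
    net$individuals <- dplyr::distinct(dplyr::bind_rows(net$individuals,
      tibble::tibble(iri = ind_rows$subject, class = ind_rows$object, module = mods)))
  }
  # restore the blank-node counter from the highest serialized _bn suffix
  bn <- grepl("#_bn", net$individuals$iri, fixed = TRUE)
  if (any(bn)) {
    suffix <- suppressWarnings(as.integer(sub(".*_(\\d+)$", "\\1",
                                              net$individuals$iri[bn])))
    net$bn_counter <- max(c(0L, suffix), na.rm = TRUE)
  }

  restr <- of_pred(red("tieneRestriccion"))
  if (nrow(restr) > 0) {
    dec <- strsplit(restr$object, "|", fixed = TRUE)
    net$restrictions <- tibble::tibble(
      class = restr$subject,
      on_property = vapply(dec, `[[`, character(1), 1),
      kind = vapply(dec, `[[`, character(1), 2),
      n = suppressWarnings(as.integer(vapply(dec, `[[`, character(1), 3))),
      filler = vapply(dec, `[[`, character(1), 4),
      derived = vapply(dec, `[[`, character(1), 5) == "derived")
  }
  same <- of_pred(OWL_SAMEAS)
  for (i in seq_len(nrow(same))) net <- add_same_as(net, same$subject[i], same$object[i])

  handled <- c(RDF_TYPE, RDFS_SUBCLASS, RDFS_DOMAIN, RDFS_RANGE, OWL_SAMEAS,
               red("esPrimitiva"), red("etapa"), red("tieneRestriccion"))
  known_props <- c(net$obj_props$iri, net$data_props$iri)
  rest <- triples[!triples$predicate %in% handled, ]
  # module/network ontology labels are regenerated, not stored
  rest <- rest[!(rest$predicate == RDFS_LABEL &
                 rest$subject %in% c(onto_subjects)), ]
  is_assertion <- rest$predicate %in% known_props
  ann <- rest[!is_assertion & rest$object_kind == "literal", ]
  if (nrow(ann) > 0) {
    net$annotations <- dplyr::distinct(dplyr::bind_rows(net$annotations,
      tibble::tibble(subject = ann$subject, property = ann$predicate,
                     value = ann$object)))
  }
  unknown <- rest[!is_assertion & rest$object_kind == "iri", ]
  if (nrow(unknown) > 0) {
    stop_onto("unparseable object triples with unknown predicate: ",
              paste(utils::head(unique(unknown$predicate), 3), collapse = ", "))
  }
  net <- add_assertions_bulk(net, rest[is_assertion, ])
  net
}

# ---------------------------------------------------------------------------

#' Write clinical records as JSON lines
#'
#' @param records List of clinical-record documents.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read clinical records from JSON lines
#'
#' @param path Input path, one record object per line.
#' @return List of clinical-record documents.
#' @export
read_records_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lapply(lines[nzchar(lines)], jsonlite::fromJSON, simplifyVector = FALSE)
}

#' Read an external-reference TSV (subject_iri, scheme, code)
#'
#' @param path TSV path.
#' @return Tibble with columns `subject`, `scheme`, `code`.
#' @export
read_refs_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  names(df)[names(df) == "subject_iri"] <- "subject"
  tibble::as_tibble(df[, c("subject", "scheme", "code")])
}

#' Read a synonym lexicon TSV (term, canonical, source)
#'
#' @param path TSV path.
#' @return Tibble with columns `term`, `canonical`, `source`.
#' @export
read_lexicon_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                                      colClasses = "character", fileEncoding = "UTF-8"))
}
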