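# Semi-automatic extraction of candidate triples from clinical note text:
# gazetteer tagging (longest match, case/diacritic-insensitive), shallow
# nominal-phrase identification, triplet formation per tag kind, a review
# round trip replacing the interactive control screen, and the integration
# flow that routes accepted triples into the network.

#' Directory of the fixture gazetteers shipped with the package
#'
#' The gazetteers are synthetic fixtures standing in for the clinical
#' vocabularies (ICD-10 disease list, anatomy, signs, symptoms, active
#' ingredients).
#'
#' @return Directory path.
#' @export
default_gazetteer_dir <- function() {
  system.file("extdata", "gazetteers", package = "ontonet")
}

#' Load gazetteer TSV files
#'
#' Each file has columns `term`, `tag`, `code`, `vocab`.
#'
#' @param dir Directory containing `.tsv` gazetteers (or a vector of file
#'   paths).
#' @return Tibble with the gazetteer rows plus folded terms and token counts.
#' @export
load_gazetteers <- function(dir = default_gazetteer_dir()) {
  files <- if (length(dir) == 1 && dir.exists(dir)) {
    list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  } else dir
  if (length(files) == 0) stop_onto("no gazetteer files found in ", dir)
  gaz <- purrr::map_dfr(files, function(f) {
    df <- utils::read.delim(f, sep = "\t", stringsAsFactors = FALSE,
                            colClasses = "character", fileEncoding = "UTF-8")
    df$source_file <- basename(f)
    tibble::as_tibble(df)
  })
  gaz$folded <- fold_term(gaz$term)
  gaz$n_tokens <- lengths(strsplit(gaz$folded, " "))
  gaz
}

# Tokenizer: words (letters/digits, decimal numbers) with character offsets.
tokenize <- function(text) {
  loc <- stringi::stri_locate_all_regex(text, "[\\p{L}\\p{N}]+(?:[.]\\p{N}+)?")[[1]]
  if (nrow(loc) == 0 || is.na(loc[1, 1])) {
    return(tibble::tibble(token = character(), start = integer(), end = integer(),
                          folded = character()))
  }
  tok <- stringi::stri_sub(text, loc[, 1], loc[, 2])
  tibble::tibble(token = tok, start = as.integer(loc[, 1]), end = as.integer(loc[, 2]),
                 folded = fold_term(tok))
}

#' Default shallow Spanish part-of-speech lexicon
#'
#' A small closed-class lexicon (verbs, determiners, prepositions, common
#' clinical adjectives); everything else defaults to Noun, numerals to Num.
#' Swappable: [tag_terms()] accepts any lexicon with the same shape.
#'
#' @return Named list of character vectors.
#' @export
default_pos_lexicon <- function() {
  list(
    Verb = c("refiere", "presenta", "tiene", "niega", "es", "padece", "puede",
             "usar", "contraindicado", "indicado", "acude", "recibe"),
    Det = c("el", "la", "los", "las", "un", "una", "unos", "unas", "su"),
    Prep = c("de", "en", "con", "por", "para", "a", "y", "o", "sin", "sobre"),
    Adj = c("cronica", "aguda", "diabetica", "diabetico", "arterial", "borrosa",
            "leve", "severa", "inferior", "superior", "fisica", "mellitus",
            "urinarias", "adversas")
  )
}

pos_tag <- function(folded, lexicon = default_pos_lexicon()) {
  out <- rep("Noun", length(folded))
  for (tag in names(lexicon)) out[folded %in% lexicon[[tag]]] <- tag
  out[grepl("^\\p{N}+(?:[.]\\p{N}+)?$", folded, perl = TRUE)] <- "Num"
  out
}

#' Tag terms in a note fragment
#'
#' Every token receives a syntactic tag from the part-of-speech lexicon;
#' token spans found in the gazetteers (longest match first, case- and
#' diacritic-insensitive) additionally receive a semantic tag carrying the
#' source vocabulary and external code. Semantic spans never overlap.
#'
#' @param text A note fragment.
#' @param gazetteers Output of [load_gazetteers()].
#' @param pos_lexicon Part-of-speech lexicon, see [default_pos_lexicon()].
#' @return Tibble of tagged terms: `start`, `end`, `text`, `tag_kind`
#'   (`semantic`/`syntactic`), `tag`, `source_vocab`, `code`, `token_start`,
#'   `token_end`.
#' @export
tag_terms <- function(text, gazetteers, pos_lexicon = default_pos_lexicon()) {
  if (is.null(gazetteers) || nrow(gazetteers) == 0) stop_onto("at least one gazetteer required")
  toks <- tokenize(text)
  if (nrow(toks) == 0) {
    return(tibble::tibble(start = integer(), end = integer(), text = character(),
                          tag_kind = character(), tag = character(),
                          source_vocab = character(), code = character(),
                          token_start = integer(), token_end = integer()))
  }
  toks$pos <- pos_tag(toks$folded, pos_lexicon)
  syntactic <- tibble::tibble(start = toks$start, end = toks$end, text = toks$token,
                              tag_kind = "syntactic", tag = toks$pos,
                              source_vocab = NA_character_, code = NA_character_,
                              token_start = seq_len(nrow(toks)),
                              token_end = seq_len(nrow(toks)))
  covered <- rep(FALSE, nrow(toks))
  semantic <- list()
  max_n <- min(max(gazetteers$n_tokens), nrow(toks))
  for (k in seq(max_n, 1)) {
    terms_k <- gazetteers[gazetteers$n_tokens == k, ]
    if (nrow(terms_k) == 0) next
    for (i in seq_len(nrow(toks) - k + 1)) {
      idx <- i:(i + k - 1)
      if (any(covered[idx])) next
      gram <- paste(toks$folded[idx], collapse = " ")
      hit <- terms_k[terms_k$folded == gram, ]
      if (nrow(hit) > 0) {
        covered[idx] <- TRUE
        semantic[[length(semantic) + 1]] <- tibble::tibble(
          start = toks$start[i], end = toks$end[i + k - 1],
          text = stringr::str_sub(text, toks$start[i], toks$end[i + k - 1]),
          tag_kind = "semantic", tag = hit$tag[[1]],
          source_vocab = hit$vocab[[1]], code = hit$code[[1]],
          token_start = i, token_end = i + k - 1)
      }
    }
  }
  dplyr::arrange(dplyr::bind_rows(syntactic, dplyr::bind_rows(semantic)),
                 .data$start, .data$tag_kind)
}

#' Identify nominal phrases among syntactically tagged tokens
#'
#' Shallow pattern `Noun (Adj | "de" Noun)*` over tokens not already covered
#' by a semantic term; returns maximal non-overlapping phrase spans. The
#' pattern set is data (swappable for other languages).
#'
#' @param tagged Output of [tag_terms()].
#' @return Tibble of phrase spans: `start`, `end`, `text`, `token_start`,
#'   `token_end`.
#' @export
find_nominal_phrases <- function(tagged) {
  syn <- tagged[tagged$tag_kind == "syntactic", ]
  sem <- tagged[tagged$tag_kind == "semantic", ]
  if (nrow(syn) == 0) {
    return(tibble::tibble(start = integer(), end = integer(), text = character(),
                          token_start = integer(), token_end = integer()))
  }
  covered <- rep(FALSE, max(syn$token_end))
  for (i in seq_len(nrow(sem))) covered[sem$token_start[i]:sem$token_end[i]] <- TRUE
  n <- nrow(syn)
  phrases <- list()
  i <- 1
  while (i <= n) {
    if (syn$tag[i] == "Noun" && !covered[syn$token_start[i]]) {
      j <- i
      repeat {
        if (j + 1 <= n && syn$tag[j + 1] == "Adj" && !covered[syn$token_start[j + 1]]) {
          j <- j + 1
        } else if (j + 2 <= n && syn$tag[j + 1] == "Prep" &&
                   fold_term(syn$text[j + 1]) == "de" && syn$tag[j + 2] == "Noun" &&
                   !covered[syn$token_start[j + 1]] && !covered[syn$token_start[j + 2]]) {
          j <- j + 2
        } else break
      }
      phrases[[length(phrases) + 1]] <- tibble::tibble(
        token_start = syn$token_start[i], token_end = syn$token_end[j],
        start = syn$start[i], end = syn$end[j])
      i <- j + 1
    } else i <- i + 1
  }
  out <- dplyr::bind_rows(phrases)
  if (nrow(out) == 0) {
    return(tibble::tibble(start = integer(), end = integer(), text = character(),
                          token_start = integer(), token_end = integer()))
  }
  out$text <- NA_character_
  out[, c("start", "end", "text", "token_start", "token_end")]
}

new_candidates <- function() {
  tibble::tibble(id = character(), domain = character(), relation = character(),
                 range = character(), range_kind = character(), datatype = character(),
                 pattern = character(), status = character())
}

candidate_row <- function(id, domain, relation, range, range_kind, datatype, pattern) {
  tibble::tibble(id = id, domain = domain, relation = relation, range = range,
                 range_kind = range_kind, datatype = datatype, pattern = pattern,
                 status = "pending")
}

#' Form candidate triples from a tagged medical-note fragment
#'
#' Applies the per-tag patterns: disease- and symptom-tagged terms become
#' ranges of `presentaEnfermedad` / `presentaSintoma` with the medical note
#' as domain (the bare-list pattern); a sign term immediately followed by a
#' number becomes a data-property candidate named `tiene` + SignName with a
#' float or string value; NominalPhrase-Verb-NominalPhrase sequences become
#' generic object-property candidates.
#'
#' @param net An `onto_network`; `note_iri` must resolve to a Medical Note
#'   individual before any candidate is emitted.
#' @param note_iri IRI of the medical note providing the domain.
#' @param tagged Output of [tag_terms()]; original text in attribute or
#'   recomputed phrases via [find_nominal_phrases()].
#' @param text The fragment text (for phrase surfaces).
#' @return Candidate tibble (`id`, `domain`, `relation`, `range`,
#'   `range_kind`, `datatype`, `pattern`, `status`).
#' @export
form_triplets <- function(net, note_iri, tagged, text = NULL) {
  if (resolve_iri(note_iri, net)$found_as != "individual") {
    stop_onto("note context does not resolve to an individual: ", note_iri)
  }
  datos <- ns_of_module(net, "datos")
  enf <- ns_of_module(net, "enfermedades")
  red <- net$network_iri
  out <- list()
  nid <- split_iri(note_iri)$local_name
  sem <- tagged[tagged$tag_kind == "semantic", ]
  syn <- tagged[tagged$tag_kind == "syntactic", ]
  k <- 0L
  nxt <- function() { k <<- k + 1L; sprintf("%s_c%02d", nid, k) }
  for (i in seq_len(nrow(sem))) {
    row <- sem[i, ]
    if (row$tag == "Disease") {
      out[[length(out) + 1]] <- candidate_row(nxt(), note_iri, iri(red, "presentaEnfermedad"),
        iri(enf, slug_camel(row$text)), "iri", NA_character_, "bare-list")
    } else if (row$tag == "Symptom") {
      out[[length(out) + 1]] <- candidate_row(nxt(), note_iri, iri(red, "presentaSintoma"),
        iri(enf, slug_camel(row$text)), "iri", NA_character_, "bare-list")
    } else if (row$tag == "Sign") {
      following <- syn[syn$token_start == row$token_end + 1, ]
      if (nrow(following) > 0 && following$tag[1] == "Num") {
        val <- following$text[1]
        dt <- if (grepl("^\\p{N}+([.]\\p{N}+)?$", val, perl = TRUE)) "float" else "string"
        out[[length(out) + 1]] <- candidate_row(nxt(), note_iri,
          iri(datos, paste0("tiene", slug_camel(row$text))), val, "literal", dt,
          "sign-literal")
      }
    }
  }
  # NominalPhrase-Verb-NominalPhrase
  phrases <- find_nominal_phrases(tagged)
  if (!is.null(text) && nrow(phrases) > 0) {
    phrases$text <- stringr::str_sub(text, phrases$start, phrases$end)
    verbs <- syn[syn$tag == "Verb", ]
    for (v in seq_len(nrow(verbs))) {
      left <- phrases[phrases$token_end == verbs$token_start[v] - 1, ]
      right <- phrases[phrases$token_start == verbs$token_end[v] + 1, ]
      if (nrow(left) == 1 && nrow(right) == 1) {
        out[[length(out) + 1]] <- candidate_row(nxt(), iri(enf, slug_camel(left$text)),
          iri(red, fold_term(verbs$text[v])), iri(enf, slug_camel(right$text)),
          "iri", NA_character_, "NP-V-NP")
      }
    }
  }
  if (length(out) == 0) return(new_candidates())
  dplyr::bind_rows(out)
}

#' Form candidate triples from a drug-leaflet section
#'
#' Clinical-entity terms found in the generalities / contraindication /
#' caution sections of a drug text become ranges of the corresponding
#' drug-scoped relation.
#'
#' @param net An `onto_network`.
#' @param drug_iri Drug individual IRI (domain of the candidates).
#' @param section One of `efectos_secundarios`, `contraindicaciones`,
#'   `precauciones`.
#' @param tagged Output of [tag_terms()] on the section text.
#' @return Candidate tibble.
#' @export
form_drug_triplets <- function(net, drug_iri, section, tagged) {
  if (resolve_iri(drug_iri, net)$found_as != "individual") {
    stop_onto("drug does not resolve to an individual: ", drug_iri)
  }
  relation <- switch(section,
    efectos_secundarios = "tieneEfectoSecundario",
    contraindicaciones = "tieneContraindicacion",
    precauciones = "tienePrecaucion",
    stop_onto("unknown drug-text section: ", section))
  enf <- ns_of_module(net, "enfermedades")
  sem <- tagged[tagged$tag_kind == "semantic" & tagged$tag %in% c("Disease", "Symptom"), ]
  if (nrow(sem) == 0) return(new_candidates())
  did <- split_iri(drug_iri)$local_name
  purrr::map_dfr(seq_len(nrow(sem)), function(i) {
    candidate_row(sprintf("%s_%s_c%02d", did, substr(section, 1, 4), i),
                  drug_iri, iri(net$network_iri, relation),
                  iri(enf, slug_camel(sem$text[i])), "iri", NA_character_,
                  "individual-anchored")
  })
}

#' Write candidates to an editable review file
#'
#' One record per candidate with id, domain, relation, range and an action
#' field (`register` by default; reviewers change it to `skip` or edit the
#' three IRI fields). Replaces the interactive control screen with a
#' deterministic emit -> edit -> apply round trip.
#'
#' @param candidates Candidate tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_review_file <- function(candidates, path) {
  df <- candidates[, c("id", "domain", "relation", "range")]
  df$action <- "register"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a review file
#'
#' @param path Review TSV path.
#' @return Tibble with `id`, `domain`, `relation`, `range`, `action`.
#' @export
read_review_file <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                                      colClasses = "character", fileEncoding = "UTF-8"))
}

#' Apply review decisions to candidates
#'
#' `register` keeps the candidate (status `registered`, or `edited` when the
#' reviewer changed any of the three fields, whose new values replace the
#' proposals); `skip` marks it skipped, leaving the network untouched
#' downstream.
#'
#' @param candidates Candidate tibble.
#' @param review Review tibble, see [read_review_file()].
#' @return The candidates tibble with statuses (and edits) applied.
#' @export
apply_review <- function(candidates, review) {
  unknown <- setdiff(review$id, candidates$id)
  if (length(unknown) > 0) {
    stop_onto("review references unknown candidate id(s): ",
              paste(unknown, collapse = ", "))
  }
  for (i in seq_len(nrow(review))) {
    j <- which(candidates$id == review$id[i])
    if (review$action[i] == "skip") {
      candidates$status[j] <- "skipped"
      next
    }
    edited <- candidates$domain[j] != review$domain[i] ||
      candidates$relation[j] != review$relation[i] ||
      candidates$range[j] != review$range[i]
    candidates$domain[j] <- review$domain[i]
    candidates$relation[j] <- review$relation[i]
    candidates$range[j] <- review$range[i]
    candidates$status[j] <- if (edited) "edited" else "registered"
  }
  candidates
}

# Route an IRI to its owning module; create the resource as an individual of
# the master class when absent. When the triple's relation is already
# declared, its domain/range class is the natural master for the new
# resource (keeps assertions inside the declared domain/range); otherwise
# the module-level master class from configuration applies.
ensure_individual <- function(net, full_iri, master_classes, preferred_class = NULL) {
  res <- resolve_iri(full_iri, net)
  if (res$found_as != "absent") return(net)
  mod <- res$owner_module
  if (is.na(mod)) stop_onto("unroutable IRI (namespace matches no module): ", full_iri)
  master_iri <- preferred_class
  if (is.null(master_iri) ||
      module_of_ns(net, split_iri(master_iri)$namespace) != mod) {
    master <- master_classes[[mod]]
    if (is.null(master) || is.na(master)) {
      stop_onto("no master class configured for module ", mod)
    }
    master_iri <- iri(ns_of_module(net, mod), master)
  }
  net <- add_individual(net, full_iri, master_iri,
                        label = gsub("_", " ", res$local_name))
  stopifnot(resolve_iri(full_iri, net)$found_as == "individual")
  net
}

#' Integrate one registered candidate triple into the network
#'
#' The integration flow: absent domain/range resources are created as
#' individuals of the owning module's master class and re-verified; absent
#' object properties are created in the network namespace with the domain
#' and range classes of the triple's endpoints; absent data properties are
#' created in the Clinical Information Administration namespace; finally the
#' assertion is added.
#'
#' @param net An `onto_network`.
#' @param candidate One-row candidate tibble with status `registered` or
#'   `edited`.
#' @param master_classes Module -> master class map.
#' @return The updated network.
#' @export
integrate_triplet <- function(net, candidate,
                              master_classes = default_schema_config()$master_classes) {
  stopifnot(nrow(candidate) == 1)
  if (!candidate$status %in% c("registered", "edited")) {
    stop_onto("only registered/edited candidates can be integrated (got '",
              candidate$status, "')")
  }
  rel <- candidate$relation
  res0 <- resolve_iri(rel, net)
  dom_pref <- rng_pref <- NULL
  if (res0$found_as == "object_property") {
    dom_pref <- net$obj_props$domain[net$obj_props$iri == rel][[1]]
    rng_pref <- net$obj_props$range[net$obj_props$iri == rel][[1]]
  } else if (res0$found_as == "data_property") {
    dom_pref <- net$data_props$domain[net$data_props$iri == rel][[1]]
  }
  net <- ensure_individual(net, candidate$domain, master_classes, dom_pref)
  if (candidate$range_kind == "iri") {
    net <- ensure_individual(net, candidate$range, master_classes, rng_pref)
  }
  res <- resolve_iri(rel, net)
  if (res$found_as == "absent") {
    local <- res$local_name
    if (candidate$range_kind == "iri") {
      # new object properties always take the network IRI
      rel <- iri(net$network_iri, local)
      if (resolve_iri(rel, net)$found_as == "absent") {
        dom_cls <- net$individuals$class[net$individuals$iri == candidate$domain][[1]]
        rng_cls <- net$individuals$class[net$individuals$iri == candidate$range][[1]]
        net <- add_object_property(net, rel, dom_cls, rng_cls, stage = "extraction")
      }
    } else {
      # new data properties live in the Clinical Information Administration module
      rel <- iri(ns_of_module(net, "datos"), local)
      if (resolve_iri(rel, net)$found_as == "absent") {
        dom_cls <- net$individuals$class[net$individuals$iri == candidate$domain][[1]]
        net <- add_data_property(net, rel, dom_cls, candidate$datatype %|na|% "string")
      }
    }
  }
  if (candidate$range_kind == "iri") {
    net <- add_assertion(net, candidate$domain, rel, candidate$range)
  } else {
    value <- if ((candidate$datatype %|na|% "string") == "float") {
      as.numeric(candidate$range)
    } else candidate$range
    net <- add_assertion(net, candidate$domain, rel, value, datatype = candidate$datatype)
  }
  net
}

#' Integrate all accepted candidates
#'
#' @param net An `onto_network`.
#' @param candidates Candidate tibble after review; skipped and pending
#'   candidates leave the network untouched.
#' @param master_classes Module -> master class map.
#' @return The updated network.
#' @export
apply_candidates <- function(net, candidates,
                             master_classes = default_schema_config()$master_classes) {
  keep <- candidates[candidates$status %in% c("registered", "edited"), ]
  for (i in seq_len(nrow(keep))) {
    net <- integrate_triplet(net, keep[i, ], master_classes)
  }
  net
}

#' Extract candidate triples from a corpus's free-text fragments
#'
#' Runs tagging and triplet formation over the note narratives (domain: the
#' populated medical-note individuals) and the drug-leaflet sections
#' (domain: the drug products containing the referenced ingredient).
#'
#' @param net A populated `onto_network`.
#' @param fragments Fragment tibble from [generate_corpus()].
#' @param gazetteers Output of [load_gazetteers()].
#' @return Candidate tibble (status `pending`).
#' @export
extract_candidates <- function(net, fragments, gazetteers = load_gazetteers()) {
  datos <- ns_of_module(net, "datos")
  medi <- ns_of_module(net, "medicamentos")
  out <- list()
  notes <- fragments[fragments$kind == "note", ]
  for (i in seq_len(nrow(notes))) {
    note_iri <- iri(datos, paste0("Nota_", notes$ref[i]))
    if (resolve_iri(note_iri, net)$found_as != "individual") next
    tagged <- tag_terms(notes$text[i], gazetteers)
    out[[length(out) + 1]] <- form_triplets(net, note_iri, tagged, text = notes$text[i])
  }
  drugs <- fragments[fragments$kind == "drug", ]
  mapper_api <- net$assertions[grepl("tienePrincipioActivo$", net$assertions$predicate), ]
  drug_mapper <- net$assertions[grepl("tienePrincipioActivoPorPorcion$",
                                      net$assertions$predicate), ]
  for (i in seq_len(nrow(drugs))) {
    api_iri <- iri(medi, slug_underscore(drugs$ref[i]))
    mappers <- mapper_api$subject[mapper_api$object == api_iri]
    products <- unique(drug_mapper$subject[drug_mapper$object %in% mappers])
    if (length(products) == 0) next
    tagged <- tag_terms(drugs$text[i], gazetteers)
    for (p in sort(products)) {
      out[[length(out) + 1]] <- form_drug_triplets(net, p, drugs$section[i], tagged)
    }
  }
  cand <- dplyr::bind_rows(c(list(new_candidates()), out))
  cand$id <- make.unique(cand$id, sep = "_")
  cand
}
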