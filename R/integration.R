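# Ontology integration: the six-stage drug/ATC integration (name matching,
# semantic verification, class-to-instance demotion of the lowest ATC levels,
# active-pharmaceutical-ingredient mapper nodes) and the external-reference
# method (ICD-10 / SNOMED CT codes as annotations). All operations are
# functional: they return an updated network and never touch inputs on disk.

#' Find same-name elements between two modules
#'
#' Stage-2 matching: case- and diacritic-insensitive exact-name matches
#' between the classes and individuals of two modules, plus synonym matches
#' mediated by a lexicon. Element names are their `rdfs:label` when present,
#' else the local name. All matches start unverified.
#'
#' @param net An `onto_network`.
#' @param base_key,incoming_key Module keys.
#' @param lexicon Optional tibble with columns `term`, `canonical`: surface
#'   terms mapped to a canonical synonym-group name.
#' @return Tibble with `element_a`, `kind_a`, `element_b`, `kind_b`,
#'   `match_basis` (`exact_name` or `synonym`), `verified`, `evidence`.
#' @export
find_name_matches <- function(net, base_key, incoming_key, lexicon = NULL) {
  elements <- function(key) {
    ns <- ns_of_module(net, key)
    cl <- net$classes[net$classes$module == key, "iri", drop = FALSE]
    cl$kind <- if (nrow(cl)) "class" else character(0)
    ind <- net$individuals[net$individuals$module == key, "iri", drop = FALSE]
    ind <- dplyr::distinct(ind)
    ind$kind <- if (nrow(ind)) "individual" else character(0)
    out <- dplyr::bind_rows(cl, ind)
    labels <- net$annotations[net$annotations$property == RDFS_LABEL, ]
    out$name <- purrr::map_chr(out$iri, function(x) {
      lb <- labels$value[labels$subject == x]
      if (length(lb) > 0) lb[[1]] else split_iri(x)$local_name
    })
    out$folded <- fold_term(gsub("_", " ", out$name))
    out
  }
  a <- elements(base_key)
  b <- elements(incoming_key)
  exact <- dplyr::inner_join(a, b, by = "folded", suffix = c("_a", "_b"),
                             relationship = "many-to-many")
  out <- tibble::tibble(element_a = exact$iri_a, kind_a = exact$kind_a,
                        element_b = exact$iri_b, kind_b = exact$kind_b,
                        match_basis = rep("exact_name", nrow(exact)))
  if (!is.null(lexicon) && nrow(lexicon) > 0) {
    lex <- dplyr::mutate(lexicon, folded = fold_term(.data$term),
                         canon = fold_term(.data$canonical))
    canon_of <- function(df) {
      df$canon <- df$folded
      hit <- match(df$folded, lex$folded)
      df$canon[!is.na(hit)] <- lex$canon[hit[!is.na(hit)]]
      df
    }
    a2 <- canon_of(a); b2 <- canon_of(b)
    syn <- dplyr::inner_join(a2, b2, by = "canon", suffix = c("_a", "_b"),
                             relationship = "many-to-many")
    syn <- syn[syn$folded_a != syn$folded_b, ]
    if (nrow(syn) > 0) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        element_a = syn$iri_a, kind_a = syn$kind_a,
        element_b = syn$iri_b, kind_b = syn$kind_b,
        match_basis = "synonym"))
    }
  }
  out$verified <- FALSE
  out$evidence <- NA_character_
  dplyr::distinct(out)
}

# External codes attached to an element: ATC key data value plus ICD10/SCTID
# annotations.
external_codes_of <- function(net, iri_) {
  red <- net$network_iri
  ann <- net$annotations[net$annotations$subject == iri_ &
                         net$annotations$property %in%
                           c(iri(red, "ICD10"), iri(red, "SCTID")), "value", drop = TRUE]
  key <- net$assertions[net$assertions$subject == iri_ &
                        grepl("tieneClaveATC$", net$assertions$predicate),
                        "object", drop = TRUE]
  unique(c(ann, key))
}

#' Semantic verification of name matches
#'
#' Stage-3 verification is a pluggable predicate. The default checks the two
#' elements' external codes (ATC / ICD-10 / SCTID) and verifies the match
#' when they share a code; matches without shared evidence stay unverified
#' and are the ones a reviewer should inspect.
#'
#' @param net An `onto_network`.
#' @param matches Output of [find_name_matches()].
#' @param verifier Function `(net, iri_a, iri_b) -> evidence string or NA`.
#' @return The matches tibble with `verified`/`evidence` filled in.
#' @export
verify_matches <- function(net, matches, verifier = NULL) {
  verifier <- verifier %||% function(net, a, b) {
    shared <- intersect(external_codes_of(net, a), external_codes_of(net, b))
    if (length(shared) > 0) paste0("shared external code ", shared[[1]]) else NA_character_
  }
  for (i in seq_len(nrow(matches))) {
    ev <- verifier(net, matches$element_a[i], matches$element_b[i])
    matches$verified[i] <- !is.na(ev)
    matches$evidence[i] <- ev
  }
  matches
}

#' Demote leaf classes to individuals of their parent class
#'
#' Stage-4/5 of the integration: the selected lowest-level classes are
#' removed as classes and re-asserted as individuals of their former parent.
#' The class's local name (its classification key, e.g. an ATC code) moves
#' into a unique-key data property; the class's label becomes the
#' individual's name. The total number of classes plus individuals is
#' conserved.
#'
#' @param net An `onto_network`.
#' @param class_iris IRIs of the leaf classes to demote.
#' @param key_property Data property IRI that receives the former key.
#' @return The updated network.
#' @export
demote_classes_to_instances <- function(net, class_iris, key_property) {
  if (length(class_iris) == 0) return(net)
  if (resolve_iri(key_property, net)$found_as != "data_property") {
    stop_onto("key_property must be a declared data property: ", key_property)
  }
  labels <- net$annotations[net$annotations$property == RDFS_LABEL, ]
  for (cl in class_iris) {
    row <- net$classes[net$classes$iri == cl, ]
    if (nrow(row) == 0) stop_onto("not a declared class: ", cl)
    kids <- net$classes$iri[!is.na(net$classes$parent) & net$classes$parent == cl]
    if (length(kids) > 0) stop_onto("refusing to demote non-leaf class: ", cl)
    parent <- row$parent[[1]]
    if (is.na(parent)) stop_onto("leaf class has no parent to instantiate from: ", cl)
    parts <- split_iri(cl)
    lb <- labels$value[labels$subject == cl]
    name <- if (length(lb) > 0) slug_underscore(lb[[1]]) else parts$local_name
    ind_iri <- iri(parts$namespace, name)
    # drop the class (and its stale annotations), create the individual
    net$classes <- net$classes[net$classes$iri != cl, ]
    net$annotations <- net$annotations[net$annotations$subject != cl, ]
    net <- add_individual(net, ind_iri, parent,
                          label = if (length(lb) > 0) lb[[1]] else name)
    net <- add_assertion(net, ind_iri, key_property, parts$local_name, datatype = "string")
  }
  net
}

#' Create active-pharmaceutical-ingredient mapper nodes for a drug
#'
#' A drug combining one or more active ingredients is linked to each through
#' an anonymous mapper node carrying the amount per portion, replacing any
#' direct drug-to-ingredient individual link.
#'
#' @param net An `onto_network` with the Drug-ATC module attached.
#' @param drug_iri Drug individual IRI.
#' @param portions Tibble with columns `api` (ATC classification individual
#'   IRI), `amount` (positive number), `unit` (free-text unit, e.g. mg, UI).
#' @return The updated network.
#' @export
create_api_mappers <- function(net, drug_iri, portions) {
  if (resolve_iri(drug_iri, net)$found_as != "individual") {
    stop_onto("drug does not resolve to an individual: ", drug_iri)
  }
  if (any(portions$amount <= 0)) stop_onto("mapper amounts must be positive")
  medi <- ns_of_module(net, "medicamentos")
  for (i in seq_len(nrow(portions))) {
    api <- portions$api[i]
    if (resolve_iri(api, net)$found_as != "individual") {
      stop_onto("API does not resolve to an individual: ", api)
    }
    bn <- next_blank(net, "Mapper")
    net <- bn$net
    net <- add_individual(net, bn$iri, iri(medi, "Mapeador_Principio_Activo"))
    net <- add_assertion(net, drug_iri, iri(medi, "tienePrincipioActivoPorPorcion"), bn$iri)
    net <- add_assertion(net, bn$iri, iri(medi, "tienePrincipioActivo"), api)
    net <- add_assertion(net, bn$iri, iri(medi, "tieneCantidadDePrincipioActivo"),
                         portions$amount[i], datatype = "float")
    net <- add_assertion(net, bn$iri, iri(medi, "tieneMedidaDePrincipioActivo"),
                         portions$unit[i], datatype = "string")
  }
  net
}

#' Annotate elements with external vocabulary references
#'
#' ICD-10 and SNOMED CT codes are stored purely as annotations (never as
#' class axioms), so queries can surface them without importing the external
#' vocabulary structure.
#'
#' @param net An `onto_network`.
#' @param refs Tibble with columns `subject` (IRI), `scheme` (`"ICD10"` or
#'   `"SCTID"`), `code`.
#' @return The updated network.
#' @export
annotate_external_refs <- function(net, refs) {
  if (nrow(refs) == 0) return(net)
  bad_scheme <- setdiff(unique(refs$scheme), c("ICD10", "SCTID"))
  if (length(bad_scheme) > 0) stop_onto("unknown reference scheme: ",
                                        paste(bad_scheme, collapse = ", "))
  for (i in seq_len(nrow(refs))) {
    subj <- refs$subject[i]
    if (resolve_iri(subj, net)$found_as == "absent") {
      stop_onto("external reference subject does not resolve: ", subj)
    }
    prop <- iri(net$network_iri, refs$scheme[i])
    existing <- net$annotations$value[net$annotations$subject == subj &
                                      net$annotations$property == prop]
    if (length(existing) > 0 && !refs$code[i] %in% existing) {
      stop_onto("conflicting ", refs$scheme[i], " code for ", subj, ": '",
                existing[[1]], "' vs '", refs$code[i], "'")
    }
    net <- add_annotation(net, subj, prop, refs$code[i])
  }
  net
}

# ---------------------------------------------------------------------------
# Drug-ATC demonstration module. The ATC branch, products and amounts are a
# synthetic fixture standing in for the national drug catalogue; codes follow
# the ATC scheme.

#' Fixture list of active pharmaceutical ingredients with ATC codes
#'
#' @return Tibble with columns `name`, `code`, `group`, `group_label`.
#' @export
fixture_apis <- function() {
  tibble::tribble(
    ~name, ~code, ~group, ~group_label,
    "Insulina Glargina", "A10AE04", "A10", "Drugs used in diabetes",
    "Insulina Lispro", "A10AB04", "A10", "Drugs used in diabetes",
    "Metformina", "A10BA02", "A10", "Drugs used in diabetes",
    "Glibenclamida", "A10BB01", "A10", "Drugs used in diabetes",
    "Diosmina Con Hesperidina", "C05CA53", "C05", "Vasoprotectives",
    "Diosmina", "C05CA03", "C05", "Vasoprotectives",
    "Hesperidina", "C05CA54", "C05", "Vasoprotectives",
    "Enalapril", "C09AA02", "C09", "Agents acting on the renin-angiotensin system",
    "Captopril", "C09AA01", "C09", "Agents acting on the renin-angiotensin system",
    "Losartan", "C09CA01", "C09", "Agents acting on the renin-angiotensin system",
    "Atorvastatina", "C10AA05", "C10", "Lipid modifying agents",
    "Bezafibrato", "C10AB02", "C10", "Lipid modifying agents",
    "Acido Acetilsalicilico", "B01AC06", "B01", "Antithrombotic agents",
    "Omeprazol", "A02BC01", "A02", "Drugs for acid related disorders",
    "Paracetamol", "N02BE01", "N02", "Analgesics",
    "Pregabalina", "N03AX16", "N03", "Antiepileptics",
    "Complejo B", "A11EA", "A11", "Vitamins"
  )
}

#' Attach the Drug-ATC demonstration module
#'
#' Builds the reused drug module the way the integration methodology
#' prescribes: an ATC classification branch whose lowest levels start life as
#' classes, are then demoted to individuals keyed by their ATC code, and drug
#' products linked to their ingredients through mapper nodes carrying
#' per-portion amounts. One product per ingredient plus a second Insulin
#' Lispro presentation (so presentation queries have two forms to return) and
#' a two-ingredient combination product.
#'
#' @param net An `onto_network` built by [build_module_schemas()].
#' @return The updated network.
#' @export
attach_drug_atc_demo <- function(net) {
  net <- add_module(net, "medicamentos", "Drug-ATC",
                    "http://www.medicamentos-mexico.org/medicamento#")
  medi <- ns_of_module(net, "medicamentos")
  m <- function(name) iri(medi, name)
  net <- net |>
    add_class(m("Medicamento"), label = "Drug") |>
    add_class(m("Clasificacion_ATC"), label = "ATC_Classification") |>
    add_class(m("Mapeador_Principio_Activo"),
              label = "Active Pharmaceutical Ingredient Mapper") |>
    add_object_property(m("tienePrincipioActivoPorPorcion"), m("Medicamento"),
                        m("Mapeador_Principio_Activo"),
                        label = "hasActivePharmacueticalIngredientPerPortion") |>
    add_object_property(m("tienePrincipioActivo"), m("Mapeador_Principio_Activo"),
                        m("Clasificacion_ATC"),
                        label = "hasActivePharmaceuticalIngredient") |>
    add_data_property(m("tieneCantidadDePrincipioActivo"), m("Mapeador_Principio_Activo"),
                      "float", label = "hasAmountOfActivePharmaceuticalIngredient") |>
    add_data_property(m("tieneMedidaDePrincipioActivo"), m("Mapeador_Principio_Activo"),
                      "string", label = "hasMeasureOfActivePharmaceuticalIngredient") |>
    add_data_property(m("tieneFormaFarmaceutica"), m("Medicamento"),
                      "string", label = "hasPharmaceuticalForm") |>
    add_data_property(m("tieneClaveATC"), m("Clasificacion_ATC"),
                      "string", label = "hasATCKey")
  apis <- fixture_apis()
  for (g in unique(apis$group)) {
    net <- add_class(net, m(g), parent = m("Clasificacion_ATC"),
                     label = apis$group_label[apis$group == g][[1]])
  }
  # the lowest classification levels start as classes keyed by ATC code ...
  for (i in seq_len(nrow(apis))) {
    net <- add_class(net, m(apis$code[i]), parent = m(apis$group[i]),
                     label = apis$name[i])
  }
  # ... and are demoted to instances of their immediate superior class.
  net <- demote_classes_to_instances(net, m(apis$code), m("tieneClaveATC"))

  # Drug products with mapper nodes.
  api_iri <- function(name) m(slug_underscore(name))
  add_product <- function(net, product, form, portions) {
    net <- add_individual(net, m(product), m("Medicamento"),
                          label = gsub("_", " ", product))
    net <- add_assertion(net, m(product), m("tieneFormaFarmaceutica"), form)
    create_api_mappers(net, m(product), portions)
  }
  simple <- function(name, amount, unit) {
    tibble::tibble(api = api_iri(name), amount = amount, unit = unit)
  }
  insulins <- c("Insulina Glargina", "Insulina Lispro")
  tablets <- setdiff(apis$name[!apis$name %in% c("Diosmina", "Hesperidina")], insulins)
  for (nm in tablets) {
    amount <- if (nm == "Metformina") 850 else 500
    net <- add_product(net, paste0(slug_underscore(nm), "_Tabletas"), "Tableta",
                       simple(nm, amount, "mg"))
  }
  net <- add_product(net, "Insulina_Glargina_Solucion", "Solución inyectable",
                     simple("Insulina Glargina", 100, "UI/ml"))
  net <- add_product(net, "Insulina_Lispro_Solucion", "Solución inyectable",
                     simple("Insulina Lispro", 100, "UI/ml"))
  net <- add_product(net, "Insulina_Lispro_Solucion_Pluma",
                     "Solución inyectable en pluma",
                     simple("Insulina Lispro", 100, "UI/ml"))
  # two-ingredient combination product
  net <- add_product(net, "Diosmina_Hesperidina_Grageas", "Gragea",
                     tibble::tibble(api = api_iri(c("Diosmina", "Hesperidina")),
                                    amount = c(450, 50), unit = "mg"))
  net
}
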