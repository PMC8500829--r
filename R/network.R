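# Core in-memory model: an ontology network is a set of modules (each a
# namespace with classes, properties, individuals, annotations) plus
# cross-module meta-relations in the network's own namespace. Everything is
# kept in tibbles so construction and queries stay vectorised.

RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
RDFS_SUBCLASS <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"
RDFS_LABEL <- "http://www.w3.org/2000/01/rdf-schema#label"
RDFS_COMMENT <- "http://www.w3.org/2000/01/rdf-schema#comment"
RDFS_DOMAIN <- "http://www.w3.org/2000/01/rdf-schema#domain"
RDFS_RANGE <- "http://www.w3.org/2000/01/rdf-schema#range"
OWL_CLASS <- "http://www.w3.org/2002/07/owl#Class"
OWL_OBJPROP <- "http://www.w3.org/2002/07/owl#ObjectProperty"
OWL_DATAPROP <- "http://www.w3.org/2002/07/owl#DatatypeProperty"
OWL_ONTOLOGY <- "http://www.w3.org/2002/07/owl#Ontology"
OWL_SAMEAS <- "http://www.w3.org/2002/07/owl#sameAs"
XSD_NS <- "http://www.w3.org/2001/XMLSchema#"

# Literal datatypes supported by the model (the only xsd types the network's
# class contracts use).
LITERAL_TYPES <- c("string", "integer", "float", "date")

BASE_PREFIXES <- c(
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl = "http://www.w3.org/2002/07/owl#",
  xsd = XSD_NS
)

# Canonical literal formatting: one string form per value so that identical
# assertions always collide on dedup and serialization is byte-stable.
format_literal <- function(x, datatype) {
  if (is.numeric(x)) {
    return(vapply(x, function(v) format(v, digits = 15, trim = TRUE, scientific = FALSE),
                  character(1)))
  }
  as.character(x)
}

empty_assertions <- function() {
  tibble::tibble(subject = character(), predicate = character(),
                 object = character(), object_kind = character(),
                 datatype = character())
}

#' Create an empty ontology network
#'
#' @param network_iri Namespace IRI of the network itself; meta-relations and
#'   network-level classes live here.
#' @return An `onto_network` object.
#' @export
new_network <- function(network_iri = "http://www.diabetes-mexico.org/red#") {
  if (!grepl("[#/]$", network_iri)) stop("network_iri must end in '#' or '/'", call. = FALSE)
  structure(list(
    network_iri = network_iri,
    modules = tibble::tibble(key = character(), label = character(), namespace = character()),
    classes = tibble::tibble(iri = character(), parent = character(),
                             primitive = logical(), module = character()),
    obj_props = tibble::tibble(iri = character(), domain = character(), range = character(),
                               stage = character(), module = character()),
    data_props = tibble::tibble(iri = character(), domain = character(),
                                range_type = character(), module = character()),
    individuals = tibble::tibble(iri = character(), class = character(), module = character()),
    assertions = empty_assertions(),
    annotations = tibble::tibble(subject = character(), property = character(),
                                 value = character()),
    restrictions = tibble::tibble(class = character(), on_property = character(),
                                  kind = character(), n = integer(), filler = character(),
                                  derived = logical()),
    same_as = tibble::tibble(a = character(), b = character()),
    bn_counter = 0L
  ), class = "onto_network")
}

#' @export
print.onto_network <- function(x, ...) {
  cat("<onto_network> ", x$network_iri, "\n", sep = "")
  cat("  modules: ", nrow(x$modules), " (", paste(x$modules$key, collapse = ", "), ")\n", sep = "")
  cat("  classes: ", nrow(x$classes),
      "  object properties: ", nrow(x$obj_props),
      "  data properties: ", nrow(x$data_props), "\n", sep = "")
  cat("  individuals: ", nrow(x$individuals),
      "  assertions: ", nrow(x$assertions),
      "  annotations: ", nrow(x$annotations), "\n", sep = "")
  invisible(x)
}

stop_onto <- function(...) stop(..., call. = FALSE)

#' Add an ontology module (a namespace) to the network
#'
#' @param net An `onto_network`.
#' @param key Short module key, used as the Turtle prefix.
#' @param label Human-readable module name.
#' @param namespace Module namespace IRI (must end in `#` or `/`).
#' @return The updated network.
#' @export
add_module <- function(net, key, label, namespace) {
  stopifnot(inherits(net, "onto_network"))
  if (!grepl("[#/]$", namespace)) namespace <- paste0(namespace, "#")
  if (namespace %in% c(net$modules$namespace, net$network_iri)) {
    stop_onto("duplicate module namespace: ", namespace)
  }
  if (key %in% net$modules$key) stop_onto("duplicate module key: ", key)
  net$modules <- dplyr::bind_rows(net$modules,
    tibble::tibble(key = key, label = label, namespace = namespace))
  net
}

module_of_ns <- function(net, namespace) {
  if (namespace == net$network_iri) return("red")
  hit <- net$modules$key[net$modules$namespace == namespace]
  if (length(hit) == 0) NA_character_ else hit[[1]]
}

ns_of_module <- function(net, key) {
  if (key == "red") return(net$network_iri)
  hit <- net$modules$namespace[net$modules$key == key]
  if (length(hit) == 0) stop_onto("unknown module key: ", key)
  hit[[1]]
}

#' Declare a class
#'
#' @param net An `onto_network`.
#' @param class_iri Full IRI of the class.
#' @param parent Optional parent class IRI (`rdfs:subClassOf`).
#' @param primitive Logical; `FALSE` for classes defined by restriction
#'   conjunctions.
#' @param label Optional `rdfs:label`.
#' @return The updated network.
#' @export
add_class <- function(net, class_iri, parent = NA_character_, primitive = TRUE, label = NULL) {
  ns <- split_iri(class_iri)$namespace
  mod <- module_of_ns(net, ns)
  if (is.na(mod)) stop_onto("class namespace matches no module: ", class_iri)
  if (!is.na(parent) && !parent %in% net$classes$iri) {
    stop_onto("parent class not declared: ", parent)
  }
  if (!class_iri %in% net$classes$iri) {
    net$classes <- dplyr::bind_rows(net$classes,
      tibble::tibble(iri = class_iri, parent = parent, primitive = primitive, module = mod))
  }
  if (!is.null(label)) net <- add_annotation(net, class_iri, RDFS_LABEL, label)
  net
}

#' Declare an object property
#'
#' @param net An `onto_network`.
#' @param prop_iri Full IRI of the property.
#' @param domain,range Class IRIs.
#' @param stage Provenance stage for meta-relations (`"design"` or
#'   `"extraction"`); `NA` for intra-module properties.
#' @param label Optional `rdfs:label` (used for English aliases).
#' @return The updated network.
#' @export
add_object_property <- function(net, prop_iri, domain, range, stage = NA_character_,
                                label = NULL) {
  ns <- split_iri(prop_iri)$namespace
  mod <- module_of_ns(net, ns)
  if (is.na(mod)) stop_onto("property namespace matches no module: ", prop_iri)
  for (cls in c(domain, range)) {
    if (!cls %in% net$classes$iri) stop_onto("cannot resolve class '", cls, "' for ", prop_iri)
  }
  if (!is.na(stage) && !stage %in% c("design", "extraction")) {
    stop_onto("stage must be 'design' or 'extraction'")
  }
  if (!prop_iri %in% net$obj_props$iri) {
    net$obj_props <- dplyr::bind_rows(net$obj_props,
      tibble::tibble(iri = prop_iri, domain = domain, range = range, stage = stage, module = mod))
  }
  if (!is.null(label)) net <- add_annotation(net, prop_iri, RDFS_LABEL, label)
  net
}

#' Declare a data property
#'
#' @param net An `onto_network`.
#' @param prop_iri Full IRI of the property.
#' @param domain Class IRI.
#' @param range_type One of `"string"`, `"integer"`, `"float"`, `"date"`.
#' @param label Optional `rdfs:label`.
#' @return The updated network.
#' @export
add_data_property <- function(net, prop_iri, domain, range_type = "string", label = NULL) {
  ns <- split_iri(prop_iri)$namespace
  mod <- module_of_ns(net, ns)
  if (is.na(mod)) stop_onto("property namespace matches no module: ", prop_iri)
  if (!domain %in% net$classes$iri) stop_onto("cannot resolve class '", domain, "'")
  if (!range_type %in% LITERAL_TYPES) stop_onto("unsupported literal type: ", range_type)
  if (!prop_iri %in% net$data_props$iri) {
    net$data_props <- dplyr::bind_rows(net$data_props,
      tibble::tibble(iri = prop_iri, domain = domain, range_type = range_type, module = mod))
  }
  if (!is.null(label)) net <- add_annotation(net, prop_iri, RDFS_LABEL, label)
  net
}

#' Declare an individual
#'
#' @param net An `onto_network`.
#' @param ind_iri Full IRI of the individual.
#' @param class_iri IRI of its asserted class.
#' @param label Optional `rdfs:label`.
#' @return The updated network.
#' @export
add_individual <- function(net, ind_iri, class_iri, label = NULL) {
  ns <- split_iri(ind_iri)$namespace
  mod <- module_of_ns(net, ns)
  if (is.na(mod)) stop_onto("individual namespace matches no module: ", ind_iri)
  if (!class_iri %in% net$classes$iri) stop_onto("cannot resolve class '", class_iri, "'")
  already <- net$individuals$iri == ind_iri & net$individuals$class == class_iri
  if (!any(already)) {
    net$individuals <- dplyr::bind_rows(net$individuals,
      tibble::tibble(iri = ind_iri, class = class_iri, module = mod))
  }
  if (!is.null(label)) net <- add_annotation(net, ind_iri, RDFS_LABEL, label)
  net
}

#' Attach an annotation (label, comment, external code) to any element
#'
#' Annotations never add logical axioms; they are stored apart from
#' assertions.
#'
#' @param net An `onto_network`.
#' @param subject Full IRI of the annotated element.
#' @param property Annotation property IRI (e.g. `rdfs:label`).
#' @param value Literal value.
#' @return The updated network.
#' @export
add_annotation <- function(net, subject, property, value) {
  row <- tibble::tibble(subject = subject, property = property, value = as.character(value))
  net$annotations <- dplyr::distinct(dplyr::bind_rows(net$annotations, row))
  net
}

#' Assert that two individuals denote the same entity
#'
#' `sameAs` is honoured at the query layer (queries through either IRI see
#' the union of both individuals' assertions); it is not OWL reasoning.
#'
#' @param net An `onto_network`.
#' @param a,b Individual IRIs.
#' @return The updated network.
#' @export
add_same_as <- function(net, a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  pair <- tibble::tibble(a = lo, b = hi)
  net$same_as <- dplyr::distinct(dplyr::bind_rows(net$same_as, pair))
  net
}

# Stable blank-node naming: reserved prefix "_bn" + deterministic counter in
# the network namespace, so serialization is reproducible.
next_blank <- function(net, hint = "n") {
  net$bn_counter <- net$bn_counter + 1L
  list(net = net, iri = iri(net$network_iri, paste0("_bn", hint, "_", net$bn_counter)))
}

#' Resolve a full IRI against the network
#'
#' Looks the IRI up among classes, individuals, object properties and data
#' properties. Never raises when the IRI is absent: the result then has
#' `found_as = "absent"` with the namespace/local-name split, and
#' `owner_module` set when the namespace matches a declared module.
#'
#' @param full_iri Absolute IRI.
#' @param net An `onto_network`.
#' @return A list with `found_as` (one of class, individual, object_property,
#'   data_property, absent), `owner_module` (module key or `NA`), `namespace`
#'   and `local_name`.
#' @export
resolve_iri <- function(full_iri, net) {
  stopifnot(length(full_iri) == 1L)
  parts <- split_iri(full_iri)
  found_as <- "absent"
  if (full_iri %in% net$classes$iri) found_as <- "class"
  else if (full_iri %in% net$individuals$iri) found_as <- "individual"
  else if (full_iri %in% net$obj_props$iri) found_as <- "object_property"
  else if (full_iri %in% net$data_props$iri) found_as <- "data_property"
  list(found_as = found_as,
       owner_module = module_of_ns(net, parts$namespace),
       namespace = parts$namespace,
       local_name = parts$local_name)
}

#' Add a single assertion (triple) to the network
#'
#' Idempotent: re-adding an identical assertion is a no-op. The predicate
#' must be a declared property; object properties take IRIs of declared
#' individuals, data properties take literals.
#'
#' @param net An `onto_network`.
#' @param subject Individual IRI (must resolve).
#' @param predicate Property IRI (must resolve).
#' @param object Individual IRI for object properties; literal value for data
#'   properties.
#' @param datatype Literal type for data-property objects; defaults to the
#'   property's declared range type.
#' @return The updated network.
#' @export
add_assertion <- function(net, subject, predicate, object, datatype = NULL) {
  if (resolve_iri(subject, net)$found_as == "absent") {
    stop_onto("subject does not resolve: ", subject)
  }
  res <- resolve_iri(predicate, net)
  if (res$found_as == "object_property") {
    looks_iri <- is.character(object) && length(object) == 1 && grepl("://", object)
    if (!looks_iri || resolve_iri(object, net)$found_as == "absent") {
      stop_onto("object-property assertion needs a resolvable IRI object: ", predicate)
    }
    row <- tibble::tibble(subject = subject, predicate = predicate, object = object,
                          object_kind = "iri", datatype = NA_character_)
  } else if (res$found_as == "data_property") {
    if (is.character(object) && grepl("^https?://", object)) {
      stop_onto("data-property assertion cannot take an IRI object: ", predicate)
    }
    dt <- datatype %||% net$data_props$range_type[net$data_props$iri == predicate][[1]]
    row <- tibble::tibble(subject = subject, predicate = predicate,
                          object = format_literal(object, dt),
                          object_kind = "literal", datatype = dt)
  } else {
    stop_onto("predicate does not resolve to a property: ", predicate)
  }
  dup <- nrow(dplyr::semi_join(row, net$assertions,
                               by = c("subject", "predicate", "object", "object_kind"))) > 0
  if (!dup) net$assertions <- dplyr::bind_rows(net$assertions, row)
  net
}

# Bulk assertion path used by population: validates vectorised, dedups once.
# `df` columns: subject, predicate, object, object_kind, datatype.
add_assertions_bulk <- function(net, df) {
  if (nrow(df) == 0) return(net)
  known_props <- c(net$obj_props$iri, net$data_props$iri)
  bad <- setdiff(unique(df$predicate), known_props)
  if (length(bad) > 0) stop_onto("undeclared predicates: ", paste(bad, collapse = ", "))
  df <- dplyr::distinct(df)
  df <- dplyr::anti_join(df, net$assertions,
                         by = c("subject", "predicate", "object", "object_kind"))
  net$assertions <- dplyr::bind_rows(net$assertions, df)
  net
}

# All subclasses of `class_iri` (inclusive), following rdfs:subClassOf down.
desc_classes <- function(net, class_iri) {
  out <- class_iri
  repeat {
    more <- net$classes$iri[!is.na(net$classes$parent) & net$classes$parent %in% out]
    more <- setdiff(more, out)
    if (length(more) == 0) break
    out <- c(out, more)
  }
  out
}

# Individuals asserted to `class_iri` or any descendant class.
individuals_of <- function(net, class_iri, closure = TRUE) {
  classes <- if (closure) desc_classes(net, class_iri) else class_iri
  unique(net$individuals$iri[net$individuals$class %in% classes])
}

#' Flatten the network to its full triple set
#'
#' Produces every triple the network carries: module declarations, class and
#' property declarations with domains/ranges, individual typings,
#' restriction annotations, `sameAs` links, annotations and assertions.
#' This is the view serialization, SPARQL matching and round-trip tests
#' operate on.
#'
#' @param net An `onto_network`.
#' @return A tibble with columns `subject`, `predicate`, `object`,
#'   `object_kind`, `datatype`.
#' @export
network_triples <- function(net) {
  red <- function(name) iri(net$network_iri, name)
  t_iri <- function(s, p, o) tibble::tibble(subject = s, predicate = p, object = o,
                                            object_kind = "iri", datatype = NA_character_)
  t_lit <- function(s, p, o, dt = "string") tibble::tibble(subject = s, predicate = p,
                                                           object = o, object_kind = "literal",
                                                           datatype = dt)
  parts <- list()
  mod_subjects <- sub("[#/]$", "", c(net$modules$namespace, net$network_iri))
  parts$mods <- t_iri(mod_subjects, RDF_TYPE, OWL_ONTOLOGY)
  parts$mod_labels <- t_lit(mod_subjects, RDFS_LABEL, c(net$modules$label, "Ontology Network"))
  if (nrow(net$classes) > 0) {
    parts$cls <- t_iri(net$classes$iri, RDF_TYPE, OWL_CLASS)
    sub <- net$classes[!is.na(net$classes$parent), ]
    if (nrow(sub) > 0) parts$sub <- t_iri(sub$iri, RDFS_SUBCLASS, sub$parent)
    np <- net$classes[!net$classes$primitive, ]
    if (nrow(np) > 0) parts$np <- t_lit(np$iri, red("esPrimitiva"), "false")
  }
  if (nrow(net$obj_props) > 0) {
    op <- net$obj_props
    parts$op <- dplyr::bind_rows(
      t_iri(op$iri, RDF_TYPE, OWL_OBJPROP),
      t_iri(op$iri, RDFS_DOMAIN, op$domain),
      t_iri(op$iri, RDFS_RANGE, op$range))
    st <- op[!is.na(op$stage), ]
    if (nrow(st) > 0) parts$stage <- t_lit(st$iri, red("etapa"), st$stage)
  }
  if (nrow(net$data_props) > 0) {
    dp <- net$data_props
    parts$dp <- dplyr::bind_rows(
      t_iri(dp$iri, RDF_TYPE, OWL_DATAPROP),
      t_iri(dp$iri, RDFS_DOMAIN, dp$domain),
      t_iri(dp$iri, RDFS_RANGE, paste0(XSD_NS, dp$range_type)))
  }
  if (nrow(net$individuals) > 0) {
    parts$ind <- t_iri(net$individuals$iri, RDF_TYPE, net$individuals$class)
  }
  if (nrow(net$restrictions) > 0) {
    r <- net$restrictions
    enc <- paste(r$on_property, r$kind, ifelse(is.na(r$n), "", r$n), r$filler,
                 ifelse(r$derived, "derived", "asserted"), sep = "|")
    parts$restr <- t_lit(r$class, red("tieneRestriccion"), enc)
  }
  if (nrow(net$same_as) > 0) parts$same <- t_iri(net$same_as$a, OWL_SAMEAS, net$same_as$b)
  if (nrow(net$annotations) > 0) {
    parts$ann <- t_lit(net$annotations$subject, net$annotations$property, net$annotations$value)
  }
  parts$assertions <- net$assertions
  dplyr::distinct(dplyr::bind_rows(parts))
}

# Query-layer sameAs expansion: triples referring to either member of a
# sameAs pair are replicated under the other, so queries through either IRI
# see the union of assertions. Closure over chains, bounded.
expand_same_as <- function(triples, same_as) {
  if (nrow(same_as) == 0) return(triples)
  map <- list()
  for (i in seq_len(nrow(same_as))) {
    a <- same_as$a[i]; b <- same_as$b[i]
    map[[a]] <- unique(c(map[[a]], b)); map[[b]] <- unique(c(map[[b]], a))
  }
  for (pass in 1:5) {
    extra <- triples[triples$subject %in% names(map) |
                     (triples$object_kind == "iri" & triples$object %in% names(map)), ]
    if (nrow(extra) == 0) break
    alts <- purrr::map_dfr(seq_len(nrow(extra)), function(i) {
      row <- extra[i, ]
      subs <- c(row$subject, map[[row$subject]])
      objs <- if (row$object_kind == "iri") c(row$object, map[[row$object]]) else row$object
      tidyr::expand_grid(subject = subs, object = objs) |>
        dplyr::mutate(predicate = row$predicate, object_kind = row$object_kind,
                      datatype = row$datatype)
    })
    before <- nrow(triples)
    triples <- dplyr::distinct(dplyr::bind_rows(triples, alts))
    if (nrow(triples) == before) break
  }
  triples
}

`%||%` <- function(x, y) if (is.null(x)) y else x
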