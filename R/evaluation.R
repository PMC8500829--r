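# Evaluation harness: competency questions as SPARQL queries with expected
# result shapes, a closed-world cardinality consistency checker for the
# non-primitive class contracts, and a pitfall lint pass (missing metadata,
# naming-convention mixing, missing inverses).

#' Default external-reference fixtures for the diabetes individuals
#'
#' ICD-10 and SNOMED CT codes for the two diabetes-mellitus individuals the
#' Clinical Entity module ships with.
#'
#' @param net An `onto_network`.
#' @return Tibble of references for [annotate_external_refs()].
#' @export
default_external_refs <- function(net) {
  enf <- ns_of_module(net, "enfermedades")
  tibble::tribble(
    ~subject, ~scheme, ~code,
    iri(enf, "DiabetesMellitusTipo1"), "ICD10", "E10",
    iri(enf, "DiabetesMellitusTipo1"), "SCTID", "46635009",
    iri(enf, "DiabetesMellitusTipo2"), "ICD10", "E11",
    iri(enf, "DiabetesMellitusTipo2"), "SCTID", "44054006"
  )
}

#' Default competency-question registry
#'
#' The clinical competency questions (patient weight listing, external code
#' lookup, drug presentations, patient residence), the structural questions
#' answered over the schema (education levels, person categories,
#' consultation data, diagnosis types) and the side-effect traversal from
#' patient through treatment to drug effects. All expectations are
#' `non-empty`.
#'
#' @param net An `onto_network` (namespaces are taken from it).
#' @return Tibble with `id`, `question`, `query`, `expect`.
#' @export
default_competency_registry <- function(net) {
  p <- default_prefixes(net)
  pfx <- function(...) {
    ks <- c(...)
    paste0("PREFIX ", ks, ": <", unlist(p[ks]), ">", collapse = "\n")
  }
  q <- function(id, question, prefixes, body) {
    tibble::tibble(id = id, question = question,
                   query = paste0(prefixes, "\n", body), expect = "non-empty")
  }
  dplyr::bind_rows(
    q("weight", "What is the weight of a patient?", pfx("dato", "red"),
      "SELECT ?patient ?weight ?date WHERE {
         ?patient red:tieneExpedienteClinico ?record .
         ?record dato:tieneNotaMedica ?note .
         ?note dato:tienePeso ?weight .
         ?note dato:tieneFecha ?date }"),
    q("icd10_t2dm", "What is the ICD-10 code for T2DM?", pfx("enf", "red"),
      "SELECT ?icd10 WHERE { enf:DiabetesMellitusTipo2 red:ICD10 ?icd10 }"),
    q("lispro_forms", "What are the presentations of Insulin Lispro?", pfx("medi"),
      "SELECT DISTINCT ?form WHERE {
         ?x medi:tienePrincipioActivo medi:Insulina_Lispro .
         ?y medi:tienePrincipioActivoPorPorcion ?x .
         ?y medi:tieneFormaFarmaceutica ?form }"),
    q("residence", "Where is the patient living?", pfx("red"),
      "SELECT ?patient ?place WHERE { ?patient red:resideEn ?place }"),
    q("education_levels", "What are the main education levels?", pfx("edu", "rdfs"),
      "SELECT ?x WHERE { ?ec rdfs:subClassOf edu:Escolaridad . ?x a ?ec }"),
    q("person_categories", "What are the main categories a person may belong to?",
      pfx("rdfs", "per"),
      "SELECT ?category WHERE { ?category rdfs:subClassOf per:Persona }"),
    q("consultation_data", "What types of data are collected during clinical consultation?",
      pfx("dato", "rdfs"),
      "SELECT ?data ?range WHERE { ?data rdfs:domain dato:Nota_Medica . ?data rdfs:range ?range }"),
    q("diagnosis_types", "What are the types of diagnosis?", pfx("rdfs", "enf"),
      "SELECT ?diagnosis WHERE { ?diagnosis rdfs:subClassOf enf:Entidad_Clinica }"),
    q("side_effects", "What side effects may a patient have from the prescribed treatment?",
      pfx("dato", "red", "medi"),
      "SELECT ?patient ?drug ?effect WHERE {
         ?patient red:tieneExpedienteClinico ?rec .
         ?rec dato:tieneNotaMedica ?note .
         ?note red:tieneTratamiento ?dose .
         ?dose red:tienePrincipioActivoEnReceta ?api .
         ?mapper medi:tienePrincipioActivo ?api .
         ?drug medi:tienePrincipioActivoPorPorcion ?mapper .
         ?drug red:tieneEfectoSecundario ?effect }")
  )
}

#' Run a competency-question registry against the network
#'
#' Each query is executed; a query passes when its expected shape is met
#' (`non-empty`: at least one row, all selected columns present).
#'
#' @param net An `onto_network`.
#' @param registry Registry tibble, see [default_competency_registry()].
#' @return Tibble `id`, `question`, `rows`, `pass`.
#' @export
run_competency_suite <- function(net, registry = default_competency_registry(net)) {
  triples <- expand_same_as(network_triples(net), net$same_as)
  purrr::map_dfr(seq_len(nrow(registry)), function(i) {
    res <- sparql_query(net, registry$query[i], triples = triples)
    pass <- switch(registry$expect[i],
                   "non-empty" = nrow(res) > 0,
                   stop_onto("unknown expectation: ", registry$expect[i]))
    tibble::tibble(id = registry$id[i], question = registry$question[i],
                   rows = nrow(res), pass = pass)
  })
}

#' Check individuals against the non-primitive class contracts
#'
#' For every individual of a restricted class, the observed count of each
#' restricted property is compared with the declared bound: `exactly n`
#' requires the count to equal `n`, `min n` at least `n`, `some` at least
#' one. Restrictions flagged `derived` (rule-produced values) are checked as
#' upper bounds only — under open-world semantics a missing derived value is
#' not a contradiction, while a duplicated one is.
#'
#' @param net An `onto_network` with restrictions attached.
#' @return A `consistency_report` tibble of violations: `individual`,
#'   `class`, `on_property`, `kind`, `n`, `observed`.
#' @export
check_cardinality <- function(net) {
  out <- list()
  r <- net$restrictions
  for (i in seq_len(nrow(r))) {
    inds <- individuals_of(net, r$class[i])
    if (length(inds) == 0) next
    hits <- net$assertions[net$assertions$predicate == r$on_property[i] &
                           net$assertions$subject %in% inds, ]
    counts <- table(factor(hits$subject, levels = inds))
    observed <- as.integer(counts)
    need <- if (r$kind[i] == "some") 1L else r$n[i]
    viol <- if (r$derived[i]) {
      r$kind[i] == "exactly" & observed > need
    } else {
      switch(r$kind[i],
             exactly = observed != need,
             min = observed < need,
             some = observed < 1L)
    }
    if (any(viol)) {
      out[[length(out) + 1]] <- tibble::tibble(
        individual = inds[viol], class = r$class[i], on_property = r$on_property[i],
        kind = r$kind[i], n = r$n[i], observed = observed[viol])
    }
  }
  res <- dplyr::bind_rows(c(list(tibble::tibble(
    individual = character(), class = character(), on_property = character(),
    kind = character(), n = integer(), observed = integer())), out))
  class(res) <- c("consistency_report", class(res))
  res
}

#' Lint the network for design pitfalls
#'
#' Reports elements lacking description metadata (`rdfs:label` or
#' `rdfs:comment`), mixing of naming conventions among property local names
#' (canonical names are Spanish; English-named properties are flagged when
#' both families are present), and object properties without a declared
#' inverse. Inverse findings are informational only: the network omits
#' inverses deliberately to keep reasoning cheap.
#'
#' @param net An `onto_network`.
#' @return Tibble `subject`, `pitfall`, `severity`.
#' @export
lint <- function(net) {
  findings <- list()
  elements <- c(net$classes$iri, net$obj_props$iri, net$data_props$iri)
  annotated <- unique(net$annotations$subject[
    net$annotations$property %in% c(RDFS_LABEL, RDFS_COMMENT)])
  missing <- setdiff(elements, annotated)
  if (length(missing) > 0) {
    findings[[1]] <- tibble::tibble(subject = missing, pitfall = "missing_metadata",
                                    severity = "minor")
  }
  props <- c(net$obj_props$iri, net$data_props$iri)
  locals <- split_iri(props)$local_name
  english <- grepl("^(has|is[A-Z]|writes|presents)", locals)
  spanish <- grepl("^(tiene|es[A-Z]|escribe|presenta|reside)", locals)
  if (any(english) && any(spanish)) {
    findings[[length(findings) + 1]] <- tibble::tibble(
      subject = props[english], pitfall = "naming_convention", severity = "minor")
  }
  op <- net$obj_props
  if (nrow(op) > 0) {
    has_inverse <- vapply(seq_len(nrow(op)), function(i) {
      any(op$domain == op$range[i] & op$range == op$domain[i] & op$iri != op$iri[i])
    }, logical(1))
    if (any(!has_inverse)) {
      findings[[length(findings) + 1]] <- tibble::tibble(
        subject = op$iri[!has_inverse], pitfall = "missing_inverse",
        severity = "informational")
    }
  }
  dplyr::bind_rows(c(list(tibble::tibble(subject = character(), pitfall = character(),
                                         severity = character())), findings))
}

#' Full design evaluation of a network
#'
#' @param net An `onto_network`.
#' @param registry Competency registry.
#' @return List with `satisfiability`, `violations`, `lint`, `competency`.
#' @export
evaluate_network <- function(net, registry = default_competency_registry(net)) {
  structure(list(
    satisfiability = satisfy_check(net),
    violations = check_cardinality(net),
    lint = lint(net),
    competency = run_competency_suite(net, registry)
  ), class = "network_evaluation")
}

#' @export
print.network_evaluation <- function(x, ...) {
  cat("<network_evaluation>\n")
  cat("  satisfiable (all modules populated): ",
      attr(x$satisfiability, "all_nonempty"), "\n", sep = "")
  cat("  cardinality violations: ", nrow(x$violations), "\n", sep = "")
  cat("  lint findings: ", nrow(x$lint),
      " (", sum(x$lint$severity != "informational"), " non-informational)\n", sep = "")
  cat("  competency questions passing: ", sum(x$competency$pass), "/",
      nrow(x$competency), "\n", sep = "")
  invisible(x)
}
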