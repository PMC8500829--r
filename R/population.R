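# Population: convert structured clinical records into individuals and
# assertions. Each module's IRI hosts its own entities; meta-relation
# assertions (livesIn, hasClinicalRecord, hasDiagnosis, ...) use the network
# IRI. Individual names are deterministic slugs from record ids, so
# re-populating the same records is a no-op.

age_at <- function(birth_date, on_date) {
  b <- as.Date(birth_date); d <- as.Date(on_date)
  by <- as.integer(format(b, "%Y")); dy <- as.integer(format(d, "%Y"))
  age <- dy - by
  had_birthday <- format(d, "%m%d") >= format(b, "%m%d")
  as.integer(age - !had_birthday)
}

#' Populate the network from clinical records
#'
#' Creates one Patient individual per record, one Clinical Record, one
#' Clinical History and one Medical Note individual per note, Prescription
#' Dose nodes per prescription with ingredient links and amount / frequency /
#' measure values, doctor individuals from the note authorship, and the
#' meta-relation assertions between them. Sign values land as data
#' properties on the note, including the age at note date (floor of the year
#' difference).
#'
#' @param net A schema-complete `onto_network` (see [build_network()]).
#' @param records List of clinical-record documents (see
#'   [generate_corpus()] or [read_records_jsonl()]).
#' @return The populated network.
#' @export
populate <- function(net, records) {
  if (length(records) == 0) return(net)
  ns <- list(persona = ns_of_module(net, "persona"), datos = ns_of_module(net, "datos"),
             enf = ns_of_module(net, "enfermedades"), est = ns_of_module(net, "estados"),
             niv = ns_of_module(net, "niveles"), tra = ns_of_module(net, "tratamiento"),
             medi = ns_of_module(net, "medicamentos"), red = net$network_iri)
  states <- split_iri(individuals_of(net, iri(ns$est, "Estado")))$local_name
  levels_ok <- split_iri(individuals_of(net, iri(ns$niv, "Escolaridad")))$local_name

  inds <- list()   # iri, class
  asserts <- list() # subject, predicate, object, object_kind, datatype
  ind <- function(iri_, class_) inds[[length(inds) + 1]] <<- c(iri_, class_)
  obj <- function(s, p, o) asserts[[length(asserts) + 1]] <<- list(s, p, o, "iri", NA_character_)
  lit <- function(s, p, o, dt) {
    if (is.null(o) || length(o) == 0 || (is.character(o) && !nzchar(o))) return(invisible())
    asserts[[length(asserts) + 1]] <<- list(s, p, format_literal(o, dt), "literal", dt)
  }
  red <- function(x) iri(ns$red, x); dat <- function(x) iri(ns$datos, x)

  for (rec in records) {
    p <- rec$patient
    if (!p$state %in% states) stop_onto("unknown state of residence: ", p$state)
    if (!p$education_level %in% levels_ok) {
      stop_onto("unknown education level: ", p$education_level)
    }
    pat <- iri(ns$persona, paste0("Paciente_", p$id))
    exp <- dat(paste0("Expediente_", p$id))
    his <- dat(paste0("Historia_", p$id))
    ind(pat, iri(ns$persona, "Paciente"))
    ind(exp, dat("Expediente_Clinico"))
    ind(his, dat("Historia_Clinica"))
    lit(pat, iri(ns$persona, "tieneSexo"), p$sex, "string")
    lit(pat, iri(ns$persona, "tieneFechaNacimiento"), p$birth_date, "date")
    obj(pat, red("resideEn"), iri(ns$est, p$state))
    obj(pat, red("tieneNivelEducativo"), iri(ns$niv, p$education_level))
    obj(pat, red("tieneExpedienteClinico"), exp)
    obj(exp, dat("tieneHistoriaClinica"), his)
    for (dis in rec$histories$disabilities %||% list()) {
      d_iri <- iri(ns$enf, slug_camel(dis))
      ind(d_iri, iri(ns$enf, "Discapacidad"))
      obj(his, red("tieneDiscapacidad"), d_iri)
    }
    for (note in rec$notes) {
      nt <- dat(paste0("Nota_", note$id))
      doc <- iri(ns$persona, note$doctor)
      ind(nt, dat("Nota_Medica"))
      ind(doc, iri(ns$persona, "Medico"))
      obj(exp, dat("tieneNotaMedica"), nt)
      obj(nt, red("esEscritaPor"), doc)
      obj(doc, red("escribeNotaMedica"), nt)
      s <- note$signs
      lit(nt, dat("tieneFecha"), note$date, "date")
      lit(nt, dat("tienePeso"), s$peso, "float")
      lit(nt, dat("tieneTalla"), s$talla, "float")
      lit(nt, dat("tieneGlucosaPostPrandial"), s$glucosa, "integer")
      lit(nt, dat("tieneFrecuenciaCardiaca"), s$frecuencia_cardiaca, "integer")
      lit(nt, dat("tieneFrecuenciaRespiratoria"), s$frecuencia_respiratoria, "integer")
      lit(nt, dat("tieneTemperaturaCorporal"), s$temperatura, "float")
      lit(nt, dat("tieneCintura"), s$cintura, "float")
      lit(nt, dat("tieneCadera"), s$cadera, "float")
      lit(nt, dat("tieneEdad"), age_at(p$birth_date, note$date), "integer")
      lit(nt, dat("tienePadecimientoActual"), note$current_condition, "string")
      lit(nt, dat("tieneExploracionFisica"), note$physical_exam, "string")
      lit(nt, dat("tieneAnalisis"), note$analysis %||% "Sin análisis.", "string")
      for (dg in note$diagnoses) {
        dg_iri <- iri(ns$enf, slug_camel(dg))
        ind(dg_iri, iri(ns$enf, "Enfermedad"))
        obj(nt, red("tieneDiagnostico"), dg_iri)
      }
      k <- 0L
      for (rx in note$prescriptions) {
        k <- k + 1L
        dose <- red(sprintf("_bnDosis_%s_%d", note$id, k))
        api <- iri(ns$medi, slug_underscore(rx$drug))
        plan <- iri(ns$tra, slug_underscore(rx$drug))
        ind(dose, red("Dosis_En_Receta"))
        if (resolve_iri(api, net)$found_as == "absent") {
          ind(api, iri(ns$medi, "Clasificacion_ATC"))
        }
        ind(plan, iri(ns$tra, "Tratamiento_Farmacologico"))
        obj(nt, red("tieneTratamiento"), dose)
        obj(dose, red("tienePrincipioActivoEnReceta"), api)
        if (rx$amount <= 0) stop_onto("prescription amount must be positive (", note$id, ")")
        lit(dose, red("tieneCantidadIndicadaEnReceta"), rx$amount, "float")
        lit(dose, red("tieneFrecuenciaIndicadaEnReceta"), rx$frequency, "float")
        lit(dose, red("tieneMedidaIndicadaEnReceta"), rx$measure, "string")
      }
    }
  }

  ind_df <- dplyr::distinct(tibble::tibble(
    iri = vapply(inds, `[[`, character(1), 1),
    class = vapply(inds, `[[`, character(1), 2)))
  ind_df$module <- vapply(split_iri(ind_df$iri)$namespace,
                          function(x) module_of_ns(net, x), character(1))
  if (anyNA(ind_df$module)) stop_onto("individual namespace matches no module")
  net$individuals <- dplyr::distinct(dplyr::bind_rows(net$individuals,
                                                      ind_df[, c("iri", "class", "module")]))
  assert_df <- tibble::tibble(
    subject = vapply(asserts, function(x) x[[1]], character(1)),
    predicate = vapply(asserts, function(x) x[[2]], character(1)),
    object = vapply(asserts, function(x) as.character(x[[3]]), character(1)),
    object_kind = vapply(asserts, function(x) x[[4]], character(1)),
    datatype = vapply(asserts, function(x) as.character(x[[5]]), character(1)))
  add_assertions_bulk(net, assert_df)
}

#' Per-module individual counts (satisfiability check)
#'
#' The network is satisfiable in the working sense when every participating
#' module holds at least one individual after population.
#'
#' @param net An `onto_network`.
#' @return A `satisfiability_report` tibble (`module`, `label`,
#'   `individuals`, `nonempty`) with attribute `all_nonempty`.
#' @export
satisfy_check <- function(net) {
  counts <- dplyr::count(dplyr::distinct(net$individuals[, c("iri", "module")]),
                         .data$module, name = "individuals")
  out <- dplyr::left_join(net$modules[, c("key", "label")], counts,
                          by = c(key = "module"))
  out$individuals[is.na(out$individuals)] <- 0L
  out$nonempty <- out$individuals > 0
  out <- dplyr::rename(out, module = "key")
  attr(out, "all_nonempty") <- all(out$nonempty)
  class(out) <- c("satisfiability_report", class(out))
  out
}
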