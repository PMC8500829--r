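# Declarative construction of the six domain ontology modules, the
# meta-relation set and the non-primitive class contracts of the diabetes
# ontology network. Spanish local names are canonical (they are the ones the
# executable competency queries use); English names ride along as rdfs:label
# and through the alias map.

#' The 32 states of Mexico
#'
#' Individual slugs used to pre-populate the Geographic Location module.
#'
#' @return Character vector of 32 state slugs.
#' @export
mexican_states <- function() {
  c("Aguascalientes", "Baja_California", "Baja_California_Sur", "Campeche",
    "Chiapas", "Chihuahua", "Ciudad_De_Mexico", "Coahuila", "Colima",
    "Durango", "Guanajuato", "Guerrero", "Hidalgo", "Jalisco",
    "Estado_De_Mexico", "Michoacan", "Morelos", "Nayarit", "Nuevo_Leon",
    "Oaxaca", "Puebla", "Queretaro", "Quintana_Roo", "San_Luis_Potosi",
    "Sinaloa", "Sonora", "Tabasco", "Tamaulipas", "Tlaxcala", "Veracruz",
    "Yucatan", "Zacatecas")
}

#' Education levels fixture
#'
#' A 13-level academic scale following Mexico's education structure, grouped
#' into basic, upper-secondary and higher education. The count is the
#' documented size of the Education Level module; the level names themselves
#' are a package fixture (synthetic), not an official enumeration.
#'
#' @return A tibble with columns `level` and `group`.
#' @export
education_levels <- function() {
  tibble::tibble(
    level = c("Ninguno", "Preescolar", "Primaria", "Secundaria",
              "Carrera_Tecnica", "Bachillerato", "Profesional_Tecnico",
              "Tecnico_Superior_Universitario", "Licenciatura", "Normal_Basica",
              "Especialidad", "Maestria", "Doctorado"),
    group = c(rep("Educacion_Basica", 4), rep("Educacion_Media_Superior", 3),
              rep("Educacion_Superior", 6))
  )
}

# English -> canonical Spanish local names. Both directions are accepted by
# rule files and query registries; canonical storage is always Spanish.
#' Name alias map between English and canonical Spanish property names
#'
#' @return Named character vector: English name -> canonical local name.
#' @export
name_aliases <- function() {
  c(
    isWrittenBy = "esEscritaPor", writesMedicalNote = "escribeNotaMedica",
    presentsDisease = "presentaEnfermedad", presentsSymptom = "presentaSintoma",
    livesIn = "resideEn", hasEducationLevel = "tieneNivelEducativo",
    hasClinicalRecord = "tieneExpedienteClinico", hasDiagnosis = "tieneDiagnostico",
    hasDisability = "tieneDiscapacidad", hasTreatment = "tieneTratamiento",
    hasTreatmento = "tieneTratamiento",
    hasAPIInPrescription = "tienePrincipioActivoEnReceta",
    hasAPIPrescription = "tienePrincipioActivoEnReceta",
    hasSideEffect = "tieneEfectoSecundario",
    hasContraindication = "tieneContraindicacion", hasCaution = "tienePrecaucion",
    hasMedicalNote = "tieneNotaMedica", hasClinicalHistory = "tieneHistoriaClinica",
    hasWeight = "tienePeso", hasHeight = "tieneTalla", hasBMI = "tieneIMC",
    hasWaistMeasure = "tieneCintura", hasHipMeasure = "tieneCadera",
    hasWHI = "tieneICC", hasAge = "tieneEdad", hasGender = "tieneSexo",
    hasBMR = "tieneTMB", hasHumanBiotype = "tieneBiotipoHumano",
    hasBirthDate = "tieneFechaNacimiento", hasDate = "tieneFecha",
    hasActivePharmaceuticalIngredient = "tienePrincipioActivo",
    hasActivePharmacueticalIngredientPerPortion = "tienePrincipioActivoPorPorcion",
    hasAmountOfActivePharmaceuticalIngredient = "tieneCantidadDePrincipioActivo",
    hasPharmaceuticalForm = "tieneFormaFarmaceutica"
  )
}

# Resolve an English alias (or pass a canonical name through).
alias_to_canonical <- function(name) {
  al <- name_aliases()
  ifelse(name %in% names(al), unname(al[name]), name)
}

#' Default schema configuration for the diabetes ontology network
#'
#' Lists the six domain modules with their namespaces, the candidate
#' meta-relations with selection decisions, the meta-relation set with
#' domains, ranges and provenance stage, the non-primitive class contracts,
#' the master-class map used when extraction creates new individuals, and the
#' properties whose values are produced by inference rules.
#'
#' @return A named list; see the methods vignette for the field-by-field
#'   description.
#' @export
default_schema_config <- function() {
  list(
    network_iri = "http://www.diabetes-mexico.org/red#",
    modules = tibble::tribble(
      ~key, ~label, ~namespace,
      "tratamiento", "Control Plan", "http://www.medida-control.com/tratamiento#",
      "enfermedades", "Clinical Entity", "http://www.padecimientos-mexico.org/enfermedades#",
      "niveles", "Education Level", "http://www.niveleseducativos-mexico.org/niveles#",
      "datos", "Clinical Information Administration", "http://www.modelo.org/datos#",
      "estados", "Geographic Location", "http://www.estados-mexico.org/estados#",
      "persona", "Person", "http://www.personas-mexico.org/persona#"
    ),
    drug_module = tibble::tibble(key = "medicamentos", label = "Drug-ATC",
                                 namespace = "http://www.medicamentos-mexico.org/medicamento#"),
    required_domains = c("Control Plan", "Clinical Entity", "Education Level",
                         "Clinical Information Administration", "Geographic Location",
                         "Person"),
    # Candidate meta-relations; selected = NA means "decide by redundancy
    # filter", FALSE needs a rejection_reason.
    candidates = tibble::tribble(
      ~domain, ~name, ~range, ~selected, ~rejection_reason,
      "Patient", "hasClinicalRecord", "Clinical Record", NA, NA,
      "Patient", "hasMedicalNote", "Medical Note", NA, NA,
      "Patient", "hasTreatment", "Prescription Dose", FALSE,
      "treatment varies over time; scoped to the dated medical note",
      "Person", "livesIn", "Geographic Location", NA, NA,
      "Person", "hasEducationLevel", "Education Level", NA, NA,
      "Person", "hasDiagnosis", "Disease", FALSE,
      "diagnoses vary over time; scoped to the dated medical note",
      "Medical Note", "hasTreatment", "Prescription Dose", NA, NA,
      "Medical Note", "hasDiagnosis", "Disease", NA, NA,
      "Drug", "isIndicatedFor", "Disease", FALSE, "not retained in the final design",
      "Medical Note", "isWrittenBy", "Doctor", NA, NA,
      "Doctor", "writesMedicalNote", "Medical Note", NA, NA,
      "Doctor", "attends", "Patient", FALSE, "not retained in the final design",
      "Patient", "isAttendedBy", "Doctor", FALSE, "not retained in the final design"
    ),
    # The 14 meta-relations: 9 from the design stage, 5 from the
    # non-ontological (extraction) stage. domain/range are "module_key:Local".
    meta_relations = tibble::tribble(
      ~name, ~canonical, ~domain, ~range, ~stage,
      "isWrittenBy", "esEscritaPor", "datos:Nota_Medica", "persona:Medico", "design",
      "presentsDisease", "presentaEnfermedad", "datos:Nota_Medica", "enfermedades:Enfermedad", "extraction",
      "presentsSymptom", "presentaSintoma", "datos:Nota_Medica", "enfermedades:Sintoma", "extraction",
      "writesMedicalNote", "escribeNotaMedica", "persona:Medico", "datos:Nota_Medica", "design",
      "livesIn", "resideEn", "persona:Paciente", "estados:Estado", "design",
      "hasAPIInPrescription", "tienePrincipioActivoEnReceta", "red:Dosis_En_Receta", "medicamentos:Clasificacion_ATC", "design",
      "hasContraindication", "tieneContraindicacion", "medicamentos:Medicamento", "enfermedades:Entidad_Clinica", "extraction",
      "hasDiagnosis", "tieneDiagnostico", "datos:Nota_Medica", "enfermedades:Enfermedad", "design",
      "hasDisability", "tieneDiscapacidad", "datos:Historia_Clinica", "enfermedades:Discapacidad", "design",
      "hasSideEffect", "tieneEfectoSecundario", "medicamentos:Medicamento", "enfermedades:Entidad_Clinica", "extraction",
      "hasEducationLevel", "tieneNivelEducativo", "persona:Paciente", "niveles:Escolaridad", "design",
      "hasClinicalRecord", "tieneExpedienteClinico", "persona:Paciente", "datos:Expediente_Clinico", "design",
      "hasCaution", "tienePrecaucion", "medicamentos:Medicamento", "enfermedades:Entidad_Clinica", "extraction",
      "hasTreatment", "tieneTratamiento", "datos:Nota_Medica", "red:Dosis_En_Receta", "design"
    ),
    # Master class per module: the class a new extraction-created individual
    # is asserted into. The mechanism is part of the design; the mapping is a
    # package configuration choice.
    master_classes = c(
      enfermedades = "Entidad_Clinica", tratamiento = "Tratamiento_Farmacologico",
      persona = "Persona", datos = "Nota_Medica", estados = "Estado",
      niveles = "Escolaridad", medicamentos = "Medicamento"
    ),
    # Properties whose values only exist after inference rules run; their
    # cardinality restrictions are checked as upper bounds (open-world
    # reading: a missing derived value is not a contradiction).
    derived_props = c("tieneIMC", "tieneICC", "tieneTMB", "tieneBiotipoHumano")
  )
}

# ---------------------------------------------------------------------------

#' Build the six empty-but-typed domain modules
#'
#' Creates the module namespaces, their class skeletons, intra-module
#' properties, and the pre-populated fixtures: 32 Mexican state individuals
#' in Geographic Location and the 13-level Education Level scale. The
#' network-level Prescription Dose class lives in the network namespace.
#'
#' @param config Schema configuration, see [default_schema_config()].
#' @return An `onto_network` with six modules.
#' @export
build_module_schemas <- function(config = default_schema_config()) {
  missing <- setdiff(config$required_domains, config$modules$label)
  if (length(missing) > 0) {
    stop_onto("schema configuration is missing module(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(config$modules$namespace) > 0) {
    stop_onto("duplicate module IRI in configuration")
  }
  net <- new_network(config$network_iri)
  for (i in seq_len(nrow(config$modules))) {
    net <- add_module(net, config$modules$key[i], config$modules$label[i],
                      config$modules$namespace[i])
  }
  ns <- function(key) ns_of_module(net, key)
  cls <- function(key, name) iri(ns(key), name)

  # Person: patients and doctors.
  net <- net |>
    add_class(cls("persona", "Persona"), label = "Person") |>
    add_class(cls("persona", "Paciente"), parent = cls("persona", "Persona"),
              primitive = FALSE, label = "Patient") |>
    add_class(cls("persona", "Medico"), parent = cls("persona", "Persona"),
              primitive = FALSE, label = "Doctor") |>
    add_data_property(cls("persona", "tieneSexo"), cls("persona", "Persona"),
                      "string", label = "hasGender") |>
    add_data_property(cls("persona", "tieneFechaNacimiento"), cls("persona", "Persona"),
                      "date", label = "hasBirthDate") |>
    add_data_property(cls("persona", "tieneNombre"), cls("persona", "Persona"),
                      "string", label = "hasName")

  # Clinical Information Administration: records, notes, histories, biotypes.
  net <- net |>
    add_class(cls("datos", "Expediente_Clinico"), label = "Clinical Record") |>
    add_class(cls("datos", "Nota_Medica"), primitive = FALSE, label = "Medical Note") |>
    add_class(cls("datos", "Historia_Clinica"), primitive = FALSE, label = "Clinical History") |>
    add_class(cls("datos", "Biotipo_Humano"), label = "Human Biotype") |>
    add_individual(cls("datos", "Overweight"), cls("datos", "Biotipo_Humano"),
                   label = "Overweight") |>
    add_object_property(cls("datos", "tieneNotaMedica"), cls("datos", "Expediente_Clinico"),
                        cls("datos", "Nota_Medica"), label = "hasMedicalNote") |>
    add_object_property(cls("datos", "tieneHistoriaClinica"), cls("datos", "Expediente_Clinico"),
                        cls("datos", "Historia_Clinica"), label = "hasClinicalHistory") |>
    add_object_property(cls("datos", "tieneBiotipoHumano"), cls("datos", "Nota_Medica"),
                        cls("datos", "Biotipo_Humano"), label = "hasHumanBiotype")
  note_props <- tibble::tribble(
    ~name, ~type, ~label,
    "tieneFecha", "date", "hasDate",
    "tienePeso", "float", "hasWeight",
    "tieneTalla", "float", "hasHeight",
    "tieneIMC", "float", "hasBMI",
    "tieneCintura", "float", "hasWaistMeasure",
    "tieneCadera", "float", "hasHipMeasure",
    "tieneICC", "float", "hasWHI",
    "tieneTMB", "float", "hasBMR",
    "tieneEdad", "integer", "hasAge",
    "tieneGlucosaPostPrandial", "integer", "hasPostprandialGlucose",
    "tieneFrecuenciaCardiaca", "integer", "hasHeartRate",
    "tieneFrecuenciaRespiratoria", "integer", "hasRespiratoryRate",
    "tieneTemperaturaCorporal", "float", "hasBodyTemperature",
    "tienePadecimientoActual", "string", "hasCurrentCondition",
    "tieneExploracionFisica", "string", "hasPhysicalExamination",
    "tieneAnalisis", "string", "hasAnalysis"
  )
  for (i in seq_len(nrow(note_props))) {
    net <- add_data_property(net, cls("datos", note_props$name[i]),
                             cls("datos", "Nota_Medica"), note_props$type[i],
                             label = note_props$label[i])
  }

  # Clinical Entity: diseases, symptoms, disabilities.
  net <- net |>
    add_class(cls("enfermedades", "Entidad_Clinica"), label = "Clinical Entity") |>
    add_class(cls("enfermedades", "Enfermedad"), parent = cls("enfermedades", "Entidad_Clinica"),
              label = "Disease") |>
    add_class(cls("enfermedades", "Sintoma"), parent = cls("enfermedades", "Entidad_Clinica"),
              label = "Symptom") |>
    add_class(cls("enfermedades", "Discapacidad"), parent = cls("enfermedades", "Entidad_Clinica"),
              label = "Disability") |>
    add_individual(cls("enfermedades", "DiabetesMellitusTipo1"), cls("enfermedades", "Enfermedad"),
                   label = "Insulin-dependent Diabetes Mellitus") |>
    add_individual(cls("enfermedades", "DiabetesMellitusTipo2"), cls("enfermedades", "Enfermedad"),
                   label = "Non-insulin-dependent Diabetes Mellitus")

  # Education Level: 13-level fixture scale under three stage subclasses.
  net <- add_class(net, cls("niveles", "Escolaridad"), label = "Education Level")
  lv <- education_levels()
  for (g in unique(lv$group)) {
    net <- add_class(net, cls("niveles", g), parent = cls("niveles", "Escolaridad"))
  }
  for (i in seq_len(nrow(lv))) {
    net <- add_individual(net, cls("niveles", lv$level[i]), cls("niveles", lv$group[i]),
                          label = gsub("_", " ", lv$level[i]))
  }

  # Geographic Location: the 32 states.
  net <- add_class(net, cls("estados", "Estado"), label = "Geographic Location")
  for (s in mexican_states()) {
    net <- add_individual(net, cls("estados", s), cls("estados", "Estado"),
                          label = gsub("_", " ", s))
  }

  # Control Plan: diet, exercise, pharmacological treatment.
  net <- net |>
    add_class(cls("tratamiento", "Plan_De_Control"), label = "Control Plan") |>
    add_class(cls("tratamiento", "Dieta"), parent = cls("tratamiento", "Plan_De_Control"),
              label = "Diet") |>
    add_class(cls("tratamiento", "Ejercicio"), parent = cls("tratamiento", "Plan_De_Control"),
              label = "Exercise") |>
    add_class(cls("tratamiento", "Tratamiento_Farmacologico"),
              parent = cls("tratamiento", "Plan_De_Control"),
              label = "Pharmaceutical Treatment")

  # Network-level Prescription Dose class and its data properties (it has no
  # module of its own; its IRI is the network's).
  red <- function(name) iri(net$network_iri, name)
  net <- net |>
    add_class(red("Dosis_En_Receta"), primitive = FALSE, label = "Prescription Dose") |>
    add_data_property(red("tieneCantidadIndicadaEnReceta"), red("Dosis_En_Receta"),
                      "float", label = "hasPrescribedAmount") |>
    add_data_property(red("tieneFrecuenciaIndicadaEnReceta"), red("Dosis_En_Receta"),
                      "float", label = "hasPrescribedFrequency") |>
    add_data_property(red("tieneMedidaIndicadaEnReceta"), red("Dosis_En_Receta"),
                      "string", label = "hasPrescribedMeasure")
  net
}

# ---------------------------------------------------------------------------

#' Filter candidate meta-relations for redundancy
#'
#' A candidate `(A, r, C)` is rejected when the relation is already reachable
#' through an intermediate class: some property or selected candidate
#' `(B, r, C)` carries the same relation name (alias-folded) and `B` is
#' reachable from `A` via declared properties or selected candidates. This
#' reproduces the two worked rejections of the design stage (a patient's
#' medical notes hang off the clinical record; treatment and diagnosis are
#' scoped to the medical note). Candidates with an explicit `selected` flag
#' are honoured as given.
#'
#' @param candidates Tibble with columns `domain`, `name`, `range`,
#'   `selected` (logical, `NA` = decide here), `rejection_reason`.
#' @param net An `onto_network` whose declared properties count as existing
#'   paths.
#' @return The candidates tibble with `selected` filled in and
#'   `rejection_reason` set for every rejected row.
#' @export
select_meta_relations <- function(candidates, net) {
  if (nrow(candidates) == 0) return(candidates)
  cand <- candidates
  # Edges: declared object properties (by label/local name) plus candidates
  # not explicitly rejected.
  declared <- net$obj_props
  declared_names <- alias_to_canonical(split_iri(declared$iri)$local_name)
  cls_label <- function(iri_) {
    lb <- net$annotations$value[net$annotations$subject == iri_ &
                                net$annotations$property == RDFS_LABEL]
    if (length(lb) > 0) lb[[1]] else split_iri(iri_)$local_name
  }
  declared_edges <- tibble::tibble(
    from = vapply(declared$domain, cls_label, character(1)),
    name = declared_names,
    to = vapply(declared$range, cls_label, character(1))
  )
  cand_edges <- tibble::tibble(
    from = cand$domain,
    name = alias_to_canonical(cand$name),
    to = cand$range,
    idx = seq_len(nrow(cand)),
    explicit_reject = !is.na(cand$selected) & !cand$selected
  )
  # subclass links (by label) are zero-cost moves for reachability: a
  # relation declared on Patient is usable where Person is, and vice versa
  sub <- net$classes[!is.na(net$classes$parent), ]
  subclass_edges <- dplyr::bind_rows(
    tibble::tibble(from = vapply(sub$parent, cls_label, character(1)),
                   to = vapply(sub$iri, cls_label, character(1))),
    tibble::tibble(from = vapply(sub$iri, cls_label, character(1)),
                   to = vapply(sub$parent, cls_label, character(1))))
  reachable_from <- function(a, excluding_idx) {
    edges <- dplyr::bind_rows(
      declared_edges[, c("from", "to")],
      subclass_edges,
      cand_edges[!cand_edges$explicit_reject & cand_edges$idx != excluding_idx,
                 c("from", "to")])
    seen <- a
    repeat {
      more <- setdiff(edges$to[edges$from %in% seen], seen)
      if (length(more) == 0) break
      seen <- c(seen, more)
    }
    setdiff(seen, a)
  }
  for (i in seq_len(nrow(cand))) {
    if (!is.na(cand$selected[i])) next
    a <- cand_edges$from[i]; r <- cand_edges$name[i]; c_ <- cand_edges$to[i]
    mids <- reachable_from(a, i)
    # an already-declared intra-module property carrying the same relation
    # from a reachable intermediate subsumes the candidate
    same_rel <- declared_edges[declared_edges$name == r & declared_edges$to == c_, ]
    if (nrow(same_rel) > 0 && any(same_rel$from %in% mids)) {
      cand$selected[i] <- FALSE
      cand$rejection_reason[i] <- paste0("redundant: already reachable via ",
                                         same_rel$from[same_rel$from %in% mids][1])
    } else {
      cand$selected[i] <- TRUE
    }
  }
  bad <- !cand$selected & (is.na(cand$rejection_reason) | cand$rejection_reason == "")
  if (any(bad)) stop_onto("rejected candidates must carry a rejection reason")
  cand
}

# ---------------------------------------------------------------------------

resolve_config_class <- function(net, spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  iri(ns_of_module(net, parts[1]), parts[2])
}

#' Attach the meta-relation set to a built network
#'
#' Materialises each meta-relation as an object property in the network
#' namespace with its domain, range and provenance stage (`design` or
#' `extraction`). Canonical Spanish local names; English names as labels.
#'
#' @param net An `onto_network` with its modules built (including the
#'   Drug-ATC module when meta-relations reference it).
#' @param meta Meta-relation table, see `default_schema_config()$meta_relations`.
#' @return The updated network.
#' @export
attach_meta_relations <- function(net, meta = default_schema_config()$meta_relations) {
  for (i in seq_len(nrow(meta))) {
    dom <- resolve_config_class(net, meta$domain[i])
    rng <- resolve_config_class(net, meta$range[i])
    for (cl in c(dom, rng)) {
      if (!cl %in% net$classes$iri) {
        stop_onto("meta-relation '", meta$name[i], "' names an absent class: ", cl)
      }
    }
    net <- add_object_property(net, iri(net$network_iri, meta$canonical[i]),
                               dom, rng, stage = meta$stage[i], label = meta$name[i])
  }
  net
}

#' Meta-relations currently declared in the network namespace
#'
#' @param net An `onto_network`.
#' @return Tibble with `iri`, `name`, `domain`, `range`, `stage`.
#' @export
meta_relations <- function(net) {
  mr <- net$obj_props[net$obj_props$module == "red" & !is.na(net$obj_props$stage), ]
  tibble::tibble(iri = mr$iri, name = split_iri(mr$iri)$local_name,
                 domain = mr$domain, range = mr$range, stage = mr$stage)
}

# ---------------------------------------------------------------------------

#' Default non-primitive class contracts
#'
#' The restriction conjunctions for Patient, Medical Note, Doctor,
#' Prescription Dose and Clinical History. Fillers are class IRI specs
#' (`module:Local`) or xsd literal types. `derived` marks restrictions over
#' rule-derived values (checked as upper bounds by the consistency checker).
#'
#' @param config Schema configuration (for the derived-property list).
#' @return Tibble with columns `class`, `on`, `kind`, `n`, `filler`.
#' @export
default_nonprimitive_defs <- function(config = default_schema_config()) {
  defs <- tibble::tribble(
    ~class, ~on, ~kind, ~n, ~filler,
    "persona:Paciente", "red:resideEn", "exactly", 1L, "estados:Estado",
    "persona:Paciente", "red:tieneNivelEducativo", "exactly", 1L, "niveles:Escolaridad",
    "persona:Paciente", "red:tieneExpedienteClinico", "exactly", 1L, "datos:Expediente_Clinico",
    "persona:Paciente", "persona:tieneFechaNacimiento", "exactly", 1L, "xsd:date",
    "persona:Paciente", "persona:tieneSexo", "exactly", 1L, "xsd:string",
    "datos:Nota_Medica", "red:tieneTratamiento", "some", NA_integer_, "red:Dosis_En_Receta",
    "datos:Nota_Medica", "datos:tieneBiotipoHumano", "some", NA_integer_, "datos:Biotipo_Humano",
    "datos:Nota_Medica", "red:tieneDiagnostico", "min", 1L, "enfermedades:Entidad_Clinica",
    "datos:Nota_Medica", "red:esEscritaPor", "exactly", 1L, "persona:Medico",
    "datos:Nota_Medica", "datos:tieneGlucosaPostPrandial", "some", NA_integer_, "xsd:integer",
    "datos:Nota_Medica", "datos:tieneAnalisis", "exactly", 1L, "xsd:string",
    "datos:Nota_Medica", "datos:tieneExploracionFisica", "exactly", 1L, "xsd:string",
    "datos:Nota_Medica", "datos:tieneFecha", "exactly", 1L, "xsd:date",
    "datos:Nota_Medica", "datos:tieneFrecuenciaCardiaca", "exactly", 1L, "xsd:integer",
    "datos:Nota_Medica", "datos:tieneFrecuenciaRespiratoria", "exactly", 1L, "xsd:integer",
    "datos:Nota_Medica", "datos:tieneICC", "exactly", 1L, "xsd:float",
    "datos:Nota_Medica", "datos:tieneIMC", "exactly", 1L, "xsd:float",
    "datos:Nota_Medica", "datos:tienePadecimientoActual", "exactly", 1L, "xsd:string",
    "datos:Nota_Medica", "datos:tienePeso", "exactly", 1L, "xsd:float",
    "datos:Nota_Medica", "datos:tieneTMB", "exactly", 1L, "xsd:float",
    "datos:Nota_Medica", "datos:tieneTalla", "exactly", 1L, "xsd:float",
    "datos:Nota_Medica", "datos:tieneTemperaturaCorporal", "exactly", 1L, "xsd:float",
    "persona:Medico", "red:escribeNotaMedica", "some", NA_integer_, "datos:Nota_Medica",
    "red:Dosis_En_Receta", "red:tienePrincipioActivoEnReceta", "some", NA_integer_, "medicamentos:Clasificacion_ATC",
    "red:Dosis_En_Receta", "red:tieneCantidadIndicadaEnReceta", "some", NA_integer_, "xsd:float",
    "red:Dosis_En_Receta", "red:tieneFrecuenciaIndicadaEnReceta", "some", NA_integer_, "xsd:float",
    "red:Dosis_En_Receta", "red:tieneMedidaIndicadaEnReceta", "some", NA_integer_, "xsd:string",
    "datos:Historia_Clinica", "red:tieneDiscapacidad", "some", NA_integer_, "enfermedades:Discapacidad"
  )
  defs
}

#' Attach non-primitive class definitions (restriction conjunctions)
#'
#' @param net An `onto_network` with modules and meta-relations attached.
#' @param defs Restriction table, see [default_nonprimitive_defs()].
#' @param derived_props Local names of rule-derived properties; restrictions
#'   on them are flagged `derived` for the consistency checker.
#' @return The updated network.
#' @export
attach_nonprimitive_defs <- function(net, defs = default_nonprimitive_defs(),
                                     derived_props = default_schema_config()$derived_props) {
  if (nrow(defs) == 0) return(net)
  for (i in seq_len(nrow(defs))) {
    class_iri <- resolve_config_class(net, defs$class[i])
    on_iri <- resolve_config_class(net, defs$on[i])
    if (resolve_iri(on_iri, net)$found_as == "absent") {
      stop_onto("restriction on undeclared property: ", on_iri)
    }
    filler <- if (startsWith(defs$filler[i], "xsd:")) {
      paste0(XSD_NS, sub("^xsd:", "", defs$filler[i]))
    } else {
      resolve_config_class(net, defs$filler[i])
    }
    local <- split_iri(on_iri)$local_name
    row <- tibble::tibble(class = class_iri, on_property = on_iri, kind = defs$kind[i],
                          n = defs$n[i], filler = filler,
                          derived = local %in% derived_props)
    net$restrictions <- dplyr::distinct(dplyr::bind_rows(net$restrictions, row))
    net$classes$primitive[net$classes$iri == class_iri] <- FALSE
  }
  net
}

#' Retrieve the restriction conjunction attached to a class
#'
#' @param net An `onto_network`.
#' @param class_iri Class IRI.
#' @return Tibble of restrictions.
#' @export
class_restrictions <- function(net, class_iri) {
  net$restrictions[net$restrictions$class == class_iri, ]
}

# ---------------------------------------------------------------------------

#' Build the full default network schema
#'
#' Convenience wrapper: module schemas, the Drug-ATC demonstration module
#' (built through the integration operations), the 14 meta-relations and the
#' non-primitive class contracts.
#'
#' @param config Schema configuration.
#' @return A schema-complete `onto_network`, unpopulated.
#' @export
build_network <- function(config = default_schema_config()) {
  build_module_schemas(config) |>
    attach_drug_atc_demo() |>
    attach_meta_relations(config$meta_relations) |>
    attach_nonprimitive_defs(default_nonprimitive_defs(config), config$derived_props)
}
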