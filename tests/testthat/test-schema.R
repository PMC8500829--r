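test_that("the six domain modules are built with their documented namespaces and fixtures", {
  net <- build_module_schemas()
  expect_equal(nrow(net$modules), 6)
  expect_setequal(net$modules$namespace, c(
    "http://www.medida-control.com/tratamiento#",
    "http://www.padecimientos-mexico.org/enfermedades#",
    "http://www.niveleseducativos-mexico.org/niveles#",
    "http://www.modelo.org/datos#",
    "http://www.estados-mexico.org/estados#",
    "http://www.personas-mexico.org/persona#"))
  geo <- net$individuals[net$individuals$module == "estados", ]
  expect_equal(nrow(geo), 32)
  edu <- net$individuals[net$individuals$module == "niveles", ]
  expect_equal(nrow(edu), 13)

  cfg <- default_schema_config()
  cfg$modules <- cfg$modules[cfg$modules$label != "Person", ]
  expect_error(build_module_schemas(cfg), "Person")
  cfg2 <- default_schema_config()
  cfg2$modules$namespace[2] <- cfg2$modules$namespace[1]
  expect_error(build_module_schemas(cfg2), "duplicate module IRI")
})

test_that("the redundancy filter rejects path-subsumed candidates and keeps the rest", {
  net <- build_module_schemas()  # declares Clinical Record -hasMedicalNote-> Medical Note
  cand <- default_schema_config()$candidates
  out <- select_meta_relations(cand, net)
  decision <- function(d, n) out$selected[out$domain == d & out$name == n]
  expect_false(decision("Patient", "hasMedicalNote"))
  expect_true(decision("Patient", "hasClinicalRecord"))
  # treatment and diagnosis are scoped to the medical note, not the patient
  expect_false(decision("Patient", "hasTreatment"))
  expect_false(decision("Person", "hasDiagnosis"))
  expect_true(decision("Medical Note", "hasTreatment"))
  expect_true(decision("Medical Note", "hasDiagnosis"))
  expect_true(all(out$selected | !is.na(out$rejection_reason)))

  empty <- cand[0, ]
  expect_identical(select_meta_relations(empty, net), empty)
})

test_that("the meta-relation set is materialised with stage provenance, 9 design + 5 extraction", {
  net <- build_network()
  mr <- meta_relations(net)
  expect_equal(nrow(mr), 14)
  expect_equal(sum(mr$stage == "design"), 9)
  expect_equal(sum(mr$stage == "extraction"), 5)
  expect_setequal(mr$name[mr$stage == "extraction"],
                  c("presentaEnfermedad", "presentaSintoma", "tieneEfectoSecundario",
                    "tieneContraindicacion", "tienePrecaucion"))
  # row-for-row domains and ranges from the configuration
  cfg <- default_schema_config()$meta_relations
  for (i in seq_len(nrow(cfg))) {
    row <- mr[mr$name == cfg$canonical[i], ]
    expect_equal(nrow(row), 1, info = cfg$canonical[i])
    expect_equal(split_iri(row$domain)$local_name,
                 sub("^.*:", "", cfg$domain[i]), info = cfg$canonical[i])
    expect_equal(split_iri(row$range)$local_name,
                 sub("^.*:", "", cfg$range[i]), info = cfg$canonical[i])
  }
  # English names ride along as labels
  lbl <- net$annotations[net$annotations$subject == iri(net$network_iri, "esEscritaPor") &
                         net$annotations$property == ontonet:::RDFS_LABEL, ]
  expect_equal(lbl$value, "isWrittenBy")
  # cross-module rule: domain and range modules differ except around the
  # network-level Prescription Dose class
  dose <- iri(net$network_iri, "Dosis_En_Receta")
  for (i in seq_len(nrow(mr))) {
    if (dose %in% c(mr$domain[i], mr$range[i])) next
    expect_false(split_iri(mr$domain[i])$namespace == split_iri(mr$range[i])$namespace,
                 info = mr$name[i])
  }
  # naming an absent class fails
  bad <- default_schema_config()$meta_relations[1, ]
  bad$domain <- "persona:NoSuchClass"
  expect_error(attach_meta_relations(build_module_schemas(), bad), "absent class")
})

test_that("non-primitive class contracts are attached and retrievable", {
  net <- build_network()
  pat <- class_restrictions(net, iri(ns <- "http://www.personas-mexico.org/persona#", "Paciente"))
  exactly1 <- pat[pat$kind == "exactly" & pat$n == 1, ]
  locals <- split_iri(exactly1$on_property)$local_name
  expect_true(all(c("resideEn", "tieneNivelEducativo", "tieneExpedienteClinico",
                    "tieneFechaNacimiento", "tieneSexo") %in% locals))
  doc <- class_restrictions(net, iri(ns, "Medico"))
  expect_equal(nrow(doc), 1)
  expect_equal(doc$kind, "some")
  expect_equal(split_iri(doc$on_property)$local_name, "escribeNotaMedica")
  # classes carrying restrictions are non-primitive
  expect_false(net$classes$primitive[net$classes$iri == iri(ns, "Paciente")])
  # empty def list leaves the network unchanged
  net0 <- build_module_schemas()
  expect_identical(attach_nonprimitive_defs(net0, default_nonprimitive_defs()[0, ]), net0)
  # restriction on an undeclared property fails
  bad <- tibble::tibble(class = "persona:Paciente", on = "persona:noSuchProp",
                        kind = "some", n = NA_integer_, filler = "xsd:string")
  expect_error(attach_nonprimitive_defs(net0, bad), "cannot resolve|undeclared")
})

test_that("schema building is deterministic", {
  expect_identical(sorted_triples(build_network()), sorted_triples(build_network()))
})
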