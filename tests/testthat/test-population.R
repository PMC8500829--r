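minimal_record <- function() {
  list(
    patient = list(id = "P001", sex = "Female", birth_date = "1950-06-15",
                   state = "Puebla", education_level = "Primaria"),
    histories = list(disabilities = list("discapacidad motriz")),
    notes = list(list(
      id = "P001_1", date = "2020-03-10", doctor = "Medico_01",
      signs = list(peso = 80, talla = 1.6, glucosa = 150L, frecuencia_cardiaca = 80L,
                   frecuencia_respiratoria = 18L, temperatura = 36.6,
                   cintura = 90, cadera = 100),
      current_condition = "Paciente refiere poliuria.",
      physical_exam = "Sin hallazgos.", analysis = "Control.",
      diagnoses = list("diabetes mellitus tipo 2"),
      prescriptions = list(list(drug = "Metformina", amount = 1, measure = "tableta",
                                frequency = 2))
    ))
  )
}

test_that("populating a minimal record creates the expected individuals and assertions", {
  net0 <- build_network()
  net <- populate(net0, list(minimal_record()))
  datos <- "http://www.modelo.org/datos#"; per <- "http://www.personas-mexico.org/persona#"
  created <- setdiff(unique(net$individuals$iri), unique(net0$individuals$iri))
  count_kind <- function(cls) sum(net$individuals$class == cls &
                                  net$individuals$iri %in% created)
  expect_equal(count_kind(iri(per, "Paciente")), 1)
  expect_equal(count_kind(iri(datos, "Expediente_Clinico")), 1)
  expect_equal(count_kind(iri(datos, "Nota_Medica")), 1)
  expect_equal(count_kind(iri(net$network_iri, "Dosis_En_Receta")), 1)

  # meta-relation assertions use the network namespace
  lives <- net$assertions[net$assertions$subject == iri(per, "Paciente_P001") &
                          grepl("resideEn$", net$assertions$predicate), ]
  expect_equal(nrow(lives), 1)
  expect_true(startsWith(lives$predicate, net$network_iri))
  expect_equal(lives$object, "http://www.estados-mexico.org/estados#Puebla")

  # age at note date: floor of year difference
  age <- net$assertions$object[net$assertions$predicate == iri(datos, "tieneEdad")]
  expect_equal(age, "69")

  # empty record list leaves the network unchanged
  expect_identical(sorted_triples(populate(net0, list())), sorted_triples(net0))
})

test_that("unknown states and education levels are rejected by name", {
  net <- build_network()
  bad_state <- minimal_record(); bad_state$patient$state <- "Atlantis"
  expect_error(populate(net, list(bad_state)), "Atlantis")
  bad_edu <- minimal_record(); bad_edu$patient$education_level <- "Cuatrimestre"
  expect_error(populate(net, list(bad_edu)), "Cuatrimestre")
})

test_that("population is idempotent and stable from record ids", {
  fix <- tiny_populated()
  net1 <- fix$net
  net2 <- populate(net1, fix$corpus$records)
  expect_identical(sorted_triples(net1), sorted_triples(net2))
})

test_that("populated patients satisfy the Patient contract; violations are detected when broken", {
  fix <- tiny_populated()
  net <- fix$net
  expect_equal(nrow(check_cardinality(net)), 0)

  # two livesIn assertions on one patient -> exactly-1 violation observed 2
  per <- "http://www.personas-mexico.org/persona#"
  est <- "http://www.estados-mexico.org/estados#"
  pat <- net$individuals$iri[net$individuals$class == iri(per, "Paciente")][1]
  current <- net$assertions$object[net$assertions$subject == pat &
                                   grepl("resideEn$", net$assertions$predicate)]
  other <- setdiff(c(iri(est, "Puebla"), iri(est, "Jalisco")), current)[1]
  net_bad <- add_assertion(net, pat, iri(net$network_iri, "resideEn"), other)
  v <- check_cardinality(net_bad)
  expect_equal(nrow(v), 1)
  expect_equal(v$individual, pat)
  expect_equal(v$observed, 2L)

  # a doctor who writes no notes violates the existential contract
  net_doc <- add_individual(net, iri(per, "Medico_99"), iri(per, "Medico"))
  v2 <- check_cardinality(net_doc)
  expect_equal(nrow(v2), 1)
  expect_match(v2$on_property, "escribeNotaMedica")
  expect_equal(v2$observed, 0L)
})

test_that("satisfiability counts agree with a brute-force scan", {
  fix <- tiny_populated()
  net <- fix$net
  rep <- satisfy_check(net)
  expect_true(attr(rep, "all_nonempty"))
  for (i in seq_len(nrow(rep))) {
    ns <- ontonet:::ns_of_module(net, rep$module[i])
    brute <- length(unique(net$individuals$iri[startsWith(net$individuals$iri, ns)]))
    expect_equal(rep$individuals[i], brute, info = rep$module[i])
  }
  # patient count equals the corpus profile
  per <- "http://www.personas-mexico.org/persona#"
  n_pat <- length(unique(net$individuals$iri[net$individuals$class == iri(per, "Paciente")]))
  expect_equal(n_pat, fix$corpus$profile$n_patients)

  # schema alone: clinical modules are empty, pre-populated fixtures are not
  rep0 <- satisfy_check(build_network())
  expect_false(attr(rep0, "all_nonempty"))
  expect_true(rep0$nonempty[rep0$module == "estados"])
  expect_true(rep0$nonempty[rep0$module == "niveles"])
  expect_false(rep0$nonempty[rep0$module == "persona"])
})
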