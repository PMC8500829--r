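toy_atc_net <- function() {
  net <- new_network("http://example.org/net#")
  net <- add_module(net, "m", "Drugs", "http://example.org/m#")
  m <- function(x) iri("http://example.org/m#", x)
  net <- add_class(net, m("Root"))
  net <- add_class(net, m("A10BA"), parent = m("Root"))
  net <- add_class(net, m("A10BA02"), parent = m("A10BA"), label = "Metformina")
  net <- add_data_property(net, m("tieneClaveATC"), m("Root"), "string")
  net
}

test_that("name matching finds exact and synonym matches, all unverified", {
  net <- build_network()
  matches <- find_name_matches(net, "tratamiento", "medicamentos")
  expect_equal(nrow(matches), 0)  # schema alone shares no names

  # seed a Control Plan entry named like an ATC ingredient
  tra <- "http://www.medida-control.com/tratamiento#"
  net <- add_individual(net, iri(tra, "Metformina"),
                        iri(tra, "Tratamiento_Farmacologico"), label = "Metformina")
  matches <- find_name_matches(net, "tratamiento", "medicamentos")
  expect_true(any(matches$match_basis == "exact_name" &
                  grepl("Metformina$", matches$element_b)))
  expect_true(all(!matches$verified))

  # synonym matches go through the lexicon (brute-force join on canonicals)
  net <- add_individual(net, iri(tra, "Acetaminofen"),
                        iri(tra, "Tratamiento_Farmacologico"), label = "Acetaminofen")
  lex <- tibble::tibble(term = c("acetaminofen", "paracetamol"),
                        canonical = "paracetamol", source = "lexicon")
  matches <- find_name_matches(net, "tratamiento", "medicamentos", lexicon = lex)
  syn <- matches[matches$match_basis == "synonym", ]
  expect_true(any(grepl("Acetaminofen$", syn$element_a) &
                  grepl("Paracetamol$", syn$element_b)))
})

test_that("semantic verification records evidence from shared external codes", {
  net <- build_network()
  tra <- "http://www.medida-control.com/tratamiento#"
  net <- add_individual(net, iri(tra, "Metformina"),
                        iri(tra, "Tratamiento_Farmacologico"), label = "Metformina")
  matches <- find_name_matches(net, "tratamiento", "medicamentos")
  out <- verify_matches(net, matches)
  expect_true(all(!out$verified))  # no shared codes yet -> manual review
  # give the control-plan entry the same ATC key the demoted leaf carries
  net2 <- add_data_property(net, iri(tra, "tieneClaveATC"),
                            iri(tra, "Tratamiento_Farmacologico"), "string")
  net2 <- add_assertion(net2, iri(tra, "Metformina"), iri(tra, "tieneClaveATC"), "A10BA02")
  out2 <- verify_matches(net2, matches)
  expect_true(all(out2$verified))
  expect_match(out2$evidence[1], "A10BA02")
})

test_that("leaf demotion converts classes to keyed individuals and conserves element counts", {
  net <- toy_atc_net()
  m <- function(x) iri("http://example.org/m#", x)
  before <- nrow(net$classes) + nrow(dplyr::distinct(net$individuals["iri"]))
  net2 <- demote_classes_to_instances(net, m("A10BA02"), m("tieneClaveATC"))
  expect_false(m("A10BA02") %in% net2$classes$iri)
  expect_equal(resolve_iri(m("Metformina"), net2)$found_as, "individual")
  expect_equal(net2$individuals$class[net2$individuals$iri == m("Metformina")], m("A10BA"))
  key <- net2$assertions[net2$assertions$subject == m("Metformina"), ]
  expect_equal(key$object, "A10BA02")
  after <- nrow(net2$classes) + nrow(dplyr::distinct(net2$individuals["iri"]))
  expect_equal(after, before)

  # refusing to demote a non-leaf names the offending IRI
  expect_error(demote_classes_to_instances(net, m("A10BA"), m("tieneClaveATC")),
               "A10BA")
  # selecting nothing leaves the module unchanged
  expect_identical(demote_classes_to_instances(net, character(0), m("tieneClaveATC")), net)
})

test_that("mapper nodes carry exactly one amount and one link per portion", {
  net <- build_network()
  medi <- "http://www.medicamentos-mexico.org/medicamento#"
  combo <- iri(medi, "Diosmina_Hesperidina_Grageas")
  mappers <- net$assertions[net$assertions$subject == combo &
                            net$assertions$predicate == iri(medi, "tienePrincipioActivoPorPorcion"), ]
  expect_equal(nrow(mappers), 2)  # two active ingredients -> two nodes
  for (node in mappers$object) {
    amounts <- net$assertions[net$assertions$subject == node &
                              net$assertions$predicate == iri(medi, "tieneCantidadDePrincipioActivo"), ]
    links <- net$assertions[net$assertions$subject == node &
                            net$assertions$predicate == iri(medi, "tienePrincipioActivo"), ]
    expect_equal(nrow(amounts), 1)
    expect_equal(nrow(links), 1)
  }

  # node count equals portion count for random portion lists
  set.seed(42)
  for (rep in 1:5) {
    k <- sample(1:4, 1)
    apis <- sample(iri(medi, slug <- c("Metformina", "Enalapril", "Omeprazol", "Losartan")), k)
    n2 <- add_individual(net, iri(medi, paste0("TestDrug", rep)), iri(medi, "Medicamento"))
    n2 <- create_api_mappers(n2, iri(medi, paste0("TestDrug", rep)),
                             tibble::tibble(api = apis, amount = runif(k, 1, 500), unit = "mg"))
    made <- n2$assertions[n2$assertions$subject == iri(medi, paste0("TestDrug", rep)), ]
    expect_equal(nrow(made), k)
  }
  # non-positive amounts are rejected
  expect_error(create_api_mappers(net, combo,
                                  tibble::tibble(api = iri(medi, "Diosmina"), amount = 0, unit = "mg")),
               "positive")
})

test_that("external references are annotations only: queryable, conflict-checked, axiom-preserving", {
  net <- build_network()
  enf <- "http://www.padecimientos-mexico.org/enfermedades#"
  before <- list(net$classes, net$obj_props, net$data_props, net$individuals, net$assertions)
  net2 <- annotate_external_refs(net, default_external_refs(net))
  after <- list(net2$classes, net2$obj_props, net2$data_props, net2$individuals, net2$assertions)
  expect_identical(before, after)  # only annotation triples differ

  res <- sparql_query(net2, paste0(
    "PREFIX enf: <", enf, ">\nPREFIX red: <", net2$network_iri, ">\n",
    "SELECT ?icd10 WHERE { enf:DiabetesMellitusTipo2 red:ICD10 ?icd10 }"))
  expect_equal(res$icd10, "E11")

  expect_identical(annotate_external_refs(net, default_external_refs(net)[0, ]), net)
  conflict <- tibble::tibble(subject = iri(enf, "DiabetesMellitusTipo2"),
                             scheme = "ICD10", code = "E14")
  expect_error(annotate_external_refs(net2, conflict), "conflicting")
  expect_error(annotate_external_refs(net2, tibble::tibble(
    subject = iri(enf, "Nope"), scheme = "ICD10", code = "X")), "does not resolve")
})

test_that("sameAs is a symmetric query-layer equivalence", {
  fix <- tiny_populated()
  net <- fix$net
  tra <- "http://www.medida-control.com/tratamiento#"
  medi <- "http://www.medicamentos-mexico.org/medicamento#"
  net <- add_same_as(net, iri(tra, "Metformina"), iri(medi, "Metformina"))
  q <- function(subj) sparql_query(net, paste0(
    "PREFIX medi: <", medi, ">\nPREFIX tra: <", tra, ">\n",
    "SELECT ?k WHERE { ", subj, " medi:tieneClaveATC ?k }"))
  # the ATC key asserted on the Drug-ATC individual answers through either IRI
  expect_equal(q("medi:Metformina")$k, "A10BA02")
  expect_equal(q("tra:Metformina")$k, "A10BA02")
})

test_that("drug-by-ingredient queries answer identically before and after population", {
  # the integrated drug module keeps fulfilling its original purpose
  q <- "PREFIX medi: <http://www.medicamentos-mexico.org/medicamento#>
        SELECT DISTINCT ?form WHERE {
          ?x medi:tienePrincipioActivo medi:Insulina_Lispro .
          ?y medi:tienePrincipioActivoPorPorcion ?x .
          ?y medi:tieneFormaFarmaceutica ?form }"
  before <- sort(sparql_query(build_network(), q)$form)
  after <- sort(sparql_query(tiny_populated()$net, q)$form)
  expect_equal(before, after)
  expect_length(before, 2)
})
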