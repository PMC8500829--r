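gaz <- load_gazetteers()

test_that("gazetteer tagging: semantic tags, longest match, diacritic folding", {
  t1 <- tag_terms("diabetes mellitus tipo 2", gaz)
  sem <- t1[t1$tag_kind == "semantic", ]
  expect_equal(nrow(sem), 1)
  expect_equal(sem$tag, "Disease")
  expect_equal(sem$source_vocab, "ICD-10")
  expect_equal(sem$code, "E11")

  # longest match wins over the contained term
  t2 <- tag_terms("se indica insulina lispro", gaz)
  sem2 <- t2[t2$tag_kind == "semantic", ]
  expect_equal(nrow(sem2), 1)
  expect_equal(tolower(sem2$text), "insulina lispro")

  # case- and accent-insensitive
  t3 <- tag_terms("HIPERTENSION ARTERIAL descontrolada", gaz)
  expect_equal(sum(t3$tag_kind == "semantic"), 1)
  t3b <- tag_terms("hipertensión arterial", gaz)
  expect_equal(t3b$code[t3b$tag_kind == "semantic"], "I10")

  # no gazetteer hits: syntactic tags only; empty text: empty result
  t4 <- tag_terms("camina diario por la mañana", gaz)
  expect_true(all(t4$tag_kind == "syntactic"))
  expect_equal(nrow(tag_terms("", gaz)), 0)
  expect_error(tag_terms("x", gaz[0, ]), "gazetteer")
})

test_that("tagging is stable under concatenation with a separator", {
  a <- "Paciente con diabetes mellitus tipo 2."
  b <- "Refiere poliuria y cefalea."
  ta <- tag_terms(a, gaz); tb <- tag_terms(b, gaz)
  tab <- tag_terms(paste(a, b), gaz)
  sem <- function(t) t[t$tag_kind == "semantic", c("text", "tag", "code")]
  expect_equal(dplyr::bind_rows(sem(ta), sem(tb)), sem(tab))
})

test_that("nominal phrases follow the shallow pattern and exclude semantic spans", {
  # Noun Adj collapses into one phrase
  t1 <- tag_terms("herida leve", gaz)
  p1 <- find_nominal_phrases(t1)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$token_start, 1); expect_equal(p1$token_end, 2)
  # an all-verb fragment yields nothing
  t2 <- tag_terms("refiere tiene presenta", gaz)
  expect_equal(nrow(find_nominal_phrases(t2)), 0)
  # tokens covered by a semantic term never re-surface as phrases
  t3 <- tag_terms("gastritis", gaz)
  expect_equal(nrow(find_nominal_phrases(t3)), 0)
})

test_that("triplet formation emits diagnosis, symptom, sign and drug-section candidates", {
  net <- tiny_populated()$net
  datos <- "http://www.modelo.org/datos#"
  note <- net$individuals$iri[grepl("#Nota_P001_1$", net$individuals$iri)][1]
  txt <- "Diagnóstico: diabetes mellitus tipo 2. Refiere poliuria. Glucosa 140."
  cand <- form_triplets(net, note, tag_terms(txt, gaz), text = txt)
  expect_true(any(grepl("presentaEnfermedad", cand$relation) &
                  grepl("DiabetesMellitusTipo2", cand$range)))
  expect_true(any(grepl("presentaSintoma", cand$relation) & grepl("Poliuria", cand$range)))
  sign <- cand[grepl("tieneGlucosa$", cand$relation), ]
  expect_equal(nrow(sign), 1)
  expect_equal(sign$range, "140")
  expect_equal(sign$datatype, "float")
  expect_equal(sign$range_kind, "literal")
  expect_true(startsWith(sign$relation, datos))
  expect_true(all(cand$status == "pending"))

  expect_error(form_triplets(net, paste0(datos, "Nota_NoSuch"), tag_terms(txt, gaz)),
               "does not resolve")

  medi <- "http://www.medicamentos-mexico.org/medicamento#"
  drug <- iri(medi, "Metformina_Tabletas")
  dc <- form_drug_triplets(net, drug, "contraindicaciones",
                           tag_terms("Contraindicado en insuficiencia renal crónica.", gaz))
  expect_equal(nrow(dc), 1)
  expect_true(grepl("tieneContraindicacion", dc$relation))
  expect_true(grepl("InsuficienciaRenalCronica", dc$range))
})

test_that("the review round trip registers, edits and skips candidates losslessly", {
  net <- tiny_populated()$net
  note <- net$individuals$iri[grepl("#Nota_P001_1$", net$individuals$iri)][1]
  txt <- "Diagnóstico: gastritis. Refiere mareo."
  cand <- form_triplets(net, note, tag_terms(txt, gaz), text = txt)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_review_file(cand, path)
  rv <- read_review_file(path)
  expect_equal(rv$id, cand$id)

  # register all
  all_reg <- apply_review(cand, rv)
  expect_true(all(all_reg$status == "registered"))
  # edit one range
  rv2 <- rv
  rv2$range[1] <- "http://www.padecimientos-mexico.org/enfermedades#GastritisCronica"
  edited <- apply_review(cand, rv2)
  expect_equal(edited$status[1], "edited")
  expect_match(edited$range[1], "GastritisCronica")
  # skip all: downstream integration is a no-op
  rv3 <- rv; rv3$action <- "skip"
  skipped <- apply_review(cand, rv3)
  expect_true(all(skipped$status == "skipped"))
  expect_identical(sorted_triples(apply_candidates(net, skipped)), sorted_triples(net))
  # unknown ids are reported
  rv4 <- rv; rv4$id[1] <- "nope_1"
  expect_error(apply_review(cand, rv4), "nope_1")
})

test_that("the integration flow creates absent resources in their owning modules", {
  net <- tiny_populated()$net
  enf <- "http://www.padecimientos-mexico.org/enfermedades#"
  note <- net$individuals$iri[grepl("#Nota_P001_1$", net$individuals$iri)][1]
  cand <- tibble::tibble(
    id = "c1", domain = note,
    relation = iri(net$network_iri, "presentaEnfermedad"),
    range = iri(enf, "EnfermedadNueva"), range_kind = "iri",
    datatype = NA_character_, pattern = "bare-list", status = "registered")
  expect_equal(resolve_iri(cand$range, net)$found_as, "absent")
  net2 <- integrate_triplet(net, cand)
  # created under the relation's range class and asserted
  expect_equal(net2$individuals$class[net2$individuals$iri == cand$range],
               iri(enf, "Enfermedad"))
  expect_true(any(net2$assertions$subject == note &
                  net2$assertions$object == cand$range))
  # when everything exists already, exactly one new triple
  n_before <- nrow(net2$assertions)
  cand2 <- cand; cand2$range <- iri(enf, "DiabetesMellitusTipo2")
  net3 <- integrate_triplet(net2, cand2)
  expect_equal(nrow(net3$assertions), n_before + 1)
  # unroutable namespace
  cand3 <- cand; cand3$range <- "http://unknown.org/x#Thing"
  expect_error(integrate_triplet(net, cand3), "unroutable")
  # pending candidates are refused
  cand4 <- cand; cand4$status <- "pending"
  expect_error(integrate_triplet(net, cand4), "registered")
})

test_that("corpus extraction is idempotent and routes new properties to the right namespaces", {
  fix <- tiny_populated()
  net <- fix$net
  cand <- extract_candidates(net, fix$corpus$fragments, gaz)
  cand$status <- "registered"
  net1 <- apply_candidates(net, cand)
  net2 <- apply_candidates(net1, cand)
  expect_identical(sorted_triples(net1), sorted_triples(net2))

  # every extraction-created object property is in the network namespace;
  # every created data property is in the Clinical Information module
  new_op <- setdiff(net1$obj_props$iri, net$obj_props$iri)
  new_dp <- setdiff(net1$data_props$iri, net$data_props$iri)
  expect_true(all(startsWith(new_op, net$network_iri)))
  expect_true(all(startsWith(new_dp, "http://www.modelo.org/datos#")))
  expect_true(any(grepl("tieneGlucosa$", new_dp)))
})
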