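test_that("scalar clinical functions match hand arithmetic and guard their domains", {
  expect_equal(compute_bmi(80, 1.6), 31.25)
  expect_equal(compute_bmi(0, 1.7), 0)
  w <- c(0.5, 55, 123.4)
  expect_equal(compute_bmi(w, 1), w)  # unit-height identity
  expect_error(compute_bmi(80, 0), "positive")
  expect_error(compute_bmi(-1, 1.6), "non-negative")

  expect_equal(compute_whi(80, 100), 0.8)
  expect_equal(compute_whi(93.2, 93.2), 1)
  expect_equal(compute_whi(0, 90), 0)
  expect_error(compute_whi(80, 0), "positive")
})

test_that("the Overweight band is inclusive below, exclusive above", {
  expect_equal(classify_biotype(25), "Overweight")
  expect_true(is.na(classify_biotype(30)))
  expect_true(is.na(classify_biotype(24.999)))
  expect_equal(classify_biotype(29.999), "Overweight")
  # boundary sweep against the direct interval predicate
  grid <- seq(10, 50, by = 0.25)
  expect_equal(!is.na(classify_biotype(grid)), grid >= 25 & grid < 30)
})

test_that("the basal metabolic rate variant fires only for women 61 and over", {
  expect_equal(compute_bmr("Female", 65, 60), 10.5 * 60 + 596)
  expect_equal(compute_bmr("FEMALE", 61, 60), 1226)  # case-insensitive, threshold inclusive
  expect_true(is.na(compute_bmr("Female", 60, 60)))
  expect_true(is.na(compute_bmr("Male", 70, 60)))
  expect_error(compute_bmr("Female", 65, -1), "non-negative")
  # linearity in weight is exact for representable inputs
  w1 <- c(0, 40, 72.5); w2 <- w1 + 2
  expect_identical(compute_bmr("Female", 65, w2) - compute_bmr("Female", 65, w1),
                   10.5 * (w2 - w1))
})

small_note_net <- function(weight = 80, height = 1.6, sex = "Female", age = 65L) {
  net <- build_network()
  datos <- "http://www.modelo.org/datos#"; per <- "http://www.personas-mexico.org/persona#"
  net <- add_individual(net, iri(per, "Paciente_X"), iri(per, "Paciente"))
  net <- add_individual(net, iri(datos, "Expediente_X"), iri(datos, "Expediente_Clinico"))
  net <- add_individual(net, iri(datos, "Nota_X"), iri(datos, "Nota_Medica"))
  net <- add_assertion(net, iri(per, "Paciente_X"), iri(per, "tieneSexo"), sex)
  net <- add_assertion(net, iri(per, "Paciente_X"),
                       iri(net$network_iri, "tieneExpedienteClinico"), iri(datos, "Expediente_X"))
  net <- add_assertion(net, iri(datos, "Expediente_X"), iri(datos, "tieneNotaMedica"),
                       iri(datos, "Nota_X"))
  net <- add_assertion(net, iri(datos, "Nota_X"), iri(datos, "tienePeso"), weight)
  net <- add_assertion(net, iri(datos, "Nota_X"), iri(datos, "tieneTalla"), height)
  net <- add_assertion(net, iri(datos, "Nota_X"), iri(datos, "tieneEdad"), age)
  net
}

note_value <- function(net, prop) {
  datos <- "http://www.modelo.org/datos#"
  v <- net$assertions$object[net$assertions$subject == iri(datos, "Nota_X") &
                             net$assertions$predicate == iri(datos, prop)]
  as.numeric(v)
}

test_that("forward chaining derives BMI, biotype and BMR on a note, recording provenance", {
  net <- apply_rules(small_note_net(weight = 80, height = 1.6))
  expect_equal(note_value(net, "tieneIMC"), 31.25, tolerance = 1e-12)
  # BMI 31.25 is outside the Overweight band
  datos <- "http://www.modelo.org/datos#"
  bt <- net$assertions[net$assertions$predicate == iri(datos, "tieneBiotipoHumano"), ]
  expect_equal(nrow(bt), 0)
  expect_equal(note_value(net, "tieneTMB"), 10.5 * 80 + 596, tolerance = 1e-12)

  net2 <- apply_rules(small_note_net(weight = 69.12, height = 1.6))  # BMI 27
  expect_equal(note_value(net2, "tieneIMC"), 27, tolerance = 1e-9)
  bt2 <- net2$assertions[net2$assertions$predicate == iri(datos, "tieneBiotipoHumano"), ]
  expect_equal(bt2$object, iri(datos, "Overweight"))
  deriv <- attr(net2, "derivations")
  expect_setequal(unique(deriv$rule[deriv$subject == iri(datos, "Nota_X")]),
                  c("BodyMassIndex", "OverweightFunction", "BasalMetabolicRateFemaleOver60"))

  # empty network: unchanged
  empty <- build_network()
  out <- apply_rules(empty)
  expect_identical(sorted_triples(out), sorted_triples(empty))
  expect_equal(nrow(attr(out, "derivations")), 0)
})

test_that("rules are rejected at load unless DL-safe, and heads are property atoms", {
  net <- build_network()
  expect_error(
    rule("bad", body = list("datos:tienePeso(?n, ?p)"),
         head = list("datos:tieneIMC(?n, ?imc)"), net = net),
    "\\?imc")
  expect_error(
    rule("bad2", body = list("datos:tienePeso(?n, ?p)"),
         head = list("datos:Nota_Medica(?n)"), net = net),
    "property atoms")
  expect_error(parse_atom("swrlb:pow(?x, ?y, 2)", net), "unsupported builtin")
})

test_that("rule files load through the alias map and derive identically to the built-ins", {
  net <- small_note_net(weight = 69.12, height = 1.6)
  from_file <- load_rules(system.file("extdata", "rules.yaml", package = "ontonet"), net)
  expect_length(from_file, 4)
  a <- apply_rules(net, default_rules(net))
  b <- apply_rules(net, from_file)
  expect_identical(sorted_triples(a), sorted_triples(b))
})

test_that("the fixpoint is confluent under rule and fact shuffling, and monotone", {
  fix <- tiny_populated()
  net <- fix$net
  base <- apply_rules(net)
  ref <- sorted_triples(base)
  # monotone: no triple is ever removed
  expect_true(nrow(dplyr::anti_join(network_triples(net), network_triples(base),
                                    by = c("subject", "predicate", "object"))) == 0)
  rules <- default_rules(net)
  for (seed in 1:3) {
    set.seed(seed)
    shuffled_rules <- sample(rules)
    net_perm <- net
    net_perm$assertions <- net_perm$assertions[sample.int(nrow(net_perm$assertions)), ]
    out <- apply_rules(net_perm, shuffled_rules)
    expect_identical(sorted_triples(out), ref, info = paste("seed", seed))
  }
})

test_that("derived note values agree with the scalar functions to 1e-9", {
  fix <- tiny_populated()
  net <- apply_rules(fix$net)
  datos <- "http://www.modelo.org/datos#"
  get <- function(prop) {
    df <- net$assertions[net$assertions$predicate == iri(datos, prop),
                         c("subject", "object")]
    stats::setNames(as.numeric(df$object), df$subject)
  }
  w <- get("tienePeso"); h <- get("tieneTalla"); bmi <- get("tieneIMC")
  expect_equal(bmi[names(w)], compute_bmi(w, h[names(w)])[], tolerance = 1e-9)
  ci <- get("tieneCintura"); ca <- get("tieneCadera"); icc <- get("tieneICC")
  expect_equal(icc[names(ci)], compute_whi(ci, ca[names(ci)])[], tolerance = 1e-9)
})

test_that("contraindication alerts match a brute-force nested-loop join", {
  fix <- tiny_populated()
  net <- fix$net
  cand <- extract_candidates(net, fix$corpus$fragments, load_gazetteers())
  cand$status <- "registered"
  net <- apply_candidates(net, cand)
  res <- contraindication_alerts(net)

  # brute force: for every note, intersect its diagnoses with the
  # contraindications of every drug product whose ingredient it was prescribed
  a <- net$assertions
  p <- function(x) iri(net$network_iri, x)
  medi <- "http://www.medicamentos-mexico.org/medicamento#"
  notes <- unique(a$subject[a$predicate == p("tieneTratamiento")])
  expected <- 0L
  for (nt in notes) {
    doses <- a$object[a$subject == nt & a$predicate == p("tieneTratamiento")]
    apis <- unique(a$object[a$subject %in% doses &
                            a$predicate == p("tienePrincipioActivoEnReceta")])
    mappers <- a$subject[a$predicate == iri(medi, "tienePrincipioActivo") &
                         a$object %in% apis]
    drugs <- unique(a$subject[a$predicate == iri(medi, "tienePrincipioActivoPorPorcion") &
                              a$object %in% mappers])
    diags <- a$object[a$subject == nt & a$predicate == p("tieneDiagnostico")]
    for (dr in drugs) {
      contra <- a$object[a$subject == dr & a$predicate == p("tieneContraindicacion")]
      expected <- expected + length(intersect(contra, diags))
    }
  }
  expect_gt(nrow(res$alerts), 0)
  expect_equal(nrow(res$alerts), expected)
  # a drug contraindicated for an undiagnosed disease raises nothing:
  # every alert's diagnosis really is among the note's diagnoses
  for (i in seq_len(min(nrow(res$alerts), 20))) {
    diags <- a$object[a$subject == res$alerts$note[i] & a$predicate == p("tieneDiagnostico")]
    expect_true(res$alerts$diagnosis[i] %in% diags)
  }
})
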