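test_that("competency queries answer with the expected shapes on a populated network", {
  fix <- tiny_populated()
  net <- fix$net
  res <- run_competency_suite(net)
  # extraction has not run yet: the side-effect traversal is legitimately empty
  expect_true(all(res$pass[res$id != "side_effects"]))

  # the weight query returns one row per note carrying a weight
  datos <- "http://www.modelo.org/datos#"
  n_notes <- sum(net$assertions$predicate == iri(datos, "tienePeso"))
  expect_equal(res$rows[res$id == "weight"], n_notes)

  # education-level query rows equal the Education Level individual count
  edu_rows <- res$rows[res$id == "education_levels"]
  expect_equal(edu_rows, sum(net$individuals$module == "niveles"))

  # on an unpopulated network the non-empty expectation fails
  res0 <- run_competency_suite(build_network())
  expect_false(res0$pass[res0$id == "weight"])
  expect_equal(res0$rows[res0$id == "weight"], 0)
})

test_that("the SPARQL subset evaluates joins, DISTINCT and FILTER", {
  net <- tiny_populated()$net
  datos <- "http://www.modelo.org/datos#"
  q <- paste0("PREFIX dato: <", datos, ">\n",
              "SELECT ?note ?g WHERE { ?note dato:tieneGlucosaPostPrandial ?g . ",
              "FILTER(?g >= 200) }")
  res <- sparql_query(net, q)
  gl <- net$assertions[net$assertions$predicate == iri(datos, "tieneGlucosaPostPrandial"), ]
  expect_equal(nrow(res), sum(as.numeric(gl$object) >= 200))
  expect_error(sparql_query(net, "PREFIX a: <http://x#>\nSELECT ?x WHERE { ?x nope:b ?y }"),
               "unknown prefix")
})

test_that("the cardinality checker agrees with a brute-force per-individual count", {
  net <- tiny_populated()$net
  # independent oracle: count every restricted property per individual with
  # nested loops and re-derive the violation set
  brute <- list()
  for (i in seq_len(nrow(net$restrictions))) {
    r <- net$restrictions[i, ]
    classes <- ontonet:::desc_classes(net, r$class)
    inds <- unique(net$individuals$iri[net$individuals$class %in% classes])
    for (ind in inds) {
      obs <- sum(net$assertions$subject == ind & net$assertions$predicate == r$on_property)
      need <- if (r$kind == "some") 1L else r$n
      bad <- if (r$derived) r$kind == "exactly" && obs > need else switch(r$kind,
        exactly = obs != need, min = obs < need, some = obs < 1L)
      if (bad) brute[[length(brute) + 1]] <- c(ind, r$on_property, obs)
    }
  }
  report <- check_cardinality(net)
  expect_equal(nrow(report), length(brute))

  # and on a deliberately broken network both find the same violation
  per <- "http://www.personas-mexico.org/persona#"
  net_bad <- add_individual(net, iri(per, "Medico_99"), iri(per, "Medico"))
  report_bad <- check_cardinality(net_bad)
  expect_equal(nrow(report_bad), nrow(report) + 1)
})

test_that("lint reports missing metadata, naming mixtures and absent inverses", {
  net <- build_network()
  f <- lint(net)
  # the education-stage subclasses carry no labels: flagged as missing metadata
  expect_true(any(f$pitfall == "missing_metadata"))
  # canonical names are Spanish throughout: no naming-convention findings
  expect_equal(sum(f$pitfall == "naming_convention"), 0)
  # inverse findings are informational only
  expect_true(all(f$severity[f$pitfall == "missing_inverse"] == "informational"))
  # mutually inverse pair is not flagged
  red <- net$network_iri
  inv <- f$subject[f$pitfall == "missing_inverse"]
  expect_false(iri(red, "esEscritaPor") %in% inv)
  expect_false(iri(red, "escribeNotaMedica") %in% inv)

  # a fully annotated Spanish-only toy network yields no non-informational findings
  tn <- new_network("http://example.org/n#")
  tn <- add_module(tn, "a", "A", "http://example.org/a#")
  tn <- add_class(tn, "http://example.org/a#Cosa", label = "Thing")
  tn <- add_data_property(tn, "http://example.org/a#tieneNombre",
                          "http://example.org/a#Cosa", "string", label = "hasName")
  ft <- lint(tn)
  expect_equal(nrow(ft[ft$severity != "informational", ]), 0)

  # mixing has*/tiene* names: finding count equals the brute-force regex count
  tn2 <- add_data_property(tn, "http://example.org/a#hasColor",
                           "http://example.org/a#Cosa", "string", label = "hasColor")
  f2 <- lint(tn2)
  locals <- split_iri(c(tn2$obj_props$iri, tn2$data_props$iri))$local_name
  expect_equal(sum(f2$pitfall == "naming_convention"),
               sum(grepl("^(has|is[A-Z]|writes|presents)", locals)))
})
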