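# The end-to-end workflow: schema -> synthetic corpus -> population ->
# external references and cross-catalogue sameAs links -> candidate
# extraction from free text -> inference rules -> evaluation.

#' Run the full ontology-network pipeline on a synthetic corpus
#'
#' Builds the default schema, generates a corpus from the profile, populates
#' the network, annotates the diabetes individuals with their external
#' codes, links same-named drug individuals across the Control Plan and
#' Drug-ATC modules, extracts and registers candidate triples from the
#' corpus's free-text fragments, runs the clinical rules to fixpoint,
#' raises contraindication alerts, and evaluates the result.
#'
#' @param profile Corpus profile (the profile's seed drives all randomness).
#' @param include_extraction Run the free-text extraction step (default
#'   `TRUE`).
#' @return List: `net`, `corpus`, `candidates`, `alerts`, `evaluation`,
#'   `derivations`.
#' @export
run_pipeline <- function(profile = default_corpus_profile(), include_extraction = TRUE) {
  net <- build_network()
  corpus <- generate_corpus(profile)
  net <- populate(net, corpus$records)
  net <- annotate_external_refs(net, default_external_refs(net))
  # Fig-2-style cross-catalogue linking: same-named pharmacological
  # treatment entries and ATC ingredient individuals denote the same drug.
  matches <- find_name_matches(net, "tratamiento", "medicamentos")
  matches <- matches[matches$kind_a == "individual" & matches$kind_b == "individual", ]
  for (i in seq_len(nrow(matches))) {
    net <- add_same_as(net, matches$element_a[i], matches$element_b[i])
  }
  candidates <- new_candidates()
  if (include_extraction) {
    gaz <- load_gazetteers()
    candidates <- extract_candidates(net, corpus$fragments, gaz)
    candidates$status <- "registered"
    net <- apply_candidates(net, candidates)
  }
  net <- apply_rules(net)
  derivations <- attr(net, "derivations")
  al <- contraindication_alerts(net)
  net <- al$net
  list(net = net, corpus = corpus, candidates = candidates, alerts = al$alerts,
       evaluation = evaluate_network(net), derivations = derivations)
}
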