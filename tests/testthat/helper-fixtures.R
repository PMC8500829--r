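# Shared fixtures: a small corpus profile and toy networks built in code.

tiny_profile <- function(seed = 7L) {
  corpus_profile(
    n_patients = 10L, n_male = 5L, n_female = 5L,
    diagnosis_quota = c(insulin_dependent = 8L, non_insulin_dependent = 9L, other = 25L),
    prescription_total = 60L,
    prescription_named = c("Metformina" = 10L, "Insulina Glargina" = 8L),
    other_drugs = c("Enalapril", "Omeprazol"),
    notes_per_record = 1:2, seed = seed)
}

tiny_populated <- local({
  cache <- NULL
  function(seed = 7L) {
    if (!is.null(cache)) return(cache)
    net <- build_network()
    co <- generate_corpus(tiny_profile(seed))
    net <- populate(net, co$records)
    net <- annotate_external_refs(net, default_external_refs(net))
    cache <<- list(net = net, corpus = co)
    cache
  }
})

# A minimal two-module network for core-model tests.
toy_network <- function() {
  net <- new_network("http://example.org/net#")
  net <- add_module(net, "a", "Module A", "http://example.org/a#")
  net <- add_module(net, "b", "Module B", "http://example.org/b#")
  net <- add_class(net, "http://example.org/a#Thing")
  net <- add_class(net, "http://example.org/b#Other")
  net <- add_individual(net, "http://example.org/a#t1", "http://example.org/a#Thing")
  net <- add_individual(net, "http://example.org/b#o1", "http://example.org/b#Other")
  net <- add_object_property(net, "http://example.org/net#linksTo",
                             "http://example.org/a#Thing", "http://example.org/b#Other",
                             stage = "design")
  net <- add_data_property(net, "http://example.org/a#hasSize",
                           "http://example.org/a#Thing", "float")
  net
}

# Brute-force resolver: linear search over every definition table.
brute_resolve <- function(full_iri, net) {
  if (full_iri %in% net$classes$iri) return("class")
  if (full_iri %in% net$individuals$iri) return("individual")
  if (full_iri %in% net$obj_props$iri) return("object_property")
  if (full_iri %in% net$data_props$iri) return("data_property")
  "absent"
}

sorted_triples <- function(net) {
  t <- network_triples(net)
  as.data.frame(t[order(t$subject, t$predicate, t$object_kind, t$object,
                        method = "radix"), ])
}
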