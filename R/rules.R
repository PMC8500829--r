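# Forward-chaining rule engine over the network: Horn-style rules whose
# bodies mix class atoms, property atoms and arithmetic/comparison builtins
# (the swrlb vocabulary subset: multiply, divide, add, greaterThanOrEqual,
# lessThan, stringEqualIgnoreCase) and whose heads assert property atoms.
# Rules are DL-safe (every head variable occurs in the body), negation-free,
# and monotone, so the fixpoint is unique regardless of rule or fact order.

SWRLB_OPS <- c("multiply", "divide", "add", "subtract",
               "greaterThanOrEqual", "lessThan", "greaterThan",
               "lessThanOrEqual", "stringEqualIgnoreCase")

rule_arg <- function(x) {
  x <- trimws(x)
  if (startsWith(x, "?")) return(list(kind = "var", value = substring(x, 2)))
  if (grepl("^\"", x)) {
    # strip optional ^^type suffix
    val <- sub("\\^\\^.*$", "", x)
    return(list(kind = "lit", value = gsub("^\"|\"$", "", val)))
  }
  if (grepl("^-?[0-9.]+$", x)) return(list(kind = "lit", value = x))
  list(kind = "iri", value = x) # prefixed name, resolved at parse time
}

#' Parse a rule atom string
#'
#' Atom syntax: `prefix:name(arg, ...)` with arguments `?var`, numbers,
#' quoted strings or prefixed IRIs. `swrlb:` atoms are builtins; other
#' predicates resolve against the network (English names are accepted
#' through the alias map and stored canonically).
#'
#' @param s Atom string.
#' @param net An `onto_network`.
#' @param prefixes Named namespace map; defaults to [default_prefixes()].
#' @return An atom object (internal representation).
#' @export
parse_atom <- function(s, net, prefixes = default_prefixes(net)) {
  m <- regmatches(s, regexec("^\\s*([A-Za-z0-9_]+):([A-Za-z0-9_]+)\\((.*)\\)\\s*$", s))[[1]]
  if (length(m) == 0) stop_onto("cannot parse atom: ", s)
  prefix <- m[2]; local <- m[3]
  args <- lapply(strsplit(m[4], ",")[[1]], rule_arg)
  resolve_arg <- function(a) {
    if (a$kind != "iri") return(a)
    pm <- regmatches(a$value, regexec("^([A-Za-z0-9_]+):([A-Za-z0-9_.]+)$", a$value))[[1]]
    if (length(pm) == 0) stop_onto("cannot resolve atom argument: ", a$value)
    if (is.null(prefixes[[pm[2]]])) stop_onto("unknown prefix: ", pm[2])
    a$value <- iri(prefixes[[pm[2]]], pm[3])
    a
  }
  if (prefix == "swrlb") {
    if (!local %in% SWRLB_OPS) stop_onto("unsupported builtin: swrlb:", local)
    return(list(type = "builtin", pred = local, args = lapply(args, resolve_arg)))
  }
  if (is.null(prefixes[[prefix]])) stop_onto("unknown prefix: ", prefix)
  full <- iri(prefixes[[prefix]], alias_to_canonical(local))
  kind <- resolve_iri(full, net)$found_as
  args <- lapply(args, resolve_arg)
  if (kind == "class") return(list(type = "class", pred = full, args = args))
  if (kind %in% c("object_property", "data_property")) {
    return(list(type = "prop", pred = full, args = args, prop_kind = kind))
  }
  stop_onto("atom predicate does not resolve: ", full)
}

#' Default prefix table for rules and queries
#'
#' Module keys plus the short forms the clinical queries use (`dato`, `per`,
#' `enf`, `edu`, `medi`) and the base RDF prefixes.
#'
#' @param net An `onto_network`.
#' @return Named list prefix -> namespace.
#' @export
default_prefixes <- function(net) {
  p <- as.list(BASE_PREFIXES)
  for (i in seq_len(nrow(net$modules))) {
    p[[net$modules$key[i]]] <- net$modules$namespace[i]
  }
  p$red <- net$network_iri
  short <- c(dato = "datos", per = "persona", enf = "enfermedades",
             edu = "niveles", edo = "estados", medi = "medicamentos")
  for (s in names(short)) if (!is.null(p[[short[[s]]]])) p[[s]] <- p[[short[[s]]]]
  p
}

atom_vars <- function(atom) {
  unlist(lapply(atom$args, function(a) if (a$kind == "var") a$value else NULL))
}

#' Construct a rule
#'
#' Validates DL-safety at construction: every head variable must occur in
#' the body.
#'
#' @param name Rule name (recorded on every derived triple).
#' @param body,head Lists of atoms (see [parse_atom()]) or atom strings.
#' @param net Network used to parse atom strings.
#' @return A `onto_rule` object.
#' @export
rule <- function(name, body, head, net = NULL) {
  parse_if_chr <- function(x) {
    if (is.character(x)) {
      if (is.null(net)) stop_onto("atom strings need a network to parse against")
      parse_atom(x, net)
    } else x
  }
  body <- lapply(body, parse_if_chr)
  head <- lapply(head, parse_if_chr)
  body_vars <- unique(unlist(lapply(body, atom_vars)))
  head_vars <- unique(unlist(lapply(head, atom_vars)))
  unsafe <- setdiff(head_vars, body_vars)
  if (length(unsafe) > 0) {
    stop_onto("rule '", name, "' is not DL-safe: head variable(s) ",
              paste0("?", unsafe, collapse = ", "), " missing from body")
  }
  if (any(vapply(head, function(a) a$type != "prop", logical(1)))) {
    stop_onto("rule '", name, "': heads must be property atoms")
  }
  structure(list(name = name, body = body, head = head), class = "onto_rule")
}

#' Load rules from a declarative YAML file
#'
#' File layout: optional `prefixes:` map and a `rules:` list of
#' `{name, body: [...], head: [...]}` entries with atoms in
#' `prefix:name(args)` syntax (swrlb builtins by name).
#'
#' @param path Rule file path.
#' @param net An `onto_network` to resolve predicates against.
#' @return List of `onto_rule` objects.
#' @export
load_rules <- function(path, net) {
  spec <- yaml::read_yaml(path)
  prefixes <- default_prefixes(net)
  for (p in names(spec$prefixes %||% list())) prefixes[[p]] <- spec$prefixes[[p]]
  lapply(spec$rules, function(r) {
    rule(r$name,
         body = lapply(r$body, parse_atom, net = net, prefixes = prefixes),
         head = lapply(r$head, parse_atom, net = net, prefixes = prefixes))
  })
}

#' The default clinical rule set
#'
#' Four rules: body-mass-index (weight / height squared), waist-hip index
#' (waist / hip), Overweight biotype banding (25 <= BMI < 30), and the basal
#' metabolic rate for women aged 61 and over (10.5 kcal/kg * weight +
#' 596 kcal). Only these are part of the default observable behaviour;
#' further bands and BMR variants are configuration extension slots shipped
#' disabled.
#'
#' @param net An `onto_network` with the default schema.
#' @return List of `onto_rule` objects.
#' @export
default_rules <- function(net) {
  list(
    rule("BodyMassIndex",
         body = list("datos:tienePeso(?n, ?p)", "datos:tieneTalla(?n, ?t)",
                     "swrlb:multiply(?t2, ?t, ?t)", "swrlb:divide(?imc, ?p, ?t2)"),
         head = list("datos:tieneIMC(?n, ?imc)"), net = net),
    rule("WaistHipIndex",
         body = list("datos:tieneCintura(?n, ?ci)", "datos:tieneCadera(?n, ?ca)",
                     "swrlb:divide(?icc, ?ci, ?ca)"),
         head = list("datos:tieneICC(?n, ?icc)"), net = net),
    rule("OverweightFunction",
         body = list("datos:tieneIMC(?n, ?imc)",
                     "swrlb:greaterThanOrEqual(?imc, 25)", "swrlb:lessThan(?imc, 30)"),
         head = list("datos:tieneBiotipoHumano(?n, datos:Overweight)"), net = net),
    rule("BasalMetabolicRateFemaleOver60",
         body = list("persona:tieneSexo(?pa, ?sx)",
                     "swrlb:stringEqualIgnoreCase(?sx, \"Female\")",
                     "red:tieneExpedienteClinico(?pa, ?ec)",
                     "datos:tieneNotaMedica(?ec, ?nm)",
                     "datos:tieneEdad(?nm, ?e)", "swrlb:greaterThanOrEqual(?e, 61)",
                     "datos:tienePeso(?nm, ?p)",
                     "swrlb:multiply(?aux, 10.5, ?p)", "swrlb:add(?tasa, ?aux, 596)"),
         head = list("datos:tieneTMB(?nm, ?tasa)"), net = net)
  )
}

# Evaluate one atom against current bindings. Bindings: tibble whose columns
# are variable names holding character values (IRIs or literal strings).
join_bindings <- function(bindings, rows) {
  if (is.null(bindings)) return(rows)
  common <- intersect(names(bindings), names(rows))
  if (length(common) == 0) {
    return(dplyr::cross_join(bindings, rows))
  }
  dplyr::inner_join(bindings, rows, by = common, relationship = "many-to-many")
}

eval_body <- function(net, body) {
  bindings <- NULL
  num <- function(x) suppressWarnings(as.numeric(x))
  arg_values <- function(a, bindings) {
    if (a$kind == "var") bindings[[a$value]] else rep(a$value, nrow(bindings))
  }
  for (atom in body) {
    if (atom$type == "class") {
      inds <- individuals_of(net, atom$pred)
      a <- atom$args[[1]]
      if (a$kind == "var") {
        rows <- tibble::tibble(!!a$value := inds)
        bindings <- join_bindings(bindings, rows)
      } else {
        if (!a$value %in% inds) return(NULL)
      }
    } else if (atom$type == "prop") {
      rows <- net$assertions[net$assertions$predicate == atom$pred,
                             c("subject", "object")]
      s <- atom$args[[1]]; o <- atom$args[[2]]
      if (s$kind != "var") rows <- rows[rows$subject == s$value, ]
      if (o$kind != "var") rows <- rows[rows$object == o$value, ]
      keep <- c(if (s$kind == "var") s$value, if (o$kind == "var") o$value)
      names(rows) <- c(if (s$kind == "var") s$value else "..s",
                       if (o$kind == "var") o$value else "..o")
      rows <- rows[, keep, drop = FALSE]
      if (s$kind == "var" && o$kind == "var" && s$value == o$value) {
        rows <- rows[rows[[1]] == rows[[2]], 1, drop = FALSE]
      }
      rows <- dplyr::distinct(tibble::as_tibble(rows))
      bindings <- join_bindings(bindings, rows)
    } else { # builtin
      if (is.null(bindings) || nrow(bindings) == 0) return(NULL)
      op <- atom$pred
      if (op == "stringEqualIgnoreCase") {
        a <- arg_values(atom$args[[1]], bindings)
        b <- arg_values(atom$args[[2]], bindings)
        bindings <- bindings[tolower(a) == tolower(b), , drop = FALSE]
      } else if (op %in% c("greaterThanOrEqual", "lessThan", "greaterThan",
                           "lessThanOrEqual")) {
        a <- num(arg_values(atom$args[[1]], bindings))
        b <- num(arg_values(atom$args[[2]], bindings))
        keep <- switch(op,
          greaterThanOrEqual = a >= b, lessThan = a < b,
          greaterThan = a > b, lessThanOrEqual = a <= b)
        keep[is.na(keep)] <- FALSE
        bindings <- bindings[keep, , drop = FALSE]
      } else { # arithmetic: first argument is the result
        a <- num(arg_values(atom$args[[2]], bindings))
        b <- num(arg_values(atom$args[[3]], bindings))
        val <- switch(op, multiply = a * b, divide = a / b, add = a + b,
                      subtract = a - b)
        r <- atom$args[[1]]
        if (r$kind == "var" && !r$value %in% names(bindings)) {
          bindings[[r$value]] <- format_literal(val, "float")
        } else {
          have <- num(arg_values(r, bindings))
          keep <- have == val
          keep[is.na(keep)] <- FALSE
          bindings <- bindings[keep, , drop = FALSE]
        }
      }
    }
    if (is.null(bindings) || nrow(bindings) == 0) return(NULL)
  }
  bindings
}

head_assertions <- function(net, head, bindings, rule_name) {
  out <- list()
  for (atom in head) {
    s <- atom$args[[1]]; o <- atom$args[[2]]
    subj <- if (s$kind == "var") bindings[[s$value]] else rep(s$value, nrow(bindings))
    obj <- if (o$kind == "var") bindings[[o$value]] else rep(o$value, nrow(bindings))
    if (atom$prop_kind == "object_property") {
      rows <- tibble::tibble(subject = subj, predicate = atom$pred, object = obj,
                             object_kind = "iri", datatype = NA_character_)
    } else {
      dt <- net$data_props$range_type[net$data_props$iri == atom$pred][[1]]
      rows <- tibble::tibble(subject = subj, predicate = atom$pred,
                             object = format_literal(suppressWarnings(as.numeric(obj)) %|na|% obj, dt),
                             object_kind = "literal", datatype = dt)
    }
    rows$rule <- rule_name
    out[[length(out) + 1]] <- rows
  }
  dplyr::bind_rows(out)
}

`%|na|%` <- function(x, y) if (all(is.na(x))) y else x

#' Apply rules to the network until fixpoint
#'
#' Runs the rules forward to saturation: every pass evaluates each rule
#' against the current assertion set and asserts the head bindings; the loop
#' stops when a full pass adds nothing. Rules only ever add triples
#' (monotone), so the final triple set does not depend on rule or fact
#' order. Every derived triple records its producing rule in the
#' `derivations` attribute of the result.
#'
#' @param net An `onto_network`.
#' @param rules List of `onto_rule` objects; defaults to [default_rules()].
#' @param max_passes Safety cap on fixpoint iterations.
#' @return The updated network, with attribute `derivations` (tibble of
#'   `subject`, `predicate`, `object`, `rule`).
#' @export
apply_rules <- function(net, rules = default_rules(net), max_passes = 50L) {
  derivations <- tibble::tibble(subject = character(), predicate = character(),
                                object = character(), rule = character())
  for (pass in seq_len(max_passes)) {
    added <- FALSE
    for (r in rules) {
      bindings <- eval_body(net, r$body)
      if (is.null(bindings) || nrow(bindings) == 0) next
      rows <- head_assertions(net, r$head, bindings, r$name)
      rows <- dplyr::distinct(rows)
      new <- dplyr::anti_join(rows, net$assertions,
                              by = c("subject", "predicate", "object", "object_kind"))
      if (nrow(new) > 0) {
        net$assertions <- dplyr::bind_rows(net$assertions,
                                           new[, names(empty_assertions())])
        derivations <- dplyr::bind_rows(derivations,
                                        new[, c("subject", "predicate", "object", "rule")])
        added <- TRUE
      }
    }
    if (!added) break
  }
  attr(net, "derivations") <- derivations
  net
}

# ---------------------------------------------------------------------------
# Scalar forms of the clinical functions (unit convention: weight kg, height
# m, waist/hip cm, age integer years).

#' Body mass index
#'
#' @param weight_kg Weight in kilograms (>= 0).
#' @param height_m Height in metres (> 0).
#' @return `weight_kg / height_m^2`.
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(height_m <= 0)) stop_onto("height must be positive")
  if (any(weight_kg < 0)) stop_onto("weight must be non-negative")
  weight_kg / height_m^2
}

#' Waist-hip index
#'
#' @param waist_cm Waist circumference in cm.
#' @param hip_cm Hip circumference in cm (> 0).
#' @return `waist_cm / hip_cm`.
#' @export
compute_whi <- function(waist_cm, hip_cm) {
  if (any(hip_cm <= 0)) stop_onto("hip circumference must be positive")
  waist_cm / hip_cm
}

#' Default biotype bands
#'
#' Only the Overweight band (25 inclusive to 30 exclusive, kg/m^2) is part
#' of the default rule set; other bands are extension slots, disabled unless
#' supplied.
#'
#' @return Tibble with columns `label`, `lo` (inclusive), `hi` (exclusive).
#' @export
biotype_bands <- function() {
  tibble::tibble(label = "Overweight", lo = 25, hi = 30)
}

#' Classify a BMI value into a biotype band
#'
#' @param bmi Numeric BMI values.
#' @param bands Band table, see [biotype_bands()]; `lo` inclusive, `hi`
#'   exclusive.
#' @return Character vector of band labels, `NA` where no band matches.
#' @export
classify_biotype <- function(bmi, bands = biotype_bands()) {
  stopifnot(all(bands$lo < bands$hi))
  out <- rep(NA_character_, length(bmi))
  for (i in seq_len(nrow(bands))) {
    hit <- !is.na(bmi) & bmi >= bands$lo[i] & bmi < bands$hi[i]
    out[hit] <- bands$label[i]
  }
  out
}

#' Default basal-metabolic-rate variants
#'
#' The default rule set carries a single affine variant: women aged 61 and
#' over, BMR = 10.5 kcal/kg * weight + 596 kcal. Further variants (other
#' sex/age strata) are extension slots, disabled by default.
#'
#' @return Tibble with `sex`, `min_age`, `slope`, `intercept`.
#' @export
bmr_variants <- function() {
  tibble::tibble(sex = "female", min_age = 61L, slope = 10.5, intercept = 596)
}

#' Basal metabolic rate
#'
#' @param sex Sex string, compared case-insensitively.
#' @param age_years Age in whole years.
#' @param weight_kg Weight in kilograms (>= 0).
#' @param variants Variant table, see [bmr_variants()].
#' @return BMR in kcal, or `NA` when no variant applies.
#' @export
compute_bmr <- function(sex, age_years, weight_kg, variants = bmr_variants()) {
  if (any(weight_kg < 0)) stop_onto("weight must be non-negative")
  n <- max(length(sex), length(age_years), length(weight_kg))
  sex <- rep_len(tolower(sex), n)
  age_years <- rep_len(age_years, n)
  weight_kg <- rep_len(weight_kg, n)
  out <- rep(NA_real_, n)
  for (i in seq_len(nrow(variants))) {
    hit <- sex == tolower(variants$sex[i]) & age_years >= variants$min_age[i]
    out[hit] <- variants$slope[i] * weight_kg[hit] + variants$intercept[i]
  }
  out
}

#' Contraindication alerts
#'
#' Flags every medical note where a prescribed drug's contraindication set
#' intersects the diagnoses of the same note: the note's prescription doses
#' are followed to their active ingredients, ingredients to the drug
#' products containing them, and products to their contraindicated clinical
#' entities. Each alert is also materialised as a network-namespace object
#' property on the note.
#'
#' @param net A populated `onto_network` (diagnoses, treatments, ingredient
#'   links and contraindications asserted where applicable).
#' @return A list with `net` (alerts asserted) and `alerts` (tibble of
#'   `note`, `drug`, `diagnosis`).
#' @export
contraindication_alerts <- function(net) {
  p <- function(name) iri(net$network_iri, name)
  medi <- ns_of_module(net, "medicamentos")
  tr <- expand_same_as(net$assertions, net$same_as)
  pick <- function(pred, from, to) {
    x <- tr[tr$predicate == pred, c("subject", "object")]
    names(x) <- c(from, to); dplyr::distinct(tibble::as_tibble(x))
  }
  mm <- function(x, y, by) dplyr::inner_join(x, y, by = by, relationship = "many-to-many")
  joined <- pick(p("tieneTratamiento"), "note", "dose") |>
    mm(pick(p("tienePrincipioActivoEnReceta"), "dose", "api"), by = "dose") |>
    mm(pick(iri(medi, "tienePrincipioActivo"), "mapper", "api"), by = "api") |>
    mm(pick(iri(medi, "tienePrincipioActivoPorPorcion"), "drug", "mapper"), by = "mapper") |>
    mm(pick(p("tieneContraindicacion"), "drug", "diagnosis"), by = "drug") |>
    dplyr::inner_join(pick(p("tieneDiagnostico"), "note", "diagnosis"),
                      by = c("note", "diagnosis"))
  alerts <- dplyr::distinct(joined[, c("note", "drug", "diagnosis")])
  alert_prop <- p("tieneAlertaDeContraindicacion")
  if (!alert_prop %in% net$obj_props$iri) {
    net <- add_object_property(net, alert_prop,
                               iri(ns_of_module(net, "datos"), "Nota_Medica"),
                               iri(medi, "Medicamento"),
                               label = "hasContraindicationAlert")
  }
  if (nrow(alerts) > 0) {
    net <- add_assertions_bulk(net, tibble::tibble(
      subject = alerts$note, predicate = alert_prop, object = alerts$drug,
      object_kind = "iri", datatype = NA_character_))
  }
  list(net = net, alerts = alerts)
}
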