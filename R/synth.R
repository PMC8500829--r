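# Seeded generator of synthetic clinical-record corpora. Marginal totals
# (patients, sex split, per-category diagnoses, per-drug prescriptions) are
# dealt from exact-quota decks, so they match the corpus profile exactly at
# every seed; randomness only permutes the assignment across patients and
# notes. Terms are drawn from the fixture gazetteers so the extraction
# pipeline has text to chew on.

#' Default synthetic corpus profile
#'
#' The documented study corpus: 171 clinical records (90 male, 81 female
#' patients), 729 diagnoses (143 insulin-dependent DM, 149
#' non-insulin-dependent DM, 437 other clinical entities) and 1626
#' prescriptions, led by Insulin Glargine (131), Metformin (61) and Diosmin
#' with Hesperidin (58); the remainder is spread over a fixture drug list.
#' Notes per record is a free distribution parameter (uniform on 1..4 by
#' default, which keeps one-diagnosis-per-note feasible).
#'
#' @param seed Integer seed for the generator.
#' @return A `corpus_profile` list.
#' @export
default_corpus_profile <- function(seed = 1L) {
  corpus_profile(
    n_patients = 171L, n_male = 90L, n_female = 81L,
    diagnosis_quota = c(insulin_dependent = 143L, non_insulin_dependent = 149L,
                        other = 437L),
    prescription_total = 1626L,
    prescription_named = c("Insulina Glargina" = 131L, "Metformina" = 61L,
                           "Diosmina Con Hesperidina" = 58L),
    other_drugs = c("Insulina Lispro", "Glibenclamida", "Enalapril", "Losartan",
                    "Atorvastatina", "Bezafibrato", "Acido Acetilsalicilico",
                    "Omeprazol", "Paracetamol", "Captopril", "Pregabalina",
                    "Complejo B"),
    notes_per_record = 1:4,
    seed = seed
  )
}

#' Construct and validate a corpus profile
#'
#' @param n_patients,n_male,n_female Patient counts; the sex split must sum
#'   to `n_patients`.
#' @param diagnosis_quota Named integer vector with entries
#'   `insulin_dependent`, `non_insulin_dependent`, `other`.
#' @param prescription_total Total prescriptions across all notes.
#' @param prescription_named Named quotas for specific drugs; the remainder
#'   up to `prescription_total` is spread evenly over `other_drugs`.
#' @param other_drugs Fixture drug names receiving the remainder.
#' @param notes_per_record Integer support of the notes-per-record
#'   distribution (sampled uniformly).
#' @param seed Integer seed.
#' @return A validated `corpus_profile` list.
#' @export
corpus_profile <- function(n_patients, n_male, n_female, diagnosis_quota,
                           prescription_total, prescription_named,
                           other_drugs, notes_per_record = 1:4, seed = 1L) {
  profile <- list(n_patients = as.integer(n_patients), n_male = as.integer(n_male),
                  n_female = as.integer(n_female),
                  diagnosis_quota = diagnosis_quota,
                  prescription_total = as.integer(prescription_total),
                  prescription_named = prescription_named,
                  other_drugs = other_drugs,
                  notes_per_record = as.integer(notes_per_record),
                  seed = as.integer(seed))
  validate_profile(profile)
  structure(profile, class = "corpus_profile")
}

validate_profile <- function(profile) {
  with(profile, {
    if (n_male + n_female != n_patients) {
      stop_onto("sex split (", n_male, "+", n_female, ") must sum to n_patients (",
                n_patients, ")")
    }
    if (any(diagnosis_quota < 0) || any(prescription_named < 0)) {
      stop_onto("quotas must be non-negative")
    }
    if (sum(prescription_named) > prescription_total) {
      stop_onto("named prescription quotas exceed the prescription total")
    }
    n_diag <- sum(diagnosis_quota)
    max_notes <- max(notes_per_record) * n_patients
    if (max_notes > n_diag || max_notes > prescription_total) {
      stop_onto("infeasible quota: up to ", max_notes, " notes but only ",
                n_diag, " diagnoses / ", prescription_total,
                " prescriptions (every note needs at least one of each)")
    }
    invisible(NULL)
  })
}

# Exact-quota deck: names repeated per count.
build_deck <- function(quota) rep(names(quota), times = quota)

# Spread `total` evenly over `items`: first `total %% k` items get one extra.
spread_quota <- function(total, items) {
  k <- length(items)
  base <- total %/% k
  extra <- total %% k
  stats::setNames(as.integer(base + (seq_len(k) <= extra)), items)
}

fixture_disabilities <- function() {
  c("discapacidad motriz", "discapacidad visual", "discapacidad auditiva",
    "discapacidad intelectual", "amputacion de miembro inferior")
}

#' Generate a synthetic clinical-record corpus
#'
#' Produces structured clinical records (patient sheet, histories, dated
#' medical notes with signs, diagnoses and prescriptions) plus companion
#' free-text fragments (note narratives and drug-leaflet sections) that
#' exercise the extraction gazetteers. All marginal totals equal the profile
#' exactly at any seed.
#'
#' @param profile A `corpus_profile`, see [default_corpus_profile()].
#' @param gazetteer_dir Directory of fixture gazetteers used for diagnosis /
#'   symptom vocabulary.
#' @return An `onto_corpus` list: `records` (list of clinical-record
#'   documents), `fragments` (tibble of free-text fragments) and `profile`.
#' @export
generate_corpus <- function(profile = default_corpus_profile(),
                            gazetteer_dir = default_gazetteer_dir()) {
  validate_profile(profile)
  gaz <- load_gazetteers(gazetteer_dir)
  diseases <- gaz$term[gaz$tag == "Disease"]
  symptoms <- gaz$term[gaz$tag == "Symptom"]
  t1dm <- "diabetes mellitus tipo 1"
  t2dm <- "diabetes mellitus tipo 2"
  other_diseases <- setdiff(diseases, c(t1dm, t2dm))

  set.seed(profile$seed)
  n <- profile$n_patients
  sexes <- sample(c(rep("Male", profile$n_male), rep("Female", profile$n_female)))
  ages <- sample(25:90, n, replace = TRUE)
  states <- sample(mexican_states(), n, replace = TRUE)
  levels <- sample(education_levels()$level, n, replace = TRUE)
  disabilities <- sample(fixture_disabilities(), n, replace = TRUE)
  notes_per <- sample(profile$notes_per_record, n, replace = TRUE)
  n_notes <- sum(notes_per)

  # diagnosis deck: exact category quotas, categories mapped to terms
  dq <- profile$diagnosis_quota
  diag_deck <- c(rep(t1dm, dq[["insulin_dependent"]]),
                 rep(t2dm, dq[["non_insulin_dependent"]]),
                 build_deck(spread_quota(dq[["other"]], other_diseases)))
  diag_deck <- sample(diag_deck)
  # prescription deck: named quotas plus an even spread of the remainder
  remainder <- profile$prescription_total - sum(profile$prescription_named)
  rx_quota <- c(profile$prescription_named, spread_quota(remainder, profile$other_drugs))
  rx_deck <- sample(build_deck(rx_quota))

  # each note gets one diagnosis and one prescription first; extras are dealt
  # to uniformly chosen notes
  diag_of_note <- vector("list", n_notes)
  rx_of_note <- vector("list", n_notes)
  for (i in seq_len(n_notes)) {
    diag_of_note[[i]] <- diag_deck[i]
    rx_of_note[[i]] <- rx_deck[i]
  }
  extra_diag <- diag_deck[-seq_len(n_notes)]
  for (d in extra_diag) {
    i <- sample.int(n_notes, 1)
    diag_of_note[[i]] <- c(diag_of_note[[i]], d)
  }
  extra_rx <- rx_deck[-seq_len(n_notes)]
  for (d in extra_rx) {
    i <- sample.int(n_notes, 1)
    rx_of_note[[i]] <- c(rx_of_note[[i]], d)
  }

  doctors <- sprintf("Medico_%02d", 1:12)
  insulins <- c("Insulina Glargina", "Insulina Lispro")
  make_prescription <- function(drug) {
    if (drug %in% insulins) {
      list(drug = drug, amount = sample(10:30, 1), measure = "UI",
           frequency = sample(1:2, 1))
    } else {
      list(drug = drug, amount = sample(1:2, 1), measure = "tableta",
           frequency = sample(1:3, 1))
    }
  }

  records <- vector("list", n)
  frag_rows <- list()
  note_idx <- 0L
  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", i)
    birth_year <- 2020L - ages[i]
    birth_date <- sprintf("%04d-%02d-%02d", birth_year, sample(1:12, 1), sample(1:28, 1))
    notes <- vector("list", notes_per[i])
    for (j in seq_len(notes_per[i])) {
      note_idx <- note_idx + 1L
      date <- sprintf("2020-%02d-%02d", sample(1:12, 1), sample(1:28, 1))
      sym <- sample(symptoms, 1)
      diagnoses <- diag_of_note[[note_idx]]
      signs <- list(
        peso = round(stats::runif(1, 45, 120), 1),
        talla = round(stats::runif(1, 1.40, 1.95), 2),
        glucosa = sample(70:300, 1),
        frecuencia_cardiaca = sample(60:100, 1),
        frecuencia_respiratoria = sample(12:24, 1),
        temperatura = round(stats::runif(1, 36, 38.5), 1),
        cintura = round(stats::runif(1, 60, 140), 1),
        cadera = round(stats::runif(1, 70, 150), 1)
      )
      notes[[j]] <- list(
        id = sprintf("%s_%d", pid, j),
        date = date,
        doctor = sample(doctors, 1),
        signs = signs,
        current_condition = paste0("Paciente refiere ", sym, "."),
        physical_exam = "Exploración física sin hallazgos adicionales.",
        analysis = paste0("Control de ", diagnoses[[1]], "."),
        diagnoses = as.list(diagnoses),
        prescriptions = lapply(rx_of_note[[note_idx]], make_prescription)
      )
      frag_rows[[length(frag_rows) + 1]] <- tibble::tibble(
        kind = "note", ref = notes[[j]]$id, section = "padecimiento_actual",
        text = paste0("Paciente refiere ", sym, ". Diagnóstico: ",
                      paste(diagnoses, collapse = "; "), ". Glucosa ",
                      signs$glucosa, "."))
    }
    records[[i]] <- list(
      patient = list(id = pid, sex = sexes[i], birth_date = birth_date,
                     state = states[i], education_level = levels[i]),
      histories = list(
        hereditary_family = "Madre con diabetes mellitus tipo 2.",
        pathological = "Sin antecedentes quirúrgicos.",
        non_pathological = "Niega tabaquismo y alcoholismo.",
        gyneco_obstetric = if (sexes[i] == "Female") "G2 P2." else "",
        allergies = "Negadas.",
        disabilities = list(disabilities[i])
      ),
      notes = notes
    )
  }

  # drug-leaflet fragments: static per drug (seed-independent text)
  drugs <- c(names(profile$prescription_named), profile$other_drugs)
  contra_pool <- other_diseases
  leaflets <- purrr::map_dfr(seq_along(drugs), function(k) {
    contra <- contra_pool[(k - 1) %% length(contra_pool) + 1]
    caution <- contra_pool[k %% length(contra_pool) + 1]
    tibble::tibble(
      kind = "drug", ref = drugs[k],
      section = c("efectos_secundarios", "contraindicaciones", "precauciones"),
      text = c(
        "Puede presentar nauseas, cefalea y mareo.",
        paste0("Contraindicado en pacientes con ", contra, "."),
        paste0("Usar con precaución en pacientes con ", caution, ".")))
  })
  fragments <- dplyr::bind_rows(dplyr::bind_rows(frag_rows), leaflets)

  structure(list(records = records, fragments = fragments, profile = profile),
            class = "onto_corpus")
}

#' @export
print.onto_corpus <- function(x, ...) {
  s <- corpus_summary(x)
  cat("<onto_corpus> ", s$records, " records, ", s$notes, " notes, ",
      s$diagnoses, " diagnoses, ", s$prescriptions, " prescriptions\n", sep = "")
  invisible(x)
}

#' Marginal counts of a corpus
#'
#' @param corpus An `onto_corpus`.
#' @return One-row tibble: `records`, `male`, `female`, `notes`, `diagnoses`,
#'   `prescriptions`.
#' @export
corpus_summary <- function(corpus) {
  sexes <- vapply(corpus$records, function(r) r$patient$sex, character(1))
  all_notes <- unlist(lapply(corpus$records, function(r) r$notes), recursive = FALSE)
  tibble::tibble(
    records = length(corpus$records),
    male = sum(sexes == "Male"),
    female = sum(sexes == "Female"),
    notes = length(all_notes),
    diagnoses = sum(vapply(all_notes, function(n) length(n$diagnoses), integer(1))),
    prescriptions = sum(vapply(all_notes, function(n) length(n$prescriptions), integer(1)))
  )
}

#' Per-drug prescription counts of a corpus
#'
#' @param corpus An `onto_corpus`.
#' @return Tibble `drug`, `n`, sorted decreasing.
#' @export
prescription_counts <- function(corpus) {
  notes <- unlist(lapply(corpus$records, function(r) r$notes), recursive = FALSE)
  drugs <- unlist(lapply(notes, function(n) vapply(n$prescriptions, `[[`, character(1), "drug")))
  dplyr::arrange(dplyr::count(tibble::tibble(drug = drugs), .data$drug, name = "n"),
                 dplyr::desc(.data$n))
}

#' Per-category diagnosis counts of a corpus
#'
#' @param corpus An `onto_corpus`.
#' @return Tibble `diagnosis`, `n`, sorted decreasing.
#' @export
diagnosis_counts <- function(corpus) {
  notes <- unlist(lapply(corpus$records, function(r) r$notes), recursive = FALSE)
  d <- unlist(lapply(notes, function(n) unlist(n$diagnoses)))
  dplyr::arrange(dplyr::count(tibble::tibble(diagnosis = d), .data$diagnosis, name = "n"),
                 dplyr::desc(.data$n))
}
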