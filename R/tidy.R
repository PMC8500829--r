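#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ontology network into its element table
#'
#' One row per declared element (class, property, individual) with its
#' module, kind and label.
#'
#' @param x An `onto_network`.
#' @param ... Unused.
#' @return A tibble with `iri`, `local_name`, `kind`, `module`, `label`.
#' @exportS3Method generics::tidy
tidy.onto_network <- function(x, ...) {
  labels <- x$annotations[x$annotations$property == RDFS_LABEL, ]
  rows <- dplyr::bind_rows(
    tibble::tibble(iri = x$classes$iri, kind = "class", module = x$classes$module),
    tibble::tibble(iri = x$obj_props$iri, kind = "object_property",
                   module = x$obj_props$module),
    tibble::tibble(iri = x$data_props$iri, kind = "data_property",
                   module = x$data_props$module),
    tibble::tibble(iri = unique(x$individuals$iri), kind = "individual",
                   module = x$individuals$module[!duplicated(x$individuals$iri)])
  )
  rows$local_name <- split_iri(rows$iri)$local_name
  rows <- dplyr::left_join(rows,
    dplyr::distinct(labels[, c("subject", "value")], .data$subject, .keep_all = TRUE),
    by = c(iri = "subject"))
  dplyr::rename(rows, label = "value")[, c("iri", "local_name", "kind", "module", "label")]
}

#' One-row summary of an ontology network
#'
#' @param x An `onto_network`.
#' @param ... Unused.
#' @return Tibble: `modules`, `classes`, `object_properties`,
#'   `data_properties`, `individuals`, `assertions`, `meta_relations_design`,
#'   `meta_relations_extraction`.
#' @exportS3Method generics::glance
glance.onto_network <- function(x, ...) {
  mr <- meta_relations(x)
  tibble::tibble(
    modules = nrow(x$modules),
    classes = nrow(x$classes),
    object_properties = nrow(x$obj_props),
    data_properties = nrow(x$data_props),
    individuals = length(unique(x$individuals$iri)),
    assertions = nrow(x$assertions),
    meta_relations_design = sum(mr$stage == "design"),
    meta_relations_extraction = sum(mr$stage == "extraction")
  )
}

#' Tidy a corpus into one row per medical note
#'
#' @param x An `onto_corpus`.
#' @param ... Unused.
#' @return Tibble with patient descriptors and per-note counts and signs.
#' @exportS3Method generics::tidy
tidy.onto_corpus <- function(x, ...) {
  purrr::map_dfr(x$records, function(r) {
    purrr::map_dfr(r$notes, function(n) {
      tibble::tibble(
        patient = r$patient$id, sex = r$patient$sex, state = r$patient$state,
        note = n$id, date = n$date,
        weight = n$signs$peso, height = n$signs$talla, glucose = n$signs$glucosa,
        waist = n$signs$cintura, hip = n$signs$cadera,
        n_diagnoses = length(n$diagnoses), n_prescriptions = length(n$prescriptions))
    })
  })
}

#' @rdname corpus_summary
#' @param x An `onto_corpus`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.onto_corpus <- function(x, ...) corpus_summary(x)

#' Plot per-module individual counts
#'
#' @param object A `satisfiability_report` from [satisfy_check()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.satisfiability_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, .data$individuals),
                                   y = .data$individuals, fill = .data$nonempty)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Individuals",
                  title = "Individuals per ontology module") +
    ggplot2::theme_minimal()
}

#' Plot per-note diagnosis and prescription loads of a corpus
#'
#' @param object An `onto_corpus`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.onto_corpus <- function(object, ...) {
  df <- tidy.onto_corpus(object)
  long <- tidyr::pivot_longer(df, c("n_diagnoses", "n_prescriptions"),
                              names_to = "what", values_to = "n")
  long$what <- ifelse(long$what == "n_diagnoses", "Diagnoses per note",
                      "Prescriptions per note")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(~what) +
    ggplot2::labs(x = NULL, y = "Notes") +
    ggplot2::theme_minimal()
}
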