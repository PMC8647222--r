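#' Homology-hit term-frequency baseline
#'
#' Alignment-based baseline for function prediction: a query protein is
#' annotated with every term present among its homology hits to the
#' training set, with posterior equal to the frequency of that term among
#' the hits (number of hits annotated with the term divided by the total
#' number of hits). Queries without hits receive no predictions, so
#' coverage can be below 1.
#'
#' @param hits A hit table as from [read_hit_table()] (columns `query`,
#'   `subject`; extra columns ignored). Subjects not present in the
#'   training annotations are dropped with a warning.
#' @param train_ann Propagated training [annotation_set()].
#' @param queries Character vector of query protein IDs (rows of the
#'   result; queries without hits get an all-zero row).
#' @param include_self_hits Keep hits whose subject equals the query
#'   (default `FALSE`: a query present in the training set would otherwise
#'   trivially receive its own labels).
#' @return Proteins x terms probability matrix (terms = all training
#'   terms), `attr(, "corrected") = TRUE` — frequencies of propagated
#'   annotations are hierarchy-consistent by construction. Attribute
#'   `n_hits` gives the per-query hit count used.
#' @export
frequency_predict <- function(hits, train_ann, queries,
                              include_self_hits = FALSE) {
  hits <- tibble::as_tibble(hits)
  train_ann <- tibble::as_tibble(train_ann)
  train_proteins <- unique(train_ann$protein)
  terms <- sort(unique(train_ann$term))

  hits <- hits[hits$query %in% queries, , drop = FALSE]
  if (!include_self_hits) {
    hits <- hits[hits$query != hits$subject, , drop = FALSE]
  }
  known <- hits$subject %in% train_proteins
  if (any(!known)) {
    warning(
      sum(!known),
      " hit(s) to subjects outside the training set dropped"
    )
    hits <- hits[known, , drop = FALSE]
  }

  P <- matrix(0,
    nrow = length(queries), ncol = length(terms),
    dimnames = list(queries, terms)
  )
  n_hits <- stats::setNames(integer(length(queries)), queries)
  if (nrow(hits) > 0L) {
    # hit rows joined to the subjects' annotations; count per (query, term)
    ann_by_subject <- split(train_ann$term, train_ann$protein)
    by_query <- split(hits$subject, hits$query)
    for (q in names(by_query)) {
      subs <- by_query[[q]] # one entry per hit row (duplicates count)
      n_hits[[q]] <- length(subs)
      term_counts <- table(unlist(ann_by_subject[subs], use.names = FALSE))
      if (length(term_counts) > 0L) {
        P[q, names(term_counts)] <- as.numeric(term_counts) / length(subs)
      }
    }
  }
  attr(P, "corrected") <- TRUE
  attr(P, "n_hits") <- n_hits
  P
}

#' Percent identity of the top homology hit per query
#'
#' The top hit is the one with the highest bitscore; ties are broken by
#' lowest e-value, then lexicographically by subject ID. Queries without
#' hits are absent from the result.
#'
#' @param hits A hit table with columns `query`, `subject`, `pident`,
#'   `evalue`, `bitscore`.
#' @param queries Queries to report on (default: all in the table).
#' @return A tibble with columns `query`, `subject`, `pident`.
#' @export
top_hit_identity <- function(hits, queries = unique(hits$query)) {
  hits <- tibble::as_tibble(hits)
  hits <- hits[hits$query %in% queries, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(tibble::tibble(
      query = character(0), subject = character(0), pident = numeric(0)
    ))
  }
  hits |>
    dplyr::group_by(.data$query) |>
    dplyr::arrange(
      dplyr::desc(.data$bitscore), .data$evalue, .data$subject,
      .by_group = TRUE
    ) |>
    dplyr::slice_head(n = 1L) |>
    dplyr::ungroup() |>
    dplyr::select("query", "subject", "pident")
}
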