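#' Construct an ontology DAG
#'
#' Builds a rooted directed acyclic graph of ontology terms from a child
#' -> parent edge table. The DAG is the backbone of everything downstream:
#' true-path propagation of annotations, term depth, information content,
#' hierarchy-consistent posterior correction and GO-category extraction.
#'
#' @param edges A data frame with columns `child`, `parent` and optionally
#'   `relation` (defaults to `"is_a"`). Each row is one child -> parent edge.
#' @param terms Optional character vector of term IDs. Terms appearing in
#'   `edges` are always included; isolated terms can be added here.
#' @param namespace Label for the ontology namespace (e.g.
#'   `"molecular_function"`).
#'
#' @return An object of class `ontology_dag`: a list with elements `terms`,
#'   `parents` (named list, term -> character vector of parents), `children`,
#'   `root`, `namespace`, `depth` (named integer, longest path from the root
#'   in edges) and `ancestors` (named list of all ancestors, term itself
#'   excluded).
#'
#' @details The root is the unique term with no parents. A cycle or a
#'   missing/ambiguous root is a hard error: both break the true-path rule
#'   and every statistic defined on the hierarchy.
#'
#' @examples
#' dag <- ontology_dag(data.frame(child = c("A", "B"), parent = c("root", "A")))
#' term_depth(dag, "B")
#' @export
ontology_dag <- function(edges, terms = NULL, namespace = "molecular_function") {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("child", "parent") %in% names(edges)))
  if (!"relation" %in% names(edges)) edges$relation <- "is_a"
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)

  all_terms <- sort(unique(c(edges$child, edges$parent, as.character(terms))))
  if (length(all_terms) == 0L) stop("ontology has no terms")

  parents <- split(edges$parent, factor(edges$child, levels = all_terms))
  parents <- lapply(parents, unique)
  children <- split(edges$child, factor(edges$parent, levels = all_terms))
  children <- lapply(children, unique)

  n_par <- lengths(parents)
  roots <- all_terms[n_par == 0L]
  if (length(roots) == 0L) {
    stop("no root term found (every term has a parent): missing root")
  }
  if (length(roots) > 1L) {
    stop(
      "multiple parentless terms found (",
      paste(utils::head(roots, 5L), collapse = ", "),
      "): root is ambiguous"
    )
  }
  root <- roots

  # Kahn topological sort; leftover nodes expose a cycle.
  indeg <- lengths(parents)
  queue <- root
  topo <- character(0)
  indeg_env <- indeg
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    topo <- c(topo, v)
    for (ch in children[[v]]) {
      indeg_env[[ch]] <- indeg_env[[ch]] - 1L
      if (indeg_env[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) < length(all_terms)) {
    stuck <- setdiff(all_terms, topo)
    bad <- stuck[1L]
    bad_parent <- intersect(parents[[bad]], stuck)[1L]
    stop("cycle detected in ontology involving edge ", bad, " -> ", bad_parent)
  }

  # Longest-path depth and full ancestor sets along topological order.
  depth <- stats::setNames(integer(length(all_terms)), all_terms)
  ancestors <- stats::setNames(vector("list", length(all_terms)), all_terms)
  for (v in topo) {
    ps <- parents[[v]]
    if (length(ps) > 0L) {
      depth[[v]] <- max(depth[ps]) + 1L
      ancestors[[v]] <- unique(c(ps, unlist(ancestors[ps], use.names = FALSE)))
    } else {
      ancestors[[v]] <- character(0)
    }
  }

  structure(
    list(
      terms = all_terms, parents = parents, children = children,
      root = root, namespace = namespace, depth = depth,
      ancestors = ancestors, edges = edges
    ),
    class = "ontology_dag"
  )
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(
    "<ontology_dag> ", length(x$terms), " terms, ",
    nrow(x$edges), " edges, root ", x$root,
    " (", x$namespace, "), max depth ", max(x$depth), "\n",
    sep = ""
  )
  invisible(x)
}

#' Parse an OBO ontology file
#'
#' Reads an OBO 1.2/1.4 file, restricts it to one namespace, drops obsolete
#' terms and keeps only the requested relation types (default `is_a` only).
#'
#' @param path Path to an OBO file.
#' @param namespace One of `"molecular_function"`, `"biological_process"`,
#'   `"cellular_component"` (or any namespace label present in the file).
#' @param relations Character vector of relations to keep as edges.
#'   `"is_a"` is the `is_a:` tag; other relations (e.g. `"part_of"`) are read
#'   from `relationship:` lines.
#'
#' @return An [ontology_dag()].
#' @export
parse_obo <- function(path, namespace = "molecular_function",
                      relations = "is_a") {
  lines <- readLines(path)
  # Split into stanzas; keep [Term] stanzas only.
  stanza_starts <- grep("^\\[", lines)
  if (length(stanza_starts) == 0L) stop("no stanzas found in OBO file: ", path)
  bounds <- c(stanza_starts, length(lines) + 1L)

  ids <- character(0)
  edge_child <- character(0)
  edge_parent <- character(0)
  edge_rel <- character(0)

  for (i in seq_along(stanza_starts)) {
    if (lines[stanza_starts[i]] != "[Term]") next
    block <- lines[(stanza_starts[i] + 1L):(bounds[i + 1L] - 1L)]
    get_vals <- function(tag) {
      hits <- grep(paste0("^", tag, ":"), block, value = TRUE)
      trimws(sub(paste0("^", tag, ":\\s*"), "", hits))
    }
    id <- get_vals("id")[1L]
    if (is.na(id) || !nzchar(id)) next
    if (any(grepl("^is_obsolete:\\s*true", block))) next
    ns <- get_vals("namespace")[1L]
    if (!is.na(ns) && nzchar(namespace) && ns != namespace) next
    ids <- c(ids, id)
    if ("is_a" %in% relations) {
      for (tgt in get_vals("is_a")) {
        parent <- trimws(sub("!.*$", "", tgt))
        edge_child <- c(edge_child, id)
        edge_parent <- c(edge_parent, parent)
        edge_rel <- c(edge_rel, "is_a")
      }
    }
    other <- setdiff(relations, "is_a")
    if (length(other) > 0L) {
      for (rl in get_vals("relationship")) {
        parts <- strsplit(trimws(sub("!.*$", "", rl)), "\\s+")[[1L]]
        if (length(parts) >= 2L && parts[1L] %in% other) {
          edge_child <- c(edge_child, id)
          edge_parent <- c(edge_parent, parts[2L])
          edge_rel <- c(edge_rel, parts[1L])
        }
      }
    }
  }
  if (length(ids) == 0L) stop("no terms in namespace '", namespace, "'")
  keep <- edge_parent %in% ids # drop edges into other namespaces / obsolete
  ontology_dag(
    tibble::tibble(
      child = edge_child[keep], parent = edge_parent[keep],
      relation = edge_rel[keep]
    ),
    terms = ids, namespace = namespace
  )
}

#' Create an annotation set
#'
#' An annotation set is a tidy protein -> term table with an evidence code
#' per record and a flag saying whether it has been closed under the
#' true-path rule (every annotated term implies all its ancestors).
#'
#' @param records A data frame with columns `protein`, `term` and optionally
#'   `evidence`.
#' @param propagated Logical; `TRUE` if the set is already ancestor-closed.
#'
#' @return A tibble of class `annotation_set` with attribute `propagated`.
#' @export
annotation_set <- function(records, propagated = FALSE) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("protein", "term") %in% names(records)))
  if (!"evidence" %in% names(records)) records$evidence <- NA_character_
  records$protein <- as.character(records$protein)
  records$term <- as.character(records$term)
  records <- dplyr::distinct(records, .data$protein, .data$term,
    .keep_all = TRUE
  )
  structure(records,
    propagated = isTRUE(propagated),
    class = c("annotation_set", class(tibble::tibble()))
  )
}

#' @rdname annotation_set
#' @param ann An annotation set.
#' @export
is_propagated <- function(ann) isTRUE(attr(ann, "propagated"))

#' Propagate annotations up the ontology (true-path rule)
#'
#' Replaces each protein's term set by its ancestor closure, so that a
#' protein annotated with a term is also annotated with every ancestor of
#' that term up to and including the root. Idempotent.
#'
#' @param dag An [ontology_dag()].
#' @param ann An [annotation_set()]. Records pointing at terms absent from
#'   the DAG are dropped with a warning giving the count.
#'
#' @return A propagated [annotation_set()]. Evidence codes are carried along:
#'   an inferred ancestor record keeps the evidence of (one of) the
#'   descendant records that implied it.
#' @export
propagate_annotations <- function(dag, ann) {
  stopifnot(inherits(dag, "ontology_dag"))
  ann <- annotation_set(ann, propagated = is_propagated(ann))
  unknown <- !(ann$term %in% dag$terms)
  if (any(unknown)) {
    warning(
      sum(unknown), " annotation record(s) to terms absent from the ",
      "ontology were dropped"
    )
    ann <- ann[!unknown, ]
  }
  if (nrow(ann) == 0L) return(annotation_set(ann, propagated = TRUE))
  closure <- lapply(seq_len(nrow(ann)), function(i) {
    t <- ann$term[i]
    c(t, dag$ancestors[[t]])
  })
  out <- tibble::tibble(
    protein = rep(ann$protein, lengths(closure)),
    term = unlist(closure, use.names = FALSE),
    evidence = rep(ann$evidence, lengths(closure))
  )
  annotation_set(out, propagated = TRUE)
}

#' Term depth: longest path from the root
#'
#' Depth of a term is the number of edges on the longest possible path from
#' the namespace root to the term; the root has depth 0.
#'
#' @param dag An [ontology_dag()].
#' @param terms Character vector of term IDs (default: all terms).
#' @return Named integer vector of depths.
#' @export
term_depth <- function(dag, terms = dag$terms) {
  stopifnot(inherits(dag, "ontology_dag"))
  missing <- setdiff(terms, dag$terms)
  if (length(missing) > 0L) {
    stop("unknown term(s): ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  dag$depth[terms]
}

#' Resnik information content of ontology terms
#'
#' For a propagated annotation corpus, the information content of a term t is
#' `ic(t) = -log(n_t / N)` where `n_t` is the number of proteins annotated
#' with t and `N` the number annotated with the root (i.e. all annotated
#' proteins, by the true-path rule). Rare terms carry high IC; the root has
#' IC 0. Terms annotated to no protein have undefined IC and are absent from
#' the result.
#'
#' @param ann A propagated [annotation_set()] (propagation is enforced).
#' @param dag An [ontology_dag()].
#' @param base Logarithm base; natural log by default. The base cancels in
#'   correlational use.
#'
#' @return A tibble with columns `term` and `ic` (non-negative reals).
#' @export
resnik_ic <- function(ann, dag, base = exp(1)) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!is_propagated(ann)) ann <- propagate_annotations(dag, ann)
  if (nrow(ann) == 0L) stop("empty annotation corpus: IC undefined")
  n_total <- length(unique(ann$protein))
  counts <- dplyr::count(tibble::as_tibble(ann), .data$term, name = "n")
  tibble::tibble(
    term = counts$term,
    ic = -log(counts$n / n_total, base = base)
  )
}

#' Extract GO categories
#'
#' A GO category is a dataset term at a given depth (default 2) with at
#' least `min_children` child terms, where children are counted among the
#' terms present in the dataset (set `within_dataset = FALSE` to count all
#' DAG children). Category members are the dataset descendant terms of the
#' category term.
#'
#' @param dag An [ontology_dag()].
#' @param terms_in_dataset Character vector of term IDs present in the
#'   dataset; must be a subset of `dag$terms`.
#' @param category_depth Depth at which category terms are selected.
#' @param min_children Minimum number of child terms for a term to qualify.
#' @param within_dataset Count children/members among dataset terms only?
#'
#' @return A tibble with columns `category` and `member` (one row per
#'   category-member pair; a category is its own member is *not* included).
#' @export
go_categories <- function(dag, terms_in_dataset,
                          category_depth = 2L, min_children = 5L,
                          within_dataset = TRUE) {
  stopifnot(inherits(dag, "ontology_dag"))
  terms_in_dataset <- unique(as.character(terms_in_dataset))
  bad <- setdiff(terms_in_dataset, dag$terms)
  if (length(bad) > 0L) {
    stop("dataset terms absent from DAG: ", paste(utils::head(bad, 5L),
      collapse = ", "
    ))
  }
  pool <- if (within_dataset) terms_in_dataset else dag$terms
  cand <- terms_in_dataset[dag$depth[terms_in_dataset] == category_depth]
  desc <- term_descendants(dag)
  rows <- lapply(cand, function(ct) {
    kids <- intersect(dag$children[[ct]], pool)
    if (length(kids) < min_children) return(NULL)
    members <- intersect(desc[[ct]], terms_in_dataset)
    if (length(members) == 0L) return(NULL)
    tibble::tibble(category = ct, member = members)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(category = character(0), member = character(0)))
  }
  out
}

#' All descendants of every term
#'
#' @param dag An [ontology_dag()].
#' @return Named list: term -> character vector of all descendant terms
#'   (term itself excluded).
#' @export
term_descendants <- function(dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  desc <- stats::setNames(vector("list", length(dag$terms)), dag$terms)
  for (t in dag$terms) desc[[t]] <- character(0)
  # children-before-parents: descending depth order
  for (t in dag$terms[order(dag$depth, decreasing = TRUE)]) {
    for (p in dag$parents[[t]]) {
      desc[[p]] <- unique(c(desc[[p]], t, desc[[t]]))
    }
  }
  desc
}
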