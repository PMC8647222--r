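# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive enumeration, not the package's algorithms.

# random DAG as a child->parent edge tibble; node 1 is the root and every
# later node picks >= 1 parent among earlier nodes (acyclic by construction)
random_dag_edges <- function(n_terms, seed, max_parents = 2L) {
  set.seed(seed)
  ids <- sprintf("T%02d", seq_len(n_terms))
  child <- character(0)
  parent <- character(0)
  for (i in 2:n_terms) {
    k <- sample(seq_len(min(max_parents, i - 1L)), 1L)
    ps <- sample(ids[seq_len(i - 1L)], k)
    child <- c(child, rep(ids[i], k))
    parent <- c(parent, ps)
  }
  tibble::tibble(child = child, parent = parent)
}

# exhaustive ancestor set by repeated parent lookup
oracle_ancestors <- function(edges, term) {
  out <- character(0)
  frontier <- term
  while (length(frontier) > 0L) {
    ps <- unique(edges$parent[edges$child %in% frontier])
    ps <- setdiff(ps, out)
    out <- c(out, ps)
    frontier <- ps
  }
  out
}

# longest root->term path by exhaustive path enumeration
oracle_depth <- function(edges, term, root) {
  if (term == root) return(0L)
  best <- -1L
  recurse <- function(node, len) {
    if (node == root) {
      best <<- max(best, len)
      return(invisible())
    }
    for (p in edges$parent[edges$child == node]) recurse(p, len + 1L)
  }
  recurse(term, 0L)
  best
}

# all-pairs concordance AUC with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# naive per-protein precision/recall/F1 aggregation
oracle_prf <- function(pred_sets, true_sets, proteins) {
  precisions <- c()
  recalls <- c()
  covered <- 0
  n_eval <- 0
  for (p in proteins) {
    tset <- true_sets[[p]]
    if (is.null(tset) || length(tset) == 0L) next
    n_eval <- n_eval + 1
    pset <- pred_sets[[p]]
    tp <- length(intersect(pset, tset))
    if (length(pset) > 0L) {
      covered <- covered + 1
      precisions <- c(precisions, tp / length(pset))
    }
    recalls <- c(recalls, tp / length(tset))
  }
  pr <- if (length(precisions) > 0) mean(precisions) else 0
  rc <- mean(recalls)
  f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  list(precision = pr, recall = rc, f1 = f1, coverage = covered / n_eval)
}

# naive ru/mi at one threshold
oracle_ru_mi <- function(pred_sets, true_sets, proteins, ic_map) {
  ru <- c()
  mi <- c()
  for (p in proteins) {
    tset <- true_sets[[p]]
    if (is.null(tset) || length(tset) == 0L) next
    pset <- pred_sets[[p]]
    ru <- c(ru, sum(ic_map[setdiff(tset, pset)]))
    mi <- c(mi, sum(ic_map[setdiff(pset, tset)]))
  }
  c(ru = mean(ru), mi = mean(mi))
}

# hit-frequency scores by explicit nested counting
oracle_frequency <- function(hit_query, hit_subject, ann_sets, query, term) {
  subs <- hit_subject[hit_query == query]
  if (length(subs) == 0L) return(0)
  n_ann <- sum(vapply(subs, function(s) term %in% ann_sets[[s]], logical(1L)))
  n_ann / length(subs)
}

# max over a term's own score and all its descendants' scores
oracle_hierarchy_one <- function(P_row, dag_edges, all_terms, term) {
  desc <- character(0)
  frontier <- term
  while (length(frontier) > 0L) {
    ch <- unique(dag_edges$child[dag_edges$parent %in% frontier])
    ch <- setdiff(ch, desc)
    desc <- c(desc, ch)
    frontier <- ch
  }
  max(P_row[intersect(c(term, desc), names(P_row))])
}

# small random world for evaluation tests: proteins with random score
# matrices and random truth sets over a term list
random_instance <- function(n_prot, n_term, seed) {
  set.seed(seed)
  proteins <- sprintf("P%02d", seq_len(n_prot))
  terms <- sprintf("T%02d", seq_len(n_term))
  P <- matrix(round(stats::runif(n_prot * n_term), 2),
    nrow = n_prot, dimnames = list(proteins, terms)
  )
  truth <- do.call(rbind, lapply(proteins, function(p) {
    k <- sample(0:min(4L, n_term), 1L)
    if (k == 0L) return(NULL)
    tibble::tibble(protein = p, term = sample(terms, k))
  }))
  list(P = P, truth = annotation_set(truth, propagated = TRUE),
    proteins = proteins, terms = terms
  )
}
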