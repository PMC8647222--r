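#' Spearman correlation between a performance metric and a covariate
#'
#' Midrank Spearman correlation with the large-sample p-value, as used to
#' relate per-term or per-protein performance to term depth, training
#' support, protein length or annotation count.
#'
#' @param metric,covariate Paired numeric vectors (>= 3 complete pairs).
#' @return A tibble with columns `rho`, `p_value`, `n`.
#' @export
correlate <- function(metric, covariate) {
  ok <- stats::complete.cases(metric, covariate)
  x <- metric[ok]
  y <- covariate[ok]
  if (length(x) < 3L) stop("correlation needs at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: Spearman correlation undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  tibble::tibble(
    rho = unname(ct$estimate), p_value = ct$p.value, n = length(x)
  )
}

#' Equal-frequency protein length bins
#'
#' Ten (by default) intervals covering the training length range, with
#' breaks at the empirical quantiles so bins hold roughly equal numbers of
#' training proteins. Used as one-hot classes by the length probe.
#'
#' @param train_lengths Numeric vector of training protein lengths.
#' @param n_bins Number of bins (default 10).
#' @return An object of class `length_bins` with `breaks` (length
#'   `n_bins + 1`) and `n_bins`.
#' @export
length_bins <- function(train_lengths, n_bins = 10L) {
  qs <- stats::quantile(train_lengths,
    probs = seq(0, 1, length.out = n_bins + 1L), names = FALSE, type = 7
  )
  breaks <- unique(qs)
  if (length(breaks) < n_bins + 1L) {
    stop("too many tied lengths for ", n_bins, " distinct bins")
  }
  structure(list(breaks = breaks, n_bins = as.integer(n_bins)),
    class = "length_bins"
  )
}

#' @rdname length_bins
#' @param bins A `length_bins` object.
#' @param lengths Lengths to assign.
#' @return Integer bin index per length (values outside the training range
#'   are clamped into the first/last bin).
#' @export
assign_length_bin <- function(bins, lengths) {
  idx <- findInterval(lengths, bins$breaks, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), bins$n_bins)
}

#' Protein length probe
#'
#' Tests whether protein-level embeddings encode protein length: one
#' one-vs-rest logistic regression per length bin, with the L2 penalty
#' chosen jointly over bins by the highest mean validation ROCAUC. Reports
#' per-bin and mean test ROCAUC. Bins empty in the training or test set
#' are skipped with a warning.
#'
#' @param X_train,X_val,X_test Standardized embedding matrices.
#' @param len_train,len_val,len_test Protein lengths matching the rows.
#' @param bins A [length_bins()] object (default: deciles of
#'   `len_train`).
#' @param grid Penalty grid (default `10^(2:-5)`).
#' @return A list of class `length_probe`: `mean_auc`, `lambda`, `per_bin`
#'   (tibble `bin`, `lower`, `upper`, `auc`), `tuning` curve.
#' @export
length_probe <- function(X_train, len_train, X_val, len_val,
                         X_test, len_test,
                         bins = NULL, grid = 10^seq(2, -5)) {
  if (is.null(bins)) bins <- length_bins(len_train)
  b_train <- assign_length_bin(bins, len_train)
  b_val <- assign_length_bin(bins, len_val)
  b_test <- assign_length_bin(bins, len_test)
  one_hot <- function(b) {
    Y <- matrix(0L, length(b), bins$n_bins,
      dimnames = list(NULL, paste0("bin", seq_len(bins$n_bins)))
    )
    Y[cbind(seq_along(b), b)] <- 1L
    Y
  }
  Y_train <- one_hot(b_train)
  Y_val <- one_hot(b_val)
  Y_test <- one_hot(b_test)
  usable <- colSums(Y_train) > 0L & colSums(Y_train) < nrow(Y_train) &
    colSums(Y_val) > 0L & colSums(Y_val) < nrow(Y_val) &
    colSums(Y_test) > 0L & colSums(Y_test) < nrow(Y_test)
  if (!all(usable)) {
    warning(sum(!usable), " length bin(s) skipped (empty in some split)")
  }
  if (!any(usable)) stop("no usable length bin")
  Xtr <- as.matrix(unclass(X_train))
  Xva <- as.matrix(unclass(X_val))
  Xte <- as.matrix(unclass(X_test))
  tuning <- tune_lambda(
    Xtr, Y_train[, usable, drop = FALSE],
    Xva, Y_val[, usable, drop = FALSE],
    grid = grid
  )
  per_bin <- purrr::map_dfr(which(usable), function(j) {
    m <- fit_term_lr(Xtr, Y_train[, j], lambda = tuning$lambda)
    tibble::tibble(
      bin = j,
      lower = bins$breaks[j], upper = bins$breaks[j + 1L],
      auc = term_rocauc(predict(m, Xte), Y_test[, j])
    )
  })
  structure(
    list(
      mean_auc = mean(per_bin$auc), lambda = tuning$lambda,
      per_bin = per_bin, tuning = tuning$curve, bins = bins
    ),
    class = "length_probe"
  )
}

#' @export
print.length_probe <- function(x, ...) {
  cat(sprintf(
    "<length_probe> mean test ROCAUC %.3f over %d bins (lambda = %g)\n",
    x$mean_auc, nrow(x$per_bin), x$lambda
  ))
  invisible(x)
}

#' Shared-feature similarity of a term's annotated proteins
#'
#' For the test proteins annotated with a term, computes the maximum
#' fraction of them sharing one structural feature (InterPro domain,
#' family or superfamily), the feature attaining it, the prevalence of
#' that feature among the remaining (non-annotated) feature-covered test
#' proteins, and the mean number of features per annotated protein. The
#' denominator of the shared fraction is the annotated proteins carrying
#' at least one feature of the kind; a term qualifies only if at least
#' `min_coverage` of its annotated proteins carry such features.
#'
#' @param annotated Protein IDs annotated with the term among the test set.
#' @param background Remaining (non-annotated) test protein IDs.
#' @param interpro Tibble from [read_interpro()].
#' @param kind `"domain"`, `"family"` or `"superfamily"`.
#' @param min_coverage Minimum fraction of annotated proteins with features
#'   of the kind (default 0.5); below it the term is skipped (`NULL`).
#' @return One-row tibble (`kind`, `n_annotated`, `n_covered`,
#'   `max_shared`, `feature`, `prevalence`, `mean_features`) or `NULL`.
#' @export
interpro_similarity <- function(annotated, background, interpro, kind,
                                min_coverage = 0.5) {
  ip <- interpro[interpro$kind == kind, , drop = FALSE]
  feats <- split(ip$accession, ip$protein)
  ann_feats <- feats[intersect(annotated, names(feats))]
  ann_feats <- lapply(ann_feats, unique)
  n_cov <- length(ann_feats)
  if (length(annotated) == 0L || n_cov / length(annotated) < min_coverage) {
    return(NULL)
  }
  counts <- table(unlist(ann_feats, use.names = FALSE))
  shared <- as.numeric(counts) / n_cov
  best <- which.max(shared)
  best_feat <- names(counts)[best]
  bg_feats <- feats[intersect(background, names(feats))]
  n_bg <- length(bg_feats)
  prevalence <- if (n_bg > 0L) {
    mean(vapply(bg_feats, function(f) best_feat %in% f, logical(1L)))
  } else {
    NA_real_
  }
  tibble::tibble(
    kind = kind, n_annotated = length(annotated), n_covered = n_cov,
    max_shared = shared[best], feature = best_feat,
    prevalence = prevalence,
    mean_features = mean(lengths(ann_feats))
  )
}

#' InterPro similarity statistics for every term
#'
#' @param truth Propagated [annotation_set()] of the test proteins.
#' @param test_proteins All test protein IDs.
#' @param interpro Tibble from [read_interpro()].
#' @param kinds Feature kinds to evaluate.
#' @param min_coverage See [interpro_similarity()].
#' @return Tibble with one row per (term, kind) passing the coverage
#'   filter, columns as in [interpro_similarity()] plus `term`.
#' @export
interpro_similarity_table <- function(truth, test_proteins, interpro,
                                      kinds = c("domain", "family", "superfamily"),
                                      min_coverage = 0.5) {
  truth <- tibble::as_tibble(truth)
  truth <- truth[truth$protein %in% test_proteins, ]
  by_term <- split(truth$protein, truth$term)
  rows <- list()
  for (t in names(by_term)) {
    annotated <- unique(by_term[[t]])
    background <- setdiff(test_proteins, annotated)
    for (k in kinds) {
      r <- interpro_similarity(annotated, background, interpro, k,
        min_coverage = min_coverage
      )
      if (!is.null(r)) rows[[length(rows) + 1L]] <- dplyr::mutate(r, term = t)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(out)
  dplyr::relocate(out, "term")
}

#' Median term-centric performance per GO category
#'
#' @param term_metrics Tibble with columns `term`, `auc` and optionally
#'   `species`.
#' @param categories Tibble from [go_categories()] (`category`, `member`).
#' @return Tibble `category`, (`species`,) `median_auc`, `n_terms`. When a
#'   `species` column is present, one row per category x species with
#'   metrics; category/species combinations without scored member terms
#'   are absent.
#' @export
category_summary <- function(term_metrics, categories) {
  m <- dplyr::inner_join(
    tibble::as_tibble(term_metrics),
    tibble::as_tibble(categories),
    by = c(term = "member")
  )
  m <- m[!is.na(m$auc), , drop = FALSE]
  grp <- if ("species" %in% names(m)) c("category", "species") else "category"
  m |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      median_auc = stats::median(.data$auc),
      n_terms = dplyr::n(), .groups = "drop"
    )
}

#' Fraction of real annotations predicted
#'
#' Cross-species evaluation is restricted to terms shared with the
#' training species; this statistic asks how much of a protein's *full*
#' annotation (including non-evaluated, species-specific terms) is still
#' recovered. Per protein: the number of true terms among the predictions
#' at threshold `tau` (predictions can only contain `eval_terms`), divided
#' by the number of all true terms. Proteins with empty truth are skipped.
#'
#' @param P Score matrix over `eval_terms` (hierarchy-corrected).
#' @param full_truth Propagated [annotation_set()] including non-evaluated
#'   terms.
#' @param tau Decision threshold.
#' @param eval_terms Terms that were predictable (default: columns of
#'   `P`).
#' @return A list: `per_protein` tibble (`protein`, `n_true`,
#'   `n_predicted_true`, `fraction`), `mean`, `median`.
#' @export
fraction_real_annotations_predicted <- function(P, full_truth, tau,
                                                eval_terms = colnames(P)) {
  full_truth <- tibble::as_tibble(full_truth)
  eval_terms <- intersect(eval_terms, colnames(P))
  truth_sets <- split(full_truth$term, full_truth$protein)
  proteins <- intersect(rownames(P), names(truth_sets))
  rows <- purrr::map_dfr(proteins, function(pr) {
    true_terms <- unique(truth_sets[[pr]])
    if (length(true_terms) == 0L) return(NULL)
    predicted <- eval_terms[P[pr, eval_terms] >= tau]
    tibble::tibble(
      protein = pr, n_true = length(true_terms),
      n_predicted_true = length(intersect(predicted, true_terms)),
      fraction = length(intersect(predicted, true_terms)) / length(true_terms)
    )
  })
  list(
    per_protein = rows,
    mean = mean(rows$fraction), median = stats::median(rows$fraction)
  )
}

#' Compare term-depth distributions across species
#'
#' Chi-square test of homogeneity on the species x depth contingency table
#' of the terms selected per species. Depth bins with expected counts
#' below 5 are merged upward (into the next shallower bin) until all
#' expected counts reach 5 or only two bins remain.
#'
#' @param term_sets Named list: species -> character vector of term IDs.
#' @param dag An [ontology_dag()].
#' @return A list: `statistic`, `p_value`, `df`, `table` (the merged
#'   contingency matrix).
#' @export
compare_depth_distributions <- function(term_sets, dag) {
  if (length(term_sets) < 2L) {
    stop("depth-distribution comparison needs at least 2 species")
  }
  depths <- lapply(term_sets, function(ts) unname(term_depth(dag, ts)))
  all_d <- sort(unique(unlist(depths)))
  tab <- t(vapply(depths, function(dd) {
    as.integer(table(factor(dd, levels = all_d)))
  }, integer(length(all_d))))
  colnames(tab) <- as.character(all_d)

  expected <- function(m) outer(rowSums(m), colSums(m)) / sum(m)
  while (ncol(tab) > 2L && min(expected(tab)) < 5) {
    jmin <- which.min(apply(expected(tab), 2L, min))
    jto <- if (jmin == 1L) 2L else jmin - 1L # merge upward (shallower)
    tab[, jto] <- tab[, jto] + tab[, jmin]
    colnames(tab)[jto] <- paste0(colnames(tab)[jto], "+", colnames(tab)[jmin])
    tab <- tab[, -jmin, drop = FALSE]
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(
    statistic = unname(ct$statistic), p_value = ct$p.value,
    df = unname(ct$parameter), table = tab
  )
}
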