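#' Term-centric ROCAUC (rank-based)
#'
#' Area under the ROC curve for one term, computed from the Mann-Whitney
#' statistic with midranks, so ties contribute half a concordant pair.
#'
#' @param scores Numeric vector of predicted probabilities/scores.
#' @param labels Binary vector (0/1 or logical) of the same length.
#' @return ROCAUC in [0, 1].
#' @export
term_rocauc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("ROCAUC needs both positive and negative examples")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-term ROCAUC over a prediction matrix
#'
#' @param P Proteins x terms numeric matrix of scores with dimnames.
#' @param truth A propagated [annotation_set()] giving true terms.
#' @param terms Terms to evaluate (default: all columns). Terms lacking
#'   either class among the scored proteins are returned with `auc = NA`.
#' @return A tibble with columns `term`, `auc`, `n_pos`.
#' @export
term_rocauc_table <- function(P, truth, terms = colnames(P)) {
  truth_m <- truth_matrix(rownames(P), terms, truth)
  auc <- vapply(terms, function(t) {
    y <- truth_m[, t]
    if (all(y == 1L) || all(y == 0L)) return(NA_real_)
    term_rocauc(P[, t], y)
  }, numeric(1L))
  tibble::tibble(term = terms, auc = auc, n_pos = colSums(truth_m)[terms])
}

#' Binary protein x term label matrix from an annotation set
#'
#' @param proteins Row protein IDs.
#' @param terms Column term IDs.
#' @param truth An [annotation_set()].
#' @return Integer 0/1 matrix with the given dimnames.
#' @export
truth_labels <- function(proteins, terms, truth) {
  truth_matrix(proteins, terms, truth)
}

# proteins x terms 0/1 matrix from an annotation set
truth_matrix <- function(proteins, terms, truth) {
  truth <- tibble::as_tibble(truth)
  m <- matrix(0L, nrow = length(proteins), ncol = length(terms),
    dimnames = list(proteins, terms)
  )
  rec <- truth[truth$protein %in% proteins & truth$term %in% terms, ]
  if (nrow(rec) > 0L) m[cbind(rec$protein, rec$term)] <- 1L
  m
}

#' Protein-centric precision, recall and F1 at a threshold
#'
#' For each protein i with predicted set `P_i = {t : p_it >= tau}` and true
#' set `T_i` (both restricted to `eval_terms`): `precision_i = |P_i n T_i| /
#' |P_i|` (defined only for covered proteins, i.e. `P_i` non-empty) and
#' `recall_i = |P_i n T_i| / |T_i|`. The aggregate F1 is the harmonic mean
#' of precision averaged over covered proteins and recall averaged over all
#' evaluated proteins. Proteins with empty truth over `eval_terms` are
#' excluded from the aggregation (their recall is undefined). Coverage is
#' the fraction of evaluated proteins with at least one prediction.
#'
#' @param P Proteins x terms score matrix with dimnames.
#' @param truth A propagated [annotation_set()].
#' @param tau Decision threshold in [0, 1].
#' @param eval_terms Terms over which prediction and truth are compared
#'   (default: the columns of `P`).
#' @return A list of class `protein_metrics`: `precision`, `recall`, `f1`,
#'   `coverage`, `n_proteins`, `per_protein` (tibble).
#' @export
protein_prf <- function(P, truth, tau, eval_terms = colnames(P)) {
  if (tau < 0 || tau > 1) stop("threshold tau must lie in [0, 1]")
  eval_terms <- intersect(eval_terms, colnames(P))
  Pm <- P[, eval_terms, drop = FALSE]
  Tm <- truth_matrix(rownames(P), eval_terms, truth)
  n_true <- rowSums(Tm)
  keep <- n_true > 0L
  if (!any(keep)) {
    stop("no protein has true annotations among eval_terms")
  }
  Pm <- Pm[keep, , drop = FALSE]
  Tm <- Tm[keep, , drop = FALSE]
  pred <- Pm >= tau
  n_pred <- rowSums(pred)
  tp <- rowSums(pred & (Tm == 1L))
  covered <- n_pred > 0L
  prec_i <- ifelse(covered, tp / n_pred, NA_real_)
  rec_i <- tp / rowSums(Tm)
  pr <- if (any(covered)) mean(prec_i[covered]) else 0
  rc <- mean(rec_i)
  f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  per_protein <- tibble::tibble(
    protein = rownames(Pm),
    n_pred = as.integer(n_pred), n_true = as.integer(rowSums(Tm)),
    tp = as.integer(tp), precision = prec_i, recall = rec_i,
    f1 = ifelse(!is.na(prec_i) & (prec_i + rec_i) > 0,
      2 * prec_i * rec_i / (prec_i + rec_i), 0
    )
  )
  structure(
    list(
      precision = pr, recall = rc, f1 = f1,
      coverage = mean(covered), n_proteins = sum(keep),
      tau = tau, per_protein = per_protein
    ),
    class = "protein_metrics"
  )
}

#' @export
print.protein_metrics <- function(x, ...) {
  cat(sprintf(
    "<protein_metrics> n = %d  tau = %.2f  precision = %.3f  recall = %.3f  F1 = %.3f  coverage = %.3f\n",
    x$n_proteins, x$tau, x$precision, x$recall, x$f1, x$coverage
  ))
  invisible(x)
}

#' Semantic distance between predicted and true annotation sets
#'
#' Information-content-weighted counterpart of precision/recall: at each
#' threshold tau, remaining uncertainty `ru(tau)` is the mean over proteins
#' of the summed IC of missed true terms (false negatives), and
#' misinformation `mi(tau)` is the mean summed IC of wrongly predicted
#' terms (false positives). The semantic distance is
#' `S = min_tau sqrt(ru^2 + mi^2)` over the threshold grid.
#'
#' @param P Proteins x terms score matrix with dimnames.
#' @param truth A propagated [annotation_set()].
#' @param ic Tibble with columns `term`, `ic` as from [resnik_ic()]; must
#'   cover all evaluated terms.
#' @param tau_grid Threshold grid (default 0 to 1 in steps of 0.01).
#' @param eval_terms Terms to evaluate over.
#' @return A list of class `semantic_distance`: `s`, `ru`, `mi`, `tau`, and
#'   the full `curve` tibble.
#' @export
semantic_distance <- function(P, truth, ic, tau_grid = seq(0, 1, by = 0.01),
                              eval_terms = colnames(P)) {
  ic <- tibble::as_tibble(ic)
  if (nrow(ic) == 0L) stop("empty IC table")
  eval_terms <- intersect(eval_terms, colnames(P))
  missing_ic <- setdiff(eval_terms, ic$term)
  if (length(missing_ic) > 0L) {
    stop(
      "IC unavailable for evaluated term(s): ",
      paste(utils::head(missing_ic, 5L), collapse = ", ")
    )
  }
  Pm <- P[, eval_terms, drop = FALSE]
  Tm <- truth_matrix(rownames(P), eval_terms, truth)
  keep <- rowSums(Tm) > 0L
  Pm <- Pm[keep, , drop = FALSE]
  Tm <- Tm[keep, , drop = FALSE]
  icv <- stats::setNames(ic$ic, ic$term)[eval_terms]
  curve <- purrr::map_dfr(tau_grid, function(tau) {
    pred <- Pm >= tau
    fn <- (Tm == 1L) & !pred
    fp <- (Tm == 0L) & pred
    tibble::tibble(
      tau = tau,
      ru = mean(fn %*% icv),
      mi = mean(fp %*% icv)
    )
  })
  curve$s <- sqrt(curve$ru^2 + curve$mi^2)
  i <- which.min(curve$s)
  structure(
    list(
      s = curve$s[i], ru = curve$ru[i], mi = curve$mi[i],
      tau = curve$tau[i], curve = curve
    ),
    class = "semantic_distance"
  )
}

#' @export
print.semantic_distance <- function(x, ...) {
  cat(sprintf(
    "<semantic_distance> S = %.4f (ru = %.4f, mi = %.4f) at tau = %.2f\n",
    x$s, x$ru, x$mi, x$tau
  ))
  invisible(x)
}

#' Bootstrap percentile confidence interval
#'
#' Resamples item indices with replacement (size equal to the original set),
#' recomputes the statistic on each replicate and reports the percentile
#' 95% interval. Each replicate uses its own seed; reusing the same seed
#' vector across methods yields paired resamples for fair comparison.
#' Optional stratified resampling draws within strata, keeping stratum
#' sizes fixed.
#'
#' @param stat A function taking an integer vector of item indices and
#'   returning one number.
#' @param n Number of items in the original set.
#' @param B Number of replicates (>= 2; default 100).
#' @param seeds Integer vector of length `B` (default `seed + 0:(B-1)`).
#' @param seed Base seed used when `seeds` is not given.
#' @param strata Optional vector of length `n`; resampling is done within
#'   each stratum.
#' @param conf Confidence level (default 0.95).
#' @return A tibble with columns `point` (statistic on the full set),
#'   `lower`, `upper`, `B`.
#' @export
bootstrap_ci <- function(stat, n, B = 100L, seeds = NULL, seed = 1L,
                         strata = NULL, conf = 0.95) {
  if (B < 2L) stop("bootstrap needs at least 2 replicates")
  if (is.null(seeds)) seeds <- seed + seq_len(B) - 1L
  stopifnot(length(seeds) == B)
  idx_all <- seq_len(n)
  reps <- vapply(seeds, function(s) {
    set.seed(s)
    idx <- if (is.null(strata)) {
      sample(idx_all, n, replace = TRUE)
    } else {
      unlist(lapply(split(idx_all, strata), function(g) {
        sample(g, length(g), replace = TRUE)
      }), use.names = FALSE)
    }
    stat(idx)
  }, numeric(1L))
  alpha <- (1 - conf) / 2
  q <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble::tibble(
    point = stat(idx_all), lower = q[1L], upper = q[2L], B = as.integer(B)
  )
}

#' Select evaluable terms for cross-species evaluation
#'
#' Protein-centric mode keeps the terms shared between the training-species
#' training set and the test-species set (a term absent from training can
#' never be predicted). Term-centric mode additionally requires enough
#' positives for a stable ROCAUC: at least `min_train` annotated proteins
#' in the training set and at least `min_other` in each of the
#' training-species validation and test sets and the test-species set.
#'
#' @param train_ann Propagated [annotation_set()] of the training split.
#' @param species_ann Propagated [annotation_set()] of the test-species
#'   evaluation set.
#' @param mode `"protein"` or `"term"`.
#' @param val_ann,test_ann Propagated annotation sets of the
#'   training-species validation and test splits (required in term mode).
#' @param min_train,min_other Support thresholds (defaults 5 and 3).
#' @param exclude Terms dropped regardless (default: none; pass the root).
#' @return Character vector of term IDs.
#' @export
select_eval_terms <- function(train_ann, species_ann,
                              mode = c("protein", "term"),
                              val_ann = NULL, test_ann = NULL,
                              min_train = 5L, min_other = 3L,
                              exclude = character(0)) {
  mode <- match.arg(mode)
  count_terms <- function(ann) {
    ann <- tibble::as_tibble(ann)
    tab <- dplyr::count(dplyr::distinct(ann, .data$protein, .data$term), .data$term)
    stats::setNames(tab$n, tab$term)
  }
  n_train <- count_terms(train_ann)
  n_species <- count_terms(species_ann)
  shared <- intersect(names(n_train), names(n_species))
  if (mode == "protein") return(setdiff(sort(shared), exclude))
  if (is.null(val_ann) || is.null(test_ann)) {
    stop("term-centric selection needs val_ann and test_ann")
  }
  n_val <- count_terms(val_ann)
  n_test <- count_terms(test_ann)
  get0n <- function(v, t) ifelse(t %in% names(v), v[t], 0L)
  keep <- shared[
    get0n(n_train, shared) >= min_train &
      get0n(n_val, shared) >= min_other &
      get0n(n_test, shared) >= min_other &
      get0n(n_species, shared) >= min_other
  ]
  setdiff(sort(keep), exclude)
}
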