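#' Run the full cross-species experiment on a synthetic world
#'
#' Orchestrates the pipeline the package implements: standardize the
#' training-species embeddings, train the multi-label MLP on the training
#' split, hierarchy-correct the posteriors, pick the decision threshold on
#' the training-species validation set, then evaluate term-centric
#' (ROCAUC), protein-centric (F1, coverage) and optionally
#' semantic-distance performance on every species, alongside the
#' homology-hit frequency baseline. Deterministic given the world and
#' `mlp$seed`.
#'
#' @param world A `synthetic_world` from [generate_world()].
#' @param mlp An [mlp_config()]; set `hidden`/`epochs` to scale compute.
#' @param methods Methods to run: subset of `c("mlp", "baseline")`.
#' @param hierarchy_correction Apply [hierarchy_correct()] to MLP scores
#'   (default `TRUE`, matching the cross-species protocol).
#' @param min_train,min_other Support thresholds for term-centric term
#'   selection (defaults 5 and 3).
#' @param semantic Also compute the semantic distance per species.
#' @param bootstrap_B Bootstrap replicates for per-species CIs on the
#'   protein-centric F1 (0 disables).
#' @param seed Seed for the bootstrap resamples.
#' @return An object of class `cross_species_run`: `metrics` (tibble with
#'   one row per species x method), `term_metrics`, `categories`
#'   (per-category median ROCAUC per species), `tau` (MLP threshold),
#'   `tau_baseline`, `identity` (mean top-hit identity per species),
#'   `depth_test` (chi-square comparison of selected term depths),
#'   `fraction_real` (per species), `mlp_fit`, `history`.
#' @export
run_cross_species <- function(world,
                              mlp = mlp_config(),
                              methods = c("mlp", "baseline"),
                              hierarchy_correction = TRUE,
                              min_train = 5L, min_other = 3L,
                              semantic = TRUE,
                              bootstrap_B = 0L, seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"))
  methods <- match.arg(methods, several.ok = TRUE)
  cfg <- world$cfg
  ts <- cfg$train_species
  dag <- world$dag

  split_tbl <- world$split
  ids <- function(s) split_tbl$protein[split_tbl$split == s]
  store <- world$embeddings[[ts]]
  std <- fit_standardizer(unclass(store)[ids("train"), , drop = FALSE])
  Xof <- function(st, rows) {
    apply_standardizer(std, unclass(st)[rows, , drop = FALSE])
  }

  truth_ts <- tibble::as_tibble(world$truth[[ts]])
  truth_of <- function(rows) {
    annotation_set(truth_ts[truth_ts$protein %in% rows, ], propagated = TRUE)
  }
  train_truth <- truth_of(ids("train"))
  val_truth <- truth_of(ids("val"))
  test_truth <- truth_of(ids("test"))

  train_terms <- sort(unique(tibble::as_tibble(train_truth)$term))
  Yof <- function(rows, truth) truth_matrix(rows, train_terms, truth)

  X_train <- Xof(store, ids("train"))
  X_val <- Xof(store, ids("val"))
  Y_train <- Yof(ids("train"), train_truth)
  Y_val <- Yof(ids("val"), val_truth)

  ic <- resnik_ic(train_truth, dag)

  fit <- NULL
  tau <- NULL
  if ("mlp" %in% methods) {
    fit <- fit_mlp(X_train, Y_train, X_val, Y_val, cfg = mlp)
    P_val <- predict_proba(fit, X_val, checkpoint = "protein")
    if (hierarchy_correction) P_val <- hierarchy_correct(P_val, dag)
    tau <- select_threshold(P_val, val_truth,
      eval_terms = setdiff(train_terms, dag$root)
    )
  }
  tau_b <- NULL
  if ("baseline" %in% methods) {
    hits_val <- world$hits[[ts]]
    P_val_b <- frequency_predict(hits_val, train_truth, ids("val"))
    tau_b <- select_threshold(P_val_b, val_truth,
      eval_terms = setdiff(colnames(P_val_b), dag$root)
    )
  }

  species_rows <- list()
  term_rows <- list()
  identity_rows <- list()
  frac_rows <- list()
  term_sets <- list()

  for (i in seq_len(nrow(cfg$species))) {
    sp <- cfg$species$name[i]
    delta <- cfg$species$delta[i]
    sp_proteins <- if (sp == ts) {
      ids("test")
    } else {
      world$proteins$protein[world$proteins$species == sp]
    }
    sp_store <- world$embeddings[[sp]]
    truth_sp_tbl <- tibble::as_tibble(world$truth[[sp]])
    truth_sp <- annotation_set(
      truth_sp_tbl[truth_sp_tbl$protein %in% sp_proteins, ],
      propagated = TRUE
    )

    terms_protein <- select_eval_terms(train_truth, truth_sp,
      mode = "protein", exclude = dag$root
    )
    terms_term <- select_eval_terms(train_truth, truth_sp,
      mode = "term", val_ann = val_truth, test_ann = test_truth,
      min_train = min_train, min_other = min_other, exclude = dag$root
    )
    term_sets[[sp]] <- terms_term

    eval_methods <- list()
    if ("mlp" %in% methods) {
      Xs <- Xof(sp_store, sp_proteins)
      P_term <- predict_proba(fit, Xs, checkpoint = "term")
      P_prot <- predict_proba(fit, Xs, checkpoint = "protein")
      if (hierarchy_correction) {
        P_term <- hierarchy_correct(P_term, dag)
        P_prot <- hierarchy_correct(P_prot, dag)
      }
      eval_methods$mlp <- list(
        P_term = P_term, P_prot = P_prot, tau = tau$tau
      )
    }
    if ("baseline" %in% methods) {
      P_b <- frequency_predict(world$hits[[sp]], train_truth, sp_proteins)
      eval_methods$baseline <- list(P_term = P_b, P_prot = P_b, tau = tau_b$tau)
    }

    for (m in names(eval_methods)) {
      em <- eval_methods[[m]]
      tt <- term_rocauc_table(
        em$P_term[, intersect(terms_term, colnames(em$P_term)), drop = FALSE],
        truth_sp
      )
      prf <- protein_prf(em$P_prot, truth_sp, em$tau,
        eval_terms = terms_protein
      )
      sd_val <- if (semantic) {
        semantic_distance(em$P_prot, truth_sp, ic,
          eval_terms = intersect(terms_protein, ic$term)
        )$s
      } else {
        NA_real_
      }
      ci <- if (bootstrap_B > 0L) {
        Pm <- em$P_prot[
          , intersect(terms_protein, colnames(em$P_prot)),
          drop = FALSE
        ]
        Tm <- truth_matrix(rownames(Pm), colnames(Pm), truth_sp)
        keep <- rowSums(Tm) > 0L
        Pm <- Pm[keep, , drop = FALSE]
        Tm <- Tm[keep, , drop = FALSE]
        tau_m <- em$tau
        bootstrap_ci(function(idx) {
          pred <- Pm[idx, , drop = FALSE] >= tau_m
          tr <- Tm[idx, , drop = FALSE]
          n_pred <- rowSums(pred)
          tp <- rowSums(pred & (tr == 1L))
          covered <- n_pred > 0L
          if (!any(covered)) return(0)
          pr <- mean((tp / n_pred)[covered])
          rc <- mean(tp / rowSums(tr))
          if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
        }, n = nrow(Pm), B = bootstrap_B, seed = seed)
      } else {
        NULL
      }
      species_rows[[length(species_rows) + 1L]] <- tibble::tibble(
        species = sp, delta = delta, method = m,
        n_proteins = length(sp_proteins),
        n_terms_term = length(terms_term),
        n_terms_protein = length(terms_protein),
        mean_rocauc = mean(tt$auc, na.rm = TRUE),
        f1 = prf$f1, precision = prf$precision, recall = prf$recall,
        coverage = prf$coverage,
        semantic_distance = sd_val,
        f1_lower = if (is.null(ci)) NA_real_ else ci$lower,
        f1_upper = if (is.null(ci)) NA_real_ else ci$upper
      )
      term_rows[[length(term_rows) + 1L]] <- dplyr::mutate(tt,
        species = sp, method = m
      )
      if (m == "mlp") {
        fr <- fraction_real_annotations_predicted(
          em$P_prot, truth_sp, em$tau,
          eval_terms = intersect(terms_protein, colnames(em$P_prot))
        )
        frac_rows[[length(frac_rows) + 1L]] <- tibble::tibble(
          species = sp, mean_fraction = fr$mean, median_fraction = fr$median
        )
      }
    }

    th <- top_hit_identity(world$hits[[sp]], queries = sp_proteins)
    identity_rows[[length(identity_rows) + 1L]] <- tibble::tibble(
      species = sp, delta = delta,
      mean_identity = if (nrow(th) > 0L) mean(th$pident) else NA_real_,
      n_with_hits = nrow(th)
    )
  }

  metrics <- dplyr::bind_rows(species_rows)
  term_metrics <- dplyr::bind_rows(term_rows)

  cats <- go_categories(dag, setdiff(train_terms, dag$root))
  cat_summary <- if (nrow(cats) > 0L) {
    category_summary(
      term_metrics[term_metrics$method == "mlp", c("term", "auc", "species")],
      cats
    )
  } else {
    tibble::tibble()
  }

  depth_test <- if (length(term_sets) >= 2L &&
    all(lengths(term_sets) > 0L)) {
    compare_depth_distributions(term_sets, dag)
  } else {
    NULL
  }

  structure(
    list(
      metrics = metrics, term_metrics = term_metrics,
      categories = cat_summary,
      tau = if (is.null(tau)) NA_real_ else tau$tau,
      tau_baseline = if (is.null(tau_b)) NA_real_ else tau_b$tau,
      identity = dplyr::bind_rows(identity_rows),
      depth_test = depth_test,
      fraction_real = dplyr::bind_rows(frac_rows),
      mlp_fit = fit,
      eval_term_sets = term_sets
    ),
    class = "cross_species_run"
  )
}

#' @export
print.cross_species_run <- function(x, ...) {
  cat("<cross_species_run>\n")
  print(x$metrics[, c(
    "species", "delta", "method", "mean_rocauc", "f1", "coverage"
  )])
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy cross_species_run
#' @export
tidy.cross_species_run <- function(x, ...) x$metrics

#' @method glance cross_species_run
#' @export
glance.cross_species_run <- function(x, ...) {
  tibble::tibble(
    n_species = length(unique(x$metrics$species)),
    tau = x$tau, tau_baseline = x$tau_baseline,
    mean_rocauc_mlp = mean(
      x$metrics$mean_rocauc[x$metrics$method == "mlp"]
    ),
    mean_f1_mlp = mean(x$metrics$f1[x$metrics$method == "mlp"])
  )
}

#' @method tidy mlp_model
#' @export
tidy.mlp_model <- function(x, ...) x$history

#' @method glance mlp_model
#' @export
glance.mlp_model <- function(x, ...) {
  tibble::tibble(
    n_terms = length(x$terms), d = x$d, hidden = x$cfg$hidden,
    epochs = x$cfg$epochs,
    best_val_term_auc = x$best_term$value,
    best_term_epoch = x$best_term$epoch,
    best_val_fmax = x$best_protein$value,
    best_protein_epoch = x$best_protein$epoch
  )
}

#' @method tidy lr_model
#' @export
tidy.lr_model <- function(x, ...) {
  purrr::map_dfr(x$terms, function(t) {
    cf <- as.numeric(stats::coef(x$models[[t]]$fit, s = x$lambda))
    tibble::tibble(
      term = t,
      intercept = cf[1L],
      coef_norm = sqrt(sum(cf[-1L]^2))
    )
  })
}

#' @method glance lr_model
#' @export
glance.lr_model <- function(x, ...) {
  tibble::tibble(
    n_terms = length(x$terms), n_skipped = length(x$skipped),
    lambda = x$lambda, d = x$d
  )
}

#' @method tidy lambda_tuning
#' @export
tidy.lambda_tuning <- function(x, ...) x$curve

#' @method tidy length_probe
#' @export
tidy.length_probe <- function(x, ...) x$per_bin

#' @method glance length_probe
#' @export
glance.length_probe <- function(x, ...) {
  tibble::tibble(
    mean_auc = x$mean_auc, lambda = x$lambda, n_bins = nrow(x$per_bin)
  )
}

#' Plot per-species performance against divergence
#'
#' @param run A `cross_species_run`.
#' @param metric Column of `run$metrics` to plot (default `"f1"`).
#' @return A ggplot object: metric versus divergence, one line per method.
#' @export
plot_species_performance <- function(run, metric = "f1") {
  stopifnot(inherits(run, "cross_species_run"))
  ggplot2::ggplot(
    run$metrics,
    ggplot2::aes(
      x = .data$delta, y = .data[[metric]],
      colour = .data$method, group = .data$method
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "divergence from training species",
      y = metric, colour = "method"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot cross_species_run
#' @export
autoplot.cross_species_run <- function(object, metric = "f1", ...) {
  plot_species_performance(object, metric = metric)
}

#' Plot MLP training history
#'
#' @param model An `mlp_model`.
#' @return A ggplot of train/validation loss per epoch.
#' @export
plot_training_history <- function(model) {
  h <- tidyr::pivot_longer(
    model$history[, c("epoch", "train_loss", "val_loss")],
    -"epoch",
    names_to = "series", values_to = "loss"
  )
  ggplot2::ggplot(
    h, ggplot2::aes(x = .data$epoch, y = .data$loss, colour = .data$series)
  ) +
    ggplot2::geom_line() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
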