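#' Per-term L2-regularized logistic regression
#'
#' Fits an independent binary logistic regression with ridge (L2) penalty
#' for a single ontology term on standardized protein-level embeddings.
#' The objective is convex, so the fit is deterministic.
#'
#' @param X Numeric matrix (proteins x features), standardized with the
#'   training standardizer.
#' @param y Binary labels (0/1 or logical); both classes must be present.
#' @param lambda L2 penalty coefficient.
#' @return An object of class `term_lr`.
#' @export
fit_term_lr <- function(X, y, lambda = 1) {
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2L) {
    stop("single-class labels: cannot fit a per-term logistic regression")
  }
  # fit along a short decreasing path ending at the target penalty:
  # ridge solutions along a path converge far more reliably than a
  # cold-started single-lambda fit
  fit <- glmnet::glmnet(
    x = X, y = y, family = "binomial", alpha = 0,
    lambda = lambda * c(100, 10, 1),
    standardize = FALSE, thresh = 1e-10, maxit = 1e6
  )
  structure(list(fit = fit, lambda = lambda, d = ncol(X)),
    class = "term_lr"
  )
}

#' @export
predict.term_lr <- function(object, newdata, ...) {
  if (ncol(newdata) != object$d) {
    stop("feature width mismatch: ", ncol(newdata), " vs ", object$d)
  }
  as.numeric(stats::predict(object$fit,
    newx = as.matrix(unclass(newdata)),
    type = "response", s = object$lambda
  ))
}

#' Multi-term logistic regression model
#'
#' Fits one [fit_term_lr()] per term of a protein x term binary label
#' matrix. Terms with a single class in the training labels are skipped
#' (they cannot be fitted and are excluded from term-centric evaluation).
#'
#' @param X Standardized feature matrix (proteins x features).
#' @param Y Binary label matrix (proteins x terms) with term column names.
#' @param lambda L2 penalty coefficient shared by all terms.
#' @return An object of class `lr_model` with elements `models` (named
#'   list), `terms` (fitted terms), `skipped`, `lambda`.
#' @export
fit_lr_model <- function(X, Y, lambda = 1) {
  stopifnot(!is.null(colnames(Y)), nrow(X) == nrow(Y))
  fitted <- list()
  skipped <- character(0)
  for (t in colnames(Y)) {
    y <- Y[, t]
    if (length(unique(y)) < 2L) {
      skipped <- c(skipped, t)
      next
    }
    fitted[[t]] <- fit_term_lr(X, y, lambda = lambda)
  }
  if (length(fitted) == 0L) stop("no term has both classes in the labels")
  structure(
    list(
      models = fitted, terms = names(fitted), skipped = skipped,
      lambda = lambda, d = ncol(X)
    ),
    class = "lr_model"
  )
}

#' Tune the L2 penalty jointly over all terms
#'
#' Fits the per-term logistic regressions at every grid value and selects
#' the penalty maximizing the mean validation ROCAUC over terms (terms
#' lacking both classes in train or validation labels are excluded). Ties
#' are broken toward the smaller penalty.
#'
#' @param X_train,Y_train Standardized training features and binary labels.
#' @param X_val,Y_val Validation features and labels.
#' @param grid Candidate penalties (default `10^(2:-3)`).
#' @return A list of class `lambda_tuning`: `lambda` (selected), `curve`
#'   (tibble with `lambda`, `mean_auc`, `n_terms`).
#' @export
tune_lambda <- function(X_train, Y_train, X_val, Y_val,
                        grid = 10^seq(2, -3)) {
  if (length(grid) == 0L) stop("empty penalty grid")
  eligible <- colnames(Y_train)[
    colSums(Y_train) > 0L & colSums(Y_train) < nrow(Y_train) &
      colSums(Y_val) > 0L & colSums(Y_val) < nrow(Y_val)
  ]
  if (length(eligible) == 0L) stop("no term usable for penalty tuning")
  grid_sorted <- sort(unique(grid))
  curve <- purrr::map_dfr(grid_sorted, function(lam) {
    aucs <- vapply(eligible, function(t) {
      m <- fit_term_lr(X_train, Y_train[, t], lambda = lam)
      term_rocauc(predict(m, X_val), Y_val[, t])
    }, numeric(1L))
    tibble::tibble(lambda = lam, mean_auc = mean(aucs), n_terms = length(aucs))
  })
  best <- min(curve$lambda[curve$mean_auc == max(curve$mean_auc)])
  structure(list(lambda = best, curve = curve), class = "lambda_tuning")
}

#' MLP configuration
#'
#' Hyperparameters of the multi-label multilayer perceptron: one hidden
#' layer with ReLU activation and dropout, a sigmoid output node per term,
#' mean binary cross-entropy loss over terms, Adam optimization in
#' mini-batches, and a plateau schedule dividing the learning rate by 10
#' after `patience` consecutive epochs without validation-loss improvement.
#'
#' @param hidden Hidden layer width (default 512).
#' @param dropout Hidden-layer dropout rate in [0, 1) (default 0.30).
#' @param batch_size Mini-batch size (default 64).
#' @param epochs Training epochs (default 100).
#' @param learning_rate Initial Adam learning rate (default 5e-4).
#' @param patience Epochs without validation-loss improvement before the
#'   learning rate is reduced by a factor of 10 (default 5).
#' @param seed Integer seed; training is deterministic given the seed.
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(hidden = 512L, dropout = 0.3, batch_size = 64L,
                       epochs = 100L, learning_rate = 5e-4, patience = 5L,
                       seed = 1L) {
  stopifnot(
    hidden >= 1L, dropout >= 0, dropout < 1, batch_size >= 1L,
    epochs >= 1L, learning_rate > 0, patience >= 1L
  )
  structure(
    list(
      hidden = as.integer(hidden), dropout = dropout,
      batch_size = as.integer(batch_size), epochs = as.integer(epochs),
      learning_rate = learning_rate, patience = as.integer(patience),
      seed = as.integer(seed)
    ),
    class = "mlp_config"
  )
}

sigmoid <- function(z) 1 / (1 + exp(-z))

bce_loss <- function(P, Y) {
  eps <- 1e-12
  P <- pmin(pmax(P, eps), 1 - eps)
  -mean(Y * log(P) + (1 - Y) * log(1 - P))
}

mlp_forward <- function(w, X) {
  H <- pmax(sweep(X %*% w$W1, 2L, w$b1, "+"), 0)
  sigmoid(sweep(H %*% w$W2, 2L, w$b2, "+"))
}

# protein-centric Fmax from score/label matrices over a coarse grid;
# used only for checkpoint selection during training.
fmax_matrices <- function(P, Y, grid = seq(0.05, 0.95, by = 0.05)) {
  keep <- rowSums(Y) > 0L
  if (!any(keep)) return(0)
  P <- P[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  best <- 0
  for (tau in grid) {
    pred <- P >= tau
    n_pred <- rowSums(pred)
    tp <- rowSums(pred & (Y == 1L))
    covered <- n_pred > 0L
    if (!any(covered)) next
    pr <- mean((tp / n_pred)[covered])
    rc <- mean(tp / rowSums(Y))
    if (pr + rc > 0) best <- max(best, 2 * pr * rc / (pr + rc))
  }
  best
}

#' Fit the multi-label MLP
#'
#' Trains the network on training features/labels with per-epoch
#' checkpointing on the validation set, and returns two model states: the
#' checkpoint with the best validation term-centric metric (mean ROCAUC
#' over terms) and the one with the best validation protein-centric metric
#' (Fmax). Training is deterministic given `cfg$seed`.
#'
#' @param X_train Standardized training features (proteins x d).
#' @param Y_train Binary label matrix (proteins x terms) with column names.
#' @param X_val,Y_val Validation features and labels (non-empty).
#' @param cfg An [mlp_config()].
#' @return An object of class `mlp_model`: `terms`, `cfg`, checkpoints
#'   `best_term` / `best_protein` / `final` (each with `weights`, `epoch`,
#'   `value`), and `history` (one row per epoch: losses, metrics, learning
#'   rate).
#' @export
fit_mlp <- function(X_train, Y_train, X_val, Y_val, cfg = mlp_config()) {
  stopifnot(!is.null(colnames(Y_train)))
  if (is.null(X_val) || nrow(X_val) == 0L) {
    stop("validation set is empty: checkpoint selection impossible")
  }
  stopifnot(
    nrow(X_train) == nrow(Y_train), nrow(X_val) == nrow(Y_val),
    identical(colnames(Y_train), colnames(Y_val))
  )
  d <- ncol(X_train)
  h <- cfg$hidden
  k <- ncol(Y_train)
  n <- nrow(X_train)

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, globalenv()),
    add = TRUE
  )
  set.seed(cfg$seed)

  w <- list(
    W1 = matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h),
    b1 = numeric(h),
    W2 = matrix(stats::rnorm(h * k, sd = sqrt(1 / h)), h, k),
    b2 = numeric(k)
  )
  adam <- list(
    m = lapply(w, function(p) p * 0), v = lapply(w, function(p) p * 0),
    t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8
  )
  lr <- cfg$learning_rate
  keep_p <- 1 - cfg$dropout

  # validation terms usable for the ROCAUC checkpoint metric
  val_ok <- colSums(Y_val) > 0L & colSums(Y_val) < nrow(Y_val)

  best_val_loss <- Inf
  stall <- 0L
  best_term <- list(weights = w, epoch = 0L, value = -Inf)
  best_protein <- list(weights = w, epoch = 0L, value = -Inf)
  history <- vector("list", cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    train_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
      Xb <- X_train[idx, , drop = FALSE]
      Yb <- Y_train[idx, , drop = FALSE]
      nb <- length(idx)

      Z1 <- sweep(Xb %*% w$W1, 2L, w$b1, "+")
      H <- pmax(Z1, 0)
      mask <- if (cfg$dropout > 0) {
        (matrix(stats::runif(nb * h), nb, h) < keep_p) / keep_p
      } else {
        1
      }
      Hd <- H * mask
      O <- sigmoid(sweep(Hd %*% w$W2, 2L, w$b2, "+"))
      train_loss <- train_loss + bce_loss(O, Yb) * nb

      dZ2 <- (O - Yb) / (nb * k)
      g <- list(
        W1 = NULL, b1 = NULL,
        W2 = crossprod(Hd, dZ2), b2 = colSums(dZ2)
      )
      dH <- (dZ2 %*% t(w$W2)) * mask
      dZ1 <- dH * (Z1 > 0)
      g$W1 <- crossprod(Xb, dZ1)
      g$b1 <- colSums(dZ1)

      adam$t <- adam$t + 1L
      bc1 <- 1 - adam$beta1^adam$t
      bc2 <- 1 - adam$beta2^adam$t
      for (p in names(w)) {
        adam$m[[p]] <- adam$beta1 * adam$m[[p]] + (1 - adam$beta1) * g[[p]]
        adam$v[[p]] <- adam$beta2 * adam$v[[p]] + (1 - adam$beta2) * g[[p]]^2
        w[[p]] <- w[[p]] -
          lr * (adam$m[[p]] / bc1) / (sqrt(adam$v[[p]] / bc2) + adam$eps)
      }
    }
    train_loss <- train_loss / n

    O_val <- mlp_forward(w, X_val)
    val_loss <- bce_loss(O_val, Y_val)
    val_auc <- if (any(val_ok)) {
      mean(vapply(which(val_ok), function(j) {
        term_rocauc(O_val[, j], Y_val[, j])
      }, numeric(1L)))
    } else {
      NA_real_
    }
    val_fmax <- fmax_matrices(O_val, Y_val)

    if (!is.na(val_auc) && val_auc > best_term$value) {
      best_term <- list(weights = w, epoch = epoch, value = val_auc)
    }
    if (val_fmax > best_protein$value) {
      best_protein <- list(weights = w, epoch = epoch, value = val_fmax)
    }

    if (val_loss < best_val_loss - 1e-12) {
      best_val_loss <- val_loss
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) {
        lr <- lr / 10
        stall <- 0L
      }
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = train_loss, val_loss = val_loss,
      val_term_auc = val_auc, val_fmax = val_fmax, learning_rate = lr
    )
  }

  structure(
    list(
      terms = colnames(Y_train), d = d, cfg = cfg,
      best_term = best_term, best_protein = best_protein,
      final = list(weights = w, epoch = cfg$epochs, value = NA_real_),
      history = dplyr::bind_rows(history)
    ),
    class = "mlp_model"
  )
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf(
    "<mlp_model> %d terms, %d -> %d -> %d; best val term AUC %.3f (epoch %d), best val Fmax %.3f (epoch %d)\n",
    length(x$terms), x$d, x$cfg$hidden, length(x$terms),
    x$best_term$value, x$best_term$epoch,
    x$best_protein$value, x$best_protein$epoch
  ))
  invisible(x)
}

#' Posterior probabilities from a fitted model
#'
#' Produces the proteins x terms matrix of posterior probabilities in
#' [0, 1]. The result is uncorrected with respect to the hierarchy
#' (`attr(, "corrected")` is `FALSE`); apply [hierarchy_correct()] where
#' hierarchy-consistent scores are required.
#'
#' @param model A fitted `lr_model` or `mlp_model`.
#' @param X Feature matrix standardized with the training standardizer.
#' @param ... Method-specific arguments; for `mlp_model`, `checkpoint`
#'   chooses among `"term"`, `"protein"` and `"final"` states.
#' @return Numeric matrix with protein row names and term column names;
#'   attribute `corrected = FALSE`.
#' @export
predict_proba <- function(model, X, ...) UseMethod("predict_proba")

#' @rdname predict_proba
#' @export
predict_proba.lr_model <- function(model, X, ...) {
  if (ncol(X) != model$d) {
    stop("feature width mismatch: ", ncol(X), " vs ", model$d)
  }
  X <- as.matrix(unclass(X))
  P <- vapply(
    model$terms, function(t) predict(model$models[[t]], X),
    numeric(nrow(X))
  )
  P <- matrix(P,
    nrow = nrow(X),
    dimnames = list(rownames(X), model$terms)
  )
  attr(P, "corrected") <- FALSE
  P
}

#' @rdname predict_proba
#' @param checkpoint Which MLP checkpoint to use.
#' @export
predict_proba.mlp_model <- function(model, X,
                                    checkpoint = c("term", "protein", "final"),
                                    ...) {
  checkpoint <- match.arg(checkpoint)
  if (ncol(X) != model$d) {
    stop("feature width mismatch: ", ncol(X), " vs ", model$d)
  }
  X <- as.matrix(unclass(X))
  w <- switch(checkpoint,
    term = model$best_term$weights,
    protein = model$best_protein$weights,
    final = model$final$weights
  )
  P <- mlp_forward(w, X)
  dimnames(P) <- list(rownames(X), model$terms)
  attr(P, "corrected") <- FALSE
  P
}

#' Hierarchy-consistent correction of posterior probabilities
#'
#' Enforces the true-path rule on predicted scores: every parent term
#' receives the highest probability among its child terms if and only if
#' that probability exceeds its own. Processing children before parents
#' makes each term's final score the maximum over itself and all its
#' predicted descendants. The operation never lowers a score, leaves leaf
#' scores untouched, and is idempotent.
#'
#' @param P Proteins x terms probability matrix; all column terms must be
#'   in the DAG.
#' @param dag An [ontology_dag()].
#' @return The corrected matrix, `attr(, "corrected") = TRUE`.
#' @export
hierarchy_correct <- function(P, dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  terms <- colnames(P)
  missing <- setdiff(terms, dag$terms)
  if (length(missing) > 0L) {
    stop(
      "predicted term(s) absent from the ontology: ",
      paste(utils::head(missing, 5L), collapse = ", ")
    )
  }
  # Work in the full term space so max-propagation crosses terms that were
  # not predicted; only the original columns are returned.
  M <- matrix(0, nrow = nrow(P), ncol = length(dag$terms),
    dimnames = list(rownames(P), dag$terms)
  )
  M[, terms] <- P
  for (t in dag$terms[order(dag$depth, decreasing = TRUE)]) {
    ps <- dag$parents[[t]]
    if (length(ps) == 0L) next
    for (p in ps) M[, p] <- pmax(M[, p], M[, t])
  }
  out <- M[, terms, drop = FALSE]
  attr(out, "corrected") <- TRUE
  out
}

#' Select the decision threshold on the validation set
#'
#' Scans a threshold grid and returns the threshold maximizing the
#' protein-centric F1 on validation predictions, mimicking a deployment
#' setting where no test-species information is available. Ties are broken
#' toward the smallest threshold.
#'
#' @param P_val Validation score matrix (hierarchy-corrected).
#' @param truth_val Propagated validation [annotation_set()].
#' @param grid Threshold grid (default 0, 0.01, ..., 1).
#' @param eval_terms Terms to evaluate over (default: columns of `P_val`).
#' @return A list of class `threshold_selection`: `tau`, `f1`, `curve`
#'   (tibble `tau`, `f1`).
#' @export
select_threshold <- function(P_val, truth_val, grid = seq(0, 1, by = 0.01),
                             eval_terms = colnames(P_val)) {
  if (nrow(P_val) == 0L) stop("empty validation set")
  grid <- sort(unique(grid))
  eval_terms <- intersect(eval_terms, colnames(P_val))
  Pm <- P_val[, eval_terms, drop = FALSE]
  Tm <- truth_matrix(rownames(P_val), eval_terms, truth_val)
  keep <- rowSums(Tm) > 0L
  if (!any(keep)) stop("no validation protein has true annotations")
  Pm <- Pm[keep, , drop = FALSE]
  Tm <- Tm[keep, , drop = FALSE]
  f1s <- vapply(grid, function(tau) {
    pred <- Pm >= tau
    n_pred <- rowSums(pred)
    tp <- rowSums(pred & (Tm == 1L))
    covered <- n_pred > 0L
    if (!any(covered)) return(0)
    pr <- mean((tp / n_pred)[covered])
    rc <- mean(tp / rowSums(Tm))
    if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  }, numeric(1L))
  i <- which(f1s == max(f1s))[1L] # grid scanned in order: smallest tau wins
  structure(
    list(
      tau = grid[i], f1 = f1s[i],
      curve = tibble::tibble(tau = grid, f1 = f1s)
    ),
    class = "threshold_selection"
  )
}
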