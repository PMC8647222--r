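#' Combine per-residue layer embeddings
#'
#' A contextual protein language model emits, for every residue n of a
#' protein of length M, one d-dimensional vector per model layer. The three
#' layer embeddings are combined by component-wise summation into a single
#' M x d residue-level embedding matrix.
#'
#' @param layers A list of three M x d numeric matrices (one per layer), or
#'   an object of class `residue_embeddings`.
#' @return An M x d matrix: the row-wise sum of the three layers.
#' @export
combine_layers <- function(layers) {
  if (inherits(layers, "residue_embeddings")) layers <- unclass(layers)
  stopifnot(is.list(layers), length(layers) == 3L)
  dims <- lapply(layers, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1L]]))) {
    stop("layer embedding matrices must share the same M x d shape")
  }
  layers[[1L]] + layers[[2L]] + layers[[3L]]
}

#' Pool residue embeddings to a protein-level embedding
#'
#' Summarizes a variable-length M x d residue embedding matrix into one
#' fixed-length d-vector by the component-wise arithmetic mean over
#' residues. The result does not depend on residue order and its length d
#' is independent of M.
#'
#' @param W An M x d numeric matrix with M >= 1.
#' @return Numeric d-vector.
#' @export
pool_protein <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) < 1L) stop("cannot pool an empty residue matrix (M = 0)")
  colMeans(W)
}

#' Pool a set of residue embeddings into an embedding store
#'
#' Convenience wrapper: combines layers and mean-pools each protein's
#' residue embeddings, collecting the protein-level vectors into an
#' [embedding_store()].
#'
#' @param residues Named list (protein ID -> `residue_embeddings`, i.e. a
#'   list of three M x d layer matrices).
#' @param source Provenance label for the store.
#' @return An [embedding_store()].
#' @export
pool_embeddings <- function(residues, source = "pooled") {
  stopifnot(length(residues) > 0L, !is.null(names(residues)))
  vecs <- t(vapply(
    residues,
    function(r) pool_protein(combine_layers(r)),
    numeric(ncol(as.matrix(residues[[1L]][[1L]])))
  ))
  rownames(vecs) <- names(residues)
  embedding_store(vecs, source = source)
}

#' Feature standardizer
#'
#' Learns per-feature means and standard deviations on a training embedding
#' store and applies the z-transform to any store. Fitting on the held-out
#' sets would leak test statistics into the model, so the standardizer is
#' fitted once on the training set and stored with the run. Zero-variance
#' features are mapped to 0.
#'
#' @param train An [embedding_store()] (or numeric matrix) with at least 2
#'   proteins.
#' @return An object of class `standardizer` with elements `mean`, `sd`
#'   and `d`.
#' @export
fit_standardizer <- function(train) {
  x <- unclass(as.matrix(train))
  if (nrow(x) < 2L) stop("standardizer needs at least 2 training proteins")
  structure(
    list(
      mean = colMeans(x),
      sd = apply(x, 2L, stats::sd),
      d = ncol(x)
    ),
    class = "standardizer"
  )
}

#' @rdname fit_standardizer
#' @param s A fitted `standardizer`.
#' @param store An [embedding_store()] or matrix with the same width.
#' @return The transformed store (same class as the input matrix).
#' @export
apply_standardizer <- function(s, store) {
  stopifnot(inherits(s, "standardizer"))
  x <- unclass(as.matrix(store))
  if (ncol(x) != s$d) stop("embedding width mismatch: ", ncol(x), " vs ", s$d)
  sdv <- ifelse(s$sd < 1e-12, Inf, s$sd) # constant features -> 0
  z <- sweep(sweep(x, 2L, s$mean, "-"), 2L, sdv, "/")
  if (inherits(store, "embedding_store")) {
    embedding_store(z, source = paste0(attr(store, "source"), "+std"))
  } else {
    z
  }
}

#' Residue embeddings container
#'
#' @param w1,w2,w3 Three M x d layer matrices.
#' @return An object of class `residue_embeddings` (list of the 3 layers).
#' @export
residue_embeddings <- function(w1, w2, w3) {
  layers <- list(w1 = as.matrix(w1), w2 = as.matrix(w2), w3 = as.matrix(w3))
  dims <- lapply(layers, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1L]]))) {
    stop("layer embedding matrices must share the same M x d shape")
  }
  if (dims[[1L]][1L] < 1L) stop("residue embeddings need M >= 1")
  structure(layers, class = "residue_embeddings")
}

#' Embedder interface
#'
#' An embedder turns protein sequences into per-residue layer embeddings
#' (`residue_embeddings`): `embed_sequences(embedder, sequences)` returns a
#' named list with one entry per input sequence, each with M rows for a
#' sequence of length M. Output is deterministic given the sequence.
#' Two implementations ship with the package: a synthetic embedder (hashed
#' pseudo-random embeddings for testing plumbing end-to-end) and a
#' precomputed embedder that looks embeddings up in a store.
#'
#' @param embedder An embedder object.
#' @param sequences Named character vector of amino-acid sequences.
#' @return Named list of `residue_embeddings`.
#' @export
embed_sequences <- function(embedder, sequences) {
  UseMethod("embed_sequences")
}

#' @rdname embed_sequences
#' @param d Embedding width.
#' @param seed Base seed; combined with a sequence hash so equal sequences
#'   always embed identically.
#' @export
synthetic_embedder <- function(d = 16L, seed = 1L) {
  structure(list(d = as.integer(d), seed = as.integer(seed)),
    class = c("synthetic_embedder", "embedder")
  )
}

#' @export
embed_sequences.synthetic_embedder <- function(embedder, sequences) {
  stopifnot(!is.null(names(sequences)))
  out <- lapply(sequences, function(sq) {
    sq <- gsub("[^ACDEFGHIKLMNPQRSTVWY]", "X", toupper(sq))
    m <- nchar(sq)
    if (m < 1L) stop("cannot embed an empty sequence")
    h <- sum(utf8ToInt(sq) * seq_len(m)) %% 1000003L
    layers <- lapply(1:3, function(l) {
      set.seed((embedder$seed + h * 7L + l) %% .Machine$integer.max)
      matrix(stats::rnorm(m * embedder$d), nrow = m, ncol = embedder$d)
    })
    residue_embeddings(layers[[1L]], layers[[2L]], layers[[3L]])
  })
  stats::setNames(out, names(sequences))
}

#' @rdname embed_sequences
#' @param residues Named list of precomputed `residue_embeddings`.
#' @export
precomputed_embedder <- function(residues) {
  stopifnot(!is.null(names(residues)))
  structure(list(residues = residues),
    class = c("precomputed_embedder", "embedder")
  )
}

#' @export
embed_sequences.precomputed_embedder <- function(embedder, sequences) {
  ids <- names(sequences)
  missing <- setdiff(ids, names(embedder$residues))
  if (length(missing) > 0L) {
    stop(
      "no precomputed embeddings for: ",
      paste(utils::head(missing, 5L), collapse = ", ")
    )
  }
  embedder$residues[ids]
}
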