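#' Evidence codes accepted by default
#'
#' The seventeen non-computational GO evidence codes (experimental,
#' high-throughput, phylogenetic and curator-assigned) used to filter
#' annotations. Electronically inferred annotations (IEA) are excluded.
#'
#' @return Character vector of evidence codes.
#' @export
default_evidence_codes <- function() {
  c(
    "EXP", "IDA", "IPI", "IMP", "IGI", "IEP",
    "HTP", "HDA", "HMP", "HGI", "HEP",
    "IBA", "IBD", "IKR", "IRD", "IC", "TAS"
  )
}

#' Read a protein annotation file
#'
#' Reads either a GAF 2.x file (17 tab-separated columns, comment lines
#' starting with `!`) or a simple 3-column TSV (`protein`, `term`,
#' `evidence`), keeping only records whose evidence code is in the
#' whitelist. Malformed rows are skipped with a warning giving the count.
#'
#' @param path Path to the annotation file.
#' @param evidence_whitelist Character vector of evidence codes to keep;
#'   `NULL` keeps everything.
#' @return An unpropagated [annotation_set()].
#' @export
read_annotations <- function(path, evidence_whitelist = default_evidence_codes()) {
  lines <- readLines(path)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  gaf <- length(nf) > 0L && stats::median(nf) >= 15L
  if (gaf) {
    ok <- nf >= 15L
    protein <- vapply(fields[ok], `[[`, "", 2L)
    term <- vapply(fields[ok], `[[`, "", 5L)
    evidence <- vapply(fields[ok], `[[`, "", 7L)
  } else {
    ok <- nf >= 2L
    protein <- vapply(fields[ok], `[[`, "", 1L)
    term <- vapply(fields[ok], `[[`, "", 2L)
    evidence <- vapply(fields[ok], function(f) {
      if (length(f) >= 3L) f[[3L]] else NA_character_
    }, "")
  }
  n_bad <- sum(!ok)
  if (n_bad > 0L) warning(n_bad, " malformed annotation row(s) skipped")
  rec <- tibble::tibble(protein = protein, term = term, evidence = evidence)
  if (!is.null(evidence_whitelist)) {
    rec <- rec[rec$evidence %in% evidence_whitelist, ]
  }
  annotation_set(rec, propagated = FALSE)
}

#' Filter proteins by sequence length
#'
#' Keeps proteins whose length lies in the inclusive range
#' `[min_len, max_len]`. Row order is preserved. If a `length` column is
#' absent it is computed from the `sequence` column.
#'
#' @param records A data frame with column `protein` and either `length` or
#'   `sequence`.
#' @param min_len,max_len Inclusive length bounds (defaults 40 and 1000).
#' @return The filtered tibble.
#' @export
filter_proteins <- function(records, min_len = 40L, max_len = 1000L) {
  records <- tibble::as_tibble(records)
  if (!"length" %in% names(records)) {
    stopifnot("sequence" %in% names(records))
    records$length <- nchar(records$sequence)
  }
  records[records$length >= min_len & records$length <= max_len, ]
}

#' Read a BLAST tabular (outfmt 6) hit file
#'
#' Parses the standard 12-column BLAST/PSI-BLAST tabular output:
#' qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart,
#' send, evalue, bitscore.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `query`, `subject`, `pident`, `length`,
#'   `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`, `evalue`,
#'   `bitscore`.
#' @export
read_hit_table <- function(path) {
  cols <- c(
    "query", "subject", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore"
  )
  df <- utils::read.table(path,
    sep = "\t", header = FALSE, col.names = cols,
    colClasses = c("character", "character", rep("numeric", 10L)),
    comment.char = "#", quote = ""
  )
  out <- tibble::as_tibble(df)
  if (any(out$pident < 0 | out$pident > 100)) {
    stop("percent identity outside [0, 100] in ", path)
  }
  out
}

#' Write a hit table in BLAST outfmt 6 layout
#'
#' @param hits A tibble as returned by [read_hit_table()].
#' @param path Output path.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read an InterPro annotation table
#'
#' Reads a TSV with columns protein, InterPro accession and entry type, and
#' routes each row into one of the three feature kinds used downstream:
#' `Domain` -> domain, `Family` -> family, `Homologous_superfamily` ->
#' superfamily. Other entry types are dropped.
#'
#' @param path Path to the TSV (header optional; detected from the first
#'   line).
#' @return A tibble with columns `protein`, `accession`, `kind`
#'   (`"domain"`, `"family"` or `"superfamily"`).
#' @export
read_interpro <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("protein", first, ignore.case = TRUE)
  df <- utils::read.table(path,
    sep = "\t", header = header, quote = "",
    col.names = c("protein", "accession", "type"),
    colClasses = "character"
  )
  kind <- dplyr::case_when(
    df$type %in% c("Domain", "domain") ~ "domain",
    df$type %in% c("Family", "family") ~ "family",
    df$type %in% c("Homologous_superfamily", "superfamily") ~ "superfamily",
    TRUE ~ NA_character_
  )
  out <- tibble::tibble(
    protein = df$protein, accession = df$accession, kind = kind
  )
  out[!is.na(out$kind), ]
}

#' Embedding stores
#'
#' An embedding store holds one fixed-length d-dimensional vector per
#' protein: a numeric matrix with protein IDs as row names and attributes
#' `source` (a label) recording provenance. Two on-disk dialects are
#' supported: a keyed binary container (RDS) and a plain TSV
#' (first column `protein`, then `e1 ... ed`).
#'
#' @param x A numeric matrix (rows = proteins, row names = protein IDs).
#' @param source Provenance label.
#' @return An `embedding_store` (matrix subclass).
#' @export
embedding_store <- function(x, source = "unknown") {
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop("embedding matrix must have protein row names")
  if (anyDuplicated(rownames(x))) {
    stop("duplicate protein ID in embedding store")
  }
  storage.mode(x) <- "double"
  structure(x, source = source, class = c("embedding_store", "matrix", "array"))
}

#' @rdname embedding_store
#' @param store An `embedding_store`.
#' @param path Output path. Format inferred from the extension unless given.
#' @param format `"rds"` (binary keyed container) or `"tsv"`.
#' @export
write_embeddings <- function(store, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.tsv$", path)) "tsv" else "rds"
  }
  format <- match.arg(format, c("rds", "tsv"))
  if (format == "rds") {
    saveRDS(
      list(
        vectors = unclass(store), d = ncol(store),
        source = attr(store, "source")
      ),
      path
    )
  } else {
    df <- data.frame(protein = rownames(store), unclass(store)[, , drop = FALSE],
      check.names = FALSE
    )
    colnames(df) <- c("protein", paste0("e", seq_len(ncol(store))))
    utils::write.table(df, path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}

#' @rdname embedding_store
#' @export
read_embeddings <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.tsv$", path)) "tsv" else "rds"
  }
  format <- match.arg(format, c("rds", "tsv"))
  if (format == "rds") {
    obj <- readRDS(path)
    embedding_store(obj$vectors, source = obj$source)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    embedding_store(m, source = "tsv")
  }
}

#' @rdname embedding_store
#' @param a,b Two embedding stores to concatenate row-wise.
#' @export
bind_embeddings <- function(a, b) {
  if (ncol(a) != ncol(b)) {
    stop("embedding width mismatch on append: ", ncol(a), " vs ", ncol(b))
  }
  if (length(intersect(rownames(a), rownames(b))) > 0L) {
    stop("duplicate protein ID in embedding store")
  }
  embedding_store(rbind(unclass(a), unclass(b)), source = attr(a, "source"))
}

#' Stratified multi-label train/validation/test split
#'
#' Splits proteins into subsets by greedy iterative stratification: labels
#' are processed from rarest to most frequent, and each protein carrying the
#' current label is placed into the subset with the greatest remaining
#' demand for that label (ties broken by overall remaining capacity, then
#' deterministically by seeded order). This preserves as many overlapping
#' terms as possible across subsets.
#'
#' @param ann An [annotation_set()] (propagated or not; label distribution
#'   is taken from the records as given).
#' @param fractions Named numeric vector of subset fractions summing to 1,
#'   e.g. `c(train = 0.7, val = 0.15, test = 0.15)`. All must be positive.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param proteins Optional character vector of all proteins to place
#'   (defaults to those present in `ann`); unannotated extras are placed by
#'   remaining capacity.
#'
#' @return A tibble with columns `protein` and `split` (factor with the
#'   names of `fractions` as levels). Subsets are disjoint and exhaustive.
#' @export
stratified_multilabel_split <- function(ann,
                                        fractions = c(train = 0.7, val = 0.15, test = 0.15),
                                        seed = 1L, proteins = NULL) {
  if (any(fractions <= 0)) stop("all split fractions must be positive")
  if (abs(sum(fractions) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (is.null(names(fractions))) {
    names(fractions) <- paste0("subset", seq_along(fractions))
  }
  ann <- tibble::as_tibble(ann)
  if (is.null(proteins)) proteins <- unique(ann$protein)
  n <- length(proteins)
  k <- length(fractions)

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, globalenv()),
    add = TRUE
  )
  set.seed(seed)

  label_sets <- split(ann$term, ann$protein)
  by_label <- split(ann$protein, ann$term)
  by_label <- lapply(by_label, unique)

  cap <- fractions * n # remaining overall demand
  lab_cap <- lapply(by_label, function(p) fractions * length(p))

  assigned <- stats::setNames(rep(NA_character_, n), proteins)
  remaining_by_label <- lapply(by_label, function(p) p)

  repeat {
    sizes <- vapply(remaining_by_label, length, 1L)
    sizes <- sizes[sizes > 0L]
    if (length(sizes) == 0L) break
    # rarest label first; ties by name for determinism
    l <- names(sizes)[order(sizes, names(sizes))][1L]
    prots <- sample(remaining_by_label[[l]])
    for (p in prots) {
      if (!is.na(assigned[[p]])) next
      demand <- lab_cap[[l]]
      best <- which(demand == max(demand))
      if (length(best) > 1L) {
        best <- best[which(cap[best] == max(cap[best]))]
      }
      j <- best[1L]
      assigned[[p]] <- names(fractions)[j]
      cap[j] <- cap[j] - 1
      for (lbl in unique(label_sets[[p]])) {
        lab_cap[[lbl]][j] <- lab_cap[[lbl]][j] - 1
      }
    }
    remaining_by_label <- lapply(remaining_by_label, function(p) {
      p[is.na(assigned[p])]
    })
    remaining_by_label[[l]] <- character(0)
  }
  # proteins without any label: fill by remaining capacity
  left <- proteins[is.na(assigned)]
  if (length(left) > 0L) {
    for (p in sample(left)) {
      j <- which.max(cap)
      assigned[[p]] <- names(fractions)[j]
      cap[j] <- cap[j] - 1
    }
  }
  tibble::tibble(
    protein = proteins,
    split = factor(assigned[proteins], levels = names(fractions))
  )
}

#' Filter terms by per-split positive support
#'
#' Keeps the terms that have at least the required number of annotated
#' proteins in every named split. Counts are taken on the annotation set as
#' given (pass a propagated set for hierarchy-aware support).
#'
#' @param ann An [annotation_set()].
#' @param split A tibble with columns `protein` and `split`, as returned by
#'   [stratified_multilabel_split()].
#' @param thresholds Named integer vector; names must be levels of
#'   `split$split`, e.g. `c(train = 40, val = 5, test = 5)`.
#' @param exclude Term IDs to drop regardless of support (typically the
#'   ontology root, which is trivially annotated to every protein).
#'
#' @return Character vector of term IDs meeting all thresholds.
#' @export
filter_terms_by_support <- function(ann, split,
                                    thresholds = c(train = 40, val = 5, test = 5),
                                    exclude = character(0)) {
  ann <- tibble::as_tibble(ann)
  m <- dplyr::inner_join(ann, tibble::as_tibble(split), by = "protein")
  counts <- dplyr::count(
    dplyr::distinct(m, .data$protein, .data$term, .data$split),
    .data$term, .data$split
  )
  wide <- tidyr::pivot_wider(counts,
    names_from = "split", values_from = "n",
    values_fill = 0L
  )
  keep <- rep(TRUE, nrow(wide))
  for (s in names(thresholds)) {
    cnt <- if (s %in% names(wide)) wide[[s]] else rep(0L, nrow(wide))
    keep <- keep & cnt >= thresholds[[s]]
  }
  setdiff(sort(wide$term[keep]), exclude)
}
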