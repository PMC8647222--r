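test_that("annotation reading filters by evidence and skips malformed rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "p1\tGO:1\tEXP",
    "p2\tGO:2\tIEA",
    "p3\tGO:3\tIBA",
    "p4\tGO:4\tTAS",
    "badrow",
    "p5\tGO:5\tIDA"
  ), path)
  expect_warning(ann <- read_annotations(path), "malformed")
  expect_setequal(ann$protein, c("p1", "p3", "p4", "p5")) # IEA dropped
  expect_false(is_propagated(ann))

  # a whitelist without IBA also drops phylogenetic annotations
  ann2 <- suppressWarnings(read_annotations(
    path, setdiff(default_evidence_codes(), "IBA")
  ))
  expect_false("p3" %in% ann2$protein)

  # well-formed file passes through completely
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sprintf("p%d\tGO:%d\tEXP", 1:5, 1:5), path2)
  expect_equal(nrow(read_annotations(path2)), 5L)
})

test_that("GAF layout is detected and parsed from the standard columns", {
  path <- withr::local_tempfile(fileext = ".gaf")
  gaf_row <- function(id, go, ev) {
    paste(c(
      "UniProtKB", id, "SYM", "", go, "PMID:1", ev, "", "F",
      "", "", "protein", "taxon:10090", "20200101", "UniProt", "", ""
    ), collapse = "\t")
  }
  writeLines(c(
    "!gaf-version: 2.1",
    gaf_row("P001", "GO:0003674", "IDA"),
    gaf_row("P002", "GO:0005515", "IEA")
  ), path)
  ann <- read_annotations(path)
  expect_equal(ann$protein, "P001")
  expect_equal(ann$term, "GO:0003674")
})

test_that("protein length filtering uses inclusive bounds", {
  recs <- tibble::tibble(protein = sprintf("p%d", 1:4),
    length = c(39L, 40L, 1000L, 1001L)
  )
  kept <- filter_proteins(recs)
  expect_equal(kept$protein, c("p2", "p3"))
  # length derived from sequence when absent
  seqs <- tibble::tibble(
    protein = c("a", "b"),
    sequence = c(strrep("M", 39L), strrep("M", 40L))
  )
  expect_equal(filter_proteins(seqs)$protein, "b")
})

test_that("hit tables and InterPro tables parse their dialects", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(
    "q1\ts1\t87.5\t100\t12\t1\t1\t100\t5\t104\t1e-30\t250.3",
    path
  )
  hits <- read_hit_table(path)
  expect_equal(hits$query, "q1")
  expect_equal(hits$pident, 87.5)
  expect_equal(hits$evalue, 1e-30)
  expect_equal(hits$bitscore, 250.3)

  # round trip
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(hits, path2)
  expect_equal(as.data.frame(read_hit_table(path2)), as.data.frame(hits))

  ip_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "p1\tIPR000001\tDomain",
    "p1\tIPR000002\tFamily",
    "p2\tIPR000003\tHomologous_superfamily",
    "p2\tIPR000004\tActive_site"
  ), ip_path)
  ip <- read_interpro(ip_path)
  expect_equal(ip$kind[ip$accession == "IPR000003"], "superfamily")
  expect_false("IPR000004" %in% ip$accession) # unknown type dropped
})

test_that("embedding stores round-trip losslessly in both dialects", {
  set.seed(42)
  m <- matrix(rnorm(10 * 8), nrow = 10,
    dimnames = list(sprintf("p%02d", 1:10), NULL)
  )
  store <- embedding_store(m, source = "test")

  rds <- withr::local_tempfile(fileext = ".rds")
  write_embeddings(store, rds)
  back <- read_embeddings(rds)
  expect_equal(unclass(back), unclass(store), ignore_attr = TRUE)
  expect_identical(rownames(back), rownames(store))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_embeddings(store, tsv)
  back2 <- read_embeddings(tsv)
  expect_equal(unclass(back2), unclass(store),
    tolerance = 1e-8, ignore_attr = TRUE
  )

  # duplicate IDs and width mismatches are rejected
  expect_error(
    embedding_store(rbind(m, m[1, , drop = FALSE])),
    "duplicate"
  )
  other <- embedding_store(
    matrix(0, 1, 5, dimnames = list("q1", NULL))
  )
  expect_error(bind_embeddings(store, other), "width mismatch")
  dup <- embedding_store(m[1, , drop = FALSE])
  expect_error(bind_embeddings(store, dup), "duplicate")
})

test_that("stratified split is deterministic, exhaustive and label-covering", {
  # single label reduces to a plain fractional split
  ann <- annotation_set(tibble::tibble(
    protein = sprintf("p%03d", 1:100), term = "T1"
  ))
  sp <- stratified_multilabel_split(ann, c(a = 0.5, b = 0.25, c = 0.25),
    seed = 7
  )
  expect_equal(nrow(sp), 100L)
  expect_true(all(abs(table(sp$split) - c(50, 25, 25)) <= 1))

  sp2 <- stratified_multilabel_split(ann, c(a = 0.5, b = 0.25, c = 0.25),
    seed = 7
  )
  expect_identical(sp, sp2)

  expect_error(
    stratified_multilabel_split(ann, c(a = 0.5, b = 0.5, c = 0)),
    "positive"
  )

  # a rare label with 4 positives lands in every subset when feasible
  set.seed(11)
  base <- tibble::tibble(
    protein = sprintf("p%03d", 1:100),
    term = sample(c("T1", "T2"), 100, replace = TRUE)
  )
  rare <- tibble::tibble(protein = sprintf("p%03d", 1:4), term = "RARE")
  ann2 <- annotation_set(dplyr::bind_rows(base, rare))
  sp3 <- stratified_multilabel_split(ann2, c(train = 0.5, val = 0.25, test = 0.25),
    seed = 3
  )
  got <- sp3$split[sp3$protein %in% sprintf("p%03d", 1:4)]
  expect_setequal(as.character(unique(got)), c("train", "val", "test"))

  # label coverage at least matches the median of random splits
  set.seed(99)
  ann3 <- annotation_set(tibble::tibble(
    protein = sample(sprintf("p%03d", 1:120), 300, replace = TRUE),
    term = sample(sprintf("L%02d", 1:30), 300, replace = TRUE)
  ))
  coverage <- function(split_tbl) {
    m <- dplyr::inner_join(tibble::as_tibble(ann3), split_tbl, by = "protein")
    sum(vapply(split(m$split, m$term), function(s) {
      length(unique(s)) == 3L
    }, logical(1L)))
  }
  strat_cov <- coverage(stratified_multilabel_split(
    ann3, c(train = 0.6, val = 0.2, test = 0.2), seed = 1
  ))
  rand_cov <- vapply(1:100, function(s) {
    set.seed(s + 1000)
    prots <- unique(ann3$protein)
    lab <- sample(rep(c("train", "val", "test"),
      times = round(c(0.6, 0.2, 0.2) * length(prots))
    )[seq_along(prots)])
    coverage(tibble::tibble(protein = prots, split = factor(lab)))
  }, numeric(1L))
  expect_gte(strat_cov, stats::median(rand_cov))
})

test_that("term support filtering counts per split and honors thresholds", {
  # term A: 40 train / 5 val / 5 test -> kept; term B: 39 train -> dropped
  recs <- dplyr::bind_rows(
    tibble::tibble(protein = sprintf("tr%02d", 1:40), term = "A"),
    tibble::tibble(protein = sprintf("va%02d", 1:5), term = "A"),
    tibble::tibble(protein = sprintf("te%02d", 1:5), term = "A"),
    tibble::tibble(protein = sprintf("tr%02d", 1:39), term = "B"),
    tibble::tibble(protein = sprintf("va%02d", 1:5), term = "B"),
    tibble::tibble(protein = sprintf("te%02d", 1:5), term = "B")
  )
  split_tbl <- tibble::tibble(
    protein = c(sprintf("tr%02d", 1:40), sprintf("va%02d", 1:5),
      sprintf("te%02d", 1:5)
    ),
    split = factor(
      rep(c("train", "val", "test"), c(40, 5, 5)),
      levels = c("train", "val", "test")
    )
  )
  ann <- annotation_set(recs)
  kept <- filter_terms_by_support(ann, split_tbl)
  expect_equal(kept, "A")
  expect_equal(
    filter_terms_by_support(ann, split_tbl, exclude = "A"),
    character(0)
  )

  # random fuzz against naive counting
  set.seed(5)
  prots <- sprintf("p%03d", 1:60)
  st <- tibble::tibble(
    protein = prots,
    split = factor(sample(c("train", "val", "test"), 60, TRUE),
      levels = c("train", "val", "test")
    )
  )
  rec <- tibble::tibble(
    protein = sample(prots, 300, replace = TRUE),
    term = sample(sprintf("T%02d", 1:12), 300, replace = TRUE)
  )
  ann2 <- annotation_set(rec)
  th <- c(train = 8, val = 2, test = 2)
  got <- filter_terms_by_support(ann2, st, th)
  uniq <- dplyr::distinct(tibble::as_tibble(ann2), protein, term)
  uniq <- dplyr::inner_join(uniq, st, by = "protein")
  expected <- sort(Filter(function(t) {
    tab <- table(uniq$split[uniq$term == t])
    all(c(tab["train"], tab["val"], tab["test"]) >= th[c("train", "val", "test")],
      na.rm = FALSE
    ) && !anyNA(tab[c("train", "val", "test")])
  }, unique(uniq$term)))
  expect_equal(got, expected)
})
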