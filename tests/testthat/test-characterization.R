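test_that("Spearman correlation matches explicit rank-Pearson and handles edges", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, x)$rho, 1)
  expect_equal(correlate(x, -x)$rho, -1)
  expect_error(correlate(rep(1, 5), x), "constant")
  expect_error(correlate(1:2, 2:1), "at least 3")

  set.seed(21)
  a <- rnorm(30)
  b <- 0.5 * a + rnorm(30)
  got <- correlate(a, b)
  expect_equal(
    got$rho,
    stats::cor(rank(a), rank(b)),
    tolerance = 1e-12
  )
  expect_lt(got$p_value, 0.05)
})

test_that("length bins partition the training range into equal-frequency deciles", {
  set.seed(22)
  lens <- round(exp(runif(500, log(40), log(1000))))
  bins <- length_bins(lens)
  expect_equal(bins$n_bins, 10L)
  expect_equal(length(bins$breaks), 11L)
  idx <- assign_length_bin(bins, lens)
  tab <- table(idx)
  expect_equal(length(tab), 10L)
  expect_true(all(tab >= 30))
  # out-of-range lengths clamp into the edge bins
  expect_equal(assign_length_bin(bins, 10), 1L)
  expect_equal(assign_length_bin(bins, 5000), 10L)
  expect_error(length_bins(rep(100, 50)), "tied")
})

test_that("length probe detects an encoded length signal and not its absence", {
  set.seed(23)
  n <- 600L
  d <- 12L
  lens <- round(exp(runif(n, log(40), log(1000))))
  lz <- (log(lens) - log(40)) / (log(1000) - log(40))
  centers <- (1:10 - 0.5) / 10
  X <- matrix(rnorm(n * d), n, d)
  X[, 1:10] <- X[, 1:10] + 3 * exp(-outer(lz, centers, "-")^2 / (2 * 0.045^2))
  rownames(X) <- sprintf("p%03d", 1:n)
  tr <- 1:400
  va <- 401:500
  te <- 501:600
  probe <- length_probe(
    X[tr, ], lens[tr], X[va, ], lens[va], X[te, ], lens[te],
    grid = c(1, 0.01)
  )
  expect_gte(probe$mean_auc, 0.9)
  expect_equal(nrow(probe$per_bin), 10L)

  # a probe on embeddings whose first feature IS the normalized length,
  # with per-bin indicator contrasts, separates almost perfectly
  Xind <- cbind(
    outer(assign_length_bin(length_bins(lens), lens), 1:10, "==") * 3,
    matrix(rnorm(n * 2), n, 2)
  )
  rownames(Xind) <- rownames(X)
  probe_ind <- length_probe(
    Xind[tr, ], lens[tr], Xind[va, ], lens[va], Xind[te, ], lens[te],
    grid = 1
  )
  expect_gte(probe_ind$mean_auc, 0.95)

  # permuting lengths destroys the signal: AUC compatible with 0.5
  perm <- sample(n)
  probe_null <- length_probe(
    X[tr, ], lens[perm][tr], X[va, ], lens[perm][va],
    X[te, ], lens[perm][te],
    grid = 1
  )
  expect_lt(abs(probe_null$mean_auc - 0.5), 0.1)

  # single-value grid is selected as-is
  expect_equal(probe_null$lambda, 1)
})

test_that("InterPro shared-feature statistics count like the exhaustive oracle", {
  ip <- tibble::tibble(
    protein = c("p1", "p2", "p3", "p3", "p4", "p5", "p6"),
    accession = c("d1", "d1", "d1", "d2", "d3", "d1", "d9"),
    kind = "domain"
  )
  # 4 annotated proteins with sets {d1},{d1},{d1,d2},{d3} -> 0.75 at d1
  r <- interpro_similarity(
    c("p1", "p2", "p3", "p4"), c("p5", "p6"), ip, "domain"
  )
  expect_equal(r$max_shared, 0.75)
  expect_equal(r$feature, "d1")
  # d1 appears in 1 of the 2 covered background proteins
  expect_equal(r$prevalence, 0.5)
  expect_equal(r$mean_features, mean(c(1, 1, 2, 1)))

  # all annotated share one family -> fraction 1
  ip_fam <- tibble::tibble(
    protein = c("p1", "p2", "p3"), accession = "f1", kind = "family"
  )
  r2 <- interpro_similarity(c("p1", "p2", "p3"), character(0), ip_fam, "family")
  expect_equal(r2$max_shared, 1)

  # coverage below 50% skips the term
  expect_null(
    interpro_similarity(c("p1", "x1", "x2", "x3"), "p5", ip, "domain")
  )

  # random fuzz: per-feature counts recomputed exhaustively
  set.seed(24)
  prots <- sprintf("p%02d", 1:20)
  ipr <- tibble::tibble(
    protein = sample(prots, 50, replace = TRUE),
    accession = sample(sprintf("d%d", 1:6), 50, replace = TRUE),
    kind = "domain"
  ) |> dplyr::distinct()
  annotated <- prots[1:8]
  background <- prots[9:20]
  rr <- interpro_similarity(annotated, background, ipr, "domain",
    min_coverage = 0
  )
  sets <- lapply(split(ipr$accession, ipr$protein), unique)
  cov_ann <- annotated[annotated %in% names(sets)]
  best <- -1
  for (f in unique(ipr$accession)) {
    frac <- mean(vapply(cov_ann, function(p) f %in% sets[[p]], logical(1)))
    best <- max(best, frac)
  }
  expect_equal(rr$max_shared, best, tolerance = 1e-12)
})

test_that("category summaries take medians over scored member terms", {
  cats <- tibble::tibble(
    category = c("c1", "c1", "c1", "c2"),
    member = c("m1", "m2", "m3", "m4")
  )
  tm <- tibble::tibble(
    term = c("m1", "m2", "m3", "m4", "m5"),
    auc = c(0.9, 0.7, NA, 0.6, 0.99)
  )
  s <- category_summary(tm, cats)
  expect_equal(s$median_auc[s$category == "c1"], 0.8) # even count midpoint
  expect_equal(s$median_auc[s$category == "c2"], 0.6) # single member
  # per-species matrix when a species column is present
  tm2 <- dplyr::bind_rows(
    dplyr::mutate(tm, species = "s1"),
    dplyr::mutate(tm, auc = auc / 2, species = "s2")
  )
  s2 <- category_summary(tm2, cats)
  expect_equal(nrow(s2), 4L)
  expect_equal(
    s2$median_auc[s2$category == "c1" & s2$species == "s2"], 0.4
  )

  # oracle on a random instance
  set.seed(25)
  members <- sprintf("m%02d", 1:12)
  catsr <- tibble::tibble(
    category = rep(c("a", "b"), each = 6), member = members
  )
  tmr <- tibble::tibble(term = members, auc = runif(12))
  sr <- category_summary(tmr, catsr)
  expect_equal(
    sr$median_auc[sr$category == "a"],
    stats::median(tmr$auc[1:6])
  )
})

test_that("fraction of real annotations counts evaluated hits over full truth", {
  # truth {A,B,C}, eval over {A,B}, both predicted -> 2/3
  P <- matrix(c(1, 1), 1, dimnames = list("p1", c("A", "B")))
  truth <- annotation_set(
    tibble::tibble(protein = "p1", term = c("A", "B", "C")),
    propagated = TRUE
  )
  fr <- fraction_real_annotations_predicted(P, truth, tau = 0.5)
  expect_equal(fr$per_protein$fraction, 2 / 3)

  # truth within eval terms and perfect predictions -> 1
  truth2 <- annotation_set(
    tibble::tibble(protein = "p1", term = c("A", "B")),
    propagated = TRUE
  )
  expect_equal(
    fraction_real_annotations_predicted(P, truth2, 0.5)$per_protein$fraction,
    1
  )

  # random instances against set arithmetic
  for (seed in 1:5) {
    inst <- random_instance(8L, 6L, seed + 90)
    eval_terms <- inst$terms[1:4]
    fr <- fraction_real_annotations_predicted(
      inst$P[, eval_terms], inst$truth, 0.5
    )
    true_sets <- split(inst$truth$term, inst$truth$protein)
    for (i in seq_len(nrow(fr$per_protein))) {
      p <- fr$per_protein$protein[i]
      pred <- eval_terms[inst$P[p, eval_terms] >= 0.5]
      expect_equal(
        fr$per_protein$fraction[i],
        length(intersect(pred, true_sets[[p]])) / length(unique(true_sets[[p]]))
      )
    }
  }
})

test_that("depth-distribution comparison: chi-square with low-count merging", {
  edges <- random_dag_edges(25L, 31)
  dag <- ontology_dag(edges)
  set.seed(32)
  base <- sample(dag$terms, 20L)
  # identical term sets -> statistic 0, p = 1
  out <- compare_depth_distributions(list(a = base, b = base), dag)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)

  expect_error(compare_depth_distributions(list(a = base), dag), "at least 2")

  # disjoint depth supports give a large statistic
  d <- term_depth(dag, dag$terms)
  shallow <- names(d)[d <= 1]
  deep <- names(d)[d >= 2]
  if (length(shallow) >= 3 && length(deep) >= 3) {
    out2 <- compare_depth_distributions(
      list(
        a = rep(shallow, length.out = 30),
        b = rep(deep, length.out = 30)
      ),
      dag
    )
    expect_lt(out2$p_value, 1e-6)
  }

  # textbook oracle on the merged table
  sets <- list(
    a = sample(dag$terms, 40L, replace = TRUE),
    b = sample(dag$terms, 40L, replace = TRUE)
  )
  out3 <- compare_depth_distributions(sets, dag)
  tab <- out3$table
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(out3$statistic, sum((tab - E)^2 / E), tolerance = 1e-9)
  expect_true(all(E >= 5) || ncol(tab) == 2L)
})
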