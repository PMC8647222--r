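#' Synthetic world configuration
#'
#' Parameters of the synthetic data generator. A world consists of a rooted
#' term DAG, protein families as clusters in a d-dimensional embedding
#' space, per-family functional annotations closed under the true-path
#' rule, several "species" whose proteins are divergence-parameterized
#' perturbations of the family prototypes, InterPro-like structural
#' features, and homology hit tables whose identities decay with
#' divergence.
#'
#' Geometry is hierarchical: each ontology term has an anchor point placed
#' at its primary parent's anchor plus a random offset whose length shrinks
#' with depth, and each family prototype sits near the anchor of its
#' primary (deepest) term. Functionally related proteins therefore cluster,
#' and clusters of related function are themselves close — the structure
#' the embedding-based predictor assumes. A minimum pairwise prototype
#' distance of `family_sep` noise standard deviations is enforced, so
#' `family_sep = 6` gives 6-sigma family separation.
#'
#' @param seed Master seed; the world is a deterministic function of it.
#' @param n_terms Number of non-root terms.
#' @param max_depth Maximum term depth.
#' @param n_families Number of protein families.
#' @param d Embedding width.
#' @param species Tibble with columns `name`, `delta` (divergence >= 0)
#'   and `n_proteins`. Exactly one species must be the training species
#'   (named by `train_species`) with `delta = 0`.
#' @param train_species Name of the training species.
#' @param split_fractions Train/validation/test fractions for the training
#'   species.
#' @param length_range Protein length bounds (inclusive); lengths are drawn
#'   log-uniformly so all deciles are populated.
#' @param beta Length-signal amplitude: each protein's normalized
#'   log-length activates one of `n_length_coords` Gaussian bumps added to
#'   the leading embedding coordinates. `beta = 0` makes embeddings
#'   length-blind. The default is calibrated against the structural spread
#'   of a coordinate (about 5 noise units under the default geometry), so
#'   the length code is strong, as observed for real protein language
#'   models.
#' @param n_length_coords Number of leading coordinates carrying the
#'   length signal.
#' @param noise_sd Within-family embedding noise standard deviation.
#' @param family_sep Minimum pairwise distance between family prototypes,
#'   in units of `noise_sd`.
#' @param drift_scale Norm of the per-(family, species) drift vector at
#'   `delta = 1`, as a fraction of `family_sep` (divergence is modeled in
#'   embedding space; the drift is a fixed random direction so divergence
#'   is systematic, not pure noise).
#' @param attenuation Fraction of the family signature lost at
#'   `delta = 1`: embeddings of a species at divergence delta sit at
#'   `(1 - attenuation * delta)` times the prototype, modeling the decay
#'   of embedding similarity toward the population mean as sequences
#'   diverge. This is what makes prediction genuinely harder for distant
#'   species.
#' @param second_term_prob Probability a family carries a second direct
#'   term (drawn from the same top-level branch, keeping term clusters
#'   geometrically coherent).
#' @param annotation_dropout Per-record probability that a direct
#'   annotation is missing from a protein (at least one is always kept).
#' @param label_noise Probability of one spurious extra term per protein.
#' @param tightness_range Range of the per-family noise multiplier; values
#'   above 1 loosen a family (more embedding noise, fewer and noisier
#'   structural features), driving the family-tightness experiments.
#' @param ip_dropout_rate Per-feature dropout slope versus the tightness
#'   multiplier.
#' @param ip_spurious_rate Per-protein spurious-feature slope versus the
#'   tightness multiplier.
#' @param max_hits Maximum number of true (same-family) homology hits per
#'   query.
#' @param align_base Probability that the aligner detects a query's true
#'   family at `delta = 0`. Alignment-based homology search misses some
#'   families even within a species; embeddings are not subject to this
#'   failure mode, which is the transfer advantage the pipeline measures.
#' @param hit_retention_decay Alignment sensitivity decays with
#'   divergence: the true family is found with probability
#'   `align_base * exp(-hit_retention_decay * delta)`. When it is missed,
#'   only spurious hits (if any) remain.
#' @param spurious_base,spurious_slope Expected number of spurious hits
#'   (remote homologs from other families, carrying unrelated functions) is
#'   `spurious_base + spurious_slope * delta`.
#' @param identity_decay Identity of true hits is
#'   `100 * exp(-identity_decay * delta)` percent before noise; the default
#'   puts `delta = 1` at the ~30% "twilight zone" boundary.
#' @param identity_noise_sd Gaussian noise on hit identities (percent).
#' @return A list of class `world_config`.
#' @export
world_config <- function(seed = 1L,
                         n_terms = 120L, max_depth = 4L,
                         n_families = 40L, d = 16L,
                         species = NULL,
                         train_species = "train",
                         split_fractions = c(train = 0.7, val = 0.15, test = 0.15),
                         length_range = c(40L, 1000L),
                         beta = 16, n_length_coords = 10L,
                         noise_sd = 1, family_sep = 6,
                         drift_scale = 0.7,
                         attenuation = 0.6,
                         second_term_prob = 0.25,
                         annotation_dropout = 0.1,
                         label_noise = 0.02,
                         tightness_range = c(0.8, 2.5),
                         ip_dropout_rate = 0.12,
                         ip_spurious_rate = 0.08,
                         max_hits = 8L,
                         align_base = 0.75,
                         hit_retention_decay = 1.5,
                         spurious_base = 1.5,
                         spurious_slope = 4,
                         identity_decay = log(100 / 30),
                         identity_noise_sd = 3) {
  if (is.null(species)) {
    species <- tibble::tibble(
      name = c("train", "sp25", "sp50", "sp75", "sp100"),
      delta = c(0, 0.25, 0.5, 0.75, 1),
      n_proteins = c(1000L, 200L, 200L, 200L, 200L)
    )
  }
  species <- tibble::as_tibble(species)
  stopifnot(all(c("name", "delta", "n_proteins") %in% names(species)))
  if (any(species$delta < 0)) stop("divergence delta must be >= 0")
  if (!train_species %in% species$name) {
    stop("train_species '", train_species, "' not among species")
  }
  if (species$delta[species$name == train_species] != 0) {
    stop("the training species must have delta = 0")
  }
  if (annotation_dropout < 0 || annotation_dropout >= 1) {
    stop("annotation_dropout must lie in [0, 1)")
  }
  if (label_noise < 0 || label_noise >= 1) stop("label_noise must lie in [0, 1)")
  if (n_families > sum(species$n_proteins)) {
    stop("infeasible config: more families than proteins")
  }
  if (n_terms < max_depth + 1L) {
    stop("infeasible config: n_terms too small for max_depth")
  }
  structure(
    list(
      seed = as.integer(seed), n_terms = as.integer(n_terms),
      max_depth = as.integer(max_depth),
      n_families = as.integer(n_families), d = as.integer(d),
      species = species, train_species = train_species,
      split_fractions = split_fractions,
      length_range = as.integer(length_range),
      beta = beta, n_length_coords = as.integer(n_length_coords),
      noise_sd = noise_sd, family_sep = family_sep,
      drift_scale = drift_scale,
      attenuation = attenuation,
      second_term_prob = second_term_prob,
      annotation_dropout = annotation_dropout, label_noise = label_noise,
      tightness_range = tightness_range,
      ip_dropout_rate = ip_dropout_rate,
      ip_spurious_rate = ip_spurious_rate,
      max_hits = as.integer(max_hits),
      align_base = align_base,
      hit_retention_decay = hit_retention_decay,
      spurious_base = spurious_base, spurious_slope = spurious_slope,
      identity_decay = identity_decay,
      identity_noise_sd = identity_noise_sd
    ),
    class = "world_config"
  )
}

rand_unit <- function(d) {
  v <- stats::rnorm(d)
  v / sqrt(sum(v^2))
}

# random rooted DAG with fixed longest-path depths:
# each term's primary parent sits one level up (preferential attachment,
# so some terms accumulate many children), optional extra parents sit at
# any shallower level.
make_dag <- function(n_terms, max_depth) {
  n_per_depth <- round(n_terms * seq_len(max_depth) / sum(seq_len(max_depth)))
  n_per_depth[max_depth] <- n_terms - sum(n_per_depth[-max_depth])
  ids <- sprintf("MF:%04d", seq_len(n_terms))
  root <- "MF:0000"
  depth_of <- rep(seq_len(max_depth), times = n_per_depth)
  by_depth <- split(ids, depth_of)
  child_count <- stats::setNames(numeric(n_terms + 1L), c(root, ids))
  primary <- character(n_terms)
  names(primary) <- ids
  extra_child <- character(0)
  extra_parent <- character(0)
  for (q in seq_len(max_depth)) {
    pool <- if (q == 1L) root else by_depth[[q - 1L]]
    for (t in by_depth[[q]]) {
      w <- child_count[pool] + 0.5
      p <- if (length(pool) == 1L) pool else sample(pool, 1L, prob = w)
      primary[[t]] <- p
      child_count[[p]] <- child_count[[p]] + 1
      if (q > 1L && stats::runif(1) < 0.25) {
        shallow <- unlist(by_depth[seq_len(q - 1L)], use.names = FALSE)
        shallow <- setdiff(shallow, p)
        if (length(shallow) > 0L) {
          ep <- if (length(shallow) == 1L) shallow else sample(shallow, 1L)
          extra_child <- c(extra_child, t)
          extra_parent <- c(extra_parent, ep)
        }
      }
    }
  }
  edges <- tibble::tibble(
    child = c(ids, extra_child),
    parent = c(unname(primary), extra_parent),
    relation = "is_a"
  )
  list(
    dag = ontology_dag(edges, namespace = "molecular_function"),
    primary = primary, by_depth = by_depth, root = root
  )
}

#' Generate a synthetic world
#'
#' Builds a complete seed-deterministic world from a [world_config()]: the
#' ontology, family prototypes and their term annotations, per-species
#' proteins with embeddings, annotations, InterPro-like features, a
#' stratified split of the training species, and homology hit tables for
#' every non-training protein against the training split.
#'
#' @param cfg A [world_config()].
#' @return A list of class `synthetic_world` with elements `cfg`, `dag`,
#'   `prototypes`, `family_terms`, `tightness`, `proteins` (tibble),
#'   `embeddings` (per-species [embedding_store()]), `annotations`
#'   (per-species direct [annotation_set()]), `truth` (per-species
#'   propagated sets), `interpro`, `split` (training-species split tibble)
#'   and `hits` (per-species hit tables against the training split).
#' @export
generate_world <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
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

  # --- ontology -------------------------------------------------------
  built <- make_dag(cfg$n_terms, cfg$max_depth)
  dag <- built$dag
  nonroot <- setdiff(dag$terms, dag$root)

  # --- term anchors (hierarchical geometry) ---------------------------
  sep <- cfg$family_sep * cfg$noise_sd
  branch_scale <- 3 * sep * 0.6^(seq_len(cfg$max_depth) - 1L)
  anchors <- matrix(0, nrow = length(dag$terms), ncol = cfg$d,
    dimnames = list(dag$terms, NULL)
  )
  for (t in dag$terms[order(dag$depth)]) {
    if (t == dag$root) next
    p <- built$primary[[t]]
    anchors[t, ] <- anchors[p, ] +
      branch_scale[dag$depth[[t]]] * rand_unit(cfg$d)
  }

  # --- families -------------------------------------------------------
  # primary term: deeper terms preferred; second term from same top branch
  deep_terms <- nonroot[dag$depth[nonroot] >= min(2L, cfg$max_depth)]
  w <- dag$depth[deep_terms]^2
  fam_primary <- sample(deep_terms, cfg$n_families, replace = TRUE, prob = w)
  top_branch <- vapply(dag$terms, function(t) {
    while (t != built$root && !identical(built$primary[[t]], built$root)) {
      t <- built$primary[[t]]
    }
    t
  }, character(1L))
  family_terms <- vector("list", cfg$n_families)
  for (f in seq_len(cfg$n_families)) {
    terms_f <- fam_primary[f]
    if (stats::runif(1) < cfg$second_term_prob) {
      same_branch <- deep_terms[
        top_branch[deep_terms] == top_branch[fam_primary[f]]
      ]
      cand <- setdiff(same_branch, terms_f)
      if (length(cand) > 0L) {
        extra <- if (length(cand) == 1L) cand else sample(cand, 1L)
        terms_f <- c(terms_f, extra)
      }
    }
    family_terms[[f]] <- terms_f
  }

  prototypes <- anchors[fam_primary, , drop = FALSE] +
    sep * t(vapply(seq_len(cfg$n_families), function(f) rand_unit(cfg$d),
      numeric(cfg$d)
    ))
  rownames(prototypes) <- paste0("F", seq_len(cfg$n_families))
  # enforce the minimum pairwise separation by redrawing offenders
  for (iter in seq_len(500L)) {
    dd <- as.matrix(stats::dist(prototypes))
    diag(dd) <- Inf
    bad <- which(dd < sep, arr.ind = TRUE)
    if (nrow(bad) == 0L) break
    f <- bad[1L, 1L]
    prototypes[f, ] <- anchors[fam_primary[f], ] +
      sep * (1 + stats::runif(1)) * rand_unit(cfg$d)
    if (iter == 500L) {
      stop("infeasible config: cannot separate family prototypes")
    }
  }

  tightness <- stats::runif(
    cfg$n_families, cfg$tightness_range[1L], cfg$tightness_range[2L]
  )

  # --- InterPro-like family features ----------------------------------
  domain_pool <- sprintf("IPRD%04d", seq_len(ceiling(1.3 * cfg$n_families)))
  superfam_pool <- sprintf("IPRS%04d", seq_len(max(3L, cfg$n_families %/% 3L)))
  fam_features <- lapply(seq_len(cfg$n_families), function(f) {
    list(
      domain = sample(domain_pool, sample(1:2, 1L)),
      family = sprintf("IPRF%04d", f),
      superfamily = sample(superfam_pool, 1L)
    )
  })

  # --- per-species drift directions -----------------------------------
  drift <- lapply(seq_len(nrow(cfg$species)), function(i) {
    m <- t(vapply(seq_len(cfg$n_families), function(f) rand_unit(cfg$d),
      numeric(cfg$d)
    ))
    m * (cfg$drift_scale * sep)
  })
  names(drift) <- cfg$species$name

  # --- proteins, embeddings, annotations, features --------------------
  lmin <- cfg$length_range[1L]
  lmax <- cfg$length_range[2L]
  bump_centers <- (seq_len(cfg$n_length_coords) - 0.5) / cfg$n_length_coords
  bump_sd <- 0.45 / cfg$n_length_coords

  proteins <- list()
  embeddings <- list()
  annotations <- list()
  interpro_rows <- list()

  for (i in seq_len(nrow(cfg$species))) {
    sp <- cfg$species$name[i]
    delta <- cfg$species$delta[i]
    n <- cfg$species$n_proteins[i]
    fams <- if (sp == cfg$train_species && n >= cfg$n_families) {
      # guarantee every family is represented in the training species
      c(seq_len(cfg$n_families), sample.int(cfg$n_families,
        n - cfg$n_families,
        replace = TRUE
      ))
    } else {
      sample.int(cfg$n_families, n, replace = TRUE)
    }
    ids <- sprintf("%s_P%05d", sp, seq_len(n))
    lens <- pmin(pmax(round(exp(stats::runif(n, log(lmin), log(lmax)))), lmin), lmax)
    lz <- (log(lens) - log(lmin)) / (log(lmax) - log(lmin))

    E <- (1 - cfg$attenuation * delta) * prototypes[fams, , drop = FALSE] +
      delta * drift[[sp]][fams, , drop = FALSE] +
      matrix(stats::rnorm(n * cfg$d), n, cfg$d) *
        (cfg$noise_sd * tightness[fams])
    if (cfg$beta > 0) {
      bumps <- cfg$beta * exp(-outer(lz, bump_centers, "-")^2 / (2 * bump_sd^2))
      E[, seq_len(cfg$n_length_coords)] <-
        E[, seq_len(cfg$n_length_coords)] + bumps
    }
    rownames(E) <- ids

    ann_p <- character(0)
    ann_t <- character(0)
    for (j in seq_len(n)) {
      direct <- family_terms[[fams[j]]]
      keep <- stats::runif(length(direct)) >= cfg$annotation_dropout
      if (!any(keep)) keep[sample.int(length(direct), 1L)] <- TRUE
      terms_j <- direct[keep]
      if (stats::runif(1) < cfg$label_noise) {
        terms_j <- unique(c(terms_j, sample(nonroot, 1L)))
      }
      ann_p <- c(ann_p, rep(ids[j], length(terms_j)))
      ann_t <- c(ann_t, terms_j)
    }

    ip_p <- character(0)
    ip_a <- character(0)
    ip_k <- character(0)
    for (j in seq_len(n)) {
      ff <- fam_features[[fams[j]]]
      m_f <- tightness[fams[j]]
      p_keep <- min(max(1 - cfg$ip_dropout_rate * m_f, 0.05), 1)
      for (k in c("domain", "family", "superfamily")) {
        kept <- ff[[k]][stats::runif(length(ff[[k]])) < p_keep]
        if (length(kept) > 0L) {
          ip_p <- c(ip_p, rep(ids[j], length(kept)))
          ip_a <- c(ip_a, kept)
          ip_k <- c(ip_k, rep(k, length(kept)))
        }
      }
      if (stats::runif(1) < cfg$ip_spurious_rate * m_f) {
        ip_p <- c(ip_p, ids[j])
        ip_a <- c(ip_a, sample(domain_pool, 1L))
        ip_k <- c(ip_k, "domain")
      }
    }

    proteins[[sp]] <- tibble::tibble(
      protein = ids, species = sp, family = fams, length = lens
    )
    embeddings[[sp]] <- embedding_store(E, source = paste0("synthetic:", sp))
    annotations[[sp]] <- annotation_set(
      tibble::tibble(protein = ann_p, term = ann_t, evidence = "EXP"),
      propagated = FALSE
    )
    interpro_rows[[sp]] <- tibble::tibble(
      protein = ip_p, accession = ip_a, kind = ip_k
    )
  }

  truth <- lapply(annotations, function(a) propagate_annotations(dag, a))

  split_tbl <- stratified_multilabel_split(
    annotations[[cfg$train_species]],
    fractions = cfg$split_fractions,
    seed = cfg$seed + 1L,
    proteins = proteins[[cfg$train_species]]$protein
  )

  # --- homology hit tables against the training split -----------------
  train_tbl <- proteins[[cfg$train_species]]
  subjects_split <- split_tbl$protein[split_tbl$split == "train"]
  subj_tbl <- train_tbl[train_tbl$protein %in% subjects_split, ]
  subj_by_family <- split(subj_tbl$protein, subj_tbl$family)

  hits <- list()
  for (i in seq_len(nrow(cfg$species))) {
    sp <- cfg$species$name[i]
    delta <- cfg$species$delta[i]
    ptab <- proteins[[sp]]
    if (sp == cfg$train_species) {
      ptab <- ptab[
        ptab$protein %in% split_tbl$protein[split_tbl$split != "train"], ,
        drop = FALSE
      ]
    }
    rows <- vector("list", nrow(ptab))
    p_align <- cfg$align_base * exp(-cfg$hit_retention_decay * delta)
    mu_spur <- cfg$spurious_base + cfg$spurious_slope * delta
    id_true <- 100 * exp(-cfg$identity_decay * delta)
    for (j in seq_len(nrow(ptab))) {
      q <- ptab$protein[j]
      qlen <- ptab$length[j]
      fam_subj <- subj_by_family[[as.character(ptab$family[j])]]
      if (is.null(fam_subj)) fam_subj <- character(0)
      # the aligner either detects the family (and returns most of its
      # training members) or misses it entirely
      if (stats::runif(1) < p_align) {
        fam_subj <- fam_subj[stats::runif(length(fam_subj)) < 0.9]
        if (length(fam_subj) > cfg$max_hits) {
          fam_subj <- sample(fam_subj, cfg$max_hits)
        }
      } else {
        fam_subj <- character(0)
      }
      n_spur <- stats::rpois(1L, mu_spur)
      spur_pool <- setdiff(subj_tbl$protein, c(fam_subj, q))
      spur <- if (n_spur > 0L && length(spur_pool) > 0L) {
        sample(spur_pool, min(n_spur, length(spur_pool)))
      } else {
        character(0)
      }
      subj <- c(fam_subj, spur)
      if (length(subj) == 0L) next
      ident <- c(
        pmin(pmax(id_true + stats::rnorm(
          length(fam_subj), 0, cfg$identity_noise_sd
        ), 1), 100),
        stats::runif(length(spur), 15, 30)
      )
      bits <- 2 * ident + stats::rnorm(length(subj), 0, 1)
      alen <- pmax(round(qlen * stats::runif(length(subj), 0.8, 1)), 10L)
      rows[[j]] <- tibble::tibble(
        query = q, subject = subj, pident = round(ident, 1),
        length = alen,
        mismatch = pmax(round(alen * (1 - ident / 100)), 0L),
        gapopen = 0L, qstart = 1L, qend = alen, sstart = 1L, send = alen,
        evalue = signif(10^(-bits / 10), 3), bitscore = round(bits, 1)
      )
    }
    hits[[sp]] <- dplyr::bind_rows(rows)
  }

  structure(
    list(
      cfg = cfg, dag = dag,
      prototypes = prototypes,
      family_terms = family_terms, tightness = tightness,
      fam_features = fam_features,
      proteins = dplyr::bind_rows(proteins),
      embeddings = embeddings,
      annotations = annotations, truth = truth,
      interpro = dplyr::bind_rows(interpro_rows),
      split = split_tbl, hits = hits
    ),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> seed %d: %d terms (depth <= %d), %d families, %d proteins in %d species (d = %d)\n",
    x$cfg$seed, length(x$dag$terms) - 1L, max(x$dag$depth),
    x$cfg$n_families, nrow(x$proteins), nrow(x$cfg$species), x$cfg$d
  ))
  invisible(x)
}

#' Restrict a world to a subset of species
#'
#' @param world A `synthetic_world`.
#' @param species Species names to keep (the training species is always
#'   kept).
#' @return A `synthetic_world` containing only those species.
#' @export
world_subset <- function(world, species) {
  species <- union(world$cfg$train_species, species)
  w <- world
  keep <- w$cfg$species$name %in% species
  w$cfg$species <- w$cfg$species[keep, ]
  w$proteins <- w$proteins[w$proteins$species %in% species, ]
  for (f in c("embeddings", "annotations", "truth", "hits")) {
    w[[f]] <- w[[f]][intersect(names(w[[f]]), species)]
  }
  w$interpro <- w$interpro[
    w$interpro$protein %in% w$proteins$protein, ,
    drop = FALSE
  ]
  w
}

#' Divergence sweep: one world per divergence level
#'
#' Generates a single master world containing the training species plus
#' one test species per divergence value, then returns per-divergence
#' world views. All views share the training species (same ontology,
#' prototypes, proteins and split), so differences between them are due to
#' divergence alone; hit identity distributions are stochastically ordered
#' by delta.
#'
#' @param cfg A [world_config()]; its `species` entry is replaced.
#' @param deltas Ascending divergence values; the first must be 0 (it
#'   becomes an independent test species at the training divergence).
#' @param n_proteins Number of proteins per sweep species.
#' @param n_train Number of proteins in the training species.
#' @return Named list (by delta) of `synthetic_world` views.
#' @export
divergence_sweep <- function(cfg, deltas = c(0, 0.25, 0.5, 0.75, 1),
                             n_proteins = 200L, n_train = 1000L) {
  stopifnot(inherits(cfg, "world_config"))
  if (is.unsorted(deltas)) stop("deltas must be ascending")
  if (deltas[1L] != 0) stop("the first delta must be 0")
  names <- sprintf("sweep_d%03d", round(100 * deltas))
  cfg$species <- tibble::tibble(
    name = c(cfg$train_species, names),
    delta = c(0, deltas),
    n_proteins = c(as.integer(n_train), rep(as.integer(n_proteins), length(deltas)))
  )
  master <- generate_world(cfg)
  out <- lapply(names, function(nm) world_subset(master, nm))
  names(out) <- as.character(deltas)
  out
}

#' Write a synthetic world to plain-text files
#'
#' Emits the OBO ontology, one annotation TSV and one embedding TSV per
#' species, the InterPro TSV, one hit TSV per species (BLAST outfmt 6
#' layout), the protein table, the training-species split, and a JSON
#' manifest holding the full configuration (including the seed), from
#' which the world can be regenerated exactly.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory; must not already contain files unless
#'   `force = TRUE`.
#' @param force Overwrite an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
    stop("directory ", dir, " is not empty (use force = TRUE)")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dag <- world$dag
  obo <- c(
    "format-version: 1.2",
    ""
  )
  for (t in dag$terms) {
    obo <- c(
      obo, "[Term]", paste0("id: ", t), paste0("name: term ", t),
      paste0("namespace: ", dag$namespace),
      paste0("is_a: ", dag$parents[[t]]), ""
    )
  }
  writeLines(obo, file.path(dir, "ontology.obo"))
  for (sp in names(world$annotations)) {
    utils::write.table(
      tibble::as_tibble(world$annotations[[sp]]),
      file.path(dir, paste0("annotations_", sp, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
    write_embeddings(
      world$embeddings[[sp]],
      file.path(dir, paste0("embeddings_", sp, ".tsv")),
      format = "tsv"
    )
    if (!is.null(world$hits[[sp]]) && nrow(world$hits[[sp]]) > 0L) {
      write_hit_table(
        world$hits[[sp]],
        file.path(dir, paste0("hits_", sp, ".tsv"))
      )
    }
  }
  utils::write.table(
    world$interpro, file.path(dir, "interpro.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    world$proteins, file.path(dir, "proteins.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    world$split, file.path(dir, "split.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  cfg <- world$cfg
  cfg$species <- as.data.frame(cfg$species)
  jsonlite::write_json(
    unclass(cfg), file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a synthetic world back from files
#'
#' Reads the files produced by [write_world()]. The returned object holds
#' the re-parsed data; `regenerate = TRUE` instead rebuilds the world from
#' the manifest configuration via [generate_world()] (bit-identical to the
#' original).
#'
#' @param dir Directory written by [write_world()].
#' @param regenerate Rebuild from the manifest seed instead of reading the
#'   data files.
#' @return A `synthetic_world` (regenerated) or a list of parsed
#'   components (`dag`, `annotations`, `embeddings`, `hits`, `interpro`,
#'   `proteins`, `split`, `cfg`).
#' @export
read_world <- function(dir, regenerate = FALSE) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
    simplifyVector = TRUE
  )
  manifest$species <- tibble::as_tibble(manifest$species)
  manifest$split_fractions <- unlist(manifest$split_fractions)
  cfg <- do.call(world_config, manifest)
  if (regenerate) return(generate_world(cfg))
  dag <- parse_obo(file.path(dir, "ontology.obo"),
    namespace = "molecular_function"
  )
  sps <- cfg$species$name
  ann <- lapply(sps, function(sp) {
    read_annotations(file.path(dir, paste0("annotations_", sp, ".tsv")))
  })
  names(ann) <- sps
  emb <- lapply(sps, function(sp) {
    read_embeddings(file.path(dir, paste0("embeddings_", sp, ".tsv")))
  })
  names(emb) <- sps
  hits <- list()
  for (sp in sps) {
    f <- file.path(dir, paste0("hits_", sp, ".tsv"))
    if (file.exists(f)) hits[[sp]] <- read_hit_table(f)
  }
  proteins <- tibble::as_tibble(utils::read.table(
    file.path(dir, "proteins.tsv"),
    header = TRUE, sep = "\t",
    colClasses = c("character", "character", "integer", "integer")
  ))
  split <- tibble::as_tibble(utils::read.table(
    file.path(dir, "split.tsv"),
    header = TRUE, sep = "\t", colClasses = "character"
  ))
  split$split <- factor(split$split, levels = names(cfg$split_fractions))
  list(
    cfg = cfg, dag = dag, annotations = ann, embeddings = emb,
    hits = hits, interpro = read_interpro(file.path(dir, "interpro.tsv")),
    proteins = proteins, split = split
  )
}
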