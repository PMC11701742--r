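#' Fixture specification
#'
#' Parameters of the synthetic-data generator that stands in for the external
#' resources the annotation pipeline normally consumes (curated region
#' databases, language-model embeddings, predictor tracks). Defaults describe
#' a well-posed transfer problem: 20 leaf-term clusters in a 16-dimensional
#' embedding space separated by ten within-cluster standard deviations, 30
#' reference regions per term and 200 queries, five vote tracks at 80%
#' per-residue agreement, and a nu mixture placed around the published
#' compaction thresholds with weights matching the reported proteome
#' fractions (2% compact-side, 45% expanded-side).
#'
#' @param seed integer seed; identical specs generate identical fixtures.
#' @param dim embedding dimension (16 for tests; 1024 matches production
#'   language-model embeddings).
#' @param dag_depth,dag_branching per-namespace ontology DAG shape: depth
#'   levels, each non-root level multiplying terms by the branching factor.
#' @param n_cross_links extra random is_a edges toward strictly shallower
#'   levels (acyclicity is preserved by construction).
#' @param namespace namespace of the generated ontology/annotations.
#' @param n_terms number of leaf terms given embedding clusters.
#' @param n_reference_per_term reference regions per planted term.
#' @param n_query_regions number of query regions.
#' @param cluster_separation distance between cluster centres in units of the
#'   within-cluster spread `noise_sd`; 0 makes terms exchangeable.
#' @param noise_sd within-cluster standard deviation per dimension.
#' @param n_track_proteins,n_tracks,track_length,track_density vote-track
#'   generation: proteins, sources per protein, residues, and the Bernoulli
#'   rate of the hidden true track.
#' @param agreement probability a source copies the hidden call at a residue
#'   (it flips otherwise).
#' @param coverage probability a source covers a residue (else no-coverage).
#' @param n_nu_regions rows of the generated nu table.
#' @param nu_means,nu_sds,nu_weights Gaussian mixture for nu sampling;
#'   weights must sum to 1.
#' @param nu_len_range region-length range for nu rows; the default straddles
#'   the 30-residue labeling gate.
#' @return an `idr_fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, dim = 16L,
                         dag_depth = 3L, dag_branching = 5L,
                         n_cross_links = 3L,
                         namespace = "molecular_function",
                         n_terms = 20L, n_reference_per_term = 30L,
                         n_query_regions = 200L,
                         cluster_separation = 10, noise_sd = 1,
                         n_track_proteins = 3L, n_tracks = 5L,
                         track_length = 200L, track_density = 0.4,
                         agreement = 0.8, coverage = 0.9,
                         n_nu_regions = 200L,
                         nu_means = c(0.44, 0.51, 0.60),
                         nu_sds = c(0.015, 0.012, 0.02),
                         nu_weights = c(0.02, 0.53, 0.45),
                         nu_len_range = c(15L, 120L)) {
  stopifnot(dag_depth >= 1L, dag_branching >= 1L, dim >= 1L,
            cluster_separation >= 0, noise_sd > 0,
            agreement >= 0, agreement <= 1,
            coverage >= 0, coverage <= 1)
  if (abs(sum(nu_weights) - 1) > 1e-9) stop("nu mixture weights must sum to 1")
  if (length(nu_means) != length(nu_sds) ||
      length(nu_means) != length(nu_weights)) {
    stop("nu mixture components must have equal length")
  }
  structure(as.list(environment()), class = "idr_fixture_spec")
}

#' Generate a random ontology DAG
#'
#' One rooted DAG for the spec's namespace: `dag_depth` levels, each term
#' below the root drawing one parent from the previous level, plus
#' `n_cross_links` extra is_a edges from deeper to strictly shallower levels,
#' which keeps the graph acyclic.
#' @param spec an [fixture_spec()].
#' @return an `idr_ontology`.
#' @export
sim_ontology <- function(spec) {
  set.seed(spec$seed + 101L)
  ids <- character(0); level <- integer(0); parents <- list()
  counter <- 0L
  prev <- character(0)
  for (d in seq_len(spec$dag_depth)) {
    n_here <- if (d == 1L) 1L else length(prev) * spec$dag_branching
    here <- sprintf("SYN:%05d", counter + seq_len(n_here))
    counter <- counter + n_here
    if (d > 1L) {
      for (i in seq_along(here)) {
        parents[[here[[i]]]] <- prev[[((i - 1L) %% length(prev)) + 1L]]
      }
    }
    ids <- c(ids, here); level <- c(level, rep(d, n_here))
    prev <- here
  }
  if (spec$n_cross_links > 0L && spec$dag_depth >= 3L) {
    deep <- ids[level >= 3L]
    for (i in seq_len(spec$n_cross_links)) {
      ch <- sample(deep, 1L)
      shallower <- ids[level < level[match(ch, ids)] & level > 1L]
      if (!length(shallower)) next
      p <- sample(shallower, 1L)
      parents[[ch]] <- unique(c(parents[[ch]], p))
    }
  }
  ontology(data.frame(id = ids,
                      name = paste("synthetic term", ids),
                      namespace = spec$namespace,
                      stringsAsFactors = FALSE),
           parents)
}

.leaves <- function(ont) ont$id[vapply(ont$children, length, 0L) == 0L]

#' Generate clustered region embeddings with planted annotations
#'
#' Each of `n_terms` leaf terms gets an isotropic cluster centre of norm
#' about `cluster_separation * noise_sd` in a random direction; reference and
#' query region embeddings are drawn around their term's centre with spread
#' `noise_sd`. Ground truth for each query is its planted leaf term plus the
#' true-path closure. With `cluster_separation = 0` all centres coincide at
#' the origin-adjacent noise cloud and terms are exchangeable.
#'
#' @param spec an [fixture_spec()].
#' @param ont ontology from [sim_ontology()] (or compatible); needs at least
#'   `n_terms` leaves.
#' @return list with `annotations` (reference table), `reference`
#'   (`idr_region_embedding_set`), `queries` (`idr_region_embedding_set`),
#'   `gold` (named list, region key -> propagated term set), `terms` (the
#'   planted leaves), `query_terms` (planted leaf per query).
#' @export
sim_embeddings <- function(spec, ont) {
  set.seed(spec$seed + 202L)
  leaves <- .leaves(ont)
  if (spec$n_terms > length(leaves)) {
    stop("requested ", spec$n_terms, " leaf terms but the DAG has only ",
         length(leaves))
  }
  terms <- sort(sample(leaves, spec$n_terms))

  centre <- matrix(stats::rnorm(spec$n_terms * spec$dim), spec$n_terms)
  centre <- centre / sqrt(rowSums(centre^2))          # unit directions
  centre <- centre * spec$cluster_separation * spec$noise_sd

  draw <- function(term_idx, prefix) {
    n <- length(term_idx)
    v <- centre[term_idx, , drop = FALSE] +
      matrix(stats::rnorm(n * spec$dim, sd = spec$noise_sd), n)
    # guard the (measure-zero, separation 0) chance of a zero-norm row
    bad <- rowSums(v^2) == 0
    v[bad, 1L] <- spec$noise_sd * 1e-3
    starts <- sample(1:50, n, replace = TRUE)
    lens <- sample(30:79, n, replace = TRUE)
    regions <- data.frame(accession = sprintf("%s%05d", prefix, seq_len(n)),
                          start = starts, end = starts + lens - 1L,
                          stringsAsFactors = FALSE)
    region_embedding_set(regions, v)
  }

  ref_idx <- rep(seq_len(spec$n_terms), each = spec$n_reference_per_term)
  reference <- draw(ref_idx, "REF")
  annotations <- data.frame(accession = reference$regions$accession,
                            start = reference$regions$start,
                            end = reference$regions$end,
                            term = terms[ref_idx],
                            namespace = spec$namespace,
                            stringsAsFactors = FALSE)

  qry_idx <- sample(seq_len(spec$n_terms), spec$n_query_regions, replace = TRUE)
  queries <- draw(qry_idx, "QRY")
  gold <- stats::setNames(
    lapply(qry_idx, function(i) propagate_true_path(terms[[i]], ont)),
    queries$keys)

  list(annotations = annotations, reference = reference, queries = queries,
       gold = gold, terms = terms, query_terms = terms[qry_idx])
}

#' Expand pooled region embeddings into per-residue matrices
#'
#' For exercising [pool_region()] end-to-end: each region's residues get the
#' planted vector plus zero-column-mean perturbations, so the mean over the
#' region reproduces the pooled vector exactly (up to floating point);
#' residues outside the region get independent noise.
#'
#' @param set an `idr_region_embedding_set` (one region per accession).
#' @param spec an [fixture_spec()] (for `noise_sd` and the seed).
#' @param tail extra residues appended after each region's end.
#' @return named list of `idr_residue_embeddings` keyed by accession.
#' @export
sim_residue_matrices <- function(set, spec, tail = 5L) {
  set.seed(spec$seed + 303L)
  out <- lapply(seq_len(nrow(set$regions)), function(i) {
    acc <- set$regions$accession[[i]]
    s <- set$regions$start[[i]]; e <- set$regions$end[[i]]
    L <- e + tail
    m <- matrix(stats::rnorm(L * ncol(set$vectors), sd = spec$noise_sd), L)
    len <- e - s + 1L
    pert <- matrix(stats::rnorm(len * ncol(set$vectors),
                                sd = spec$noise_sd / 4), len)
    pert <- sweep(pert, 2L, colMeans(pert))   # zero column means
    m[s:e, ] <- matrix(set$vectors[i, ], len, ncol(set$vectors),
                       byrow = TRUE) + pert
    residue_embeddings(acc, m)
  })
  stats::setNames(out, set$regions$accession)
}

#' Generate vote tracks with a known hidden consensus
#'
#' For each protein a hidden binary track is sampled at `track_density`; each
#' source copies the hidden call with probability `agreement` (flips
#' otherwise) and covers each residue with probability `coverage`.
#'
#' @param spec an [fixture_spec()].
#' @return list with `tracks` (flat list of `idr_track`), `truth` (named list
#'   of hidden 0/1 vectors per accession).
#' @export
sim_tracks <- function(spec) {
  set.seed(spec$seed + 404L)
  tracks <- list(); truth <- list()
  for (p in seq_len(spec$n_track_proteins)) {
    acc <- sprintf("TRK%05d", p)
    hidden <- stats::rbinom(spec$track_length, 1L, spec$track_density)
    truth[[acc]] <- hidden
    for (s in seq_len(spec$n_tracks)) {
      copy <- stats::rbinom(spec$track_length, 1L, spec$agreement) == 1L
      calls <- ifelse(copy, hidden, 1L - hidden)
      covered <- stats::rbinom(spec$track_length, 1L, spec$coverage) == 1L
      calls[!covered] <- NA_integer_
      tracks[[length(tracks) + 1L]] <-
        disorder_track(acc, sprintf("prediction-disorder-src%d", s), calls)
    }
  }
  list(tracks = tracks, truth = truth)
}

#' Generate a table of apparent Flory scaling exponents
#'
#' nu values are drawn from the spec's Gaussian mixture and region lengths
#' from `nu_len_range` (straddling the 30-residue labeling gate by default).
#' @param spec an [fixture_spec()].
#' @return data.frame with `accession`, `start`, `end`, `nu`.
#' @export
sim_nu_table <- function(spec) {
  set.seed(spec$seed + 505L)
  n <- spec$n_nu_regions
  comp <- sample.int(length(spec$nu_weights), n, replace = TRUE,
                     prob = spec$nu_weights)
  nu <- stats::rnorm(n, spec$nu_means[comp], spec$nu_sds[comp])
  nu <- pmin(pmax(nu, 0.301), 0.799)    # keep inside the plausibility band
  len <- sample(spec$nu_len_range[[1L]]:spec$nu_len_range[[2L]], n,
                replace = TRUE)
  start <- sample(1:50, n, replace = TRUE)
  data.frame(accession = sprintf("NUP%05d", seq_len(n)),
             start = start, end = start + len - 1L, nu = nu,
             component = comp, stringsAsFactors = FALSE)
}

#' Deterministic mock embedder
#'
#' A stand-in for a protein language model: maps (accession, sequence) to an
#' L x D matrix through a fixed trigonometric hash of residue identity and
#' position. Purely synthetic — it carries no biology — but deterministic
#' across platforms, which is what the tests need.
#' @param accession protein identifier (enters the hash).
#' @param sequence amino-acid string.
#' @param dim embedding dimension.
#' @return an `idr_residue_embeddings`.
#' @export
mock_embedder <- function(accession, sequence, dim = 16L) {
  codes <- utf8ToInt(sequence)
  acc_seed <- sum(utf8ToInt(accession) * seq_along(utf8ToInt(accession)))
  L <- length(codes)
  m <- outer(seq_len(L), seq_len(dim), function(i, d) {
    sin(codes[i] * d * 0.1 + i * 0.01 + acc_seed %% 97)
  })
  residue_embeddings(accession, m, sequence)
}

#' Write a full synthetic input bundle to disk
#'
#' Emits everything a from-files pipeline run needs: the ontology (OBO),
#' reference annotations (TSV), reference and query region embeddings (TSV),
#' synthetic protein sequences (FASTA), vote tracks (TSV) and the nu table
#' (TSV), all generated from the spec's seed.
#'
#' @param spec an [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of written paths plus the in-memory
#'   fixture objects.
#' @export
sim_bundle <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ont <- sim_ontology(spec)
  emb <- sim_embeddings(spec, ont)
  trk <- sim_tracks(spec)
  nu <- sim_nu_table(spec)

  paths <- list(
    obo = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "reference_annotations.tsv"),
    reference_embeddings = file.path(dir, "reference_embeddings.tsv"),
    query_embeddings = file.path(dir, "query_embeddings.tsv"),
    gold = file.path(dir, "gold_annotations.tsv"),
    fasta = file.path(dir, "sequences.fasta"),
    tracks = file.path(dir, "tracks.tsv"),
    nu = file.path(dir, "nu.tsv"))

  write_obo(ont, paths$obo)
  write_annotations(emb$annotations, paths$annotations)
  write_region_embeddings(emb$reference, paths$reference_embeddings)
  write_region_embeddings(emb$queries, paths$query_embeddings)
  gold_df <- data.frame(accession = emb$queries$regions$accession,
                        start = emb$queries$regions$start,
                        end = emb$queries$regions$end,
                        term = emb$query_terms,
                        namespace = spec$namespace,
                        stringsAsFactors = FALSE)
  write_annotations(gold_df, paths$gold)

  set.seed(spec$seed + 606L)
  all_regions <- rbind(emb$reference$regions, emb$queries$regions)
  seqs <- vapply(seq_len(nrow(all_regions)), function(i) {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
                 all_regions$end[[i]] + 5L, replace = TRUE), collapse = "")
  }, "")
  aa <- Biostrings::AAStringSet(stats::setNames(seqs, all_regions$accession))
  Biostrings::writeXStringSet(aa, paths$fasta)

  write_tracks(trk$tracks, paths$tracks)
  write_nu_table(nu[c("accession", "start", "end", "nu")], paths$nu)

  invisible(list(paths = paths, ontology = ont, embeddings = emb,
                 tracks = trk, nu = nu))
}
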