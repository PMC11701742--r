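test_that("generated ontologies validate and have the forced term counts", {
  spec <- fixture_spec(seed = 2, dag_depth = 3L, dag_branching = 2L,
                       n_cross_links = 0L)
  ont <- sim_ontology(spec)
  expect_s3_class(ont, "idr_ontology")     # construction ran the validators
  expect_length(ont$id, 1 + 2 + 4)
  expect_length(ont$roots, 1)

  root_only <- sim_ontology(fixture_spec(seed = 2, dag_depth = 1L))
  expect_length(root_only$id, 1)

  # cross-links preserve acyclicity for a range of seeds
  for (s in 1:5) {
    expect_s3_class(sim_ontology(fixture_spec(seed = s, n_cross_links = 10L)),
                    "idr_ontology")
  }
})

test_that("fixtures are bit-identical under a fixed seed", {
  spec <- fixture_spec(seed = 9, n_terms = 5L, n_reference_per_term = 4L,
                       n_query_regions = 10L, n_nu_regions = 20L,
                       track_length = 50L)
  a <- sim_embeddings(spec, sim_ontology(spec))
  b <- sim_embeddings(spec, sim_ontology(spec))
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$reference$vectors, b$reference$vectors)
  expect_identical(a$gold, b$gold)
  expect_identical(sim_tracks(spec), sim_tracks(spec))
  expect_identical(sim_nu_table(spec), sim_nu_table(spec))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sim_bundle(spec, d1); sim_bundle(spec, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f2))))
})

test_that("generated fixtures satisfy the consuming modules' invariants", {
  spec <- fixture_spec(seed = 3, n_terms = 6L, n_reference_per_term = 5L,
                       n_query_regions = 15L)
  ont <- sim_ontology(spec)
  fix <- sim_embeddings(spec, ont)
  expect_true(all(fix$annotations$start >= 1L))
  expect_true(all(fix$annotations$end >= fix$annotations$start))
  expect_true(all(fix$annotations$term %in% ont$id))
  expect_true(all(is.finite(fix$reference$vectors)))
  # gold sets are propagated (closed under ancestors minus roots) and nonempty
  for (g in fix$gold) {
    expect_gt(length(g), 0)
    expect_setequal(propagate_true_path(g, ont), g)
  }
  # the index builds cleanly from the fixture
  expect_s3_class(knn_index(fix$annotations, fix$reference, ont), "idr_knn")
})

test_that("with well-separated clusters the nearest reference shares the planted term", {
  spec <- fixture_spec(seed = 4, cluster_separation = 10, noise_sd = 1,
                       n_query_regions = 500L)
  ont <- sim_ontology(spec)
  fix <- sim_embeddings(spec, ont)
  ref_term <- fix$annotations$term
  qn <- sweep(fix$queries$vectors, 1, sqrt(rowSums(fix$queries$vectors^2)), "/")
  rn <- sweep(fix$reference$vectors, 1, sqrt(rowSums(fix$reference$vectors^2)), "/")
  nearest <- max.col(qn %*% t(rn), ties.method = "first")   # max cosine similarity = min distance
  expect_gte(mean(ref_term[nearest] == fix$query_terms), 0.99)
})

test_that("with separation zero the planted terms are exchangeable", {
  spec <- fixture_spec(seed = 4, cluster_separation = 0, n_query_regions = 300L)
  ont <- sim_ontology(spec)
  fix <- sim_embeddings(spec, ont)
  qn <- sweep(fix$queries$vectors, 1, sqrt(rowSums(fix$queries$vectors^2)), "/")
  rn <- sweep(fix$reference$vectors, 1, sqrt(rowSums(fix$reference$vectors^2)), "/")
  nearest <- max.col(qn %*% t(rn), ties.method = "first")
  acc <- mean(fix$annotations$term[nearest] == fix$query_terms)
  expect_lt(acc, 0.2)  # ~1/20 under exchangeability
})

test_that("per-residue matrices pool back to the planted region vectors", {
  spec <- fixture_spec(seed = 6, n_terms = 4L, n_reference_per_term = 3L,
                       n_query_regions = 5L)
  ont <- sim_ontology(spec)
  fix <- sim_embeddings(spec, ont)
  mats <- sim_residue_matrices(fix$reference, spec)
  pooled <- pool_regions(mats, fix$reference$regions)
  expect_equal(unname(pooled$vectors), unname(fix$reference$vectors),
               tolerance = 1e-10)
})

test_that("track agreement follows the closed-form 3-voter majority probability", {
  # with per-residue copy probability p, majority-of-3 recovers the hidden
  # call with probability p^3 + 3 p^2 (1 - p)
  p <- 0.8
  spec <- fixture_spec(seed = 8, n_track_proteins = 1L, n_tracks = 3L,
                       track_length = 10000L, agreement = p, coverage = 1)
  trk <- sim_tracks(spec)
  vm <- vote_matrix(trk$tracks)
  maj <- consensus(vm, consensus_config("majority"))$calls
  acc <- mean(maj == trk$truth[[1L]])
  expect_equal(acc, p^3 + 3 * p^2 * (1 - p), tolerance = 0.02)

  # perfect agreement, full coverage: every mode recovers the hidden track
  spec1 <- fixture_spec(seed = 8, n_track_proteins = 1L, n_tracks = 3L,
                        track_length = 500L, agreement = 1, coverage = 1)
  trk1 <- sim_tracks(spec1)
  vm1 <- vote_matrix(trk1$tracks)
  for (m in c("merge", "majority", "strict")) {
    expect_identical(consensus(vm1, consensus_config(m))$calls,
                     as.integer(trk1$truth[[1L]]))
  }
})

test_that("fully masked tracks contribute to no vote denominators", {
  spec <- fixture_spec(seed = 8, n_track_proteins = 1L, n_tracks = 2L,
                       track_length = 100L, agreement = 1, coverage = 1)
  trk <- sim_tracks(spec)
  masked <- disorder_track("TRK00001", "masked", rep(NA_integer_, 100L))
  vm_with <- vote_matrix(c(trk$tracks, list(masked)))
  vm_without <- vote_matrix(trk$tracks)
  for (m in c("merge", "majority", "strict")) {
    expect_identical(consensus(vm_with, consensus_config(m))$calls,
                     consensus(vm_without, consensus_config(m))$calls)
  }
})

test_that("nu mixture labels recover the component weights at large n", {
  spec <- fixture_spec(seed = 10, n_nu_regions = 5000L,
                       nu_len_range = c(30L, 80L))  # all past the length gate
  nu <- sim_nu_table(spec)
  lt <- label_table(nu)
  frac <- table(factor(lt$table$label,
                       c("compact", "unlabeled", "expanded"))) / nrow(nu)
  expect_equal(unname(frac[["compact"]]), spec$nu_weights[[1L]], tolerance = 0.03)
  expect_equal(unname(frac[["unlabeled"]]), spec$nu_weights[[2L]], tolerance = 0.03)
  expect_equal(unname(frac[["expanded"]]), spec$nu_weights[[3L]], tolerance = 0.03)
})

test_that("degenerate nu mixtures force a single label", {
  base <- fixture_spec(seed = 11, n_nu_regions = 100L,
                       nu_means = 0.412, nu_sds = 1e-9, nu_weights = 1,
                       nu_len_range = c(30L, 60L))
  expect_true(all(label_table(sim_nu_table(base))$table$label == "compact"))
  mid <- fixture_spec(seed = 11, n_nu_regions = 100L,
                      nu_means = 0.50, nu_sds = 1e-9, nu_weights = 1,
                      nu_len_range = c(30L, 60L))
  expect_true(all(label_table(sim_nu_table(mid))$table$label == "unlabeled"))
})

test_that("the mock embedder is deterministic and sequence-shaped", {
  e1 <- mock_embedder("P1", "MKVLA", dim = 8L)
  e2 <- mock_embedder("P1", "MKVLA", dim = 8L)
  expect_identical(e1$matrix, e2$matrix)
  expect_equal(dim(e1$matrix), c(5L, 8L))
  e3 <- mock_embedder("P2", "MKVLA", dim = 8L)
  expect_false(identical(e1$matrix, e3$matrix))
})
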