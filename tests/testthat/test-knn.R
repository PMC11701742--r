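# shared toy setup: root R with children A, B, C; references annotated with
# leaf terms so propagated sets are {leaf} (root excluded)
knn_toy <- function(distances, terms, dim2 = TRUE) {
  ont <- toy_ontology()
  n <- length(distances)
  regs <- data.frame(accession = sprintf("P%02d", seq_len(n)),
                     start = 1L, end = 10L)
  vecs <- t(vapply(distances, vec_at_distance, numeric(2)))
  ann <- data.frame(accession = regs$accession, start = 1L, end = 10L,
                    term = terms, stringsAsFactors = FALSE)
  list(index = knn_index(ann, region_embedding_set(regs, vecs), ont),
       ont = ont)
}

test_that("a single reference at distance zero gives unit score", {
  toy <- knn_toy(0, "A")
  s <- transfer(c(1, 0), toy$index, transfer_config(), "molecular_function",
                apply_threshold = FALSE)
  expect_equal(as.numeric(s), 1)
  expect_named(s, "A")
})

test_that("references beyond the cutoff never vote", {
  toy <- knn_toy(c(0.9, 1.2), c("A", "B"))
  s <- transfer(c(1, 0), toy$index, transfer_config(), "molecular_function",
                apply_threshold = FALSE)
  expect_length(s, 0)
})

test_that("three-neighbour vote matches the hand-derived weights", {
  # d = {0.2, 0.4, 0.6}, cutoff 0.8 -> raw w = {0.75, 0.5, 0.25},
  # normalised {1/2, 1/3, 1/6}; terms {A},{A},{B} -> A = 5/6, B = 1/6
  toy <- knn_toy(c(0.2, 0.4, 0.6), c("A", "A", "B"))
  s <- transfer(c(1, 0), toy$index, transfer_config(), "molecular_function",
                apply_threshold = FALSE)
  expect_equal(s[["A"]], 5 / 6, tolerance = 1e-9)
  expect_equal(s[["B"]], 1 / 6, tolerance = 1e-9)
  expect_equal(sum(s), 1, tolerance = 1e-9)
})

test_that("annotations on one region are unioned; empty tables give empty indexes", {
  ont <- toy_ontology()
  regs <- data.frame(accession = "P1", start = 1L, end = 10L)
  set <- region_embedding_set(regs, matrix(c(1, 0), 1))
  ann <- data.frame(accession = "P1", start = 1L, end = 10L,
                    term = c("A", "B"))
  idx <- knn_index(ann, set, ont)
  expect_equal(nrow(idx$entries), 1L)
  expect_setequal(idx$terms[[1L]]$molecular_function, c("A", "B"))

  empty <- knn_index(ann[0, ], set, ont)
  expect_equal(nrow(empty$entries), 0L)
  s <- transfer(c(1, 0), empty, transfer_config(), "molecular_function")
  expect_length(s, 0)
})

test_that("index build matches brute-force grouping on a fixture set", {
  set.seed(21)
  dag <- rand_dag(20)
  n <- 20L
  acc <- sample(sprintf("P%02d", 1:8), n, replace = TRUE)
  start <- sample(1:5, n, replace = TRUE) * 10L
  ann <- data.frame(accession = acc, start = start, end = start + 9L,
                    term = sample(dag$ids[-1L], n, replace = TRUE),
                    stringsAsFactors = FALSE)
  ureg <- unique(ann[c("accession", "start", "end")])
  set <- region_embedding_set(ureg, matrix(stats::rnorm(nrow(ureg) * 4), ncol = 4))
  idx <- knn_index(ann, set, dag$ont, propagate = FALSE)

  # hash-join oracle
  key <- paste(ann$accession, ann$start, ann$end, sep = "|")
  expected <- lapply(split(ann$term, key), unique)
  expect_equal(nrow(idx$entries), length(expected))
  got_keys <- paste(idx$entries$accession, idx$entries$start, idx$entries$end,
                    sep = "|")
  expect_false(is.unsorted(got_keys))
  for (i in seq_along(got_keys)) {
    expect_setequal(idx$terms[[i]]$molecular_function, expected[[got_keys[[i]]]])
  }
})

test_that("regions without embeddings are reported by name", {
  ont <- toy_ontology()
  set <- region_embedding_set(data.frame(accession = "P1", start = 1L, end = 5L),
                              matrix(c(1, 0), 1))
  ann <- data.frame(accession = c("P1", "P9"), start = c(1L, 1L),
                    end = c(5L, 5L), term = "A")
  expect_error(knn_index(ann, set, ont), "P9")
})

test_that("transfer agrees with the brute-force oracle on random instances", {
  set.seed(22)
  for (rep in 1:40) {
    dag <- rand_dag(sample(8:20, 1))
    n_ref <- sample(5:50, 1)
    D <- sample(2:8, 1)
    acc <- sprintf("P%03d", sample(seq_len(n_ref), n_ref))  # shuffled ids
    ann_rows <- lapply(seq_len(n_ref), function(i) {
      data.frame(accession = acc[[i]], start = 1L, end = 10L,
                 term = sample(dag$ids, sample(1:3, 1)),
                 stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, ann_rows)
    regs <- unique(ann[c("accession", "start", "end")])
    vecs <- matrix(stats::rnorm(nrow(regs) * D), ncol = D)
    set <- region_embedding_set(regs, vecs)
    idx <- knn_index(ann, set, dag$ont)

    cutoff <- sample(c(0.4, 0.8, 1.2), 1)
    k <- sample(1:10, 1)
    tau <- sample(c(0, 0.3, 0.6), 1)
    strict <- if (rep %% 3 == 0)
      stats::setNames(0.9, sample(dag$ids, 1)) else numeric(0)
    cfg <- transfer_config(distance_cutoff = cutoff,
                           k = c(molecular_function = k),
                           score_threshold = c(molecular_function = tau),
                           strict_terms = strict)
    query <- stats::rnorm(D)

    got <- transfer(query, idx, cfg, "molecular_function")
    vbk <- stats::setNames(
      lapply(seq_len(nrow(regs)), function(i) vecs[i, ]),
      paste(regs$accession, regs$start, regs$end, sep = "|"))
    closure <- oracle_closure(dag$ids, dag$parents)
    want <- oracle_transfer(query, ann, vbk,
                            list(closure = closure, roots = dag$ont$roots,
                                 namespace = dag$ont$namespace),
                            cutoff, k, tau, strict)
    expect_setequal(term_names(got), term_names(want))
    if (length(want)) {
      expect_equal(as.numeric(got[names(want)]), as.numeric(want),
                   tolerance = 1e-12)
    }
  }
})

test_that("scores are convex: in [0,1] and weights sum to one", {
  set.seed(23)
  dag <- rand_dag(12)
  regs <- data.frame(accession = sprintf("P%02d", 1:30), start = 1L, end = 10L)
  set <- region_embedding_set(regs, matrix(stats::rnorm(30 * 4), ncol = 4))
  ann <- data.frame(accession = regs$accession, start = 1L, end = 10L,
                    term = sample(dag$ids, 30, replace = TRUE))
  idx <- knn_index(ann, set, dag$ont)
  for (rep in 1:20) {
    s <- transfer(stats::rnorm(4), idx,
                  transfer_config(distance_cutoff = 1.5,
                                  k = c(molecular_function = 5L)),
                  "molecular_function", apply_threshold = FALSE)
    expect_true(all(s >= 0 & s <= 1))
    nb <- attr(s, "neighbors")
    if (!is.null(nb)) expect_equal(sum(nb$weight), 1, tolerance = 1e-12)
  }
})

test_that("shrinking the cutoff never adds neighbours", {
  set.seed(24)
  dag <- rand_dag(10)
  regs <- data.frame(accession = sprintf("P%02d", 1:25), start = 1L, end = 10L)
  set <- region_embedding_set(regs, matrix(stats::rnorm(25 * 3), ncol = 3))
  ann <- data.frame(accession = regs$accession, start = 1L, end = 10L,
                    term = sample(dag$ids, 25, replace = TRUE))
  idx <- knn_index(ann, set, dag$ont)
  q <- stats::rnorm(3)
  cuts <- c(0.3, 0.6, 0.9, 1.2)
  nbs <- lapply(cuts, function(ct) {
    s <- transfer(q, idx, transfer_config(distance_cutoff = ct,
                                          k = c(molecular_function = 50L)),
                  "molecular_function", apply_threshold = FALSE)
    nb <- attr(s, "neighbors")
    if (is.null(nb)) character(0) else nb$key
  })
  for (i in seq_len(length(cuts) - 1L)) {
    expect_true(all(nbs[[i]] %in% nbs[[i + 1L]]))
  }
})

test_that("k = 1 copies the nearest entry's propagated terms with score 1", {
  set.seed(25)
  dag <- rand_dag(10)
  regs <- data.frame(accession = sprintf("P%02d", 1:15), start = 1L, end = 10L)
  vecs <- matrix(stats::rnorm(15 * 3), ncol = 3)
  set <- region_embedding_set(regs, vecs)
  ann <- data.frame(accession = regs$accession, start = 1L, end = 10L,
                    term = sample(dag$ids[-1L], 15, replace = TRUE))
  idx <- knn_index(ann, set, dag$ont)
  q <- stats::rnorm(3)
  s <- transfer(q, idx, transfer_config(distance_cutoff = 2,
                                        k = c(molecular_function = 1L)),
                "molecular_function", apply_threshold = FALSE)
  d <- vapply(seq_len(15), function(i) cosine_distance(q, vecs[i, ]), 0)
  nearest <- which.min(d)
  key <- paste(regs$accession[[nearest]], 1L, 10L, sep = "|")
  i_entry <- match(key, idx$keys)
  expect_setequal(names(s), idx$terms[[i_entry]]$molecular_function)
  expect_true(all(abs(as.numeric(s) - 1) < 1e-12))
})

test_that("batch transfer equals per-query transfer; BP/CC are refused", {
  set.seed(26)
  dag <- rand_dag(10)
  regs <- data.frame(accession = sprintf("P%02d", 1:20), start = 1L, end = 10L)
  set <- region_embedding_set(regs, matrix(stats::rnorm(20 * 3), ncol = 3))
  ann <- data.frame(accession = regs$accession, start = 1L, end = 10L,
                    term = sample(dag$ids, 20, replace = TRUE))
  idx <- knn_index(ann, set, dag$ont)
  qregs <- data.frame(accession = c("Q1", "Q2"), start = 1L, end = 10L)
  qset <- region_embedding_set(qregs, matrix(stats::rnorm(6), ncol = 3))
  batch <- transfer_all(qset, idx, transfer_config(), "molecular_function",
                        apply_threshold = FALSE)
  expect_named(batch, qset$keys)
  for (i in 1:2) {
    single <- transfer(qset$vectors[i, ], idx, transfer_config(),
                       "molecular_function", apply_threshold = FALSE)
    expect_equal(unclass(batch[[i]])[order(names(batch[[i]]))],
                 unclass(single)[order(names(single))])
  }
  expect_error(transfer(qset$vectors[1, ], idx, transfer_config(),
                        "biological_process"), "not executed")
  # a query identical to a reference entry is its own nearest neighbour
  s <- transfer(set$vectors[5, ], idx, transfer_config(),
                "molecular_function", apply_threshold = FALSE)
  expect_equal(attr(s, "neighbors")$key[[1L]], set$keys[[5L]])
  expect_equal(attr(s, "neighbors")$distance[[1L]], 0)
})

test_that("strict binding-style terms need their stricter threshold", {
  # two neighbours at equal distance, only one carries the strict term:
  # score 0.5 passes the namespace threshold but not the 0.9 strict one
  toy <- knn_toy(c(0.2, 0.2), c("A", "B"))
  cfg <- transfer_config(score_threshold = c(molecular_function = 0.4),
                         strict_terms = c(A = 0.9))
  s <- transfer(c(1, 0), toy$index, cfg, "molecular_function")
  expect_false("A" %in% names(s))       # 0.5 < strict 0.9
  expect_true("B" %in% names(s))        # 0.5 >= namespace threshold 0.4
})

test_that("prediction tables are sorted, thresholded and TSV-stable", {
  set.seed(27)
  dag <- rand_dag(12)
  regs <- data.frame(accession = sprintf("P%02d", 1:20), start = 1L, end = 10L)
  set <- region_embedding_set(regs, matrix(stats::rnorm(20 * 4), ncol = 4))
  ann <- data.frame(accession = regs$accession, start = 1L, end = 10L,
                    term = sample(dag$ids[-1L], 20, replace = TRUE))
  idx <- knn_index(ann, set, dag$ont)
  qregs <- data.frame(accession = c("Q1", "Q2", "Q3"), start = 1L, end = 10L)
  qset <- region_embedding_set(qregs, matrix(stats::rnorm(12), ncol = 4))
  cfg <- transfer_config(score_threshold = c(molecular_function = 0.2))
  pred <- predict(idx, qset, cfg)
  expect_true(all(pred$score >= 0.2))
  expect_false(is.unsorted(pred$accession))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(pred, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), nrow(pred))
  expect_equal(back$score, round(pred$score, 6), tolerance = 1e-9)
})
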