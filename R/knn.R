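#' Configuration for embedding-based annotation transfer
#'
#' Holds the tunables of the weighted-KNN transfer. Defaults follow the values
#' optimised on the DisProt release split: cosine-distance cutoff 0.8 applied
#' before weight normalisation; K = 10 with score threshold 0.44 for Molecular
#' Function; K = 5 with threshold 0.59 for Disorder Function; and a stricter
#' 0.9 threshold for the generic binding labels GO:0005488 and GO:0005515,
#' which dominate curated annotations and would otherwise swamp the output.
#'
#' @param distance_cutoff cosine-distance cutoff in (0, 2]; reference regions
#'   farther than this never vote.
#' @param k named integer vector, namespace -> number of neighbours.
#' @param score_threshold named numeric vector, namespace -> minimum score a
#'   term must reach to be reported.
#' @param strict_terms named numeric vector, term id -> stricter threshold
#'   applied to that term after hierarchy enforcement.
#' @param allowed_namespaces namespaces the transfer will run for. Biological
#'   Process and Cellular Component describe whole-protein functions too
#'   abstract for region-level transfer and are refused by default.
#' @return an `idr_transfer_config` list.
#' @export
transfer_config <- function(distance_cutoff = 0.8,
                            k = c(molecular_function = 10L,
                                  disorder_function = 5L),
                            score_threshold = c(molecular_function = 0.44,
                                                disorder_function = 0.59),
                            strict_terms = c("GO:0005488" = 0.9,
                                             "GO:0005515" = 0.9),
                            allowed_namespaces = c("molecular_function",
                                                   "disorder_function")) {
  if (!(distance_cutoff > 0 && distance_cutoff <= 2)) {
    stop("distance_cutoff must be in (0, 2]")
  }
  if (any(k < 1L)) stop("k must be >= 1")
  if (any(score_threshold < 0 | score_threshold > 1)) {
    stop("score thresholds must lie in [0, 1]")
  }
  if (length(strict_terms) && any(strict_terms < 0 | strict_terms > 1)) {
    stop("strict term thresholds must lie in [0, 1]")
  }
  structure(list(distance_cutoff = distance_cutoff,
                 k = k, score_threshold = score_threshold,
                 strict_terms = strict_terms,
                 allowed_namespaces = allowed_namespaces),
            class = "idr_transfer_config")
}

#' Build a reference index for annotation transfer
#'
#' The "fit" step of the transfer model: joins a region annotation table
#' (e.g. a DisProt import) with pooled region embeddings into an index of
#' annotated reference regions. Annotations on the same region are unioned;
#' term sets are partitioned by namespace and, by default, expanded by the
#' true-path rule at build time so neighbour votes are hierarchy-complete.
#' Entries are ordered by (accession, start, end) — the stable order used for
#' distance ties.
#'
#' @param annotations data.frame with columns `accession`, `start`, `end`,
#'   `term` (one row per region/term pair).
#' @param embeddings an [region_embedding_set()] covering every annotated
#'   region.
#' @param ont an `idr_ontology` resolving every term.
#' @param propagate logical; apply true-path propagation to reference term
#'   sets (default TRUE).
#' @return an object of class `idr_knn`: the reference index, with
#'   [predict.idr_knn()] performing the transfer.
#' @export
knn_index <- function(annotations, embeddings, ont, propagate = TRUE) {
  stopifnot(is.data.frame(annotations),
            inherits(embeddings, "idr_region_embedding_set"),
            inherits(ont, "idr_ontology"))
  need <- c("accession", "start", "end", "term")
  miss <- setdiff(need, names(annotations))
  if (length(miss)) stop("annotation table missing column(s): ",
                         paste(miss, collapse = ", "))

  if (nrow(annotations) == 0L) {
    entries <- data.frame(accession = character(0), start = integer(0),
                          end = integer(0), stringsAsFactors = FALSE)
    return(structure(list(entries = entries,
                          vectors = embeddings$vectors[0, , drop = FALSE],
                          terms = list(), ontology = ont,
                          build_config = list(propagate = propagate)),
                     class = "idr_knn"))
  }

  annotations$term <- resolve_terms(ont, annotations$term)
  key <- region_key(annotations$accession, annotations$start, annotations$end)
  missing_emb <- setdiff(unique(key), embeddings$keys)
  if (length(missing_emb)) {
    stop("annotated region(s) without an embedding: ",
         paste(utils::head(missing_emb, 10L), collapse = ", "))
  }

  term_sets <- lapply(split(annotations$term, key), unique)
  keys <- names(term_sets)
  parts <- strsplit(keys, "|", fixed = TRUE)
  entries <- data.frame(
    accession = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, `[[`, "", 2L)),
    end = as.integer(vapply(parts, `[[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  ord <- order(entries$accession, entries$start, entries$end)
  entries <- entries[ord, , drop = FALSE]
  rownames(entries) <- NULL
  keys <- keys[ord]
  term_sets <- term_sets[ord]

  # per-entry term sets partitioned by namespace, optionally propagated
  terms_ns <- lapply(term_sets, function(ts) {
    if (propagate) ts <- propagate_true_path(ts, ont)
    split(ts, ont$namespace[ts])
  })

  structure(list(entries = entries,
                 vectors = embeddings$vectors[keys, , drop = FALSE],
                 keys = keys,
                 terms = terms_ns,
                 ontology = ont,
                 build_config = list(propagate = propagate)),
            class = "idr_knn")
}

#' @export
print.idr_knn <- function(x, ...) {
  cat(sprintf("Weighted-KNN annotation transfer index: %d reference regions, dim %d\n",
              nrow(x$entries), ncol(x$vectors)))
  ns <- sort(unique(unlist(lapply(x$terms, names))))
  if (length(ns)) cat("  namespaces:", paste(ns, collapse = ", "), "\n")
  cat(sprintf("  reference terms true-path propagated: %s\n",
              x$build_config$propagate))
  invisible(x)
}

#' @export
summary.idr_knn <- function(object, ...) {
  ns <- sort(unique(unlist(lapply(object$terms, names))))
  counts <- vapply(ns, function(n) {
    sum(vapply(object$terms, function(t) length(t[[n]]) > 0L, logical(1)))
  }, 0L)
  terms_per_ns <- vapply(ns, function(n) {
    length(unique(unlist(lapply(object$terms, `[[`, n))))
  }, 0L)
  out <- list(n_regions = nrow(object$entries),
              dim = ncol(object$vectors),
              namespaces = data.frame(namespace = ns,
                                      regions = as.integer(counts),
                                      distinct_terms = as.integer(terms_per_ns)),
              propagate = object$build_config$propagate)
  class(out) <- "summary.idr_knn"
  out
}

#' @export
print.summary.idr_knn <- function(x, ...) {
  cat(sprintf("Reference index: %d regions, embedding dim %d (propagated: %s)\n",
              x$n_regions, x$dim, x$propagate))
  print(x$namespaces, row.names = FALSE)
  invisible(x)
}

#' Transfer terms to one query region
#'
#' The core weighted-KNN vote. Cosine distances from the query embedding to
#' every reference entry are computed; entries beyond the distance cutoff are
#' discarded; the k nearest survivors (ties broken by the index's stable
#' order) vote with raw weights `w_i = 1 - d_i / cutoff`, normalised to sum
#' to one, so each term's score is the weighted fraction of neighbours
#' annotated with it — a convex combination in [0, 1]. Scores are then made
#' hierarchy-consistent and thresholded: the namespace threshold for ordinary
#' terms, the stricter per-term threshold for the generic binding labels.
#'
#' @param query an `idr_region_embedding`, or a bare numeric vector.
#' @param index an [knn_index()] object.
#' @param config an [transfer_config()].
#' @param namespace the namespace to transfer (must be allowed by `config`).
#' @param apply_threshold logical; set FALSE to keep all scored terms (used
#'   when sweeping thresholds afterwards, e.g. in [grid_search()]).
#' @return an `idr_term_scores`: named numeric score vector with attributes
#'   `query` (the region, if known) and `neighbors` (a provenance data.frame
#'   of reference keys, distances and normalised weights).
#' @export
transfer <- function(query, index, config = transfer_config(), namespace,
                     apply_threshold = TRUE) {
  stopifnot(inherits(index, "idr_knn"))
  if (!namespace %in% config$allowed_namespaces) {
    stop("transfer is not executed for namespace '", namespace,
         "'; add it to allowed_namespaces to override")
  }
  qreg <- NULL
  if (inherits(query, "idr_region_embedding")) {
    qreg <- query$region
    query <- query$vector
  }
  query <- as.numeric(query)
  if (nrow(index$entries) == 0L) return(.term_scores(numeric(0), qreg, NULL))
  if (length(query) != ncol(index$vectors)) {
    stop("query dimension ", length(query), " != index dimension ",
         ncol(index$vectors))
  }

  d <- vapply(seq_len(nrow(index$vectors)),
              function(i) cosine_distance(query, index$vectors[i, ]), 0)
  keep <- which(d <= config$distance_cutoff)
  if (!length(keep)) return(.term_scores(numeric(0), qreg, NULL))

  k <- config$k[[namespace]]
  if (is.null(k) || is.na(k)) k <- config$k[[1L]]
  ord <- keep[order(d[keep])]          # order() is stable: ties keep index order
  nn <- ord[seq_len(min(k, length(ord)))]

  w <- 1 - d[nn] / config$distance_cutoff
  if (sum(w) == 0) {
    warning("all surviving neighbours sit exactly at the distance cutoff; ",
            "no weights to normalise")
    return(.term_scores(numeric(0), qreg, NULL))
  }
  w <- w / sum(w)

  scores <- list()
  for (i in seq_along(nn)) {
    for (t in index$terms[[nn[[i]]]][[namespace]]) {
      scores[[t]] <- (if (is.null(scores[[t]])) 0 else scores[[t]]) + w[[i]]
    }
  }
  s <- unlist(scores)
  if (is.null(s)) s <- numeric(0)
  s <- pmin(s, 1)                       # guard rounding just above 1

  if (length(s)) s <- enforce_hierarchy(s, index$ontology)

  if (apply_threshold && length(s)) {
    tau <- config$score_threshold[[namespace]]
    if (is.null(tau) || is.na(tau)) tau <- 0
    keep_t <- s >= tau
    strict <- intersect(names(s), names(config$strict_terms))
    keep_t[strict] <- keep_t[strict] & (s[strict] >= config$strict_terms[strict])
    s <- s[keep_t]
  }

  nb <- data.frame(key = index$keys[nn], distance = d[nn], weight = w,
                   stringsAsFactors = FALSE)
  .term_scores(s, qreg, nb)
}

.term_scores <- function(scores, query, neighbors) {
  structure(scores, class = "idr_term_scores", query = query,
            neighbors = neighbors)
}

#' @export
print.idr_term_scores <- function(x, ...) {
  q <- attr(x, "query")
  if (!is.null(q)) cat(sprintf("Query %s:%d-%d\n", q$accession, q$start, q$end))
  if (!length(x)) {
    cat("(no terms above threshold)\n")
  } else {
    s <- sort(unclass(x), decreasing = TRUE)
    for (i in seq_along(s)) cat(sprintf("  %s\t%.6f\n", names(s)[[i]], s[[i]]))
  }
  invisible(x)
}

#' Transfer terms to a batch of query regions
#'
#' Applies [transfer()] independently to every query; output order matches
#' input order.
#' @param queries an `idr_region_embedding_set`.
#' @inheritParams transfer
#' @return named list (by region key) of `idr_term_scores`.
#' @export
transfer_all <- function(queries, index, config = transfer_config(), namespace,
                         apply_threshold = TRUE) {
  stopifnot(inherits(queries, "idr_region_embedding_set"))
  out <- lapply(seq_len(nrow(queries$regions)), function(i) {
    ts <- transfer(queries$vectors[i, ], index, config, namespace,
                   apply_threshold = apply_threshold)
    attr(ts, "query") <- region(queries$regions$accession[[i]],
                                queries$regions$start[[i]],
                                queries$regions$end[[i]])
    ts
  })
  stats::setNames(out, queries$keys)
}

#' Predict method for the transfer index
#'
#' Runs [transfer_all()] for each requested namespace and returns one long,
#' sorted prediction table — the TSV-ready form of the transfer output.
#'
#' @param object an `idr_knn` index.
#' @param queries an `idr_region_embedding_set`.
#' @param config an [transfer_config()].
#' @param namespaces namespaces to predict (default: all allowed ones present
#'   in the index).
#' @param apply_threshold logical, as in [transfer()].
#' @param ... unused.
#' @return data.frame with columns `accession`, `start`, `end`, `term`,
#'   `namespace`, `score`, `n_neighbors`.
#' @export
predict.idr_knn <- function(object, queries, config = transfer_config(),
                            namespaces = NULL, apply_threshold = TRUE, ...) {
  present <- sort(unique(unlist(lapply(object$terms, names))))
  if (is.null(namespaces)) {
    namespaces <- intersect(config$allowed_namespaces, present)
  }
  rows <- list()
  for (ns in namespaces) {
    maps <- transfer_all(queries, object, config, ns,
                         apply_threshold = apply_threshold)
    for (i in seq_along(maps)) {
      m <- maps[[i]]
      if (!length(m)) next
      q <- attr(m, "query")
      nb <- attr(m, "neighbors")
      rows[[length(rows) + 1L]] <- data.frame(
        accession = q$accession, start = q$start, end = q$end,
        term = names(m), namespace = ns, score = as.numeric(m),
        n_neighbors = if (is.null(nb)) 0L else nrow(nb),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(accession = character(0), start = integer(0),
                      end = integer(0), term = character(0),
                      namespace = character(0), score = numeric(0),
                      n_neighbors = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$accession, out$start, out$end, out$namespace,
                   -out$score, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a prediction table as TSV
#' @param pred the data.frame returned by [predict.idr_knn()].
#' @param path output TSV path.
#' @export
write_predictions <- function(pred, path) {
  pred$score <- .fmt6(pred$score)
  .write_tsv(pred, path)
}
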