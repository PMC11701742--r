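#' Region-level f-max evaluation
#'
#' CAFA-style protein-centric evaluation, applied at the IDR level: for each
#' score threshold t, precision is averaged over regions with at least one
#' prediction scoring >= t, recall is averaged over ALL gold regions (a gold
#' region with no surviving prediction contributes zero recall), and f-max is
#' the maximum harmonic mean over the threshold grid. Both prediction and
#' gold term sets are assumed true-path propagated with namespace roots
#' removed; namespaces are evaluated separately.
#'
#' @param predictions named list (by region key `acc|start|end`) of named
#'   numeric score vectors (term -> score), e.g. [transfer_all()] output with
#'   `apply_threshold = FALSE`.
#' @param gold named list (by region key) of character vectors of true terms;
#'   every region must have at least one term.
#' @param thresholds numeric grid of score thresholds (default 0..1 step
#'   0.01, the CAFA convention).
#' @return an `idr_fmax` object: `fmax`, `optimal_threshold` (smallest grid
#'   point attaining the max), `curve` (threshold, precision, recall, f1),
#'   `n_regions`, `n_predicted` (regions with >= 1 prediction at the optimum).
#' @export
fmax_evaluate <- function(predictions, gold, thresholds = seq(0, 1, by = 0.01)) {
  if (length(gold) == 0L) stop("empty gold standard")
  if (any(vapply(gold, length, 0L) == 0L)) {
    stop("gold regions with no terms: ",
         paste(utils::head(names(gold)[vapply(gold, length, 0L) == 0L], 10L),
               collapse = ", "))
  }
  stray <- setdiff(names(predictions), names(gold))
  if (length(stray)) {
    stop("predicted region(s) absent from the gold standard: ",
         paste(utils::head(stray, 10L), collapse = ", "))
  }
  if (!length(thresholds)) stop("empty threshold grid")
  thresholds <- sort(unique(thresholds))

  keys <- names(gold)
  pr <- vapply(thresholds, function(t) {
    prec_terms <- numeric(0)
    rec_terms <- numeric(length(keys))
    for (j in seq_along(keys)) {
      p <- predictions[[keys[[j]]]]
      hit <- if (is.null(p)) character(0) else names(p)[as.numeric(p) >= t]
      if (length(hit)) {
        tp <- length(intersect(hit, gold[[keys[[j]]]]))
        prec_terms <- c(prec_terms, tp / length(hit))
        rec_terms[[j]] <- tp / length(gold[[keys[[j]]]])
      }
    }
    p_t <- if (length(prec_terms)) mean(prec_terms) else 0
    r_t <- mean(rec_terms)
    f_t <- if (p_t + r_t > 0) 2 * p_t * r_t / (p_t + r_t) else 0
    c(p_t, r_t, f_t, length(prec_terms))
  }, numeric(4))

  curve <- data.frame(threshold = thresholds, precision = pr[1L, ],
                      recall = pr[2L, ], f1 = pr[3L, ])
  best <- which.max(curve$f1)           # first (= smallest threshold) maximum
  structure(list(fmax = curve$f1[[best]],
                 optimal_threshold = curve$threshold[[best]],
                 curve = curve,
                 n_regions = length(keys),
                 n_predicted = as.integer(pr[4L, best])),
            class = "idr_fmax")
}

#' @export
print.idr_fmax <- function(x, ...) {
  cat(sprintf("f-max = %.4f at threshold %.2f (%d gold regions, %d predicted at optimum)\n",
              x$fmax, x$optimal_threshold, x$n_regions, x$n_predicted))
  invisible(x)
}

#' Build a gold standard from an annotation table
#'
#' Groups region/term rows by region, applies true-path propagation and drops
#' namespace roots, keeping only terms of the requested namespace.
#' @param annotations data.frame with `accession`, `start`, `end`, `term`.
#' @param ont an `idr_ontology`.
#' @param namespace namespace to retain.
#' @return named list (region key) of propagated term-id vectors; regions
#'   ending up with no term in the namespace are dropped.
#' @export
gold_standard <- function(annotations, ont, namespace) {
  annotations$term <- resolve_terms(ont, annotations$term)
  key <- region_key(annotations$accession, annotations$start, annotations$end)
  sets <- lapply(split(annotations$term, key), function(ts) {
    ts <- propagate_true_path(ts, ont)
    ts[ont$namespace[ts] == namespace]
  })
  Filter(length, sets)
}

#' Grid search over K and the score threshold
#'
#' Reproduces the tuning protocol behind the published transfer parameters:
#' for each candidate K, the transfer is run once with no score threshold,
#' then the threshold is swept over `tau_grid` by the evaluator (f-max's
#' optimal threshold IS the best tau for that K). The strict binding filter
#' is disabled during the search. Ties are broken toward smaller K, then
#' smaller tau.
#'
#' @param index an [knn_index()] built from the reference release.
#' @param queries an `idr_region_embedding_set` for the test regions.
#' @param gold gold standard as from [gold_standard()] (same namespace).
#' @param namespace namespace to optimise.
#' @param k_candidates integer vector of K values to try.
#' @param tau_grid numeric threshold grid (default 0..1 step 0.01).
#' @param config template [transfer_config()] supplying the distance cutoff.
#' @return an `idr_grid_search`: `best` (list with k, tau, fmax), `results`
#'   (one row per candidate), `evaluations` (the `idr_fmax` per candidate).
#' @export
grid_search <- function(index, queries, gold, namespace, k_candidates,
                        tau_grid = seq(0, 1, by = 0.01),
                        config = transfer_config()) {
  if (!length(k_candidates)) stop("empty k candidate list")
  if (!length(tau_grid)) stop("empty tau grid")
  k_candidates <- sort(unique(as.integer(k_candidates)))

  evals <- vector("list", length(k_candidates))
  rows <- vector("list", length(k_candidates))
  for (i in seq_along(k_candidates)) {
    cfg <- config
    cfg$k[[namespace]] <- k_candidates[[i]]
    cfg$strict_terms <- stats::setNames(numeric(0), character(0))
    preds <- transfer_all(queries, index, cfg, namespace,
                          apply_threshold = FALSE)
    ev <- fmax_evaluate(preds, gold, thresholds = tau_grid)
    evals[[i]] <- ev
    rows[[i]] <- data.frame(k = k_candidates[[i]], tau = ev$optimal_threshold,
                            fmax = ev$fmax)
  }
  results <- do.call(rbind, rows)
  # argmax fmax; ties -> smaller k (already sorted), then smaller tau
  # (fmax_evaluate returns the smallest optimal threshold)
  best_i <- which.max(results$fmax)
  structure(list(best = list(k = results$k[[best_i]],
                             tau = results$tau[[best_i]],
                             fmax = results$fmax[[best_i]]),
                 results = results,
                 evaluations = stats::setNames(evals, results$k)),
            class = "idr_grid_search")
}

#' @export
print.idr_grid_search <- function(x, ...) {
  cat(sprintf("best: K = %d, tau = %.2f, f-max = %.4f\n",
              x$best$k, x$best$tau, x$best$fmax))
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' Map predicted regions onto gold regions by overlap
#'
#' Utility for when predicted IDRs and curated gold regions do not share exact
#' coordinates: each predicted region on a protein is assigned the key of the
#' gold region with the highest interval Jaccard index, provided it reaches
#' `min_jaccard`. Exact-key evaluation remains the default; this mapping is a
#' toolkit convenience with an explicit threshold, not a published rule.
#'
#' @param pred_regions data.frame with `accession`, `start`, `end`.
#' @param gold_regions data.frame with `accession`, `start`, `end`.
#' @param min_jaccard minimum interval Jaccard to accept a match (default 0.5).
#' @return data.frame of `pred_key`, `gold_key`, `jaccard` for accepted pairs.
#' @export
map_regions <- function(pred_regions, gold_regions, min_jaccard = 0.5) {
  out <- list()
  for (i in seq_len(nrow(pred_regions))) {
    acc <- pred_regions$accession[[i]]
    g <- gold_regions[gold_regions$accession == acc, , drop = FALSE]
    if (!nrow(g)) next
    inter <- pmax(0L, pmin(pred_regions$end[[i]], g$end) -
                    pmax(pred_regions$start[[i]], g$start) + 1L)
    uni <- (pred_regions$end[[i]] - pred_regions$start[[i]] + 1L) +
      (g$end - g$start + 1L) - inter
    jac <- inter / uni
    j <- which.max(jac)
    if (jac[[j]] >= min_jaccard) {
      out[[length(out) + 1L]] <- data.frame(
        pred_key = region_key(acc, pred_regions$start[[i]], pred_regions$end[[i]]),
        gold_key = region_key(acc, g$start[[j]], g$end[[j]]),
        jaccard = jac[[j]], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(pred_key = character(0), gold_key = character(0),
                      jaccard = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
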