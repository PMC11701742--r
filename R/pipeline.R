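#' Run the full annotation pipeline
#'
#' Orchestrates simulate -> build-index -> transfer -> evaluate, plus the
#' consensus and compaction-labeling stages, against a directory layout:
#' inputs under `<dir>/inputs`, outputs under `<dir>/outputs`, and a
#' `manifest.json` recording the configuration snapshot, input checksums and
#' package version. All randomness flows from `spec$seed` through fixed
#' per-stage substreams, and every output is formatted deterministically, so
#' rerunning with the same spec yields bit-identical files.
#'
#' @param dir working directory for the run (created if needed).
#' @param spec an [fixture_spec()] controlling the simulate stage.
#' @param config an [transfer_config()].
#' @param cons_modes consensus modes to compute (default all three).
#' @param stages subset of `c("simulate", "transfer", "evaluate",
#'   "consensus", "label-nu")`; later stages read the files earlier stages
#'   wrote, so a partial run needs its inputs already on disk.
#' @return invisibly, a list with the per-stage results and output paths.
#' @export
run_pipeline <- function(dir, spec = fixture_spec(),
                         config = transfer_config(),
                         cons_modes = c("merge", "majority", "strict"),
                         stages = c("simulate", "transfer", "evaluate",
                                    "consensus", "label-nu")) {
  in_dir <- file.path(dir, "inputs")
  out_dir <- file.path(dir, "outputs")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- list()

  if ("simulate" %in% stages) {
    results$simulate <- sim_bundle(spec, in_dir)
  }

  p <- function(...) file.path(in_dir, ...)
  need <- function(path) {
    if (!file.exists(path)) stop("missing pipeline input: ", path)
    path
  }

  ont <- NULL
  preds_by_ns <- NULL
  if (any(c("transfer", "evaluate") %in% stages)) {
    ont <- load_obo(need(p("ontology.obo")))
    annotations <- read_annotations(need(p("reference_annotations.tsv")))
    ref_emb <- read_region_embeddings(need(p("reference_embeddings.tsv")))
    qry_emb <- read_region_embeddings(need(p("query_embeddings.tsv")))
    index <- knn_index(annotations, ref_emb, ont)
    results$index <- index

    if ("transfer" %in% stages) {
      pred <- predict(index, qry_emb, config)
      write_predictions(pred, file.path(out_dir, "predictions.tsv"))
      results$predictions <- pred
    }

    if ("evaluate" %in% stages) {
      gold_ann <- read_annotations(need(p("gold_annotations.tsv")))
      ns_all <- intersect(config$allowed_namespaces,
                          unique(ont$namespace[resolve_terms(ont, gold_ann$term)]))
      evals <- list()
      for (ns in ns_all) {
        gold <- gold_standard(gold_ann, ont, ns)
        maps <- transfer_all(qry_emb, index, config, ns,
                             apply_threshold = FALSE)
        evals[[ns]] <- fmax_evaluate(maps, gold)
      }
      results$evaluation <- evals
      jsonlite::write_json(
        lapply(evals, function(e) {
          list(fmax = e$fmax, optimal_threshold = e$optimal_threshold,
               n_regions = e$n_regions, n_predicted = e$n_predicted,
               curve = e$curve)
        }),
        file.path(out_dir, "evaluation.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      summ <- data.frame(
        namespace = names(evals),
        fmax = .fmt6(vapply(evals, `[[`, 0, "fmax")),
        optimal_threshold = .fmt6(vapply(evals, `[[`, 0, "optimal_threshold")),
        n_regions = vapply(evals, `[[`, 0L, "n_regions"),
        stringsAsFactors = FALSE)
      .write_tsv(summ, file.path(out_dir, "evaluation_summary.tsv"))
    }
  }

  if ("consensus" %in% stages) {
    tracks <- read_tracks(need(p("tracks.tsv")))
    acc <- vapply(tracks, `[[`, "", "accession")
    cons <- list()
    for (a in sort(unique(acc))) {
      vm <- vote_matrix(tracks[acc == a])
      for (m in cons_modes) {
        cons[[length(cons) + 1L]] <- consensus(vm, consensus_config(mode = m))
      }
    }
    write_tracks(cons, file.path(out_dir, "consensus.tsv"))
    write_tracks_json(cons, file.path(out_dir, "consensus.json"))
    stats <- content_fraction(c(tracks, cons))
    stats$fraction <- .fmt6(stats$fraction)
    .write_tsv(stats, file.path(out_dir, "content_fraction.tsv"))
    results$consensus <- cons
    results$content <- stats
  }

  if ("label-nu" %in% stages) {
    nu <- read_nu_table(need(p("nu.tsv")))
    labels <- label_table(nu)
    write_nu_labels(labels, file.path(out_dir, "nu_labels.tsv"))
    summ <- data.frame(metric = c("frac_expanded", "frac_compact", "n_proteins"),
                       value = .fmt6(as.numeric(labels$summary)),
                       stringsAsFactors = FALSE)
    .write_tsv(summ, file.path(out_dir, "nu_summary.tsv"))
    results$nu_labels <- labels
  }

  inputs <- list.files(in_dir, full.names = TRUE)
  manifest <- list(
    package = "idranno",
    version = as.character(utils::packageVersion("idranno")),
    seed = spec$seed,
    stages = stages,
    transfer_config = unclass(config),
    fixture_spec = unclass(spec),
    input_checksums = as.list(tools::md5sum(inputs))
  )
  names(manifest$input_checksums) <- basename(inputs)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(c(results, list(dir = dir, in_dir = in_dir, out_dir = out_dir)))
}
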