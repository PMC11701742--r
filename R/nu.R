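#' Compaction label for one disordered region
#'
#' Classifies an IDR's conformational ensemble from its apparent Flory
#' scaling exponent nu (supplied by a sequence-based predictor): regions with
#' nu <= 0.475 are "compact", nu > 0.55 are "expanded" (well-solvated), the
#' band in between is "unlabeled". The label is only assigned to regions of
#' at least `min_length` residues; shorter regions are "unlabeled". Boundary
#' semantics are exact: nu = 0.475 is compact, nu = 0.55 is unlabeled.
#'
#' @param nu apparent Flory scaling exponent (dimensionless, in (0, 1);
#'   values outside [0.3, 0.8] trigger a plausibility warning).
#' @param length region length in residues.
#' @param min_length minimum region length for labeling (default 30).
#' @param compact_max compact iff nu <= this (default 0.475).
#' @param expanded_min expanded iff nu > this (default 0.55).
#' @return one of "compact", "expanded", "unlabeled".
#' @export
label_region <- function(nu, length, min_length = 30L,
                         compact_max = 0.475, expanded_min = 0.55) {
  if (!is.finite(nu)) stop("non-finite nu")
  if (nu <= 0 || nu >= 1) stop("nu = ", nu, " outside (0, 1)")
  if (nu < 0.3 || nu > 0.8) {
    warning("nu = ", nu, " outside the plausible range [0.3, 0.8]")
  }
  if (length < min_length) return("unlabeled")
  if (nu <= compact_max) return("compact")
  if (nu > expanded_min) return("expanded")
  "unlabeled"
}

#' Label a table of nu predictions
#'
#' Applies [label_region()] to each row and summarises, over distinct
#' proteins, the fraction with at least one expanded and at least one compact
#' region.
#'
#' @param preds data.frame with columns `accession`, `start`, `end`, `nu`.
#' @param min_length minimum region length for labeling (default 30).
#' @return an `idr_nu_labels`: `table` (input plus `length` and `label`
#'   columns) and `summary` (named numeric: `frac_expanded`, `frac_compact`,
#'   `n_proteins`).
#' @export
label_table <- function(preds, min_length = 30L) {
  if (nrow(preds) == 0L) {
    tab <- cbind(preds, length = integer(0), label = character(0))
    return(structure(list(table = tab,
                          summary = c(frac_expanded = 0, frac_compact = 0,
                                      n_proteins = 0)),
                     class = "idr_nu_labels"))
  }
  len <- preds$end - preds$start + 1L
  lab <- vapply(seq_len(nrow(preds)), function(i) {
    label_region(preds$nu[[i]], len[[i]], min_length = min_length)
  }, "")
  tab <- cbind(preds, length = len, label = lab, stringsAsFactors = FALSE)
  prot <- unique(preds$accession)
  has <- function(what) {
    mean(vapply(prot, function(a) any(lab[preds$accession == a] == what),
                logical(1)))
  }
  structure(list(table = tab,
                 summary = c(frac_expanded = has("expanded"),
                             frac_compact = has("compact"),
                             n_proteins = length(prot))),
            class = "idr_nu_labels")
}

#' @export
print.idr_nu_labels <- function(x, ...) {
  cat(sprintf("%d regions on %d proteins: %d compact, %d expanded, %d unlabeled\n",
              nrow(x$table), as.integer(x$summary[["n_proteins"]]),
              sum(x$table$label == "compact"),
              sum(x$table$label == "expanded"),
              sum(x$table$label == "unlabeled")))
  cat(sprintf("proteins with >=1 expanded region: %.1f%%; >=1 compact: %.1f%%\n",
              100 * x$summary[["frac_expanded"]],
              100 * x$summary[["frac_compact"]]))
  invisible(x)
}

#' Write labeled compaction regions
#'
#' Emits the labeled rows as TSV with MobiDB-style feature keys
#' (`prediction-compact-mobidb_lite`, `prediction-extended-mobidb_lite`);
#' unlabeled regions are omitted.
#' @param labels an `idr_nu_labels`.
#' @param path output TSV path.
#' @export
write_nu_labels <- function(labels, path) {
  tab <- labels$table
  tab <- tab[tab$label != "unlabeled", , drop = FALSE]
  tab$feature_key <- ifelse(tab$label == "compact",
                            "prediction-compact-mobidb_lite",
                            "prediction-extended-mobidb_lite")
  tab$nu <- .fmt6(tab$nu)
  .write_tsv(tab[, c("accession", "start", "end", "nu", "label", "feature_key")],
             path)
}
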