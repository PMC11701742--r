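#' Construct an ontology from term tables
#'
#' Builds an immutable DAG of function terms (GO- or IDPO-style) from a term
#' table and a parent (is_a) list, validating the invariants the annotation
#' transfer relies on: unique ids, resolvable parents, one namespace along
#' every is_a edge, and acyclicity. Ancestor closures are precomputed so
#' true-path propagation and hierarchy enforcement are cheap lookups.
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param parents named list mapping each term id to a character vector of
#'   parent term ids (is_a targets); terms absent from the list are roots.
#' @param alt_ids optional named character vector mapping alternative ids to
#'   their primary id.
#' @return An object of class `idr_ontology` with elements `id`, `name`,
#'   `namespace` (aligned vectors), `parents`, `children`, `ancestors`
#'   (named lists), `roots` (parentless term ids) and `alt_ids`.
#' @export
ontology <- function(terms, parents = list(), alt_ids = character()) {
  stopifnot(is.data.frame(terms),
            all(c("id", "name", "namespace") %in% names(terms)))
  ids <- as.character(terms$id)
  if (length(ids) == 0L) stop("ontology has no terms")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate term ids: ", paste(unique(dup), collapse = ", "))

  par <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  for (id in intersect(names(parents), ids)) {
    par[[id]] <- unique(as.character(parents[[id]]))
  }
  extra <- setdiff(names(parents), ids)
  if (length(extra)) stop("parents given for unknown terms: ",
                          paste(utils::head(extra, 10L), collapse = ", "))
  all_par <- unique(unlist(par, use.names = FALSE))
  dangling <- setdiff(all_par, ids)
  if (length(dangling)) {
    stop("is_a target(s) not defined in the ontology: ",
         paste(utils::head(dangling, 10L), collapse = ", "))
  }

  ns <- stats::setNames(as.character(terms$namespace), ids)
  for (id in ids) {
    bad <- par[[id]][ns[par[[id]]] != ns[[id]]]
    if (length(bad)) {
      stop(sprintf("namespace mismatch along is_a edge: %s (%s) is_a %s (%s)",
                   id, ns[[id]], bad[[1L]], ns[[bad[[1L]]]]))
    }
  }

  topo <- .topo_sort(ids, par)

  # ancestor closure in topological order (parents before children)
  anc <- stats::setNames(vector("list", length(ids)), ids)
  for (id in topo) {
    a <- character(0)
    for (p in par[[id]]) a <- c(a, p, anc[[p]])
    anc[[id]] <- unique(a)
  }

  children <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  for (id in ids) for (p in par[[id]]) children[[p]] <- c(children[[p]], id)

  structure(list(
    id = ids,
    name = stats::setNames(as.character(terms$name), ids),
    namespace = ns,
    parents = par,
    children = children,
    ancestors = anc,
    roots = ids[vapply(par, length, 0L) == 0L],
    alt_ids = alt_ids
  ), class = "idr_ontology")
}

# Kahn topological sort over parent edges; on failure walks the residual
# graph to report one concrete edge that lies on a cycle.
.topo_sort <- function(ids, par) {
  unmet <- vapply(par, length, 0L)
  children <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  for (id in ids) for (p in par[[id]]) children[[p]] <- c(children[[p]], id)
  queue <- ids[unmet == 0L]
  topo <- character(0)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    topo <- c(topo, v)
    for (ch in children[[v]]) {
      unmet[[ch]] <- unmet[[ch]] - 1L
      if (unmet[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) < length(ids)) {
    rem <- setdiff(ids, topo)
    # every remaining node has a remaining parent: follow until a repeat
    seen <- character(0)
    v <- rem[[1L]]
    while (!(v %in% seen)) {
      seen <- c(seen, v)
      v <- intersect(par[[v]], rem)[[1L]]
    }
    nxt <- intersect(par[[v]], rem)[[1L]]
    stop(sprintf("cycle detected in ontology: edge %s is_a %s lies on a cycle",
                 v, nxt))
  }
  topo
}

#' Read an OBO flat file
#'
#' Minimal OBO 1.2/1.4 reader covering what GO/IDPO annotation transfer needs:
#' `[Term]` stanzas with `id`, `name`, `namespace`, `is_a`, `alt_id` and
#' `is_obsolete`. Obsolete terms are dropped with a warning; `alt_id` entries
#' resolve to their primary term. Other relationship types (`part_of`, ...)
#' are ignored: the true-path rule here runs on is_a edges only.
#'
#' @param path path to an OBO file.
#' @param default_namespace namespace assigned to terms that state none and
#'   where the file header has no `default-namespace`; `NULL` means error.
#' @return An `idr_ontology`.
#' @export
load_obo <- function(path, default_namespace = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)

  header_default <- NULL
  stanza <- NULL   # NULL = header, "Term", or other
  cur <- NULL
  terms <- list()

  flush_term <- function(cur) {
    if (is.null(cur) || is.null(cur$id)) return(NULL)
    cur
  }

  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      if (!is.null(cur)) terms[[length(terms) + 1L]] <- cur
      cur <- NULL
      stanza <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (identical(stanza, "Term")) cur <- list(is_a = character(0),
                                                 alt_id = character(0))
      next
    }
    if (!nzchar(ln) || !grepl(":", ln, fixed = TRUE)) next
    key <- sub(":.*$", "", ln)
    val <- sub("^[^:]+:\\s*", "", ln)
    val <- sub("\\s*!.*$", "", val)  # strip trailing OBO comment
    if (is.null(stanza)) {
      if (key == "default-namespace") header_default <- val
      next
    }
    if (!identical(stanza, "Term")) next
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, val)
    else if (key == "alt_id") cur$alt_id <- c(cur$alt_id, val)
    else if (key == "is_obsolete" && tolower(val) == "true") cur$obsolete <- TRUE
  }
  if (!is.null(cur)) terms[[length(terms) + 1L]] <- cur
  terms <- Filter(function(t) !is.null(t$id), terms)
  if (!length(terms)) stop("no [Term] stanzas found in ", path)

  obs <- vapply(terms, function(t) isTRUE(t$obsolete), logical(1))
  if (any(obs)) {
    warning(sprintf("dropping %d obsolete term(s): %s", sum(obs),
                    paste(utils::head(vapply(terms[obs], `[[`, "", "id"), 5L),
                          collapse = ", ")))
    terms <- terms[!obs]
  }
  if (!length(terms)) stop("all terms in ", path, " are obsolete")

  fallback <- if (!is.null(header_default)) header_default else default_namespace
  get_ns <- function(t) {
    if (!is.null(t$namespace)) return(t$namespace)
    if (!is.null(fallback)) return(fallback)
    stop("term ", t$id, " has no namespace and no default-namespace is set")
  }

  df <- data.frame(
    id = vapply(terms, `[[`, "", "id"),
    name = vapply(terms, function(t) if (is.null(t$name)) t$id else t$name, ""),
    namespace = vapply(terms, get_ns, ""),
    stringsAsFactors = FALSE
  )
  par <- stats::setNames(lapply(terms, `[[`, "is_a"), df$id)
  par <- Filter(length, par)
  alt <- unlist(lapply(terms, function(t) {
    if (length(t$alt_id)) stats::setNames(rep(t$id, length(t$alt_id)), t$alt_id)
  }))
  if (is.null(alt)) alt <- character(0)
  ontology(df, par, alt_ids = alt)
}

#' Resolve term ids against an ontology
#'
#' Maps alternative ids to their primary id and errors on unknown terms.
#' @param ont an `idr_ontology`.
#' @param ids character vector of term ids.
#' @return character vector of primary term ids.
#' @export
resolve_terms <- function(ont, ids) {
  ids <- as.character(ids)
  is_alt <- ids %in% names(ont$alt_ids)
  ids[is_alt] <- ont$alt_ids[ids[is_alt]]
  unknown <- setdiff(ids, ont$id)
  if (length(unknown)) {
    stop("unknown term(s): ", paste(utils::head(unknown, 10L), collapse = ", "))
  }
  ids
}

#' Ancestors of a term
#'
#' All terms reachable from `term` via is_a edges, excluding the term itself.
#' @param ont an `idr_ontology`.
#' @param term a term id (alternative ids are resolved).
#' @return character vector of ancestor term ids.
#' @export
ancestors <- function(ont, term) {
  term <- resolve_terms(ont, term)
  if (length(term) != 1L) stop("ancestors() takes a single term")
  ont$ancestors[[term]]
}

#' True-path propagation of an annotation set
#'
#' Expands a set of term annotations with all their ancestors, as the
#' true-path rule demands (annotation with a term implies annotation with
#' every ancestor), then removes the namespace roots, which carry no
#' information for evaluation.
#'
#' @param annotations character vector of term ids.
#' @param ont an `idr_ontology`.
#' @return character vector: annotations plus ancestors, minus root terms.
#' @export
propagate_true_path <- function(annotations, ont) {
  if (length(annotations) == 0L) return(character(0))
  annotations <- resolve_terms(ont, annotations)
  out <- unique(c(annotations,
                  unlist(ont$ancestors[annotations], use.names = FALSE)))
  setdiff(out, ont$roots)
}

#' Make term scores hierarchy-consistent
#'
#' Raises each scored term's value to the maximum over itself and all its
#' scored descendants, so that along every is_a edge the parent's score is at
#' least the child's — the consistency CAFA-style evaluation assumes. The set
#' of scored terms is unchanged; only values move (upward).
#'
#' @param scores named numeric vector, term id -> score in [0, 1].
#' @param ont an `idr_ontology`.
#' @return named numeric vector with the same names.
#' @export
enforce_hierarchy <- function(scores, ont) {
  if (length(scores) == 0L) return(scores)
  ids <- resolve_terms(ont, names(scores))
  names(scores) <- ids
  out <- scores
  for (i in seq_along(scores)) {
    up <- intersect(ont$ancestors[[ids[[i]]]], ids)
    if (length(up)) out[up] <- pmax(out[up], scores[[i]])
  }
  out
}

#' @export
print.idr_ontology <- function(x, ...) {
  cat(sprintf("Ontology: %d terms, %d root(s), namespaces: %s\n",
              length(x$id), length(x$roots),
              paste(unique(x$namespace), collapse = ", ")))
  invisible(x)
}

#' Write an OBO file
#'
#' Emits `[Term]` stanzas with id, name, namespace and is_a lines; used by the
#' fixture generator and the pipeline so simulated ontologies round-trip
#' through the same reader real GO/IDPO files use.
#' @param ont an `idr_ontology`.
#' @param path output path.
#' @export
write_obo <- function(ont, path) {
  con <- file(path, open = "wb")  # LF line endings on every platform
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con, sep = "\n")
  w("format-version: 1.2")
  for (id in ont$id) {
    w("")
    w("[Term]")
    w("id: %s", id)
    w("name: %s", ont$name[[id]])
    w("namespace: %s", ont$namespace[[id]])
    for (p in ont$parents[[id]]) w("is_a: %s ! %s", p, ont$name[[p]])
  }
  invisible(path)
}
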