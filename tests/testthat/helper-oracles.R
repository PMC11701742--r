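# Independent brute-force oracles. These re-derive every quantity from first
# principles (matrix reachability, literal sorting and voting, exhaustive
# threshold loops) and share no code with the implementation they check.

# --- ontology oracle -------------------------------------------------------

# transitive closure of the parent relation by repeated squaring;
# closure[a, b] == 1 iff b is reachable from a via parent edges (a != b)
oracle_closure <- function(ids, parents) {
  n <- length(ids)
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (id in names(parents)) A[id, parents[[id]]] <- 1L
  R <- A
  repeat {
    R2 <- ((R + R %*% R) > 0) * 1L
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

oracle_ancestors <- function(closure, term) {
  colnames(closure)[closure[term, ] > 0]
}

oracle_propagate <- function(terms, closure, roots) {
  if (!length(terms)) return(character(0))
  out <- unique(c(terms, unlist(lapply(terms, oracle_ancestors, closure = closure))))
  setdiff(out, roots)
}

# out[t] = max score over t and every scored term that has t as ancestor
oracle_enforce <- function(scores, closure) {
  ids <- names(scores)
  out <- scores
  for (t in ids) {
    below <- ids[ids == t | closure[ids, t] > 0]
    out[[t]] <- max(scores[below])
  }
  out
}

# random single-namespace DAG: parents only among lower-numbered terms
rand_dag <- function(n_terms, p_edge = 0.25, namespace = "molecular_function") {
  ids <- sprintf("T%03d", seq_len(n_terms))
  parents <- list()
  for (i in 2:n_terms) {
    cand <- ids[seq_len(i - 1L)]
    par <- cand[stats::runif(length(cand)) < p_edge]
    if (!length(par)) par <- sample(cand, 1L)
    parents[[ids[[i]]]] <- par
  }
  list(ids = ids, parents = parents,
       ont = ontology(data.frame(id = ids, name = ids, namespace = namespace),
                      parents))
}

# --- weighted-KNN oracle ---------------------------------------------------

# literal reimplementation of index build + transfer steps:
# group -> propagate -> distances -> cutoff -> k nearest (stable ties) ->
# raw weights 1 - d/cutoff -> normalise -> vote -> hierarchy max -> thresholds
oracle_transfer <- function(query, annotations, vectors_by_key, ont_info,
                            cutoff, k, tau, strict = numeric(0)) {
  closure <- ont_info$closure
  roots <- ont_info$roots
  ns_of <- ont_info$namespace

  key <- paste(annotations$accession, annotations$start, annotations$end,
               sep = "|")
  sets <- lapply(split(annotations$term, key), function(ts) {
    oracle_propagate(unique(ts), closure, roots)
  })
  parts <- do.call(rbind, strsplit(names(sets), "|", fixed = TRUE))
  ord <- order(parts[, 1L], as.integer(parts[, 2L]), as.integer(parts[, 3L]))
  keys <- names(sets)[ord]
  sets <- sets[ord]

  d <- vapply(keys, function(kk) {
    v <- vectors_by_key[[kk]]
    val <- 1 - sum(query * v) / (sqrt(sum(query^2)) * sqrt(sum(v^2)))
    min(max(val, 0), 2)
  }, 0)
  surv <- which(d <= cutoff)
  if (!length(surv)) return(numeric(0))
  nn <- surv[order(d[surv])]
  nn <- nn[seq_len(min(k, length(nn)))]
  w <- 1 - d[nn] / cutoff
  if (sum(w) == 0) return(numeric(0))
  w <- w / sum(w)

  all_terms <- unique(unlist(sets[nn]))
  if (!length(all_terms)) return(numeric(0))
  s <- vapply(all_terms, function(t) {
    sum(w[vapply(nn, function(i) t %in% sets[[i]], logical(1))])
  }, 0)
  names(s) <- all_terms
  s <- pmin(s, 1)
  s <- oracle_enforce(s, closure)
  keep <- s >= tau
  for (t in intersect(names(s), names(strict))) {
    keep[[t]] <- keep[[t]] && s[[t]] >= strict[[t]]
  }
  s[keep]
}

# --- f-max oracle ----------------------------------------------------------

oracle_fmax <- function(predictions, gold, thresholds) {
  best <- 0; best_t <- NA
  curve <- data.frame()
  for (t in sort(unique(thresholds))) {
    precs <- c(); recs <- c()
    for (key in names(gold)) {
      p <- predictions[[key]]
      hit <- if (is.null(p)) character(0) else names(p)[p >= t]
      if (length(hit)) {
        tp <- length(intersect(hit, gold[[key]]))
        precs <- c(precs, tp / length(hit))
        recs <- c(recs, tp / length(gold[[key]]))
      } else {
        recs <- c(recs, 0)
      }
    }
    pp <- if (length(precs)) mean(precs) else 0
    rr <- mean(recs)
    ff <- if (pp + rr > 0) 2 * pp * rr / (pp + rr) else 0
    curve <- rbind(curve, data.frame(threshold = t, precision = pp,
                                     recall = rr, f1 = ff))
    if (ff > best) { best <- ff; best_t <- t }
  }
  list(fmax = best, curve = curve, optimal_threshold = best_t)
}

# --- consensus oracle ------------------------------------------------------

# literal per-residue rule on one column of calls
oracle_consensus_residue <- function(col, mode, maj = 0.5, strict = 0.9,
                                     denominator = "covered", n_tracks = length(col)) {
  cov <- sum(!is.na(col))
  ann <- sum(col == 1L, na.rm = TRUE)
  if (cov == 0L) return(NA_integer_)
  if (mode == "merge") return(as.integer(ann >= 1L))
  thr <- if (mode == "majority") maj else strict
  den <- if (denominator == "covered") cov else n_tracks
  as.integer(ann / den >= thr)
}

oracle_consensus <- function(m, mode, ...) {
  vapply(seq_len(ncol(m)), function(j) {
    oracle_consensus_residue(m[, j], mode, n_tracks = nrow(m), ...)
  }, integer(1))
}

# all ternary columns of a given height, as a matrix (height x 3^height)
all_ternary_columns <- function(height) {
  vals <- c(0L, 1L, NA_integer_)
  grid <- do.call(expand.grid, rep(list(vals), height))
  t(as.matrix(grid))
}

# --- small shared fixtures -------------------------------------------------

# ontology R -> {A, B, C}: three siblings under one root
toy_ontology <- function(namespace = "molecular_function") {
  ontology(data.frame(id = c("R", "A", "B", "C"),
                      name = c("root", "a", "b", "c"),
                      namespace = namespace),
           list(A = "R", B = "R", C = "R"))
}

# vector at a given cosine distance from (1, 0)
vec_at_distance <- function(d) c(1 - d, sqrt(1 - (1 - d)^2))

# names(), but character(0) instead of NULL for unnamed/empty vectors
term_names <- function(x) {
  n <- names(x)
  if (is.null(n)) character(0) else n
}
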