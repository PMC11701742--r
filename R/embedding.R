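#' Per-residue embedding matrix
#'
#' Wraps an L x D matrix of residue embeddings (row i = residue i, 1-based)
#' for one protein, e.g. the last hidden layer of a protein language model
#' (D = 1024 for ProtT5-XL-UniRef50). The toolkit consumes these matrices
#' from files; it never computes them.
#'
#' @param accession protein identifier.
#' @param matrix numeric matrix, L rows (residues) x D columns (dimensions).
#' @param sequence optional amino-acid sequence; when given, its length must
#'   equal `nrow(matrix)`.
#' @return an `idr_residue_embeddings` object.
#' @export
residue_embeddings <- function(accession, matrix, sequence = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("embeddings for ", accession, " must be a numeric matrix")
  }
  if (nrow(matrix) < 1L || ncol(matrix) < 1L) {
    stop("embedding matrix for ", accession, " is empty")
  }
  if (any(!is.finite(matrix))) {
    stop("embedding matrix for ", accession, " contains non-finite values")
  }
  if (!is.null(sequence) && nchar(sequence) != nrow(matrix)) {
    stop(sprintf("%s: sequence length %d != embedding rows %d",
                 accession, nchar(sequence), nrow(matrix)))
  }
  structure(list(accession = as.character(accession), matrix = matrix,
                 dim = ncol(matrix)),
            class = "idr_residue_embeddings")
}

#' Sequence region
#'
#' A 1-based, inclusive residue interval on a protein (UniProt convention, as
#' in DisProt and MobiDB region tables).
#' @param accession protein identifier.
#' @param start,end 1-based inclusive residue indices, `start <= end`.
#' @return an `idr_region` object.
#' @export
region <- function(accession, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    stop(sprintf("invalid region %s:%s-%s (need 1 <= start <= end)",
                 accession, start, end))
  }
  structure(list(accession = as.character(accession), start = start, end = end),
            class = "idr_region")
}

#' @export
print.idr_region <- function(x, ...) {
  cat(sprintf("%s:%d-%d (%d aa)\n", x$accession, x$start, x$end,
              x$end - x$start + 1L))
  invisible(x)
}

region_key <- function(accession, start, end) {
  paste(accession, start, end, sep = "|")
}

#' Mean-pool a region embedding
#'
#' The fixed-length representation of an IDR: the arithmetic mean of the
#' residue embeddings within the region, one value per embedding dimension.
#'
#' @param emb an `idr_residue_embeddings`.
#' @param reg an `idr_region` on the same protein.
#' @return an `idr_region_embedding`: list with `region` and `vector`.
#' @export
pool_region <- function(emb, reg) {
  stopifnot(inherits(emb, "idr_residue_embeddings"), inherits(reg, "idr_region"))
  if (!identical(emb$accession, reg$accession)) {
    stop(sprintf("region %s pooled against embeddings of %s",
                 reg$accession, emb$accession))
  }
  L <- nrow(emb$matrix)
  if (reg$end > L) {
    stop(sprintf("%s: region %d-%d out of bounds (protein has %d residues)",
                 reg$accession, reg$start, reg$end, L))
  }
  v <- colMeans(emb$matrix[reg$start:reg$end, , drop = FALSE])
  structure(list(region = reg, vector = as.numeric(v)),
            class = "idr_region_embedding")
}

#' Cosine distance
#'
#' `1 - u.v / (|u||v|)`, in [0, 2]; the metric used for neighbour search over
#' region embeddings. Zero-norm vectors are degenerate embeddings and error.
#' @param u,v numeric vectors of equal length.
#' @return a single number in [0, 2].
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) stop("dimension mismatch: ", length(u), " vs ", length(v))
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) stop("cosine distance undefined for a zero-norm vector")
  d <- 1 - sum(u * v) / (nu * nv)
  min(max(d, 0), 2)  # clamp floating-point spill just outside [0, 2]
}

#' Region-embedding collection
#'
#' A set of pooled region embeddings with aligned bookkeeping: a region table
#' and a matrix with one row per region.
#' @param regions data.frame with columns `accession`, `start`, `end`.
#' @param vectors numeric matrix, `nrow(regions)` rows.
#' @return an `idr_region_embedding_set`.
#' @export
region_embedding_set <- function(regions, vectors) {
  stopifnot(is.data.frame(regions),
            all(c("accession", "start", "end") %in% names(regions)))
  vectors <- as.matrix(vectors)
  if (nrow(regions) != nrow(vectors)) {
    stop("regions (", nrow(regions), ") and vectors (", nrow(vectors),
         ") row counts differ")
  }
  if (nrow(vectors) && any(!is.finite(vectors))) stop("non-finite embedding values")
  regions <- data.frame(accession = as.character(regions$accession),
                        start = as.integer(regions$start),
                        end = as.integer(regions$end),
                        stringsAsFactors = FALSE)
  if (nrow(regions) && any(regions$start < 1L | regions$end < regions$start)) {
    stop("invalid region coordinates in embedding set")
  }
  keys <- region_key(regions$accession, regions$start, regions$end)
  if (anyDuplicated(keys)) {
    stop("duplicate regions in embedding set: ",
         paste(utils::head(keys[duplicated(keys)], 5L), collapse = ", "))
  }
  rownames(vectors) <- keys
  structure(list(regions = regions, vectors = vectors, keys = keys),
            class = "idr_region_embedding_set")
}

#' @export
print.idr_region_embedding_set <- function(x, ...) {
  cat(sprintf("%d region embeddings, dim %d\n", nrow(x$regions),
              ncol(x$vectors)))
  invisible(x)
}

#' Pool many regions against residue-embedding matrices
#'
#' @param mats named list of `idr_residue_embeddings` keyed by accession.
#' @param regions data.frame with `accession`, `start`, `end`.
#' @return an `idr_region_embedding_set`.
#' @export
pool_regions <- function(mats, regions) {
  missing <- setdiff(unique(regions$accession), names(mats))
  if (length(missing)) {
    stop("no embedding matrix for accession(s): ",
         paste(utils::head(missing, 10L), collapse = ", "))
  }
  vecs <- t(vapply(seq_len(nrow(regions)), function(i) {
    pool_region(mats[[regions$accession[[i]]]],
                region(regions$accession[[i]], regions$start[[i]],
                       regions$end[[i]]))$vector
  }, numeric(ncol(mats[[1L]]$matrix))))
  region_embedding_set(regions, vecs)
}

#' Protein lengths from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences.
#' @return named integer vector of sequence lengths, keyed by the first token
#'   of each FASTA header.
#' @export
read_fasta_lengths <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  nm <- vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1L)
  stats::setNames(Biostrings::width(seqs), nm)
}
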