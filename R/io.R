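# Plain-text I/O: every table crossing the package boundary is TSV with a
# header, LF line endings and fixed 6-decimal formatting for scores, so runs
# diff bit-exactly across platforms.

.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

.fmt6 <- function(x) sprintf("%.6f", x)

#' Read a region annotation table
#'
#' TSV with columns `accession`, `start`, `end`, `term` and optionally
#' `namespace` and `evidence` — the DisProt-style input for reference-index
#' construction.
#' @param path TSV path.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  df <- .read_tsv(path)
  need <- c("accession", "start", "end", "term")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df
}

#' Write a region annotation table
#' @param df data.frame with `accession`, `start`, `end`, `term`, `namespace`.
#' @param path output TSV path.
#' @export
write_annotations <- function(df, path) .write_tsv(df, path)

#' Read per-residue embedding matrices from TSV
#'
#' Long format: columns `accession`, `residue_index`, then `e1`..`eD`. Rows
#' for one accession must cover residues 1..L exactly once.
#' @param path TSV path.
#' @return named list of `idr_residue_embeddings`, keyed by accession.
#' @export
read_residue_embeddings <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("accession", "residue_index") %in% names(df))) {
    stop("embedding TSV must have accession and residue_index columns")
  }
  dims <- setdiff(names(df), c("accession", "residue_index"))
  out <- lapply(split(df, df$accession), function(d) {
    d <- d[order(d$residue_index), ]
    if (!identical(as.integer(d$residue_index), seq_len(nrow(d)))) {
      stop("embedding rows for ", d$accession[[1L]],
           " do not cover residues 1..L exactly once")
    }
    residue_embeddings(d$accession[[1L]], as.matrix(d[, dims, drop = FALSE]))
  })
  out
}

#' Write per-residue embedding matrices to TSV
#' @param mats named list of `idr_residue_embeddings`.
#' @param path output TSV path.
#' @export
write_residue_embeddings <- function(mats, path) {
  rows <- lapply(mats, function(m) {
    data.frame(accession = m$accession,
               residue_index = seq_len(nrow(m$matrix)),
               apply(m$matrix, 2L, .fmt6),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  names(df) <- c("accession", "residue_index",
                 paste0("e", seq_len(ncol(mats[[1L]]$matrix))))
  .write_tsv(df, path)
}

#' Read pooled region embeddings from TSV
#'
#' Columns `accession`, `start`, `end`, then `e1`..`eD` (one row per region).
#' @param path TSV path.
#' @return an `idr_region_embedding_set`.
#' @export
read_region_embeddings <- function(path) {
  df <- .read_tsv(path)
  need <- c("accession", "start", "end")
  if (!all(need %in% names(df))) {
    stop("region embedding TSV must have accession, start, end columns")
  }
  dims <- setdiff(names(df), need)
  region_embedding_set(df[need], as.matrix(df[, dims, drop = FALSE]))
}

#' Write pooled region embeddings to TSV
#' @param set an `idr_region_embedding_set`.
#' @param path output TSV path.
#' @param digits decimal places for embedding values.
#' @export
write_region_embeddings <- function(set, path, digits = 6L) {
  vals <- apply(set$vectors, 2L, function(x) sprintf(paste0("%.", digits, "f"), x))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(set$vectors))
  df <- cbind(set$regions, as.data.frame(vals, stringsAsFactors = FALSE))
  names(df) <- c("accession", "start", "end",
                 paste0("e", seq_len(ncol(set$vectors))))
  .write_tsv(df, path)
}

#' Read a table of apparent Flory scaling exponents
#'
#' TSV with columns `accession`, `start`, `end`, `nu` — the output format of
#' sequence-based compaction predictors consumed by [label_table()].
#' @param path TSV path.
#' @return data.frame.
#' @export
read_nu_table <- function(path) {
  df <- .read_tsv(path)
  need <- c("accession", "start", "end", "nu")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("nu table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$nu <- as.numeric(df$nu)
  df
}

#' Write a nu table
#' @param df data.frame with `accession`, `start`, `end`, `nu`.
#' @param path output TSV path.
#' @export
write_nu_table <- function(df, path) {
  df$nu <- .fmt6(df$nu)
  .write_tsv(df, path)
}
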