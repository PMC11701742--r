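#' Per-residue annotation track
#'
#' One source's per-residue calls over a protein: annotated (1), not
#' annotated (0), or no coverage (NA) — e.g. a disorder predictor, or a
#' PDB-derived missing-residues track that only covers resolved chains.
#'
#' @param accession protein identifier.
#' @param feature_key source identifier, e.g. "prediction-disorder-iupl".
#' @param calls integer/numeric vector of 1, 0 and NA, one entry per residue.
#' @return an `idr_track`.
#' @export
disorder_track <- function(accession, feature_key, calls) {
  if (!nzchar(feature_key)) stop("feature_key must be nonempty")
  calls <- as.integer(calls)
  if (!length(calls)) stop("track for ", accession, " has zero length")
  if (any(!calls %in% c(0L, 1L, NA_integer_))) {
    stop("track calls must be 1, 0 or NA")
  }
  structure(list(accession = as.character(accession),
                 feature_key = as.character(feature_key),
                 calls = calls),
            class = "idr_track")
}

#' @export
print.idr_track <- function(x, ...) {
  cat(sprintf("%s [%s]: %d residues, %d annotated, %d uncovered\n",
              x$accession, x$feature_key, length(x$calls),
              sum(x$calls == 1L, na.rm = TRUE), sum(is.na(x$calls))))
  invisible(x)
}

#' Vote matrix over multiple tracks
#'
#' Stacks tracks for one protein into a matrix and tallies, per residue, how
#' many sources cover it and how many call it annotated.
#' @param tracks list of `idr_track` of equal length (same protein).
#' @return an `idr_votes`: `accession`, `matrix` (tracks x residues),
#'   `n_annotated`, `n_covered`, `n_tracks`.
#' @export
vote_matrix <- function(tracks) {
  if (!length(tracks)) stop("vote matrix needs at least one track")
  lens <- vapply(tracks, function(t) length(t$calls), 0L)
  if (length(unique(lens)) != 1L) {
    stop("track length mismatch: ", paste(unique(lens), collapse = " vs "))
  }
  m <- do.call(rbind, lapply(tracks, `[[`, "calls"))
  rownames(m) <- vapply(tracks, `[[`, "", "feature_key")
  structure(list(accession = tracks[[1L]]$accession,
                 matrix = m,
                 n_annotated = colSums(m == 1L, na.rm = TRUE),
                 n_covered = colSums(!is.na(m)),
                 n_tracks = nrow(m)),
            class = "idr_votes")
}

#' Consensus configuration
#'
#' @param mode "merge" (union: annotated iff any source annotates), "majority"
#'   or "strict" (annotated iff the fraction of agreeing votes reaches the
#'   threshold: 50% and 90% by default, as in the published consensus tracks).
#' @param majority_threshold vote fraction for majority mode (default 0.5).
#' @param strict_threshold vote fraction for strict mode (default 0.9).
#' @param min_region_length annotated runs shorter than this are erased after
#'   thresholding (default 1 = keep everything).
#' @param denominator "covered" (default): the vote fraction divides by the
#'   number of sources covering the residue, so missing coverage is not a
#'   negative vote; "all": divide by the total number of tracks.
#' @return an `idr_consensus_config`.
#' @export
consensus_config <- function(mode = c("merge", "majority", "strict"),
                             majority_threshold = 0.5,
                             strict_threshold = 0.9,
                             min_region_length = 1L,
                             denominator = c("covered", "all")) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  if (!(majority_threshold > 0 && majority_threshold <= strict_threshold &&
        strict_threshold <= 1)) {
    stop("need 0 < majority_threshold <= strict_threshold <= 1")
  }
  if (min_region_length < 1L) stop("min_region_length must be >= 1")
  structure(list(mode = mode, majority_threshold = majority_threshold,
                 strict_threshold = strict_threshold,
                 min_region_length = as.integer(min_region_length),
                 denominator = denominator),
            class = "idr_consensus_config")
}

#' Consensus of multiple annotation tracks
#'
#' Per-residue aggregation of the sources' votes. Merge annotates a residue
#' iff at least one source does; majority/strict annotate iff the fraction of
#' annotating votes reaches the configured threshold. Residues covered by no
#' source stay no-coverage. Annotated runs shorter than `min_region_length`
#' are then erased.
#'
#' @param votes an [vote_matrix()].
#' @param config an [consensus_config()].
#' @return an `idr_track` with feature key `consensus-<mode>`.
#' @export
consensus <- function(votes, config = consensus_config()) {
  stopifnot(inherits(votes, "idr_votes"),
            inherits(config, "idr_consensus_config"))
  ann <- votes$n_annotated
  cov <- votes$n_covered
  out <- rep(NA_integer_, length(ann))
  covered <- cov > 0L
  if (config$mode == "merge") {
    out[covered] <- as.integer(ann[covered] >= 1L)
  } else {
    thr <- if (config$mode == "majority") config$majority_threshold
           else config$strict_threshold
    den <- if (config$denominator == "covered") cov else
      rep(votes$n_tracks, length(cov))
    out[covered] <- as.integer(ann[covered] / den[covered] >= thr)
  }
  if (config$min_region_length > 1L) {
    r <- rle(ifelse(is.na(out), -1L, out))
    pos <- cumsum(r$lengths) - r$lengths + 1L
    for (i in seq_along(r$lengths)) {
      if (r$values[[i]] == 1L && r$lengths[[i]] < config$min_region_length) {
        idx <- pos[[i]]:(pos[[i]] + r$lengths[[i]] - 1L)
        out[idx] <- 0L
      }
    }
  }
  disorder_track(votes$accession, paste0("consensus-", config$mode), out)
}

#' Extract annotated regions from a track
#'
#' Maximal runs of annotated residues of at least `min_length`, as 1-based
#' inclusive regions sorted by start.
#' @param track an `idr_track`.
#' @param min_length minimum run length (default 1).
#' @return data.frame with `accession`, `start`, `end`.
#' @export
extract_regions <- function(track, min_length = 1L) {
  stopifnot(inherits(track, "idr_track"), min_length >= 1L)
  is_ann <- !is.na(track$calls) & track$calls == 1L
  r <- rle(is_ann)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  data.frame(accession = rep(track$accession, sum(keep)),
             start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

#' Rasterise regions into a track
#'
#' Inverse of [extract_regions()]: builds a binary track with the given
#' regions annotated and everything else 0.
#' @param accession protein identifier.
#' @param feature_key track feature key.
#' @param regions data.frame with `start`, `end`.
#' @param length protein length.
#' @return an `idr_track`.
#' @export
regions_to_track <- function(accession, feature_key, regions, length) {
  calls <- rep(0L, length)
  for (i in seq_len(nrow(regions))) {
    if (regions$end[[i]] > length) stop("region beyond protein length")
    calls[regions$start[[i]]:regions$end[[i]]] <- 1L
  }
  disorder_track(accession, feature_key, calls)
}

#' Annotated-residue content per feature
#'
#' For each feature key, the fraction of annotated residues computed over the
#' total residues of ANNOTATED proteins only — proteins without any annotated
#' residue for that feature are excluded from the denominator — plus the
#' count of annotated proteins.
#'
#' @param tracks list of `idr_track` (one per protein/feature pair).
#' @return data.frame with `feature_key`, `fraction`, `n_proteins`, sorted by
#'   feature key.
#' @export
content_fraction <- function(tracks) {
  if (!length(tracks)) stop("empty track collection")
  fk <- vapply(tracks, `[[`, "", "feature_key")
  out <- lapply(sort(unique(fk)), function(f) {
    tr <- tracks[fk == f]
    ann <- vapply(tr, function(t) sum(t$calls == 1L, na.rm = TRUE), 0L)
    len <- vapply(tr, function(t) length(t$calls), 0L)
    has <- ann > 0L
    data.frame(feature_key = f,
               fraction = if (any(has)) sum(ann[has]) / sum(len[has]) else 0,
               n_proteins = length(unique(vapply(tr[has], `[[`, "", "accession"))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# --- track I/O -------------------------------------------------------------

# run-length encoding of ternary calls: "5x1,3x0,2x-" = 1 1 1 1 1 0 0 0 NA NA
.encode_calls <- function(calls) {
  sym <- ifelse(is.na(calls), "-", as.character(calls))
  r <- rle(sym)
  paste(sprintf("%dx%s", r$lengths, r$values), collapse = ",")
}

.decode_calls <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^([0-9]+)x([01-])$", parts))
  if (any(vapply(m, length, 0L) != 3L)) stop("malformed RLE call string: ", s)
  unlist(lapply(m, function(g) {
    v <- if (g[[3L]] == "-") NA_integer_ else as.integer(g[[3L]])
    rep(v, as.integer(g[[2L]]))
  }))
}

#' Write tracks as TSV
#'
#' Columns `accession`, `feature_key`, `calls`, the latter run-length encoded
#' as e.g. `5x1,3x0,2x-` (1 annotated, 0 not, `-` no coverage).
#' @param tracks list of `idr_track`.
#' @param path output TSV path.
#' @export
write_tracks <- function(tracks, path) {
  df <- data.frame(
    accession = vapply(tracks, `[[`, "", "accession"),
    feature_key = vapply(tracks, `[[`, "", "feature_key"),
    calls = vapply(tracks, function(t) .encode_calls(t$calls), ""),
    stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Read tracks from TSV
#' @param path TSV written by [write_tracks()].
#' @return list of `idr_track`.
#' @export
read_tracks <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  lapply(seq_len(nrow(df)), function(i) {
    disorder_track(df$accession[[i]], df$feature_key[[i]],
                   .decode_calls(df$calls[[i]]))
  })
}

#' Write tracks as JSON
#'
#' Each track carries its per-residue states explicitly ("1"/"0"/"-"), so the
#' ternary encoding round-trips bit-exactly, plus the derived `regions` array
#' of `[start, end]` pairs in the style of MobiDB entry documents.
#' @param tracks list of `idr_track`.
#' @param path output JSON path.
#' @export
write_tracks_json <- function(tracks, path) {
  obj <- lapply(tracks, function(t) {
    regs <- extract_regions(t)
    list(accession = t$accession,
         feature_key = t$feature_key,
         length = length(t$calls),
         states = ifelse(is.na(t$calls), "-", as.character(t$calls)),
         regions = unname(lapply(seq_len(nrow(regs)),
                                 function(i) c(regs$start[[i]], regs$end[[i]]))))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read tracks from JSON
#' @param path JSON written by [write_tracks_json()].
#' @return list of `idr_track`.
#' @export
read_tracks_json <- function(path) {
  obj <- jsonlite::read_json(path)
  lapply(obj, function(t) {
    states <- unlist(t$states)
    calls <- rep(NA_integer_, length(states))
    calls[states != "-"] <- as.integer(states[states != "-"])
    disorder_track(t$accession, t$feature_key, calls)
  })
}
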