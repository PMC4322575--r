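#' Canonical bin widths
#'
#' The set of temporal bin widths, in days, over which counts are computed:
#' 1, 7, 30, 90, 180, 365 and infinity (the whole patient record as one bin).
#'
#' @return numeric vector of length 7.
#' @export
canonicalWidths <- function() c(1, 7, 30, 90, 180, 365, Inf)

#' Filter patients eligible for counting
#'
#' A patient is retained when their record holds at least \code{minNotes}
#' notes spanning at least \code{minSpanDays} days (span = max timestamp -
#' min timestamp, boundaries inclusive).
#'
#' @param notes data.frame with columns \code{patient_id}, \code{timestamp}.
#' @param minNotes minimum note count (default 10).
#' @param minSpanDays minimum record span in days (default 365).
#' @return character vector of eligible patient IDs (sorted).
#' @examples
#' notes <- data.frame(patient_id = "a", timestamp = c(0, 365))
#' filterPatients(notes, minNotes = 2)
#' @export
filterPatients <- function(notes, minNotes = 10L, minSpanDays = 365) {
  stopifnot(nrow(notes) > 0)
  ts <- split(notes$timestamp, notes$patient_id)
  ok <- vapply(ts, function(t)
    length(t) >= minNotes && (max(t) - min(t)) >= minSpanDays, logical(1))
  sort(names(ts)[ok])
}

#' Hash a note into its temporal bin
#'
#' The patient-specific offset-floor hash: for bin width \code{w}, random
#' offset \code{r} in [0, w] and note time \code{t} (days since the patient's
#' first note), the bin index is \code{floor((t + r) / w)}. The random offset
#' guards against global timestamp recording biases (e.g. a
#' gone-for-the-weekend effect); whatever its value, two notes more than
#' \code{w} days apart can never share a bin.
#'
#' @param w finite positive bin width in days (the infinite width is handled
#'   by \code{\link{buildBins}} as a single bin per patient).
#' @param r offset in [0, w].
#' @param t note time in days since the patient's first note; must be >= 0.
#' @return non-negative integer bin index (vectorized over \code{t}).
#' @examples
#' assignBin(7, 3, 5)   # floor(8/7) = 1
#' @export
assignBin <- function(w, r, t) {
  stopifnot(length(w) == 1L, is.finite(w), w > 0,
            length(r) == 1L, r >= 0, r <= w)
  if (any(t < 0)) stop("t must be >= 0 (days since the patient's first note)")
  as.integer(floor((t + r) / w))
}

#' Draw per-patient random bin offsets
#'
#' One offset r ~ Uniform[0, w] per patient, from an RNG stream keyed on
#' (seed, patient ID, width), so that offsets are reproducible, patients are
#' independent, and each width gets its own draw.
#'
#' @param patientIds character vector of patient IDs.
#' @param width finite positive width, or \code{Inf} (offsets all 0).
#' @param seed integer seed.
#' @return named numeric vector, patient_id -> r.
#' @export
drawOffsets <- function(patientIds, width, seed) {
  patientIds <- as.character(patientIds)
  if (is.infinite(width))
    return(stats::setNames(rep(0, length(patientIds)), patientIds))
  r <- vapply(patientIds, function(p) {
    withr::with_seed(keyedSeed(seed, paste0(p, "|w", widthToken(width))),
                     stats::runif(1))
  }, numeric(1))
  stats::setNames(r * width, patientIds)
}

#' Build temporal bins from annotated notes
#'
#' Hashes each patient's annotated notes into temporal bins with
#' \code{\link{assignBin}} (taking t0 = the patient's earliest timestamp) and
#' splices the member notes of each bin by unioning their ID sets. Only
#' non-empty bins (bins holding at least one note) are materialized. At the
#' infinite width every patient contributes exactly one bin holding the whole
#' record.
#'
#' @param annotated data.frame with columns \code{patient_id},
#'   \code{timestamp} and list column \code{ids}, as produced by
#'   \code{\link{annotateCorpus}}.
#' @param width positive number of days or \code{Inf}.
#' @param seed integer seed used to key the per-patient offsets (ignored if
#'   \code{offsets} supplied).
#' @param level ID level tag carried on the result (\code{"term"} or
#'   \code{"concept"}).
#' @param offsets optional precomputed named offset vector.
#' @param patients optional character vector restricting to eligible
#'   patients (e.g. from \code{\link{filterPatients}}); default all.
#' @return a \code{\linkS4class{BinSet}}.
#' @export
buildBins <- function(annotated, width, seed = 1L, level = "term",
                      offsets = NULL, patients = NULL) {
  stopifnot(all(c("patient_id", "timestamp", "ids") %in% names(annotated)))
  if (!is.null(patients))
    annotated <- annotated[annotated$patient_id %in% patients, , drop = FALSE]
  pids <- unique(annotated$patient_id)
  empty <- setdiff(if (is.null(patients)) character() else patients, pids)
  if (length(empty))
    warning("patients with zero notes skipped: ", paste(empty, collapse = ", "))
  if (is.null(offsets)) offsets <- drawOffsets(pids, width, seed)
  rows <- vector("list", length(pids))
  for (k in seq_along(pids)) {
    pid <- pids[k]
    sel <- which(annotated$patient_id == pid)
    t0 <- min(annotated$timestamp[sel])
    bin <- if (is.infinite(width)) rep(0L, length(sel)) else
      assignBin(width, offsets[[pid]], annotated$timestamp[sel] - t0)
    ub <- sort(unique(bin))
    sets <- lapply(ub, function(b) {
      sort(unique(unlist(annotated$ids[sel[bin == b]], use.names = FALSE)))
    })
    df <- data.frame(patient_id = pid, bin_index = ub,
                     n_notes = as.integer(tabulate(match(bin, ub), length(ub))),
                     stringsAsFactors = FALSE)
    df$term_ids <- sets
    rows[[k]] <- df
  }
  bins <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), bin_index = integer(),
               n_notes = integer(), term_ids = I(list()))
  rownames(bins) <- NULL
  new("BinSet", bins = bins, width = as.numeric(width), level = level,
      offsets = offsets, seed = as.integer(seed))
}

#' Write / read a bin file
#'
#' Bins are serialized as a header-less TSV with columns patient_id,
#' bin_index, n_notes, and a comma-joined sorted ID list (empty string for an
#' ID-free bin).
#'
#' @param binset a \code{\linkS4class{BinSet}}.
#' @param path file path.
#' @param width,level tags to attach on read (the file itself does not carry
#'   them).
#' @return \code{readBins} returns a \code{BinSet} (with empty offsets).
#' @export
writeBins <- function(binset, path) {
  b <- binset@bins
  idstr <- vapply(b$term_ids, function(x) paste(x, collapse = ","), character(1))
  lines <- sprintf("%s\t%d\t%d\t%s", b$patient_id, b$bin_index, b$n_notes, idstr)
  atomicWriteLines(lines, path)
}

#' @rdname writeBins
#' @export
readBins <- function(path, width, level = "term") {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) {
    bins <- data.frame(patient_id = character(), bin_index = integer(),
                       n_notes = integer())
    bins$term_ids <- list()
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    # an empty trailing ID field is dropped by strsplit; restore it
    parts <- lapply(parts, function(p) if (length(p) == 3L) c(p, "") else p)
    bad <- which(lengths(parts) != 4L)
    if (length(bad))
      stop(sprintf("malformed bin row at line %d: expected 4 tab-delimited fields", bad[1]))
    m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
    bins <- data.frame(patient_id = m[, 1],
                       bin_index = as.integer(m[, 2]),
                       n_notes = as.integer(m[, 3]),
                       stringsAsFactors = FALSE)
    bins$term_ids <- lapply(strsplit(m[, 4], ",", fixed = TRUE),
                            function(x) sort(unique(as.integer(x[nzchar(x)]))))
  }
  new("BinSet", bins = bins, width = as.numeric(width), level = level,
      offsets = stats::setNames(numeric(), character()), seed = NA_integer_)
}

#' Per-width bin summary
#'
#' Summary statistics in the usual per-width layout: number of bins, mean
#' notes per bin, mean term IDs per bin, and (when a concept-level
#' \code{BinSet} is also given) mean concept IDs per bin.
#'
#' @param binsets list of \code{\linkS4class{BinSet}} objects (term level),
#'   one per width.
#' @param conceptBinsets optional parallel list at concept level.
#' @return data.frame with columns width, n_bins, notes_per_bin,
#'   terms_per_bin and optionally concepts_per_bin.
#' @export
binSummary <- function(binsets, conceptBinsets = NULL) {
  row1 <- function(bs) {
    b <- bs@bins
    data.frame(width = bs@width,
               n_bins = nrow(b),
               notes_per_bin = if (nrow(b)) mean(b$n_notes) else NA_real_,
               terms_per_bin = if (nrow(b)) mean(lengths(b$term_ids)) else NA_real_)
  }
  out <- do.call(rbind, lapply(binsets, row1))
  if (!is.null(conceptBinsets)) {
    out$concepts_per_bin <- vapply(conceptBinsets, function(bs) {
      b <- bs@bins
      if (nrow(b)) mean(lengths(b$term_ids)) else NA_real_
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}
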