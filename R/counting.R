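#' @importFrom data.table data.table rbindlist setkeyv as.data.table setorderv :=
NULL

# Long form of a BinSet: one row per (bin serial, patient, id), set
# semantics (IDs already unique within a bin).
binsLong <- function(binset) {
  b <- binset@bins
  len <- lengths(b$term_ids)
  data.table(
    bin = rep.int(seq_len(nrow(b)), len),
    patient_id = rep.int(b$patient_id, len),
    id = as.integer(unlist(b$term_ids, use.names = FALSE))
  )
}

#' Count singleton frequencies over bins
#'
#' Per-bin aggregation counts, for every ID, the number of bins whose spliced
#' term set contains it (one patient can contribute many counts); per-patient
#' aggregation counts the number of patients with at least one such bin (each
#' patient contributes at most one count). The universe size N is the number
#' of bins at this width, or the number of patients, respectively — which
#' also makes per-patient singleton counts independent of the bin width.
#'
#' @param binset a \code{\linkS4class{BinSet}} built at a single width.
#' @param mode \code{"per-bin"} or \code{"per-patient"}.
#' @return a \code{\linkS4class{SingletonCounts}}.
#' @export
countSingletons <- function(binset, mode = c("per-bin", "per-patient")) {
  mode <- match.arg(mode)
  stopifnot(is(binset, "BinSet"))
  long <- binsLong(binset)
  if (mode == "per-bin") {
    N <- nrow(binset@bins)
    ct <- if (nrow(long)) long[, list(count = .N), by = "id"] else
      data.table(id = integer(), count = integer())
  } else {
    N <- length(unique(binset@bins$patient_id))
    ct <- if (nrow(long))
      unique(long[, c("patient_id", "id")])[, list(count = .N), by = "id"]
    else data.table(id = integer(), count = integer())
  }
  setorderv(ct, "id")
  new("SingletonCounts",
      counts = as.data.frame(ct), mode = mode, width = binset@width,
      level = binset@level, N = as.integer(N))
}

# Pair enumeration for one shard of bins: unordered (id_x < id_y) pairs per
# bin, with the owning patient attached.
shardPairs <- function(long) {
  if (!nrow(long)) return(data.table(patient_id = character(),
                                     id_x = integer(), id_y = integer()))
  long <- long[order(long$bin, long$id)]
  out <- long[, {
    if (.N < 2L) NULL else {
      pr <- allPairs(id)
      list(patient_id = patient_id[1L], id_x = pr[, 1L], id_y = pr[, 2L])
    }
  }, by = "bin"]
  out[, c("patient_id", "id_x", "id_y")]
}

#' Count pairwise co-frequencies over bins (production counter)
#'
#' For every unordered ID pair, per-bin aggregation counts the bins whose
#' spliced set contains both IDs; per-patient aggregation counts the patients
#' having at least one such bin. Bins are sharded across \code{nWorkers}
#' logical workers, each emitting a partial sparse map; partials are reduced
#' by summation (per-bin) or by patient-wise union before counting
#' (per-patient), so the result is identical for any worker count and any
#' bin processing order.
#'
#' @param binset a \code{\linkS4class{BinSet}}.
#' @param mode \code{"per-bin"} or \code{"per-patient"}.
#' @param nWorkers positive integer shard count (default 1).
#' @param verbose log shard progress and the running pair-evaluation count.
#' @return a \code{\linkS4class{CoFrequencyMatrix}} (self-pairs excluded;
#'   within-bin multiplicity ignored).
#' @export
countCofrequencies <- function(binset, mode = c("per-bin", "per-patient"),
                               nWorkers = 1L, verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is(binset, "BinSet"), nWorkers >= 1L)
  long <- binsLong(binset)
  N <- if (mode == "per-bin") nrow(binset@bins) else
    length(unique(binset@bins$patient_id))
  shard <- if (nrow(long)) (long$bin %% as.integer(nWorkers)) else integer()
  parts <- vector("list", nWorkers)
  pairEvals <- 0
  for (s in seq_len(nWorkers)) {
    sub <- long[shard == (s - 1L)]
    pp <- shardPairs(sub)
    pairEvals <- pairEvals + nrow(pp)
    parts[[s]] <- if (mode == "per-bin") {
      if (nrow(pp)) pp[, list(count = .N), by = c("id_x", "id_y")] else
        data.table(id_x = integer(), id_y = integer(), count = integer())
    } else {
      unique(pp[, c("patient_id", "id_x", "id_y")])
    }
    if (verbose)
      message(sprintf("shard %d/%d: %d bins, %d pair evaluations (running total %.0f)",
                      s, nWorkers, length(unique(sub$bin)), nrow(pp), pairEvals))
  }
  merged <- rbindlist(parts)
  pairs <- if (mode == "per-bin") {
    if (nrow(merged)) merged[, list(count = sum(count)), by = c("id_x", "id_y")]
    else data.table(id_x = integer(), id_y = integer(), count = integer())
  } else {
    un <- unique(merged)
    if (nrow(un)) un[, list(count = .N), by = c("id_x", "id_y")] else
      data.table(id_x = integer(), id_y = integer(), count = integer())
  }
  setorderv(pairs, c("id_x", "id_y"))
  new("CoFrequencyMatrix",
      pairs = as.data.frame(pairs), mode = mode, width = binset@width,
      level = binset@level, N = as.integer(N))
}

#' Single-threaded reference co-frequency counter
#'
#' A deliberately naive, order-obvious counter kept as an independent oracle
#' for \code{\link{countCofrequencies}}: a double loop over bins and over the
#' unordered ID pairs within each bin, accumulating counts in a hash keyed by
#' pair (per-bin) or by collecting the distinct patients per pair
#' (per-patient). No sharding, no vectorized joins.
#'
#' @inheritParams countCofrequencies
#' @return a \code{\linkS4class{CoFrequencyMatrix}}.
#' @export
referenceCount <- function(binset, mode = c("per-bin", "per-patient")) {
  mode <- match.arg(mode)
  stopifnot(is(binset, "BinSet"))
  b <- binset@bins
  acc <- new.env(parent = emptyenv())
  for (row in seq_len(nrow(b))) {
    ids <- sort(unique(b$term_ids[[row]]))
    n <- length(ids)
    if (n < 2L) next
    pid <- b$patient_id[row]
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        key <- paste0(ids[i], ":", ids[j])
        if (mode == "per-bin") {
          prev <- if (is.null(acc[[key]])) 0L else acc[[key]]
          acc[[key]] <- prev + 1L
        } else {
          acc[[key]] <- unique(c(acc[[key]], pid))
        }
      }
    }
  }
  keys <- ls(acc)
  if (length(keys)) {
    xy <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
    count <- if (mode == "per-bin")
      vapply(keys, function(k) as.integer(acc[[k]]), integer(1), USE.NAMES = FALSE) else
      vapply(keys, function(k) length(acc[[k]]), integer(1), USE.NAMES = FALSE)
    pairs <- data.frame(id_x = as.integer(xy[, 1]), id_y = as.integer(xy[, 2]),
                        count = as.integer(count))
    pairs <- pairs[order(pairs$id_x, pairs$id_y), , drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(id_x = integer(), id_y = integer(), count = integer())
  }
  N <- if (mode == "per-bin") nrow(b) else length(unique(b$patient_id))
  new("CoFrequencyMatrix", pairs = pairs, mode = mode, width = binset@width,
      level = binset@level, N = as.integer(N))
}

#' Remove low-count rows
#'
#' Drops every row whose count is less than or equal to \code{threshold}
#' (the published files removed rows with counts of 100 or fewer; a count of
#' exactly \code{threshold} is removed, \code{threshold + 1} is retained).
#' The in-memory counts used for statistics keep their exact values; this
#' filter is intended for serialization.
#'
#' @param x a \code{\linkS4class{CoFrequencyMatrix}} or
#'   \code{\linkS4class{SingletonCounts}}.
#' @param threshold non-negative integer (default 100).
#' @return a filtered copy of \code{x}.
#' @export
applyCountThreshold <- function(x, threshold = 100L) {
  stopifnot(threshold >= 0)
  if (is(x, "CoFrequencyMatrix")) {
    p <- x@pairs[x@pairs$count > threshold, , drop = FALSE]
    rownames(p) <- NULL
    initialize(x, pairs = p)
  } else if (is(x, "SingletonCounts")) {
    ct <- x@counts[x@counts$count > threshold, , drop = FALSE]
    rownames(ct) <- NULL
    initialize(x, counts = ct)
  } else stop("x must be a CoFrequencyMatrix or SingletonCounts")
}

#' Estimated pair-evaluation cost of a counting run
#'
#' The co-frequency scan is O(n * m^2) in the number of bins n and the mean
#' number of IDs per bin m; this returns n * m^2, useful for planning and
#' progress estimation. For instance 5.5 million bins at 200 terms each
#' means on the order of 220 billion pair evaluations.
#'
#' @param nBins number of bins (>= 0).
#' @param meanTermsPerBin mean IDs per bin (>= 0).
#' @return numeric estimate of pair evaluations.
#' @examples
#' pairEnumerationCost(5.5e6, 200)   # 2.2e11
#' @export
pairEnumerationCost <- function(nBins, meanTermsPerBin) {
  stopifnot(nBins >= 0, meanTermsPerBin >= 0)
  as.numeric(nBins) * as.numeric(meanTermsPerBin)^2
}
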