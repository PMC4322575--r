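# Shared fixtures: tiny corpora, lexicons and bin sets built in code.

# A SyntheticCorpus assembled by hand (bypassing the generator) from
# per-note term sets; timestamps in days, one row per note.
handCorpus <- function(patient_id, timestamp, sets, vocab = 10L) {
  ord <- order(patient_id, timestamp)
  notes <- data.frame(patient_id = patient_id[ord], timestamp = timestamp[ord],
                      text = vapply(sets[ord], function(s)
                        paste(sprintf("synterm%04d", s), collapse = " "), character(1)),
                      stringsAsFactors = FALSE)
  new("SyntheticCorpus", notes = notes,
      groundTruth = lapply(sets[ord], function(s) sort(unique(as.integer(s)))),
      config = list(vocabularySize = as.integer(vocab)))
}

# BinSet built directly from explicit bins: list of list(patient, bin, ids).
handBins <- function(entries, width = 7, level = "term") {
  bins <- data.frame(
    patient_id = vapply(entries, function(e) e$patient, character(1)),
    bin_index = vapply(entries, function(e) as.integer(e$bin), integer(1)),
    n_notes = vapply(entries, function(e) as.integer(e$n %||% 1L), integer(1)),
    stringsAsFactors = FALSE)
  bins$term_ids <- lapply(entries, function(e) sort(unique(as.integer(e$ids))))
  pids <- unique(bins$patient_id)
  new("BinSet", bins = bins, width = as.numeric(width), level = level,
      offsets = stats::setNames(rep(0, length(pids)), pids), seed = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Annotated-notes frame (patient_id, timestamp, ids) built directly.
handAnnotated <- function(patient_id, timestamp, sets) {
  out <- data.frame(patient_id = patient_id, timestamp = timestamp,
                    stringsAsFactors = FALSE)
  out$ids <- lapply(sets, function(s) sort(unique(as.integer(s))))
  out
}

# A random sparse pair table: nPairs distinct unordered pairs over nIds IDs.
allPairsFixture <- function(nIds, nPairs) {
  full <- which(upper.tri(matrix(0, nIds, nIds)), arr.ind = TRUE)
  pick <- full[sample.int(nrow(full), min(nPairs, nrow(full))), , drop = FALSE]
  out <- data.frame(id_x = as.integer(pick[, 1]), id_y = as.integer(pick[, 2]),
                    count = sample.int(500L, nrow(pick), replace = TRUE))
  out <- out[order(out$id_x, out$id_y), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Pair counts as a named lookup "x:y" -> count, for order-free comparison.
pairMap <- function(mat) {
  p <- pairCounts(mat)
  stats::setNames(p$count, paste0(p$id_x, ":", p$id_y))
}

expectSameCounts <- function(a, b) {
  ma <- pairMap(a); mb <- pairMap(b)
  expect_identical(ma[order(names(ma))], mb[order(names(mb))])
}
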