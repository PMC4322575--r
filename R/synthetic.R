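#' Simulation configuration for a synthetic note corpus
#'
#' Assembles and validates the parameters of the note-corpus simulator. The
#' simulator emulates the validation design used for co-occurrence counting
#' pipelines: a known number of patients, a range of notes per patient with
#' timestamps drawn uniformly over the study span, note texts made of
#' dictionary term tokens plus out-of-dictionary filler tokens, and optional
#' planted pairwise associations injected by co-writing both terms into the
#' same note with a configured probability.
#'
#' @param nPatients positive integer; number of simulated patients.
#' @param notesPerPatient integer vector of length 2, inclusive range of notes
#'   drawn per patient.
#' @param timeSpanDays positive number; timestamps are uniform on
#'   \code{[0, timeSpanDays]} and sorted within each patient.
#' @param vocabularySize positive integer; term IDs run 1..vocabularySize.
#' @param termsPerNote integer vector of length 2, inclusive range of
#'   background terms drawn (without replacement) per note.
#' @param plantedPairs list of planted associations, each a list or vector
#'   with elements \code{x}, \code{y} (term IDs) and \code{p} (probability,
#'   per note, that both terms are co-injected).
#' @param seed integer seed making the corpus fully reproducible.
#' @return a validated list of class \code{"SimulationConfig"}.
#' @examples
#' cfg <- simulationConfig(nPatients = 5, notesPerPatient = c(2, 4), seed = 1)
#' @export
simulationConfig <- function(nPatients = 100L,
                             notesPerPatient = c(10L, 12L),
                             timeSpanDays = 730,
                             vocabularySize = 100L,
                             termsPerNote = c(2L, 6L),
                             plantedPairs = list(),
                             seed = 1L) {
  stopifnot(length(nPatients) == 1L, nPatients >= 1,
            length(timeSpanDays) == 1L, timeSpanDays > 0,
            length(vocabularySize) == 1L, vocabularySize >= 1,
            length(notesPerPatient) == 2L, length(termsPerNote) == 2L,
            length(seed) == 1L)
  notesPerPatient <- as.integer(notesPerPatient)
  termsPerNote <- as.integer(termsPerNote)
  if (notesPerPatient[1] > notesPerPatient[2] || notesPerPatient[1] < 1L)
    stop("notesPerPatient must be an increasing range with lower bound >= 1")
  if (termsPerNote[1] > termsPerNote[2] || termsPerNote[1] < 0L)
    stop("termsPerNote must be a non-negative increasing range")
  if (termsPerNote[2] > vocabularySize)
    stop("termsPerNote upper bound exceeds the vocabulary size")
  planted <- lapply(plantedPairs, function(pp) {
    pp <- as.list(pp)
    names(pp) <- if (is.null(names(pp)) || !all(nzchar(names(pp))))
      c("x", "y", "p") else names(pp)
    x <- as.integer(pp$x); y <- as.integer(pp$y); p <- as.numeric(pp$p)
    if (x == y) stop(sprintf("planted pair (%d, %d) is a self-pair", x, y))
    if (x < 1L || x > vocabularySize || y < 1L || y > vocabularySize)
      stop(sprintf("planted pair (%d, %d): term ID outside vocabulary 1..%d",
                   x, y, vocabularySize))
    if (!is.finite(p) || p < 0 || p > 1)
      stop(sprintf("planted pair (%d, %d): joint probability %s is unsatisfiable (must lie in [0, 1])",
                   x, y, format(p)))
    list(x = min(x, y), y = max(x, y), p = p)
  })
  structure(list(nPatients = as.integer(nPatients),
                 notesPerPatient = notesPerPatient,
                 timeSpanDays = as.numeric(timeSpanDays),
                 vocabularySize = as.integer(vocabularySize),
                 termsPerNote = termsPerNote,
                 plantedPairs = planted,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# Canonical synthetic term string for a term ID. Every fifth term is a
# two-word phrase so that multi-token dictionary matching is exercised; all
# tokens are unique to their term, so annotation of synthetic text is exactly
# invertible.
syntheticTermString <- function(id) {
  ifelse(id %% 5L == 0L,
         sprintf("synphrase%04d variant%04d", id, id),
         sprintf("synterm%04d", id))
}

#' Lexicon and concept map for the synthetic vocabulary
#'
#' The companion dictionaries for simulated corpora: every synthetic term ID
#' maps to its own concept (so term- and concept-level counts coincide on
#' synthetic data by construction), each concept carries a unique CUI-style
#' identifier, and semantic groups alternate between disease and drug.
#'
#' @param vocabularySize positive integer, as in \code{\link{simulationConfig}}.
#' @return \code{syntheticLexicon}: a \code{\linkS4class{Lexicon}};
#'   \code{syntheticConceptMap}: a \code{\linkS4class{ConceptMap}}.
#' @export
syntheticLexicon <- function(vocabularySize) {
  ids <- seq_len(vocabularySize)
  new("Lexicon",
      terms = data.frame(term_id = as.integer(ids),
                         term = syntheticTermString(ids),
                         stringsAsFactors = FALSE),
      stopWords = character(), nameHomonyms = character(),
      minLength = 4L,
      dropped = data.frame(term = character(), term_id = integer(),
                           reason = character(), stringsAsFactors = FALSE))
}

#' @rdname syntheticLexicon
#' @export
syntheticConceptMap <- function(vocabularySize) {
  ids <- as.integer(seq_len(vocabularySize))
  new("ConceptMap",
      termConcept = data.frame(term_id = ids, concept_id = ids),
      concepts = data.frame(concept_id = ids,
                            string = syntheticTermString(ids),
                            cui = sprintf("C%07d", ids),
                            stringsAsFactors = FALSE),
      semanticGroup = data.frame(concept_id = ids,
                                 group = ifelse(ids %% 2L == 0L, "drug", "disease"),
                                 stringsAsFactors = FALSE),
      suppressedPairs = data.frame(term_id = integer(), concept_id = integer()),
      ingredientMap = data.frame(concept_id = integer(), ingredient_id = integer()))
}

#' Generate a synthetic longitudinal note corpus
#'
#' Simulates timestamped notes for each patient. Each note draws a random
#' number of background terms uniformly without replacement from the
#' vocabulary; each planted pair then co-injects both of its terms with its
#' configured per-note probability. Note text is the space-separated term
#' strings (in shuffled order) interleaved with filler tokens that are absent
#' from the lexicon, so dictionary annotation recovers the planted term sets
#' exactly. Timestamps are uniform over the study span and sorted per
#' patient. The generator is bit-reproducible for a fixed seed.
#'
#' @param config a \code{\link{simulationConfig}} object.
#' @return a \code{\linkS4class{SyntheticCorpus}}.
#' @examples
#' corp <- generateCorpus(simulationConfig(nPatients = 3, seed = 7))
#' corpusNotes(corp)[1:2, c("patient_id", "timestamp")]
#' @export
generateCorpus <- function(config) {
  if (!inherits(config, "SimulationConfig"))
    config <- do.call(simulationConfig, config)
  withr::with_seed(config$seed, {
    rows <- vector("list", config$nPatients)
    truth <- vector("list", config$nPatients)
    for (i in seq_len(config$nPatients)) {
      pid <- sprintf("P%05d", i)
      n <- sampleRange(config$notesPerPatient)
      ts <- sort(stats::runif(n, 0, config$timeSpanDays))
      sets <- vector("list", n)
      texts <- character(n)
      for (j in seq_len(n)) {
        k <- sampleRange(config$termsPerNote)
        ids <- if (k > 0L) sample.int(config$vocabularySize, k) else integer()
        for (pp in config$plantedPairs) {
          if (stats::runif(1) < pp$p) ids <- c(ids, pp$x, pp$y)
        }
        ids <- sort(unique(as.integer(ids)))
        nfill <- sample.int(4L, 1L) - 1L
        fillers <- if (nfill > 0L)
          sprintf("xxf%05d", sample.int(99999L, nfill)) else character()
        toks <- c(syntheticTermString(ids), fillers)
        if (length(toks) > 1L) toks <- sample(toks)
        sets[[j]] <- ids
        texts[j] <- paste(toks, collapse = " ")
      }
      rows[[i]] <- data.frame(patient_id = pid, timestamp = ts, text = texts,
                              stringsAsFactors = FALSE)
      truth[[i]] <- sets
    }
    new("SyntheticCorpus",
        notes = do.call(rbind, rows),
        groundTruth = do.call(c, truth),
        config = unclass(config))
  })
}

sampleRange <- function(r) {
  if (r[1] == r[2]) r[1] else r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L
}

#' Known-answer counts from a synthetic corpus
#'
#' Computes singleton and pairwise co-occurrence counts directly from the
#' generator's ground-truth term placements, independently of the annotation
#' and counting machinery, for use as the known-answer oracle. Bin indices
#' are re-derived inline from the offset-floor formula with the exact offsets
#' of the binning run under test, and counts are obtained from binary
#' occurrence-matrix cross-products: per bin, the pair count is the inner
#' product of the two term columns; per patient, a patient contributes one
#' count when any of its bins contains both terms.
#'
#' @param corpus a \code{\linkS4class{SyntheticCorpus}}.
#' @param width positive number of days or \code{Inf}.
#' @param mode \code{"per-bin"} or \code{"per-patient"}.
#' @param offsets named numeric vector, patient_id -> offset r in [0, width],
#'   as returned by \code{\link{buildBins}} / \code{\link{binOffsets}}; the
#'   patients named here define the eligible set that is counted.
#' @return list with elements \code{cofreq} (a
#'   \code{\linkS4class{CoFrequencyMatrix}}) and \code{singletons} (a
#'   \code{\linkS4class{SingletonCounts}}).
#' @export
groundTruthCounts <- function(corpus, width, mode = c("per-bin", "per-patient"),
                              offsets) {
  mode <- match.arg(mode)
  stopifnot(is(corpus, "SyntheticCorpus"), length(width) == 1L, width > 0)
  notes <- corpus@notes
  missing <- setdiff(names(offsets), notes$patient_id)
  if (length(missing))
    stop("patients in offsets missing from corpus: ", paste(missing, collapse = ", "))
  V <- corpus@config$vocabularySize
  patients <- names(offsets)
  perPatientMat <- function(pid) {
    sel <- which(notes$patient_id == pid)
    t0 <- min(notes$timestamp[sel])
    bin <- if (is.infinite(width)) rep(0L, length(sel)) else
      as.integer(floor((notes$timestamp[sel] - t0 + offsets[[pid]]) / width))
    ub <- sort(unique(bin))
    M <- matrix(0L, nrow = length(ub), ncol = V)
    for (j in seq_along(sel)) {
      ids <- corpus@groundTruth[[sel[j]]]
      if (length(ids)) M[match(bin[j], ub), ids] <- 1L
    }
    M
  }
  C <- matrix(0, V, V)
  single <- numeric(V)
  nbins <- 0L
  for (pid in patients) {
    M <- perPatientMat(pid)
    nbins <- nbins + nrow(M)
    if (mode == "per-bin") {
      C <- C + crossprod(M)
      single <- single + colSums(M)
    } else {
      Cp <- crossprod(M)
      C <- C + (Cp > 0)
      single <- single + as.integer(colSums(M) > 0)
    }
  }
  N <- if (mode == "per-bin") nbins else length(patients)
  ut <- which(upper.tri(C) & C > 0, arr.ind = TRUE)
  pairs <- data.frame(id_x = as.integer(ut[, 1]), id_y = as.integer(ut[, 2]),
                      count = as.integer(C[ut]))
  pairs <- pairs[order(pairs$id_x, pairs$id_y), , drop = FALSE]
  rownames(pairs) <- NULL
  keep <- which(single > 0)
  singles <- data.frame(id = as.integer(keep), count = as.integer(single[keep]))
  list(
    cofreq = new("CoFrequencyMatrix", pairs = pairs, mode = mode,
                 width = as.numeric(width), level = "term", N = as.integer(N)),
    singletons = new("SingletonCounts", counts = singles, mode = mode,
                     width = as.numeric(width), level = "term", N = as.integer(N))
  )
}

#' Write / read a corpus as a three-column TSV
#'
#' The on-disk corpus form is a header-less UTF-8 TSV with columns
#' patient_id, timestamp_days, text.
#'
#' @param corpus a \code{SyntheticCorpus} or a data.frame with columns
#'   \code{patient_id}, \code{timestamp}, \code{text}.
#' @param path file path.
#' @return \code{readCorpus} returns a data.frame with those three columns.
#' @export
writeCorpus <- function(corpus, path) {
  notes <- if (is(corpus, "SyntheticCorpus")) corpus@notes else corpus
  stopifnot(all(c("patient_id", "timestamp", "text") %in% names(notes)))
  lines <- sprintf("%s\t%s\t%s", notes$patient_id,
                   format(notes$timestamp, scientific = FALSE, trim = TRUE, digits = 15),
                   notes$text)
  atomicWriteLines(lines, path)
}

#' @rdname writeCorpus
#' @export
readCorpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines))
    return(data.frame(patient_id = character(), timestamp = numeric(),
                      text = character(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop(sprintf("malformed corpus row at line %d: expected 3 tab-delimited fields", bad[1]))
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  ts <- suppressWarnings(as.numeric(m[, 2]))
  if (anyNA(ts))
    stop(sprintf("malformed corpus row at line %d: non-numeric timestamp",
                 which(is.na(ts))[1]))
  data.frame(patient_id = m[, 1], timestamp = ts, text = m[, 3],
             stringsAsFactors = FALSE)
}
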