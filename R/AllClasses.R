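#' @import methods
NULL

#' Lexicon of recognizable terms
#'
#' Holds the retained dictionary entries (unique term string -> unique integer
#' term ID) together with the suppression resources that were applied when the
#' lexicon was built: stop words, name homonyms, and the minimum term length
#' (terms shorter than this are treated as ambiguous abbreviations and
#' dropped). A report of the dropped raw entries is kept for auditing.
#'
#' @slot terms data.frame with columns \code{term_id} (integer) and
#'   \code{term} (normalized string), one row per retained entry.
#' @slot stopWords character vector of stop-word strings (normalized).
#' @slot nameHomonyms character vector of terms homonymous with first or
#'   surnames (normalized).
#' @slot minLength single integer; entries with fewer characters are dropped.
#' @slot dropped data.frame with columns \code{term}, \code{term_id},
#'   \code{reason} recording suppressed raw entries.
#' @export
setClass("Lexicon",
  representation(
    terms = "data.frame",
    stopWords = "character",
    nameHomonyms = "character",
    minLength = "integer",
    dropped = "data.frame"
  )
)

setValidity("Lexicon", function(object) {
  tm <- object@terms
  msg <- character()
  if (!all(c("term_id", "term") %in% names(tm)))
    msg <- c(msg, "terms must have columns term_id, term")
  else {
    if (anyDuplicated(tm$term_id)) msg <- c(msg, "term_id values must be unique")
    if (anyDuplicated(tm$term)) msg <- c(msg, "term strings must be unique")
    if (nrow(tm)) {
      if (any(nchar(tm$term) < object@minLength))
        msg <- c(msg, sprintf("retained terms shorter than minLength (%d)", object@minLength))
      bad <- tm$term %in% c(object@stopWords, object@nameHomonyms)
      if (any(bad))
        msg <- c(msg, "retained terms overlap stop words or name homonyms")
    }
  }
  if (length(object@minLength) != 1L || object@minLength < 0L)
    msg <- c(msg, "minLength must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Term-to-concept mapping resources
#'
#' Captures the decode dictionaries: a many-to-many term->concept map, the
#' injective concept->CUI map, human-readable concept strings, optional
#' semantic groups, optional suppressed (term, concept) interpretations (the
#' ambiguity rule), and an optional drug->ingredient normalization map.
#'
#' @slot termConcept data.frame with columns \code{term_id}, \code{concept_id}.
#' @slot concepts data.frame with columns \code{concept_id}, \code{string},
#'   \code{cui}; \code{concept_id -> cui} must be one-to-one.
#' @slot semanticGroup data.frame with columns \code{concept_id}, \code{group}
#'   (one of drug, disease, device, procedure, other); may be empty.
#' @slot suppressedPairs data.frame with columns \code{term_id},
#'   \code{concept_id}; every row must exist in \code{termConcept}.
#' @slot ingredientMap data.frame with columns \code{concept_id},
#'   \code{ingredient_id} normalizing drug concepts to their ingredients.
#' @export
setClass("ConceptMap",
  representation(
    termConcept = "data.frame",
    concepts = "data.frame",
    semanticGroup = "data.frame",
    suppressedPairs = "data.frame",
    ingredientMap = "data.frame"
  )
)

setValidity("ConceptMap", function(object) {
  msg <- character()
  cc <- object@concepts
  if (!all(c("concept_id", "string", "cui") %in% names(cc)))
    msg <- c(msg, "concepts must have columns concept_id, string, cui")
  else {
    if (anyDuplicated(cc$concept_id)) msg <- c(msg, "concept_id values must be unique")
    if (anyDuplicated(cc$cui)) msg <- c(msg, "concept->CUI must be one-to-one (duplicate CUI)")
  }
  tc <- object@termConcept
  if (!all(c("term_id", "concept_id") %in% names(tc)))
    msg <- c(msg, "termConcept must have columns term_id, concept_id")
  else if (nrow(tc) && nrow(cc) && !all(tc$concept_id %in% cc$concept_id))
    msg <- c(msg, "termConcept references concept_ids absent from concepts")
  sp <- object@suppressedPairs
  if (nrow(sp)) {
    key <- paste(sp$term_id, sp$concept_id)
    if (!all(key %in% paste(tc$term_id, tc$concept_id)))
      msg <- c(msg, "suppressedPairs contains pairs absent from termConcept")
  }
  if (length(msg)) msg else TRUE
})

#' Temporal bins of annotated notes for one corpus at one width
#'
#' The result of hashing each eligible patient's notes into temporal bins of a
#' single width and unioning ("splicing") the term-ID sets of the member
#' notes. Only non-empty bins are materialized. The per-patient random offsets
#' used by the hashing formula are retained so that counts can be checked
#' against an independent oracle run with the same offsets.
#'
#' @slot bins data.frame with columns \code{patient_id} (character),
#'   \code{bin_index} (integer), \code{n_notes} (integer) and a list column
#'   \code{term_ids} of sorted unique integer vectors.
#' @slot width single numeric bin width in days, or \code{Inf}.
#' @slot level \code{"term"} or \code{"concept"}; what the IDs denote.
#' @slot offsets named numeric vector, patient_id -> random offset r in [0, w].
#' @slot seed integer seed the offsets were keyed from (NA if supplied).
#' @export
setClass("BinSet",
  representation(
    bins = "data.frame",
    width = "numeric",
    level = "character",
    offsets = "numeric",
    seed = "integer"
  )
)

setValidity("BinSet", function(object) {
  msg <- character()
  b <- object@bins
  need <- c("patient_id", "bin_index", "n_notes", "term_ids")
  if (!all(need %in% names(b)))
    msg <- c(msg, paste("bins must have columns", paste(need, collapse = ", ")))
  if (length(object@width) != 1L || (is.finite(object@width) && object@width <= 0))
    msg <- c(msg, "width must be a single positive number or Inf")
  if (!object@level %in% c("term", "concept"))
    msg <- c(msg, "level must be 'term' or 'concept'")
  if (is.finite(object@width) && length(object@offsets)) {
    if (any(object@offsets < 0 | object@offsets > object@width))
      msg <- c(msg, "offsets must lie in [0, width]")
  }
  if (length(msg)) msg else TRUE
})

#' Singleton frequency counts
#'
#' One count per term or concept ID under a given aggregation mode. Under
#' per-bin aggregation the count is the number of bins whose spliced term set
#' contains the ID and N is the total number of bins at this width; under
#' per-patient aggregation the count is the number of patients with at least
#' one such bin and N is the number of patients (per-patient counts are
#' therefore independent of bin width).
#'
#' @slot counts data.frame with columns \code{id} (integer), \code{count}
#'   (integer), sorted by id.
#' @slot mode \code{"per-bin"} or \code{"per-patient"}.
#' @slot width numeric width in days (Inf allowed).
#' @slot level \code{"term"} or \code{"concept"}.
#' @slot N single integer universe size.
#' @export
setClass("SingletonCounts",
  representation(
    counts = "data.frame",
    mode = "character",
    width = "numeric",
    level = "character",
    N = "integer"
  )
)

setValidity("SingletonCounts", function(object) {
  msg <- character()
  if (!object@mode %in% c("per-bin", "per-patient"))
    msg <- c(msg, "mode must be 'per-bin' or 'per-patient'")
  ct <- object@counts
  if (!all(c("id", "count") %in% names(ct)))
    msg <- c(msg, "counts must have columns id, count")
  else if (nrow(ct)) {
    if (anyDuplicated(ct$id)) msg <- c(msg, "duplicate ids in counts")
    if (any(ct$count < 0)) msg <- c(msg, "negative counts")
    if (any(ct$count > object@N)) msg <- c(msg, "count exceeds universe size N")
  }
  if (length(msg)) msg else TRUE
})

#' Sparse symmetric pairwise co-frequency matrix
#'
#' A sparse map from unordered ID pairs to co-occurrence counts, stored with
#' the canonical ordering id_x < id_y (one row per unordered pair, no
#' self-pairs). Tagged with aggregation mode, bin width, ID level and the
#' universe size N that contingency tables over these counts must use.
#'
#' @slot pairs data.frame with integer columns \code{id_x}, \code{id_y}
#'   (id_x < id_y) and \code{count}, sorted by (id_x, id_y).
#' @slot mode \code{"per-bin"} or \code{"per-patient"}.
#' @slot width numeric width in days (Inf allowed).
#' @slot level \code{"term"} or \code{"concept"}.
#' @slot N single integer universe size.
#' @export
setClass("CoFrequencyMatrix",
  representation(
    pairs = "data.frame",
    mode = "character",
    width = "numeric",
    level = "character",
    N = "integer"
  )
)

setValidity("CoFrequencyMatrix", function(object) {
  msg <- character()
  if (!object@mode %in% c("per-bin", "per-patient"))
    msg <- c(msg, "mode must be 'per-bin' or 'per-patient'")
  p <- object@pairs
  if (!all(c("id_x", "id_y", "count") %in% names(p)))
    msg <- c(msg, "pairs must have columns id_x, id_y, count")
  else if (nrow(p)) {
    if (any(p$id_x >= p$id_y)) msg <- c(msg, "pairs must satisfy id_x < id_y (no self-pairs)")
    if (anyDuplicated(paste(p$id_x, p$id_y))) msg <- c(msg, "duplicate pairs")
    if (any(p$count < 0)) msg <- c(msg, "negative counts")
    if (any(p$count > object@N)) msg <- c(msg, "count exceeds universe size N")
  }
  if (length(msg)) msg else TRUE
})

#' 2-by-2 contingency table from frequency counts
#'
#' Cells follow the co-frequency construction: A = f(X,Y), B = f(X) - f(X,Y),
#' C = f(Y) - f(X,Y), D = N - (A + B + C), where N is the number of bins at
#' the relevant width (or the number of patients for per-patient counts).
#'
#' @slot A,B,C,D single non-negative numeric cell counts.
#' @slot N single numeric universe size; A + B + C + D == N.
#' @export
setClass("ContingencyTable",
  representation(A = "numeric", B = "numeric", C = "numeric", D = "numeric",
                 N = "numeric")
)

setValidity("ContingencyTable", function(object) {
  cells <- c(object@A, object@B, object@C, object@D)
  msg <- character()
  if (length(cells) != 4L || any(!is.finite(cells)) || any(cells < 0))
    msg <- c(msg, "cells A, B, C, D must be single finite non-negative numbers")
  else if (!isTRUE(all.equal(sum(cells), object@N)))
    msg <- c(msg, "A + B + C + D must equal N")
  if (length(msg)) msg else TRUE
})

#' Synthetic longitudinal note corpus with known term placements
#'
#' A simulated corpus: timestamped note texts plus the generator's own record
#' of which term IDs it planted in each note (the ground truth against which
#' annotation and counting are validated).
#'
#' @slot notes data.frame with columns \code{patient_id} (character),
#'   \code{timestamp} (numeric days), \code{text} (character); timestamps are
#'   non-decreasing within each patient.
#' @slot groundTruth list of sorted unique integer vectors, parallel to the
#'   rows of \code{notes}: the term IDs planted in each note.
#' @slot config the \code{SimulationConfig}-style list used to generate it.
#' @export
setClass("SyntheticCorpus",
  representation(notes = "data.frame", groundTruth = "list", config = "list")
)

setValidity("SyntheticCorpus", function(object) {
  msg <- character()
  nt <- object@notes
  if (!all(c("patient_id", "timestamp", "text") %in% names(nt)))
    msg <- c(msg, "notes must have columns patient_id, timestamp, text")
  else {
    if (length(object@groundTruth) != nrow(nt))
      msg <- c(msg, "groundTruth must be parallel to notes")
    ts <- split(nt$timestamp, nt$patient_id)
    if (!all(vapply(ts, function(x) !is.unsorted(x), logical(1))))
      msg <- c(msg, "timestamps must be non-decreasing within each patient")
  }
  if (length(msg)) msg else TRUE
})
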