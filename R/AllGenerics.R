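#' Accessors for count containers and bins
#'
#' Small accessor generics shared by the count containers: aggregation mode,
#' bin width, ID level and universe size.
#'
#' @param x a \code{BinSet}, \code{SingletonCounts} or
#'   \code{CoFrequencyMatrix}.
#' @return \code{aggregationMode} and \code{idLevel} return a character
#'   scalar; \code{binWidth} a numeric scalar (possibly \code{Inf});
#'   \code{universeSize} an integer scalar.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname accessors
#' @export
setGeneric("aggregationMode", function(x) standardGeneric("aggregationMode"))

#' @rdname accessors
#' @export
setGeneric("idLevel", function(x) standardGeneric("idLevel"))

#' @rdname accessors
#' @export
setGeneric("universeSize", function(x) standardGeneric("universeSize"))

#' @rdname accessors
#' @export
setMethod("binWidth", "BinSet", function(x) x@width)
#' @rdname accessors
#' @export
setMethod("binWidth", "SingletonCounts", function(x) x@width)
#' @rdname accessors
#' @export
setMethod("binWidth", "CoFrequencyMatrix", function(x) x@width)

#' @rdname accessors
#' @export
setMethod("aggregationMode", "SingletonCounts", function(x) x@mode)
#' @rdname accessors
#' @export
setMethod("aggregationMode", "CoFrequencyMatrix", function(x) x@mode)

#' @rdname accessors
#' @export
setMethod("idLevel", "BinSet", function(x) x@level)
#' @rdname accessors
#' @export
setMethod("idLevel", "SingletonCounts", function(x) x@level)
#' @rdname accessors
#' @export
setMethod("idLevel", "CoFrequencyMatrix", function(x) x@level)

#' @rdname accessors
#' @export
setMethod("universeSize", "SingletonCounts", function(x) x@N)
#' @rdname accessors
#' @export
setMethod("universeSize", "CoFrequencyMatrix", function(x) x@N)

#' Extract count tables
#'
#' @param x a \code{SingletonCounts} or \code{CoFrequencyMatrix}.
#' @return for \code{singletonCounts}, a data.frame (id, count); for
#'   \code{pairCounts}, a data.frame (id_x, id_y, count) with id_x < id_y.
#' @name counts-accessors
NULL

#' @rdname counts-accessors
#' @export
setGeneric("singletonCounts", function(x) standardGeneric("singletonCounts"))
#' @rdname counts-accessors
#' @export
setMethod("singletonCounts", "SingletonCounts", function(x) x@counts)

#' @rdname counts-accessors
#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))
#' @rdname counts-accessors
#' @export
setMethod("pairCounts", "CoFrequencyMatrix", function(x) x@pairs)

#' @rdname accessors
#' @export
setGeneric("binTable", function(x) standardGeneric("binTable"))
#' @rdname accessors
#' @export
setMethod("binTable", "BinSet", function(x) x@bins)

#' @rdname accessors
#' @export
setGeneric("binOffsets", function(x) standardGeneric("binOffsets"))
#' @rdname accessors
#' @export
setMethod("binOffsets", "BinSet", function(x) x@offsets)

#' Notes and ground truth of a synthetic corpus
#'
#' @param x a \code{SyntheticCorpus}.
#' @return \code{corpusNotes}: data.frame (patient_id, timestamp, text);
#'   \code{corpusGroundTruth}: list of integer vectors parallel to the notes.
#' @name corpus-accessors
NULL

#' @rdname corpus-accessors
#' @export
setGeneric("corpusNotes", function(x) standardGeneric("corpusNotes"))
#' @rdname corpus-accessors
#' @export
setMethod("corpusNotes", "SyntheticCorpus", function(x) x@notes)

#' @rdname corpus-accessors
#' @export
setGeneric("corpusGroundTruth", function(x) standardGeneric("corpusGroundTruth"))
#' @rdname corpus-accessors
#' @export
setMethod("corpusGroundTruth", "SyntheticCorpus", function(x) x@groundTruth)

#' Lexicon and concept-map accessors
#'
#' @param x a \code{Lexicon} or \code{ConceptMap}.
#' @return \code{lexiconTerms}: data.frame (term_id, term);
#'   \code{droppedTerms}: data.frame (term, term_id, reason);
#'   \code{conceptTable}: data.frame (concept_id, string, cui);
#'   \code{termConceptMap}: data.frame (term_id, concept_id).
#' @name lexicon-accessors
NULL

#' @rdname lexicon-accessors
#' @export
setGeneric("lexiconTerms", function(x) standardGeneric("lexiconTerms"))
#' @rdname lexicon-accessors
#' @export
setMethod("lexiconTerms", "Lexicon", function(x) x@terms)

#' @rdname lexicon-accessors
#' @export
setGeneric("droppedTerms", function(x) standardGeneric("droppedTerms"))
#' @rdname lexicon-accessors
#' @export
setMethod("droppedTerms", "Lexicon", function(x) x@dropped)

#' @rdname lexicon-accessors
#' @export
setGeneric("conceptTable", function(x) standardGeneric("conceptTable"))
#' @rdname lexicon-accessors
#' @export
setMethod("conceptTable", "ConceptMap", function(x) x@concepts)

#' @rdname lexicon-accessors
#' @export
setGeneric("termConceptMap", function(x) standardGeneric("termConceptMap"))
#' @rdname lexicon-accessors
#' @export
setMethod("termConceptMap", "ConceptMap", function(x) x@termConcept)

#' Contingency-table cell accessor
#'
#' @param x a \code{ContingencyTable}.
#' @return named numeric vector with elements A, B, C, D, N.
#' @export
setGeneric("tableCells", function(x) standardGeneric("tableCells"))
#' @rdname tableCells
#' @export
setMethod("tableCells", "ContingencyTable", function(x)
  c(A = x@A, B = x@B, C = x@C, D = x@D, N = x@N))

setMethod("show", "Lexicon", function(object) {
  cat(sprintf("Lexicon: %d retained terms (minLength=%d, %d stop words, %d name homonyms, %d dropped)\n",
              nrow(object@terms), object@minLength, length(object@stopWords),
              length(object@nameHomonyms), nrow(object@dropped)))
})

setMethod("show", "ConceptMap", function(object) {
  cat(sprintf("ConceptMap: %d term->concept links, %d concepts, %d suppressed pairs, %d ingredient normalizations\n",
              nrow(object@termConcept), nrow(object@concepts),
              nrow(object@suppressedPairs), nrow(object@ingredientMap)))
})

setMethod("show", "BinSet", function(object) {
  w <- if (is.finite(object@width)) sprintf("%g-day", object@width) else "Inf-day"
  cat(sprintf("BinSet (%s, %s level): %d bins over %d patients\n", w,
              object@level, nrow(object@bins), length(unique(object@bins$patient_id))))
})

setMethod("show", "SingletonCounts", function(object) {
  w <- if (is.finite(object@width)) sprintf("%g", object@width) else "Inf"
  cat(sprintf("SingletonCounts (%s, width=%s, %s level): %d ids, N=%d\n",
              object@mode, w, object@level, nrow(object@counts), object@N))
})

setMethod("show", "CoFrequencyMatrix", function(object) {
  w <- if (is.finite(object@width)) sprintf("%g", object@width) else "Inf"
  cat(sprintf("CoFrequencyMatrix (%s, width=%s, %s level): %d pairs, N=%d\n",
              object@mode, w, object@level, nrow(object@pairs), object@N))
})

setMethod("show", "ContingencyTable", function(object) {
  cat(sprintf("ContingencyTable: A=%g B=%g C=%g D=%g (N=%g)\n",
              object@A, object@B, object@C, object@D, object@N))
})

setMethod("show", "SyntheticCorpus", function(object) {
  cat(sprintf("SyntheticCorpus: %d notes over %d patients\n",
              nrow(object@notes), length(unique(object@notes$patient_id))))
})
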