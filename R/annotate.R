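#' Build a clean lexicon from raw dictionary entries
#'
#' Applies the suppression rules used when compiling a clinical term
#' dictionary: entries shorter than \code{minLength} characters are dropped
#' (short strings tend to be ambiguous abbreviations), as are stop words and
#' terms homonymous with first or surnames. Term strings are normalized
#' (lowercased, punctuation stripped at token boundaries, whitespace
#' collapsed) before the rules are applied.
#'
#' @param rawEntries data.frame with columns \code{term} (string) and
#'   \code{term_id} (unique integer), or a named integer vector
#'   (names = terms).
#' @param stopWords,nameHomonyms character vectors of strings to suppress.
#' @param minLength minimum retained term length in characters (default 4).
#' @return a \code{\linkS4class{Lexicon}}; the dropped entries and the reason
#'   each was dropped are available via \code{\link{droppedTerms}}.
#' @examples
#' lex <- buildLexicon(data.frame(term = c("clip", "mi", "myocardial infarction"),
#'                                term_id = 1:3))
#' lexiconTerms(lex)       # "mi" dropped: fewer than four characters
#' @export
buildLexicon <- function(rawEntries, stopWords = character(),
                         nameHomonyms = character(), minLength = 4L) {
  if (!is.data.frame(rawEntries)) {
    rawEntries <- data.frame(term = names(rawEntries),
                             term_id = as.integer(rawEntries),
                             stringsAsFactors = FALSE)
  }
  stopifnot(all(c("term", "term_id") %in% names(rawEntries)),
            nrow(rawEntries) > 0)
  minLength <- as.integer(minLength)
  term <- normalizeTerm(rawEntries$term)
  id <- as.integer(rawEntries$term_id)
  if (anyDuplicated(id)) stop("duplicate term_id values in raw entries")
  dup <- duplicated(term) | duplicated(term, fromLast = TRUE)
  if (any(dup)) {
    # identical normalized string under different IDs is a conflict
    stop("duplicate term string with conflicting IDs: ",
         paste(unique(term[dup]), collapse = ", "))
  }
  stopWords <- unique(normalizeTerm(stopWords))
  nameHomonyms <- unique(normalizeTerm(nameHomonyms))
  reason <- rep(NA_character_, length(term))
  reason[nchar(term) < minLength] <- "short"
  reason[is.na(reason) & term %in% stopWords] <- "stop_word"
  reason[is.na(reason) & term %in% nameHomonyms] <- "name_homonym"
  keep <- is.na(reason)
  new("Lexicon",
      terms = data.frame(term_id = id[keep], term = term[keep],
                         stringsAsFactors = FALSE),
      stopWords = stopWords,
      nameHomonyms = nameHomonyms,
      minLength = minLength,
      dropped = data.frame(term = term[!keep], term_id = id[!keep],
                           reason = reason[!keep], stringsAsFactors = FALSE))
}

# Matching index: first token -> candidate terms sorted by token length
# (longest first), so matching is maximal-munch and insertion-order free.
lexiconIndex <- function(lexicon) {
  tm <- lexicon@terms
  toks <- strsplit(tm$term, " ", fixed = TRUE)
  first <- vapply(toks, `[`, character(1), 1L)
  idx <- split(seq_along(first), first)
  lapply(idx, function(rows) {
    ord <- order(-lengths(toks[rows]), tm$term_id[rows])
    rows <- rows[ord]
    list(tokens = toks[rows], id = tm$term_id[rows])
  })
}

#' Annotate a note with dictionary term mentions
#'
#' Case-insensitive, longest-match-wins, leftmost, non-overlapping matching
#' of lexicon terms over the whitespace/punctuation-tokenized note text.
#' Returned mentions carry character spans into the original text; the
#' negation/history flags are unset (see \code{\link{flagMentions}}).
#'
#' @param text a single note string (may be empty).
#' @param lexicon a \code{\linkS4class{Lexicon}}.
#' @param index optional prebuilt matching index (internal reuse across a
#'   corpus); when NULL it is built from the lexicon.
#' @return data.frame with columns \code{term_id}, \code{start}, \code{end}
#'   (character span), \code{token_start}, \code{token_end} (token indices),
#'   and logical columns \code{negated}, \code{history},
#'   \code{family_history} (all FALSE).
#' @examples
#' lex <- buildLexicon(data.frame(term = "chest pain", term_id = 7))
#' annotateNote("pt denies chest pain", lex)
#' @export
annotateNote <- function(text, lexicon, index = NULL) {
  if (is.null(index)) index <- lexiconIndex(lexicon)
  tk <- tokenizeText(text)
  n <- length(tk$token)
  out_id <- integer(); out_s <- integer(); out_e <- integer()
  out_ts <- integer(); out_te <- integer()
  i <- 1L
  while (i <= n) {
    cands <- index[[tk$token[i]]]
    matched <- FALSE
    if (!is.null(cands)) {
      for (c_i in seq_along(cands$id)) {
        ct <- cands$tokens[[c_i]]
        len <- length(ct)
        if (i + len - 1L <= n && identical(tk$token[i:(i + len - 1L)], ct)) {
          out_id <- c(out_id, cands$id[c_i])
          out_s <- c(out_s, tk$start[i]); out_e <- c(out_e, tk$end[i + len - 1L])
          out_ts <- c(out_ts, i); out_te <- c(out_te, i + len - 1L)
          i <- i + len
          matched <- TRUE
          break
        }
      }
    }
    if (!matched) i <- i + 1L
  }
  data.frame(term_id = out_id, start = out_s, end = out_e,
             token_start = out_ts, token_end = out_te,
             negated = logical(length(out_id)),
             history = logical(length(out_id)),
             family_history = logical(length(out_id)))
}

#' Default NegEx-style trigger and section-marker lists
#'
#' Loads the trigger phrase lists shipped with the package: pre-mention and
#' post-mention negation triggers (a compact NegEx-style set) and the
#' history / family-history / other section markers used for section
#' flagging. Each is a plain text file, one phrase per line, which users can
#' replace with their own lists.
#'
#' @return list with character-vector elements \code{negationPre},
#'   \code{negationPost}, \code{historyMarkers}, \code{familyHistoryMarkers},
#'   \code{otherSectionMarkers}.
#' @export
defaultTriggers <- function() {
  rd <- function(f) {
    path <- system.file("extdata", f, package = "ClinCooccur")
    x <- readLines(path, encoding = "UTF-8")
    x[nzchar(trimws(x)) & !startsWith(x, "#")]
  }
  list(negationPre = rd("negation_triggers_pre.txt"),
       negationPost = rd("negation_triggers_post.txt"),
       historyMarkers = rd("history_section_markers.txt"),
       familyHistoryMarkers = rd("family_history_markers.txt"),
       otherSectionMarkers = rd("other_section_markers.txt"))
}

# Locate occurrences of multi-token phrases in a token stream; returns
# data.frame(first, last) of token indices.
findPhrases <- function(tokens, phrases) {
  hits_first <- integer(); hits_last <- integer()
  plist <- strsplit(normalizeTerm(phrases), " ", fixed = TRUE)
  for (pt in plist) {
    len <- length(pt)
    if (len == 0L || len > length(tokens)) next
    for (i in seq_len(length(tokens) - len + 1L)) {
      if (identical(tokens[i:(i + len - 1L)], pt)) {
        hits_first <- c(hits_first, i); hits_last <- c(hits_last, i + len - 1L)
      }
    }
  }
  data.frame(first = hits_first, last = hits_last)
}

#' Flag mentions for negation and clinical-history sections
#'
#' NegEx-style flagging: a mention is negated when a pre-trigger phrase ends
#' within \code{window} tokens before the mention, or a post-trigger phrase
#' starts within \code{window} tokens after it (e.g. "myocardial infarction
#' was ruled out"). A mention is flagged history/family-history when it falls
#' after a matching section marker and before the next section marker of any
#' kind.
#'
#' @param text the note text the mentions were extracted from.
#' @param mentions data.frame as returned by \code{\link{annotateNote}}.
#' @param triggers list as returned by \code{\link{defaultTriggers}}; any
#'   element may be replaced.
#' @param window token window for negation triggers (default 6).
#' @return the mentions data.frame with \code{negated}, \code{history},
#'   \code{family_history} set.
#' @examples
#' lex <- buildLexicon(data.frame(term = "myocardial infarction", term_id = 2))
#' m <- annotateNote("myocardial infarction was ruled out", lex)
#' flagMentions("myocardial infarction was ruled out", m)$negated
#' @export
flagMentions <- function(text, mentions, triggers = defaultTriggers(),
                         window = 6L) {
  if (!nrow(mentions)) return(mentions)
  tk <- tokenizeText(text)
  pre <- findPhrases(tk$token, triggers$negationPre)
  post <- findPhrases(tk$token, triggers$negationPost)
  hist <- findPhrases(tk$token, triggers$historyMarkers)
  fam <- findPhrases(tk$token, triggers$familyHistoryMarkers)
  other <- findPhrases(tk$token, triggers$otherSectionMarkers)
  allMarkers <- rbind(hist, fam, other)
  for (r in seq_len(nrow(mentions))) {
    ts <- mentions$token_start[r]; te <- mentions$token_end[r]
    neg <- FALSE
    if (nrow(pre))
      neg <- any(pre$last < ts & pre$last >= ts - window)
    if (!neg && nrow(post))
      neg <- any(post$first > te & post$first <= te + window)
    mentions$negated[r] <- neg
    sectionOf <- function(markers) {
      if (!nrow(markers)) return(FALSE)
      opened <- markers$last[markers$last < ts]
      if (!length(opened)) return(FALSE)
      open <- max(opened)
      closers <- allMarkers$last[allMarkers$last < ts & allMarkers$last > open]
      # mention is in this section iff no other marker opened later
      openerIsLatest <- !length(closers)
      openerIsLatest
    }
    mentions$history[r] <- sectionOf(hist)
    mentions$family_history[r] <- sectionOf(fam)
  }
  mentions
}

#' Map term mentions onto clinical concepts
#'
#' Applies the concept-mapping rules: suppressed (term, concept)
#' interpretations are removed first (the ambiguity rule, e.g. suppressing
#' the peptide reading of "clip"); when \code{restrictToGroups} is given, a
#' term survives only if all of its remaining concepts fall in those semantic
#' groups and the mapping is unambiguous (exactly one concept); drug concepts
#' are then normalized to their ingredient concepts; terms with no remaining
#' concept are dropped from concept-level output.
#'
#' @param mentions data.frame with a \code{term_id} column (other columns are
#'   carried through).
#' @param conceptMap a \code{\linkS4class{ConceptMap}}.
#' @param level \code{"term"} (mentions returned unchanged) or
#'   \code{"concept"}.
#' @param restrictToGroups optional character vector of semantic groups
#'   (e.g. \code{c("drug", "disease")}).
#' @return at concept level, a data.frame like \code{mentions} but with a
#'   \code{concept_id} column (term rows may expand to several concepts, or
#'   vanish).
#' @export
mapToConcepts <- function(mentions, conceptMap, level = c("concept", "term"),
                          restrictToGroups = NULL) {
  level <- match.arg(level)
  if (level == "term") return(mentions)
  tc <- conceptMap@termConcept
  cc <- conceptMap@concepts
  if (nrow(tc) && !all(tc$concept_id %in% cc$concept_id))
    stop("concept_id without a CUI entry in the concept dictionary")
  sp <- conceptMap@suppressedPairs
  if (nrow(sp)) {
    drop <- paste(tc$term_id, tc$concept_id) %in% paste(sp$term_id, sp$concept_id)
    tc <- tc[!drop, , drop = FALSE]
  }
  if (!is.null(restrictToGroups)) {
    grp <- conceptMap@semanticGroup
    cg <- grp$group[match(tc$concept_id, grp$concept_id)]
    cg[is.na(cg)] <- "other"
    byTerm <- split(cg, tc$term_id)
    okTerms <- as.integer(names(byTerm))[
      vapply(byTerm, function(g) length(g) == 1L && all(g %in% restrictToGroups),
             logical(1))]
    tc <- tc[tc$term_id %in% okTerms, , drop = FALSE]
  }
  if (!nrow(mentions)) {
    out <- mentions
    out$concept_id <- integer()
    return(out)
  }
  hit <- merge(cbind(mentions, .row = seq_len(nrow(mentions))), tc,
               by = "term_id", sort = FALSE)
  if (!nrow(hit)) {
    out <- mentions[0, , drop = FALSE]
    out$concept_id <- integer()
    return(out)
  }
  im <- conceptMap@ingredientMap
  if (nrow(im)) {
    j <- match(hit$concept_id, im$concept_id)
    hit$concept_id <- ifelse(is.na(j), hit$concept_id, im$ingredient_id[j])
  }
  hit <- hit[order(hit$.row, hit$concept_id), , drop = FALSE]
  hit <- hit[!duplicated(hit[c(".row", "concept_id")]), , drop = FALSE]
  hit$.row <- NULL
  rownames(hit) <- NULL
  hit
}

#' Annotate a whole corpus into per-note term (or concept) ID sets
#'
#' Runs \code{\link{annotateNote}}, \code{\link{flagMentions}} and (at
#' concept level) \code{\link{mapToConcepts}} over every note, then applies
#' the counting inclusion policy: by default negated and family-history
#' mentions are excluded from counting and history mentions are included.
#'
#' @param notes data.frame with columns \code{patient_id}, \code{timestamp},
#'   \code{text} (e.g. from \code{\link{readCorpus}} or
#'   \code{\link{corpusNotes}}).
#' @param lexicon a \code{\linkS4class{Lexicon}}.
#' @param conceptMap a \code{\linkS4class{ConceptMap}} (required when
#'   \code{level = "concept"}).
#' @param level \code{"term"} or \code{"concept"}.
#' @param restrictToGroups see \code{\link{mapToConcepts}}.
#' @param includeNegated,includeHistory,includeFamilyHistory logicals
#'   controlling which flagged mentions are counted (defaults FALSE, TRUE,
#'   FALSE).
#' @param triggers trigger lists for \code{\link{flagMentions}}; set to NULL
#'   to skip flagging entirely (all mentions counted).
#' @return data.frame with columns \code{patient_id}, \code{timestamp} and a
#'   list column \code{ids} of sorted unique integer vectors, ready for
#'   \code{\link{buildBins}}.
#' @export
annotateCorpus <- function(notes, lexicon, conceptMap = NULL,
                           level = c("term", "concept"),
                           restrictToGroups = NULL,
                           includeNegated = FALSE, includeHistory = TRUE,
                           includeFamilyHistory = FALSE,
                           triggers = defaultTriggers()) {
  level <- match.arg(level)
  if (level == "concept" && is.null(conceptMap))
    stop("conceptMap is required for concept-level annotation")
  index <- lexiconIndex(lexicon)
  ids <- vector("list", nrow(notes))
  for (i in seq_len(nrow(notes))) {
    m <- annotateNote(notes$text[i], lexicon, index = index)
    if (nrow(m) && !is.null(triggers))
      m <- flagMentions(notes$text[i], m, triggers = triggers)
    keep <- (includeNegated | !m$negated) &
            (includeHistory | !m$history) &
            (includeFamilyHistory | !m$family_history)
    m <- m[keep, , drop = FALSE]
    if (level == "concept") {
      m <- mapToConcepts(m, conceptMap, level = "concept",
                         restrictToGroups = restrictToGroups)
      ids[[i]] <- sort(unique(as.integer(m$concept_id)))
    } else {
      ids[[i]] <- sort(unique(as.integer(m$term_id)))
    }
  }
  out <- data.frame(patient_id = notes$patient_id, timestamp = notes$timestamp,
                    stringsAsFactors = FALSE)
  out$ids <- ids
  out
}
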