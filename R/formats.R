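utils::globalVariables(c(".N", "id", "patient_id", "count", "id_x", "id_y"))

# Strict reader for header-less integer TSVs with a fixed column count.
readIntTsv <- function(path, ncol, what) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) return(matrix(numeric(), ncol = ncol))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != ncol)
  if (length(bad))
    stop(sprintf("%s: malformed row at line %d: expected %d tab-delimited fields, got %d",
                 what, bad[1], ncol, lengths(parts)[bad[1]]))
  m <- matrix(unlist(parts), ncol = ncol, byrow = TRUE)
  num <- suppressWarnings(apply(m, 2L, as.numeric))
  if (is.null(dim(num))) num <- matrix(num, ncol = ncol)
  if (anyNA(num)) {
    bad <- which(apply(is.na(num), 1L, any))[1]
    stop(sprintf("%s: malformed row at line %d: non-integer field", what, bad))
  }
  if (any(num != floor(num))) {
    bad <- which(apply(num != floor(num), 1L, any))[1]
    stop(sprintf("%s: malformed row at line %d: non-integer field", what, bad))
  }
  num
}

#' Write / read a co-frequency count file
#'
#' A co-frequency file holds one row per unordered ID pair: three
#' tab-delimited integer columns id_x, id_y, count with id_x < id_y, rows
#' sorted by (id_x, id_y), header-less, UTF-8, LF-terminated. Writing then
#' reading reproduces the matrix exactly, and the writer output is
#' byte-canonical.
#'
#' @param matrix a \code{\linkS4class{CoFrequencyMatrix}} with positive
#'   counts.
#' @param path file path.
#' @param threshold optional count threshold applied at serialization time
#'   (rows with count <= threshold are omitted; see
#'   \code{\link{applyCountThreshold}}). NULL writes all rows.
#' @param mode,width,level,N tags to attach to the matrix on read (a count
#'   file does not carry them).
#' @return \code{readCofrequencyFile} returns a
#'   \code{\linkS4class{CoFrequencyMatrix}}.
#' @export
writeCofrequencyFile <- function(matrix, path, threshold = NULL) {
  stopifnot(is(matrix, "CoFrequencyMatrix"))
  if (!is.null(threshold)) matrix <- applyCountThreshold(matrix, threshold)
  p <- matrix@pairs
  if (nrow(p) && any(p$count <= 0)) stop("co-frequency counts must be positive")
  p <- p[order(p$id_x, p$id_y), , drop = FALSE]
  atomicWriteLines(sprintf("%d\t%d\t%d", p$id_x, p$id_y, p$count), path)
}

#' @rdname writeCofrequencyFile
#' @export
readCofrequencyFile <- function(path, mode = "per-bin", width = Inf,
                                level = "term", N = NA_integer_) {
  m <- readIntTsv(path, 3L, basename(path))
  pairs <- data.frame(id_x = as.integer(m[, 1]), id_y = as.integer(m[, 2]),
                      count = as.integer(m[, 3]))
  if (nrow(pairs)) {
    if (any(pairs$id_x >= pairs$id_y))
      stop(basename(path), ": row with id_x >= id_y")
    dup <- which(duplicated(paste(pairs$id_x, pairs$id_y)))
    if (length(dup))
      stop(sprintf("%s: duplicate pair at line %d", basename(path), dup[1]))
  }
  Nuse <- if (is.na(N)) as.integer(max(0L, pairs$count)) else as.integer(N)
  new("CoFrequencyMatrix", pairs = pairs, mode = mode,
      width = as.numeric(width), level = level,
      N = if (is.na(N)) as.integer(max(1L, Nuse)) else as.integer(N))
}

#' Write / read a singleton count file
#'
#' Two tab-delimited integer columns id, count; one row per ID, sorted by id,
#' header-less. Round-trip exact and byte-canonical, as for
#' \code{\link{writeCofrequencyFile}}.
#'
#' @param singletons a \code{\linkS4class{SingletonCounts}}.
#' @param path file path.
#' @param threshold optional serialization-time count threshold.
#' @param mode,width,level,N tags to attach on read.
#' @return \code{readSingletonFile} returns a
#'   \code{\linkS4class{SingletonCounts}}.
#' @export
writeSingletonFile <- function(singletons, path, threshold = NULL) {
  stopifnot(is(singletons, "SingletonCounts"))
  if (!is.null(threshold)) singletons <- applyCountThreshold(singletons, threshold)
  ct <- singletons@counts
  if (nrow(ct) && any(ct$count <= 0)) stop("singleton counts must be positive")
  ct <- ct[order(ct$id), , drop = FALSE]
  atomicWriteLines(sprintf("%d\t%d", ct$id, ct$count), path)
}

#' @rdname writeSingletonFile
#' @export
readSingletonFile <- function(path, mode = "per-bin", width = Inf,
                              level = "term", N = NA_integer_) {
  m <- readIntTsv(path, 2L, basename(path))
  ct <- data.frame(id = as.integer(m[, 1]), count = as.integer(m[, 2]))
  dup <- which(duplicated(ct$id))
  if (length(dup)) stop(sprintf("%s: duplicate id at line %d", basename(path), dup[1]))
  new("SingletonCounts", counts = ct, mode = mode, width = as.numeric(width),
      level = level,
      N = if (is.na(N)) as.integer(max(1L, ct$count, 0L)) else as.integer(N))
}

#' Write / read the ID-mapping dictionary files
#'
#' The five decode dictionaries: File 1 (term_id TAB string), File 2a
#' (concept_id TAB string TAB CUI), File 2b (concept_id TAB CUI), File 3
#' (term_id TAB concept_id, many-to-many; terms without a listed concept
#' mapping are suppressed from concept counts), File 4 (one stop word per
#' line; also carries the name-homonym strings). \code{readDictionaries}
#' enforces cross-file consistency: File 3 term IDs must exist in File 1,
#' its concept IDs in File 2a, and Files 2a/2b must agree on the injective
#' concept-to-CUI map.
#'
#' @param lexicon a \code{\linkS4class{Lexicon}}.
#' @param conceptMap a \code{\linkS4class{ConceptMap}}.
#' @param dir output directory (created if missing).
#' @param paths named list with elements \code{file1}, \code{file2a},
#'   \code{file2b}, \code{file3}, \code{file4} (any of the last four may be
#'   omitted; file1 is required).
#' @param minLength minimum term length recorded on the loaded lexicon.
#' @return \code{writeDictionaries} returns the named vector of paths
#'   written; \code{readDictionaries} returns
#'   \code{list(lexicon =, conceptMap =)}.
#' @export
writeDictionaries <- function(lexicon, conceptMap, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tm <- lexicon@terms[order(lexicon@terms$term_id), , drop = FALSE]
  cc <- conceptMap@concepts[order(conceptMap@concepts$concept_id), , drop = FALSE]
  tc <- conceptMap@termConcept[order(conceptMap@termConcept$term_id,
                                     conceptMap@termConcept$concept_id), , drop = FALSE]
  paths <- c(file1 = file.path(dir, "term_dictionary.tsv"),
             file2a = file.path(dir, "concept_dictionary.tsv"),
             file2b = file.path(dir, "concept_cui.tsv"),
             file3 = file.path(dir, "term_concept_map.tsv"),
             file4 = file.path(dir, "stop_words.txt"))
  atomicWriteLines(sprintf("%d\t%s", tm$term_id, tm$term), paths[["file1"]])
  atomicWriteLines(sprintf("%d\t%s\t%s", cc$concept_id, cc$string, cc$cui),
                   paths[["file2a"]])
  atomicWriteLines(sprintf("%d\t%s", cc$concept_id, cc$cui), paths[["file2b"]])
  atomicWriteLines(sprintf("%d\t%d", tc$term_id, tc$concept_id), paths[["file3"]])
  atomicWriteLines(sort(unique(c(lexicon@stopWords, lexicon@nameHomonyms))),
                   paths[["file4"]])
  paths
}

#' @rdname writeDictionaries
#' @export
readDictionaries <- function(paths, minLength = 4L) {
  paths <- as.list(paths)
  stopifnot(!is.null(paths$file1))
  readCols <- function(path, ncol, what) {
    lines <- readLines(path, encoding = "UTF-8")
    if (!length(lines)) return(matrix(character(), ncol = ncol))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != ncol)
    if (length(bad))
      stop(sprintf("%s: malformed row at line %d: expected %d fields", what, bad[1], ncol))
    matrix(unlist(parts), ncol = ncol, byrow = TRUE)
  }
  f1 <- readCols(paths$file1, 2L, "File 1")
  terms <- data.frame(term_id = as.integer(f1[, 1]), term = f1[, 2],
                      stringsAsFactors = FALSE)
  stopWords <- if (!is.null(paths$file4)) {
    sw <- readLines(paths$file4, encoding = "UTF-8")
    sw[nzchar(trimws(sw))]
  } else character()
  lexicon <- new("Lexicon", terms = terms, stopWords = stopWords,
                 nameHomonyms = character(), minLength = as.integer(minLength),
                 dropped = data.frame(term = character(), term_id = integer(),
                                      reason = character(), stringsAsFactors = FALSE))
  concepts <- data.frame(concept_id = integer(), string = character(),
                         cui = character(), stringsAsFactors = FALSE)
  if (!is.null(paths$file2a)) {
    f2a <- readCols(paths$file2a, 3L, "File 2a")
    concepts <- data.frame(concept_id = as.integer(f2a[, 1]), string = f2a[, 2],
                           cui = f2a[, 3], stringsAsFactors = FALSE)
    if (anyDuplicated(concepts$cui))
      stop("File 2a: concept->CUI must be one-to-one; duplicate CUI: ",
           concepts$cui[duplicated(concepts$cui)][1])
  }
  if (!is.null(paths$file2b)) {
    f2b <- readCols(paths$file2b, 2L, "File 2b")
    cui2b <- data.frame(concept_id = as.integer(f2b[, 1]), cui = f2b[, 2],
                        stringsAsFactors = FALSE)
    if (anyDuplicated(cui2b$concept_id) || anyDuplicated(cui2b$cui))
      stop("File 2b: concept->CUI must be one-to-one")
    if (nrow(concepts)) {
      j <- match(cui2b$concept_id, concepts$concept_id)
      mismatch <- which(!is.na(j) & concepts$cui[j] != cui2b$cui)
      if (length(mismatch))
        stop("Files 2a and 2b disagree on CUI for concept_id ",
             cui2b$concept_id[mismatch[1]])
    } else {
      concepts <- data.frame(concept_id = cui2b$concept_id,
                             string = NA_character_, cui = cui2b$cui,
                             stringsAsFactors = FALSE)
    }
  }
  termConcept <- data.frame(term_id = integer(), concept_id = integer())
  if (!is.null(paths$file3)) {
    f3 <- readIntTsv(paths$file3, 2L, "File 3")
    termConcept <- data.frame(term_id = as.integer(f3[, 1]),
                              concept_id = as.integer(f3[, 2]))
    dangling <- setdiff(termConcept$term_id, terms$term_id)
    if (length(dangling))
      stop("File 3 references term_ids absent from File 1: ",
           paste(utils::head(dangling, 10), collapse = ", "))
    if (nrow(concepts)) {
      danglingC <- setdiff(termConcept$concept_id, concepts$concept_id)
      if (length(danglingC))
        stop("File 3 references concept_ids absent from File 2a: ",
             paste(utils::head(danglingC, 10), collapse = ", "))
    }
  }
  conceptMap <- new("ConceptMap", termConcept = termConcept, concepts = concepts,
                    semanticGroup = data.frame(concept_id = integer(),
                                               group = character(),
                                               stringsAsFactors = FALSE),
                    suppressedPairs = data.frame(term_id = integer(),
                                                 concept_id = integer()),
                    ingredientMap = data.frame(concept_id = integer(),
                                               ingredient_id = integer()))
  list(lexicon = lexicon, conceptMap = conceptMap)
}

#' Decode a count file through an ID dictionary
#'
#' Replaces the integer IDs of a co-frequency or singleton file by the
#' strings (or CUIs) of a lookup dictionary, preserving row order. An ID
#' missing from the dictionary is an error, never silently skipped.
#'
#' @param countFile path to a 2- or 3-column count file.
#' @param dictionary named character vector, ID -> string (names are the
#'   integer IDs as character), or a 2-column data.frame (id, string).
#' @return data.frame with the decoded columns (\code{x}, \code{y},
#'   \code{count} or \code{x}, \code{count}).
#' @examples
#' tmp <- tempfile()
#' writeLines("1\t2\t150", tmp)
#' decodeCounts(tmp, c("1" = "shunt", "2" = "hydrocephalus"))
#' @export
decodeCounts <- function(countFile, dictionary) {
  if (is.data.frame(dictionary))
    dictionary <- stats::setNames(as.character(dictionary[[2]]),
                                  as.character(dictionary[[1]]))
  lines <- readLines(countFile, encoding = "UTF-8")
  if (!length(lines))
    return(data.frame(x = character(), count = integer(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  arity <- unique(lengths(parts))
  if (length(arity) != 1L || !arity %in% c(2L, 3L))
    stop("count file must have uniformly 2 or 3 tab-delimited columns")
  m <- matrix(unlist(parts), ncol = arity, byrow = TRUE)
  lookup <- function(ids) {
    out <- dictionary[ids]
    if (anyNA(out))
      stop("unknown ID in count file: ", ids[is.na(out)][1])
    unname(out)
  }
  if (arity == 3L) {
    data.frame(x = lookup(m[, 1]), y = lookup(m[, 2]),
               count = as.integer(m[, 3]), stringsAsFactors = FALSE)
  } else {
    data.frame(x = lookup(m[, 1]), count = as.integer(m[, 2]),
               stringsAsFactors = FALSE)
  }
}

#' Canonical count-file name for a (level, mode, width) cell
#'
#' @param type \code{"cofreq"} or \code{"singleton"}.
#' @param level \code{"term"} or \code{"concept"}.
#' @param mode \code{"per-bin"} or \code{"per-patient"}.
#' @param width numeric width (ignored for per-patient singletons, which are
#'   width-independent).
#' @return file name string.
#' @export
countFileName <- function(type = c("cofreq", "singleton"), level, mode, width) {
  type <- match.arg(type)
  if (type == "singleton" && mode == "per-patient")
    sprintf("singleton_%s_per-patient.tsv", level)
  else
    sprintf("%s_%s_%s_w%s.tsv", type, level, mode, widthToken(width))
}

#' Expected manifest of a full export
#'
#' A complete term+concept export over the seven canonical widths comprises
#' 28 co-frequency files (7 widths x 2 modes x 2 levels) and 16 singleton
#' files (per-bin: 7 widths x 2 levels; per-patient: one per level).
#'
#' @param widths numeric widths (default \code{\link{canonicalWidths}}).
#' @param modes,levels subsets of the modes/levels to export.
#' @return data.frame with columns type, level, mode, width, filename.
#' @export
exportManifest <- function(widths = canonicalWidths(),
                           modes = c("per-bin", "per-patient"),
                           levels = c("term", "concept")) {
  rows <- list()
  for (lv in levels) {
    for (md in modes) {
      for (w in widths) {
        rows[[length(rows) + 1L]] <- data.frame(
          type = "cofreq", level = lv, mode = md, width = w,
          filename = countFileName("cofreq", lv, md, w),
          stringsAsFactors = FALSE)
      }
      if (md == "per-bin") {
        for (w in widths) {
          rows[[length(rows) + 1L]] <- data.frame(
            type = "singleton", level = lv, mode = md, width = w,
            filename = countFileName("singleton", lv, md, w),
            stringsAsFactors = FALSE)
        }
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          type = "singleton", level = lv, mode = md, width = Inf,
          filename = countFileName("singleton", lv, md, Inf),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
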