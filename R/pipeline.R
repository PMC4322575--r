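#' Run the full counting pipeline and export the data-record files
#'
#' Orchestrates annotate -> filter -> bin -> count -> export over a corpus of
#' timestamped notes. For each requested width, each aggregation mode and
#' each ID level, singleton and co-frequency counts are computed and written
#' as canonical tab-delimited count files (the serialization-time count
#' threshold removes rows with counts at or below it). A full run over both
#' levels, both modes and the seven canonical widths yields 28 co-frequency
#' and 16 singleton files. All randomness (the per-patient bin offsets) is
#' keyed from \code{seed}, so a re-run with the same inputs and seed
#' produces byte-identical files.
#'
#' @param notes data.frame with columns \code{patient_id}, \code{timestamp},
#'   \code{text}, or a \code{\linkS4class{SyntheticCorpus}}.
#' @param lexicon a \code{\linkS4class{Lexicon}}.
#' @param conceptMap a \code{\linkS4class{ConceptMap}} (required when
#'   \code{"concept"} is among \code{levels}).
#' @param outDir output directory (created).
#' @param widths numeric bin widths (default \code{\link{canonicalWidths}}).
#' @param modes aggregation modes to export.
#' @param levels ID levels to export.
#' @param threshold serialization count threshold (rows with count <=
#'   threshold are omitted from files; default 100). Use 0 to keep all
#'   positive counts.
#' @param seed integer seed for the bin offsets.
#' @param minNotes,minSpanDays patient eligibility (see
#'   \code{\link{filterPatients}}).
#' @param includeNegated,includeHistory,includeFamilyHistory counting policy
#'   for flagged mentions (see \code{\link{annotateCorpus}}).
#' @param restrictToGroups semantic-group restriction for concept-level
#'   counting (default drugs and diseases, with unambiguous mapping
#'   required).
#' @param triggers trigger lists for flagging, or NULL to skip flagging.
#' @param nWorkers shard count for the co-frequency counter.
#' @param verbose log per-stage progress and timings.
#' @return invisibly, a list with \code{manifest} (data.frame of written
#'   files with row counts), \code{summary} (per-width bin summary in the
#'   standard layout), \code{patients} (eligible IDs), and \code{seed}.
#' @export
runPipeline <- function(notes, lexicon, conceptMap = NULL, outDir,
                        widths = canonicalWidths(),
                        modes = c("per-bin", "per-patient"),
                        levels = c("term", "concept"),
                        threshold = 100L, seed = 1L,
                        minNotes = 10L, minSpanDays = 365,
                        includeNegated = FALSE, includeHistory = TRUE,
                        includeFamilyHistory = FALSE,
                        restrictToGroups = c("drug", "disease"),
                        triggers = NULL, nWorkers = 1L, verbose = FALSE) {
  if (is(notes, "SyntheticCorpus")) notes <- corpusNotes(notes)
  stopifnot(all(c("patient_id", "timestamp", "text") %in% names(notes)))
  modes <- match.arg(modes, several.ok = TRUE)
  levels <- match.arg(levels, c("term", "concept"), several.ok = TRUE)
  if ("concept" %in% levels && is.null(conceptMap))
    stop("conceptMap is required to export concept-level counts")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  t0 <- Sys.time()
  eligible <- filterPatients(notes, minNotes = minNotes, minSpanDays = minSpanDays)
  if (!length(eligible)) stop("no patient passes the eligibility filter")
  notes <- notes[notes$patient_id %in% eligible, , drop = FALSE]
  say("eligibility: %d patients, %d notes (%.1fs)", length(eligible),
      nrow(notes), as.numeric(Sys.time() - t0, units = "secs"))

  annotated <- list()
  for (lv in levels) {
    tA <- Sys.time()
    annotated[[lv]] <- annotateCorpus(
      notes, lexicon, conceptMap = conceptMap, level = lv,
      restrictToGroups = if (lv == "concept") restrictToGroups else NULL,
      includeNegated = includeNegated, includeHistory = includeHistory,
      includeFamilyHistory = includeFamilyHistory, triggers = triggers)
    say("annotate (%s level): %d notes (%.1fs)", lv, nrow(notes),
        as.numeric(Sys.time() - tA, units = "secs"))
  }

  manifest <- list()
  summaries <- list(term = list(), concept = list())
  for (w in widths) {
    for (lv in levels) {
      tB <- Sys.time()
      bs <- buildBins(annotated[[lv]], width = w, seed = seed, level = lv)
      summaries[[lv]][[widthToken(w)]] <- bs
      for (md in modes) {
        sing <- countSingletons(bs, mode = md)
        cof <- countCofrequencies(bs, mode = md, nWorkers = nWorkers,
                                  verbose = verbose)
        fns <- countFileName("singleton", lv, md, w)
        # per-patient singleton counts are width-independent: one file
        writeSing <- md == "per-bin" || identical(w, widths[[1]])
        if (writeSing) {
          writeSingletonFile(sing, file.path(outDir, fns), threshold = threshold)
          manifest[[fns]] <- data.frame(type = "singleton", level = lv,
                                        mode = md, width = w, filename = fns,
                                        rows = sum(sing@counts$count > threshold),
                                        stringsAsFactors = FALSE)
        }
        fnc <- countFileName("cofreq", lv, md, w)
        writeCofrequencyFile(cof, file.path(outDir, fnc), threshold = threshold)
        manifest[[fnc]] <- data.frame(type = "cofreq", level = lv, mode = md,
                                      width = w, filename = fnc,
                                      rows = sum(cof@pairs$count > threshold),
                                      stringsAsFactors = FALSE)
      }
      say("width %s (%s level): %d bins counted (%.1fs)", widthToken(w), lv,
          nrow(bs@bins), as.numeric(Sys.time() - tB, units = "secs"))
    }
  }
  manifest <- do.call(rbind, unname(manifest))
  manifest <- manifest[order(manifest$type, manifest$level, manifest$mode,
                             manifest$width), , drop = FALSE]
  rownames(manifest) <- NULL
  summaryTab <- binSummary(summaries$term,
                           if ("concept" %in% levels) summaries$concept else NULL)
  res <- list(manifest = manifest, summary = summaryTab,
              patients = eligible, seed = as.integer(seed))
  manifestLines <- sprintf("%s\t%s\t%s\t%s\t%d", manifest$type, manifest$level,
                           manifest$mode, widthToken2(manifest$width),
                           manifest$rows)
  atomicWriteLines(c(paste("# seed", seed),
                     paste("# patients", length(eligible)),
                     manifestLines),
                   file.path(outDir, "MANIFEST.tsv"))
  invisible(res)
}

widthToken2 <- function(w) vapply(w, widthToken, character(1))

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form \code{key = value}; blank lines and \code{#} comments
#' ignored. Recognized keys: corpus, file1..file4 (dictionary paths), out,
#' widths (comma list, "inf" allowed), modes, levels, threshold, seed,
#' workers, min_notes, min_span_days, include_negated, include_history,
#' include_family_history.
#'
#' @param path config file path.
#' @return named list of parsed values.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop("unparseable config line: ", lines[bad[1]])
  out <- stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, character(1), 2L))
  parseBool <- function(x) tolower(trimws(x)) %in% c("1", "true", "yes")
  if (!is.null(out$widths))
    out$widths <- parseWidth(strsplit(out$widths, ",")[[1]])
  for (k in c("modes", "levels"))
    if (!is.null(out[[k]])) out[[k]] <- trimws(strsplit(out[[k]], ",")[[1]])
  for (k in c("threshold", "seed", "workers", "min_notes"))
    if (!is.null(out[[k]])) out[[k]] <- as.integer(out[[k]])
  if (!is.null(out$min_span_days)) out$min_span_days <- as.numeric(out$min_span_days)
  for (k in c("include_negated", "include_history", "include_family_history"))
    if (!is.null(out[[k]])) out[[k]] <- parseBool(out[[k]])
  out
}
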