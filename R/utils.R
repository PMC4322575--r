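# Internal helpers: keyed RNG, tokenization, width tokens.

# Deterministic 31-bit hash of a string (polynomial rolling hash); used to
# derive an independent RNG stream per (patient, width) key.
stringHash31 <- function(s) {
  vapply(s, function(one) {
    v <- utf8ToInt(one)
    h <- 0
    for (x in v) h <- (h * 131 + x) %% 2147483563
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Combine a base seed with a string key into a valid 32-bit seed.
keyedSeed <- function(seed, key) {
  as.integer((as.numeric(seed) %% 2147483563 + stringHash31(key)) %% 2147483563)
}

# Normalize text for dictionary matching: lowercase; punctuation is handled
# by the tokenizer, which keeps only alphanumeric runs.
normalizeTerm <- function(x) {
  x <- tolower(x)
  toks <- regmatches(x, gregexpr("[a-z0-9']+", x))
  vapply(toks, paste, character(1), collapse = " ")
}

# Tokenize raw note text, preserving character spans of each token.
# Returns list(token = lowercase character, start = int, end = int).
tokenizeText <- function(text) {
  if (is.na(text) || !nzchar(text))
    return(list(token = character(), start = integer(), end = integer()))
  m <- gregexpr("[A-Za-z0-9']+", text)[[1]]
  if (m[1] == -1L)
    return(list(token = character(), start = integer(), end = integer()))
  start <- as.integer(m)
  len <- attr(m, "match.length")
  end <- start + len - 1L
  list(token = tolower(substring(text, start, end)), start = start, end = end)
}

# Canonical filename token for a bin width ("inf" for the infinite width).
widthToken <- function(w) {
  if (is.infinite(w)) "inf" else format(w, scientific = FALSE, trim = TRUE)
}

# Parse a width given on a command line or in a config file.
parseWidth <- function(x) {
  x <- trimws(tolower(as.character(x)))
  out <- ifelse(x %in% c("inf", "infinity", "∞"), Inf, suppressWarnings(as.numeric(x)))
  if (any(is.na(out))) stop("unparseable bin width: ", paste(x[is.na(out)], collapse = ", "))
  out
}

# Enumerate all unordered pairs (i < j) of a sorted integer vector.
# Returns a two-column integer matrix (possibly 0-row).
allPairs <- function(ids) {
  n <- length(ids)
  if (n < 2L) return(matrix(integer(), ncol = 2L))
  i <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
  j <- sequence(rev(seq_len(n - 1L)), from = seq_len(n - 1L) + 1L)
  cbind(ids[i], ids[j])
}

# Atomic text write: write to a temp file in the same directory, then rename.
atomicWriteLines <- function(lines, path) {
  dir <- dirname(path)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  con <- file(tmp, open = "wb")
  ok <- FALSE
  tryCatch({
    if (length(lines)) writeLines(lines, con, sep = "\n", useBytes = TRUE)
    close(con)
    ok <- TRUE
  }, finally = {
    if (!ok) { try(close(con), silent = TRUE); unlink(tmp) }
  })
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("failed to move temporary file into place for ", path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
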